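# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's own computational paths:
# matrix exponentials via expm, exhaustive enumeration over internal
# states, numerical integration for OU means and covariances, and dense
# determinant/solve multivariate-normal evaluation.

toy_tree <- function() {
  read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5):0;")
}

# random ultrametric tree with unit-free depth, tips relabelled
random_ultrametric_tree <- function(n, depth = 1) {
  tr <- ape::rcoal(n)
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# painting built from randomly assigned node states
random_painting <- function(tree, states, seed) {
  withr::with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    n_all <- n_tip + tree$Nnode
    st <- sample(states, n_all, replace = TRUE)
    prob <- matrix(0, n_all, length(states),
                   dimnames = list(NULL, states))
    prob[cbind(seq_len(n_all), match(st, states))] <- 1
    tips <- setNames(st[seq_len(n_tip)], tree$tip.label)
    paint_branches(tree, prob, tips, states)
  })
}

# --- Mk oracles --------------------------------------------------------------

mk_enum <- function(tree, tip_states, rate, states) {
  k <- length(states)
  n_tip <- ape::Ntip(tree)
  Q <- matrix(rate, k, k); diag(Q) <- -(k - 1) * rate
  Ps <- lapply(tree$edge.length, function(t) expm::expm(Q * t))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  tipidx <- match(tip_states[tree$tip.label], states)
  n_all <- n_tip + tree$Nnode
  total <- 0
  node_post <- matrix(0, n_all, k)
  for (g in seq_len(nrow(grid))) {
    st <- c(tipidx, grid[g, ])
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Ps[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
    }
    total <- total + pr
    node_post[cbind(seq_len(n_all), st)] <-
      node_post[cbind(seq_len(n_all), st)] + pr
  }
  list(loglik = log(total), post = node_post / total)
}

# --- dense multivariate-normal oracle for the six trait models ---------------

dense_mvn_loglik <- function(y, m, V) {
  n <- length(y)
  as.numeric(-n / 2 * log(2 * pi) -
               0.5 * determinant(V, logarithm = TRUE)$modulus -
               0.5 * t(y - m) %*% solve(V) %*% (y - m))
}

# edge index from parent a to child b
edge_between <- function(tree, a, b) {
  which(tree$edge[, 1L] == a & tree$edge[, 2L] == b)
}

# per-lineage regime segments (t0, t1, regime) from root to each tip
lineage_segments <- function(tree, painting) {
  depth <- ape::node.depth.edgelength(tree)
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    np <- ape::nodepath(tree, root, tip)
    do.call(rbind, lapply(seq_len(length(np) - 1L), function(i) {
      e <- edge_between(tree, np[i], np[i + 1L])
      data.frame(t0 = depth[np[i]], t1 = depth[np[i + 1L]],
                 regime = painting$edge_regime[e])
    }))
  })
}

dense_model_loglik <- function(tree, y, model, params, painting = NULL) {
  sp <- names(y)
  S <- ape::vcv(tree)[sp, sp]
  Td <- diag(S)
  n <- length(y)
  if (model == "WN") {
    return(dense_mvn_loglik(y, rep(params$mu, n), params$s2 * diag(n)))
  }
  if (model == "BM.s") {
    return(dense_mvn_loglik(y, rep(params$z0, n), params$sigma2 * S))
  }
  if (model == "Lambda") {
    C <- params$lambda * S
    diag(C) <- Td
    return(dense_mvn_loglik(y, rep(params$z0, n), params$sigma2 * C))
  }
  if (model == "BM.rate") {
    segs <- lineage_segments(tree, painting)
    tipno <- match(sp, tree$tip.label)
    M <- ape::mrca(tree)[sp, sp]
    depth <- ape::node.depth.edgelength(tree)
    V <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      smax <- depth[M[i, j]]
      si <- segs[[tipno[i]]]
      for (r in seq_len(nrow(si))) {
        ov <- min(si$t1[r], smax) - si$t0[r]
        if (ov > 0) V[i, j] <- V[i, j] + params$sigma2[[si$regime[r]]] * ov
      }
    }
    return(dense_mvn_loglik(y, rep(params$z0, n), V))
  }
  # OU models: covariance and Hansen weights by numerical integration
  a <- params$alpha
  M <- ape::mrca(tree)[sp, sp]
  depth <- ape::node.depth.edgelength(tree)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sij <- depth[M[i, j]]
    f <- function(t) exp(-a * (Td[i] - t)) * exp(-a * (Td[j] - t))
    V[i, j] <- params$sigma2 *
      stats::integrate(f, 0, sij, rel.tol = 1e-12)$value
  }
  if (model == "OU.s") {
    return(dense_mvn_loglik(y, rep(params$theta, n), V))
  }
  segs <- lineage_segments(tree, painting)
  tipno <- match(sp, tree$tip.label)
  regs <- names(params$theta)
  W <- matrix(0, n, length(regs), dimnames = list(sp, regs))
  for (i in seq_len(n)) {
    si <- segs[[tipno[i]]]
    for (r in seq_len(nrow(si))) {
      f <- function(t) a * exp(-a * (Td[i] - t))
      W[i, si$regime[r]] <- W[i, si$regime[r]] +
        stats::integrate(f, si$t0[r], si$t1[r], rel.tol = 1e-12)$value
    }
    W[i, painting$root_regime] <- W[i, painting$root_regime] +
      exp(-a * Td[i])
  }
  dense_mvn_loglik(y, as.numeric(W %*% params$theta[regs]), V)
}
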