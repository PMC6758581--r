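# Equal-rates Mk machinery: pruning likelihood, ML rate, marginal ancestral
# states, and regime painting for the OU stage.

# ER transition probability matrix; q is the per-pair (off-diagonal) rate.
mk_transition <- function(k, q, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

mk_states_of <- function(tip_states, states = NULL) {
  if (!is.null(states)) return(states)
  if (all(tip_states %in% syndrome_levels())) return(syndrome_levels())
  sort(unique(tip_states))
}

# Downward (pruning) pass. Returns per-node partial likelihood vectors
# (rescaled) plus accumulated log-scalers and per-edge messages, reused by
# the marginal reconstruction.
mk_down_pass <- function(tree, tip_states, rate, states) {
  k <- length(states)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  if (!all(tree$tip.label %in% names(tip_states))) {
    abort("every tip needs a state")
  }
  st_idx <- match(tip_states[tree$tip.label], states)
  if (anyNA(st_idx)) abort("tip state not in the state set")
  D <- matrix(1, n_all, k)
  D[seq_len(n_tip), ] <- 0
  D[cbind(seq_len(n_tip), st_idx)] <- 1
  msg <- matrix(NA_real_, nrow(tree$edge), k)  # message edge -> parent
  logscale <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(
    paste(po$edge[, 1L], po$edge[, 2L]),
    paste(tree$edge[, 1L], tree$edge[, 2L])
  )
  for (j in seq_len(nrow(po$edge))) {
    p <- po$edge[j, 1L]
    ch <- po$edge[j, 2L]
    P <- mk_transition(k, rate, po$edge.length[j])
    v <- as.numeric(P %*% D[ch, ])
    s <- sum(v)
    if (s <= 0 || !is.finite(s)) abort("numerical underflow in Mk pruning")
    logscale <- logscale + log(s)
    v <- v / s
    msg[ord[j], ] <- v
    D[p, ] <- D[p, ] * v
    # renormalize accumulating internal nodes to keep numbers in range
    m <- max(D[p, ])
    if (m < 1e-10) {
      D[p, ] <- D[p, ] / m
      logscale <- logscale + log(m)
    }
  }
  root <- n_tip + 1L
  list(D = D, msg = msg, logscale = logscale, root = root, k = k,
       states = states)
}

#' Log-likelihood of tip states under the equal-rates Mk model
#'
#' Felsenstein pruning on a rooted tree with a k-state continuous-time
#' Markov model with equal transition rates and a uniform root prior.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tip_states Named character vector, one state per tip.
#' @param rate Nonnegative per-pair transition rate (per Ma).
#' @param states Optional state set fixing the order; defaults to
#'   [syndrome_levels()] when all states are syndromes, else the sorted
#'   unique tip states.
#' @return Log-likelihood (a single number, at most 0 for any rate).
#' @export
mk_loglik <- function(tree, tip_states, rate, states = NULL) {
  if (rate < 0) abort("rate must be nonnegative")
  states <- mk_states_of(tip_states, states)
  dp <- mk_down_pass(tree, tip_states, rate, states)
  log(sum(dp$D[dp$root, ] / dp$k)) + dp$logscale
}

#' Fit the equal-rates Mk model by maximum likelihood
#'
#' One-dimensional bounded search for the transition rate on the log scale.
#' Monomorphic tip data leave the rate unidentifiable: the fit returns rate
#' 0 with `monomorphic = TRUE` and a warning rather than failing.
#'
#' @inheritParams mk_loglik
#' @return Object of class `mk_fit`: list with `rate`, `loglik`, `n_states`,
#'   `states`, `monomorphic`.
#' @export
fit_mk_er <- function(tree, tip_states, states = NULL) {
  states <- mk_states_of(tip_states, states)
  k <- length(states)
  obs <- unique(tip_states[tree$tip.label])
  if (length(obs) < 2L) {
    warn("monomorphic tip states: Mk rate not identifiable, returning 0")
    fit <- list(rate = 0, loglik = log(1 / k), n_states = k, states = states,
                monomorphic = TRUE)
    class(fit) <- "mk_fit"
    return(fit)
  }
  T_ <- crown_age(tree)
  f <- function(lr) mk_loglik(tree, tip_states, exp(lr), states)
  opt <- optimize(f, interval = c(log(1e-7 / T_), log(1e3 / T_)),
                  maximum = TRUE, tol = 1e-9)
  fit <- list(rate = exp(opt$maximum), loglik = opt$objective, n_states = k,
              states = states, monomorphic = FALSE)
  class(fit) <- "mk_fit"
  fit
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Equal-rates Mk fit:", x$n_states, "states\n")
  cat("  rate =", format(x$rate, digits = 4),
      " loglik =", format(x$loglik, digits = 6), "\n")
  if (x$monomorphic) cat("  (monomorphic data: rate fixed at 0)\n")
  invisible(x)
}

#' Marginal ancestral-state probabilities under the ER Mk model
#'
#' Standard up-down algorithm: the pruning pass supplies subtree partials,
#' a preorder pass supplies the likelihood of the rest of the tree, and the
#' marginal posterior at each node is their normalized product under the
#' uniform root prior. Tip rows are point masses on the observed states.
#'
#' @inheritParams mk_loglik
#' @return Matrix (`Ntip + Nnode` rows, one column per state) of marginal
#'   probabilities; each row sums to 1.
#' @export
marginal_asr <- function(tree, tip_states, rate, states = NULL) {
  states <- mk_states_of(tip_states, states)
  k <- length(states)
  dp <- mk_down_pass(tree, tip_states, rate, states)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  O <- matrix(NA_real_, n_all, k)     # outside likelihoods, rescaled
  O[dp$root, ] <- 1
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ord <- ape::reorder.phylo(tree, "cladewise")
  eord <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (j in seq_len(nrow(ord$edge))) {
    e <- eord[j]
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    sibs <- setdiff(children[[as.character(p)]], e)
    u <- O[p, ]
    for (se in sibs) u <- u * dp$msg[se, ]
    P <- mk_transition(k, rate, tree$edge.length[e])
    v <- as.numeric(crossprod(P, u))   # symmetric P, but be explicit
    O[ch, ] <- v / max(v)
  }
  post <- dp$D * O
  post / rowSums(post)
}

#' Paint regimes onto branches from ancestral-state probabilities
#'
#' Each internal node is assigned its most probable state (ties broken
#' deterministically by the lowest index in the state order); each branch
#' inherits the state of its tipward endpoint, terminal branches using the
#' observed tip state; the root regime is the root node's assignment.
#'
#' @inheritParams mk_loglik
#' @param node_prob Matrix from [marginal_asr()].
#' @return Object of class `regime_painting`: `edge_regime` (character, one
#'   per row of `tree$edge`), `root_regime`, `node_states`, `node_prob`,
#'   `states`.
#' @export
paint_branches <- function(tree, node_prob, tip_states, states = NULL) {
  states <- mk_states_of(tip_states, states)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  stopifnot(nrow(node_prob) == n_all, ncol(node_prob) == length(states))
  amax <- apply(node_prob, 1L, function(p) which(p >= max(p) - 1e-12)[1L])
  node_states <- states[amax]
  node_states[seq_len(n_tip)] <- tip_states[tree$tip.label]
  ties <- apply(node_prob, 1L, function(p) sum(p >= max(p) - 1e-12) > 1L)
  if (any(ties[-seq_len(n_tip)])) {
    inform(paste0(sum(ties[-seq_len(n_tip)]),
                  " ancestral nodes tied; lowest-index state used"))
  }
  edge_regime <- node_states[tree$edge[, 2L]]
  painting <- list(edge_regime = edge_regime,
                   root_regime = node_states[n_tip + 1L],
                   node_states = node_states,
                   node_prob = node_prob,
                   states = states,
                   edge = tree$edge)
  class(painting) <- "regime_painting"
  painting
}

#' Reconstruct syndromes and paint regimes in one step
#'
#' Convenience wrapper: fit the ER Mk rate, compute marginal ancestral
#' states, and paint branches.
#'
#' @inheritParams mk_loglik
#' @return A `regime_painting` with the `mk_fit` attached as attribute
#'   `"mk_fit"`.
#' @export
reconstruct_regimes <- function(tree, tip_states, states = NULL) {
  states <- mk_states_of(tip_states, states)
  fit <- fit_mk_er(tree, tip_states, states)
  pr <- marginal_asr(tree, tip_states, fit$rate, states)
  painting <- paint_branches(tree, pr, tip_states, states)
  attr(painting, "mk_fit") <- fit
  painting
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", length(x$edge_regime), "branches,",
      length(x$states), "states\n")
  cat("  root regime:", x$root_regime, "\n")
  print(table(x$edge_regime))
  invisible(x)
}

#' @rdname paint_branches
#' @param x A `regime_painting`.
#' @param ... Unused.
#' @method as_tibble regime_painting
#' @export
as_tibble.regime_painting <- function(x, ...) {
  tibble(edge = seq_along(x$edge_regime),
         parent = x$edge[, 1L], child = x$edge[, 2L],
         regime = x$edge_regime)
}
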