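# Six-model menu for continuous trait evolution on a chronogram:
#   WN       white noise (star phylogeny), iid Normal(mu, s2)
#   BM.s     Brownian motion, one rate
#   BM.rate  Brownian motion, one rate per selective regime
#   Lambda   BM with Pagel's lambda scaling the off-diagonal covariance
#   OU.s     Ornstein-Uhlenbeck, single optimum
#   OU.poll  Ornstein-Uhlenbeck, one optimum per pollination-syndrome regime
# All likelihoods are exact multivariate-normal densities built from the
# tree geometry; OU means use the Hansen weight matrix over regime history.

EVO_MODELS <- c("WN", "OU.s", "OU.poll", "BM.s", "BM.rate", "Lambda")

#' The six-model comparison menu
#'
#' @return Tibble with columns `name` and `regimes_required`.
#' @export
evo_models <- function() {
  tibble(name = EVO_MODELS,
         regimes_required = EVO_MODELS %in% c("OU.poll", "BM.rate"))
}

# ---- geometry ---------------------------------------------------------------

# Shared-depth matrix, tip depths, tip-tip distances, restricted and ordered
# to the species of y.
model_geometry <- function(tree, species) {
  geo <- tip_covariance_geometry(tree)
  missing <- setdiff(species, geo$tips)
  if (length(missing)) {
    abort(paste0("species absent from tree: ", paste(missing, collapse = ", ")))
  }
  S <- geo$shared[species, species, drop = FALSE]
  depth <- diag(S)
  D <- outer(depth, depth, "+") - 2 * S
  list(shared = S, depth = depth, dist = D, species = species)
}

# Regimes actually present in a painting (edges plus root), in state order.
painting_regimes <- function(painting) {
  r <- unique(c(painting$root_regime, painting$edge_regime))
  painting$states[painting$states %in% r]
}

# Hansen weight matrix: entry (i, r) is the weight the optimum of regime r
# receives in tip i's expected value; the root's weight exp(-alpha*T_i) goes
# to the root regime. Rows sum to 1 exactly.
hansen_weights <- function(tree, painting, alpha, species) {
  regs <- painting_regimes(painting)
  depth <- node_depths(tree)
  paths <- root_paths(tree)
  tip_idx <- match(species, tree$tip.label)
  W <- matrix(0, length(species), length(regs),
              dimnames = list(species, regs))
  for (i in seq_along(species)) {
    v <- tip_idx[i]
    Ti <- depth[v]
    for (e in paths[[v]]) {
      t0 <- depth[tree$edge[e, 1L]]
      t1 <- depth[tree$edge[e, 2L]]
      r <- painting$edge_regime[e]
      W[i, r] <- W[i, r] + exp(-alpha * (Ti - t1)) - exp(-alpha * (Ti - t0))
    }
    W[i, painting$root_regime] <- W[i, painting$root_regime] + exp(-alpha * Ti)
  }
  W
}

# OU covariance on an ultrametric tree, at unit sigma2:
# V0_ij = exp(-alpha d_ij) (1 - exp(-2 alpha s_ij)) / (2 alpha)
ou_unit_covariance <- function(geom, alpha) {
  V0 <- exp(-alpha * geom$dist) * (1 - exp(-2 * alpha * geom$shared)) / (2 * alpha)
  V0
}

# Per-regime shared-path matrices for BM.rate: C_r[i, j] is the time the
# shared root-to-MRCA path of i and j spends in regime r.
regime_shared_matrices <- function(tree, painting, species) {
  regs <- painting_regimes(painting)
  depth <- node_depths(tree)
  n_all <- ape::Ntip(tree) + tree$Nnode
  rt <- matrix(0, n_all, length(regs), dimnames = list(NULL, regs))
  ord <- ape::reorder.phylo(tree, "cladewise")
  eord <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (j in seq_len(nrow(ord$edge))) {
    e <- eord[j]
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    rt[ch, ] <- rt[p, ]
    r <- painting$edge_regime[e]
    rt[ch, r] <- rt[ch, r] + tree$edge.length[e]
  }
  tip_idx <- match(species, tree$tip.label)
  M <- ape::mrca(tree)[species, species, drop = FALSE]
  lapply(setNames(regs, regs), function(r) {
    C <- matrix(rt[M, r], nrow(M), ncol(M), dimnames = dimnames(M))
    diag(C) <- rt[tip_idx, r]
    C
  })
}

# ---- multivariate-normal pieces --------------------------------------------

mvn_loglik <- function(y, mean, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, y - mean, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z * z)
}

# Profile the linear mean (design X) and the overall scale out of
# V = sigma2 * V0. Returns ML beta, sigma2, profile loglik.
gls_profile <- function(y, X, V0) {
  n <- length(y)
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  fit <- stats::lm.fit(Xt, yt)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  rss <- sum((yt - Xt %*% beta)^2)
  # an exact linear fit leaves rss = 0; floor the ML variance so callers
  # see a finite (huge) likelihood and near-zero standard errors instead
  # of a failure
  sigma2 <- max(rss / n, 1e-300)
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - sum(log(diag(R))) - n / 2
  list(beta = beta, sigma2 = sigma2, loglik = ll, chol = R, Xt = Xt, yt = yt,
       rank = fit$rank)
}

check_ou_tree <- function(tree, ultra_tol) {
  ok <- is_ultrametric_rel(tree, ultra_tol)
  if (!ok) {
    abort(paste0("OU models require an ultrametric tree (max relative ",
                 "deviation ", format(attr(ok, "max_rel_dev"), digits = 3), ")"))
  }
}

# ---- likelihood at given parameters ----------------------------------------

#' Log-likelihood of a trait under one of the six evolutionary models
#'
#' Evaluates the exact multivariate-normal log-density of the (transformed)
#' trait values at the supplied parameters. Mainly useful for checking and
#' for profiling; [fit_model()] maximizes it.
#'
#' @param tree Ultrametric `phylo` (ultrametricity enforced for OU models).
#' @param trait Named numeric vector on the analysis scale.
#' @param model One of `"WN"`, `"OU.s"`, `"OU.poll"`, `"BM.s"`, `"BM.rate"`,
#'   `"Lambda"`.
#' @param params Named list of parameters: `mu`, `s2` (WN); `z0`, `sigma2`
#'   (BM.s); `z0`, `sigma2`, `lambda` (Lambda); `z0`, `sigma2` a named
#'   per-regime vector (BM.rate); `theta`, `alpha`, `sigma2` (OU.s);
#'   `theta` a named per-regime vector, `alpha`, `sigma2` (OU.poll).
#' @param painting A `regime_painting`; required for OU.poll and BM.rate.
#' @param ultra_tol Relative ultrametricity tolerance for OU models.
#' @return Log-likelihood.
#' @export
model_loglik <- function(tree, trait, model, params, painting = NULL,
                         ultra_tol = 1e-3) {
  model <- match.arg(model, EVO_MODELS)
  y <- trait
  sp <- names(y)
  if (is.null(sp)) abort("trait must be a named vector")
  if (model %in% c("OU.poll", "BM.rate") && is.null(painting)) {
    abort(paste0(model, " requires a regime painting"))
  }
  geom <- model_geometry(tree, sp)
  n <- length(y)
  switch(model,
    "WN" = {
      if (params$s2 <= 0) abort("s2 must be positive")
      sum(stats::dnorm(y, params$mu, sqrt(params$s2), log = TRUE))
    },
    "BM.s" = {
      mvn_loglik(y, rep(params$z0, n), params$sigma2 * geom$shared)
    },
    "Lambda" = {
      lam <- params$lambda
      if (lam < 0 || lam > 1) abort("lambda must lie in [0, 1]")
      C <- lam * geom$shared
      diag(C) <- geom$depth
      mvn_loglik(y, rep(params$z0, n), params$sigma2 * C)
    },
    "BM.rate" = {
      Cr <- regime_shared_matrices(tree, painting, sp)
      s2 <- params$sigma2
      if (is.null(names(s2))) names(s2) <- names(Cr)
      V <- Reduce(`+`, lapply(names(Cr), function(r) s2[[r]] * Cr[[r]]))
      mvn_loglik(y, rep(params$z0, n), V)
    },
    "OU.s" = {
      if (params$alpha <= 0) abort("alpha must be positive")
      check_ou_tree(tree, ultra_tol)
      V0 <- ou_unit_covariance(geom, params$alpha)
      mvn_loglik(y, rep(params$theta, n), params$sigma2 * V0)
    },
    "OU.poll" = {
      if (params$alpha <= 0) abort("alpha must be positive")
      check_ou_tree(tree, ultra_tol)
      W <- hansen_weights(tree, painting, params$alpha, sp)
      th <- params$theta[colnames(W)]
      V0 <- ou_unit_covariance(geom, params$alpha)
      mvn_loglik(y, as.numeric(W %*% th), params$sigma2 * V0)
    }
  )
}

# ---- maximum-likelihood fitting --------------------------------------------

ou_alpha_profile <- function(alpha, y, tree, geom, painting, multi) {
  V0 <- ou_unit_covariance(geom, alpha)
  X <- if (multi) {
    hansen_weights(tree, painting, alpha, geom$species)
  } else {
    matrix(1, length(y), 1, dimnames = list(geom$species, "theta"))
  }
  gls_profile(y, X, V0)
}

#' Fit one evolutionary model by maximum likelihood
#'
#' Means and optima are profiled by generalized least squares and the
#' overall variance analytically; the remaining parameters (alpha on the
#' log scale over `[1e-9/T, 1e3/T]` with three deterministic starts, lambda
#' bounded in `[0, 1]`, per-regime log rates for BM.rate) are optimized
#' numerically. Parameter counts: WN and BM.s 2, OU.s 3, Lambda 3,
#' BM.rate `1 + R`, OU.poll `2 + R` for `R` regimes in the painting.
#'
#' @inheritParams model_loglik
#' @return Object of class `evo_model_fit` with elements `model`, `params`,
#'   `loglik`, `k`, `n`, `aicc`, and for OU fits `half_life`.
#' @export
fit_model <- function(tree, trait, model, painting = NULL, ultra_tol = 1e-3) {
  model <- match.arg(model, EVO_MODELS)
  y <- trait[!is.na(trait)]
  sp <- names(y)
  n <- length(y)
  if (n < 3L) abort("need at least 3 species")
  if (stats::var(y) == 0) abort("constant trait: degenerate data")
  if (model %in% c("OU.poll", "BM.rate") && is.null(painting)) {
    abort(paste0(model, " requires a regime painting"))
  }
  geom <- model_geometry(tree, sp)
  T_ <- max(geom$depth)
  out <- list(model = model, n = n)

  if (model == "WN") {
    mu <- mean(y)
    s2 <- mean((y - mu)^2)
    out$params <- list(mu = mu, s2 = s2)
    out$loglik <- sum(stats::dnorm(y, mu, sqrt(s2), log = TRUE))
    out$k <- 2L
  } else if (model == "BM.s") {
    pr <- gls_profile(y, matrix(1, n, 1), geom$shared)
    out$params <- list(z0 = unname(pr$beta[1L]), sigma2 = pr$sigma2)
    out$loglik <- pr$loglik
    out$k <- 2L
  } else if (model == "Lambda") {
    prof <- function(lam) {
      C <- lam * geom$shared
      diag(C) <- geom$depth
      gls_profile(y, matrix(1, n, 1), C)$loglik
    }
    opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
    # the interior optimum can be beaten at an endpoint; check both
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, prof(0), prof(1))
    lam <- cand[which.max(lls)]
    C <- lam * geom$shared
    diag(C) <- geom$depth
    pr <- gls_profile(y, matrix(1, n, 1), C)
    out$params <- list(z0 = unname(pr$beta[1L]), sigma2 = pr$sigma2,
                       lambda = lam)
    out$loglik <- pr$loglik
    out$k <- 3L
    out$lambda_ci <- lambda_profile_ci(prof, lam, pr$loglik)
  } else if (model %in% c("OU.s", "OU.poll")) {
    check_ou_tree(tree, ultra_tol)
    multi <- model == "OU.poll"
    lo <- log(1e-9 / T_)
    hi <- log(1e3 / T_)
    starts <- log(log(2) / (c(2, 0.1, 0.001) * T_))
    f <- function(la) -ou_alpha_profile(exp(la), y, tree, geom, painting,
                                        multi)$loglik
    best <- NULL
    for (s0 in starts) {
      o <- tryCatch(
        optim(s0, f, method = "L-BFGS-B", lower = lo, upper = hi,
              control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) abort("OU optimization failed")
    alpha <- exp(best$par)
    pr <- ou_alpha_profile(alpha, y, tree, geom, painting, multi)
    theta <- pr$beta
    if (multi) names(theta) <- colnames(hansen_weights(tree, painting, alpha, sp))
    out$params <- if (multi) {
      list(theta = theta, alpha = alpha, sigma2 = pr$sigma2)
    } else {
      list(theta = unname(theta[1L]), alpha = alpha, sigma2 = pr$sigma2)
    }
    out$loglik <- pr$loglik
    out$k <- if (multi) 2L + length(theta) else 3L
    out$half_life <- phylogenetic_half_life(alpha)
  } else { # BM.rate
    regs <- painting_regimes(painting)
    Cr <- regime_shared_matrices(tree, painting, sp)
    bm <- gls_profile(y, matrix(1, n, 1), geom$shared)
    f <- function(ls2) {
      V <- Reduce(`+`, lapply(seq_along(Cr),
                              function(i) exp(ls2[i]) * Cr[[i]]))
      -gls_profile(y, matrix(1, n, 1), V)$loglik
    }
    base <- log(bm$sigma2)
    starts <- list(rep(base, length(Cr)),
                   rep(base + log(5), length(Cr)),
                   rep(base - log(5), length(Cr)))
    best <- NULL
    for (s0 in starts) {
      o <- tryCatch(
        optim(s0, f, method = "L-BFGS-B",
              lower = base - 15, upper = base + 15,
              control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) abort("BM.rate optimization failed")
    s2 <- setNames(exp(best$par), regs)
    V <- Reduce(`+`, lapply(seq_along(Cr), function(i) s2[i] * Cr[[i]]))
    pr <- gls_profile(y, matrix(1, n, 1), V)
    out$params <- list(z0 = unname(pr$beta[1L]), sigma2 = s2)
    out$loglik <- pr$loglik
    out$k <- 1L + length(s2)
  }

  if (n - out$k - 1 <= 0) {
    abort("too few species for AICc with this parameter count")
  }
  out$aicc <- aicc(out$loglik, out$k, out$n)
  class(out) <- "evo_model_fit"
  out
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat("Evolutionary model fit:", x$model, "\n")
  cat("  n =", x$n, " k =", x$k,
      " loglik =", format(x$loglik, digits = 6),
      " AICc =", format(x$aicc, digits = 6), "\n")
  p <- x$params
  for (nm in names(p)) {
    cat("  ", nm, "=", paste(format(p[[nm]], digits = 4), collapse = " "), "\n")
  }
  if (!is.null(x$half_life)) {
    cat("  half-life =", format(x$half_life, digits = 4), "Ma\n")
  }
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters (variance and mean parameters count).
#' @param n Number of observations (species).
#' @return AICc value.
#' @export
#' @examples
#' aicc(0, 1, 10)  # 2.5
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) abort("AICc requires n - k - 1 > 0")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min AICc`; invariant to adding a constant to all
#' values. Non-finite entries get weight 0.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Numeric vector of weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(128.4, 126.1, 80.6, 155.2, 155.4, 126.2))
akaike_weights <- function(aicc_values) {
  if (!any(is.finite(aicc_values))) abort("no finite AICc values")
  d <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Phylogenetic half-life
#'
#' `t_1/2 = ln(2) / alpha`: the time for the expected trait value to move
#' halfway from the ancestral state to a new optimum.
#'
#' @param alpha Positive rate of adaptation (per Ma).
#' @return Half-life in Ma.
#' @export
#' @examples
#' phylogenetic_half_life(14.9)  # ~0.047 Ma
phylogenetic_half_life <- function(alpha) {
  if (any(alpha <= 0)) abort("alpha must be positive")
  log(2) / alpha
}

#' Fit and compare the six evolutionary models
#'
#' Fits every model in [evo_models()], ranks by AICc, and attaches Akaike
#' weights. A model whose fit fails is recorded with its error message and
#' weight 0 rather than aborting the comparison.
#'
#' @inheritParams model_loglik
#' @return Object of class `model_comparison`: list with `fits` (named
#'   list), `table` (tibble: model, loglik, k, n, aicc, delta_aicc, weight,
#'   error) and `best` (model name with minimal AICc).
#' @export
compare_models <- function(tree, trait, painting = NULL, ultra_tol = 1e-3) {
  fits <- lapply(setNames(EVO_MODELS, EVO_MODELS), function(m) {
    tryCatch(fit_model(tree, trait, m, painting = painting,
                       ultra_tol = ultra_tol),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "evo_model_error"))
  })
  ok <- !vapply(fits, inherits, logical(1), "evo_model_error")
  av <- vapply(fits, function(f) if (inherits(f, "evo_model_fit")) f$aicc
               else Inf, numeric(1))
  w <- akaike_weights(av)
  tab <- tibble(
    model = EVO_MODELS,
    loglik = vapply(fits, function(f) f$loglik %||% NA_real_, numeric(1)),
    k = vapply(fits, function(f) as.integer(f$k %||% NA), integer(1)),
    n = vapply(fits, function(f) as.integer(f$n %||% NA), integer(1)),
    aicc = ifelse(is.finite(av), av, NA_real_),
    delta_aicc = ifelse(is.finite(av), av - min(av), NA_real_),
    weight = w,
    error = vapply(fits, function(f) {
      if (inherits(f, "evo_model_error")) f$error else NA_character_
    }, character(1))
  )
  res <- list(fits = fits, table = tab, best = EVO_MODELS[which.min(av)])
  class(res) <- "model_comparison"
  res
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (best:", x$best, ")\n")
  print(x$table[order(x$table$aicc), c("model", "loglik", "k", "aicc", "weight")])
  invisible(x)
}

# Profile-likelihood interval for Pagel's lambda. The point estimate is
# constrained to [0, 1]; the interval is computed on the unconstrained
# profile surface, so the upper bound may exceed 1 (up to the positive-
# definiteness limit of the lambda-scaled covariance).
lambda_profile_ci <- function(prof, lam_hat, ll_hat, level = 0.95) {
  target <- ll_hat - stats::qchisq(level, 1) / 2
  f <- function(l) prof(l) - target
  lower <- if (f(0) >= 0) 0 else {
    tryCatch(stats::uniroot(f, c(0, lam_hat), tol = 1e-6)$root,
             error = function(e) NA_real_)
  }
  lmax <- lam_hat
  for (l in seq(max(lam_hat, 1e-6), 3, length.out = 60)) {
    if (is.finite(prof(l))) lmax <- l else break
  }
  upper <- if (f(lmax) >= 0) lmax else {
    tryCatch(stats::uniroot(f, c(lam_hat, lmax), tol = 1e-6)$root,
             error = function(e) NA_real_)
  }
  c(lower = lower, upper = upper)
}

# ---- uncertainty of optima --------------------------------------------------

full_negloglik_fun <- function(fit, tree, trait, painting, ultra_tol) {
  model <- fit$model
  y <- trait[!is.na(trait)]
  if (model == "OU.poll") {
    regs <- names(fit$params$theta)
    function(p) {
      th <- setNames(p[-(1:2)], regs)
      -model_loglik(tree, y, "OU.poll",
                    list(theta = th, alpha = exp(p[2L]), sigma2 = exp(p[1L])),
                    painting = painting, ultra_tol = ultra_tol)
    }
  } else if (model == "OU.s") {
    function(p) {
      -model_loglik(tree, y, "OU.s",
                    list(theta = p[3L], alpha = exp(p[2L]),
                         sigma2 = exp(p[1L])),
                    ultra_tol = ultra_tol)
    }
  } else {
    abort("optimum uncertainty is defined for OU fits")
  }
}

#' Standard errors and confidence intervals for OU optima
#'
#' Standard errors come from the inverse numerical Hessian of the negative
#' log-likelihood at the maximum (variance and alpha on the log scale,
#' optima on the analysis scale); 95% intervals are `theta +- 1.96 se` on
#' the analysis scale and are then back-transformed, giving the asymmetric
#' intervals natural-scale reporting requires. If the Hessian is singular a
#' seeded parametric bootstrap (refitting on data simulated from the fitted
#' model) supplies the standard errors instead, flagged in the output.
#'
#' @param fit An `evo_model_fit` for `"OU.s"` or `"OU.poll"`.
#' @inheritParams model_loglik
#' @param transform,offset,from_percent Back-transform specification
#'   (defaults taken from the `trait` attributes set by
#'   [transform_trait()]); `NULL` transform reports the analysis scale only.
#' @param n_boot Bootstrap replicates for the fallback.
#' @param seed Seed for the bootstrap fallback.
#' @return Tibble with one row per regime: `regime`, `theta`, `se`,
#'   `ci_lower`, `ci_upper` on the analysis scale, back-transformed
#'   `theta_natural`, `ci_lower_natural`, `ci_upper_natural` when a
#'   transform is known, and `method` (`"hessian"` or `"bootstrap"`).
#' @export
estimate_theta_uncertainty <- function(fit, tree, trait, painting = NULL,
                                       transform = NULL, offset = NULL,
                                       from_percent = NULL,
                                       n_boot = 199, seed = 1,
                                       ultra_tol = 1e-3) {
  stopifnot(inherits(fit, "evo_model_fit"))
  if (!fit$model %in% c("OU.s", "OU.poll")) {
    abort("optimum uncertainty is defined for OU fits")
  }
  transform <- transform %||% attr(trait, "transform")
  offset <- offset %||% attr(trait, "offset") %||% 0
  from_percent <- from_percent %||% attr(trait, "from_percent") %||% FALSE
  theta <- fit$params$theta
  regs <- if (fit$model == "OU.poll") names(theta) else "all"
  nll <- full_negloglik_fun(fit, tree, trait, painting, ultra_tol)
  p_hat <- c(log(fit$params$sigma2), log(fit$params$alpha), unname(theta))
  se <- NULL
  method <- "hessian"
  H <- tryCatch(pracma::hessian(nll, p_hat), error = function(e) NULL)
  if (!is.null(H)) {
    Vm <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vm)) {
      v <- diag(Vm)[-(1:2)]
      if (all(is.finite(v)) && all(v > 0)) se <- sqrt(v)
    }
  }
  if (is.null(se)) {
    method <- "bootstrap"
    se <- theta_bootstrap_se(fit, tree, trait, painting, n_boot, seed,
                             ultra_tol)
  }
  lo <- unname(theta) - qnorm(0.975) * se
  hi <- unname(theta) + qnorm(0.975) * se
  out <- tibble(regime = regs, theta = unname(theta), se = se,
                ci_lower = lo, ci_upper = hi, method = method)
  if (!is.null(transform)) {
    bt <- function(v) inverse_transform_trait(v, kind = transform,
                                              offset = offset,
                                              to_percent = from_percent)
    out$theta_natural <- bt(out$theta)
    out$ci_lower_natural <- bt(out$ci_lower)
    out$ci_upper_natural <- bt(out$ci_upper)
  }
  out
}

theta_bootstrap_se <- function(fit, tree, trait, painting, n_boot, seed,
                               ultra_tol) {
  y <- trait[!is.na(trait)]
  theta <- fit$params$theta
  est <- matrix(NA_real_, n_boot, length(theta))
  for (b in seq_len(n_boot)) {
    yb <- simulate_trait(tree, model = fit$model, params = fit$params,
                         painting = painting, seed = seed * 10000L + b)
    yb <- yb[names(y)]
    fb <- tryCatch(fit_model(tree, yb, fit$model, painting = painting,
                             ultra_tol = ultra_tol),
                   error = function(e) NULL)
    if (!is.null(fb)) {
      th <- fb$params$theta
      est[b, ] <- if (length(theta) > 1L) th[names(theta)] else th
    }
  }
  apply(est, 2L, sd, na.rm = TRUE)
}

# ---- broom-style methods ----------------------------------------------------

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$table

#' @rdname compare_models
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  b <- x$fits[[x$best]]
  tibble(best_model = x$best, best_aicc = b$aicc,
         best_weight = x$table$weight[x$table$model == x$best],
         n = b$n)
}

#' @rdname fit_model
#' @param x An `evo_model_fit`.
#' @param ... Unused.
#' @method tidy evo_model_fit
#' @export
tidy.evo_model_fit <- function(x, ...) {
  p <- x$params
  rows <- lapply(names(p), function(nm) {
    v <- p[[nm]]
    tibble(term = if (length(v) > 1L) paste0(nm, "_", names(v)) else nm,
           estimate = unname(v))
  })
  dplyr::bind_rows(rows)
}

#' @rdname fit_model
#' @method glance evo_model_fit
#' @export
glance.evo_model_fit <- function(x, ...) {
  tibble(model = x$model, loglik = x$loglik, k = x$k, n = x$n,
         aicc = x$aicc, half_life = x$half_life %||% NA_real_)
}
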