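# Phylogenetic generalized least squares with jointly ML-estimated Pagel's
# lambda: residual covariance sigma2 * C_lambda, where C_lambda scales the
# off-diagonal phylogenetic covariance by lambda.

pgls_core <- function(y, X, shared, lam) {
  C <- lam * shared
  diag(C) <- diag(shared)
  gls_profile(y, X, C)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `formula` on `data` with residual covariance `sigma2 * C_lambda`
#' built from the tree; `lambda` is either estimated by maximum likelihood
#' over `[0, 1]` (default) or fixed. Categorical predictors use treatment
#' coding; a `syndrome` column is releveled to the canonical order of
#' [syndrome_levels()], so contrasts are tested against the bird syndrome.
#' Coefficient standard errors use the unbiased residual variance
#' (`RSS_gls / (n - p)`) and p-values a t distribution with `n - p` d.f.;
#' the reported AICc uses the ML likelihood with `k = p + 2` when lambda is
#' estimated (`p + 1` when fixed).
#'
#' @param data Data frame with a `species` column, the response and the
#'   predictors; rows are matched to tree tips by species and rows with
#'   missing values are dropped.
#' @param formula Model formula, e.g. `log(volume_ul) ~ syndrome +
#'   log(total_spur_mm)`.
#' @param tree Ultrametric `phylo` containing the species.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return Object of class `pgls_fit`: `coefficients` tibble (term,
#'   estimate, std_error, t_value, p_value), `lambda`, `lambda_ml`,
#'   `loglik`, `sigma2`, `aicc`, `n`, `df_residual`.
#' @export
pgls_fit <- function(data, formula, tree, lambda = "ML") {
  stopifnot(is.data.frame(data), "species" %in% names(data))
  df <- as.data.frame(data)
  if ("syndrome" %in% names(df) && !is.factor(df$syndrome)) {
    df$syndrome <- factor(df$syndrome,
                          levels = intersect(syndrome_levels(),
                                             unique(df$syndrome)))
  }
  df <- df[df$species %in% tree$tip.label, , drop = FALSE]
  rownames(df) <- NULL
  mf <- stats::model.frame(formula, df, na.action = stats::na.omit)
  sp <- df$species[as.integer(rownames(mf))]
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) abort("rank-deficient design matrix")
  if (n < p + 2L) abort("need at least 2 more observations than coefficients")
  geom <- model_geometry(tree, sp)
  shared <- geom$shared

  if (identical(lambda, "ML")) {
    f <- function(lam) pgls_core(y, X, shared, lam)$loglik
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, f(0), f(1))
    lam <- cand[which.max(lls)]
    lambda_ml <- TRUE
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam <- lambda
    lambda_ml <- FALSE
  }
  fit <- pgls_core(y, X, shared, lam)
  rss <- fit$sigma2 * n
  s2_unbiased <- rss / (n - p)
  XtX_inv <- tryCatch(solve(crossprod(fit$Xt)), error = function(e) NULL)
  if (is.null(XtX_inv)) abort("singular GLS cross-product")
  se <- sqrt(pmax(diag(XtX_inv) * s2_unbiased, 0))
  tv <- fit$beta / se
  tv[!is.finite(tv)] <- sign(fit$beta[!is.finite(tv)]) * 1e8
  pv <- 2 * pt(abs(tv), df = n - p, lower.tail = FALSE)
  k <- p + 1L + as.integer(lambda_ml)
  out <- list(
    coefficients = tibble(term = colnames(X), estimate = unname(fit$beta),
                          std_error = unname(se), t_value = unname(tv),
                          p_value = unname(pv)),
    lambda = lam, lambda_ml = lambda_ml,
    loglik = fit$loglik, sigma2 = fit$sigma2,
    aicc = aicc(fit$loglik, k, n), k = k,
    n = n, df_residual = n - p,
    formula = formula, species = sp
  )
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", deparse(x$formula), ")\n", sep = "")
  cat("  lambda =", format(x$lambda, digits = 4),
      if (x$lambda_ml) "(ML)" else "(fixed)",
      " loglik =", format(x$loglik, digits = 6),
      " AICc =", format(x$aicc, digits = 6), "\n")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @rdname pgls_fit
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @rdname pgls_fit
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(lambda = x$lambda, loglik = x$loglik, aicc = x$aicc,
         sigma2 = x$sigma2, n = x$n, df_residual = x$df_residual)
}

#' Phylogenetic correlation between two traits
#'
#' PGLS of `y` on `x` with ML lambda; reports the slope t-test and the
#' lambda estimate. With an exactly collinear pair the t statistic is
#' capped at 1e8.
#'
#' @param x,y Named numeric vectors (names are species) on their analysis
#'   scales.
#' @param tree Ultrametric `phylo`.
#' @return Tibble with `estimate`, `t_value`, `p_value`, `lambda`, `n`.
#' @export
phylo_correlation <- function(x, y, tree) {
  sp <- intersect(intersect(names(x), names(y)), tree$tip.label)
  if (length(sp) < 4L) abort("need at least 4 shared species")
  df <- data.frame(species = sp, xv = x[sp], yv = y[sp])
  fit <- pgls_fit(df, yv ~ xv, tree, lambda = "ML")
  row <- fit$coefficients[fit$coefficients$term == "xv", ]
  tibble(estimate = row$estimate, t_value = row$t_value,
         p_value = row$p_value, lambda = fit$lambda, n = fit$n)
}
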