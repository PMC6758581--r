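# Multivariate nectar-syndrome stage: standardized nectar matrix, PCA,
# UPGMA clustering, the hand-built syndrome distance, the Mantel
# permutation test, and the lambda signal of syndrome on the dendrogram.

#' Build a standardized species-by-variable nectar matrix
#'
#' @param traits Tibble with a `species` column and numeric variables.
#' @param variables Character vector of columns to keep.
#' @param standardize Z-score each column (default `TRUE`).
#' @return Numeric matrix with species rownames and attribute
#'   `"standardized"`; species with any missing value among the selected
#'   variables are dropped with a message.
#' @export
nectar_matrix <- function(traits, variables, standardize = TRUE) {
  stopifnot(all(variables %in% names(traits)))
  M <- as.matrix(traits[, variables])
  rownames(M) <- traits$species
  keep <- stats::complete.cases(M)
  if (any(!keep)) {
    inform(paste0("dropping ", sum(!keep), " species with missing values"))
    M <- M[keep, , drop = FALSE]
  }
  if (standardize) {
    M <- scale(M)
    attr(M, "scaled:center") <- NULL
    attr(M, "scaled:scale") <- NULL
  }
  attr(M, "standardized") <- standardize
  M
}

#' Principal component analysis with a deterministic sign convention
#'
#' Eigen-decomposition of the correlation (`scale = TRUE`) or covariance
#' matrix via [stats::prcomp()]. Each axis is flipped, if needed, so its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms. Per-variable correlations with the axes are reported for
#' interpretation.
#'
#' @param M Species-by-variable numeric matrix (rownames are species).
#' @param scale Scale variables to unit variance (default `TRUE`).
#' @return Object of class `nectar_pca`: `scores` (tibble with `species`),
#'   `loadings` (matrix), `correlations` (variable-axis correlation
#'   matrix), `variance_explained` (fractions summing to 1), `sdev`.
#' @export
nectar_pca <- function(M, scale = TRUE) {
  stopifnot(is.matrix(M) || is.data.frame(M))
  M <- as.matrix(M)
  if (nrow(M) < 2L || ncol(M) < 2L) abort("PCA needs >= 2 species and >= 2 variables")
  if (scale) {
    v <- apply(M, 2L, stats::var)
    if (any(v == 0)) {
      abort(paste0("zero-variance columns: ",
                   paste(colnames(M)[v == 0], collapse = ", ")))
    }
  }
  pc <- prcomp(M, center = TRUE, scale. = scale)
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cors <- suppressWarnings(stats::cor(M, pc$x))
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(species = rownames(M)), scores)
  out <- list(scores = scores, loadings = pc$rotation, correlations = cors,
              variance_explained = ve, sdev = pc$sdev,
              center = pc$center, scale = pc$scale)
  class(out) <- "nectar_pca"
  out
}

#' @export
print.nectar_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "species,", nrow(x$loadings), "variables\n")
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 2)
  cat("  variance explained (first axes):", paste0(ve, "%", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname nectar_pca
#' @param x A `nectar_pca`.
#' @param ... Unused.
#' @method tidy nectar_pca
#' @export
tidy.nectar_pca <- function(x, ...) {
  tibble(axis = seq_along(x$variance_explained),
         sdev = x$sdev,
         variance_explained = x$variance_explained,
         cumulative = cumsum(x$variance_explained))
}

#' UPGMA clustering into an ultrametric dendrogram
#'
#' Average-linkage agglomerative clustering of a distance matrix; the merge
#' tree is returned as an ultrametric `phylo` whose node heights are half
#' the merge distances, so cophenetic distances on the tree reproduce the
#' average-linkage merge levels.
#'
#' @param D A `dist` object or symmetric nonnegative matrix with zero
#'   diagonal and labeled rows.
#' @return An ultrametric `phylo`.
#' @export
upgma <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D), tol = 1e-8)) abort("distance matrix must be symmetric")
    if (any(D < 0)) abort("distances must be nonnegative")
    if (any(abs(diag(D)) > 1e-12)) abort("distance matrix must have zero diagonal")
    D <- stats::as.dist(D)
  }
  hc <- hclust(D, method = "average")
  tree <- ape::as.phylo(hc)
  # as.phylo halves merge heights; enforce exact ultrametricity
  dep <- node_depths(tree)
  tips <- seq_len(ape::Ntip(tree))
  h <- max(dep[tips])
  term <- tree$edge[, 2L] %in% tips
  tree$edge.length[term] <- tree$edge.length[term] +
    (h - dep[tree$edge[term, 2L]])
  tree
}

#' Hand-built pollination-syndrome distance matrix
#'
#' Distance 0 between identical syndromes, 0.5 between the mixed
#' bee-and-butterfly syndrome and either the bee or the butterfly syndrome,
#' and 1 between any other pair.
#'
#' @param syndromes Named character vector of syndrome labels.
#' @return Symmetric numeric matrix with species dimnames.
#' @export
syndrome_distance_matrix <- function(syndromes) {
  bad <- setdiff(unique(syndromes), syndrome_levels())
  if (length(bad)) abort(paste0("unknown syndrome label: ", paste(bad, collapse = ", ")))
  n <- length(syndromes)
  D <- matrix(1, n, n, dimnames = list(names(syndromes), names(syndromes)))
  mixed <- c("bee", "butterfly")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- syndromes[i]; b <- syndromes[j]
    if (a == b) D[i, j] <- 0
    else if ((a == "bee_and_butterfly" && b %in% mixed) ||
             (b == "bee_and_butterfly" && a %in% mixed)) D[i, j] <- 0.5
  }
  D
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries; significance by
#' jointly permuting the row/column labels of the second matrix. The
#' one-sided p-value is `(1 + #{permuted r >= observed}) / (1 + n_perm)`.
#'
#' @param D1,D2 Distance matrices (square, matching labels; `dist` objects
#'   accepted). When both carry dimnames, `D2` is aligned to `D1`'s order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return Object of class `mantel_test`: list with `r`, `p`, `n_perm`,
#'   `n`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999, seed = NULL) {
  if (inherits(D1, "dist")) D1 <- as.matrix(D1)
  if (inherits(D2, "dist")) D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) abort("distance matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2))) abort("label sets differ")
    D2 <- D2[rownames(D1), rownames(D1)]
  }
  if (n_perm < 99) abort("use at least 99 permutations")
  n <- nrow(D1)
  lt <- lower.tri(D1)
  v1 <- D1[lt]
  r_obs <- stats::cor(v1, D2[lt])
  with_seed_local(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      rp <- stats::cor(v1, D2[pm, pm][lt])
      if (rp >= r_obs) count <- count + 1L
    }
    out <- list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm,
                n = n)
    class(out) <- "mantel_test"
    out
  })
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test: r =", format(x$r, digits = 4),
      " p =", format(x$p, digits = 4),
      " (", x$n_perm, "permutations,", x$n, "objects )\n")
  invisible(x)
}

#' @rdname mantel_test
#' @param x A `mantel_test`.
#' @param ... Unused.
#' @method glance mantel_test
#' @export
glance.mantel_test <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm, n = x$n)
}

#' Lambda signal of a discrete trait on a dendrogram
#'
#' Measures whether a discrete trait (pollination syndrome) tracks the
#' structure of an ultrametric dendrogram from nectar-composition
#' clustering. The dendrogram's internal branches are scaled by lambda
#' (tip depths preserved, the continuous-trait lambda analog), an
#' equal-rates Mk model is fitted on the transformed tree, and lambda is
#' maximized in `[0, 1]`; at `lambda = 0` the tree is a star, i.e. the
#' white-noise reference, against which a 1-d.f. likelihood-ratio test is
#' reported.
#'
#' @param dendrogram Ultrametric `phylo` (e.g. from [upgma()]).
#' @param syndromes Named character vector over the dendrogram's tips.
#' @return List with `lambda`, `loglik`, `loglik_star`, `lrt`, `p`,
#'   `rate` (Mk rate at the optimum).
#' @export
dendrogram_lambda_signal <- function(dendrogram, syndromes) {
  if (!setequal(dendrogram$tip.label, names(syndromes))) {
    abort("dendrogram tips and syndrome species differ")
  }
  if (length(unique(syndromes)) < 2L) abort("monomorphic syndromes")
  states <- mk_states_of(syndromes)
  prof <- function(lam) {
    tr <- lambda_transform_tree(dendrogram, lam)
    # guard against numerically zero terminal branches
    tr$edge.length <- pmax(tr$edge.length, 0)
    fit_mk_er_quiet(tr, syndromes, states)
  }
  f <- function(lam) prof(lam)$loglik
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, f(0), f(1))
  lam <- cand[which.max(lls)]
  fit <- prof(lam)
  ll0 <- f(0)
  lrt <- 2 * (fit$loglik - ll0)
  list(lambda = lam, loglik = fit$loglik, loglik_star = ll0,
       lrt = max(0, lrt), p = pchisq(max(0, lrt), df = 1, lower.tail = FALSE),
       rate = fit$rate)
}

fit_mk_er_quiet <- function(tree, tip_states, states) {
  withCallingHandlers(fit_mk_er(tree, tip_states, states),
                      warning = function(w) invokeRestart("muffleWarning"))
}
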