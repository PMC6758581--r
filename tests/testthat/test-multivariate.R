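# PCA, UPGMA, syndrome distances, the Mantel permutation test, and the
# lambda signal of syndrome on a dendrogram.

test_that("PCA matches a direct eigendecomposition and its invariants", {
  M <- matrix(c(2.0, 1.1, 0.3,
                1.4, 0.8, 0.9,
                3.1, 2.2, 0.1,
                0.5, 0.4, 1.7,
                2.6, 1.9, 0.6), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), c("v1", "v2", "v3")))
  pc <- nectar_pca(M, scale = TRUE)
  ev <- eigen(stats::cor(M))
  expect_equal(pc$sdev^2, ev$values, tolerance = 1e-10)
  scores <- as.matrix(pc$scores[, -1])
  Z <- scale(M)
  expect_equal(unname(scores %*% t(pc$loadings)), unname(Z),
               tolerance = 1e-8, ignore_attr = TRUE)
  # orthogonal axes, nonincreasing variance shares summing to one
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_equal(sum(pc$variance_explained), 1)
  # deterministic sign: dominant loading positive per axis
  expect_true(all(apply(pc$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))

  # two perfectly correlated variables load on a single axis
  M2 <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  rownames(M2) <- paste0("x", 1:6)
  pc2 <- nectar_pca(M2, scale = TRUE)
  expect_equal(pc2$variance_explained[1], 1, tolerance = 1e-12)

  expect_error(nectar_pca(cbind(a = rep(1, 4), b = 1:4)), "zero-variance")
})

test_that("UPGMA reproduces hand-computed average-linkage merges", {
  D <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- upgma(D)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 4)
  expect_equal(cp["B", "C"], 4)
  expect_true(is_ultrametric_rel(tr, 1e-12))
  expect_equal(crown_age(tr), 2)   # merge heights are half the distances

  # equal distances collapse at a common height
  De <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  te <- upgma(De)
  expect_true(is_ultrametric_rel(te, 1e-12))
  expect_equal(crown_age(te), 1.5)

  bad <- D; bad[1, 2] <- 9
  expect_error(upgma(bad), "symmetric")
})

test_that("the syndrome distance follows the published rule", {
  syn <- c(s1 = "bee", s2 = "bee", s3 = "bee_and_butterfly",
           s4 = "butterfly", s5 = "bird", s6 = "fly")
  D <- syndrome_distance_matrix(syn)
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 0.5)
  expect_equal(D["s4", "s3"], 0.5)
  expect_equal(D["s5", "s6"], 1)
  expect_equal(D["s5", "s1"], 1)
  expect_true(isSymmetric(D))
  expect_error(syndrome_distance_matrix(c(a = "bat")), "unknown")
})

test_that("the Mantel test is exact on identical matrices and invariant", {
  withr::with_seed(33, {
    X <- matrix(rnorm(20 * 3), 20)
    rownames(X) <- paste0("s", 1:20)
  })
  D <- as.matrix(dist(X))
  m <- mantel_test(D, D, n_perm = 999, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$p, 1 / 1000)

  # joint relabeling of both matrices leaves r unchanged
  pm <- sample(20)
  m2 <- mantel_test(D[pm, pm], D[pm, pm], n_perm = 99, seed = 2)
  expect_equal(m2$r, 1, tolerance = 1e-12)

  expect_equal(formals(mantel_test)$n_perm, 9999)
  expect_error(mantel_test(D, D[1:10, 1:10]), "size")
})

test_that("mantel agrees with vegan on the observed statistic", {
  skip_if_not_installed("vegan")
  withr::with_seed(34, {
    X <- matrix(rnorm(25 * 3), 25)
    Y <- matrix(rnorm(25 * 2), 25)
    rownames(X) <- rownames(Y) <- paste0("s", 1:25)
  })
  D1 <- as.matrix(dist(X)); D2 <- as.matrix(dist(Y))
  mine <- mantel_test(D1, D2, n_perm = 199, seed = 3)
  ref <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                       permutations = 199)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("dendrogram lambda responds to real and shuffled structure", {
  # two deep clusters perfectly aligned with two syndromes
  n_half <- 12
  D <- matrix(4, 2 * n_half, 2 * n_half)
  withr::with_seed(35, {
    jitter <- matrix(runif(4 * n_half^2, 0, 0.2), 2 * n_half)
  })
  D <- D + (jitter + t(jitter)) / 2
  D[1:n_half, 1:n_half] <- 1
  D[(n_half + 1):(2 * n_half), (n_half + 1):(2 * n_half)] <- 1
  diag(D) <- 0
  labs <- paste0("s", seq_len(2 * n_half))
  dimnames(D) <- list(labs, labs)
  dend <- upgma(D)
  syn <- setNames(rep(c("bird", "bee"), each = n_half), labs)
  strong <- dendrogram_lambda_signal(dend, syn)
  expect_gte(strong$lambda, 0.9)
  expect_lt(strong$p, 0.01)
  # lambda = 0 likelihood equals the star-tree white-noise reference
  star <- dend
  dep <- node_depths(dend)[seq_len(ape::Ntip(dend))]
  star <- ape::stree(length(labs), "star", tip.label = dend$tip.label)
  star$edge.length <- dep[match(star$tip.label, dend$tip.label)]
  expect_equal(strong$loglik_star,
               suppressWarnings(fit_mk_er(star, syn)$loglik),
               tolerance = 1e-6)

  expect_error(dendrogram_lambda_signal(dend, setNames(rep("bee", 24), labs)),
               "monomorphic")
})

test_that("shuffled syndromes carry no dendrogram lambda signal", {
  # realistic five-syndrome setting: nectar dendrogram of a synthetic bundle
  b <- suppressMessages(generate_study_like_dataset(seed = 11))
  M <- scale(cbind(log(b$traits$volume_ul), log(b$traits$aa_mm),
                   stats::qlogis(b$traits$sugar_pct / 100),
                   stats::qlogis(b$traits$nsp_pct / 100)))
  rownames(M) <- b$traits$species
  dend <- upgma(as.matrix(dist(M)))
  syn <- b$syndromes[dend$tip.label]
  out <- sapply(1:100, function(s) {
    shuffled <- withr::with_seed(1000 + s,
                                 setNames(sample(syn), names(syn)))
    r <- dendrogram_lambda_signal(dend, shuffled)
    c(lam = r$lambda, p = r$p)
  })
  expect_lte(median(out["lam", ]), 0.2)
  expect_lte(mean(out["p", ] < 0.05), 0.12)
})
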