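# Six-model likelihoods against the dense oracle, analytic limits, AICc /
# Akaike-weight / half-life arithmetic, fitting behaviour and optimum
# uncertainty.

test_that("every model matches the dense multivariate-normal oracle", {
  states <- c("r1", "r2", "r3")
  withr::with_seed(21, {
    for (i in 1:6) {
      n <- sample(4:6, 1)
      tr <- random_ultrametric_tree(n, depth = 2)
      pa <- random_painting(tr, states, seed = 500 + i)
      y <- setNames(rnorm(n), tr$tip.label)
      th <- setNames(rnorm(3, 0, 2), states)
      s2r <- setNames(runif(3, 0.3, 2), states)
      cases <- list(
        list("WN", list(mu = 0.4, s2 = 1.3)),
        list("BM.s", list(z0 = -0.2, sigma2 = 0.8)),
        list("Lambda", list(z0 = 0.1, sigma2 = 1.1, lambda = runif(1))),
        list("BM.rate", list(z0 = 0.3, sigma2 = s2r)),
        list("OU.s", list(theta = 0.5, alpha = runif(1, 0.2, 2),
                          sigma2 = 0.9)),
        list("OU.poll", list(theta = th, alpha = runif(1, 0.2, 2),
                             sigma2 = 1.4))
      )
      for (cs in cases) {
        mine <- model_loglik(tr, y, cs[[1]], cs[[2]], painting = pa)
        oracle <- dense_model_loglik(tr, y, cs[[1]], cs[[2]], painting = pa)
        expect_equal(mine, oracle, tolerance = 1e-8,
                     label = paste(cs[[1]], "loglik"))
      }
    }
  })
})

test_that("analytic limits connect the models", {
  tr <- toy_tree()
  y <- c(A = 0.3, B = -0.2, C = 1.1, D = 0.4)
  bm <- model_loglik(tr, y, "BM.s", list(z0 = 0.2, sigma2 = 0.5))
  # OU -> BM as alpha -> 0 (with z0 = theta)
  ou <- model_loglik(tr, y, "OU.s",
                     list(theta = 0.2, alpha = 1e-8, sigma2 = 0.5))
  expect_equal(ou, bm, tolerance = 1e-4)
  # lambda = 1 is BM, lambda = 0 is white noise with s2 = sigma2 * T
  expect_equal(model_loglik(tr, y, "Lambda",
                            list(z0 = 0.2, sigma2 = 0.5, lambda = 1)),
               bm, tolerance = 1e-8)
  expect_equal(model_loglik(tr, y, "Lambda",
                            list(z0 = 0.2, sigma2 = 0.5, lambda = 0)),
               model_loglik(tr, y, "WN", list(mu = 0.2, s2 = 0.5 * 2)),
               tolerance = 1e-8)
})

test_that("regime models collapse to their single-regime forms", {
  states <- c("r1", "r2")
  tr <- toy_tree()
  pa <- random_painting(tr, states, seed = 31)
  y <- c(A = 0.3, B = -0.2, C = 1.1, D = 0.4)
  expect_identical(
    model_loglik(tr, y, "OU.poll",
                 list(theta = c(r1 = 0.7, r2 = 0.7), alpha = 0.9,
                      sigma2 = 1.2), painting = pa),
    model_loglik(tr, y, "OU.s",
                 list(theta = 0.7, alpha = 0.9, sigma2 = 1.2)))
  expect_equal(
    model_loglik(tr, y, "BM.rate",
                 list(z0 = 0.1, sigma2 = c(r1 = 0.8, r2 = 0.8)),
                 painting = pa),
    model_loglik(tr, y, "BM.s", list(z0 = 0.1, sigma2 = 0.8)),
    tolerance = 1e-12)
})

test_that("AICc, weights and half-life follow their formulas", {
  expect_equal(aicc(0, 1, 10), 2.5)
  expect_equal(aicc(0, 2, 1e6), 4, tolerance = 1e-3)
  lls <- sapply(1:5, function(k) aicc(-10, k, 30))
  expect_true(all(diff(lls) > 0))
  expect_error(aicc(0, 10, 11), "n - k - 1")

  w <- akaike_weights(rep(100, 4))
  expect_equal(w, rep(0.25, 4))
  a <- c(10, 12, 15)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3),
               tolerance = 1e-12)
  expect_equal(sum(akaike_weights(c(1, 3, Inf))), 1)
  expect_error(akaike_weights(c(Inf, Inf)), "finite")

  expect_equal(phylogenetic_half_life(log(2)), 1.0)
  a <- seq(0.1, 5, by = 0.3)
  hl <- phylogenetic_half_life(a)
  expect_true(all(hl > 0) && all(diff(hl) < 0))
  expect_error(phylogenetic_half_life(0), "positive")
})

test_that("fitting is an actual maximum and flags degenerate data", {
  tr <- simulate_yule_tree(40, 10, seed = 41)
  sim <- simulate_mk_regimes(tr, states = c("r1", "r2"), rate = 0.1,
                             root_state = "r1", seed = 42)
  truth <- list(theta = c(r1 = 0, r2 = 3), alpha = 0.7, sigma2 = 1)
  for (s in 1:5) {
    y <- simulate_trait(tr, "OU.poll", truth, painting = sim$painting,
                        seed = 50 + s)
    fit <- fit_model(tr, y, "OU.poll", painting = sim$painting)
    expect_gte(fit$loglik + 1e-6,
               model_loglik(tr, y, "OU.poll", truth,
                            painting = sim$painting))
  }
  const <- setNames(rep(1, 40), tr$tip.label)
  expect_error(fit_model(tr, const, "BM.s"), "degenerate")

  uneven <- read_newick("((A:1,B:2):1,C:4);")
  yy <- c(A = 0.1, B = 0.5, C = -0.3)
  expect_error(fit_model(uneven, yy, "OU.s"), "ultrametric")
})

test_that("model comparison selects sensibly and reports coherent weights", {
  tr <- simulate_yule_tree(57, 22, seed = 61)
  sim <- simulate_mk_regimes(tr, rate = 0.03, root_state = "bee", seed = 62)
  y <- simulate_trait(tr, "OU.poll",
                      list(theta = c(bird = 6, butterfly = 0, bee = 3,
                                     fly = -3, bee_and_butterfly = -6),
                           alpha = 0.9, sigma2 = 1),
                      painting = sim$painting, seed = 63)
  cm <- compare_models(tr, y, painting = sim$painting)
  expect_equal(sum(cm$table$weight), 1, tolerance = 1e-9)
  expect_equal(cm$best, "OU.poll")
  expect_equal(cm$table$model[which.min(cm$table$aicc)], cm$best)
  expect_s3_class(tidy(cm), "tbl_df")
  expect_equal(nrow(tidy(cm)), 6L)

  # white-noise data should not reward the phylogeny-bound model
  sel <- sapply(1:40, function(s) {
    yw <- simulate_trait(tr, "WN", list(mu = 0, s2 = 1), seed = 100 + s)
    tab <- compare_models(tr, yw, painting = sim$painting)$table
    tab$weight[tab$model == "WN"] - tab$weight[tab$model == "BM.s"]
  })
  expect_gt(median(sel), 0)
})

test_that("optimum uncertainty gives ordered, transform-respecting intervals", {
  tr <- simulate_yule_tree(57, 22, seed = 71)
  sim <- simulate_mk_regimes(tr, rate = 0.03, root_state = "bee", seed = 72)
  truth <- list(theta = c(bird = 3.6, butterfly = 1.5, bee = 1.7,
                          fly = -0.7, bee_and_butterfly = 1.25),
                alpha = 0.315, sigma2 = 1)
  y <- simulate_trait(tr, "OU.poll", truth, painting = sim$painting,
                      seed = 73)
  attr(y, "transform") <- "log"
  fit <- fit_model(tr, y, "OU.poll", painting = sim$painting)
  unc <- estimate_theta_uncertainty(fit, tr, y, painting = sim$painting)
  expect_true(all(unc$ci_lower < unc$theta & unc$theta < unc$ci_upper))
  expect_true(all(unc$ci_lower_natural < unc$theta_natural &
                    unc$theta_natural < unc$ci_upper_natural))
  expect_true(all(unc$se > 0))
  expect_equal(unc$theta_natural, exp(unc$theta))
})

test_that("standard errors shrink as a regime gains tips", {
  # two fixed star-like designs differing only in tips per regime
  make_balanced <- function(m) {
    tr <- simulate_yule_tree(2 * m, 10, seed = 81)
    sim_states <- rep(c("r1", "r2"), m)
    ts <- setNames(sim_states, tr$tip.label)
    n_all <- 2 * m + tr$Nnode
    prob <- matrix(0, n_all, 2, dimnames = list(NULL, c("r1", "r2")))
    prob[cbind(seq_len(n_all),
               c(match(sim_states, c("r1", "r2")), rep(1L, tr$Nnode)))] <- 1
    list(tree = tr, painting = paint_branches(tr, prob, ts, c("r1", "r2")))
  }
  truth <- list(theta = c(r1 = 0, r2 = 2), alpha = 1.5, sigma2 = 1)
  se_of <- function(m) {
    d <- make_balanced(m)
    y <- simulate_trait(d$tree, "OU.poll", truth, painting = d$painting,
                        seed = 82)
    fit <- fit_model(d$tree, y, "OU.poll", painting = d$painting)
    mean(estimate_theta_uncertainty(fit, d$tree, y,
                                    painting = d$painting)$se)
  }
  expect_gte(1 - se_of(28) / se_of(7), 0.2)
})

test_that("the lambda fit reports a profile interval around its estimate", {
  tr <- simulate_yule_tree(57, 22, seed = 91)
  y <- simulate_trait(tr, "Lambda", list(z0 = 0, sigma2 = 0.4, lambda = 0.6),
                      seed = 92)
  fit <- fit_model(tr, y, "Lambda")
  ci <- fit$lambda_ci
  expect_true(ci["lower"] <= fit$params$lambda)
  expect_true(ci["upper"] >= fit$params$lambda)
})
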