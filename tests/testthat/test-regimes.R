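# Mk pruning likelihood, ML rate fitting, marginal ancestral states and
# branch painting, checked against matrix-exponential and enumeration
# oracles.

test_that("pruning equals the matrix-exponential oracle on a cherry", {
  tr <- read_newick("(A:1,B:1);")
  states <- c("s1", "s2", "s3", "s4", "s5")
  ts <- c(A = "s1", B = "s3")
  for (q in c(0.05, 0.1, 0.7)) {
    expect_equal(mk_loglik(tr, ts, q, states),
                 mk_enum(tr, ts, q, states)$loglik, tolerance = 1e-10)
  }
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  withr::with_seed(7, {
    for (i in 1:8) {
      n <- sample(3:5, 1)
      k <- sample(2:4, 1)
      states <- paste0("s", seq_len(k))
      tr <- random_ultrametric_tree(n, depth = 2)
      ts <- setNames(sample(states, n, replace = TRUE), tr$tip.label)
      q <- runif(1, 0.02, 1)
      expect_equal(mk_loglik(tr, ts, q, states),
                   mk_enum(tr, ts, q, states)$loglik, tolerance = 1e-8)
    }
  })
})

test_that("likelihood is invariant under relabeling of states", {
  tr <- toy_tree()
  states <- c("x", "y", "z")
  ts <- c(A = "x", B = "y", C = "x", D = "z")
  swap <- c(x = "z", y = "x", z = "y")
  ts2 <- setNames(unname(swap[ts]), names(ts))
  expect_equal(mk_loglik(tr, ts, 0.2, states),
               mk_loglik(tr, ts2, 0.2, states), tolerance = 1e-12)
})

test_that("zero rate and monomorphic data reduce to the root draw", {
  tr <- toy_tree()
  ts <- c(A = "bee", B = "bee", C = "bee", D = "bee")
  expect_equal(mk_loglik(tr, ts, 0), log(1 / 5), tolerance = 1e-12)
  expect_warning(fit <- fit_mk_er(tr, ts), "monomorphic")
  expect_equal(fit$rate, 0)
  expect_equal(fit$loglik, log(1 / 5))
})

test_that("the ML rate maximizes the likelihood and recovers the truth", {
  tr <- toy_tree()
  ts <- c(A = "x", B = "y", C = "x", D = "z")
  fit <- fit_mk_er(tr, ts, states = c("x", "y", "z"))
  expect_gte(fit$loglik,
             mk_loglik(tr, ts, fit$rate * 0.5, c("x", "y", "z")))
  expect_gte(fit$loglik,
             mk_loglik(tr, ts, fit$rate * 2, c("x", "y", "z")))

  # recovery: q = 0.05 on 200-tip unit-depth... use depth 10 so q*T = 0.5
  rates <- sapply(1:100, function(s) {
    t200 <- simulate_yule_tree(200, 10, seed = 5000 + s)
    sim <- simulate_mk_regimes(t200, states = c("a", "b", "c"), rate = 0.05,
                               seed = 6000 + s)
    if (length(unique(sim$tip_states)) < 2) return(NA_real_)
    fit_mk_er(t200, sim$tip_states, states = c("a", "b", "c"))$rate
  })
  expect_gte(median(rates, na.rm = TRUE), 0.025)
  expect_lte(median(rates, na.rm = TRUE), 0.10)
})

test_that("the ML rate agrees with an independent reference implementation", {
  tr <- simulate_yule_tree(40, 22, seed = 901)
  sim <- simulate_mk_regimes(tr, rate = 0.03, root_state = "bee", seed = 902)
  fit <- fit_mk_er(tr, sim$tip_states)
  ref <- ape::ace(sim$tip_states[tr$tip.label], tr, type = "discrete",
                  model = "ER")
  expect_equal(fit$rate, unname(ref$rates), tolerance = 1e-4)
  # the reference omits the uniform root prior factor of 1/k
  expect_equal(fit$loglik - ref$loglik, log(1 / 5), tolerance = 1e-4)
})

test_that("marginal reconstruction matches enumeration and its symmetries", {
  # symmetric cherry: root equally torn between the two observed states
  cherry <- read_newick("(A:1,B:1);")
  pr <- marginal_asr(cherry, c(A = "p", B = "q"), 0.3, c("p", "q"))
  expect_equal(pr[3, 1], pr[3, 2], tolerance = 1e-12)
  # tips are point masses
  expect_equal(pr[1, ], c(p = 1, q = 0), ignore_attr = TRUE)

  # near-zero rate with uniform tips concentrates every node
  tr <- toy_tree()
  mono <- c(A = "p", B = "p", C = "p", D = "p")
  pr0 <- marginal_asr(tr, mono, 1e-9, c("p", "q"))
  expect_true(all(pr0[, 1] > 1 - 1e-6))

  withr::with_seed(13, {
    for (i in 1:5) {
      tr4 <- random_ultrametric_tree(4, depth = 1.5)
      states <- c("u", "v", "w")
      ts <- setNames(sample(states, 4, replace = TRUE), tr4$tip.label)
      q <- runif(1, 0.05, 0.8)
      mine <- marginal_asr(tr4, ts, q, states)
      oracle <- mk_enum(tr4, ts, q, states)$post
      expect_equal(unname(mine), unname(oracle), tolerance = 1e-8)
    }
  })
})

test_that("painting follows argmax with the deterministic tie rule", {
  cherry <- read_newick("(A:1,B:1);")
  states <- c("p", "q")
  ts <- c(A = "q", B = "p")
  prob <- rbind(c(0, 1), c(1, 0), c(0.5, 0.5))
  p <- paint_branches(cherry, prob, ts, states)
  expect_equal(p$root_regime, "p")        # tie broken to the lowest index
  expect_setequal(p$edge_regime, c("p", "q"))

  conc <- rbind(c(0, 1), c(0, 1), c(0, 1))
  p2 <- paint_branches(cherry, conc, c(A = "q", B = "q"), states)
  expect_true(all(p2$edge_regime == "q"))
  expect_equal(p2$root_regime, "q")
})

test_that("reconstruction recovers most true node states at moderate rates", {
  hits <- sapply(1:60, function(s) {
    tr <- simulate_yule_tree(57, 22, seed = 7000 + s)
    sim <- simulate_mk_regimes(tr, rate = 0.02, root_state = "bee",
                               seed = 8000 + s)
    if (length(unique(sim$tip_states)) < 2) return(NA_real_)
    pa <- suppressMessages(suppressWarnings(
      reconstruct_regimes(tr, sim$tip_states)))
    idx <- 58:113  # internal nodes
    mean(pa$node_states[idx] == sim$node_states[idx])
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})
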