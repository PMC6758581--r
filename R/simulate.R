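# Synthetic-data generators: Yule chronograms, Mk regime histories and
# trait data under each candidate evolutionary model. Everything is a pure
# function of its inputs and seed.

with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Simulate a Yule (pure-birth) chronogram with a fixed crown age
#'
#' Forward simulation: starting from the crown split, each of `k` extant
#' lineages waits an exponential time with total rate `k`, a uniformly
#' chosen lineage splits, and after `n_tips` lineages are reached one final
#' exponential wait sets the present; all node times are then rescaled so
#' the root-to-tip distance equals `crown_age`. The unscaled
#' inter-speciation waits are kept in the `"waits"` attribute (together
#' with `"k_at_wait"`), so the Yule property that `k * wait` is standard
#' exponential remains checkable after rescaling.
#'
#' @param n_tips Number of tips (at least 2).
#' @param crown_age Root-to-tip distance in Ma.
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @return An ultrametric, strictly bifurcating `phylo` with tip labels
#'   `sp01`, `sp02`, ...
#' @export
simulate_yule_tree <- function(n_tips, crown_age = 22, seed = NULL) {
  stopifnot(n_tips >= 2, crown_age > 0)
  with_seed_local(seed, {
    parent <- c(NA_integer_, 1L, 1L)
    birth <- c(0, 0, 0)
    death <- rep(NA_real_, 3L)
    active <- c(2L, 3L)
    t_now <- 0
    waits <- numeric(0)
    k_at <- integer(0)
    nid <- 3L
    while (length(active) < n_tips) {
      k <- length(active)
      w <- rexp(1L, rate = k)
      waits <- c(waits, w)
      k_at <- c(k_at, k)
      t_now <- t_now + w
      split <- active[sample.int(k, 1L)]
      death[split] <- t_now
      parent <- c(parent, split, split)
      birth <- c(birth, t_now, t_now)
      death <- c(death, NA_real_, NA_real_)
      active <- c(setdiff(active, split), nid + 1L, nid + 2L)
      nid <- nid + 2L
    }
    w <- rexp(1L, rate = n_tips)
    waits <- c(waits, w)
    k_at <- c(k_at, n_tips)
    t_now <- t_now + w
    death[active] <- t_now
    sc <- crown_age / t_now
    birth <- birth * sc
    death <- death * sc

    tip_ids <- sort(active)
    int_ids <- setdiff(which(!is.na(parent) | seq_along(parent) == 1L),
                       tip_ids)
    int_ids <- c(1L, setdiff(int_ids, 1L))
    map <- integer(nid)
    map[tip_ids] <- seq_len(n_tips)
    map[int_ids] <- n_tips + seq_along(int_ids)
    nonroot <- setdiff(seq_len(nid), 1L)
    edge <- cbind(map[parent[nonroot]], map[nonroot])
    elen <- death[nonroot] - birth[nonroot]
    w <- max(2L, nchar(as.character(n_tips)))
    tree <- list(edge = edge, edge.length = elen,
                 tip.label = sprintf(paste0("sp%0", w, "d"), seq_len(n_tips)),
                 Nnode = n_tips - 1L)
    class(tree) <- "phylo"
    tree <- ape::reorder.phylo(tree, "cladewise")
    attr(tree, "waits") <- waits
    attr(tree, "k_at_wait") <- k_at
    attr(tree, "requested_crown_age") <- crown_age
    tree
  })
}

#' Simulate a discrete regime history under the equal-rates Mk model
#'
#' States jump along each branch as a continuous-time Markov chain with
#' total leave rate `(k - 1) * rate` and a uniform choice among the other
#' states. Both the node states and the full within-branch change points
#' are returned; the collapsed painting assigns each branch the state of
#' its tipward endpoint, matching the convention of the reconstruction
#' stage.
#'
#' @param tree A `phylo` with branch lengths.
#' @param states Character vector of states (default the five syndromes).
#' @param rate Per-pair transition rate (per Ma), nonnegative.
#' @param root_state State at the root (default the first state).
#' @param seed Optional integer seed.
#' @return List with `tip_states` (named character), `node_states`
#'   (character, all nodes), `painting` (a `regime_painting` from the true
#'   history), and `segments` (per-edge tibbles with `len` and `regime`,
#'   rootward first).
#' @export
simulate_mk_regimes <- function(tree, states = syndrome_levels(), rate,
                                root_state = states[1L], seed = NULL) {
  stopifnot(rate >= 0, root_state %in% states)
  k <- length(states)
  with_seed_local(seed, {
    n_tip <- ape::Ntip(tree)
    n_all <- n_tip + tree$Nnode
    node_states <- character(n_all)
    node_states[n_tip + 1L] <- root_state
    segments <- vector("list", nrow(tree$edge))
    ord <- ape::reorder.phylo(tree, "cladewise")
    eord <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                  paste(tree$edge[, 1L], tree$edge[, 2L]))
    leave <- (k - 1L) * rate
    for (j in seq_len(nrow(ord$edge))) {
      e <- eord[j]
      p <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      s <- node_states[p]
      remaining <- len
      seg_len <- numeric(0)
      seg_reg <- character(0)
      repeat {
        w <- if (leave > 0) rexp(1L, leave) else Inf
        if (w >= remaining) {
          seg_len <- c(seg_len, remaining)
          seg_reg <- c(seg_reg, s)
          break
        }
        seg_len <- c(seg_len, w)
        seg_reg <- c(seg_reg, s)
        remaining <- remaining - w
        s <- sample(setdiff(states, s), 1L)
      }
      segments[[e]] <- tibble(len = seg_len, regime = seg_reg)
      node_states[ch] <- s
    }
    tip_states <- setNames(node_states[seq_len(n_tip)], tree$tip.label)
    prob <- matrix(0, n_all, k, dimnames = list(NULL, states))
    prob[cbind(seq_len(n_all), match(node_states, states))] <- 1
    painting <- paint_branches(tree, prob, tip_states, states)
    list(tip_states = tip_states, node_states = node_states,
         painting = painting, segments = segments)
  })
}

#' Simulate a continuous trait under one of the six evolutionary models
#'
#' Recursive root-to-tip simulation. White noise draws iid values at the
#' tips; BM adds Gaussian increments with variance `sigma2 * t`; the lambda
#' model runs BM on the lambda-transformed tree; BM.rate uses the regime's
#' rate on each branch (segment-wise when a `segments` history is given);
#' OU updates segment-wise with
#' `x' ~ Normal(theta + (x - theta) e^{-alpha t}, sigma2 (1 - e^{-2 alpha t}) / (2 alpha))`.
#'
#' @param tree A `phylo` with branch lengths.
#' @param model Model name, see [evo_models()].
#' @param params Parameter list as in [model_loglik()]; the root state
#'   `z0` defaults to `theta` (root regime's optimum for OU.poll).
#' @param painting `regime_painting` for OU.poll / BM.rate.
#' @param segments Optional per-edge regime segments from
#'   [simulate_mk_regimes()]; used instead of the painting when supplied.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, model, params, painting = NULL,
                           segments = NULL, seed = NULL) {
  model <- match.arg(model, EVO_MODELS)
  if (model %in% c("OU.poll", "BM.rate") && is.null(painting) &&
      is.null(segments)) {
    abort(paste0(model, " requires a painting or segment history"))
  }
  if (model %in% c("OU.s", "OU.poll") && params$alpha <= 0) {
    abort("alpha must be positive")
  }
  with_seed_local(seed, {
    n_tip <- ape::Ntip(tree)
    if (model == "WN") {
      return(setNames(rnorm(n_tip, params$mu, sqrt(params$s2)),
                      tree$tip.label))
    }
    if (model == "Lambda") {
      tr2 <- lambda_transform_tree(tree, params$lambda)
      return(simulate_trait(tr2, "BM.s",
                            list(z0 = params$z0, sigma2 = params$sigma2)))
    }
    n_all <- n_tip + tree$Nnode
    x <- numeric(n_all)
    root <- n_tip + 1L
    x[root] <- params$z0 %||% switch(model,
      "OU.s" = params$theta,
      "OU.poll" = params$theta[[if (!is.null(painting)) painting$root_regime
                                else segments[[1L]]$regime[1L]]],
      abort("z0 required for BM models"))
    ord <- ape::reorder.phylo(tree, "cladewise")
    eord <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                  paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (j in seq_len(nrow(ord$edge))) {
      e <- eord[j]
      p <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      segs <- if (!is.null(segments)) {
        segments[[e]]
      } else if (!is.null(painting)) {
        list(len = len, regime = painting$edge_regime[e])
      } else {
        list(len = len, regime = NA_character_)
      }
      v <- x[p]
      if (model == "BM.s") {
        v <- v + rnorm(1L, 0, sqrt(params$sigma2 * len))
      } else if (model == "BM.rate") {
        s2 <- sum(params$sigma2[segs$regime] * segs$len)
        v <- v + rnorm(1L, 0, sqrt(s2))
      } else { # OU.s / OU.poll
        a <- params$alpha
        s2 <- params$sigma2
        for (i in seq_along(segs$len)) {
          th <- if (model == "OU.s") params$theta
                else params$theta[[segs$regime[i]]]
          dt <- segs$len[i]
          m <- th + (v - th) * exp(-a * dt)
          sdv <- sqrt(s2 * (1 - exp(-2 * a * dt)) / (2 * a))
          v <- rnorm(1L, m, sdv)
        }
      }
      x[ch] <- v
    }
    setNames(x[seq_len(n_tip)], tree$tip.label)
  })
}

# deterministic sub-seed stream, kept within 32-bit integer range
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% 2147483593) + 1L
}

# OU simulation whose terminal-branch draws are truncated to [lo, hi] on
# the analysis scale: internal nodes follow the exact transition law, tip
# values are redrawn (bounded retries) until they fall inside the envelope.
# Used by the study-like generator to respect the published trait range.
sim_ou_truncated <- function(tree, model, params, painting, lo, hi, seed) {
  with_seed_local(seed, {
    n_tip <- ape::Ntip(tree)
    n_all <- n_tip + tree$Nnode
    x <- numeric(n_all)
    root <- n_tip + 1L
    a <- params$alpha
    s2 <- params$sigma2
    theta_of <- function(e) {
      if (model == "OU.s") params$theta else
        params$theta[[painting$edge_regime[e]]]
    }
    x[root] <- if (model == "OU.s") params$theta else
      params$theta[[painting$root_regime]]
    ord <- ape::reorder.phylo(tree, "cladewise")
    eord <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                  paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (j in seq_len(nrow(ord$edge))) {
      e <- eord[j]
      p <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      dt <- tree$edge.length[e]
      th <- theta_of(e)
      m <- th + (x[p] - th) * exp(-a * dt)
      sdv <- sqrt(s2 * (1 - exp(-2 * a * dt)) / (2 * a))
      if (ch <= n_tip) {
        for (try in seq_len(1000L)) {
          v <- rnorm(1L, m, sdv)
          if (v >= lo && v <= hi) break
          v <- NA_real_
        }
        if (is.na(v)) abort("truncated tip draw failed; envelope unreachable")
      } else {
        v <- rnorm(1L, m, sdv)
      }
      x[ch] <- v
    }
    setNames(x[seq_len(n_tip)], tree$tip.label)
  })
}

aa_names <- function() {
  c("ala", "arg", "asn", "asp", "cys", "gaba", "gln", "glu", "gly", "his",
    "ile", "leu", "lys", "met", "orn", "phe", "pro", "ser", "thr", "trp",
    "tyr", "val")
}

study_trait_defaults <- function() {
  list(
    volume_ul = list(model = "OU.poll", transform = "log",
                     theta_natural = c(bird = 37.1, butterfly = 4.5,
                                       bee = 5.5, fly = 0.5,
                                       bee_and_butterfly = 3.5),
                     sigma2 = 5.42, alpha = 14.9,
                     range = c(0.06, 72.16)),
    sugar_pct = list(model = "OU.poll", transform = "logit",
                     theta_natural = c(bird = 0.15, butterfly = 0.30,
                                       bee = 0.36, fly = 0.04,
                                       bee_and_butterfly = 0.25),
                     sigma2 = 29.4, alpha = 15.0,
                     range = c(0.73, 76.9)),
    nsp_pct = list(model = "OU.poll", transform = "logit",
                   theta_natural = c(bird = 0.991, butterfly = 0.85,
                                     bee = 0.80, fly = 0.32,
                                     bee_and_butterfly = 0.82),
                   sigma2 = 58.1, alpha = 14.9,
                   range = c(25.2, 99.8)),
    aa_mm = list(model = "OU.s", transform = "log",
                 theta_natural = 3.40,
                 sigma2 = 0.26, alpha = 0.45,
                 range = c(0.20, 69.70))
  )
}

#' Generate a study-like synthetic dataset
#'
#' Produces a bundle shaped like the study design: a Yule chronogram (57
#' tips, 22 Ma crown age by default), a five-syndrome Mk regime history
#' (conditioned on all five syndromes being present at the tips), and
#' nectar traits simulated under the per-syndrome OU model (volume, sugar
#' concentration, sucrose proportion) or single-optimum OU (amino-acid
#' concentration) with optima and process parameters at the magnitudes the
#' analyses target; tip values are drawn from the OU transition law
#' truncated to the published trait envelope
#' (volume 0.06-72.16 uL, sugar 0.73-76.9%, sucrose proportion 25.2-99.8%,
#' amino acids 0.20-69.70 mM). Amino-acid composition (22 fractions summing
#' to 100%, with structural zeros for rare amino acids) and spur lengths
#' (48-species subset, allometrically tied to volume) complete the table.
#'
#' @param seed Integer seed; the bundle is a pure function of it.
#' @param n_tips,crown_age Tree size and age (defaults 57 tips, 22 Ma; the
#'   alternative total tree length 23.7 can be requested).
#' @param mk_rate Per-pair syndrome transition rate per Ma.
#' @return List with `tree` (`phylo`), `traits` (tibble in the trait-table
#'   layout), `syndromes` (named character), `painting` (true
#'   `regime_painting`), `segments`, and `config` (the generating
#'   parameters).
#' @export
generate_study_like_dataset <- function(seed = 42, n_tips = 57,
                                        crown_age = 22, mk_rate = 0.03) {
  tree <- simulate_yule_tree(n_tips, crown_age, seed = sub_seed(seed, 1L))
  reg <- NULL
  for (j in seq_len(200L)) {
    cand <- simulate_mk_regimes(tree, rate = mk_rate, root_state = "bee",
                                seed = sub_seed(seed, 10L + j))
    if (length(unique(cand$tip_states)) == 5L) { reg <- cand; break }
  }
  if (is.null(reg)) abort("could not realize all five syndromes; raise mk_rate")

  defs <- study_trait_defaults()
  sim_one <- function(def, offset_base) {
    theta <- if (def$transform == "log") log(def$theta_natural)
             else stats::qlogis(def$theta_natural)
    params <- list(theta = theta, alpha = def$alpha, sigma2 = def$sigma2)
    bounds <- if (def$transform == "log") log(def$range)
              else stats::qlogis(def$range / 100)
    y <- sim_ou_truncated(tree, def$model, params,
                          painting = reg$painting,
                          lo = bounds[1L], hi = bounds[2L],
                          seed = sub_seed(seed, offset_base))
    if (def$transform == "log") exp(y) else 100 * stats::plogis(y)
  }
  volume <- sim_one(defs$volume_ul, 1000L)
  sugar <- sim_one(defs$sugar_pct, 3000L)
  nsp <- sim_one(defs$nsp_pct, 5000L)
  aa <- sim_one(defs$aa_mm, 7000L)

  # 22 amino-acid fractions (% of total), with structural zeros
  frac <- with_seed_local(sub_seed(seed, 9001L), {
    base_mean <- seq(1.5, -2.5, length.out = 22L)
    names(base_mean) <- aa_names()
    base_mean[c("met", "tyr", "trp")] <- -4
    m <- sapply(aa_names(), function(a) exp(rnorm(n_tips, base_mean[[a]], 1.2)))
    m <- m / rowSums(m) * 100
    m[m < 0.3] <- 0
    m <- m / rowSums(m) * 100
    rownames(m) <- tree$tip.label
    m
  })

  # spur lengths for a 48-species subset, allometric in volume
  spur <- with_seed_local(sub_seed(seed, 9501L), {
    lts <- 0.4 + 0.6 * log(volume) + rnorm(n_tips, 0, 0.3)
    total <- exp(lts)
    miss <- sample.int(n_tips, max(0L, n_tips - 48L))
    total[miss] <- NA_real_
    cbind(spur_mm = 0.8 * total, total_spur_mm = total)
  })

  traits <- tibble(
    species = tree$tip.label,
    syndrome = unname(reg$tip_states[tree$tip.label]),
    volume_ul = unname(volume[tree$tip.label]),
    sugar_pct = unname(sugar[tree$tip.label]),
    nsp_pct = unname(nsp[tree$tip.label]),
    aa_mm = unname(aa[tree$tip.label])
  )
  frac_tbl <- as_tibble(frac)
  names(frac_tbl) <- paste0("aa_frac_", aa_names())
  traits <- dplyr::bind_cols(traits, frac_tbl,
                             as_tibble(spur))
  list(tree = tree, traits = traits, syndromes = reg$tip_states,
       painting = reg$painting, segments = reg$segments,
       config = list(seed = seed, n_tips = n_tips, crown_age = crown_age,
                     mk_rate = mk_rate, trait_defaults = defs))
}

#' Write a synthetic bundle to disk
#'
#' Writes the tree as Newick, the trait table as CSV (with seed recorded in
#' a comment header), and the generating configuration as YAML.
#'
#' @param bundle List from [generate_study_like_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(dir, "tree.nwk")
  traits_path <- file.path(dir, "traits.csv")
  config_path <- file.path(dir, "config.yaml")
  write_newick(bundle$tree, tree_path)
  con <- file(traits_path, "w")
  writeLines(paste0("# seed: ", bundle$config$seed), con)
  write.csv(bundle$traits, con, row.names = FALSE)
  close(con)
  cfg <- bundle$config
  cfg$trait_defaults <- lapply(cfg$trait_defaults, function(d) {
    d$theta_natural <- as.list(d$theta_natural)
    d$range <- as.list(d$range)
    d
  })
  yaml::write_yaml(cfg, config_path)
  invisible(c(tree = tree_path, traits = traits_path, config = config_path))
}
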