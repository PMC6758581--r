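# Configuration-driven orchestration: one call reproduces the full
# analysis (model comparison, OU parameters and optima, PGLS reports,
# PCA / UPGMA / Mantel stage) on user data or a synthetic bundle.

#' Reconcile a tree with a trait table
#'
#' Reports species present in only one of the two inputs, proportion traits
#' containing zeros (which trigger a logit offset downstream), and the
#' ultrametricity verdict. Errors if the species sets are disjoint.
#'
#' @param tree A `phylo`.
#' @param traits Trait tibble with a `species` column.
#' @param syndromes Optional named syndrome vector (defaults to the
#'   `syndrome` column).
#' @param ultra_tol Relative ultrametricity tolerance.
#' @return Object of class `validation_report`: list with `shared`,
#'   `only_tree`, `only_table`, `zero_proportion_traits`, `ultrametric`,
#'   `max_rel_dev`, `notes` (tibble).
#' @export
validate_inputs <- function(tree, traits, syndromes = NULL, ultra_tol = 1e-3) {
  stopifnot(inherits(tree, "phylo"), "species" %in% names(traits))
  sp_tree <- tree$tip.label
  sp_tab <- traits$species
  shared <- intersect(sp_tree, sp_tab)
  if (length(shared) == 0L) abort("tree and trait table share no species")
  only_tree <- setdiff(sp_tree, sp_tab)
  only_table <- setdiff(sp_tab, sp_tree)
  prop_cols <- grep("_pct$|^aa_frac_", names(traits), value = TRUE)
  zero_traits <- prop_cols[vapply(prop_cols, function(cl) {
    any(!is.na(traits[[cl]]) & traits[[cl]] == 0)
  }, logical(1))]
  um <- is_ultrametric_rel(tree, ultra_tol)
  notes <- dplyr::bind_rows(
    if (length(only_tree)) tibble(kind = "pruned_from_tree",
                                  detail = paste(only_tree, collapse = ", ")),
    if (length(only_table)) tibble(kind = "dropped_from_table",
                                   detail = paste(only_table, collapse = ", ")),
    if (length(zero_traits)) tibble(kind = "zero_proportion_offset",
                                    detail = paste0(zero_traits, collapse = ", ")),
    tibble(kind = "ultrametric",
           detail = paste0(isTRUE(um), " (max relative deviation ",
                           format(attr(um, "max_rel_dev"), digits = 3), ")"))
  )
  out <- list(shared = shared, only_tree = only_tree,
              only_table = only_table,
              zero_proportion_traits = zero_traits,
              ultrametric = isTRUE(um),
              max_rel_dev = attr(um, "max_rel_dev"),
              notes = notes)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation:", length(x$shared), "shared species\n")
  print(as.data.frame(x$notes))
  invisible(x)
}

# Transform the main nectar traits to their analysis scales; zeros in the
# percentage traits get the 0.001 offset, amino-acid fractions always the
# 0.01 offset, both on the proportion scale.
transform_study_traits <- function(traits) {
  out <- list()
  sp <- traits$species
  grab <- function(cl) setNames(traits[[cl]], sp)
  if ("volume_ul" %in% names(traits)) {
    out$volume <- transform_trait(grab("volume_ul"), "log")
  }
  if ("aa_mm" %in% names(traits)) {
    out$aa <- transform_trait(grab("aa_mm"), "log")
  }
  for (cl in c("sugar_pct", "nsp_pct")) {
    if (cl %in% names(traits)) {
      v <- grab(cl)
      off <- if (any(v == 0, na.rm = TRUE)) 0.001 else 0
      out[[sub("_pct$", "", cl)]] <- transform_trait(v, "logit", offset = off,
                                                     from_percent = TRUE)
    }
  }
  frac_cols <- grep("^aa_frac_", names(traits), value = TRUE)
  if (length(frac_cols)) {
    out$aa_fracs <- sapply(frac_cols, function(cl) {
      transform_trait(grab(cl), "logit", offset = 0.01, from_percent = TRUE)
    })
    rownames(out$aa_fracs) <- sp
  }
  out
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

write_report_csv <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  writeLines(c(paste0("# seed: ", seed),
               paste0("# config_hash: ", config_hash)), con)
  write.csv(as.data.frame(df), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full comparative analysis
#'
#' Orchestrates the entire pipeline on either user inputs (tree + trait
#' table) or a synthetic bundle, and writes six report files to
#' `out_dir`: `model_comparison.csv` (six models x analysed traits, AICc
#' and Akaike weights), `ou_parameters.csv` (sigma2, alpha, half-life for
#' best-fitting OU models), `optima.csv` (per-syndrome optima with s.e. and
#' back-transformed 95% CI), `pgls.csv` (regression reports), `
#' multivariate_report.csv` (PCA variance, Mantel, dendrogram lambda
#' signal) and `run_log.json`. Supporting artifacts (dendrogram Newick,
#' PCA scores, regime painting) go into `out_dir/details/`.
#'
#' @param config A list or path to a YAML file with fields: exactly one of
#'   `tree` + `traits` (paths or objects) or `simulation` (list with
#'   `seed`, optionally `n_tips`, `crown_age`, `mk_rate`); optional `seed`
#'   (analysis seed, default 1), `n_perm` (default 9999), `out_dir`
#'   (default `tempfile()`), `ultra_tol`.
#' @return Invisibly, a list with all fitted objects and the report paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_paths <- !is.null(config$tree) && !is.null(config$traits)
  has_sim <- !is.null(config$simulation)
  if (has_paths == has_sim) {
    abort("config must contain exactly one of {tree+traits, simulation}")
  }
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 9999L
  ultra_tol <- config$ultra_tol %||% 1e-3
  out_dir <- config$out_dir %||% tempfile("nectarevo_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  details_dir <- file.path(out_dir, "details")
  dir.create(details_dir, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(name, t) timings[[name]] <<- as.numeric(Sys.time() - t,
                                                          units = "secs")

  # ---- inputs ----
  t <- tic()
  if (has_sim) {
    sim <- config$simulation
    bundle <- run_stage("simulate", generate_study_like_dataset(
      seed = sim$seed %||% seed,
      n_tips = sim$n_tips %||% 57L,
      crown_age = sim$crown_age %||% 22,
      mk_rate = sim$mk_rate %||% 0.03))
    tree <- bundle$tree
    traits <- bundle$traits
    syndromes <- bundle$syndromes
  } else {
    tree <- if (inherits(config$tree, "phylo")) config$tree
            else run_stage("read_tree", read_newick(config$tree))
    tt <- run_stage("read_traits", read_trait_table(config$traits))
    traits <- tt$traits
    syndromes <- tt$syndromes
  }
  report <- run_stage("validate", validate_inputs(tree, traits, syndromes,
                                                  ultra_tol))
  shared <- report$shared
  if (length(report$only_tree)) tree <- ape::drop.tip(tree, report$only_tree)
  traits <- traits[traits$species %in% shared, , drop = FALSE]
  syndromes <- syndromes[shared]
  toc("inputs", t)

  # ---- transforms and composition PCAs ----
  t <- tic()
  tv <- run_stage("transform", transform_study_traits(traits))
  # amino acids absent from (or identical in) every species carry no
  # compositional information and would break a correlation PCA
  aa_keep <- apply(tv$aa_fracs, 2L, stats::var) > 0
  if (any(!aa_keep)) {
    inform(paste0("dropping ", sum(!aa_keep),
                  " constant amino-acid fraction columns before PCA"))
  }
  aa_pca <- run_stage("aa_pca",
                      nectar_pca(tv$aa_fracs[, aa_keep, drop = FALSE],
                                 scale = TRUE))
  aa_axes <- as.matrix(aa_pca$scores[, c("PC1", "PC2", "PC3")])
  rownames(aa_axes) <- aa_pca$scores$species
  main_mat <- cbind(volume = as.numeric(tv$volume),
                    sugar = as.numeric(tv$sugar),
                    nsp = as.numeric(tv$nsp),
                    aa = as.numeric(tv$aa))
  rownames(main_mat) <- traits$species
  nectar_all <- cbind(main_mat[rownames(aa_axes), , drop = FALSE], aa_axes)
  nectar_all <- nectar_all[stats::complete.cases(nectar_all), , drop = FALSE]
  nect_pca <- run_stage("nectar_pca", nectar_pca(nectar_all, scale = TRUE))
  nect_axes <- as.matrix(nect_pca$scores[, c("PC1", "PC2", "PC3")])
  rownames(nect_axes) <- nect_pca$scores$species
  toc("pca", t)

  # ---- regimes ----
  t <- tic()
  painting <- run_stage("regimes", reconstruct_regimes(tree, syndromes))
  utils::write.csv(as.data.frame(as_tibble(painting)),
                   file.path(details_dir, "regime_painting.csv"),
                   row.names = FALSE)
  toc("regimes", t)

  # ---- model comparison over the ten analysed variables ----
  t <- tic()
  variables <- c(
    list(volume = tv$volume, sugar = tv$sugar, aa = tv$aa, nsp = tv$nsp),
    setNames(lapply(1:3, function(i) setNames(aa_axes[, i],
                                              rownames(aa_axes))),
             paste0("aa_pc", 1:3)),
    setNames(lapply(1:3, function(i) setNames(nect_axes[, i],
                                              rownames(nect_axes))),
             paste0("nectar_pc", 1:3))
  )
  comparisons <- lapply(variables, function(y) {
    run_stage("fit_models",
              compare_models(tree, y[!is.na(y)], painting = painting,
                             ultra_tol = ultra_tol))
  })
  comp_tbl <- dplyr::bind_rows(
    lapply(names(comparisons),
           function(nm) dplyr::mutate(tidy(comparisons[[nm]]), trait = nm,
                                      .before = 1))
  )
  toc("models", t)

  # ---- OU parameters and optima for the best OU fits ----
  t <- tic()
  transform_of <- c(volume = "log", aa = "log", sugar = "logit",
                    nsp = "logit")
  par_rows <- list()
  opt_rows <- list()
  for (nm in names(comparisons)) {
    cm <- comparisons[[nm]]
    if (!cm$best %in% c("OU.s", "OU.poll")) next
    fit <- cm$fits[[cm$best]]
    par_rows[[nm]] <- tibble(trait = nm, model = cm$best,
                             sigma2 = fit$params$sigma2,
                             alpha = fit$params$alpha,
                             half_life = fit$half_life)
    y <- variables[[nm]]
    unc <- run_stage("optima", estimate_theta_uncertainty(
      fit, tree, y[!is.na(y)],
      painting = if (cm$best == "OU.poll") painting,
      transform = if (nm %in% names(transform_of)) transform_of[[nm]],
      offset = attr(tv[[nm]], "offset") %||% 0,
      from_percent = attr(tv[[nm]], "from_percent") %||% FALSE,
      seed = seed))
    opt_rows[[nm]] <- dplyr::mutate(unc, trait = nm, model = cm$best,
                                    .before = 1)
  }
  par_tbl <- if (length(par_rows)) dplyr::bind_rows(par_rows) else
    tibble(trait = character(), model = character(), sigma2 = numeric(),
           alpha = numeric(), half_life = numeric())
  opt_tbl <- if (length(opt_rows)) dplyr::bind_rows(opt_rows) else tibble()
  toc("optima", t)

  # ---- PGLS reports ----
  t <- tic()
  pgls_rows <- list()
  pgls_fits <- list()
  if (all(c("volume_ul", "total_spur_mm", "syndrome") %in% names(traits)) ||
      all(c("volume_ul", "total_spur_mm") %in% names(traits))) {
    dat <- data.frame(species = traits$species,
                      syndrome = unname(syndromes[traits$species]),
                      log_volume = log(traits$volume_ul),
                      log_total_spur = log(traits$total_spur_mm))
    if ("nsp_pct" %in% names(traits)) {
      dat$logit_nsp <- as.numeric(tv$nsp[traits$species])
    }
    specs <- list(
      volume_spur = log_volume ~ log_total_spur,
      volume_syndrome_spur = log_volume ~ syndrome + log_total_spur
    )
    if (!is.null(dat$logit_nsp)) {
      specs$nsp_syndrome_spur <- logit_nsp ~ syndrome + log_total_spur
    }
    for (nm in names(specs)) {
      f <- run_stage("pgls", pgls_fit(dat, specs[[nm]], tree, lambda = "ML"))
      pgls_fits[[nm]] <- f
      pgls_rows[[nm]] <- dplyr::mutate(tidy(f), model = nm,
                                       lambda = f$lambda, aicc = f$aicc,
                                       .before = 1)
    }
  }
  pgls_tbl <- if (length(pgls_rows)) dplyr::bind_rows(pgls_rows) else
    tibble(model = character())
  toc("pgls", t)

  # ---- multivariate nectar-syndrome stage ----
  t <- tic()
  clust_mat <- scale(nectar_all)
  D_nectar <- dist(clust_mat)
  dendro <- run_stage("upgma", upgma(D_nectar))
  D_syn <- syndrome_distance_matrix(syndromes[rownames(nectar_all)])
  mant <- run_stage("mantel",
                    mantel_test(as.matrix(D_nectar), D_syn,
                                n_perm = n_perm, seed = seed))
  lamsig <- run_stage("dendrogram_lambda",
                      dendrogram_lambda_signal(dendro,
                                               syndromes[dendro$tip.label]))
  write_newick(dendro, file.path(details_dir, "dendrogram.nwk"))
  utils::write.csv(as.data.frame(nect_pca$scores),
                   file.path(details_dir, "nectar_pca_scores.csv"),
                   row.names = FALSE)
  multiv_tbl <- tibble(
    metric = c("aa_pca_var_axis1", "aa_pca_var_axis2", "aa_pca_var_axis3",
               "nectar_pca_var_axis1", "nectar_pca_var_axis2",
               "nectar_pca_var_axis3",
               "mantel_r", "mantel_p", "mantel_n_perm",
               "dendrogram_lambda", "dendrogram_lrt", "dendrogram_p"),
    value = c(aa_pca$variance_explained[1:3],
              nect_pca$variance_explained[1:3],
              mant$r, mant$p, mant$n_perm,
              lamsig$lambda, lamsig$lrt, lamsig$p)
  )
  toc("multivariate", t)

  # ---- reports ----
  paths <- c(
    model_comparison = write_report_csv(comp_tbl,
      file.path(out_dir, "model_comparison.csv"), seed, cfg_hash),
    ou_parameters = write_report_csv(par_tbl,
      file.path(out_dir, "ou_parameters.csv"), seed, cfg_hash),
    optima = write_report_csv(opt_tbl,
      file.path(out_dir, "optima.csv"), seed, cfg_hash),
    pgls = write_report_csv(pgls_tbl,
      file.path(out_dir, "pgls.csv"), seed, cfg_hash),
    multivariate = write_report_csv(multiv_tbl,
      file.path(out_dir, "multivariate_report.csv"), seed, cfg_hash)
  )
  log <- list(
    package = "nectarevo",
    version = as.character(utils::packageVersion("nectarevo")),
    r_version = as.character(getRversion()),
    seed = seed, config_hash = cfg_hash,
    n_species = length(shared), n_perm = n_perm,
    timings_sec = timings,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, run_log = log_path)

  invisible(list(
    tree = tree, traits = traits, syndromes = syndromes,
    painting = painting, comparisons = comparisons,
    aa_pca = aa_pca, nectar_pca = nect_pca,
    parameters = par_tbl, optima = opt_tbl,
    pgls = pgls_fits, mantel = mant, dendrogram = dendro,
    dendrogram_lambda = lamsig, validation = report,
    report_paths = paths, out_dir = out_dir
  ))
}
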