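#' Read a species-by-trait table
#'
#' Reads a CSV or TSV table with one row per nectar sample. Required columns
#' are `species` and `syndrome` (one of the five labels in
#' [syndrome_levels()]); every other column must be numeric. Replicate rows
#' for a species (repeated flower samples) are averaged on the raw scale
#' with an informative message, matching the convention of aggregating
#' before transformation.
#'
#' @param path Path to a CSV/TSV file (delimiter inferred from the
#'   extension, `.tsv`/`.txt` means tab), or a data frame already in memory.
#' @return A list with `traits` (tibble, one row per species, averaged
#'   numeric columns) and `syndromes` (named character vector).
#' @export
read_trait_table <- function(path) {
  df <- if (is.data.frame(path)) {
    as.data.frame(path)
  } else {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    read.csv(path, sep = sep, stringsAsFactors = FALSE, comment.char = "#",
             check.names = FALSE)
  }
  if (nrow(df) == 0L) abort("empty trait table")
  if (!all(c("species", "syndrome") %in% names(df))) {
    abort("trait table needs 'species' and 'syndrome' columns")
  }
  bad_syn <- which(!df$syndrome %in% syndrome_levels())
  if (length(bad_syn)) {
    abort(paste0("unknown syndrome label '", df$syndrome[bad_syn[1L]],
                 "' in row ", bad_syn[1L], " (species ",
                 df$species[bad_syn[1L]], ")"))
  }
  trait_cols <- setdiff(names(df), c("species", "syndrome"))
  for (cl in trait_cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad)) {
        abort(paste0("non-numeric value '", v[bad[1L]], "' in column '", cl,
                     "', row ", bad[1L]))
      }
      df[[cl]] <- vn
    } else if (!is.numeric(v) && !is.logical(v)) {
      abort(paste0("column '", cl, "' is not numeric"))
    }
  }
  # syndrome must be consistent within species
  syn_by_sp <- tapply(df$syndrome, df$species, function(s) unique(s))
  multi <- names(syn_by_sp)[lengths(syn_by_sp) > 1L]
  if (length(multi)) {
    abort(paste0("conflicting syndrome labels for species: ",
                 paste(multi, collapse = ", ")))
  }
  n_rep <- table(df$species)
  if (any(n_rep > 1L)) {
    inform(paste0(sum(n_rep > 1L),
                  " species with replicate rows; raw values averaged per species"))
  }
  traits <- df |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(trait_cols),
                                   ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    as_tibble()
  syndromes <- vapply(syn_by_sp, `[[`, character(1), 1L)[traits$species]
  names(syndromes) <- traits$species
  list(traits = traits, syndromes = syndromes)
}

#' Extract one trait as a named vector, paired with a tree
#'
#' Drops species with missing values for that trait (with a message) and,
#' when a tree is supplied, restricts to species present in the tree.
#'
#' @param traits Tibble as returned by [read_trait_table()].
#' @param trait Column name.
#' @param tree Optional `phylo`; values are returned in no particular order
#'   but restricted to tree tips.
#' @return Named numeric vector.
#' @export
trait_vector <- function(traits, trait, tree = NULL) {
  stopifnot(trait %in% names(traits))
  v <- setNames(traits[[trait]], traits$species)
  miss <- names(v)[is.na(v)]
  if (length(miss)) {
    inform(paste0("dropping ", length(miss), " species with missing '", trait,
                  "': ", paste(head(miss, 5), collapse = ", "),
                  if (length(miss) > 5) ", ..." else ""))
    v <- v[!is.na(v)]
  }
  if (!is.null(tree)) {
    extra <- setdiff(names(v), tree$tip.label)
    if (length(extra)) {
      inform(paste0("dropping ", length(extra), " species absent from the tree"))
    }
    v <- v[intersect(names(v), tree$tip.label)]
  }
  v
}
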