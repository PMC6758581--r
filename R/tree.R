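#' Read a rooted phylogeny from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] adding the validity checks the
#' downstream comparative machinery relies on: unique non-empty tip labels
#' and branch lengths on every edge.
#'
#' @param x A Newick string, or the path to a file containing one tree.
#' @return A rooted `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2):0;")
#' crown_age(tr)
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tree <- if (grepl("\\(", x)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))))
  } else {
    tryCatch(ape::read.tree(file = x),
             error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))))
  }
  if (is.null(tree)) abort("Newick parse error: no tree could be read")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("branch lengths must be present and nonnegative")
  }
  lab <- tree$tip.label
  if (any(!nzchar(lab))) abort("empty tip labels")
  if (anyDuplicated(lab)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  invisible(tree)
}

#' Node depths (time from the root) for every node
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, indexed like the nodes of
#'   `tree`; the root has depth 0.
#' @export
node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  depth <- numeric(n_all)
  # preorder guarantee: parents appear before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]
    c_ <- ord$edge[i, 2L]
    depth[c_] <- depth[p] + ord$edge.length[i]
  }
  depth[root] <- 0
  depth
}

#' Crown age of a rooted tree
#'
#' The maximum root-to-tip path length, in the tree's branch-length units
#' (Ma for a chronogram).
#'
#' @param tree A `phylo` object.
#' @return A single number.
#' @export
crown_age <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Check ultrametricity within a relative tolerance
#'
#' A chronogram should have all root-to-tip paths equal to the crown age.
#' The verdict uses the maximum relative deviation
#' `max_i |depth_i - crown| / crown`.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (default `1e-3`).
#' @return Logical scalar with attribute `"max_rel_dev"`.
#' @export
is_ultrametric_rel <- function(tree, tol = 1e-3) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  ca <- max(d)
  dev <- if (ca > 0) max(abs(d - ca)) / ca else 0
  structure(dev <= tol, max_rel_dev = dev)
}

# Edge index (row of tree$edge) leading into each node; NA for the root.
parent_edge_index <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  idx <- rep(NA_integer_, n_all)
  idx[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  idx
}

# List of edge indices on the root-to-node path, rootmost first.
root_paths <- function(tree) {
  pe <- parent_edge_index(tree)
  parent_of <- integer(length(pe))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ape::Ntip(tree) + 1L
  lapply(seq_along(pe), function(v) {
    path <- integer(0)
    while (v != root) {
      e <- pe[v]
      path <- c(e, path)
      v <- parent_of[v]
    }
    path
  })
}

# Pagel lambda transform of an ultrametric tree: internal branches scaled by
# lambda, terminal branches stretched so every tip keeps its original depth.
lambda_transform_tree <- function(tree, lambda) {
  stopifnot(lambda >= 0)
  n_tip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  out <- tree
  is_term <- tree$edge[, 2L] <= n_tip
  out$edge.length[!is_term] <- tree$edge.length[!is_term] * lambda
  par <- tree$edge[is_term, 1L]
  chi <- tree$edge[is_term, 2L]
  out$edge.length[is_term] <- depth[chi] - lambda * depth[par]
  out
}

# Shared-depth matrix among tips (depth of the MRCA), plus tip depths.
tip_covariance_geometry <- function(tree) {
  V <- ape::vcv(tree)            # shared root-to-MRCA path length
  tips <- rownames(V)
  depth <- diag(V)
  list(shared = V, depth = depth, tips = tips)
}
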