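#' Read a time-calibrated phylogeny from a Newick file
#'
#' Reads a rooted tree with branch lengths (in Myr) and validates it: branch
#' lengths must be present, finite and non-negative, and tip labels unique.
#' Tip labels are normalized by converting spaces to underscores.
#'
#' @param path Path to a Newick file containing a single rooted tree.
#' @return An object of class `phylo`.
#' @seealso [validate_tree()], [prune_to()], [phylo_covariance()]
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in: ", path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("file contains ", length(tree), " trees; expected one")
    tree <- tree[[1L]]
  }
  as_phylo_tree(tree)
}

#' Coerce and validate a phylo object as a time-calibrated tree
#'
#' @param tree A `phylo` object.
#' @return The validated tree (tip labels space-normalized).
#' @export
as_phylo_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tree$tip.label <- normalize_labels(tree$tip.label)
  rep <- validate_tree(tree)
  if (!rep$ok) stop("invalid tree: ", paste(rep$errors, collapse = "; "))
  tree
}

#' Normalize species labels (spaces to underscores)
#'
#' Matching between trees and trait tables is exact and case-sensitive after
#' this normalization, the dominant Newick dialect convention.
#'
#' @param x Character vector of labels.
#' @return Normalized labels.
#' @export
normalize_labels <- function(x) gsub(" ", "_", trimws(as.character(x)))

#' Validate a phylogeny and produce a plain-text-able report
#'
#' Checks: branch lengths present, finite, non-negative; tip labels unique;
#' single root. Zero-length terminal branches are accepted but flagged (they
#' distort tip-age histograms).
#'
#' @param tree A `phylo` object.
#' @return A list with elements `ok` (logical), `errors`, `warnings`,
#'   `n_tips`, and `zero_length_tips` (labels of tips on zero-length pendant
#'   edges). Has a `format()`/`print()` method giving the plain-text report.
#' @export
validate_tree <- function(tree) {
  errors <- character()
  warnings <- character()
  if (is.null(tree$edge.length)) {
    errors <- c(errors, "branch lengths missing")
  } else {
    if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
      errors <- c(errors, "non-finite branch lengths")
    else if (any(tree$edge.length < 0))
      errors <- c(errors, "negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label))
    errors <- c(errors, "duplicate tip labels")
  zero_tips <- character()
  if (length(errors) == 0L && ape::Ntip(tree) > 1L) {
    tl <- terminal_branch_lengths(tree)
    zero_tips <- names(tl)[tl == 0]
    if (length(zero_tips))
      warnings <- c(warnings, paste0(length(zero_tips),
        " zero-length terminal branch(es): ",
        paste(utils::head(zero_tips, 5L), collapse = ", ")))
  }
  out <- list(ok = length(errors) == 0L, errors = errors, warnings = warnings,
              n_tips = ape::Ntip(tree), zero_length_tips = zero_tips)
  class(out) <- "tree_validation"
  out
}

#' @export
format.tree_validation <- function(x, ...) {
  lines <- c(
    paste0("Tree validation: ", if (x$ok) "OK" else "FAILED"),
    paste0("  tips: ", x$n_tips),
    if (length(x$errors)) paste0("  error: ", x$errors),
    if (length(x$warnings)) paste0("  warning: ", x$warnings)
  )
  paste(lines, collapse = "\n")
}

#' @export
print.tree_validation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Prune a tree to a set of tips
#'
#' Drops all tips not in `keep`, suppressing unbranched internal nodes and
#' summing their edge lengths, so root-to-tip distances of kept tips are
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (must all be present).
#' @return The pruned `phylo` object.
#' @export
prune_to <- function(tree, keep) {
  keep <- normalize_labels(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("labels not in tree: ", paste(utils::head(missing, 5L), collapse = ", "))
  if (length(keep) < 1L) stop("must keep at least one tip")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic (Brownian) covariance matrix
#'
#' Returns the n_tips x n_tips shared-path-length matrix C in Myr:
#' C\[i,j\] is the path length from the root to the most recent common
#' ancestor of tips i and j, and the diagonal holds root-to-tip distances.
#' For an ultrametric tree the diagonal is constant; for a star tree the
#' matrix is diagonal.
#'
#' @param tree A `phylo` object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (ape::Ntip(tree) == 1L) {
    d <- sum(tree$edge.length)
    return(matrix(d, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  ape::vcv(tree)
}

#' Terminal (pendant) branch lengths
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector, one value per tip: the length in Myr of the
#'   pendant edge subtending that tip.
#' @export
terminal_branch_lengths <- function(tree) {
  n <- ape::Ntip(tree)
  idx <- match(seq_len(n), tree$edge[, 2L])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}
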