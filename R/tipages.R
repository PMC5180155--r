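#' Terminal-branch-length histograms by defence group
#'
#' Density histograms of pendant edge lengths for defended and undefended
#' species on shared half-open bins \[k*w, (k+1)*w), plus a young-tip excess
#' statistic: the difference (defended minus undefended) in the proportion of
#' tips whose terminal branch is shorter than `cutoff`. If extinction-prone
#' species are younger, defended tips should be overrepresented below the
#' cutoff and the excess positive.
#'
#' @param tree A `phylo` object.
#' @param defence Named binary tip map covering every tip.
#' @param bin_width Bin width in Myr (default 5).
#' @param cutoff Young-tip cutoff in Myr (default 15).
#' @return A `tip_age_histogram`: `breaks`, per-group `counts` and
#'   `densities` (each integrating to 1 within group), group sizes,
#'   `young_tip_excess`, `cutoff`.
#' @export
tip_age_histogram <- function(tree, defence, bin_width = 5, cutoff = 15) {
  ages <- terminal_branch_lengths(tree)
  d <- .as_tip_vector(defence, tree, "defence")
  stopifnot(all(d %in% 0:1))
  if (!any(d == 1) || !any(d == 0))
    stop("both defence groups must be non-empty")
  breaks <- seq(0, (floor(max(ages) / bin_width) + 1) * bin_width, bin_width)
  grp <- list(undefended = ages[d == 0], defended = ages[d == 1])
  counts <- lapply(grp, function(a)
    as.integer(table(cut(a, breaks, right = FALSE, include.lowest = FALSE))))
  densities <- lapply(seq_along(grp), function(i)
    counts[[i]] / (length(grp[[i]]) * bin_width))
  names(densities) <- names(grp)
  excess <- mean(grp$defended < cutoff) - mean(grp$undefended < cutoff)
  structure(list(breaks = breaks, counts = counts, densities = densities,
                 n = vapply(grp, length, 0L),
                 young_tip_excess = excess, cutoff = cutoff,
                 bin_width = bin_width),
            class = "tip_age_histogram")
}

#' @export
print.tip_age_histogram <- function(x, ...) {
  cat("Terminal branch-length histogram (bin width", x$bin_width, "Myr)\n")
  cat("  n:", x$n["undefended"], "undefended,", x$n["defended"], "defended\n")
  cat(sprintf("  young-tip excess (< %g Myr, defended - undefended): %.4f\n",
              x$cutoff, x$young_tip_excess))
  invisible(x)
}

#' Permutation test for the young-tip excess
#'
#' The source analysis presents the histogram contrast qualitatively; this
#' permutation test is an addition of this package that makes the claim
#' assertable. Defence labels are permuted across tips and a two-sided
#' p-value computed for the observed excess statistic (with the +1
#' finite-sample correction).
#'
#' @param tree A `phylo` object.
#' @param defence Named binary tip map.
#' @param cutoff Young-tip cutoff in Myr.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return List with `observed`, `p_value`, `n_perm`, and a `note` flagging
#'   the test as a package addition.
#' @export
young_tip_permutation_test <- function(tree, defence, cutoff = 15,
                                       n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  ages <- terminal_branch_lengths(tree)
  d <- .as_tip_vector(defence, tree, "defence")
  young <- ages < cutoff
  obs <- mean(young[d == 1]) - mean(young[d == 0])
  set.seed(derive_seed(seed, "young_tip_permutation_test"))
  perm <- replicate(n_perm, {
    dp <- sample(d)
    mean(young[dp == 1]) - mean(young[dp == 0])
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = n_perm,
       note = paste("permutation test is an addition of this package;",
                    "the histogram contrast itself is descriptive"))
}
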