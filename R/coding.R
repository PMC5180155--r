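#' IUCN Red List category codings
#'
#' The binary "threat" coding groups LC and NT as non-threatened (0) and VU,
#' EN, CR, EW, EX as threatened (1), following IUCN recommendations. The
#' ordinal "status" coding represents increasing severity:
#' 0 = LC, 1 = NT, 2 = VU, 3 = EN, 4 = CR, 5 = EW and EX.
#' DD (data deficient) and NE (not evaluated) species cannot be coded and are
#' excluded from analysis datasets.
#'
#' @param category Character vector of IUCN category codes
#'   (LC, NT, VU, EN, CR, EW, EX; DD/NE are not codable).
#' @param allow_na If `TRUE`, DD/NE (and `NA`) return `NA` instead of an
#'   error, signalling exclusion.
#' @return Integer vector: 0/1 for `code_threat()`, 0..5 for `code_status()`.
#' @examples
#' code_threat(c("LC", "NT", "VU", "EX"))   # 0 0 1 1
#' code_status(c("LC", "NT", "VU", "EN", "CR", "EW", "EX"))  # 0 1 2 3 4 5 5
#' @export
code_threat <- function(category, allow_na = FALSE) {
  s <- code_status(category, allow_na = allow_na)
  as.integer(s >= 2L)
}

#' @rdname code_threat
#' @export
code_status <- function(category, allow_na = FALSE) {
  map <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L, EW = 5L, EX = 5L)
  category <- toupper(trimws(as.character(category)))
  out <- map[category]
  bad <- is.na(out)
  if (any(bad) && !allow_na) {
    stop("category cannot be coded (DD/NE/unknown): ",
         paste(unique(category[bad]), collapse = ", "))
  }
  unname(out)
}

#' Read a species trait table from CSV
#'
#' Expects columns `species`, `chemical_defence` (0/1) and `iucn_category`;
#' optional covariate columns `absolute_latitude`, `male_length`,
#' `female_length`. Species labels are space/underscore normalized. A sexual
#' size dimorphism index `ssd_index` = max(male, female) / min(male, female)
#' is derived where both lengths are present.
#'
#' @param path CSV file path.
#' @return A data.frame with normalized labels and any derived columns.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "chemical_defence", "iucn_category")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("trait table missing columns: ", paste(miss, collapse = ", "))
  df$species <- normalize_labels(df$species)
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if (all(c("male_length", "female_length") %in% names(df))) {
    m <- df$male_length; f <- df$female_length
    df$ssd_index <- ifelse(!is.na(m) & !is.na(f) & m > 0 & f > 0,
                           pmax(m, f) / pmin(m, f), NA_real_)
  }
  df
}

#' Build the joint analysis dataset from a trait table and a tree
#'
#' Intersects the trait table with the tree: species must be present in both,
#' have a known chemical-defence state (0/1), and carry a codable IUCN
#' category (not DD/NE). Derives the binary `threat` and ordinal `status`
#' codes, prunes the tree to the retained species, and reports per-reason
#' attrition counts so dataset filtering is auditable. The operation is
#' idempotent: applying it to its own output changes nothing.
#'
#' @param traits A trait table data.frame (see [read_trait_table()]).
#' @param tree A `phylo` object.
#' @return A list of class `defrisk_dataset` with elements `traits` (filtered
#'   table with `threat` and `status` columns, ordered as the tree tips),
#'   `tree` (pruned), and `attrition` (named counts of species dropped per
#'   reason plus `retained`).
#' @export
build_dataset <- function(traits, tree) {
  stopifnot(is.data.frame(traits), inherits(tree, "phylo"))
  traits$species <- normalize_labels(traits$species)
  n_in <- nrow(traits)

  on_tree <- traits$species %in% tree$tip.label
  defence_known <- !is.na(traits$chemical_defence) &
    traits$chemical_defence %in% c(0, 1)
  status <- code_status(traits$iucn_category, allow_na = TRUE)
  codable <- !is.na(status)

  keep <- on_tree & defence_known & codable
  attrition <- list(
    input = n_in,
    not_on_tree = sum(!on_tree),
    defence_unknown = sum(on_tree & !defence_known),
    iucn_not_codable = sum(on_tree & defence_known & !codable),
    retained = sum(keep),
    unmatched_tree_tips = sum(!tree$tip.label %in% traits$species[keep])
  )
  if (attrition$retained == 0L) stop("no species retained after filtering")

  out <- traits[keep, , drop = FALSE]
  out$status <- status[keep]
  out$threat <- as.integer(out$status >= 2L)
  ptree <- prune_to(tree, out$species)
  out <- out[match(ptree$tip.label, out$species), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all((out$threat == 1L) == (out$status >= 2L)))

  structure(list(traits = out, tree = ptree, attrition = attrition),
            class = "defrisk_dataset")
}

#' @export
print.defrisk_dataset <- function(x, ...) {
  cat("defrisk dataset:", nrow(x$traits), "species on a",
      ape::Ntip(x$tree), "tip tree\n")
  a <- x$attrition
  cat(sprintf("  attrition: %d in; %d not on tree; %d defence unknown; %d IUCN not codable; %d retained\n",
              a$input, a$not_on_tree, a$defence_unknown, a$iucn_not_codable, a$retained))
  invisible(x)
}

#' Write the attrition (exclusion) report as JSON
#'
#' @param dataset A `defrisk_dataset` from [build_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_attrition_report <- function(dataset, path) {
  stopifnot(inherits(dataset, "defrisk_dataset"))
  jsonlite::write_json(dataset$attrition, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Map ordinal status codes back to representative IUCN categories
#'
#' Inverse of [code_status()] used by the synthetic-data generator
#' (status 5 maps to EX).
#'
#' @param status Integer vector in 0..5.
#' @return Character vector of categories.
#' @export
status_to_category <- function(status) {
  stopifnot(all(status %in% 0:5))
  c("LC", "NT", "VU", "EN", "CR", "EX")[status + 1L]
}
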