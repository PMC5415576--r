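#' Construct a TFome count matrix object
#'
#' The central container of the pipeline: an integer species-by-family count
#' matrix together with per-species metadata (proteome size, lineage labels,
#' whole-genome-duplication flag). Cells masked by the single-species
#' expansion correction are stored as `NA` and excluded from fits and totals;
#' the original values are kept in the `masked` record.
#'
#' @param counts Integer matrix, rownames = species ids, colnames = family
#'   labels (sorted lexicographically on construction).
#' @param meta Species metadata tibble with a `species_id` column covering
#'   every matrix row.
#' @param masked Optional tibble (`species_id`, `family`, `count`) recording
#'   cells removed by the expansion correction.
#' @return An object of class `tfome_matrix`.
#' @export
tfome_matrix <- function(counts, meta, masked = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts))) stop("counts must have species rownames")
  missing <- setdiff(rownames(counts), meta$species_id)
  if (length(missing) > 0) {
    stop("species missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  meta <- meta[match(rownames(counts), meta$species_id), ]
  if (is.null(masked)) {
    masked <- tibble::tibble(species_id = character(), family = character(),
                             count = integer())
  }
  structure(list(counts = counts, meta = meta, masked = masked),
            class = "tfome_matrix")
}

#' @export
print.tfome_matrix <- function(x, ...) {
  cat("TFome matrix: ", nrow(x$counts), " species x ", ncol(x$counts),
      " TF gene families\n", sep = "")
  cat("lineage groups:",
      paste(sort(unique(x$meta$lineage_group)), collapse = ", "), "\n")
  if (nrow(x$masked) > 0) {
    cat(nrow(x$masked), "cell(s) masked as single-species expansions\n")
  }
  invisible(x)
}

#' Per-species total TF counts
#'
#' Row sums over every family column (retained, marginal and dual-specificity
#' families alike), skipping cells masked by the expansion correction.
#'
#' @param m A `tfome_matrix`.
#' @param exclude_families Optional character vector of family columns to
#'   leave out (e.g. to reproduce the Zn-cluster-subtraction view of the
#'   whole-TFome fit).
#' @return Named integer vector of totals.
#' @export
tf_totals <- function(m, exclude_families = NULL) {
  stopifnot(inherits(m, "tfome_matrix"))
  keep <- setdiff(colnames(m$counts), exclude_families)
  as.integer(rowSums(m$counts[, keep, drop = FALSE], na.rm = TRUE)) |>
    stats::setNames(rownames(m$counts))
}

#' Species ids belonging to a metadata group
#'
#' @param m A `tfome_matrix`.
#' @param column Metadata column to match (`"lineage_group"`, `"phylum"`,
#'   `"class"`).
#' @param value Group label.
#' @return Character vector of species ids.
#' @export
species_in_group <- function(m, column, value) {
  stopifnot(inherits(m, "tfome_matrix"))
  if (!column %in% names(m$meta)) {
    stop("no metadata column called ", column, call. = FALSE)
  }
  m$meta$species_id[m$meta[[column]] %in% value]
}
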