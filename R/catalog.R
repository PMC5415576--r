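#' Read a TF-type DNA-binding-domain catalog
#'
#' A catalog is the curated list of DBD families that define "TF-type-ness":
#' a protein is called a TF if and only if it carries at least one domain
#' whose accession appears here. Each entry carries the gene-family label
#' (`family`) used for dominant-DBD grouping, the TF class (`tf_class`) used
#' by the dual-specificity rules, and a `superclass` that collapses classes
#' which should never count as two distinct binding specificities (the
#' homeodomain, CUT, lambda-repressor-like and POU classes all belong to the
#' HTH superclass). The three C2H2-, CCHC- and CCCH-type zinc fingers share
#' one `tf_class` so that their combinations are never treated as dual.
#'
#' @param path Path to a tab- or comma-separated file with a header row and
#'   at least the columns `accession`, `name`, `tf_class`. Optional columns:
#'   `family` (defaults to `name`), `superclass` (defaults to `tf_class`),
#'   `specificity` (defaults to `"other"`).
#' @return A tibble of class `dbd_catalog` with columns `accession`, `name`,
#'   `family`, `tf_class`, `superclass`, `specificity`.
#' @seealso [default_dbd_catalog()] for the catalog shipped with the package.
#' @export
read_dbd_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("catalog file does not exist: ", path, call. = FALSE)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("accession", "name", "tf_class")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0) {
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"family" %in% names(cat)) cat$family <- cat$name
  if (!"superclass" %in% names(cat)) cat$superclass <- cat$tf_class
  if (!"specificity" %in% names(cat)) cat$specificity <- "other"
  cat <- dplyr::select(cat, dplyr::all_of(
    c("accession", "name", "family", "tf_class", "superclass", "specificity")))
  validate_dbd_catalog(cat)
}

validate_dbd_catalog <- function(cat) {
  dup <- unique(cat$accession[duplicated(cat$accession)])
  if (length(dup) > 0) {
    stop("duplicate accession(s) in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(cat$tf_class) | !nzchar(cat$tf_class))) {
    stop("catalog entries with empty tf_class", call. = FALSE)
  }
  allowed <- c("fungal", "metazoan", "plant", "bacterial/archaeal/viral",
               "pan-eukaryotic", "other")
  bad <- setdiff(unique(cat$specificity), allowed)
  if (length(bad) > 0) {
    stop("unknown specificity value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(cat) <- c("dbd_catalog", class(cat))
  cat
}

#' The TF-type DBD catalog shipped with the package
#'
#' ~80 DBD families typically found in fungal genomes plus the metazoan CUT
#' and GR-like (nuclear-hormone-receptor-type zinc finger) domains required
#' for metazoan dual-specificity combinations.
#'
#' @return A `dbd_catalog` tibble.
#' @export
default_dbd_catalog <- function() {
  path <- system.file("extdata", "dbd_catalog.tsv", package = "tfomer",
                      mustWork = TRUE)
  read_dbd_catalog(path)
}

catalog_lookup <- function(cat, accessions, column) {
  idx <- match(accessions, cat$accession)
  if (anyNA(idx)) {
    stop("accession(s) not in catalog: ",
         paste(unique(accessions[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  cat[[column]][idx]
}

# Canonical names for the recurrent multi-DBD combinations, keyed by the
# sorted set of TF classes. Combinations without an alias get the sorted
# class labels joined with " + ".
dstf_alias_table <- function() {
  key <- function(...) paste(sort(c(...)), collapse = "|")
  stats::setNames(
    c("Zn cluster+C2H2-like ZF",
      "C2H2-like ZF+HD",
      "Zn_cluster+C2H2-like+HD",
      "GATA+HD",
      "Zn_cluster+HD",
      "Copper fist+Zn cluster",
      "bZIP+HLH",
      "Zn cluster+bZIP",
      "bZIP+C2H2",
      "HD+lambda repressor-like",
      "bZIP+HD-like",
      "GATA+Zn cluster",
      "GR-like+GATA",
      "HD+GR-like",
      "HD+CUT",
      "zf-C2H2+GR-like",
      "C2H2+GATA"),
    c(key("Zn-cluster", "C2H2-like ZF"),
      key("C2H2-like ZF", "HD"),
      key("Zn-cluster", "C2H2-like ZF", "HD"),
      key("GATA", "HD"),
      key("Zn-cluster", "HD"),
      key("Copper-fist", "Zn-cluster"),
      key("bZIP", "HLH"),
      key("Zn-cluster", "bZIP"),
      key("bZIP", "C2H2-like ZF"),
      key("HD", "lambda-repressor-like"),
      key("bZIP", "HD"),
      key("GATA", "Zn-cluster"),
      key("GR-like", "GATA"),
      key("HD", "GR-like"),
      key("HD", "CUT"),
      key("C2H2-like ZF", "GR-like"),
      key("C2H2-like ZF", "GATA")))
}

dstf_combination_label <- function(classes) {
  classes <- sort(unique(classes))
  alias <- dstf_alias_table()
  key <- paste(classes, collapse = "|")
  if (key %in% names(alias)) unname(alias[key]) else paste(classes, collapse = " + ")
}
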