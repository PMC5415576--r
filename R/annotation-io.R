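#' Read an InterProScan-style domain table for one species
#'
#' Consumes the standard InterProScan tab-separated output (no header, 11+
#' columns). Only four columns are used: the protein identifier, the InterPro
#' accession, and the 1-based inclusive start/end coordinates of the match.
#' Signature-level rows without an InterPro accession (`-` or empty) are
#' skipped. Hits are aggregated per protein and sorted by start coordinate.
#'
#' @param path Path to the TSV file.
#' @param species_id Species identifier attached to every record.
#' @param roster Optional character vector of protein ids constituting the
#'   full proteome; when given, proteins with no retained hits still appear
#'   with empty hit lists.
#' @param cols Named integer vector giving the 1-based column indices of
#'   `protein_id`, `interpro`, `start`, `end` in the file. Defaults to the
#'   standard InterProScan layout (columns 1, 12, 7, 8).
#' @return A tibble with one row per protein: `species_id`, `protein_id`,
#'   and a `hits` list-column of tibbles (`accession`, `start`, `end`) sorted
#'   by `start`.
#' @export
read_interpro_table <- function(path, species_id,
                                roster = NULL,
                                cols = c(protein_id = 1L, interpro = 12L,
                                         start = 7L, end = 8L)) {
  if (!file.exists(path)) {
    stop("domain table does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    return(empty_protein_records(species_id, roster))
  }
  need <- max(cols)
  if (ncol(raw) < need) {
    stop("domain table has ", ncol(raw), " columns; at least ", need,
         " expected for the InterProScan dialect", call. = FALSE)
  }
  tab <- tibble::tibble(
    line = seq_len(nrow(raw)),
    protein_id = raw[[cols[["protein_id"]]]],
    accession = raw[[cols[["interpro"]]]],
    start_chr = raw[[cols[["start"]]]],
    end_chr = raw[[cols[["end"]]]])
  # rows without an InterPro accession are legitimate and skipped
  tab <- tab[!is.na(tab$accession) & tab$accession != "-" & tab$accession != "", ]
  if (nrow(tab) == 0) {
    return(empty_protein_records(species_id, roster))
  }
  start <- suppressWarnings(as.integer(tab$start_chr))
  end <- suppressWarnings(as.integer(tab$end_chr))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("non-numeric domain coordinates at line ", tab$line[bad[1]],
         " of ", path, call. = FALSE)
  }
  rev <- which(start > end)
  if (length(rev) > 0) {
    stop("domain start > end at line ", tab$line[rev[1]], " of ", path,
         call. = FALSE)
  }
  tab$start <- start
  tab$end <- end
  recs <- tab |>
    dplyr::arrange(.data$protein_id, .data$start, .data$end, .data$accession) |>
    dplyr::select(dplyr::all_of(c("protein_id", "accession", "start", "end"))) |>
    tidyr::nest(hits = dplyr::all_of(c("accession", "start", "end")))
  out <- tibble::tibble(species_id = species_id,
                        protein_id = recs$protein_id,
                        hits = recs$hits)
  if (!is.null(roster)) {
    missing <- setdiff(roster, out$protein_id)
    if (length(missing) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        species_id = species_id, protein_id = missing,
        hits = replicate(length(missing),
                         tibble::tibble(accession = character(),
                                        start = integer(), end = integer()),
                         simplify = FALSE)))
    }
    out <- out[order(out$protein_id), ]
  }
  out
}

empty_protein_records <- function(species_id, roster = NULL) {
  if (is.null(roster) || length(roster) == 0) {
    return(tibble::tibble(species_id = character(), protein_id = character(),
                          hits = list()))
  }
  tibble::tibble(species_id = species_id, protein_id = sort(roster),
                 hits = replicate(length(roster),
                                  tibble::tibble(accession = character(),
                                                 start = integer(),
                                                 end = integer()),
                                  simplify = FALSE))
}

#' Read species metadata
#'
#' @param path Tab-separated file with header and columns `species_id`,
#'   `proteome_size`, `phylum`, `class`, `lineage_group`, `wgd`.
#' @return A tibble; `proteome_size` integer, `wgd` logical. Lineage labels
#'   are kept verbatim.
#' @export
read_species_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            species_id = readr::col_character(),
                            proteome_size = readr::col_double(),
                            phylum = readr::col_character(),
                            class = readr::col_character(),
                            lineage_group = readr::col_character(),
                            wgd = readr::col_logical()))
  required <- c("species_id", "proteome_size", "phylum", "class",
                "lineage_group", "wgd")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("species metadata missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_species_meta(meta)
}

validate_species_meta <- function(meta) {
  if (any(is.na(meta$proteome_size) | meta$proteome_size <= 0)) {
    bad <- meta$species_id[is.na(meta$proteome_size) | meta$proteome_size <= 0]
    stop("non-positive proteome_size for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(meta$species_id[duplicated(meta$species_id)])
  if (length(dup) > 0) {
    stop("duplicate species_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  meta$class[is.na(meta$class)] <- ""
  meta$proteome_size <- as.integer(meta$proteome_size)
  meta
}

#' Write / read a species-by-family TFome count matrix
#'
#' The exchange format is a TSV with one row per species: the metadata
#' columns (`species_id`, `proteome_size`, `phylum`, `class`,
#' `lineage_group`, `wgd`) followed by one column per TF gene family, in
#' lexicographic family order so the file is byte-stable.
#'
#' @param m A [tfome_matrix] object.
#' @param path Output path.
#' @return `write_tfome_matrix` returns `path` invisibly;
#'   `read_tfome_matrix` returns a `tfome_matrix`.
#' @export
write_tfome_matrix <- function(m, path) {
  stopifnot(inherits(m, "tfome_matrix"))
  counts <- m$counts[, order(colnames(m$counts)), drop = FALSE]
  df <- dplyr::bind_cols(m$meta[match(rownames(counts), m$meta$species_id), ],
                         tibble::as_tibble(counts))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tfome_matrix
#' @export
read_tfome_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("species_id", "proteome_size", "phylum", "class",
                 "lineage_group", "wgd")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing) > 0) {
    stop("TFome matrix file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- validate_species_meta(df[meta_cols])
  fam_cols <- setdiff(names(df), meta_cols)
  counts <- as.matrix(df[fam_cols])
  mode(counts) <- "integer"
  rownames(counts) <- meta$species_id
  tfome_matrix(counts, meta)
}
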