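#' Call transcription factors from domain architectures
#'
#' A protein is a TF if it carries at least one TF-type DNA-binding domain,
#' i.e. at least one hit whose accession is in the catalog. Non-catalog hits
#' are dropped from the returned gene records (they do not contribute to
#' family assignment), but their presence never disqualifies a protein.
#'
#' @param proteins Protein records as returned by [read_interpro_table()]
#'   (rows from several species may be concatenated).
#' @param catalog A `dbd_catalog`.
#' @return A tibble of TF genes: `species_id`, `protein_id`, `tf_dbds`
#'   (list-column, the multiset of catalog accessions found in the protein),
#'   `family` (empty until [assign_families()]), `dual` (FALSE until then).
#' @export
call_tfs <- function(proteins, catalog) {
  stopifnot(inherits(catalog, "dbd_catalog"))
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  if (nrow(proteins) == 0) {
    return(tibble::tibble(species_id = character(), protein_id = character(),
                          tf_dbds = list(), family = character(),
                          dual = logical()))
  }
  tf_dbds <- purrr::map(proteins$hits, function(h) {
    h$accession[h$accession %in% catalog$accession]
  })
  keep <- lengths(tf_dbds) > 0
  tibble::tibble(species_id = proteins$species_id[keep],
                 protein_id = proteins$protein_id[keep],
                 tf_dbds = tf_dbds[keep],
                 family = "",
                 dual = FALSE)
}

#' Partition families into retained and marginal sets
#'
#' Families observed in fewer than `min_species` species are "marginal":
#' they are excluded from the family-level dynamics and signature analyses
#' but their genes still count toward each species' total TFome size.
#'
#' @param x A `tfome_matrix`, or any species-by-unit count matrix (species in
#'   rows). The same rule serves both the domain-family (TFDF) and the
#'   gene-family (TFgF) level.
#' @param min_species Occurrence threshold; a family present in
#'   `min_species` or more species is retained (default 5, i.e. marginal
#'   means "< 5 species").
#' @return A list of class `family_partition` with character vectors
#'   `retained` and `marginal`.
#' @export
filter_marginal <- function(x, min_species = 5) {
  if (min_species < 1) stop("min_species must be >= 1", call. = FALSE)
  counts <- if (inherits(x, "tfome_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) == 0) {
    part <- list(retained = character(), marginal = character())
    class(part) <- "family_partition"
    return(part)
  }
  occurrence <- colSums(counts > 0, na.rm = TRUE)
  part <- list(retained = sort(names(occurrence)[occurrence >= min_species]),
               marginal = sort(names(occurrence)[occurrence < min_species]))
  class(part) <- "family_partition"
  part
}

#' Species occurrence of individual DBD accessions
#'
#' Number of species in which each catalog accession is seen in at least one
#' called TF; input to the domain-level marginal filter.
#'
#' @param genes TF genes from [call_tfs()].
#' @return A species-by-accession incidence matrix usable with
#'   [filter_marginal()].
#' @export
dbd_incidence <- function(genes) {
  if (nrow(genes) == 0) {
    return(matrix(integer(), 0, 0))
  }
  long <- tibble::tibble(
    species_id = rep(genes$species_id, lengths(genes$tf_dbds)),
    accession = unlist(genes$tf_dbds, use.names = FALSE)) |>
    dplyr::distinct()
  species <- sort(unique(long$species_id))
  acc <- sort(unique(long$accession))
  m <- matrix(0L, length(species), length(acc),
              dimnames = list(species, acc))
  m[cbind(match(long$species_id, species), match(long$accession, acc))] <- 1L
  m
}

# Dataset-wide gene count per family: the number of called TF genes carrying
# at least one accession of the family. Defines "dominant DBD" abundance.
# Computed once per distinct domain architecture.
family_abundance <- function(genes, catalog) {
  if (nrow(genes) == 0) {
    return(stats::setNames(integer(), character()))
  }
  keys <- architecture_keys(genes$tf_dbds)
  u <- unique(keys)
  fams_u <- lapply(genes$tf_dbds[match(u, keys)],
                   function(a) unique(catalog_lookup(catalog, a, "family")))
  n_per_arch <- as.integer(table(keys)[u])
  tab <- tapply(rep(n_per_arch, lengths(fams_u)),
                unlist(fams_u, use.names = FALSE), sum)
  stats::setNames(as.integer(tab), names(tab))
}

architecture_keys <- function(tf_dbds) {
  vapply(tf_dbds, function(a) paste(sort(a), collapse = ";"), character(1))
}

#' Assign each TF gene to a TF gene family
#'
#' Genes are merged into groups around their dominant DBD: among the
#' candidate families of a gene's TF-type DBDs, the gene is assigned to the
#' family with the highest dataset-wide gene count (ties broken by the
#' lexicographically smaller label). Accessions sharing a merged `tf_class`
#' (the C2H2/CCHC/CCCH zinc fingers) already map to a single family in the
#' catalog. Genes resolved by the dual-specificity classifier keep their
#' combination label (accepted or retained combinations) or are folded into
#' the constituent family chosen by the merge rule.
#'
#' @param genes TF genes from [call_tfs()].
#' @param catalog A `dbd_catalog`.
#' @param dstf Result of [classify_dstf()] on the same genes; `NULL` runs the
#'   classifier with its defaults.
#' @return `genes` with `family` filled in and `dual` set.
#' @export
assign_families <- function(genes, catalog, dstf = NULL) {
  if (nrow(genes) == 0) return(genes)
  if (any(lengths(genes$tf_dbds) == 0)) {
    stop("TF gene with empty tf_dbds: invariant violation", call. = FALSE)
  }
  if (is.null(dstf)) dstf <- classify_dstf(genes, catalog)
  abundance <- family_abundance(genes, catalog)
  combos <- dstf$combinations
  gene_combo <- dstf$genes$combination
  family <- character(nrow(genes))
  dual <- logical(nrow(genes))
  # dual-specificity genes: keep the combination label (accepted/retained)
  # or fold into the recorded merge-target family
  has_combo <- !is.na(gene_combo)
  if (any(has_combo)) {
    status <- combos$status[match(gene_combo[has_combo], combos$label)]
    keep <- status %in% c("accepted", "retained-insignificant")
    family[has_combo][keep] <- gene_combo[has_combo][keep]
    dual[has_combo][keep] <- TRUE
    family[has_combo][!keep] <-
      combos$merge_target[match(gene_combo[has_combo][!keep], combos$label)]
  }
  # single-specificity genes: dominant-DBD rule, resolved once per distinct
  # architecture
  if (any(!has_combo)) {
    keys <- architecture_keys(genes$tf_dbds[!has_combo])
    u <- unique(keys)
    choice_u <- vapply(genes$tf_dbds[!has_combo][match(u, keys)],
                       function(a) {
                         cand <- sort(unique(
                           catalog_lookup(catalog, a, "family")))
                         ab <- abundance[cand]
                         ab[is.na(ab)] <- 0L
                         cand[order(-ab, cand)][1]
                       }, character(1))
    names(choice_u) <- u
    family[!has_combo] <- unname(choice_u[keys])
  }
  genes$family <- family
  genes$dual <- dual
  genes
}

#' Build the species-by-family TFome count matrix
#'
#' Cell (s, f) is the number of TF genes of family f in species s. Every
#' species in the metadata gets a row (all-zero for TF-less species) and
#' every assigned family label a column, so row sums equal per-species total
#' TF counts including marginal-family and dual-specificity genes.
#'
#' @param genes TF genes with families assigned ([assign_families()]).
#' @param meta Species metadata covering every species in `genes`.
#' @return A [tfome_matrix].
#' @export
build_tfome_matrix <- function(genes, meta) {
  meta <- validate_species_meta(meta)
  missing <- setdiff(unique(genes$species_id), meta$species_id)
  if (length(missing) > 0) {
    stop("species missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(genes) > 0 && any(!nzchar(genes$family))) {
    stop("genes without an assigned family; run assign_families() first",
         call. = FALSE)
  }
  species <- meta$species_id
  fams <- sort(unique(genes$family))
  counts <- matrix(0L, length(species), length(fams),
                   dimnames = list(species, fams))
  if (nrow(genes) > 0) {
    tab <- table(factor(genes$species_id, levels = species),
                 factor(genes$family, levels = fams))
    counts[] <- as.integer(tab)
  }
  tfome_matrix(counts, meta)
}

#' Annotate a TFome corpus end to end
#'
#' Convenience wrapper: TF calling, dual-specificity classification,
#' dominant-DBD family assignment and matrix construction, with the marginal
#' partition reported at both the domain-family and the gene-family level.
#'
#' @param proteins Concatenated protein records for all species.
#' @param meta Species metadata.
#' @param catalog A `dbd_catalog` (default: the shipped catalog).
#' @param min_species Marginal-family threshold (default 5).
#' @param min_genomes,rel_threshold Dual-specificity parameters, see
#'   [classify_dstf()].
#' @return A list: `matrix` (the [tfome_matrix]), `genes`, `dstf`
#'   (combination table), `dbd_partition`, `family_partition`.
#' @export
annotate_tfome <- function(proteins, meta, catalog = default_dbd_catalog(),
                           min_species = 5, min_genomes = 5,
                           rel_threshold = 0.001) {
  genes <- call_tfs(proteins, catalog)
  dstf <- classify_dstf(genes, catalog, min_genomes = min_genomes,
                        rel_threshold = rel_threshold)
  genes <- assign_families(genes, catalog, dstf)
  m <- build_tfome_matrix(genes, meta)
  list(matrix = m,
       genes = genes,
       dstf = dstf$combinations,
       dbd_partition = filter_marginal(dbd_incidence(genes), min_species),
       family_partition = filter_marginal(m, min_species))
}
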