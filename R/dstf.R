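#' Is a gene a dual-specificity TF candidate?
#'
#' A gene is a candidate when its TF-type DBDs span two or more distinct
#' binding specificities. Specificity is judged at the superclass level, so
#' combinations inside one superclass (e.g. a homeodomain next to another
#' HTH-type domain) do not count — with two whitelisted exceptions of known
#' dual-specificity pairs within the HTH superclass: {HD, CUT} and
#' {HD, lambda-repressor-like}. The merged C2H2/CCHC/CCCH zinc fingers share
#' one class and therefore never count as distinct.
#'
#' @param tf_dbds Character vector of catalog accessions found in the gene
#'   (repeats allowed; repeats of one domain are never dual).
#' @param catalog A `dbd_catalog`.
#' @return A list: `dual` (logical), `classes` (sorted distinct tf_class
#'   labels), `label` (canonical combination name, `NA` if not dual).
#' @export
is_dual_candidate <- function(tf_dbds, catalog) {
  classes <- sort(unique(catalog_lookup(catalog, tf_dbds, "tf_class")))
  superclasses <- unique(catalog_lookup(catalog, tf_dbds, "superclass"))
  exceptions <- list(c("CUT", "HD"), c("HD", "lambda-repressor-like"))
  dual <- length(superclasses) >= 2 ||
    any(vapply(exceptions, function(e) identical(classes, e), logical(1)))
  list(dual = dual,
       classes = classes,
       label = if (dual) dstf_combination_label(classes) else NA_character_)
}

#' Prevalence filter for dual-specificity combinations
#'
#' A combination is reliably represented when it occurs in at least
#' `min_genomes` genomes.
#'
#' @param combinations Tibble with columns `label` and `n_genomes`.
#' @param min_genomes Genome-count threshold (default 5).
#' @return The tibble with a logical `prevalent` column.
#' @export
apply_prevalence_filter <- function(combinations, min_genomes = 5) {
  combinations$prevalent <- combinations$n_genomes >= min_genomes
  combinations
}

#' Merge insignificant dual-specificity combinations into background families
#'
#' A failing combination is folded into the constituent single-DBD family
#' with the largest dataset-wide gene count (ties broken lexicographically);
#' if none of its constituent families has any single-specificity genes in
#' the dataset, the combination is retained as its own (insignificant) group.
#'
#' @param combinations Tibble from [apply_prevalence_filter()] with a
#'   logical `failing` column and a `families` list-column of constituent
#'   family labels.
#' @param background Named integer vector: dataset-wide single-specificity
#'   gene count per family.
#' @return The tibble with `status` and `merge_target` filled in.
#' @export
merge_insignificant <- function(combinations, background) {
  status <- combinations$status
  target <- combinations$merge_target
  for (i in seq_len(nrow(combinations))) {
    if (!combinations$failing[i]) next
    fams <- combinations$families[[i]]
    bg <- background[fams]
    bg[is.na(bg)] <- 0L
    if (all(bg == 0)) {
      status[i] <- "retained-insignificant"
    } else {
      best <- fams[order(-bg, fams)][1]
      status[i] <- paste0("merged:", best)
      target[i] <- best
    }
  }
  combinations$status <- status
  combinations$merge_target <- target
  combinations
}

#' Classify dual-specificity TFs
#'
#' Applies the four dual-specificity rules to a called gene set:
#' 1. candidate = two or more DBDs of different TF classes, with the HD+CUT
#'    and HD+lambda-repressor-like exceptions and the merged
#'    C2H2/CCHC/CCCH group;
#' 2. a combination must be represented in at least `min_genomes` genomes;
#' 3. combinations represented by a non-significant number of genes on the
#'    background of their constituent single-DBD families are merged into
#'    the largest such family ("non-significant" = failing rule 2, or fewer
#'    genes than `rel_threshold` times the largest constituent background);
#' 4. combinations with no background family to merge into are retained as
#'    insignificant.
#'
#' @param genes TF genes from [call_tfs()].
#' @param catalog A `dbd_catalog`.
#' @param min_genomes Prevalence threshold (default 5 genomes).
#' @param rel_threshold Relative gene-count threshold of rule 3
#'   (default 0.001 of the largest constituent background).
#' @return A list: `genes` (input plus `combination` column, `NA` for
#'   single-specificity genes) and `combinations` (one row per combination:
#'   `label`, `classes`, `families`, `n_genomes`, `n_genes`, `status` one of
#'   accepted / merged:<family> / retained-insignificant, `merge_target`).
#' @export
classify_dstf <- function(genes, catalog, min_genomes = 5,
                          rel_threshold = 0.001) {
  # candidacy depends only on the domain architecture; compute once per
  # distinct architecture and map back
  arch_key <- vapply(genes$tf_dbds,
                     function(a) paste(sort(a), collapse = ";"),
                     character(1))
  uniq <- !duplicated(arch_key)
  cand_uniq <- purrr::map(genes$tf_dbds[uniq], is_dual_candidate,
                          catalog = catalog)
  names(cand_uniq) <- arch_key[uniq]
  cand <- cand_uniq[arch_key]
  combination <- purrr::map_chr(cand, "label")
  out_genes <- dplyr::mutate(genes, combination = combination)
  if (all(is.na(combination))) {
    combos <- tibble::tibble(label = character(), classes = list(),
                             families = list(), n_genomes = integer(),
                             n_genes = integer(), status = character(),
                             merge_target = character())
    return(list(genes = out_genes, combinations = combos))
  }
  idx <- which(!is.na(combination))
  combo_fams <- purrr::map(genes$tf_dbds[idx],
                           function(a) sort(unique(
                             catalog_lookup(catalog, a, "family"))))
  combos <- tibble::tibble(label = combination[idx],
                           species_id = genes$species_id[idx],
                           classes = purrr::map(cand[idx], "classes"),
                           families = combo_fams) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      classes = list(sort(unique(unlist(.data$classes)))),
      families = list(sort(unique(unlist(.data$families)))),
      n_genomes = dplyr::n_distinct(.data$species_id),
      n_genes = dplyr::n(),
      .groups = "drop")
  # single-specificity background per family, for the merge rule
  single <- genes[is.na(combination), ]
  background <- family_abundance(single, catalog)
  combos <- apply_prevalence_filter(combos, min_genomes)
  max_bg <- purrr::map_dbl(combos$families, function(f) {
    bg <- background[f]
    bg[is.na(bg)] <- 0
    max(c(bg, 0))
  })
  combos$failing <- !combos$prevalent |
    combos$n_genes < rel_threshold * max_bg
  combos$status <- ifelse(combos$failing, "", "accepted")
  combos$merge_target <- NA_character_
  combos <- merge_insignificant(combos, background)
  combos <- dplyr::select(combos, -dplyr::all_of(c("prevalent", "failing")))
  list(genes = out_genes, combinations = combos)
}

#' Summarize dual-specificity TFs over a count matrix
#'
#' @param m A [tfome_matrix] whose columns include dual-specificity
#'   combination labels.
#' @param combinations Combination table from [classify_dstf()]; rows with
#'   status `"accepted"` or `"retained-insignificant"` are summarized.
#' @return A list: `table` (per combination: genomes carrying it, percentage
#'   of genomes, maximum per-genome count, total genes) and `fraction`
#'   (dataset-wide dual-specificity share of all TF genes).
#' @export
summarize_dstf <- function(m, combinations) {
  stopifnot(inherits(m, "tfome_matrix"))
  labels <- combinations$label[combinations$status != "" &
                                 !startsWith(combinations$status, "merged:")]
  labels <- intersect(labels, colnames(m$counts))
  n_species <- nrow(m$counts)
  if (length(labels) == 0) {
    return(list(table = tibble::tibble(label = character(),
                                       n_genomes = integer(),
                                       pct_genomes = double(),
                                       max_per_genome = integer(),
                                       n_genes = integer()),
                fraction = 0))
  }
  sub <- m$counts[, labels, drop = FALSE]
  tab <- tibble::tibble(
    label = labels,
    n_genomes = as.integer(colSums(sub > 0, na.rm = TRUE)),
    pct_genomes = unname(round(100 * colSums(sub > 0, na.rm = TRUE) /
                                 n_species)),
    max_per_genome = as.integer(apply(sub, 2, max, na.rm = TRUE)),
    n_genes = as.integer(colSums(sub, na.rm = TRUE))) |>
    dplyr::arrange(dplyr::desc(.data$n_genomes), .data$label)
  total <- sum(tf_totals(m))
  list(table = tab,
       fraction = if (total > 0) sum(tab$n_genes) / total else 0)
}
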