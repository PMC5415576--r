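#' Signature family panels
#'
#' `"fungal6"` is the 6-family panel of the most abundant fungal TF gene
#' families (Zn cluster, C2H2-like zinc fingers, homeodomain-like, bZIP,
#' HLH, GATA), suited to discriminating the main fungal phyla. `"broad9"`
#' extends it with three lineage-restricted families (GR-like, Ets,
#' Fork head) to resolve a wider range of eukaryotic lineages.
#'
#' @param panel `"fungal6"` or `"broad9"`.
#' @return Character vector of family labels (catalog family names).
#' @export
signature_families <- function(panel = c("fungal6", "broad9")) {
  panel <- match.arg(panel)
  fungal6 <- c("Zn cluster", "C2H2/CCHC/CCCH", "HTH/Homeodomain-like",
               "bZIP", "HLH", "GATA")
  switch(panel,
         fungal6 = fungal6,
         broad9 = c(fungal6, "GR-like", "Ets", "Fork head TF"))
}

# per-species fractions of the TFome for the given families; zero-TF
# species dropped with a warning
signature_fractions <- function(m, species, families) {
  totals <- tf_totals(m)[species]
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    warning("skipping zero-TF species: ", paste(zero, collapse = ", "),
            call. = FALSE)
    species <- setdiff(species, zero)
    totals <- totals[species]
  }
  frac <- matrix(0, length(species), length(families),
                 dimnames = list(species, families))
  present <- intersect(families, colnames(m$counts))
  if (length(present) > 0 && length(species) > 0) {
    cnt <- m$counts[species, present, drop = FALSE]
    cnt[is.na(cnt)] <- 0L
    frac[, present] <- cnt / totals
  }
  frac
}

#' Build a lineage TF signature
#'
#' A signature is the vector of central per-family fractions of the TFome
#' (per species, count(s, f) / total TFs(s); then the mean or median over
#' the species of the group) for a fixed, ordered panel of families.
#' Families absent from the matrix get fraction 0.
#'
#' @param m A [tfome_matrix].
#' @param species Character vector of species ids, or a single group label
#'   looked up in `group_by`.
#' @param families Ordered family panel (default the fungal 6-family panel).
#' @param statistic `"mean"` or `"median"`.
#' @param group_by Metadata column used when `species` is a group label.
#' @param label Signature label (defaults to the group label or
#'   `"signature"`).
#' @return An object of class `tf_signature`: `group_label`, `families`,
#'   `fractions`, `n_species`, `statistic`.
#' @export
build_signature <- function(m, species, families = signature_families(),
                            statistic = c("mean", "median"),
                            group_by = "lineage_group", label = NULL) {
  stopifnot(inherits(m, "tfome_matrix"))
  statistic <- match.arg(statistic)
  if (length(species) == 1 && !species %in% m$meta$species_id) {
    if (is.null(label)) label <- species
    species <- species_in_group(m, group_by, species)
  }
  if (length(species) == 0) stop("empty species group", call. = FALSE)
  if (is.null(label)) label <- "signature"
  frac <- signature_fractions(m, species, families)
  stat_fun <- if (statistic == "mean") colMeans else
    function(x) apply(x, 2, stats::median)
  structure(list(group_label = label,
                 families = families,
                 fractions = stats::setNames(as.numeric(stat_fun(frac)),
                                             families),
                 n_species = nrow(frac),
                 statistic = statistic),
            class = "tf_signature")
}

#' @export
print.tf_signature <- function(x, ...) {
  cat("TF signature '", x$group_label, "' (", x$statistic, " over ",
      x$n_species, " species)\n", sep = "")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Leave-class-out signature pair
#'
#' Builds the training signature from a phylum minus one of its classes and
#' the test signature from that class alone, so the test species never enter
#' the training signature.
#'
#' @param m A [tfome_matrix].
#' @param phylum Phylum label (matched against metadata `phylum`).
#' @param klass Class label within the phylum (metadata `class`).
#' @param families Family panel.
#' @param statistic Central statistic, see [build_signature()].
#' @return A list with `train` and `test` signatures.
#' @export
leave_class_out <- function(m, phylum, klass,
                            families = signature_families(),
                            statistic = "mean") {
  stopifnot(inherits(m, "tfome_matrix"))
  phylum_sp <- species_in_group(m, "phylum", phylum)
  class_sp <- intersect(species_in_group(m, "class", klass), phylum_sp)
  if (length(class_sp) == 0) {
    stop("class ", klass, " has no species within phylum ", phylum,
         call. = FALSE)
  }
  train_sp <- setdiff(phylum_sp, class_sp)
  if (length(train_sp) == 0) {
    stop("class covers the whole phylum; empty training set", call. = FALSE)
  }
  list(train = build_signature(m, train_sp, families, statistic,
                               label = paste0(phylum, "-minus-", klass)),
       test = build_signature(m, class_sp, families, statistic,
                              label = klass))
}

signature_distance <- function(a, b, metric = c("euclidean", "jsd")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    return(sqrt(sum((a - b)^2)))
  }
  # Jensen-Shannon divergence on renormalized fraction vectors
  p <- a / sum(a)
  q <- b / sum(b)
  m <- (p + q) / 2
  kl <- function(x, y) {
    keep <- x > 0
    sum(x[keep] * log2(x[keep] / y[keep]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Assign a test signature to its nearest reference lineage
#'
#' @param test A `tf_signature`.
#' @param references List of `tf_signature` objects sharing the test's
#'   family panel (same families, same order).
#' @param metric `"euclidean"` (default) or `"jsd"` (Jensen-Shannon).
#' @return A list of class `assignment_result`: `test_label`, `best_match`,
#'   `distances` (named, sorted ascending), `margin` (gap between best and
#'   second best; 0 on ties, broken by lexicographic reference label).
#' @export
assign_lineage <- function(test, references, metric = c("euclidean", "jsd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(test, "tf_signature"))
  for (ref in references) {
    if (!identical(ref$families, test$families)) {
      stop("reference '", ref$group_label,
           "' has a different family panel than the test signature",
           call. = FALSE)
    }
  }
  labels <- vapply(references, function(r) r$group_label, character(1))
  d <- vapply(references,
              function(r) signature_distance(test$fractions, r$fractions,
                                             metric),
              numeric(1))
  names(d) <- labels
  ord <- order(d, labels)
  d <- d[ord]
  margin <- if (length(d) > 1) unname(d[2] - d[1]) else Inf
  structure(list(test_label = test$group_label,
                 best_match = names(d)[1],
                 distances = d,
                 margin = margin),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("'", x$test_label, "' assigned to '", x$best_match,
      "' (margin ", signif(x$margin, 3), ")\n", sep = "")
  invisible(x)
}

#' Test between-group differences of signature fractions
#'
#' For each family of the panel, a two-sample rank test (Wilcoxon) on the
#' per-species TFome fractions of the two groups, with Benjamini-Hochberg
#' adjustment across families. Groups of fewer than 3 species, or families
#' whose fractions are identical across both groups, are reported as
#' not-assessed.
#'
#' @param m A [tfome_matrix].
#' @param species_a,species_b Species id vectors of the two groups.
#' @param families Family panel.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return Tibble: `family`, `p`, `p_adj`, `significant` (logical, `NA` when
#'   not assessed), `status`.
#' @export
test_ratio_differences <- function(m, species_a, species_b,
                                   families = signature_families(),
                                   alpha = 0.05) {
  stopifnot(inherits(m, "tfome_matrix"))
  base <- tibble::tibble(family = families, p = NA_real_, p_adj = NA_real_,
                         significant = NA, status = "not-assessed")
  if (length(species_a) < 3 || length(species_b) < 3) {
    return(base)
  }
  fa <- signature_fractions(m, species_a, families)
  fb <- signature_fractions(m, species_b, families)
  p <- unname(vapply(families, function(f) {
    x <- fa[, f]
    y <- fb[, f]
    if (length(unique(c(x, y))) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1)))
  assessed <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  p_adj[assessed] <- stats::p.adjust(p[assessed], method = "BH")
  tibble::tibble(family = families, p = unname(p), p_adj = p_adj,
                 significant = ifelse(assessed, p_adj < alpha, NA),
                 status = ifelse(assessed, "assessed", "not-assessed"))
}
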