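#' Coefficient of determination
#'
#' R^2 = 1 - sum((y_i - f_i)^2) / sum((y_i - ybar)^2), where y_i is the
#' observed TF count in genome i, ybar the mean of the observed data, and
#' f_i the corresponding modeled value. Can be negative for models worse
#' than the mean; undefined (error) when the observations are constant.
#'
#' @param observed Numeric vector of observed values.
#' @param modeled Numeric vector of modeled values, same length.
#' @return R^2 in (-Inf, 1].
#' @export
r_squared <- function(observed, modeled) {
  if (length(observed) != length(modeled)) {
    stop("observed and modeled must have the same length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("need at least 2 observations", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("observed values are constant; R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - modeled)^2) / sst
}

undefined_fit <- function(n_used, n_total) {
  structure(list(exponent = NA_real_, intercept = NA_real_, se = NA_real_,
                 r2 = NA_real_, n_used = n_used, n_total = n_total,
                 defined = FALSE),
            class = "power_law_fit")
}

#' Fit a power law of TF count against proteome size
#'
#' Least-squares line fit of log10(count) on log10(P). The slope is the
#' family's growth exponent (base-invariant); the intercept is log10 of the
#' scale. Genomes with no representatives of the family are ignored
#' (`drop_zeros`), as are `NA` cells masked by the expansion correction.
#' R^2 is evaluated on the original count scale against the back-transformed
#' model values.
#'
#' @param counts Per-genome TF counts.
#' @param sizes Per-genome proteome sizes, aligned with `counts`.
#' @param drop_zeros Drop zero-count genomes before fitting (default TRUE).
#' @return An object of class `power_law_fit`: `exponent`, `intercept`
#'   (log10 scale), `se` (standard error of the exponent), `r2`, `n_used`,
#'   `n_total`, `defined`. Fewer than 3 usable genomes gives an undefined
#'   fit rather than an error.
#' @export
fit_power_law <- function(counts, sizes, drop_zeros = TRUE) {
  if (length(counts) != length(sizes)) {
    stop("counts and sizes must be aligned", call. = FALSE)
  }
  n_total <- length(counts)
  use <- !is.na(counts) & !is.na(sizes)
  if (drop_zeros) use <- use & counts > 0
  y <- counts[use]
  p <- sizes[use]
  n_used <- length(y)
  if (n_used < 3 || length(unique(p)) < 2) {
    return(undefined_fit(n_used, n_total))
  }
  if (length(unique(y)) == 1) {
    # frozen family: flat line in log space, exponent exactly 0
    return(structure(list(exponent = 0, intercept = log10(y[1]), se = 0,
                          r2 = NA_real_, n_used = n_used, n_total = n_total,
                          defined = TRUE),
                     class = "power_law_fit"))
  }
  fit <- stats::lm(log10(y) ~ log10(p))
  co <- summary(fit)$coefficients
  modeled <- 10^stats::fitted(fit)
  r2 <- if (stats::var(y) > 0) r_squared(y, modeled) else NA_real_
  structure(list(exponent = unname(co[2, 1]),
                 intercept = unname(co[1, 1]),
                 se = unname(co[2, 2]),
                 r2 = r2,
                 n_used = n_used,
                 n_total = n_total,
                 defined = TRUE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!x$defined) {
    cat("power-law fit: undefined (", x$n_used, " usable genomes)\n", sep = "")
  } else {
    cat(sprintf("power-law fit: exponent %.3f (se %.3f), R2 %.3f, n = %d/%d\n",
                x$exponent, x$se, x$r2, x$n_used, x$n_total))
  }
  invisible(x)
}

#' Classify a family as small or abundant
#'
#' Small = fewer than 5 genes per genome on average, zeros included.
#'
#' @param counts Per-genome counts over all genomes of the group.
#' @param threshold Mean-count boundary (default 5; the boundary itself is
#'   abundant).
#' @return `"small"` or `"abundant"`.
#' @export
classify_size <- function(counts, threshold = 5) {
  if (mean(counts, na.rm = TRUE) < threshold) "small" else "abundant"
}

#' Classify a family's responsiveness to proteome growth
#'
#' A family is eligible for the responsiveness call when it is present in
#' more than `min_species` species and reaches more than `min_max_count`
#' genes in at least one genome (ruling out small increments such as 1 to 4
#' genes). An eligible family is responsive when its fitted exponent exceeds
#' `exp_threshold` and the fit quality R^2 exceeds `r2_threshold`.
#'
#' @param fit A `power_law_fit` computed on `counts`.
#' @param counts Per-genome counts (zeros included) the fit was based on.
#' @param exp_threshold Growth-exponent threshold (default 0.5).
#' @param r2_threshold Fit-quality threshold (default 0.5).
#' @param min_species Presence threshold: eligible needs strictly more
#'   nonzero genomes than this (default 10).
#' @param min_max_count Maximal-count threshold: eligible needs a genome
#'   with strictly more genes than this (default 5).
#' @return A list of class `family_classification`: `size_class`,
#'   `eligibility` (eligible / too-few-species / never-exceeds-5),
#'   `responsiveness` (responsive / non-responsive / not-assessed), `fit`.
#' @export
classify_responsiveness <- function(fit, counts, exp_threshold = 0.5,
                                    r2_threshold = 0.5, min_species = 10,
                                    min_max_count = 5) {
  n_nonzero <- sum(counts > 0, na.rm = TRUE)
  max_count <- if (all(is.na(counts))) 0 else max(counts, na.rm = TRUE)
  eligibility <- if (n_nonzero <= min_species) {
    "too-few-species"
  } else if (max_count <= min_max_count) {
    "never-exceeds-5"
  } else {
    "eligible"
  }
  responsiveness <- "not-assessed"
  if (eligibility == "eligible" && fit$defined) {
    responsiveness <- if (!is.na(fit$r2) && fit$exponent > exp_threshold &&
                            fit$r2 > r2_threshold) {
      "responsive"
    } else {
      "non-responsive"
    }
  }
  structure(list(size_class = classify_size(counts),
                 eligibility = eligibility,
                 responsiveness = responsiveness,
                 fit = fit),
            class = "family_classification")
}

#' Detect single-species expansions
#'
#' A species is flagged as a single-species expansion of a family when its
#' count is at least `fold` times the largest count among all other species
#' and at least `min_abs` genes in absolute terms (so small families with
#' one 10-gene species are not outliers).
#'
#' @param counts Named per-species counts for one family.
#' @param fold Fold-change over the background maximum (default 3).
#' @param min_abs Absolute floor (default 20 genes).
#' @return Character vector of flagged species ids.
#' @export
detect_single_expansions <- function(counts, fold = 3.0, min_abs = 20) {
  if (length(counts) < 5) {
    stop("need at least 5 genomes to call expansion outliers", call. = FALSE)
  }
  if (is.null(names(counts))) {
    stop("counts must be named by species", call. = FALSE)
  }
  flagged <- character()
  for (s in names(counts)) {
    x <- counts[[s]]
    if (is.na(x)) next
    others <- counts[setdiff(names(counts), s)]
    bg <- suppressWarnings(max(others, na.rm = TRUE))
    if (!is.finite(bg)) bg <- 0
    if (x >= fold * bg && x >= min_abs) flagged <- c(flagged, s)
  }
  flagged
}

#' Flag single-species expansions across a whole matrix
#'
#' Runs [detect_single_expansions()] on every family column within each
#' lineage group (expansion is judged against the family's background in the
#' same group).
#'
#' @param m A [tfome_matrix].
#' @param group_by Metadata column defining the groups
#'   (default `"lineage_group"`); `NULL` treats all species as one group.
#' @param fold,min_abs See [detect_single_expansions()].
#' @return Tibble `species_id`, `family`, `count`, `group`.
#' @export
flag_expansions <- function(m, group_by = "lineage_group", fold = 3.0,
                            min_abs = 20) {
  stopifnot(inherits(m, "tfome_matrix"))
  groups <- if (is.null(group_by)) {
    list(all = rownames(m$counts))
  } else {
    split(m$meta$species_id, m$meta[[group_by]])
  }
  out <- list()
  for (g in names(groups)) {
    sp <- groups[[g]]
    if (length(sp) < 5) next
    for (f in colnames(m$counts)) {
      counts <- stats::setNames(m$counts[sp, f], sp)
      hits <- detect_single_expansions(counts, fold = fold, min_abs = min_abs)
      if (length(hits) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          species_id = hits, family = f,
          count = as.integer(counts[hits]), group = g)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(species_id = character(), family = character(),
                          count = integer(), group = character()))
  }
  dplyr::bind_rows(out)
}

#' Remove flagged single-species expansions from the fit sets
#'
#' Single-species expansions are outliers of the count-versus-proteome-size
#' relation; the correction removes the flagged (species, family) cells so
#' they take part neither in the family's fit nor in the species' total used
#' by whole-TFome fits. Removed counts are recorded in the matrix's `masked`
#' table; other cells are untouched.
#'
#' @param m A [tfome_matrix].
#' @param flags Tibble with `species_id` and `family` columns (from
#'   [flag_expansions()]).
#' @return The corrected `tfome_matrix`.
#' @export
correct_for_expansions <- function(m, flags) {
  stopifnot(inherits(m, "tfome_matrix"))
  if (nrow(flags) == 0) return(m)
  counts <- m$counts
  masked <- m$masked
  for (i in seq_len(nrow(flags))) {
    s <- flags$species_id[i]
    f <- flags$family[i]
    if (!s %in% rownames(counts) || !f %in% colnames(counts)) {
      stop("flagged cell (", s, ", ", f, ") not in matrix", call. = FALSE)
    }
    if (!is.na(counts[s, f])) {
      masked <- dplyr::bind_rows(masked, tibble::tibble(
        species_id = s, family = f, count = as.integer(counts[s, f])))
      counts[s, f] <- NA_integer_
    }
  }
  tfome_matrix(counts, m$meta, masked)
}

#' Fit the whole-TFome power law for a lineage group
#'
#' Total TF count (all families, masked expansion cells excluded, optionally
#' minus `exclude_families` — e.g. subtracting the Zn cluster family to show
#' its contribution) against proteome size. Species with a recorded
#' whole-genome duplication grow their TFome by a different mechanism and
#' are excluded by default.
#'
#' @param m A [tfome_matrix].
#' @param group Group label(s); `NULL` fits all species.
#' @param group_by Metadata column matched against `group`.
#' @param exclude_wgd Exclude WGD-flagged species (default TRUE).
#' @param exclude_families Families subtracted from the totals before the
#'   fit.
#' @param drop_zeros Passed to [fit_power_law()].
#' @return A `power_law_fit` (undefined when fewer than 3 species remain).
#' @export
fit_group_tfome <- function(m, group = NULL, group_by = "lineage_group",
                            exclude_wgd = TRUE, exclude_families = NULL,
                            drop_zeros = TRUE) {
  stopifnot(inherits(m, "tfome_matrix"))
  sp <- if (is.null(group)) m$meta$species_id else
    species_in_group(m, group_by, group)
  if (exclude_wgd) sp <- setdiff(sp, m$meta$species_id[m$meta$wgd])
  if (length(sp) < 3) return(undefined_fit(length(sp), length(sp)))
  totals <- tf_totals(m, exclude_families = exclude_families)[sp]
  sizes <- m$meta$proteome_size[match(sp, m$meta$species_id)]
  fit_power_law(totals, sizes, drop_zeros = drop_zeros)
}

#' Per-family dynamics report for every lineage group
#'
#' Fits each retained family within each lineage group, classifies size and
#' responsiveness, and (optionally) flags and corrects single-species
#' expansions before fitting.
#'
#' @param m A [tfome_matrix].
#' @param group_by Metadata column defining the groups
#'   (default `"lineage_group"`).
#' @param families Families to analyze (default: families retained by the
#'   marginal filter at `min_occurrence`).
#' @param correct_expansions Flag and mask single-species expansions first
#'   (default TRUE, mirroring the outlier correction).
#' @param exclude_wgd Exclude WGD-flagged species from the fits.
#' @param exp_threshold,r2_threshold,min_species,min_max_count See
#'   [classify_responsiveness()].
#' @param min_occurrence Marginal-family threshold (default 5 species).
#' @param fold,min_abs See [detect_single_expansions()].
#' @return A list: `report` (tibble: group, family, size_class, eligibility,
#'   exponent, intercept, se, r2, n_used, n_total, responsiveness,
#'   flagged_species) and `flags` (the expansion flags used).
#' @export
tfome_dynamics <- function(m, group_by = "lineage_group", families = NULL,
                           correct_expansions = TRUE, exclude_wgd = TRUE,
                           exp_threshold = 0.5, r2_threshold = 0.5,
                           min_species = 10, min_max_count = 5,
                           min_occurrence = 5, fold = 3.0, min_abs = 20) {
  stopifnot(inherits(m, "tfome_matrix"))
  if (is.null(families)) {
    families <- filter_marginal(m, min_occurrence)$retained
  }
  flags <- if (correct_expansions) {
    flag_expansions(m, group_by = group_by, fold = fold, min_abs = min_abs)
  } else {
    tibble::tibble(species_id = character(), family = character(),
                   count = integer(), group = character())
  }
  mc <- correct_for_expansions(m, flags)
  groups <- split(mc$meta$species_id, mc$meta[[group_by]])
  rows <- list()
  for (g in names(groups)) {
    sp <- groups[[g]]
    if (exclude_wgd) sp <- setdiff(sp, mc$meta$species_id[mc$meta$wgd])
    sizes <- mc$meta$proteome_size[match(sp, mc$meta$species_id)]
    for (f in families) {
      if (!f %in% colnames(mc$counts)) next
      counts <- mc$counts[sp, f]
      if (all(counts == 0, na.rm = TRUE)) next  # family absent from group
      fit <- fit_power_law(counts, sizes)
      cls <- classify_responsiveness(fit, counts,
                                     exp_threshold = exp_threshold,
                                     r2_threshold = r2_threshold,
                                     min_species = min_species,
                                     min_max_count = min_max_count)
      flagged <- flags$species_id[flags$family == f & flags$group == g]
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, family = f, size_class = cls$size_class,
        eligibility = cls$eligibility, exponent = fit$exponent,
        intercept = fit$intercept, se = fit$se, r2 = fit$r2,
        n_used = fit$n_used, n_total = fit$n_total,
        responsiveness = cls$responsiveness,
        flagged_species = paste(flagged, collapse = ","))
    }
  }
  report <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(group = character(), family = character(),
                   size_class = character(), eligibility = character(),
                   exponent = double(), intercept = double(), se = double(),
                   r2 = double(), n_used = integer(), n_total = integer(),
                   responsiveness = character(), flagged_species = character())
  list(report = report, flags = flags)
}
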