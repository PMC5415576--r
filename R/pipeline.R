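#' Default pipeline configuration
#'
#' All thresholds of the downstream stages with their defaults: marginal
#' families at < 5 species, dual-specificity prevalence at >= 5 genomes and
#' relative background threshold 0.001, responsiveness at exponent > 0.5 and
#' R^2 > 0.5 for families in > 10 species reaching > 5 genes somewhere,
#' expansion outliers at 3-fold over background and >= 20 genes, signature
#' tests at alpha = 0.05.
#'
#' @return Named list of defaults; override any entry via the `config`
#'   argument of [run_tfome_pipeline()] or a YAML file.
#' @export
default_config <- function() {
  list(
    tables = NULL,          # directory of per-species InterProScan TSVs
    catalog = NULL,         # catalog path; NULL = shipped catalog
    meta = NULL,            # species metadata TSV
    outdir = NULL,
    group_by = "lineage_group",
    min_species = 5,        # marginal-family occurrence threshold
    min_genomes = 5,        # dsTF prevalence threshold
    rel_threshold = 0.001,  # dsTF relative-background threshold
    exp_threshold = 0.5,
    r2_threshold = 0.5,
    dyn_min_species = 10,   # responsiveness eligibility: present in > 10
    min_max_count = 5,      # ... and > 5 genes in at least one genome
    correct_expansions = TRUE,
    fold = 3,
    min_abs = 20,
    alpha = 0.05,
    signature_panel = "fungal6",
    statistic = "mean",
    seed = 1)
}

validate_config <- function(config) {
  base <- default_config()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop("unknown config entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(base, config)
  bounds <- list(min_species = c(1, Inf), min_genomes = c(1, Inf),
                 rel_threshold = c(0, 1), exp_threshold = c(0, Inf),
                 r2_threshold = c(0, 1), dyn_min_species = c(1, Inf),
                 min_max_count = c(0, Inf), fold = c(1, Inf),
                 min_abs = c(0, Inf), alpha = c(0, 1))
  for (nm in names(bounds)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < bounds[[nm]][1] || v > bounds[[nm]][2]) {
      stop("config value out of bounds: ", nm, " = ", v, call. = FALSE)
    }
  }
  for (nm in c("tables", "meta", "outdir")) {
    if (is.null(cfg[[nm]])) stop("config must set ", nm, call. = FALSE)
  }
  cfg
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  writeLines(msg, con)
}

#' Run the whole TFome pipeline
#'
#' Orchestrates annotation (TF calling, dual-specificity classification,
#' family assignment, matrix construction), dynamics (per-family power-law
#' fits with expansion correction and whole-TFome fits per group), and
#' signatures, writing a run directory with all reports, a log, and a
#' machine-readable manifest (package version, seed, effective config and
#' its hash, output file hashes). Reruns with the same config and inputs
#' are bit-identical except for timestamps.
#'
#' @param config A named list overriding [default_config()], or the path to
#'   a YAML file of such overrides. `tables`, `meta` and `outdir` are
#'   required.
#' @return Invisibly, a list with the matrix, reports and manifest.
#' @export
run_tfome_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)

  stage <- "annotate"
  result <- tryCatch({
    catalog <- if (is.null(cfg$catalog)) default_dbd_catalog() else
      read_dbd_catalog(cfg$catalog)
    meta <- read_species_meta(cfg$meta)
    files <- list.files(cfg$tables, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0) {
      stop("no .tsv domain tables found in ", cfg$tables, call. = FALSE)
    }
    proteins <- dplyr::bind_rows(lapply(files, function(f) {
      read_interpro_table(f, species_id = sub("\\.tsv$", "", basename(f)))
    }))
    pipeline_log(con, "annotate: ", length(files), " species tables, ",
                 nrow(proteins), " annotated proteins")
    ann <- annotate_tfome(proteins, meta, catalog,
                          min_species = cfg$min_species,
                          min_genomes = cfg$min_genomes,
                          rel_threshold = cfg$rel_threshold)
    pipeline_log(con, "annotate: ", nrow(ann$genes), " TF genes called, ",
                 length(ann$family_partition$marginal),
                 " marginal families, ", nrow(ann$dstf),
                 " dsTF combinations")
    matrix_path <- file.path(cfg$outdir, "tfome_matrix.tsv")
    write_tfome_matrix(ann$matrix, matrix_path)

    stage <- "dstf"
    dstf_sum <- summarize_dstf(ann$matrix, ann$dstf)
    readr::write_tsv(dstf_sum$table,
                     file.path(cfg$outdir, "dstf_report.tsv"),
                     progress = FALSE)
    pipeline_log(con, "dstf: fraction of TF repertoires = ",
                 signif(dstf_sum$fraction, 3))

    stage <- "dynamics"
    dyn <- tfome_dynamics(ann$matrix, group_by = cfg$group_by,
                          correct_expansions = cfg$correct_expansions,
                          exp_threshold = cfg$exp_threshold,
                          r2_threshold = cfg$r2_threshold,
                          min_species = cfg$dyn_min_species,
                          min_max_count = cfg$min_max_count,
                          min_occurrence = cfg$min_species,
                          fold = cfg$fold, min_abs = cfg$min_abs)
    readr::write_tsv(dyn$report,
                     file.path(cfg$outdir, "dynamics_report.tsv"),
                     progress = FALSE)
    groups <- sort(unique(ann$matrix$meta[[cfg$group_by]]))
    whole <- dplyr::bind_rows(lapply(groups, function(g) {
      fit <- fit_group_tfome(ann$matrix, g, group_by = cfg$group_by)
      tibble::tibble(group = g, exponent = fit$exponent,
                     intercept = fit$intercept, r2 = fit$r2,
                     n_used = fit$n_used)
    }))
    readr::write_tsv(whole, file.path(cfg$outdir, "whole_tfome_fits.tsv"),
                     progress = FALSE)
    pipeline_log(con, "dynamics: ", nrow(dyn$report), " family fits, ",
                 nrow(dyn$flags), " expansion flags")

    stage <- "signatures"
    fams <- signature_families(cfg$signature_panel)
    sigs <- lapply(groups, function(g) {
      s <- build_signature(ann$matrix, g, families = fams,
                           statistic = cfg$statistic,
                           group_by = cfg$group_by)
      list(group = s$group_label, families = s$families,
           fractions = unname(s$fractions), n_species = s$n_species,
           statistic = s$statistic)
    })
    jsonlite::write_json(sigs, file.path(cfg$outdir, "signatures.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log(con, "signatures: ", length(sigs), " group signatures (",
                 cfg$signature_panel, " panel)")
    list(matrix = ann$matrix, genes = ann$genes, dstf = dstf_sum,
         dynamics = dyn, whole_tfome = whole, signatures = sigs)
  }, error = function(e) {
    pipeline_log(con, "FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_path <- file.path(cfg$outdir, "effective_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  outputs <- c("tfome_matrix.tsv", "dstf_report.tsv", "dynamics_report.tsv",
               "whole_tfome_fits.tsv", "signatures.json")
  manifest <- list(
    package = "tfomer",
    version = as.character(utils::packageVersion("tfomer")),
    seed = cfg$seed,
    config = cfg,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(tools::md5sum(file.path(cfg$outdir, outputs))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
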