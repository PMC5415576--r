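#' Specify a synthetic lineage
#'
#' A lineage is a set of species whose proteome sizes are drawn log-uniformly
#' from a range and whose per-family TF counts follow family-specific power
#' laws of proteome size, count = round(a * P^b * eps) with multiplicative
#' lognormal noise eps ~ LN(0, sigma), or stay frozen at a constant.
#'
#' @param label Lineage label (used for species ids and as default
#'   `lineage_group`).
#' @param n_species Number of species.
#' @param p_range Proteome-size range, log-uniform (default 3,000-30,000
#'   protein-coding genes, the span observed in fungal genomes).
#' @param families Named list; each element is either a single non-negative
#'   number (a frozen family at that constant count) or a list with `a`
#'   (scale > 0), `b` (exponent), and optional `sigma` (lognormal sd,
#'   default 0.2).
#' @param signature Optional fraction-target mode: a list with `a` and `b`
#'   (scale and exponent of the lineage's whole-TFome power law),
#'   `fractions` (named vector of per-family TFome fraction targets summing
#'   to <= 1) and optional `sigma`. Each named family is generated as
#'   count = round(a * fraction * P^b * eps), so its mean TFome share
#'   converges to the target as the group grows. Merged with any `families`
#'   entries (e.g. frozen dual-specificity families).
#' @param phylum,klass,lineage_group Metadata labels (default: `label`,
#'   empty class, `label`).
#' @param wgd_species Species ids (of this lineage) flagged as
#'   whole-genome-duplicated.
#' @return A validated list of class `lineage_spec`.
#' @export
lineage_spec <- function(label, n_species, p_range = c(3000, 30000),
                         families = list(), signature = NULL,
                         phylum = label, klass = "",
                         lineage_group = label, wgd_species = character()) {
  if (!is.null(signature)) {
    if (is.null(signature$a) || is.null(signature$b) ||
          is.null(signature$fractions) ||
          is.null(names(signature$fractions))) {
      stop("signature mode needs a, b and a named fractions vector",
           call. = FALSE)
    }
    if (any(signature$fractions < 0) || sum(signature$fractions) > 1 + 1e-9) {
      stop("signature fractions must be non-negative and sum to <= 1",
           call. = FALSE)
    }
    sigma <- if (is.null(signature$sigma)) 0.2 else signature$sigma
    sig_fams <- lapply(signature$fractions, function(fr) {
      if (fr == 0) return(list(frozen = 0))
      list(a = signature$a * fr, b = signature$b, sigma = sigma)
    })
    families <- c(sig_fams[setdiff(names(sig_fams), names(families))],
                  families)
  }
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (length(p_range) != 2 || p_range[1] > p_range[2] || p_range[1] < 100 ||
        p_range[2] > 1e6) {
    stop("p_range must be an increasing pair within [100, 1e6]",
         call. = FALSE)
  }
  if (length(families) == 0 || is.null(names(families)) ||
        any(!nzchar(names(families)))) {
    stop("families must be a non-empty named list", call. = FALSE)
  }
  fams <- lapply(names(families), function(f) {
    spec <- families[[f]]
    if (is.numeric(spec) && length(spec) == 1) {
      spec <- list(frozen = spec)
    }
    if (!is.null(spec$frozen)) {
      if (spec$frozen < 0) stop("frozen count must be >= 0 for ", f,
                                call. = FALSE)
      return(list(frozen = spec$frozen))
    }
    if (is.null(spec$a) || is.null(spec$b)) {
      stop("family ", f, " needs either a frozen count or a, b (and sigma)",
           call. = FALSE)
    }
    if (spec$a <= 0) stop("scale a must be > 0 for ", f, call. = FALSE)
    sigma <- if (is.null(spec$sigma)) 0.2 else spec$sigma
    if (sigma < 0) stop("sigma must be >= 0 for ", f, call. = FALSE)
    list(a = spec$a, b = spec$b, sigma = sigma)
  })
  names(fams) <- names(families)
  structure(list(label = label, n_species = n_species, p_range = p_range,
                 families = fams, phylum = phylum, klass = klass,
                 lineage_group = lineage_group, wgd_species = wgd_species),
            class = "lineage_spec")
}

#' Simulate a TFome count matrix
#'
#' Draws proteome sizes and per-family TF counts for every lineage spec.
#' Fully deterministic under a fixed seed: reruns give a byte-identical
#' matrix.
#'
#' @param specs A `lineage_spec` or list of them.
#' @param seed Integer seed for all randomness.
#' @return A [tfome_matrix] whose metadata carries the lineage labels.
#' @export
simulate_matrix <- function(specs, seed) {
  if (inherits(specs, "lineage_spec")) specs <- list(specs)
  if (!all(vapply(specs, inherits, logical(1), "lineage_spec"))) {
    stop("specs must be lineage_spec objects", call. = FALSE)
  }
  withr::local_seed(seed)
  meta_rows <- list()
  count_rows <- list()
  for (spec in specs) {
    n <- spec$n_species
    ids <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", spec$label),
                   seq_len(n))
    p <- round(10^stats::runif(n, log10(spec$p_range[1]),
                               log10(spec$p_range[2])))
    fam_counts <- lapply(spec$families, function(fs) {
      if (!is.null(fs$frozen)) {
        rep(as.integer(round(fs$frozen)), n)
      } else {
        eps <- stats::rlnorm(n, 0, fs$sigma)
        as.integer(round(fs$a * p^fs$b * eps))
      }
    })
    counts <- do.call(cbind, fam_counts)
    rownames(counts) <- ids
    meta_rows[[length(meta_rows) + 1]] <- tibble::tibble(
      species_id = ids, proteome_size = as.integer(p),
      phylum = spec$phylum, class = spec$klass,
      lineage_group = spec$lineage_group,
      wgd = ids %in% spec$wgd_species)
    count_rows[[length(count_rows) + 1]] <- counts
  }
  meta <- dplyr::bind_rows(meta_rows)
  fams <- sort(unique(unlist(lapply(count_rows, colnames))))
  counts <- matrix(0L, nrow(meta), length(fams),
                   dimnames = list(meta$species_id, fams))
  for (block in count_rows) {
    counts[rownames(block), colnames(block)] <- block
  }
  tfome_matrix(counts, meta)
}

#' Inject a single-species expansion into a count matrix
#'
#' Sets one (species, family) cell to `magnitude`, leaving everything else
#' untouched. Emulates outlier expansions such as a nematode
#' glucocorticoid-receptor-like family at 270 genes against a background
#' that never exceeds 35.
#'
#' @param m A [tfome_matrix].
#' @param species_id,family Target cell.
#' @param magnitude New count; must exceed the family's maximum across the
#'   other species, otherwise it would not be an expansion.
#' @return The modified `tfome_matrix`.
#' @export
inject_expansion <- function(m, species_id, family, magnitude) {
  stopifnot(inherits(m, "tfome_matrix"))
  if (!species_id %in% rownames(m$counts)) {
    stop("unknown species: ", species_id, call. = FALSE)
  }
  if (!family %in% colnames(m$counts)) {
    stop("unknown family: ", family, call. = FALSE)
  }
  others <- m$counts[setdiff(rownames(m$counts), species_id), family]
  bg <- suppressWarnings(max(others, na.rm = TRUE))
  if (is.finite(bg) && magnitude <= bg) {
    stop("magnitude ", magnitude, " does not exceed the background maximum ",
         bg, " of family ", family, call. = FALSE)
  }
  m$counts[species_id, family] <- as.integer(magnitude)
  m
}

#' Multi-domain architectures for dual-specificity combination labels
#'
#' Accession recipes used by [emit_domain_tables()] to realize
#' dual-specificity genes; e.g. the most frequent fungal type is written as
#' two tightly located C2H2 zinc fingers followed by a single Zn cluster.
#'
#' @return Named list: combination label -> character vector of catalog
#'   accessions (with repeats).
#' @export
default_dstf_recipes <- function() {
  list(
    "Zn cluster+C2H2-like ZF" = c("IPR007087", "IPR007087", "IPR001138"),
    "C2H2-like ZF+HD" = c("IPR007087", "IPR001356"),
    "Zn_cluster+C2H2-like+HD" = c("IPR001138", "IPR007087", "IPR001356"),
    "GATA+HD" = c("IPR000679", "IPR001356"),
    "Zn_cluster+HD" = c("IPR001138", "IPR001356"),
    "Copper fist+Zn cluster" = c("IPR001083", "IPR001138"),
    "bZIP+HLH" = c("IPR004827", "IPR011598"),
    "Zn cluster+bZIP" = c("IPR001138", "IPR004827"),
    "bZIP+C2H2" = c("IPR004827", "IPR007087"),
    "HD+lambda repressor-like" = c("IPR001356", "IPR010982"),
    "bZIP+HD-like" = c("IPR004827", "IPR001356"),
    "GATA+Zn cluster" = c("IPR000679", "IPR001138"),
    "GR-like+GATA" = c("IPR001628", "IPR000679"),
    "HD+GR-like" = c("IPR001356", "IPR001628"),
    "HD+CUT" = c("IPR001356", "IPR003350"),
    "zf-C2H2+GR-like" = c("IPR007087", "IPR001628"),
    "C2H2+GATA" = c("IPR007087", "IPR000679"))
}

#' Emit InterProScan-style domain tables realizing a count matrix
#'
#' Writes one tab-separated file per species in the standard InterProScan
#' layout (13 columns, no header). Each TF gene of a single-DBD family gets
#' one row carrying a representative accession of that family; genes of
#' dual-specificity families get one row per domain of their recipe
#' architecture. Filler proteins pad each file to the species' proteome
#' size; they carry the reserved signature accession `SYNTHFILL` with no
#' InterPro integration, so they can never be called as TFs.
#' Re-annotating the emitted tables reproduces the input matrix exactly.
#'
#' @param m A [tfome_matrix] (no masked cells).
#' @param outdir Output directory, created if needed; files are named
#'   `<species_id>.tsv`.
#' @param catalog A `dbd_catalog`; every single-DBD matrix family must map
#'   to at least one catalog accession.
#' @param dstf_recipes Architectures for dual-specificity family columns
#'   (default [default_dstf_recipes()]).
#' @return Invisibly, the vector of written file paths.
#' @export
emit_domain_tables <- function(m, outdir, catalog = default_dbd_catalog(),
                               dstf_recipes = default_dstf_recipes()) {
  stopifnot(inherits(m, "tfome_matrix"))
  if (anyNA(m$counts)) {
    stop("matrix has masked cells; emit tables from an uncorrected matrix",
         call. = FALSE)
  }
  fams <- colnames(m$counts)
  arch <- lapply(fams, function(f) {
    if (f %in% names(dstf_recipes)) return(dstf_recipes[[f]])
    acc <- catalog$accession[catalog$family == f]
    if (length(acc) == 0) {
      stop("family without accession mapping in catalog: ", f, call. = FALSE)
    }
    acc[1]
  })
  names(arch) <- fams
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(m$counts))
  for (i in seq_len(nrow(m$counts))) {
    sp <- rownames(m$counts)[i]
    p_size <- m$meta$proteome_size[match(sp, m$meta$species_id)]
    gene_fams <- rep(fams, times = m$counts[i, ])
    n_genes <- length(gene_fams)
    gene_ids <- sprintf("g%06d", seq_len(n_genes))
    doms_per_gene <- lengths(arch)[gene_fams]
    row_gene <- rep(seq_len(n_genes), times = doms_per_gene)
    dom_idx <- sequence(doms_per_gene)
    start <- 10L + (dom_idx - 1L) * 100L
    tf_rows <- tibble::tibble(
      protein_id = gene_ids[row_gene],
      md5 = "-",
      length = if (length(start) > 0) max(start) + 120L else integer(),
      analysis = "ProfileScan",
      sig_acc = "PS99999",
      sig_desc = "synthetic signature",
      start = start,
      end = start + 50L,
      score = "0.0",
      status = "T",
      date = "01-01-2026",
      ipr_acc = unlist(arch[gene_fams], use.names = FALSE),
      ipr_desc = "synthetic domain")
    n_filler <- max(0L, p_size - n_genes)
    filler <- tibble::tibble(
      protein_id = sprintf("f%06d", seq_len(n_filler)),
      md5 = "-", length = 200L, analysis = "ProfileScan",
      sig_acc = "SYNTHFILL", sig_desc = "synthetic filler protein",
      start = 10L, end = 60L, score = "0.0", status = "T",
      date = "01-01-2026", ipr_acc = "-", ipr_desc = "-")
    paths[i] <- file.path(outdir, paste0(sp, ".tsv"))
    readr::write_tsv(dplyr::bind_rows(tf_rows, filler), paths[i],
                     col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

# shared small-family background of the fungal presets: mostly frozen one-
# or two-gene families, a couple of abundant frozen ones
fungal_background_families <- function() {
  cat <- default_dbd_catalog()
  big <- c(signature_families("broad9"), "CUT",
           "Trp repressor/replication initiator")
  fams <- setdiff(sort(unique(cat$family)), big)
  consts <- rep(c(1, 1, 2, 1, 3, 2, 1, 4, 2, 6), length.out = length(fams))
  # two abundant frozen families exercise the abundant/non-responsive case
  consts[match(c("TATA box binding protein associated factor (TAF)",
                 "TFIID"), fams)] <- c(8, 7)
  as.list(stats::setNames(consts, fams))
}

#' Synthetic fungal corpus preset
#'
#' Four lineages mirroring the structure of a fungal genome corpus:
#' an Ascomycota phylum of four classes (10 species each) in which three
#' families respond to proteome growth (Zn cluster b = 1.2, C2H2-like
#' b = 0.9, homeodomain-like b = 0.8) over ~60 frozen or slow background
#' families; a Basidiomycota lineage whose Zn cluster exponent is ~2.5-fold
#' lower; and small Mucoromycota (with one WGD-flagged species) and
#' Zoopagomycota lineages with minor Zn-cluster shares. Proteome sizes are
#' log-uniform on 3,000-30,000. Two dual-specificity families are carried
#' at frozen counts across most lineages, and one background family occurs
#' only in the 4-species Zoopagomycota lineage (hence marginal).
#'
#' @return A list of `lineage_spec` objects for [simulate_matrix()].
#' @export
preset_fungal <- function() {
  bg <- fungal_background_families()
  asco_fams <- c(list(
    "Zn cluster" = list(a = 0.00285, b = 1.2, sigma = 0.2),
    "C2H2/CCHC/CCCH" = list(a = 0.0176, b = 0.9, sigma = 0.2),
    "HTH/Homeodomain-like" = list(a = 0.0284, b = 0.8, sigma = 0.2),
    "bZIP" = list(a = 1.89, b = 0.3, sigma = 0.2),
    "HLH" = list(a = 1.90, b = 0.2, sigma = 0.2),
    "GATA" = list(a = 1.0, b = 0.25, sigma = 0.2),
    "Zn cluster+C2H2-like ZF" = 2,
    "C2H2-like ZF+HD" = 1), bg)
  basidio_fams <- c(list(
    "Zn cluster" = list(a = 0.72, b = 0.48, sigma = 0.2),
    "C2H2/CCHC/CCCH" = list(a = 0.0176, b = 0.9, sigma = 0.2),
    "HTH/Homeodomain-like" = list(a = 0.0284, b = 0.8, sigma = 0.2),
    "bZIP" = list(a = 1.89, b = 0.3, sigma = 0.2),
    "HLH" = list(a = 1.90, b = 0.2, sigma = 0.2),
    "GATA" = list(a = 1.0, b = 0.25, sigma = 0.2),
    "Zn cluster+C2H2-like ZF" = 2,
    "C2H2-like ZF+HD" = 1), bg)
  zygo_fams <- function(extra = list()) c(list(
    "Zn cluster" = list(a = 0.63, b = 0.4, sigma = 0.2),
    "C2H2/CCHC/CCCH" = list(a = 0.0176, b = 0.9, sigma = 0.2),
    "HTH/Homeodomain-like" = list(a = 0.0284, b = 0.8, sigma = 0.2),
    "bZIP" = list(a = 1.89, b = 0.3, sigma = 0.2),
    "HLH" = list(a = 1.90, b = 0.2, sigma = 0.2),
    "GATA" = list(a = 1.0, b = 0.25, sigma = 0.2),
    "Zn cluster+C2H2-like ZF" = 2), extra, bg)
  classes <- c("Dothideomycetes", "Eurotiomycetes", "Sordariomycetes",
               "Leotiomycetes")
  asco <- lapply(classes, function(k) {
    lineage_spec(paste0("Asco_", k), n_species = 10, families = asco_fams,
                 phylum = "Ascomycota", klass = k,
                 lineage_group = "Ascomycota")
  })
  c(asco, list(
    lineage_spec("Basidio", n_species = 25, families = basidio_fams,
                 phylum = "Basidiomycota", lineage_group = "Basidiomycota"),
    lineage_spec("Mucoro", n_species = 10, families = zygo_fams(),
                 phylum = "Mucoromycota", lineage_group = "Zygomycetes",
                 wgd_species = "Mucoro_001"),
    lineage_spec("Zoopago", n_species = 4,
                 families = zygo_fams(
                   list("Trp repressor/replication initiator" = 1)),
                 phylum = "Zoopagomycota", lineage_group = "Zygomycetes")))
}

#' Synthetic metazoan corpus preset
#'
#' Two lineages mirroring the metazoan analysis: a chordate-like group with
#' a steep whole-TFome growth (many responsive families) and an
#' ecdysozoan-like group with a flat TFome in which the GR-like family sits
#' near 30 genes per genome regardless of size — the background against
#' which a single-species expansion to 270 genes is an outlier.
#'
#' @return A list of `lineage_spec` objects.
#' @export
preset_metazoan <- function() {
  chordate_fams <- list(
    "C2H2/CCHC/CCCH" = list(a = 0.0028, b = 1.2, sigma = 0.2),
    "HTH/Homeodomain-like" = list(a = 0.0075, b = 1.0, sigma = 0.2),
    "GR-like" = list(a = 0.003, b = 1.0, sigma = 0.2),
    "bZIP" = list(a = 0.029, b = 0.8, sigma = 0.2),
    "HLH" = list(a = 0.022, b = 0.8, sigma = 0.2),
    "GATA" = list(a = 0.106, b = 0.5, sigma = 0.2),
    "Ets" = list(a = 0.004, b = 0.9, sigma = 0.2),
    "Fork head TF" = list(a = 0.0244, b = 0.7, sigma = 0.2),
    "T-box" = 2, "Paired box" = 2, "DM DNA-binding" = 2, "STAT" = 2,
    "MADS-box/SRF" = 1, "RFX_DNA_binding" = 1, "p53" = 1, "E2F_TDP" = 2,
    "HD+CUT" = 3, "GR-like+GATA" = 2, "HD+GR-like" = 2)
  ecdyso_fams <- list(
    "C2H2/CCHC/CCCH" = list(a = 0.0028, b = 1.2, sigma = 0.2),
    "HTH/Homeodomain-like" = list(a = 0.05, b = 0.7, sigma = 0.2),
    "GR-like" = list(a = 30, b = 0, sigma = 0.1),
    "bZIP" = list(a = 0.5, b = 0.4, sigma = 0.2),
    "HLH" = list(a = 0.4, b = 0.4, sigma = 0.2),
    "GATA" = list(a = 0.3, b = 0.4, sigma = 0.2),
    "Ets" = list(a = 0.1, b = 0.5, sigma = 0.2),
    "Fork head TF" = list(a = 0.2, b = 0.4, sigma = 0.2),
    "T-box" = 2, "Paired box" = 1, "DM DNA-binding" = 3,
    "MADS-box/SRF" = 1, "E2F_TDP" = 2,
    "GR-like+GATA" = 2, "C2H2-like ZF+HD" = 1)
  list(
    lineage_spec("Chordata", n_species = 20, p_range = c(14000, 45000),
                 families = chordate_fams, phylum = "Chordata",
                 lineage_group = "Chordata"),
    lineage_spec("Ecdysozoa", n_species = 20, p_range = c(8000, 25000),
                 families = ecdyso_fams, phylum = "Ecdysozoa",
                 lineage_group = "Ecdysozoa"))
}
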