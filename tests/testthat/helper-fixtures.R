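# Shared in-code fixtures: a small catalog, hand-built protein records and
# count matrices. Everything is generated at test time; nothing binary.

write_mini_catalog <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "accession\tname\tfamily\ttf_class\tsuperclass\tspecificity",
    "IPR001138\tZn2 Cys6 Zn_cluster\tZn cluster\tZn-cluster\tZn-cluster\tfungal",
    "IPR007087\tZinc finger, C2H2-type\tC2H2/CCHC/CCCH\tC2H2-like ZF\tC2H2-like ZF\tpan-eukaryotic",
    "IPR001878\tZinc finger, CCHC-type\tC2H2/CCHC/CCCH\tC2H2-like ZF\tC2H2-like ZF\tpan-eukaryotic",
    "IPR000571\tZinc finger CCCH-type\tC2H2/CCHC/CCCH\tC2H2-like ZF\tC2H2-like ZF\tpan-eukaryotic",
    "IPR001356\tHomeobox\tHTH/Homeodomain-like\tHD\tHTH\tpan-eukaryotic",
    "IPR009057\tHomeodomain-like\tHTH/Homeodomain-like\tHD\tHTH\tpan-eukaryotic",
    "IPR010982\tLambda repressor-like\tlambda repressor-like/POU\tlambda-repressor-like\tHTH\tbacterial/archaeal/viral",
    "IPR003350\tHomeodomain CUT\tCUT\tCUT\tHTH\tmetazoan",
    "IPR004827\tBasic-leucine zipper (bZIP) TF\tbZIP\tbZIP\tbZIP\tpan-eukaryotic",
    "IPR000679\tZinc finger, GATA-type\tGATA\tGATA\tGATA\tpan-eukaryotic",
    "IPR011598\tHelix-loop-helix DNA-binding\tHLH\tHLH\tHLH\tpan-eukaryotic"),
    path)
  path
}

mini_catalog <- function() read_dbd_catalog(write_mini_catalog())

# one protein record row (the reader's output shape)
protein_rec <- function(species, protein, accessions,
                        starts = 10 + 100 * (seq_along(accessions) - 1)) {
  tibble::tibble(
    species_id = species, protein_id = protein,
    hits = list(tibble::tibble(accession = accessions,
                               start = as.integer(starts),
                               end = as.integer(starts + 50))))
}

# gene table as produced by call_tfs()
make_genes <- function(species, accession_sets) {
  tibble::tibble(
    species_id = species,
    protein_id = sprintf("p%03d", seq_along(species)),
    tf_dbds = accession_sets,
    family = "",
    dual = FALSE)
}

make_meta <- function(species, proteome_size = 10000, phylum = "PhyA",
                      klass = "", lineage_group = "GrpA", wgd = FALSE) {
  tibble::tibble(species_id = species,
                 proteome_size = as.integer(proteome_size),
                 phylum = phylum, class = klass,
                 lineage_group = lineage_group, wgd = wgd)
}

make_matrix <- function(counts, meta = NULL) {
  if (is.null(meta)) meta <- make_meta(rownames(counts))
  tfome_matrix(counts, meta)
}

# minimal InterProScan-style 13-column TSV writer for handcrafted rows
write_ipr_rows <- function(rows, path = tempfile(fileext = ".tsv")) {
  lines <- vapply(rows, function(r) {
    paste(c(r$protein, "-", "500", "ProfileScan", "PS1", "desc",
            r$start, r$end, "0.0", "T", "01-01-2026",
            r$ipr, "desc2"), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
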