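test_that("dual candidacy requires two distinct TF classes", {
  cat <- default_dbd_catalog()
  # Zn cluster + C2H2: distinct classes, canonical fungal combination
  r <- is_dual_candidate(c("IPR001138", "IPR007087"), cat)
  expect_true(r$dual)
  expect_equal(r$label, "Zn cluster+C2H2-like ZF")
  # two hits of the same accession: one class, never dual
  expect_false(is_dual_candidate(c("IPR001138", "IPR001138"), cat)$dual)
  # merged zinc fingers count as one class
  expect_false(is_dual_candidate(c("IPR007087", "IPR001878"), cat)$dual)
  expect_false(is_dual_candidate(c("IPR007087", "IPR000571"), cat)$dual)
  # unknown accession is a classification error
  expect_error(is_dual_candidate(c("IPR001138", "IPR999999"), cat),
               "IPR999999")
})

test_that("HTH-internal pairs are rejected except the whitelisted ones", {
  cat <- default_dbd_catalog()
  # homeodomain + CUT and homeodomain + lambda repressor-like are known
  # dual-specificity TFs despite the shared HTH superclass
  expect_true(is_dual_candidate(c("IPR001356", "IPR003350"), cat)$dual)
  expect_true(is_dual_candidate(c("IPR001356", "IPR010982"), cat)$dual)
  expect_equal(is_dual_candidate(c("IPR001356", "IPR010982"), cat)$label,
               "HD+lambda repressor-like")
  # two homeodomain-class accessions are one specificity
  expect_false(is_dual_candidate(c("IPR001356", "IPR009057"), cat)$dual)
  # CUT + lambda-repressor-like is not whitelisted
  expect_false(is_dual_candidate(c("IPR003350", "IPR010982"), cat)$dual)
})

test_that("prevalence filter keeps combinations in >= 5 genomes", {
  combos <- tibble::tibble(label = c("a", "b", "c"),
                           n_genomes = c(140L, 4L, 5L))
  out <- apply_prevalence_filter(combos)
  expect_equal(out$prevalent, c(TRUE, FALSE, TRUE))
})

test_that("insignificant combinations merge into the largest background", {
  # the worked example: one GATA+bZIP gene against ~5,600 bZIP and ~3,000
  # GATA single-DBD genes merges into bZIP
  combos <- tibble::tibble(
    label = c("GATA+bZIP-like", "kept"),
    families = list(c("GATA", "bZIP"), c("Zn cluster", "C2H2/CCHC/CCCH")),
    failing = c(TRUE, FALSE),
    status = c("", "accepted"),
    merge_target = NA_character_)
  bg <- c(bZIP = 5600L, GATA = 3000L)
  out <- merge_insignificant(combos, bg)
  expect_equal(out$status, c("merged:bZIP", "accepted"))
  expect_equal(out$merge_target[1], "bZIP")
  # no background anywhere: retained as its own insignificant group
  combos$families[[1]] <- c("CUT", "lambda repressor-like/POU")
  out2 <- merge_insignificant(combos, bg)
  expect_equal(out2$status[1], "retained-insignificant")
})

test_that("the full classifier resolves the worked GATA+bZIP example", {
  cat <- default_dbd_catalog()
  # a larger bZIP than GATA background across 10 species; one gene in one
  # species combines both domains
  sp <- sprintf("s%02d", 1:10)
  genes <- make_genes(
    c(sp, sp[1:5], sp, "s01"),
    c(as.list(rep("IPR004827", 15)), as.list(rep("IPR000679", 10)),
      list(c("IPR000679", "IPR004827"))))
  res <- classify_dstf(genes, cat)
  combo <- res$combinations
  expect_equal(nrow(combo), 1)
  expect_equal(combo$status, "merged:bZIP")
  assigned <- assign_families(genes, cat, res)
  expect_equal(assigned$family[26], "bZIP")
  expect_false(assigned$dual[26])
  # merging conserves the total gene count
  m <- build_tfome_matrix(assigned, make_meta(sp))
  expect_equal(sum(m$counts), nrow(genes))
})

test_that("accepted combinations keep their genes and label", {
  cat <- default_dbd_catalog()
  sp <- sprintf("s%02d", 1:6)
  genes <- make_genes(
    c(sp, sp),
    c(as.list(rep("IPR001138", 6)),
      replicate(6, c("IPR007087", "IPR007087", "IPR001138"),
                simplify = FALSE)))
  res <- classify_dstf(genes, cat)
  expect_equal(res$combinations$status, "accepted")
  expect_equal(res$combinations$n_genomes, 6L)
  assigned <- assign_families(genes, cat, res)
  expect_true(all(assigned$dual[7:12]))
  expect_true(all(assigned$family[7:12] == "Zn cluster+C2H2-like ZF"))
  # classification is deterministic: rerunning changes nothing
  expect_identical(res$combinations, classify_dstf(genes, cat)$combinations)
})

test_that("every recipe architecture maps to its canonical label", {
  cat <- default_dbd_catalog()
  recipes <- default_dstf_recipes()
  for (label in names(recipes)) {
    r <- is_dual_candidate(recipes[[label]], cat)
    expect_true(r$dual, info = label)
    expect_equal(r$label, label)
  }
})

test_that("dsTF summary reports genome percentages and the dsTF fraction", {
  sp <- sprintf("s%03d", 1:192)
  counts <- cbind(
    "Zn cluster" = rep(10L, 192),
    "Zn cluster+C2H2-like ZF" = c(rep(2L, 140), rep(0L, 52)))
  rownames(counts) <- sp
  m <- make_matrix(counts)
  combos <- tibble::tibble(label = "Zn cluster+C2H2-like ZF",
                           status = "accepted")
  s <- summarize_dstf(m, combos)
  expect_equal(s$table$n_genomes, 140L)
  expect_equal(s$table$pct_genomes, 73)
  expect_equal(s$table$max_per_genome, 2L)
  # fraction agrees with a brute-force recount over the cells
  expect_equal(s$fraction, sum(counts[, 2]) / sum(counts))
  # no dsTFs: empty table, fraction 0
  s0 <- summarize_dstf(m, combos[0, ])
  expect_equal(nrow(s0$table), 0)
  expect_equal(s0$fraction, 0)
})
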