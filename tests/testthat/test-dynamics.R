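test_that("r_squared matches the determination-coefficient formula", {
  y <- c(3, 7, 11, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # SSE = 1, SST = 2
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("noiseless power laws are recovered exactly", {
  p <- round(10^seq(log10(3000), log10(30000), length.out = 50))
  counts <- round(0.003 * p)
  fit <- fit_power_law(counts, p)
  expect_true(fit$defined)
  expect_lt(abs(fit$exponent - 1), 0.02)
  expect_gt(fit$r2, 0.99)
})

test_that("zero-count genomes are ignored by the exponent calculation", {
  p <- c(3000, 5000, 8000, 12000, 18000, 25000, 4000, 6000, 9000, 15000)
  counts <- c(10, 15, 22, 30, 41, 52, 0, 0, 0, 0)
  fit <- fit_power_law(counts, p)
  expect_equal(fit$n_used, 6L)
  expect_equal(fit$n_total, 10L)
})

test_that("constant counts fit as a flat line; tiny groups are undefined", {
  p <- c(3000, 9000, 27000, 15000)
  fit <- fit_power_law(rep(4, 4), p)
  expect_equal(fit$exponent, 0)
  expect_equal(fit$intercept, log10(4))
  fit2 <- fit_power_law(c(3, 5), p[1:2])
  expect_false(fit2$defined)
  expect_true(is.na(fit2$exponent))
})

test_that("the exponent is invariant to rescaling proteome size", {
  set.seed(5)
  p <- round(10^runif(40, log10(3000), log10(30000)))
  counts <- round(0.01 * p^0.8 * rlnorm(40, 0, 0.2))
  f1 <- fit_power_law(counts, p)
  f2 <- fit_power_law(counts, p * 7)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-10)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
})

test_that("power-law parameter recovery across the exponent grid", {
  set.seed(20)
  for (b in c(0, 0.5, 1.0, 1.5)) {
    ok <- 0
    for (rep in 1:20) {
      p <- 10^runif(50, log10(3000), log10(30000))
      counts <- p^b * rlnorm(50, 0, 0.2)
      fit <- fit_power_law(counts, p)
      if (abs(fit$exponent - b) <= 3 * fit$se) ok <- ok + 1
    }
    expect_gte(ok, 19)
  }
})

test_that("families split into small and abundant at mean 5", {
  expect_equal(classify_size(c(2, 2, 2.3)), "small")
  expect_equal(classify_size(rep(40, 10)), "abundant")
  expect_equal(classify_size(rep(5, 8)), "abundant")  # boundary: not small
  expect_equal(classify_size(c(4.9, 5.1)), "abundant")
})

test_that("responsiveness eligibility and thresholds match the rules", {
  p <- round(10^seq(log10(3000), log10(30000), length.out = 30))
  # present in only 8 species: too few
  counts <- c(rep(0, 22), 6:13)
  cls <- classify_responsiveness(fit_power_law(counts, p), counts)
  expect_equal(cls$eligibility, "too-few-species")
  expect_equal(cls$responsiveness, "not-assessed")
  # present everywhere but never exceeding 5 genes
  counts2 <- rep(c(4, 5), 15)
  cls2 <- classify_responsiveness(fit_power_law(counts2, p), counts2)
  expect_equal(cls2$eligibility, "never-exceeds-5")
  # eligible, steep and clean: responsive
  counts3 <- round(0.003 * p^1.1)
  cls3 <- classify_responsiveness(fit_power_law(counts3, p), counts3)
  expect_equal(cls3$eligibility, "eligible")
  expect_equal(cls3$responsiveness, "responsive")
  # eligible but shallow: non-responsive
  counts4 <- round(2 * p^0.3)
  cls4 <- classify_responsiveness(fit_power_law(counts4, p), counts4)
  expect_equal(cls4$responsiveness, "non-responsive")
})

test_that("eligibility boundaries are strict", {
  p <- round(10^seq(log10(3000), log10(30000), length.out = 30))
  # exactly 10 nonzero species is still too few (> 10 required)
  counts <- c(rep(0, 20), rep(8, 10))
  expect_equal(classify_responsiveness(fit_power_law(counts, p),
                                       counts)$eligibility,
               "too-few-species")
  # 11 nonzero species with max exactly 5: still ineligible (> 5 required)
  counts2 <- c(rep(0, 19), rep(5, 11))
  expect_equal(classify_responsiveness(fit_power_law(counts2, p),
                                       counts2)$eligibility,
               "never-exceeds-5")
})

test_that("raising the exponent threshold never creates responsives", {
  set.seed(9)
  p <- 10^runif(40, log10(3000), log10(30000))
  for (b in c(0.3, 0.6, 0.9)) {
    counts <- round(0.01 * p^b * rlnorm(40, 0, 0.2)) + 1
    fit <- fit_power_law(counts, p)
    verdicts <- vapply(seq(0.1, 1.5, by = 0.1), function(thr) {
      classify_responsiveness(fit, counts,
                              exp_threshold = thr)$responsiveness ==
        "responsive"
    }, logical(1))
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})

test_that("single-species expansions are flagged by the outlier rule", {
  # the glucocorticoid-receptor-like picture: background at <= 35 genes,
  # one species at 270
  counts <- stats::setNames(c(25, 31, 35, 28, 30, 270),
                            sprintf("s%d", 1:6))
  expect_equal(detect_single_expansions(counts), "s6")
  expect_length(detect_single_expansions(stats::setNames(rep(30, 6),
                                                         sprintf("s%d", 1:6))),
                0)
  # below the absolute floor: 16 < 20, never an outlier
  expect_length(detect_single_expansions(
    stats::setNames(c(4, 4, 4, 4, 16), sprintf("s%d", 1:5))), 0)
  expect_error(detect_single_expansions(stats::setNames(c(1, 50), c("a", "b"))),
               "5 genomes")
})

test_that("expansion correction masks only the flagged cells", {
  counts <- cbind(famA = c(30L, 28L, 270L, 33L, 25L),
                  famB = c(5L, 6L, 7L, 5L, 6L))
  rownames(counts) <- sprintf("s%d", 1:5)
  m <- make_matrix(counts)
  flags <- flag_expansions(m, group_by = NULL)
  expect_equal(flags$species_id, "s3")
  expect_equal(flags$family, "famA")
  mc <- correct_for_expansions(m, flags)
  expect_true(is.na(mc$counts["s3", "famA"]))
  # locality: every other cell untouched
  expect_identical(mc$counts[, "famB"], m$counts[, "famB"])
  expect_identical(mc$counts[c("s1", "s2", "s4", "s5"), "famA"],
                   m$counts[c("s1", "s2", "s4", "s5"), "famA"])
  # conservation: totals drop by exactly the removed genes
  expect_equal(sum(tf_totals(mc)), sum(tf_totals(m)) - 270L)
  expect_equal(mc$masked$count, 270L)
  # no flags: identity
  expect_identical(correct_for_expansions(m, flags[0, ]), m)
})

test_that("corrected fits recover the background exponent", {
  set.seed(14)
  p <- round(10^runif(50, log10(3000), log10(30000)))
  counts <- as.integer(round(12 * p^0.1 * rlnorm(50, 0, 0.2)))
  counts_mat <- matrix(counts, ncol = 1,
                       dimnames = list(sprintf("s%02d", 1:50), "fam"))
  m <- make_matrix(counts_mat, make_meta(rownames(counts_mat),
                                         proteome_size = p))
  big <- rownames(counts_mat)[which.max(p)]
  m_exp <- inject_expansion(m, big, "fam", 300)
  uncorrected <- fit_power_law(m_exp$counts[, 1], p)
  flags <- flag_expansions(m_exp, group_by = NULL)
  expect_equal(flags$species_id, big)
  corrected_m <- correct_for_expansions(m_exp, flags)
  corrected <- fit_power_law(corrected_m$counts[, 1], p)
  expect_gt(uncorrected$exponent, corrected$exponent)
  expect_lt(abs(corrected$exponent - 0.1), 0.1)
})

test_that("whole-TFome group fits respect exclusions", {
  set.seed(8)
  n <- 30
  p <- round(10^runif(n, log10(3000), log10(30000)))
  zn <- as.integer(round(0.003 * p^1.2 * rlnorm(n, 0, 0.1)))
  flat <- as.integer(round(30 * rlnorm(n, 0, 0.1)))
  counts <- cbind("Zn cluster" = zn, "flatfam" = flat)
  rownames(counts) <- sprintf("s%02d", 1:n)
  meta <- make_meta(rownames(counts), proteome_size = p,
                    wgd = c(TRUE, rep(FALSE, n - 1)))
  m <- tfome_matrix(counts, meta)
  fit <- fit_group_tfome(m, "GrpA")
  # WGD-flagged species are excluded from the fit
  expect_equal(fit$n_total, n - 1L)
  # subtracting the dominant responsive family flattens the fit
  fit_noZn <- fit_group_tfome(m, "GrpA", exclude_families = "Zn cluster")
  expect_lt(fit_noZn$exponent, fit$exponent)
  # groups of fewer than 3 species have no fit
  m2 <- tfome_matrix(counts[1:2, ], meta[1:2, ])
  expect_false(fit_group_tfome(m2, "GrpA")$defined)
})

test_that("the dynamics report covers retained families per group", {
  m <- simulate_matrix(preset_fungal()[5], seed = 31)  # Basidiomycota only
  dyn <- tfome_dynamics(m)
  expect_true(all(dyn$report$family %in% colnames(m$counts)))
  expect_true(all(dyn$report$group == "Basidiomycota"))
  resp <- dyn$report$family[dyn$report$responsiveness == "responsive"]
  expect_true("C2H2/CCHC/CCCH" %in% resp)
  # frozen background families are never responsive
  expect_false("TFIID" %in% resp)
})
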