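make_cm <- function(counts, conditions = c("BH", "BH", "BH", "BN", "BN", "BN"),
                    lengths = NULL) {
  samples <- paste0(conditions, "-", stats::ave(seq_along(conditions),
                                                conditions, FUN = seq_along))
  colnames(counts) <- samples
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  count_matrix(counts, stats::setNames(conditions, samples),
               lengths = lengths)
}

test_that("fpkm matches the closed form and its invariances", {
  counts <- matrix(c(10, 999990), nrow = 2)
  colnames(counts) <- "BH-1"
  rownames(counts) <- c("a", "b")
  cm <- count_matrix(counts, c(`BH-1` = "BH"),
                     lengths = c(a = 1000, b = 500))
  f <- fpkm(cm)
  expect_equal(f["a", 1], 10) # 10 * 1e9 / (1000 * 1e6)

  set.seed(1)
  counts <- matrix(rpois(24, 50) + 1, nrow = 4)
  counts[2, 1] <- 0
  cm <- make_cm(counts, lengths = stats::setNames(c(500, 1000, 1500, 2000),
                                                  paste0("f", 1:4)))
  f <- fpkm(cm)
  expect_equal(f[2, 1], 0)
  # doubling a column leaves its FPKM unchanged
  cm2 <- cm
  cm2$counts[, 3] <- cm2$counts[, 3] * 2L
  expect_equal(fpkm(cm2)[, 3], f[, 3])
  # errors name the offender
  cm_bad <- cm
  cm_bad$lengths["f2"] <- 0
  expect_error(fpkm(cm_bad), "f2")
  cm_bad2 <- cm
  cm_bad2$counts[, 2] <- 0L
  expect_error(fpkm(cm_bad2), colnames(cm$counts)[2], fixed = TRUE)
})

test_that("tpm columns sum to one million and split symmetrically", {
  one <- count_matrix(matrix(42L, 1, 1, dimnames = list("f1", "BH-1")),
                      c(`BH-1` = "BH"))
  expect_equal(unname(tpm_mirna(one)[1, 1]), 1e6)

  two <- count_matrix(matrix(c(7L, 7L), 2, 1,
                             dimnames = list(c("a", "b"), "BN-1")),
                      c(`BN-1` = "BN"))
  expect_equal(unname(tpm_mirna(two)[, 1]), c(5e5, 5e5))

  set.seed(42)
  cm <- make_cm(matrix(rpois(60, 30) + 1, nrow = 10))
  expect_equal(unname(colSums(tpm_mirna(cm))), rep(1e6, 6),
               tolerance = 1e-6)
})

test_that("differential_test: null identity, antisymmetry, degenerate cases", {
  set.seed(7)
  block <- matrix(rpois(30, 100), nrow = 10)
  cm <- make_cm(cbind(block, block)) # BH columns identical to BN columns
  dt <- differential_test(cm)
  expect_equal(dt$log2fc, rep(0, 10))
  expect_equal(dt$p_value, rep(1, 10))

  set.seed(8)
  cm <- make_cm(matrix(rpois(60, 80), nrow = 10))
  dt1 <- differential_test(cm)
  cm_swapped <- cm
  cm_swapped$design[] <- ifelse(cm$design == "BH", "BN", "BH")
  dt2 <- differential_test(cm_swapped)
  expect_equal(dt2$log2fc, -dt1$log2fc)
  expect_equal(dt2$p_value, dt1$p_value)

  # all-constant feature with equal means -> p = 1 by convention
  cm0 <- make_cm(matrix(5L, nrow = 1, ncol = 6))
  expect_equal(differential_test(cm0)$p_value, 1)

  expect_error(differential_test(make_cm(matrix(1L, 2, 3),
                                         c("BH", "BN", "BN"))),
               ">= 2 samples")
})

test_that("bh_adjust agrees with oracles and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(11)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
    expect_equal(bh_adjust(p), oracle_bh(p))
    # order invariance and p <= q
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(-0.1)), "0, 1")
})

test_that("call_de applies strict printed inequalities", {
  stats_df <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    log2fc = c(2, 1.0, -2, -1.5, 0.2),
    p_value = rep(0.001, 5),
    fdr = c(0.01, 0.01, 0.05, 0.01, 0.01))
  out <- call_de(stats_df)
  expect_equal(out$call, c("up", "null", "null", "down", "null"))
  # b: log2fc exactly 1 -> null; c: fdr exactly 0.05 -> null
})

test_that("2^-ddCt identities", {
  expect_equal(delta_delta_ct(20, 15, 22, 17), 1.0)
  expect_equal(delta_delta_ct(19, 15, 22, 17), 2.0)  # ddCt = -1
  expect_equal(delta_delta_ct(25, 17, 22, 17), 0.125) # ddCt = 3
  expect_error(delta_delta_ct(Inf, 15, 22, 17), "finite")
})

test_that("stand-in DE test is roughly calibrated on NB nulls (quick check)", {
  # full 200-seed calibration lives in test-acceptance.R
  fp <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_mrna = 500, n_lncrna = 5, n_mirna = 14,
                      n_planted_triads = 0, n_anti_pairs = 0,
                      n_decoy_site_pairs = 0, n_decoy_coexpressed_pairs = 0,
                      de_fraction = 0)
    cnt <- generate_counts(cfg, plan_truth(cfg))
    mean(differential_test(cnt$mrna)$p_value < 0.05)
  }, numeric(1))
  expect_gt(mean(fp), 0.02)
  expect_lt(mean(fp), 0.08)
})
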