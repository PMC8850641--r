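test_that("correlation coefficients match hand-computed closed forms", {
  expect_equal(spearman_rho(1:3, c(1, 3, 2)), 0.5) # 1 - 6*2/(3*8)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(pearson_r(1:4, 2 * (1:4) + 3), 1)
  expect_equal(pearson_r(1:4, -(1:4)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8) # Sigma forms
  # rank invariance under strictly monotone transforms
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
  expect_equal(spearman_rho(x, y^3 + 5 * y), spearman_rho(x, y))
  # guards
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(pearson_r(c(1, 2), c(2, 1)), "3 samples")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("sponge_test equals the combinatorial sum and behaves at edges", {
  expect_equal(sponge_test(character(0), c("a", "b"), 10)$p_value, 1)
  expect_equal(sponge_test(letters[1:5], letters[1:5], 5)$p_value, 1)
  st <- sponge_test(paste0("m", 1:5), paste0("m", c(1:3, 6:8)), 20)
  expect_equal(st$k, 3)
  expect_equal(st$p_value, oracle_hyper_sum(3, 5, 6, 20))
  expect_error(sponge_test(paste0("m", 1:5), paste0("m", 1:3), 4),
               "smaller than the union")
  # p monotone non-increasing in k for fixed (N, K, n)
  p_by_k <- vapply(0:4, function(k) oracle_hyper_sum(k, 4, 4, 12),
                   numeric(1))
  expect_true(all(diff(p_by_k) <= 0))
})

test_that("pair filters use strict thresholds on computed coefficients", {
  set.seed(14)
  x <- matrix(rnorm(18), 3, 6,
              dimnames = list(paste0("m", 1:3), paste0("s", 1:6)))
  y <- matrix(rnorm(18), 3, 6,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:6)))
  pairs <- expand.grid(mirna_id = rownames(x), target_id = rownames(y),
                       stringsAsFactors = FALSE)
  rho <- spearman_rho(x["m1", ], y["t1", ])
  # threshold equal to the computed value -> excluded (strict <)
  kept <- negative_pairs(x, y, pairs, rho_threshold = rho)
  expect_false(any(kept$mirna_id == "m1" & kept$target_id == "t1"))
  kept2 <- negative_pairs(x, y, pairs, rho_threshold = rho + 1e-9)
  expect_true(any(kept2$mirna_id == "m1" & kept2$target_id == "t1"))

  r <- pearson_r(x["m2", ], y["t2", ])
  co <- coexpressed_pairs(x, y, r_threshold = r)
  expect_false(any(co$lncrna_id == "m2" & co$mrna_id == "t2"))
  co2 <- coexpressed_pairs(x, y, r_threshold = r - 1e-9)
  expect_true(any(co2$lncrna_id == "m2" & co2$mrna_id == "t2"))

  # constant features are excluded with a status, not a coefficient
  xc <- x; xc["m3", ] <- 1
  keptc <- negative_pairs(xc, y, pairs, rho_threshold = 0.99)
  expect_false("m3" %in% keptc$mirna_id)
  expect_true(any(attr(keptc, "excluded")$mirna_id == "m3"))
  coc <- coexpressed_pairs(xc, y, r_threshold = -1 + 1e-9)
  expect_true("m3" %in% attr(coc, "excluded"))
  expect_error(negative_pairs(x, y, data.frame(mirna_id = "zz",
                                               target_id = "t1")), "zz")
})

test_that("coexpressed_pairs equals the brute-force double loop", {
  set.seed(15)
  lx <- matrix(rnorm(20 * 6), 20, 6,
               dimnames = list(paste0("l", 1:20), paste0("s", 1:6)))
  mx <- matrix(rnorm(20 * 6), 20, 6,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  got <- coexpressed_pairs(lx, mx, r_threshold = 0.5)
  want <- 0L
  for (i in 1:20) {
    for (j in 1:20) {
      if (oracle_pearson(lx[i, ], mx[j, ]) > 0.5) want <- want + 1L
    }
  }
  expect_equal(nrow(got), want)
})

test_that("network assembly enforces >=1 shared miRNA and strict p", {
  neg <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m1", "m2", "m3", "m4", "m5"),
    target_id = c("l1", "l1", "l1", "g1", "g1", "g1", "g2", "g3"),
    method = "spearman", coefficient = -0.95, n_samples = 6)
  coex <- data.frame(lncrna_id = c("l1", "l2"), mrna_id = c("g1", "g2"),
                     method = "pearson", coefficient = 0.99, n_samples = 6)
  net <- build_cerna_network(neg, coex, universe = paste0("m", 1:10))
  # l2-g2 shares no miRNA with l2 (none negative with l2) -> absent
  expect_equal(net$triads$lncrna_id, "l1")
  expect_equal(net$triads$k, 3)
  st <- sponge_test(c("m1", "m2", "m3"), c("m1", "m2", "m3"), 10)
  expect_equal(net$triads$p_value, st$p_value)
  # threshold exactly at the computed p -> excluded (strict <)
  net2 <- build_cerna_network(neg, coex, universe = paste0("m", 1:10),
                              p_threshold = st$p_value)
  expect_equal(nrow(net2$triads), 0)
  expect_error(build_cerna_network(neg[0, ], coex), "empty miRNA universe")
})

test_that("every emitted triad passes independent re-verification", {
  run <- run_small_pipeline(3)
  expect_gt(nrow(run$network$triads), 0)
  tri <- expand_triads(run$network$triads)
  for (i in seq_len(nrow(tri))) {
    l <- tri$lncrna_id[i]; m <- tri$mirna_id[i]; g <- tri$mrna_id[i]
    expect_lt(oracle_spearman(run$expr$mirna[m, ], run$expr$lncrna[l, ]),
              -0.7)
    expect_lt(oracle_spearman(run$expr$mirna[m, ], run$expr$mrna[g, ]),
              -0.7)
    expect_gt(oracle_pearson(run$expr$lncrna[l, ], run$expr$mrna[g, ]), 0.9)
  }
  for (i in seq_len(nrow(run$network$triads))) {
    row <- run$network$triads[i, ]
    expect_lt(row$p_value, 0.05)
    expect_equal(row$p_value,
                 oracle_hyper_sum(row$k, row$K, row$n, row$N))
  }
})

test_that("decoy structures are rejected by the matching filter", {
  run <- run_small_pipeline(3)
  plan <- run$plan
  # decoy site pairs (co-directional expression): never negative pairs
  D <- run$config$n_decoy_site_pairs
  A <- run$config$n_anti_pairs
  T_ <- run$config$n_planted_triads
  P <- ceiling(T_ / run$config$mirnas_per_cerna_pair)
  decoy_mirs <- plan$ids$mirna[(T_ + A + 1):(T_ + A + D)]
  expect_false(any(run$negative$mirna_id %in% decoy_mirs))
  # decoy co-expressed lncRNAs never reach the triad table
  C <- run$config$n_decoy_coexpressed_pairs
  decoy_lncs <- plan$ids$lncrna[(P + 1):(P + C)]
  expect_false(any(run$network$triads$lncrna_id %in% decoy_lncs))
})

test_that("SIF export round-trips the edge set", {
  run <- run_small_pipeline(3)
  out <- withr::local_tempdir()
  node_attr <- do.call(rbind, lapply(run$de, function(t) {
    data.frame(feature_id = t$feature_id, call = t$call)
  }))
  paths <- export_network(run$network, out, node_attributes = node_attr)
  edges <- read_sif(paths[["sif"]])
  expect_equal(edges, run$network$edges, ignore_attr = TRUE)
  nodes <- read_tsv_file(paths[["nodes"]])
  tri <- expand_triads(run$network$triads)
  expect_equal(nrow(nodes),
               length(unique(c(tri$lncrna_id, tri$mirna_id, tri$mrna_id))))
  # triad (L, {M}, G) appears as both SIF edge lines
  expect_true(all(paste(tri$lncrna_id, "lncRNA-miRNA", tri$mirna_id) %in%
                    paste(edges$source, edges$interaction, edges$target)))
  expect_true(all(paste(tri$mirna_id, "miRNA-mRNA", tri$mrna_id) %in%
                    paste(edges$source, edges$interaction, edges$target)))
})
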