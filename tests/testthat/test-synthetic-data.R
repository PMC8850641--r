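test_that("config validation catches impossible worlds", {
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(triad_correlation_strength = 1.5), "strength")
  expect_error(sim_config(n_planted_triads = 60, n_mirna = 48), "n_mirna")
  expect_error(sim_config(seed = 1.5), "seed")
  expect_error(generate_gene_models(tiny_config(genome_length = 1000)),
               "chr1")
})

test_that("identical seeds give byte-identical fixtures", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim1 <- simulate_cerna_experiment(tiny_config(2))
  sim2 <- simulate_cerna_experiment(tiny_config(2))
  write_fixture(sim1, d1)
  write_fixture(sim2, d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  # a different seed changes the data
  sim3 <- simulate_cerna_experiment(tiny_config(3))
  expect_false(identical(sim1$counts$mrna$counts, sim3$counts$mrna$counts))
})

test_that("five lncRNAs stratify into exactly one per category", {
  cfg <- sim_config(seed = 4, n_mrna = 10, n_lncrna = 5, n_mirna = 10,
                    n_planted_triads = 4, n_anti_pairs = 2,
                    n_decoy_site_pairs = 1, n_decoy_coexpressed_pairs = 1)
  models <- generate_gene_models(cfg)
  expect_equal(sort(unname(models$lnc_categories)),
               sort(c("sense", "antisense", "intronic", "bidirectional",
                      "intergenic")))
})

test_that("planted categories and planted sites round-trip", {
  cfg <- tiny_config(6)
  plan <- plan_truth(cfg)
  models <- generate_gene_models(cfg)
  cats <- classify_lncrnas(models$lncrnas, models$genes)
  expect_equal(cats[names(models$lnc_categories)], models$lnc_categories)

  seqs <- generate_sequences(cfg, models, plan$sites_plan)
  targets <- c(seqs$lncrna, seqs$utr)
  ps <- seqs$planted_sites
  expect_equal(nrow(ps), nrow(plan$sites_plan))
  for (i in seq_len(nrow(ps))) {
    s <- find_seed_sites(seqs$mirna[[ps$mirna_id[i]]],
                         targets[[ps$target_id[i]]])
    expect_true(any(s$site_type == "8mer" & s$start == ps$start[i]))
  }
  # pairs NOT in the plan have zero 7mer-or-better sites
  set.seed(1)
  planted_keys <- paste(plan$sites_plan$mirna_id, plan$sites_plan$target_id)
  all_pairs <- expand.grid(m = names(seqs$mirna), t = names(targets),
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[!paste(all_pairs$m, all_pairs$t) %in% planted_keys, ]
  take <- all_pairs[sample(nrow(all_pairs), 60), ]
  for (i in seq_len(nrow(take))) {
    s <- find_seed_sites(seqs$mirna[[take$m[i]]], targets[[take$t[i]]])
    expect_false(any(site_rank(s$site_type) >= site_rank("7mer")),
                 label = paste(take$m[i], take$t[i]))
  }
})

test_that("miRNA lengths have mode 22 over ~200 draws", {
  lens <- integer(0)
  for (s in 1:5) {
    cfg <- sim_config(seed = s, n_mirna = 48, n_mrna = 20, n_lncrna = 10,
                      n_planted_triads = 8, n_anti_pairs = 4,
                      n_decoy_site_pairs = 2, n_decoy_coexpressed_pairs = 2)
    seqs <- generate_sequences(cfg, generate_gene_models(cfg),
                               plan_truth(cfg)$sites_plan)
    lens <- c(lens, nchar(seqs$mirna))
  }
  expect_gte(length(lens), 200)
  tags <- lapply(seq_along(lens), function(i) srna_tag(random_rna(lens[i])))
  expect_equal(length_distribution(tags)$mode, 22L)
  expect_true(all(lens %in% 21:23))
})

test_that("counts obey NB moments and null symmetry", {
  # 1000 replicates, no depth variation or latent factors: the sample
  # variance must track mu + phi * mu^2, clearly away from Poisson
  cfg <- sim_config(seed = 8, n_mrna = 20, n_lncrna = 2, n_mirna = 2,
                    n_replicates_per_group = 500, n_planted_triads = 0,
                    n_anti_pairs = 0, n_decoy_site_pairs = 0,
                    n_decoy_coexpressed_pairs = 0, de_fraction = 0,
                    nb_dispersion = 0.1, library_size_cv = 0)
  cnt <- generate_counts(cfg, plan_truth(cfg))$mrna$counts
  m <- rowMeans(cnt)
  v <- apply(cnt, 1, stats::var)
  expected <- m + 0.1 * m^2
  expect_true(all(v / expected > 0.7 & v / expected < 1.4))
  expect_true(all(v > 2 * m)) # super-Poisson at these means

  # planted nulls are symmetric: mean log2fc across seeds ~ 0
  lfc <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, n_mrna = 40, n_lncrna = 2, n_mirna = 2,
                      n_planted_triads = 0, n_anti_pairs = 0,
                      n_decoy_site_pairs = 0, n_decoy_coexpressed_pairs = 0,
                      de_fraction = 0)
    mean(differential_test(generate_counts(cfg, plan_truth(cfg))$mrna)$log2fc)
  }, numeric(1))
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("truth bookkeeping is internally consistent", {
  sim <- simulate_cerna_experiment(tiny_config(9))
  tr <- sim$truth$planted_triads
  de <- sim$truth$de_flags
  flag_of <- stats::setNames(de$flag, de$feature_id)
  # every triad member is flagged DE
  expect_true(all(flag_of[tr$lncrna_id] != "null"))
  expect_true(all(flag_of[tr$mirna_id] != "null"))
  expect_true(all(flag_of[tr$mrna_id] != "null"))
  # every triad edge appears in the planted sites
  sites <- paste(sim$truth$planted_sites$mirna_id,
                 sim$truth$planted_sites$target_id)
  expect_true(all(paste(tr$mirna_id, tr$lncrna_id) %in% sites))
  expect_true(all(paste(tr$mirna_id, tr$mrna_id) %in% sites))
  # fixture truth table row count matches
  d <- withr::local_tempdir()
  write_fixture(sim, d)
  tt <- read_tsv_file(file.path(d, "truth_triads.tsv"))
  expect_equal(nrow(tt), sim$config$n_planted_triads)
})
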