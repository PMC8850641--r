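# Shared fixture builders. Everything is generated in code at test time.

# small, fast simulation config for module tests
tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_mrna = 20, n_lncrna = 10, n_mirna = 10,
             n_planted_triads = 4, mirnas_per_cerna_pair = 4,
             n_anti_pairs = 2, n_decoy_site_pairs = 1,
             n_decoy_coexpressed_pairs = 1, ...)
}

make_tm <- function(id, exons, strand = "+", chrom = "chr1",
                    biotype = "lncRNA") {
  transcript_model(id, chrom, strand,
                   data.frame(start = exons[, 1], end = exons[, 2]),
                   biotype = biotype)
}

make_gene <- function(id, exons, strand = "+", chrom = "chr1") {
  gene_model(id, chrom, strand,
             data.frame(start = exons[, 1], end = exons[, 2]))
}

# a 3-exon coding gene on [1001, 4100]: exons 1001-1500, 2301-2800,
# 3601-4100; introns 1501-2300 and 2801-3600; TSS 1001 (+) / 4100 (-)
ref_gene <- function(strand = "+") {
  make_gene("g1", cbind(c(1001, 2301, 3601), c(1500, 2800, 4100)),
            strand = strand)
}

# run the generator plus the full in-memory analysis chain; returns all
# intermediates so tests can re-verify any stage against the planted truth
run_small_pipeline <- function(seed, nb_dispersion = 1e-3, permute = FALSE,
                               config = NULL) {
  cfg <- config %||%
    sim_config(seed = seed, nb_dispersion = nb_dispersion)
  plan <- plan_truth(cfg)
  models <- generate_gene_models(cfg)
  seqs <- generate_sequences(cfg, models, plan$sites_plan)
  cnt <- generate_counts(cfg, plan)
  if (permute) {
    # break miRNA-target correlation while keeping the marginal counts;
    # permutations that map a condition group onto itself (or swap the two
    # groups wholesale) preserve the correlation structure and are not
    # label-breaking, so they are excluded from the permutation null
    set.seed(seed + 5000)
    ns <- ncol(cnt$mirna$counts)
    bh_idx <- which(cnt$mirna$design == "BH")
    repeat {
      perm <- sample(ns)
      grp <- perm[bh_idx]
      if (!setequal(grp, bh_idx) && !setequal(grp, setdiff(seq_len(ns),
                                                           bh_idx))) {
        break
      }
    }
    cnt$mirna$counts <- cnt$mirna$counts[, perm]
    colnames(cnt$mirna$counts) <- names(cnt$mirna$design)
  }
  de <- lapply(cnt, de_table)
  de_ids <- lapply(de, function(t) t$feature_id[t$call != "null"])
  mir <- seqs$mirna[names(seqs$mirna) %in% de_ids$mirna]
  lnc <- seqs$lncrna[names(seqs$lncrna) %in% de_ids$lncrna]
  utr <- seqs$utr[names(seqs$utr) %in% de_ids$mrna]
  pairs_lnc <- predict_targets(mir, lnc)
  pairs_mrna <- predict_targets(mir, utr)
  expr <- lapply(cnt, log_expression)
  neg <- rbind(negative_pairs(expr$mirna, expr$lncrna, pairs_lnc),
               negative_pairs(expr$mirna, expr$mrna, pairs_mrna))
  coex <- coexpressed_pairs(
    expr$lncrna[rownames(expr$lncrna) %in% de_ids$lncrna, , drop = FALSE],
    expr$mrna[rownames(expr$mrna) %in% de_ids$mrna, , drop = FALSE])
  net <- if (nrow(neg) > 0 && nrow(coex) > 0) {
    build_cerna_network(neg, coex)
  } else NULL
  list(config = cfg, plan = plan, models = models, sequences = seqs,
       counts = cnt, de = de, de_ids = de_ids, expr = expr,
       negative = neg, coexpressed = coex, network = net)
}

# fraction of planted triad rows present in the emitted network
triad_recovery <- function(run) {
  tr <- run$plan$triads
  if (is.null(run$network)) return(0)
  got <- expand_triads(run$network$triads)
  mean(paste(tr$lncrna_id, tr$mirna_id, tr$mrna_id) %in%
         paste(got$lncrna_id, got$mirna_id, got$mrna_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
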