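#' Simulation configuration
#'
#' Parameters of the synthetic two-condition (blind-side hypermelanotic
#' `BH` vs normal `BN`) skin-transcriptome experiment: a miniature genome
#' with protein-coding genes and lncRNAs of all five positional categories,
#' miRNA/UTR/lncRNA sequences with planted 8mer seed sites, and
#' negative-binomial count matrices with planted differential features and
#' planted ceRNA triads. All downstream stages are testable against the
#' returned ground truth.
#'
#' Planted triads are grouped into ceRNA pairs: each (lncRNA, mRNA) pair
#' shares a block of `mirnas_per_cerna_pair` miRNAs (one triad row per
#' shared miRNA), so the hypergeometric sponge test has a non-trivial
#' overlap to detect. Decoy structures make both filters individually
#' falsifiable: `n_anti_pairs` miRNA-mRNA pairs with sites and negative
#' correlation but no lncRNA partner; `n_decoy_site_pairs` miRNA-mRNA
#' pairs with a seed site but positively co-regulated expression (site
#' without correlation); `n_decoy_coexpressed_pairs` lncRNA-mRNA pairs
#' co-expressed without any shared miRNA site (correlation without sites).
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   fixtures.
#' @param n_mrna,n_lncrna,n_mirna Feature counts per RNA class.
#' @param n_replicates_per_group Replicates per condition (default 3, the
#'   BH-1..3 / BN-1..3 design).
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`).
#' @param base_mean_log_range Range (log2 scale) of per-feature base mean
#'   counts, drawn uniformly.
#' @param planted_de_lfc True |log2 fold change| of planted DE features.
#' @param n_planted_triads Number of planted (lncRNA, miRNA, mRNA) triad
#'   rows.
#' @param mirnas_per_cerna_pair Shared miRNAs per planted ceRNA pair.
#' @param triad_correlation_strength Multiplier in (0, 1] on the shared
#'   latent factor driving within-group co-expression of triad members.
#' @param latent_sd Standard deviation (log2 scale) of the per-sample
#'   latent factor.
#' @param n_anti_pairs,n_decoy_site_pairs,n_decoy_coexpressed_pairs Decoy
#'   structure counts (see Details).
#' @param de_fraction Fraction of unreserved features planted DE.
#' @param utr_length 3'UTR length (nt) for mRNA target sequences.
#' @param genome_length Chromosome length (nt); computed from the layout
#'   when `NULL`, and an error names the crowded chromosome when too small.
#' @param library_size_cv Coefficient of variation of the log-normal
#'   per-sample depth factors.
#' @param mirna_length_weights Sampling weights for miRNA lengths 21/22/23
#'   (mode 22).
#' @param n_terms,term_size_range Synthetic term-map shape for the
#'   enrichment stage.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mrna = 80L, n_lncrna = 40L, n_mirna = 48L,
                       n_replicates_per_group = 3L,
                       nb_dispersion = 0.01,
                       base_mean_log_range = c(6, 10),
                       planted_de_lfc = 2.0,
                       n_planted_triads = 8L,
                       mirnas_per_cerna_pair = 4L,
                       triad_correlation_strength = 1.0,
                       latent_sd = 0.25,
                       n_anti_pairs = 4L,
                       n_decoy_site_pairs = 2L,
                       n_decoy_coexpressed_pairs = 2L,
                       de_fraction = 0.15,
                       utr_length = 300L,
                       genome_length = NULL,
                       library_size_cv = 0.2,
                       mirna_length_weights = c(`21` = 0.2, `22` = 0.6,
                                                `23` = 0.2),
                       n_terms = 10L,
                       term_size_range = c(5L, 15L)) {
  cfg <- list(
    seed = assert_count(seed, "seed"),
    n_mrna = assert_count(n_mrna, "n_mrna", 1L),
    n_lncrna = assert_count(n_lncrna, "n_lncrna", 1L),
    n_mirna = assert_count(n_mirna, "n_mirna", 1L),
    n_replicates_per_group = assert_count(n_replicates_per_group,
                                          "n_replicates_per_group", 2L),
    nb_dispersion = nb_dispersion,
    base_mean_log_range = base_mean_log_range,
    planted_de_lfc = planted_de_lfc,
    n_planted_triads = assert_count(n_planted_triads, "n_planted_triads"),
    mirnas_per_cerna_pair = assert_count(mirnas_per_cerna_pair,
                                         "mirnas_per_cerna_pair", 1L),
    triad_correlation_strength = triad_correlation_strength,
    latent_sd = latent_sd,
    n_anti_pairs = assert_count(n_anti_pairs, "n_anti_pairs"),
    n_decoy_site_pairs = assert_count(n_decoy_site_pairs,
                                      "n_decoy_site_pairs"),
    n_decoy_coexpressed_pairs = assert_count(n_decoy_coexpressed_pairs,
                                             "n_decoy_coexpressed_pairs"),
    de_fraction = de_fraction,
    utr_length = assert_count(utr_length, "utr_length", 50L),
    genome_length = genome_length,
    library_size_cv = library_size_cv,
    mirna_length_weights = mirna_length_weights,
    n_terms = assert_count(n_terms, "n_terms", 1L),
    term_size_range = term_size_range,
    # genome layout (fixed shapes; generous spacing keeps categories clean)
    gene_n_exons = 3L, gene_exon_length = 500L, gene_intron_length = 800L,
    lnc_exon_length = 150L, lnc_intron_length = 100L,
    gene_spacing = 20000L, genome_margin = 5000L
  )
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stop("nb_dispersion must be > 0")
  }
  if (cfg$triad_correlation_strength <= 0 ||
      cfg$triad_correlation_strength > 1) {
    stop("triad_correlation_strength must be in (0, 1]")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("de_fraction must be in [0, 1]")
  }
  if (length(cfg$base_mean_log_range) != 2 ||
      diff(cfg$base_mean_log_range) < 0) {
    stop("base_mean_log_range must be an increasing pair")
  }
  if (cfg$n_planted_triads >
      min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna) * cfg$mirnas_per_cerna_pair) {
    stop("n_planted_triads exceeds what the feature counts can host")
  }
  if (cfg$n_planted_triads > cfg$n_mirna) {
    stop("n_planted_triads (", cfg$n_planted_triads,
         ") must be <= n_mirna (", cfg$n_mirna, ")")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d | %d mRNA, %d lncRNA, %d miRNA",
                     " | %dv%d | %d planted triad rows\n"),
              x$seed, x$n_mrna, x$n_lncrna, x$n_mirna,
              x$n_replicates_per_group, x$n_replicates_per_group,
              x$n_planted_triads))
  invisible(x)
}

sim_ids <- function(config) {
  list(mrna = sprintf("gene%04d", seq_len(config$n_mrna)),
       lncrna = sprintf("lnc%04d", seq_len(config$n_lncrna)),
       mirna = sprintf("miR%04d", seq_len(config$n_mirna)))
}

#' Plan the planted ground truth
#'
#' Deterministically (given the seed) assigns DE flags, latent-factor
#' groups, the seed-site plan and the planted triads. Triad members are
#' always flagged DE with coherent directions (lncRNA and mRNA together,
#' their miRNAs opposite), matching the repression model the pipeline is
#' meant to recover.
#'
#' @param config A [sim_config()].
#' @return List with per-class `de_flags`, `latent_groups`, `sites_plan`,
#'   `triads` and role bookkeeping.
#' @export
plan_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 11L))
  ids <- sim_ids(config)
  P <- ceiling(config$n_planted_triads /
                 config$mirnas_per_cerna_pair) # ceRNA pairs
  A <- config$n_anti_pairs
  D <- config$n_decoy_site_pairs
  C <- config$n_decoy_coexpressed_pairs
  if (config$n_mrna < P + A + D + C) {
    stop("n_mrna too small for the planted structures: need >= ",
         P + A + D + C)
  }
  if (config$n_lncrna < P + C) {
    stop("n_lncrna too small for the planted structures: need >= ", P + C)
  }
  if (config$n_mirna < config$n_planted_triads + A + D) {
    stop("n_mirna too small for the planted structures: need >= ",
         config$n_planted_triads + A + D)
  }

  flags <- list(
    mrna = stats::setNames(rep("null", config$n_mrna), ids$mrna),
    lncrna = stats::setNames(rep("null", config$n_lncrna), ids$lncrna),
    mirna = stats::setNames(rep("null", config$n_mirna), ids$mirna)
  )
  flip <- function(d) ifelse(d == "up", "down", "up")
  latent_groups <- list()
  sites <- list()
  triads <- list()

  # ceRNA pairs with shared miRNA blocks
  T_ <- config$n_planted_triads
  for (i in seq_len(P)) {
    lnc <- ids$lncrna[i]
    mrna <- ids$mrna[i]
    block <- ids$mirna[seq((i - 1) * config$mirnas_per_cerna_pair + 1,
                           min(i * config$mirnas_per_cerna_pair, T_))]
    dir <- sample(c("up", "down"), 1)
    flags$lncrna[lnc] <- dir
    flags$mrna[mrna] <- dir
    flags$mirna[block] <- flip(dir)
    latent_groups[[length(latent_groups) + 1]] <- data.frame(
      class = c("lncrna", "mrna", rep("mirna", length(block))),
      feature_id = c(lnc, mrna, block),
      sign = c(1, 1, rep(-1, length(block))), stringsAsFactors = FALSE)
    for (m in block) {
      sites[[length(sites) + 1]] <- data.frame(
        mirna_id = m, target_id = c(lnc, mrna),
        target_class = c("lncrna", "mrna"), stringsAsFactors = FALSE)
      triads[[length(triads) + 1]] <- data.frame(
        lncrna_id = lnc, mirna_id = m, mrna_id = mrna,
        stringsAsFactors = FALSE)
    }
  }
  # anti pairs: miRNA-mRNA with site and negative correlation (no lncRNA);
  # these enlarge the sponge-test universe without sharing miRNAs
  for (j in seq_len(A)) {
    mrna <- ids$mrna[P + j]
    mir <- ids$mirna[T_ + j]
    dir <- sample(c("up", "down"), 1)
    flags$mrna[mrna] <- dir
    flags$mirna[mir] <- flip(dir)
    latent_groups[[length(latent_groups) + 1]] <- data.frame(
      class = c("mrna", "mirna"), feature_id = c(mrna, mir),
      sign = c(1, -1), stringsAsFactors = FALSE)
    sites[[length(sites) + 1]] <- data.frame(
      mirna_id = mir, target_id = mrna, target_class = "mrna",
      stringsAsFactors = FALSE)
  }
  # decoy sites: seed site present but expression co-directional, so the
  # Spearman filter must reject the pair
  for (j in seq_len(D)) {
    mrna <- ids$mrna[P + A + j]
    mir <- ids$mirna[T_ + A + j]
    dir <- sample(c("up", "down"), 1)
    flags$mrna[mrna] <- dir
    flags$mirna[mir] <- dir
    sites[[length(sites) + 1]] <- data.frame(
      mirna_id = mir, target_id = mrna, target_class = "mrna",
      stringsAsFactors = FALSE)
  }
  # decoy co-expression: lncRNA-mRNA correlated but sharing no miRNA site,
  # so the >=1-shared-miRNA rule must drop the pair
  for (j in seq_len(C)) {
    lnc <- ids$lncrna[P + j]
    mrna <- ids$mrna[P + A + D + j]
    dir <- sample(c("up", "down"), 1)
    flags$lncrna[lnc] <- dir
    flags$mrna[mrna] <- dir
    latent_groups[[length(latent_groups) + 1]] <- data.frame(
      class = c("lncrna", "mrna"), feature_id = c(lnc, mrna),
      sign = c(1, 1), stringsAsFactors = FALSE)
  }
  # unreserved features: DE with probability de_fraction
  reserved <- list(
    mrna = ids$mrna[seq_len(P + A + D + C)],
    lncrna = ids$lncrna[seq_len(P + C)],
    mirna = ids$mirna[seq_len(T_ + A + D)]
  )
  for (cls in names(flags)) {
    free <- setdiff(names(flags[[cls]]), reserved[[cls]])
    de <- free[stats::runif(length(free)) < config$de_fraction]
    flags[[cls]][de] <- sample(c("up", "down"), length(de), replace = TRUE)
  }

  sites_plan <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna_id = character(0), target_id = character(0),
               target_class = character(0), stringsAsFactors = FALSE)
  triads <- if (length(triads)) do.call(rbind, triads) else
    data.frame(lncrna_id = character(0), mirna_id = character(0),
               mrna_id = character(0), stringsAsFactors = FALSE)
  list(ids = ids, de_flags = flags, latent_groups = latent_groups,
       sites_plan = sites_plan, triads = triads, reserved = reserved)
}

#' Generate the miniature genome
#'
#' Places `n_mrna` three-exon protein-coding genes on one chromosome with
#' generous spacing, then plants two-exon lncRNAs stratified over the five
#' positional categories (cycling sense, antisense, intronic,
#' bidirectional, intergenic), each placed so that [classify_lncrna()]
#' provably recovers its category: sense lncRNAs overlap a host exon on the
#' same strand, antisense ones overlap the host span on the opposite
#' strand, intronic ones sit strictly inside intron 1, bidirectional ones
#' start 100-900 nt upstream of the host TSS on the divergent strand, and
#' intergenic ones sit mid-gap, far from every gene and TSS.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (gene models), `lncrnas` (transcript models)
#'   and `lnc_categories` (named character vector of planted categories).
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  spacing <- config$gene_spacing
  margin <- config$genome_margin
  exl <- config$gene_exon_length
  inl <- config$gene_intron_length
  nex <- config$gene_n_exons
  gene_span <- nex * exl + (nex - 1) * inl
  needed <- 2L * margin + config$n_mrna * spacing
  genome_length <- config$genome_length %||% needed
  if (genome_length < needed) {
    stop("placement failure on chr1: genome_length ", genome_length,
         " cannot host ", config$n_mrna, " coding genes without forced ",
         "overlap (need >= ", needed, ")")
  }
  ids <- sim_ids(config)
  strands <- sample(c("+", "-"), config$n_mrna, replace = TRUE)
  genes <- lapply(seq_len(config$n_mrna), function(i) {
    gs <- margin + (i - 1L) * spacing + 1L
    ex_start <- gs + (seq_len(nex) - 1L) * (exl + inl)
    gene_model(ids$mrna[i], "chr1", strands[i],
               data.frame(start = ex_start, end = ex_start + exl - 1L))
  })

  lnc_span <- 2L * config$lnc_exon_length + config$lnc_intron_length
  categories <- LNC_CATEGORIES[((seq_len(config$n_lncrna) - 1L) %% 5L) + 1L]
  make_lnc <- function(id, s, strand) {
    e1 <- config$lnc_exon_length
    transcript_model(id, "chr1", strand,
                     data.frame(start = c(s, s + e1 +
                                            config$lnc_intron_length),
                                end = c(s + e1 - 1L, s + lnc_span - 1L)),
                     biotype = "lncRNA")
  }
  lncrnas <- vector("list", config$n_lncrna)
  for (j in seq_len(config$n_lncrna)) {
    host <- genes[[((j - 1L) %% config$n_mrna) + 1L]]
    gs <- model_span(host)["start"]
    ge <- model_span(host)["end"]
    id <- ids$lncrna[j]
    lncrnas[[j]] <- switch(
      categories[j],
      sense = make_lnc(id, gs + sample.int(exl - config$lnc_exon_length, 1),
                       host$strand),
      antisense = make_lnc(id, gs + exl + inl + sample.int(200L, 1),
                           setdiff(c("+", "-"), host$strand)),
      intronic = {
        room <- inl - lnc_span - 2L
        if (room < 1L) {
          stop("placement failure in intron of ", host$id,
               ": intron too short for a lncRNA")
        }
        make_lnc(id, gs + exl + 1L + sample.int(room, 1), host$strand)
      },
      bidirectional = {
        d <- sample(100:900, 1)
        if (host$strand == "+") {
          make_lnc(id, gs - d - lnc_span + 1L, "-")
        } else {
          make_lnc(id, ge + d, "+")
        }
      },
      intergenic = make_lnc(id, gs + spacing %/% 2L,
                            sample(c("+", "-"), 1))
    )
  }
  list(genes = genes, lncrnas = lncrnas,
       lnc_categories = stats::setNames(categories, ids$lncrna),
       genome_length = genome_length)
}

# fast 7mer-or-better check used inside the rejection sampler; `core` is
# the reverse complement of miRNA positions 2-7 and `m8c` the complement of
# position 8 (both DNA). Equivalent to filtering find_seed_sites() at
# rank >= 7mer; the equivalence is asserted in the test suite.
has_7mer_site <- function(core, m8c, tgt) {
  hits <- gregexpr(core, tgt, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(FALSE)
  n <- nchar(tgt)
  for (p in hits) {
    if (p >= 2 && substr(tgt, p - 1, p - 1) == m8c) return(TRUE)
    if (p + 6 <= n && substr(tgt, p + 6, p + 6) == "A") return(TRUE)
  }
  FALSE
}

# miRNA ids with a 7mer-or-better site on a sequence
mirnas_hitting <- function(target_seq, mirna_seqs) {
  cores <- rc_dna(substr(mirna_seqs, 2, 7))
  m8c <- rc_dna(substr(mirna_seqs, 8, 8))
  hit <- vapply(seq_along(mirna_seqs), function(i) {
    has_7mer_site(cores[i], m8c[i], target_seq)
  }, logical(1))
  names(mirna_seqs)[hit]
}

#' Generate miRNA, 3'UTR and lncRNA sequences with planted seed sites
#'
#' miRNA lengths are drawn from \{21, 22, 23\} nt with mode 22 and pairwise
#' distinct 6mer seed cores. Target backgrounds (mRNA 3'UTRs of
#' `utr_length` nt and lncRNA transcripts at their spliced length) are
#' rejection-sampled until free of 7mer-or-better sites for every
#' non-planted miRNA; each planted (miRNA, target) pair then receives one
#' exact 8mer site at a recorded position.
#'
#' @param config A [sim_config()].
#' @param models Output of [generate_gene_models()].
#' @param sites_plan The `sites_plan` of [plan_truth()] (`mirna_id`,
#'   `target_id`, `target_class` rows).
#' @param max_tries Rejection-sampling bound per sequence.
#' @return List with `mirna` (RNA-alphabet named vector), `lncrna` and
#'   `utr` (DNA named vectors) and `planted_sites` (`data.frame` with
#'   0-based `start` and `site_type = "8mer"`).
#' @export
generate_sequences <- function(config, models, sites_plan,
                               max_tries = 500L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 2L))
  ids <- sim_ids(config)

  lens <- sample(c(21L, 22L, 23L), config$n_mirna, replace = TRUE,
                 prob = config$mirna_length_weights)
  site_of <- function(mir_seq) paste0(rc_dna(substr(mir_seq, 2, 8)), "A")
  # seed cores must be pairwise distinct AND no miRNA may have a
  # 7mer-or-better match inside another miRNA's fixed 8mer site string;
  # such conflicts would survive any amount of background resampling
  mirna_dna <- character(config$n_mirna)
  cores <- character(config$n_mirna)
  m8cs <- character(config$n_mirna)
  sites <- character(config$n_mirna)
  for (i in seq_len(config$n_mirna)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- random_dna(lens[i])
      core_c <- rc_dna(substr(cand, 2, 7))
      m8c_c <- rc_dna(substr(cand, 8, 8))
      site_c <- site_of(cand)
      if (core_c %in% cores[seq_len(i - 1L)]) next
      clash <- FALSE
      for (j in seq_len(i - 1L)) {
        if (has_7mer_site(core_c, m8c_c, sites[j]) ||
            has_7mer_site(cores[j], m8cs[j], site_c)) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        mirna_dna[i] <- cand
        cores[i] <- core_c
        m8cs[i] <- m8c_c
        sites[i] <- site_c
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not draw ", config$n_mirna,
           " miRNAs with non-conflicting seed regions")
    }
  }
  names(mirna_dna) <- ids$mirna

  target_lengths <- c(
    stats::setNames(vapply(models$lncrnas, spliced_length, integer(1)),
                    vapply(models$lncrnas, function(m) m$id, character(1))),
    stats::setNames(rep(config$utr_length, config$n_mrna), ids$mrna)
  )
  planted_by_target <- split(sites_plan$mirna_id, sites_plan$target_id)

  site_string <- function(mir_seq) paste0(rc_dna(substr(mir_seq, 2, 8)), "A")
  seqs <- character(length(target_lengths))
  names(seqs) <- names(target_lengths)
  planted_rows <- list()
  for (t in names(target_lengths)) {
    L <- target_lengths[[t]]
    planted <- planted_by_target[[t]] %||% character(0)
    if (length(planted) * 10L > L) {
      stop("target ", t, " too short (", L, " nt) to host ",
           length(planted), " planted sites")
    }
    done <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- random_dna(L)
      pos <- integer(0)
      if (length(planted)) {
        slot <- L %/% length(planted)
        pos <- vapply(seq_along(planted), function(i) {
          (i - 1L) * slot + sample.int(slot - 9L, 1)
        }, integer(1))
        for (i in seq_along(planted)) {
          site <- site_string(mirna_dna[[planted[i]]])
          substr(cand, pos[i], pos[i] + 7L) <- site
        }
      }
      hit <- mirnas_hitting(cand, mirna_dna)
      if (setequal(hit, planted)) {
        ok <- TRUE
        for (i in seq_along(planted)) {
          s <- find_seed_sites(mirna_dna[[planted[i]]], cand, planted[i], t)
          s <- s[site_rank(s$site_type) >= site_rank("7mer"), ]
          if (!(nrow(s) == 1 && s$site_type == "8mer" &&
                s$start == pos[i] - 1L)) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          seqs[t] <- cand
          for (i in seq_along(planted)) {
            planted_rows[[length(planted_rows) + 1]] <- data.frame(
              mirna_id = planted[i], target_id = t, start = pos[i] - 1L,
              site_type = "8mer", stringsAsFactors = FALSE)
          }
          done <- TRUE
          break
        }
      }
    }
    if (!done) {
      stop("could not generate a background free of unintended seed sites ",
           "for target ", t, " after ", max_tries, " attempts")
    }
  }
  planted_sites <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame(mirna_id = character(0), target_id = character(0),
               start = integer(0), site_type = character(0),
               stringsAsFactors = FALSE)
  list(mirna = dna_to_rna(mirna_dna),
       lncrna = seqs[names(seqs) %in%
                       vapply(models$lncrnas, function(m) m$id, character(1))],
       utr = seqs[names(seqs) %in% ids$mrna],
       planted_sites = planted_sites)
}

#' Generate negative-binomial count matrices
#'
#' Counts are drawn `NB(mu, phi)` with `mu = 2^(u + s + z) * lib`, where
#' `u` is the per-feature base mean (log2), `s` the condition shift (+/-
#' half the planted log2 fold change for DE features, 0 for nulls), `z`
#' the shared latent factor of the feature's planted group scaled by
#' `triad_correlation_strength`, and `lib` the per-sample log-normal depth
#' factor. Null features have identical means in both conditions.
#'
#' @param config A [sim_config()].
#' @param plan Output of [plan_truth()].
#' @return List of three [count_matrix()] objects: `mrna`, `lncrna`,
#'   `mirna`.
#' @export
generate_counts <- function(config, plan) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 3L))
  r <- config$n_replicates_per_group
  samples <- c(sprintf("BH-%d", seq_len(r)), sprintf("BN-%d", seq_len(r)))
  design <- stats::setNames(rep(c("BH", "BN"), each = r), samples)
  ns <- length(samples)
  cv <- config$library_size_cv
  lib <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, ns)
  }
  z <- if (length(plan$latent_groups)) {
    matrix(stats::rnorm(length(plan$latent_groups) * ns,
                        sd = config$latent_sd),
           nrow = length(plan$latent_groups), ncol = ns)
  } else {
    matrix(0, nrow = 0, ncol = ns)
  }
  latent <- list(mrna = NULL, lncrna = NULL, mirna = NULL)
  for (cls in names(latent)) {
    latent[[cls]] <- matrix(0, nrow = length(plan$ids[[cls]]), ncol = ns,
                            dimnames = list(plan$ids[[cls]], samples))
  }
  for (g in seq_along(plan$latent_groups)) {
    grp <- plan$latent_groups[[g]]
    for (i in seq_len(nrow(grp))) {
      latent[[grp$class[i]]][grp$feature_id[i], ] <-
        latent[[grp$class[i]]][grp$feature_id[i], ] +
        grp$sign[i] * config$triad_correlation_strength * z[g, ]
    }
  }
  lengths_by_class <- list(
    mrna = config$gene_n_exons * config$gene_exon_length,
    lncrna = 2L * config$lnc_exon_length,
    mirna = 22L
  )
  half <- config$planted_de_lfc / 2
  out <- list()
  for (cls in c("mrna", "lncrna", "mirna")) {
    feats <- plan$ids[[cls]]
    flags <- plan$de_flags[[cls]][feats]
    u <- stats::runif(length(feats), config$base_mean_log_range[1],
                      config$base_mean_log_range[2])
    shift <- matrix(0, nrow = length(feats), ncol = ns)
    bh_cols <- design == "BH"
    shift[flags == "up", bh_cols] <- half
    shift[flags == "up", !bh_cols] <- -half
    shift[flags == "down", bh_cols] <- -half
    shift[flags == "down", !bh_cols] <- half
    log2mu <- u + shift + latent[[cls]]
    mu <- t(t(2^log2mu) * lib)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = 1 / config$nb_dispersion),
      nrow = length(feats), dimnames = list(feats, samples))
    out[[cls]] <- count_matrix(
      counts, design,
      lengths = stats::setNames(rep(lengths_by_class[[cls]], length(feats)),
                                feats))
  }
  out
}

#' Generate a synthetic term-to-gene map
#'
#' Random terms over the mRNA universe plus one planted term
#' (`TERM_PLANTED`) loaded with the ceRNA-pair mRNAs, so over-representation
#' of network genes is detectable by construction.
#'
#' @param config A [sim_config()].
#' @param plan Output of [plan_truth()].
#' @return `data.frame` with `term_id`, `term_name`, `gene_id`.
#' @export
generate_term_map <- function(config, plan) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 4L))
  genes <- plan$ids$mrna
  rows <- lapply(seq_len(config$n_terms), function(i) {
    sz <- sample(seq(config$term_size_range[1],
                     min(config$term_size_range[2], length(genes))), 1)
    data.frame(term_id = sprintf("TERM%03d", i),
               term_name = sprintf("synthetic term %03d", i),
               gene_id = sample(genes, sz), stringsAsFactors = FALSE)
  })
  planted_genes <- unique(plan$triads$mrna_id)
  if (length(planted_genes)) {
    extra <- sample(setdiff(genes, planted_genes),
                    min(2L, length(setdiff(genes, planted_genes))))
    rows[[length(rows) + 1]] <- data.frame(
      term_id = "TERM_PLANTED", term_name = "planted ceRNA-mRNA term",
      gene_id = c(planted_genes, extra), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the whole generator
#'
#' Chains [plan_truth()], [generate_gene_models()], [generate_sequences()],
#' [generate_counts()] and [generate_term_map()] and assembles the truth
#' table.
#'
#' @param config A [sim_config()].
#' @return Object of class `cerna_simulation`: `config`, `plan`, `models`,
#'   `sequences`, `counts`, `term_map` and `truth` (with `de_flags`,
#'   `planted_sites`, `planted_triads`, `planted_lnc_categories`).
#' @export
simulate_cerna_experiment <- function(config = sim_config()) {
  plan <- plan_truth(config)
  models <- generate_gene_models(config)
  sequences <- generate_sequences(config, models, plan$sites_plan)
  counts <- generate_counts(config, plan)
  term_map <- generate_term_map(config, plan)
  de_flags <- do.call(rbind, lapply(names(plan$de_flags), function(cls) {
    data.frame(class = cls, feature_id = names(plan$de_flags[[cls]]),
               flag = unname(plan$de_flags[[cls]]), stringsAsFactors = FALSE)
  }))
  truth <- list(de_flags = de_flags,
                planted_sites = sequences$planted_sites,
                planted_triads = plan$triads,
                planted_lnc_categories = models$lnc_categories)
  structure(list(config = config, plan = plan, models = models,
                 sequences = sequences, counts = counts,
                 term_map = term_map, truth = truth),
            class = "cerna_simulation")
}

#' @export
print.cerna_simulation <- function(x, ...) {
  cat(sprintf(
    "<cerna_simulation> seed %d: %d/%d/%d features, %d planted triad rows\n",
    x$config$seed, x$config$n_mrna, x$config$n_lncrna, x$config$n_mirna,
    nrow(x$truth$planted_triads)))
  invisible(x)
}

#' Write a simulation to disk as a plain-text fixture
#'
#' Writes counts (TSV), the design, feature lengths, the GTF genome, FASTA
#' sequences, the term map, the truth tables and a deterministic
#' `manifest.json` (config, seed, file checksums). Rerunning with the same
#' seed reproduces byte-identical files.
#'
#' @param sim A [simulate_cerna_experiment()] result (or a [sim_config()],
#'   which is simulated first).
#' @param out_dir Output directory, created if needed.
#' @return Named vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  if (inherits(sim, "sim_config")) sim <- simulate_cerna_experiment(sim)
  stopifnot(inherits(sim, "cerna_simulation"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- c()
  counts_df <- function(cm) {
    data.frame(feature_id = rownames(cm$counts), cm$counts,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  for (cls in c("mrna", "lncrna", "mirna")) {
    p <- file.path(out_dir, paste0(cls, "_counts.tsv"))
    write_tsv(counts_df(sim$counts[[cls]]), p)
    paths[paste0(cls, "_counts")] <- p
  }
  design <- sim$counts$mrna$design
  paths["design"] <- write_tsv(
    data.frame(sample = names(design), condition = unname(design)),
    file.path(out_dir, "design.tsv"))
  lens <- do.call(rbind, lapply(c("mrna", "lncrna", "mirna"), function(cls) {
    data.frame(feature_id = names(sim$counts[[cls]]$lengths),
               length = unname(sim$counts[[cls]]$lengths),
               stringsAsFactors = FALSE)
  }))
  paths["lengths"] <- write_tsv(lens, file.path(out_dir, "lengths.tsv"))
  paths["gtf"] <- write_gtf(c(sim$models$genes, sim$models$lncrnas),
                            file.path(out_dir, "models.gtf"))
  mirna_set <- Biostrings::RNAStringSet(sim$sequences$mirna)
  Biostrings::writeXStringSet(mirna_set, file.path(out_dir, "mirna.fa"))
  paths["mirna_fa"] <- file.path(out_dir, "mirna.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences$lncrna),
                              file.path(out_dir, "lncrna.fa"))
  paths["lncrna_fa"] <- file.path(out_dir, "lncrna.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences$utr),
                              file.path(out_dir, "utr.fa"))
  paths["utr_fa"] <- file.path(out_dir, "utr.fa")
  paths["term_map"] <- write_tsv(sim$term_map,
                                 file.path(out_dir, "term_map.tsv"))
  paths["truth_de"] <- write_tsv(sim$truth$de_flags,
                                 file.path(out_dir, "truth_de.tsv"))
  paths["truth_sites"] <- write_tsv(sim$truth$planted_sites,
                                    file.path(out_dir, "truth_sites.tsv"))
  paths["truth_triads"] <- write_tsv(sim$truth$planted_triads,
                                     file.path(out_dir, "truth_triads.tsv"))
  paths["truth_categories"] <- write_tsv(
    data.frame(transcript_id = names(sim$truth$planted_lnc_categories),
               category = unname(sim$truth$planted_lnc_categories),
               stringsAsFactors = FALSE),
    file.path(out_dir, "truth_lnc_categories.tsv"))
  manifest <- list(
    seed = sim$config$seed,
    config = unclass(sim$config),
    files = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$files) <- basename(names(manifest$files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths["manifest"] <- manifest_path
  invisible(paths)
}
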