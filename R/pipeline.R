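#' Pipeline configuration
#'
#' Single structured configuration holding every threshold the pipeline
#' applies (all stages read thresholds only from here), the I/O locations,
#' and the simulation parameters for the `simulate` stage. Invalid
#' thresholds error before any work is done.
#'
#' @param out_dir Output directory; stage artifacts are written to
#'   per-stage subdirectories.
#' @param input_dir Directory holding the fixture inputs (defaults to
#'   `<out_dir>/fixture`, where the `simulate` stage writes).
#' @param seed Integer seed forwarded to the simulation stage.
#' @param fdr_threshold,lfc_threshold DE thresholds (strict `fdr < .05`,
#'   `|log2fc| > 1`).
#' @param spearman_threshold Strict Spearman cut-off for negative pairs
#'   (default -0.7).
#' @param pearson_threshold Strict Pearson cut-off for co-expressed pairs
#'   (default 0.9).
#' @param sponge_p_threshold Strict sponge-test p cut-off (default 0.05).
#' @param enrichment_threshold Enrichment cut-off (default 0.05).
#' @param bidirectional_window lncRNA classifier TSS window (nt).
#' @param min_site_type Minimum seed-site evidence for target prediction.
#' @param sim List of [sim_config()] overrides for the simulate stage.
#' @param verbose Emit timestamped log messages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "spongenet_out",
                            input_dir = NULL,
                            seed = 1L,
                            fdr_threshold = 0.05,
                            lfc_threshold = 1.0,
                            spearman_threshold = -0.7,
                            pearson_threshold = 0.9,
                            sponge_p_threshold = 0.05,
                            enrichment_threshold = 0.05,
                            bidirectional_window = 1000,
                            min_site_type = "7mer",
                            sim = list(),
                            verbose = TRUE) {
  assert_prob(fdr_threshold, "fdr_threshold")
  assert_prob(sponge_p_threshold, "sponge_p_threshold")
  assert_prob(enrichment_threshold, "enrichment_threshold")
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (spearman_threshold < -1 || spearman_threshold > 1) {
    stop("spearman_threshold must lie in [-1, 1]")
  }
  if (pearson_threshold < -1 || pearson_threshold > 1) {
    stop("pearson_threshold must lie in [-1, 1]")
  }
  site_rank(min_site_type) # validates
  assert_count(bidirectional_window, "bidirectional_window")
  structure(list(
    out_dir = out_dir,
    input_dir = input_dir %||% file.path(out_dir, "fixture"),
    seed = assert_count(seed, "seed"),
    fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
    spearman_threshold = spearman_threshold,
    pearson_threshold = pearson_threshold,
    sponge_p_threshold = sponge_p_threshold,
    enrichment_threshold = enrichment_threshold,
    bidirectional_window = bidirectional_window,
    min_site_type = min_site_type,
    sim = sim, verbose = isTRUE(verbose)), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Top-level keys map to [pipeline_config()] arguments; the `sim` section
#' holds [sim_config()] overrides. `overrides` (e.g. parsed CLI flags)
#' take precedence over file values.
#'
#' @param path JSON config file.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

log_msg <- function(config, ...) {
  if (config$verbose) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
}

require_inputs <- function(paths, stage, hint) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("stage '", stage, "' is missing input file(s): ",
         paste(missing, collapse = ", "), "; ", hint)
  }
  invisible(TRUE)
}

read_count_matrix_tsv <- function(counts_path, design_path,
                                  lengths_path = NULL) {
  cdf <- read_tsv(counts_path)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$feature_id
  ddf <- read_tsv(design_path)
  design <- stats::setNames(ddf$condition, ddf$sample)
  lengths <- NULL
  if (!is.null(lengths_path) && file.exists(lengths_path)) {
    ldf <- read_tsv(lengths_path)
    lengths <- stats::setNames(ldf$length, ldf$feature_id)
  }
  count_matrix(counts, design, lengths = lengths)
}

read_fasta_vector <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

#' Run pipeline stages
#'
#' Orchestrates the analysis as subcommands over one [pipeline_config()]:
#' \describe{
#'   \item{simulate}{write the synthetic fixture with planted truth;}
#'   \item{de}{differential expression per RNA class at the configured
#'     thresholds;}
#'   \item{classify}{parse the GTF, filter novel transcripts and classify
#'     lncRNAs (TSV + BED);}
#'   \item{targets}{seed-match target prediction restricted to DE
#'     features;}
#'   \item{network}{correlation filters, sponge test and triad assembly,
#'     with Cytoscape export;}
#'   \item{enrich}{term over-representation of network mRNAs;}
#'   \item{all}{the full chain, plus a deterministic run manifest.}
#' }
#' Stages check for their inputs before writing anything and fail with a
#' clean error if an upstream stage has not run.
#'
#' @param stage One of `simulate`, `de`, `classify`, `targets`, `network`,
#'   `enrich`, `all`.
#' @param config A [pipeline_config()].
#' @return Invisible list of stage outputs.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "de", "classify",
                                   "targets", "network", "enrich"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  out <- switch(stage,
                simulate = stage_simulate(config),
                de = stage_de(config),
                classify = stage_classify(config),
                targets = stage_targets(config),
                network = stage_network(config),
                enrich = stage_enrich(config),
                all = stage_all(config))
  invisible(out)
}

stage_simulate <- function(config) {
  log_msg(config, "simulate: seed ", config$seed)
  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_cerna_experiment(cfg)
  paths <- write_fixture(sim, config$input_dir)
  log_msg(config, "simulate: fixture written to ", config$input_dir)
  list(sim = sim, paths = paths)
}

stage_de <- function(config) {
  fx <- config$input_dir
  needed <- file.path(fx, c("mrna_counts.tsv", "lncrna_counts.tsv",
                            "mirna_counts.tsv", "design.tsv"))
  require_inputs(needed, "de",
                 "run the 'simulate' stage or point input_dir at a fixture")
  d <- stage_dir(config, "de")
  log_msg(config, "de: FDR < ", config$fdr_threshold,
          ", |log2FC| > ", config$lfc_threshold)
  out <- list()
  for (cls in c("mrna", "lncrna", "mirna")) {
    cm <- read_count_matrix_tsv(file.path(fx, paste0(cls, "_counts.tsv")),
                                file.path(fx, "design.tsv"),
                                file.path(fx, "lengths.tsv"))
    tab <- de_table(cm, fdr_threshold = config$fdr_threshold,
                    lfc_threshold = config$lfc_threshold)
    write_tsv(tab, file.path(d, paste0("de_", cls, ".tsv")))
    out[[cls]] <- tab
  }
  out
}

stage_classify <- function(config) {
  gtf <- file.path(config$input_dir, "models.gtf")
  require_inputs(gtf, "classify", "a models.gtf is required")
  d <- stage_dir(config, "classify")
  models <- read_gtf_models(gtf)
  lncs <- Filter(function(m) identical(m$biotype, "lncRNA"),
                 models$transcripts)
  lncs <- filter_novel_transcripts(lncs)
  cats <- classify_lncrnas(lncs, models$genes,
                           bidirectional_window = config$bidirectional_window)
  log_msg(config, "classify: ", length(cats), " lncRNAs, window ",
          config$bidirectional_window, " nt")
  write_category_table(cats, file.path(d, "lncrna_categories.tsv"))
  write_lncrna_bed(lncs, file.path(d, "lncrna.bed"))
  cats
}

stage_targets <- function(config) {
  fx <- config$input_dir
  de_dir <- file.path(config$out_dir, "de")
  needed <- c(file.path(fx, c("mirna.fa", "lncrna.fa", "utr.fa")),
              file.path(de_dir, c("de_mrna.tsv", "de_lncrna.tsv",
                                  "de_mirna.tsv")))
  require_inputs(needed, "targets", "run the 'de' stage first")
  d <- stage_dir(config, "targets")
  de <- lapply(c(mrna = "de_mrna.tsv", lncrna = "de_lncrna.tsv",
                 mirna = "de_mirna.tsv"),
               function(f) read_tsv(file.path(de_dir, f)))
  de_ids <- lapply(de, function(t) t$feature_id[t$call != "null"])
  mirnas <- read_fasta_vector(file.path(fx, "mirna.fa"))
  lnc_seq <- read_fasta_vector(file.path(fx, "lncrna.fa"))
  utr_seq <- read_fasta_vector(file.path(fx, "utr.fa"))
  mirnas <- mirnas[names(mirnas) %in% de_ids$mirna]
  lnc_seq <- lnc_seq[names(lnc_seq) %in% de_ids$lncrna]
  utr_seq <- utr_seq[names(utr_seq) %in% de_ids$mrna]
  log_msg(config, "targets: ", length(mirnas), " DE miRNAs vs ",
          length(lnc_seq), " DE lncRNAs + ", length(utr_seq),
          " DE mRNA UTRs at >= ", config$min_site_type)
  pairs_lnc <- predict_targets(mirnas, lnc_seq,
                               min_site_type = config$min_site_type)
  pairs_mrna <- predict_targets(mirnas, utr_seq,
                                min_site_type = config$min_site_type)
  write_tsv(pairs_lnc, file.path(d, "pairs_mirna_lncrna.tsv"))
  write_tsv(pairs_mrna, file.path(d, "pairs_mirna_mrna.tsv"))
  list(lncrna = pairs_lnc, mrna = pairs_mrna)
}

stage_network <- function(config) {
  fx <- config$input_dir
  de_dir <- file.path(config$out_dir, "de")
  tg_dir <- file.path(config$out_dir, "targets")
  needed <- c(file.path(fx, c("mrna_counts.tsv", "lncrna_counts.tsv",
                              "mirna_counts.tsv", "design.tsv")),
              file.path(de_dir, c("de_mrna.tsv", "de_lncrna.tsv",
                                  "de_mirna.tsv")),
              file.path(tg_dir, c("pairs_mirna_lncrna.tsv",
                                  "pairs_mirna_mrna.tsv")))
  require_inputs(needed, "network", "run the 'de' and 'targets' stages first")
  d <- stage_dir(config, "network")
  expr <- lapply(c(mrna = "mrna_counts.tsv", lncrna = "lncrna_counts.tsv",
                   mirna = "mirna_counts.tsv"), function(f) {
    log_expression(read_count_matrix_tsv(file.path(fx, f),
                                         file.path(fx, "design.tsv")))
  })
  de <- lapply(c(mrna = "de_mrna.tsv", lncrna = "de_lncrna.tsv",
                 mirna = "de_mirna.tsv"),
               function(f) read_tsv(file.path(de_dir, f)))
  de_ids <- lapply(de, function(t) t$feature_id[t$call != "null"])
  pairs_lnc <- read_tsv(file.path(tg_dir, "pairs_mirna_lncrna.tsv"))
  pairs_mrna <- read_tsv(file.path(tg_dir, "pairs_mirna_mrna.tsv"))
  log_msg(config, "network: Spearman < ", config$spearman_threshold,
          ", Pearson > ", config$pearson_threshold,
          ", sponge p < ", config$sponge_p_threshold)
  neg <- rbind(
    negative_pairs(expr$mirna, expr$lncrna, pairs_lnc,
                   rho_threshold = config$spearman_threshold),
    negative_pairs(expr$mirna, expr$mrna, pairs_mrna,
                   rho_threshold = config$spearman_threshold))
  coex <- coexpressed_pairs(
    expr$lncrna[rownames(expr$lncrna) %in% de_ids$lncrna, , drop = FALSE],
    expr$mrna[rownames(expr$mrna) %in% de_ids$mrna, , drop = FALSE],
    r_threshold = config$pearson_threshold)
  if (nrow(neg) == 0) {
    log_msg(config, "network: no negative pairs survive; empty network")
    net <- NULL
  } else {
    net <- build_cerna_network(neg, coex,
                               p_threshold = config$sponge_p_threshold)
  }
  write_tsv(neg, file.path(d, "negative_pairs.tsv"))
  write_tsv(coex, file.path(d, "coexpressed_pairs.tsv"))
  if (!is.null(net) && nrow(net$triads) > 0) {
    node_attr <- do.call(rbind, lapply(names(de), function(cls) {
      data.frame(feature_id = de[[cls]]$feature_id, call = de[[cls]]$call,
                 stringsAsFactors = FALSE)
    }))
    export_network(net, d, node_attributes = node_attr)
  } else {
    write_tsv(data.frame(lncrna_id = character(0), mrna_id = character(0)),
              file.path(d, "triads.tsv"))
  }
  list(negative_pairs = neg, coexpressed_pairs = coex, network = net)
}

stage_enrich <- function(config) {
  fx <- config$input_dir
  de_dir <- file.path(config$out_dir, "de")
  net_dir <- file.path(config$out_dir, "network")
  needed <- c(file.path(fx, "term_map.tsv"),
              file.path(de_dir, "de_mrna.tsv"),
              file.path(net_dir, "triads.tsv"))
  require_inputs(needed, "enrich", "run the 'network' stage first")
  d <- stage_dir(config, "enrich")
  term_map <- read_tsv(file.path(fx, "term_map.tsv"))
  de_mrna <- read_tsv(file.path(de_dir, "de_mrna.tsv"))
  triads <- read_tsv(file.path(net_dir, "triads.tsv"))
  study <- unique(triads$mrna_id)
  population <- de_mrna$feature_id
  if (length(study) == 0) {
    log_msg(config, "enrich: empty network, nothing to test")
    res <- enrich(character(0), population, term_map)
  } else {
    res <- enrich(study, population, term_map)
  }
  write_tsv(res, file.path(d, "enrichment.tsv"))
  write_tsv(filter_enrichment(res, "go", config$enrichment_threshold),
            file.path(d, "enrichment_go_significant.tsv"))
  write_tsv(filter_enrichment(res, "kegg", config$enrichment_threshold),
            file.path(d, "enrichment_kegg_significant.tsv"))
  res
}

stage_all <- function(config) {
  out <- list()
  out$simulate <- stage_simulate(config)
  out$de <- stage_de(config)
  out$classify <- stage_classify(config)
  out$targets <- stage_targets(config)
  out$network <- stage_network(config)
  out$enrich <- stage_enrich(config)
  manifest <- list(
    seed = config$seed,
    thresholds = config[c("fdr_threshold", "lfc_threshold",
                          "spearman_threshold", "pearson_threshold",
                          "sponge_p_threshold", "enrichment_threshold",
                          "bidirectional_window", "min_site_type")],
    config_md5 = config_md5(config),
    n_triads = if (!is.null(out$network$network)) {
      nrow(out$network$network$triads)
    } else 0L
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg(config, "all: ", manifest$n_triads, " ceRNA pair(s); manifest at ",
          file.path(config$out_dir, "manifest.json"))
  out
}

# md5 of the canonical JSON serialization of the config (paths excluded so
# the hash identifies the analysis, not its location)
config_md5 <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL
  core$input_dir <- NULL
  core$verbose <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
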