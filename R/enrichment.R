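#' Hypergeometric term over-representation analysis
#'
#' For each term in the map, tests whether the study set contains more of
#' the term's genes than expected under random draws from the population:
#' `N = |population|`, `K = |term in population|`, `n = |study|`,
#' `k = |term in study|`, upper-tail hypergeometric p (shared kernel with
#' the ceRNA sponge test). A Benjamini-Hochberg adjusted column is added
#' and results are sorted by p ascending, ties broken by term id. Terms are
#' intersected with the population before testing; this substitutes a plain
#' hypergeometric test for the named GO/KEGG tooling (no length-bias
#' correction).
#'
#' @param study_genes Character vector of genes of interest; must be a
#'   subset of `population_genes`.
#' @param population_genes Character vector: the background universe
#'   (typically all features tested for differential expression).
#' @param term_map `data.frame` with columns `term_id`, `gene_id` and
#'   optionally `term_name`.
#' @return `data.frame` with `term_id`, `term_name`, `k_study`, `n_study`,
#'   `K_pop`, `N_pop`, `p_value`, `adjusted_p`.
#' @export
enrich <- function(study_genes, population_genes, term_map) {
  study <- unique(as.character(study_genes))
  pop <- unique(as.character(population_genes))
  stopifnot(is.data.frame(term_map),
            all(c("term_id", "gene_id") %in% names(term_map)))
  offenders <- setdiff(study, pop)
  if (length(offenders)) {
    stop("study genes absent from the population: ",
         paste(offenders, collapse = ", "))
  }
  tm <- term_map[term_map$gene_id %in% pop, , drop = FALSE]
  terms <- sort(unique(tm$term_id))
  names_by_term <- if ("term_name" %in% names(tm)) {
    tapply(tm$term_name, tm$term_id, function(x) x[1])
  } else NULL
  N <- length(pop)
  n <- length(study)
  rows <- lapply(terms, function(t) {
    members <- unique(tm$gene_id[tm$term_id == t])
    K <- length(members)
    k <- length(intersect(members, study))
    data.frame(term_id = t,
               term_name = if (is.null(names_by_term)) t else
                 unname(names_by_term[t]),
               k_study = k, n_study = n, K_pop = K, N_pop = N,
               p_value = hyper_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term_id = character(0), term_name = character(0),
                      k_study = integer(0), n_study = integer(0),
                      K_pop = integer(0), N_pop = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  }
  res$adjusted_p <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter enrichment results at the published thresholds
#'
#' `go` mode keeps terms with `adjusted_p < 0.05` (GO-style, multiplicity
#' corrected); `kegg` mode keeps `p_value < 0.05` (KEGG-style, raw). Both
#' comparisons are strict.
#'
#' @param results Output of [enrich()].
#' @param mode `"go"` or `"kegg"`.
#' @param threshold Cut-off, default 0.05.
#' @return The significant subset of `results`.
#' @export
filter_enrichment <- function(results, mode = c("go", "kegg"),
                              threshold = 0.05) {
  mode <- match.arg(mode)
  keep <- switch(mode,
                 go = results$adjusted_p < threshold,
                 kegg = results$p_value < threshold)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
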