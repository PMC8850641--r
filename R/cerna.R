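#' Correlation coefficients for expression vectors
#'
#' `spearman_rho()` is the tie-aware Spearman rank correlation (Pearson
#' correlation of average ranks); `pearson_r()` is the product-moment
#' coefficient. Both require vectors of equal length >= 3 and error on
#' constant input (such pairs are excluded, with a status record, by the
#' pair-filtering functions rather than assigned a coefficient).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman_rho
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 samples, got ", length(x))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined")
  }
  invisible(TRUE)
}

#' Negative miRNA-target expression pairs
#'
#' Computes the Spearman rank correlation across samples for each candidate
#' (miRNA, target) pair from seed-match prediction and retains pairs with
#' `rho < rho_threshold` (strict; default -0.7). Applied identically to
#' miRNA-mRNA and miRNA-lncRNA pairs. Pairs with a constant expression
#' vector are excluded and listed in the `"excluded"` attribute.
#'
#' @param mirna_expr Numeric matrix (miRNA features x samples).
#' @param target_expr Numeric matrix (target features x samples), same
#'   sample columns in the same order.
#' @param candidate_pairs `data.frame` with `mirna_id`, `target_id`.
#' @param rho_threshold Strict upper bound on Spearman rho. Default -0.7.
#' @return `data.frame` of retained pairs with `mirna_id`, `target_id`,
#'   `method`, `coefficient`, `n_samples`.
#' @export
negative_pairs <- function(mirna_expr, target_expr, candidate_pairs,
                           rho_threshold = -0.7) {
  stopifnot(is.matrix(mirna_expr), is.matrix(target_expr))
  if (!identical(colnames(mirna_expr), colnames(target_expr))) {
    stop("expression matrices must share identical sample columns")
  }
  missing_m <- setdiff(unique(candidate_pairs$mirna_id), rownames(mirna_expr))
  missing_t <- setdiff(unique(candidate_pairs$target_id),
                       rownames(target_expr))
  if (length(missing_m) || length(missing_t)) {
    stop("features absent from expression matrices: ",
         paste(c(missing_m, missing_t), collapse = ", "))
  }
  n <- ncol(mirna_expr)
  if (nrow(candidate_pairs) == 0) {
    out <- data.frame(mirna_id = character(0), target_id = character(0),
                      method = character(0), coefficient = numeric(0),
                      n_samples = integer(0), stringsAsFactors = FALSE)
    attr(out, "excluded") <- candidate_pairs
    return(out)
  }
  coef <- rep(NA_real_, nrow(candidate_pairs))
  ok <- rep(TRUE, nrow(candidate_pairs))
  for (i in seq_len(nrow(candidate_pairs))) {
    x <- mirna_expr[candidate_pairs$mirna_id[i], ]
    y <- target_expr[candidate_pairs$target_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      ok[i] <- FALSE
      next
    }
    coef[i] <- spearman_rho(x, y)
  }
  res <- data.frame(mirna_id = candidate_pairs$mirna_id,
                    target_id = candidate_pairs$target_id,
                    method = "spearman", coefficient = coef,
                    n_samples = n, stringsAsFactors = FALSE)
  kept <- res[ok & res$coefficient < rho_threshold, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "excluded") <- candidate_pairs[!ok, , drop = FALSE]
  kept
}

#' Co-expressed lncRNA-mRNA pairs
#'
#' Evaluates the Pearson correlation for every lncRNA x mRNA combination
#' (both matrices should already be restricted to differentially expressed
#' features) and retains pairs with `r > r_threshold` (strict; default
#' 0.9). Constant features are excluded with a status record.
#'
#' @param lncrna_expr Numeric matrix (lncRNA features x samples).
#' @param mrna_expr Numeric matrix (mRNA features x samples), same samples.
#' @param r_threshold Strict lower bound on Pearson r. Default 0.9.
#' @return `data.frame` with `lncrna_id`, `mrna_id`, `method`,
#'   `coefficient`, `n_samples`; excluded constant features in the
#'   `"excluded"` attribute.
#' @export
coexpressed_pairs <- function(lncrna_expr, mrna_expr, r_threshold = 0.9) {
  stopifnot(is.matrix(lncrna_expr), is.matrix(mrna_expr))
  if (!identical(colnames(lncrna_expr), colnames(mrna_expr))) {
    stop("expression matrices must share identical sample columns")
  }
  const_l <- apply(lncrna_expr, 1, stats::sd) == 0
  const_m <- apply(mrna_expr, 1, stats::sd) == 0
  lx <- lncrna_expr[!const_l, , drop = FALSE]
  mx <- mrna_expr[!const_m, , drop = FALSE]
  out <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                    method = character(0), coefficient = numeric(0),
                    n_samples = integer(0), stringsAsFactors = FALSE)
  if (nrow(lx) && nrow(mx)) {
    cc <- stats::cor(t(lx), t(mx), method = "pearson")
    hit <- which(cc > r_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      out <- data.frame(lncrna_id = rownames(lx)[hit[, 1]],
                        mrna_id = rownames(mx)[hit[, 2]],
                        method = "pearson",
                        coefficient = cc[hit],
                        n_samples = ncol(lx), stringsAsFactors = FALSE)
      out <- out[order(out$lncrna_id, out$mrna_id), ]
      rownames(out) <- NULL
    }
  }
  attr(out, "excluded") <- c(rownames(lncrna_expr)[const_l],
                             rownames(mrna_expr)[const_m])
  out
}

#' Hypergeometric shared-sponge test
#'
#' Tests whether a lncRNA and an mRNA share more targeting miRNAs than
#' expected by chance: with `K` miRNAs targeting the lncRNA, `n` targeting
#' the mRNA, `k` shared, and a universe of `N` eligible miRNAs, the
#' p-value is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param lnc_mirnas Character vector of miRNAs targeting the lncRNA.
#' @param mrna_mirnas Character vector of miRNAs targeting the mRNA.
#' @param universe_size Number of eligible miRNAs `N`; must be at least
#'   the size of the union of the two sets.
#' @return List with `p_value`, `k`, `K`, `n`, `N` and `shared` (the
#'   shared miRNA ids).
#' @export
sponge_test <- function(lnc_mirnas, mrna_mirnas, universe_size) {
  lnc_mirnas <- unique(as.character(lnc_mirnas))
  mrna_mirnas <- unique(as.character(mrna_mirnas))
  N <- assert_count(universe_size, "universe_size", min = 1L)
  shared <- intersect(lnc_mirnas, mrna_mirnas)
  K <- length(lnc_mirnas)
  n <- length(mrna_mirnas)
  if (N < length(union(lnc_mirnas, mrna_mirnas))) {
    stop("universe_size (", N, ") smaller than the union of the two sets (",
         length(union(lnc_mirnas, mrna_mirnas)), ")")
  }
  list(p_value = hyper_upper_tail(length(shared), K, n, N),
       k = length(shared), K = K, n = n, N = N, shared = sort(shared))
}

#' Assemble the ceRNA network
#'
#' For each co-expressed lncRNA-mRNA pair, collects the miRNAs negatively
#' paired with \emph{both} partners, requires at least one shared miRNA,
#' applies the hypergeometric sponge test, and keeps pairs with
#' `p < p_threshold` (strict). The universe for the test defaults to the
#' distinct miRNAs participating in at least one negative pair; pass
#' `universe` explicitly (e.g. all DE miRNAs) to condition on a larger
#' pool.
#'
#' @param neg_pairs Output of [negative_pairs()], pooled over miRNA-mRNA
#'   and miRNA-lncRNA edges.
#' @param coexpr_pairs Output of [coexpressed_pairs()].
#' @param universe Optional character vector of eligible miRNA ids; default
#'   is the distinct miRNAs in `neg_pairs`.
#' @param p_threshold Strict sponge-test p-value cut-off. Default 0.05.
#' @return List of class `cerna_network` with `triads` (one row per ceRNA
#'   pair: `lncrna_id`, `mrna_id`, `shared_mirnas` (`;`-collapsed), `k`,
#'   `K`, `n`, `N`, `p_value`) and `edges` (deduplicated
#'   `source`/`interaction`/`target` rows).
#' @export
build_cerna_network <- function(neg_pairs, coexpr_pairs, universe = NULL,
                                p_threshold = 0.05) {
  if (is.null(universe)) universe <- unique(neg_pairs$mirna_id)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    stop("empty miRNA universe: no negative pairs and no explicit universe")
  }
  if (!all(neg_pairs$mirna_id %in% universe)) {
    stop("negative-pair miRNAs outside the declared universe")
  }
  triads <- list()
  for (i in seq_len(nrow(coexpr_pairs))) {
    l <- coexpr_pairs$lncrna_id[i]
    g <- coexpr_pairs$mrna_id[i]
    lnc_m <- unique(neg_pairs$mirna_id[neg_pairs$target_id == l])
    mrna_m <- unique(neg_pairs$mirna_id[neg_pairs$target_id == g])
    shared <- intersect(lnc_m, mrna_m)
    if (length(shared) == 0) next
    st <- sponge_test(lnc_m, mrna_m, length(universe))
    if (st$p_value < p_threshold) {
      triads[[length(triads) + 1]] <- data.frame(
        lncrna_id = l, mrna_id = g,
        shared_mirnas = paste(sort(shared), collapse = ";"),
        k = st$k, K = st$K, n = st$n, N = st$N, p_value = st$p_value,
        pearson_r = coexpr_pairs$coefficient[i], stringsAsFactors = FALSE)
    }
  }
  triads <- if (length(triads)) do.call(rbind, triads) else
    data.frame(lncrna_id = character(0), mrna_id = character(0),
               shared_mirnas = character(0), k = integer(0), K = integer(0),
               n = integer(0), N = integer(0), p_value = numeric(0),
               pearson_r = numeric(0), stringsAsFactors = FALSE)
  triads <- triads[order(triads$lncrna_id, triads$mrna_id), , drop = FALSE]
  rownames(triads) <- NULL
  edges <- expand_triads(triads)
  edge_df <- unique(rbind(
    data.frame(source = edges$lncrna_id,
               interaction = rep("lncRNA-miRNA", nrow(edges)),
               target = edges$mirna_id, stringsAsFactors = FALSE),
    data.frame(source = edges$mirna_id,
               interaction = rep("miRNA-mRNA", nrow(edges)),
               target = edges$mrna_id, stringsAsFactors = FALSE)))
  rownames(edge_df) <- NULL
  structure(list(triads = triads, edges = edge_df, universe = universe),
            class = "cerna_network")
}

#' Expand ceRNA pairs into one row per (lncRNA, miRNA, mRNA) triple
#'
#' @param triads The `triads` table of a [build_cerna_network()] result.
#' @return `data.frame` with `lncrna_id`, `mirna_id`, `mrna_id`.
#' @export
expand_triads <- function(triads) {
  if (nrow(triads) == 0) {
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(triads)), function(i) {
    ms <- strsplit(triads$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    data.frame(lncrna_id = triads$lncrna_id[i], mirna_id = ms,
               mrna_id = triads$mrna_id[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf(
    "<cerna_network> %d ceRNA pair(s), %d edge(s), miRNA universe N = %d\n",
    nrow(x$triads), nrow(x$edges), length(x$universe)))
  invisible(x)
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes `network.sif` (`source<TAB>interaction<TAB>target`), `nodes.tsv`
#' (node id, type in `{lncRNA, miRNA, mRNA}`, and DE direction when node
#' attributes are supplied) and `triads.tsv` (the ceRNA pair table with k,
#' K, n, N and p).
#'
#' @param network A [build_cerna_network()] result.
#' @param out_dir Output directory (created if needed).
#' @param node_attributes Optional `data.frame` with `feature_id`, `type`,
#'   `call` columns (e.g. concatenated DE tables).
#' @return Named character vector of the written file paths, invisibly.
#' @export
export_network <- function(network, out_dir, node_attributes = NULL) {
  stopifnot(inherits(network, "cerna_network"))
  if (nrow(network$triads) == 0) stop("refusing to export an empty network")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(out_dir, "network.sif")
  writeLines(paste(network$edges$source, network$edges$interaction,
                   network$edges$target, sep = "\t"), sif)
  tri <- expand_triads(network$triads)
  nodes <- unique(data.frame(
    id = c(tri$lncrna_id, tri$mirna_id, tri$mrna_id),
    type = rep(c("lncRNA", "miRNA", "mRNA"),
               times = c(nrow(tri), nrow(tri), nrow(tri))),
    stringsAsFactors = FALSE))
  if (!is.null(node_attributes)) {
    idx <- match(nodes$id, node_attributes$feature_id)
    nodes$de_call <- node_attributes$call[idx]
  }
  nodes <- nodes[order(nodes$type, nodes$id), ]
  nodes_path <- file.path(out_dir, "nodes.tsv")
  write_tsv(nodes, nodes_path)
  triads_path <- file.path(out_dir, "triads.tsv")
  write_tsv(network$triads, triads_path)
  invisible(c(sif = sif, nodes = nodes_path, triads = triads_path))
}

#' Read a SIF file back into an edge table
#'
#' @param path Path to a `.sif` file.
#' @return `data.frame` with `source`, `interaction`, `target`.
#' @export
read_sif <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("source", "interaction", "target"))
  df
}
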