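#' Count matrix with sample design
#'
#' Container for a features x samples matrix of non-negative integer counts
#' together with the sample-to-condition design (conditions `BN`, the
#' blind-side normal reference, and `BH`, blind-side hypermelanotic) and
#' optional feature lengths (required only for FPKM).
#'
#' @param counts Integer matrix, features in rows, samples in columns; both
#'   dimensions must be named and free of duplicates.
#' @param design Named character vector, sample -> condition; every sample
#'   column must be present and map to `"BN"` or `"BH"`.
#' @param lengths Optional named numeric vector of feature lengths (nt).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!all(colnames(counts) %in% names(design))) {
    stop("design is missing samples: ",
         paste(setdiff(colnames(counts), names(design)), collapse = ", "))
  }
  design <- design[colnames(counts)]
  if (!all(design %in% c("BN", "BH"))) {
    stop("conditions must be 'BN' or 'BH'")
  }
  if (!is.null(lengths)) {
    if (!all(rownames(counts) %in% names(lengths))) {
      stop("lengths missing for some features")
    }
    lengths <- lengths[rownames(counts)]
  }
  structure(list(counts = counts, design = design, lengths = lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples (BH: %d, BN: %d)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$design == "BH"), sum(x$design == "BN")))
  invisible(x)
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM[f,s] = counts[f,s] * 1e9 / (length[f] * total[s])` with `total[s]`
#' the column sum.
#'
#' @param cm A [count_matrix()] with feature lengths.
#' @return Numeric matrix of FPKM values, same dimensions as the counts.
#' @export
fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$lengths)) stop("FPKM requires feature lengths")
  bad_len <- cm$lengths <= 0
  if (any(bad_len)) {
    stop("zero or negative length for feature(s): ",
         paste(names(cm$lengths)[bad_len], collapse = ", "))
  }
  totals <- colSums(cm$counts)
  if (any(totals <= 0)) {
    stop("zero sequencing depth in sample(s): ",
         paste(colnames(cm$counts)[totals <= 0], collapse = ", "))
  }
  cm$counts * 1e9 / outer(cm$lengths, totals)
}

#' TPM normalization for miRNA counts
#'
#' Tag-count transcripts-per-million: `TPM[f,s] = counts[f,s] * 1e6 /
#' total[s]`. Columns sum to one million.
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix of TPM values.
#' @export
tpm_mirna <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  if (any(totals <= 0)) {
    stop("zero sequencing depth in sample(s): ",
         paste(colnames(cm$counts)[totals <= 0], collapse = ", "))
  }
  sweep(cm$counts, 2, totals, "/") * 1e6
}

# Total-count normalization to the mean library depth; the basis for the
# stand-in differential test and the correlation stages.
normalized_counts <- function(cm) {
  totals <- colSums(cm$counts)
  if (any(totals <= 0)) {
    stop("zero sequencing depth in sample(s): ",
         paste(colnames(cm$counts)[totals <= 0], collapse = ", "))
  }
  sweep(cm$counts, 2, mean(totals) / totals, "*")
}

#' Log-scale expression matrix used for correlation filtering
#'
#' `log2(normalized counts + 1)` with per-sample total-count scaling to the
#' mean depth.
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix.
#' @export
log_expression <- function(cm) log2(normalized_counts(cm) + 1)

#' Stand-in differential expression test
#'
#' A transparent substitute for the named DE callers (DESeq2 / edgeR are out
#' of scope): per-sample total-count normalization to the mean depth, then a
#' two-sample unequal-variance (Welch) t-test per feature on
#' `log2(normalized + 1)`, with `log2fc = log2((mean_BH + c)/(mean_BN + c))`
#' on the normalized scale (pseudocount `c` stabilizes zeros). Fold changes
#' are BH over BN. The test's type-I calibration on negative-binomial nulls
#' is checked by simulation in the test suite, not assumed.
#'
#' @param cm A [count_matrix()] with at least 2 samples per condition.
#' @param pseudocount Pseudocount `c` added to the normalized group means.
#' @return `data.frame` with `feature_id`, `log2fc`, `p_value`.
#' @export
differential_test <- function(cm, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  bh <- cm$design == "BH"
  bn <- cm$design == "BN"
  if (sum(bh) < 2 || sum(bn) < 2) {
    stop("need >= 2 samples per condition (BH: ", sum(bh),
         ", BN: ", sum(bn), ")")
  }
  norm <- normalized_counts(cm)
  logn <- log2(norm + 1)
  n1 <- sum(bh); n2 <- sum(bn)
  m1 <- rowMeans(logn[, bh, drop = FALSE])
  m2 <- rowMeans(logn[, bn, drop = FALSE])
  v1 <- rowSums((logn[, bh, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((logn[, bn, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate features: no variance in either group
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  lfc <- log2((rowMeans(norm[, bh, drop = FALSE]) + pseudocount) /
              (rowMeans(norm[, bn, drop = FALSE]) + pseudocount))
  data.frame(feature_id = rownames(cm$counts), log2fc = unname(lfc),
             p_value = unname(pmin(pmax(p, 0), 1)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sort p ascending, `q_(i) = p_(i) * m / i`,
#' enforce monotonicity from the largest rank down, cap at 1; returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (FDR), same order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # compute the m/i ratio first so that rank m gives exactly p (no
  # round-trip through p*m/m, which can differ in the last ulp)
  q <- pmin(1, cummin((m / (m:1)) * p[o]))[ro]
  q
}

#' Call differentially expressed features
#'
#' Applies the printed thresholds with strict inequalities: a feature is
#' `up` iff `fdr < fdr_threshold` and `log2fc > lfc_threshold`, `down` iff
#' `fdr < fdr_threshold` and `log2fc < -lfc_threshold`, otherwise `null`.
#' Values exactly at a threshold are therefore not called.
#'
#' @param stats `data.frame` with `feature_id`, `log2fc`, `p_value` and
#'   optionally `fdr` (computed with [bh_adjust()] when absent).
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cut-off (default 1).
#' @return `data.frame` with `feature_id`, `log2fc`, `p_value`, `fdr`,
#'   `call` in `{up, down, null}`.
#' @export
call_de <- function(stats, fdr_threshold = 0.05, lfc_threshold = 1.0) {
  stopifnot(is.data.frame(stats),
            all(c("feature_id", "log2fc", "p_value") %in% names(stats)))
  fdr <- if ("fdr" %in% names(stats)) stats$fdr else bh_adjust(stats$p_value)
  call <- rep("null", nrow(stats))
  sig <- fdr < fdr_threshold
  call[sig & stats$log2fc > lfc_threshold] <- "up"
  call[sig & stats$log2fc < -lfc_threshold] <- "down"
  data.frame(feature_id = stats$feature_id, log2fc = stats$log2fc,
             p_value = stats$p_value, fdr = fdr, call = call,
             stringsAsFactors = FALSE)
}

#' Differential expression table in one step
#'
#' Convenience wrapper: [differential_test()] then [bh_adjust()] then
#' [call_de()].
#'
#' @inheritParams differential_test
#' @inheritParams call_de
#' @return See [call_de()].
#' @export
de_table <- function(cm, fdr_threshold = 0.05, lfc_threshold = 1.0,
                     pseudocount = 1) {
  call_de(differential_test(cm, pseudocount = pseudocount),
          fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold)
}

#' Relative expression by the 2^-ddCt method
#'
#' qRT-PCR relative quantification:
#' `2^-((ct_target - ct_reference) - (ct_target_calibrator -
#' ct_reference_calibrator))`.
#'
#' @param ct_target Ct of the gene of interest in the sample.
#' @param ct_reference Ct of the internal reference gene in the sample.
#' @param ct_target_calibrator Ct of the gene of interest in the calibrator.
#' @param ct_reference_calibrator Ct of the reference in the calibrator.
#' @return Relative expression (1 when sample and calibrator dCt agree).
#' @export
delta_delta_ct <- function(ct_target, ct_reference,
                           ct_target_calibrator, ct_reference_calibrator) {
  vals <- c(ct_target, ct_reference, ct_target_calibrator,
            ct_reference_calibrator)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
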