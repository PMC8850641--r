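`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, i.e. the
#' probability of drawing at least `k` marked items when `n` items are drawn
#' without replacement from a universe of `N` items of which `K` are marked.
#' This single kernel backs both the ceRNA shared-sponge test
#' ([sponge_test()]) and term over-representation analysis ([enrich()]).
#'
#' @param k Observed number of marked items in the draw (overlap).
#' @param K Number of marked items in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return The upper-tail probability, a number in (0, 1].
#' @examples
#' hyper_upper_tail(3, 5, 6, 20)
#' hyper_upper_tail(0, 5, 6, 20) # == 1
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || any(c(k, K, n, N) != floor(c(k, K, n, N)))) {
    stop("hypergeometric arguments must be non-negative integers")
  }
  if (N < K || N < n) {
    stop("universe size N (", N, ") must be >= K (", K, ") and n (", n, ")")
  }
  if (k > min(K, n)) {
    stop("overlap k (", k, ") cannot exceed min(K, n) = ", min(K, n))
  }
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# --- sequence helpers ---------------------------------------------------

# Uppercase, map RNA U to DNA T, and validate the alphabet. N is allowed but
# never matches anything in the seed scanner.
normalize_seq <- function(x, what = "sequence") {
  stopifnot(is.character(x))
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,U,T,N}: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  x
}

# Reverse complement of DNA-normalized character strings. Hot path of the
# seed scanner, so plain chartr/strsplit rather than XStringSet round-trips.
rc_dna <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

dna_to_rna <- function(x) chartr("T", "U", x)

# Deterministic sub-seed per generator stage so each stage is reproducible
# independently of call order. Kept below 2^31 - 1.
stage_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 97 + offset) %% .Machine$integer.max)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1 || is.na(x) || x != floor(x) || x < min) {
    stop("'", name, "' must be a single integer >= ", min, ", got: ",
         paste(x, collapse = ","))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    stop("'", name, "' must be a single value strictly between 0 and 1")
  }
  as.numeric(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
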