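# Independent oracles. These deliberately re-derive results from first
# principles (combinatorial sums, explicit Sigma-formulas, window
# enumeration) and must stay independent of the package implementations
# they check.

# upper-tail hypergeometric by direct combinatorial sum
oracle_hyper_sum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# Pearson by explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman as Pearson of average ranks (tie-aware), via the sums formula
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# Spearman for tie-free data via the classical d^2 formula
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Benjamini-Hochberg by the definition q_i = min over j with p_(j) >= p_i
# of p_(j) * m / j  (a different formulation than the package's cummin)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ranks_ge <- which(p[o] >= p[i] - 1e-15)
    q[i] <- min(1, min(p[o][ranks_ge] * m / ranks_ge))
  }
  q
}

# Brute-force seed-site oracle: assemble the four literal site patterns and
# compare every target window against them, longest pattern first.
oracle_seed_sites <- function(mirna, target) {
  norm <- function(s) chartr("U", "T", toupper(s))
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  mir <- norm(mirna); tgt <- norm(target)
  core <- rc1(substr(mir, 2, 7))
  m8c <- rc1(substr(mir, 8, 8))
  if (grepl("N", core, fixed = TRUE)) {
    return(data.frame(start = integer(0), site_type = character(0)))
  }
  pat <- list(`8mer` = paste0(m8c, core, "A"),
              `7mer-m8` = paste0(m8c, core),
              `7mer-A1` = paste0(core, "A"),
              `6mer` = core)
  out <- list()
  L <- nchar(tgt)
  # one site per core occurrence, classified by the longest pattern that
  # matches around it
  for (p in seq_len(L - 5)) {
    if (substr(tgt, p, p + 5) != core) next
    if (!grepl("N", m8c, fixed = TRUE) && p >= 2 && p + 6 <= L &&
        substr(tgt, p - 1, p + 6) == pat$`8mer`) {
      out[[length(out) + 1]] <- data.frame(start = p - 2L,
                                           site_type = "8mer")
    } else if (!grepl("N", m8c, fixed = TRUE) && p >= 2 &&
               substr(tgt, p - 1, p + 5) == pat$`7mer-m8`) {
      out[[length(out) + 1]] <- data.frame(start = p - 2L,
                                           site_type = "7mer-m8")
    } else if (p + 6 <= L && substr(tgt, p, p + 6) == pat$`7mer-A1`) {
      out[[length(out) + 1]] <- data.frame(start = p - 1L,
                                           site_type = "7mer-A1")
    } else {
      out[[length(out) + 1]] <- data.frame(start = p - 1L,
                                           site_type = "6mer")
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), site_type = character(0)))
  }
  do.call(rbind, out)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
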