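SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Rank of a canonical seed-site type
#'
#' `6mer < 7mer-A1 <= 7mer-m8 < 8mer`; `"7mer"` is accepted as an alias for
#' the weaker 7mer class (rank of 7mer-A1), so `min_site_type = "7mer"`
#' means "7mer or better".
#'
#' @param type Site type string.
#' @return Integer rank 1-4.
#' @export
site_rank <- function(type) {
  type[type == "7mer"] <- "7mer-A1"
  r <- match(type, SITE_TYPES)
  if (any(is.na(r))) {
    stop("unknown site type: ", paste(type[is.na(r)], collapse = ", "))
  }
  r
}

empty_sites <- function() {
  data.frame(mirna_id = character(0), target_id = character(0),
             start = integer(0), site_type = character(0),
             site_length = integer(0), stringsAsFactors = FALSE)
}

#' Scan a target sequence for canonical miRNA seed sites
#'
#' Finds every exact reverse-complement match of miRNA positions 2-7 (the
#' 6mer core) on the target's sense strand and classifies each occurrence
#' with the canonical taxonomy:
#' \describe{
#'   \item{8mer}{match to positions 2-8 plus an `A` opposite position 1;}
#'   \item{7mer-m8}{match to positions 2-8;}
#'   \item{7mer-A1}{6mer core plus the `A` opposite position 1;}
#'   \item{6mer}{the core alone.}
#' }
#' Each core occurrence is reported once at its single best (longest) type;
#' overlapping occurrences are all reported. RNA and DNA spellings are
#' equivalent (`U == T`); `N` never matches.
#'
#' @param mirna_sequence miRNA sequence, 5'->3', length >= 8.
#' @param target_sequence Target (3'UTR or lncRNA) sequence, 5'->3'.
#' @param mirna_id,target_id Identifiers copied into the result.
#' @return `data.frame` with columns `mirna_id`, `target_id`, `start`
#'   (0-based position of the full site on the target), `site_type`,
#'   `site_length`.
#' @examples
#' # let-7 family seed: target carrying the 8mer CTACCTCA
#' find_seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "GGGGCTACCTCAGGGG")
#' @export
find_seed_sites <- function(mirna_sequence, target_sequence,
                            mirna_id = "miRNA", target_id = "target") {
  mir <- normalize_seq(mirna_sequence, "miRNA sequence")
  tgt <- normalize_seq(target_sequence, "target sequence")
  if (nchar(mir) < 8) stop("miRNA must be at least 8 nt, got ", nchar(mir))
  core <- rc_dna(substr(mir, 2, 7))      # reverse complement of seed 2-7
  m8c <- rc_dna(substr(mir, 8, 8))       # complement of position 8
  if (grepl("N", core, fixed = TRUE)) return(empty_sites())
  hits <- gregexpr(core, tgt, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(empty_sites())
  rows <- lapply(as.integer(hits), function(p) {
    has_m8 <- p >= 2 && m8c != "N" && substr(tgt, p - 1, p - 1) == m8c
    has_a1 <- p + 6 <= nchar(tgt) && substr(tgt, p + 6, p + 6) == "A"
    if (has_m8 && has_a1) {
      list(start = p - 2L, type = "8mer", len = 8L)
    } else if (has_m8) {
      list(start = p - 2L, type = "7mer-m8", len = 7L)
    } else if (has_a1) {
      list(start = p - 1L, type = "7mer-A1", len = 7L)
    } else {
      list(start = p - 1L, type = "6mer", len = 6L)
    }
  })
  data.frame(
    mirna_id = mirna_id, target_id = target_id,
    start = vapply(rows, function(r) r$start, integer(1)),
    site_type = vapply(rows, function(r) r$type, character(1)),
    site_length = vapply(rows, function(r) r$len, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Predict miRNA-target candidate pairs by seed match
#'
#' Scans every (miRNA, target) combination with [find_seed_sites()] and
#' keeps pairs having at least one site at or above `min_site_type`
#' (default "7mer", i.e. 7mer-or-better evidence). Output is sorted by
#' miRNA then target id, so it is deterministic.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param min_site_type Minimum qualifying site type (see [site_rank()]).
#' @return `data.frame` with `mirna_id`, `target_id`, `n_sites` (qualifying
#'   sites) and `best_type`.
#' @export
predict_targets <- function(mirnas, targets, min_site_type = "7mer") {
  stopifnot(is.character(mirnas), is.character(targets))
  if (length(mirnas) == 0 || length(targets) == 0) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      n_sites = integer(0), best_type = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(mirnas)) || is.null(names(targets))) {
    stop("mirnas and targets must be named")
  }
  min_rank <- site_rank(min_site_type)
  out <- list()
  for (m in sort(names(mirnas))) {
    for (t in sort(names(targets))) {
      sites <- find_seed_sites(mirnas[[m]], targets[[t]], m, t)
      if (nrow(sites) == 0) next
      keep <- site_rank(sites$site_type) >= min_rank
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        mirna_id = m, target_id = t, n_sites = sum(keep),
        best_type = SITE_TYPES[max(site_rank(sites$site_type[keep]))],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      n_sites = integer(0), best_type = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
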