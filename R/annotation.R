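LNC_CATEGORIES <- c("sense", "antisense", "intronic", "bidirectional",
                    "intergenic")

#' Filter novel transcripts
#'
#' Keeps transcripts whose spliced length is strictly greater than
#' `min_length` (default 200 nt) and whose exon count is at least
#' `min_exons`. The exon rule defaults to >= 2 (the common multi-exon
#' convention); set `min_exons = 3` for the literal ">2 exons" reading.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param min_length Minimum spliced length, exclusive (nt).
#' @param min_exons Minimum exon count, inclusive.
#' @return The kept subset of `transcripts`.
#' @export
filter_novel_transcripts <- function(transcripts, min_length = 200,
                                     min_exons = 2) {
  keep <- vapply(transcripts, function(m) {
    spliced_length(m) > min_length && n_exons(m) >= min_exons
  }, logical(1))
  transcripts[keep]
}

#' Classify a lncRNA by position relative to protein-coding genes
#'
#' Assigns one of five positional categories by the first matching rule:
#' \enumerate{
#'   \item \strong{sense} — any exon of the lncRNA overlaps an exon of a
#'     same-strand coding gene;
#'   \item \strong{antisense} — the lncRNA span overlaps the span of an
#'     opposite-strand coding gene;
#'   \item \strong{intronic} — the lncRNA span lies fully inside a single
#'     intron of a same-strand coding gene;
#'   \item \strong{bidirectional} — no span overlap with any coding gene,
#'     and the lncRNA TSS lies within `bidirectional_window` of the TSS of
#'     an opposite-strand (divergently transcribed) coding gene;
#'   \item \strong{intergenic} — otherwise.
#' }
#' Precedence puts physical overlap ahead of proximity and uses strand to
#' disambiguate overlap; both the order and the window are package design
#' choices, documented in the methods vignette.
#'
#' @param lnc A [transcript_model()] for the lncRNA.
#' @param coding_genes List of [gene_model()] objects (protein-coding).
#' @param bidirectional_window Maximum TSS-to-TSS distance (nt) for the
#'   bidirectional call. Default 1000.
#' @return A single category string.
#' @export
classify_lncrna <- function(lnc, coding_genes, bidirectional_window = 1000) {
  if (!lnc$strand %in% c("+", "-")) stop("unknown strand for ", lnc$id)
  chroms <- vapply(coding_genes, function(g) g$chromosome, character(1))
  if (length(coding_genes) && !lnc$chromosome %in% chroms) {
    stop("unknown chromosome '", lnc$chromosome, "' for ", lnc$id,
         ": no coding gene annotated there")
  }
  genes <- coding_genes[chroms == lnc$chromosome]
  lsp <- model_span(lnc)

  same <- Filter(function(g) g$strand == lnc$strand, genes)
  anti <- Filter(function(g) g$strand != lnc$strand, genes)

  # 1. sense: exonic overlap, same strand
  for (g in same) {
    for (i in seq_len(nrow(lnc$exons))) {
      if (any(intervals_overlap(lnc$exons$start[i], lnc$exons$end[i],
                                g$exons$start, g$exons$end))) {
        return("sense")
      }
    }
  }
  # 2. antisense: span overlap, opposite strand
  for (g in anti) {
    gsp <- model_span(g)
    if (intervals_overlap(lsp["start"], lsp["end"], gsp["start"], gsp["end"])) {
      return("antisense")
    }
  }
  # 3. intronic: span fully inside one intron of a same-strand gene
  for (g in same) {
    intr <- model_introns(g)
    if (nrow(intr) &&
        any(lsp["start"] >= intr$start & lsp["end"] <= intr$end)) {
      return("intronic")
    }
  }
  # 4. bidirectional: no span overlap anywhere, divergent TSS within window
  overlaps_any <- any(vapply(genes, function(g) {
    gsp <- model_span(g)
    intervals_overlap(lsp["start"], lsp["end"], gsp["start"], gsp["end"])
  }, logical(1)))
  if (!overlaps_any) {
    for (g in anti) {
      if (abs(model_tss(lnc) - model_tss(g)) <= bidirectional_window) {
        return("bidirectional")
      }
    }
  }
  # 5. intergenic
  "intergenic"
}

#' @rdname classify_lncrna
#' @param lncs List of lncRNA transcript models.
#' @return For `classify_lncrnas`, a named character vector of categories.
#' @export
classify_lncrnas <- function(lncs, coding_genes, bidirectional_window = 1000) {
  out <- vapply(lncs, classify_lncrna, character(1),
                coding_genes = coding_genes,
                bidirectional_window = bidirectional_window)
  names(out) <- vapply(lncs, function(m) m$id, character(1))
  out
}

#' Write the lncRNA category table
#'
#' @param categories Named character vector from [classify_lncrnas()].
#' @param path Output TSV path (`transcript_id <TAB> category`).
#' @return `path`, invisibly.
#' @export
write_category_table <- function(categories, path) {
  write_tsv(data.frame(transcript_id = names(categories),
                       category = unname(categories)), path)
}

# --- small RNA annotation cascade --------------------------------------

SRNA_PRIORITY <- c("rrna_etc", "existing_mirna", "existing_mirna_edit",
                   "known_mirna", "repeat", "exon", "novel_mirna", "intron")

#' Small RNA tag
#'
#' A clean sequencing tag with its read count and (optionally) the genomic
#' intervals it maps to, used by the annotation priority cascade.
#'
#' @param sequence Tag sequence (RNA or DNA alphabet), length >= 15 nt.
#' @param count Read count, >= 1.
#' @param matches Optional `data.frame` of genomic matches with columns
#'   `chromosome`, `start`, `end`.
#' @return An object of class `srna_tag`.
#' @export
srna_tag <- function(sequence, count = 1L, matches = NULL) {
  sequence <- normalize_seq(sequence, "tag sequence")
  if (nchar(sequence) < 15) stop("sRNA tag shorter than 15 nt")
  count <- assert_count(count, "count", min = 1L)
  if (!is.null(matches)) {
    stopifnot(all(c("chromosome", "start", "end") %in% names(matches)))
  }
  structure(list(sequence = sequence, count = count, matches = matches),
            class = "srna_tag")
}

# does a tag match one annotation track?
# A track is a list with optional members:
#   $sequences - character vector, exact (T/U-normalized) sequence match
#   $intervals - data.frame(chromosome, start, end), overlap with tag matches
#   $edit_of   - character vector of mature miRNAs matched with <= 1 internal
#                substitution and length within +/- 2 nt (and not exactly)
track_matches <- function(tag, track) {
  if (is.null(track)) return(FALSE)
  if (!is.list(track)) stop("malformed annotation track: not a list")
  if (!is.null(track$sequences)) {
    if (tag$sequence %in% normalize_seq(track$sequences, "track")) {
      return(TRUE)
    }
  }
  if (!is.null(track$edit_of)) {
    if (is_mirna_edit(tag$sequence, normalize_seq(track$edit_of, "track"))) {
      return(TRUE)
    }
  }
  if (!is.null(track$intervals)) {
    iv <- track$intervals
    if (!all(c("chromosome", "start", "end") %in% names(iv))) {
      stop("malformed annotation track: intervals need chromosome/start/end")
    }
    if (!is.null(tag$matches) && nrow(tag$matches)) {
      for (i in seq_len(nrow(tag$matches))) {
        hit <- iv$chromosome == tag$matches$chromosome[i] &
          intervals_overlap(tag$matches$start[i], tag$matches$end[i],
                            iv$start, iv$end)
        if (any(hit)) return(TRUE)
      }
    }
  }
  FALSE
}

# "edit" of a known mature miRNA: length within +/- 2 nt and at most one
# substitution over the shared prefix, at an internal position (not the
# first or last base of the comparison window); exact matches do not count.
is_mirna_edit <- function(seq, mature) {
  for (m in mature) {
    if (abs(nchar(seq) - nchar(m)) > 2) next
    L <- min(nchar(seq), nchar(m))
    a <- strsplit(substr(seq, 1, L), "")[[1]]
    b <- strsplit(substr(m, 1, L), "")[[1]]
    mism <- which(a != b)
    if (seq == m) next
    if (length(mism) == 0 && nchar(seq) != nchar(m)) return(TRUE)
    if (length(mism) == 1 && mism > 1 && mism < L) return(TRUE)
  }
  FALSE
}

#' Annotate a small RNA tag through the priority cascade
#'
#' Tries each annotation track in the fixed priority order
#' `rrna_etc > existing_mirna > existing_mirna_edit > known_mirna > repeat >
#' exon > novel_mirna > intron` and returns the first category whose track
#' matches; tags matching no track are `"unannotated"`. When an
#' `existing_mirna` track with `$sequences` is supplied and no explicit
#' `existing_mirna_edit` track is given, the edit track is derived from it.
#'
#' @param tag An [srna_tag()].
#' @param tracks Named list of tracks (names from the priority order); each
#'   track is a list with optional `$sequences`, `$intervals`, `$edit_of`.
#' @param priority Category order; defaults to the cascade above.
#' @return The annotation category string.
#' @export
annotate_srna <- function(tag, tracks, priority = SRNA_PRIORITY) {
  stopifnot(inherits(tag, "srna_tag"), is.list(tracks))
  unknown <- setdiff(names(tracks), priority)
  if (length(unknown)) {
    stop("unknown annotation track(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(tracks[["existing_mirna_edit"]]) &&
      !is.null(tracks[["existing_mirna"]]$sequences)) {
    tracks$existing_mirna_edit <-
      list(edit_of = tracks[["existing_mirna"]]$sequences)
  }
  for (cat in priority) {
    if (track_matches(tag, tracks[[cat]])) return(cat)
  }
  "unannotated"
}

#' Length distribution of small RNA tags
#'
#' Per-length totals weighted by tag count, plus the modal length; ties are
#' broken toward the smaller length.
#'
#' @param tags List of [srna_tag()] objects.
#' @return List with `histogram` (`data.frame` of `length`, `count`) and
#'   `mode` (integer modal length).
#' @export
length_distribution <- function(tags) {
  if (length(tags) == 0) stop("no tags supplied")
  len <- vapply(tags, function(t) nchar(t$sequence), integer(1))
  cnt <- vapply(tags, function(t) t$count, integer(1))
  agg <- stats::aggregate(list(count = cnt), by = list(length = len), FUN = sum)
  agg <- agg[order(agg$length), ]
  mode_len <- agg$length[which.max(agg$count)] # which.max: first == smallest
  list(histogram = agg, mode = as.integer(mode_len))
}
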