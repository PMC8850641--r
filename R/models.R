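#' Transcript and gene models
#'
#' Lightweight exon-structured interval models used by the lncRNA classifier
#' and the fixture generator. Coordinates are 1-based inclusive throughout
#' (GTF convention); BED export converts to 0-based half-open.
#'
#' @param id Transcript (or gene) identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with integer columns `start`, `end`; exons must
#'   be sorted and non-overlapping.
#' @param biotype `"protein_coding"` or `"lncRNA"`.
#' @param gene_id Parent gene identifier (transcripts only).
#' @return An object of class `transcript_model` / `gene_model`.
#' @export
transcript_model <- function(id, chromosome, strand, exons,
                             biotype = "lncRNA", gene_id = id) {
  validate_exons(exons, id)
  if (!strand %in% c("+", "-")) {
    stop("transcript ", id, ": strand must be '+' or '-', got '", strand, "'")
  }
  structure(
    list(id = id, gene_id = gene_id, chromosome = chromosome, strand = strand,
         exons = exons[order(exons$start), c("start", "end"), drop = FALSE],
         biotype = biotype),
    class = "transcript_model"
  )
}

#' @rdname transcript_model
#' @export
gene_model <- function(id, chromosome, strand, exons,
                       biotype = "protein_coding") {
  tm <- transcript_model(id, chromosome, strand, exons, biotype)
  class(tm) <- c("gene_model", "transcript_model")
  tm
}

validate_exons <- function(exons, id) {
  if (!is.data.frame(exons) || !all(c("start", "end") %in% names(exons)) ||
      nrow(exons) < 1) {
    stop("model ", id, ": exons must be a data.frame with start/end rows")
  }
  ex <- exons[order(exons$start), ]
  if (any(ex$end < ex$start)) stop("model ", id, ": exon end < start")
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    stop("model ", id, ": exons overlap or touch; merge them first")
  }
  invisible(ex)
}

model_span <- function(m) c(start = min(m$exons$start), end = max(m$exons$end))

model_tss <- function(m) {
  sp <- model_span(m)
  if (m$strand == "+") unname(sp["start"]) else unname(sp["end"])
}

spliced_length <- function(m) sum(m$exons$end - m$exons$start + 1L)

n_exons <- function(m) nrow(m$exons)

# Introns as a data.frame of 1-based inclusive gaps between exons.
model_introns <- function(m) {
  ex <- m$exons
  if (nrow(ex) < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<%s> %s %s:%d-%d(%s) %d exon(s), %s\n",
              class(x)[1], x$id, x$chromosome,
              model_span(x)["start"], model_span(x)["end"], x$strand,
              n_exons(x), x$biotype))
  invisible(x)
}

# --- GTF I/O ------------------------------------------------------------

#' Write transcript/gene models to GTF
#'
#' Emits `transcript` and `exon` features with `gene_id`, `transcript_id`
#' and `gene_biotype` attributes, 1-based inclusive coordinates.
#'
#' @param models List of `transcript_model` / `gene_model` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     m$gene_id, m$id, m$biotype)
    sp <- model_span(m)
    tline <- paste(m$chromosome, "spongenet", "transcript", sp["start"],
                   sp["end"], ".", m$strand, ".", attrs, sep = "\t")
    elines <- paste(m$chromosome, "spongenet", "exon", m$exons$start,
                    m$exons$end, ".", m$strand, ".", attrs, sep = "\t")
    c(tline, elines)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Parses a GTF file (via \pkg{rtracklayer}) into `transcript_model`
#' objects, grouping `exon` features by `transcript_id`. Gene models are
#' rebuilt from protein-coding transcripts (exon union per `gene_id`).
#'
#' @param path GTF file path.
#' @return List with `transcripts` (all transcript models) and `genes`
#'   (protein-coding gene models).
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    biotype = if (!is.null(gr$gene_biotype)) gr$gene_biotype else NA_character_,
    stringsAsFactors = FALSE
  )
  transcripts <- lapply(split(df, df$transcript_id), function(d) {
    transcript_model(d$transcript_id[1], d$chromosome[1], d$strand[1],
                     data.frame(start = d$start, end = d$end),
                     biotype = d$biotype[1], gene_id = d$gene_id[1])
  })
  coding <- df[df$biotype %in% "protein_coding", ]
  genes <- lapply(split(coding, coding$gene_id), function(d) {
    ex <- unique(d[order(d$start), c("start", "end")])
    gene_model(d$gene_id[1], d$chromosome[1], d$strand[1], ex)
  })
  list(transcripts = unname(transcripts), genes = unname(genes))
}

#' Export lncRNA models to BED
#'
#' Span-level BED6 (0-based, half-open) with the transcript id as name.
#'
#' @param models List of transcript models.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lncrna_bed <- function(models, path) {
  lines <- vapply(models, function(m) {
    sp <- model_span(m)
    paste(m$chromosome, sp["start"] - 1L, sp["end"], m$id, 0L, m$strand,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
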