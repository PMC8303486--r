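#' Construct a transcript model
#'
#' A `transcript_model` holds the exon structure of one transcript in
#' transcription (5'->3') order, with internal 0-based half-open genomic
#' coordinates, plus an optional transcript-relative coding interval.
#' On the minus strand the exon list is descending in genomic coordinates.
#' By package convention the coding interval includes the stop codon, i.e.
#' `cds_end` is the transcript-relative end (exclusive) of the stop codon
#' when a stop is annotated.
#'
#' @param transcript_id,gene_id identifier strings.
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open, rows in transcription order).
#' @param cds_start,cds_end transcript-relative 0-based half-open coding
#'   interval, or `NA` when the transcript is noncoding.
#' @param biotype transcript biotype string (e.g. `"protein_coding"`).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             biotype = "protein_coding") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            is.data.frame(exons),
            all(c("chrom", "start", "end", "strand") %in% names(exons)))
  if (nrow(exons) < 1L)
    stop("transcript '", transcript_id, "' has no exons", call. = FALSE)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0L) || any(exons$start >= exons$end))
    stop("invalid exon interval in transcript '", transcript_id, "'",
         call. = FALSE)
  if (!all(exons$strand %in% c("+", "-")))
    stop("exon strand must be '+' or '-'", call. = FALSE)
  strand <- exons$strand[1L]
  if (length(unique(exons$strand)) != 1L)
    stop("mixed strands in transcript '", transcript_id, "'", call. = FALSE)
  # non-overlap + transcription order
  if (nrow(exons) > 1L) {
    d <- diff(exons$start)
    ok <- if (strand == "+") all(d > 0) else all(d < 0)
    if (!ok)
      stop("exons of transcript '", transcript_id,
           "' are not in transcription order", call. = FALSE)
    g <- exons[order(exons$start), , drop = FALSE]
    if (any(g$start[-1L] < g$end[-nrow(g)]))
      stop("overlapping exons in transcript '", transcript_id, "'",
           call. = FALSE)
  }
  len <- sum(exons$end - exons$start)
  if (!is.na(cds_start)) {
    cds_start <- as.integer(cds_start)
    cds_end <- as.integer(cds_end)
    if (cds_start < 0L || cds_start >= cds_end || cds_end > len)
      stop("cds interval outside transcript '", transcript_id, "'",
           call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         exons = exons[, c("chrom", "start", "end", "strand")],
         cds_start = cds_start, cds_end = cds_end, biotype = biotype),
    class = "transcript_model")
}

#' Total exonic length of a transcript
#' @param t a [transcript_model()].
#' @return integer length in nucleotides.
#' @export
transcript_length <- function(t) {
  sum(t$exons$end - t$exons$start)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s, %s, %d exon(s), %d nt",
              x$transcript_id, x$gene_id, x$exons$strand[1L],
              nrow(x$exons), transcript_length(x)))
  if (!is.na(x$cds_start))
    cat(sprintf(", CDS [%d,%d)", x$cds_start, x$cds_end))
  cat(")\n")
  invisible(x)
}

# Map a transcript-relative half-open interval [tstart, tend) onto genomic
# pieces, one row per overlapped exon, in transcription order.
transcript_to_genomic <- function(t, tstart, tend) {
  w <- t$exons$end - t$exons$start
  cum <- c(0L, cumsum(w))
  out <- list()
  for (k in seq_len(nrow(t$exons))) {
    a <- max(tstart, cum[k]); b <- min(tend, cum[k + 1L])
    if (a >= b) next
    ra <- a - cum[k]; rb <- b - cum[k]           # offsets within exon
    ex <- t$exons[k, ]
    if (ex$strand == "+") {
      gs <- ex$start + ra; ge <- ex$start + rb
    } else {
      gs <- ex$end - rb; ge <- ex$end - ra
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = ex$chrom, start = gs, end = ge, strand = ex$strand,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Map genomic half-open intervals (data.frame chrom/start/end) lying within
# the exons of `t` to a transcript-relative [min,max) envelope.
genomic_to_transcript_bounds <- function(t, g) {
  w <- t$exons$end - t$exons$start
  cum <- c(0L, cumsum(w))
  tpos <- c()
  for (i in seq_len(nrow(g))) {
    hit <- FALSE
    for (k in seq_len(nrow(t$exons))) {
      ex <- t$exons[k, ]
      if (g$chrom[i] != ex$chrom) next
      a <- max(g$start[i], ex$start); b <- min(g$end[i], ex$end)
      if (a >= b) next
      hit <- TRUE
      if (ex$strand == "+") {
        tpos <- c(tpos, cum[k] + (a - ex$start), cum[k] + (b - ex$start))
      } else {
        tpos <- c(tpos, cum[k] + (ex$end - b), cum[k] + (ex$end - a))
      }
    }
    if (!hit)
      stop("CDS feature [", g$start[i], ",", g$end[i],
           ") of transcript '", t$transcript_id,
           "' does not overlap its exons", call. = FALSE)
  }
  c(min(tpos), max(tpos))
}
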