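#' Load transcript models from a GTF file
#'
#' Reads exon and CDS features of an Ensembl-dialect GTF and assembles one
#' [transcript_model()] per transcript. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention at this boundary;
#' exons are stored in transcription order (descending genomic coordinates on
#' the minus strand). Genomic CDS features are mapped to a transcript-relative
#' coding interval.
#'
#' @param path path to a GTF file.
#' @param attribute_keys named list giving the GTF attribute names used for
#'   the gene id, transcript id and biotype.
#' @return named list of [transcript_model()] objects (names = transcript id).
#' @export
load_gtf <- function(path,
                     attribute_keys = list(gene_id = "gene_id",
                                           transcript_id = "transcript_id",
                                           biotype = "transcript_biotype")) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf < 9L)
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, found %d",
                   i, nf), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS features in GTF: ", path, call. = FALSE)
  gid_k <- attribute_keys$gene_id
  tid_k <- attribute_keys$transcript_id
  bt_k <- attribute_keys$biotype
  if (!tid_k %in% names(df))
    stop("GTF lacks attribute '", tid_k, "'", call. = FALSE)
  df$chrom <- as.character(df$seqnames)
  df$start0 <- df$start - 1L                    # to 0-based half-open
  df$end0 <- df$end
  df$strand <- as.character(df$strand)

  out <- list()
  for (tid in unique(df[[tid_k]])) {
    sub <- df[df[[tid_k]] == tid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) {
      if (nrow(cds) > 0L)
        stop("transcript '", tid, "' has CDS features but no exons",
             call. = FALSE)
      next
    }
    strand <- ex$strand[1L]
    ord <- order(ex$start0, decreasing = (strand == "-"))
    exons <- data.frame(chrom = ex$chrom[ord], start = ex$start0[ord],
                        end = ex$end0[ord], strand = ex$strand[ord],
                        stringsAsFactors = FALSE)
    gid <- if (gid_k %in% names(sub)) sub[[gid_k]][1L] else NA_character_
    bt <- if (bt_k %in% names(sub) && !is.na(sub[[bt_k]][1L]))
      sub[[bt_k]][1L] else "protein_coding"
    t <- transcript_model(tid, gid, exons, biotype = bt)
    if (nrow(cds) > 0L) {
      b <- genomic_to_transcript_bounds(
        t, data.frame(chrom = cds$chrom, start = cds$start0, end = cds$end0,
                      stringsAsFactors = FALSE))
      t <- transcript_model(tid, gid, exons, cds_start = b[1L],
                            cds_end = b[2L], biotype = bt)
    }
    out[[tid]] <- t
  }
  out
}

#' Write transcript models to a GTF file
#'
#' Inverse of [load_gtf()]: emits exon and CDS features with 1-based
#' inclusive coordinates. A load/write round trip reproduces the original
#' feature coordinates.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  rows <- character(0)
  fmt <- function(t, type, chrom, s0, e0, strand, frame = ".") {
    sprintf(paste0("%s\torthosplice\t%s\t%d\t%d\t.\t%s\t%s\t",
                   "gene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"%s\";"),
            chrom, type, s0 + 1L, e0, strand, frame,
            t$gene_id, t$transcript_id, t$biotype)
  }
  for (t in transcripts) {
    for (k in seq_len(nrow(t$exons))) {
      ex <- t$exons[k, ]
      rows <- c(rows, fmt(t, "exon", ex$chrom, ex$start, ex$end, ex$strand))
    }
    if (!is.na(t$cds_start)) {
      g <- transcript_to_genomic(t, t$cds_start, t$cds_end)
      done <- 0L
      for (k in seq_len(nrow(g))) {
        frame <- as.character((3L - done %% 3L) %% 3L)
        rows <- c(rows, fmt(t, "CDS", g$chrom[k], g$start[k], g$end[k],
                            g$strand[k], frame))
        done <- done + (g$end[k] - g$start[k])
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Returns a named character vector (names = full header after `>`,
#' sequences uppercased, whitespace stripped). Duplicate headers raise a
#' warning but both records are kept; an empty record is an error.
#'
#' @param path path to a text FASTA file.
#' @return named character vector of sequences.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L))
    stop("empty FASTA record(s): ",
         paste(names(set)[Biostrings::width(set) == 0L], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(set)))
    warning("duplicate FASTA header(s): ",
            paste(unique(names(set)[duplicated(names(set))]), collapse = ", "),
            call. = FALSE)
  x <- toupper(gsub("[[:space:]]", "", as.character(set)))
  names(x) <- names(set)
  x
}

#' Write a FASTA file (60 characters per line)
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Load a UniProt idmapping table
#'
#' Reads the 3-column UniProt `*_idmapping.dat` dialect (accession, id type,
#' value) and retains the rows whose id type equals `geneid_label`, giving
#' accession-to-gene pairs for one taxon. Duplicate pairs are deduplicated.
#'
#' @param path path to the idmapping file.
#' @param taxon positive integer NCBI taxon id of the file's species.
#' @param geneid_label id type selecting gene identifier rows (default
#'   `"GeneID"`, the NCBI gene id rows).
#' @return data.frame with columns `accession`, `gene_id`, `taxon`.
#' @export
load_id_mapping <- function(path, taxon, geneid_label = "GeneID") {
  stopifnot(is.numeric(taxon), taxon > 0)
  df <- read.delim(path, header = FALSE, quote = "",
                   col.names = c("accession", "id_type", "value"),
                   colClasses = "character")
  df <- df[df$id_type == geneid_label, , drop = FALSE]
  out <- unique(data.frame(accession = df$accession, gene_id = df$value,
                           taxon = rep(as.integer(taxon), nrow(df)),
                           stringsAsFactors = FALSE))
  if (nrow(out) == 0L)
    warning("no '", geneid_label, "' rows in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Load an NCBI gene_orthologs table for a taxon pair
#'
#' Reads the 5-column NCBI `gene_orthologs` dialect (tax_id, GeneID,
#' relationship, Other_tax_id, Other_GeneID; `#` comment lines allowed),
#' keeping rows for the requested taxon pair in either orientation and with
#' the configured relationship label. Pairs are normalized to the
#' `(taxon_a, taxon_b)` orientation and deduplicated.
#'
#' @param path path to the gene_orthologs file.
#' @param taxon_a,taxon_b positive integer taxon ids.
#' @param relationship relationship label retained (default `"Ortholog"`).
#' @return data.frame with columns `taxon_a`, `gene_a`, `taxon_b`, `gene_b`,
#'   `relationship`.
#' @export
load_gene_orthologs <- function(path, taxon_a, taxon_b,
                                relationship = "Ortholog") {
  stopifnot(taxon_a > 0, taxon_b > 0)
  df <- read.delim(path, header = FALSE, quote = "", comment.char = "#",
                   col.names = c("tax_id", "gene_id", "relationship",
                                 "other_tax_id", "other_gene_id"),
                   colClasses = c("integer", "character", "character",
                                  "integer", "character"))
  df <- df[df$relationship == relationship, , drop = FALSE]
  fwd <- df[df$tax_id == taxon_a & df$other_tax_id == taxon_b, , drop = FALSE]
  rev <- df[df$tax_id == taxon_b & df$other_tax_id == taxon_a, , drop = FALSE]
  out <- rbind(
    data.frame(taxon_a = rep(as.integer(taxon_a), nrow(fwd)),
               gene_a = fwd$gene_id,
               taxon_b = rep(as.integer(taxon_b), nrow(fwd)),
               gene_b = fwd$other_gene_id,
               relationship = rep(relationship, nrow(fwd)),
               stringsAsFactors = FALSE),
    data.frame(taxon_a = rep(as.integer(taxon_a), nrow(rev)),
               gene_a = rev$other_gene_id,
               taxon_b = rep(as.integer(taxon_b), nrow(rev)),
               gene_b = rev$gene_id,
               relationship = rep(relationship, nrow(rev)),
               stringsAsFactors = FALSE))
  out <- unique(out)
  if (nrow(out) == 0L)
    warning("no '", relationship, "' rows for taxa ", taxon_a, "/", taxon_b,
            " in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a peptide identification table
#'
#' Headered TSV with columns `peptide`, `db_entry_id`, `sample_group`,
#' `spectral_count` (one row per peptide/database entry/sample group).
#' Peptides are uppercased on load.
#'
#' @param path path to the TSV.
#' @return data.frame with the four columns above.
#' @export
read_identifications <- function(path) {
  df <- read.delim(path, quote = "", colClasses = "character")
  need <- c("peptide", "db_entry_id", "sample_group", "spectral_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("identification table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$peptide <- toupper(df$peptide)
  df$spectral_count <- as.integer(df$spectral_count)
  if (any(is.na(df$spectral_count)) || any(df$spectral_count < 0L))
    stop("spectral_count must be a nonnegative integer in ", path,
         call. = FALSE)
  df[, need]
}

#' Read an iTRAQ reporter-intensity table
#'
#' Headered TSV with columns `spectrum_id`, `peptide` and one numeric column
#' per reporter channel label (e.g. `117`, `118`).
#'
#' @param path path to the TSV.
#' @return data.frame; channel columns keep their literal labels.
#' @export
read_quant_table <- function(path) {
  df <- read.delim(path, quote = "", check.names = FALSE)
  need <- c("spectrum_id", "peptide")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("quant table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  chan <- setdiff(names(df), need)
  if (length(chan) < 2L)
    stop("quant table ", path, " needs at least two channel columns",
         call. = FALSE)
  for (cc in chan) df[[cc]] <- as.numeric(df[[cc]])
  df$peptide <- toupper(as.character(df$peptide))
  df
}

#' Read a qPCR Ct table
#'
#' Headered TSV with columns `sample_id`, `group`, `gene`, `ct`.
#'
#' @param path path to the TSV.
#' @return data.frame with the four columns above.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, quote = "")
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$ct <- as.numeric(df$ct)
  df[, need]
}

#' Read a transcript count table
#'
#' Headered TSV with columns `transcript_id`, `count`, `effective_length`.
#'
#' @param path path to the TSV.
#' @return data.frame with the three columns above.
#' @export
read_transcript_counts <- function(path) {
  df <- read.delim(path, quote = "")
  need <- c("transcript_id", "count", "effective_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$count <- as.numeric(df$count)
  df$effective_length <- as.numeric(df$effective_length)
  df[, need]
}
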