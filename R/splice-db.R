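#' NMD classification configuration
#'
#' The classifier implements the canonical 50-nt rule of the NMD literature:
#' a transcript is a nonsense-mediated-decay candidate when its stop codon
#' ends more than `junction_distance_threshold` nucleotides upstream of the
#' last exon-exon junction.
#'
#' @param junction_distance_threshold nonnegative integer, nucleotides
#'   (default 50).
#' @return list of class `nmd_config`.
#' @export
nmd_config <- function(junction_distance_threshold = 50L) {
  stopifnot(junction_distance_threshold >= 0)
  structure(list(junction_distance_threshold =
                   as.integer(junction_distance_threshold)),
            class = "nmd_config")
}

#' In-silico trypsin digestion configuration
#'
#' @param max_missed_cleavages maximum internal uncut K/R sites per peptide
#'   (default 2, mirroring typical database-search settings).
#' @param min_peptide_length,max_peptide_length retained peptide length
#'   window in amino acids (defaults 6 and 45, the MS-observable range).
#' @param proline_rule if `TRUE` (default) do not cleave after K/R when the
#'   next residue is proline.
#' @param collapse_IL if `TRUE`, treat isoleucine and leucine as identical
#'   for exclusivity/identity comparisons (isobaric in MS); default `FALSE`.
#' @return list of class `digest_config`.
#' @export
digest_config <- function(max_missed_cleavages = 2L, min_peptide_length = 6L,
                          max_peptide_length = 45L, proline_rule = TRUE,
                          collapse_IL = FALSE) {
  stopifnot(max_missed_cleavages >= 0, min_peptide_length >= 1,
            min_peptide_length <= max_peptide_length)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_peptide_length = as.integer(min_peptide_length),
                 max_peptide_length = as.integer(max_peptide_length),
                 proline_rule = isTRUE(proline_rule),
                 collapse_IL = isTRUE(collapse_IL)),
            class = "digest_config")
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code; translation halts at the first stop codon (the
#' stop symbol is not included in the returned protein). Codons containing
#' `N` translate to `X`. A trailing partial codon is ignored.
#'
#' @param nt nucleotide string over the alphabet `ACGTN` (case-insensitive),
#'   length >= 3.
#' @return list with `aa` (amino-acid string) and `stop_found` (logical).
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n < 3L) stop("coding sequence shorter than one codon", call. = FALSE)
  if (grepl("[^ACGTN]", nt))
    stop("coding sequence contains characters outside ACGTN", call. = FALSE)
  n3 <- n - n %% 3L
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n3)),
                          if.fuzzy.codon = "X")))
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) {
    list(aa = substr(aa, 1L, star - 1L), stop_found = TRUE)
  } else {
    list(aa = aa, stop_found = FALSE)
  }
}

# Positions (1-based residue index) after which trypsin cleaves.
cleavage_sites <- function(sequence, proline_rule = TRUE) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) return(integer(0))
  pos <- which(ch[-n] %in% c("K", "R"))
  if (proline_rule && length(pos)) pos <- pos[ch[pos + 1L] != "P"]
  pos
}

#' Tryptic in-silico digestion of one proteoform
#'
#' Cleaves after K or R (and, with the proline rule, not when the next
#' residue is P), emits every peptide with 0..`max_missed_cleavages`
#' internal uncut sites, then filters to the configured length window.
#' The 0-based offset of each peptide within the parent is recorded.
#'
#' @param sequence amino-acid string of the proteoform.
#' @param parent_id identifier of the parent proteoform.
#' @param cfg a [digest_config()].
#' @return data.frame with columns `sequence`, `parent_id`, `start`
#'   (0-based), `missed_cleavages`.
#' @export
digest <- function(sequence, parent_id = NA_character_,
                   cfg = digest_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sites <- cleavage_sites(sequence, cfg$proline_rule)
  bounds <- c(0L, sites, nchar(sequence))       # fragment boundaries
  f <- length(bounds) - 1L
  seqs <- character(0); starts <- integer(0); mcs <- integer(0)
  for (m in 0:min(cfg$max_missed_cleavages, f - 1L)) {
    for (i in seq_len(f - m)) {
      s <- bounds[i]; e <- bounds[i + m + 1L]
      seqs <- c(seqs, substr(sequence, s + 1L, e))
      starts <- c(starts, s)
      mcs <- c(mcs, m)
    }
  }
  len <- nchar(seqs)
  keep <- len >= cfg$min_peptide_length & len <= cfg$max_peptide_length
  data.frame(sequence = seqs[keep], parent_id = parent_id,
             start = starts[keep], missed_cleavages = mcs[keep],
             stringsAsFactors = FALSE)
}

#' Deduplicate peptides across proteoforms
#'
#' Merges digestion output over parents: one row per distinct peptide
#' sequence, parent ids and per-parent offsets collected into list columns.
#' Rows are sorted lexicographically by sequence for deterministic output.
#'
#' @param peptides data.frame as returned by (row-bound) [digest()] calls.
#' @return data.frame with columns `sequence`, `parents` (list of character),
#'   `offsets` (list of integer, parallel to `parents`).
#' @export
dedup_peptides <- function(peptides) {
  if (nrow(peptides) == 0L)
    return(data.frame(sequence = character(0),
                      parents = I(list()), offsets = I(list())))
  sp <- split(peptides, peptides$sequence)
  seqs <- sort(names(sp))
  parents <- vector("list", length(seqs))
  offsets <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sub <- sp[[seqs[i]]]
    first <- !duplicated(sub$parent_id)
    ord <- order(sub$parent_id[first])
    parents[[i]] <- sub$parent_id[first][ord]
    offsets[[i]] <- as.integer(sub$start[first][ord])
  }
  data.frame(sequence = seqs, parents = I(parents), offsets = I(offsets),
             stringsAsFactors = FALSE)
}

#' Select noncanonical (AS) transcripts
#'
#' Keeps protein-coding transcripts whose in-silico translation is not
#' identical to any canonical sequence of the species. Transcripts without a
#' CDS (or whose translation is empty) are dropped with a logged count.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param cds_seqs named character vector of CDS nucleotide sequences, named
#'   by transcript id.
#' @param canonical data.frame of canonical proteoforms with at least a
#'   `sequence` column.
#' @return list with `transcripts` (retained models), `proteins` (named
#'   character of their translations) and `dropped` (counts by reason).
#' @export
select_noncanonical <- function(transcripts, cds_seqs, canonical) {
  canon_set <- unique(canonical$sequence)
  kept <- list(); prot <- character(0)
  dropped <- c(no_cds = 0L, empty_translation = 0L, redundant = 0L)
  for (t in transcripts) {
    if (is.na(t$cds_start) || !t$transcript_id %in% names(cds_seqs)) {
      dropped["no_cds"] <- dropped["no_cds"] + 1L
      next
    }
    tr <- translate_cds(cds_seqs[[t$transcript_id]])
    if (!nzchar(tr$aa)) {
      dropped["empty_translation"] <- dropped["empty_translation"] + 1L
      next
    }
    if (tr$aa %in% canon_set) {
      dropped["redundant"] <- dropped["redundant"] + 1L
      next
    }
    kept[[t$transcript_id]] <- t
    prot[[t$transcript_id]] <- tr$aa
  }
  if (sum(dropped) > 0L)
    message("select_noncanonical: dropped ", dropped[["no_cds"]],
            " without CDS, ", dropped[["empty_translation"]],
            " with empty translation, ", dropped[["redundant"]],
            " identical to a canonical sequence")
  list(transcripts = kept, proteins = prot, dropped = dropped)
}

#' Classify a transcript as an NMD candidate
#'
#' Applies the 50-nt rule: the transcript is flagged `nmd_candidate` when its
#' stop codon ends more than the configured threshold upstream of the last
#' exon-exon junction (transcript-relative). Single-exon transcripts are
#' never candidates. When `cds_seq` is supplied the first in-frame stop codon
#' is located from the sequence (so a premature stop inside the annotated ORF
#' is positioned correctly); otherwise the annotated `cds_end` is taken as
#' the stop end per the package's CDS convention. A coding sequence without
#' any stop codon yields `not_nmd` with a warning.
#'
#' @param t a [transcript_model()] with a CDS.
#' @param cfg an [nmd_config()].
#' @param cds_seq optional CDS nucleotide sequence of `t`.
#' @return `"nmd_candidate"` or `"not_nmd"`. When no stop codon is found the
#'   result carries attribute `no_stop = TRUE`.
#' @export
classify_nmd <- function(t, cfg = nmd_config(), cds_seq = NULL) {
  if (is.na(t$cds_start))
    stop("transcript '", t$transcript_id, "' has no CDS", call. = FALSE)
  stop_end <- t$cds_end
  if (!is.null(cds_seq)) {
    tr <- translate_cds(cds_seq)
    if (!tr$stop_found) {
      warning("no stop codon found in CDS of transcript '",
              t$transcript_id, "'", call. = FALSE)
      return(structure("not_nmd", no_stop = TRUE))
    }
    stop_end <- t$cds_start + 3L * nchar(tr$aa) + 3L
  }
  if (nrow(t$exons) < 2L) return("not_nmd")
  last_junction <- transcript_length(t) -
    (t$exons$end[nrow(t$exons)] - t$exons$start[nrow(t$exons)])
  if (last_junction - stop_end > cfg$junction_distance_threshold)
    "nmd_candidate" else "not_nmd"
}

# Concatenate sequences with a separator outside the amino-acid alphabet so
# substring containment can be tested against one blob.
canonical_blob <- function(seqs, collapse_IL = FALSE) {
  if (collapse_IL) seqs <- chartr("I", "L", seqs)
  paste(seqs, collapse = "|")
}

#' Retain peptides exclusive to noncanonical proteoforms
#'
#' Keeps exactly the peptides whose sequence is not a substring of any
#' canonical protein sequence (with I/L collapsed first when
#' `collapse_IL`). Input must be deduplicated (see [dedup_peptides()]);
#' output is sorted lexicographically by sequence.
#'
#' @param peptides data.frame from [dedup_peptides()].
#' @param canonical_seqs character vector of canonical protein sequences.
#' @param collapse_IL treat I and L as identical during the substring test.
#' @return the retained subset of `peptides`, sorted by sequence.
#' @export
filter_exclusive <- function(peptides, canonical_seqs, collapse_IL = FALSE) {
  if (nrow(peptides) == 0L) return(peptides)
  blob <- canonical_blob(canonical_seqs, collapse_IL)
  probe <- peptides$sequence
  if (collapse_IL) probe <- chartr("I", "L", probe)
  keep <- !vapply(probe, function(p) grepl(p, blob, fixed = TRUE),
                  logical(1L), USE.NAMES = FALSE)
  out <- peptides[keep, , drop = FALSE]
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a customized protein sequence database
#'
#' Combines canonical proteoforms with peptide entries exclusive to
#' noncanonical proteoforms. Exclusivity and pairwise distinctness are
#' re-verified here as defense in depth. Peptide entries receive stable ids
#' `pep_00001, ...` assigned in lexicographic sequence order.
#'
#' @param canonical data.frame of canonical proteoforms with columns
#'   `proteoform_id`, `gene_id`, `sequence`.
#' @param exclusive data.frame from [filter_exclusive()], optionally with a
#'   `genes` list column parallel to `parents`.
#' @param taxon integer NCBI taxon id of the species.
#' @param noncanonical_parents optional named character vector of the full
#'   noncanonical proteoform sequences (used by [is_proteotypic()]); kept in
#'   memory only, not serialized.
#' @return object of class `custom_db`.
#' @export
build_custom_db <- function(canonical, exclusive, taxon,
                            noncanonical_parents = NULL) {
  stopifnot(is.data.frame(canonical),
            all(c("proteoform_id", "sequence") %in% names(canonical)))
  if (!"gene_id" %in% names(canonical)) canonical$gene_id <- NA_character_
  if (nrow(exclusive) > 0L) {
    if (anyDuplicated(exclusive$sequence))
      stop("exclusive peptide sequences are not pairwise distinct",
           call. = FALSE)
    blob <- canonical_blob(canonical$sequence)
    bad <- vapply(exclusive$sequence, function(p) grepl(p, blob, fixed = TRUE),
                  logical(1L), USE.NAMES = FALSE)
    if (any(bad))
      stop("exclusivity violation: ",
           paste(utils::head(exclusive$sequence[bad], 3L), collapse = ", "),
           " occur in canonical sequences", call. = FALSE)
    exclusive <- exclusive[order(exclusive$sequence), , drop = FALSE]
    exclusive$entry_id <- sprintf("pep_%05d", seq_len(nrow(exclusive)))
    if (!"genes" %in% names(exclusive))
      exclusive$genes <- I(lapply(exclusive$parents,
                                  function(p) rep(NA_character_, length(p))))
  } else {
    exclusive <- data.frame(sequence = character(0), parents = I(list()),
                            offsets = I(list()), entry_id = character(0),
                            genes = I(list()))
  }
  rownames(exclusive) <- NULL
  canonical <- canonical[order(canonical$proteoform_id), , drop = FALSE]
  rownames(canonical) <- NULL
  structure(list(canonical = canonical, peptides = exclusive,
                 taxon = as.integer(taxon),
                 noncanonical_parents = noncanonical_parents),
            class = "custom_db")
}

#' @export
print.custom_db <- function(x, ...) {
  cat(sprintf("<custom_db> taxon %d: %d canonical entries + %d exclusive peptide entries\n",
              x$taxon, nrow(x$canonical), nrow(x$peptides)))
  invisible(x)
}

#' Number of entries in a custom database
#' @param db a `custom_db`.
#' @return integer: canonical entries + exclusive peptide entries.
#' @export
db_n_entries <- function(db) nrow(db$canonical) + nrow(db$peptides)

#' Write a custom database to FASTA
#'
#' Header grammar (stable, parsed back by [read_custom_db()]):
#' \preformatted{
#' can|<proteoform_id>|gene:<gene_id>|taxon:<taxon>
#' pep|<entry_id>|parents:<id,id>|genes:<g,g>|offsets:<o,o>|taxon:<taxon>
#' }
#' Missing gene ids are written as `-`. Output is deterministic for a fixed
#' database (entries in the stored sorted order, 60 chars/line).
#'
#' @param db a `custom_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_custom_db <- function(db, path) {
  dash <- function(x) ifelse(is.na(x) | !nzchar(x), "-", x)
  can_hdr <- sprintf("can|%s|gene:%s|taxon:%d",
                     db$canonical$proteoform_id, dash(db$canonical$gene_id),
                     db$taxon)
  pep_hdr <- character(0)
  if (nrow(db$peptides) > 0L)
    pep_hdr <- sprintf("pep|%s|parents:%s|genes:%s|offsets:%s|taxon:%d",
                       db$peptides$entry_id,
                       vapply(db$peptides$parents, paste, "", collapse = ","),
                       vapply(db$peptides$genes,
                              function(g) paste(dash(g), collapse = ","), ""),
                       vapply(db$peptides$offsets, paste, "", collapse = ","),
                       db$taxon)
  x <- c(setNames(db$canonical$sequence, can_hdr),
         setNames(db$peptides$sequence, pep_hdr))
  write_fasta(x, path)
}

#' Read a custom database written by [write_custom_db()]
#'
#' @param path path to the database FASTA.
#' @return object of class `custom_db` (without in-memory noncanonical
#'   parent sequences).
#' @export
read_custom_db <- function(path) {
  x <- load_fasta(path)
  hdr <- names(x)
  undash <- function(v) ifelse(v == "-", NA_character_, v)
  is_can <- startsWith(hdr, "can|")
  is_pep <- startsWith(hdr, "pep|")
  if (!all(is_can | is_pep))
    stop("unrecognized header(s) in custom database ", path, call. = FALSE)
  field <- function(h, key) sub(paste0(".*\\|", key, ":([^|]*).*"), "\\1", h)
  taxa <- as.integer(field(hdr, "taxon"))
  can <- data.frame(
    proteoform_id = sub("^can\\|([^|]+)\\|.*", "\\1", hdr[is_can]),
    gene_id = undash(field(hdr[is_can], "gene")),
    sequence = unname(x[is_can]), stringsAsFactors = FALSE)
  ph <- hdr[is_pep]
  pep <- data.frame(
    sequence = unname(x[is_pep]),
    parents = I(lapply(strsplit(field(ph, "parents"), ",", fixed = TRUE),
                       identity)),
    offsets = I(lapply(strsplit(field(ph, "offsets"), ",", fixed = TRUE),
                       as.integer)),
    entry_id = sub("^pep\\|([^|]+)\\|.*", "\\1", ph),
    genes = I(lapply(strsplit(field(ph, "genes"), ",", fixed = TRUE),
                     undash)),
    stringsAsFactors = FALSE)
  db <- structure(list(canonical = can, peptides = pep,
                       taxon = unique(taxa)[1L],
                       noncanonical_parents = NULL),
                  class = "custom_db")
  db
}

#' Parse a canonical proteome FASTA with UniProt-style headers
#'
#' Headers of the form `sp|ACCESSION|NAME ...` yield the accession as
#' proteoform id; any other header is used verbatim (first whitespace-free
#' token).
#'
#' @param path path to the canonical proteome FASTA.
#' @return data.frame of canonical proteoforms (`proteoform_id`, `gene_id`
#'   (`NA`, filled later via idmapping), `sequence`, `status`, `source`).
#' @export
load_canonical_proteome <- function(path) {
  x <- load_fasta(path)
  hdr <- sub("\\s.*$", "", names(x))
  acc <- ifelse(grepl("^(sp|tr)\\|", hdr),
                sub("^(sp|tr)\\|([^|]+)\\|.*$", "\\2", hdr), hdr)
  data.frame(proteoform_id = acc, gene_id = NA_character_,
             sequence = unname(x), status = "canonical",
             source = "canonical_fasta", stringsAsFactors = FALSE)
}

#' Build the customized database end-to-end for one species
#'
#' Runs the full database-construction pipeline: select noncanonical
#' transcripts (dropping those identical to a canonical sequence), remove
#' NMD candidates, digest the surviving proteoforms with trypsin, discard
#' peptides containing `X`, keep peptides exclusive to noncanonical
#' proteoforms, and assemble the custom database.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param cds_seqs named character vector of CDS nucleotide sequences.
#' @param canonical data.frame from [load_canonical_proteome()].
#' @param taxon integer NCBI taxon id.
#' @param digest_cfg a [digest_config()].
#' @param nmd_cfg an [nmd_config()].
#' @return list with `db` (the `custom_db`) and `report` (list of
#'   per-transcript and per-peptide decision data.frames, suitable for a
#'   TSV audit trail).
#' @export
build_splice_db <- function(transcripts, cds_seqs, canonical, taxon,
                            digest_cfg = digest_config(),
                            nmd_cfg = nmd_config()) {
  sel <- select_noncanonical(transcripts, cds_seqs, canonical)
  nmd <- vapply(sel$transcripts, function(t)
    classify_nmd(t, nmd_cfg, cds_seqs[[t$transcript_id]]), character(1L))
  keep_ids <- names(nmd)[nmd == "not_nmd"]
  gene_of <- vapply(sel$transcripts, function(t) t$gene_id, character(1L))

  digests <- lapply(keep_ids, function(id)
    digest(sel$proteins[[id]], id, digest_cfg))
  peps <- if (length(digests)) do.call(rbind, digests) else
    data.frame(sequence = character(0), parent_id = character(0),
               start = integer(0), missed_cleavages = integer(0))
  n_x <- sum(grepl("X", unique(peps$sequence), fixed = TRUE))
  peps <- peps[!grepl("X", peps$sequence, fixed = TRUE), , drop = FALSE]
  dd <- dedup_peptides(peps)
  excl <- filter_exclusive(dd, canonical$sequence, digest_cfg$collapse_IL)
  if (nrow(excl) > 0L)
    excl$genes <- I(lapply(excl$parents,
                           function(p) unname(gene_of[p])))
  db <- build_custom_db(canonical, excl, taxon,
                        noncanonical_parents = sel$proteins[keep_ids])

  tx_report <- data.frame(
    transcript_id = vapply(transcripts, `[[`, "", "transcript_id"),
    gene_id = vapply(transcripts, `[[`, "", "gene_id"),
    stringsAsFactors = FALSE)
  tx_report$selected <- tx_report$transcript_id %in% names(sel$transcripts)
  tx_report$nmd_flag <- nmd[match(tx_report$transcript_id, names(nmd))]
  tx_report$retained <- tx_report$transcript_id %in% keep_ids
  pep_report <- data.frame(sequence = dd$sequence,
                           exclusive = dd$sequence %in% excl$sequence,
                           stringsAsFactors = FALSE)
  message("build_splice_db: ", length(sel$transcripts),
          " noncanonical transcripts, ", sum(nmd == "nmd_candidate"),
          " NMD candidates removed, ", n_x, " X-containing peptides dropped, ",
          nrow(excl), " exclusive peptides retained")
  list(db = db, report = list(transcripts = tx_report, peptides = pep_report))
}
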