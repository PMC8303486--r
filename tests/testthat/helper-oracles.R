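# Brute-force oracles, written independently of the package implementation:
# the digest oracle enumerates boundary-position pairs and checks each
# candidate substring, rather than building fragments and concatenating runs.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = AAS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

oracle_digest <- function(seq, mc = 2L, minl = 1L, maxl = .Machine$integer.max,
                          proline = TRUE) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  cut <- which(ch[-n] %in% c("K", "R"))
  if (proline && length(cut)) cut <- cut[ch[cut + 1L] != "P"]
  bounds <- c(0L, cut, n)
  rows <- list()
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (j <= i) next
      if (j - i - 1L > mc) next
      len <- bounds[j] - bounds[i]
      if (len < minl || len > maxl) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seq, bounds[i] + 1L, bounds[j]),
        start = bounds[i], missed_cleavages = j - i - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), start = integer(0),
               missed_cleavages = integer(0))
  out <- out[order(out$start, out$missed_cleavages, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_exclusive <- function(peps, canonical) {
  keep <- vapply(peps, function(p) {
    !any(vapply(canonical, function(s) grepl(p, s, fixed = TRUE),
                logical(1L)))
  }, logical(1L), USE.NAMES = FALSE)
  sort(peps[keep])
}

oracle_intersections <- function(sets) {
  labels <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  sig_of <- vapply(universe, function(it)
    paste(labels[vapply(sets, function(s) it %in% s, logical(1L))],
          collapse = "&"), "")
  table(sig_of)
}

# run the database + orthomap pipeline over a generated fixture directory
fixture_species <- function(d, sp, taxon) {
  res <- suppressMessages(build_splice_db(
    load_gtf(file.path(d, sprintf("species_%s.gtf", sp))),
    load_fasta(file.path(d, sprintf("species_%s_cds.fasta", sp))),
    load_canonical_proteome(
      file.path(d, sprintf("species_%s_canonical.fasta", sp))), taxon))
  idmap <- load_id_mapping(
    file.path(d, sprintf("species_%s_idmapping.dat", sp)), taxon)
  ids <- do.call(rbind, lapply(c("CC", "OB"), function(g)
    read_identifications(
      file.path(d, sprintf("ids_species_%s_%s.tsv", sp, g)))))
  list(db = res$db, report = res$report,
       idx = index_identifications(ids, res$db, idmap))
}

fixture_pipeline_config <- function(d, out) {
  list(out_dir = out,
       species_a = list(
         taxon = 9606, gtf = file.path(d, "species_a.gtf"),
         cds_fasta = file.path(d, "species_a_cds.fasta"),
         canonical_fasta = file.path(d, "species_a_canonical.fasta"),
         idmapping = file.path(d, "species_a_idmapping.dat"),
         identifications = file.path(d, c("ids_species_a_CC.tsv",
                                          "ids_species_a_OB.tsv"))),
       species_b = list(
         taxon = 10090, gtf = file.path(d, "species_b.gtf"),
         cds_fasta = file.path(d, "species_b_cds.fasta"),
         canonical_fasta = file.path(d, "species_b_canonical.fasta"),
         idmapping = file.path(d, "species_b_idmapping.dat"),
         identifications = file.path(d, c("ids_species_b_CC.tsv",
                                          "ids_species_b_OB.tsv"))),
       orthologs = file.path(d, "gene_orthologs.txt"),
       quant = list(table = file.path(d, "itraq_quant.tsv"),
                    control = "117", case = "118"))
}
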