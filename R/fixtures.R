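#' Specification of a synthetic two-species fixture
#'
#' Defines the toy study conditions emulated by [generate_fixture()]: two
#' "species" with orthologous genes, a canonical transcript plus
#' alternatively spliced variants per gene (exon skip, alternative last
#' exon, mutually exclusive exons), a configurable fraction of NMD-target
#' variants, cross-species identical exclusive peptides planted in a
#' fraction of genes, and an iTRAQ table with planted log2 fold changes.
#'
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of `seed` and the spec.
#' @param n_genes number of genes per species (default 10).
#' @param n_as_per_gene AS variants per gene (default 1).
#' @param as_mix proportions of the three AS event types.
#' @param nmd_fraction fraction of AS variants built as NMD candidates
#'   (default 0.2).
#' @param orthology_fraction fraction of genes whose cross-species partner
#'   carries an identical exclusive peptide (default 0.5).
#' @param quant list: `n_diff_peptides` (20), `n_null_peptides` (60),
#'   `planted_log2fc` (1.0, applied sign-balanced), `noise_sd` (0.3),
#'   `n_spectra` (8 per peptide).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 10L, n_as_per_gene = 1L,
                         as_mix = c(exon_skip = 1/3,
                                    alternative_last_exon = 1/3,
                                    mutually_exclusive_exons = 1/3),
                         nmd_fraction = 0.2, orthology_fraction = 0.5,
                         quant = list(n_diff_peptides = 20L,
                                      n_null_peptides = 60L,
                                      planted_log2fc = 1.0,
                                      noise_sd = 0.3, n_spectra = 8L)) {
  stopifnot(n_genes >= 2, n_as_per_gene >= 1,
            all(as_mix >= 0), sum(as_mix) > 0,
            nmd_fraction >= 0, nmd_fraction <= 1,
            orthology_fraction >= 0, orthology_fraction <= 1,
            quant$n_diff_peptides >= 0, quant$noise_sd >= 0,
            quant$n_spectra >= 2)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_as_per_gene = as.integer(n_as_per_gene),
                 as_mix = as_mix / sum(as_mix),
                 nmd_fraction = nmd_fraction,
                 orthology_fraction = orthology_fraction, quant = quant),
            class = "fixture_spec")
}

# ---- independent straightforward re-derivation code (also used by audit) --

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codon-by-codon translation via a plain lookup loop
naive_translate <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  out <- character(0)
  i <- 1L
  stop_found <- FALSE
  while (i + 2L <= nchar(nt)) {
    codon <- substr(nt, i, i + 2L)
    aa <- if (grepl("N", codon, fixed = TRUE)) "X" else unname(gc[codon])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") { stop_found <- TRUE; break }
    out <- c(out, aa)
    i <- i + 3L
  }
  list(aa = paste(out, collapse = ""), stop_found = stop_found)
}

# enumerate tryptic peptides by scanning boundary positions directly
naive_digest_set <- function(seq, mc = 2L, minl = 6L, maxl = 45L) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  is_cut <- logical(n)
  for (i in seq_len(n - 1L))
    if (ch[i] %in% c("K", "R") && ch[i + 1L] != "P") is_cut[i] <- TRUE
  bounds <- c(0L, which(is_cut), n)
  peps <- character(0)
  for (bi in seq_along(bounds)) {
    for (bj in seq_along(bounds)) {
      if (bj <= bi) next
      internal <- bj - bi - 1L
      if (internal > mc) next
      len <- bounds[bj] - bounds[bi]
      if (len < minl || len > maxl) next
      peps <- c(peps, substr(seq, bounds[bi] + 1L, bounds[bj]))
    }
  }
  sort(unique(peps))
}

naive_exclusive <- function(peps, canonical_seqs) {
  keep <- logical(length(peps))
  for (i in seq_along(peps)) {
    found <- FALSE
    for (s in canonical_seqs)
      if (grepl(peps[i], s, fixed = TRUE)) { found <- TRUE; break }
    keep[i] <- !found
  }
  peps[keep]
}

random_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# deterministic one-codon-per-amino-acid back-translation
backtranslate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(split(names(gc), gc), `[`, "", 1L)
  paste(tab[strsplit(aa, "")[[1L]]], collapse = "")
}

# assemble a transcript_model laid out in a fresh genomic window
fixture_tx <- function(tid, gid, chrom, strand, exon_nts, cds_len, wstart) {
  lens <- nchar(exon_nts)
  n <- length(lens)
  offs <- cumsum(c(0L, utils::head(lens, -1L) + 100L))
  if (strand == "+") {
    starts <- wstart + offs
  } else {
    span <- sum(lens) + 100L * (n - 1L)
    starts <- wstart + span - offs - lens
  }
  exons <- data.frame(chrom = chrom, start = starts, end = starts + lens,
                      strand = strand, stringsAsFactors = FALSE)
  transcript_model(tid, gid, exons, cds_start = 0L, cds_end = cds_len)
}

#' Generate a seeded synthetic fixture with ground truth
#'
#' Writes to `out_dir`: a GTF and CDS FASTA per species, canonical proteome
#' FASTA per species, `gene_orthologs.txt`, idmapping tables, four
#' identification TSVs (two species x two tissue labels CC/OB), an iTRAQ
#' reporter table, a qPCR Ct table and `ground_truth.json`. Identical seed
#' and spec give byte-identical files.
#'
#' AS variants are built by editing the exon-block structure of the gene's
#' canonical protein, so each surviving variant carries at least one
#' junction-spanning or variant-exclusive tryptic peptide. Cross-species
#' identical peptides are planted via a shared mutually-exclusive-exon
#' cassette (K + 9-residue tag + R). NMD candidates place the stop codon 80
#' nt upstream of an extra 3'UTR exon junction. Ground-truth labels are
#' derived with independent straightforward code (plain codon-loop
#' translation, boundary-scan digestion, substring checks).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `ground_truth` and `files`.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  TAG_AA <- setdiff(AA20, c("K", "R", "P"))
  taxa <- c(a = 9606L, b = 10090L)
  ng <- spec$n_genes

  # event assignment and planting plan
  variants <- expand.grid(gene = seq_len(ng), v = seq_len(spec$n_as_per_gene))
  variants <- variants[order(variants$gene, variants$v), , drop = FALSE]
  variants$event <- sample(names(spec$as_mix), nrow(variants), replace = TRUE,
                           prob = spec$as_mix)
  n_orth <- round(spec$orthology_fraction * ng)
  orth_genes <- if (n_orth > 0) sort(sample(seq_len(ng), n_orth)) else integer(0)
  variants$planted <- variants$gene %in% orth_genes & variants$v == 1L
  variants$event[variants$planted] <- "mutually_exclusive_exons"
  n_nmd <- floor(spec$nmd_fraction * nrow(variants))
  free <- which(!variants$planted)
  if (n_nmd > length(free))
    stop("impossible spec: nmd_fraction requires ", n_nmd,
         " NMD variants but only ", length(free),
         " non-planted variants exist", call. = FALSE)
  variants$nmd <- FALSE
  if (n_nmd > 0)
    variants$nmd[sample(free, n_nmd)] <- TRUE
  tags <- setNames(vapply(seq_len(ng), function(i) random_aa(9L, TAG_AA), ""),
                   seq_len(ng))

  species <- list()
  for (sp in c("a", "b")) {
    SP <- toupper(sp)
    gene_ids <- as.character((if (sp == "a") 100000L else 200000L) +
                               seq_len(ng))
    accs <- sprintf("%s%05d", SP, seq_len(ng))
    blocks <- lapply(seq_len(ng), function(i) {
      b <- lapply(sample(15:25, 4L, replace = TRUE), random_aa)
      b[[1L]] <- paste0("M", substr(b[[1L]], 2L, nchar(b[[1L]])))
      b
    })
    txs <- list(); cds <- character(0); prot_canon <- character(0)
    var_protein <- character(0)
    for (i in seq_len(ng)) {
      chrom <- sprintf("chr%s_%d", sp, i)
      strand <- if (i %% 2L == 1L) "+" else "-"
      bl <- blocks[[i]]
      canon_aa <- paste(unlist(bl), collapse = "")
      prot_canon[accs[i]] <- canon_aa
      tid <- sprintf("TX%s%03d_C", SP, i)
      bl_nt <- vapply(bl, backtranslate, "")
      cds_len <- 3L * nchar(canon_aa) + 3L
      exon_nts <- bl_nt
      exon_nts[4L] <- paste0(exon_nts[4L], "TAA",
                             random_aa(30L, c("A", "C", "G", "T")))
      txs[[tid]] <- fixture_tx(tid, gene_ids[i], chrom, strand, exon_nts,
                               cds_len, 1000L)
      cds[tid] <- paste0(backtranslate(canon_aa), "TAA")
      vrows <- variants[variants$gene == i, , drop = FALSE]
      for (r in seq_len(nrow(vrows))) {
        v <- vrows$v[r]; ev <- vrows$event[r]
        vb <- bl
        if (ev == "exon_skip") {
          vb <- bl[-3L]
        } else if (ev == "alternative_last_exon") {
          vb[[4L]] <- random_aa(sample(15:25, 1L))
        } else {                       # mutually exclusive exons
          if (vrows$planted[r]) {
            flank1 <- random_aa(3L, TAG_AA)
            flank2 <- random_aa(3L, TAG_AA)
            vb[[3L]] <- paste0(flank1, "K", tags[[as.character(i)]], "R",
                               flank2)
          } else {
            vb[[3L]] <- random_aa(sample(15:25, 1L))
          }
        }
        var_aa <- paste(unlist(vb), collapse = "")
        vtid <- sprintf("TX%s%03d_V%d", SP, i, v)
        var_protein[vtid] <- var_aa
        vb_nt <- vapply(vb, backtranslate, "")
        vcds_len <- 3L * nchar(var_aa) + 3L
        if (vrows$nmd[r]) {
          ex <- vb_nt
          ex[length(ex)] <- paste0(ex[length(ex)], "TAA",
                                   random_aa(80L, c("A", "C", "G", "T")))
          ex <- c(ex, random_aa(60L, c("A", "C", "G", "T")))
        } else {
          ex <- vb_nt
          ex[length(ex)] <- paste0(ex[length(ex)], "TAA",
                                   random_aa(30L, c("A", "C", "G", "T")))
        }
        txs[[vtid]] <- fixture_tx(vtid, gene_ids[i], chrom, strand, ex,
                                  vcds_len, 1000L + v * 20000L)
        cds[vtid] <- paste0(backtranslate(var_aa), "TAA")
      }
    }
    species[[sp]] <- list(SP = SP, taxon = taxa[[sp]], gene_ids = gene_ids,
                          accs = accs, txs = txs, cds = cds,
                          canonical = prot_canon, var_protein = var_protein)
  }

  # ground-truth labels via the naive re-derivation code
  gt <- list(seed = spec$seed, taxa = unname(taxa))
  excl_by_species <- list()
  for (sp in c("a", "b")) {
    s <- species[[sp]]
    nmd_labels <- list()
    pep_parents <- list()
    for (i in seq_len(ng)) {
      vrows <- variants[variants$gene == i, , drop = FALSE]
      for (r in seq_len(nrow(vrows))) {
        vtid <- sprintf("TX%s%03d_V%d", s$SP, i, vrows$v[r])
        nmd_labels[[vtid]] <- if (vrows$nmd[r]) "nmd_candidate" else "not_nmd"
        if (vrows$nmd[r]) next
        peps <- naive_digest_set(s$var_protein[[vtid]])
        peps <- naive_exclusive(peps, s$canonical)
        for (p in peps)
          pep_parents[[p]] <- sort(unique(c(pep_parents[[p]], vtid)))
      }
    }
    excl_by_species[[sp]] <- pep_parents
    gt$nmd_labels[[paste0("species_", sp)]] <- nmd_labels
    gt$exclusive_peptides[[paste0("species_", sp)]] <-
      pep_parents[sort(names(pep_parents))]
  }
  gt$ortholog_pairs <- lapply(seq_len(ng), function(i)
    c(species$a$gene_ids[i], species$b$gene_ids[i]))
  gt$planted_identical_peptides <- lapply(orth_genes, function(i) {
    list(peptide = paste0(tags[[as.character(i)]], "R"),
         gene_a = species$a$gene_ids[i], gene_b = species$b$gene_ids[i],
         transcript_a = sprintf("TXA%03d_V1", i),
         transcript_b = sprintf("TXB%03d_V1", i))
  })

  # ---- files -------------------------------------------------------------
  files <- c()
  wf <- function(name) { p <- file.path(out_dir, name); files <<- c(files, p); p }
  for (sp in c("a", "b")) {
    s <- species[[sp]]
    write_gtf(s$txs, wf(sprintf("species_%s.gtf", sp)))
    write_fasta(s$cds, wf(sprintf("species_%s_cds.fasta", sp)))
    hdr <- sprintf("sp|%s|PROT%d_%s", s$accs, seq_len(ng), s$SP)
    write_fasta(setNames(unname(s$canonical), hdr),
                wf(sprintf("species_%s_canonical.fasta", sp)))
    idm <- rbind(
      data.frame(a = s$accs, b = "GeneID", c = s$gene_ids),
      data.frame(a = s$accs, b = "Ensembl",
                 c = sprintf("TX%s%03d_C", s$SP, seq_len(ng))))
    write.table(idm[order(idm$a, idm$b), ],
                wf(sprintf("species_%s_idmapping.dat", sp)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  orth_lines <- c("#tax_id\tGeneID\trelationship\tOther_tax_id\tOther_GeneID",
                  sprintf("%d\t%s\tOrtholog\t%d\t%s", taxa[["a"]],
                          species$a$gene_ids, taxa[["b"]],
                          species$b$gene_ids),
                  sprintf("%d\t%s\tRegion member\t%d\t%s", taxa[["a"]],
                          species$a$gene_ids[1L], taxa[["b"]], "999999"))
  writeLines(orth_lines, wf("gene_orthologs.txt"))

  # identification tables: canonical reference peptides + exclusive peptides
  for (sp in c("a", "b")) {
    s <- species[[sp]]
    excl <- sort(names(excl_by_species[[sp]]))
    entry_ids <- setNames(sprintf("pep_%05d", seq_along(excl)), excl)
    canon_rows <- list()
    for (i in seq_len(ng)) {
      frags <- naive_digest_set(s$canonical[[i]], mc = 0L)
      if (length(frags) == 0L) next
      canon_rows[[i]] <- data.frame(peptide = frags[1L],
                                    db_entry_id = s$accs[i],
                                    stringsAsFactors = FALSE)
    }
    base <- rbind(do.call(rbind, canon_rows),
                  data.frame(peptide = excl, db_entry_id = entry_ids[excl],
                             stringsAsFactors = FALSE))
    for (grp in c("CC", "OB")) {
      tab <- base
      tab$sample_group <- grp
      tab$spectral_count <- 1L + rpois(nrow(tab), 3)
      write.table(tab, wf(sprintf("ids_species_%s_%s.tsv", sp, grp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # iTRAQ quant table with planted sign-balanced log2 fold changes
  q <- spec$quant
  n_null <- if (is.null(q$n_null_peptides)) 3L * q$n_diff_peptides else
    q$n_null_peptides
  qpeps <- vapply(seq_len(q$n_diff_peptides + n_null), function(i)
    paste0(random_aa(11L, setdiff(AA20, c("K", "R", "P"))), "K"), "")
  lfc <- c(rep(c(1, -1), length.out = q$n_diff_peptides) * q$planted_log2fc,
           rep(0, n_null))
  qrows <- list()
  for (i in seq_along(qpeps)) {
    ctrl <- rlnorm(q$n_spectra, log(1e4), 0.5)
    lr <- rnorm(q$n_spectra, lfc[i], q$noise_sd)
    qrows[[i]] <- data.frame(
      spectrum_id = sprintf("sp%05d_%02d", i, seq_len(q$n_spectra)),
      peptide = qpeps[i], `117` = round(ctrl, 4),
      `118` = round(ctrl * 2^lr, 4), check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, qrows), wf("itraq_quant.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt$quant_truth <- as.list(setNames(lfc, qpeps))

  # qPCR Ct table (Hprt1 reference, whole-brain calibrator, CC vs OB shift)
  samples <- c("whole_brain", paste0("CC_", 1:3), paste0("OB_", 1:3))
  groups <- c("calibrator", rep("CC", 3L), rep("OB", 3L))
  ct_rows <- list()
  target_base <- c(AS1 = 24, AS2 = 22.5)
  ob_shift <- c(AS1 = -2, AS2 = 1.5)
  for (k in seq_along(samples)) {
    ct_rows[[length(ct_rows) + 1L]] <- data.frame(
      sample_id = samples[k], group = groups[k], gene = "Hprt1",
      ct = round(20 + rnorm(1L, 0, 0.1), 3), stringsAsFactors = FALSE)
    for (g in names(target_base)) {
      mu <- target_base[[g]] + if (groups[k] == "OB") ob_shift[[g]] else 0
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample_id = samples[k], group = groups[k], gene = g,
        ct = round(mu + rnorm(1L, 0, 0.15), 3), stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, ct_rows), wf("ct_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  gt$counts <- list(
    n_genes = ng, n_variants = nrow(variants), n_nmd = n_nmd,
    n_planted_identical = length(orth_genes),
    n_exclusive_a = length(excl_by_species$a),
    n_exclusive_b = length(excl_by_species$b))
  jsonlite::write_json(gt, wf("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(ground_truth = gt, files = files))
}

#' Audit a generated fixture against its ground truth
#'
#' Re-derives every label with independent straightforward code (plain
#' codon-loop translation, boundary-scan tryptic digestion, brute-force
#' substring exclusivity) and confirms the fixture's `ground_truth.json`:
#' canonical CDS translations match the canonical proteome, recomputed NMD
#' flags match, per-variant exclusive peptide sets match, and every planted
#' identical peptide is exclusive in both species on an ortholog pair. Any
#' mismatch raises an error naming the affected transcript or peptide.
#'
#' @param dir fixture directory written by [generate_fixture()].
#' @return invisibly, a list of per-check counts (all checks passed).
#' @export
audit_fixture <- function(dir) {
  need <- c("species_a.gtf", "species_b.gtf", "species_a_cds.fasta",
            "species_b_cds.fasta", "species_a_canonical.fasta",
            "species_b_canonical.fasta", "gene_orthologs.txt",
            "species_a_idmapping.dat", "species_b_idmapping.dat",
            "ids_species_a_CC.tsv", "ids_species_a_OB.tsv",
            "ids_species_b_CC.tsv", "ids_species_b_OB.tsv",
            "itraq_quant.tsv", "ct_table.tsv", "ground_truth.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("fixture audit: missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = FALSE)
  checks <- c(canonical = 0L, nmd = 0L, exclusive = 0L, planted = 0L)
  for (sp in c("a", "b")) {
    txs <- load_gtf(file.path(dir, sprintf("species_%s.gtf", sp)))
    cds <- load_fasta(file.path(dir, sprintf("species_%s_cds.fasta", sp)))
    canon <- load_canonical_proteome(
      file.path(dir, sprintf("species_%s_canonical.fasta", sp)))
    # canonical transcripts must translate to their proteome entry
    can_tids <- grep("_C$", names(txs), value = TRUE)
    for (tid in can_tids) {
      tr <- naive_translate(cds[[tid]])
      idx <- as.integer(sub("^TX[AB](\\d+)_C$", "\\1", tid))
      expect <- canon$sequence[idx]
      if (!identical(tr$aa, expect) || !tr$stop_found)
        stop("fixture audit: canonical CDS of transcript '", tid,
             "' does not translate to its proteome entry", call. = FALSE)
      checks["canonical"] <- checks["canonical"] + 1L
    }
    # NMD labels from the 50-nt rule applied to structure + naive stop
    gt_nmd <- gt$nmd_labels[[paste0("species_", sp)]]
    for (tid in names(gt_nmd)) {
      t <- txs[[tid]]
      tr <- naive_translate(cds[[tid]])
      stop_end <- 3L * nchar(tr$aa) + 3L
      last_ex <- t$exons$end[nrow(t$exons)] - t$exons$start[nrow(t$exons)]
      dist <- (transcript_length(t) - last_ex) - stop_end
      lab <- if (nrow(t$exons) >= 2L && dist > 50L) "nmd_candidate" else
        "not_nmd"
      if (!identical(lab, gt_nmd[[tid]]))
        stop("fixture audit: NMD label mismatch for transcript '", tid, "'",
             call. = FALSE)
      checks["nmd"] <- checks["nmd"] + 1L
    }
    # exclusive peptide sets per surviving variant
    gt_excl <- gt$exclusive_peptides[[paste0("species_", sp)]]
    derived <- list()
    for (tid in names(gt_nmd)) {
      if (gt_nmd[[tid]] == "nmd_candidate") next
      tr <- naive_translate(cds[[tid]])
      peps <- naive_exclusive(naive_digest_set(tr$aa), canon$sequence)
      for (p in peps)
        derived[[p]] <- sort(unique(c(derived[[p]], tid)))
    }
    gt_map <- lapply(gt_excl, function(v) sort(unlist(v)))
    if (!setequal(names(derived), names(gt_map))) {
      bad <- c(setdiff(names(derived), names(gt_map)),
               setdiff(names(gt_map), names(derived)))
      parents <- sort(unique(unlist(c(derived[bad], gt_map[bad]))))
      stop("fixture audit: exclusive peptide set mismatch in species_", sp,
           " affecting transcript(s) ", paste(parents, collapse = ", "),
           call. = FALSE)
    }
    for (p in names(derived)) {
      if (!identical(derived[[p]], gt_map[[p]]))
        stop("fixture audit: parent mismatch for peptide '", p,
             "' (transcripts ",
             paste(union(derived[[p]], gt_map[[p]]), collapse = ", "), ")",
             call. = FALSE)
      checks["exclusive"] <- checks["exclusive"] + 1L
    }
  }
  # planted identical peptides sit on ortholog pairs, exclusive in both
  pairs <- vapply(gt$ortholog_pairs, function(p)
    paste(p[[1L]], p[[2L]], sep = "\r"), "")
  for (pl in gt$planted_identical_peptides) {
    ok <- pl$peptide %in% names(gt$exclusive_peptides$species_a) &&
      pl$peptide %in% names(gt$exclusive_peptides$species_b) &&
      paste(pl$gene_a, pl$gene_b, sep = "\r") %in% pairs
    if (!ok)
      stop("fixture audit: planted peptide '", pl$peptide,
           "' not exclusive on an ortholog pair", call. = FALSE)
    checks["planted"] <- checks["planted"] + 1L
  }
  message("fixture audit passed: ", paste(names(checks), checks,
                                          sep = "=", collapse = ", "))
  invisible(as.list(checks))
}
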