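test_that("translation follows the standard code and halts at stops", {
  expect_equal(translate_cds("ATGAAATAA"), list(aa = "MK", stop_found = TRUE))
  expect_equal(translate_cds("ATGTGA"), list(aa = "M", stop_found = TRUE))
  expect_equal(translate_cds("ATGAAA"), list(aa = "MK", stop_found = FALSE))
  expect_equal(translate_cds("ATGANATAA")$aa, "MX")  # N codon -> X
  expect_error(translate_cds("AT"), "shorter")
})

test_that("tryptic digestion honors the proline rule and missed cleavages", {
  cfg0 <- digest_config(max_missed_cleavages = 0, min_peptide_length = 1)
  expect_setequal(digest("MKAAARPK", "p", cfg0)$sequence, c("MK", "AAARPK"))
  expect_equal(digest("AAAA", "p", cfg0)$sequence, "AAAA")
  cfg1 <- digest_config(max_missed_cleavages = 1, min_peptide_length = 1)
  expect_setequal(digest("MKAAARPK", "p", cfg1)$sequence,
                  c("MK", "AAARPK", "MKAAARPK"))
  # offsets locate every peptide inside its parent
  d <- digest("MKAAARPKLLK", "p", cfg1)
  expect_true(all(substring("MKAAARPKLLK", d$start + 1L,
                            d$start + nchar(d$sequence)) == d$sequence))
})

test_that("0-missed-cleavage fragments reconstruct the protein", {
  set.seed(21)
  cfg <- digest_config(max_missed_cleavages = 0, min_peptide_length = 1,
                       max_peptide_length = 10000)
  for (i in 1:20) {
    p <- random_protein(sample(10:120, 1))
    d <- digest(p, "x", cfg)
    expect_equal(paste(d$sequence[order(d$start)], collapse = ""), p)
  }
})

test_that("emitted peptide count follows sum_m max(0, f - m)", {
  set.seed(22)
  for (i in 1:20) {
    p <- random_protein(sample(20:150, 1))
    M <- sample(0:4, 1)
    cfg <- digest_config(max_missed_cleavages = M, min_peptide_length = 1,
                         max_peptide_length = 10000)
    d <- digest(p, "x", cfg)
    f <- sum(d$missed_cleavages == 0)
    expect_equal(nrow(d), sum(pmax(0L, f - 0:M)))
  }
})

test_that("digest agrees with the boundary-pair brute-force oracle", {
  set.seed(23)
  for (i in 1:150) {
    p <- random_protein(sample(5:200, 1))
    M <- sample(0:3, 1)
    got <- digest(p, "x", digest_config(max_missed_cleavages = M,
                                        min_peptide_length = 1,
                                        max_peptide_length = 10000))
    got <- got[order(got$start, got$missed_cleavages, got$sequence),
               c("sequence", "start", "missed_cleavages")]
    rownames(got) <- NULL
    expect_equal(got, oracle_digest(p, M))
  }
})

test_that("the NMD rule flags stops far upstream of the last junction", {
  two_exon <- function(len1, len2, cds_end) {
    transcript_model("t", "g", data.frame(
      chrom = "c", start = c(0L, len1 + 100L),
      end = c(len1, len1 + 100L + len2), strand = "+"),
      cds_start = 0L, cds_end = cds_end)
  }
  single <- transcript_model("s", "g",
                             data.frame(chrom = "c", start = 0L, end = 300L,
                                        strand = "+"),
                             cds_start = 0L, cds_end = 150L)
  expect_equal(classify_nmd(single), "not_nmd")
  # stop ends 100 nt upstream of the junction (junction at 300)
  expect_equal(classify_nmd(two_exon(300L, 60L, 200L)), "nmd_candidate")
  # 10 nt upstream: within the 50-nt threshold
  expect_equal(classify_nmd(two_exon(300L, 60L, 290L)), "not_nmd")
  expect_error(classify_nmd(transcript_model("t", "g", data.frame(
    chrom = "c", start = 0L, end = 30L, strand = "+"))), "no CDS")
})

test_that("NMD classification is monotone in the stop position", {
  two_exon <- function(cds_end) transcript_model("t", "g", data.frame(
    chrom = "c", start = c(0L, 400L), end = c(300L, 520L), strand = "+"),
    cds_start = 0L, cds_end = cds_end)
  flags <- vapply(10:299, function(e) classify_nmd(two_exon(e)),
                  character(1L))
  # moving the stop codon closer to the junction never flips not_nmd -> nmd
  runs <- rle(flags)$values
  expect_equal(runs, c("nmd_candidate", "not_nmd"))
})

test_that("a CDS without a stop codon yields not_nmd with a warning", {
  t <- transcript_model("t", "g", data.frame(
    chrom = "c", start = c(0L, 400L), end = c(300L, 520L), strand = "+"),
    cds_start = 0L, cds_end = 60L)
  expect_warning(flag <- classify_nmd(t, cds_seq = "ATGAAAAAAAAA"),
                 "no stop codon")
  expect_equal(as.character(flag), "not_nmd")
})

test_that("exclusivity filtering is substring containment vs canonicals", {
  peps <- data.frame(sequence = c("AAARPK", "QQQQQK"),
                     stringsAsFactors = FALSE)
  out <- filter_exclusive(peps, "MKAAARPK")
  expect_equal(out$sequence, "QQQQQK")
  # I/L collapse: ALK occurs in AIKR once I==L
  peps2 <- data.frame(sequence = "ALK", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_exclusive(peps2, "AIKR", collapse_IL = TRUE)), 0L)
  expect_equal(nrow(filter_exclusive(peps2, "AIKR", collapse_IL = FALSE)), 1L)
})

test_that("exclusivity agrees with the brute-force oracle on random sets", {
  set.seed(24)
  for (i in 1:100) {
    canon <- vapply(seq_len(sample(2:5, 1)),
                    function(j) random_protein(sample(30:60, 1)), "")
    inside <- unlist(lapply(canon, function(s) {
      a <- sample(nchar(s) - 6L, 2L)
      substr(rep(s, 2L), a, a + sample(4:6, 2L, TRUE))
    }))
    outside <- vapply(1:8, function(j) random_protein(sample(6:12, 1)), "")
    peps <- unique(c(inside, outside))
    got <- filter_exclusive(data.frame(sequence = peps), canon)$sequence
    expect_equal(got, oracle_exclusive(peps, canon))
  }
})

test_that("custom database assembly enforces invariants and round-trips", {
  canon <- data.frame(proteoform_id = c("P1", "P2", "P3"),
                      gene_id = c("10", "11", NA),
                      sequence = c("MKAAARPK", "MDDDDK", "MEEEEK"),
                      stringsAsFactors = FALSE)
  excl <- dedup_peptides(rbind(digest("MQQQQKWWWWR", "tx1",
                                      digest_config(min_peptide_length = 5))))
  excl <- filter_exclusive(excl, canon$sequence)
  db <- build_custom_db(canon, excl, 9606)
  expect_equal(db_n_entries(db), 3L + nrow(excl))

  # defense in depth: planting a canonical substring must be rejected
  bad <- rbind(excl[, c("sequence", "parents", "offsets")],
               data.frame(sequence = "AAARPK", parents = I(list("tx9")),
                          offsets = I(list(0L))))
  expect_error(build_custom_db(canon, bad, 9606), "exclusivity")
  expect_error(build_custom_db(canon, rbind(excl, excl), 9606), "distinct")

  f <- withr::local_tempfile(fileext = ".fasta")
  write_custom_db(db, f)
  back <- read_custom_db(f)
  expect_equal(back$canonical, db$canonical)
  expect_equal(back$peptides$sequence, db$peptides$sequence)
  expect_equal(back$peptides$entry_id, db$peptides$entry_id)
  expect_equal(back$peptides$parents, db$peptides$parents)
  expect_equal(back$peptides$offsets, db$peptides$offsets)
  expect_equal(back$taxon, db$taxon)
  # byte-deterministic output
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_custom_db(db, f2)
  expect_equal(readLines(f), readLines(f2))
  # empty exclusive set: database is the canonical input alone
  db0 <- build_custom_db(canon, excl[0, ], 9606)
  expect_equal(db_n_entries(db0), 3L)
})

test_that("noncanonical selection drops redundant and CDS-less transcripts", {
  mk <- function(id, len) transcript_model(id, "g", data.frame(
    chrom = "c", start = 0L, end = len, strand = "+"),
    cds_start = 0L, cds_end = len)
  canon <- data.frame(sequence = "MK", stringsAsFactors = FALSE)
  txs <- list(mk("same", 9L), mk("diff", 9L),
              transcript_model("nocds", "g", data.frame(
                chrom = "c", start = 0L, end = 9L, strand = "+")))
  cds <- c(same = "ATGAAATAA", diff = "ATGCCCTAA")
  expect_message(sel <- select_noncanonical(txs, cds, canon), "dropped 1")
  expect_equal(names(sel$transcripts), "diff")
  expect_equal(unname(sel$proteins["diff"]), "MP")
})

test_that("build_splice_db recovers exactly the planted exclusive peptides", {
  d <- withr::local_tempdir()
  gt <- generate_fixture(fixture_spec(seed = 33), d)$ground_truth
  for (sp in c("a", "b")) {
    res <- suppressMessages(build_splice_db(
      load_gtf(file.path(d, sprintf("species_%s.gtf", sp))),
      load_fasta(file.path(d, sprintf("species_%s_cds.fasta", sp))),
      load_canonical_proteome(
        file.path(d, sprintf("species_%s_canonical.fasta", sp))),
      if (sp == "a") 9606 else 10090))
    truth <- gt$exclusive_peptides[[paste0("species_", sp)]]
    expect_setequal(res$db$peptides$sequence, names(truth))
    got_parents <- lapply(res$db$peptides$parents, sort)
    names(got_parents) <- res$db$peptides$sequence
    expect_equal(got_parents[names(truth)],
                 lapply(truth, function(v) sort(unlist(v))))
    # NMD flags match the generator's labels
    flags <- res$report$transcripts
    truth_nmd <- gt$nmd_labels[[paste0("species_", sp)]]
    expect_equal(unname(flags$nmd_flag[match(names(truth_nmd),
                                             flags$transcript_id)]),
                 unname(unlist(truth_nmd)))
  }
})
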