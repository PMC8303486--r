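test_that("reporter extraction respects the ppm window and threshold", {
  cfg <- quant_config()
  c117 <- 117.1144
  peaks <- data.frame(mz = c(c117 * (1 + 50e-6), 200),
                      intensity = c(500, 1000))
  r <- extract_reporters(peaks, cfg)
  expect_equal(unname(r["117"]), 500)         # inside 100 ppm
  peaks2 <- data.frame(mz = c(c117 * (1 + 200e-6), 200),
                       intensity = c(500, 1000))
  expect_equal(unname(extract_reporters(peaks2, cfg)["117"]), 0)
  # below 2.5% of the base peak -> zeroed
  peaks3 <- data.frame(mz = c(c117, 200), intensity = c(10, 1000))
  expect_equal(unname(extract_reporters(peaks3, cfg)["117"]), 0)
  peaks4 <- data.frame(mz = c(c117, 200), intensity = c(30, 1000))
  expect_equal(unname(extract_reporters(peaks4, cfg)["117"]), 30)
  # overlapping windows are a configuration error
  bad <- quant_config(reporter_channels = data.frame(
    label = c("x", "y"), mz = c(100.000, 100.001)))
  expect_error(extract_reporters(peaks, bad), "overlap")
})

test_that("channel normalization equalizes totals and is self-adjusting", {
  rec <- data.frame(spectrum_id = c("s1", "s2"), peptide = "P",
                    `117` = c(150, 50), `118` = c(60, 40),
                    check.names = FALSE)
  out <- normalize_channels(rec)
  expect_equal(sum(out$`117`), sum(out$`118`), tolerance = 1e-12)
  expect_equal(sum(out$`117`), 150)           # grand mean of 200 and 100
  expect_equal(out$`118`, c(60, 40) * 1.5)
  # already equal -> identity
  rec2 <- data.frame(spectrum_id = "s", peptide = "P",
                     `117` = 100, `118` = 100, check.names = FALSE)
  expect_equal(normalize_channels(rec2), rec2)
  # self-adjusting: multiplying one channel's raw data by a constant leaves
  # the normalized cross-channel ratios (all that feeds the ratio test)
  # unchanged
  rec3 <- rec; rec3$`118` <- rec3$`118` * 7
  out3 <- normalize_channels(rec3)
  expect_equal(out3$`118` / out3$`117`, out$`118` / out$`117`,
               tolerance = 1e-12)
  expect_equal(peptide_ratio_test(out3)$p_value,
               peptide_ratio_test(out)$p_value, tolerance = 1e-12)
  rec4 <- rec; rec4$`118` <- 0
  expect_error(normalize_channels(rec4), "118")
})

test_that("the paired log2-ratio test reproduces the worked example", {
  # log2 ratios exactly [1.0, 1.2, 0.8]
  rec <- data.frame(spectrum_id = paste0("s", 1:3), peptide = "PEP",
                    `117` = c(100, 100, 100),
                    `118` = 100 * 2^c(1.0, 1.2, 0.8), check.names = FALSE)
  r <- peptide_ratio_test(rec)
  expect_equal(r$mean_log2_ratio, 1.0, tolerance = 1e-10)
  expect_equal(r$sd, 0.2, tolerance = 1e-10)
  expect_equal(r$sem, 0.2 / sqrt(3), tolerance = 1e-6)
  expect_equal(r$t_statistic, 8.6603, tolerance = 1e-4)
  expect_equal(r$degrees_of_freedom, 2L)
  expect_equal(r$p_value, 0.013072, tolerance = 1e-4)
  expect_false(r$degenerate)
})

test_that("ratio test matches the reference t implementation", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    lr <- rnorm(n, sample(c(0, 0.5, 1), 1), runif(1, 0.1, 1))
    rec <- data.frame(spectrum_id = seq_len(n), peptide = "P",
                      `117` = rep(1000, n), `118` = 1000 * 2^lr,
                      check.names = FALSE)
    r <- peptide_ratio_test(rec)
    ref <- t.test(lr, mu = 0)
    expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(r$mean_log2_ratio, unname(ref$estimate), tolerance = 1e-8)
  }
})

test_that("ratio test conventions: degenerate cases and antisymmetry", {
  rec0 <- data.frame(spectrum_id = 1:3, peptide = "P",
                     `117` = c(10, 20, 30), `118` = c(10, 20, 30),
                     check.names = FALSE)
  r0 <- peptide_ratio_test(rec0)           # log2 ratios all zero
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
  rec1 <- rec0; rec1$`118` <- rec1$`117` * 2
  r1 <- peptide_ratio_test(rec1)           # zero variance, nonzero mean
  expect_true(r1$degenerate)
  expect_equal(r1$p_value, 0)
  # swapping case and control negates the mean, |t| and p unchanged
  set.seed(52)
  rec <- data.frame(spectrum_id = 1:6, peptide = "P",
                    `117` = rlnorm(6, 7), `118` = rlnorm(6, 7),
                    check.names = FALSE)
  fwd <- peptide_ratio_test(rec, quant_config(control_label = "117",
                                              case_label = "118"))
  rev <- peptide_ratio_test(rec, quant_config(control_label = "118",
                                              case_label = "117"))
  expect_equal(rev$mean_log2_ratio, -fwd$mean_log2_ratio)
  expect_equal(abs(rev$t_statistic), abs(fwd$t_statistic))
  expect_equal(rev$p_value, fwd$p_value)
  # spectra with a zero channel are dropped and counted
  recz <- rbind(rec, data.frame(spectrum_id = 7, peptide = "P",
                                `117` = 0, `118` = 5, check.names = FALSE))
  rz <- peptide_ratio_test(recz)
  expect_equal(rz$n_spectra, 6L)
  expect_equal(rz$n_dropped, 1L)
  expect_error(peptide_ratio_test(
    data.frame(spectrum_id = 1, peptide = "P", `117` = 0, `118` = 1,
               check.names = FALSE)), "no usable spectra")
})

test_that("TPM normalizes rates to one million", {
  one <- compute_tpm(data.frame(transcript_id = "t", count = 5,
                                effective_length = 1234))
  expect_equal(one$tpm, 1e6)
  two <- compute_tpm(data.frame(transcript_id = c("t1", "t2"),
                                count = c(10, 10),
                                effective_length = c(1000, 2000)))
  expect_equal(two$tpm, c(666666.67, 333333.33), tolerance = 1e-6)
  zero <- compute_tpm(data.frame(transcript_id = c("t1", "t2"),
                                 count = c(0, 0),
                                 effective_length = c(1000, 2000)))
  expect_equal(zero$tpm, c(0, 0))
  expect_error(compute_tpm(data.frame(transcript_id = "t", count = 1,
                                      effective_length = 0)), "positive")
  set.seed(53)
  r <- compute_tpm(data.frame(transcript_id = paste0("t", 1:50),
                              count = rpois(50, 100),
                              effective_length = runif(50, 200, 5000)))
  expect_equal(sum(r$tpm), 1e6, tolerance = 1e-6)
})

test_that("2^-ddCt gives rq = 1 for the calibrator and halves per cycle", {
  ct <- data.frame(
    sample_id = rep(c("cal", "s1", "s2"), each = 2),
    group = rep(c("calibrator", "CC", "OB"), each = 2),
    gene = rep(c("Hprt1", "tgt"), 3),
    ct = c(20, 27, 20, 28, 20, 25))
  r <- ddct(ct, "Hprt1", "cal")
  expect_equal(r$rq[r$sample_id == "cal"], 1)          # ddCt = 0
  expect_equal(r$rq[r$sample_id == "s1"], 0.5)         # ddCt = 1
  expect_equal(r$rq[r$sample_id == "s2"], 4)           # dCt 5 vs 7 -> -2
  # missing reference Ct errors per sample
  expect_error(ddct(ct[ct$gene != "Hprt1" | ct$sample_id != "s1", ],
                    "Hprt1", "cal"), "s1")
  # a shared dCt shift leaves between-group rq ratios unchanged
  ct2 <- ct; ct2$ct[ct2$gene == "tgt"] <- ct2$ct[ct2$gene == "tgt"] + 3
  r2 <- ddct(ct2, "Hprt1", "cal")
  expect_equal(r2$rq[r2$sample_id == "s2"] / r2$rq[r2$sample_id == "s1"],
               r$rq[r$sample_id == "s2"] / r$rq[r$sample_id == "s1"])
})

test_that("two-sample comparison behaves like a Welch t-test", {
  expect_equal(group_difference_test(c(1, 1, 1), c(1, 1, 1)),
               list(t = 0, df = 4L, p = 1))
  set.seed(54)
  a <- c(1, 1, 1) + rnorm(3, 0, 1e-6)
  b <- c(2, 2, 2) + rnorm(3, 0, 1e-6)
  r <- group_difference_test(a, b)
  expect_lt(r$p, 0.05)
  rr <- group_difference_test(b, a)
  expect_equal(rr$t, -r$t)
  expect_equal(rr$p, r$p)
  expect_error(group_difference_test(1, c(1, 2)), "at least 2")
  # agrees with stats::t.test on random draws
  x <- rnorm(8); y <- rnorm(9, 0.5)
  ref <- t.test(x, y)
  got <- group_difference_test(x, y)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, unname(ref$p.value))
})

test_that("whole-table ratio testing is deterministic and sorted", {
  d <- withr::local_tempdir()
  gt <- generate_fixture(fixture_spec(seed = 9), d)$ground_truth
  tab <- read_quant_table(file.path(d, "itraq_quant.tsv"))
  # the fixture's channels are already on a common scale, so the planted
  # effects are assessed without the data-driven normalization offset
  res <- test_peptide_ratios(tab, normalize = FALSE)
  expect_equal(res$peptide, sort(unique(tab$peptide)))
  truth <- unlist(gt$quant_truth)
  planted <- names(truth)[truth != 0]
  # planted effects recovered within 3 SEM for nearly all peptides
  dev <- abs(res$mean_log2_ratio[match(planted, res$peptide)] -
               truth[planted])
  cover <- dev <= 3 * res$sem[match(planted, res$peptide)]
  expect_gte(mean(cover), 0.95)
  res_bh <- test_peptide_ratios(tab, adjust = "BH")
  expect_true("p_adjusted" %in% names(res_bh))
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value - 1e-12))
})
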