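#' Default iTRAQ 8-plex reporter channels
#'
#' Reporter-ion m/z values of the iTRAQ 8-plex labels, overridable in
#' [quant_config()].
#'
#' @return data.frame with columns `label`, `mz`.
#' @export
itraq8_channels <- function() {
  data.frame(
    label = c("113", "114", "115", "116", "117", "118", "119", "121"),
    mz = c(113.1078, 114.1107, 115.1077, 116.1111,
           117.1144, 118.1115, 119.1148, 121.1221),
    stringsAsFactors = FALSE)
}

#' iTRAQ quantitation configuration
#'
#' Mirrors the isobaric-labeling settings of the quantitation workflow:
#' reporter peaks are matched within `marker_ppm` parts per million of each
#' channel m/z, and assigned intensities below `ion_count_threshold` times
#' the spectrum base peak are zeroed. The ratio orientation is
#' case/control, so a positive log2 ratio means more abundant in the case
#' (disease-model) channel.
#'
#' @param reporter_channels data.frame with `label` and `mz` columns
#'   (default [itraq8_channels()]).
#' @param marker_ppm reporter matching tolerance in ppm (default 100).
#' @param ion_count_threshold minimum assigned intensity as a fraction of
#'   the spectrum base peak (default 0.025).
#' @param control_label,case_label channel labels of the control
#'   (denominator) and case (numerator) samples; defaults `"117"`
#'   (wild-type) and `"118"` (disease model).
#' @return list of class `quant_config`.
#' @export
quant_config <- function(reporter_channels = itraq8_channels(),
                         marker_ppm = 100, ion_count_threshold = 0.025,
                         control_label = "117", case_label = "118") {
  stopifnot(marker_ppm > 0, ion_count_threshold >= 0,
            control_label != case_label,
            all(c("label", "mz") %in% names(reporter_channels)))
  structure(list(reporter_channels = reporter_channels,
                 marker_ppm = marker_ppm,
                 ion_count_threshold = ion_count_threshold,
                 control_label = as.character(control_label),
                 case_label = as.character(case_label)),
            class = "quant_config")
}

#' Extract reporter intensities from an MS2 peak list
#'
#' For each configured channel the most intense peak within
#' `marker_ppm * 1e-6 * channel_mz` of the channel m/z is assigned; an
#' assigned intensity below `ion_count_threshold` of the spectrum base peak
#' is zeroed. Overlapping channel windows are a configuration error.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param cfg a [quant_config()].
#' @return named numeric vector, one intensity per channel label.
#' @export
extract_reporters <- function(peaks, cfg = quant_config()) {
  ch <- cfg$reporter_channels[order(cfg$reporter_channels$mz), , drop = FALSE]
  tol <- cfg$marker_ppm * 1e-6 * ch$mz
  if (nrow(ch) > 1L) {
    hi <- ch$mz[-nrow(ch)] + tol[-nrow(ch)]
    lo <- ch$mz[-1L] - tol[-1L]
    if (any(hi >= lo))
      stop("reporter channel windows overlap at the configured ppm",
           call. = FALSE)
  }
  base <- if (nrow(peaks)) max(peaks$intensity) else 0
  out <- setNames(numeric(nrow(ch)), ch$label)
  for (i in seq_len(nrow(ch))) {
    inwin <- abs(peaks$mz - ch$mz[i]) <= tol[i]
    if (any(inwin)) {
      v <- max(peaks$intensity[inwin])
      if (base > 0 && v < cfg$ion_count_threshold * base) v <- 0
      out[ch$label[i]] <- v
    }
  }
  out[cfg$reporter_channels$label]
}

#' Normalize reporter channels over identified spectra
#'
#' Scales each channel so its summed intensity over all identified spectra
#' equals the common target (the grand mean of the channel totals), leaving
#' within-channel structure untouched. The normalization is self-adjusting:
#' multiplying one channel's raw data by a constant does not change the
#' output.
#'
#' @param records data.frame with `spectrum_id`, `peptide` and one numeric
#'   column per channel label (see [read_quant_table()]).
#' @param channels channel column names to normalize; default all columns
#'   except `spectrum_id`/`peptide`.
#' @return `records` with the channel columns rescaled.
#' @export
normalize_channels <- function(records,
                               channels = setdiff(names(records),
                                                  c("spectrum_id",
                                                    "peptide"))) {
  totals <- vapply(channels, function(cc) sum(records[[cc]]), numeric(1L))
  if (any(totals <= 0))
    stop("channel(s) with nonpositive total intensity: ",
         paste(channels[totals <= 0], collapse = ", "), call. = FALSE)
  target <- mean(totals)
  for (cc in channels) records[[cc]] <- records[[cc]] * (target / totals[cc])
  records
}

#' Paired log2-ratio one-sample t-test for one peptide
#'
#' Treats the two reporter intensities of each MS2 spectrum as a paired
#' sample: the per-spectrum ratio case/control is log2-transformed, and the
#' mean, standard deviation (n-1 denominator) and standard error of the
#' mean are computed over the peptide's spectra. A two-sided one-sample
#' t-test (t = mean/SEM, df = n-1) assesses whether the mean log2 ratio
#' differs from zero. Spectra where either channel intensity is zero are
#' dropped and counted. With a single usable spectrum or zero variance the
#' result is flagged degenerate, with p = 1 when the mean is 0 and p = 0
#' otherwise.
#'
#' @param records data.frame of the spectra assigned to one peptide, with
#'   the channel columns named by their labels.
#' @param cfg a [quant_config()] (provides case/control labels).
#' @return one-row data.frame: `peptide`, `n_spectra`, `n_dropped`,
#'   `mean_log2_ratio`, `sd`, `sem`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `degenerate`.
#' @export
peptide_ratio_test <- function(records, cfg = quant_config()) {
  ctrl <- records[[cfg$control_label]]
  case <- records[[cfg$case_label]]
  if (is.null(ctrl) || is.null(case))
    stop("records lack channel column(s) '", cfg$control_label, "'/'",
         cfg$case_label, "'", call. = FALSE)
  usable <- ctrl > 0 & case > 0
  n_dropped <- sum(!usable)
  lr <- log2(case[usable] / ctrl[usable])
  n <- length(lr)
  if (n == 0L)
    stop("no usable spectra (a channel is zero in every spectrum)",
         call. = FALSE)
  pep <- if ("peptide" %in% names(records))
    records$peptide[1L] else NA_character_
  m <- mean(lr)
  s <- if (n >= 2L) sd(lr) else NA_real_
  sem <- if (n >= 2L) s / sqrt(n) else NA_real_
  degenerate <- n == 1L || isTRUE(s == 0)
  if (degenerate) {
    tstat <- NA_real_
    p <- if (m == 0) 1 else 0
  } else {
    tstat <- m / sem
    p <- 2 * pt(-abs(tstat), df = n - 1L)
  }
  data.frame(peptide = pep, n_spectra = n, n_dropped = n_dropped,
             mean_log2_ratio = m, sd = s, sem = sem, t_statistic = tstat,
             degrees_of_freedom = n - 1L, p_value = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Per-peptide differential abundance over a whole quant table
#'
#' Applies [normalize_channels()] (optional) followed by
#' [peptide_ratio_test()] to every peptide of a reporter-intensity table.
#' Peptides with no usable spectra are reported with `n_spectra = 0` and
#' `NA` statistics rather than dropped.
#'
#' @param records full quant table (see [read_quant_table()]).
#' @param cfg a [quant_config()].
#' @param normalize apply channel normalization first (default `TRUE`).
#' @param adjust optional multiple-testing correction for the p-values,
#'   e.g. `"BH"`; default `"none"` (raw 5% level convention).
#' @return data.frame with one row per peptide, sorted by peptide; when
#'   `adjust != "none"` an extra `p_adjusted` column is included.
#' @export
test_peptide_ratios <- function(records, cfg = quant_config(),
                                normalize = TRUE, adjust = "none") {
  if (normalize)
    records <- normalize_channels(
      records, channels = intersect(names(records),
                                    cfg$reporter_channels$label))
  out <- lapply(split(records, records$peptide), function(sub) {
    tryCatch(peptide_ratio_test(sub, cfg), error = function(e)
      data.frame(peptide = sub$peptide[1L], n_spectra = 0L,
                 n_dropped = nrow(sub), mean_log2_ratio = NA_real_,
                 sd = NA_real_, sem = NA_real_, t_statistic = NA_real_,
                 degrees_of_freedom = NA_integer_, p_value = NA_real_,
                 degenerate = TRUE, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$peptide), , drop = FALSE]
  if (adjust != "none")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  out
}

#' Transcripts per million
#'
#' `tpm_i = (c_i / l_i) / sum_j(c_j / l_j) * 1e6`. When every count is zero
#' all TPM values are zero. An FPKM report column
#' (`count / (length/1e3) / (total_counts/1e6)`) is included alongside.
#'
#' @param quants data.frame with columns `transcript_id`, `count`,
#'   `effective_length`.
#' @return `quants` with `tpm` and `fpkm` columns added.
#' @export
compute_tpm <- function(quants) {
  if (any(quants$effective_length <= 0))
    stop("effective_length must be positive", call. = FALSE)
  if (any(quants$count < 0))
    stop("counts must be nonnegative", call. = FALSE)
  rate <- quants$count / quants$effective_length
  denom <- sum(rate)
  quants$tpm <- if (denom > 0) rate / denom * 1e6 else rep(0, nrow(quants))
  total <- sum(quants$count)
  quants$fpkm <- if (total > 0)
    quants$count / (quants$effective_length / 1e3) / (total / 1e6)
  else rep(0, nrow(quants))
  quants
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, `dCt = Ct_target - Ct_reference`; `ddCt = dCt -
#' dCt_calibrator`; `rq = 2^-ddCt`. The calibrator sample has `rq = 1` by
#' construction. One result row is produced per sample and target gene.
#'
#' @param ct data.frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (see [read_ct_table()]); technical replicates should be averaged
#'   beforehand.
#' @param reference_gene reference (housekeeping) gene label, e.g.
#'   `"Hprt1"`.
#' @param calibrator_sample sample id of the calibrator (e.g. whole brain).
#' @return data.frame: `sample_id`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @export
ddct <- function(ct, reference_gene, calibrator_sample) {
  samples <- unique(ct$sample_id)
  if (!calibrator_sample %in% samples)
    stop("calibrator sample '", calibrator_sample, "' absent from Ct table",
         call. = FALSE)
  targets <- setdiff(unique(ct$gene), reference_gene)
  ref_ct <- function(s) {
    v <- ct$ct[ct$sample_id == s & ct$gene == reference_gene]
    if (length(v) == 0L)
      stop("sample '", s, "' lacks a reference (", reference_gene,
           ") Ct value", call. = FALSE)
    mean(v)
  }
  rows <- list()
  for (g in targets) {
    cal_dct <- NULL
    v <- ct$ct[ct$sample_id == calibrator_sample & ct$gene == g]
    if (length(v) > 0L) cal_dct <- mean(v) - ref_ct(calibrator_sample)
    for (s in samples) {
      v <- ct$ct[ct$sample_id == s & ct$gene == g]
      if (length(v) == 0L) next
      if (is.null(cal_dct))
        stop("calibrator sample lacks a Ct for target gene '", g, "'",
             call. = FALSE)
      dct <- mean(v) - ref_ct(s)
      ddct_v <- dct - cal_dct
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, group = ct$group[ct$sample_id == s][1L], gene = g,
        delta_ct = dct, delta_delta_ct = ddct_v, rq = 2^(-ddct_v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample t-test on relative expression values
#'
#' Two-sided two-sample t-test comparing group means (Welch by default,
#' pooled-variance optional), as used to compare 2^-ddCt values between
#' tissue groups.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param var_equal pooled-variance test when `TRUE` (default `FALSE`,
#'   Welch).
#' @return list with `t`, `df`, `p`.
#' @export
group_difference_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    # t.test errors on two constant groups; identical means are a clean no-difference
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2L, p = 0))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
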