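# Model-rank and motif-resolved fit statistics: parameter counts, nested-
# model F values, the decomposition of the total SSR into motif/position
# classes, and the bias (QF) / sampling-error (SE) split of fit inadequacy.

#' Construct a fit report
#'
#' Holds residuals and summary statistics of one sensitivity fit. `ssr_total`
#' is the mean squared residual (the raw sum is kept alongside); motif
#' statistics are computed lazily by [motif_ssr()] and friends.
#'
#' @param rank model rank.
#' @param residuals per-probe residuals `Y^exp - Y^theo`.
#' @param fitted per-probe fitted sensitivities `Y^theo`.
#' @param y_exp per-probe experimental sensitivities.
#' @param probes probe annotation rows of the fitted ensemble.
#' @param param_count number of independent model parameters.
#' @return object of class `fit_report`.
#' @export
fit_report <- function(rank, residuals, fitted, y_exp, probes, param_count) {
  structure(
    list(rank = as.integer(rank), residuals = residuals, fitted = fitted,
         y_exp = y_exp, probes = probes,
         probe_count = length(residuals),
         param_count = as.integer(param_count),
         ssr_total = mean(residuals^2),
         ssr_sum = sum(residuals^2)),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: rank %d, %d probes, %d parameters, SSR = %.4g (mean sq.)\n",
              x$rank, x$probe_count, x$param_count, x$ssr_total))
  invisible(x)
}

#' Independent parameter count of a positional sensitivity model
#'
#' Under the per-position centering gauge, a rank-r model for probes of
#' length n has `(4^r - 1) * (n - r + 1) + 1` independent parameters
#' (76, 361, 1450 and 5611 for ranks 1..4 at n = 25).
#'
#' @param rank model rank 1..4.
#' @param probe_len probe length (default 25).
#' @return integer parameter count.
#' @export
count_parameters <- function(rank, probe_len = 25L) {
  if (!(rank %in% 1:4)) stop("rank must be an integer in 1..4")
  as.integer((4L^rank - 1L) * (probe_len - rank + 1L) + 1L)
}

#' Parameter count of the PDNN model class
#'
#' Models with one set of position-independent nearest-neighbor energies
#' plus a single common positional shape function: `(4^2 - 1)` independent
#' energy terms under one centering constraint plus one shape value per
#' nearest-neighbor position, i.e. 39 for 25-mers (vs 361 for the full
#' positional NN model).
#'
#' @param probe_len probe length (default 25).
#' @return integer parameter count.
#' @export
pdnn_parameter_count <- function(probe_len = 25L) {
  as.integer((4L^2 - 1L) + (probe_len - 1L))
}

#' Nested-model F statistic between consecutive ranks
#'
#' Standard nested form with the degrees of freedom
#' `df(r) = #p - #sigma(r) + 1`. With microarray-sized ensembles the
#' residuals are not normal, so the value is reported as an empirical
#' measure of fit improvement rather than a formal test.
#'
#' @param report_low,report_high `fit_report`s of rank r-1 and r on the
#'   same probe ensemble.
#' @return list with `F`, `df1` (parameter increment), `df2` (residual df)
#'   and `flagged` (TRUE when the higher model fits exactly and F is Inf).
#' @export
f_statistic <- function(report_low, report_high) {
  if (report_high$rank != report_low$rank + 1L)
    stop("reports must be of consecutive ranks")
  if (report_high$probe_count != report_low$probe_count)
    stop("reports must refer to the same probe ensemble")
  d_par <- report_high$param_count - report_low$param_count
  df2 <- report_high$probe_count - report_high$param_count + 1L
  if (report_high$ssr_total == 0)
    return(list(F = Inf, df1 = d_par, df2 = df2, flagged = TRUE))
  Fv <- ((report_low$ssr_total - report_high$ssr_total) / d_par) /
    (report_high$ssr_total / df2)
  list(F = Fv, df1 = d_par, df2 = df2, flagged = FALSE)
}

# shared per-class statistics for motifs of length s:
# class = probes containing motif b_s at position k (positional = TRUE)
# or anywhere in the sequence (positional = FALSE)
motif_class_stats <- function(report, s, positional = TRUE) {
  if (!(s %in% 1:4)) stop("motif length s must be in 1..4")
  index <- enumerate_motifs(s)
  codes <- motif_code_matrix(
    seq_code_matrix(report$probes$sequence, index$probe_len), s)
  res <- report$residuals
  n_tot <- length(res)
  agg <- function(member_code, k_label) {
    df <- data.frame(code = as.integer(member_code), res = res)
    n <- tapply(df$res, df$code, length)
    m <- tapply(df$res, df$code, mean)
    v <- tapply(df$res, df$code, function(r)
      if (length(r) >= 2) var(r) else NA_real_)
    msq <- tapply(df$res, df$code, function(r) mean(r^2))
    code <- as.integer(names(n))
    data.frame(motif = index$motifs[code + 1L], position = k_label,
               occupancy = as.integer(n), f = as.integer(n) / n_tot,
               ssr = as.numeric(msq), qf = as.numeric(m)^2,
               se = sqrt(as.numeric(v) / as.integer(n)),
               stringsAsFactors = FALSE)
  }
  if (positional) {
    out <- do.call(rbind, lapply(seq_len(index$n_pos), function(k)
      agg(codes[, k], k)))
  } else {
    # a probe may contain a motif at several positions; membership is
    # "contains at least once", so classes overlap and f sums above 1
    hits <- lapply(seq_len(index$n_motifs) - 1L, function(cd)
      which(rowSums(codes == cd) > 0))
    out <- do.call(rbind, lapply(seq_along(hits), function(i) {
      p <- hits[[i]]
      if (!length(p)) return(NULL)
      r <- res[p]
      data.frame(motif = index$motifs[i], position = NA_integer_,
                 occupancy = length(p), f = length(p) / n_tot,
                 ssr = mean(r^2), qf = mean(r)^2,
                 se = if (length(p) >= 2) sqrt(var(r) / length(p)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Motif-specific sum of squared residuals
#'
#' Mean squared residual over every class of probes containing a motif of
#' length `s` at position k (`positional = TRUE`) or anywhere
#' (`positional = FALSE`). For positional classes, the occupancy-weighted
#' sum over motifs at any fixed position reproduces the total SSR exactly.
#' Empty classes are omitted.
#'
#' @param report a `fit_report`.
#' @param s motif length 1..4 (independent of the fitted rank).
#' @param positional whether classes are position-resolved.
#' @return data.frame with `motif`, `position`, `occupancy`, `f`
#'   (class fraction) and `ssr`.
#' @export
motif_ssr <- function(report, s = 3L, positional = TRUE) {
  motif_class_stats(report, s, positional)[
    c("motif", "position", "occupancy", "f", "ssr")]
}

#' Motif-specific quality of fit (systematic bias)
#'
#' `QF = (mean class residual)^2`: zero for unbiased fits of the class,
#' positive when the model of the fitted rank systematically mis-describes
#' the motif. Always `QF <= SSR` of the class.
#'
#' @inheritParams motif_ssr
#' @return data.frame with `motif`, `position`, `occupancy` and `qf`.
#' @export
quality_of_fit <- function(report, s = 3L, positional = TRUE) {
  motif_class_stats(report, s, positional)[
    c("motif", "position", "occupancy", "qf")]
}

#' Motif-specific standard error
#'
#' `SE = sqrt(residual variance / class size)`, the sampling-noise floor of
#' a class's sensitivity estimate. Classes of size < 2 carry `NA`. Values
#' above 0.01 are flagged in the `qc_flag` column (rule-of-thumb threshold
#' for trustworthy sensitivity terms).
#'
#' @inheritParams motif_ssr
#' @return data.frame with `motif`, `position`, `occupancy`, `se`, `qc_flag`.
#' @export
standard_error <- function(report, s = 3L, positional = TRUE) {
  out <- motif_class_stats(report, s, positional)[
    c("motif", "position", "occupancy", "se")]
  out$qc_flag <- !is.na(out$se) & out$se > 0.01
  out
}

#' Relative amplitude of the (GGG)1 effect
#'
#' `delta_sigma = sigma_1(GGG) - sigma_12(CCC)`: the solution-end triple-G
#' sensitivity relative to the mid-sequence triple-C level, a chip-level
#' summary of the G-stack bias amplitude.
#'
#' @param profile a rank-3 `sensitivity_profile`.
#' @return numeric scalar.
#' @export
delta_sigma_ggg <- function(profile) {
  if (profile$rank != 3) stop("delta_sigma_ggg needs a rank-3 profile")
  if (profile$zero_occupancy["GGG", 1] || profile$zero_occupancy["CCC", 12])
    stop("(GGG, k=1) or (CCC, k=12) cell unpopulated")
  unname(profile$sigma["GGG", 1] - profile$sigma["CCC", 12])
}

#' Convert a log10 sensitivity increment to an intensity fold factor
#'
#' @param sigma log10 sensitivity increment(s).
#' @return `10^sigma`, the multiplicative effect on intensity.
#' @export
sensitivity_to_fold <- function(sigma) 10^sigma
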