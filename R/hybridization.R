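# Two-species Langmuir intensity model and the operations built on it:
# optical (zone) background, saturation linearization, absent/present
# selection, and empirical/theoretical hybridization isotherms.

#' Hybridization parameters of a chip
#'
#' Chip-level constants of the hyperbolic intensity response
#' \eqn{I = I_{min} + L / (1 + L / I_{max})}: the optical background
#' `I_min`, the saturation intensity `I_max`, the mean binding constants of
#' non-specific (`K_N`) and specific (`K_S`) hybridization, and the
#' transcript concentrations `conc_N`, `conc_S`. The linearized signal
#' decomposes as \eqn{L = I_{max}(K^S [S] + K^N [N])}.
#'
#' @param I_min optical background intensity (>= 0).
#' @param I_max saturation intensity (> 0); the asymptote is `I_min + I_max`.
#' @param K_N,K_S mean non-specific / specific binding constants.
#' @param conc_N,conc_S non-specific / specific transcript concentrations.
#' @return object of class `hyb_params`.
#' @export
hyb_params <- function(I_min = 40, I_max = 10^4.7, K_N = 1, K_S = 1000,
                       conc_N = 1, conc_S = 0) {
  stopifnot(I_max > 0, I_min >= 0, K_N >= 0, K_S >= 0,
            conc_N >= 0, conc_S >= 0)
  structure(list(I_min = I_min, I_max = I_max, K_N = K_N, K_S = K_S,
                 conc_N = conc_N, conc_S = conc_S),
            class = "hyb_params")
}

#' Langmuir probe intensity from a linearized signal
#'
#' The hyperbolic two-species isotherm: background `I_min` at vanishing
#' signal, a linear regime \eqn{I - I_{min} \approx L} for
#' \eqn{L \ll I_{max}}, and saturation at `I_min + I_max`.
#'
#' @param L non-negative linearized signal (vectorized).
#' @param params a [hyb_params()] object.
#' @return intensity values in `[I_min, I_min + I_max)`.
#' @export
langmuir_intensity <- function(L, params = hyb_params()) {
  if (any(L < 0)) stop("linearized signal L must be non-negative")
  params$I_min + L / (1 + L / params$I_max)
}

#' Invert the Langmuir isotherm (saturation correction)
#'
#' Exact inverse of [langmuir_intensity()] on the open intensity range
#' `[I_min, I_min + I_max)`.
#'
#' @param I intensity (vectorized).
#' @param params a [hyb_params()] object.
#' @return linearized signal L with
#'   `langmuir_intensity(linearize_intensity(I)) == I` to 1e-10 relative.
#' @export
linearize_intensity <- function(I, params = hyb_params()) {
  if (any(I < params$I_min)) stop("intensity below the optical background I_min")
  if (any(I >= params$I_min + params$I_max))
    stop("intensity at or above saturation I_min + I_max cannot be linearized")
  d <- I - params$I_min
  d / (1 - d / params$I_max)
}

#' Zone-wise optical background estimate
#'
#' Splits the chip into a grid of zones, estimates each zone's background as
#' the mean of its lowest `fraction` of intensities, and smooths zone values
#' to probe resolution with inverse-squared-distance weights to the zone
#' centers (plus a smoothing constant), in the manner of the vendor zone
#' algorithm. Subtraction is done by [subtract_background()], which floors
#' corrected intensities at a small positive constant.
#'
#' @param chip a `chip_data` object.
#' @param n_zones_x,n_zones_y zone grid (default 4 x 4).
#' @param fraction fraction of lowest intensities per zone (default 0.02).
#' @param smooth smoothing constant added to squared distances (default 100).
#' @return numeric vector of per-cell background values aligned with
#'   `chip$intensities`.
#' @export
zone_background <- function(chip, n_zones_x = 4L, n_zones_y = 4L,
                            fraction = 0.02, smooth = 100) {
  stopifnot(inherits(chip, "chip_data"), fraction > 0, fraction < 1)
  ints <- chip$intensities
  if (nrow(ints) == 0) stop("chip has no intensities")
  lowest_mean <- function(v) {
    n <- max(1L, floor(length(v) * fraction))
    mean(sort(v)[seq_len(n)])
  }
  zx <- pmin(n_zones_x - 1L, floor(ints$x / (chip$n_cols / n_zones_x)))
  zy <- pmin(n_zones_y - 1L, floor(ints$y / (chip$n_rows / n_zones_y)))
  zid <- zx * n_zones_y + zy
  sizes <- table(zid)
  if (any(sizes < 1 / fraction)) {
    warning("zone(s) with fewer than 1/fraction probes; ",
            "falling back to a whole-chip background estimate")
    bg <- rep(lowest_mean(ints$intensity), nrow(ints))
  } else {
    zvals <- tapply(ints$intensity, zid, lowest_mean)
    cx <- (tapply(ints$x, zid, min) + tapply(ints$x, zid, max)) / 2
    cy <- (tapply(ints$y, zid, min) + tapply(ints$y, zid, max)) / 2
    if (length(zvals) == 1L) {
      bg <- rep(zvals[[1]], nrow(ints))
    } else {
      num <- den <- numeric(nrow(ints))
      for (z in seq_along(zvals)) {
        w <- 1 / ((ints$x - cx[z])^2 + (ints$y - cy[z])^2 + smooth)
        num <- num + w * zvals[z]
        den <- den + w
      }
      bg <- num / den
    }
  }
  bg
}

#' Subtract a background estimate from a chip
#'
#' Returns a copy of the chip with `intensity - background`, floored at a
#' small positive constant so the log transform stays defined.
#'
#' @param chip a `chip_data` object.
#' @param background per-cell background (e.g. from [zone_background()]).
#' @param floor_value minimum corrected intensity (default 0.5).
#' @return corrected `chip_data`.
#' @export
subtract_background <- function(chip, background, floor_value = 0.5) {
  stopifnot(inherits(chip, "chip_data"),
            length(background) == nrow(chip$intensities))
  chip$intensities$intensity <-
    pmax(chip$intensities$intensity - background, floor_value)
  chip
}

#' Absent/present classification of probe sets
#'
#' Partition of the probe sets into a non-specifically hybridized ("absent",
#' N) ensemble and a "present" ensemble. The built-in `mixture` method is a
#' documented stand-in for external single-chip calibration callers: it fits
#' a two-component Gaussian location mixture to the probe-set median log10
#' intensities by EM and labels a set absent when the posterior of the lower
#' component exceeds 0.5. With `method = "override"` calls are read verbatim
#' from a TSV (`probe_set_id`, `call` in {A, P}), the route intended for
#' real data where external calls exist.
#'
#' @param chip a `chip_data` object (intensities background-corrected).
#' @param method `"mixture"` or `"override"`.
#' @param calls_path TSV path for `method = "override"`.
#' @return list with `absent` and `present` (character vectors of probe-set
#'   ids) and `posterior_absent` (named numeric, mixture route only).
#' @export
classify_absent <- function(chip, method = c("mixture", "override"),
                            calls_path = NULL) {
  method <- match.arg(method)
  sets <- unique(chip$probes$probe_set_id)
  if (method == "override") {
    tab <- read.delim(calls_path, stringsAsFactors = FALSE)
    if (!all(c("probe_set_id", "call") %in% names(tab)))
      stop("override calls file needs columns probe_set_id, call")
    missing <- setdiff(sets, tab$probe_set_id)
    if (length(missing))
      stop("override file lacks calls for probe sets: ",
           paste(utils::head(missing, 10), collapse = ", "))
    call <- tab$call[match(sets, tab$probe_set_id)]
    return(list(absent = sets[call == "A"], present = sets[call == "P"],
                posterior_absent = NULL))
  }
  ip <- probe_intensities(chip)
  med <- tapply(log10(pmax(ip, .Machine$double.eps)),
                chip$probes$probe_set_id, stats::median)
  med <- med[sets]
  if (length(med) < 2 || sd(med) == 0) {
    thr <- stats::median(med)
    absent <- sets[med <= thr]
    return(list(absent = absent, present = setdiff(sets, absent),
                posterior_absent = setNames(as.numeric(med <= thr), sets)))
  }
  post <- fit_two_gaussians(as.numeric(med))
  absent <- sets[post > 0.5]
  list(absent = absent, present = setdiff(sets, absent),
       posterior_absent = setNames(post, sets))
}

# EM for a two-component Gaussian location mixture (common scale, the
# components differ only in location); returns the posterior of the
# lower-mean component. Deterministic quantile-based start.
fit_two_gaussians <- function(x, max_iter = 500L, tol = 1e-10) {
  mu <- quantile(x, c(0.25, 0.75), names = FALSE)
  s2 <- var(x) / 2
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], sqrt(s2))
    d2 <- (1 - pi1) * dnorm(x, mu[2], sqrt(s2))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    pi1 <- mean(g)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    s2 <- max((sum(g * (x - mu[1])^2) +
               sum((1 - g) * (x - mu[2])^2)) / length(x), 1e-8)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] <= mu[2]) g else 1 - g
}

#' Empirical hybridization isotherm
#'
#' Sorts probes by their expression degree (proportional to the log
#' specific signal), then smooths log10 intensity with a centered moving
#' mean (window truncated at the ends). The `subset` predicate supports
#' restriction to e.g. (GGG)1-containing probes for bias diagnosis.
#'
#' @param chip a `chip_data` object.
#' @param expression numeric vector of per-probe expression degrees aligned
#'   with `chip$probes`.
#' @param subset logical vector or predicate function on `chip$probes`
#'   selecting probes (default: all).
#' @param window moving-window size in probes (default 1000).
#' @return object of class `isotherm_curve`: data.frame with `abscissa`
#'   (sorted expression), `ordinate` (smoothed log10 intensity) and the
#'   window size as attribute.
#' @export
empirical_isotherm <- function(chip, expression, subset = NULL, window = 1000L) {
  stopifnot(inherits(chip, "chip_data"), window >= 1)
  keep <- rep(TRUE, nrow(chip$probes))
  if (is.function(subset)) keep <- subset(chip$probes)
  else if (!is.null(subset)) keep <- subset
  ip <- probe_intensities(chip)[keep]
  ex <- expression[keep]
  ok <- !is.na(ip) & !is.na(ex) & ip > 0
  ip <- ip[ok]; ex <- ex[ok]
  if (length(ip) == 0) stop("no probes selected for the isotherm")
  if (length(ip) < window) {
    warning("fewer probes (", length(ip), ") than window; shrinking window")
    window <- length(ip)
  }
  o <- order(ex)
  y <- log10(ip[o])
  sm <- running_mean(y, window)
  structure(data.frame(abscissa = ex[o], ordinate = sm),
            class = c("isotherm_curve", "data.frame"),
            window = as.integer(window))
}

# centered moving mean, window truncated at the series ends
running_mean <- function(y, window) {
  n <- length(y)
  half <- (window - 1) %/% 2
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - 1L - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Theoretical hybridization isotherms (scenarios A/B/C)
#'
#' Computes log10 intensity as a function of log10 specific concentration
#' from the Langmuir model with \eqn{L = I_{max}(K^S [S] + K^N [N])}.
#' Scenario `A` is the reference; `B` multiplies only the non-specific
#' binding constant `K_N` by `factor` (raising the N-range plateau by
#' log10(factor) and leaving the inflection abscissa unchanged); `C`
#' multiplies both `K_N` and `K_S` (additionally shifting the inflection
#' point left by log10(factor)).
#'
#' @param params_ref reference [hyb_params()].
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param factor multiplicative binding-constant factor (> 1 for B and C).
#' @param log_S_range range of log10 specific concentration.
#' @param n number of grid points.
#' @return `isotherm_curve` data.frame (`abscissa` = log10 [S],
#'   `ordinate` = log10 I).
#' @export
theoretical_isotherm <- function(params_ref, scenario = c("A", "B", "C"),
                                 factor = 1, log_S_range = c(-4, 4),
                                 n = 401L) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("B", "C") && factor < 1)
    stop("factor must be >= 1 for scenarios B and C")
  p <- params_ref
  if (scenario %in% c("B", "C")) p$K_N <- p$K_N * factor
  if (scenario == "C") p$K_S <- p$K_S * factor
  logS <- seq(log_S_range[1], log_S_range[2], length.out = n)
  L <- p$I_max * (p$K_S * 10^logS + p$K_N * p$conc_N)
  I <- langmuir_intensity(L, p)
  structure(data.frame(abscissa = logS, ordinate = log10(I)),
            class = c("isotherm_curve", "data.frame"),
            window = NA_integer_)
}

#' Inflection abscissa of an isotherm curve
#'
#' The abscissa where the ordinate crosses halfway between its low-end
#' (N-range) plateau and its high-end (saturation) level, located by
#' linear interpolation.
#'
#' @param curve an `isotherm_curve`.
#' @return numeric abscissa value.
#' @export
isotherm_inflection <- function(curve) {
  lev <- (curve$ordinate[1] + curve$ordinate[nrow(curve)]) / 2
  i <- which(curve$ordinate >= lev)[1]
  if (is.na(i) || i == 1) return(curve$abscissa[1])
  x0 <- curve$abscissa[i - 1]; x1 <- curve$abscissa[i]
  y0 <- curve$ordinate[i - 1]; y1 <- curve$ordinate[i]
  x0 + (lev - y0) / (y1 - y0) * (x1 - x0)
}
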