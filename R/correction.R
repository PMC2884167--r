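# The NN+GGG hybrid-rank calibration: a rank-2 (nearest-neighbor) model for
# probes without triple-G motifs plus rank-3 excess terms sigma_k(GGG) for
# probes that contain them, fitted on the non-specifically hybridized
# ("absent") ensemble and applied as a pre-correction of probe intensities.

#' Positions of triple-G runs in a probe sequence
#'
#' All (overlapping) windows `sequence[k..k+2] == "GGG"`, 1-based; a GGGG
#' run yields two consecutive positions.
#'
#' @param sequence a probe sequence string.
#' @return integer vector of start positions (possibly empty).
#' @export
find_ggg_runs <- function(sequence) {
  hits <- gregexpr("(?=GGG)", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

has_ggg <- function(seqs) grepl("GGG", seqs, fixed = TRUE)

#' Split the absent ensemble by triple-G content
#'
#' A probe set joins `ps_ggg` when any member probe carries at least one
#' run of three consecutive guanines anywhere in its sequence; the two
#' parts are disjoint and cover the absent set.
#'
#' @param chip a `chip_data` object.
#' @param n_set character vector of absent probe-set ids.
#' @return list with `ps_nn` and `ps_ggg` (probe-set id vectors).
#' @export
split_probesets <- function(chip, n_set) {
  keep <- chip$probes$probe_set_id %in% n_set
  ggg_by_set <- tapply(has_ggg(chip$probes$sequence[keep]),
                       chip$probes$probe_set_id[keep], any)
  sets <- names(ggg_by_set)
  list(ps_nn = sets[!ggg_by_set], ps_ggg = sets[ggg_by_set])
}

#' Fit the basal nearest-neighbor profile
#'
#' Rank-2 fit restricted to the triple-G-free absent probe sets (`ps_nn`);
#' the resulting terms are the basal sigma^NN of the hybrid model.
#'
#' @param chip a `chip_data` object.
#' @param linearized per-probe linearized signals aligned with `chip$probes`.
#' @param ps_nn probe-set ids of the triple-G-free absent ensemble.
#' @return list with `profile` and `report` as in [fit_profiles()].
#' @export
fit_basal_nn <- function(chip, linearized, ps_nn) {
  if (!length(ps_nn)) stop("empty PS_NN ensemble")
  fit_profiles(chip, linearized, rank = 2L, subset = ps_nn, mode = "N")
}

# uncentered sequence effect sum_k sigma_k(motif at k) for given sequences
predict_delta_A <- function(profile, seqs) {
  codes <- motif_code_matrix(seq_code_matrix(seqs, profile$index$probe_len),
                             profile$rank)
  dA <- numeric(length(seqs))
  for (k in seq_len(ncol(codes)))
    dA <- dA + profile$sigma[codes[, k] + 1L, k]
  dA
}

#' Fit the triple-G excess profile
#'
#' On the `ps_ggg` probes, the residual sensitivity (experimental minus
#' basal NN prediction, both probe-set centered) is regressed on probe-set
#' centered indicators of a GGG run at each of the 23 triple positions.
#' Positions with zero GGG occupancy are pinned to 0 and flagged.
#'
#' @param chip a `chip_data` object.
#' @param linearized per-probe linearized signals aligned with `chip$probes`.
#' @param ps_ggg probe-set ids of the triple-G-containing absent ensemble.
#' @param basal the basal NN `sensitivity_profile`.
#' @return list with `excess` (numeric, positions 1..23), `occupancy`
#'   (GGG probe count per position), `se` (per-position standard errors)
#'   and `empty` (logical flag of pinned positions).
#' @export
fit_ggg_excess <- function(chip, linearized, ps_ggg, basal) {
  if (!length(ps_ggg)) stop("empty PS_GGG ensemble")
  keep <- chip$probes$probe_set_id %in% ps_ggg
  probes <- chip$probes[keep, , drop = FALSE]
  sub <- chip; sub$probes <- probes
  y_exp <- as.numeric(experimental_sensitivity(sub, linearized[keep]))
  y_bas <- center_by_set(predict_delta_A(basal, probes$sequence),
                         probes$probe_set_id)
  y <- y_exp - y_bas
  codes3 <- motif_code_matrix(seq_code_matrix(probes$sequence), 3L)
  ggg_code <- 2L * 16L + 2L * 4L + 2L
  G <- (codes3 == ggg_code) * 1
  occ <- colSums(G)
  Gc <- apply(G, 2, center_by_set, set_id = probes$probe_set_id)
  live <- which(occ > 0 & colSums(Gc^2) > 0)
  excess <- numeric(ncol(G))
  se <- rep(NA_real_, ncol(G))
  if (length(live)) {
    fit <- lm.fit(Gc[, live, drop = FALSE], y)
    excess[live] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    res <- y - Gc[, live, drop = FALSE] %*% ifelse(is.na(fit$coefficients), 0,
                                                   fit$coefficients)
    s2 <- sum(res^2) / max(length(y) - length(live), 1)
    xtx <- crossprod(Gc[, live, drop = FALSE])
    dg <- tryCatch(diag(solve(xtx)), error = function(e)
      1 / pmax(diag(xtx), 1e-12))
    se[live] <- sqrt(s2 * dg)
  }
  list(excess = excess, occupancy = occ, se = se, empty = occ == 0)
}

#' Bundle the fitted components of the hybrid model
#'
#' @param basal_nn rank-2 `sensitivity_profile` (non-specific mode).
#' @param ggg_excess numeric vector of triple-G excess terms (positions
#'   1..23), or NULL for a plain NN model.
#' @param specific_nn rank-2 `sensitivity_profile` of specific mode, or
#'   NULL if no specific-side correction is available.
#' @param specific_fraction named per-probe-set specific-hybridization
#'   weights in `[0, 1]`.
#' @param ps_ggg probe-set ids whose probes receive the GGG term.
#' @return object of class `hybrid_model`.
#' @export
hybrid_model <- function(basal_nn, ggg_excess = NULL, specific_nn = NULL,
                         specific_fraction = NULL, ps_ggg = character(0)) {
  structure(list(basal_nn = basal_nn, ggg_excess = ggg_excess,
                 specific_nn = specific_nn,
                 specific_fraction = specific_fraction,
                 ps_ggg = ps_ggg),
            class = "hybrid_model")
}

# per-probe GGG excess term sum_k sigma_k(GGG) 1{GGG at k}
ggg_delta_A <- function(seqs, excess) {
  codes3 <- motif_code_matrix(seq_code_matrix(seqs), 3L)
  ggg_code <- 2L * 16L + 2L * 4L + 2L
  as.numeric((codes3 == ggg_code) %*% excess)
}

#' Apply a fitted hybrid model to probe signals
#'
#' Computes per-probe corrections in log10 space and returns corrected
#' linearized signals. Absent probes receive the basal NN term plus, for
#' members of `ps_ggg`, the triple-G excess; present probes with specific
#' fraction above `specific_threshold` receive the specific NN term; mixed
#' sets a weighted combination `w * dA^S + (1 - w) * dA^(N+GGG)`. All
#' corrections are centered within each probe set, so probe-set mean log
#' signals (the expression information) are preserved exactly.
#'
#' @param chip a `chip_data` object.
#' @param model a [hybrid_model()].
#' @param linearized per-probe linearized signals aligned with `chip$probes`.
#' @param n_set character vector of absent probe-set ids.
#' @param specific_threshold sets above this specific fraction use the
#'   specific profile alone (default 0.8).
#' @return list with `L0` (corrected linearized signals) and `correction`
#'   (the applied per-probe log10 corrections).
#' @export
correct_probes <- function(chip, model, linearized, n_set,
                           specific_threshold = 0.8) {
  probes <- chip$probes
  seqs <- probes$sequence
  dA_n <- predict_delta_A(model$basal_nn, seqs)
  if (!is.null(model$ggg_excess)) {
    in_ggg <- probes$probe_set_id %in% model$ps_ggg
    dA_n <- dA_n + ifelse(in_ggg, ggg_delta_A(seqs, model$ggg_excess), 0)
  }
  w <- rep(0, nrow(probes))
  is_absent <- probes$probe_set_id %in% n_set
  if (!is.null(model$specific_fraction)) {
    hit <- model$specific_fraction[probes$probe_set_id]
    w <- ifelse(is.na(hit), 0, hit)
  } else if (any(!is_absent)) {
    warning("no specific-fraction estimates; present probes treated with w = 0")
  }
  w[is_absent] <- 0
  dA <- dA_n * (1 - w)
  if (!is.null(model$specific_nn)) {
    dA_s <- predict_delta_A(model$specific_nn, seqs)
    full_s <- w > specific_threshold
    dA <- ifelse(full_s, dA_s, dA + dA_s * w)
  }
  corr <- center_by_set(dA, probes$probe_set_id)
  list(L0 = 10^(log10(linearized) - corr), correction = corr)
}

#' Run the full calibration pipeline on a chip
#'
#' Executes: (1) zone background correction and saturation linearization;
#' (2) absent/present classification; (3) model fitting on the absent
#' ensemble (plain rank 1/2/3 or the NN+GGG hybrid); (4) specific-side
#' rank-2 fit on strongly specific probe sets, when they suffice; (5)
#' correction of all probes and assembly of a corrected chip. Ensemble
#' sizes and fit statistics are collected in `log`.
#'
#' @param chip a `chip_data` object (raw intensities).
#' @param model_type `"nn+ggg"` (default), `"n"`, `"nn"` or `"nnn"`.
#' @param params a [hyb_params()] with the chip's `I_min`/`I_max`; when
#'   NULL, `I_min` is the zone-background floor (0 after subtraction) and
#'   `I_max` is set 5% above the largest background-corrected intensity.
#' @param absent_method,calls_path passed to [classify_absent()];
#'   alternatively supply `absent_sets` directly.
#' @param absent_sets optional explicit absent probe-set ids (overrides
#'   classification).
#' @param specific_fraction optional named per-set specific weights; by
#'   default derived from the mixture posterior (1 - posterior of absence).
#' @param specific_threshold specific-profile cutoff (default 0.8).
#' @param zone_grid zones per axis for the background (default 4).
#' @param output_scale `"intensity"` (refold corrected signals through the
#'   Langmuir isotherm, CEL-like magnitudes) or `"linear"` (write L0).
#' @return list with `chip` (corrected `chip_data`), `model`
#'   (`hybrid_model`), `report` (absent-side `fit_report`) and `log`.
#' @export
run_pipeline <- function(chip, model_type = c("nn+ggg", "n", "nn", "nnn"),
                         params = NULL,
                         absent_method = "mixture", calls_path = NULL,
                         absent_sets = NULL, specific_fraction = NULL,
                         specific_threshold = 0.8, zone_grid = 4L,
                         output_scale = c("intensity", "linear")) {
  model_type <- match.arg(model_type)
  output_scale <- match.arg(output_scale)
  logi <- list(model = model_type)

  bg <- zone_background(chip, zone_grid, zone_grid)
  chip_bc <- subtract_background(chip, bg)
  if (is.null(params)) {
    imax <- max(chip_bc$intensities$intensity) * 1.05
    params <- hyb_params(I_min = 0, I_max = imax)
  } else {
    params <- hyb_params(I_min = 0, I_max = params$I_max,
                         K_N = params$K_N, K_S = params$K_S,
                         conc_N = params$conc_N, conc_S = params$conc_S)
  }
  ip <- probe_intensities(chip_bc)
  if (anyNA(ip)) stop("probes without intensities; cannot run the pipeline")
  L <- linearize_intensity(pmin(ip, params$I_min + params$I_max * 0.9999),
                           params)
  L <- pmax(L, .Machine$double.eps)

  if (is.null(absent_sets)) {
    cls <- classify_absent(chip_bc, absent_method, calls_path)
    absent_sets <- cls$absent
    if (is.null(specific_fraction) && !is.null(cls$posterior_absent))
      specific_fraction <- 1 - cls$posterior_absent
  }
  logi$n_sets <- length(unique(chip$probes$probe_set_id))
  logi$n_absent <- length(absent_sets)

  if (model_type == "nn+ggg") {
    parts <- split_probesets(chip, absent_sets)
    logi$n_ps_nn <- length(parts$ps_nn)
    logi$n_ps_ggg <- length(parts$ps_ggg)
    basal <- fit_basal_nn(chip, L, parts$ps_nn)
    if (length(parts$ps_ggg)) {
      exc <- fit_ggg_excess(chip, L, parts$ps_ggg, basal$profile)
      model <- hybrid_model(basal$profile, exc$excess,
                            specific_fraction = specific_fraction,
                            ps_ggg = parts$ps_ggg)
      logi$ggg_excess <- exc$excess
    } else {
      model <- hybrid_model(basal$profile, NULL,
                            specific_fraction = specific_fraction)
    }
    report <- basal$report
  } else {
    rank <- c(n = 1L, nn = 2L, nnn = 3L)[[model_type]]
    fit <- fit_profiles(chip, L, rank = rank, subset = absent_sets, mode = "N")
    model <- hybrid_model(fit$profile, NULL,
                          specific_fraction = specific_fraction)
    report <- fit$report
  }
  logi$ssr_absent <- report$ssr_total

  # specific-side rank-2 fit on strongly specific sets, when they suffice
  if (!is.null(specific_fraction)) {
    s_sets <- names(specific_fraction)[specific_fraction > specific_threshold]
    s_sets <- setdiff(s_sets, absent_sets)
    n_s_probes <- sum(chip$probes$probe_set_id %in% s_sets)
    if (n_s_probes >= 2 * count_parameters(2L)) {
      sfit <- suppressWarnings(tryCatch(
        fit_profiles(chip, L, rank = 2L, subset = s_sets, mode = "S"),
        error = function(e) NULL))
      if (!is.null(sfit)) {
        model$specific_nn <- sfit$profile
        logi$ssr_specific <- sfit$report$ssr_total
        logi$n_specific_probes <- n_s_probes
      }
    }
  }

  corr <- correct_probes(chip, model, L, absent_sets, specific_threshold)
  out_chip <- chip
  pkey <- grid_key(chip$probes$x, chip$probes$y, chip$n_cols)
  ikey <- grid_key(chip$intensities$x, chip$intensities$y, chip$n_cols)
  new_int <- chip$intensities$intensity
  vals <- if (output_scale == "intensity")
    langmuir_intensity(corr$L0, params) else corr$L0
  new_int[match(pkey, ikey)] <- vals
  out_chip$intensities$intensity <- new_int

  if (!is.null(model$ggg_excess))
    logi$delta_sigma_like <- model$ggg_excess[1]
  list(chip = out_chip, model = model, report = report, log = logi)
}
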