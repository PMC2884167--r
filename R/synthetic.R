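# Synthetic chips with fully known ground truth: sequences with controllable
# base composition and (GGG)1 enrichment, two-species Langmuir intensities,
# a configurable fraction of purely non-specifically hybridized ("absent")
# probe sets, and injectable solution-end / along-sequence triple-G biases.
# Every other module is validated against the truth these chips carry.

#' Specification of a synthetic chip
#'
#' Defaults encode a realistic small expression array: probe sets of 11
#' probes, uniform base composition, ~2% of probes starting with GGG, 60%
#' absent probe sets, set-level non-specific signals around log10 L^N = 2.2
#' (sd 0.35), specific signals around log10 L^S = 3.0 (sd 0.8), optical
#' background 40, saturation 10^4.7, and multiplicative noise of 0.1 on the
#' log10 intensity scale.
#'
#' @param n_probe_sets number of probe sets.
#' @param probes_per_set probes per set (default 11).
#' @param pm_mm also generate an MM partner under each PM (doubles probes).
#' @param base_composition probabilities for A, C, G, T.
#' @param ggg1_enrichment fraction of probes forced to start with GGG.
#' @param ggg_internal_rate fraction of probes given a triple-G run at a
#'   random internal position 2..23 (real designs avoid G runs, so internal
#'   triples are rare; a small rate keeps those positions testable).
#' @param suppress_g_runs break spontaneous triple-G runs in the random
#'   sequences, so triple-G content is controlled by `ggg1_enrichment` and
#'   `ggg_internal_rate` alone (matching the ~2% (GGG)1 probes and ~20%
#'   triple-G probe sets of real chips).
#' @param profile_spec generating profile description, see
#'   [default_paperlike_profile()].
#' @param absent_fraction fraction of sets with zero specific signal.
#' @param conc_N_meanlog,conc_N_sdlog log10-scale parameters of set-level
#'   non-specific signals L0^N.
#' @param conc_S_meanlog,conc_S_sdlog log10-scale parameters of set-level
#'   specific signals L0^S (present sets only).
#' @param I_min,I_max optical background / saturation intensity.
#' @param mm_specific_factor fraction of specific signal retained by an MM
#'   probe (middle-base mismatch weakens specific binding).
#' @param noise_sd sd of Gaussian noise on log10 intensity.
#' @param seed integer RNG seed controlling all draws.
#' @return object of class `synthetic_chip_spec`.
#' @export
synthetic_chip_spec <- function(n_probe_sets = 500L, probes_per_set = 11L,
                                pm_mm = FALSE,
                                base_composition = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                                ggg1_enrichment = 0.02,
                                ggg_internal_rate = 0.01,
                                suppress_g_runs = TRUE,
                                profile_spec = default_paperlike_profile(2),
                                absent_fraction = 0.6,
                                conc_N_meanlog = 2.2, conc_N_sdlog = 0.35,
                                conc_S_meanlog = 3.2, conc_S_sdlog = 0.7,
                                I_min = 40, I_max = 10^4.7,
                                mm_specific_factor = 0.1,
                                noise_sd = 0.1, seed = 1L) {
  stopifnot(n_probe_sets >= 1, probes_per_set >= 1,
            abs(sum(base_composition) - 1) < 1e-8,
            ggg1_enrichment >= 0, ggg1_enrichment <= 1,
            absent_fraction >= 0, absent_fraction <= 1,
            noise_sd >= 0, I_max > 0, I_min >= 0)
  structure(as.list(environment()), class = "synthetic_chip_spec")
}

#' Generating sensitivity profile emulating real expression arrays
#'
#' Per-base parabolic positional curves ordered A < T < G < C at
#' mid-sequence and vanishing at both sequence ends, combined per motif as
#' the mean of its base amplitudes plus (for rank >= 2) a homo-stack
#' interaction (inflated CC and GG, depressed TT — a genuinely
#' non-additive nearest-neighbor structure that a single-base model cannot
#' represent). The profile is centered over motifs at every position. An
#' optional triple-G excess of +0.4 at the solution end (k = 1) and +0.1
#' at later positions reproduces the amplitudes observed on T7-amplified
#' expression hybridizations; `ggg_k1 = ggg_rest = 0` gives a pure rank-r
#' world.
#'
#' @param rank generating rank 1..3.
#' @param amps named base amplitudes at mid-sequence (must sum to 0).
#' @param stack_amps named homo-pair interaction amplitudes (AA/CC/GG/TT);
#'   centered internally over all 16 pairs.
#' @param ggg_k1 triple-G excess at position 1.
#' @param ggg_rest triple-G excess at positions k > 1.
#' @return object of class `profile_spec`.
#' @export
default_paperlike_profile <- function(rank = 2L,
                                      amps = c(A = -0.06, C = 0.06,
                                               G = 0.02, T = -0.02),
                                      stack_amps = c(AA = 0, CC = 0.08,
                                                     GG = 0.06, TT = -0.08),
                                      ggg_k1 = 0, ggg_rest = 0) {
  if (!(rank %in% 1:3)) stop("generating rank must be 1..3")
  if (abs(sum(amps)) > 1e-12) stop("base amplitudes must sum to zero")
  if (rank == 1L) stack_amps <- c(AA = 0, CC = 0, GG = 0, TT = 0)
  structure(list(rank = as.integer(rank), amps = amps[BASES],
                 stack_amps = stack_amps[c("AA", "CC", "GG", "TT")],
                 ggg_k1 = ggg_k1, ggg_rest = ggg_rest),
            class = "profile_spec")
}

# centered pair-interaction amplitude epsilon(b1 b2): homo-pair bonuses
# minus their mean over all 16 pairs
pair_interaction <- function(pspec) {
  eps <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  diag(eps) <- pspec$stack_amps
  eps - mean(eps)
}

# parabolic positional weight over n_pos positions, 0 at both ends, 1 in
# the middle
parabola_weights <- function(n_pos) {
  k <- seq_len(n_pos)
  c0 <- (n_pos + 1) / 2
  h <- (n_pos - 1) / 2
  1 - ((k - c0) / h)^2
}

#' Generating sigma matrix of a profile spec
#'
#' The truth against which fitted profiles are compared: motif value =
#' mean base amplitude x parabolic positional weight (centered over motifs
#' at each position by construction). The triple-G excess is NOT included
#' here; it is a separate rank-3 additive term returned by
#' [true_ggg_excess()].
#'
#' @param pspec a `profile_spec`.
#' @param rank rank of the requested matrix (default: the generating rank).
#' @param canonical return the minimum-norm gauge representative (default;
#'   this is the gauge [fit_profiles()] estimates in, see
#'   [canonical_sigma()]). The raw separable parabola predicts identical
#'   probe sensitivities.
#' @return matrix (4^rank motifs x positions) with motif rownames.
#' @export
true_profile_sigma <- function(pspec, rank = pspec$rank, canonical = TRUE) {
  index <- enumerate_motifs(rank)
  w <- parabola_weights(index$n_pos)
  base_amp <- pspec$amps
  eps <- pair_interaction(pspec)
  motif_amp <- vapply(strsplit(index$motifs, ""), function(b) {
    a <- mean(base_amp[b])
    if (length(b) >= 2 && rank >= 2)
      a <- a + mean(eps[cbind(b[-length(b)], b[-1])])
    a
  }, numeric(1))
  out <- outer(motif_amp, w)
  dimnames(out) <- list(index$motifs, NULL)
  if (canonical) canonical_sigma(out, rank) else out
}

#' Generating triple-G excess terms
#'
#' @param pspec a `profile_spec`.
#' @return numeric vector over positions 1..23 (triple-motif positions).
#' @export
true_ggg_excess <- function(pspec) {
  c(pspec$ggg_k1, rep(pspec$ggg_rest, 22L))
}

# sequence effect deltaA(xi) of a probe under the generating model:
# base-profile term at the generating rank plus the triple-G excess
generating_delta_A <- function(seqs, pspec, with_ggg = TRUE) {
  codes <- seq_code_matrix(seqs)
  sig <- true_profile_sigma(pspec)
  mc <- motif_code_matrix(codes, pspec$rank)
  dA <- numeric(length(seqs))
  for (k in seq_len(ncol(mc)))
    dA <- dA + sig[mc[, k] + 1L, k]
  if (with_ggg && (pspec$ggg_k1 != 0 || pspec$ggg_rest != 0)) {
    mc3 <- motif_code_matrix(codes, 3L)
    ggg_code <- 2L * 16L + 2L * 4L + 2L      # "GGG"
    ex <- true_ggg_excess(pspec)
    for (k in seq_len(ncol(mc3)))
      dA <- dA + ex[k] * (mc3[, k] == ggg_code)
  }
  dA
}

#' Generate a synthetic chip with known truth
#'
#' Draws sequences, set-level concentrations and noise according to the
#' spec, builds per-probe linearized signals
#' `log10 L^h = log10 L0^h(set) + deltaA^h(xi)` for non-specific (with
#' triple-G excess) and specific (without) hybridization, and maps
#' `L = L^N + L^S` through the Langmuir isotherm with multiplicative
#' log-normal noise. Fully reproducible from `(spec, seed)`.
#'
#' @param spec a [synthetic_chip_spec()].
#' @return list with `chip` (a `chip_data`) and `truth` (generating
#'   profiles, concentrations, per-probe L components, absent labels,
#'   (GGG)1 membership, hybridization parameters).
#' @export
generate_chip <- function(spec) {
  stopifnot(inherits(spec, "synthetic_chip_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n_sets <- spec$n_probe_sets
  n_pm <- n_sets * spec$probes_per_set
  set_id <- rep(sprintf("set%05d", seq_len(n_sets)), each = spec$probes_per_set)

  # sequences: iid bases per composition; spontaneous triple-G runs are
  # broken (real probe selection avoids them), then a (GGG)1 prefix and
  # rare internal triple-G runs are injected at controlled rates
  chars <- sample(BASES, n_pm * PROBE_LEN, replace = TRUE,
                  prob = spec$base_composition)
  seq_mat <- matrix(chars, n_pm, PROBE_LEN)
  if (spec$suppress_g_runs) {
    non_g <- setdiff(BASES, "G")
    p_non_g <- spec$base_composition[non_g] / sum(spec$base_composition[non_g])
    for (k in 3:PROBE_LEN) {
      run <- seq_mat[, k - 2] == "G" & seq_mat[, k - 1] == "G" &
        seq_mat[, k] == "G"
      if (any(run))
        seq_mat[run, k] <- sample(non_g, sum(run), replace = TRUE,
                                  prob = p_non_g)
    }
  }
  force_ggg <- runif(n_pm) < spec$ggg1_enrichment
  seq_mat[force_ggg, 1:3] <- "G"
  internal <- !force_ggg & runif(n_pm) < spec$ggg_internal_rate
  if (any(internal)) {
    at <- sample(2:(PROBE_LEN - 2), sum(internal), replace = TRUE)
    rows <- which(internal)
    for (i in seq_along(rows))
      seq_mat[rows[i], at[i]:(at[i] + 2L)] <- "G"
  }
  seqs <- do.call(paste0, as.data.frame(seq_mat, stringsAsFactors = FALSE))

  # set-level signals; absent sets carry exactly zero specific signal
  absent <- rep(FALSE, n_sets)
  n_abs <- round(spec$absent_fraction * n_sets)
  if (n_abs > 0) absent[sample.int(n_sets, n_abs)] <- TRUE
  log_L0N <- rnorm(n_sets, spec$conc_N_meanlog, spec$conc_N_sdlog)
  log_L0S <- ifelse(absent, -Inf,
                    rnorm(n_sets, spec$conc_S_meanlog, spec$conc_S_sdlog))

  build_signals <- function(sequences, specific_scale = 1) {
    dA_N <- generating_delta_A(sequences, spec$profile_spec, with_ggg = TRUE)
    dA_S <- generating_delta_A(sequences, spec$profile_spec, with_ggg = FALSE)
    si <- match(set_id, unique(set_id))
    L_N <- 10^(log_L0N[si] + dA_N)
    L_S <- ifelse(is.infinite(log_L0S[si]), 0,
                  specific_scale * 10^(log_L0S[si] + dA_S))
    list(L_N = L_N, L_S = L_S, dA_N = dA_N, dA_S = dA_S)
  }
  pm_sig <- build_signals(seqs)

  params <- hyb_params(I_min = spec$I_min, I_max = spec$I_max)
  noise_pm <- rnorm(n_pm, 0, spec$noise_sd)
  I_pm <- langmuir_intensity(pm_sig$L_N + pm_sig$L_S, params) * 10^noise_pm

  if (spec$pm_mm) {
    mm_seqs <- paste0(substr(seqs, 1, 12),
                      chartr("ACGT", "TGCA", substr(seqs, 13, 13)),
                      substr(seqs, 14, 25))
    mm_sig <- build_signals(mm_seqs, specific_scale = spec$mm_specific_factor)
    noise_mm <- rnorm(n_pm, 0, spec$noise_sd)
    I_mm <- langmuir_intensity(mm_sig$L_N + mm_sig$L_S, params) * 10^noise_mm
  }

  # grid layout: row-major; with PM/MM the MM sits directly below its PM
  n_cols <- ceiling(sqrt(if (spec$pm_mm) 2 * n_pm else n_pm))
  if (spec$pm_mm && n_cols %% 2 == 1) n_cols <- n_cols + 1L
  if (spec$pm_mm) {
    slot <- seq_len(n_pm) - 1L
    x <- slot %% n_cols
    y_pm <- (slot %/% n_cols) * 2L
    probes <- data.frame(
      probe_set_id = c(set_id, set_id),
      x = c(x, x), y = c(y_pm, y_pm + 1L),
      sequence = c(seqs, mm_seqs),
      role = rep(c("PM", "MM"), each = n_pm),
      pair_id = rep(sprintf("pair%06d", seq_len(n_pm)), 2),
      stringsAsFactors = FALSE)
    intens <- data.frame(x = probes$x, y = probes$y,
                         intensity = c(I_pm, I_mm))
  } else {
    slot <- seq_len(n_pm) - 1L
    probes <- data.frame(
      probe_set_id = set_id,
      x = slot %% n_cols, y = slot %/% n_cols,
      sequence = seqs, role = "PM", pair_id = NA_character_,
      stringsAsFactors = FALSE)
    intens <- data.frame(x = probes$x, y = probes$y, intensity = I_pm)
  }
  n_rows <- max(intens$y) + 1L
  chip <- chip_data(probes, intens, n_cols = n_cols, n_rows = n_rows)

  sets <- unique(set_id)
  ggg_any <- vapply(split(grepl("GGG", seqs, fixed = TRUE), set_id)[sets],
                    any, logical(1))
  truth <- list(
    spec = spec, params = params,
    sigma_true = true_profile_sigma(spec$profile_spec),
    ggg_excess_true = true_ggg_excess(spec$profile_spec),
    absent_sets = sets[absent], present_sets = sets[!absent],
    set_log_L0N = setNames(log_L0N, sets),
    set_log_L0S = setNames(log_L0S, sets),
    L_N = pm_sig$L_N, L_S = pm_sig$L_S,
    delta_A_N = pm_sig$dA_N, delta_A_S = pm_sig$dA_S,
    noise = noise_pm,
    ggg1_probe = force_ggg | substr(seqs, 1, 3) == "GGG",
    ggg_sets = sets[ggg_any],
    seed = spec$seed)
  list(chip = chip, truth = truth)
}
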