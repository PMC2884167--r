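test_that("Langmuir intensity has the right limits and inverse", {
  p <- hyb_params(I_min = 50, I_max = 1e4)
  expect_equal(langmuir_intensity(0, p), 50)                 # background only
  expect_lt(abs(langmuir_intensity(1e12, p) - (50 + 1e4)), 0.02)  # saturation
  # linear regime: I - I_min ~ L for L << I_max
  p0 <- hyb_params(I_min = 0, I_max = 1e4)
  expect_equal(langmuir_intensity(10, p0), 10 / (1 + 10 / 1e4))
  expect_lt(abs(langmuir_intensity(10, p0) - 9.99), 0.001)
  expect_error(langmuir_intensity(-1, p), "non-negative")

  # exact inverse on 1e4 random signals
  set.seed(1)
  L <- 10^runif(1e4, -2, 6)
  I <- langmuir_intensity(L, p)
  rel <- abs(linearize_intensity(I, p) - L) / L
  expect_lt(max(rel), 1e-10)
  expect_equal(linearize_intensity(50, p), 0)
  expect_error(linearize_intensity(50 + 1e4, p), "saturation")
  expect_error(linearize_intensity(10, p), "below")
  # monotone divergence near saturation
  near <- linearize_intensity(50 + 1e4 * c(0.9, 0.99, 0.999), p)
  expect_true(all(diff(near) > 0))
  expect_gt(near[3], 100 * near[1])
})

test_that("langmuir_intensity is strictly monotone and bounded", {
  p <- hyb_params(I_min = 30, I_max = 2e4)
  L <- sort(10^runif(500, -3, 8))
  I <- langmuir_intensity(L, p)
  expect_true(all(diff(I) > 0))
  expect_true(all(I >= 30 & I < 30 + 2e4))
})

test_that("zone background reduces to brute force and interpolates", {
  # uniform chip: background equals the constant field
  n <- 400
  probes <- tiny_probes(rand_seq(n))
  probes$x <- (seq_len(n) - 1L) %% 20L
  probes$y <- (seq_len(n) - 1L) %/% 20L
  ints <- data.frame(x = probes$x, y = probes$y, intensity = rep(100, n))
  chip <- chip_data(probes, ints)
  expect_equal(zone_background(chip, 2L, 2L), rep(100, n))

  # single zone equals the whole-chip lowest-2% mean
  set.seed(3)
  ints$intensity <- 10^runif(n, 1, 4)
  chip <- chip_data(probes, ints)
  bg <- zone_background(chip, 1L, 1L)
  brute <- mean(sort(ints$intensity)[seq_len(floor(0.02 * n))])
  expect_equal(unname(bg), rep(brute, n))

  # two zones with very different levels: monotone gradient along x
  ints$intensity <- ifelse(probes$x < 10, 50, 500) * (1 + 0.001 * probes$y)
  chip <- chip_data(probes, ints)
  bg2 <- zone_background(chip, 2L, 1L)
  prof <- tapply(bg2, ints$x, mean)
  expect_true(all(diff(prof) > 0))

  # tiny zones fall back to the whole-chip estimate with a warning
  expect_warning(zone_background(chip, 20L, 20L), "whole-chip")

  # subtraction floors at a positive constant
  cor <- subtract_background(chip, rep(1e6, n))
  expect_true(all(cor$intensities$intensity == 0.5))
})

test_that("mixture classifier recovers the absent fraction within 5 points", {
  # present sets are genuinely expressed here; when specific signals dip to
  # the non-specific floor, sets become indistinguishable by intensity
  # alone and the intensity-only stand-in over-calls (see the vignette)
  sim <- generate_chip(synthetic_chip_spec(n_probe_sets = 1200, seed = 21,
                                           conc_S_meanlog = 3.6,
                                           conc_S_sdlog = 0.4))
  chip_bc <- subtract_background(sim$chip, zone_background(sim$chip))
  cls <- classify_absent(chip_bc)
  frac <- length(cls$absent) / 1200
  expect_lt(abs(frac - 0.6), 0.05)
  # recall of truly absent sets is high
  hit <- mean(sim$truth$absent_sets %in% cls$absent)
  expect_gt(hit, 0.9)
  # on the default (overlapping) world the absent recall survives even
  # though weakly-expressed present sets inflate the called fraction
  sim2 <- generate_chip(synthetic_chip_spec(n_probe_sets = 1200, seed = 21))
  cbc2 <- subtract_background(sim2$chip, zone_background(sim2$chip))
  cls2 <- classify_absent(cbc2)
  expect_gt(mean(sim2$truth$absent_sets %in% cls2$absent), 0.9)
})

test_that("override calls are verbatim and complete", {
  sim <- generate_chip(synthetic_chip_spec(n_probe_sets = 30, seed = 2))
  sets <- unique(sim$chip$probes$probe_set_id)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(probe_set_id = sets, call = "A"), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- classify_absent(sim$chip, "override", path)
  expect_setequal(cls$absent, sets)
  expect_length(cls$present, 0)
  write.table(data.frame(probe_set_id = sets[-1], call = "A"), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(classify_absent(sim$chip, "override", path), sets[1])
})

test_that("degenerate single-set chips classify without error", {
  chip <- tiny_chip(rand_seq(5), intensities = c(10, 12, 9, 11, 10))
  cls <- classify_absent(chip)
  expect_length(c(cls$absent, cls$present), 1)
})

test_that("empirical isotherm smooths sorted log intensities", {
  n <- 200
  chip <- tiny_chip(rand_seq(n), intensities = rep(100, n),
                    sets = sprintf("s%03d", seq_len(n)))
  expr <- seq_len(n)
  expect_warning(curve <- empirical_isotherm(chip, expr, window = 1000L),
                 "window")
  expect_true(all(abs(curve$ordinate - 2) < 1e-12))     # flat at log10(100)

  set.seed(9)
  ints <- 10^runif(n, 1, 3)
  chip2 <- tiny_chip(rand_seq(n), intensities = ints,
                     sets = sprintf("s%03d", seq_len(n)))
  c1 <- empirical_isotherm(chip2, expr, window = 1L)
  expect_equal(c1$ordinate, log10(ints)[order(expr)])   # no smoothing
})

test_that("theoretical isotherm scenarios obey the plateau/inflection contract", {
  p <- hyb_params(I_min = 0, I_max = 10^4.5, K_N = 1e-4, K_S = 1, conc_N = 1)
  f <- 10^0.5
  A <- theoretical_isotherm(p, "A", log_S_range = c(-8, 6), n = 1401L)
  B <- theoretical_isotherm(p, "B", factor = f, log_S_range = c(-8, 6),
                            n = 1401L)
  C <- theoretical_isotherm(p, "C", factor = f, log_S_range = c(-8, 6),
                            n = 1401L)
  # N-range plateau raised by log10(factor), unchanged in the S-range
  expect_equal(B$ordinate[1] - A$ordinate[1], log10(f), tolerance = 1e-3)
  expect_lt(abs(B$ordinate[1401] - A$ordinate[1401]), 1e-9)
  # inflection abscissa: C shifted left of B by exactly log10(factor)
  # (identical plateaus; C(logS) == B(logS + log10 f)), and left of A
  expect_equal(isotherm_inflection(C) - isotherm_inflection(B), -log10(f),
               tolerance = 2e-3)
  expect_lt(isotherm_inflection(C), isotherm_inflection(A))
  # factor 1: all three identical
  for (sc in c("B", "C"))
    expect_equal(theoretical_isotherm(p, sc, factor = 1)$ordinate,
                 theoretical_isotherm(p, "A")$ordinate)
  expect_error(theoretical_isotherm(p, "B", factor = 0.5), "factor")
})

test_that("(GGG)1 isotherm offset appears in the N-range and vanishes in S", {
  sim <- generate_chip(synthetic_chip_spec(
    n_probe_sets = 1500, seed = 13, ggg1_enrichment = 0.05,
    profile_spec = default_paperlike_profile(2, ggg_k1 = 0.5, ggg_rest = 0)))
  tr <- sim$truth
  L <- measured_L(sim)
  # expression degree: log10 of the true specific signal per probe
  expr <- log10(pmax(tr$L_S, 1e-6))
  I <- probe_intensities(sim$chip)
  g1 <- tr$ggg1_probe
  # offsets at matched expression, referenced to the all-probe isotherm
  all_curve <- empirical_isotherm(sim$chip, expr, window = 501L)
  f <- approxfun(all_curve$abscissa, all_curve$ordinate, ties = mean,
                 rule = 2)
  d <- log10(I) - f(expr)
  # N-range (absent probes): offset near the injected 0.5
  ia <- sim$chip$probes$probe_set_id %in% tr$absent_sets
  n_off <- mean(d[ia & g1]) - mean(d[ia & !g1])
  expect_gt(n_off, 0.35)
  expect_lt(n_off, 0.65)
  # S-range: the offset vanishes once specific binding dominates
  hiS <- expr > 3.6
  s_off <- mean(d[hiS & g1]) - mean(d[hiS & !g1])
  expect_lt(abs(s_off), 0.1)
  # the (GGG)1-restricted isotherm sits above the all-probe curve in the
  # N-range
  g_curve <- suppressWarnings(
    empirical_isotherm(sim$chip, expr, subset = g1, window = 501L))
  lowS <- g_curve$abscissa < 0
  expect_gt(mean(g_curve$ordinate[lowS] -
                   f(g_curve$abscissa[lowS])), 0.3)
})
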