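test_that("motif enumeration has the right cardinalities and order", {
  cases <- list(c(1, 4, 25), c(2, 16, 24), c(3, 64, 23), c(4, 256, 22))
  for (cs in cases) {
    idx <- enumerate_motifs(cs[1])
    expect_equal(idx$n_motifs, cs[2])
    expect_equal(idx$n_pos, cs[3])
    expect_equal(idx$n_cells, cs[2] * cs[3])
  }
  expect_identical(enumerate_motifs(1)$motifs, c("A", "C", "G", "T"))
  expect_identical(enumerate_motifs(2)$motifs[1:5],
                   c("AA", "AC", "AG", "AT", "CA"))
  expect_error(enumerate_motifs(5), "rank")
  expect_error(enumerate_motifs(0), "rank")
})

test_that("experimental sensitivities are probe-set centered deviations", {
  chip <- tiny_chip(rand_seq(3), intensities = rep(1, 3))
  expect_equal(as.numeric(experimental_sensitivity(chip, c(10, 10, 10))),
               c(0, 0, 0))
  expect_equal(as.numeric(experimental_sensitivity(chip, 10^(1:3))),
               c(-1, 0, 1))
  sim <- generate_chip(synthetic_chip_spec(n_probe_sets = 100, seed = 4))
  y <- experimental_sensitivity(sim$chip, measured_L(sim))
  sums <- tapply(as.numeric(y), sim$chip$probes$probe_set_id, sum)
  expect_lt(max(abs(sums)), 1e-12)
  # singleton sets give zero and are flagged
  chip1 <- tiny_chip(rand_seq(2), c(1, 1), sets = c("a", "b"))
  y1 <- experimental_sensitivity(chip1, c(100, 200))
  expect_equal(as.numeric(y1), c(0, 0))
  expect_true(all(attr(y1, "uninformative")))
})

test_that("centered design rows sum to zero within every position block", {
  idx <- enumerate_motifs(1)
  # identical sequences in a set: indicator equals its set mean, all zero
  p_same <- tiny_probes(rep(strrep("ACGTA", 5), 4))
  D0 <- build_design(p_same, idx)
  expect_equal(max(abs(D0)), 0)

  # the textbook 2-probe example: +1/2 against -1/2 at k = 1
  p2 <- tiny_probes(c(strrep("A", 25), strrep("C", 25)))
  D2 <- build_design(p2, idx)
  expect_equal(D2[1, 1], 0.5)    # A at k=1 for the A-probe
  expect_equal(D2[1, 2], -0.5)   # C at k=1 for the A-probe
  expect_equal(D2[2, 1], -0.5)
  expect_equal(D2[2, 2], 0.5)

  set.seed(11)
  for (rank in 1:3) {
    idx <- enumerate_motifs(rank)
    probes <- tiny_probes(rand_seq(60), sets = rep(sprintf("s%d", 1:6), 10))
    D <- build_design(probes, idx)
    S <- Matrix::sparseMatrix(
      i = seq_len(idx$n_cells),
      j = rep(seq_len(idx$n_pos), each = idx$n_motifs), x = 1)
    expect_lt(max(abs(as.matrix(D %*% S))), 1e-12)
  }
})

test_that("noise-free chips are refit exactly (rank 1 and 2)", {
  for (rank in 1:2) {
    spec <- synthetic_chip_spec(
      n_probe_sets = if (rank == 1) 300L else 1000L, noise_sd = 0,
      absent_fraction = 1, seed = 40 + rank,
      profile_spec = default_paperlike_profile(rank))
    sim <- generate_chip(spec)
    fit <- suppressWarnings(fit_profiles(sim$chip, sim$truth$L_N, rank))
    expect_lt(fit$report$ssr_total, 1e-20)
    expect_lt(max(abs(fit$profile$sigma - sim$truth$sigma_true)), 1e-8)
    # per-position centering gauge holds
    expect_lt(max(abs(colSums(fit$profile$sigma))), 1e-9)
  }
})

test_that("sparse fit equals a dense minimum-norm solve on tiny chips", {
  set.seed(17)
  probes <- tiny_probes(rand_seq(200), sets = rep(sprintf("s%02d", 1:20), 10))
  ints <- data.frame(x = probes$x, y = probes$y,
                     intensity = 10^runif(200, 1.5, 3))
  chip <- chip_data(probes, ints)
  L <- ints$intensity
  fit <- suppressWarnings(fit_profiles(chip, L, 1))
  # dense oracle: SVD pseudoinverse of the dense centered design
  Dc <- as.matrix(build_design(probes, enumerate_motifs(1)))
  y <- as.numeric(experimental_sensitivity(chip, L))
  sv <- svd(Dc)
  keep <- sv$d > max(sv$d) * 1e-10
  beta <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% y) / sv$d[keep])
  expect_lt(max(abs(as.numeric(fit$profile$sigma) - as.numeric(beta))), 1e-8)
  # residual orthogonality to every design column
  res <- fit$report$residuals
  expect_lt(max(abs(t(Dc) %*% res)), 1e-8 * max(1, max(abs(y))))
})

test_that("per-position constant shifts are exact gauge directions", {
  sim <- generate_chip(synthetic_chip_spec(n_probe_sets = 150, seed = 6))
  L <- measured_L(sim)
  fit <- suppressWarnings(fit_profiles(sim$chip, L, 2))
  prof <- fit$profile
  shifted <- prof
  set.seed(8)
  shifts <- rnorm(ncol(prof$sigma))
  shifted$sigma <- sweep(prof$sigma, 2, shifts, "+")
  p1 <- gstackr:::predict_delta_A(prof, sim$chip$probes$sequence)
  p2 <- gstackr:::predict_delta_A(shifted, sim$chip$probes$sequence)
  d <- p2 - p1 - sum(shifts)
  expect_lt(max(abs(d)), 1e-9)
})

test_that("SSR is non-increasing in model rank on one ensemble", {
  sim <- generate_chip(synthetic_chip_spec(
    n_probe_sets = 600, seed = 23, absent_fraction = 1,
    profile_spec = default_paperlike_profile(2, ggg_k1 = 0.3, ggg_rest = 0.1)))
  L <- measured_L(sim)
  ssr <- vapply(1:4, function(r)
    suppressWarnings(fit_profiles(sim$chip, L, r))$report$ssr_total,
    numeric(1))
  expect_true(all(diff(ssr) <= 0))
})

test_that("fit ensembles below the parameter count are refused", {
  sim <- generate_chip(synthetic_chip_spec(n_probe_sets = 20, seed = 1))
  expect_error(fit_profiles(sim$chip, measured_L(sim), 2), "fewer probes")
  expect_error(fit_profiles(sim$chip, measured_L(sim), 2,
                            subset = character(0)), "empty")
  expect_error(fit_profiles(sim$chip, measured_L(sim), 4, mode = "S"),
               "rank 3")
})

test_that("integral sensitivities sum positions with range normalization", {
  idx <- enumerate_motifs(2)
  prof <- structure(list(rank = 2L, mode = "N", index = idx,
                         sigma = matrix(0, 16, 24,
                                        dimnames = list(idx$motifs, NULL)),
                         occupancy = matrix(1, 16, 24),
                         zero_occupancy = matrix(FALSE, 16, 24)),
                    class = "sensitivity_profile")
  expect_equal(unname(integral_sensitivity(prof)), rep(0, 16))
  # profile constant in k: reduced range with its normalization factor
  # reproduces the full-range integral
  prof$sigma[] <- rep(seq(-0.075, 0.075, by = 0.01), 24)
  full <- integral_sensitivity(prof)
  red <- integral_sensitivity(prof, k_range = 3:24)
  expect_equal(red, full, tolerance = 1e-12)
  # a k=1 spike on GG drops when the solution end is excluded
  prof$sigma["GG", 1] <- prof$sigma["GG", 1] + 1
  full2 <- integral_sensitivity(prof)
  red2 <- integral_sensitivity(prof, k_range = 3:24)
  expect_lt(red2[["GG"]], full2[["GG"]])
  expect_equal(red2[names(red2) != "GG"], full2[names(full2) != "GG"],
               tolerance = 1e-12)
  expect_error(integral_sensitivity(prof, integer(0)), "empty")
  expect_error(integral_sensitivity(prof, 0:3), "k_range")
})

test_that("profile similarity is affine-invariant and flags constants", {
  idx <- enumerate_motifs(2)
  sig <- matrix(rnorm(16 * 24, sd = 0.05), 16, 24,
                dimnames = list(idx$motifs, NULL))
  sig["CA", ] <- 2 * sig["AA", ] + 0.3          # exact affine image
  sig["GG", ] <- sig["AA", ] + c(1, rep(0, 23)) # solution-end spike
  sig["TT", ] <- 0                              # constant profile
  prof <- structure(list(rank = 2L, mode = "N", index = idx, sigma = sig,
                         occupancy = matrix(1, 16, 24),
                         zero_occupancy = matrix(FALSE, 16, 24)),
                    class = "sensitivity_profile")
  expect_equal(as.numeric(profile_similarity(prof, "AC", "AC")), 0)
  expect_equal(as.numeric(profile_similarity(prof, "CA", "AA")), 0)
  expect_gt(profile_similarity(prof, "GG", "AA"),
            profile_similarity(prof, "CA", "AA"))
  si <- profile_similarity(prof, "AA", "TT")
  expect_true(attr(si, "flagged"))
  expect_equal(as.numeric(si), 1)
  m <- profile_similarity_matrix(prof, c("AA", "CA", "GG"))
  expect_equal(unname(diag(m)), rep(0, 3))
})

test_that("profiles export to long-format TSV and report occupancy", {
  sim <- generate_chip(synthetic_chip_spec(n_probe_sets = 150, seed = 31))
  fit <- suppressWarnings(fit_profiles(sim$chip, measured_L(sim), 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(fit$profile, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 100)
  expect_equal(sum(tab$occupancy), 25 * nrow(sim$chip$probes))
})
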