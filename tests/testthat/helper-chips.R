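# Shared fixtures, all generated in code.

# a tiny deterministic chip with hand-laid probes
tiny_probes <- function(seqs, sets = NULL) {
  n <- length(seqs)
  if (is.null(sets)) sets <- rep("s1", n)
  data.frame(probe_set_id = sets, x = seq_len(n) - 1L, y = 0L,
             sequence = seqs, stringsAsFactors = FALSE)
}

tiny_chip <- function(seqs, intensities, sets = NULL) {
  p <- tiny_probes(seqs, sets)
  chip_data(p, data.frame(x = p$x, y = p$y, intensity = intensities))
}

rand_seq <- function(n, len = 25L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# random sequences guaranteed free of triple-G runs
rand_seq_nog <- function(n, len = 25L) {
  out <- rand_seq(n, len)
  while (any(hit <- grepl("GGG", out, fixed = TRUE)))
    out[hit] <- rand_seq(sum(hit), len)
  out
}

# measured linearized signals of a synthetic chip: truth L times the drawn
# multiplicative noise (the clean input contract of fit_profiles)
measured_L <- function(sim) {
  (sim$truth$L_N + sim$truth$L_S) * 10^sim$truth$noise
}

# mean log-offset of absent (GGG)1 probes vs all absent probes, computed
# from linearized signals over the given probe-set ids
ggg1_offset <- function(chip, L, sets, ggg1) {
  ia <- chip$probes$probe_set_id %in% sets
  sub <- chip
  sub$probes <- chip$probes[ia, , drop = FALSE]
  y <- as.numeric(experimental_sensitivity(sub, pmax(L[ia], 1e-300)))
  mean(y[ggg1[ia]])
}

# linearized signals recovered from a (possibly corrected) chip written on
# the background-free intensity scale
relinearize <- function(chip, I_max) {
  p <- hyb_params(I_min = 0, I_max = I_max)
  ip <- probe_intensities(chip)
  pmax(linearize_intensity(pmin(ip, I_max * 0.9999), p), 1e-300)
}
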