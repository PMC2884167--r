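# Positional- and motif-dependent sensitivity models.
#
# The model of rank r assigns a sensitivity sigma_k(b_r) to every motif b_r
# of r adjacent bases starting at sequence position k of the 25-mer. The
# per-probe sequence effect is the sum of these terms over all positions;
# probe-set centering removes the unknown (constant within a set) transcript
# concentration, and a per-position centering gauge fixes the otherwise
# undetermined additive constants.

#' Enumerate motif/position cells of a sensitivity model
#'
#' @param rank motif length r in 1..4 (single base, nearest neighbor,
#'   next-nearest neighbor, quadruple).
#' @param probe_len probe length (default 25).
#' @return object of class `motif_index`: motifs in lexicographic order
#'   over A<C<G<T, positions `1 .. probe_len - rank + 1`, and the flat
#'   cell indexing `cell = (k - 1) * 4^rank + motif`.
#' @export
enumerate_motifs <- function(rank, probe_len = 25L) {
  if (!(rank %in% 1:4)) stop("rank must be an integer in 1..4")
  n_pos <- probe_len - rank + 1L
  motifs <- do.call(paste0, rev(expand.grid(
    rep(list(BASES), rank), stringsAsFactors = FALSE)))
  motifs <- sort(motifs)   # lexicographic A<C<G<T
  structure(list(rank = as.integer(rank), probe_len = as.integer(probe_len),
                 motifs = motifs, n_motifs = length(motifs),
                 n_pos = n_pos, n_cells = length(motifs) * n_pos),
            class = "motif_index")
}

# sequence strings -> integer base-code matrix (#probes x probe_len), A=0..T=3
seq_code_matrix <- function(seqs, probe_len = 25L) {
  codes <- match(strsplit(paste(seqs, collapse = ""), "")[[1]], BASES) - 1L
  matrix(codes, ncol = probe_len, byrow = TRUE)
}

# motif code of the substring of length rank starting at each position:
# (#probes x n_pos), values in 0 .. 4^rank - 1, first base most significant
motif_code_matrix <- function(codes, rank) {
  n_pos <- ncol(codes) - rank + 1L
  out <- matrix(0L, nrow(codes), n_pos)
  for (j in seq_len(rank))
    out <- out + codes[, j:(j + n_pos - 1L), drop = FALSE] * 4L^(rank - j)
  out
}

#' Experimental probe sensitivities
#'
#' The deviation of the logged linearized signal of each probe from the
#' average over its probe set. Per-set means of the result are exactly zero;
#' singleton probe sets yield 0 and are flagged.
#'
#' @param chip a `chip_data` object.
#' @param linearized per-probe linearized signals L (> 0), aligned with
#'   `chip$probes`.
#' @return numeric vector Y^exp with attribute `uninformative` marking
#'   singleton-set probes.
#' @export
experimental_sensitivity <- function(chip, linearized) {
  if (any(linearized <= 0)) stop("linearized signals must be positive")
  y <- log10(linearized)
  set <- chip$probes$probe_set_id
  mu <- tapply(y, set, mean)
  out <- y - as.numeric(mu[set])
  n <- table(set)
  attr(out, "uninformative") <- as.numeric(n[set]) == 1
  out
}

#' Centered sparse design matrix of a sensitivity model
#'
#' One column per (motif, position) cell. The entry for probe p is the
#' motif indicator minus the within-probe-set frequency of the motif at
#' that position, so per-row sums over motifs at any fixed position vanish
#' exactly and probe-set-constant effects are projected out.
#'
#' @param probes probe annotation data.frame (rows define the ensemble).
#' @param index a [enumerate_motifs()] object.
#' @return sparse `dgCMatrix` (#probes x n_cells) with attribute
#'   `occupancy` (probe count per cell).
#' @export
build_design <- function(probes, index) {
  n <- nrow(probes)
  codes <- motif_code_matrix(seq_code_matrix(probes$sequence, index$probe_len),
                             index$rank)
  rows <- rep(seq_len(n), index$n_pos)
  cols <- as.integer(sweep(codes + 1L, 2,
                           (seq_len(index$n_pos) - 1L) * index$n_motifs, "+"))
  D <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(n, index$n_cells))
  set <- factor(probes$probe_set_id, levels = unique(probes$probe_set_id))
  B <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(set), x = 1,
                            dims = c(n, nlevels(set)))
  nset <- Matrix::colSums(B)
  Tm <- Matrix::crossprod(B, D)                       # set totals per cell
  M <- B %*% (Tm / nset)                              # per-probe set means
  Dc <- D - M
  attr(Dc, "occupancy") <- Matrix::colSums(D)
  Dc
}

# set-centering of a response vector (same projection as build_design rows)
center_by_set <- function(y, set_id) {
  mu <- tapply(y, set_id, mean)
  y - as.numeric(mu[set_id])
}

#' Fit positional-dependent sensitivity profiles
#'
#' Least-squares estimation of all `4^rank * (probe_len - rank + 1)`
#' sensitivity terms from probe-set-centered log signals (multiple linear
#' regression on the centered motif design). The per-position additive
#' constants are pure gauge (they cancel in every prediction); the solution
#' is made unique by constraining occupied cells to sum to zero at each
#' position. Cells with zero occupancy are pinned to 0 and flagged.
#'
#' @param chip a `chip_data` object.
#' @param linearized per-probe linearized signals aligned with `chip$probes`.
#' @param rank model rank 1..4 (rank 4 is refused for `mode = "S"`, where
#'   the smaller specific ensemble limits the model to rank 3).
#' @param subset logical vector over probes, or character vector of
#'   probe-set ids, selecting the fit ensemble (default: all probes).
#' @param mode `"N"` (non-specific) or `"S"` (specific); recorded in the
#'   profile and used for the rank cap.
#' @param mem_cap_cells refuse designs whose dense normal matrix would
#'   exceed this many cells squared (default 6000, comfortably above rank 4).
#' @return list with `profile` (a `sensitivity_profile`) and `report`
#'   (a `fit_report`, see [fit_report()]).
#' @export
fit_profiles <- function(chip, linearized, rank, subset = NULL,
                         mode = c("N", "S"), mem_cap_cells = 6000L) {
  mode <- match.arg(mode)
  if (mode == "S" && rank > 3)
    stop("specific-mode fits are limited to rank 3")
  index <- enumerate_motifs(rank)
  if (index$n_cells > mem_cap_cells)
    stop("design of ", index$n_cells, " cells exceeds the memory cap; ",
         "consider the NN+GGG hybrid model instead of a full high-rank fit")
  keep <- rep(TRUE, nrow(chip$probes))
  if (is.character(subset)) keep <- chip$probes$probe_set_id %in% subset
  else if (!is.null(subset)) keep <- subset
  probes <- chip$probes[keep, , drop = FALSE]
  if (nrow(probes) == 0) stop("empty probe subset")
  L <- linearized[keep]
  sub_chip <- chip
  sub_chip$probes <- probes
  y <- as.numeric(experimental_sensitivity(sub_chip, L))
  n_param <- count_parameters(rank, index$probe_len)
  if (nrow(probes) < n_param)
    stop("fewer probes (", nrow(probes), ") than independent parameters (",
         n_param, ")")
  if (nrow(probes) < 10 * n_param)
    warning("probe/parameter ratio below 10; sensitivity estimates may be noisy")
  Dc <- build_design(probes, index)
  occ <- attr(Dc, "occupancy")
  sol <- solve_centered_ls(Dc, y, occ, index)
  sigma <- matrix(0, index$n_motifs, index$n_pos,
                  dimnames = list(index$motifs, NULL))
  sigma[] <- sol$sigma
  occ_m <- matrix(occ, index$n_motifs, index$n_pos,
                  dimnames = list(index$motifs, NULL))
  profile <- structure(
    list(rank = index$rank, mode = mode, index = index,
         sigma = sigma, occupancy = occ_m,
         zero_occupancy = occ_m == 0, degenerate = sol$degenerate),
    class = "sensitivity_profile")
  res <- y - sol$fitted
  report <- fit_report(rank = rank, residuals = res, fitted = sol$fitted,
                       y_exp = y, probes = probes, param_count = n_param)
  list(profile = profile, report = report)
}

# Minimum-norm least-squares solve of the centered design. Positional
# motif designs are structurally rank-deficient beyond the per-position
# constants (e.g. single-base marginals of adjacent nearest-neighbor
# positions coincide), so the solution is computed from the eigen
# decomposition of the normal matrix: the minimum-norm solution is
# orthogonal to the full null space, which in particular makes the
# per-position sums of occupied cells vanish. One refinement step keeps
# noise-free recovery at ~1e-12; an explicit final re-centering absorbs
# the last rounding.
solve_centered_ls <- function(Dc, y, occ, index) {
  live <- which(occ > 0)
  X <- Dc[, live, drop = FALSE]
  XtX <- as.matrix(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, y))
  ev <- eigen(XtX, symmetric = TRUE)
  if (max(ev$values) <= nrow(X) * 1e-12) {
    # all-zero centered design (e.g. identical sequences within every set)
    return(list(sigma = numeric(index$n_cells), fitted = numeric(nrow(X)),
                degenerate = TRUE))
  }
  pos <- ev$values > max(ev$values) * 1e-10
  Vp <- ev$vectors[, pos, drop = FALSE]
  ginv_mult <- function(v) as.numeric(Vp %*% (crossprod(Vp, v) / ev$values[pos]))
  beta <- ginv_mult(Xty)
  beta <- beta + ginv_mult(Xty - as.numeric(XtX %*% beta))
  degenerate <- sum(!pos) > structural_null_dim(index, length(live))
  # exact gauge: re-center occupied cells at each position
  pos_of <- rep(seq_len(index$n_pos), each = index$n_motifs)[live]
  shift <- tapply(beta, pos_of, mean)
  beta <- beta - as.numeric(shift[pos_of])
  sigma <- numeric(index$n_cells)
  sigma[live] <- beta
  list(sigma = sigma, fitted = as.numeric(X %*% beta),
       degenerate = degenerate)
}

# expected null-space dimension of a fully occupied design (per-position
# constants plus lower-order marginal collinearities); exceeding it flags
# a degenerate probe ensemble. Computed lazily from the canonical design
# and cached per (rank, n_live).
structural_null_dim <- function(index, n_live) {
  if (n_live < index$n_cells) return(Inf)  # partial occupancy: no reference
  key <- paste0("nulldim_r", index$rank)
  if (!is.null(.gstackr_cache[[key]])) return(.gstackr_cache[[key]])
  nd <- ncol(canonical_null_basis(index$rank))
  .gstackr_cache[[key]] <- nd
  nd
}

.gstackr_cache <- new.env(parent = emptyenv())

# Orthonormal basis of the structural null space of the rank-r positional
# model: directions sigma for which the sequence effect is the same
# constant for every possible probe sequence (and which therefore cancel
# from every probe-set-centered prediction). Determined numerically from
# a large fixed pseudo-random sequence ensemble; cached per rank.
canonical_null_basis <- function(rank) {
  key <- paste0("nullbasis_r", rank)
  if (!is.null(.gstackr_cache[[key]])) return(.gstackr_cache[[key]])
  index <- enumerate_motifs(rank)
  n_seq <- max(4096L, 8L * index$n_cells)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(20100427L)
  codes <- matrix(sample.int(4L, n_seq * index$probe_len, replace = TRUE) - 1L,
                  n_seq, index$probe_len)
  mc <- matrix(0L, n_seq, index$n_pos)
  for (j in seq_len(rank))
    mc <- mc + codes[, j:(j + index$n_pos - 1L), drop = FALSE] * 4L^(rank - j)
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(n_seq), index$n_pos),
    j = as.integer(sweep(mc + 1L, 2,
                         (seq_len(index$n_pos) - 1L) * index$n_motifs, "+")),
    x = 1, dims = c(n_seq, index$n_cells))
  cm <- Matrix::colMeans(D)
  XtX <- as.matrix(Matrix::crossprod(D)) / n_seq - tcrossprod(cm)
  ev <- eigen(XtX, symmetric = TRUE)
  null <- ev$values < max(ev$values) * 1e-8
  basis <- ev$vectors[, null, drop = FALSE]
  .gstackr_cache[[key]] <- basis
  basis
}

#' Canonical (minimum-norm) representative of a sensitivity matrix
#'
#' Projects a motif x position sigma matrix onto the orthogonal complement
#' of the model's structural null space. Two sigma matrices that predict
#' identical probe sensitivities have the same canonical representative,
#' which is also what [fit_profiles()] returns; comparing profiles in this
#' gauge is therefore meaningful.
#'
#' @param sigma motif x position matrix (rows in lexicographic motif order).
#' @param rank model rank.
#' @return matrix of the same shape.
#' @export
canonical_sigma <- function(sigma, rank) {
  basis <- canonical_null_basis(rank)
  v <- as.numeric(sigma)
  out <- v - as.numeric(basis %*% crossprod(basis, v))
  matrix(out, nrow(sigma), ncol(sigma), dimnames = dimnames(sigma))
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("sensitivity_profile: rank %d (%s mode), %d motifs x %d positions; %d empty cells%s\n",
              x$rank, x$mode, nrow(x$sigma), ncol(x$sigma),
              sum(x$zero_occupancy),
              if (isTRUE(x$degenerate)) "; DEGENERATE design" else ""))
  invisible(x)
}

#' Look up sensitivity terms of one motif
#'
#' @param profile a `sensitivity_profile`.
#' @param motif motif string, e.g. `"GG"`.
#' @return numeric vector over positions.
#' @export
profile_sigma <- function(profile, motif) {
  if (!motif %in% rownames(profile$sigma))
    stop("motif ", motif, " not in a rank-", profile$rank, " profile")
  profile$sigma[motif, ]
}

#' Integral (position-summed) sensitivities
#'
#' Sums the positional terms of every motif over all positions or a
#' reduced positional range; reduced-range sums are rescaled by
#' `full_width / reduced_width` for comparability with full sums (used,
#' e.g., to correlate nearest-neighbor terms with solution free energies
#' while excluding the solution-end guanine region).
#'
#' @param profile a `sensitivity_profile`.
#' @param k_range integer vector of positions (default: all).
#' @return named numeric vector, one value per motif.
#' @export
integral_sensitivity <- function(profile, k_range = NULL) {
  n_pos <- ncol(profile$sigma)
  if (is.null(k_range)) k_range <- seq_len(n_pos)
  if (length(k_range) == 0) stop("empty position range")
  if (any(k_range < 1 | k_range > n_pos)) stop("k_range outside 1..", n_pos)
  norm <- n_pos / length(k_range)
  rowSums(profile$sigma[, k_range, drop = FALSE]) * norm
}

#' Shape similarity of two sensitivity profiles
#'
#' Least-squares match of sigma(b1) by an affine transform of sigma(b2)
#' (scale a, shift c), normalized by the positional variance of sigma(b1):
#' `SI = 0` means a perfect affine match, `SI = 1` no linear relation.
#' A constant sigma(b2) makes the scale undefined; the score is then
#' computed with `a = 0` and flagged.
#'
#' @param profile a `sensitivity_profile`.
#' @param b1,b2 motif strings of the profile's rank.
#' @return similarity score in `[0, 1]`, with attribute `flagged` if the
#'   reference motif profile is constant.
#' @export
profile_similarity <- function(profile, b1, b2) {
  s1 <- profile_sigma(profile, b1)
  s2 <- profile_sigma(profile, b2)
  tss <- sum((s1 - mean(s1))^2)
  if (tss == 0) return(structure(0, flagged = FALSE))
  if (var(s2) == 0) {
    rss <- sum((s1 - mean(s1))^2)
    return(structure(rss / tss, flagged = TRUE))
  }
  a <- stats::cov(s1, s2) / var(s2)
  c0 <- mean(s1) - a * mean(s2)
  rss <- sum((s1 - a * s2 - c0)^2)
  structure(rss / tss, flagged = FALSE)
}

#' All-pairs profile similarity matrix
#'
#' @param profile a `sensitivity_profile`.
#' @param motifs motifs to compare (default: all of the profile).
#' @return symmetric-layout numeric matrix of [profile_similarity()] scores
#'   (rows = b1, columns = b2; not symmetric in general).
#' @export
profile_similarity_matrix <- function(profile, motifs = rownames(profile$sigma)) {
  out <- matrix(NA_real_, length(motifs), length(motifs),
                dimnames = list(motifs, motifs))
  for (i in motifs) for (j in motifs)
    out[i, j] <- as.numeric(profile_similarity(profile, i, j))
  out
}

#' Export / import a sensitivity profile as TSV
#'
#' Long format: rank, motif, position, sigma, occupancy.
#'
#' @param profile a `sensitivity_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  long <- data.frame(
    rank = profile$rank, mode = profile$mode,
    motif = rep(rownames(profile$sigma), ncol(profile$sigma)),
    position = rep(seq_len(ncol(profile$sigma)), each = nrow(profile$sigma)),
    sigma = as.numeric(profile$sigma),
    occupancy = as.numeric(profile$occupancy))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
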