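# Fluctuation observables derived from a mode set.
#
# All fluctuation amplitudes use the convention k_B T / gamma = 1, so MSFs,
# ADP tensors and distance fluctuations are in arbitrary units proportional
# to Angstrom^2; the least-squares scale from fit_experimental_b() maps
# them onto the crystallographic scale.

.check_modes <- function(m) {
  stopifnot(inherits(m, "anm_modes"))
  if (!length(m$eigenvalues) || !ncol(m$vectors)) {
    abort_argument("empty mode set")
  }
  if (anyNA(m$eigenvalues)) {
    abort_argument("mode set carries no eigenvalues (imported without an eigenvalue row)")
  }
  if (any(m$eigenvalues <= 0)) abort_argument("non-positive eigenvalue in mode set")
  invisible(m)
}

# per-node 3-vector blocks of column k: rows 3i-2 .. 3i
.node_rows <- function(i) (3L * (i - 1L) + 1L):(3L * i)

#' Per-node mean-square fluctuations and theoretical B-factors
#'
#' `msf_i = sum_k (1 / lambda_k) * |u_{k,i}|^2` over the modes in the set,
#' where `u_{k,i}` is the 3-component sub-vector of node i; the theoretical
#' B-factor is `(8 * pi^2 / 3) * msf_i`.
#'
#' @param m an `anm_modes` with eigenvalues.
#' @return An `anm_fluct` data.frame with columns `node`, `msf`, `b_theory`.
#' @export
square_fluctuations <- function(m) {
  .check_modes(m)
  W <- m$vectors^2 / rep(m$eigenvalues, each = nrow(m$vectors))
  per_coord <- rowSums(W)
  msf <- colSums(matrix(per_coord, nrow = 3))
  out <- data.frame(node = seq_len(m$N) - 1L, msf = msf,
                    b_theory = (8 * pi^2 / 3) * msf)
  class(out) <- c("anm_fluct", "data.frame")
  out
}

#' Least-squares scale and Pearson correlation against experimental B
#'
#' Finds the scale `s` minimizing `sum (s * b_theory_i - b_exp_i)^2` in
#' closed form (`s = <b_theory, b_exp> / <b_theory, b_theory>`) and the
#' Pearson correlation `r`, which is scale-invariant.
#'
#' @param profile an `anm_fluct` from [square_fluctuations()].
#' @param b_exp experimental B-factors, one per node (Angstrom^2).
#' @param offset also fit an additive offset (`b_exp ~ s * b_theory + c`)?
#'   Default is the scale-only fit.
#' @return List with `scale`, `r`, and `offset` (0 unless requested).
#' @export
fit_experimental_b <- function(profile, b_exp, offset = FALSE) {
  stopifnot(inherits(profile, "anm_fluct"))
  bt <- profile$b_theory
  if (length(b_exp) != length(bt)) {
    abort_dimension(sprintf("b_exp has %d values for %d nodes",
                            length(b_exp), length(bt)))
  }
  if (sd(b_exp) == 0 || sd(bt) == 0) {
    abort_argument("undefined correlation: zero-variance B-factors")
  }
  if (offset) {
    fit <- stats::lm.fit(cbind(1, bt), b_exp)
    s <- unname(fit$coefficients[2]); c0 <- unname(fit$coefficients[1])
  } else {
    s <- sum(bt * b_exp) / sum(bt^2); c0 <- 0
  }
  list(scale = s, r = cor(bt, b_exp), offset = c0)
}

#' Per-node anisotropic displacement (ADP) tensors
#'
#' `U_i = sum_k (1 / lambda_k) * (u_{k,i} %o% u_{k,i})`: the 3x3 positional
#' covariance of node i under the harmonic ensemble, same unit convention
#' as the mean-square fluctuations (`trace(U_i) = msf_i`).
#'
#' @param m an `anm_modes` with eigenvalues.
#' @return An `anm_adps`: list with `tensors` (list of 3x3 matrices).
#' @export
adp_tensors <- function(m) {
  .check_modes(m)
  inv_l <- 1 / m$eigenvalues
  tensors <- lapply(seq_len(m$N), function(i) {
    B <- m$vectors[.node_rows(i), , drop = FALSE]  # 3 x k
    U <- B %*% (inv_l * t(B))
    (U + t(U)) / 2
  })
  structure(list(tensors = tensors, N = m$N), class = "anm_adps")
}

# scalar covariances cov_ij = sum_k (1/lambda_k) u_{k,i} . u_{k,j}
.mode_covariance <- function(m) {
  k <- length(m$eigenvalues)
  n <- m$N
  # stack per-node blocks: (N x 3k) matrix, then weighted inner products
  V <- m$vectors
  C <- matrix(0, n, n)
  for (kk in seq_len(k)) {
    u <- matrix(V[, kk], nrow = 3)      # 3 x N
    C <- C + crossprod(u) / m$eigenvalues[kk]
  }
  (C + t(C)) / 2
}

#' Cross-correlation map of node motions
#'
#' `C_ij = cov_ij / sqrt(msf_i * msf_j)` with
#' `cov_ij = sum_k (1/lambda_k) u_{k,i} . u_{k,j}`.  Values near +1 mark
#' node pairs moving in concert, near -1 in anti-phase.
#'
#' @param m an `anm_modes` with eigenvalues.
#' @return N x N numeric matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
cross_correlation_map <- function(m) {
  .check_modes(m)
  C <- .mode_covariance(m)
  msf <- diag(C)
  if (any(msf <= 0)) {
    abort_argument(sprintf("undefined correlation: node %d has zero fluctuation",
                           which(msf <= 0)[1] - 1L))
  }
  D <- sqrt(msf)
  out <- C / (D %o% D)
  diag(out) <- 1
  pmin(pmax(out, -1), 1)
}

#' Inter-node distance-fluctuation map
#'
#' `D_ij = msf_i + msf_j - 2 * cov_ij`: the mean-square fluctuation of the
#' relative displacement vector of nodes i and j.  Small values flag pairs
#' that move as a rigid unit; large values flag decoupled pairs.
#'
#' @param m an `anm_modes` with eigenvalues.
#' @return N x N nonnegative symmetric matrix with zero diagonal.
#' @export
distance_fluctuation_map <- function(m) {
  .check_modes(m)
  C <- .mode_covariance(m)
  msf <- diag(C)
  D <- outer(msf, msf, "+") - 2 * C
  D <- pmax((D + t(D)) / 2, 0)
  diag(D) <- 0
  D
}

#' Animate one normal mode as a multi-frame trajectory
#'
#' Frame f (f = 0..n_frames-1) displaces the input coordinates by
#' `a * sin(2*pi*f / n_frames)` along the unit mode vector, with the
#' prefactor `a` chosen so the maximum per-node displacement over the whole
#' cycle equals `amplitude`.  Frame 0 is the input structure exactly.
#'
#' @param nodes the `anm_nodes` the modes were computed for.
#' @param m an `anm_modes`.
#' @param mode_index 1-based index into the mode set.
#' @param amplitude peak per-node displacement in Angstrom.
#' @param n_frames frames per full period.
#' @param thermal_amplitude scale the excursion by `1/sqrt(lambda)` instead
#'   of normalizing the peak displacement (relative amplitudes across modes).
#' @return An `anm_trajectory` for [write_xyz_trajectory()].
#' @export
animate_mode <- function(nodes, m, mode_index, amplitude = 2.0,
                         n_frames = 20, thermal_amplitude = FALSE) {
  stopifnot(inherits(nodes, "anm_nodes"), inherits(m, "anm_modes"))
  if (nodes$N != m$N) abort_dimension("node set and mode set sizes differ")
  k <- length(m$eigenvalues)
  if (!is.numeric(mode_index) || length(mode_index) != 1 ||
      mode_index < 1 || mode_index > k || mode_index != round(mode_index)) {
    abort_argument(sprintf("mode_index must be in 1..%d", k))
  }
  if (n_frames < 2) abort_argument("n_frames must be >= 2")
  u <- matrix(m$vectors[, mode_index], ncol = 3, byrow = TRUE)  # N x 3
  disp <- sqrt(rowSums(u^2))
  phases <- sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
  if (thermal_amplitude) {
    lam <- m$eigenvalues[mode_index]
    if (is.na(lam)) abort_argument("thermal amplitude needs eigenvalues")
    a <- amplitude / sqrt(lam)
  } else {
    a <- amplitude / (max(abs(phases)) * max(disp))
  }
  R0 <- as.matrix(nodes$nodes[, c("x", "y", "z")])
  frames <- lapply(seq_len(n_frames), function(f) {
    R0 + a * phases[f] * u
  })
  comments <- sprintf("frame %d mode %d amplitude %.4f", seq_len(n_frames) - 1L,
                      mode_index, amplitude)
  trajectory(nodes$nodes$element, frames, comments)
}

#' Write the per-node fluctuation profile as TSV
#'
#' Columns: node index, chain, residue number, atom name, msf, b_theory and
#' (when available) experimental B.
#'
#' @param profile an `anm_fluct`.
#' @param nodes matching `anm_nodes` (identity columns and experimental B).
#' @param file optional output path.
#' @param fmt `sprintf` format for the numeric columns.
#' @return Character vector of lines (invisibly when `file` given).
#' @export
write_fluct_tsv <- function(profile, nodes, file = NULL, fmt = "%.4f") {
  stopifnot(inherits(profile, "anm_fluct"), inherits(nodes, "anm_nodes"))
  if (nrow(profile) != nodes$N) abort_dimension("profile/node count mismatch")
  nd <- nodes$nodes
  out <- c("node\tchain\tresno\tname\tmsf\tb_theory\tb_exp",
           sprintf(paste0("%d\t%s\t%d\t%s\t", fmt, "\t", fmt, "\t", fmt),
                   profile$node, nd$chain_id, nd$res_no, nd$name,
                   profile$msf, profile$b_theory, nd$b_exp))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}
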