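# Eigendecomposition of the network Hessian and mode-set handling.
#
# A connected 3-D network has exactly six zero eigenvalues (rigid-body
# translations/rotations); the low-frequency nonzero modes are the soft
# collective motions.  Two solver routes are provided: full dense
# decomposition, and a sparse shift-invert Lanczos that extracts only the
# smallest eigenpairs; both must agree (tested property).

.ZERO_REL_TOL <- 1e-8
.ZERO_ABS_TOL <- 1e-10

# largest eigenvalue estimate by power iteration (sparse-friendly)
.lambda_max_est <- function(H, iters = 80, seed_vec = NULL) {
  n <- nrow(H)
  v <- if (is.null(seed_vec)) rep(1, n) + sin(seq_len(n)) else seed_vec
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(iters)) {
    w <- as.numeric(H %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lam <- nw
  }
  lam
}

# deterministic sign convention: largest-|component| entry made positive
.fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

# Lanczos with full reorthogonalization on the operator (H + sigma I)^{-1}.
# Returns the `nev` algebraically smallest eigenpairs of H.
.lanczos_smallest <- function(H, nev, lam_max) {
  n <- nrow(H)
  sigma <- max(lam_max * 1e-6, 1e-12)
  A <- H + Matrix::Diagonal(n, sigma)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  opinv <- function(x) as.numeric(Matrix::solve(ch, x, system = "A"))

  m_max <- min(n, max(4 * nev + 40, 80))
  # deterministic start vector
  v1 <- sin(seq_len(n) * 0.7) + 0.5
  v1 <- v1 / sqrt(sum(v1^2))

  V <- matrix(0, n, m_max)
  alpha <- numeric(m_max); beta <- numeric(m_max)
  V[, 1] <- v1
  res_tol <- max(lam_max * 1e-11, 1e-13)
  m_used <- m_max
  for (j in seq_len(m_max)) {
    w <- opinv(V[, j])
    if (j > 1) w <- w - beta[j - 1] * V[, j - 1]
    alpha[j] <- sum(w * V[, j])
    w <- w - alpha[j] * V[, j]
    # full reorthogonalization (twice for stability)
    for (rep in 1:2) {
      w <- w - V[, 1:j, drop = FALSE] %*% crossprod(V[, 1:j, drop = FALSE], w)
    }
    b <- sqrt(sum(w^2))
    if (j == m_max || b < 1e-14) { m_used <- j; break }
    beta[j] <- b
    V[, j + 1] <- as.numeric(w) / b
  }
  Tm <- diag(alpha[1:m_used], m_used, m_used)
  if (m_used > 1) {
    idx <- cbind(1:(m_used - 1), 2:m_used)
    Tm[idx] <- beta[1:(m_used - 1)]
    Tm[idx[, 2:1, drop = FALSE]] <- beta[1:(m_used - 1)]
  }
  te <- eigen(Tm, symmetric = TRUE)
  # largest Ritz values of (H + sigma I)^{-1}  <->  smallest eigenvalues of H
  take <- seq_len(min(nev, m_used))
  theta <- te$values[take]
  Y <- V[, 1:m_used, drop = FALSE] %*% te$vectors[, take, drop = FALSE]
  lam <- 1 / theta - sigma
  ord <- order(lam)
  lam <- lam[ord]; Y <- Y[, ord, drop = FALSE]
  # Rayleigh quotient refinement on H itself
  for (k in seq_along(lam)) {
    y <- Y[, k]; y <- y / sqrt(sum(y^2)); Y[, k] <- y
    lam[k] <- sum(y * as.numeric(H %*% y))
  }
  list(values = lam, vectors = Y)
}

#' Compute low-frequency normal modes of the Hessian
#'
#' Returns the `n_modes` smallest nonzero eigenpairs.  Eigenvalues below
#' `max(1e-8 * lambda_max, 1e-10)` are classified as rigid-body (zero)
#' modes, counted and excluded.  A connected network must yield exactly six
#' of them; anything else raises a disconnected/degenerate-network error
#' unless `allow_rigid_mismatch = TRUE`, which downgrades it to a warning.
#'
#' `solver = "auto"` uses the dense decomposition up to 3N = 1500 and the
#' sparse shift-invert Lanczos beyond; the two routes agree to tight
#' tolerance (a tested invariant).  Eigenvector signs are fixed so each
#' vector's largest-magnitude component is positive.
#'
#' @param h an `anm_hessian`.
#' @param n_modes number of nonzero modes to return (default 20, the
#'   classical fixed mode count).
#' @param solver `"auto"`, `"dense"` or `"subset"`.
#' @param allow_rigid_mismatch proceed with a warning when the zero-mode
#'   count is not six.
#' @return An `anm_modes` object: `eigenvalues` (ascending), `vectors`
#'   (3N x m, orthonormal columns), `N`, `n_zero_skipped`, `source`.
#' @examples
#' s <- parse_pdb(make_ca_chain(30, seed = 1))
#' h <- build_hessian(assign_ranges(select_nodes(s)))
#' m <- compute_modes(h, n_modes = 5)
#' m$eigenvalues
#' @export
compute_modes <- function(h, n_modes = 20,
                          solver = c("auto", "dense", "subset"),
                          allow_rigid_mismatch = FALSE) {
  stopifnot(inherits(h, "anm_hessian"))
  solver <- match.arg(solver)
  n3 <- 3L * h$N
  if (!is.numeric(n_modes) || length(n_modes) != 1 || n_modes < 1 ||
      n_modes != round(n_modes)) {
    abort_argument("n_modes must be a positive integer")
  }
  # a two-node (necessarily collinear) system has 5 rigid modes and one
  # internal stretch mode, so the usual 3N - 6 bound would forbid it
  max_modes <- if (h$N == 2L) 1L else n3 - 6L
  if (n_modes > max_modes) {
    abort_argument(sprintf("n_modes (%d) exceeds the %d internal modes of this system",
                           n_modes, max_modes))
  }
  if (solver == "auto") solver <- if (n3 <= 1500) "dense" else "subset"

  if (solver == "dense") {
    e <- eigen(as.matrix(h$H), symmetric = TRUE)
    lam <- rev(e$values)
    V <- e$vectors[, rev(seq_len(n3)), drop = FALSE]
    lam_max <- max(lam)
    tol <- max(.ZERO_REL_TOL * lam_max, .ZERO_ABS_TOL)
    n_zero <- sum(lam < tol)
    nz <- which(lam >= tol)
    take <- nz[seq_len(min(n_modes, length(nz)))]
    values <- lam[take]
    vectors <- V[, take, drop = FALSE]
  } else {
    lam_max <- .lambda_max_est(h$H)
    # request enough pairs to cover rigid modes of up to two components
    nev <- min(n3, n_modes + 14L)
    ls <- .lanczos_smallest(h$H, nev, lam_max)
    tol <- max(.ZERO_REL_TOL * lam_max, .ZERO_ABS_TOL)
    n_zero <- sum(ls$values < tol)
    nz <- which(ls$values >= tol)
    if (length(nz) < n_modes) {
      ls <- .lanczos_smallest(h$H, min(n3, n_modes + n_zero + 10L), lam_max)
      n_zero <- sum(ls$values < tol)
      nz <- which(ls$values >= tol)
    }
    take <- nz[seq_len(min(n_modes, length(nz)))]
    values <- ls$values[take]
    vectors <- ls$vectors[, take, drop = FALSE]
  }

  if (n_zero != 6) {
    msg <- sprintf(paste0("disconnected or degenerate network: %d rigid-body ",
                          "modes found (expected 6)"), n_zero)
    if (allow_rigid_mismatch) warning(msg, call. = FALSE)
    else abort_disconnected(msg)
  }
  if (length(values) < n_modes) {
    abort_argument(sprintf("only %d nonzero modes available (requested %d)",
                           length(values), n_modes))
  }

  vectors <- .fix_signs(vectors)
  structure(
    list(N = h$N, eigenvalues = values, vectors = vectors,
         n_zero_skipped = n_zero, source = "computed"),
    class = "anm_modes"
  )
}

#' @export
print.anm_modes <- function(x, ...) {
  cat(sprintf("<anm_modes> %s, N = %d, %d modes, %d zero modes skipped\n",
              x$source, x$N, length(x$eigenvalues), x$n_zero_skipped))
  if (length(x$eigenvalues)) {
    cat("  lambda:", paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "),
        if (length(x$eigenvalues) > 5) "...\n" else "\n")
  }
  invisible(x)
}

#' Import externally computed mode vectors
#'
#' Accepts a numeric matrix whose columns are candidate mode vectors of
#' length 3N for the given node set; an optional extra first row is read as
#' eigenvalues (the layout written by [write_modes()]).  Vectors are
#' normalized to unit length.  Mutual orthogonality is not enforced — a
#' notice is emitted when the largest off-diagonal overlap exceeds 1e-3.
#'
#' @param m numeric matrix (3N x k, or (3N+1) x k with an eigenvalue row),
#'   or a path to a whitespace-delimited matrix file.
#' @param nodes the `anm_nodes` the vectors must match.
#' @return An `anm_modes` with `source = "imported"`; eigenvalues are `NA`
#'   when the input carries none.
#' @export
import_external_modes <- function(m, nodes) {
  stopifnot(inherits(nodes, "anm_nodes"))
  if (is.character(m)) m <- read_matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) abort_parse("mode input must be a numeric matrix")
  n3 <- 3L * nodes$N
  values <- rep(NA_real_, ncol(m))
  if (nrow(m) == n3 + 1L) {
    values <- m[1, ]
    m <- m[-1, , drop = FALSE]
  }
  if (nrow(m) != n3) {
    abort_dimension(sprintf(
      "mode vectors have %d rows but the node set requires 3N = %d", nrow(m), n3))
  }
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) abort_argument("zero-length mode vector in import")
  V <- sweep(m, 2, nrm, "/")
  if (ncol(V) > 1) {
    G <- abs(crossprod(V))
    diag(G) <- 0
    if (max(G) > 1e-3) {
      anm_notify(sprintf("imported modes are not mutually orthogonal (max overlap %.3g)",
                         max(G)))
    }
  }
  structure(
    list(N = nodes$N, eigenvalues = unname(values), vectors = .fix_signs(V),
         n_zero_skipped = 0L, source = "imported"),
    class = "anm_modes"
  )
}

#' Overlap matrix between two mode sets
#'
#' Entry (k, l) is the absolute inner product between mode k of `a` and
#' mode l of `b`; 1 means identical collective motions, 0 orthogonal ones.
#'
#' @param a,b `anm_modes` over the same number of nodes.
#' @return Numeric matrix with entries in `[0, 1]`.
#' @export
mode_overlap <- function(a, b) {
  stopifnot(inherits(a, "anm_modes"), inherits(b, "anm_modes"))
  if (a$N != b$N) {
    abort_dimension(sprintf("mode sets span different systems (N = %d vs %d)",
                            a$N, b$N))
  }
  pmin(abs(crossprod(a$vectors, b$vectors)), 1)
}

#' Write a mode set as a plain-text matrix
#'
#' Layout: a `# rows cols` header, one row of eigenvalues, then the 3N x m
#' vector matrix.  [import_external_modes()] reads this layout back.
#'
#' @param m an `anm_modes`.
#' @param file optional output path.
#' @param fmt `sprintf` format for entries.
#' @return Character vector of lines (invisibly when `file` given).
#' @export
write_modes <- function(m, file = NULL, fmt = "%.6e") {
  stopifnot(inherits(m, "anm_modes"))
  mat <- rbind(m$eigenvalues, m$vectors)
  write_matrix(mat, file = file, fmt = fmt)
}
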