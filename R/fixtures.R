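# Deterministic toy-structure generators in PDB format.
#
# Geometry is schematic (the network model depends only on node positions
# and identities, not on stereochemistry); determinism is part of the
# contract: identical arguments + seed give byte-identical output.

# run fn with a local RNG state, leaving the caller's stream untouched
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.atom_record <- function(serial, name, resn, chain, resno, x, y, z, b,
                         record = "ATOM", element = "C") {
  .fmt_atom_line(record, serial, name, "", resn, chain, resno, "",
                 x, y, z, 1, b, element)
}

# Backbone curve for toy chains: a spherical spiral with ~4 A turn
# separation, sized so n points at the given spacing fill the sphere.  This
# keeps large fixtures compact (globular, like a folded protein) instead of
# rod-like, so their softest internal modes stay well separated from the
# rigid-body modes.  A two-point chain degenerates to a straight x-axis
# segment (the analytic two-node system).
.curve_points <- function(n, spacing) {
  if (n <= 2) {
    return(cbind(x = (seq_len(n) - 1) * spacing, y = rep(0, n), z = rep(0, n)))
  }
  h <- 4.0
  R <- max(sqrt(n * spacing * h / (4 * pi)), spacing) * 1.1
  cc <- 2 * pi * R / h
  th <- seq(0, pi, length.out = 20001)
  speed <- R * sqrt(1 + cc^2 * sin(th)^2)
  s <- c(0, cumsum((speed[-1] + speed[-length(th)]) / 2 * diff(th)))
  theta <- stats::approx(s, th, xout = (seq_len(n) - 1) * spacing)$y
  phi <- cc * theta
  cbind(x = R * sin(theta) * cos(phi),
        y = R * sin(theta) * sin(phi),
        z = R * cos(theta))
}

#' Generate a toy C-alpha chain as PDB text
#'
#' `n` alanine residues with CA atoms at the given consecutive spacing along
#' a compact 3-D curve (a spherical spiral, so large chains are globular
#' rather than rod-like), jittered in all three axes — which guarantees a
#' non-collinear and, at the default spacing, connected network for
#' `n >= 3`.  `n = 2` with zero jitter gives two atoms on the x-axis: the
#' analytic two-node system.  The B-factor column carries a smooth
#' synthetic profile.
#'
#' @param n number of residues (>= 2).
#' @param spacing consecutive-CA spacing in Angstrom.
#' @param jitter uniform jitter half-width per axis, Angstrom.
#' @param seed RNG seed; same arguments + seed give byte-identical text.
#' @return Character vector of PDB lines.
#' @examples
#' s <- parse_pdb(make_ca_chain(10, seed = 42))
#' @export
make_ca_chain <- function(n, spacing = 3.8, jitter = 0.5, seed = 0) {
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    abort_argument("n must be an integer >= 2")
  }
  .with_seed(seed, function() {
    xyz <- .curve_points(n, spacing)
    if (jitter > 0) {
      xyz <- xyz + matrix(runif(3 * n, -jitter, jitter), n, 3)
    }
    b <- 10 + 5 * sin(2 * pi * seq_len(n) / max(n, 2))
    c(vapply(seq_len(n), function(i) {
      .atom_record(i, "CA", "ALA", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3], b[i])
    }, character(1)), "END")
  })
}

#' Generate a toy protein / nucleic-acid / ligand complex as PDB text
#'
#' A CA-only protein chain (chain A), a mock nucleotide chain (chain B,
#' alternating DA/DT) where each residue carries P, C4' and C2 atoms except
#' the 5'-terminal residue which lacks P, one multi-atom HETATM ligand
#' (chain C, residue LIG) and one water (HOH).  The components are laid out
#' so everything stays within contact range of the default scheme.
#'
#' @param n_res protein residues (CA nodes).
#' @param n_nt nucleotides (3 nodes each, 2 for the first).
#' @param n_lig ligand heavy atoms.
#' @param seed RNG seed; deterministic output.
#' @return Character vector of PDB lines.
#' @examples
#' s <- parse_pdb(make_mixed_complex(3, 2, 4, seed = 7))
#' @export
make_mixed_complex <- function(n_res, n_nt, n_lig, seed = 0) {
  counts <- c(n_res, n_nt, n_lig)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 2) {
    abort_argument("need nonnegative counts with n_res + n_nt + n_lig >= 2")
  }
  .with_seed(seed, function() {
    lines <- character(0)
    serial <- 0L
    jit <- function(k) runif(k, -0.3, 0.3)
    add <- function(name, resn, chain, resno, x, y, z, record = "ATOM",
                    element = "C") {
      serial <<- serial + 1L
      lines <<- c(lines, .atom_record(serial, name, resn, chain, resno,
                                      x, y, z, 15, record, element))
    }
    if (n_res > 0) {
      x <- (seq_len(n_res) - 1) * 3.8 + jit(n_res)
      y <- jit(n_res); z <- jit(n_res)
      for (i in seq_len(n_res)) add("CA", "ALA", "A", i, x[i], y[i], z[i])
    }
    if (n_nt > 0) {
      for (i in seq_len(n_nt)) {
        resn <- if (i %% 2 == 1) "DA" else "DT"
        bx <- (i - 1) * 5.5 + jit(1)
        by <- 6 + jit(1); bz <- jit(1)
        if (i > 1) add("P", resn, "B", i, bx, by + 2.5, bz, element = "P")
        add("C4'", resn, "B", i, bx + 1.5, by, bz + 1.0)
        add("C2", resn, "B", i, bx + 3.0, by - 2.0, bz)
      }
    }
    if (n_lig > 0) {
      cx <- max(3.8 * max(n_res, 1), 5.5 * max(n_nt, 1)) / 2
      for (i in seq_len(n_lig)) {
        ang <- 2 * pi * i / n_lig
        add(paste0("C", i), "LIG", "C", 1,
            cx + 1.6 * cos(ang) + jit(1), 3 + 1.6 * sin(ang) + jit(1),
            3 + jit(1), record = "HETATM")
      }
    }
    add("O", "HOH", "W", 1, -6, -6, -6, record = "HETATM", element = "O")
    c(lines, "END")
  })
}

#' Apply an exact rigid motion to a parsed structure
#'
#' Rotates and translates every atom position in full double precision
#' (`x -> Q x + t`); attached ADP tensors, being positional covariances,
#' are conjugated to `Q U t(Q)`.  Atom identities and B-factors are
#' untouched.  This is the route invariance tests use: unlike a PDB-text
#' round trip, nothing is quantized, so inter-atom distances — and hence
#' the network spectrum — are preserved to machine precision.
#'
#' @param s an `anm_structure`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector, Angstrom.
#' @return The transformed `anm_structure`.
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(s, "anm_structure"))
  Q <- rotation
  if (!all(dim(Q) == c(3, 3)) || max(abs(crossprod(Q) - diag(3))) > 1e-8 ||
      det(Q) < 0) {
    abort_argument("rotation must be a proper orthogonal 3x3 matrix")
  }
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(Q) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  s$atoms$x <- new[, 1]; s$atoms$y <- new[, 2]; s$atoms$z <- new[, 3]
  s$adp <- lapply(s$adp, function(U) {
    if (is.null(U)) NULL else Q %*% U %*% t(Q)
  })
  s
}

#' Apply a random rigid motion to all coordinates of a PDB
#'
#' Parses the input, applies one seeded proper rotation plus translation to
#' every atom (see [transform_structure()]), and re-serializes as PDB text.
#' Atom identities and B-factors are untouched.  Because PDB coordinate
#' columns carry three decimals, the text round trip quantizes positions to
#' 1e-3 Angstrom; inter-atom distances are preserved to that resolution
#' (use [transform_structure()] directly when exact invariance is needed).
#'
#' @param pdb PDB text (lines or path).
#' @param seed RNG seed.
#' @return Character vector of PDB lines.
#' @export
perturb_rigid <- function(pdb, seed = 0) {
  s <- parse_pdb(pdb)
  .with_seed(seed, function() {
    Q <- rigid_rotation_matrix()
    tr <- runif(3, -10, 10)
    write_pdb(transform_structure(s, Q, tr))
  })
}

#' Draw a random proper rotation matrix
#'
#' QR-based uniform rotation (determinant +1) from the current RNG stream.
#'
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rigid_rotation_matrix <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
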