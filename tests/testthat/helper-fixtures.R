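# Shared builders and independent oracles for the test suite.

# default-scheme pipeline up to the Hessian for a toy CA chain
chain_network <- function(n, seed = 1, ...) {
  s <- parse_pdb(make_ca_chain(n, seed = seed, ...))
  nodes <- assign_ranges(select_nodes(s))
  list(nodes = nodes, contacts = build_contacts(nodes),
       hessian = build_hessian(nodes))
}

# the analytic two-node system: one stretch mode along x
two_node_modes <- function(spacing = 3.8) {
  s <- parse_pdb(make_ca_chain(2, jitter = 0, spacing = spacing, seed = 0))
  nodes <- assign_ranges(select_nodes(s))
  h <- build_hessian(nodes)
  m <- suppressWarnings(compute_modes(h, n_modes = 1,
                                      allow_rigid_mismatch = TRUE))
  list(nodes = nodes, hessian = h, modes = m)
}

node_xyz <- function(nodes) as.matrix(nodes$nodes[, c("x", "y", "z")])

# independent harmonic network energy for the finite-difference oracle
harmonic_energy <- function(x, contacts) {
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  d <- sqrt(rowSums((xyz[contacts$i, , drop = FALSE] -
                     xyz[contacts$j, , drop = FALSE])^2))
  sum(contacts$gamma / 2 * (d - contacts$d0)^2)
}

# central finite-difference Hessian of a scalar function
fd_hessian <- function(f, x0, h = 1e-4) {
  n <- length(x0)
  H <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in a:n) {
      ea <- eb <- rep(0, n); ea[a] <- h; eb[b] <- h
      H[a, b] <- (f(x0 + ea + eb) - f(x0 + ea - eb) -
                  f(x0 - ea + eb) + f(x0 - ea - eb)) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# per-mode subspace overlap of a's modes onto b's, pooling b-modes whose
# eigenvalues lie within rel_tol of a's (degenerate clusters compare as spans)
subspace_overlaps <- function(a, b, rel_tol = 1e-6) {
  vapply(seq_along(a$eigenvalues), function(k) {
    lam <- a$eigenvalues[k]
    cl <- which(abs(b$eigenvalues - lam) <= rel_tol * max(lam, 1e-12))
    if (!length(cl)) return(0)
    B <- b$vectors[, cl, drop = FALSE]
    sqrt(sum(crossprod(B, a$vectors[, k])^2))
  }, numeric(1))
}

# count of near-zero eigenvalues under the package's classification rule
n_zero_eigs <- function(h) {
  ev <- eigen(as.matrix(h$H), symmetric = TRUE, only.values = TRUE)$values
  sum(ev < max(1e-8 * max(ev), 1e-10))
}

# PDB text of two copies of a chain separated far beyond any cutoff
two_component_pdb <- function(n = 8, seed = 5, offset = 200) {
  s <- parse_pdb(make_ca_chain(n, seed = seed))
  s2 <- s
  s2$atoms$x <- s2$atoms$x + offset
  s2$atoms$chain_id <- "B"
  s$atoms <- rbind(s$atoms, s2$atoms)
  s$adp <- c(s$adp, s2$adp)
  write_pdb(s)
}

# exact seeded rigid motion of a parsed structure; returns the rotation too
exact_rigid <- function(s, seed) {
  set.seed(seed)
  Q <- rigid_rotation_matrix()
  tr <- runif(3, -10, 10)
  list(s = transform_structure(s, Q, tr), Q = Q, tr = tr)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
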