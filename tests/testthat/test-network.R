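# Node selection, range assignment, contact enumeration, Hessian assembly

test_that("default scheme: 1 node per residue, 3 per complete nucleotide", {
  lines <- character(0)
  for (i in 1:3) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 10.00", i, i,
      i * 3.8, 0, 0))
  }
  k <- 3
  for (j in 1:2) {
    for (nm in c(" P  ", " C4'", " C2 ")) {
      k <- k + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s DA  B%4d    %8.3f%8.3f%8.3f  1.00 10.00", k, nm, j,
        j * 5.0 + k, 5, 0))
    }
  }
  nodes <- select_nodes(parse_pdb(lines))
  expect_equal(nodes$N, 3 + 2 * 3)
  expect_equal(sum(nodes$nodes$class == "NUC"), 6)
})

test_that("ligand and water policy, hydrogens never become nodes", {
  pdb <- make_mixed_complex(3, 2, 4, seed = 7)
  s <- suppressMessages(parse_pdb(pdb))
  n_def <- suppressMessages(select_nodes(s))
  expect_equal(n_def$N, 3 + (3 + 2) + 4)   # first nucleotide lacks P
  expect_false(any(n_def$nodes$res_name == "HOH"))

  n_nolig <- suppressMessages(select_nodes(s, node_scheme(include_ligands = FALSE)))
  expect_equal(n_nolig$N, 3 + 5)

  n_p <- suppressMessages(select_nodes(s, node_scheme(nucleotide_atoms = "P")))
  expect_equal(sum(n_p$nodes$class == "NUC"), 1)  # only the 3'-side nt has P

  hline <- "ATOM      9  HB  ALA A   1       0.000   0.000   1.000  1.00 10.00  H"
  s2 <- suppressMessages(parse_pdb(c(pdb[-length(pdb)], hline, "END")))
  expect_equal(suppressMessages(select_nodes(s2))$N, n_def$N)
})

test_that("degenerate selections raise a classed error", {
  one <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00"
  expect_error(select_nodes(parse_pdb(one)), "degenerate",
               class = "anm_degenerate_error")
})

test_that("range assignment: table by type key, atom-name fallback, r_c/2", {
  pdb <- make_mixed_complex(3, 2, 4, seed = 7)
  nodes <- suppressMessages(select_nodes(parse_pdb(pdb)))

  u <- assign_ranges(nodes, node_scheme(cutoff = 15))
  expect_true(all(u$nodes$t == 7.5))

  sch <- node_scheme(range_table = c("NUC:P" = 9.0), cutoff = 15)
  v <- assign_ranges(suppressMessages(select_nodes(parse_pdb(pdb), sch)))
  expect_true(all(v$nodes$t[v$nodes$type_key == "NUC:P"] == 9.0))
  expect_true(all(v$nodes$t[v$nodes$type_key != "NUC:P"] == 7.5))

  sch2 <- node_scheme(range_table = c("CA" = 6.0), cutoff = 15)
  w <- assign_ranges(suppressMessages(select_nodes(parse_pdb(pdb), sch2)))
  expect_true(all(w$nodes$t[w$nodes$name == "CA"] == 6.0))

  expect_error(node_scheme(range_table = c("CA" = -1)),
               class = "anm_config_error")
})

test_that("range tables parse from plain-text config", {
  f <- tempfile()
  writeLines(c("# half-ranges in Angstrom", "NUC:P 9.0", "CA 6.5  # calpha"), f)
  tab <- read_range_table(f)
  expect_equal(tab, c("NUC:P" = 9.0, "CA" = 6.5))
})

test_that("contact rule d0 <= t_i + t_j is inclusive and exact", {
  mk <- function(xs) {
    parse_pdb(vapply(seq_along(xs), function(i) sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 10.00",
      i, i, xs[i], 0, 0), character(1)))
  }
  near <- build_contacts(assign_ranges(select_nodes(mk(c(0, 10)))))
  expect_equal(length(near$i), 1)
  at_cut <- build_contacts(assign_ranges(select_nodes(mk(c(0, 15)))))
  expect_equal(length(at_cut$i), 1)      # inclusive boundary
  far <- build_contacts(assign_ranges(select_nodes(mk(c(0, 16)))))
  expect_equal(length(far$i), 0)
  tri <- build_contacts(assign_ranges(select_nodes(mk(c(0, 8, 16)))))
  expect_equal(cbind(tri$i, tri$j), cbind(c(1, 2), c(2, 3)))
})

test_that("coincident nodes are an error naming both atoms", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00",
    "ATOM      2  CA  ALA A   2       0.000   0.000   0.000  1.00 10.00"
  )
  expect_error(build_contacts(assign_ranges(select_nodes(parse_pdb(lines)))),
               "identical coordinates", class = "anm_argument_error")
})

test_that("uniform ranges reduce to the classical single-cutoff model", {
  for (seed in 1:10) {
    nodes <- assign_ranges(select_nodes(parse_pdb(make_ca_chain(30, seed = seed))))
    ct <- build_contacts(nodes)
    dm <- as.matrix(dist(node_xyz(nodes)))
    ref <- which(upper.tri(dm) & dm <= 15, arr.ind = TRUE)
    expect_setequal(paste(ct$i, ct$j), paste(ref[, 1], ref[, 2]))
    expect_equal(length(ct$i), nrow(ref))
  }
})

test_that("two-node Hessian matches the analytic 6x6 form", {
  tn <- two_node_modes()
  H <- as.matrix(tn$hessian$H)
  expect_equal(H[1:3, 4:6], diag(c(-1, 0, 0)), tolerance = 1e-12)
  expect_equal(sort(eigen(H, symmetric = TRUE)$values),
               c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
})

test_that("Hessian super-rows sum to zero blocks and H is PSD", {
  net <- chain_network(25, seed = 4)
  H <- as.matrix(net$hessian$H)
  n <- net$nodes$N
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    expect_lt(max(abs(rowSums(matrix(H[rows, ], 3)))), 1e-12)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("Hessian equals the finite-difference Hessian of the energy", {
  net <- chain_network(10, seed = 8)
  x0 <- as.numeric(t(node_xyz(net$nodes)))
  Hfd <- fd_hessian(function(x) harmonic_energy(x, net$contacts), x0)
  expect_lt(max(abs(as.matrix(net$hessian$H) - Hfd)), 1e-5)
})

test_that("Hessian matches an independent elastic-network implementation", {
  skip_if_not_installed("bio3d")
  nodes <- assign_ranges(select_nodes(parse_pdb(make_ca_chain(20, seed = 9))))
  h <- build_hessian(nodes)
  xyz <- as.numeric(t(node_xyz(nodes)))
  ref <- bio3d::build.hessian(xyz, pfc.fun = bio3d::load.enmff("anm"),
                              cutoff = 15)
  expect_lt(max(abs(as.matrix(h$H) - ref)), 1e-10)
})

test_that("node permutation conjugates H and leaves the spectrum unchanged", {
  set.seed(17)
  pdb <- make_ca_chain(12, seed = 17)
  s <- parse_pdb(pdb)
  perm <- sample(nrow(s$atoms))
  s2 <- s
  s2$atoms <- s$atoms[perm, , drop = FALSE]
  s2$adp <- s$adp[perm]
  h1 <- build_hessian(assign_ranges(select_nodes(s)))
  h2 <- build_hessian(assign_ranges(select_nodes(s2)))
  ev1 <- eigen(as.matrix(h1$H), symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(as.matrix(h2$H), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev1, ev2, tolerance = 1e-10)
  # explicit conjugation by the coordinate permutation
  P <- matrix(0, 36, 36)
  for (a in seq_along(perm)) {
    P[cbind((3 * a - 2):(3 * a), (3 * perm[a] - 2):(3 * perm[a]))] <- 1
  }
  expect_lt(max(abs(P %*% as.matrix(h1$H) %*% t(P) - as.matrix(h2$H))), 1e-12)
})

test_that("connected fixtures have 6 zero modes; 2 components have 12", {
  expect_equal(n_zero_eigs(chain_network(40, seed = 3)$hessian), 6)
  s <- parse_pdb(two_component_pdb(8, seed = 5))
  h <- build_hessian(assign_ranges(select_nodes(s)))
  expect_equal(n_zero_eigs(h), 12)
})
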