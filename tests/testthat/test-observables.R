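# Fluctuations, B-factors, ADPs, correlation / distance-fluctuation maps,
# animations

test_that("two-node analytic observables", {
  tn <- two_node_modes()
  m <- tn$modes
  p <- square_fluctuations(m)
  expect_equal(p$msf, c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(p$b_theory, (8 * pi^2 / 3) * c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(cross_correlation_map(m)[1, 2], -1, tolerance = 1e-10)
  D <- distance_fluctuation_map(m)
  expect_equal(D[1, 2], 1.0, tolerance = 1e-10)
  expect_equal(diag(D), c(0, 0))
  U <- adp_tensors(m)
  expect_equal(U$tensors[[1]], diag(c(0.25, 0, 0)), tolerance = 1e-10)
})

test_that("msf is symmetric under a symmetry swap and grows with mode count", {
  # mirror-symmetric non-planar 6-node fixture (x -> -x maps i to 7-i)
  pos <- rbind(c(-6, 0, 0), c(-2, 2, 1), c(-1, -2, 2),
               c(1, -2, 2), c(2, 2, 1), c(6, 0, 0))
  lines <- vapply(1:6, function(i) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 10.00",
    i, i, pos[i, 1], pos[i, 2], pos[i, 3]), character(1))
  h <- build_hessian(assign_ranges(select_nodes(parse_pdb(lines))))
  m <- compute_modes(h, n_modes = 12)
  msf <- square_fluctuations(m)$msf
  expect_equal(msf[1:3], msf[6:4], tolerance = 1e-10)

  net <- chain_network(20, seed = 14)
  m_all <- compute_modes(net$hessian, n_modes = 3 * 20 - 6)
  m_few <- compute_modes(net$hessian, n_modes = 10)
  expect_true(all(square_fluctuations(m_few)$msf <=
                  square_fluctuations(m_all)$msf + 1e-12))
})

test_that("B-factor fit: closed form scale and scale-free correlation", {
  net <- chain_network(40, seed = 20)
  m <- compute_modes(net$hessian, 20)
  p <- square_fluctuations(m)

  fit <- fit_experimental_b(p, 2.5 * p$b_theory)
  expect_equal(fit$scale, 2.5, tolerance = 1e-10)
  expect_equal(fit$r, 1.0, tolerance = 1e-10)

  set.seed(1)
  b_shuf <- sample(p$b_theory)
  fit2 <- fit_experimental_b(p, b_shuf)
  expect_true(abs(fit2$r) <= 1)

  # closed-form scale equals brute-force 1-D minimization
  set.seed(2)
  b_noisy <- 3 * p$b_theory + rnorm(length(p$b_theory), sd = sd(p$b_theory))
  fit3 <- fit_experimental_b(p, b_noisy)
  opt <- optimize(function(s) sum((s * p$b_theory - b_noisy)^2),
                  interval = c(0, 100), tol = 1e-12)
  expect_equal(fit3$scale, opt$minimum, tolerance = 1e-8)

  expect_error(fit_experimental_b(p, rep(5, nrow(p))),
               class = "anm_argument_error")
})

test_that("ADP tensors are symmetric PSD with trace equal to msf", {
  net <- chain_network(25, seed = 22)
  m <- compute_modes(net$hessian, 20)
  U <- adp_tensors(m)
  msf <- square_fluctuations(m)$msf
  for (i in seq_along(U$tensors)) {
    Ui <- U$tensors[[i]]
    expect_true(isSymmetric(Ui, tol = 1e-12))
    ev <- eigen(Ui, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
    expect_equal(sum(diag(Ui)), msf[i], tolerance = 1e-12)
  }
})

test_that("ADP tensors rotate equivariantly under rigid motion", {
  s <- parse_pdb(make_ca_chain(15, seed = 25))
  rig <- exact_rigid(s, seed = 77)
  n1 <- assign_ranges(select_nodes(s))
  n2 <- assign_ranges(select_nodes(rig$s))
  # all 3N-6 modes so the observable is basis-independent even under
  # degenerate eigenvalues
  m1 <- compute_modes(build_hessian(n1), 3 * 15 - 6)
  m2 <- compute_modes(build_hessian(n2), 3 * 15 - 6)
  Q <- rig$Q
  U1 <- adp_tensors(m1); U2 <- adp_tensors(m2)
  for (i in seq_len(n1$N)) {
    expect_lt(max(abs(Q %*% U1$tensors[[i]] %*% t(Q) - U2$tensors[[i]])), 1e-8)
  }
})

test_that("correlation map is a unit-diagonal matrix bounded by [-1, 1]", {
  net <- chain_network(30, seed = 28)
  m <- compute_modes(net$hessian, 20)
  C <- cross_correlation_map(m)
  expect_equal(diag(C), rep(1, 30))
  expect_true(all(C >= -1 & C <= 1))
  expect_lt(max(abs(C - t(C))), 1e-12)
})

test_that("full-mode covariance equals the Hessian pseudo-inverse blocks", {
  skip_if_not_installed("MASS")
  for (n in c(12, 25, 40)) {
    net <- chain_network(n, seed = n + 2)
    m <- compute_modes(net$hessian, 3 * n - 6)
    msf <- square_fluctuations(m)$msf
    C <- cross_correlation_map(m)
    cov_impl <- C * sqrt(msf %o% msf)
    Hp <- MASS::ginv(as.matrix(net$hessian$H))
    cov_ref <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      cov_ref[i, j] <- sum(diag(Hp[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
    }
    expect_lt(max(abs(cov_impl - cov_ref)), 1e-8)
  }
})

test_that("distance fluctuations are symmetric nonnegative with zero diagonal", {
  net <- chain_network(30, seed = 30)
  m <- compute_modes(net$hessian, 20)
  D <- distance_fluctuation_map(m)
  expect_equal(diag(D), rep(0, 30))
  expect_true(all(D >= 0))
  expect_lt(max(abs(D - t(D))), 1e-12)
  # consistency with its definition from msf and covariance
  msf <- square_fluctuations(m)$msf
  C <- cross_correlation_map(m)
  covm <- C * sqrt(msf %o% msf)
  expect_lt(max(abs(D - (outer(msf, msf, "+") - 2 * covm))), 1e-10)
})

test_that("adding a spring never increases the total fluctuation", {
  for (seed in c(2, 9, 33)) {
    # an 8 A cutoff keeps the chain connected but leaves distant pairs free
    nodes <- assign_ranges(select_nodes(parse_pdb(make_ca_chain(15, seed = seed))),
                           node_scheme(cutoff = 8))
    ct <- build_contacts(nodes)
    h1 <- build_hessian(nodes, ct)
    # add one extra spring between the most distant non-contacting pair
    dm <- as.matrix(dist(node_xyz(nodes)))
    have <- matrix(FALSE, 15, 15)
    have[cbind(ct$i, ct$j)] <- TRUE
    cand <- which(upper.tri(dm) & !have & !t(have), arr.ind = TRUE)
    if (nrow(cand) == 0) next
    k <- which.max(dm[cand])
    ct2 <- ct
    ct2$i <- c(ct$i, cand[k, 1]); ct2$j <- c(ct$j, cand[k, 2])
    ct2$d0 <- c(ct$d0, dm[cand[k, , drop = FALSE]]); ct2$gamma <- c(ct$gamma, 1)
    h2 <- build_hessian(nodes, ct2)
    tot1 <- sum(square_fluctuations(compute_modes(h1, 3 * 15 - 6))$msf)
    tot2 <- sum(square_fluctuations(compute_modes(h2, 3 * 15 - 6))$msf)
    expect_lte(tot2, tot1 + 1e-10)
  }
})

test_that("mode animation obeys the amplitude and symmetry contracts", {
  net <- chain_network(12, seed = 40)
  m <- compute_modes(net$hessian, 5)
  tr <- animate_mode(net$nodes, m, mode_index = 2, amplitude = 2, n_frames = 20)
  expect_length(tr$frames, 20)
  R0 <- node_xyz(net$nodes)
  expect_identical(tr$frames[[1]], R0)          # frame 0 is the input exactly
  dmax <- max(vapply(tr$frames, function(f) {
    max(sqrt(rowSums((f - R0)^2)))
  }, numeric(1)))
  expect_equal(dmax, 2, tolerance = 1e-9)
  for (f in 1:9) {                              # sin antisymmetry about R0
    expect_lt(max(abs((tr$frames[[1 + f]] - R0) +
                      (tr$frames[[1 + 20 - f]] - R0))), 1e-9)
  }
  expect_error(animate_mode(net$nodes, m, 6), class = "anm_argument_error")
})

test_that("fluctuation profile TSV carries node identity and values", {
  net <- chain_network(6, seed = 44)
  m <- compute_modes(net$hessian, 4)
  p <- square_fluctuations(m)
  out <- write_fluct_tsv(p, net$nodes)
  expect_length(out, 7)
  expect_match(out[1], "^node\tchain")
  row <- strsplit(out[2], "\t")[[1]]
  expect_equal(as.numeric(row[5]), p$msf[1], tolerance = 1e-3)
})
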