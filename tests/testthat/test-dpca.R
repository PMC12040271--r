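# Dihedral extraction, circular embedding, covariance eigendecomposition,
# contribution profiles and variance fractions.

test_that("torsion angles of planar arrangements are analytic", {
  # cis: all four atoms planar, 1-4 on the same side
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0); p4 <- c(2, 1, 0)
  expect_equal(dimerscope:::torsion_angle(p1, p2, p3, p4), 0)
  # trans: opposite sides, canonicalised to +pi
  p4t <- c(2, -1, 0)
  expect_equal(dimerscope:::torsion_angle(p1, p2, p3, p4t), pi)
})

test_that("embedding sends each angle to its unit-circle point", {
  s <- dihedral_series(matrix(c(0, pi / 2), 1, 2),
                       data.frame(chain_id = "A", res_seq = c(1, 2),
                                  kind = c("psi", "phi")))
  q <- embed_dihedrals(s)
  expect_equal(as.numeric(q), c(1, 0, 0, 1))
  set.seed(8)
  s2 <- dihedral_series(matrix(stats::runif(60, -pi, pi), 10, 6),
                        data.frame(chain_id = "A", res_seq = 1:6,
                                   kind = rep(c("phi", "psi"), 3)))
  q2 <- embed_dihedrals(s2)
  cs <- q2[, seq(1, 11, 2)]^2 + q2[, seq(2, 12, 2)]^2
  expect_equal(cs, matrix(1, 10, 6))
})

test_that("fit reproduces a hand-built covariance exactly", {
  # three points realising covariance diag(2, 1) exactly:
  # col1 = a(-2, 1, 1) with a = sqrt(2/3) -> var 2; col2 = (0, 1, -1) -> var 1
  a <- sqrt(2 / 3)
  q <- rbind(c(-2 * a, 0), c(a, 1), c(a, -1))
  m <- dpca_fit(q)
  expect_equal(m$eigenvalues, c(2, 1), tolerance = 1e-12)
  expect_equal(abs(m$eigenvectors[, 1]), c(1, 0), tolerance = 1e-12)
})

test_that("zero-variance input gives all-zero eigenvalues", {
  q <- matrix(0.5, 5, 4)
  m <- dpca_fit(q)
  expect_equal(m$eigenvalues, rep(0, 4))
  expect_warning(cumulative_variance(m, 1), "zero")
  expect_error(dpca_fit(q[1, , drop = FALSE]), "two frames")
})

test_that("fit agrees with an independent brute-force construction", {
  set.seed(13)
  q <- matrix(stats::rnorm(120), 20, 6)
  m <- dpca_fit(q)
  or <- oracle_pca(q)
  expect_equal(sum(m$eigenvalues), sum(diag(or$cov)), tolerance = 1e-10)
  expect_equal(m$eigenvalues, or$eigenvalues, tolerance = 1e-8)
  v_or <- sign_align(m$eigenvectors, or$eigenvectors)
  expect_equal(m$eigenvectors, v_or, tolerance = 1e-8)
  expect_equal(m$projections, or$projections %*%
                 diag(sign(colSums(or$eigenvectors * v_or))), tolerance = 1e-8)
})

test_that("centred embedding is reconstructed from projections (completeness)", {
  set.seed(21)
  s <- helix_series(8, t_n = 30, kappa = 10, seed = 21)
  q <- embed_dihedrals(s)
  m <- dpca_fit(s)
  qc <- sweep(q, 2, m$mean_q)
  expect_equal(m$projections %*% t(m$eigenvectors), qc, tolerance = 1e-8)
  # orthonormality
  expect_equal(crossprod(m$eigenvectors), diag(ncol(q)), tolerance = 1e-10)
})

test_that("contribution profiles pair sin/cos weights and sum to one", {
  set.seed(5)
  s <- helix_series(10, t_n = 40, kappa = 15, seed = 5)
  m <- dpca_fit(s)
  for (k in c(1, 2, 7, ncol(m$eigenvectors))) {
    contr <- dpca_contributions(m, k)
    expect_equal(sum(contr$contribution), 1, tolerance = 1e-9)
    expect_true(all(contr$contribution >= 0))
  }
  expect_error(dpca_contributions(m, 0), "out of range")
  expect_error(dpca_contributions(m, ncol(m$eigenvectors) + 1), "out of range")
  # single angle: its contribution is 1 for every component
  s1 <- dihedral_series(matrix(stats::runif(10, -1, 1), 10, 1),
                        data.frame(chain_id = "A", res_seq = 1, kind = "psi"))
  m1 <- dpca_fit(s1)
  expect_equal(dpca_contributions(m1, 1)$contribution, 1)
  expect_equal(dpca_contributions(m1, 2)$contribution, 1)
})

test_that("cumulative variance is monotone, correct on known eigenvalues, 1 at 2N", {
  m <- structure(list(eigenvalues = c(3, 1, 0, 0)), class = "dpca")
  expect_equal(cumulative_variance(m, 1), 0.75)
  expect_equal(cumulative_variance(m, 4), 1.0)
  set.seed(2)
  mf <- dpca_fit(matrix(stats::rnorm(80), 20, 4))
  cv <- vapply(1:4, cumulative_variance, numeric(1), model = mf)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[4], 1)
})

test_that("dPCA is invariant under per-frame rigid motion of the trajectory", {
  spec <- synthetic_spec(n_res_per_chain = 8, n_frames = 15, n_states = 2,
                         concentration = 10, seed = 17)
  sim <- simulate_dimer(spec)
  tr <- sim$trajectory
  tr2 <- tr
  set.seed(99)
  for (f in seq_len(n_frames(tr))) {
    R <- dimerscope:::random_rotation()
    tt <- stats::rnorm(3, 0, 20)
    tr2$coords[f, , ] <- sweep(frame_coords(tr, f) %*% R, 2, tt, "+")
  }
  d1 <- compute_dihedrals(tr); d2 <- compute_dihedrals(tr2)
  expect_lt(max(abs(wrap_angle(d1$angles - d2$angles))), 1e-8)
  m1 <- dpca_fit(d1); m2 <- dpca_fit(d2)
  expect_lt(max(abs(m1$projections - m2$projections)), 1e-8)
})

test_that("chain breaks exclude the spanning angles with a warning", {
  tr <- build_backbone(helix_series(6), "A")
  # push residues 4..6 away to break the 3-4 peptide bond
  idx <- select_atoms(tr, res_range = c(4, 6))
  tr$coords[, idx, 1] <- tr$coords[, idx, 1] + 50
  expect_warning(d <- compute_dihedrals(tr), "chain break")
  # psi_3 and phi_4 span the break and must be gone
  expect_false(any(d$labels$res_seq == 3 & d$labels$kind == "psi"))
  expect_false(any(d$labels$res_seq == 4 & d$labels$kind == "phi"))
})
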