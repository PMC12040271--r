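# Kabsch superposition, RMSD/RMSF, distance traces, SASA.

test_that("superposition is exact for identical and rigidly moved copies", {
  set.seed(1)
  X <- matrix(stats::rnorm(30), 10, 3)
  f0 <- superpose(X, X)
  expect_lt(f0$rmsd, 1e-10)
  R <- dimerscope:::random_rotation()
  Y <- sweep(X %*% R, 2, c(5, -3, 2), "+")
  f <- superpose(X, Y)
  expect_lt(f$rmsd, 1e-8)
  expect_equal(det(f$rotation), 1, tolerance = 1e-10)
  expect_equal(sweep(Y %*% f$rotation, 2, f$translation, "+"), X,
               tolerance = 1e-8)
})

test_that("rotation is always proper, even for near-reflective cases", {
  set.seed(7)
  for (i in 1:20) {
    X <- matrix(stats::rnorm(12), 4, 3)
    Y <- -X + matrix(stats::rnorm(12, 0, 0.1), 4, 3)  # mirror-ish partner
    f <- superpose(X, Y)
    expect_equal(det(f$rotation), 1, tolerance = 1e-8)
  }
})

test_that("a known single-atom displacement gives RMSD 1 A", {
  # equilateral triangle + centre point: displacing the centre along z by
  # d leaves the identity superposition optimal (the rotational gradient
  # vanishes by 3-fold symmetry), and after centroid matching the
  # deviations are 3 x (d/4)^2 + (3d/4)^2 = 3 d^2 / 4, so
  # rmsd = sqrt(3) d / 4; with d = 4/sqrt(3) that is exactly 1 A
  d <- 4 / sqrt(3)
  tri <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  ref <- rbind(tri, c(0, 0, 0))
  mob <- ref
  mob[4, 3] <- d
  f <- superpose(ref, mob)
  expect_equal(f$rmsd, 1.0, tolerance = 1e-9)
  # brute-force: no random rigid placement beats the returned optimum
  set.seed(33)
  brute <- min(vapply(1:500, function(i) {
    R <- dimerscope:::random_rotation()
    ms <- mob %*% R
    fit <- sweep(ms, 2, colMeans(ms) - colMeans(ref))
    sqrt(mean(rowSums((fit - ref)^2)))
  }, numeric(1)))
  expect_gte(brute, f$rmsd - 1e-9)
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(line[1:2, ], line[1:2, ]), "3 atoms")
})

test_that("rmsd series is zero for static or rigidly moved trajectories", {
  tr <- toy_two_chain(n_res = 6, t_n = 1)
  coords <- array(NA_real_, dim = c(3, n_atoms(tr), 3))
  x <- frame_coords(tr, 1)
  coords[1, , ] <- x
  coords[2, , ] <- sweep(x, 2, c(3, 0, 0), "+")      # pure translation
  set.seed(5)
  coords[3, , ] <- sweep(x %*% dimerscope:::random_rotation(), 2, c(1, 2, 3), "+")
  tr3 <- trajectory(tr$atoms, coords)
  v <- rmsd_series(tr3, 1)
  expect_equal(v[1], 0, tolerance = 1e-12)
  expect_lt(max(v), 1e-8)
})

test_that("rmsf matches the variance oracle for one oscillating atom", {
  n_static <- 30; t_n <- 200; d <- 0.8
  set.seed(10)
  base <- matrix(stats::rnorm(3 * n_static, sd = 5), n_static, 3)
  disp <- d * sign(sin(seq_len(t_n)))            # +/- d square wave
  coords <- array(NA_real_, dim = c(t_n, n_static + 1, 3))
  for (f in seq_len(t_n)) {
    coords[f, seq_len(n_static), ] <- base
    coords[f, n_static + 1, ] <- c(10 + disp[f], 0, 0)
  }
  atoms <- data.frame(serial = seq_len(n_static + 1), name = "CA",
                      element = "C", res_name = "ALA",
                      res_seq = seq_len(n_static + 1), chain_id = "A")
  tr <- trajectory(atoms, coords)
  v <- rmsf(tr, seq_len(n_static + 1))
  oracle <- sqrt(mean((disp - mean(disp))^2))
  expect_equal(unname(v[n_static + 1]), oracle, tolerance = 0.05)
  expect_lt(max(v[seq_len(n_static)]), 0.05)
  # rigid per-frame motion leaves RMSF unchanged
  tr2 <- tr
  set.seed(11)
  for (f in seq_len(t_n)) {
    tr2$coords[f, , ] <- sweep(coords[f, , ] %*% dimerscope:::random_rotation(),
                               2, stats::rnorm(3, 0, 10), "+")
  }
  expect_equal(as.numeric(rmsf(tr2, seq_len(n_static + 1))), as.numeric(v),
               tolerance = 1e-6)
})

test_that("distance traces are Euclidean and drive H-bond fractions", {
  atoms <- data.frame(serial = 1:2, name = c("ND2", "OG1"),
                      element = c("N", "O"), res_name = c("ASN", "THR"),
                      res_seq = c(1, 1), chain_id = c("A", "B"))
  coords <- array(0, dim = c(2, 2, 3))
  coords[1, 2, ] <- c(3, 4, 0)        # 3-4-5 triangle
  coords[2, 2, ] <- c(0, 0, 0)
  tr <- trajectory(atoms, coords)
  d <- distance_trace(tr, "A:1:ND2", "B:1:OG1")
  expect_equal(d$distances, c(5, 0))
  expect_equal(d$criterion_cutoff, 3.5)
  expect_equal(hbond_fraction(d), 0.5)
  expect_equal(hbond_fraction(d, cutoff = 6), 1.0)
  expect_error(distance_trace(tr, "A:9:ND2", "B:1:OG1"), "A:9:ND2")
})

test_that("hydrogen atom pairs default to the 2.5 A criterion", {
  atoms <- data.frame(serial = 1:2, name = c("HD21", "OG1"),
                      element = c("H", "O"), res_name = c("ASN", "THR"),
                      res_seq = c(1, 1), chain_id = c("A", "B"))
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 2, 1] <- 2.0
  tr <- trajectory(atoms, coords)
  d <- distance_trace(tr, "A:1:HD21", "B:1:OG1")
  expect_equal(d$criterion_cutoff, 2.5)
  expect_equal(hbond_fraction(d), 1.0)
})

test_that("noisy contact distances give the normal-CDF H-bond fraction", {
  t_n <- 500
  spec <- synthetic_spec(n_res_per_chain = 8, n_frames = t_n, n_states = 1,
                         concentration = 200, seed = 3)
  spec$contact_pairs$target <- 3.4
  spec$contact_pairs$noise <- 0.4
  sim <- simulate_dimer(spec)
  d <- distance_trace(sim$trajectory, "A:4:ND2", "B:4:OG1")
  p <- stats::pnorm(3.5, 3.4, 0.4)
  se <- sqrt(p * (1 - p) / t_n)
  expect_lt(abs(hbond_fraction(d, 3.5) - p), 3 * se)
})

test_that("SASA of an isolated atom matches the analytic sphere area", {
  atoms <- data.frame(serial = 1L, name = "CA", element = "C",
                      res_name = "ALA", res_seq = 1L, chain_id = "A")
  tr <- trajectory(atoms, matrix(0, 1, 3))
  s <- sasa(tr, probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.02)
})

test_that("far atoms do not occlude; a tight cage buries completely", {
  atoms <- data.frame(serial = 1:2, name = c("CA", "CA"), element = "C",
                      res_name = "ALA", res_seq = 1:2, chain_id = "A")
  x <- matrix(c(0, 0, 0, 50, 0, 0), 2, 3, byrow = TRUE)
  s <- sasa(trajectory(atoms, x))
  expect_equal(s$per_atom, rep(4 * pi * 3.1^2, 2), tolerance = 0.02)
  # cage: central C surrounded by 26 close neighbours on a cubic shell
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 2.2
  atoms_c <- data.frame(serial = seq_len(nrow(g)), name = "CA", element = "C",
                        res_name = "ALA", res_seq = seq_len(nrow(g)),
                        chain_id = "A")
  sc <- sasa(trajectory(atoms_c, g))
  centre <- which(rowSums(abs(g)) == 0)
  expect_equal(sc$per_atom[centre], 0)
})

test_that("SASA is rigid-motion invariant and non-increasing with neighbours", {
  set.seed(20)
  g <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  atoms <- data.frame(serial = 1:10, name = "CA", element = "C",
                      res_name = "ALA", res_seq = 1:10, chain_id = "A")
  tr <- trajectory(atoms, g)
  s1 <- sasa(tr)
  g2 <- sweep(g %*% dimerscope:::random_rotation(), 2, c(4, 5, 6), "+")
  s2 <- sasa(trajectory(atoms, g2))
  expect_equal(s2$per_atom, s1$per_atom, tolerance = 1e-6)
  # adding a neighbour can only reduce per-atom SASA of the others
  # (evaluated in one fixed frame so the quadrature points coincide)
  s_all <- sasa(tr, canonicalize = FALSE)
  s_sub <- sasa(tr, indices = 1:9, canonicalize = FALSE)
  expect_true(all(s_all$per_atom[1:9] <= s_sub$per_atom + 1e-9))
})
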