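# Shared fixtures and independent oracles, built in code at test time.

# tiny hand-built two-chain trajectory: n_res CA-only residues per chain
toy_two_chain <- function(n_res = 5L, t_n = 2L, sep = 20) {
  atoms <- do.call(rbind, lapply(c("A", "B"), function(ch) {
    data.frame(serial = seq_len(n_res), name = "CA", element = "C",
               res_name = "ALA", res_seq = seq_len(n_res), chain_id = ch,
               stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  coords <- array(0, dim = c(t_n, nrow(atoms), 3))
  for (f in seq_len(t_n)) {
    coords[f, , 1] <- c(3.8 * seq_len(n_res), 3.8 * seq_len(n_res))
    coords[f, , 2] <- rep(c(0, sep), each = n_res)
    coords[f, , 3] <- 0.01 * (f - 1)   # tiny drift so frames differ
  }
  trajectory(atoms, coords)
}

# helix spec: all phi/psi at the classic alpha-helix means
helix_series <- function(n_res, t_n = 1L, kappa = 1e6, seed = 1L) {
  kinds <- dimerscope:::chain_angle_kinds(n_res)
  means <- ifelse(kinds == "phi", -57, -47) * pi / 180
  spec <- synthetic_spec(n_res_per_chain = n_res, n_frames = t_n,
                         n_states = 1L, state_means = matrix(means, 1),
                         concentration = kappa, seed = seed)
  sample_dihedral_series(spec)$series
}

# independent dense construction of a dPCA fit: explicit centering,
# brute-force covariance by loops over column pairs, eigen via SVD of the
# centred data matrix (a different code path than eigen(cov(q)))
oracle_pca <- function(q) {
  t_n <- nrow(q); p <- ncol(q)
  mu <- colMeans(q)
  qc <- sweep(q, 2, mu)
  cv <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      cv[i, j] <- sum(qc[, i] * qc[, j]) / (t_n - 1)
    }
  }
  sv <- svd(qc)
  vals <- sv$d^2 / (t_n - 1)
  vecs <- sv$v
  if (p > length(vals)) {  # complete the basis if T-1 < p
    vals <- c(vals, rep(0, p - length(vals)))
  }
  list(cov = cv, eigenvalues = vals, eigenvectors = vecs,
       projections = qc %*% vecs)
}

# align eigenvector signs of b to a, column by column
sign_align <- function(a, b) {
  for (k in seq_len(ncol(b))) {
    if (sum(a[, k] * b[, k]) < 0) b[, k] <- -b[, k]
  }
  b
}

# independent quadratic-space Needleman-Wunsch with affine gaps
# (Gotoh three-matrix DP) under BLOSUM62; returns the aligned strings
oracle_global_align <- function(sa, sb, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  # Ix: gap in b (consume a); Iy: gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - gap_extend * (j - 1)
  ptrM <- ptrX <- ptrY <- matrix(0L, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[a[i - 1], b[j - 1]]
      cand <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      ptrM[i, j] <- which.max(cand)
      M[i, j] <- max(cand) + s
      candx <- c(M[i - 1, j] - gap_open - gap_extend,
                 Ix[i - 1, j] - gap_extend)
      ptrX[i, j] <- which.max(candx)
      Ix[i, j] <- max(candx)
      candy <- c(M[i, j - 1] - gap_open - gap_extend,
                 Iy[i, j - 1] - gap_extend)
      ptrY[i, j] <- which.max(candy)
      Iy[i, j] <- max(candy)
    }
  }
  best <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  pa <- pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1L) {
      pa <- c(a[i - 1], pa); pb <- c(b[j - 1], pb)
      state <- ptrM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      pa <- c(a[i - 1], pa); pb <- c("-", pb)
      ns <- if (i == 2 && j == 1) 1L else if (j == 1) 2L else ptrX[i, j]
      state <- ns; i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(b[j - 1], pb)
      ns <- if (j == 2 && i == 1) 1L else if (i == 1) 3L else ptrY[i, j]
      state <- ns; j <- j - 1
    }
    if (i == 1 && j > 1) state <- 3L
    if (j == 1 && i > 1) state <- 2L
  }
  list(pa = pa, pb = pb, score = best,
       identity = dimerscope:::aligned_identity(pa, pb))
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}
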