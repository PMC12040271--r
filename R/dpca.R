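# Dihedral-angle principal component analysis (dPCA).
#
# Backbone (phi, psi) angles are extracted per frame, mapped onto the unit
# circle as (cos g, sin g) pairs, and the covariance matrix of that 2N-dim
# embedding is diagonalised.  Projections of the centred embedding onto the
# eigenvectors are the principal components V_k; the squared paired
# eigenvector entries give the per-angle contribution profile Delta_n(k).
# The circular embedding sidesteps the -pi/+pi periodicity artefacts that a
# naive PCA on raw angles would suffer.

#' Dihedral angle series
#'
#' @param angles `T x N` matrix of angles in radians in `(-pi, pi]`.
#' @param labels data.frame with columns `chain_id`, `res_seq`,
#'   `kind` (`"phi"`/`"psi"`), one row per column of `angles`.
#' @return object of class `dihedral_series`.
#' @export
dihedral_series <- function(angles, labels) {
  angles <- as.matrix(angles)
  stopifnot(ncol(angles) >= 1L, nrow(labels) == ncol(angles),
            all(c("chain_id", "res_seq", "kind") %in% names(labels)))
  if (anyNA(angles)) stop("dihedral series must not contain undefined angles")
  key <- paste(labels$chain_id, labels$res_seq, labels$kind)
  if (anyDuplicated(key)) stop("duplicate dihedral labels")
  structure(list(angles = angles, labels = labels), class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("dihedral_series:", nrow(x$angles), "frames x", ncol(x$angles),
      "angles (chains", paste(unique(x$labels$chain_id), collapse = ","), ")\n")
  invisible(x)
}

#' Backbone phi/psi angles along a trajectory
#'
#' Standard backbone torsions per frame: `phi_i = C(i-1)-N(i)-CA(i)-C(i)`
#' and `psi_i = N(i)-CA(i)-C(i)-N(i+1)`, IUPAC sign convention, radians.
#' Terminal residues contribute only their defined angle.  An angle that
#' spans a chain break (peptide `C(i-1)-N(i)` distance > 2 Angstrom in any
#' frame) is excluded with a warning.  Column order is by chain, then
#' residue, phi before psi.
#'
#' @param traj a [trajectory] with N, CA, C backbone atoms.
#' @param chains optional chain ids to restrict to.
#' @return a [dihedral_series].
#' @export
compute_dihedrals <- function(traj, chains = NULL) {
  a <- traj$atoms
  if (is.null(chains)) chains <- unique(a$chain_id)
  t_n <- n_frames(traj)
  cols <- list(); labs <- list()
  get_xyz <- function(i) matrix(traj$coords[, i, ], ncol = 3)
  for (ch in chains) {
    res <- sort(unique(a$res_seq[a$chain_id == ch]))
    idx_of <- function(r, nm) {
      i <- which(a$chain_id == ch & a$res_seq == r & a$name == nm)
      if (length(i) == 1L) i else NA_integer_
    }
    n_i <- vapply(res, idx_of, integer(1), nm = "N")
    ca_i <- vapply(res, idx_of, integer(1), nm = "CA")
    c_i <- vapply(res, idx_of, integer(1), nm = "C")
    ok <- !is.na(n_i) & !is.na(ca_i) & !is.na(c_i)
    # peptide-bond continuity between consecutive residues (both complete)
    linked <- rep(FALSE, length(res))
    for (j in seq_along(res)[-1]) {
      if (ok[j - 1] && ok[j]) {
        d <- vnorm3(get_xyz(n_i[j]) - get_xyz(c_i[j - 1]))
        linked[j] <- all(d <= 2.0)
        if (ok[j - 1] && ok[j] && !linked[j])
          warning("chain break before ", ch, ":", res[j],
                  "; spanning angles excluded")
      }
    }
    for (j in seq_along(res)) {
      if (!ok[j]) next
      if (j > 1L && linked[j]) {                       # phi_j
        cols[[length(cols) + 1L]] <- torsion_angle(
          get_xyz(c_i[j - 1]), get_xyz(n_i[j]), get_xyz(ca_i[j]), get_xyz(c_i[j]))
        labs[[length(labs) + 1L]] <- data.frame(
          chain_id = ch, res_seq = res[j], kind = "phi")
      }
      if (j < length(res) && linked[j + 1L]) {         # psi_j
        cols[[length(cols) + 1L]] <- torsion_angle(
          get_xyz(n_i[j]), get_xyz(ca_i[j]), get_xyz(c_i[j]), get_xyz(n_i[j + 1]))
        labs[[length(labs) + 1L]] <- data.frame(
          chain_id = ch, res_seq = res[j], kind = "psi")
      }
    }
  }
  if (!length(cols)) stop("no defined backbone dihedral angles found")
  dihedral_series(do.call(cbind, cols), do.call(rbind, labs))
}

#' Circular sin/cos embedding of a dihedral series
#'
#' Maps each angle g onto the unit circle; column order is
#' `(cos g1, sin g1, ..., cos gN, sin gN)`.
#'
#' @param series a [dihedral_series].
#' @return `T x 2N` numeric matrix.
#' @export
embed_dihedrals <- function(series) {
  stopifnot(inherits(series, "dihedral_series"))
  g <- series$angles
  n <- ncol(g)
  q <- matrix(NA_real_, nrow(g), 2L * n)
  q[, seq(1L, 2L * n, by = 2L)] <- cos(g)
  q[, seq(2L, 2L * n, by = 2L)] <- sin(g)
  q
}

#' Fit a dPCA model
#'
#' Mean-centres the embedded coordinates, forms their covariance matrix
#' (unbiased, 1/(T-1)), and diagonalises it.  Eigenpairs are sorted by
#' decreasing eigenvalue; each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive, which makes projections
#' reproducible across linear-algebra backends.  Components are 1-based
#' (PC1, PC2, ...).
#'
#' @param x a [dihedral_series], or a `T x 2N` embedding matrix as produced
#'   by [embed_dihedrals()].
#' @return object of class `dpca` with elements `mean_q`, `eigenvectors`
#'   (`2N x 2N`, orthonormal columns), `eigenvalues` (non-increasing, >= 0),
#'   `projections` (`T x 2N`), `variance_fraction`, `cumulative_fraction`
#'   and, when available, the angle `labels`.
#' @export
dpca_fit <- function(x) {
  labels <- NULL
  if (inherits(x, "dihedral_series")) {
    labels <- x$labels
    x <- embed_dihedrals(x)
  }
  q <- as.matrix(x)
  if (nrow(q) < 2L) stop("need at least two frames to fit a dPCA model")
  if (ncol(q) %% 2L != 0L) stop("embedded matrix must have 2N columns")
  mean_q <- colMeans(q)
  qc <- sweep(q, 2L, mean_q)
  cv <- stats::cov(q)
  ed <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  vecs <- ed$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  total <- sum(vals)
  vf <- if (total > 0) vals / total else rep(0, length(vals))
  structure(list(mean_q = mean_q, eigenvectors = vecs, eigenvalues = vals,
                 projections = qc %*% vecs, variance_fraction = vf,
                 cumulative_fraction = cumsum(vf), labels = labels),
            class = "dpca")
}

#' @export
print.dpca <- function(x, ...) {
  n2 <- length(x$eigenvalues)
  cat("dpca model:", nrow(x$projections), "frames,", n2 / 2, "angles\n")
  m <- min(4L, n2)
  cat("  variance fraction PC1..PC", m, ": ",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(m)]), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Per-angle contribution profile of one principal component
#'
#' The influence of dihedral angle n on component k is the sum of the
#' squares of its paired (cos, sin) eigenvector entries,
#' `Delta_n(k) = v_{2n-1}(k)^2 + v_{2n}(k)^2`.  Because each eigenvector
#' has unit length the profile sums to one over angles and reads as the
#' fraction of the component carried by each angle.
#'
#' @param model a fitted [dpca_fit()] model.
#' @param k component index (1-based, `1 <= k <= 2N`).
#' @return data.frame of angle labels (when known) with a `contribution`
#'   column summing to 1.
#' @export
dpca_contributions <- function(model, k = 1L) {
  stopifnot(inherits(model, "dpca"))
  n2 <- length(model$eigenvalues)
  if (k < 1L || k > n2) stop("component index k out of range 1..", n2)
  v <- model$eigenvectors[, k]
  n <- n2 / 2L
  contr <- v[seq(1L, n2, by = 2L)]^2 + v[seq(2L, n2, by = 2L)]^2
  out <- if (!is.null(model$labels)) model$labels else
    data.frame(angle = seq_len(n))
  out$contribution <- contr
  out
}

#' Cumulative variance fraction of the leading components
#'
#' @param model a fitted [dpca_fit()] model.
#' @param m number of leading components (`1 <= m <= 2N`).
#' @return fraction in `[0, 1]`; 1 at `m = 2N`.
#' @export
cumulative_variance <- function(model, m) {
  stopifnot(inherits(model, "dpca"))
  n2 <- length(model$eigenvalues)
  if (m < 1L || m > n2) stop("m out of range 1..", n2)
  total <- sum(model$eigenvalues)
  if (total == 0) {
    warning("all eigenvalues are zero; cumulative variance undefined, returning 0")
    return(0)
  }
  sum(model$eigenvalues[seq_len(m)]) / total
}
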