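# Superposition, RMSD/RMSF, atom-pair distance traces with hydrogen-bond
# criteria, and Shrake-Rupley solvent-accessible surface area.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1; a reflection is never returned) and
#' translation minimising the RMSD between selected atoms of two frames.
#' The mobile frame maps onto the reference as `x %*% rotation + translation`
#' (row-vector convention).
#'
#' @param reference,mobile `M x 3` coordinate matrices.
#' @param indices atom indices used for the fit (default: all).
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   (Angstrom, over the selection after the transform).
#' @export
superpose <- function(reference, mobile, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(nrow(reference))
  if (length(indices) < 3L) stop("superposition needs at least 3 atoms")
  P <- mobile[indices, , drop = FALSE]
  Q <- reference[indices, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  if (svd(Pc)$d[2] < 1e-8 * max(svd(Pc)$d[1], 1))
    stop("selected atoms are collinear; superposition is underdetermined")
  H <- crossprod(Pc, Qc)           # maximise tr(R' H)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- cq - as.numeric(cp %*% R)
  moved <- sweep(P %*% R, 2L, tr, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

#' Per-frame RMSD to a reference frame
#'
#' Each frame is optimally superposed onto the reference frame over the
#' selection, then the RMSD over that same selection is reported; the entry
#' at the reference frame is 0.  The default selection is the alpha
#' carbons.
#'
#' @param traj a [trajectory].
#' @param reference_frame frame index of the reference (default 1).
#' @param indices atom selection (default: all CA atoms).
#' @return numeric vector of length T (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, indices = NULL) {
  if (is.null(indices)) indices <- select_atoms(traj, atom_names = "CA")
  ref <- frame_coords(traj, reference_frame)
  vapply(seq_len(n_frames(traj)), function(f) {
    superpose(ref, frame_coords(traj, f), indices)$rmsd
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed (over the selection) onto the selection's mean
#' structure -- first aligned to frame 1, then twice re-aligned to the
#' updated mean -- and `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` is
#' reported for the selected atoms.
#'
#' @param traj a [trajectory] with at least two frames.
#' @param indices atom selection (default: all CA atoms).
#' @return named numeric vector (Angstrom), one entry per selected atom.
#' @export
rmsf <- function(traj, indices = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least two frames")
  if (is.null(indices)) indices <- select_atoms(traj, atom_names = "CA")
  t_n <- n_frames(traj)
  sel <- array(NA_real_, dim = c(t_n, length(indices), 3L))
  for (f in seq_len(t_n)) sel[f, , ] <- frame_coords(traj, f)[indices, ]
  ref <- matrix(sel[1, , ], ncol = 3)
  for (iter in 1:3) {  # align to frame 1, then twice to the running mean
    for (f in seq_len(t_n)) {
      x <- matrix(sel[f, , ], ncol = 3)
      fit <- superpose(ref, x)
      sel[f, , ] <- sweep(x %*% fit$rotation, 2L, fit$translation, "+")
    }
    ref <- apply(sel, c(2, 3), mean)
  }
  dev2 <- sweep(sel, c(2, 3), ref)^2     # T x M x 3 squared deviations
  out <- sqrt(colMeans(apply(dev2, c(1, 2), sum)))
  a <- traj$atoms[indices, ]
  stats::setNames(out, paste0(a$chain_id, ":", a$res_seq, ":", a$name))
}

#' Atom-pair distance trace
#'
#' Euclidean distance between two atoms along the trajectory.  Atoms are
#' given as `chain:res_seq:name` specs (e.g. `"A:226:HD21"`).  The default
#' hydrogen-bond criterion cutoff stored with the trace is 2.5 Angstrom
#' when either atom is a hydrogen (H-to-acceptor style) and 3.5 Angstrom
#' for a heavy-atom donor-acceptor pair.
#'
#' @param traj a [trajectory].
#' @param a,b atom spec strings.
#' @return object of class `distance_trace`: `pair`, `distances` (length T,
#'   Angstrom), `times`, `criterion_cutoff`.
#' @export
distance_trace <- function(traj, a, b) {
  ia <- resolve_atom(traj, a)
  ib <- resolve_atom(traj, b)
  d <- vnorm3(matrix(traj$coords[, ia, ], ncol = 3) -
              matrix(traj$coords[, ib, ], ncol = 3))
  has_h <- any(traj$atoms$element[c(ia, ib)] == "H")
  structure(list(pair = c(a, b), distances = as.numeric(d),
                 times = traj$times,
                 criterion_cutoff = if (has_h) 2.5 else 3.5),
            class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat("distance trace ", x$pair[1], " - ", x$pair[2], ": ",
      length(x$distances), " frames, mean ",
      sprintf("%.2f", mean(x$distances)), " A (criterion <= ",
      x$criterion_cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Fraction of frames satisfying a hydrogen-bond distance criterion
#'
#' @param trace a [distance_trace()].
#' @param cutoff distance cutoff in Angstrom; defaults to the trace's own
#'   criterion cutoff.
#' @return fraction in `[0, 1]`.
#' @export
hbond_fraction <- function(trace, cutoff = trace$criterion_cutoff) {
  stopifnot(inherits(trace, "distance_trace"))
  mean(trace$distances <= cutoff)
}

# Canonical molecular orientation: principal axes of the coordinates with
# a deterministic sign convention.  Running the quadrature in this frame
# makes SASA invariant under rigid motion of the input (up to floating
# point), since the sphere-point layout is fixed in space.
canonical_orientation <- function(xyz) {
  if (nrow(xyz) < 3L) return(xyz)
  xc <- sweep(xyz, 2L, colMeans(xyz))
  ed <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  v <- ed$vectors
  pr <- xc %*% v
  for (k in 1:3) {
    # data-intrinsic sign: positive skewness of the projections (the same
    # for any rigidly moved copy); fall back to the eigenvector entries
    # only when the distribution is symmetric along the axis
    sk <- sum(pr[, k]^3)
    flip <- if (abs(sk) > 1e-8 * max(sum(abs(pr[, k]))^3, 1e-300)) sk < 0
            else v[which.max(abs(v[, k])), k] < 0
    if (flip) pr[, k] <- -pr[, k]
  }
  pr
}

# Deterministic quasi-uniform unit-sphere points (golden-spiral layout).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius `r_vdw + probe` is sampled at `n_points`
#' quasi-uniform points on a deterministic golden-spiral layout (no RNG, so
#' results are bit-reproducible); a point is accessible iff it lies outside
#' every neighbouring atom's inflated sphere, and the atom's SASA is the
#' accessible fraction times its sphere area.  Radii are the Bondi set
#' (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Angstrom).  The quadrature is
#' run in a canonical principal-axes orientation of the selection, so
#' results are invariant under rigid motion of the input (degenerate,
#' exactly symmetric point sets excepted).
#'
#' @param traj a [trajectory] (or a frame view).
#' @param frame frame index.
#' @param indices atoms to include (default: all); excluded atoms do not
#'   occlude.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @param canonicalize run the quadrature in the canonical principal-axes
#'   orientation (rigid-motion invariant); set `FALSE` to evaluate in the
#'   frame of the supplied coordinates, e.g. when several selections of
#'   the same structure must share one quadrature frame.
#' @return object of class `sasa_result`: `per_atom` (Angstrom^2),
#'   `total`, `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(traj, frame = 1L, indices = NULL, probe = 1.4,
                 n_points = 960L, canonicalize = TRUE) {
  fv <- if (inherits(traj, "trajectory")) frame_view(traj, frame) else traj
  if (is.null(indices)) indices <- seq_len(nrow(fv$atoms))
  xyz <- fv$xyz[indices, , drop = FALSE]
  if (canonicalize) xyz <- canonical_orientation(xyz)
  rad <- vdw_radius(fv$atoms$element[indices]) + probe
  m <- length(indices)
  pts <- sphere_points(n_points)
  per_atom <- numeric(m)
  for (i in seq_len(m)) {
    ri <- rad[i]
    # neighbours whose inflated spheres can intersect atom i's surface
    dz <- sweep(xyz, 2L, xyz[i, ])
    d2 <- rowSums(dz^2)
    nb <- which(d2 < (ri + rad)^2 & seq_len(m) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(sp[acc, , drop = FALSE], 2L, xyz[j, ])
      acc[acc] <- rowSums(dj^2) > rad[j]^2
    }
    per_atom[i] <- mean(acc) * 4 * pi * ri^2
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_sphere_points = n_points,
                 indices = indices),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("SASA:", sprintf("%.1f", x$total), "A^2 over", length(x$per_atom),
      "atoms (probe", x$probe_radius, "A,", x$n_sphere_points, "points)\n")
  invisible(x)
}
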