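# Ground-truthed synthetic dimer trajectories.
#
# Because no study trajectories are deposited, every downstream analysis is
# validated on generated data with known answers: backbone dihedrals follow
# a hidden-Markov chain over a few metastable states with von Mises angular
# noise, chains are rebuilt frame-by-frame from internal coordinates with
# ideal geometry, and chain B is rigidly placed each frame so a set of
# inter-chain contact pairs hits prescribed distances.  The generator
# records the hidden-state sequence, the per-frame interface residue sets
# and the frames on which each contact satisfies its hydrogen-bond
# criterion, so cluster recovery, hot-spot consensus and H-bond analyses
# can be scored exactly.

#' Wrap angles to the principal interval (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' von Mises random angles
#'
#' Best-Fisher rejection sampler; numerically stable from the uniform limit
#' (kappa ~ 0) up to near-degenerate concentrations (kappa ~ 1e6).
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (> 0 for a non-uniform draw).
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 16L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, th)
  }
  wrap_angle(out[seq_len(n)] + mu)
}

# Default state means: alternating helix-like / extended-like (phi, psi)
# rows, one column per dihedral of a chain with n_res residues (label order
# psi_1, phi_2, psi_2, ..., phi_n).  Consecutive states are separated by
# >= 2 rad mean circular distance.
default_state_means <- function(n_states, n_res) {
  base <- list(c(phi = -1.00, psi = -0.82),   # alpha-helical basin
               c(phi = -2.10, psi = 2.27),    # extended/beta basin
               c(phi = 1.00, psi = 0.70),     # left-handed basin
               c(phi = -1.40, psi = 2.90))
  if (n_states > length(base))
    stop("default state means support at most ", length(base), " states")
  kinds <- chain_angle_kinds(n_res)
  t(vapply(seq_len(n_states), function(k) {
    unname(base[[k]][kinds])
  }, numeric(2 * n_res - 2)))
}

# angle kinds ("phi"/"psi") in label order for one chain
chain_angle_kinds <- function(n_res) {
  kinds <- character(0)
  for (i in seq_len(n_res)) {
    if (i > 1) kinds <- c(kinds, "phi")
    if (i < n_res) kinds <- c(kinds, "psi")
  }
  kinds
}

chain_angle_resseq <- function(n_res) {
  rs <- integer(0)
  for (i in seq_len(n_res)) {
    if (i > 1) rs <- c(rs, i)
    if (i < n_res) rs <- c(rs, i)
  }
  rs
}

#' Specification of a synthetic dimer trajectory
#'
#' Defaults emulate the study conditions at desk scale: a ~171-frame run at
#' 1 ns/frame of a two-chain dimer whose backbone hops between two
#' metastable dihedral states, with one persistent inter-chain
#' hydrogen-bond contact and a GlcNAc-like glycan stand-in on an interface
#' asparagine.
#'
#' @param n_res_per_chain residues per chain.
#' @param n_frames number of frames T.
#' @param n_states number of metastable states K.
#' @param state_means `K x N` matrix of per-angle state means (radians),
#'   `N = 2 * n_res_per_chain - 2`; default alternating helix/extended.
#' @param concentration von Mises kappa (scalar or length N).
#' @param transition_matrix `K x K` row-stochastic matrix; default 0.05
#'   symmetric switching.
#' @param initial_state hidden state of frame 1 (1-based).
#' @param contact_pairs data.frame with columns `res_a`, `name_a`, `res_b`,
#'   `name_b`, `target` (Angstrom), `noise` (Angstrom sd), `active_states`
#'   (comma-separated state list or `"all"`).  Default: one persistent
#'   Asn ND2 -- Thr OG1 pair at 3.0 A between the chain midpoints.
#' @param glycan_sites data.frame with columns `chain`, `res_seq`: residues
#'   that carry the 5-heavy-atom GlcNAc stand-in.  Default: one site on
#'   chain A next to the contact residue.
#' @param interface_cutoff heavy-atom interface distance cutoff (Angstrom).
#' @param inactive_distance distance imposed on a contact pair in frames
#'   where it is inactive (Angstrom).
#' @param time_step ns between frames.
#' @param seed RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_res_per_chain = 24L, n_frames = 171L,
                           n_states = 2L, state_means = NULL,
                           concentration = 20, transition_matrix = NULL,
                           initial_state = 1L, contact_pairs = NULL,
                           glycan_sites = NULL, interface_cutoff = 5.0,
                           inactive_distance = 12.0, time_step = 1.0,
                           seed = 1L) {
  n_angles <- 2L * n_res_per_chain - 2L
  if (n_res_per_chain < 2L) stop("need at least 2 residues per chain")
  if (is.null(state_means))
    state_means <- default_state_means(n_states, n_res_per_chain)
  state_means <- matrix(state_means, nrow = n_states)
  if (ncol(state_means) != n_angles)
    stop("state_means must have ", n_angles, " columns")
  if (is.null(transition_matrix)) {
    p <- 0.05
    transition_matrix <- matrix(p / max(1, n_states - 1), n_states, n_states)
    diag(transition_matrix) <- 1 - p
    if (n_states == 1L) transition_matrix <- matrix(1, 1, 1)
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix rows must sum to 1")
  if (any(transition_matrix < 0)) stop("transition_matrix must be nonnegative")
  if (any(concentration <= 0)) stop("concentration kappa must be > 0")
  mid <- as.integer(ceiling(n_res_per_chain / 2))
  if (is.null(contact_pairs))
    contact_pairs <- data.frame(
      res_a = mid, name_a = "ND2", res_b = mid, name_b = "OG1",
      target = 3.0, noise = 0.0, active_states = "all",
      stringsAsFactors = FALSE)
  if (is.null(glycan_sites))
    glycan_sites <- data.frame(chain = "A", res_seq = mid + 3L,
                               stringsAsFactors = FALSE)
  structure(list(n_res_per_chain = as.integer(n_res_per_chain),
                 n_frames = as.integer(n_frames),
                 n_states = as.integer(n_states),
                 state_means = state_means,
                 concentration = concentration,
                 transition_matrix = transition_matrix,
                 initial_state = as.integer(initial_state),
                 contact_pairs = contact_pairs,
                 glycan_sites = glycan_sites,
                 interface_cutoff = interface_cutoff,
                 inactive_distance = inactive_distance,
                 time_step = time_step, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$n_frames, "frames,", x$n_res_per_chain,
      "res/chain,", x$n_states, "state(s), kappa",
      paste(unique(x$concentration), collapse = ","), "\n")
  invisible(x)
}

# Hidden-state Markov chain (1-based labels).
markov_labels <- function(spec) {
  z <- integer(spec$n_frames)
  z[1] <- spec$initial_state
  if (spec$n_frames > 1L) {
    for (t in 2:spec$n_frames) {
      z[t] <- sample.int(spec$n_states, 1L,
                         prob = spec$transition_matrix[z[t - 1], ])
    }
  }
  z
}

#' Sample a hidden-Markov von Mises dihedral series for one chain
#'
#' Frame `t` draws each angle from von Mises(state mean, kappa) given the
#' hidden state of that frame.
#'
#' @param spec a [synthetic_spec].
#' @param chain_id chain label for the angle labels.
#' @param state_labels optional precomputed hidden-state sequence (shared
#'   between chains of one dimer); sampled from the spec when `NULL`.
#' @param seed RNG seed; `spec$seed` by default, `NULL` to continue the
#'   current RNG stream.
#' @return list with `series` (a [dihedral_series]) and `state_labels`.
#' @export
sample_dihedral_series <- function(spec, chain_id = "A",
                                   state_labels = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state_labels)) state_labels <- markov_labels(spec)
  n_ang <- ncol(spec$state_means)
  kap <- rep(spec$concentration, length.out = n_ang)
  ang <- matrix(NA_real_, spec$n_frames, n_ang)
  for (k in seq_len(spec$n_states)) {
    rows <- which(state_labels == k)
    if (!length(rows)) next
    for (j in seq_len(n_ang)) {
      ang[rows, j] <- rvonmises(length(rows), spec$state_means[k, j], kap[j])
    }
  }
  labels <- data.frame(chain_id = chain_id,
                       res_seq = chain_angle_resseq(spec$n_res_per_chain),
                       kind = chain_angle_kinds(spec$n_res_per_chain),
                       stringsAsFactors = FALSE)
  list(series = dihedral_series(ang, labels), state_labels = state_labels)
}

# residue names implied by the pseudo side-chain atoms a residue carries
.sidechain_residue <- c(ND2 = "ASN", OD1 = "ASN", HD21 = "ASN", HD22 = "ASN",
                        OG1 = "THR", HG1 = "THR", OG = "SER", HG = "SER",
                        NZ = "LYS", OH = "TYR", NE2 = "GLN", OE1 = "GLN")

# ideal backbone geometry (Angstrom / radians)
.geom <- list(b_n_ca = 1.46, b_ca_c = 1.53, b_c_n = 1.33, b_c_o = 1.23,
              b_ca_cb = 1.53,
              a_n_ca_c = 111 * pi / 180, a_ca_c_n = 117 * pi / 180,
              a_c_n_ca = 121 * pi / 180, a_ca_c_o = 120.5 * pi / 180,
              a_c_ca_cb = 110.5 * pi / 180, omega = pi)

#' Rebuild an ideal-geometry backbone from dihedral angles
#'
#' Sequential internal-to-Cartesian placement, frame by frame: N, CA, C
#' per residue with fixed ideal bond lengths/angles and omega held at 180
#' degrees, plus the carbonyl O, a C-beta on every non-glycine residue, and
#' any requested pseudo side-chain atoms (placed along the CA->CB
#' direction; enough for contact and hydrogen-bond tests without a rotamer
#' library).
#'
#' @param dihedrals a [dihedral_series] for one chain (label order
#'   `psi_1, phi_2, psi_2, ..., phi_n`).
#' @param chain_id chain label.
#' @param res_names residue names (length `n_res`, default all `"ALA"`,
#'   upgraded automatically for residues carrying pseudo side-chain atoms).
#' @param extra_atoms optional data.frame (`res_seq`, `name`) of pseudo
#'   side-chain atoms (e.g. `ND2`, `OG1`, `HD21`).
#' @param times frame times in ns.
#' @return a [trajectory] of one chain.
#' @export
build_backbone <- function(dihedrals, chain_id = "A", res_names = NULL,
                           extra_atoms = NULL, times = NULL) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  n_ang <- ncol(dihedrals$angles)
  if (n_ang < 2L || n_ang %% 2L != 0L)
    stop("need 2*n_res - 2 dihedral angles for n_res >= 2 (got ", n_ang, ")")
  n_res <- (n_ang + 2L) %/% 2L
  kinds <- chain_angle_kinds(n_res)
  ress <- chain_angle_resseq(n_res)
  if (!identical(dihedrals$labels$kind, kinds) ||
      !identical(as.integer(dihedrals$labels$res_seq), as.integer(ress)))
    stop("dihedral labels do not match the expected psi/phi chain layout")
  if (is.null(res_names)) res_names <- rep("ALA", n_res)
  if (!is.null(extra_atoms) && nrow(extra_atoms)) {
    for (r in seq_len(nrow(extra_atoms))) {
      nm <- extra_atoms$name[r]
      if (nm %in% names(.sidechain_residue))
        res_names[extra_atoms$res_seq[r]] <- .sidechain_residue[[nm]]
    }
  }
  t_n <- nrow(dihedrals$angles)
  g <- .geom
  phi_col <- function(i) which(kinds == "phi" & ress == i)
  psi_col <- function(i) which(kinds == "psi" & ress == i)

  # atom table
  atoms <- list()
  for (i in seq_len(n_res)) {
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    if (res_names[i] != "GLY") { nm <- c(nm, "CB"); el <- c(el, "C") }
    if (!is.null(extra_atoms) && nrow(extra_atoms)) {
      ex <- extra_atoms$name[extra_atoms$res_seq == i]
      nm <- c(nm, ex)
      el <- c(el, element_from_name(ex))
    }
    atoms[[i]] <- data.frame(name = nm, element = el, res_name = res_names[i],
                             res_seq = i, chain_id = chain_id,
                             stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  row_of <- function(i, nm) which(atoms$res_seq == i & atoms$name == nm)

  coords <- array(NA_real_, dim = c(t_n, nrow(atoms), 3))
  for (f in seq_len(t_n)) {
    ang <- dihedrals$angles[f, ]
    phi <- function(i) ang[phi_col(i)]
    psi <- function(i) ang[psi_col(i)]
    xyz <- matrix(NA_real_, nrow(atoms), 3)
    # residue 1
    N <- c(0, 0, 0)
    CA <- c(g$b_n_ca, 0, 0)
    C <- CA + g$b_ca_c * c(cos(pi - g$a_n_ca_c), sin(pi - g$a_n_ca_c), 0)
    xyz[row_of(1, "N"), ] <- N
    xyz[row_of(1, "CA"), ] <- CA
    xyz[row_of(1, "C"), ] <- C
    prevN <- N; prevCA <- CA; prevC <- C
    for (i in seq_len(n_res)[-1]) {
      Ni <- place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, psi(i - 1))
      CAi <- place_atom(prevCA, prevC, Ni, g$b_n_ca, g$a_c_n_ca, g$omega)
      Ci <- place_atom(prevC, Ni, CAi, g$b_ca_c, g$a_n_ca_c, phi(i))
      xyz[row_of(i, "N"), ] <- Ni
      xyz[row_of(i, "CA"), ] <- CAi
      xyz[row_of(i, "C"), ] <- Ci
      prevN <- Ni; prevCA <- CAi; prevC <- Ci
    }
    # carbonyl O, CB and pseudo side-chain atoms
    for (i in seq_len(n_res)) {
      Ni <- xyz[row_of(i, "N"), ]; CAi <- xyz[row_of(i, "CA"), ]
      Ci <- xyz[row_of(i, "C"), ]
      chi_o <- if (i < n_res) psi(i) - pi else 0
      xyz[row_of(i, "O"), ] <- place_atom(Ni, CAi, Ci, g$b_c_o, g$a_ca_c_o, chi_o)
      cb_row <- row_of(i, "CB")
      if (length(cb_row)) {
        CBi <- place_atom(Ni, Ci, CAi, g$b_ca_cb, g$a_c_ca_cb, 122.6 * pi / 180)
        xyz[cb_row, ] <- CBi
        ex <- atoms$name[atoms$res_seq == i &
                         !atoms$name %in% c("N", "CA", "C", "O", "CB")]
        if (length(ex)) {
          u <- as.numeric(unit3(CBi - CAi))
          v <- as.numeric(unit3(cross3(u, as.numeric(unit3(Ni - CAi)))))
          kh <- 0L
          for (nm in ex) {
            reach <- if (substr(nm, 1, 1) == "H") 2.5 else 1.5
            xyz[row_of(i, nm), ] <- CBi + reach * u + 0.3 * kh * v
            kh <- kh + 1L
          }
        }
      }
    }
    coords[f, , ] <- xyz
  }
  if (is.null(times)) times <- seq_len(t_n) - 1
  trajectory(atoms, coords, times)
}

# GlcNAc-like pseudo-residue (5 heavy atoms) bonded to an Asn ND2; rebuilt
# per frame from that residue's local frame so it moves with the chain.
add_glycan_standin <- function(traj, chain, res_seq) {
  a <- traj$atoms
  need <- function(nm) {
    i <- which(a$chain_id == chain & a$res_seq == res_seq & a$name == nm)
    if (length(i) != 1L)
      stop("glycan site ", chain, ":", res_seq, " lacks atom ", nm)
    i
  }
  if (!any(a$chain_id == chain & a$res_seq == res_seq))
    stop("unknown glycan residue ", chain, ":", res_seq)
  i_nd2 <- need("ND2"); i_cb <- need("CB"); i_ca <- need("CA")
  gly_res <- 500L + res_seq
  gly <- data.frame(serial = max(a$serial) + 1:5,
                    name = c("C1", "O5", "C2", "N2", "O7"),
                    element = c("C", "O", "C", "N", "O"),
                    res_name = "NAG", res_seq = gly_res, chain_id = chain,
                    stringsAsFactors = FALSE)
  t_n <- n_frames(traj)
  coords <- array(NA_real_, dim = c(t_n, nrow(a) + 5L, 3))
  coords[, seq_len(nrow(a)), ] <- traj$coords
  for (f in seq_len(t_n)) {
    nd2 <- traj$coords[f, i_nd2, ]; cb <- traj$coords[f, i_cb, ]
    ca <- traj$coords[f, i_ca, ]
    u <- as.numeric(unit3(nd2 - cb))
    vv <- cross3(u, as.numeric(unit3(ca - cb)))
    v <- if (vnorm3(vv) > 1e-6) as.numeric(unit3(vv)) else perp_unit(u)
    w <- as.numeric(cross3(u, v))
    c1 <- nd2 + 1.45 * u
    coords[f, nrow(a) + 1L, ] <- c1
    coords[f, nrow(a) + 2L, ] <- c1 + 1.43 * (0.50 * u + 0.87 * v)
    coords[f, nrow(a) + 3L, ] <- c1 + 1.52 * (0.50 * u - 0.87 * v)
    coords[f, nrow(a) + 4L, ] <- c1 + 1.52 * (0.50 * u - 0.87 * v) + 1.45 * w
    coords[f, nrow(a) + 5L, ] <- c1 + 1.43 * (1.20 * u + 0.60 * v)
  }
  trajectory(rbind(a, gly), coords, traj$times)
}

# states on which a contact pair is imposed at its target distance
pair_active_states <- function(active_states, n_states) {
  if (identical(active_states, "all")) return(seq_len(n_states))
  as.integer(strsplit(active_states, ",", fixed = TRUE)[[1]])
}

#' Rigidly assemble two chains into a dimer with controlled contacts
#'
#' For every frame, chain B is rigidly placed (rotation + translation) so
#' that each contact pair's inter-atom distance equals its target (plus
#' Gaussian noise); pairs inactive in the frame's hidden state are driven
#' to `spec$inactive_distance` instead.  A single pair is solved exactly by
#' translation; multiple simultaneous targets are solved by quasi-Newton
#' least squares over the 6 rigid degrees of freedom, erroring after
#' bounded restarts if the targets are jointly infeasible.
#'
#' @param chain_a,chain_b one-chain [trajectory] objects with equal frame
#'   counts.
#' @param spec the [synthetic_spec] (contact pairs, cutoffs).
#' @param state_labels hidden-state sequence (for state-dependent pairs);
#'   defaults to all-active.
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return list with the merged `trajectory` and a `truth` list:
#'   `state_labels`, `pair_distances` (T x P), `true_hbond_frames` (per
#'   pair), `interface_per_frame` (per-frame chainwise residue sets) and
#'   `true_interface_residues` (residues in the interface in every frame).
#' @export
assemble_dimer <- function(chain_a, chain_b, spec, state_labels = NULL,
                           seed = NULL) {
  stopifnot(inherits(chain_a, "trajectory"), inherits(chain_b, "trajectory"))
  if (!is.null(seed)) set.seed(seed)
  t_n <- n_frames(chain_a)
  if (n_frames(chain_b) != t_n) stop("chains must have equal frame counts")
  if (is.null(state_labels)) state_labels <- rep(1L, t_n)
  cp <- spec$contact_pairs
  p_n <- nrow(cp)
  ia <- vapply(seq_len(p_n), function(p)
    which(chain_a$atoms$res_seq == cp$res_a[p] &
          chain_a$atoms$name == cp$name_a[p])[1], integer(1))
  ib <- vapply(seq_len(p_n), function(p)
    which(chain_b$atoms$res_seq == cp$res_b[p] &
          chain_b$atoms$name == cp$name_b[p])[1], integer(1))
  if (anyNA(ia) || anyNA(ib)) stop("contact pair atom not found in chain")
  active <- lapply(cp$active_states, pair_active_states, spec$n_states)

  # frame-specific noisy target distances
  targets <- matrix(NA_real_, t_n, p_n)
  for (p in seq_len(p_n)) {
    base <- ifelse(state_labels %in% active[[p]], cp$target[p],
                   spec$inactive_distance)
    targets[, p] <- pmax(0.5, base + stats::rnorm(t_n, 0, cp$noise[p]))
  }

  mb <- n_atoms(chain_b)
  coords_b <- array(NA_real_, dim = c(t_n, mb, 3))
  # initial guess: chain B shifted +x beyond chain A
  off0 <- c(max(chain_a$coords[1, , 1]) - min(chain_b$coords[1, , 1]) + 10, 0, 0)
  prev <- list(R = diag(3), t = off0)
  for (f in seq_len(t_n)) {
    A <- matrix(chain_a$coords[f, , ], ncol = 3)
    B0 <- matrix(chain_b$coords[f, , ], ncol = 3)
    apos <- A[ia, , drop = FALSE]
    d_t <- targets[f, ]
    if (p_n == 1L) {
      b_now <- as.numeric(B0[ib, ] %*% prev$R + prev$t)
      u <- b_now - as.numeric(apos)
      nu <- sqrt(sum(u^2))
      u <- if (nu < 1e-9) c(1, 0, 0) else u / nu
      tshift <- (as.numeric(apos) + d_t * u) - b_now
      R <- prev$R; tt <- prev$t + tshift
    } else {
      # rotate about the centroid of chain B's pair atoms, translate it;
      # parameters are a rotation-vector increment on the previous frame's
      # orientation plus a centroid shift
      ctr <- colMeans(B0[ib, , drop = FALSE])
      ctr_prev <- as.numeric(ctr %*% prev$R) + prev$t
      Bc <- sweep(B0[ib, , drop = FALSE], 2, ctr)
      obj <- function(par) {
        R <- prev$R %*% rotvec_to_matrix(par[1:3])
        bp <- sweep(Bc %*% R, 2, ctr_prev + par[4:6], "+")
        sum((sqrt(rowSums((bp - apos)^2)) - d_t)^2)
      }
      fit <- NULL
      for (try in 1:5) {
        par0 <- if (try == 1) rep(0, 6) else c(stats::rnorm(3, 0, 0.5),
                                               stats::rnorm(3, 0, 1))
        cand <- stats::optim(par0, obj, method = "BFGS",
                             control = list(maxit = 500, reltol = 1e-14))
        if (is.null(fit) || cand$value < fit$value) fit <- cand
        if (fit$value < 1e-10) break
      }
      if (fit$value > 1e-6)
        stop("infeasible simultaneous contact targets (residual ",
             sprintf("%.3g", sqrt(fit$value)), " A)")
      R <- prev$R %*% rotvec_to_matrix(fit$par[1:3])
      tt <- ctr_prev + fit$par[4:6] - as.numeric(ctr %*% R)
    }
    coords_b[f, , ] <- sweep(B0 %*% R, 2, tt, "+")
    prev <- list(R = R, t = tt)
  }

  atoms_b <- chain_b$atoms
  atoms_b$serial <- atoms_b$serial + max(chain_a$atoms$serial)
  atoms <- rbind(chain_a$atoms, atoms_b)
  coords <- array(NA_real_, dim = c(t_n, nrow(atoms), 3))
  coords[, seq_len(n_atoms(chain_a)), ] <- chain_a$coords
  coords[, n_atoms(chain_a) + seq_len(mb), ] <- coords_b
  traj <- trajectory(atoms, coords, chain_a$times)

  # ---- ground truth -------------------------------------------------------
  pair_d <- matrix(NA_real_, t_n, p_n)
  for (p in seq_len(p_n)) {
    pa <- matrix(traj$coords[, ia[p], ], ncol = 3)
    pb <- matrix(traj$coords[, n_atoms(chain_a) + ib[p], ], ncol = 3)
    pair_d[, p] <- vnorm3(pa - pb)
  }
  hb_cut <- vapply(seq_len(p_n), function(p) {
    if (any(c(substr(cp$name_a[p], 1, 1), substr(cp$name_b[p], 1, 1)) == "H"))
      2.5 else 3.5
  }, numeric(1))
  true_hbond_frames <- lapply(seq_len(p_n), function(p)
    which(pair_d[, p] <= hb_cut[p]))

  ch_a <- chain_a$atoms$chain_id[1]; ch_b <- chain_b$atoms$chain_id[1]
  heavy_a <- which(atoms$chain_id == ch_a & atoms$element != "H")
  heavy_b <- which(atoms$chain_id == ch_b & atoms$element != "H")
  interface_per_frame <- vector("list", t_n)
  for (f in seq_len(t_n)) {
    xa <- matrix(coords[f, heavy_a, ], ncol = 3)
    xb <- matrix(coords[f, heavy_b, ], ncol = 3)
    d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
      outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
    close <- d2 <= spec$interface_cutoff^2
    interface_per_frame[[f]] <- list(
      a = sort(unique(atoms$res_seq[heavy_a][rowSums(close) > 0])),
      b = sort(unique(atoms$res_seq[heavy_b][colSums(close) > 0])))
  }
  persistent <- list(
    a = Reduce(intersect, lapply(interface_per_frame, `[[`, "a")),
    b = Reduce(intersect, lapply(interface_per_frame, `[[`, "b")))
  list(trajectory = traj,
       truth = list(state_labels = state_labels, pair_distances = pair_d,
                    true_hbond_frames = true_hbond_frames,
                    interface_per_frame = interface_per_frame,
                    true_interface_residues = persistent))
}

#' Generate a complete ground-truthed synthetic dimer trajectory
#'
#' Convenience driver: samples one hidden-state sequence, draws both
#' chains' dihedrals from it, rebuilds ideal-geometry chains A and B,
#' attaches the glycan stand-ins, and rigidly assembles the dimer with the
#' spec's contact pairs.  Bit-reproducible for a given `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @return list with `trajectory`, `truth` (see [assemble_dimer()], plus
#'   the hidden-state sequence), `dihedrals` (list of per-chain
#'   [dihedral_series]) and the `spec`.
#' @export
simulate_dimer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  z <- markov_labels(spec)
  cp <- spec$contact_pairs
  extras_for <- function(chain, res_col, name_col) {
    ex <- data.frame(res_seq = cp[[res_col]], name = cp[[name_col]],
                     stringsAsFactors = FALSE)
    ex <- ex[!ex$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
    gs <- spec$glycan_sites
    if (!is.null(gs) && nrow(gs)) {
      gly <- gs[gs$chain == chain, , drop = FALSE]
      if (nrow(gly))
        ex <- rbind(ex, data.frame(res_seq = gly$res_seq, name = "ND2",
                                   stringsAsFactors = FALSE))
    }
    unique(ex)
  }
  sa <- sample_dihedral_series(spec, "A", state_labels = z, seed = NULL)
  sb <- sample_dihedral_series(spec, "B", state_labels = z, seed = NULL)
  times <- (seq_len(spec$n_frames) - 1) * spec$time_step
  tra <- build_backbone(sa$series, "A", extra_atoms = extras_for("A", "res_a", "name_a"),
                        times = times)
  trb <- build_backbone(sb$series, "B", extra_atoms = extras_for("B", "res_b", "name_b"),
                        times = times)
  gs <- spec$glycan_sites
  if (!is.null(gs) && nrow(gs)) {
    for (r in seq_len(nrow(gs))) {
      if (gs$chain[r] == "A") tra <- add_glycan_standin(tra, "A", gs$res_seq[r])
      else trb <- add_glycan_standin(trb, "B", gs$res_seq[r])
    }
  }
  out <- assemble_dimer(tra, trb, spec, state_labels = z, seed = NULL)
  out$dihedrals <- list(A = sa$series, B = sb$series)
  out$spec <- spec
  out
}
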