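# Trajectory container and multi-model PDB input/output.
#
# A `trajectory` is the central data structure: a fixed atom table plus a
# T x M x 3 coordinate array (Angstrom) and per-frame times (ns).  Heavy
# lifting of PDB parsing/writing is delegated to bio3d; this layer adds the
# validation and per-model diagnostics the rest of the package relies on.

# Bondi van der Waals radii (Angstrom) for the elements this package meets.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  if (any(is.na(r))) {
    bad <- unique(element[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(r)
}

# Guess the element symbol from a PDB atom name when the element column is
# blank: strip digits, take the first letter; names like "HD21"/"1HB" are H.
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    if (nchar(nm) == 0L) stop("cannot infer element for atom '", nm, "'")
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a trajectory
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain_id` (one row per atom, order fixed
#'   across frames).
#' @param coords numeric array `T x M x 3` of coordinates in Angstrom, or a
#'   single `M x 3` matrix for a one-frame trajectory.
#' @param times numeric vector of frame times in ns, strictly increasing.
#'   Defaults to `0, 1, ..., T-1`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  t_n <- dim(coords)[1]
  m <- dim(coords)[2]
  if (t_n < 1L) stop("trajectory needs at least one frame")
  if (nrow(atoms) != m)
    stop("atom table has ", nrow(atoms), " rows but frames have ", m, " atoms")
  req <- c("serial", "name", "element", "res_name", "res_seq", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  vdw_radius(atoms$element)  # errors on unknown elements
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, res_seq, name): ",
         key[duplicated(key)][1])
  if (is.null(times)) times <- seq_len(t_n) - 1
  if (length(times) != t_n) stop("times length must equal frame count")
  if (t_n > 1L && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frame(s),", n_atoms(x), "atoms,",
      "chains", paste(unique(x$atoms$chain_id), collapse = ","), "\n")
  cat("  time span:", x$times[1], "-", x$times[n_frames(x)], "ns\n")
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Coordinates of one frame
#'
#' @param traj a `trajectory`.
#' @param frame frame index (1-based).
#' @return `M x 3` numeric matrix.
#' @export
frame_coords <- function(traj, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(traj))
  matrix(traj$coords[frame, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is a single-frame trajectory.  Atom order must be identical in
#' every model.  Alternate locations other than `''`/`'A'` are dropped with
#' a warning.  Frame times are taken from `times` (a numeric vector or the
#' path of a plain-text file with one ns value per line) and default to the
#' frame index.
#'
#' @param path PDB file path.
#' @param times optional numeric vector or times-file path.
#' @return A [trajectory].
#' @export
read_multimodel_pdb <- function(path, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    # per-model atom counts, for a diagnostic naming the offending model
    model_id <- cumsum(grepl("^MODEL", lines))
    counts <- table(model_id[is_atom])
    if (length(unique(as.integer(counts))) != 1L) {
      ref <- as.integer(counts[1])
      bad <- names(counts)[as.integer(counts) != ref][1]
      stop("atom count mismatch in model ", bad, ": ",
           counts[bad], " atoms, expected ", ref, call. = FALSE)
    }
  }
  alt <- substr(lines[is_atom], 17, 17)
  if (any(!alt %in% c(" ", "", "A"))) {
    warning("dropping alternate locations other than ''/'A'")
    drop <- is_atom & !(substr(lines, 17, 17) %in% c(" ", "", "A"))
    writeLines(lines[!drop], con = tmp <- tempfile(fileext = ".pdb"))
    path <- tmp
    on.exit(unlink(tmp), add = TRUE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  elem <- a$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) elem[blank] <- element_from_name(a$elety[blank])
  atoms <- data.frame(serial = a$eleno, name = a$elety,
                      element = trimws(elem), res_name = a$resid,
                      res_seq = a$resno, chain_id = a$chain,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  t_n <- nrow(xyz)
  coords <- array(NA_real_, dim = c(t_n, nrow(atoms), 3))
  for (f in seq_len(t_n)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (is.character(times)) times <- as.numeric(readLines(times, warn = FALSE))
  trajectory(atoms, coords, times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, fixed-column PDB formatting.
#' Errors if any coordinate exceeds the PDB `%8.3f` field width.
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1L) stop("empty frame list")
  if (any(abs(traj$coords) > 9999.999))
    stop("coordinates exceed the PDB fixed-column field width")
  t_n <- n_frames(traj)
  m <- n_atoms(traj)
  xyz <- matrix(NA_real_, nrow = t_n, ncol = 3L * m)
  for (f in seq_len(t_n)) {
    xyz[f, ] <- as.numeric(t(frame_coords(traj, f)))
  }
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", m),
                   eleno = a$serial, elety = a$name, resid = a$res_name,
                   chain = a$chain_id, resno = a$res_seq, elesy = a$element)
  invisible(path)
}

#' Select atom indices
#'
#' Indices (topology order) of atoms matching all given criteria; criteria
#' left `NULL` do not filter.
#'
#' @param traj a [trajectory].
#' @param chain single chain id character (or vector of ids).
#' @param res_range inclusive `(lo, hi)` integer pair of author residue
#'   numbers.
#' @param atom_names character set of atom names (e.g. `"CA"`).
#' @param heavy if `TRUE`, restrict to non-hydrogen atoms.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, chain = NULL, res_range = NULL,
                         atom_names = NULL, heavy = FALSE) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2L)
    keep <- keep & a$res_seq >= res_range[1] & a$res_seq <= res_range[2]
  }
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  if (heavy) keep <- keep & a$element != "H"
  which(keep)
}

#' Resolve an atom specification string
#'
#' Atom specs follow the `chain:res_seq:name` convention used for
#' hydrogen-bond pairs, e.g. `"A:226:HD21"`.
#'
#' @param traj a [trajectory].
#' @param spec atom spec string.
#' @return single atom index.
#' @export
resolve_atom <- function(traj, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("atom spec must be 'chain:res_seq:name', got '", spec, "'")
  idx <- which(traj$atoms$chain_id == parts[1] &
               traj$atoms$res_seq == as.integer(parts[2]) &
               traj$atoms$name == parts[3])
  if (length(idx) != 1L)
    stop("atom spec '", spec, "' matched ", length(idx), " atoms")
  idx
}

# "frame view": atoms plus one frame's coordinates, used by the per-frame
# analyses (SASA, interface).
frame_view <- function(traj, frame = 1L) {
  list(atoms = traj$atoms, xyz = frame_coords(traj, frame),
       time = traj$times[frame])
}
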