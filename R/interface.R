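# Interface residue detection, contact typing, snapshot-consensus hot
# spots, buried-area metrics and glycan contact tables.
#
# Interface membership is a transparent distance criterion: a residue is in
# the interface of a snapshot when any of its heavy atoms lies within a
# cutoff (default 5 Angstrom) of the other chain.  Contacts are typed with
# a fixed priority -- hydrogen bond, then carbon-hydrogen, then van der
# Waals -- and the hot spots of a trajectory are the residues present in
# the interface of every analysed snapshot.

# Fixed donor/acceptor atom tables for the 20 amino acids plus the
# GlcNAc-like stand-in (NAG).  Backbone N donates (except proline),
# backbone O accepts, side chains per standard chemistry; no protonation
# inference is attempted.
.hb_donors <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG",
  NAG = c("N2", "O3", "O4", "O6"))
.hb_acceptors <- list(
  backbone = "O",
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD", SER = "OG", THR = "OG1", TYR = "OH",
  CYS = "SG", NAG = c("O3", "O4", "O5", "O6", "O7"))

is_hb_donor <- function(res_name, name) {
  (name == "N" & res_name != "PRO") |
    mapply(function(rn, nm) nm %in% (.hb_donors[[rn]] %||% character(0)),
           res_name, name, USE.NAMES = FALSE)
}

is_hb_acceptor <- function(res_name, name) {
  name == "O" |
    mapply(function(rn, nm) nm %in% (.hb_acceptors[[rn]] %||% character(0)),
           res_name, name, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a single atom-atom contact
#'
#' Typing rules, applied in priority order (a pair carries one kind):
#' \describe{
#'   \item{hydrogen_bond}{both atoms N/O/S with one a plausible donor and
#'     the other an acceptor at heavy-atom distance <= 3.5 Angstrom, or a
#'     donor hydrogen within 2.5 Angstrom of an acceptor;}
#'   \item{carbon_hydrogen}{one atom carbon, the other N/O, distance in
#'     (3.5, 3.8];}
#'   \item{van_der_waals}{any other heavy-atom pair within 4.5 Angstrom.}
#' }
#'
#' @param atom_a,atom_b one-row data.frames with `name`, `element`,
#'   `res_name` columns (rows of a trajectory atom table).
#' @param distance inter-atom distance in Angstrom.
#' @return `"hydrogen_bond"`, `"carbon_hydrogen"`, `"van_der_waals"`, or
#'   `NA` if no contact criterion is met.
#' @export
classify_contact <- function(atom_a, atom_b, distance) {
  ea <- atom_a$element; eb <- atom_b$element
  nos <- c("N", "O", "S")
  if (ea %in% nos && eb %in% nos && distance <= 3.5) {
    da <- is_hb_donor(atom_a$res_name, atom_a$name)
    db <- is_hb_donor(atom_b$res_name, atom_b$name)
    aa <- is_hb_acceptor(atom_a$res_name, atom_a$name)
    ab <- is_hb_acceptor(atom_b$res_name, atom_b$name)
    if ((da && ab) || (db && aa)) return("hydrogen_bond")
  }
  if (distance <= 2.5) {  # donor hydrogen to acceptor
    if (ea == "H" && eb %in% nos &&
        is_hb_acceptor(atom_b$res_name, atom_b$name)) return("hydrogen_bond")
    if (eb == "H" && ea %in% nos &&
        is_hb_acceptor(atom_a$res_name, atom_a$name)) return("hydrogen_bond")
  }
  if (distance > 3.5 && distance <= 3.8 &&
      ((ea == "C" && eb %in% c("N", "O")) ||
       (eb == "C" && ea %in% c("N", "O")))) return("carbon_hydrogen")
  if (ea != "H" && eb != "H" && distance <= 4.5) return("van_der_waals")
  NA_character_
}

# Enumerate and type all contacts between two atom index sets of a frame.
enumerate_contacts <- function(atoms, xyz, idx_a, idx_b, max_dist = 4.5) {
  xa <- xyz[idx_a, , drop = FALSE]
  xb <- xyz[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  hits <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (!nrow(hits)) return(NULL)
  out <- vector("list", nrow(hits))
  n_out <- 0L
  for (r in seq_len(nrow(hits))) {
    i <- idx_a[hits[r, 1]]; j <- idx_b[hits[r, 2]]
    d <- sqrt(max(0, d2[hits[r, 1], hits[r, 2]]))
    kind <- classify_contact(atoms[i, ], atoms[j, ], d)
    if (is.na(kind)) next
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(
      atom_a = paste(atoms$chain_id[i], atoms$res_seq[i], atoms$name[i], sep = ":"),
      atom_b = paste(atoms$chain_id[j], atoms$res_seq[j], atoms$name[j], sep = ":"),
      res_a = atoms$res_seq[i], res_b = atoms$res_seq[j],
      res_name_a = atoms$res_name[i], res_name_b = atoms$res_name[j],
      distance = d, kind = kind, stringsAsFactors = FALSE)
  }
  if (n_out == 0L) return(NULL)
  do.call(rbind, out[seq_len(n_out)])
}

#' Interface analysis of one trajectory frame
#'
#' Residues with any heavy atom within `cutoff` of the other chain are
#' interface residues.  All inter-chain contacts are enumerated and typed
#' (see [classify_contact()]); the buried interface area is
#' `0.5 * (SASA(A) + SASA(B) - SASA(AB))` by Shrake-Rupley quadrature, and
#' the residue percentages are interface residues over chain residues.
#'
#' @param traj a [trajectory].
#' @param frame frame index.
#' @param chain_a,chain_b the two chain ids.
#' @param cutoff heavy-atom interface distance cutoff (Angstrom).
#' @param sasa_points sphere points for the buried-area quadrature.
#' @return object of class `interface_snapshot`: `time`, `residues_a`,
#'   `residues_b` (data.frames of `res_name`, `res_seq`), `contacts`,
#'   `interface_area` (Angstrom^2), `pct_interface_a`, `pct_interface_b`.
#' @export
interface_snapshot <- function(traj, frame = 1L, chain_a = "A", chain_b = "B",
                               cutoff = 5.0, sasa_points = 240L) {
  a <- traj$atoms
  for (ch in c(chain_a, chain_b)) {
    if (!any(a$chain_id == ch)) stop("chain ", ch, " not present")
  }
  xyz <- frame_coords(traj, frame)
  ha <- which(a$chain_id == chain_a & a$element != "H")
  hb <- which(a$chain_id == chain_b & a$element != "H")
  xa <- xyz[ha, , drop = FALSE]; xb <- xyz[hb, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  close <- d2 <= cutoff^2
  res_of <- function(idx, sel) {
    u <- unique(data.frame(res_name = a$res_name[idx][sel],
                           res_seq = a$res_seq[idx][sel],
                           stringsAsFactors = FALSE))
    u[order(u$res_seq), , drop = FALSE]
  }
  residues_a <- res_of(ha, rowSums(close) > 0)
  residues_b <- res_of(hb, colSums(close) > 0)
  ia_all <- which(a$chain_id == chain_a)
  ib_all <- which(a$chain_id == chain_b)
  contacts <- enumerate_contacts(a, xyz, ia_all, ib_all)
  # one shared quadrature frame (canonical orientation of the complex) so
  # the three SASA terms cancel exactly when the chains do not touch
  fv <- frame_view(traj, frame)
  fv$xyz <- canonical_orientation(fv$xyz)
  s_a <- sasa(fv, indices = ia_all, n_points = sasa_points,
              canonicalize = FALSE)$total
  s_b <- sasa(fv, indices = ib_all, n_points = sasa_points,
              canonicalize = FALSE)$total
  s_ab <- sasa(fv, indices = c(ia_all, ib_all), n_points = sasa_points,
               canonicalize = FALSE)$total
  area <- 0.5 * (s_a + s_b - s_ab)
  nres <- function(ch) length(unique(a$res_seq[a$chain_id == ch]))
  structure(list(time = traj$times[frame],
                 residues_a = residues_a, residues_b = residues_b,
                 contacts = contacts, interface_area = area,
                 pct_interface_a = 100 * nrow(residues_a) / nres(chain_a),
                 pct_interface_b = 100 * nrow(residues_b) / nres(chain_b),
                 chain_a = chain_a, chain_b = chain_b),
            class = "interface_snapshot")
}

#' @export
print.interface_snapshot <- function(x, ...) {
  cat("interface snapshot @", x$time, "ns:",
      nrow(x$residues_a), "+", nrow(x$residues_b), "interface residues,",
      if (is.null(x$contacts)) 0 else nrow(x$contacts), "typed contacts,",
      sprintf("area %.1f A^2", x$interface_area), "\n")
  invisible(x)
}

#' Consensus hot spots across snapshots
#'
#' A residue is a hot spot when it appears in the interface of every
#' analysed snapshot: the chainwise set intersection.
#'
#' @param snapshots list of [interface_snapshot()] results.
#' @return list with `residues_a`, `residues_b`: sorted residue numbers
#'   present in all snapshots.
#' @export
hotspot_consensus <- function(snapshots) {
  if (length(snapshots) == 0L) stop("empty snapshot list")
  sets_a <- lapply(snapshots, function(s) s$residues_a$res_seq)
  sets_b <- lapply(snapshots, function(s) s$residues_b$res_seq)
  list(residues_a = sort(Reduce(intersect, sets_a)),
       residues_b = sort(Reduce(intersect, sets_b)))
}

#' Typed glycan-protein contacts of one frame
#'
#' Enumerates and types the contacts from the atoms of the given glycan
#' residues to all protein residues, labelling each contact `intra_chain`
#' or `inter_chain` relative to the glycan's own chain.
#'
#' @param traj a [trajectory].
#' @param frame frame index.
#' @param glycan_residues data.frame with `chain`, `res_seq` columns.
#' @param cutoff maximum contact distance considered (Angstrom).
#' @return data.frame of typed contacts with a `span` column, or `NULL`
#'   when there are none.
#' @export
glycan_interactions <- function(traj, frame = 1L, glycan_residues,
                                cutoff = 4.5) {
  a <- traj$atoms
  xyz <- frame_coords(traj, frame)
  out <- NULL
  for (r in seq_len(nrow(glycan_residues))) {
    ch <- glycan_residues$chain[r]; rs <- glycan_residues$res_seq[r]
    gi <- which(a$chain_id == ch & a$res_seq == rs)
    if (!length(gi)) stop("unknown glycan residue ", ch, ":", rs)
    pi_ <- which(!(a$chain_id == ch & a$res_seq == rs) & a$res_name != "NAG")
    cc <- enumerate_contacts(a, xyz, gi, pi_, max_dist = cutoff)
    if (is.null(cc)) next
    part_chain <- sub(":.*", "", cc$atom_b)
    cc$span <- ifelse(part_chain == ch, "intra_chain", "inter_chain")
    cc$glycan <- paste(ch, rs, sep = ":")
    out <- rbind(out, cc)
  }
  out
}

#' Interface summary over a set of snapshot times
#'
#' Maps each requested time to its nearest frame (warning when the match is
#' worse than half the frame spacing; error when outside the trajectory
#' span), analyses each snapshot, and reports one summary row per snapshot
#' plus the consensus hot-spot set.
#'
#' @param traj a [trajectory].
#' @param times snapshot times in ns.  The documented study-style default
#'   is `c(0, 20, 60, 100, 120, 160, 170)`.
#' @param chain_a,chain_b chain ids.
#' @param cutoff interface distance cutoff (Angstrom).
#' @param sasa_points sphere points for buried-area quadrature.
#' @return list with `summary` (one row per snapshot: time, frame, residue
#'   counts, contacts, area, percentages), `snapshots`, and `hotspots`.
#' @export
snapshot_report <- function(traj, times = c(0, 20, 60, 100, 120, 160, 170),
                            chain_a = "A", chain_b = "B", cutoff = 5.0,
                            sasa_points = 240L) {
  tr_t <- traj$times
  if (any(times < min(tr_t) | times > max(tr_t)))
    stop("requested time outside the trajectory span")
  frames <- vapply(times, function(tt) which.min(abs(tr_t - tt)), integer(1))
  dt <- abs(tr_t[frames] - times)
  spacing <- if (length(tr_t) > 1) stats::median(diff(tr_t)) else Inf
  if (any(dt > spacing / 2))
    warning("snapshot time(s) matched with |dt| > half the frame spacing")
  snaps <- lapply(frames, function(f)
    interface_snapshot(traj, f, chain_a, chain_b, cutoff, sasa_points))
  summary <- data.frame(
    time = times, frame = frames,
    n_residues_a = vapply(snaps, function(s) nrow(s$residues_a), integer(1)),
    n_residues_b = vapply(snaps, function(s) nrow(s$residues_b), integer(1)),
    n_contacts = vapply(snaps, function(s)
      if (is.null(s$contacts)) 0L else nrow(s$contacts), integer(1)),
    interface_area = vapply(snaps, function(s) s$interface_area, numeric(1)),
    pct_interface_a = vapply(snaps, function(s) s$pct_interface_a, numeric(1)),
    pct_interface_b = vapply(snaps, function(s) s$pct_interface_b, numeric(1)))
  summary$n_interface_residues <- summary$n_residues_a + summary$n_residues_b
  list(summary = summary, snapshots = snaps,
       hotspots = hotspot_consensus(snaps))
}
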