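# Interface detection, contact typing, hot-spot consensus, glycan tables.

atom_row <- function(name, element, res_name) {
  data.frame(name = name, element = element, res_name = res_name,
             stringsAsFactors = FALSE)
}

test_that("contact typing follows the priority rules and cutoffs", {
  asn <- atom_row("ND2", "N", "ASN")
  thr <- atom_row("OG1", "O", "THR")
  cc <- atom_row("CB", "C", "ALA")
  oo <- atom_row("O", "O", "ALA")
  expect_equal(classify_contact(asn, thr, 2.9), "hydrogen_bond")
  expect_equal(classify_contact(thr, asn, 2.9), "hydrogen_bond")  # symmetric
  expect_equal(classify_contact(cc, oo, 3.6), "carbon_hydrogen")
  expect_equal(classify_contact(cc, cc, 4.0), "van_der_waals")
  expect_true(is.na(classify_contact(cc, cc, 4.6)))
  # N/O pair that is donor-donor only falls through to vdW at close range
  bbn <- atom_row("N", "N", "ALA")
  lys <- atom_row("NZ", "N", "LYS")
  expect_equal(classify_contact(bbn, lys, 3.0), "van_der_waals")
  # hydrogen to acceptor within 2.5 A is a hydrogen bond
  hd <- atom_row("HD21", "H", "ASN")
  expect_equal(classify_contact(hd, thr, 2.0), "hydrogen_bond")
  expect_true(is.na(classify_contact(hd, cc, 2.0)))  # H to carbon: nothing
})

test_that("separated chains give an empty interface and ~zero buried area", {
  tr <- toy_two_chain(n_res = 6, sep = 30)
  snap <- interface_snapshot(tr, 1)
  expect_equal(nrow(snap$residues_a), 0)
  expect_equal(nrow(snap$residues_b), 0)
  expect_lt(abs(snap$interface_area), 1e-6)
  expect_error(interface_snapshot(tr, 1, chain_a = "Z"), "chain Z")
})

test_that("interface residue sets match the generator's ground truth", {
  spec <- synthetic_spec(n_res_per_chain = 16, n_frames = 6, n_states = 1,
                         concentration = 100, seed = 8)
  sim <- simulate_dimer(spec)
  for (f in c(1L, 4L)) {
    snap <- interface_snapshot(sim$trajectory, f)
    expect_equal(snap$residues_a$res_seq, sim$truth$interface_per_frame[[f]]$a)
    expect_equal(snap$residues_b$res_seq, sim$truth$interface_per_frame[[f]]$b)
  }
})

test_that("buried area equals the independently assembled SASA difference", {
  spec <- synthetic_spec(n_res_per_chain = 10, n_frames = 2, n_states = 1,
                         concentration = 100, seed = 8)
  sim <- simulate_dimer(spec)
  tr <- sim$trajectory
  snap <- interface_snapshot(tr, 1, sasa_points = 240)
  ia <- select_atoms(tr, chain = "A")
  ib <- select_atoms(tr, chain = "B")
  fv <- dimerscope:::frame_view(tr, 1)
  fv$xyz <- dimerscope:::canonical_orientation(fv$xyz)
  oracle <- 0.5 *
    (sasa(fv, indices = ia, n_points = 240, canonicalize = FALSE)$total +
     sasa(fv, indices = ib, n_points = 240, canonicalize = FALSE)$total -
     sasa(fv, indices = c(ia, ib), n_points = 240, canonicalize = FALSE)$total)
  expect_equal(snap$interface_area, oracle, tolerance = 1e-6)
})

test_that("interface detection is symmetric in the chain labels", {
  spec <- synthetic_spec(n_res_per_chain = 10, n_frames = 2, n_states = 1,
                         concentration = 100, seed = 8)
  sim <- simulate_dimer(spec)
  s1 <- interface_snapshot(sim$trajectory, 1, "A", "B")
  s2 <- interface_snapshot(sim$trajectory, 1, "B", "A")
  expect_identical(s1$residues_a, s2$residues_b)
  expect_identical(s1$residues_b, s2$residues_a)
  expect_equal(s1$interface_area, s2$interface_area, tolerance = 1e-9)
  expect_equal(nrow(s1$contacts), nrow(s2$contacts))
})

test_that("hot-spot consensus is the chainwise intersection and is monotone", {
  mk <- function(a, b) structure(list(
    residues_a = data.frame(res_name = "ALA", res_seq = a),
    residues_b = data.frame(res_name = "ALA", res_seq = b)),
    class = "interface_snapshot")
  s1 <- mk(c(1, 2), c(7, 8)); s2 <- mk(1, c(7, 9)); s3 <- mk(c(1, 3), 7)
  hs <- hotspot_consensus(list(s1, s2, s3))
  expect_equal(hs$residues_a, 1)
  expect_equal(hs$residues_b, 7)
  # disjoint snapshots: empty consensus is valid
  hs2 <- hotspot_consensus(list(mk(1, 1), mk(2, 2)))
  expect_length(hs2$residues_a, 0)
  # adding snapshots never grows the consensus
  hs12 <- hotspot_consensus(list(s1, s2))
  expect_true(all(hs$residues_a %in% hs12$residues_a))
  expect_error(hotspot_consensus(list()), "empty")
})

test_that("consensus on a synthetic dimer keeps only persistent residues", {
  spec <- synthetic_spec(
    n_res_per_chain = 16, n_frames = 24, n_states = 2, concentration = 200,
    transition_matrix = matrix(c(.8, .2, .2, .8), 2),
    contact_pairs = data.frame(
      res_a = c(8, 13), name_a = c("ND2", "OG1"), res_b = c(8, 13),
      name_b = c("OG1", "ND2"), target = c(3.0, 3.2), noise = 0,
      active_states = c("all", "1"), stringsAsFactors = FALSE),
    glycan_sites = data.frame(chain = character(0), res_seq = integer(0)),
    seed = 21)
  sim <- simulate_dimer(spec)
  z <- sim$truth$state_labels
  expect_true(any(z == 1) && any(z == 2))
  snaps <- lapply(seq_len(n_frames(sim$trajectory)), function(f)
    interface_snapshot(sim$trajectory, f, sasa_points = 60))
  hs <- hotspot_consensus(snaps)
  expect_equal(hs$residues_a, sim$truth$true_interface_residues$a)
  expect_equal(hs$residues_b, sim$truth$true_interface_residues$b)
  # the transient pair's residues are in some frames but not the consensus
  in_any_a <- sort(unique(unlist(lapply(sim$truth$interface_per_frame, `[[`, "a"))))
  expect_true(13 %in% in_any_a)
  expect_false(13 %in% hs$residues_a)
})

test_that("glycan contacts are typed and span-labelled correctly", {
  spec <- synthetic_spec(n_res_per_chain = 12, n_frames = 2, n_states = 1,
                         concentration = 100, seed = 6)
  sim <- simulate_dimer(spec)
  gl <- glycan_interactions(sim$trajectory, 1,
                            data.frame(chain = "A", res_seq = 509L))
  expect_false(is.null(gl))
  expect_true(all(gl$kind %in% c("hydrogen_bond", "carbon_hydrogen",
                                 "van_der_waals")))
  part_chain <- sub(":.*", "", gl$atom_b)
  expect_identical(gl$span,
                   ifelse(part_chain == "A", "intra_chain", "inter_chain"))
  expect_error(glycan_interactions(sim$trajectory, 1,
                                   data.frame(chain = "A", res_seq = 999L)),
               "unknown glycan")
})

test_that("snapshot report maps times to frames and summarises consistently", {
  spec <- synthetic_spec(n_res_per_chain = 10, n_frames = 12, n_states = 1,
                         concentration = 100, seed = 9)
  sim <- simulate_dimer(spec)
  rep_ <- snapshot_report(sim$trajectory, times = c(0, 5, 11),
                          sasa_points = 60)
  expect_equal(nrow(rep_$summary), 3)
  expect_equal(rep_$summary$frame, c(1, 6, 12))
  expect_equal(rep_$summary$n_interface_residues,
               rep_$summary$n_residues_a + rep_$summary$n_residues_b)
  expect_true(all(rep_$summary$pct_interface_a >= 0 &
                  rep_$summary$pct_interface_a <= 100))
  expect_error(snapshot_report(sim$trajectory, times = c(0, 50)), "span")
  # a single-frame trajectory answers a single time
  one <- sim$trajectory
  one$coords <- one$coords[1, , , drop = FALSE]
  one$times <- one$times[1]
  r1 <- snapshot_report(one, times = 0, sasa_points = 60)
  expect_equal(nrow(r1$summary), 1)
})
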