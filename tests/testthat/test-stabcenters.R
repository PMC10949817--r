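test_that("residue contact applies vdW-sum-plus-tolerance with a strict <", {
  two_c <- function(d) mini_structure(
    atom_row("CA", "C", 1, "GLY", "A", 0, 0, 0),
    atom_row("CA", "C", 20, "GLY", "A", d, 0, 0))
  # carbon/carbon threshold: 1.70 + 1.70 + 1.0 = 4.40
  r1 <- residue_contact(two_c(4.3), "A", 1, "A", 20)
  expect_true(r1$contact)
  expect_equal(r1$min_distance, 4.3)
  expect_false(residue_contact(two_c(4.5), "A", 1, "A", 20)$contact)
  # multi-atom residues agree with the exhaustive check
  s <- make_random_structure(n_res = 10, seed = 3)
  for (pr in list(c(1, 5), c(2, 9), c(3, 8))) {
    got <- residue_contact(s, "A", pr[1], "A", pr[2])
    want <- oracle_pair(s, "A", pr[1], "A", pr[2])
    expect_equal(got$contact, want$contact)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
  }
})

test_that("the planted crossing is the one and only stabilization center", {
  fx <- make_sc_fixture()
  s <- fx$structure
  det <- detect_scs_frame(s)
  expect_equal(sc_pair_key(det), sc_pair_key(fx$manifest$planted_sc))
  # the planted non-SC contact touches but fails the triplet criterion
  ns <- fx$manifest$planted_non_sc
  expect_true(residue_contact(s, ns$chain_a, ns$res_a, ns$chain_b,
                              ns$res_b)$contact)
  expect_false(is_stabilization_center(s, ns$chain_a, ns$res_a, ns$chain_b,
                                       ns$res_b))
})

test_that("short sequence separation defeats an otherwise perfect contact", {
  fx <- make_sc_fixture(sep = 5)
  cp <- fx$manifest$central_pair
  expect_false(is_stabilization_center(fx$structure, "A", cp[1], "A", cp[2]))
  expect_true(residue_contact(fx$structure, "A", cp[1], "A", cp[2])$contact)
})

test_that("a straight chain has no stabilization centers", {
  rows <- lapply(1:12, function(i) atom_row("CA", "C", i, "GLY", "A",
                                            i * 3.8, 0, 0))
  s <- do.call(mini_structure, rows)
  expect_equal(nrow(detect_scs_frame(s)), 0L)
})

test_that("the SC relation is symmetric and monotone in the tolerance", {
  fx <- make_sc_fixture()
  s <- fx$structure
  rs <- oracle_residues(s)
  set.seed(21)
  picks <- sample(nrow(rs), 6)
  for (i in picks[1:3]) for (j in picks[4:6]) {
    expect_equal(
      is_stabilization_center(s, rs$chain[i], rs$res[i], rs$chain[j], rs$res[j]),
      is_stabilization_center(s, rs$chain[j], rs$res[j], rs$chain[i], rs$res[i]))
  }
  # enlarging the tolerance never removes a detection
  strict <- detect_scs_frame(s, params = analysis_parameters(sc_vdw_tolerance = 1.0))
  loose <- detect_scs_frame(s, params = analysis_parameters(sc_vdw_tolerance = 1.6))
  expect_true(all(sc_pair_key(strict) %in% sc_pair_key(loose)))
})

test_that("frame detection equals the exhaustive reference on random folds", {
  for (seed in 1:5) {
    s <- make_random_structure(n_res = 22, n_chains = 1, seed = seed,
                               confine = 14)
    got <- sc_pair_key(detect_scs_frame(s))
    want <- sc_pair_key(oracle_detect_scs(s))
    expect_equal(got, want)
  }
  # a two-chain instance exercises the cross-chain separation rule
  s2 <- make_random_structure(n_res = 15, n_chains = 2, seed = 9,
                              confine = 12)
  expect_equal(sc_pair_key(detect_scs_frame(s2)),
               sc_pair_key(oracle_detect_scs(s2)))
})

test_that("pair classification distinguishes the three interface classes", {
  cls <- classify_trans_gj(c("A", "A", "C"), c("J", "B", "C"))
  expect_equal(cls$class,
               c("trans-GJ", "inter-subunit-intra-HC", "intra-subunit"))
  expect_equal(cls$subunit_pair, c("A-J", NA, NA))
  # non-canonical cross-HC pair keeps its literal chains, HC1 first
  cls2 <- classify_trans_gj("K", "A")
  expect_equal(cls2$class, "trans-GJ")
  expect_equal(cls2$subunit_pair, "A-K")
  expect_error(classify_trans_gj("A", "Z"), "unknown chain")
})

test_that("extracellular filtering applies both the loop and the 2% rule", {
  tab <- data.frame(
    chain_a = "A", res_a = c(50, 50, 100), name_a = "GLY",
    chain_b = "J", res_b = c(190, 190, 150), name_b = "GLY",
    class = "trans-GJ", subunit_pair = "A-J",
    fraction = c(0.05, 0.01, 0.9), stringsAsFactors = FALSE)
  kept <- filter_extracellular(tab)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$fraction, 0.05)
})

test_that("stability fractions track a deterministic make/break schedule", {
  fx <- make_sc_fixture()
  on <- schedule_onoff(100, 0.5, "deterministic")
  tr <- make_trajectory(fx$structure, n_frames = 100, jitter_sigma = 0,
                        schedule = list(sc_onoff_event(fx, on)),
                        seed = 2)$trajectory
  ts <- sc_timeseries(tr)
  key <- sc_pair_key(fx$manifest$planted_sc)
  row <- ts$stability[sc_pair_key(ts$stability) == key, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$fraction, 0.5)
  expect_equal(row$n_frames_present, 50L)
  # reported min distance equals the brute-force minimum over present frames
  want <- min(vapply(which(on), function(i)
    oracle_pair(frame_structure(tr, i), "A", 5, "A", 17)$min_distance, 0))
  expect_equal(row$d_min, want, tolerance = 1e-9)
  # single-frame trajectories give all-or-nothing fractions
  tr1 <- gj_trajectory(fx$structure,
                       matrix(as.numeric(t(coords(fx$structure))), nrow = 1),
                       10)
  ts1 <- sc_timeseries(tr1)
  expect_true(all(ts1$stability$fraction %in% c(0, 1)))
})
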