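test_that("generators are deterministic for a fixed seed", {
  f1 <- make_sc_fixture(seed = 3)
  f2 <- make_sc_fixture(seed = 3)
  expect_identical(coords(f1$structure), coords(f2$structure))
  r1 <- make_random_structure(seed = 5)
  r2 <- make_random_structure(seed = 5)
  expect_identical(coords(r1), coords(r2))
  # byte-identical PDB output for the same seed
  t1 <- make_trajectory(f1$structure, n_frames = 4, jitter_sigma = 0.1,
                        seed = 9)$trajectory
  t2 <- make_trajectory(f1$structure, n_frames = 4, jitter_sigma = 0.1,
                        seed = 9)$trajectory
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_trajectory(t1, p1); write_trajectory(t2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("fixture manifests state verified planted truths", {
  fx <- make_sc_fixture()
  expect_true(fx$manifest$passes_separation)
  expect_equal(fx$manifest$planted_sc$res_a, 5L)
  expect_equal(fx$manifest$planted_sc$res_b, 17L)
  tc <- make_toy_connexon(12, "closed")
  expect_equal(tc$manifest$expected$n_disulfides, 36L)
  hx <- make_toy_connexon(6, "closed")
  expect_equal(hx$manifest$expected$n_disulfides, 18L)
  oc <- make_toy_connexon(12, "open", plants = "cys_cys")
  expect_equal(oc$manifest$expected$n_cys_cys_hbonds, 12L)
  # infeasible requests are refused
  expect_error(make_toy_connexon(6, "open", plants = "cys_cys"), "dodecamer")
  expect_error(make_toy_connexon(12, "closed", plants = "cys_cys"), "open")
  expect_error(make_toy_connexon(7), "6 or 12")
  expect_error(make_sc_fixture(cos_cross = 0.2), "window")
})

test_that("trajectory span follows frame count and interval", {
  base <- make_sc_fixture()$structure
  tr <- make_trajectory(base, n_frames = 100, interval_ps = 10,
                        seed = 2)$trajectory
  expect_equal(n_frames(tr), 100L)
  expect_equal(max(frame_times(tr)), 1000)  # 1 ns at 10 ps spacing
  expect_equal(n_atoms(tr$topology) * 3L, ncol(tr$xyz))
})

test_that("scheduled atoms sit exactly on their on/off geometry", {
  fx <- make_sc_fixture()
  on <- schedule_onoff(10, 0.3, "deterministic")
  ev <- sc_onoff_event(fx, on)
  made <- make_trajectory(fx$structure, n_frames = 10, jitter_sigma = 0.5,
                          schedule = list(ev), seed = 6)
  tr <- made$trajectory
  expect_equal(made$manifest$events[[1]]$fraction, 0.3)
  cols <- as.vector(rbind(3L * ev$atoms - 2L, 3L * ev$atoms - 1L,
                          3L * ev$atoms))
  for (i in c(1, 4, 10)) {
    want <- if (on[i]) ev$xyz_on else ev$xyz_off
    expect_equal(matrix(tr$xyz[i, cols], ncol = 3, byrow = TRUE), unname(want),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # schedule validation
  expect_error(make_trajectory(fx$structure, n_frames = 5,
                               schedule = list(ev)), "length")
  bad <- ev; bad$atoms <- c(bad$atoms, n_atoms(fx$structure) + 1L)
  expect_error(make_trajectory(fx$structure, n_frames = 10,
                               schedule = list(bad)), "beyond")
})

test_that("Bernoulli schedules recover the planted fraction within 3 sigma", {
  fx <- make_sc_fixture()
  n <- 400
  p <- 0.5
  on <- schedule_onoff(n, p, "bernoulli", seed = 13)
  tr <- make_trajectory(fx$structure, n_frames = n, jitter_sigma = 0.05,
                        schedule = list(sc_onoff_event(fx, on)),
                        seed = 13)$trajectory
  ts <- sc_timeseries(tr)
  key <- sc_pair_key(fx$manifest$planted_sc)
  row <- ts$stability[sc_pair_key(ts$stability) == key, ]
  # the detector recovers the realized schedule exactly under small jitter
  expect_equal(row$fraction, mean(on))
  expect_lt(abs(row$fraction - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("cylinder fixtures reject radii inside the atom surface", {
  expect_error(make_cylinder_channel(c(6.7, 1.5)), "vdW")
  cy <- make_cylinder_channel(c(5, 6, 7), spacing = 3)
  expect_equal(cy$manifest$analytic_radius, c(5, 6, 7) - 1.7)
  # monotone radius taper gives a monotone analytic profile
  expect_true(!is.unsorted(cy$manifest$analytic_radius))
})
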