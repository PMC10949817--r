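# hand-placed interface pieces: a Gln58 donor on HC1, acceptors on HC2
trans_fixture <- function(d_ha) {
  mini_structure(
    atom_row("NE2", "N", 58, "GLN", "A", 0, 0, 0),
    atom_row("HE21", "H", 58, "GLN", "A", 1, 0, 0),
    atom_row("CA", "C", 58, "GLN", "A", 0, 1.6, 0),
    atom_row("OE1", "O", 58, "GLN", "J", 1 + d_ha, 0, 0),
    atom_row("CA", "C", 58, "GLN", "J", 1 + d_ha, 1.6, 0))
}

test_that("trans-GJ H-bonds obey the 2.5 A donor-H/acceptor cutoff", {
  expect_equal(nrow(detect_trans_gj_hbonds(trans_fixture(2.4))), 1L)
  expect_equal(nrow(detect_trans_gj_hbonds(trans_fixture(2.6))), 0L)
  b <- detect_trans_gj_hbonds(trans_fixture(2.4))
  expect_equal(b$distance, 2.4, tolerance = 1e-9)
  expect_equal(b$subunit_pair, "A-J")
  expect_equal(b$donor, "NE2")
  expect_equal(b$acceptor, "OE1")
})

test_that("intra-hemichannel interface bonds are excluded unless requested", {
  s <- mini_structure(
    atom_row("NE2", "N", 58, "GLN", "A", 0, 0, 0),
    atom_row("HE21", "H", 58, "GLN", "A", 1, 0, 0),
    atom_row("CA", "C", 58, "GLN", "A", 0, 1.6, 0),
    atom_row("OE1", "O", 57, "GLN", "B", 3.0, 0, 0),  # same HC
    atom_row("CA", "C", 57, "GLN", "B", 3.0, 1.6, 0))
  expect_equal(nrow(detect_trans_gj_hbonds(s)), 0L)
  expect_equal(nrow(detect_trans_gj_hbonds(s, restrict = "intra")), 1L)
  expect_equal(nrow(detect_trans_gj_hbonds(s, restrict = "all")), 1L)
})

test_that("donors without any hydrogens in the frame raise a clear error", {
  s <- mini_structure(
    atom_row("NE2", "N", 58, "GLN", "A", 0, 0, 0),
    atom_row("CA", "C", 58, "GLN", "A", 0, 1.6, 0),
    atom_row("OE1", "O", 58, "GLN", "J", 2, 0, 0),
    atom_row("CA", "C", 58, "GLN", "J", 2, 1.6, 0))
  expect_error(detect_trans_gj_hbonds(s), "explicit hydrogens")
})

test_that("trans-GJ detection equals brute-force enumeration on random frames", {
  set.seed(31)
  for (rep in 1:5) {
    rows <- list()
    for (ch in c("A", "B", "J", "K")) for (r in 55:58) {
      p <- runif(3, 0, 8)
      rn <- c("ASN", "THR", "GLN", "GLN")[r - 54]
      rows <- c(rows, list(
        atom_row("N", "N", r, rn, ch, p[1], p[2], p[3]),
        atom_row("H", "H", r, rn, ch, p[1] + 1, p[2], p[3]),
        atom_row("O", "O", r, rn, ch, p[1], p[2] + 1.6, p[3])))
      if (rn == "GLN")
        rows <- c(rows, list(
          atom_row("OE1", "O", r, rn, ch, p[1], p[2], p[3] + 1.8)))
    }
    s <- do.call(mini_structure, rows)
    got <- detect_trans_gj_hbonds(s)
    # direct enumeration: every donor hydrogen against every acceptor
    a <- s$atoms
    n_bonds <- 0L
    hs <- which(a$is_hydrogen)
    for (h in hs) {
      heavy <- which(!a$is_hydrogen)
      dh <- sqrt((a$x[heavy] - a$x[h])^2 + (a$y[heavy] - a$y[h])^2 +
                   (a$z[heavy] - a$z[h])^2)
      don <- heavy[which.min(dh)]
      if (min(dh) > 1.25) next
      if (!(a$name[don] %in% c("N", "NE2"))) next
      hc_d <- a$chain_id[don] %in% c("A", "B")
      for (acc in which(a$name %in% c("O", "OE1"))) {
        if (a$chain_id[acc] %in% c("A", "B") == hc_d) next
        d <- sqrt((a$x[acc] - a$x[h])^2 + (a$y[acc] - a$y[h])^2 +
                    (a$z[acc] - a$z[h])^2)
        if (d < 2.5) n_bonds <- n_bonds + 1L
      }
    }
    expect_equal(nrow(got), n_bonds)
  }
})

test_that("Cys-Cys thiol bonds obey the 4.3 A S/H cutoff", {
  fix <- function(d) mini_structure(
    atom_row("SG", "S", 54, "CYS", "A", 0, 0, 0),
    atom_row("CB", "C", 54, "CYS", "A", 0, 1.8, 0),
    atom_row("SG", "S", 61, "CYS", "A", 10, 0, 0),
    atom_row("CB", "C", 61, "CYS", "A", 10, 1.8, 0),
    atom_row("HG1", "H", 61, "CYS", "A", d, 0, 0))
  expect_equal(nrow(detect_cys_cys_hbonds(fix(4.2))), 1L)
  expect_equal(nrow(detect_cys_cys_hbonds(fix(4.4))), 0L)
  b <- detect_cys_cys_hbonds(fix(4.2))
  expect_equal(b$distance, 4.2, tolerance = 1e-9)
  expect_equal(b$res_d, 61L)  # the HG1 side donates
  expect_equal(b$res_a, 54L)
})

test_that("one donor and one acceptor geometry per subunit totals a dozen bonds", {
  oc <- make_toy_connexon(12, "open", plants = "cys_cys")
  b <- detect_cys_cys_hbonds(oc$structure)
  expect_equal(nrow(b), 12L)
  expect_true(all(b$distance < 4.3))
  # one donor and one acceptor per chain
  expect_equal(sort(table(b$chain_d)), sort(table(b$chain_a)))
  expect_true(all(table(b$chain_d) == 1))
})

test_that("Cys-interface bonds require both the 4.1 A and 3.2 A criteria", {
  fix <- function(d_s, d_h) mini_structure(
    atom_row("O", "O", 58, "GLN", "A", 0, 0, 0),
    atom_row("CA", "C", 58, "GLN", "A", 0, 1.6, 0),
    atom_row("SG", "S", 61, "CYS", "A", d_s, 0, 0),
    atom_row("CB", "C", 61, "CYS", "A", d_s + 1.8, 0, 0),
    atom_row("HG1", "H", 61, "CYS", "A", d_h, 0, 0))
  hit <- detect_cys_interface_hbonds(fix(4.0, 3.1))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$s_heavy_distance, 4.0, tolerance = 1e-9)
  expect_equal(hit$distance, 3.1, tolerance = 1e-9)
  # H criterion fails
  expect_equal(nrow(detect_cys_interface_hbonds(fix(4.0, 3.3))), 0L)
  # S-heavy criterion fails regardless of the hydrogen
  expect_equal(nrow(detect_cys_interface_hbonds(fix(4.2, 3.1))), 0L)
})

test_that("the planted Cys61-Gln58 intra-subunit geometry is detected", {
  oc <- make_toy_connexon(12, "open", plants = "cys_interface")
  b <- detect_cys_interface_hbonds(oc$structure)
  hit <- b[b$res_d == 61 & b$res_a == 58 & b$acceptor == "O" &
             b$chain_d == b$chain_a, ]
  expect_equal(nrow(hit), 12L)  # one per chain
  expect_true(all(hit$s_heavy_distance < 4.1))
  expect_true(all(hit$distance < 3.2))
})

test_that("no detector ever reports a bond violating its own cutoffs", {
  oc <- make_toy_connexon(12, "open",
                          plants = c("cys_cys", "trans_gj", "cys_interface"))
  s <- oc$structure
  tg <- detect_trans_gj_hbonds(s)
  expect_true(all(tg$distance < 2.5))
  cc <- detect_cys_cys_hbonds(s)
  expect_true(all(cc$distance < 4.3))
  ci <- detect_cys_interface_hbonds(s)
  expect_true(all(ci$s_heavy_distance < 4.1 & ci$distance < 3.2))
  # trans-GJ count is monotone non-decreasing in the H...A cutoff
  n1 <- nrow(detect_trans_gj_hbonds(s, params = analysis_parameters(
    hbond_HA_cutoff = 2.0)))
  n2 <- nrow(tg)
  n3 <- nrow(detect_trans_gj_hbonds(s, params = analysis_parameters(
    hbond_HA_cutoff = 3.0)))
  expect_true(n1 <= n2 && n2 <= n3)
})

test_that("disulfide assignment records canonical bonds and manages thiols", {
  dod <- make_toy_connexon(12, "closed")$structure
  asg <- assign_disulfides(dod, mode = "closed")
  expect_equal(nrow(asg$bonds), 36L)
  expect_true(all(asg$bonds$sg_sg_distance < 2.3))
  hx <- make_toy_connexon(6, "closed")$structure
  expect_equal(nrow(assign_disulfides(hx, mode = "closed")$bonds), 18L)
  # open mode: no bonds, every canonical Cys gains HG1
  op <- assign_disulfides(hx, mode = "open")
  expect_equal(nrow(op$bonds), 0L)
  hg <- select_atoms(op$structure, resid = "CYS", elety = "HG1")
  expect_equal(n_atoms(hg), 6L * 6L)
  # the added hydrogen sits 1.34 A from SG, opposite CB
  a <- op$structure$atoms
  sg <- a[a$chain_id == "A" & a$res_num == 54 & a$name == "SG", ]
  h <- a[a$chain_id == "A" & a$res_num == 54 & a$name == "HG1", ]
  expect_equal(sqrt(sum((sg[c("x", "y", "z")] - h[c("x", "y", "z")])^2)),
               1.34, tolerance = 1e-9)
  # a chain missing a canonical Cys is named
  crop <- select_atoms(hx, resno = setdiff(20:230, 61))
  expect_error(assign_disulfides(crop, mode = "closed"), "Cys 61")
})

test_that("closed assignment then geometric detection agree: 3 bonds per chain", {
  dod <- make_toy_connexon(12, "closed")$structure
  found <- detect_disulfides(dod)
  expect_equal(nrow(found), 36L)
  expect_true(all(found$canonical))
  expect_true(all(found$sg_sg_distance <= 2.3))
  expect_equal(as.integer(table(found$chain_a)), rep(3L, 12))
  # typical S-S length accepted, a stretched pair is not
  pair <- function(d) mini_structure(
    atom_row("SG", "S", 54, "CYS", "A", 0, 0, 0),
    atom_row("SG", "S", 198, "CYS", "A", d, 0, 0))
  expect_equal(nrow(detect_disulfides(pair(2.05))), 1L)
  expect_equal(nrow(detect_disulfides(pair(3.5))), 0L)
  # open state has no S-S pairs inside the cutoff
  expect_equal(nrow(detect_disulfides(
    make_toy_connexon(12, "open")$structure)), 0L)
})

test_that("H-bond time series count schedules and chain restrictions", {
  oc <- make_toy_connexon(12, "open", plants = "cys_cys")
  s <- oc$structure
  # break the planted bonds in half the frames by moving all thiol hydrogens
  hg <- which(s$atoms$name == "HG1")
  base <- as.matrix(s$atoms[hg, c("x", "y", "z")])
  ev <- list(name = "cys_bonds", atoms = hg,
             on = rep(c(TRUE, FALSE), each = 10),
             xyz_on = base, xyz_off = base + 50)
  tr <- make_trajectory(s, n_frames = 20, schedule = list(ev),
                        seed = 3)$trajectory
  ts <- hbond_timeseries(tr, "cys_cys")
  expect_equal(ts$counts$n_bonds, rep(c(12L, 0L), each = 10))
  # presence fraction of the schedule is recovered
  expect_equal(mean(ts$counts$n_bonds > 0), 0.5)
  # counting only HC1 halves the count (one donor or acceptor per chain)
  ts_af <- hbond_timeseries(tr, "cys_cys", chains_counted = LETTERS[1:6])
  expect_true(all(ts_af$counts$n_bonds <= ts$counts$n_bonds))
  # a bond whose chains lie outside the counted set is excluded
  ts_gl <- hbond_timeseries(tr, "cys_cys", chains_counted = c("G", "L"))
  expect_true(all(ts_gl$counts$n_bonds == 0L))
  # per-frame counts equal direct per-frame detector calls
  for (i in c(1, 11)) {
    expect_equal(ts$counts$n_bonds[i],
                 nrow(detect_cys_cys_hbonds(frame_structure(tr, i))))
  }
})
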