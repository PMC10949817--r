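rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("superposition recovers rigid motions exactly", {
  set.seed(11)
  x <- matrix(rnorm(30), ncol = 3)
  sup <- kabsch_superpose(x, x)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)
  # 90-degree rotated copy superposes to zero
  y <- x %*% t(rot_z(90)) + matrix(rep(c(3, -1, 2), each = 10), ncol = 3)
  sup2 <- kabsch_superpose(x, y)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_superposition(sup2, x), y, tolerance = 1e-8)
  expect_equal(det(sup2$rotation), 1, tolerance = 1e-8)
})

test_that("superposition rmsd matches the bio3d fitting oracle", {
  set.seed(12)
  for (rep in 1:10) {
    a <- matrix(rnorm(30, sd = 4), ncol = 3)
    b <- matrix(rnorm(30, sd = 4), ncol = 3)
    ours <- kabsch_superpose(a, b)$rmsd
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a))))
    oracle <- sqrt(mean(rowSums(
      (matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), ncol = 3),
                                matrix(rnorm(6), ncol = 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("chain translation shifts z exactly and inverts cleanly", {
  s <- make_toy_connexon(6, "closed")$structure
  s3 <- translate_chains(s, c("A", "B"), 3)
  moved <- s$atoms$chain_id %in% c("A", "B")
  expect_equal(s3$atoms$z[moved], s$atoms$z[moved] + 3)
  expect_equal(s3$atoms$z[!moved], s$atoms$z[!moved])
  expect_equal(s3$atoms$x, s$atoms$x)
  # zero offset is the identity; +d then -d restores coordinates
  expect_equal(translate_chains(s, "A", 0)$atoms, s$atoms)
  back <- translate_chains(translate_chains(s, "A", 2.5), "A", -2.5)
  expect_equal(coords(back), coords(s), tolerance = 1e-12)
  # intra-group distances are preserved under the shift
  ai <- select_atoms(s, chain = "A", value = "indices")[1:50]
  d0 <- dist(coords(s)[ai, ])
  d1 <- dist(coords(s3)[ai, ])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
  expect_error(translate_chains(s, "Q", 1), "not in structure")
})

test_that("clash report applies a strict cutoff and matches brute force", {
  two <- function(d) mini_structure(
    atom_row("CA", "C", 1, "GLY", "A", 0, 0, 0),
    atom_row("CA", "C", 1, "GLY", "B", d, 0, 0))
  expect_equal(nrow(clash_report(two(1.9), "A", "B")), 1L)
  expect_equal(nrow(clash_report(two(2.0), "A", "B")), 0L)  # strict <
  expect_error(clash_report(two(1), c("A", "B"), "B"), "overlap")
  # random fixture equals O(n^2) enumeration, sorted ascending
  s <- make_random_structure(n_res = 40, n_chains = 2, seed = 5, confine = 12)
  cr <- clash_report(s, "A", "B", cutoff = 4.0)
  expect_equal(nrow(cr), oracle_clashes(s, "A", "B", 4.0))
  expect_true(!is.unsorted(cr$distance))
})

test_that("extracellular RMSD isolates extracellular change after TM alignment", {
  hx <- make_toy_connexon(6, "closed")$structure
  ann <- connexin_annotation()
  base <- as.numeric(t(coords(hx)))
  # identical frames: all-zero series
  tr0 <- gj_trajectory(hx, rbind(base, base, base), 10)
  expect_equal(extracellular_rmsd_series(tr0, ann)$rmsd, rep(0, 3),
               tolerance = 1e-9)
  # shifting every extracellular atom by 1 A with the TM fixed reads 1.0 A
  ec <- select_atoms(hx, resno = extracellular_residues(ann),
                     value = "indices")
  f2 <- coords(hx); f2[ec, 1] <- f2[ec, 1] + 1
  tr1 <- gj_trajectory(hx, rbind(base, as.numeric(t(f2))), 10)
  expect_equal(extracellular_rmsd_series(tr1, ann)$rmsd[2], 1.0,
               tolerance = 1e-9)
  # a whole-frame rigid motion reads 0
  f3 <- coords(hx) %*% t(rot_z(25))
  f3 <- sweep(f3, 2, c(4, -2, 7), "+")
  tr2 <- gj_trajectory(hx, rbind(base, as.numeric(t(f3))), 10)
  expect_equal(extracellular_rmsd_series(tr2, ann)$rmsd[2], 0,
               tolerance = 1e-8)
})

test_that("missing alignment residues are reported", {
  hx <- make_toy_connexon(6, "closed")$structure
  crop <- select_atoms(hx, resno = 47:230)  # drop residues 20-46
  tr <- gj_trajectory(crop, matrix(as.numeric(t(coords(crop))), nrow = 1), 10)
  expect_error(extracellular_rmsd_series(tr), "missing")
})

test_that("hemichannel pair assembly relabels, renumbers and logs clashes", {
  hx <- make_toy_connexon(6, "closed")$structure
  dod <- make_toy_connexon(12, "closed")$structure
  hh <- build_hc_hc(hx, dod)
  expect_equal(sort(unique(hh$atoms$chain_id)), LETTERS[1:12])
  expect_equal(hh$atoms$serial, seq_len(n_atoms(hh)))
  # copy 2 serials continue after copy 1
  n1 <- n_atoms(hx)
  expect_equal(hh$atoms$serial[n1 + 1], n1 + 1)
  expect_true(all(hh$atoms$chain_id[seq_len(n1)] %in% LETTERS[1:6]))
  expect_true(all(hh$atoms$chain_id[-seq_len(n1)] %in% LETTERS[7:12]))
  log <- attr(hh, "build_log")
  # the hexamer is a verbatim copy of template chains A-F: self-alignment
  expect_equal(log$rmsd_copy1, 0, tolerance = 1e-8)
  expect_s3_class(log$clashes, "data.frame")
  # chain-count contracts
  expect_error(build_hc_hc(dod, dod), "6 chains")
  tpl11 <- select_atoms(dod, chain = LETTERS[1:11])
  expect_error(build_hc_hc(hx, tpl11), "12 chains")
})
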