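test_that("CA-trace reader handles chains, models, altlocs and HETATM rules", {
  lines <- pdb_fixture_lines()
  st <- read_ca_trace(lines)
  expect_s3_class(st, "ca_structure")
  expect_named(st$chains, c("A", "B"))
  # residues 1, 2 (altloc resolved), 3 (altloc tie), 3A (insertion code)
  expect_equal(st$chains$A$resid, c("1", "2", "3", "3A"))
  expect_equal(nrow(st$chains$B$xyz), 1)
  # only MODEL 1 retained
  expect_false(any(st$chains$A$xyz == 50))
  # highest occupancy wins for residue 2
  expect_equal(unname(st$chains$A$xyz[2, ]), c(7, 8, 9))
  # occupancy tie resolved to altloc A for residue 3
  expect_equal(unname(st$chains$A$xyz[3, ]), c(1, 1, 1))
  # HETATM CA (water/calcium) ignored
  expect_false(any(st$chains$A$xyz[, 1] == 5))
})

test_that("CA-trace reader errors are informative", {
  expect_error(read_ca_trace("REMARK only remarks here\nEND"), "no CA atoms")
  het <- "HETATM    1  CA  HOH A   1       1.000   1.000   1.000  1.00 10.00"
  expect_error(read_ca_trace(het), "no CA atoms")
  broken <- c("ATOM      1  CA  ALA A   1       1.000   2.000", "END")
  expect_error(read_ca_trace(broken), "line 1")
  nonnum <- "ATOM      1  CA  ALA A   1       x.000   2.000   3.000  1.00 10.00"
  expect_error(read_ca_trace(nonnum), "line 1")
})

test_that("reader agrees with bio3d on a generated structure", {
  skip_if_not_installed("bio3d")
  set.seed(21)
  coords <- list(A = make_helix_trace(25), B = make_coil_trace(15))
  f <- write_ca_pdb(coords, tempfile(fileext = ".pdb"))
  st <- read_ca_trace(f)
  ref <- bio3d::read.pdb(f)
  ca <- ref$atom[ref$atom$elety == "CA", ]
  expect_equal(nrow(ca), 40)
  got <- rbind(st$chains$A$xyz, st$chains$B$xyz)
  expect_equal(unname(got), unname(as.matrix(ca[, c("x", "y", "z")])),
               tolerance = 1e-12)
})

test_that("helix decomposition recovers closed-form curvature and torsion", {
  # ideal alpha-helix: a = 2.3 A, b = 0.8594 A/rad, 100 degrees per anchor
  h <- make_helix_trace(50, radius = 2.3, rise = 1.5, twist = 100)
  k0 <- attr(h, "kappa_oracle")
  t0 <- attr(h, "tau_oracle")
  expect_equal(k0, 2.3 / (2.3^2 + (1.5 / (100 * pi / 180))^2), tolerance = 1e-12)
  pr <- decompose_chain(h)
  interior <- 4:47  # >= 3 residues from either end
  expect_lt(max(abs(pr$curvature[interior] - k0) / k0), 0.05)
  expect_lt(max(abs(pr$torsion[interior] - t0) / t0), 0.05)
  expect_true(all(pr$curvature >= 0))
  expect_true(all(diff(pr$arc_length) > 0))
})

test_that("planar circle has kappa = 1/R and zero torsion", {
  th <- (0:19) * (2 * pi / 22)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  pr <- decompose_chain(circ)
  expect_equal(pr$curvature[4:17], rep(0.1, 14), tolerance = 0.01)
  expect_equal(pr$torsion, rep(0, 20), tolerance = 1e-8)
})

test_that("collinear anchors give zero curvature and torsion", {
  line <- cbind(3.8 * (0:9), 0, 0)
  pr <- decompose_chain(line)
  expect_equal(pr$curvature, rep(0, 10), tolerance = 1e-10)
  expect_equal(pr$torsion, rep(0, 10), tolerance = 1e-10)
})

test_that("decomposition input contracts are enforced", {
  expect_error(decompose_chain(make_helix_trace(10)[1:3, ]), "too short")
  bad <- make_helix_trace(10)
  bad[5, ] <- bad[4, ]
  expect_error(decompose_chain(bad), "coincident")
  gappy <- make_coil_trace(12)
  gappy[7:12, ] <- gappy[7:12, ] + 25
  expect_warning(decompose_chain(gappy), "chain break")
})

test_that("curvature/torsion respect rigid motion, mirror and scaling symmetries", {
  set.seed(42)
  for (rep in 1:3) {
    xyz <- make_coil_trace(30)
    pr <- decompose_chain(xyz)
    # rigid motion
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- xyz %*% t(R) + matrix(rnorm(3, sd = 10), nrow(xyz), 3, byrow = TRUE)
    pm <- decompose_chain(moved)
    expect_lt(max(abs(pm$curvature - pr$curvature)), 1e-6)
    expect_lt(max(abs(pm$torsion - pr$torsion)), 1e-6)
    # mirror: kappa invariant, tau negated
    mir <- xyz %*% diag(c(-1, 1, 1))
    pmir <- decompose_chain(mir)
    expect_lt(max(abs(pmir$curvature - pr$curvature)), 1e-6)
    expect_lt(max(abs(pmir$torsion + pr$torsion)), 1e-6)
    # scaling by c scales kappa and tau by 1/c
    cfac <- 2.5
    psc <- suppressWarnings(decompose_chain(xyz * cfac))  # larger CA-CA steps
    expect_lt(max(abs(psc$curvature - pr$curvature / cfac)), 1e-6)
    expect_lt(max(abs(psc$torsion - pr$torsion / cfac)), 1e-6)
  }
})

test_that("protein tensor has the padded 6 x 1500 layout with a consistent mask", {
  pr <- decompose_chain(make_helix_trace(100))
  pt <- build_protein_tensor(pr)
  expect_equal(dim(pt$values), c(2, 9000))
  expect_equal(sum(pt$mask), 100)
  expect_true(all(pt$values[, !pt$mask] == 0))
  expect_equal(pt$chain_offsets, 0L)

  # two chains occupy slot-aligned blocks
  pr2 <- decompose_chain(make_coil_trace(40, persistence = 0.3))
  pt2 <- build_protein_tensor(list(pr, pr2))
  expect_equal(pt2$chain_offsets, c(0L, 1500L))
  expect_equal(sum(pt2$mask[1501:1540]), 40)

  # exact fit: 6 chains x 1500 residues, no padding
  set.seed(8)
  full <- replicate(6, decompose_chain(make_helix_trace(1500)), simplify = FALSE)
  ptf <- build_protein_tensor(full)
  expect_equal(sum(ptf$mask), 9000)
})

test_that("tensor chain/residue limits error unless truncation is requested", {
  pr <- decompose_chain(make_helix_trace(10))
  seven <- replicate(7, pr, simplify = FALSE)
  expect_error(build_protein_tensor(seven), "limit exceeded")
  pt <- build_protein_tensor(seven, truncate = TRUE)
  expect_equal(length(pt$chain_lengths), 6)
  expect_error(build_protein_tensor(list()), "non-empty")
  long <- decompose_chain(make_helix_trace(40))
  expect_error(build_protein_tensor(long, max_residues = 30), "limit exceeded")
  ptt <- build_protein_tensor(long, max_residues = 30, truncate = TRUE)
  expect_equal(sum(ptt$mask), 30)
})
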