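test_that("helix traces have the expected chord geometry and oracles", {
  h <- make_helix_trace(50)
  # chord = sqrt((2 a sin(dtheta/2))^2 + rise^2) for the alpha-helix defaults
  chord <- sqrt((2 * 2.3 * sin(100 * pi / 180 / 2))^2 + 1.5^2)
  steps <- sqrt(rowSums(diff(h)^2))
  expect_equal(unname(steps), rep(chord, 49), tolerance = 1e-12)
  expect_equal(chord, 3.829, tolerance = 1e-3)
  expect_equal(attr(h, "kappa_oracle"), 0.3815, tolerance = 1e-3)
  expect_equal(attr(h, "tau_oracle"), 0.1426, tolerance = 1e-3)

  # zero twist degenerates to a straight line
  line <- make_helix_trace(10, twist = 0)
  expect_equal(attr(line, "kappa_oracle"), 0)
  d <- diff(line)
  expect_equal(unname(d / sqrt(rowSums(d^2))), matrix(rep(c(0, 0, 1), each = 9), 9),
               tolerance = 1e-12)
  expect_error(make_helix_trace(3), "n >= 4")
})

test_that("coil traces keep a fixed CA-CA step and never self-coincide", {
  set.seed(71)
  for (i in 1:5) {
    tr <- make_coil_trace(60)
    steps <- sqrt(rowSums(diff(tr)^2))
    expect_equal(unname(steps), rep(3.8, 59), tolerance = 1e-9)
    expect_gt(min(dist(tr)), 0.5)  # no near-coincident residues
  }
})

test_that("CA PDB writing round-trips coordinates to format precision", {
  set.seed(72)
  h <- make_helix_trace(50)
  f <- write_ca_pdb(list(A = h), tempfile(fileext = ".pdb"))
  st <- read_ca_trace(f)
  expect_equal(nrow(st$chains$A$xyz), 50)
  expect_lt(max(abs(st$chains$A$xyz - h)), 0.001)

  # two chains -> two chain IDs with TER separation
  f2 <- write_ca_pdb(list(make_coil_trace(10), make_coil_trace(8)),
                     tempfile(fileext = ".pdb"))
  lines <- readLines(f2)
  expect_equal(sum(startsWith(lines, "TER")), 2)
  expect_equal(substr(grep("^ATOM", lines, value = TRUE), 22, 22),
               rep(c("A", "B"), c(10, 8)))

  # fixed-width overflow
  big <- make_coil_trace(10); big[, 1] <- big[, 1] + 99999
  expect_error(write_ca_pdb(list(big), tempfile()), "overflow")
})

test_that("dataset generation is byte-identical for a fixed seed", {
  a <- make_synthetic_dataset(n_proteins = 10, n_ligands = 6,
                              residues_per_protein = 50, motif_length = 20,
                              n_bits = 32, seed = 5)
  b <- make_synthetic_dataset(n_proteins = 10, n_ligands = 6,
                              residues_per_protein = 50, motif_length = 20,
                              n_bits = 32, seed = 5)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- make_synthetic_dataset(n_proteins = 10, n_ligands = 6,
                              residues_per_protein = 50, motif_length = 20,
                              n_bits = 32, seed = 6)
  expect_false(identical(a$pairs$label, c$pairs$label))
})

test_that("noise-free labels equal the planted AND rule", {
  ds <- make_synthetic_dataset(n_proteins = 16, n_ligands = 10,
                               residues_per_protein = 50, motif_length = 20,
                               n_bits = 32, noise = 0, seed = 2)
  man <- ds$manifest
  rule <- man$proteins$has_motif[match(ds$pairs$protein_id, man$proteins$protein_id)] &
    man$ligands$has_key[match(ds$pairs$ligand_id, man$ligands$ligand_id)]
  expect_equal(ds$pairs$label, as.integer(rule))
  # key bit is present exactly in the key ligands
  expect_equal(unname(ds$fingerprints[, man$key_bit] == 1), man$ligands$has_key)
})

test_that("label noise flips the planted rule at the requested rate", {
  ds <- make_synthetic_dataset(n_proteins = 200, n_ligands = 50,
                               residues_per_protein = 50, motif_length = 20,
                               n_bits = 32, noise = 0.05, seed = 3)
  agree <- mean(ds$pairs$label == as.integer(ds$manifest$rule))
  expect_gt(agree, 0.94)  # 95% +/- 1% over 10^4 pairs
  expect_lt(agree, 0.96)
})

test_that("infeasible planted fractions are rejected", {
  expect_error(make_synthetic_dataset(n_proteins = 10, n_ligands = 6,
                                      residues_per_protein = 50,
                                      motif_length = 20, motif_fraction = 0,
                                      n_bits = 32),
               "infeasible")
  expect_error(make_synthetic_dataset(n_proteins = 10, n_ligands = 6,
                                      residues_per_protein = 50,
                                      motif_length = 20, key_fraction = 1,
                                      n_bits = 32),
               "infeasible")
})

test_that("featurizing a written helix PDB recovers the closed-form oracles", {
  h <- make_helix_trace(60)
  f <- write_ca_pdb(list(A = h), tempfile(fileext = ".pdb"))
  pt <- featurize_structure(f)
  expect_equal(sum(pt$mask), 60)
  interior <- 4:57
  kap <- pt$values[1, interior]
  tau <- pt$values[2, interior]
  expect_lt(max(abs(kap - attr(h, "kappa_oracle")) / attr(h, "kappa_oracle")), 0.05)
  expect_lt(max(abs(tau - attr(h, "tau_oracle")) / attr(h, "tau_oracle")), 0.05)
})

test_that("planted motif segments carry helix-like geometry inside coil chains", {
  ds <- make_synthetic_dataset(n_proteins = 12, n_ligands = 6,
                               residues_per_protein = 80, motif_length = 30,
                               n_bits = 32, seed = 11)
  man <- ds$manifest$proteins
  h <- make_helix_trace(10)
  for (i in which(man$has_motif)[1:3]) {
    pt <- ds$tensors[[man$protein_id[i]]]
    core <- (man$motif_start[i] + 5):(man$motif_end[i] - 5)
    kap <- pt$values[1, core]
    expect_lt(max(abs(kap - attr(h, "kappa_oracle"))), 0.05)
  }
})
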