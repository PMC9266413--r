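test_that("full hydrophobic correlation puts only hydrophobic residues in the cap", {
  cfg <- synth_config(hydro_correlation = 1.0)
  blob <- make_blob(cfg, "lock", seed = 2)
  cap_res <- blob$cloud$residue_names[blob$interface]
  expect_true(all(cap_res %in% surfppi:::hydrophobic_residues))
})

test_that("without jitter and bump, the blob reduces to its ideal geometry", {
  cfg <- synth_config(noise_sd = 0, bump_height = 0)
  blob <- make_blob(cfg, "key", seed = 5)
  r <- sqrt(rowSums(blob$cloud$xyz^2))
  outside <- setdiff(seq_len(blob$n_surface), blob$interface)
  expect_equal(r[outside], rep(cfg$blob_radius, length(outside)),
               tolerance = 1e-12)
  # cap atoms sit exactly on the facet plane
  expect_equal(blob$cloud$xyz[blob$interface, 3],
               rep(cfg$blob_radius * cos(cfg$cap_angle),
                   length(blob$interface)),
               tolerance = 1e-12)
})

test_that("generation is deterministic down to the serialised bytes", {
  b1 <- make_blob(synth_config(), "lock", seed = 9)
  b2 <- make_blob(synth_config(), "lock", seed = 9)
  expect_identical(b1$cloud, b2$cloud)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(b1$cloud, f1); write_pdb(b2$cloud, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seeds give different clouds but equal planted-cap sizes
  b3 <- make_blob(synth_config(), "lock", seed = 10)
  expect_false(isTRUE(all.equal(b1$cloud$xyz, b3$cloud$xyz)))
})

test_that("config validation enforces the generator preconditions", {
  expect_error(synth_config(n_atoms = 5), "at least 20")
  expect_error(synth_config(cap_angle = 2.0), "hemisphere")
  expect_error(synth_config(hydro_correlation = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(noise_sd = -1), "non-negative")
})

test_that("posed pairs put complementary surfaces at the target gap", {
  sp <- make_synth_pair(synth_config(), seed = 13)
  ma <- surface_protein(sp$pair$a)
  mb <- surface_protein(sp$pair$b)
  # nominal surface gap 1.0; the measured minimum sits below it by the jitter
  # extremes of the facing facets, vdW-radius spread and mesh interpolation
  nn <- knn(ma$vertices, mb$vertices, 1)
  expect_gt(min(nn$dist), 0.25)
  expect_lt(min(nn$dist), 1.6)
  # no atomic collisions
  expect_false(any(cpp_within_dist(sp$pair$a$xyz, sp$pair$b$xyz, 1.5)))

  lab <- label_interface(ma, mb)
  expect_gt(sum(lab$a), 0)
  expect_gt(sum(lab$b), 0)
  # positives concentrate in the planted caps
  va <- sweep(ma$vertices[lab$a == 1, , drop = FALSE], 2, sp$center_a)
  ang <- acos(pmin(pmax((va %*% sp$cap_axis_a) / sqrt(rowSums(va^2)), -1), 1))
  expect_gt(mean(ang <= sp$config$cap_angle + 0.25), 0.8)
})

test_that("datasets split 80/20 and serialise reproducibly", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- synth_config(n_atoms = 60, blob_radius = 6)
  ds1 <- make_dataset(10, cfg, seed = 3, dir = dir1)
  ds2 <- make_dataset(10, cfg, seed = 3, dir = dir2)
  expect_length(ds1$train, 8)
  expect_length(ds1$test, 2)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  for (f in ds1$manifest$pdb_path_a) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  expect_error(make_dataset(1, cfg), "at least 2")
})

test_that("analytic fixtures carry exact geometry and normals", {
  sph <- analytic_fixture("sphere", size = 2, resolution = 3)
  expect_equal(sqrt(rowSums(sph$vertices^2)), rep(2, nrow(sph$vertices)),
               tolerance = 1e-12)
  pl <- analytic_fixture("plane", size = 4, resolution = 7)
  expect_true(all(pl$normals[, 3] == 1))
  sad <- analytic_fixture("saddle", size = 2, resolution = 11)
  origin <- which(rowSums(abs(sad$vertices)) == 0)
  expect_length(origin, 1)
  expect_equal(sad$normals[origin, ], c(0, 0, 1))
  expect_error(analytic_fixture("torus"), "unknown")
  expect_error(analytic_fixture("plane", resolution = 2), "at least 3")
})
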