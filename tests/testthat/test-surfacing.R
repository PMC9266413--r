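test_that("the distance field obeys its defining formula", {
  cl <- atom_cloud("C", matrix(0, 1, 3))
  # r_vdw(C) = 1.7, probe 1.4: zero crossing at 3.1 A, centre value -3.1
  expect_equal(distance_field_at(cl, c(3.1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(distance_field_at(cl, c(0, 0, 0)), -3.1, tolerance = 1e-12)
  expect_error(build_distance_field(cl, spacing = -1), "spacing")
  expect_error(build_distance_field(cl, spacing = 0.05, max_cells = 1e4),
               "coarser")
})

test_that("grid values equal the brute-force minimum over atoms", {
  set.seed(31)
  cl <- atom_cloud(sample(c("C", "N", "O", "S"), 20, replace = TRUE),
                   matrix(runif(60, -5, 5), 20, 3))
  field <- build_distance_field(cl, spacing = 1.1)
  pick <- cbind(sample(field$dims[1], 50, TRUE), sample(field$dims[2], 50, TRUE),
                sample(field$dims[3], 50, TRUE))
  pts <- sweep(sweep(pick - 1, 2, rep(field$spacing, 3), "*"), 2,
               field$origin, "+")
  expect_equal(field$values[pick], distance_field_at(cl, pts),
               tolerance = 1e-12)
})

test_that("banded evaluation matches the exact field near the level set", {
  sp <- make_blob(tiny_synth_config(), "lock", seed = 8)
  exact <- build_distance_field(sp$cloud, spacing = 1.0)
  banded <- build_distance_field(sp$cloud, spacing = 1.0, band = 4.0)
  near <- abs(exact$values) < 2.5
  expect_equal(banded$values[near], exact$values[near], tolerance = 1e-12)
  expect_true(all(banded$values <= 4.0 + 1e-12))
})

test_that("the single-atom isosurface is a sphere of the inflated radius", {
  cl <- atom_cloud("C", matrix(0, 1, 3))
  spacing <- 0.7
  mesh <- extract_isosurface(build_distance_field(cl, spacing = spacing), 0)
  r <- sqrt(rowSums(mesh$vertices^2))
  expect_true(all(abs(r - 3.1) < 1.5 * spacing))
  expect_lt(mean(abs(r - 3.1)), spacing)
  expect_equal(euler_characteristic(mesh), 2)
  # outward orientation on a convex fixture
  expect_true(all(rowSums(mesh$normals * mesh$vertices) > 0))
  expect_error(extract_isosurface(build_distance_field(cl), 99), "outside")
})

test_that("two far-apart atoms give two surface components", {
  cl <- atom_cloud(c("C", "C"), rbind(c(0, 0, 0), c(50, 0, 0)))
  mesh <- extract_isosurface(build_distance_field(cl, spacing = 1.0), 0)
  expect_equal(mesh_n_components(mesh), 2)
  expect_equal(euler_characteristic(mesh), 4)  # two spheres
})

test_that("translation of the cloud translates the surface exactly", {
  sp <- make_blob(synth_config(n_atoms = 60, blob_radius = 5), "lock", seed = 2)
  t_vec <- c(3.25, -1.5, 0.75)
  m1 <- surface_protein(sp$cloud, spacing = 1.0)
  moved <- atom_cloud(sp$cloud$elements, sweep(sp$cloud$xyz, 2, t_vec, "+"),
                      residue_names = sp$cloud$residue_names)
  m2 <- surface_protein(moved, spacing = 1.0)
  expect_equal(sweep(m2$vertices, 2, t_vec, "-"), m1$vertices,
               tolerance = 1e-9)
  expect_equal(m2$normals, m1$normals, tolerance = 1e-9)
})

test_that("vertex normals average incident face normals to high accuracy", {
  ico <- analytic_fixture("sphere", size = 5, resolution = 3)
  computed <- compute_vertex_normals(surface_mesh(ico$vertices, ico$faces))
  radial <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  ang <- acos(pmin(1, rowSums(computed$normals * radial)))
  expect_lt(max(ang) * 180 / pi, 2)
  expect_equal(sqrt(rowSums(computed$normals^2)), rep(1, nrow(ico$vertices)),
               tolerance = 1e-6)
  # flat grid: all normals exactly +z
  plane <- analytic_fixture("plane", size = 2, resolution = 5)
  flat <- compute_vertex_normals(surface_mesh(plane$vertices, plane$faces))
  expect_equal(flat$normals, matrix(rep(c(0, 0, 1), each = 25), 25, 3))
})

test_that("mesh files round-trip through PLY and OFF", {
  mesh <- analytic_fixture("sphere", size = 2, resolution = 3)
  ply <- tempfile(fileext = ".ply")
  write_mesh(mesh, ply)
  back <- load_mesh(ply)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_equal(back$faces, mesh$faces)
  off <- tempfile(fileext = ".off")
  write_mesh(mesh, off)
  expect_equal(load_mesh(off)$vertices, mesh$vertices, tolerance = 1e-6)
})

test_that("an OFF tetrahedron loads and a PLY quad face is rejected", {
  off <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"), off)
  tet <- load_mesh(off)
  expect_equal(nrow(tet$vertices), 4)
  expect_equal(nrow(tet$faces), 4)
  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), ply)
  expect_error(load_mesh(ply), "triangular")
})

test_that("mesh validation catches malformed input", {
  expect_error(surface_mesh(matrix(0, 3, 3), rbind(c(1, 1, 2))), "repeated")
  expect_error(surface_mesh(matrix(0, 3, 3), rbind(c(1, 2, 4))), "range")
  expect_error(surface_mesh(matrix(NA_real_, 3, 3), rbind(c(1, 2, 3))),
               "finite")
})
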