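test_that("knn returns exact neighbours with a deterministic tie-break", {
  refs <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  res <- knn(c(0, 0, 0), refs, 2)
  expect_equal(res$idx[1, ], c(1L, 2L))
  expect_equal(res$dist[1, ], c(1, 2))
  # equidistant: lower index wins
  tie <- knn(c(0, 0, 0), rbind(c(1, 0, 0), c(-1, 0, 0)), 1)
  expect_equal(tie$idx[1, 1], 1L)
  expect_error(knn(c(0, 0, 0), refs, 4), "exceeds")
})

test_that("knn matches an O(NM) brute-force oracle on random clouds", {
  for (trial in 1:10) {
    set.seed(trial)
    ref <- matrix(runif(900), 300, 3)
    query <- matrix(runif(60), 20, 3)
    res <- knn(query, ref, 8)
    for (q in seq_len(20)) {
      d <- sqrt(colSums((t(ref) - query[q, ])^2))
      expect_equal(res$idx[q, ], order(d)[1:8])
      expect_equal(res$dist[q, ], sort(d)[1:8], tolerance = 1e-12)
    }
  }
})

test_that("radius_neighbors includes the boundary and handles self matches", {
  line <- cbind(0:4, 0, 0)
  nb <- radius_neighbors(line[3, , drop = FALSE], line, 1.0)
  expect_equal(nb[[1]], c(2L, 3L, 4L))
  nb_small <- radius_neighbors(line[3, , drop = FALSE], line, 0.5)
  expect_equal(nb_small[[1]], 3L)
  # self-exclusion only when requested on the identical set
  nb_self <- radius_neighbors(line, line, 1.0, exclude_self = TRUE)
  expect_equal(nb_self[[3]], c(2L, 4L))
  # empty neighbourhoods are allowed
  far <- radius_neighbors(matrix(c(99, 99, 99), 1, 3), line, 1.0)
  expect_equal(far[[1]], integer(0))
})

test_that("radius_neighbors equals brute-force thresholding on random data", {
  set.seed(7)
  pts <- matrix(runif(1500, 0, 10), 500, 3)
  nb <- radius_neighbors(pts[1:40, , drop = FALSE], pts, 3.0)
  for (q in 1:40) {
    d <- sqrt(colSums((t(pts) - pts[q, ])^2))
    expect_equal(nb[[q]], which(d <= 3.0))
  }
})

test_that("tangent frames are deterministic right-handed orthonormal bases", {
  fr <- build_tangent_frame(c(0, 0, 1))
  expect_equal(fr$u, c(0, -1, 0))
  expect_equal(fr$v, c(1, 0, 0))
  set.seed(11)
  for (trial in 1:100) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    fr <- build_tangent_frame(n)
    B <- cbind(fr$u, fr$v, fr$n)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-6)
    expect_equal(det(B), 1, tolerance = 1e-6)
  }
  # n and -n span the same tangent plane
  n <- c(0.6, 0.8, 0)
  f1 <- build_tangent_frame(n)
  f2 <- build_tangent_frame(-n)
  expect_lt(abs(sum(f1$u * f2$n)) + abs(sum(f1$v * f2$n)), 1e-12)
  expect_error(build_tangent_frame(c(0, 0, 0)), "zero")
})

test_that("curvatures recover closed forms on analytic fixtures", {
  ico <- analytic_fixture("sphere", size = 2, resolution = 4)
  set.seed(3)
  idx <- sample(nrow(ico$vertices), 50)
  k <- estimate_curvatures(ico, idx, k_geom = 16)
  expect_lt(mean(abs(k[, 1] - 0.5) / 0.5), 0.1)
  expect_lt(mean(abs(k[, 2] - 0.5) / 0.5), 0.1)
  expect_true(all(k > 0))  # convex-outward sign convention

  plane <- analytic_fixture("plane", size = 2, resolution = 15)
  kp <- estimate_curvatures(plane, k_geom = 16)
  expect_lt(max(abs(kp)), 1e-6)

  cyl <- analytic_fixture("cylinder", size = 2, resolution = 32)
  interior <- which(abs(cyl$vertices[, 3]) < 0.5)
  kc <- estimate_curvatures(cyl, interior[1:40], k_geom = 16)
  expect_lt(max(abs(kc[, 1] - 0)), 0.15 * 0.5)
  expect_lt(max(abs(kc[, 2] - 0.5) / 0.5), 0.15)

  sad <- analytic_fixture("saddle", size = 2, resolution = 41)
  origin <- which(rowSums(abs(sad$vertices)) == 0)
  ks <- estimate_shape_operator(sad, origin, k_geom = 16)
  expect_equal(ks$k1, -1, tolerance = 0.15)
  expect_equal(ks$k2, 1, tolerance = 0.15)
})

test_that("the shape operator is symmetric, rigid-motion invariant and scale covariant", {
  ico <- analytic_fixture("sphere", size = 2, resolution = 3)
  est <- estimate_shape_operator(ico, 7, k_geom = 16)
  expect_equal(est$S, t(est$S))
  expect_false(est$degenerate)

  set.seed(5)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- surface_mesh(ico$vertices %*% t(R), ico$faces, ico$normals %*% t(R))
  k0 <- estimate_curvatures(ico, 1:30, k_geom = 16)
  kr <- estimate_curvatures(rot, 1:30, k_geom = 16)
  expect_equal(unclass(kr), unclass(k0), tolerance = 1e-5,
               ignore_attr = TRUE)

  sc <- surface_mesh(ico$vertices * 2, ico$faces, ico$normals)
  ksc <- estimate_curvatures(sc, 1:30, k_geom = 16)
  expect_equal(unclass(ksc), unclass(k0) / 2, tolerance = 0.01,
               ignore_attr = TRUE)
})
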