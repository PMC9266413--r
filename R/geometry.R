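#' Exact k-nearest-neighbour query
#'
#' Brute-force Euclidean k-NN with a deterministic tie-break: among
#' equidistant references the lower index wins.
#'
#' @param query m x 3 matrix of query points (Angstrom).
#' @param ref n x 3 matrix of reference points.
#' @param k number of neighbours (`1 <= k <= n`).
#' @return list with `idx` (m x k, 1-based) and `dist` (m x k), both ordered
#'   by ascending distance.
#' @export
knn <- function(query, ref, k) {
  query <- rbind(query); ref <- rbind(ref)
  storage.mode(query) <- "double"; storage.mode(ref) <- "double"
  cpp_knn(query, ref, as.integer(k))
}

#' Fixed-radius neighbour query
#'
#' Returns, per query point, all reference points within `radius` (boundary
#' inclusive). When `query` and `ref` are the same point set, `exclude_self`
#' drops the trivial self match.
#'
#' @param query m x 3 matrix.
#' @param ref n x 3 matrix.
#' @param radius search radius in Angstrom.
#' @param exclude_self drop i == i pairs (only meaningful for identical sets).
#' @return list of integer index vectors, one per query point (possibly empty).
#' @export
radius_neighbors <- function(query, ref, radius, exclude_self = FALSE) {
  e <- radius_edges(query, ref, radius, exclude_self)
  out <- rep(list(integer(0)), nrow(rbind(query)))
  if (length(e$i)) {
    sp <- split(e$j, e$i)
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

#' Fixed-radius neighbour query as an edge list
#'
#' Same query as [radius_neighbors()], returned as parallel vectors
#' `i` (query index), `j` (reference index), `dist`. This is the form consumed
#' by the radius convolution.
#' @inheritParams radius_neighbors
#' @export
radius_edges <- function(query, ref, radius, exclude_self = FALSE) {
  query <- rbind(query); ref <- rbind(ref)
  storage.mode(query) <- "double"; storage.mode(ref) <- "double"
  if (radius <= 0) stop("radius must be positive")
  cpp_radius_edges(query, ref, radius, isTRUE(exclude_self))
}

#' Deterministic orthonormal tangent frame from a unit normal
#'
#' `u = normalize(e x n)` where `e` is the global axis least parallel to `n`
#' (ties resolved x before y before z), and `v = n x u`, giving a right-handed
#' orthonormal triple `{u, v, n}`.
#'
#' @param normal unit 3-vector.
#' @return list with unit vectors `u`, `v`, `n`.
#' @export
build_tangent_frame <- function(normal) {
  normal <- as.numeric(normal)
  len <- sqrt(sum(normal^2))
  if (!is.finite(len) || len < 1e-12) stop("zero or non-finite normal")
  if (abs(len - 1) > 1e-6) stop("normal must have unit length")
  n <- normal / len
  axes <- diag(3)
  e <- axes[, which.min(abs(as.numeric(crossprod(axes, n))))]
  u <- cross3(e, n)
  u <- u / sqrt(sum(u^2))
  v <- cross3(n, u)
  list(u = u, v = v, n = n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Estimate the shape operator and principal curvatures at one vertex
#'
#' Takes the `k_geom` nearest mesh vertices, projects relative positions and
#' relative normals onto the tangent plane of the vertex, and fits the 2 x 2
#' differential of the normal field by least squares (ridge-regularised when
#' the projected neighbourhood is rank deficient). The fit is symmetrised
#' before eigendecomposition; the sign convention makes convex regions of an
#' outward-normal surface positively curved, so a sphere of radius r yields
#' k1 = k2 = +1/r.
#'
#' @param mesh a [surface_mesh()] with normals.
#' @param vertex_index 1-based vertex index.
#' @param k_geom neighbourhood size (>= 4).
#' @return list with the 2 x 2 matrix `S` (1/Angstrom, in the `{u,v}` basis),
#'   principal curvatures `k1 <= k2`, the tangent `frame`, and a `degenerate`
#'   flag set when the ridge fallback was triggered.
#' @export
estimate_shape_operator <- function(mesh, vertex_index, k_geom = 16) {
  stopifnot(inherits(mesh, "surface_mesh"), !is.null(mesh$normals))
  if (k_geom < 4) stop("k_geom must be at least 4")
  res <- estimate_curvatures(mesh, vertex_index, k_geom, full = TRUE)
  res[[1]]
}

#' Principal curvatures at many vertices
#'
#' Vectorised driver for [estimate_shape_operator()].
#'
#' @param mesh a [surface_mesh()] with normals.
#' @param indices vertex indices (default: all vertices).
#' @param k_geom neighbourhood size.
#' @param full if TRUE, return per-vertex lists with the full shape-operator
#'   estimate instead of the curvature matrix.
#' @return an n x 2 matrix with columns `k1`, `k2` (ascending), with an
#'   attribute `degenerate` (logical vector); or a list of estimates when
#'   `full = TRUE`.
#' @export
estimate_curvatures <- function(mesh, indices = NULL, k_geom = 16, full = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"), !is.null(mesh$normals))
  point_cloud_curvatures(mesh$vertices, mesh$normals, indices, k_geom, full)
}

#' Principal curvatures of an oriented point cloud
#'
#' The same shape-operator fit as [estimate_curvatures()], applied to any
#' point set with unit normals (e.g. a subsampled surface): the neighbourhood
#' is the k nearest points of the set, so the estimation scale follows the
#' sampling density.
#'
#' @param points n x 3 positions (Angstrom).
#' @param normals n x 3 unit normals.
#' @param indices query indices (default all).
#' @param k_geom neighbourhood size (>= 4).
#' @param full return full shape-operator estimates instead of the matrix.
#' @return as [estimate_curvatures()].
#' @export
point_cloud_curvatures <- function(points, normals, indices = NULL,
                                   k_geom = 16, full = FALSE) {
  v <- rbind(points)
  nrm <- rbind(normals)
  indices <- indices %||% seq_len(nrow(v))
  if (k_geom < 4) stop("k_geom must be at least 4")
  if (k_geom + 1 > nrow(v)) stop("point set too small for requested k_geom")
  nb <- cpp_knn(v[indices, , drop = FALSE], v, as.integer(k_geom + 1))
  out <- matrix(NA_real_, length(indices), 2, dimnames = list(NULL, c("k1", "k2")))
  degen <- logical(length(indices))
  fulls <- if (full) vector("list", length(indices)) else NULL
  for (q in seq_along(indices)) {
    i <- indices[q]
    nbrs <- setdiff(nb$idx[q, ], i)[seq_len(k_geom)]
    frame <- build_tangent_frame(nrm[i, ] / sqrt(sum(nrm[i, ]^2)))
    UV <- cbind(frame$u, frame$v)                    # 3 x 2 projector
    dp <- v[nbrs, , drop = FALSE] - matrix(v[i, ], k_geom, 3, byrow = TRUE)
    dn <- nrm[nbrs, , drop = FALSE] - matrix(nrm[i, ], k_geom, 3, byrow = TRUE)
    X <- dp %*% UV                                   # k x 2 tangent coords
    Y <- dn %*% UV
    XtX <- crossprod(X)
    dg <- abs(det(XtX)) < 1e-10 * (sum(diag(XtX))^2 + 1e-30)
    if (dg) XtX <- XtX + diag(1e-8, 2)
    degen[q] <- dg
    D <- crossprod(Y, X) %*% solve(XtX)              # fits D x_j ~ y_j
    S <- (D + t(D)) / 2
    ev <- sort(eigen(S, symmetric = TRUE, only.values = !full)$values)
    out[q, ] <- ev
    if (full) {
      fulls[[q]] <- list(S = S, k1 = ev[1], k2 = ev[2], frame = frame,
                         degenerate = dg)
    }
  }
  if (full) return(fulls)
  attr(out, "degenerate") <- degen
  out
}
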