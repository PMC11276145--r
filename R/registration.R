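#' Rigid transform (rotation + translation)
#'
#' Pose object mapping points as `R %*% p + t`. No scale, no reflection:
#' the rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal matrix, det = +1.
#' @param translation length-3 numeric (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("reflection is not a rigid transform")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %.3f deg about (%s), t = (%s) mm\n",
              rotation_angle(x),
              paste(sprintf("%.3f", rotation_axis(x)), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Rotation angle of a transform, in degrees
#' @param transform a `rigid_transform`.
#' @return angle in degrees, in [0, 180].
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

rotation_axis <- function(transform) {
  R <- transform$rotation
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  n <- sqrt(sum(ax^2))
  if (n < 1e-12) c(0, 0, 1) else ax / n
}

#' Compose two rigid transforms
#'
#' `compose_transform(T2, T1)` is the transform applying `T1` first,
#' then `T2`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.vector(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Rotation about an axis
#'
#' Convenience constructor from axis-angle (Rodrigues formula).
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @param translation optional translation (mm).
#' @return a `rigid_transform`.
#' @export
axis_angle_transform <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, translation)
}

#' Apply a rigid transform to points or a mesh
#'
#' Surface area and volume are invariant (isometry).
#'
#' @param x a `triangle_mesh` or an n x 3 point matrix.
#' @param transform a `rigid_transform`.
#' @return object of the same type as `x`.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  p <- as.matrix(x)
  sweep(p %*% t(transform$rotation), 2L, -transform$translation)
}

#' As 4x4 homogeneous matrix
#' @param transform a `rigid_transform`.
#' @return 4x4 numeric matrix.
#' @export
as_homogeneous <- function(transform) {
  M <- diag(4)
  M[1:3, 1:3] <- transform$rotation
  M[1:3, 4] <- transform$translation
  M
}

#' Write / read a pose matrix as plain text
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @return `path` (write) or a `rigid_transform` (read).
#' @export
write_pose <- function(transform, path) {
  utils::write.table(as_homogeneous(transform), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pose
#' @export
read_pose <- function(path) {
  M <- as.matrix(utils::read.table(path))
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

# --- Horn's absolute orientation -------------------------------------------

#' Horn's absolute orientation
#'
#' Closed-form least-squares rigid alignment of matched point sets: finds
#' the rotation and translation minimising `sum(|ref_i - (R mov_i + t)|^2)`
#' via the quaternion eigen-decomposition of the cross-covariance matrix.
#' No scale is estimated and the determinant +1 constraint of the
#' quaternion parameterisation excludes reflections.
#'
#' @param ref_points n x 3 matrix of reference positions, n >= 3.
#' @param mov_points n x 3 matrix of matched moving positions.
#' @return a `rigid_transform` mapping `mov_points` onto `ref_points`.
#' @export
horn_align <- function(ref_points, mov_points) {
  P <- as.matrix(ref_points); Q <- as.matrix(mov_points)
  if (nrow(P) != nrow(Q)) stop("point counts differ")
  if (nrow(P) < 3L) stop("at least 3 correspondences required")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2L, pc); Qc <- sweep(Q, 2L, qc)
  # collinearity check on the reference
  sv <- svd(Pc)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("degenerate configuration: reference points are collinear")
  M <- crossprod(Qc, Pc)   # sum mov_i ref_i^T (centered)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y+w*z),     2*(x*z-w*y),
    2*(x*y-w*z),     w*w-x*x+y*y-z*z, 2*(y*z+w*x),
    2*(x*z+w*y),     2*(y*z-w*x),     w*w-x*x-y*y+z*z), 3, 3)
  rigid_transform(R, pc - as.vector(R %*% qc))
}

# --- landmark and region selection -----------------------------------------

#' Most prominent vertex along a direction
#'
#' Automated stand-in for manually picking "the most prominent point" of a
#' condyle: the vertex maximising the dot product with `direction`. Ties
#' are broken by the lowest vertex index.
#'
#' @param mesh a `triangle_mesh`.
#' @param direction length-3 direction (default superior, +z).
#' @return vertex index (1-based).
#' @export
pick_prominent_vertex <- function(mesh, direction = c(0, 0, 1)) {
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  which.max(as.vector(mesh$vertices %*% direction))
}

#' Select the mesh region within a radius of a seed vertex
#'
#' Euclidean-ball selection around the seed position, emulating the
#' "selecting radius" used to extract matching condylar patches for ICP.
#'
#' @param mesh a `triangle_mesh`.
#' @param seed seed vertex index.
#' @param radius selection radius in mm.
#' @return an object of class `region_selection` with fields `seed_vertex`,
#'   `radius`, `index` and `points`.
#' @export
select_region <- function(mesh, seed, radius) {
  if (length(seed) != 1L || is.na(seed) || seed < 1L ||
      seed > nrow(mesh$vertices)) stop("invalid seed vertex")
  if (radius <= 0) stop("radius must be positive")
  p0 <- mesh$vertices[seed, ]
  d2 <- rowSums(sweep(mesh$vertices, 2L, p0)^2)
  idx <- which(d2 <= radius^2)
  if (length(idx) == 1L)
    warning("selection radius captured only the seed vertex")
  structure(list(seed_vertex = seed, radius = radius, index = idx,
                 points = mesh$vertices[idx, , drop = FALSE]),
            class = "region_selection")
}

# --- ICP -------------------------------------------------------------------

#' Iterative closest point registration
#'
#' Point-to-point ICP: alternate nearest-neighbour correspondence (moving
#' to reference) with Horn alignment of the matched pairs until the RMS
#' residual change drops below `tolerance` or `max_iter` is reached. An
#' optional trimming fraction discards the worst-matching pairs each
#' iteration for robustness to partial overlap.
#'
#' @param ref n x 3 reference point set (or `region_selection`).
#' @param mov m x 3 moving point set (or `region_selection`).
#' @param max_iter iteration cap (default 300).
#' @param tolerance RMS-change stopping threshold in mm (default 1e-7).
#' @param trim fraction in [0, 0.5) of worst pairs rejected (default 0).
#' @param init optional initial `rigid_transform` applied to `mov`.
#' @param max_points deterministic thinning cap on moving points.
#' @return list with `transform` (the full pose, including `init`),
#'   `rms` (per-iteration RMS trace, non-increasing), `iterations`,
#'   `converged`.
#' @export
icp_register <- function(ref, mov, max_iter = 300L, tolerance = 1e-7,
                         trim = 0, init = NULL, max_points = 5000L) {
  if (inherits(ref, "region_selection")) ref <- ref$points
  if (inherits(mov, "region_selection")) mov <- mov$points
  ref_mesh <- if (inherits(ref, "triangle_mesh")) ref else NULL
  if (!is.null(ref_mesh)) ref <- ref_mesh$vertices
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) == 0L || nrow(mov) == 0L) stop("empty point set")
  if (is.finite(max_points) && nrow(mov) > max_points) {
    # deterministic thinning: every k-th moving point
    mov <- mov[seq(1L, nrow(mov),
                   length.out = max_points), , drop = FALSE]
  }
  match_ref <- function(p) {
    # correspondence target: closest point on the reference surface when a
    # mesh is given, nearest reference point otherwise
    if (!is.null(ref_mesh))
      cpp_closest_on_mesh_grid(p, ref_mesh$vertices, ref_mesh$faces,
                               -1)$closest
    else ref[cpp_nn_index(p, ref), , drop = FALSE]
  }
  pose <- if (is.null(init)) rigid_transform() else init
  cur <- apply_transform(mov, pose)
  rms <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  nkeep <- max(3L, ceiling(nrow(mov) * (1 - trim)))
  repeat {
    it <- it + 1L
    tgt <- match_ref(cur)
    d2 <- rowSums((cur - tgt)^2)
    r <- sqrt(mean(d2))
    rms <- c(rms, r)
    if (is.finite(prev) && abs(prev - r) < tolerance) {
      converged <- TRUE
      break
    }
    if (it > max_iter) break
    prev <- r
    keep <- if (trim > 0) order(d2)[seq_len(nkeep)] else seq_len(nrow(cur))
    step <- horn_align(tgt[keep, , drop = FALSE],
                       cur[keep, , drop = FALSE])
    pose <- compose_transform(step, pose)
    cur <- apply_transform(mov, pose)
  }
  list(transform = pose, rms = rms, iterations = it, converged = converged)
}

#' Pose-invariant canonical frame of a mesh
#'
#' The rigid transform taking the mesh into its principal-axes frame:
#' origin at the vertex centroid, axes along the covariance eigenvectors
#' (decreasing eigenvalue), each axis sign-fixed by the third moment of
#' the vertex distribution so the frame is reproducible under arbitrary
#' rigid motion of the mesh.
#'
#' @param mesh a `triangle_mesh`.
#' @return a `rigid_transform` mapping world to canonical coordinates.
#' @export
canonical_frame <- function(mesh) {
  X <- mesh$vertices
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:3) {
    s <- sum((Xc %*% V[, j])^3)
    if (s < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  R <- t(V)
  rigid_transform(R, -as.vector(R %*% ctr))
}

#' Semiautomatic registration chain
#'
#' The full alignment used for condyle models: pick the most prominent
#' superior vertex on each mesh, Horn-pre-align on those landmarks plus the
#' mesh centroids, select a radius-limited patch around the prominent
#' vertices, and refine with ICP on the patches.
#'
#' @param ref_mesh,mov_mesh `triangle_mesh` objects.
#' @param radius patch selection radius in mm (default 8).
#' @param direction prominence direction (default +z, superior).
#' @param landmarks optional list with `ref` and `mov` n x 3 matched
#'   landmark matrices overriding the automatic picks.
#' @param ... passed to [icp_register()].
#' @return as [icp_register()], plus `prealign` (the Horn-only pose).
#' @export
register_meshes <- function(ref_mesh, mov_mesh, radius = 12,
                            direction = c(0, 0, 1), landmarks = NULL, ...) {
  if (is.null(landmarks)) {
    # automated correspondence triad: each mesh's prominent vertex along
    # `direction` *of its own canonical frame* (so the pick is
    # pose-invariant), the centroid, and the canonical-frame prominent
    # vertex along the first principal axis
    fr <- canonical_frame(ref_mesh)
    fm <- canonical_frame(mov_mesh)
    cref <- apply_transform(ref_mesh, fr)
    cmov <- apply_transform(mov_mesh, fm)
    pr <- pick_prominent_vertex(cref, direction)
    pm <- pick_prominent_vertex(cmov, direction)
    dir2 <- c(1, 0, 0)
    lr <- rbind(ref_mesh$vertices[pr, ], colMeans(ref_mesh$vertices),
                ref_mesh$vertices[pick_prominent_vertex(cref, dir2), ])
    lm <- rbind(mov_mesh$vertices[pm, ], colMeans(mov_mesh$vertices),
                mov_mesh$vertices[pick_prominent_vertex(cmov, dir2), ])
  } else {
    lr <- as.matrix(landmarks$ref); lm <- as.matrix(landmarks$mov)
    pr <- pick_prominent_vertex(ref_mesh, direction)
    pm <- pick_prominent_vertex(mov_mesh, direction)
  }
  pre <- horn_align(lr, lm)
  mov_patch <- select_region(mov_mesh, pm, radius)
  out <- icp_register(ref_mesh, mov_patch$points, init = pre, ...)
  out$prealign <- pre
  out
}

#' Read a landmark file
#'
#' Plain-text landmarks: one `name x y z` row per point (mm), whitespace or
#' comma separated.
#'
#' @param path file path.
#' @return named list of length-3 numeric positions.
#' @export
read_landmarks <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) as.numeric(tab[i, 2:4]))
  names(out) <- tab$name
  out
}

#' Pose recovery error
#'
#' Compares an estimated transform with the truth it should invert:
#' rotation error in degrees, and translation error as the residual
#' displacement of `anchor` (mm) under the composed error transform.
#' Anchoring at the object centroid makes the translation component
#' independent of where the world origin happens to lie.
#'
#' @param estimated the recovered `rigid_transform` (mapping moving to
#'   reference).
#' @param truth the `rigid_transform` that was applied to create the
#'   moving object.
#' @param anchor point at which translation error is evaluated (mm).
#' @return list with `rotation_deg` and `translation_mm`.
#' @export
pose_error <- function(estimated, truth, anchor = c(0, 0, 0)) {
  err <- compose_transform(estimated, truth)
  disp <- as.vector(err$rotation %*% anchor) + err$translation - anchor
  list(rotation_deg = rotation_angle(err),
       translation_mm = sqrt(sum(disp^2)))
}
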