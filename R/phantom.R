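#' Condyle phantom specification
#'
#' Parameterises a synthetic condyle: a superellipsoid head (ellipsoid for
#' `exponent = 2`) fused by a smooth union to a cylindrical neck stump
#' extending inferiorly. Default dimensions give a head volume in the
#' 1.2-1.6e3 mm^3 range of adult condyles. The canonical solid describes a
#' right condyle; `side = "left"` mirrors it about the mid-sagittal plane
#' (x = 0) and both sides are offset laterally by `lateral_offset`.
#' Axes: +x patient-left, +y anterior, +z superior.
#'
#' @param semi_axes length-3 positive semi-axes (mm): medio-lateral,
#'   antero-posterior, supero-inferior.
#' @param neck_length neck stump length below the head (mm); 0 for none.
#' @param neck_radius neck radius (mm).
#' @param exponent superellipsoid exponent (2 = ellipsoid).
#' @param asymmetry medio-lateral shape skew (0 = mirror-symmetric head).
#' @param blend smooth-union blending scale (mm).
#' @param side `"left"` or `"right"`.
#' @param lateral_offset distance of the condyle centre from the
#'   mid-sagittal plane (mm).
#' @param pitch marching grid pitch for mesh generation (mm).
#' @param seed integer RNG seed recorded with the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(8.5, 6.9, 4.8), neck_length = 5,
                         neck_radius = 3.4, exponent = 2, asymmetry = 0.12,
                         blend = 0.8, side = c("right", "left"),
                         lateral_offset = 40, pitch = 0.25, seed = 1L) {
  side <- match.arg(side)
  if (any(semi_axes <= 0)) stop("semi_axes must all be positive")
  if (neck_length < 0 || neck_radius <= 0) stop("invalid neck dimensions")
  if (pitch <= 0) stop("pitch must be positive")
  structure(list(semi_axes = as.numeric(semi_axes),
                 neck_length = neck_length, neck_radius = neck_radius,
                 exponent = exponent, asymmetry = asymmetry, blend = blend,
                 side = side, lateral_offset = lateral_offset,
                 pitch = pitch, seed = as.integer(seed)),
            class = "phantom_spec")
}

# signed implicit function of the canonical (right, centred) solid;
# negative inside, approximately in mm near the surface
phantom_implicit <- function(spec) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
  e <- spec$exponent; asym <- spec$asymmetry
  rn <- spec$neck_radius; nl <- spec$neck_length; k <- spec$blend
  scale <- min(a, b, cc)
  function(x, y, z) {
    xa <- x / a
    xa <- xa * (1 - asym * xa)   # medio-lateral skew
    head <- ((abs(xa)^e + abs(y / b)^e + abs(z / cc)^e)^(1 / e) - 1) * scale
    if (nl <= 0) return(head)
    neck <- pmax(sqrt(x^2 + y^2) - rn, z, -(z + cc + nl))
    if (k > 0) -log(exp(-head / k) + exp(-neck / k)) * k  # smooth union
    else pmin(head, neck)
  }
}

#' Generate a phantom condyle mesh
#'
#' Extracts the phantom's implicit surface on a regular grid at the spec's
#' pitch and places it at its lateral position. The result is watertight
#' and outward-oriented; generation is fully deterministic for a given
#' spec.
#'
#' @param spec a [phantom_spec()].
#' @return a `triangle_mesh` with attribute `reference`: list with the
#'   reference surface `S` (mm^2) and volume `V` (mm^3) of the generating
#'   solid (closed form for the neckless ellipsoid; fine-grid extraction
#'   otherwise) and the method used.
#' @export
make_condyle_mesh <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- phantom_implicit(spec)
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
  pad <- 2 + spec$blend
  lo <- c(-a - pad, -b - pad, -cc - spec$neck_length - pad)
  hi <- c(a + pad, b + pad, cc + pad)
  mesh <- implicit_to_mesh(f, lo, hi, spec$pitch)
  ref <- phantom_reference(spec)
  # mirror for the left side (canonical solid is a right condyle)
  if (spec$side == "left") {
    mesh$vertices[, 1L] <- -mesh$vertices[, 1L]
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  shift <- if (spec$side == "left") spec$lateral_offset else -spec$lateral_offset
  mesh$vertices[, 1L] <- mesh$vertices[, 1L] + shift
  attr(mesh, "reference") <- ref
  attr(mesh, "spec") <- spec
  mesh
}

# sample an implicit function on a regular grid and extract the 0-level
implicit_to_mesh <- function(f, lo, hi, pitch, iso = 0) {
  gx <- seq(lo[1], hi[1], by = pitch)
  gy <- seq(lo[2], hi[2], by = pitch)
  gz <- seq(lo[3], hi[3], by = pitch)
  gr <- expand.grid(x = gx, y = gy, z = gz)
  vals <- f(gr$x, gr$y, gr$z)
  res <- cpp_marching_tets(vals, c(length(gx), length(gy), length(gz)), iso)
  v <- res$vertices
  v[, 1L] <- lo[1] + v[, 1L] * pitch
  v[, 2L] <- lo[2] + v[, 2L] * pitch
  v[, 3L] <- lo[3] + v[, 3L] * pitch
  orient_outward(triangle_mesh(v, res$faces, validate = FALSE))
}

# reference S and V of the generating solid, for oracle use
phantom_reference <- function(spec) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
  if (spec$neck_length == 0 && spec$exponent == 2 && spec$asymmetry == 0) {
    V <- 4 / 3 * pi * a * b * cc
    p <- 1.6075  # Thomsen approximation, exact for the sphere
    S <- 4 * pi * (((a * b)^p + (a * cc)^p + (b * cc)^p) / 3)^(1 / p)
    return(list(V = V, S = S,
                method = if (a == b && b == cc) "closed form (sphere)"
                         else "closed form V, Thomsen S (ellipsoid)"))
  }
  fine <- spec
  fine$pitch <- min(spec$pitch, 0.15)
  fine$side <- "right"; fine$lateral_offset <- 0
  f <- phantom_implicit(fine)
  pad <- 2 + spec$blend
  lo <- c(-a - pad, -b - pad, -cc - spec$neck_length - pad)
  hi <- c(a + pad, b + pad, cc + pad)
  m <- implicit_to_mesh(f, lo, hi, fine$pitch)
  list(V = mesh_volume(m, check = FALSE), S = surface_area(m),
       method = sprintf("fine-grid extraction at %.3g mm", fine$pitch))
}

#' Generate an anatomically paired left/right phantom
#'
#' Two watertight condyle meshes in a shared frame, separated laterally as
#' anatomical left and right. Mirrored identical specs produce exact mirror
#' images about the mid-sagittal plane.
#'
#' @param spec_left,spec_right [phantom_spec()] objects with matching
#'   `side` fields.
#' @return list with `left`, `right` (`triangle_mesh`), and `reference`
#'   (per-side reference S/V of the generating solids).
#' @export
make_condyle_pair <- function(spec_left = phantom_spec(side = "left"),
                              spec_right = phantom_spec(side = "right")) {
  if (spec_left$side != "left" || spec_right$side != "right")
    stop("specs must be labelled side = 'left' and side = 'right'")
  ml <- make_condyle_mesh(spec_left)
  mr <- make_condyle_mesh(spec_right)
  list(left = ml, right = mr,
       reference = list(left = attr(ml, "reference"),
                        right = attr(mr, "reference")))
}

#' Imaging modality model
#'
#' Describes how a phantom solid is rendered into an intensity volume.
#' CBCT-like volumes are isotropic 0.4 mm with bright bone; MRI-like
#' volumes are 0.55 x 0.55 x 0.5 mm with dark bone and an inward
#' surface-erosion bias emulating the systematic underestimation of bony
#' contours segmented from MRI. Intensity bands are arbitrary units:
#' bone = 1000, background = 0 for `bone_bright`, inverted for
#' `bone_dark`.
#'
#' @param name `"cbct_like"` or `"mri_like"`.
#' @param voxel_size length-3 voxel spacing (mm).
#' @param polarity `"bone_bright"` or `"bone_dark"`; fixed by modality.
#' @param erosion_bias inward offset of the bone boundary (mm, >= 0;
#'   must be 0 for cbct_like).
#' @param boundary_noise_sd Gaussian jitter of the boundary position (mm).
#' @param intensity_noise_sd additive Gaussian intensity noise (AU).
#' @param edge_width partial-volume ramp width (mm): intensity grades
#'   linearly from background to bone across this distance around the
#'   (biased, jittered) boundary, emulating the scanner point-spread
#'   blur that makes threshold choice matter.
#' @return an object of class `modality_model`.
#' @export
modality_model <- function(name = c("cbct_like", "mri_like"),
                           voxel_size = NULL, polarity = NULL,
                           erosion_bias = NULL, boundary_noise_sd = NULL,
                           intensity_noise_sd = 30, edge_width = NULL) {
  name <- match.arg(name)
  if (name == "cbct_like") {
    voxel_size <- voxel_size %||% c(0.4, 0.4, 0.4)
    polarity <- polarity %||% "bone_bright"
    erosion_bias <- erosion_bias %||% 0
    boundary_noise_sd <- boundary_noise_sd %||% 0.05
    edge_width <- edge_width %||% 0.4
    if (polarity != "bone_bright") stop("cbct_like must be bone_bright")
    if (erosion_bias != 0) stop("cbct_like has no erosion bias")
  } else {
    voxel_size <- voxel_size %||% c(0.55, 0.55, 0.5)
    polarity <- polarity %||% "bone_dark"
    erosion_bias <- erosion_bias %||% 0.3
    boundary_noise_sd <- boundary_noise_sd %||% 0.12
    edge_width <- edge_width %||% 0.6
    if (polarity != "bone_dark") stop("mri_like must be bone_dark")
    if (erosion_bias < 0) stop("erosion_bias must be >= 0")
  }
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (edge_width < 0) stop("edge_width must be >= 0")
  structure(list(name = name, voxel_size = as.numeric(voxel_size),
                 polarity = polarity, erosion_bias = erosion_bias,
                 boundary_noise_sd = boundary_noise_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 edge_width = edge_width,
                 bone_value = 1000, background_value = 0),
            class = "modality_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelize a mesh under a modality model
#'
#' Renders a watertight mesh into an intensity volume: voxel centres are
#' classified interior/exterior by ray parity, the boundary is offset
#' inward by the modality's erosion bias and jittered by its boundary
#' noise (both applied through the signed distance to the surface), and
#' the bone/background intensity bands for the modality's polarity are
#' filled with additive Gaussian noise. Deterministic for a given seed.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param modality a [modality_model()].
#' @param seed integer RNG seed.
#' @param pad margin of background around the mesh bounding box (mm).
#' @return a `voxel_volume` (see [voxel_volume()]).
#' @export
voxelize <- function(mesh, modality = modality_model("cbct_like"),
                     seed = 1L, pad = 3) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(modality, "modality_model"))
  if (!is_watertight(mesh)) stop("voxelize requires a watertight mesh")
  sp <- modality$voxel_size
  lo <- apply(mesh$vertices, 2L, min) - pad
  hi <- apply(mesh$vertices, 2L, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  inside <- cpp_ray_parity_fill(mesh$vertices, mesh$faces, dims, sp, lo)
  delta <- modality$erosion_bias
  bnsd <- modality$boundary_noise_sd
  w <- modality$edge_width
  set.seed(seed)
  n <- prod(dims)
  if (delta > 0 || bnsd > 0 || w > 0) {
    band <- delta + 4 * bnsd + w + max(sp)
    centers <- voxel_centers(dims, sp, lo)
    cd <- cpp_closest_on_mesh_grid(centers, mesh$vertices, mesh$faces, band)
    d <- cd$distance
    d[!is.finite(d)] <- band * 2
    sgn <- ifelse(inside, d, -d) - delta   # signed, + = inside the
                                           # (eroded) bone boundary
    inband <- d <= band
    eps <- numeric(n)
    eps[inband] <- stats::rnorm(sum(inband), 0, bnsd)
    sgn <- sgn + eps
    # partial-volume ramp across the boundary
    frac <- if (w > 0) pmin(1, pmax(0, 0.5 + sgn / w)) else as.numeric(sgn >= 0)
  } else {
    frac <- as.numeric(inside)
  }
  base <- modality$background_value +
    (modality$bone_value - modality$background_value) * frac
  if (modality$polarity == "bone_dark")
    base <- modality$bone_value + modality$background_value - base
  vals <- base + stats::rnorm(n, 0, modality$intensity_noise_sd)
  voxel_volume(array(vals, dim = dims), spacing = sp, origin = lo,
               polarity = modality$polarity)
}

voxel_centers <- function(dims, spacing, origin) {
  gx <- origin[1] + (seq_len(dims[1]) - 1L) * spacing[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1L) * spacing[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1L) * spacing[3]
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}

#' Perturb a mesh as a registration replicate
#'
#' Applies a random rigid offset (rotation up to `max_angle` about a random
#' axis, translation up to `max_shift` in a random direction) plus optional
#' iid Gaussian vertex noise, and returns both the perturbed mesh and the
#' exact transform applied, so registration can be tested against known
#' truth.
#'
#' @param mesh a `triangle_mesh`.
#' @param max_angle maximum rotation angle (degrees).
#' @param max_shift maximum translation magnitude (mm).
#' @param vertex_noise_sd per-coordinate vertex noise SD (mm).
#' @param seed integer RNG seed.
#' @return list with `mesh` (perturbed) and `transform` (the applied
#'   `rigid_transform`).
#' @export
perturb_replicate <- function(mesh, max_angle = 10, max_shift = 5,
                              vertex_noise_sd = 0, seed = 1L) {
  set.seed(seed)
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  shift <- dir * stats::runif(1, 0, max_shift)
  tr <- if (max_angle == 0 && max_shift == 0) rigid_transform()
        else axis_angle_transform(axis, ang, shift)
  out <- apply_transform(mesh, tr)
  if (vertex_noise_sd > 0)
    out$vertices <- out$vertices +
      matrix(stats::rnorm(length(out$vertices), 0, vertex_noise_sd),
             ncol = 3L)
  list(mesh = out, transform = tr)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; the standard well-behaved
#' test surface with closed-form S and V.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-fold subdivision passes.
#' @param center sphere centre.
#' @return a watertight `triangle_mesh`.
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      verts[[length(verts) + 1L]] <<- matrix(p, 1L)
      nv <<- nv + 1L
      mid[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, verts)
    v <- v / sqrt(rowSums(v^2))
    f <- newf
  }
  m <- triangle_mesh(sweep(v * radius, 2L, -center), f, validate = FALSE)
  orient_outward(m)
}

#' Axis-aligned box mesh
#'
#' @param lo,hi opposite box corners.
#' @return a watertight `triangle_mesh` (12 triangles).
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corners: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0) 5=(0,0,1) 6=(1,0,1)
  #          7=(0,1,1) 8=(1,1,1)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z = lo), outward -z
    c(5, 6, 7), c(6, 8, 7),   # top
    c(1, 2, 5), c(2, 6, 5),   # front (y = lo)
    c(3, 7, 4), c(4, 7, 8),   # back
    c(1, 5, 3), c(3, 5, 7),   # left (x = lo)
    c(2, 4, 6), c(4, 8, 6))   # right
  orient_outward(triangle_mesh(v, f, validate = FALSE))
}
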