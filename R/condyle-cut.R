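#' Build the two orthogonal condylar cutting planes
#'
#' Plane A passes through the anterior nasal spine (ANS) and both sigmoid
#' notch points; plane B contains the two notch points with its normal
#' orthogonal to plane A's normal (so the planes are orthogonal) and lying
#' in plane A's direction span. Both normals are sign-canonicalised
#' towards `superior_hint`, so the "kept" side of each plane is the
#' superior one and swapping the two notch points leaves the plane set
#' unchanged.
#'
#' @param ANS anterior nasal spine position (mm).
#' @param notch_L,notch_R left/right sigmoid notch positions (mm).
#' @param superior_hint direction used to fix normal signs (default +z).
#' @return an object of class `cut_plane_set`: `plane_A`, `plane_B` (each
#'   `point` + unit `normal`) and the landmarks.
#' @export
build_cut_planes <- function(ANS, notch_L, notch_R,
                             superior_hint = c(0, 0, 1)) {
  ANS <- as.numeric(ANS); notch_L <- as.numeric(notch_L)
  notch_R <- as.numeric(notch_R)
  u <- notch_L - ANS; v <- notch_R - ANS
  nA <- cross3(u, v)
  nrmA <- sqrt(sum(nA^2))
  if (nrmA < 1e-9 * max(sqrt(sum(u^2)), sqrt(sum(v^2)), 1))
    stop("degenerate landmarks: ANS and notch points are collinear")
  nA <- canonical_sign(nA / nrmA, superior_hint)
  d <- notch_R - notch_L
  nB <- cross3(nA, d)
  nB <- canonical_sign(nB / sqrt(sum(nB^2)), superior_hint)
  structure(list(
    plane_A = list(point = ANS, normal = nA),
    plane_B = list(point = (notch_L + notch_R) / 2, normal = nB),
    landmarks = list(ANS = ANS, notch_L = notch_L, notch_R = notch_R)),
    class = "cut_plane_set")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

canonical_sign <- function(n, hint) {
  s <- sum(n * hint)
  if (abs(s) > 1e-12) return(if (s < 0) -n else n)
  nz <- which(abs(n) > 1e-12)[1]   # hint orthogonal: first nonzero positive
  if (n[nz] < 0) -n else n
}

#' Transform a cut plane set
#'
#' @param planes a `cut_plane_set`.
#' @param transform a `rigid_transform`.
#' @return the transformed `cut_plane_set` (rebuilt from the transformed
#'   landmarks, so equivariance is exact).
#' @export
transform_planes <- function(planes, transform) {
  lm <- lapply(planes$landmarks, function(p)
    as.vector(transform$rotation %*% p) + transform$translation)
  hint <- as.vector(transform$rotation %*% c(0, 0, 1))
  build_cut_planes(lm$ANS, lm$notch_L, lm$notch_R, superior_hint = hint)
}

#' Clip a watertight mesh by a half-space and cap the cut
#'
#' Keeps the part of the mesh with `dot(x - point, normal) >= 0`,
#' splitting crossing triangles along the plane. Cut boundary loops are
#' closed with planar triangulated caps (ear clipping in the plane), so a
#' watertight input yields a watertight output.
#'
#' @param mesh a watertight, outward-oriented `triangle_mesh`.
#' @param point a point on the plane.
#' @param normal plane normal; the kept side is the positive one.
#' @param eps snapping tolerance for vertices on the plane (mm).
#' @return a `triangle_mesh`; attribute `cap_area` (mm^2) holds the area
#'   added by the caps (0 when the plane misses the mesh).
#' @export
clip_halfspace <- function(mesh, point, normal, eps = 1e-9) {
  n <- normal / sqrt(sum(normal^2))
  d <- as.vector(sweep(mesh$vertices, 2L, as.numeric(point)) %*% n)
  d[abs(d) < eps] <- 0
  if (all(d >= 0)) { attr(mesh, "cap_area") <- 0; return(mesh) }
  if (all(d <= 0)) {
    out <- triangle_mesh(mesh$vertices[0, , drop = FALSE],
                         matrix(integer(), 0L, 3L), validate = FALSE)
    attr(out, "cap_area") <- 0
    return(out)
  }
  v <- mesh$vertices
  nv <- nrow(v)
  newv <- list()
  cutmap <- new.env(hash = TRUE)  # edge key -> new vertex index
  nextid <- nv
  cut_edge <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- cutmap[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    nextid <<- nextid + 1L
    newv[[length(newv) + 1L]] <<- p
    cutmap[[key]] <- nextid
    nextid
  }
  keepf <- list()
  bedges <- list()  # directed boundary edges of the kept side, in-plane
  inplane <- list() # kept-face edges with both endpoints on the plane
  for (fi in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[fi, ]
    dd <- d[tri]
    if (all(dd >= 0)) {
      if (!all(dd == 0)) {
        keepf[[length(keepf) + 1L]] <- tri
        z <- dd == 0
        if (sum(z) == 2L) {
          # the in-plane edge, directed per the face winding
          ij <- switch(which(!z), c(2L, 3L), c(3L, 1L), c(1L, 2L))
          inplane[[length(inplane) + 1L]] <- tri[ij]
        }
      }
      next
    }
    if (all(dd <= 0)) next
    # rotate so the pattern starts at vertex 1
    for (r in 0:2) {
      rt <- tri[(0:2 + r) %% 3 + 1]
      rd <- dd[(0:2 + r) %% 3 + 1]
      pos <- rd > 0; neg <- rd < 0
      if (sum(pos) == 1L && pos[1]) {          # + - -, + - 0, + 0 -
        a <- rt[1]; b <- rt[2]; c <- rt[3]
        pab <- if (rd[2] < 0) cut_edge(a, b) else b
        pca <- if (rd[3] < 0) cut_edge(c, a) else c
        keepf[[length(keepf) + 1L]] <- c(a, pab, pca)
        bedges[[length(bedges) + 1L]] <- c(pab, pca)
        break
      }
      if (sum(neg) == 1L && neg[1]) {          # - + +, - + 0, - 0 +
        a <- rt[1]; b <- rt[2]; c <- rt[3]
        pab <- if (rd[2] > 0) cut_edge(a, b) else b
        pca <- if (rd[3] > 0) cut_edge(c, a) else c
        # when b or c lies exactly on the plane one sub-triangle
        # degenerates to an edge and is skipped
        if (pab != b)
          keepf[[length(keepf) + 1L]] <- c(pab, b, c)
        if (pca != c)
          keepf[[length(keepf) + 1L]] <- c(pab, c, pca)
        bedges[[length(bedges) + 1L]] <- c(pca, pab)
        break
      }
      if (sum(pos) == 1L && sum(neg) == 1L && rd[1] == 0) { # 0 + - / 0 - +
        a <- rt[1]; b <- rt[2]; c <- rt[3]
        pbc <- cut_edge(b, c)
        if (rd[2] > 0) {
          keepf[[length(keepf) + 1L]] <- c(a, b, pbc)
          bedges[[length(bedges) + 1L]] <- c(pbc, a)
        } else {
          keepf[[length(keepf) + 1L]] <- c(a, pbc, c)
          bedges[[length(bedges) + 1L]] <- c(a, pbc)
        }
        break
      }
    }
  }
  # an in-plane kept edge is a boundary edge iff its reverse is not also a
  # kept in-plane edge (i.e. the face across the plane was dropped)
  if (length(inplane) > 0) {
    ip <- do.call(rbind, inplane)
    keys <- paste(ip[, 1L], ip[, 2L])
    rkeys <- paste(ip[, 2L], ip[, 1L])
    open <- !(rkeys %in% keys)
    for (i in which(open))
      bedges[[length(bedges) + 1L]] <- ip[i, ]
  }
  allv <- rbind(v, do.call(rbind, newv))
  faces <- do.call(rbind, keepf)
  cap_area <- 0
  if (length(bedges) > 0) {
    loops <- chain_loops(do.call(rbind, bedges))
    for (loop in loops) {
      capf <- triangulate_loop(allv[loop, , drop = FALSE], n)
      if (nrow(capf) == 0L) next
      # cap outward normal must be -n (faces away from the kept side)
      cf <- matrix(loop[capf[, c(1L, 3L, 2L)]], ncol = 3L)
      # a pinched loop can map two positions to one vertex: drop those
      ok <- cf[, 1L] != cf[, 2L] & cf[, 2L] != cf[, 3L] & cf[, 1L] != cf[, 3L]
      faces <- rbind(faces, cf[ok, , drop = FALSE])
      cap_area <- cap_area + polygon_area(allv[loop, , drop = FALSE], n)
    }
  }
  out <- compact_mesh(allv, faces)
  attr(out, "cap_area") <- cap_area
  out
}

# chain directed edges into closed loops; a boundary vertex may carry
# several outgoing edges (the cut pinching at a vertex on the plane), so
# each directed edge is consumed once, Eulerian-walk style
chain_loops <- function(edges) {
  out <- split(seq_len(nrow(edges)), edges[, 1L])
  used <- rep(FALSE, nrow(edges))
  loops <- list()
  for (start_e in seq_len(nrow(edges))) {
    if (used[start_e]) next
    s <- edges[start_e, 1L]
    loop <- integer()
    cur_e <- start_e
    repeat {
      used[cur_e] <- TRUE
      loop <- c(loop, edges[cur_e, 1L])
      head <- edges[cur_e, 2L]
      if (head == s) { loops[[length(loops) + 1L]] <- loop; break }
      cand <- out[[as.character(head)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break   # open chain: cannot cap
      cur_e <- cand[1L]
    }
  }
  loops
}

# ear-clipping triangulation of a planar polygon (indices are local,
# 1..nrow(pts)); returns an m x 3 matrix of local indices wound
# counter-clockwise in the plane whose normal is `n`
triangulate_loop <- function(pts, n) {
  k <- nrow(pts)
  if (k < 3L) return(matrix(integer(), 0L, 3L))
  # plane basis
  e1 <- pts[2, ] - pts[1, ]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  p2 <- cbind(as.vector(sweep(pts, 2L, pts[1, ]) %*% e1),
              as.vector(sweep(pts, 2L, pts[1, ]) %*% e2))
  idx <- seq_len(k)   # positions into pts, so repeated vertices are safe
  area2 <- sum(p2[idx, 1] * p2[c(idx[-1], idx[1]), 2] -
               p2[c(idx[-1], idx[1]), 1] * p2[idx, 2])
  if (area2 < 0) idx <- rev(idx)      # make CCW in (e1, e2)
  tris <- matrix(integer(), 0L, 3L)
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      ia <- (i - 2L) %% m + 1L; ib <- (i - 1L) %% m + 1L; ic <- i %% m + 1L
      a <- idx[ia]; b <- idx[ib]; c <- idx[ic]
      ab <- p2[b, ] - p2[a, ]; ac <- p2[c, ] - p2[a, ]
      crossz <- ab[1] * ac[2] - ab[2] * ac[1]
      if (crossz <= 1e-14) next      # reflex or degenerate corner
      # no other loop vertex strictly inside the candidate ear
      others <- idx[-c(ia, ib, ic)]
      others <- others[!(others %in% c(a, b, c))]
      if (length(others) > 0 &&
          any(point_in_tri2(p2[others, , drop = FALSE],
                            p2[a, ], p2[b, ], p2[c, ]))) next
      tris <- rbind(tris, c(a, b, c))
      idx <- idx[-ib]
      clipped <- TRUE
      break
    }
    if (!clipped) break   # numerically stuck: fan the remainder
  }
  if (length(idx) == 3L) tris <- rbind(tris, idx)
  else if (length(idx) > 3L) {
    for (i in 2:(length(idx) - 1L))
      tris <- rbind(tris, c(idx[1L], idx[i], idx[i + 1L]))
  }
  # wound so cross(b-a, c-a) . n > 0
  tris
}

point_in_tri2 <- function(p, a, b, c) {
  d1 <- (p[, 1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p[, 2] - b[2])
  d2 <- (p[, 1] - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (p[, 2] - c[2])
  d3 <- (p[, 1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (p[, 2] - a[2])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

polygon_area <- function(pts, n) {
  k <- nrow(pts)
  s <- c(0, 0, 0)
  for (i in seq_len(k)) {
    j <- i %% k + 1L
    s <- s + cross3(pts[i, ], pts[j, ])
  }
  abs(sum(s * n)) / 2
}

compact_mesh <- function(vertices, faces) {
  used <- sort(unique(as.vector(faces)))
  # keep zero-area slivers: they can be topologically required for closure
  triangle_mesh(vertices[used, , drop = FALSE],
                matrix(match(faces, used), ncol = 3L), validate = FALSE)
}

#' Isolate the condylar head with the two cutting planes
#'
#' Clips the mesh by plane A then plane B, keeping for each plane the side
#' containing `keep_point` (by default the most prominent superior vertex,
#' i.e. the head side), capping each cut so the result stays watertight.
#' If a plane misses the mesh the mesh passes through unchanged with a
#' warning; if a cut splits the mesh into several components the largest
#' by volume is kept with a warning.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param planes a `cut_plane_set` from [build_cut_planes()].
#' @param keep_point point identifying the side to keep (default the most
#'   prominent +z vertex of the input).
#' @return a watertight `triangle_mesh`; attribute `cap_area` totals the
#'   planar cap area added (mm^2).
#' @export
cut_head <- function(mesh, planes, keep_point = NULL) {
  stopifnot(inherits(planes, "cut_plane_set"))
  if (is.null(keep_point))
    keep_point <- mesh$vertices[pick_prominent_vertex(mesh), ]
  total_cap <- 0
  for (pl in list(planes$plane_A, planes$plane_B)) {
    side <- sum((keep_point - pl$point) * pl$normal)
    n <- if (side >= 0) pl$normal else -pl$normal
    d <- as.vector(sweep(mesh$vertices, 2L, pl$point) %*% n)
    if (all(d >= -1e-9)) {
      warning("cut plane does not intersect the mesh; returning input")
      next
    }
    cut <- clip_halfspace(mesh, pl$point, n)
    total_cap <- total_cap + attr(cut, "cap_area")
    comps <- mesh_components(cut)
    if (length(comps) > 1L) {
      warning(sprintf("cut produced %d components; keeping the largest",
                      length(comps)))
      vols <- vapply(comps, function(m)
        tryCatch(mesh_volume(m), error = function(e) 0), 1)
      cut <- comps[[which.max(vols)]]
    }
    mesh <- cut
  }
  attr(mesh, "cap_area") <- total_cap
  mesh
}
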