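#' Triangle mesh constructor
#'
#' Builds the indexed triangle surface used throughout the pipeline. All
#' coordinates are in millimetres. Faces are 1-based vertex-index triples,
#' counter-clockwise when seen from outside for an outward-oriented mesh.
#'
#' @param vertices numeric matrix, n x 3 (mm).
#' @param faces integer matrix, m x 3 of vertex indices.
#' @param validate drop degenerate (zero-area) faces and unreferenced
#'   vertices when `TRUE`.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (validate) m <- drop_degenerate_faces(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  wt <- tryCatch(is_watertight(x), error = function(e) NA)
  cat(sprintf("triangle_mesh: %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), wt))
  invisible(x)
}

triangle_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - a
  w <- v[f[, 3L], , drop = FALSE] - a
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  cr <- triangle_cross(mesh)
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 > tol
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half the cross-product magnitudes).
#'
#' @param mesh a `triangle_mesh`.
#' @return area in mm^2.
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) return(0)
  cr <- triangle_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedra spanned by each
#' face and the origin. Requires a closed, consistently oriented mesh; the
#' absolute value is returned so either global orientation measures the
#' same solid.
#'
#' @param mesh a `triangle_mesh`.
#' @param check verify watertightness first (default `TRUE`).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (check && !is_watertight(mesh)) {
    op <- open_edges(mesh)
    stop(sprintf("mesh is not watertight: %d open/odd edges (first: %s)",
                 nrow(op), paste(op[1, ], collapse = "-")))
  }
  abs(signed_volume(mesh))
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) +
      a[, 2L] * (b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

edge_table <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1L], f[, 2L], f[, 3L]),
        c(f[, 2L], f[, 3L], f[, 1L]))
}

#' Edges not shared by exactly two faces
#'
#' @param mesh a `triangle_mesh`.
#' @return 2-column matrix of offending undirected edges.
#' @export
open_edges <- function(mesh) {
  e <- edge_table(mesh)
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad) == 0L)
    return(matrix(integer(), 0L, 2L))
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent orientation).
#'
#' @param mesh a `triangle_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  e <- edge_table(mesh)
  # directed edges must be unique and each must have its exact reverse
  dkey <- paste(e[, 1L], e[, 2L])
  if (anyDuplicated(dkey)) return(FALSE)
  rkey <- paste(e[, 2L], e[, 1L])
  all(rkey %in% dkey)
}

#' Flip mesh to outward orientation
#'
#' Ensures positive signed volume by reversing all faces if needed.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @return the mesh, outward-oriented.
#' @export
orient_outward <- function(mesh) {
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Merge exactly coincident vertices
#'
#' Collapses vertices with identical coordinates (as produced by STL files,
#' which store one coordinate triple per triangle corner) and reindexes
#' faces.
#'
#' @param mesh a `triangle_mesh`.
#' @return a `triangle_mesh` with shared vertices.
#' @export
merge_vertices <- function(mesh) {
  key <- paste(mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L])
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- mesh$vertices[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3L)
  triangle_mesh(newv, newf)
}

#' Connected components of a mesh
#'
#' Splits a mesh into its vertex-connected face components.
#'
#' @param mesh a `triangle_mesh`.
#' @return list of `triangle_mesh`, largest (by face count) first.
#' @export
mesh_components <- function(mesh) {
  g <- igraph::graph_from_edgelist(edge_table(mesh), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  fcomp <- comp[mesh$faces[, 1L]]
  out <- lapply(sort(unique(fcomp)), function(cc) {
    f <- mesh$faces[fcomp == cc, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    triangle_mesh(mesh$vertices[used, , drop = FALSE],
                  matrix(match(f, used), ncol = 3L), validate = FALSE)
  })
  out[order(vapply(out, function(m) nrow(m$faces), 1L), decreasing = TRUE)]
}

# --- STL IO -----------------------------------------------------------------

#' Write a mesh as binary STL
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%-80s", "condylometry binary STL")), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  v <- mesh$vertices; f <- mesh$faces
  cr <- triangle_cross(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), 1e-30)
  # facet record: 12 little-endian floats + 2 attribute bytes
  rec <- cbind(nrm, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
               v[f[, 3L], , drop = FALSE])
  fraw <- writeBin(as.numeric(t(rec)), raw(), size = 4L,
                   endian = "little")
  dim(fraw) <- c(48L, nf)
  out <- rbind(fraw, matrix(as.raw(0L), 2L, nf))
  writeBin(as.vector(out), con)
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Coincident corners are merged so the result is indexed and, for closed
#' surfaces, watertight.
#'
#' @param path STL file path.
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 6L)
  if (identical(rawToChar(head[1:5]), "solid") &&
      is_ascii_stl(path)) return(read_stl_ascii(path))
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  body <- readBin(con, "raw", n = nf * 50L)
  dim(body) <- c(50L, nf)
  vals <- readBin(as.vector(body[1:48, , drop = FALSE]), "numeric",
                  n = nf * 12L, size = 4L, endian = "little")
  rec <- matrix(vals, ncol = 12L, byrow = TRUE)
  verts <- matrix(0, nf * 3L, 3L)
  verts[seq(1L, by = 3L, length.out = nf), ] <- rec[, 4:6, drop = FALSE]
  verts[seq(2L, by = 3L, length.out = nf), ] <- rec[, 7:9, drop = FALSE]
  verts[seq(3L, by = 3L, length.out = nf), ] <- rec[, 10:12, drop = FALSE]
  faces <- matrix(seq_len(nf * 3L), ncol = 3L, byrow = TRUE)
  merge_vertices(triangle_mesh(verts, faces, validate = FALSE))
}

is_ascii_stl <- function(path) {
  # a binary STL whose header starts with "solid" is legal; check facet count
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- suppressWarnings(
    readBin(con, "integer", n = 1L, size = 4L, endian = "little"))
  !(length(nf) == 1L && !is.na(nf) && sz == 84 + 50 * as.numeric(nf))
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3L, byrow = TRUE)
  merge_vertices(triangle_mesh(nums, faces, validate = FALSE))
}
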