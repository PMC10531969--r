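#' Triangulated surface mesh
#'
#' Construct a triangle mesh from vertex coordinates (mm) and triangle
#' indices. On construction the mesh is cleaned: vertices closer than
#' `merge_tol` are merged and degenerate (zero-area or repeated-index)
#' triangles are dropped, so downstream geometry is deterministic.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param clean merge duplicate vertices and drop degenerate triangles
#'   (default `TRUE`).
#' @param merge_tol vertex merge tolerance in mm (default `1e-6`).
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `triangles`.
#' @export
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1, 2, 3)))
#' mesh_area(m)
surface_mesh <- function(vertices, triangles, clean = TRUE, merge_tol = 1e-6) {
  v <- matrix(as.numeric(vertices), ncol = 3)
  f <- matrix(as.integer(triangles), ncol = 3)
  if (!all(is.finite(v))) stop("non-finite vertex coordinates")
  if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
    stop("triangle indices out of range")
  if (clean) {
    key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
                 round(v[, 3] / merge_tol))
    first <- !duplicated(key)
    map <- match(key, key[first])
    v <- v[first, , drop = FALSE]
    f <- matrix(map[f], ncol = 3)
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
    if (nrow(f) > 0) {
      keep <- triangle_areas_idx(v, f) > (10 * merge_tol)^2
      f <- f[keep, , drop = FALSE]
    }
  }
  structure(list(vertices = v, triangles = f), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles, area",
      sprintf("%.1f", mesh_area(x)), "mm^2\n")
  invisible(x)
}

#' @noRd
triangle_areas_idx <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Triangle areas of a mesh
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of per-triangle areas (mm^2).
#' @export
mesh_triangle_areas <- function(mesh) triangle_areas_idx(mesh$vertices, mesh$triangles)

#' Total surface area of a mesh
#' @param mesh A [surface_mesh()].
#' @return Total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh_triangle_areas(mesh))

#' Per-face unit normals
#' @param mesh A [surface_mesh()].
#' @return m x 3 matrix of unit face normals.
#' @export
mesh_face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Per-vertex unit normals (area-weighted average of incident face normals)
#' @param mesh A [surface_mesh()].
#' @return n x 3 matrix of unit vertex normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # length = 2*area
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1] <- n[, 1] + unname(tapply2(fn[, 1], idx, nrow(v)))
    n[, 2] <- n[, 2] + unname(tapply2(fn[, 2], idx, nrow(v)))
    n[, 3] <- n[, 3] + unname(tapply2(fn[, 3], idx, nrow(v)))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# fast grouped sum into a fixed-length vector
#' @noRd
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Boundary edges of a mesh
#'
#' Edges incident to exactly one triangle.
#'
#' @param mesh A [surface_mesh()].
#' @return k x 2 integer matrix of vertex index pairs (each row sorted).
#' @export
mesh_boundary_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  b <- names(cnt)[cnt == 1]
  out <- e[!duplicated(key) & key %in% b, , drop = FALSE]
  out
}

#' Check that a mesh is edge-manifold
#'
#' Every edge belongs to at most two triangles (boundary edges allowed).
#'
#' @param mesh A [surface_mesh()].
#' @return `TRUE` if edge-manifold.
#' @export
mesh_is_edge_manifold <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) <= 2)
}

#' Transform a mesh by a rigid motion
#' @param mesh A [surface_mesh()].
#' @param rt A [rigid_transform()].
#' @return The transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, rt) {
  mesh$vertices <- rt_apply(rt, mesh$vertices)
  mesh
}

#' Merge meshes into one composite surface
#'
#' Concatenates vertex and triangle lists; coincident vertices are merged by
#' the construction-time cleaning.
#'
#' @param meshes list of [surface_mesh()] objects.
#' @return A single [surface_mesh()].
#' @export
merge_meshes <- function(meshes) {
  off <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$triangles + off
    off <- off + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Restrict a mesh to a vertex subset
#'
#' Keeps triangles whose three vertices all belong to `vertex_ids`.
#'
#' @param mesh A [surface_mesh()].
#' @param vertex_ids integer vertex indices to keep.
#' @return List with `mesh` (the submesh, uncleaned so indices are stable)
#'   and `orig_ids` mapping submesh vertex i to the original index.
#' @export
submesh <- function(mesh, vertex_ids) {
  keep <- sort(unique(as.integer(vertex_ids)))
  sel <- logical(nrow(mesh$vertices))
  sel[keep] <- TRUE
  fkeep <- sel[mesh$triangles[, 1]] & sel[mesh$triangles[, 2]] & sel[mesh$triangles[, 3]]
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  f <- matrix(map[mesh$triangles[fkeep, , drop = FALSE]], ncol = 3)
  sm <- structure(list(vertices = mesh$vertices[keep, , drop = FALSE],
                       triangles = f), class = "surface_mesh")
  list(mesh = sm, orig_ids = keep)
}

# Connected components of a vertex subset under mesh edge adjacency.
# Returns component label per selected vertex (names = vertex id).
#' @noRd
vertex_components <- function(mesh, vertex_ids) {
  ids <- sort(unique(as.integer(vertex_ids)))
  pos <- integer(nrow(mesh$vertices)); pos[ids] <- seq_along(ids)
  sel <- pos > 0
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- e[sel[e[, 1]] & sel[e[, 2]], , drop = FALSE]
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(e) > 0) {
    a <- pos[e[, 1]]; b <- pos[e[, 2]]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  names(comp) <- ids
  comp
}
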