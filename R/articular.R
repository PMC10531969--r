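#' Delineate the articular surface of a fragment
#'
#' Two methods are supported. `"annotation"` uses the fragment's stored
#' per-vertex articular mask verbatim (the primary, operator-derived path).
#' `"heuristic"` selects vertices with a proximally facing incident face
#' (face normal within `theta_deg` of the proximal axis) *and* a height
#' along the proximal axis above the fragment's `height_q` height quantile,
#' then keeps the largest connected component.
#'
#' @param frag A [fragment()].
#' @param frame A [plateau_frame()].
#' @param method `"annotation"` or `"heuristic"`.
#' @param theta_deg normal-angle threshold in degrees (default 45).
#' @param height_q height-quantile cutoff: keep vertices whose proximal
#'   height lies above the `height_q` quantile of the fragment (default
#'   0.25, i.e. the lowest quarter — the shaft side — is excluded).
#' @return An object of class `articular_patch` with the selected vertex
#'   ids, the restricted submesh, chained boundary loops and boundary edges
#'   (as original-mesh vertex index pairs).
#' @export
delineate_articular_patch <- function(frag, frame,
                                      method = c("annotation", "heuristic"),
                                      theta_deg = 45, height_q = 0.25) {
  method <- match.arg(method)
  mesh <- frag$mesh
  if (method == "annotation") {
    if (is.null(frag$articular_mask))
      stop("fragment '", frag$id, "' has no articular annotation")
    sel <- which(frag$articular_mask)
  } else {
    fn <- mesh_face_normals(mesh)
    fup <- as.numeric(fn %*% frame$proximal)
    # a vertex faces proximally if its most proximal incident face does
    up <- rep(-1, nrow(mesh$vertices))
    for (k in 1:3) {
      idx <- mesh$triangles[, k]
      agg <- tapply(fup, idx, max)
      vi <- as.integer(names(agg))
      up[vi] <- pmax(up[vi], as.numeric(agg))
    }
    h <- as.numeric(mesh$vertices %*% frame$proximal)
    cand <- which(up >= cos(theta_deg * pi / 180) &
                    h >= quantile(h, height_q))
    if (length(cand) == 0)
      stop("empty articular patch for fragment '", frag$id, "'")
    comp <- vertex_components(mesh, cand)
    big <- names(which.max(table(comp)))
    sel <- as.integer(names(comp)[comp == as.integer(big)])
  }
  if (length(sel) == 0)
    stop("empty articular patch for fragment '", frag$id, "'")
  sm <- submesh(mesh, sel)
  be_local <- mesh_boundary_edges(sm$mesh)
  be <- cbind(sm$orig_ids[be_local[, 1]], sm$orig_ids[be_local[, 2]])
  loops <- chain_edge_loops(be)
  structure(list(fragment_id = frag$id, vertex_ids = sel, submesh = sm$mesh,
                 orig_ids = sm$orig_ids, boundary_edges = be,
                 boundary_loops = loops, edge_labels = NULL,
                 fracture_lines = NULL, mesh = mesh),
            class = "articular_patch")
}

#' @export
print.articular_patch <- function(x, ...) {
  cat("<articular_patch> fragment", x$fragment_id, ":",
      length(x$vertex_ids), "vertices,", nrow(x$boundary_edges),
      "boundary edges")
  if (!is.null(x$edge_labels))
    cat(" (", sum(x$edge_labels == "fracture"), "fracture /",
        sum(x$edge_labels == "rim"), "rim )")
  cat("\n")
  invisible(x)
}

# Chain undirected edges (vertex id pairs) into loops / open paths.
# Returns list of integer vertex sequences (closed loops repeat no vertex;
# attribute "closed" marks cycles).
#' @noRd
chain_edge_loops <- function(edges) {
  if (nrow(edges) == 0) return(list())
  verts <- sort(unique(as.integer(edges)))
  adj <- vector("list", length(verts))
  eidx <- vector("list", length(verts))
  for (i in seq_len(nrow(edges))) {
    a <- match(edges[i, 1], verts); b <- match(edges[i, 2], verts)
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    eidx[[a]] <- c(eidx[[a]], i); eidx[[b]] <- c(eidx[[b]], i)
  }
  used <- logical(nrow(edges))
  deg <- lengths(adj)
  out <- list()
  walk <- function(start) {
    path <- start
    repeat {
      cur <- path[length(path)]
      nxt_i <- which(!used[eidx[[cur]]])[1]
      if (is.na(nxt_i)) break
      e <- eidx[[cur]][nxt_i]
      used[e] <<- TRUE
      ends <- c(match(edges[e, 1], verts), match(edges[e, 2], verts))
      nb <- ends[ends != cur][1]
      if (is.na(nb)) nb <- cur   # degenerate self-loop
      path <- c(path, nb)
      if (nb == start) break
    }
    path
  }
  for (s in order(deg)) {       # start at open ends first
    if (all(used[eidx[[s]]])) next
    p <- walk(s)
    closed <- length(p) > 2 && p[1] == p[length(p)]
    if (closed) p <- p[-length(p)]
    out[[length(out) + 1]] <- structure(verts[p], closed = closed)
  }
  out
}

#' Outer footprint boundary of projected points (alpha shape)
#'
#' Computes the alpha shape of a 2D point set via the Delaunay
#' triangulation (triangles with circumradius below `alpha` form the alpha
#' complex; its once-used edges are the boundary) and returns the outer
#' closed boundary polygon. Falls back to the convex hull with a warning if
#' no single closed outer boundary emerges.
#'
#' @param pts2d n x 2 matrix of points (mm).
#' @param alpha alpha radius in mm (default 15).
#' @param grid snap spacing in mm used to thin the point set before
#'   triangulation (default 0.3).
#' @return k x 2 matrix of boundary polygon vertices in order (closed
#'   implicitly: last connects to first).
#' @export
footprint_boundary <- function(pts2d, alpha = 15, grid = 0.3) {
  p <- unique(round(pts2d / grid)) * grid
  if (nrow(p) < 3) stop("footprint needs at least 3 distinct points")
  boundary <- tryCatch({
    dd <- deldir::deldir(p[, 1], p[, 2], suppressMsge = TRUE)
    tl <- deldir::triang.list(dd)
    tri <- do.call(rbind, lapply(tl, function(t) t$ptNum))
    keep <- vapply(seq_len(nrow(tri)), function(i) {
      a <- p[tri[i, 1], ]; b <- p[tri[i, 2], ]; cc <- p[tri[i, 3], ]
      la <- sqrt(sum((b - cc)^2)); lb <- sqrt(sum((a - cc)^2))
      lc <- sqrt(sum((a - b)^2))
      K <- abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
      if (K < 1e-12) return(FALSE)
      (la * lb * lc) / (4 * K) <= alpha
    }, logical(1))
    tri <- tri[keep, , drop = FALSE]
    if (nrow(tri) == 0) stop("empty alpha complex")
    e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    once <- names(which(table(key) == 1))
    be <- e[!duplicated(key) & key %in% once, , drop = FALSE]
    loops <- chain_edge_loops(be)
    loops <- Filter(function(l) isTRUE(attr(l, "closed")) && length(l) >= 3, loops)
    if (length(loops) == 0) stop("no closed alpha boundary")
    areas <- vapply(loops, function(l) {
      q <- p[l, , drop = FALSE]
      abs(sum(q[, 1] * q[c(2:nrow(q), 1), 2] - q[c(2:nrow(q), 1), 1] * q[, 2])) / 2
    }, numeric(1))
    p[loops[[which.max(areas)]], , drop = FALSE]
  }, error = function(e) NULL)
  if (is.null(boundary)) {
    warning("alpha shape failed to produce a single outer boundary; ",
            "falling back to convex hull")
    boundary <- p[chull(p), , drop = FALSE]
  }
  boundary
}

# Distance from points to a closed 2D polygon boundary, plus the unit
# tangent of the nearest boundary segment.
#' @noRd
polyline_distance <- function(pts, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  n <- nrow(pts)
  best <- rep(Inf, n)
  tx <- numeric(n); ty <- numeric(n)
  for (s in seq_len(nrow(a))) {
    dx <- b[s, 1] - a[s, 1]; dy <- b[s, 2] - a[s, 2]
    L2 <- dx * dx + dy * dy
    if (L2 == 0) next
    t <- ((pts[, 1] - a[s, 1]) * dx + (pts[, 2] - a[s, 2]) * dy) / L2
    t <- pmin(1, pmax(0, t))
    qx <- a[s, 1] + t * dx; qy <- a[s, 2] + t * dy
    d <- sqrt((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2)
    upd <- d < best
    best[upd] <- d[upd]
    L <- sqrt(L2)
    tx[upd] <- dx / L; ty[upd] <- dy / L
  }
  list(dist = best, tangent = cbind(tx, ty))
}

#' Label patch boundary edges as rim or fracture
#'
#' Projects all patch vertices into the plateau plane, computes the outer
#' footprint boundary as an alpha shape, and labels each patch boundary
#' edge: *rim* if its projected midpoint lies within `delta` of the
#' footprint boundary and the edge runs within 45 degrees of the local
#' boundary tangent; *fracture* otherwise. Fracture edges are then chained
#' into per-fragment fracture-line polylines, split at sharp turns
#' (> `split_angle_deg`) so that junction corners separate corridors.
#'
#' @param case A [fracture_case()].
#' @param patches list of [delineate_articular_patch()] results, one per
#'   fragment, in case fragment order.
#' @param delta rim band width in mm (default 2).
#' @param alpha alpha-shape radius in mm (default 15).
#' @param split_angle_deg turn angle above which fracture polylines are
#'   split (default 45).
#' @return The patch list with `edge_labels` and `fracture_lines` filled in.
#' @export
classify_patch_boundary <- function(case, patches, delta = 2, alpha = 15,
                                    split_angle_deg = 45) {
  frame <- case$frame %||% compute_plateau_frame(case)
  all2d <- do.call(rbind, lapply(patches, function(p)
    project_to_plane(p$submesh$vertices, frame)))
  fp <- footprint_boundary(all2d, alpha = alpha)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (nrow(p$boundary_edges) == 0) {
      patches[[i]]$edge_labels <- character(0)
      patches[[i]]$fracture_lines <- list()
      next
    }
    v <- p$mesh$vertices
    mid3 <- (v[p$boundary_edges[, 1], , drop = FALSE] +
               v[p$boundary_edges[, 2], , drop = FALSE]) / 2
    mid2 <- project_to_plane(mid3, frame)
    e2 <- project_to_plane(v[p$boundary_edges[, 2], , drop = FALSE], frame) -
      project_to_plane(v[p$boundary_edges[, 1], , drop = FALSE], frame)
    elen <- sqrt(rowSums(e2^2))
    elen[elen == 0] <- 1
    e2 <- e2 / elen
    pd <- polyline_distance(mid2, fp)
    along <- abs(e2[, 1] * pd$tangent[, 1] + e2[, 2] * pd$tangent[, 2])
    rim <- pd$dist <= delta & along >= cos(45 * pi / 180)
    labels <- ifelse(rim, "rim", "fracture")
    fe <- p$boundary_edges[labels == "fracture", , drop = FALSE]
    ext <- extract_fracture_lines(p$fragment_id, v, fe, split_angle_deg)
    # rim-corner stubs split off a real fracture chain are rim after all
    if (nrow(ext$stub_edges) > 0) {
      key <- paste(pmin(p$boundary_edges[, 1], p$boundary_edges[, 2]),
                   pmax(p$boundary_edges[, 1], p$boundary_edges[, 2]))
      skey <- paste(pmin(ext$stub_edges[, 1], ext$stub_edges[, 2]),
                    pmax(ext$stub_edges[, 1], ext$stub_edges[, 2]))
      labels[key %in% skey] <- "rim"
    }
    patches[[i]]$edge_labels <- labels
    patches[[i]]$fracture_lines <- ext$lines
  }
  patches
}

# Chain fracture edges into polylines, split at sharp turns, and separate
# rim-corner stubs: where the footprint notch at a gap opening pulls a few
# rim edges past the rim band, they appear as a short (< stub_mm) piece
# hanging off a much longer fracture chain at a sharp corner. Such pieces
# are returned as stub edges, not fracture lines.
#' @noRd
extract_fracture_lines <- function(fragment_id, vertices, edges,
                                   split_angle_deg = 45, stub_mm = 5) {
  if (nrow(edges) == 0)
    return(list(lines = list(), stub_edges = matrix(integer(0), 0, 2)))
  chains <- chain_edge_loops(edges)
  lines <- list()
  stubs <- list()
  for (ch in chains) {
    ids <- ch
    if (isTRUE(attr(ch, "closed"))) ids <- c(ids, ids[1])
    segs <- split_at_turns_idx(ids, vertices, split_angle_deg)
    lens <- vapply(segs, function(s)
      sum(sqrt(rowSums(diff(vertices[s, , drop = FALSE])^2))), numeric(1))
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (length(s) < 2) next
      is_stub <- length(segs) > 1 && lens[k] < stub_mm &&
        lens[k] < 0.5 * max(lens)
      if (is_stub) {
        stubs[[length(stubs) + 1]] <- cbind(s[-length(s)], s[-1])
      } else {
        lines[[length(lines) + 1]] <-
          fracture_line(fragment_id, vertices[s, , drop = FALSE])
      }
    }
  }
  list(lines = lines,
       stub_edges = if (length(stubs)) do.call(rbind, stubs)
       else matrix(integer(0), 0, 2))
}

# split a vertex-id path at sharp turns, returning id subsequences
#' @noRd
split_at_turns_idx <- function(ids, vertices, split_angle_deg) {
  n <- length(ids)
  if (n < 3) return(list(ids))
  pts <- vertices[ids, , drop = FALSE]
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- 1
  u <- d / len
  cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  brk <- which(cosang < cos(split_angle_deg * pi / 180)) + 1L
  cuts <- c(1L, brk, n)
  lapply(seq_len(length(cuts) - 1L), function(k) ids[cuts[k]:cuts[k + 1L]])
}

#' Fracture line
#'
#' An ordered 3D polyline along the fractured portion of an articular patch
#' boundary.
#'
#' @param fragment_id label of the fragment the line belongs to.
#' @param points k x 3 matrix of ordered points (mm), k >= 2, consecutive
#'   points distinct.
#' @return An object of class `fracture_line`.
#' @export
fracture_line <- function(fragment_id, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  if (nrow(p) >= 2) {
    keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                               p[-nrow(p), , drop = FALSE])^2) > 1e-18)
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) < 2) stop("a fracture line needs at least 2 distinct points")
  structure(list(fragment_id = as.character(fragment_id), points = p),
            class = "fracture_line")
}

#' Collect fracture lines from classified patches
#' @param patches output of [classify_patch_boundary()].
#' @return Flat list of [fracture_line()] objects.
#' @export
case_fracture_lines <- function(patches) {
  do.call(c, lapply(patches, function(p) p$fracture_lines %||% list()))
}
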