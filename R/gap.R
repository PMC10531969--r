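#' Gap loop
#'
#' A closed 3D polyline formed by stitching fracture lines from one or more
#' fragments; the boundary of one corridor of the gap surface.
#'
#' @param points k x 3 matrix of ordered points (mm), treated as cyclic.
#' @return An object of class `gap_loop`.
#' @export
gap_loop <- function(points) {
  p <- matrix(as.numeric(points), ncol = 3)
  if (nrow(p) >= 2 && sum((p[1, ] - p[nrow(p), ])^2) < 1e-18)
    p <- p[-nrow(p), , drop = FALSE]
  keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2) > 1e-18)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 3) stop("a gap loop needs at least 3 distinct points")
  structure(list(points = p), class = "gap_loop")
}

#' Stitch fracture lines into closed gap loops
#'
#' Endpoints of fracture lines from *different* fragments are paired
#' greedily. A pair is admissible when its distance does not exceed
#' `max(join_tol, 2 x local join scale)`, the local join scale being the
#' distance to the nearest cross-fragment endpoint — so the admissible
#' radius scales with the local gap width. Greedy order is by
#' endpoint distance plus half the symmetric chamfer distance between the
#' two chains, which makes chains running along the same fracture corridor
#' pair up at multi-fragment junctions. Matched chains and their joining
#' segments form closed loops; chains left with open ends are closed onto
#' themselves with a warning (and discarded when the folded loop spans
#' under 1 mm^2).
#'
#' @param fracture_lines list of [fracture_line()] objects.
#' @param join_tol base join tolerance in mm (default 1).
#' @return List of [gap_loop()] objects (empty when no loop can be formed).
#' @export
stitch_gap_loops <- function(fracture_lines, join_tol = 1.0) {
  lines <- fracture_lines
  if (length(lines) == 0) return(list())
  frag <- vapply(lines, `[[`, character(1), "fragment_id")
  nch <- length(lines)
  ends <- do.call(rbind, lapply(lines, function(l)
    rbind(l$points[1, ], l$points[nrow(l$points), ])))
  end_chain <- rep(seq_len(nch), each = 2)
  end_port <- rep(c(1L, 2L), nch)
  # local join scale: distance to the nearest other-fragment endpoint
  np <- 2L * nch
  epd <- matrix(Inf, np, np)
  for (i in seq_len(np - 1)) {
    for (j in seq((i + 1), np)) {
      if (frag[end_chain[i]] == frag[end_chain[j]]) next
      epd[i, j] <- epd[j, i] <- sqrt(sum((ends[i, ] - ends[j, ])^2))
    }
  }
  d_ep <- apply(epd, 1, min)
  # chamfer distance between chain pairs (subsampled), cached
  cham <- matrix(NA_real_, nch, nch)
  chain_pts <- lapply(lines, function(l) {
    p <- l$points
    if (nrow(p) > 100) p <- p[round(seq(1, nrow(p), length.out = 100)), , drop = FALSE]
    p
  })
  chamfer <- function(a, b) {
    if (!is.na(cham[a, b])) return(cham[a, b])
    pa <- chain_pts[[a]]; pb <- chain_pts[[b]]
    d1 <- RANN::nn2(pb, pa, k = 1)$nn.dists
    d2 <- RANN::nn2(pa, pb, k = 1)$nn.dists
    v <- (mean(d1) + mean(d2)) / 2
    cham[a, b] <<- v; cham[b, a] <<- v
    v
  }
  # admissible candidate pairs: within twice the local join scale
  cand <- NULL
  for (i in seq_len(np - 1)) {
    for (j in seq((i + 1), np)) {
      if (!is.finite(epd[i, j])) next
      d <- epd[i, j]
      if (d <= max(join_tol, 2 * min(d_ep[i], d_ep[j])))
        cand <- rbind(cand, c(i, j, d, d + 0.5 * chamfer(end_chain[i], end_chain[j])))
    }
  }
  match_of <- integer(2 * nch)
  if (!is.null(cand)) {
    ord <- order(cand[, 4], end_chain[cand[, 1]], end_chain[cand[, 2]],
                 cand[, 1], cand[, 2])
    for (r in ord) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (match_of[i] == 0 && match_of[j] == 0) {
        match_of[i] <- j; match_of[j] <- i
      }
    }
  }
  if (all(match_of == 0)) {
    warning("no gap loop could be formed from the fracture lines")
    return(list())
  }
  # traverse chains + joins into loops; self-close open paths
  chain_pts_oriented <- function(ch, flip) {
    p <- lines[[ch]]$points
    if (flip) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
  }
  visited <- logical(nch)
  loops <- list()
  for (c0 in seq_len(nch)) {
    if (visited[c0]) next
    visited[c0] <- TRUE
    ordered <- list(list(chain = c0, flip = FALSE))
    closed <- FALSE
    # forward: follow the match at the oriented end of the current chain
    cur_exit <- 2L * c0
    repeat {
      m <- match_of[cur_exit]
      if (m == 0L) break
      nc <- end_chain[m]
      if (nc == c0) { closed <- TRUE; break }
      if (visited[nc]) break
      flip <- end_port[m] == 2L        # entered at its far end -> reverse
      ordered[[length(ordered) + 1]] <- list(chain = nc, flip = flip)
      visited[nc] <- TRUE
      cur_exit <- if (flip) 2L * nc - 1L else 2L * nc
    }
    if (!closed) {
      # backward: extend before the start chain from its entry port
      cur_entry <- 2L * c0 - 1L
      repeat {
        m <- match_of[cur_entry]
        if (m == 0L) break
        nc <- end_chain[m]
        if (visited[nc]) break
        flip <- end_port[m] == 1L      # its matched end must come last
        ordered <- c(list(list(chain = nc, flip = flip)), ordered)
        visited[nc] <- TRUE
        cur_entry <- if (flip) 2L * nc else 2L * nc - 1L
      }
    }
    pts <- do.call(rbind, lapply(ordered, function(o)
      chain_pts_oriented(o$chain, o$flip)))
    lp <- tryCatch(gap_loop(pts), error = function(e) NULL)
    if (is.null(lp)) next
    if (!closed) {
      # an unmatched chain folded back on itself spans (almost) no surface;
      # keep it only if it encloses measurable area
      if (.min_area_triangulation(lp$points)$area < 1) next
      warning("open gap chain closed onto itself")
    }
    loops[[length(loops) + 1]] <- lp
  }
  loops
}

#' Triangulate gap loops into a gap surface
#'
#' Each loop is triangulated with the minimal-total-area triangulation over
#' its own vertices (dynamic programming over chords); triangle areas are
#' summed in 3D. Collinear (zero-area) loops yield zero area without error.
#'
#' @param loops list of [gap_loop()] objects.
#' @return An object of class `gap_surface` with elements `mesh` (triangle
#'   soup as a [surface_mesh()]), `area_mm2` and `loop_areas`.
#' @export
triangulate_gap <- function(loops) {
  loop_areas <- numeric(length(loops))
  vs <- list(); fs <- list(); off <- 0L
  for (k in seq_along(loops)) {
    p <- loops[[k]]$points
    res <- .min_area_triangulation(p)
    loop_areas[k] <- res$area
    if (nrow(res$triangles) > 0) {
      vs[[length(vs) + 1]] <- p
      fs[[length(fs) + 1]] <- res$triangles + off
      off <- off + nrow(p)
    }
  }
  mesh <- if (length(vs) > 0)
    structure(list(vertices = do.call(rbind, vs),
                   triangles = do.call(rbind, fs)), class = "surface_mesh")
  else surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  structure(list(mesh = mesh, area_mm2 = sum(loop_areas),
                 loop_areas = loop_areas), class = "gap_surface")
}

#' @export
print.gap_surface <- function(x, ...) {
  cat("<gap_surface> area", sprintf("%.1f", x$area_mm2), "mm^2 over",
      length(x$loop_areas), "loop(s)\n")
  invisible(x)
}

#' Quantify the 3D gap area of a fracture case
#'
#' Full measurement pipeline: plateau frame, articular delineation per
#' fragment, rim/fracture boundary classification, fracture-line stitching,
#' and gap-surface triangulation. Deterministic for fixed inputs and
#' parameters.
#'
#' @param case A [fracture_case()].
#' @param method articular delineation method, `"annotation"` (default) or
#'   `"heuristic"`.
#' @param theta_deg,height_q heuristic delineation parameters, see
#'   [delineate_articular_patch()].
#' @param delta rim band width in mm (default 2).
#' @param alpha alpha-shape radius in mm (default 15).
#' @param join_tol stitching tolerance in mm (default 1).
#' @return An object of class `gap_quantification`: list with `area_mm2`,
#'   `loop_areas`, `group`, `surface`, `fracture_lines`, `patches` and a
#'   `params` provenance block.
#' @export
#' @examples
#' sc <- fracture_scenario(cut_angles = c(0, 180),
#'                         displacements = list(list(translation = c(0, -5, 0)),
#'                                              list(translation = c(0, 0, 0))))
#' syn <- fracture_and_displace(sc)
#' q <- quantify_gap(syn$case)
#' q$area_mm2   # close to the 2*R*w = 300 mm^2 oracle
quantify_gap <- function(case, method = c("annotation", "heuristic"),
                         theta_deg = 45, height_q = 0.25, delta = 2,
                         alpha = 15, join_tol = 1.0) {
  method <- match.arg(method)
  frame <- case$frame %||% compute_plateau_frame(case)
  case$frame <- frame
  patches <- lapply(case$fragments, delineate_articular_patch, frame = frame,
                    method = method, theta_deg = theta_deg,
                    height_q = height_q)
  patches <- classify_patch_boundary(case, patches, delta = delta, alpha = alpha)
  lines <- case_fracture_lines(patches)
  loops <- if (length(lines) == 0) list() else
    stitch_gap_loops(lines, join_tol = join_tol)
  surf <- triangulate_gap(loops)
  structure(list(area_mm2 = surf$area_mm2, loop_areas = surf$loop_areas,
                 group = assign_prognostic_group(surf$area_mm2),
                 surface = surf, fracture_lines = lines, patches = patches,
                 params = list(method = method, theta_deg = theta_deg,
                               height_q = height_q, delta = delta,
                               alpha = alpha, join_tol = join_tol)),
            class = "gap_quantification")
}

#' @export
print.gap_quantification <- function(x, ...) {
  cat("<gap_quantification> 3D gap area", sprintf("%.1f", x$area_mm2),
      "mm^2 (", as.character(x$group), "),",
      length(x$loop_areas), "loop(s)\n")
  invisible(x)
}

#' @rdname quantify_gap
#' @param ... passed on to `quantify_gap()`.
#' @return `gap_area()` returns the total 3D gap area in mm^2 as a scalar.
#' @export
gap_area <- function(case, ...) quantify_gap(case, ...)$area_mm2

#' Assign prognostic groups by 3D gap area
#'
#' Gap-area strata associated with expected functional outcome:
#' excellent \[0, 150\], good (150, 550\], moderate (550, 1000\], poor
#' (1000, Inf) mm^2. Upper-inclusive intervals partition the non-negative
#' reals, consistent with the integer-labeled published bins
#' (0-150, 151-550, 551-1000, >1000).
#'
#' @param area_mm2 numeric vector of gap areas (mm^2), non-negative.
#' @return Factor with levels excellent, good, moderate, poor.
#' @export
#' @examples
#' assign_prognostic_group(c(100, 1000, 1000.01))
assign_prognostic_group <- function(area_mm2) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 < 0))
    stop("gap area must be finite and non-negative")
  cut(area_mm2, breaks = c(0, 150, 550, 1000, Inf),
      labels = c("excellent", "good", "moderate", "poor"),
      include.lowest = TRUE, right = TRUE)
}

#' Prognostic group interval bounds
#' @return data.frame of group labels and interval bounds in mm^2.
#' @export
prognostic_group_bounds <- function() {
  data.frame(label = c("excellent", "good", "moderate", "poor"),
             lower = c(0, 150, 550, 1000),
             upper = c(150, 550, 1000, Inf),
             lower_inclusive = c(TRUE, FALSE, FALSE, FALSE),
             upper_inclusive = c(TRUE, TRUE, TRUE, FALSE))
}
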