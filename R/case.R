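AO_OTA_CODES <- c("41-B1", "41-B2", "41-B3", "41-C1", "41-C2", "41-C3")

#' Fracture fragment
#'
#' A labeled fragment surface mesh with an optional per-vertex articular
#' annotation.
#'
#' @param id fragment label.
#' @param mesh A [surface_mesh()].
#' @param articular_mask optional logical vector, one entry per vertex,
#'   `TRUE` where the vertex belongs to the articular surface.
#' @return An object of class `fragment`.
#' @export
fragment <- function(id, mesh, articular_mask = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.null(articular_mask)) {
    if (length(articular_mask) != nrow(mesh$vertices))
      stop("articular_mask length (", length(articular_mask),
           ") does not match vertex count (", nrow(mesh$vertices), ")")
    articular_mask <- as.logical(articular_mask)
  }
  structure(list(id = as.character(id), mesh = mesh,
                 articular_mask = articular_mask), class = "fragment")
}

#' Fracture case
#'
#' A patient's set of fragment meshes in one coordinate frame.
#'
#' @param case_id case identifier.
#' @param fragments list of [fragment()] objects (at least one).
#' @param side `"left"` or `"right"`.
#' @param ao_ota AO/OTA code (41-B1, 41-B2, 41-B3, 41-C1, 41-C2, 41-C3).
#' @param frame optional precomputed [plateau_frame()].
#' @return An object of class `fracture_case`.
#' @export
fracture_case <- function(case_id, fragments, side = c("left", "right"),
                          ao_ota = "41-B1", frame = NULL) {
  side <- match.arg(side)
  if (length(fragments) < 1) stop("a fracture case needs at least one fragment")
  if (!all(vapply(fragments, inherits, logical(1), "fragment")))
    stop("fragments must be a list of fragment objects")
  if (!ao_ota %in% AO_OTA_CODES)
    stop("ao_ota must be one of: ", paste(AO_OTA_CODES, collapse = ", "))
  names(fragments) <- vapply(fragments, `[[`, character(1), "id")
  structure(list(case_id = as.character(case_id), fragments = fragments,
                 side = side, ao_ota = ao_ota, frame = frame),
            class = "fracture_case")
}

#' @export
print.fracture_case <- function(x, ...) {
  cat("<fracture_case>", x$case_id, " (", x$ao_ota, ", ", x$side, "): ",
      length(x$fragments), " fragment(s)\n", sep = "")
  for (fr in x$fragments)
    cat("  ", fr$id, ": ", nrow(fr$mesh$vertices), " vertices",
        if (!is.null(fr$articular_mask))
          paste0(", ", sum(fr$articular_mask), " articular"), "\n", sep = "")
  invisible(x)
}

#' Plateau coordinate frame
#'
#' Right-handed orthonormal frame for the tibial plateau: `proximal` points
#' away from the shaft (normal to the plateau plane), `anterior` and
#' `medial` span the plateau plane. All 2D footprint projections use the
#' plane orthogonal to `proximal`.
#'
#' @param origin length-3 origin point (mm).
#' @param proximal,anterior,medial length-3 unit axes.
#' @return An object of class `plateau_frame`.
#' @export
plateau_frame <- function(origin, proximal, anterior, medial) {
  A <- cbind(proximal, anterior, medial)
  if (max(abs(crossprod(A) - diag(3))) > 1e-6)
    stop("frame axes must be orthonormal")
  if (det(A) < 0) stop("frame must be right-handed")
  structure(list(origin = as.numeric(origin), proximal = as.numeric(proximal),
                 anterior = as.numeric(anterior), medial = as.numeric(medial)),
            class = "plateau_frame")
}

#' @export
print.plateau_frame <- function(x, ...) {
  cat("<plateau_frame> proximal [",
      paste(sprintf("%.3f", x$proximal), collapse = ", "), "]\n")
  invisible(x)
}

# Articular-candidate vertices: union of articular masks when any fragment
# carries one, otherwise all vertices.
#' @noRd
candidate_vertices <- function(case) {
  has_mask <- vapply(case$fragments, function(fr) !is.null(fr$articular_mask),
                     logical(1))
  pts <- lapply(case$fragments, function(fr) {
    if (any(has_mask)) {
      if (is.null(fr$articular_mask)) return(NULL)
      fr$mesh$vertices[fr$articular_mask, , drop = FALSE]
    } else fr$mesh$vertices
  })
  do.call(rbind, pts)
}

#' Estimate the plateau frame of a case
#'
#' The proximal axis is the principal direction of smallest variance of the
#' articular-candidate vertices (articular-masked vertices when annotations
#' are present, all vertices otherwise), oriented so that the mean articular
#' vertex normal has positive dot product with it. The medial axis is the
#' in-plane direction of largest variance, its sign fixed so the third
#' central moment along it is non-negative (falling back to a fixed world
#' sign when the distribution is symmetric); the anterior axis completes a
#' right-handed frame.
#'
#' @param case A [fracture_case()].
#' @return A [plateau_frame()].
#' @export
compute_plateau_frame <- function(case) {
  pts <- candidate_vertices(case)
  if (is.null(pts) || nrow(pts) < 10)
    stop("degenerate geometry: fewer than 10 articular-candidate vertices")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  proximal <- ev$vectors[, 3]           # smallest variance
  # orient proximal along the mean candidate normal
  nsum <- c(0, 0, 0)
  has_mask <- vapply(case$fragments, function(fr) !is.null(fr$articular_mask),
                     logical(1))
  for (fr in case$fragments) {
    vn <- mesh_vertex_normals(fr$mesh)
    sel <- if (any(has_mask)) {
      if (is.null(fr$articular_mask)) rep(FALSE, nrow(vn)) else fr$articular_mask
    } else rep(TRUE, nrow(vn))
    if (any(sel)) nsum <- nsum + colSums(vn[sel, , drop = FALSE])
  }
  if (sum(nsum * proximal) < 0) proximal <- -proximal
  medial <- ev$vectors[, 1]             # largest variance (medial-lateral width)
  medial <- unit3(medial - sum(medial * proximal) * proximal)
  m3 <- mean((sweep(pts, 2, ctr) %*% medial)^3)
  scale3 <- mean(rowSums(sweep(pts, 2, ctr)^2))^1.5
  if (abs(m3) > 1e-6 * scale3) {
    if (m3 < 0) medial <- -medial
  } else {
    w <- c(1, 0, 0)
    if (abs(sum(medial * w)) < 1e-8) w <- c(0, 1, 0)
    if (sum(medial * w) < 0) medial <- -medial
  }
  anterior <- unit3(cross3(medial, proximal))
  medial <- cross3(proximal, anterior)
  plateau_frame(origin = ctr, proximal = proximal, anterior = anterior,
                medial = medial)
}

#' Apply a rigid motion to a whole case
#'
#' Transforms every fragment mesh (annotations ride along unchanged) and
#' drops any cached frame so it is recomputed in the new pose.
#'
#' @param case A [fracture_case()].
#' @param rt A [rigid_transform()].
#' @return The transformed [fracture_case()].
#' @export
transform_case <- function(case, rt) {
  case$fragments <- lapply(case$fragments, function(fr) {
    fr$mesh <- transform_mesh(fr$mesh, rt)
    fr
  })
  case$frame <- NULL
  case
}

# 2D footprint coordinates of points in the plateau plane
#' @noRd
project_to_plane <- function(points, frame) {
  p <- sweep(matrix(as.numeric(points), ncol = 3), 2, frame$origin)
  cbind(p %*% frame$anterior, p %*% frame$medial)
}
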