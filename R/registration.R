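# Deterministic vertex subsample: evenly spaced indices (seeded offset).
#' @noRd
sample_vertex_idx <- function(n, k, seed = 0L) {
  if (n <= k) return(seq_len(n))
  idx <- floor(seq(1 + (seed %% 7), n, length.out = k))
  unique(pmin(n, pmax(1, idx)))
}

#' Coarse alignment of a preoperative case to a postoperative model
#'
#' Aligns the centroid and principal axes of the largest preoperative
#' fragment (by surface area, the shaft-bearing fragment) to those of the
#' postoperative model. The axis sign ambiguity leaves four proper-rotation
#' candidates; each is refined by a short trimmed ICP and the candidate
#' minimizing the symmetric sampled surface distance of the *whole*
#' preoperative case is returned, so near-symmetric anatomy does not trap
#' the alignment in a flipped pose. The result is always a proper rotation.
#'
#' @param pre_case A [fracture_case()].
#' @param post_mesh A [surface_mesh()] (composite postoperative model).
#' @param n_sample points sampled per surface for scoring (default 500).
#' @return A [rigid_transform()] mapping preoperative to postoperative
#'   coordinates.
#' @export
coarse_align <- function(pre_case, post_mesh, n_sample = 500) {
  areas <- vapply(pre_case$fragments, function(fr) mesh_area(fr$mesh), numeric(1))
  src <- pre_case$fragments[[which.max(areas)]]$mesh
  eig_basis <- function(v) {
    e <- eigen(stats::cov(v), symmetric = TRUE)$vectors
    if (det(e) < 0) e[, 3] <- -e[, 3]
    e
  }
  cs <- colMeans(src$vertices); ct <- colMeans(post_mesh$vertices)
  Es <- eig_basis(src$vertices); Et <- eig_basis(post_mesh$vertices)
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  whole <- merge_meshes(lapply(pre_case$fragments, `[[`, "mesh"))
  ps <- whole$vertices[sample_vertex_idx(nrow(whole$vertices), n_sample), , drop = FALSE]
  pt <- post_mesh$vertices[sample_vertex_idx(nrow(post_mesh$vertices), n_sample), , drop = FALSE]
  best <- NULL; best_d <- Inf
  for (fl in flips) {
    R <- Et %*% diag(fl) %*% t(Es)
    rt <- rigid_transform(project_rotation(R), as.numeric(ct - R %*% cs))
    rt <- tryCatch(
      icp_point_to_plane(whole, post_mesh, init = rt, max_iter = 15,
                         tol = 1e-3, cutoff = 5, n_sample = 600)$transform,
      error = function(e) rt)
    q <- rt_apply(rt, ps)
    d <- mean(RANN::nn2(pt, q, k = 1)$nn.dists) +
      mean(RANN::nn2(q, pt, k = 1)$nn.dists)
    if (d < best_d) { best_d <- d; best <- rt }
  }
  best
}

#' Trimmed point-to-plane ICP registration
#'
#' Iterative closest point with a point-to-plane error metric:
#' correspondences are nearest postoperative vertices (with their vertex
#' normals); pairs beyond the distance cutoff or whose source and target
#' normals disagree by more than 60 degrees are discarded each iteration
#' (normal gating stops points on one side of a narrow fracture gap from
#' latching onto the opposing wall of a neighbouring fragment), and the
#' linearized rigid update solves a 6x6 system. The trimming radius starts
#' at `max(cutoff, 1.5 x median correspondence distance)` and tightens to
#' `cutoff` as the fit converges, so moderately displaced initializations
#' are not starved of correspondences. Deterministic: source points are an
#' evenly spaced vertex subsample (seeded offset).
#'
#' @param source_mesh,target_mesh [surface_mesh()] objects (mm).
#' @param init initial [rigid_transform()] (default identity).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the RMS change in mm (default 1e-4).
#' @param cutoff correspondence distance cutoff in mm (default 3).
#' @param n_sample number of source sample points (default 1500).
#' @param seed sampling seed (default 0).
#' @return List with `transform` (composed with `init`), `rms`
#'   (point-to-plane RMS, mm), `inlier_fraction` and `n_valid`.
#' @export
icp_point_to_plane <- function(source_mesh, target_mesh, init = rt_identity(),
                               max_iter = 100, tol = 1e-4, cutoff = 3,
                               n_sample = 1500, seed = 0L) {
  sidx <- sample_vertex_idx(nrow(source_mesh$vertices), n_sample, seed)
  p0 <- source_mesh$vertices[sidx, , drop = FALSE]
  n0 <- mesh_vertex_normals(source_mesh)[sidx, , drop = FALSE]
  tv <- target_mesh$vertices
  tn <- mesh_vertex_normals(target_mesh)
  rt <- init
  rms_prev <- Inf
  rms <- Inf
  for (it in seq_len(max_iter)) {
    p <- rt_apply(rt, p0)
    nn <- RANN::nn2(tv, p, k = 1)
    d <- as.numeric(nn$nn.dists)
    if (it == 1 && sum(d <= cutoff) < 50)
      stop("registration failure: fewer than 50 valid correspondences at initialization")
    cut_eff <- max(cutoff, 1.5 * median(d))
    ndot <- rowSums((n0 %*% t(rt$R)) * tn[nn$nn.idx, , drop = FALSE])
    valid <- d <= cut_eff & ndot >= cos(60 * pi / 180)
    if (sum(valid) < 10) valid <- d <= cut_eff
    q <- tv[nn$nn.idx[valid], , drop = FALSE]
    n <- tn[nn$nn.idx[valid], , drop = FALSE]
    pv <- p[valid, , drop = FALSE]
    e <- rowSums((pv - q) * n)
    rms <- sqrt(mean(e^2))
    if (abs(rms_prev - rms) < tol && cut_eff <= cutoff * 1.000001) break
    rms_prev <- rms
    cxn <- cbind(pv[, 2] * n[, 3] - pv[, 3] * n[, 2],
                 pv[, 3] * n[, 1] - pv[, 1] * n[, 3],
                 pv[, 1] * n[, 2] - pv[, 2] * n[, 1])
    A <- cbind(cxn, n)
    AtA <- crossprod(A)
    Atb <- crossprod(A, -e)
    x <- tryCatch(solve(AtA + 1e-12 * diag(6), Atb), error = function(err) NULL)
    if (is.null(x)) break
    w <- x[1:3]
    ang <- sqrt(sum(w^2))
    upd <- if (ang > 1e-15)
      rt_axis_angle(w / ang, ang * 180 / pi)
    else rt_identity()
    upd$t <- upd$t + x[4:6]
    rt <- rt_compose(upd, rt)
  }
  p <- rt_apply(rt, p0)
  d <- as.numeric(RANN::nn2(tv, p, k = 1)$nn.dists)
  list(transform = rt, rms = rms, inlier_fraction = mean(d <= cutoff),
       n_valid = sum(d <= cutoff))
}

#' Match preoperative fragments to the postoperative model
#'
#' Surface-based matching: a global coarse alignment (principal axes +
#' whole-model ICP) followed by per-fragment trimmed point-to-plane ICP of
#' each preoperative fragment against the composite postoperative surface.
#' Fragments with fewer than `min_vertices` vertices inherit the global
#' transform (small rim fragments register unstably) and are flagged, as
#' are fragments whose final inlier fraction falls below 0.5.
#'
#' @param pre_case A [fracture_case()].
#' @param post_mesh composite postoperative [surface_mesh()].
#' @param cutoff ICP correspondence cutoff in mm (default 3).
#' @param min_vertices minimum fragment size for independent ICP
#'   (default 200).
#' @param ... further arguments to [icp_point_to_plane()].
#' @return An object of class `match_result`: per-fragment `transforms`
#'   ([rigid_transform()]), `rms`, `inlier_fraction` and `flagged`.
#' @export
match_fragments <- function(pre_case, post_mesh, cutoff = 3,
                            min_vertices = 200, ...) {
  global0 <- coarse_align(pre_case, post_mesh)
  whole <- merge_meshes(lapply(pre_case$fragments, `[[`, "mesh"))
  gfit <- tryCatch(
    icp_point_to_plane(whole, post_mesh, init = global0, cutoff = cutoff, ...),
    error = function(e) list(transform = global0, rms = NA_real_,
                             inlier_fraction = 0))
  global <- gfit$transform
  ids <- names(pre_case$fragments)
  transforms <- list(); rms <- numeric(0); infr <- numeric(0); flagged <- logical(0)
  any_ok <- FALSE
  for (id in ids) {
    fr <- pre_case$fragments[[id]]
    if (nrow(fr$mesh$vertices) < min_vertices) {
      transforms[[id]] <- global
      rms[id] <- NA_real_; infr[id] <- NA_real_; flagged[id] <- TRUE
      next
    }
    fit <- tryCatch(
      icp_point_to_plane(fr$mesh, post_mesh, init = global, cutoff = cutoff, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      transforms[[id]] <- global
      rms[id] <- NA_real_; infr[id] <- 0; flagged[id] <- TRUE
      next
    }
    transforms[[id]] <- fit$transform
    rms[id] <- fit$rms
    infr[id] <- fit$inlier_fraction
    flagged[id] <- fit$inlier_fraction < 0.5
    if (!flagged[id]) any_ok <- TRUE
  }
  if (!any_ok && length(ids) > 0)
    stop("registration failed for every fragment")
  structure(list(transforms = transforms, rms = rms,
                 inlier_fraction = infr, flagged = flagged,
                 global = global), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>", length(x$transforms), "fragment(s)\n")
  for (id in names(x$transforms))
    cat(sprintf("  %s: rms %.4f mm, inliers %.2f%s\n", id, x$rms[id],
                x$inlier_fraction[id], if (x$flagged[id]) "  [flagged]" else ""))
  invisible(x)
}

#' Residual 3D gap area after surgery
#'
#' Applies the per-fragment transforms of a [match_fragments()] result to
#' the preoperative fragments (annotations carried along) and measures the
#' 3D gap area on the repositioned case — the residual displacement is
#' always measured on preoperative fragment geometry, never re-extracted
#' from the (implant-bearing) postoperative mesh.
#'
#' @param pre_case A [fracture_case()].
#' @param match A `match_result`, or a named list of per-fragment
#'   [rigid_transform()]s.
#' @param ... passed to [quantify_gap()].
#' @return Residual gap area in mm^2 (scalar); the full
#'   `gap_quantification` is attached as attribute `"quantification"`.
#' @export
residual_gap_area <- function(pre_case, match, ...) {
  transforms <- if (inherits(match, "match_result")) match$transforms else match
  case <- pre_case
  for (id in names(case$fragments)) {
    tf <- transforms[[id]]
    if (is.null(tf)) stop("no transform for fragment '", id, "'")
    case$fragments[[id]]$mesh <- transform_mesh(case$fragments[[id]]$mesh, tf)
  }
  case$frame <- NULL
  q <- quantify_gap(case, ...)
  structure(q$area_mm2, quantification = q)
}
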