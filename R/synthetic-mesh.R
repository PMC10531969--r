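#' Synthetic fracture scenario
#'
#' Defines a synthetic tibial-plateau model and a radial fracture pattern
#' with known displacements, used to exercise the gap-area pipeline against
#' analytic and numeric oracles. The plateau footprint is a disc of radius
#' `radius`; the articular surface is a mildly concave bicondylar top
#' (two shallow Gaussian dishes); cuts are vertical half-planes from the
#' footprint center at the given angles, partitioning the disc into
#' sector fragments.
#'
#' @param radius footprint radius in mm (default 30).
#' @param cut_angles numeric vector of cut angles in degrees (length >= 2,
#'   distinct modulo 360), or `NULL` for an intact (unfractured) plateau.
#' @param displacements list with one entry per fragment (sector between
#'   consecutive cut angles), each a list with elements `translation`
#'   (length-3 mm, default zero), `rotation_deg` (default 0) and
#'   `rotation_axis` (default `c(0, 0, 1)`); rotations act about the
#'   fragment centroid.
#' @param depth slab thickness in mm from footprint plane to articular
#'   surface (default 15).
#' @param concavity depth of each condylar dish in mm (default 1.2).
#' @param n_radial number of radial subdivisions (default 20; at least 10,
#'   so the diameter is sampled by >= 20 vertices).
#' @param n_angular number of angular subdivisions for the full circle
#'   (default 80).
#' @param stub_len shaft-stub length in mm for the intact model (default 10).
#' @param seed integer seed recorded with the scenario (the construction is
#'   deterministic; the seed is provenance only).
#' @return An object of class `fracture_scenario`.
#' @export
fracture_scenario <- function(radius = 30, cut_angles = NULL,
                              displacements = NULL, depth = 15,
                              concavity = 1.2, n_radial = 20, n_angular = 80,
                              stub_len = 10, seed = 1L) {
  if (radius <= 0) stop("degenerate footprint: radius must be positive")
  if (depth <= 0) stop("zero-height slab: depth must be positive")
  if (2 * n_radial < 20)
    stop("resolution too low: need at least 20 vertices per diameter")
  if (!is.null(cut_angles)) {
    ca <- sort(as.numeric(cut_angles) %% 360)
    if (length(ca) < 2) stop("need at least 2 cut angles (or NULL for intact)")
    gaps <- diff(c(ca, ca[1] + 360))
    if (any(gaps <= 1e-9))
      stop("cuts leave an empty fragment (coincident cut angles)")
    cut_angles <- ca
  }
  nfrag <- if (is.null(cut_angles)) 1L else length(cut_angles)
  if (is.null(displacements))
    displacements <- replicate(nfrag, list(), simplify = FALSE)
  if (length(displacements) != nfrag)
    stop("displacements must have one entry per fragment (", nfrag, ")")
  displacements <- lapply(displacements, function(d) {
    d$translation <- as.numeric(d$translation %||% c(0, 0, 0))
    if (length(d$translation) != 3 || !all(is.finite(d$translation)))
      stop("displacement translation must be a finite length-3 vector")
    d$rotation_deg <- as.numeric(d$rotation_deg %||% 0)
    if (!is.finite(d$rotation_deg)) stop("displacement rotation must be finite")
    d$rotation_axis <- as.numeric(d$rotation_axis %||% c(0, 0, 1))
    d
  })
  structure(list(radius = radius, cut_angles = cut_angles,
                 displacements = displacements, depth = depth,
                 concavity = concavity, n_radial = n_radial,
                 n_angular = n_angular, stub_len = stub_len,
                 seed = as.integer(seed)),
            class = "fracture_scenario")
}

# rim radius as a function of angle: mild asymmetric modulation
#' @noRd
radius_fun <- function(sc) {
  R <- sc$radius
  function(theta) R * (1 + 0.10 * cos(theta) + 0.05 * sin(2 * theta))
}

# articular height field: slab depth, a mild posterior (-y) slope, minus
# two condylar dishes. The slope emulates the tibial posterior slope and,
# with the rim modulation, breaks the symmetries that would make
# surface-based alignment of the slab ambiguous; it vanishes along the
# x-axis so diameter-cut oracles keep their flat-top closed forms.
#' @noRd
height_fun <- function(sc) {
  R <- sc$radius
  cx <- c(-0.45, 0.45) * R
  w <- 0.3 * R
  function(x, y) {
    sc$depth - 0.08 * y -
      sc$concavity * (exp(-((x - cx[1])^2 + y^2) / (2 * w^2)) +
                        exp(-((x - cx[2])^2 + y^2) / (2 * w^2)))
  }
}

#' Build the intact synthetic plateau mesh
#'
#' Watertight surface of revolution-style slab: concave bicondylar top,
#' outer wall, bottom annulus and a short shaft stub. Top-surface vertices
#' are flagged as the ground-truth articular mask.
#'
#' @param scenario A [fracture_scenario()].
#' @return List with `mesh` (a [surface_mesh()]), `articular_mask` (logical
#'   per vertex) and `frame` (the true [plateau_frame()], proximal = +z).
#' @export
make_plateau_mesh <- function(scenario) {
  sc <- scenario
  h <- height_fun(sc)
  rfun <- radius_fun(sc)
  R <- sc$radius; n_r <- sc$n_radial; m <- sc$n_angular
  th <- 2 * pi * (seq_len(m) - 1) / m
  redge <- rfun(th)
  ring <- function(r, z) cbind(r * cos(th), r * sin(th), z)
  top_ring <- function(frac) {
    x <- frac * redge * cos(th); y <- frac * redge * sin(th)
    cbind(x, y, h(x, y))
  }
  verts <- rbind(c(0, 0, h(0, 0)))
  for (i in seq_len(n_r)) verts <- rbind(verts, top_ring(i / n_r))
  n_top <- 1L + n_r * m
  stub_r <- 0.6 * R
  prof <- list(cbind(redge * cos(th), redge * sin(th), 0),
               ring(stub_r, 0), ring(stub_r, -sc$stub_len))
  for (p in prof) verts <- rbind(verts, p)
  bot_apex <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, -sc$stub_len))
  Tidx <- function(i, j) 1L + (i - 1L) * m + ((j - 1L) %% m) + 1L
  Pidx <- function(k, j) n_top + (k - 1L) * m + ((j - 1L) %% m) + 1L
  tris <- list()
  # top fan + strips (CCW from above)
  tris[[1]] <- cbind(1L, Tidx(1, 1:m), Tidx(1, 2:(m + 1)))
  for (i in seq_len(n_r - 1))
    tris[[length(tris) + 1]] <- rbind(
      cbind(Tidx(i, 1:m), Tidx(i + 1, 1:m), Tidx(i + 1, 2:(m + 1))),
      cbind(Tidx(i, 1:m), Tidx(i + 1, 2:(m + 1)), Tidx(i, 2:(m + 1))))
  # outer wall and profile strips (rim ring -> P1 -> P2 -> P3)
  rings_chain <- list(Tidx(n_r, 1:m), Pidx(1, 1:m), Pidx(2, 1:m), Pidx(3, 1:m))
  for (k in seq_len(length(rings_chain) - 1)) {
    A <- rings_chain[[k]]; B <- rings_chain[[k + 1]]
    An <- c(A[-1], A[1]); Bn <- c(B[-1], B[1])
    tris[[length(tris) + 1]] <- rbind(cbind(A, B, An), cbind(An, B, Bn))
  }
  # stub bottom fan (faces -z)
  P3 <- rings_chain[[4]]; P3n <- c(P3[-1], P3[1])
  tris[[length(tris) + 1]] <- cbind(P3n, P3, bot_apex)
  mesh <- surface_mesh(verts, do.call(rbind, tris))
  mask <- logical(nrow(mesh$vertices))
  mask[seq_len(n_top)] <- TRUE
  # true articular-plane normal: the top slopes posteriorly by 0.08
  p_ax <- c(0, 0.08, 1) / sqrt(1 + 0.08^2)
  m_ax <- c(1, 0, 0)
  a_ax <- c(0, -1, 0.08) / sqrt(1 + 0.08^2)
  list(mesh = mesh, articular_mask = mask,
       frame = plateau_frame(origin = c(0, 0, sc$depth),
                             proximal = p_ax, anterior = a_ax,
                             medial = m_ax))
}

# Build one sector fragment [a0, a1] (radians) with ground truth.
#' @noRd
build_sector <- function(sc, a0, a1, id) {
  h <- height_fun(sc)
  rfun <- radius_fun(sc)
  R <- sc$radius; n_r <- sc$n_radial
  m <- max(3L, ceiling(sc$n_angular * (a1 - a0) / (2 * pi)))
  th <- a0 + (a1 - a0) * (0:m) / m
  redge <- rfun(th)
  grid_xy <- function(i) cbind(redge * i / n_r * cos(th),
                               redge * i / n_r * sin(th))
  verts <- rbind(c(0, 0, h(0, 0)))
  for (i in seq_len(n_r)) {
    xy <- grid_xy(i)
    verts <- rbind(verts, cbind(xy, h(xy[, 1], xy[, 2])))
  }
  n_top <- 1L + n_r * (m + 1L)
  bot <- verts[, ]
  bot[, 3] <- 0
  verts <- rbind(verts, bot)
  Tidx <- function(i, j) 1L + (i - 1L) * (m + 1L) + j + 1L   # j in 0..m
  Bidx <- function(i, j) n_top + Tidx(i, j)
  Tapex <- 1L; Bapex <- n_top + 1L
  tris <- list()
  j0 <- 0:(m - 1)
  tris[[1]] <- cbind(Tapex, Tidx(1, j0), Tidx(1, j0 + 1))
  tris[[2]] <- cbind(Bapex, Bidx(1, j0 + 1), Bidx(1, j0))
  for (i in seq_len(n_r - 1)) {
    tris[[length(tris) + 1]] <- rbind(
      cbind(Tidx(i, j0), Tidx(i + 1, j0), Tidx(i + 1, j0 + 1)),
      cbind(Tidx(i, j0), Tidx(i + 1, j0 + 1), Tidx(i, j0 + 1)))
    tris[[length(tris) + 1]] <- rbind(
      cbind(Bidx(i, j0), Bidx(i + 1, j0 + 1), Bidx(i + 1, j0)),
      cbind(Bidx(i, j0), Bidx(i, j0 + 1), Bidx(i + 1, j0 + 1)))
  }
  # boundary cycle (CCW from above): apex -> radial j=0 -> arc -> radial j=m
  bc_top <- c(Tapex, Tidx(1:n_r, 0), Tidx(n_r, 1:m), Tidx((n_r - 1):1, m))
  bc_bot <- c(Bapex, Bidx(1:n_r, 0), Bidx(n_r, 1:m), Bidx((n_r - 1):1, m))
  k <- seq_along(bc_top)
  kn <- c(k[-1], k[1])
  tris[[length(tris) + 1]] <- rbind(
    cbind(bc_top[k], bc_bot[k], bc_top[kn]),
    cbind(bc_top[kn], bc_bot[k], bc_bot[kn]))
  mesh <- surface_mesh(verts, do.call(rbind, tris))
  mask <- logical(nrow(mesh$vertices))
  mask[seq_len(n_top)] <- TRUE
  # ground-truth fracture edges/polylines along the two radial cuts
  edge_chain <- function(jj) {
    ids <- c(Tapex, Tidx(1:n_r, jj))
    cbind(ids[-length(ids)], ids[-1])
  }
  line_pts <- function(jj) verts[c(Tapex, Tidx(1:n_r, jj)), , drop = FALSE]
  list(fragment = fragment(id, mesh, mask),
       gt_edges = rbind(edge_chain(0), edge_chain(m)),
       gt_lines = list(line_pts(0), line_pts(m)),
       cut_angles_rad = c(a0, a1))
}

#' Fracture and displace a synthetic plateau
#'
#' Partitions the footprint into sector fragments at the scenario's cut
#' angles, applies the per-fragment rigid displacements, and returns the
#' fracture case together with ground truth: true transforms, fracture
#' edges, and gap-area oracles (numeric ruled-surface integration at 0.1 mm
#' sampling along every cut; closed-form `2 R w` / `2 R d` values apply for
#' the canonical flat half-disc modes).
#'
#' @param scenario A [fracture_scenario()] with `cut_angles`.
#' @return List with `case` (a [fracture_case()]), `true_transforms`
#'   (per-fragment displacement [rigid_transform()]s), `gt_edges`
#'   (per-fragment matrices of fracture-edge vertex pairs), and `oracle`
#'   (list with numeric `area` and `per_cut`).
#' @export
fracture_and_displace <- function(scenario) {
  sc <- scenario
  if (is.null(sc$cut_angles)) {
    mp <- make_plateau_mesh(sc)
    case <- fracture_case("synthetic-intact",
                          list(fragment("whole", mp$mesh, mp$articular_mask)),
                          side = "left", ao_ota = "41-B1")
    return(list(case = case, true_transforms = list(whole = rt_identity()),
                gt_edges = list(whole = matrix(integer(0), 0, 2)),
                oracle = list(area = 0, per_cut = numeric(0))))
  }
  ang <- sc$cut_angles * pi / 180
  k <- length(ang)
  sectors <- vector("list", k)
  for (i in seq_len(k)) {
    a0 <- ang[i]
    a1 <- if (i < k) ang[i + 1] else ang[1] + 2 * pi
    sectors[[i]] <- build_sector(sc, a0, a1, sprintf("frag%02d", i))
  }
  transforms <- vector("list", k)
  frs <- vector("list", k)
  for (i in seq_len(k)) {
    d <- sc$displacements[[i]]
    fr <- sectors[[i]]$fragment
    ctr <- colMeans(fr$mesh$vertices)
    rt <- rt_compose(rigid_transform(diag(3), d$translation),
                     rt_axis_angle(d$rotation_axis, d$rotation_deg, ctr))
    fr$mesh <- transform_mesh(fr$mesh, rt)
    transforms[[i]] <- rt
    frs[[i]] <- fr
  }
  names(transforms) <- vapply(frs, `[[`, character(1), "id")
  case <- fracture_case("synthetic", frs, side = "left", ao_ota = "41-C3")
  gt_edges <- lapply(sectors, `[[`, "gt_edges")
  names(gt_edges) <- names(transforms)
  oracle <- ruled_gap_oracle(sc, transforms)
  list(case = case, true_transforms = transforms, gt_edges = gt_edges,
       oracle = oracle, scenario = sc)
}

# Numeric gap-area oracle: for each cut, integrate the ruled surface
# between the two displaced copies of the cut line (0.1 mm sampling).
#' @noRd
ruled_gap_oracle <- function(sc, transforms, step = 0.1) {
  h <- height_fun(sc)
  ang <- sc$cut_angles * pi / 180
  k <- length(ang)
  per_cut <- numeric(k)
  rfun <- radius_fun(sc)
  for (i in seq_len(k)) {
    a <- ang[i]
    t <- seq(0, rfun(a), by = step)
    x <- t * cos(a); y <- t * sin(a)
    base <- cbind(x, y, h(x, y))
    iA <- if (i == 1) k else i - 1   # sector ending at this cut
    iB <- i                          # sector starting at this cut
    A <- rt_apply(transforms[[iA]], base)
    B <- rt_apply(transforms[[iB]], base)
    per_cut[i] <- ruled_area(A, B)
  }
  list(area = sum(per_cut), per_cut = per_cut)
}

# Area of the ruled surface between two correspondence-sampled curves.
#' @noRd
ruled_area <- function(A, B) {
  n <- nrow(A)
  i <- seq_len(n - 1)
  tri <- function(p, q, r) {
    u <- q - p; v <- r - p
    0.5 * sqrt((u[, 2] * v[, 3] - u[, 3] * v[, 2])^2 +
                 (u[, 3] * v[, 1] - u[, 1] * v[, 3])^2 +
                 (u[, 1] * v[, 2] - u[, 2] * v[, 1])^2)
  }
  sum(tri(A[i, , drop = FALSE], A[i + 1, , drop = FALSE], B[i + 1, , drop = FALSE])) +
    sum(tri(A[i, , drop = FALSE], B[i + 1, , drop = FALSE], B[i, , drop = FALSE]))
}

#' Build a synthetic postoperative model
#'
#' Moves each displaced fragment a fraction `lambda` back toward its intact
#' pose (`lambda = 1`: perfect reduction; `lambda = 0`: unchanged), merges
#' the fragments into one unlabeled composite surface, and returns the true
#' per-fragment transforms mapping the *preoperative* (displaced) fragments
#' onto their postoperative poses, for registration oracles.
#'
#' @param synthetic result of [fracture_and_displace()].
#' @param lambda reduction factor in \[0, 1\].
#' @param omit optional character vector of fragment ids to leave out of
#'   the composite (emulating missing bone in the postoperative model).
#' @return List with `mesh` (composite [surface_mesh()]), `true_transforms`
#'   (preop -> postop [rigid_transform()] per fragment) and `oracle`
#'   (numeric residual gap-area oracle at the postoperative poses).
#' @export
make_postop_model <- function(synthetic, lambda, omit = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  sc <- synthetic$scenario
  if (is.null(sc)) stop("synthetic input must come from fracture_and_displace()")
  ang <- sc$cut_angles * pi / 180
  k <- length(ang)
  post_tf <- vector("list", k)
  for (i in seq_len(k)) {
    d <- sc$displacements[[i]]
    a0 <- ang[i]
    a1 <- if (i < k) ang[i + 1] else ang[1] + 2 * pi
    sec <- build_sector(sc, a0, a1, sprintf("frag%02d", i))
    ctr <- colMeans(sec$fragment$mesh$vertices)
    post_tf[[i]] <- rt_compose(
      rigid_transform(diag(3), (1 - lambda) * d$translation),
      rt_axis_angle(d$rotation_axis, (1 - lambda) * d$rotation_deg, ctr))
  }
  names(post_tf) <- names(synthetic$true_transforms)
  true_tf <- Map(function(p, t) rt_compose(p, rt_invert(t)),
                 post_tf, synthetic$true_transforms)
  keep <- setdiff(names(post_tf), omit)
  parts <- lapply(keep, function(id) {
    fr <- synthetic$case$fragments[[id]]
    transform_mesh(fr$mesh, true_tf[[id]])
  })
  list(mesh = merge_meshes(parts), true_transforms = true_tf,
       oracle = ruled_gap_oracle(sc, post_tf))
}
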