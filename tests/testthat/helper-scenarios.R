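# Shared synthetic scenarios for the geometry tests.

# Two half-plateau fragments split along the x-axis diameter; fragment 1
# (upper half) displaced by w mm of in-plane separation (toward -y, i.e.
# perpendicular to the cut) and d mm of depression.
half_disc_scenario <- function(w = 0, d = 0, ...) {
  fracture_scenario(cut_angles = c(0, 180),
                    displacements = list(list(translation = c(0, -w, -d)),
                                         list(translation = c(0, 0, 0))),
                    ...)
}

# Three sector fragments meeting at a central Y-junction.
y_junction_scenario <- function(...) {
  fracture_scenario(cut_angles = c(90, 210, 330),
                    displacements = list(list(translation = c(3, 0, 0)),
                                         list(translation = c(-2, -2, -1)),
                                         list(translation = c(0, 3, 0))),
                    ...)
}

# Maximum angular / translational deviation between two rigid transforms.
rt_error <- function(a, b) {
  e <- rt_compose(rt_invert(a), b)
  c(angle_deg = rt_angle_deg(e), trans_mm = sqrt(sum(e$t^2)))
}

# Articular (top) submesh of the intact plateau for a scenario.
submesh_top <- function(sc) {
  mp <- make_plateau_mesh(sc)
  submesh(mp$mesh, which(mp$articular_mask))$mesh
}

# An open downward-facing bowl (lower hemisphere): no proximally facing
# faces anywhere, used as a degenerate input for the articular heuristic.
bowl_fragment <- function(radius = 20, n = 12) {
  th <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  ph <- seq(pi / 2 + 0.1, pi, length.out = n)   # below the equator
  verts <- do.call(rbind, lapply(ph[-length(ph)], function(p)
    cbind(radius * sin(p) * cos(th), radius * sin(p) * sin(th),
          radius * cos(p))))
  verts <- rbind(verts, c(0, 0, -radius))
  nr <- length(ph) - 1
  idx <- function(i, j) (i - 1) * 2 * n + ((j - 1) %% (2 * n)) + 1
  tris <- list()
  for (i in seq_len(nr - 1)) {
    j <- 1:(2 * n)
    tris[[length(tris) + 1]] <- rbind(
      cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j)),
      cbind(idx(i, j + 1), idx(i + 1, j + 1), idx(i + 1, j)))
  }
  apex <- nr * 2 * n + 1
  j <- 1:(2 * n)
  tris[[length(tris) + 1]] <- cbind(idx(nr, j), idx(nr, j + 1), apex)
  m <- surface_mesh(verts, do.call(rbind, tris))
  if (mean(mesh_face_normals(m)[, 3]) > 0)   # ensure normals face downward
    m$triangles <- m$triangles[, c(1, 3, 2)]
  fragment("bowl", m)
}
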