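test_that("coarse alignment recovers identity and known global motions", {
  syn <- fracture_and_displace(half_disc_scenario(5, 2))
  whole <- merge_meshes(lapply(syn$case$fragments, `[[`, "mesh"))
  rt0 <- coarse_align(syn$case, whole)
  e0 <- rt_error(rt_identity(), rt0)
  expect_lt(e0["angle_deg"], 0.1)
  expect_lt(e0["trans_mm"], 0.1)

  rtg <- rt_compose(rigid_transform(diag(3), c(15, -8, 5)),
                    rt_axis_angle(c(1, 1, 0), 20))
  target <- transform_mesh(whole, rtg)
  fit <- icp_point_to_plane(whole, target,
                            init = coarse_align(syn$case, target))
  e <- rt_error(rtg, fit$transform)
  expect_lt(e["angle_deg"], 1)
  expect_lt(e["trans_mm"], 0.5)
})

test_that("coarse alignment returns a proper rotation even for a reflected target", {
  syn <- fracture_and_displace(half_disc_scenario(4, 0))
  whole <- merge_meshes(lapply(syn$case$fragments, `[[`, "mesh"))
  refl <- whole
  refl$vertices[, 1] <- -refl$vertices[, 1]
  refl$triangles <- refl$triangles[, c(1, 3, 2)]
  rt <- coarse_align(syn$case, refl)
  expect_equal(det(rt$R), 1, tolerance = 1e-9)
})

test_that("point-to-plane ICP is exact on identity and small perturbations", {
  syn <- fracture_and_displace(half_disc_scenario(4, 0))
  m <- syn$case$fragments[[1]]$mesh
  fit <- icp_point_to_plane(m, m)
  expect_lt(fit$rms, 1e-3)
  e <- rt_error(rt_identity(), fit$transform)
  expect_lt(e["angle_deg"], 0.01)
  expect_lt(e["trans_mm"], 0.01)

  rtp <- rt_compose(rigid_transform(diag(3), c(1, 0.5, -0.3)),
                    rt_axis_angle(c(0, 0, 1), 2))
  fit2 <- icp_point_to_plane(m, transform_mesh(m, rtp))
  e2 <- rt_error(rtp, fit2$transform)
  expect_lt(e2["angle_deg"], 0.2)
  expect_lt(e2["trans_mm"], 0.05)
})

test_that("disjoint surfaces raise a registration-failure error", {
  syn <- fracture_and_displace(half_disc_scenario(4, 0))
  m <- syn$case$fragments[[1]]$mesh
  far <- transform_mesh(m, rigid_transform(diag(3), c(100, 0, 0)))
  expect_error(icp_point_to_plane(m, far), "registration failure")
})

test_that("fragment matching recovers the generator's per-fragment transforms", {
  syn <- fracture_and_displace(half_disc_scenario(5, 3))
  for (lam in c(0.4, 1)) {
    post <- make_postop_model(syn, lambda = lam)
    m <- match_fragments(syn$case, post$mesh)
    expect_true(all(vapply(m$transforms, function(tf) det(tf$R),
                           numeric(1)) > 0))
    for (id in names(m$transforms)) {
      e <- rt_error(post$true_transforms[[id]], m$transforms[[id]])
      expect_lt(e["angle_deg"], 1)
      expect_lt(e["trans_mm"], 0.5)
    }
  }
  # unchanged postoperative model: transforms are the identity
  post0 <- make_postop_model(syn, lambda = 0)
  m0 <- match_fragments(syn$case, post0$mesh)
  for (id in names(m0$transforms)) {
    e <- rt_error(rt_identity(), m0$transforms[[id]])
    expect_lt(e["angle_deg"], 0.5)
    expect_lt(e["trans_mm"], 0.25)
  }
})

test_that("a fragment missing from the postoperative model is flagged", {
  sc <- fracture_scenario(cut_angles = c(90, 210, 330),
                          displacements = list(list(translation = c(0, 0, 25)),
                                               list(),
                                               list()))
  syn <- fracture_and_displace(sc)
  post <- make_postop_model(syn, lambda = 0, omit = "frag01")
  m <- match_fragments(syn$case, post$mesh)
  expect_true(m$flagged["frag01"])
  expect_false(any(m$flagged[c("frag02", "frag03")]))
})

test_that("identity transforms reproduce the initial gap area exactly", {
  syn <- fracture_and_displace(half_disc_scenario(5, 2))
  a0 <- gap_area(syn$case)
  ident <- lapply(syn$case$fragments, function(fr) rt_identity())
  expect_identical(as.numeric(residual_gap_area(syn$case, ident)), a0)
})

test_that("residual gap area tracks the achieved reduction", {
  syn <- fracture_and_displace(half_disc_scenario(5, 2))
  a0 <- gap_area(syn$case)
  areas <- vapply(c(0, 0.5, 1), function(lam) {
    post <- make_postop_model(syn, lambda = lam)
    m <- match_fragments(syn$case, post$mesh)
    as.numeric(suppressWarnings(residual_gap_area(syn$case, m)))
  }, numeric(1))
  expect_equal(areas[1], a0, tolerance = 0.01)
  expect_lt(areas[3], 5)                       # perfect reduction
  expect_lt(areas[2], areas[1])                # partial reduction in between
  expect_gt(areas[2], areas[3])
})

test_that("residual area does not depend on the frame it is measured in", {
  syn <- fracture_and_displace(half_disc_scenario(4, 2))
  post <- make_postop_model(syn, lambda = 0.5)
  m1 <- match_fragments(syn$case, post$mesh)
  a1 <- as.numeric(residual_gap_area(syn$case, m1))
  g <- rt_compose(rigid_transform(diag(3), c(30, -10, 12)),
                  rt_axis_angle(c(0, 1, 1), 25))
  m2 <- match_fragments(syn$case, transform_mesh(post$mesh, g))
  a2 <- as.numeric(residual_gap_area(syn$case, m2))
  expect_equal(a2, a1, tolerance = 1e-3)
})
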