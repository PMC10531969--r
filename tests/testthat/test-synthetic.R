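# numeric surface-integral oracle for the articular top: integrate
# sqrt(1 + |grad h|^2) over the modulated footprint on a fine polar grid
top_area_oracle <- function(sc, n_r = 400, n_t = 720) {
  h <- plateaugap:::height_fun(sc)
  rfun <- plateaugap:::radius_fun(sc)
  th <- 2 * pi * (seq_len(n_t) - 0.5) / n_t
  area <- 0
  eps <- 1e-5
  for (t in th) {
    redge <- rfun(t)
    r <- redge * (seq_len(n_r) - 0.5) / n_r
    x <- r * cos(t); y <- r * sin(t)
    hx <- (h(x + eps, y) - h(x - eps, y)) / (2 * eps)
    hy <- (h(x, y + eps) - h(x, y - eps)) / (2 * eps)
    area <- area + sum(sqrt(1 + hx^2 + hy^2) * r) * (redge / n_r) * (2 * pi / n_t)
  }
  area
}

test_that("the intact plateau is watertight with the expected articular area", {
  sc <- fracture_scenario()
  mp <- make_plateau_mesh(sc)
  expect_equal(nrow(mesh_boundary_edges(mp$mesh)), 0)
  expect_true(mesh_is_edge_manifold(mp$mesh))
  top <- submesh(mp$mesh, which(mp$articular_mask))$mesh
  oracle <- top_area_oracle(sc)
  expect_lt(abs(mesh_area(top) - oracle) / oracle, 0.01)
  # nominal disc area, adjusted for concavity, within 5%
  expect_lt(abs(mesh_area(top) - pi * 30^2) / (pi * 30^2), 0.05)
})

test_that("the articular area estimate is converged in resolution", {
  a1 <- mesh_area(submesh_top(fracture_scenario(n_radial = 20, n_angular = 80)))
  a2 <- mesh_area(submesh_top(fracture_scenario(n_radial = 40, n_angular = 160)))
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("degenerate scenarios are rejected", {
  expect_error(fracture_scenario(depth = 0), "zero-height")
  expect_error(fracture_scenario(radius = -1), "degenerate footprint")
  expect_error(fracture_scenario(n_radial = 5), "resolution")
  expect_error(fracture_scenario(cut_angles = c(45, 45)), "empty fragment")
  expect_error(fracture_scenario(cut_angles = c(0, 180),
                                 displacements = list(list())),
               "one entry per fragment")
})

test_that("numeric ruled-surface oracles match the flat-top closed forms", {
  # diameter cut of total length 2R: separation w -> 2 R w, depression d -> 2 R d
  syn_w <- fracture_and_displace(half_disc_scenario(5, 0))
  expect_equal(syn_w$oracle$area, 300, tolerance = 0.005)
  syn_d <- fracture_and_displace(half_disc_scenario(0, 4))
  expect_equal(syn_d$oracle$area, 240, tolerance = 0.005)
  syn_0 <- fracture_and_displace(half_disc_scenario(0, 0))
  expect_equal(syn_0$oracle$area, 0, tolerance = 1e-12)
})

test_that("postoperative models interpolate between injury and intact poses", {
  syn <- fracture_and_displace(half_disc_scenario(6, 0))
  post0 <- make_postop_model(syn, lambda = 0)
  for (tf in post0$true_transforms) {
    e <- rt_error(rt_identity(), tf)
    expect_lt(e["angle_deg"], 1e-9)
    expect_lt(e["trans_mm"], 1e-9)
  }
  post1 <- make_postop_model(syn, lambda = 1)
  expect_lt(post1$oracle$area, 5)
  # separation scales linearly in the reduction factor
  post5 <- make_postop_model(syn, lambda = 0.5)
  expect_equal(post5$oracle$area, syn$oracle$area / 2, tolerance = 0.02)
  expect_error(make_postop_model(syn, lambda = 1.5), "lambda")
})

test_that("cohort simulation is reproducible and leaves the RNG untouched", {
  spec <- cohort_spec(n = 120, seed = 99)
  set.seed(1); before <- runif(1)
  set.seed(1)
  c1 <- simulate_cohort(spec)
  after <- runif(1)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  expect_identical(before, after)
})

test_that("simulated covariate marginals converge to the specified laws", {
  spec <- cohort_spec(n = 10000, seed = 123)
  co <- simulate_cohort(spec)
  # truncated-normal means in closed form
  tn_mean <- function(mu, s, a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    mu + s * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  expect_equal(mean(co$age), tn_mean(52, 14, 18, 90), tolerance = 0.02)
  expect_equal(sd(co$bmi), 4.7, tolerance = 0.02)
  expect_equal(mean(co$follow_up), tn_mean(7, 3.7, 0, Inf), tolerance = 0.02)
  expect_equal(mean(co$sex == "female"), 0.69, tolerance = 0.02)
  expect_equal(mean(co$smoking), 0.23, tolerance = 0.1)
  expect_equal(unname(prop.table(table(co$ao_ota))["41-B3"]), 195 / 362,
               tolerance = 0.05)
  expect_equal(mean(co$tka), 51 / 362, tolerance = 0.1)
  # gap areas: log-normal truncated at 3000
  expect_lte(max(co$initial_gap_mm2), 3000)
  med_trunc <- qlnorm(0.5 * plnorm(3000, 6.14, 1.10), 6.14, 1.10)
  expect_equal(median(co$initial_gap_mm2), med_trunc, tolerance = 0.05)
})

test_that("prognostic-group counts approximate the published 55/148/72/87 split", {
  counts <- matrix(0, 20, 4)
  for (r in 1:20) {
    co <- simulate_cohort(cohort_spec(n = 362, seed = 500 + r))
    counts[r, ] <- table(assign_prognostic_group(co$initial_gap_mm2))
  }
  target <- c(55, 148, 72, 87)
  expect_true(all(abs(colMeans(counts) - target) <= 0.2 * target))
})

test_that("the zero-noise outcome model is deterministic and linear in gap", {
  spec <- cohort_spec(n = 60, seed = 8, p_tka = 0, outcome = list(
    qol = list(intercept = 90, b_gap = -1, sd = 0)))
  co <- simulate_cohort(spec)
  # a record with gap 1000 mm^2 would score exactly 80 under this model
  expect_equal(co$qol,
               pmin(100, pmax(0, 90 - co$initial_gap_mm2 / 100)),
               tolerance = 1e-12)
})
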