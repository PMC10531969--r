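ap_lm <- function(med, lat, prox = c(0, 0), dist = c(0, -100), pairs = NULL)
  radiograph_landmarks("AP", shaft_axis = rbind(prox, dist),
                       plateau_line = rbind(med, lat),
                       incongruity_pairs = pairs)

lat_lm <- function(ant, post, prox = c(0, 0), dist = c(0, -100))
  radiograph_landmarks("lateral", shaft_axis = rbind(prox, dist),
                       plateau_line = rbind(ant, post))

test_that("MPTA measures the medial plateau-shaft angle", {
  expect_equal(mpta(ap_lm(c(-30, 0), c(30, 0))), 90, tolerance = 1e-9)
  # plateau sloping 3 degrees down medially, vertical shaft -> 87
  s <- tan(3 * pi / 180) * 30
  expect_equal(mpta(ap_lm(c(-30, -s), c(30, s))), 87, tolerance = 1e-9)
  # mirrored (right-knee) landmarks give the identical angle
  expect_equal(mpta(ap_lm(c(30, -s), c(-30, s))), 87, tolerance = 1e-9)
})

test_that("PPTA is the signed posterior slope", {
  expect_equal(ppta(lat_lm(c(-25, 0), c(25, 0))), 0, tolerance = 1e-9)
  s9 <- tan(9 * pi / 180) * 25
  expect_equal(ppta(lat_lm(c(-25, s9), c(25, -s9))), 9, tolerance = 1e-9)
  s2 <- tan(2 * pi / 180) * 25
  expect_equal(ppta(lat_lm(c(-25, -s2), c(25, s2))), -2, tolerance = 1e-9)
})

test_that("angles are invariant under global rotation and translation", {
  rot2 <- function(p, th, t) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    as.numeric(R %*% p + t)
  }
  th <- 0.6; t <- c(14, -8)
  s <- tan(3 * pi / 180) * 30
  lm0 <- ap_lm(c(-30, -s), c(30, s))
  lm1 <- ap_lm(rot2(c(-30, -s), th, t), rot2(c(30, s), th, t),
               prox = rot2(c(0, 0), th, t), dist = rot2(c(0, -100), th, t))
  expect_equal(mpta(lm1), mpta(lm0), tolerance = 1e-9)
})

test_that("articular incongruity decomposes along and across the plateau line", {
  lm <- ap_lm(c(-30, 0), c(30, 0),
              pairs = rbind(c(0, 0, 2, 0),      # 2 mm along the line
                            c(10, 0, 10, 3),    # 3 mm perpendicular
                            c(0, 0, 3, 4)))     # 3-4 decomposition
  inc <- articular_incongruity(lm)
  expect_equal(unname(inc["gap_mm"]), 3, tolerance = 1e-12)
  expect_equal(unname(inc["step_mm"]), 4, tolerance = 1e-12)
  expect_error(articular_incongruity(ap_lm(c(-30, 0), c(30, 0))),
               "incongruity pair")
})

test_that("reduction classification applies the published thresholds", {
  expect_equal(classify_reduction(reduction_assessment(1, 1, 87, 9)),
               "anatomical")
  expect_equal(classify_reduction(reduction_assessment(2.5, 1, 87, 9)),
               "inadequate")
  # boundary values are anatomical (closed intervals)
  expect_equal(classify_reduction(reduction_assessment(2, 2, 82, 4)),
               "anatomical")
  expect_equal(classify_reduction(reduction_assessment(2, 2, 92, 14)),
               "anatomical")
  expect_error(reduction_assessment(1, 1, NA, 9), "must be present")
})

test_that("worsening any single measure never improves the classification", {
  base <- list(gap = 1, step = 1, mpta = 87, ppta = 9)
  worsen <- list(gap = 3, step = 3, mpta = 95, ppta = 20)
  for (k in names(base)) {
    args <- base; args[[k]] <- worsen[[k]]
    cls <- classify_reduction(reduction_assessment(args$gap, args$step,
                                                   args$mpta, args$ppta))
    expect_equal(cls, "inadequate")
  }
})

test_that("landmark CSV round-trips into per-case landmark sets", {
  p <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(
    case_id = "c1", view = "AP",
    point_role = c("shaft_proximal", "shaft_distal", "plateau_medial",
                   "plateau_lateral", "pair1_a", "pair1_b"),
    x_mm = c(0, 0, -30, 30, 0, 2), y_mm = c(0, -100, 0, 0, 0, 0))
  write.csv(d, p, row.names = FALSE)
  lms <- read_landmarks(p)
  expect_equal(mpta(lms$c1$AP), 90, tolerance = 1e-9)
  expect_equal(unname(articular_incongruity(lms$c1$AP)["gap_mm"]), 2)
})
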