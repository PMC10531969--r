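test_that("two opposing fracture polylines stitch into exactly one loop", {
  syn <- fracture_and_displace(half_disc_scenario(5, 0))
  q <- quantify_gap(syn$case)
  loops <- stitch_gap_loops(q$fracture_lines)
  expect_length(loops, 1)
  expect_gte(nrow(loops[[1]]$points), 3)
})

test_that("no fracture lines stitch to an empty loop set", {
  expect_identical(stitch_gap_loops(list()), list())
  one <- fracture_line("a", rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_warning(loops <- stitch_gap_loops(list(one)), "no gap loop")
  expect_length(loops, 0)
})

test_that("a three-fragment Y junction yields one loop per corridor", {
  syn <- fracture_and_displace(y_junction_scenario())
  q <- quantify_gap(syn$case)
  expect_length(q$loop_areas, 3)
})

test_that("a planar rectangular loop triangulates to its exact area", {
  rect <- gap_loop(rbind(c(0, 0, 0), c(60, 0, 0), c(60, 5, 0), c(0, 5, 0)))
  gs <- triangulate_gap(list(rect))
  expect_equal(gs$area_mm2, 300, tolerance = 1e-12)
})

test_that("a skew quadrilateral triangulates to the smaller diagonal split", {
  p <- rbind(c(0, 0, 0), c(10, 0, 2), c(11, 7, -1), c(-2, 8, 3))
  tri_area <- function(a, b, c) {
    n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
           (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
           (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    0.5 * sqrt(sum(n^2))
  }
  # brute-force oracle: the two possible triangulations of a quadrilateral
  oracle <- min(tri_area(p[1, ], p[2, ], p[3, ]) + tri_area(p[1, ], p[3, ], p[4, ]),
                tri_area(p[1, ], p[2, ], p[4, ]) + tri_area(p[2, ], p[3, ], p[4, ]))
  gs <- triangulate_gap(list(gap_loop(p)))
  expect_equal(gs$area_mm2, oracle, tolerance = 1e-12)
})

test_that("collinear loop points give zero area without error", {
  line3 <- gap_loop(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(triangulate_gap(list(line3))$area_mm2, 0, tolerance = 1e-12)
})

test_that("canonical half-plateau displacements match the analytic oracles", {
  # pure separation w = 5 mm across a diameter of total length 60 mm
  syn_w <- fracture_and_displace(half_disc_scenario(5, 0))
  expect_equal(gap_area(syn_w$case), 300, tolerance = 0.02)
  # pure depression d = 4 mm: vertical band
  syn_d <- fracture_and_displace(half_disc_scenario(0, 4))
  expect_equal(gap_area(syn_d$case), 240, tolerance = 0.02)
  # combined separation + depression vs the numeric ruled-surface oracle
  syn_c <- fracture_and_displace(half_disc_scenario(5, 4))
  expect_equal(gap_area(syn_c$case), syn_c$oracle$area, tolerance = 0.03)
})

test_that("gap area increases with separation and with depression", {
  aw <- vapply(c(0, 2, 5, 8), function(w)
    gap_area(fracture_and_displace(half_disc_scenario(w, 0))$case), numeric(1))
  ad <- vapply(c(0, 2, 5, 8), function(d)
    gap_area(fracture_and_displace(half_disc_scenario(0, d))$case), numeric(1))
  expect_true(all(diff(aw) > 0))
  expect_true(all(diff(ad) > 0))
})

test_that("gap area is invariant under rigid motion of the whole case", {
  syn <- fracture_and_displace(half_disc_scenario(5, 3))
  a0 <- gap_area(syn$case)
  rt <- rt_compose(rigid_transform(diag(3), c(-15, 22, 8)),
                   rt_axis_angle(c(1, -2, 2), 40))
  a1 <- gap_area(transform_case(syn$case, rt))
  expect_equal(a1, a0, tolerance = 1e-3)
})

test_that("total gap area equals the sum of per-loop areas", {
  syn <- fracture_and_displace(y_junction_scenario())
  q <- quantify_gap(syn$case)
  expect_equal(q$area_mm2, sum(q$loop_areas), tolerance = 1e-12)
})

test_that("prognostic groups use upper-inclusive published bounds", {
  expect_equal(as.character(assign_prognostic_group(c(0, 100, 150, 150.01,
                                                      550, 550.01, 1000,
                                                      1000.01))),
               c("excellent", "excellent", "excellent", "good", "good",
                 "moderate", "moderate", "poor"))
  expect_error(assign_prognostic_group(-1), "non-negative")
  b <- prognostic_group_bounds()
  expect_equal(b$lower, c(0, 150, 550, 1000))
})
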