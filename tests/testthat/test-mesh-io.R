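test_that("mesh construction cleans duplicate vertices and degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0),              # exact duplicate of vertex 2
             c(0, 0, 0) + 1e-9)       # duplicate of vertex 1 within tolerance
  f <- rbind(c(1, 2, 3), c(5, 4, 3),  # same triangle after merging? no: (1,2,3)
             c(1, 2, 2),              # repeated index
             c(1, 2, 5))              # degenerate after merge (5 -> 1)
  m <- surface_mesh(v, f)
  expect_equal(nrow(m$vertices), 3)
  expect_true(all(m$triangles >= 1 & m$triangles <= 3))
  expect_true(all(mesh_triangle_areas(m) > 0))
  expect_true(mesh_is_edge_manifold(m))
})

test_that("STL round trip preserves geometry (ASCII) and binary STL parses", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)),
                    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, p)
  m2 <- read_stl(p)
  expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-9)
  expect_equal(nrow(m2$vertices), nrow(m$vertices))

  # binary STL written by hand
  pb <- withr::local_tempfile(fileext = ".stl")
  con <- file(pb, "wb")
  writeBin(raw(80), con)
  tri <- m$triangles
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  fn <- mesh_face_normals(m)
  for (i in seq_len(nrow(tri))) {
    rec <- c(fn[i, ], t(m$vertices[tri[i, ], ]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  close(con)
  m3 <- read_stl(pb)
  expect_equal(mesh_area(m3), mesh_area(m), tolerance = 1e-5)
})

test_that("PLY round trip preserves vertices and faces", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 1)),
                    rbind(c(1, 2, 3), c(2, 4, 3)))
  p <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, p)
  m2 <- read_ply(p)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-9)
  expect_equal(m2$triangles, m$triangles)
})

test_that("load_case assembles fragments with annotations from files", {
  syn <- fracture_and_displace(y_junction_scenario(n_radial = 10, n_angular = 40))
  dir <- withr::local_tempdir()
  paths <- character(0); apaths <- character(0)
  for (fr in syn$case$fragments) {
    mp <- file.path(dir, paste0(fr$id, ".ply"))
    ap <- file.path(dir, paste0(fr$id, ".csv"))
    write_ply(fr$mesh, mp)
    write_annotation(fr$articular_mask, ap)
    paths <- c(paths, mp); apaths <- c(apaths, ap)
  }
  case <- load_case(paths, apaths, case_id = "t", side = "right",
                    ao_ota = "41-C3")
  expect_s3_class(case, "fracture_case")
  expect_length(case$fragments, 3)
  for (i in 1:3)
    expect_equal(sum(case$fragments[[i]]$articular_mask),
                 sum(syn$case$fragments[[i]]$articular_mask))

  # single STL of an intact plateau, no annotation -> one fragment
  mp0 <- file.path(dir, "intact.stl")
  write_stl(make_plateau_mesh(fracture_scenario(n_radial = 10,
                                                n_angular = 40))$mesh, mp0)
  case0 <- load_case(mp0)
  expect_length(case0$fragments, 1)
  expect_null(case0$fragments[[1]]$articular_mask)
})

test_that("IO errors name the offending file and catch annotation mismatch", {
  expect_error(read_mesh("no/such/file.stl"), "no/such/file.stl")
  dir <- withr::local_tempdir()
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  mp <- file.path(dir, "a.ply"); write_ply(m, mp)
  ap <- file.path(dir, "a.csv")
  write.csv(data.frame(vertex_index = c(1, 9), label = 1), ap,
            row.names = FALSE)
  expect_error(load_case(mp, ap), "out of range")
  expect_error(fragment("x", m, articular_mask = c(TRUE, FALSE)),
               "does not match vertex count")
})
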