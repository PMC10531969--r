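#' Read a mesh from STL or PLY
#'
#' Dispatches on file extension. STL may be binary or ASCII (auto-detected);
#' PLY must be ASCII format 1.0. Coordinates are taken as mm. The loaded
#' mesh is cleaned (duplicate vertices merged at 1e-6 mm, degenerate
#' triangles dropped).
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format '", ext, "' for file: ", path))
}

#' @rdname read_mesh
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.info(path)$size
  is_binary <- length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    rec <- readBin(con, "raw", 50 * ntri)
    m <- matrix(rec, nrow = 50)
    fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12L * ntri,
                  endian = "little")
    fl <- matrix(fl, nrow = 12)   # cols: normal(3), v1(3), v2(3), v3(3)
    v <- rbind(t(fl[4:6, , drop = FALSE]), t(fl[7:9, , drop = FALSE]),
               t(fl[10:12, , drop = FALSE]))
    idx <- seq_len(ntri)
    f <- cbind(idx, idx + ntri, idx + 2L * ntri)
    return(surface_mesh(v, f))
  }
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  ntri <- nrow(v) / 3
  f <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}

#' Write a mesh as ASCII STL
#' @param mesh A [surface_mesh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path) {
  n <- mesh_face_normals(mesh)
  v <- mesh$vertices; f <- mesh$triangles
  lines <- character(2 + 7 * nrow(f))
  lines[1] <- "solid mesh"
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
  k <- 2
  for (i in seq_len(nrow(f))) {
    lines[k:(k + 6)] <- c(
      paste("facet normal", fmt(n[i, ])),
      "  outer loop",
      paste("    vertex", fmt(v[f[i, 1], ])),
      paste("    vertex", fmt(v[f[i, 2], ])),
      paste("    vertex", fmt(v[f[i, 3], ])),
      "  endloop",
      "endfacet")
    k <- k + 7
  }
  lines[k] <- "endsolid mesh"
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || trimws(txt[1]) != "ply")
    stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(txt))
  if (is.na(endh)) stop("malformed PLY header: ", path)
  hdr <- trimws(txt[seq_len(endh)])
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1) stop("malformed PLY header: ", path)
  body <- txt[(endh + 1):length(txt)]
  body <- body[nzchar(trimws(body))]
  vlines <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vlines, function(x) as.numeric(x[1:3])))
  flines <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(flines, function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("non-triangular face in PLY: ", path)
    x[2:4] + 1L
  }))
  surface_mesh(v, f)
}

#' Write a mesh as ASCII PLY
#' @param mesh A [surface_mesh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$triangles
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vb <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fb <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, vb, fb), path)
  invisible(path)
}

#' Read a per-fragment articular annotation file
#'
#' CSV with columns `vertex_index` (1-based) and `label` (1 = articular,
#' 0 = not). Rows may list only articular vertices, in which case all other
#' vertices are non-articular.
#'
#' @param path CSV path.
#' @param n_vertices vertex count of the fragment mesh.
#' @return Logical vector of length `n_vertices`.
#' @export
read_annotation <- function(path, n_vertices) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  d <- read.csv(path)
  if (!all(c("vertex_index", "label") %in% names(d)))
    stop("annotation file must have columns vertex_index,label: ", path)
  if (any(d$vertex_index < 1) || any(d$vertex_index > n_vertices))
    stop("annotation vertex_index out of range for mesh with ",
         n_vertices, " vertices: ", path)
  mask <- logical(n_vertices)
  mask[d$vertex_index[d$label != 0]] <- TRUE
  mask
}

#' Write an articular annotation file
#' @param mask logical per-vertex articular mask.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(mask, path) {
  write.csv(data.frame(vertex_index = which(mask), label = 1L),
            path, row.names = FALSE)
  invisible(path)
}

#' Load a fracture case from fragment mesh files
#'
#' Either pass a vector of STL/PLY paths (plus optional annotation CSVs),
#' or a JSON case manifest via [load_case_manifest()].
#'
#' @param mesh_paths character vector of STL/PLY files, one per fragment.
#' @param annotation_paths optional character vector of annotation CSVs
#'   (same length as `mesh_paths`; `NA` entries allowed).
#' @param case_id case identifier.
#' @param side `"left"` or `"right"`.
#' @param ao_ota AO/OTA code, one of 41-B1..41-C3.
#' @return A [fracture_case()].
#' @export
load_case <- function(mesh_paths, annotation_paths = NULL, case_id = "case",
                      side = "left", ao_ota = "41-B1") {
  if (!is.null(annotation_paths) &&
      length(annotation_paths) != length(mesh_paths))
    stop("annotation_paths must match mesh_paths in length")
  frs <- vector("list", length(mesh_paths))
  for (i in seq_along(mesh_paths)) {
    m <- read_mesh(mesh_paths[i])
    mask <- NULL
    if (!is.null(annotation_paths) && !is.na(annotation_paths[i]))
      mask <- read_annotation(annotation_paths[i], nrow(m$vertices))
    frs[[i]] <- fragment(id = tools::file_path_sans_ext(basename(mesh_paths[i])),
                         mesh = m, articular_mask = mask)
  }
  fracture_case(case_id = case_id, fragments = frs, side = side, ao_ota = ao_ota)
}

#' @rdname load_case
#' @param manifest_path JSON manifest listing `case_id`, `side`, `ao_ota`
#'   and a `fragments` array of `{id, mesh, annotation?}` entries with paths
#'   relative to the manifest location.
#' @export
load_case_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("cannot read manifest: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  frs <- lapply(man$fragments, function(fr) {
    m <- read_mesh(file.path(base, fr$mesh))
    mask <- NULL
    if (!is.null(fr$annotation))
      mask <- read_annotation(file.path(base, fr$annotation), nrow(m$vertices))
    fragment(id = fr$id, mesh = m, articular_mask = mask)
  })
  fracture_case(case_id = man$case_id %||% "case", fragments = frs,
                side = man$side %||% "left", ao_ota = man$ao_ota %||% "41-B1")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
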