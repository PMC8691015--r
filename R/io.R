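#' Mesh file I/O (ASCII PLY and STL)
#'
#' Reads and writes triangle meshes in ASCII PLY or ASCII STL, coordinates in
#' mm. STL stores no connectivity, so [read_stl()] welds vertices that agree
#' to 1e-6 mm.
#'
#' @param mesh a [tri_mesh()].
#' @param path file path; the format is chosen by extension in the generic
#'   wrappers.
#' @return `read_*` return a [tri_mesh()]; `write_*` return `path`
#'   invisibly.
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")  # binary connection => "\n" endings on any OS
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment cardatlas mesh, units mm",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(sprintf("%.6g %.6g %.6g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  fmt <- grep("^format ", lines, value = TRUE)[1]
  if (!grepl("ascii", fmt))
    stop("only ASCII PLY is supported (got: ", fmt, ")")
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  vl <- lines[endh + seq_len(nv)]
  v <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- lines[endh + nv + seq_len(nf)]
  fm <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular faces in ", path)
  tri_mesh(v, fm[, 2:4] + 1L)
}

#' @rdname mesh_io
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("solid cardatlas", con)
  body <- sprintf(
    "facet normal %.6g %.6g %.6g\n outer loop\n  vertex %.6g %.6g %.6g\n  vertex %.6g %.6g %.6g\n  vertex %.6g %.6g %.6g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
    b[, 1], b[, 2], b[, 3], c[, 1], c[, 2], c[, 3])
  writeLines(body, con)
  writeLines("endsolid cardatlas", con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  if (!identical(rawToChar(head), "solid"))
    stop("only ASCII STL is supported: ", path)
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  xyz <- matrix(scan(text = sub("^\\s*vertex ", "", vl), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  if (nrow(xyz) %% 3 != 0) stop("malformed STL: ", path)
  key <- apply(round(xyz / 1e-6), 1, paste, collapse = "|")
  uid <- match(key, unique(key))
  v <- xyz[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

#' Scalar grid I/O (ASCII-encoded NRRD)
#'
#' Writes a 3D scalar field (dose grid or binary mask) as a detached-free
#' NRRD file with `encoding: ascii`, recording origin and spacing in mm.
#'
#' @param x a [dose_grid()] or [binary_mask()].
#' @param path file path.
#' @return `read_nrrd` returns a [dose_grid()] for floating-point data or a
#'   [binary_mask()] for 0/1 integer data; writers return `path` invisibly.
#' @name nrrd_io
#' @export
write_nrrd <- function(x, path) {
  g <- x$grid
  if (inherits(x, "binary_mask")) {
    vals <- as.integer(x$values)
    type <- "uint8"
  } else {
    vals <- as.double(x$dose)
    type <- "double"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               sprintf("type: %s", type),
               "dimension: 3",
               "space: left-posterior-superior",
               sprintf("sizes: %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
               sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                       g$spacing[1], g$spacing[2], g$spacing[3]),
               "kinds: domain domain domain",
               "encoding: ascii",
               sprintf("space origin: (%g,%g,%g)",
                       g$origin[1] + g$spacing[1] / 2,
                       g$origin[2] + g$spacing[2] / 2,
                       g$origin[3] + g$spacing[3] / 2),
               ""), con)
  writeLines(paste(format(vals, trim = TRUE, digits = 10), collapse = " "),
             con)
  invisible(path)
}

#' @rdname nrrd_io
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!grepl("^NRRD", lines[1])) stop("not a NRRD file: ", path)
  blank <- which(lines == "")[1]
  hdr <- lines[2:(blank - 1)]
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  if (!identical(field("encoding"), "ascii"))
    stop("only ascii-encoded NRRD is supported")
  shape <- as.integer(strsplit(field("sizes"), " ")[[1]])
  nums <- function(s) as.double(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- nums(field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  center0 <- nums(field("space origin"))
  grid <- grid_spec(center0 - spacing / 2, spacing, shape)
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != prod(shape)) stop("NRRD data length mismatch")
  if (identical(field("type"), "uint8")) {
    binary_mask(grid, array(vals > 0, dim = shape))
  } else {
    dose_grid(grid, array(vals, dim = shape))
  }
}

#' Landmark JSON I/O
#'
#' Landmarks are stored as a JSON object with named length-3 points in mm.
#' @param landmarks a [heart_landmarks()] object.
#' @param path file path.
#' @return `read_landmarks` returns a [heart_landmarks()]; the writer
#'   returns `path` invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(aortic_root_center = landmarks$aortic_root_center,
         truncus_point = landmarks$truncus_point,
         heart_axis_lr = landmarks$heart_axis_lr),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  heart_landmarks(x$aortic_root_center, x$truncus_point, x$heart_axis_lr)
}
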