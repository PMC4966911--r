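#' Read a triangle mesh from OFF, PLY or STL
#'
#' Coordinates are interpreted as millimetres. OFF and PLY are read as
#' written; STL (ASCII or binary, auto-detected) stores no connectivity, so
#' vertices are reconstructed by merging points within 1e-6 mm. Meshes are
#' re-oriented outward (signed-volume check) on load, with a warning.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"off"`, `"ply"`, `"stl"`.
#' @param name surface label; default is the file base name.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "stl"),
                      name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("off", "ply", "stl"))
      stop("cannot infer mesh format from extension '", format, "'")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  res <- switch(format,
                off = read_off(path),
                ply = read_ply(path),
                stl = read_stl(path))
  tri_mesh(res$vertices, res$faces, name = name)
}

#' Write a triangle mesh to OFF, PLY or STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format as in [read_mesh()]; `"auto"` uses the extension.
#' @param binary write binary STL instead of ASCII (STL only).
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply", "stl"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("off", "ply", "stl"))
      stop("cannot infer mesh format from extension '", format, "'")
  }
  v <- mesh$vertices
  f <- mesh$faces
  switch(format,
    off = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines("OFF", con)
      writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
      writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    },
    ply = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(c("ply", "format ascii 1.0",
                   sprintf("element vertex %d", nrow(v)),
                   "property float x", "property float y", "property float z",
                   sprintf("element face %d", nrow(f)),
                   "property list uchar int vertex_indices",
                   "end_header"), con)
      writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    },
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path))
  invisible(NULL)
}

read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) < 2L) stop("OFF parse error: file is empty or truncated")
  if (toupper(ln[1]) != "OFF") stop("OFF parse error at line 1: missing OFF header")
  cnt <- suppressWarnings(as.integer(strsplit(ln[2], "\\s+")[[1]]))
  if (length(cnt) < 2L || anyNA(cnt[1:2]))
    stop("OFF parse error at line 2: expected vertex/face counts")
  nv <- cnt[1]; nf <- cnt[2]
  if (length(ln) < 2L + nv + nf) stop("OFF parse error: truncated file")
  vtx <- matrix(suppressWarnings(as.numeric(unlist(strsplit(ln[3:(2 + nv)], "\\s+")))),
                ncol = 3, byrow = TRUE)
  if (anyNA(vtx)) stop("OFF parse error in vertex block")
  frows <- strsplit(ln[(3 + nv):(2 + nv + nf)], "\\s+")
  fm <- t(vapply(frows, function(r) {
    r <- suppressWarnings(as.integer(r))
    if (length(r) < 4L || r[1] != 3L || anyNA(r[1:4]))
      stop("OFF parse error: only triangular faces supported")
    r[2:4]
  }, integer(3)))
  list(vertices = vtx, faces = fm + 1L)
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 1L || trimws(ln[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic")
  endh <- which(trimws(ln) == "end_header")[1]
  if (is.na(endh)) stop("PLY parse error: no end_header")
  header <- trimws(ln[1:endh])
  if (any(grepl("^format\\s+binary", header)))
    stop("PLY parse error: only ASCII PLY supported")
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY parse error: missing element counts")
  body <- trimws(ln[(endh + 1):length(ln)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop("PLY parse error: truncated body")
  vtx <- matrix(suppressWarnings(as.numeric(unlist(lapply(strsplit(body[1:nv], "\\s+"), `[`, 1:3)))),
                ncol = 3, byrow = TRUE)
  if (anyNA(vtx)) stop("PLY parse error in vertex block")
  fm <- t(vapply(strsplit(body[(nv + 1):(nv + nf)], "\\s+"), function(r) {
    r <- suppressWarnings(as.integer(r))
    if (r[1] != 3L || anyNA(r[1:4])) stop("PLY parse error: only triangular faces supported")
    r[2:4]
  }, integer(3)))
  list(vertices = vtx, faces = fm + 1L)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("STL parse error: empty file")
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = min(5, sz))
  close(con)
  is_ascii <- identical(rawToChar(magic), "solid") && {
    txt <- readLines(path, n = 50, warn = FALSE)
    any(grepl("facet", txt))
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  merge_triangle_soup(tri)
}

read_stl_ascii <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex\\s", ln, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("STL parse error: vertex count not a multiple of 3")
  m <- matrix(suppressWarnings(as.numeric(unlist(lapply(strsplit(vl, "\\s+"), `[`, 2:4)))),
              ncol = 3, byrow = TRUE)
  if (anyNA(m)) stop("STL parse error in vertex lines")
  m
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(nf) || nf <= 0) stop("STL parse error: bad facet count")
  out <- matrix(NA_real_, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("STL parse error: truncated facet ", i)
    out[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "integer", n = 1, size = 2, endian = "little")
  }
  out
}

# Rebuild shared vertices from a triangle soup (3 rows per face), merging
# points within 1e-6 mm.
merge_triangle_soup <- function(tri, tol = 1e-6) {
  key <- paste(round(tri[, 1] / tol), round(tri[, 2] / tol), round(tri[, 3] / tol))
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- face_normals(mesh)
  f <- mesh$faces; v <- mesh$vertices
  writeLines(sprintf("solid %s", mesh$name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("facet normal %.10g %.10g %.10g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("vertex %.10g %.10g %.10g",
                         v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3]), con)
    writeLines(c("endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw(sprintf("%-79s", "headbem binary STL")), as.raw(0)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  n <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    rec <- c(n[i, ], t(v[f[i, ], ]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
}
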