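#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Formats are detected from the file extension unless `format` is
#' given. PLY is supported in ascii and binary_little_endian flavours;
#' STL in ascii and binary. Quad faces (OBJ/PLY) are fan-triangulated.
#' The mesh is cleaned on construction: duplicate vertices within
#' 1e-6 mm merged, zero-area faces dropped (their count is kept in
#' `n_dropped_faces`). Vertex order is otherwise preserved for OBJ and
#' PLY; STL has no shared vertices, so they are rebuilt by merging.
#'
#' @param path file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; default from extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("mesh file does not exist: %s", path)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path),
         stopf("unsupported mesh format '%s'", format))
}

#' Write a triangle mesh to OBJ, PLY (ascii) or STL
#'
#' Indices are converted to each format's convention (OBJ/PLY writers
#' emit the package's 1-based faces as OBJ 1-based / PLY 0-based). A
#' written mesh re-reads with vertices equal within 1e-6 mm and
#' identical faces (STL excepted: its vertex soup is re-merged).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; default from extension.
#' @param binary write binary STL instead of ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- tolower(format %||% tools::file_ext(path))
  ok <- switch(format,
               obj = write_obj(mesh, path),
               ply = write_ply(mesh, path),
               stl = write_stl(mesh, path, binary = binary),
               stopf("unsupported mesh format '%s'", format))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L) stopf("OBJ parse error in %s: no vertex records", path)
  vparts <- strsplit(sub("^v +", "", vl), "[ \t]+")
  v <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (any(!is.finite(v))) {
    bad <- which(rowSums(!is.finite(v)) > 0)[1]
    stopf("OBJ parse error in %s: malformed vertex record %d", path, bad)
  }
  if (length(fl) == 0L) stopf("OBJ parse error in %s: no face records", path)
  f <- lapply(strsplit(sub("^f +", "", fl), "[ \t]+"), function(p) {
    idx <- as.integer(sub("/.*", "", p))
    if (any(is.na(idx))) stopf("OBJ parse error in %s: bad face '%s'",
                               path, paste(p, collapse = " "))
    idx[idx < 0] <- nrow(v) + 1L + idx[idx < 0]
    if (length(idx) < 3L) stopf("OBJ face with fewer than 3 vertices in %s", path)
    # fan triangulation for polygons
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
  })
  triangle_mesh(v, do.call(rbind, f))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  TRUE
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stopf("PLY parse error in %s: truncated header", path)
    header <- c(header, trimws(line))
    if (trimws(line) == "end_header") break
  }
  if (header[1] != "ply") stopf("PLY parse error in %s: missing 'ply' magic", path)
  fmt <- sub("^format +", "", grep("^format", header, value = TRUE)[1])
  fmt <- strsplit(fmt, " +")[[1]][1]
  el <- grep("^element", header)
  get_count <- function(name) {
    ln <- grep(paste0("^element +", name), header, value = TRUE)
    if (length(ln) == 0L) stopf("PLY parse error in %s: no %s element", path, name)
    as.integer(strsplit(ln[1], " +")[[1]][3])
  }
  nv <- get_count("vertex")
  nf <- get_count("face")
  # per-vertex scalar properties in declaration order
  vert_start <- grep("^element +vertex", header)
  vert_end <- min(c(el[el > vert_start], length(header)))
  vprops <- grep("^property +(float|float32|double|float64|uchar|uint8|int|int32)",
                 header[(vert_start + 1):(vert_end - 1)], value = TRUE)
  vnames <- vapply(strsplit(vprops, " +"), function(x) x[3], character(1))
  vtypes <- vapply(strsplit(vprops, " +"), function(x) x[2], character(1))
  xyz <- match(c("x", "y", "z"), vnames)
  if (any(is.na(xyz))) stopf("PLY parse error in %s: vertex lacks x/y/z", path)
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nv + nf) stopf("PLY parse error in %s: truncated body", path)
    vrows <- strsplit(trimws(body[seq_len(nv)]), "[ \t]+")
    v <- t(vapply(vrows, function(r) as.numeric(r[xyz]), numeric(3)))
    frows <- strsplit(trimws(body[nv + seq_len(nf)]), "[ \t]+")
    f <- lapply(frows, function(r) {
      n <- as.integer(r[1])
      idx <- as.integer(r[2:(1 + n)]) + 1L
      cbind(idx[1], idx[2:(n - 1)], idx[3:n])
    })
    f <- do.call(rbind, f)
  } else if (fmt == "binary_little_endian") {
    sz <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
            uchar = 1L, uint8 = 1L, int = 4L, int32 = 4L)
    rtype <- function(tp) if (tp %in% c("float", "float32", "double", "float64"))
      "double" else "integer"
    v <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      for (k in seq_along(vtypes)) {
        val <- readBin(con, rtype(vtypes[k]), n = 1, size = sz[[vtypes[k]]],
                       endian = "little")
        j <- match(k, xyz)
        if (!is.na(j)) v[i, j] <- as.numeric(val)
      }
    }
    f <- vector("list", nf)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", n = 1, size = 1, signed = FALSE,
                   endian = "little")
      idx <- readBin(con, "integer", n = n, size = 4, endian = "little") + 1L
      f[[i]] <- cbind(idx[1], idx[2:(n - 1)], idx[3:n])
    }
    f <- do.call(rbind, f)
  } else stopf("PLY format '%s' not supported in %s", fmt, path)
  triangle_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  TRUE
}

read_stl <- function(path) {
  # sniff: ascii STL starts with "solid" AND contains "facet"
  head_raw <- readBin(path, "raw", n = 512)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  Encoding(head_txt) <- "bytes"
  is_ascii <- grepl("^[[:space:]]*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- grep("^vertex ", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3 != 0L)
      stopf("STL parse error in %s: vertex count %d not a multiple of 3",
            path, length(vl))
    v <- t(vapply(strsplit(sub("^vertex +", "", vl), "[ \t]+"),
                  function(p) as.numeric(p[1:3]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", n = nf * 50)  # 12 float32 + uint16 per facet
    if (length(raw) < nf * 50) stopf("STL parse error in %s: truncated body", path)
    rec <- matrix(raw, nrow = 50)
    dat <- readBin(as.raw(rec[1:48, , drop = FALSE]), "double",
                   n = nf * 12, size = 4, endian = "little")
    m <- matrix(dat, ncol = 12, byrow = TRUE)
    v <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  }
  nfac <- nrow(v) / 3
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  n <- normalize_rows(cbind(
    (b - a)[, 2] * (c_ - a)[, 3] - (b - a)[, 3] * (c_ - a)[, 2],
    (b - a)[, 3] * (c_ - a)[, 1] - (b - a)[, 1] * (c_ - a)[, 3],
    (b - a)[, 1] * (c_ - a)[, 2] - (b - a)[, 2] * (c_ - a)[, 1]))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c_[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid densecranio", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
                   sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
                   sprintf("    vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid densecranio", con)
  }
  TRUE
}

#' Named sparse landmark configurations
#'
#' `landmark_config` wraps a K x 3 coordinate matrix (mm) with unique
#' landmark names and the identifier of the mesh/space the points live
#' in. Used both for the 20 validation landmarks and the 11
#' initialization landmarks of the registration step.
#'
#' @param points K x 3 matrix (mm).
#' @param names character vector of K unique names.
#' @param frame identifier of the mesh/space (free-form string).
#' @export
landmark_config <- function(points, names, frame = "unknown") {
  points <- as_point_matrix(points, "landmark points")
  names <- as.character(names)
  if (length(names) != nrow(points)) stopf("K names required for K points")
  if (anyDuplicated(names)) stopf("landmark names must be unique")
  if (nrow(points) < 1L) stopf("at least one landmark required")
  rownames(points) <- names
  structure(list(points = points, names = names, frame = frame),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config: %d landmarks in frame '%s'\n",
              nrow(x$points), x$frame))
  print(utils::head(round(x$points, 3), 5))
  if (nrow(x$points) > 5) cat(sprintf("  ... %d more\n", nrow(x$points) - 5))
  invisible(x)
}

#' Read landmarks from CSV (`name,x,y,z`) or JSON (`{name: [x,y,z]}`)
#'
#' Blank lines are skipped; names are case-sensitive.
#' @param path file path; format from extension (`.csv` or `.json`).
#' @param frame frame identifier to attach.
#' @export
read_landmarks <- function(path, frame = basename(path)) {
  if (!file.exists(path)) stopf("landmark file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, blank.lines.skip = TRUE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(d)))
      stopf("landmark CSV %s must have header name,x,y,z", path)
    landmark_config(as.matrix(d[, c("x", "y", "z")]), d$name, frame)
  } else if (ext == "json") {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- do.call(rbind, lapply(d, function(p) as.numeric(p[1:3])))
    landmark_config(pts, names(d), frame)
  } else stopf("unsupported landmark format '%s'", ext)
}

#' Write landmarks to CSV (`name,x,y,z`) or JSON
#' @param lm a [landmark_config()]
#' @param path output path; format from extension.
#' @export
write_landmarks <- function(lm, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- data.frame(name = lm$names, x = lm$points[, 1], y = lm$points[, 2],
                    z = lm$points[, 3])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    obj <- stats::setNames(lapply(seq_len(nrow(lm$points)),
                                  function(i) unname(lm$points[i, ])), lm$names)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else stopf("unsupported landmark format '%s'", ext)
  invisible(path)
}
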