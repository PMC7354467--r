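# Surface-mesh containers and file IO (STL, PLY, OBJ) plus the per-subject
# cohort table. Coordinates are millimetres throughout; none of the supported
# formats carries unit metadata, so units are a documented convention, not a
# parsed property. Orientation axes are arbitrary but assumed consistent
# within a subject's diastole/systole pair (CTA phases share the scanner
# frame).

#' Triangulated surface mesh
#'
#' Construct (and validate) a triangulated surface mesh. Validation rejects
#' meshes with fewer than 4 vertices, non-finite coordinates, out-of-range
#' face indices and degenerate (zero-area) triangles.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces k x 3 integer matrix of 1-based vertex indices.
#' @param subject_id Subject identifier string.
#' @param validate Run [validate_mesh()]? Default `TRUE`.
#' @return An object of class `surface_mesh` with fields `vertices`, `faces`,
#'   `subject_id`.
#' @export
surface_mesh <- function(vertices, faces, subject_id = "", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  mesh <- structure(list(vertices = vertices, faces = faces,
                         subject_id = as.character(subject_id)),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @param area_tol Triangles with area below this (mm^2) are reported as
#'   degenerate.
#' @return The mesh, invisibly, if valid; otherwise an error naming the defect
#'   (including offending face indices for degenerate triangles).
#' @export
validate_mesh <- function(mesh, area_tol = 1e-9) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (ncol(v) != 3L) stop("mesh vertices must be an n x 3 matrix", call. = FALSE)
  if (ncol(f) != 3L) stop("mesh faces must be a k x 3 matrix", call. = FALSE)
  if (nrow(v) < 4L)
    stop(sprintf("mesh has %d vertices; at least 4 required", nrow(v)), call. = FALSE)
  if (!all(is.finite(v)))
    stop("mesh has non-finite vertex coordinates", call. = FALSE)
  if (nrow(f) < 1L) stop("mesh has no faces", call. = FALSE)
  if (min(f) < 1L || max(f) > nrow(v))
    stop(sprintf("face indices out of range [1, %d]", nrow(v)), call. = FALSE)
  areas <- triangle_areas(v, f)
  bad <- which(areas <= area_tol)
  if (length(bad))
    stop(sprintf("degenerate (zero-area) triangle(s) at face index: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(mesh)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s: %d vertices, %d faces\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a surface mesh from file
#'
#' Supports ASCII and binary STL, ASCII and binary little-endian PLY, and
#' OBJ. STL triangle soups are merged into an indexed mesh on exact vertex
#' coincidence. Face winding is preserved as stored.
#'
#' @param path Path to the mesh file.
#' @param format One of `"auto"` (by extension), `"stl"`, `"ply"`, `"obj"`.
#' @param subject_id Subject id to attach; defaults to the file base name.
#' @param validate Validate the mesh geometry? Default `TRUE`.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      subject_id = NULL, validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj"))
      stop(sprintf("cannot infer mesh format from extension '.%s'", format), call. = FALSE)
  }
  raw <- switch(format,
                stl = read_stl(path),
                ply = read_ply(path),
                obj = read_obj(path))
  surface_mesh(raw$vertices, raw$faces,
               subject_id = subject_id %||% tools::file_path_sans_ext(basename(path)),
               validate = validate)
}

#' Write a surface mesh to file
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path; format inferred from extension unless given.
#' @param format One of `"auto"`, `"stl"`, `"ply"`, `"obj"`.
#' @param binary Write the binary variant (STL, PLY)? Default `FALSE` (ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply_mesh(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", format), call. = FALSE))
  invisible(path)
}

## ---- STL ----

read_stl <- function(path) {
  # Binary sniff: an ASCII STL starts with "solid" AND parses as text; some
  # binary files also start with "solid", so cross-check the byte count
  # implied by the binary triangle count.
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(84, sz))
  close(con)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  starts_solid <- identical(rawToChar(head84[seq_len(min(5, length(head84)))]), "solid")
  if (!starts_solid) is_binary <- TRUE
  soup <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(soup) == 0L || nrow(soup) %% 3L != 0L)
    stop(sprintf("STL file %s: triangle vertex count %d is not a multiple of 3",
                 path, nrow(soup)), call. = FALSE)
  merge_soup(soup)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop(sprintf("no vertices found in ASCII STL %s", path), call. = FALSE)
  toks <- strsplit(trimws(vl), "\\s+")
  m <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(m)) stop(sprintf("unparseable vertex line in ASCII STL %s", path), call. = FALSE)
  m
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(ntri) || ntri <= 0)
    stop(sprintf("binary STL %s reports %s triangles", path, ntri), call. = FALSE)
  rec <- readBin(con, "raw", n = 50 * ntri)
  if (length(rec) < 50 * ntri)
    stop(sprintf("binary STL %s truncated", path), call. = FALSE)
  idx <- rep(seq(0, by = 50, length.out = ntri), each = 36) +
    rep(13:48, times = ntri)  # skip the 12 normal bytes, keep 9 float32s
  vals <- readBin(rec[idx], "numeric", size = 4, n = 9 * ntri, endian = "little")
  matrix(vals, ncol = 3, byrow = TRUE)
}

merge_soup <- function(soup) {
  key <- paste(soup[, 1], soup[, 2], soup[, 3], sep = "|")
  uk <- !duplicated(key)
  vertices <- soup[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(v, f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (k in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[k, ], t(v[f[k, ], ]))), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- character(7 * nrow(f) + 2)
    out[1] <- sprintf("solid %s", mesh$subject_id)
    pos <- 2L
    for (k in seq_len(nrow(f))) {
      tri <- v[f[k, ], , drop = FALSE]
      out[pos] <- sprintf("  facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3])
      out[pos + 1L] <- "    outer loop"
      out[pos + 2:4] <- sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3])
      out[pos + 5L] <- "    endloop"
      out[pos + 6L] <- "  endfacet"
      pos <- pos + 7L
    }
    out[pos] <- sprintf("endsolid %s", mesh$subject_id)
    writeLines(out, path)
  }
  invisible(path)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- read_bin_line(con)
    if (is.null(ln)) stop(sprintf("PLY %s: header not terminated", path), call. = FALSE)
    hdr <- c(hdr, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  if (!identical(trimws(hdr[1]), "ply"))
    stop(sprintf("%s is not a PLY file", path), call. = FALSE)
  fmt_line <- grep("^format ", trimws(hdr), value = TRUE)
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("PLY format '%s' not supported (ascii / binary_little_endian only)", fmt),
         call. = FALSE)

  # Parse element/property declarations in order.
  elements <- list(); cur <- NULL
  for (ln in trimws(hdr)) {
    t <- strsplit(ln, "\\s+")[[1]]
    if (t[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      if (t[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[5], list = TRUE, count_type = t[3], type = t[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <- list(name = t[3], list = FALSE, type = t[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop(sprintf("PLY %s has no vertex element", path), call. = FALSE)

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    parse_ply_ascii(elements, body, path)
  } else {
    parse_ply_binary(elements, con, path)
  }
}

read_bin_line <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (!length(b)) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10L)) return(rawToChar(out))
    if (b != as.raw(13L)) out <- c(out, b)
  }
}

ply_rtype <- function(t) {
  switch(t,
         float = , float32 = list(what = "numeric", size = 4),
         double = , float64 = list(what = "numeric", size = 8),
         char = , int8 = list(what = "integer", size = 1, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
         stop(sprintf("unsupported PLY property type '%s'", t), call. = FALSE))
}

parse_ply_ascii <- function(elements, body, path) {
  body <- body[nzchar(trimws(body))]
  pos <- 1L
  vertices <- NULL; faces <- NULL
  for (el in elements) {
    n <- el$count
    rows <- body[seq(pos, length.out = n)]
    pos <- pos + n
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      toks <- strsplit(trimws(rows), "\\s+")
      m <- t(vapply(toks, function(t) as.numeric(t[seq_along(pn)]), numeric(length(pn))))
      if (length(pn) == 1L) m <- matrix(m, ncol = 1)
      colnames(m) <- pn
      vertices <- m[, c("x", "y", "z"), drop = FALSE]
    } else if (el$name == "face") {
      toks <- strsplit(trimws(rows), "\\s+")
      faces <- t(vapply(toks, function(t) {
        cnt <- as.integer(t[1])
        if (cnt != 3L) stop(sprintf("PLY %s: non-triangular face", path), call. = FALSE)
        as.integer(t[2:4]) + 1L
      }, integer(3)))
    }
  }
  list(vertices = vertices, faces = faces)
}

read_ply_value <- function(con, tt, n = 1) {
  if (tt$what == "numeric") {
    readBin(con, "numeric", size = tt$size, n = n, endian = "little")
  } else {
    # readBin honours `signed` only for 1- and 2-byte integers
    readBin(con, "integer", size = tt$size, n = n, endian = "little",
            signed = if (tt$size <= 2) (tt$signed %||% TRUE) else TRUE)
  }
}

parse_ply_binary <- function(elements, con, path) {
  vertices <- NULL; faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      types <- lapply(el$props, function(p) ply_rtype(p$type))
      m <- matrix(0, el$count, length(pn))
      for (i in seq_len(el$count)) {
        for (j in seq_along(types)) {
          m[i, j] <- read_ply_value(con, types[[j]])
        }
      }
      colnames(m) <- pn
      vertices <- m[, c("x", "y", "z"), drop = FALSE]
    } else if (el$name == "face") {
      p <- el$props[[1]]
      ct <- ply_rtype(p$count_type)
      it <- ply_rtype(p$type)
      faces <- matrix(0L, el$count, 3)
      for (i in seq_len(el$count)) {
        cnt <- read_ply_value(con, ct)
        if (cnt != 3L) stop(sprintf("PLY %s: non-triangular face", path), call. = FALSE)
        faces[i, ] <- read_ply_value(con, it, n = 3) + 1L
      }
    } else {
      # skip unknown fixed-size elements
      for (i in seq_len(el$count)) {
        for (p in el$props) read_ply_value(con, ply_rtype(p$type))
      }
    }
  }
  list(vertices = vertices, faces = faces)
}

write_ply_mesh <- function(mesh, path, binary = FALSE) {
  write_ply_data(mesh$vertices, mesh$faces, path, binary = binary)
}

#' Write a point cloud (optionally with a per-point scalar) as PLY
#'
#' Vertex-only PLY export, used for templates, deformed templates and strain
#' fields (`scalar` becomes a named float vertex property).
#'
#' @param points n x 3 matrix or `point_cloud`.
#' @param path Output path.
#' @param scalar Optional numeric vector of length n.
#' @param scalar_name Property name for `scalar`. Default `"strain"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud_ply <- function(points, path, scalar = NULL, scalar_name = "strain") {
  write_ply_data(as_xyz_matrix(points), NULL, path, binary = FALSE,
                 scalar = scalar, scalar_name = scalar_name)
}

write_ply_data <- function(vertices, faces, path, binary = FALSE,
                           scalar = NULL, scalar_name = "strain") {
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(vertices)),
           "property double x", "property double y", "property double z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nrow(vertices))
    hdr <- c(hdr, sprintf("property double %s", scalar_name))
  }
  if (!is.null(faces))
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    vv <- if (is.null(scalar)) vertices else cbind(vertices, scalar)
    for (i in seq_len(nrow(vv))) writeBin(as.numeric(vv[i, ]), con, size = 8, endian = "little")
    if (!is.null(faces)) {
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(faces[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  } else {
    vv <- if (is.null(scalar)) vertices else cbind(vertices, scalar)
    vlines <- apply(vv, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
    flines <- if (!is.null(faces))
      apply(faces, 1, function(r) paste(c(3L, r - 1L), collapse = " ")) else character()
    writeLines(c(hdr, vlines, flines), path)
  }
  invisible(path)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    stop(sprintf("OBJ %s has no vertices or no faces", path), call. = FALSE)
  vertices <- t(vapply(strsplit(trimws(vl), "\\s+"),
                       function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(t) {
    if (length(t) != 4L) stop(sprintf("OBJ %s: non-triangular face", path), call. = FALSE)
    as.integer(sub("/.*$", "", t[2:4]))
  }, integer(3)))
  list(vertices = vertices, faces = faces)
}

write_obj <- function(mesh, path) {
  writeLines(c(sprintf("v %.10g %.10g %.10g",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])),
             path)
  invisible(path)
}

## ---- Cohort table ----

VALVE_LEVELS <- c("BAV", "TAV", "control")

#' Read a per-subject cohort table
#'
#' Reads a CSV with one row per subject. Required columns: `subject_id`,
#' `valve` (one of `BAV`, `TAV`, `control`), `surgery` (logical/0-1).
#' Recognised optional columns: `diameter_sinus`, `diameter_stj`,
#' `diameter_midaa` (mm), `orifice_area` (mm^2), `flow_jet` (m/s),
#' `wss_stj` (Pa), `strain_midaa` (dimensionless), `group`, `mesh_path`.
#' Missing optional columns are added as `NA` (absent, not zero).
#'
#' @param path CSV path (comma separated, UTF-8, header row).
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Coerce a data frame to a validated cohort table
#'
#' @param df A data frame with at least `subject_id`, `valve`, `surgery`.
#' @return A `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  req <- c("subject_id", "valve", "surgery")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("cohort table missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop(sprintf("duplicate subject_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  bad <- which(!df$valve %in% VALVE_LEVELS)
  if (length(bad))
    stop(sprintf("unknown valve label '%s' at row %d (subject %s); must be one of %s",
                 df$valve[bad[1]], bad[1], df$subject_id[bad[1]],
                 paste(VALVE_LEVELS, collapse = ", ")), call. = FALSE)
  df$surgery <- as.logical(df$surgery)
  optional <- c("diameter_sinus", "diameter_stj", "diameter_midaa", "orifice_area",
                "flow_jet", "wss_stj", "strain_midaa", "group", "mesh_path",
                "tortuosity", "curvature", "pattern")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA
  for (col in c("diameter_sinus", "diameter_stj", "diameter_midaa")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s for subject %s", col,
                   paste(df$subject_id[bad], collapse = ", ")), call. = FALSE)
  }
  if (all(is.na(df$group))) df$group <- df$valve
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table` (or plain data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
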