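## Point-cloud, landmark and report I/O.
##
## Units are always millimetres; there is no unit autodetection.  Landmarks
## travel in a JSON sidecar, never embedded in the mesh file.

#' Construct a head model
#'
#' A head model is a cranial-surface point cloud in millimetres, optionally
#' carrying the three anatomical landmarks used for registration.
#'
#' @param points N x 3 numeric matrix of coordinates (mm).
#' @param id character identifier.
#' @param landmarks optional [landmarks()] object.
#' @param is_aligned logical; `TRUE` once the cloud is in the anatomical frame.
#' @return An object of class `head_model`.
#' @export
head_model <- function(points, id = "head", landmarks = NULL, is_aligned = FALSE) {
  points <- check_num_matrix(points)
  if (!is.null(landmarks) && !inherits(landmarks, "cranial_landmarks"))
    landmarks <- do.call(landmarks_new, landmarks)
  structure(list(id = as.character(id), points = points,
                 landmarks = landmarks, is_aligned = isTRUE(is_aligned)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model '%s': %d points%s%s>\n", x$id, nrow(x$points),
              if (x$is_aligned) ", aligned" else "",
              if (!is.null(x$landmarks)) ", landmarks" else ""))
  invisible(x)
}

## Minimum cloud size for analysis: must exceed the number of harmonic
## coefficients fitted ((lmax+1)^2 = 25 at the default lmax = 4).
MIN_ANALYSIS_POINTS <- 25L

check_analysis_size <- function(model) {
  if (nrow(model$points) < MIN_ANALYSIS_POINTS)
    stop_craniosh("insufficient_data",
                  "head '%s' has %d points; analysis needs at least %d",
                  model$id, nrow(model$points), MIN_ANALYSIS_POINTS)
  invisible(model)
}

#' Construct validated anatomical landmarks
#'
#' The three landmarks are the left/right preauricular points (just anterior
#' to each ear canal) and the glabella (point between the eyes).  They must
#' be pairwise distinct and non-collinear (triangle area > 1 mm^2).
#'
#' @param preauricular_left,preauricular_right,glabella numeric 3-vectors (mm).
#' @return An object of class `cranial_landmarks`.
#' @export
landmarks_new <- function(preauricular_left, preauricular_right, glabella) {
  lm <- list(preauricular_left = as.double(preauricular_left),
             preauricular_right = as.double(preauricular_right),
             glabella = as.double(glabella))
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L || !all(is.finite(lm[[nm]])))
      stop_craniosh("schema", "landmark '%s' must be a finite 3-vector", nm)
  }
  area <- triangle_area(lm$preauricular_left, lm$preauricular_right, lm$glabella)
  if (!is.finite(area) || area <= 1)
    stop_craniosh("geometry",
                  "landmarks are collinear or coincident (triangle area %.3g mm^2 <= 1)",
                  area)
  structure(lm, class = "cranial_landmarks")
}

#' @export
print.cranial_landmarks <- function(x, ...) {
  cat("<cranial_landmarks>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-19s %s\n", nm, paste(format(x[[nm]], digits = 6), collapse = " ")))
  invisible(x)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = "ply", obj = "obj", xyz = "xyz", txt = "xyz", csv = "csv",
         stop_craniosh("format", "cannot infer point-cloud format from '%s'", path))
}

#' Read a head point cloud
#'
#' Reads vertices from PLY (ASCII or binary little-endian), OBJ (`v` records),
#' XYZ (whitespace-separated) or CSV (headerless `x,y,z`; a non-numeric header
#' row is detected and skipped).  Faces, normals and colors are discarded;
#' point order is preserved.  Coordinates are assumed to be millimetres.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"xyz"`, `"csv"`; inferred from the
#'   file extension when `NULL`.
#' @param id identifier for the model; defaults to the file base name.
#' @return A [head_model()].
#' @export
read_point_cloud <- function(path, format = NULL, id = NULL) {
  if (!file.exists(path)) stop_craniosh("io", "file not found: %s", path)
  if (is.null(format)) format <- infer_format(path)
  format <- match.arg(tolower(format), c("ply", "obj", "xyz", "csv"))
  pts <- switch(format,
                ply = read_ply_vertices(path),
                obj = read_obj_vertices(path),
                xyz = read_xyz_vertices(path),
                csv = read_csv_vertices(path))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  head_model(pts, id = id)
}

read_ply_vertices <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop_craniosh("format", "'%s' is not a PLY file", path)
  fmt <- NULL; n_vert <- NA_integer_
  vert_props <- character(); vert_types <- character()
  elements <- list()  # name -> count, to know what precedes/follows vertices
  cur_elem <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop_craniosh("format", "PLY header truncated in '%s'", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      cur_elem <- tok[2]
      elements[[cur_elem]] <- as.integer(tok[3])
      if (cur_elem == "vertex") n_vert <- as.integer(tok[3])
    }
    if (tok[1] == "property" && identical(cur_elem, "vertex")) {
      if (tok[2] == "list")
        stop_craniosh("format", "list property on vertex element is unsupported")
      vert_types <- c(vert_types, tok[2])
      vert_props <- c(vert_props, tok[3])
    }
    if (tok[1] == "end_header") break
  }
  if (is.na(n_vert)) stop_craniosh("format", "PLY file '%s' has no vertex element", path)
  ixyz <- match(c("x", "y", "z"), vert_props)
  if (anyNA(ixyz)) stop_craniosh("format", "PLY vertex element lacks x/y/z properties")
  if (identical(fmt, "ascii")) {
    lines <- readLines(con)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < n_vert)
      stop_craniosh("format", "PLY body has %d rows, expected %d vertices",
                    length(lines), n_vert)
    rows <- strsplit(trimws(lines[seq_len(n_vert)]), "\\s+")
    pts <- t(vapply(rows, function(r) as.double(r[ixyz]), double(3)))
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[vert_types]
    if (anyNA(sz)) stop_craniosh("format", "unsupported PLY property type")
    stride <- sum(sz)
    raw <- readBin(con, "raw", n = n_vert * stride)
    if (length(raw) < n_vert * stride)
      stop_craniosh("format", "PLY binary body truncated")
    offs <- c(0L, cumsum(sz))
    read_prop <- function(j) {
      type <- vert_types[j]
      what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
      size <- sz[[j]]
      idx <- as.vector(outer(seq_len(size), (seq_len(n_vert) - 1L) * stride + offs[j], "+"))
      readBin(raw[idx], what, n = n_vert, size = size, endian = "little",
              signed = !(vert_types[j] %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    pts <- cbind(read_prop(ixyz[1]), read_prop(ixyz[2]), read_prop(ixyz[3]))
  } else {
    stop_craniosh("format", "unsupported PLY format '%s'", fmt)
  }
  check_num_matrix(pts)
}

read_obj_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  v <- grep("^v\\s", lines, value = TRUE)
  if (length(v) == 0L) stop_craniosh("format", "no 'v' records in OBJ file '%s'", path)
  rows <- strsplit(trimws(v), "\\s+")
  pts <- t(vapply(rows, function(r) {
    xyz <- suppressWarnings(as.double(r[2:4]))
    if (anyNA(xyz)) stop_craniosh("format", "non-numeric OBJ vertex record: '%s'",
                                  paste(r, collapse = " "))
    xyz
  }, double(3)))
  check_num_matrix(pts)
}

read_xyz_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "\\s+")
  pts <- t(vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (length(r) < 3L) stop_craniosh("format", "XYZ row %d has fewer than 3 fields", i)
    xyz <- suppressWarnings(as.double(r[1:3]))
    if (anyNA(xyz)) stop_craniosh("format", "non-numeric value in XYZ row %d", i)
    xyz
  }, double(3)))
  check_num_matrix(pts)
}

read_csv_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_craniosh("format", "empty CSV file '%s'", path)
  rows <- strsplit(trimws(lines), ",")
  first <- suppressWarnings(as.double(rows[[1]][1:3]))
  start <- if (anyNA(first)) 2L else 1L  # header detected and skipped
  idx <- seq(start, length(rows))
  pts <- t(vapply(idx, function(i) {
    r <- rows[[i]]
    if (length(r) < 3L) stop_craniosh("format", "CSV row %d has fewer than 3 fields", i)
    xyz <- suppressWarnings(as.double(r[1:3]))
    if (anyNA(xyz)) stop_craniosh("format", "non-numeric cell in CSV row %d", i)
    xyz
  }, double(3)))
  check_num_matrix(pts)
}

#' Write a head point cloud
#'
#' @param model a [head_model()].
#' @param path output path.
#' @param format `"ply"`, `"xyz"` or `"csv"`; inferred from the extension when
#'   `NULL`.  PLY can be written ASCII (default) or binary little-endian.
#' @param binary logical; write binary little-endian PLY.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(model, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(model, "head_model"))
  if (is.null(format)) format <- infer_format(path)
  format <- match.arg(tolower(format), c("ply", "xyz", "csv"))
  p <- model$points
  if (format == "ply") {
    hdr <- c("ply",
             if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
             sprintf("element vertex %d", nrow(p)),
             "property double x", "property double y", "property double z",
             "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con)
      writeBin(as.vector(t(p)), con, size = 8, endian = "little")
    } else {
      writeLines(c(hdr, apply(p, 1, function(r)
        paste(sprintf("%.9f", r), collapse = " "))), path)
    }
  } else if (format == "xyz") {
    writeLines(apply(p, 1, function(r) paste(sprintf("%.9f", r), collapse = " ")), path)
  } else {
    writeLines(apply(p, 1, function(r) paste(sprintf("%.9f", r), collapse = ",")), path)
  }
  invisible(path)
}

#' Read landmarks from a JSON sidecar
#'
#' The file must be a JSON object with keys `preauricular_left`,
#' `preauricular_right` and `glabella`, each a 3-number array (mm).
#'
#' @param path JSON file path.
#' @return A `cranial_landmarks` object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_craniosh("io", "file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  keys <- c("preauricular_left", "preauricular_right", "glabella")
  missing <- setdiff(keys, names(obj))
  if (length(missing))
    stop_craniosh("schema", "landmark file '%s' lacks key(s): %s",
                  path, paste(missing, collapse = ", "))
  landmarks_new(obj$preauricular_left, obj$preauricular_right, obj$glabella)
}

#' Write landmarks to a JSON sidecar
#'
#' @param lm a `cranial_landmarks` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "cranial_landmarks"))
  jsonlite::write_json(unclass(lm), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

report_required_blocks <- c("id", "ellipsoid", "indexes", "coefficients",
                            "sweep", "screening", "config")

validate_report <- function(report) {
  if (!inherits(report, "cranial_report"))
    stop_craniosh("schema", "not a cranial_report object")
  missing <- setdiff(report_required_blocks, names(report))
  if (length(missing))
    stop_craniosh("schema", "report is missing block(s): %s",
                  paste(missing, collapse = ", "))
  invisible(report)
}

#' Write an analysis report
#'
#' JSON preserves the full report and round-trips losslessly through
#' [read_report()].  CSV flattens one head per row with a fixed column schema
#' (use a list of reports for a cohort).
#'
#' @param report a `cranial_report`, or a list of them for CSV.
#' @param path output path.
#' @param format `"json"` or `"csv"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else "json"
  }
  format <- match.arg(tolower(format), c("json", "csv"))
  if (format == "json") {
    validate_report(report)
    obj <- unclass(report)
    obj$ellipsoid <- unclass(obj$ellipsoid)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    reports <- if (inherits(report, "cranial_report")) list(report) else report
    lapply(reports, validate_report)
    rows <- do.call(rbind, lapply(reports, report_row))
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

report_row <- function(r) {
  idx <- r$indexes
  scr <- r$screening
  data.frame(
    id = r$id,
    n_points = r$n_points,
    center_x = r$ellipsoid$center[1], center_y = r$ellipsoid$center[2],
    center_z = r$ellipsoid$center[3],
    ax = r$ellipsoid$semi_axes[1], ay = r$ellipsoid$semi_axes[2],
    az = r$ellipsoid$semi_axes[3],
    CP = idx$CP, CI = idx$CI, AI = idx$AI, AAI = idx$AAI, PAI = idx$PAI,
    OCLR = idx$OCLR, OCLR100 = idx$OCLR100,
    f22 = idx$f22, f22_x10 = idx$f22_x10, lmax_used = idx$lmax_used,
    rmse = r$rmse,
    flag_AI = scr$flags[["AI"]], flag_AAI = scr$flags[["AAI"]],
    flag_PAI = scr$flags[["PAI"]], flag_OCLR = scr$flags[["OCLR"]],
    flag_CI = scr$flags[["CI"]], flag_f22 = scr$flags[["f22"]],
    classification_indexes = scr$classification_indexes,
    classification_sh = scr$classification_sh,
    stringsAsFactors = FALSE
  )
}

#' Read a JSON analysis report
#'
#' @param path JSON file written by [write_report()].
#' @return A `cranial_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_craniosh("io", "file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$ellipsoid <- ellipsoid_new(obj$ellipsoid$center, obj$ellipsoid$semi_axes)
  obj$coefficients <- as.data.frame(obj$coefficients)
  if (!is.null(obj$sweep) && length(obj$sweep)) obj$sweep <- as.data.frame(obj$sweep)
  structure(obj, class = "cranial_report")
}
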