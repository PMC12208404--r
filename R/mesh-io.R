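#' Read and write surface meshes as ASCII OBJ or PLY
#'
#' Minimal readers/writers for the two plain-text surface formats the
#' pipeline exchanges. Coordinates are written with 9 significant digits so
#' a write/read round trip reproduces vertices and faces to formatting
#' precision. Only triangular faces are supported.
#'
#' @param mesh a [landmarked_mesh()] (landmarks are *not* stored in the mesh
#'   file; see [write_landmarks_json()]).
#' @param path file path; format chosen by extension (`.obj` or `.ply`).
#' @return `read_mesh()` returns a `landmarked_mesh` with empty landmarks.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "obj") {
    lines <- c(
      sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      if (nrow(f) > 0) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    )
  } else if (ext == "ply") {
    lines <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      if (nrow(f) > 0) sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    )
  } else {
    stop("unsupported mesh format: .", ext, call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply")) {
    stop("unsupported mesh format: .", ext, call. = FALSE)
  }
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- parse_numeric_records(substring(vl, 3), 3, path, "vertex")
    f <- if (length(fl) > 0) {
      # strip any texture/normal refs ("f 1/1/1 ...")
      recs <- gsub("/[0-9/]*", "", substring(fl, 3))
      matrix(as.integer(parse_numeric_records(recs, 3, path, "face")), ncol = 3)
    } else matrix(integer(), 0, 3)
    landmarked_mesh(v, f)
  } else if (ext == "ply") {
    if (lines[1] != "ply" || !grepl("ascii", lines[2])) {
      stop("not an ASCII PLY file: ", path, call. = FALSE)
    }
    hdr_end <- match("end_header", lines)
    if (is.na(hdr_end)) stop("PLY header not terminated in ", path, call. = FALSE)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    v <- parse_numeric_records(lines[hdr_end + seq_len(nv)], 3, path, "vertex")
    f <- if (nf > 0) {
      recs <- parse_numeric_records(lines[hdr_end + nv + seq_len(nf)], 4,
                                    path, "face")
      if (any(recs[, 1] != 3)) stop("non-triangular face in ", path, call. = FALSE)
      matrix(as.integer(recs[, 2:4]) + 1L, ncol = 3)
    } else matrix(integer(), 0, 3)
    landmarked_mesh(v, f)
  } else {
    stop("unsupported mesh format: .", ext, call. = FALSE)
  }
}

parse_numeric_records <- function(recs, nfield, path, what) {
  parts <- strsplit(trimws(recs), "[[:space:]]+")
  bad <- which(lengths(parts) < nfield)
  if (length(bad) > 0) {
    stop("malformed ", what, " record ", bad[1], " in ", path, call. = FALSE)
  }
  out <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[seq_len(nfield)]),
             numeric(nfield)))
  )
  if (anyNA(out)) {
    stop("non-numeric ", what, " record in ", path, call. = FALSE)
  }
  matrix(out, ncol = nfield)
}

#' Read and write landmark sets as JSON
#'
#' Landmarks are stored as a JSON object mapping names to `[x, y, z]`
#' coordinates in metres. Duplicate names are rejected on read.
#'
#' @param landmarks named list of length-3 coordinates, or a
#'   `landmarked_mesh` (its landmarks are resolved to coordinates first).
#' @param path file path.
#' @export
write_landmarks_json <- function(landmarks, path) {
  if (inherits(landmarks, "landmarked_mesh")) {
    co <- landmark_coords(landmarks)
    landmarks <- stats::setNames(lapply(seq_len(nrow(co)), function(i) co[i, ]),
                                 rownames(co))
  }
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    stop("duplicate landmark names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  lapply(raw, function(l) {
    if (length(l) != 3) stop("landmark is not a 3-vector in ", path, call. = FALSE)
    as.numeric(unlist(l))
  })
}
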