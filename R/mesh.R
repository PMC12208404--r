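#' Landmarked triangulated surface mesh
#'
#' The unit of every morphing operation: a triangulated surface together with
#' a set of named landmarks. Landmarks are either explicit 3D coordinates (in
#' metres, the package-wide length unit) or integer vertex indices into the
#' mesh; indices are resolved to coordinates on access so that a landmark
#' riding on a vertex follows the vertex through a warp.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (m).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#'   May have zero rows for a pure point cloud.
#' @param landmarks named list; each element a length-3 numeric coordinate or
#'   a single integer vertex index. Names must be unique.
#' @return An object of class `landmarked_mesh`.
#' @export
landmarked_mesh <- function(vertices, faces = matrix(integer(), 0, 3),
                            landmarks = list()) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3 || !is.numeric(vertices)) {
    stop("`vertices` must be a numeric matrix with 3 columns", call. = FALSE)
  }
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (length(landmarks) > 0) {
    if (is.null(names(landmarks)) || anyNA(names(landmarks)) ||
        any(names(landmarks) == "")) {
      stop("all landmarks must be named", call. = FALSE)
    }
    if (anyDuplicated(names(landmarks))) {
      stop("duplicate landmark names: ",
           paste(unique(names(landmarks)[duplicated(names(landmarks))]),
                 collapse = ", "), call. = FALSE)
    }
    ok <- vapply(landmarks, function(l) {
      (length(l) == 3 && all(is.finite(l))) ||
        (length(l) == 1 && l >= 1 && l <= nrow(vertices))
    }, logical(1))
    if (!all(ok)) {
      stop("invalid landmarks: ", paste(names(landmarks)[!ok], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(vertices = vertices, faces = faces, landmarks = landmarks),
            class = "landmarked_mesh")
}

#' @export
print.landmarked_mesh <- function(x, ...) {
  cat("<landmarked_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces, ", length(x$landmarks), " landmarks\n", sep = "")
  invisible(x)
}

#' Landmark coordinates as a matrix
#'
#' Resolves vertex-index landmarks to coordinates and returns a named
#' point matrix (rows = landmarks, columns = x/y/z).
#'
#' @param mesh a [landmarked_mesh()].
#' @param names optional character vector selecting (and ordering) landmarks;
#'   missing names raise an error.
#' @return numeric matrix with rownames.
#' @export
landmark_coords <- function(mesh, names = NULL) {
  lm <- mesh$landmarks
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(lm))
    if (length(missing) > 0) {
      stop("landmarks not present: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    lm <- lm[names]
  }
  out <- t(vapply(lm, function(l) {
    if (length(l) == 1) mesh$vertices[l, ] else as.numeric(l)
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Bounding-box diagonal of a point set or mesh
#' @param x a `landmarked_mesh` or a point matrix.
#' @return length of the axis-aligned bounding-box diagonal (m).
#' @export
bbox_diagonal <- function(x) {
  pts <- if (inherits(x, "landmarked_mesh")) x$vertices else as.matrix(x)
  sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
}

# Replace vertices (and coordinate landmarks) via a point-mapping function.
# Faces and index landmarks are untouched, so topology is preserved.
transform_mesh <- function(mesh, fun) {
  mesh$vertices <- fun(mesh$vertices)
  mesh$landmarks <- lapply(mesh$landmarks, function(l) {
    if (length(l) == 1) l else as.numeric(fun(matrix(l, 1, 3)))
  })
  mesh
}
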