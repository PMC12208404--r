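#' Fit a 3D thin-plate spline landmark warp
#'
#' Interpolates a smooth deformation of space carrying each source landmark
#' to its target, the standard tool of landmark-based geometric
#' morphometrics. The 3D kernel is `U(r) = r`. With `regularization = 0`
#' (the default) the warp interpolates exactly: every source landmark maps
#' onto its target to numerical precision. Positive regularization trades
#' interpolation accuracy for smoothness.
#'
#' The fitted warp is an affine part plus a weighted sum of kernels centred
#' on the source landmarks; the kernel weights satisfy the classical side
#' conditions (orthogonality to constants and to the source coordinates),
#' which makes the non-affine part vanish at infinity relative to the
#' affine trend.
#'
#' @param source,target N x 3 matrices of paired landmarks (rows correspond).
#' @param regularization nonnegative scalar added (scaled by the mean kernel
#'   magnitude) to the kernel diagonal.
#' @return An object of class `tps_warp`.
#' @export
fit_tps <- function(source, target, regularization = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n < 4) stop("need at least 4 landmarks to fit a 3D warp", call. = FALSE)
  if (!all(dim(source) == dim(target))) {
    stop("`source` and `target` must have identical dimensions", call. = FALSE)
  }
  if (regularization < 0) stop("`regularization` must be >= 0", call. = FALSE)
  dup <- duplicated(round(source, 12))
  if (any(dup)) {
    stop("duplicated source landmarks at rows: ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  P <- cbind(1, source)
  if (qr(P)$rank < 4) {
    stop("source landmarks are coplanar or collinear; ",
         "the warp is not determined", call. = FALSE)
  }
  K <- pairwise_dist(source, source)
  if (regularization > 0) {
    diag(K) <- diag(K) + regularization * mean(K)
  }
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular landmark configuration: ", conditionMessage(e), call. = FALSE)
  })
  structure(list(
    source_landmarks = source,
    target_landmarks = target,
    kernel_weights = sol[seq_len(n), , drop = FALSE],
    affine_part = sol[n + 1:4, , drop = FALSE],  # rows: 1, x, y, z
    regularization = regularization
  ), class = "tps_warp")
}

#' Apply a thin-plate spline warp to points
#'
#' @param warp a [fit_tps()] result.
#' @param points M x 3 matrix of probe points.
#' @return M x 3 matrix of warped points, same order.
#' @export
apply_tps <- function(warp, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!all(is.finite(points))) stop("probe points must be finite", call. = FALSE)
  U <- pairwise_dist(points, warp$source_landmarks)
  cbind(1, points) %*% warp$affine_part + U %*% warp$kernel_weights
}

#' Warp a mesh through a thin-plate spline
#'
#' Maps every vertex (and explicit-coordinate landmark) through the warp.
#' Faces and index landmarks are untouched: vertex count and connectivity
#' are preserved exactly.
#'
#' @param mesh a [landmarked_mesh()].
#' @param warp a `tps_warp`.
#' @return the warped `landmarked_mesh`.
#' @export
warp_mesh <- function(mesh, warp) {
  transform_mesh(mesh, function(p) apply_tps(warp, p))
}

#' Serialize / restore a warp as JSON
#' @param warp a `tps_warp`.
#' @param path file path.
#' @export
write_tps_json <- function(warp, path) {
  jsonlite::write_json(lapply(unclass(warp), unclass), path,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tps_json
#' @export
read_tps_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  structure(list(
    source_landmarks = matrix(raw$source_landmarks, ncol = 3),
    target_landmarks = matrix(raw$target_landmarks, ncol = 3),
    kernel_weights = matrix(raw$kernel_weights, ncol = 3),
    affine_part = matrix(raw$affine_part, ncol = 3),
    regularization = raw$regularization
  ), class = "tps_warp")
}

# Euclidean distance matrix between row sets (M x N).
pairwise_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
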