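#' Least-squares rigid alignment of paired point sets (Kabsch)
#'
#' @param moving,fixed N x 3 matrices of corresponding points.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3);
#'   the transform maps `moving` onto `fixed` as `moving %*% t(R) + t`.
#' @export
rigid_fit <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cf - R %*% cm))
}

apply_rigid <- function(transform, points) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Rigid registration by iterative closest point
#'
#' Point-to-point ICP: alternate nearest-neighbour matching of the moving
#' cloud into the fixed cloud with the least-squares rigid update, until the
#' RMS matching distance stops improving. The RMS sequence is
#' non-increasing by construction. Because plain ICP only converges
#' locally, the iteration starts from the best of a set of coarse
#' centroid-and-principal-axes alignments (all proper-rotation sign
#' combinations) plus the identity, the standard remedy for large initial
#' rotations.
#'
#' @param moving,fixed point matrices (N x 3, M x 3), at least 3 points each.
#' @param max_iter iteration cap.
#' @param tol stop when the RMS improves by less than `tol` (m).
#' @param init `"auto"` (coarse principal-axes candidates, default) or
#'   `"identity"` (start from the clouds as given).
#' @return list with `rotation`, `translation`, `rms` (final RMS, m),
#'   `rms_trace` (per-iteration RMS), `converged` (logical; `FALSE` flags an
#'   alignment that hit `max_iter` without meeting `tol` -- returned, not
#'   raised).
#' @export
icp_align <- function(moving, fixed, max_iter = 100, tol = 1e-10,
                      init = c("auto", "identity")) {
  init <- match.arg(init)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) < 3 || nrow(fixed) < 3) {
    stop("both point sets need at least 3 points", call. = FALSE)
  }
  starts <- list(list(rotation = diag(3), translation = numeric(3)))
  if (init == "auto") starts <- c(starts, pca_starts(moving, fixed))
  best <- NULL
  for (st in starts) {
    res <- icp_iterate(moving, fixed, st, max_iter, tol)
    if (is.null(best) || res$rms < best$rms) best <- res
    if (best$rms < tol) break
  }
  best
}

icp_iterate <- function(moving, fixed, start, max_iter, tol) {
  R <- start$rotation; t <- start$translation
  cur <- apply_rigid(start, moving)
  trace <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- pairwise_dist(cur, fixed)
    nn <- max.col(-D, ties.method = "first")
    matched <- fixed[nn, , drop = FALSE]
    rms <- sqrt(mean(rowSums((cur - matched)^2)))
    trace <- c(trace, rms)
    upd <- rigid_fit(cur, matched)
    R <- upd$rotation %*% R
    t <- as.numeric(upd$rotation %*% t) + upd$translation
    cur <- apply_rigid(upd, cur)
    if (prev_rms - rms < tol) { converged <- TRUE; break }
    prev_rms <- rms
  }
  list(rotation = R, translation = t, rms = trace[length(trace)],
       rms_trace = trace, converged = converged)
}

# Coarse centroid + principal-axes starting transforms (all proper
# sign combinations).
pca_starts <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  Vm <- svd(sweep(moving, 2, cm))$v
  Vf <- svd(sweep(fixed, 2, cf))$v
  out <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))  # keeps det = +1
    R0 <- Vf %*% S %*% t(Vm)
    if (det(R0) < 0) R0 <- Vf %*% (S * -1) %*% t(Vm)
    out[[length(out) + 1]] <- list(
      rotation = R0, translation = as.numeric(cf - R0 %*% cm))
  }
  out
}
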