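#' Coherent point drift configuration
#'
#' Settings for staged non-rigid coherent point drift (CPD). `beta` is the
#' Gaussian kernel width controlling the spatial coherence of the
#' deformation field and `lambda` the regularization weight; both act on
#' clouds that are internally centred and scaled to unit RMS, so they are
#' dimensionless. The default staged schedule starts very stiff and relaxes
#' (beta 50, 30, 10, 8 with lambda 1), each stage initialised from the
#' previous stage's deformation.
#'
#' @param lambda positive regularization weight.
#' @param beta_schedule positive kernel widths, run in order.
#' @param max_iter EM iterations per stage.
#' @param tol relative change in the estimated noise variance below which a
#'   stage stops.
#' @return list of class `cpd_config`.
#' @export
cpd_config <- function(lambda = 1, beta_schedule = c(50, 30, 10, 8),
                       max_iter = 100, tol = 1e-8) {
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (length(beta_schedule) < 1 || any(beta_schedule <= 0)) {
    stop("`beta_schedule` must be positive", call. = FALSE)
  }
  structure(list(lambda = lambda, beta_schedule = beta_schedule,
                 max_iter = max_iter, tol = tol), class = "cpd_config")
}

#' Non-rigid correspondence by staged coherent point drift
#'
#' Deforms a template cloud onto a target cloud with the Gaussian-mixture
#' CPD formulation, producing one output point per template point --
#' geometrically homologous locations on the target shape. The clouds are
#' assumed pre-aligned (e.g. by [icp_align()]); both are centred on the
#' target centroid and scaled to the target's RMS radius internally, and the
#' result is mapped back to the input frame.
#'
#' @param template N x 3 matrix; points whose homologues are sought.
#' @param target_cloud M x 3 matrix; the shape to correspond onto.
#' @param config a [cpd_config()].
#' @return list with `points` (N x 3 deformed template), `sigma` (final
#'   estimated noise SD in input units) and `stages` (per-stage tibble:
#'   beta, iterations, sigma2).
#' @export
cpd_correspond <- function(template, target_cloud, config = cpd_config()) {
  Y <- as.matrix(template); X <- as.matrix(target_cloud)
  if (nrow(Y) == 0 || nrow(X) == 0) stop("empty point cloud", call. = FALSE)
  centre <- colMeans(X)
  scale <- sqrt(mean(rowSums(sweep(X, 2, centre)^2)))
  if (scale == 0) stop("degenerate target cloud", call. = FALSE)
  Xn <- sweep(X, 2, centre) / scale
  Yn <- sweep(Y, 2, centre) / scale

  stages <- vector("list", length(config$beta_schedule))
  cur <- Yn
  s2 <- NA_real_
  for (k in seq_along(config$beta_schedule)) {
    beta <- config$beta_schedule[k]
    res <- tryCatch(
      cpd_stage(cur, Xn, beta, config$lambda, config$max_iter, config$tol),
      error = function(e) {
        stop("CPD stage ", k, " (beta = ", beta, ") diverged: ",
             conditionMessage(e), call. = FALSE)
      }
    )
    cur <- res$points
    s2 <- res$sigma2
    stages[[k]] <- tibble::tibble(stage = k, beta = beta,
                                  iterations = res$iterations, sigma2 = s2)
  }
  list(points = sweep(cur * scale, 2, centre, "+"),
       sigma = sqrt(s2) * scale,
       stages = dplyr::bind_rows(stages))
}

# One EM stage of non-rigid CPD on normalized clouds.
cpd_stage <- function(Y0, X, beta, lambda, max_iter, tol) {
  n <- nrow(Y0); m <- nrow(X)
  G <- exp(-pairwise_dist(Y0, Y0)^2 / (2 * beta^2))
  TY <- Y0
  sigma2 <- sum(pairwise_dist(X, TY)^2) / (3 * m * n)
  it <- 0
  repeat {
    it <- it + 1
    D2 <- pairwise_dist(TY, X)^2           # n x m
    num <- exp(-D2 / (2 * sigma2))
    den <- colSums(num)
    den[den < .Machine$double.xmin] <- .Machine$double.xmin
    P <- sweep(num, 2, den, "/")           # posterior, columns sum to 1
    P1 <- rowSums(P)
    Np <- sum(P1)
    PX <- P %*% X
    A <- G * P1 + diag(lambda * sigma2, n) # = diag(P1) G + lam s2 I
    W <- solve(A, PX - P1 * Y0)
    TY <- Y0 + G %*% W
    xPx <- sum(colSums(P) * rowSums(X^2))
    trPXT <- sum(PX * TY)
    tTdT <- sum(P1 * rowSums(TY^2))
    new_s2 <- (xPx - 2 * trPXT + tTdT) / (3 * Np)
    if (!is.finite(new_s2)) stop("noise variance became non-finite")
    new_s2 <- max(new_s2, 1e-12)
    done <- abs(new_s2 - sigma2) < tol * sigma2 || it >= max_iter
    sigma2 <- new_s2
    if (done) break
  }
  list(points = TY, sigma2 = sigma2, iterations = it)
}
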