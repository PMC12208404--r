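#' Permutation repeated-measures SPM ANOVA over stride curves
#'
#' One-dimensional statistical parametric mapping of a two-level
#' within-subject factor (hip shape variant) with replicate trials per
#' subject and condition. At every stride node the repeated-measures F
#' statistic for the condition effect (subject as blocking factor,
#' condition-by-subject interaction as the error term) is computed; for a
#' two-level factor this reduces to the paired t-squared statistic on the
#' per-subject condition differences, F = s(s-1) dbar^2 / sum((d - dbar)^2).
#'
#' Inference is by permutation: condition labels are flipped within
#' subject as whole trial blocks (the exchangeable units under the null),
#' the distribution of the field maximum of F gives the family-wise
#' critical threshold at level `alpha`, and suprathreshold clusters
#' receive p-values from the permutation distribution of the maximum
#' cluster extent. The observed labelling is always included in the
#' permutation set, making the test exact under exchangeability. The
#' design must be balanced (equal trials per subject per condition).
#'
#' @param curves tibble with columns `subject`, `trial`, `condition` (two
#'   levels), `node`, `value`.
#' @param alpha family-wise error level.
#' @param n_permutations number of within-subject sign flips (including
#'   the identity).
#' @param seed integer seed for the permutation draw.
#' @return object of class `spm_result`: tibble `field` (node, F), the
#'   critical `threshold`, tibble `clusters` (start/end node, extent,
#'   p_value), `alpha`, `n_permutations`, `seed`.
#' @export
spm_rm_anova <- function(curves, alpha = 0.05, n_permutations = 1000,
                         seed = 1) {
  need <- c("subject", "trial", "condition", "node", "value")
  if (!all(need %in% names(curves))) {
    stop("`curves` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  conds <- sort(unique(curves$condition))
  if (length(conds) != 2) {
    stop("exactly two condition levels are required", call. = FALSE)
  }
  counts <- dplyr::count(curves, .data$subject, .data$condition, .data$node)
  if (length(unique(counts$n)) != 1) {
    stop("unbalanced design: subset to equal trial counts per subject ",
         "and condition before calling", call. = FALSE)
  }
  nodes <- sort(unique(curves$node))
  # per-subject mean condition difference at each node
  cell <- dplyr::summarise(
    dplyr::group_by(curves, .data$subject, .data$condition, .data$node),
    value = mean(.data$value), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(cell, names_from = "condition",
                             values_from = "value")
  wide$d <- wide[[conds[1]]] - wide[[conds[2]]]
  D <- matrix(
    wide$d[order(match(wide$subject, unique(wide$subject)),
                 match(wide$node, nodes))],
    nrow = length(unique(wide$subject)), byrow = TRUE
  )
  s <- nrow(D)

  f_field <- function(Dm) {
    m <- colMeans(Dm)
    ss <- colSums(Dm^2) - s * m^2
    ss[ss < .Machine$double.eps] <- .Machine$double.eps
    s * (s - 1) * m^2 / ss
  }
  F_obs <- f_field(D)

  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), (n_permutations - 1) * s, replace = TRUE),
                    ncol = s)
    signs <- rbind(rep(1, s), signs)  # identity labelling included
    maxF <- numeric(n_permutations)
    maxExt <- numeric(n_permutations)
    # first pass: max-F distribution -> threshold
    Fs <- vector("list", n_permutations)
    for (b in seq_len(n_permutations)) {
      Fs[[b]] <- f_field(D * signs[b, ])
      maxF[b] <- max(Fs[[b]])
    }
    thr <- sort(maxF)[ceiling((1 - alpha) * n_permutations)]
    for (b in seq_len(n_permutations)) {
      maxExt[b] <- max_cluster_extent(Fs[[b]] >= thr)
    }
    cl <- cluster_runs(F_obs >= thr)
    clusters <- if (nrow(cl) == 0) {
      tibble::tibble(start_node = numeric(), end_node = numeric(),
                     extent = integer(), p_value = numeric())
    } else {
      cl$start_node <- nodes[cl$start]
      cl$end_node <- nodes[cl$end]
      cl$p_value <- vapply(cl$extent, function(e) {
        mean(maxExt >= e)
      }, numeric(1))
      cl[, c("start_node", "end_node", "extent", "p_value")]
    }
    structure(list(
      field = tibble::tibble(node = nodes, F = F_obs),
      threshold = thr,
      clusters = tibble::as_tibble(clusters),
      alpha = alpha, n_permutations = n_permutations, seed = seed,
      conditions = conds, n_subjects = s
    ), class = "spm_result")
  })
}

max_cluster_extent <- function(above) {
  r <- rle(above)
  ext <- r$lengths[r$values]
  if (length(ext) == 0) 0L else max(ext)
}

cluster_runs <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             extent = r$lengths[keep])
}

#' @export
print.spm_result <- function(x, ...) {
  cat("<spm_result> ", x$conditions[1], " vs ", x$conditions[2], ", ",
      x$n_subjects, " subjects; F* = ", round(x$threshold, 2),
      " (alpha = ", x$alpha, ", ", x$n_permutations, " permutations)\n",
      sep = "")
  if (nrow(x$clusters) == 0) {
    cat("no suprathreshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the suprathreshold clusters of an SPM result
#' @param x an `spm_result`.
#' @param ... unused.
#' @return tibble of clusters (start/end node, extent, p-value).
#' @exportS3Method generics::tidy
tidy.spm_result <- function(x, ...) x$clusters

#' One-row summary of an SPM result
#' @param x an `spm_result`.
#' @param ... unused.
#' @return tibble: threshold, max F, number of clusters, smallest cluster
#'   p-value, alpha, permutations.
#' @exportS3Method generics::glance
glance.spm_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    max_F = max(x$field$F),
    n_clusters = nrow(x$clusters),
    min_p = if (nrow(x$clusters) == 0) NA_real_ else min(x$clusters$p_value),
    alpha = x$alpha,
    n_permutations = x$n_permutations
  )
}

#' Plot an SPM F-field with its critical threshold
#'
#' @param object an `spm_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spm_result <- function(object, ...) {
  ggplot2::ggplot(object$field, ggplot2::aes(x = .data$node, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "stride (%)", y = "F",
                  title = paste(object$conditions, collapse = " vs "),
                  subtitle = sprintf("permutation threshold %.2f (alpha %.2f)",
                                     object$threshold, object$alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
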