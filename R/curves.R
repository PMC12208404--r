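#' Normalize a time series onto the 0-100% stride axis
#'
#' Linear interpolation of per-frame values onto `n_nodes` equally spaced
#' stride nodes, endpoints preserved. The stride window is half-open
#' `[start, end)` in frames, so the last node sits on the frame before the
#' ipsilateral contact.
#'
#' @param series tibble with a `frame` column and one or more value
#'   columns, or a numeric vector (one value per frame of the window).
#' @param stride_window a list with `start` and `end` (e.g. from
#'   [extract_stride()]).
#' @param n_nodes number of output nodes (default 101 = every 1% stride).
#' @return tibble with `node` (0-100) and the interpolated value columns.
#' @export
time_normalize <- function(series, stride_window, n_nodes = 101) {
  fr <- seq(stride_window$start, stride_window$end - 1)
  if (length(fr) < 2) stop("stride window too short", call. = FALSE)
  nodes <- seq(0, 100, length.out = n_nodes)
  src <- seq(0, 100, length.out = length(fr))
  if (is.numeric(series)) {
    if (length(series) != length(fr)) {
      stop("series length does not match the stride window", call. = FALSE)
    }
    return(tibble::tibble(
      node = nodes,
      value = stats::approx(src, series, xout = nodes)$y
    ))
  }
  value_cols <- setdiff(names(series), c("frame", "time"))
  series <- series[series$frame %in% fr, ]
  series <- series[order(series$frame), ]
  out <- tibble::tibble(node = nodes)
  for (cl in value_cols) {
    out[[cl]] <- stats::approx(src, series[[cl]], xout = nodes)$y
  }
  out
}

#' Aggregate muscle elements into anatomical muscles
#'
#' Forces sum within each anatomical group; activations combine as the
#' strength-weighted mean, which keeps the aggregate inside the range of
#' the element activations (e.g. the 12 gluteus medius elements combine
#' into one gluteus medius curve).
#'
#' @param solution a [solve_stride()] result (or its `activations` tibble
#'   with columns element, group, side, frame, activation, force).
#' @param grouping optional named vector mapping element -> anatomical
#'   muscle; defaults to the model grouping carried in the solution.
#' @param strengths optional named vector of element strengths for the
#'   weighted mean; equal weights if missing.
#' @return tibble: frame, muscle, side, activation, force.
#' @export
aggregate_elements <- function(solution, grouping = NULL, strengths = NULL) {
  act <- if (inherits(solution, "redundancy_solution")) {
    solution$activations
  } else solution
  if (!is.null(grouping)) {
    unmapped <- setdiff(unique(act$element), names(grouping))
    if (length(unmapped) > 0) {
      stop("elements without a group mapping: ",
           paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
    }
    act$group <- unname(grouping[act$element])
  }
  act$w <- if (is.null(strengths)) {
    1
  } else {
    unname(strengths[act$element])
  }
  dplyr::ungroup(dplyr::summarise(
    dplyr::group_by(act, .data$frame, muscle = .data$group, .data$side),
    activation = sum(.data$activation * .data$w) / sum(.data$w),
    force = sum(.data$force),
    .groups = "drop"
  ))
}

#' Normalize forces and moments by body weight
#'
#' Forces become dimensionless (N/N) and moments N m/N, the conventional
#' presentation of gait loads.
#'
#' @param curves tibble with `force` and/or `moment` columns.
#' @param body_weight body weight in newtons (> 0).
#' @return the tibble with normalized columns.
#' @export
normalize_loads <- function(curves, body_weight) {
  if (!is.numeric(body_weight) || body_weight <= 0) {
    stop("`body_weight` must be a positive force in newtons", call. = FALSE)
  }
  for (cl in intersect(c("force", "moment", "value"), names(curves))) {
    curves[[cl]] <- curves[[cl]] / body_weight
  }
  curves
}

#' Mirror left-side trials to pseudo-right
#'
#' To pool left- and right-side strides, the mediolateral (Y) components
#' of left-foot trials change sign; X (travel) and Z (vertical) components
#' are unchanged, as are scalar quantities such as activations. Applying
#' the mirror twice is the identity.
#'
#' @param curves tibble with columns `side` (`"left"`/`"right"`), `axis`
#'   (`"x"`/`"y"`/`"z"`, or NA for scalars) and value columns.
#' @return the tibble with left trials mirrored and relabelled
#'   `pseudo_right` in a `mirrored` column.
#' @export
mirror_left_to_right <- function(curves) {
  if (!"side" %in% names(curves)) {
    stop("`curves` must carry a `side` column", call. = FALSE)
  }
  if (!"mirrored" %in% names(curves)) curves$mirrored <- FALSE
  sel <- curves$side == "left" & !curves$mirrored
  if ("axis" %in% names(curves)) {
    flip <- sel & !is.na(curves$axis) & curves$axis == "y"
    for (cl in intersect(c("force", "moment", "value"), names(curves))) {
      curves[[cl]][flip] <- -curves[[cl]][flip]
    }
  }
  curves$mirrored[sel] <- TRUE
  curves
}
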