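#' Muscle element lengths and moment arms
#'
#' Muscle paths are straight-line polylines through origin, optional via
#' points and insertion, each point fixed in its segment's frame. Length is
#' the world-frame polyline length; the moment arm about a generalized
#' coordinate is the tendon-excursion derivative `-dL/dtheta`, evaluated by
#' central finite difference (default step 1e-5 rad).
#'
#' @param model a `skeleton_model`.
#' @param q named posture vector.
#' @param elements character vector of element names (default: all).
#' @return `muscle_lengths()`: named numeric vector of lengths (m).
#' @export
muscle_lengths <- function(model, q, elements = NULL) {
  cache <- path_cache(model)
  st <- fk_state(model, q)
  W <- matrix(0, nrow(cache$pts), 3)
  for (sg in names(cache$seg_rows)) {
    idx <- cache$seg_rows[[sg]]
    s <- st[[sg]]
    W[idx, ] <- sweep(cache$pts[idx, , drop = FALSE] %*% t(s$R), 2,
                      s$origin, "+")
  }
  link <- cache$mus[-1] == cache$mus[-length(cache$mus)]
  d2 <- rowSums((W[-1, , drop = FALSE] - W[-nrow(W), , drop = FALSE])^2)
  lens <- sqrt(d2[link])
  if (any(lens == 0)) stop("zero-length segment in muscle path", call. = FALSE)
  out <- as.numeric(rowsum(lens, cache$mus[-1][link]))
  names(out) <- model$muscles$element
  if (!is.null(elements)) out <- out[elements]
  out
}

# Flat attachment-point arrays for vectorized length evaluation.
path_cache <- function(model) {
  if (!is.null(attr(model, "path_cache"))) return(attr(model, "path_cache"))
  pts <- do.call(rbind, lapply(model$muscles$path, function(p) {
    t(vapply(p, function(a) as.numeric(a$point), numeric(3)))
  }))
  segs <- unlist(lapply(model$muscles$path, function(p) {
    vapply(p, `[[`, character(1), "segment")
  }))
  mus <- rep(seq_len(nrow(model$muscles)), lengths(model$muscles$path))
  list(pts = pts, segs = segs, mus = mus, seg_rows = split(seq_along(segs), segs))
}

#' @rdname muscle_lengths
#' @param element one element name.
#' @param dof one coordinate name (e.g. `"hip_flexion_r"`).
#' @param h finite-difference step (rad).
#' @return `moment_arm()`: signed moment arm (m); positive when shortening
#'   drives the coordinate positive.
#' @export
moment_arm <- function(model, q, element, dof, h = 1e-5) {
  if (!dof %in% model$coord_names) {
    stop("unknown coordinate: ", dof, call. = FALSE)
  }
  qp <- q; qp[dof] <- qp[dof] + h
  qm <- q; qm[dof] <- qm[dof] - h
  unname(-(muscle_lengths(model, qp, element) -
             muscle_lengths(model, qm, element)) / (2 * h))
}

# Moment-arm matrix (DOFs x elements) for all elements at a posture.
# Only elements whose path spans a coordinate's joint have nonzero arms;
# crossings are detected once from the segment topology.
moment_arm_matrix <- function(model, q, dofs, h = 1e-5) {
  crossing <- muscle_crossings(model)
  n_mus <- nrow(model$muscles)
  R <- matrix(0, length(dofs), n_mus,
              dimnames = list(dofs, model$muscles$element))
  L0 <- muscle_lengths(model, q)
  for (d in dofs) {
    hit <- crossing[[d]]
    if (!any(hit)) next
    qp <- q; qp[d] <- qp[d] + h
    qm <- q; qm[d] <- qm[d] - h
    Lp <- muscle_lengths(model, qp, model$muscles$element[hit])
    Lm <- muscle_lengths(model, qm, model$muscles$element[hit])
    R[d, hit] <- -(Lp - Lm) / (2 * h)
  }
  R
}

# For each rotational coordinate: logical over elements, TRUE if the
# element's path has attachments on both sides of that coordinate's joint.
muscle_crossings <- function(model) {
  if (!is.null(model$.crossings)) return(model$.crossings)
  coord_seg <- list()
  for (sg in model$segments) {
    for (rot in sg$rotations) coord_seg[[rot$coord]] <- sg$name
  }
  desc <- descendants(model)
  out <- lapply(coord_seg, function(seg) {
    below <- c(seg, desc[[seg]])
    vapply(model$muscles$path, function(path) {
      segs <- vapply(path, `[[`, character(1), "segment")
      any(segs %in% below) && any(!segs %in% below)
    }, logical(1))
  })
  out
}

descendants <- function(model) {
  kids <- split(
    vapply(model$segments, `[[`, character(1), "name"),
    vapply(model$segments, function(s) as.character(s$parent), character(1))
  )
  out <- list()
  walk <- function(nm) {
    ch <- kids[[nm]]
    if (is.null(ch)) return(character(0))
    res <- unlist(lapply(ch, function(c2) c(c2, walk(c2))))
    out[[nm]] <<- res
    res
  }
  for (nm in names(model$segments)) if (is.null(out[[nm]])) walk(nm)
  out
}

#' Morph muscle attachment geometry through a landmark warp
#'
#' Maps every attachment point that lives on an affected segment through a
#' thin-plate-spline warp defined in that segment's own frame. Joint
#' centres, segment masses and inertias are untouched, so inter-joint
#' distances are preserved exactly; only the musculature path geometry
#' moves with the bone shape.
#'
#' @param model a `skeleton_model`.
#' @param warp a `tps_warp` (expressed in the affected segments' frames).
#' @param affected_segments character vector of segment names.
#' @return the morphed `skeleton_model`, with a `path_check` attribute
#'   flagging warped points that moved implausibly far (> 25% of the
#'   segment length).
#' @export
morph_attachments <- function(model, warp, affected_segments) {
  flags <- character(0)
  model$muscles$path <- lapply(model$muscles$path, function(path) {
    lapply(path, function(a) {
      if (!a$segment %in% affected_segments) return(a)
      new <- drop(apply_tps(warp, matrix(a$point, 1, 3)))
      lim <- 0.25 * model$segments[[a$segment]]$length
      if (sqrt(sum((new - a$point)^2)) > lim) {
        flags <<- c(flags, a$segment)
      }
      list(segment = a$segment, point = new)
    })
  })
  attr(model, "path_cache") <- NULL
  attr(model, "path_cache") <- path_cache(model)
  attr(model, "path_check") <- flags
  model
}

#' Scan muscle path geometry for malalignment over a set of postures
#'
#' Report-only diagnostics run after morphing: per element, flags a moment
#' arm that changes sign *substantially* across the postures (small
#' zero-crossings are normal for fan elements; the threshold is calibrated
#' so the unmorphed model over a normal stride is clean), a hip-crossing
#' path passing within tolerance of the hip centre, and total length
#' excursion beyond a physiologic fraction of the mean.
#'
#' @param model a `skeleton_model`.
#' @param postures list of named posture vectors (e.g. stride frames).
#' @param joint_tol distance (m) below which a hip-crossing path is
#'   flagged as running through the joint centre.
#' @param flip_tol arm magnitude (m) both signs must exceed before a sign
#'   flip is flagged.
#' @param excursion_frac allowed (max-min)/mean length excursion.
#' @return tibble: element, flag, detail; zero rows = clean geometry.
#' @export
check_muscle_paths <- function(model, postures, joint_tol = 2e-3,
                               flip_tol = 0.025, excursion_frac = 0.35) {
  crossing <- muscle_crossings(model)
  joint_of <- sub("^([a-z]+)_.*_(r|l)$", "\\1_\\2", names(crossing))
  lens <- t(vapply(postures, function(q) muscle_lengths(model, q),
                   numeric(nrow(model$muscles))))
  arms <- lapply(postures, function(q) {
    moment_arm_matrix(model, q, names(crossing))
  })
  out <- list()
  flag <- function(element, what, detail) {
    out[[length(out) + 1]] <<- tibble::tibble(element = element, flag = what,
                                              detail = detail)
  }
  for (j in seq_len(nrow(model$muscles))) {
    el <- model$muscles$element[j]
    excursion <- (max(lens[, j]) - min(lens[, j])) / mean(lens[, j])
    if (excursion > excursion_frac) {
      flag(el, "length_excursion", sprintf("%.1f%% of mean", 100 * excursion))
    }
    for (d in names(crossing)) {
      if (!crossing[[d]][j]) next
      a <- vapply(arms, function(A) A[d, j], numeric(1))
      if (max(a) > flip_tol && min(a) < -flip_tol) {
        flag(el, "moment_arm_sign_flip", d)
      }
    }
    # a crossed hip about which every arm stays tiny = path through the
    # joint centre
    for (jt in grep("^hip_", unique(joint_of), value = TRUE)) {
      dofs_j <- names(crossing)[joint_of == jt]
      if (!any(vapply(dofs_j, function(d) crossing[[d]][j], logical(1)))) next
      amax <- max(vapply(dofs_j, function(d) {
        max(abs(vapply(arms, function(A) A[d, j], numeric(1))))
      }, numeric(1)))
      if (amax < joint_tol) flag(el, "path_through_joint_center", jt)
    }
  }
  if (length(out) == 0) {
    tibble::tibble(element = character(), flag = character(),
                   detail = character())
  } else dplyr::bind_rows(dplyr::distinct(dplyr::bind_rows(out)))
}
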