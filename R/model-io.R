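#' Serialize a skeleton model to a structured JSON config
#'
#' Writes the complete model definition — segments (parent, joint
#' location, rotation axes and coordinates, mass, centre of mass, inertia),
#' muscle elements (group, side, strength, attachment path), the marker
#' set, subject anthropometry and the shape-variant parameters — as a
#' single JSON document, and restores it losslessly (up to float
#' formatting).
#'
#' @param model a `skeleton_model`.
#' @param path file path (.json).
#' @return `read_model_json()` returns the restored `skeleton_model`.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    schema = "hipmorph_skeleton_model/1",
    variant = unclass(model$variant),
    subject = as.list(model$subject),
    dims = model$dims,
    coord_names = model$coord_names,
    segments = lapply(model$segments, function(sg) {
      list(name = sg$name,
           parent = if (is.na(sg$parent)) NULL else sg$parent,
           joint_location = sg$joint_location,
           rotations = lapply(sg$rotations, function(r) {
             list(axis = r$axis, coord = r$coord)
           }),
           mass = sg$mass, com = sg$com,
           inertia = as.numeric(sg$inertia), length = sg$length)
    }),
    muscles = lapply(seq_len(nrow(model$muscles)), function(i) {
      list(element = model$muscles$element[i],
           group = model$muscles$group[i],
           side = model$muscles$side[i],
           max_strength = model$muscles$max_strength[i],
           path = lapply(model$muscles$path[[i]], function(a) {
             list(segment = a$segment, point = as.numeric(a$point))
           }))
    }),
    markers = lapply(seq_len(nrow(model$markers)), function(i) {
      list(marker = model$markers$marker[i],
           segment = model$markers$segment[i],
           point = as.numeric(model$markers$point[[i]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "hipmorph_skeleton_model/1")) {
    stop("not a skeleton model config: ", path, call. = FALSE)
  }
  segments <- lapply(doc$segments, function(sg) {
    list(name = sg$name,
         parent = if (is.null(sg$parent)) NA else sg$parent,
         joint_location = if (is.null(sg$joint_location)) NULL else
           as.numeric(unlist(sg$joint_location)),
         rotations = lapply(sg$rotations, function(r) {
           list(axis = as.numeric(unlist(r$axis)), coord = r$coord)
         }),
         mass = sg$mass, com = as.numeric(unlist(sg$com)),
         inertia = matrix(as.numeric(unlist(sg$inertia)), 3, 3),
         length = sg$length)
  })
  names(segments) <- vapply(segments, `[[`, character(1), "name")
  muscles <- dplyr::bind_rows(lapply(doc$muscles, function(mu) {
    tibble::tibble(element = mu$element, group = mu$group, side = mu$side,
                   max_strength = mu$max_strength,
                   path = list(lapply(mu$path, function(a) {
                     list(segment = a$segment,
                          point = as.numeric(unlist(a$point)))
                   })))
  }))
  markers <- dplyr::bind_rows(lapply(doc$markers, function(mk) {
    tibble::tibble(marker = mk$marker, segment = mk$segment,
                   point = list(as.numeric(unlist(mk$point))))
  }))
  variant <- doc$variant
  variant <- hip_shape_params(variant$variant,
                              variant$biacetabular_breadth_ratio,
                              variant$neck_length_ratio,
                              variant$iliac_flare_angle,
                              variant$ap_depth_ratio)
  model <- structure(list(
    segments = segments,
    order = names(segments),
    coord_names = as.character(unlist(doc$coord_names)),
    muscles = muscles,
    markers = markers,
    dims = lapply(doc$dims, function(x) as.numeric(x)),
    subject = tibble::as_tibble(doc$subject),
    variant = variant
  ), class = "skeleton_model")
  attr(model, "path_cache") <- path_cache(model)
  model
}
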