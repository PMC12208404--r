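#' Write and read gait trials as columnar text plus a JSON sidecar
#'
#' A trial is stored as three files sharing a stem: `<stem>_markers.tsv`
#' (frame, marker, x, y, z), `<stem>_grf.tsv` (frame, plate, fx, fy, fz,
#' copx, copy, copz, tz) and `<stem>.json` (events, anthropometry, side,
#' sample rate, walking speed). Numbers are written with 9 significant
#' digits, so a write/read round trip reproduces the trial to formatting
#' precision. Frames are 0-based.
#'
#' @param trial a `gait_trial`.
#' @param stem path stem (no extension).
#' @return `read_gait_trial()` returns a `gait_trial`.
#' @export
write_gait_trial <- function(trial, stem) {
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.9g", x) else x
  }
  mk <- trial$markers[, c("frame", "marker", "x", "y", "z")]
  mk[] <- lapply(mk, fmt)
  utils::write.table(mk, paste0(stem, "_markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gr <- trial$grf[, c("frame", "plate", "fx", "fy", "fz",
                      "copx", "copy", "copz", "tz")]
  gr[] <- lapply(gr, fmt)
  utils::write.table(gr, paste0(stem, "_grf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    subject = as.list(trial$subject),
    side = trial$side,
    sample_rate = trial$sample_rate,
    walking_speed = trial$walking_speed,
    stride_period = trial$stride_period,
    events = trial$events,
    plate_sides = as.list(trial$plate_sides)
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_gait_trial
#' @export
read_gait_trial <- function(stem) {
  parse_tsv <- function(path, num_cols) {
    if (!file.exists(path)) stop("missing trial file: ", path, call. = FALSE)
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) {
        stop("malformed table ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    for (cl in num_cols) {
      if (!is.numeric(df[[cl]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1]
        stop("non-numeric value in column ", cl, ", record ", bad,
             " of ", path, call. = FALSE)
      }
    }
    tibble::as_tibble(df)
  }
  mk <- parse_tsv(paste0(stem, "_markers.tsv"), c("frame", "x", "y", "z"))
  gr <- parse_tsv(paste0(stem, "_grf.tsv"),
                  c("frame", "plate", "fx", "fy", "fz"))
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  fs <- meta$sample_rate
  mk$time <- mk$frame / fs
  gr$time <- gr$frame / fs
  structure(list(
    subject = tibble::as_tibble(meta$subject),
    side = meta$side,
    sample_rate = fs,
    walking_speed = meta$walking_speed,
    stride_period = meta$stride_period,
    markers = mk[, c("frame", "time", "marker", "x", "y", "z")],
    grf = gr[, c("frame", "time", "plate", "fx", "fy", "fz",
                 "copx", "copy", "copz", "tz")],
    events = meta$events,
    plate_sides = unlist(meta$plate_sides)
  ), class = "gait_trial")
}

#' Write tidy stride curves as columnar text
#'
#' @param curves tibble (subject, trial, condition, quantity, node,
#'   value ... any tidy curve table).
#' @param path output file.
#' @export
write_curves <- function(curves, path) {
  out <- curves
  out[] <- lapply(out, function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.9g", x) else x
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
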