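#' Generate a seeded synthetic cohort of walking subjects
#'
#' Draws subject anthropometry spanning small-to-large adults, with sexes
#' alternating F, M, F, ... so an even `n_subjects` gives a balanced split
#' (10 subjects = 5 female + 5 male). Deterministic given `seed`.
#'
#' Documented sampling bounds (uniform draws):
#' stature 1.50-1.75 m (F) / 1.62-1.92 m (M); body mass from a BMI of
#' 19-29 kg/m^2; inter-hip-centre distance 10.2-11.4% of stature; hip- to
#' knee-centre femur length 24-26% of stature.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer RNG seed.
#' @return tibble: `subject_id`, `sex`, `body_mass` (kg), `stature` (m),
#'   `hip_breadth` (m, inter-hip-centre), `femur_length` (m).
#' @export
generate_cohort <- function(n_subjects = 10, seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be a positive count", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  with_seed(seed, {
    sex <- rep(c("F", "M"), length.out = n_subjects)
    stature <- ifelse(sex == "F", stats::runif(n_subjects, 1.50, 1.75),
                      stats::runif(n_subjects, 1.62, 1.92))
    bmi <- stats::runif(n_subjects, 19, 29)
    tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      sex = sex,
      body_mass = bmi * stature^2,
      stature = stature,
      hip_breadth = stats::runif(n_subjects, 0.102, 0.114) * stature,
      femur_length = stats::runif(n_subjects, 0.24, 0.26) * stature
    )
  })
}

#' Documented anthropometry bounds used by [generate_cohort()]
#' @return named list of c(min, max) bounds.
#' @export
cohort_bounds <- function() {
  list(stature_F = c(1.50, 1.75), stature_M = c(1.62, 1.92),
       bmi = c(19, 29), hip_breadth_frac = c(0.102, 0.114),
       femur_length_frac = c(0.24, 0.26))
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
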