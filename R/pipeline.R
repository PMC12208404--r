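#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end experiment: cohort size and
#' seed, trials per subject, gait settings, the two hip shape variants,
#' dynamics filtering, the recruitment criterion and the SPM settings.
#' All defaults reproduce the package's reference study design: 10
#' subjects (5 F / 5 M), 3 trials each, two hip variants fed identical
#' kinematics and kinetics, permutation SPM on 101 stride nodes.
#'
#' @param n_subjects,cohort_seed cohort settings.
#' @param trials_per_subject replicate walking trials per subject.
#' @param walking_speed m/s or `NULL` (stature-scaled self-selected).
#' @param noise_sd,jitter trial generator settings.
#' @param variants list of two [hip_shape_params()].
#' @param filter_cutoff Hz, kinematics/GRF low-pass.
#' @param redundancy a [redundancy_config()].
#' @param alpha,n_permutations,stats_seed SPM settings.
#' @param out_dir output directory for [run_pipeline()] artifacts (NULL =
#'   no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 10, cohort_seed = 1,
                            trials_per_subject = 3,
                            walking_speed = NULL,
                            noise_sd = 0.002, jitter = 0.03,
                            variants = list(hip_shape_params("human_like"),
                                            hip_shape_params("australopith_like")),
                            filter_cutoff = 6,
                            redundancy = redundancy_config(),
                            alpha = 0.05, n_permutations = 1000,
                            stats_seed = 1,
                            out_dir = NULL) {
  stopifnot(length(variants) == 2)
  structure(list(
    n_subjects = n_subjects, cohort_seed = cohort_seed,
    trials_per_subject = trials_per_subject,
    walking_speed = walking_speed, noise_sd = noise_sd, jitter = jitter,
    variants = variants, filter_cutoff = filter_cutoff,
    redundancy = redundancy, alpha = alpha,
    n_permutations = n_permutations, stats_seed = stats_seed,
    out_dir = out_dir, version = "1"
  ), class = "pipeline_config")
}

#' Run the full hip-variant comparison pipeline
#'
#' Generates the cohort and its walking trials, fits marker kinematics
#' and computes inverse-dynamics joint loads ONCE per trial, then
#' resolves the muscle redundancy problem separately for each hip shape
#' variant against those identical external loads -- the study's central
#' control. Aggregated gluteal activations and muscle-inclusive hip joint
#' reaction forces are stride-normalized (101 nodes), body-weight
#' normalized, mirrored to pseudo-right, and compared between variants by
#' permutation SPM repeated-measures ANOVA.
#'
#' @param config a [pipeline_config()].
#' @param quantities curve quantities to run SPM on.
#' @param progress print per-trial progress.
#' @return list of class `pipeline_result`: `curves` (tidy tibble:
#'   subject, trial, condition, quantity, node, value), `spm` (named list
#'   of [spm_rm_anova()] results), `residuals` (per-trial max residual
#'   force / BW), `solver_status` counts, `cohort`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         quantities = c("gluteus_medius_activation",
                                        "gluteus_maximus_activation",
                                        "hip_jrf_x", "hip_jrf_z"),
                         progress = interactive()) {
  cohort <- generate_cohort(config$n_subjects, config$cohort_seed)
  vnames <- vapply(config$variants, `[[`, character(1), "variant")
  curve_rows <- list()
  resid_rows <- list()
  status_rows <- list()

  for (si in seq_len(nrow(cohort))) {
    subject <- cohort[si, ]
    models <- lapply(config$variants, build_subject_model, subject = subject)
    bw <- subject$body_mass * 9.80665
    for (ti in seq_len(config$trials_per_subject)) {
      trial_seed <- config$cohort_seed * 10000L + si * 100L + ti
      trial <- generate_gait_trial(
        subject, walking_speed = config$walking_speed,
        trial_seed = trial_seed, noise_sd = config$noise_sd,
        jitter = config$jitter
      )
      if (progress) {
        message("subject ", subject$subject_id, " trial ", ti)
      }
      kin <- fit_kinematics(trial, models[[1]],
                            filter_cutoff = config$filter_cutoff)
      loads <- net_joint_loads(models[[1]], kin, trial)
      resid <- residual_loads(models[[1]], kin, trial)
      stride <- extract_stride(trial)
      fr <- seq(stride$start, stride$end - 1)
      loads_s <- loads[loads$frame %in% fr, ]
      resid_rows[[length(resid_rows) + 1]] <- tibble::tibble(
        subject = subject$subject_id, trial = ti,
        max_residual_bw = max(abs(resid$force[resid$frame %in% fr])) / bw
      )
      side_s <- if (stride$side == "right") "r" else "l"
      side_long <- stride$side
      for (vi in 1:2) {
        sol <- solve_stride(models[[vi]], kin, loads_s,
                            config = config$redundancy)
        status_rows[[length(status_rows) + 1]] <- tibble::tibble(
          subject = subject$subject_id, trial = ti, condition = vnames[vi],
          status = sol$frames$status
        )
        agg <- aggregate_elements(sol)
        agg <- agg[agg$side == side_s, ]
        for (g in c("gluteus_medius", "gluteus_maximus", "gluteus_minimus")) {
          tn <- time_normalize(
            agg[agg$muscle == g, c("frame", "activation")], stride)
          curve_rows[[length(curve_rows) + 1]] <- tibble::tibble(
            subject = subject$subject_id, trial = ti, condition = vnames[vi],
            quantity = paste0(g, "_activation"),
            node = tn$node, value = tn$activation
          )
        }
        jrf <- joint_reaction_with_muscles(models[[vi]], kin, sol, loads_s,
                                           joint = "hip", side = side_long)
        jrf$side <- side_long
        jrf <- mirror_left_to_right(jrf)
        jrf <- normalize_loads(jrf, bw)
        for (ax in c("x", "y", "z")) {
          tn <- time_normalize(
            jrf[jrf$axis == ax, c("frame", "force")], stride)
          curve_rows[[length(curve_rows) + 1]] <- tibble::tibble(
            subject = subject$subject_id, trial = ti, condition = vnames[vi],
            quantity = paste0("hip_jrf_", ax),
            node = tn$node, value = tn$force
          )
        }
      }
    }
  }
  curves <- dplyr::bind_rows(curve_rows)
  spm <- list()
  for (qt in intersect(quantities, unique(curves$quantity))) {
    spm[[qt]] <- spm_rm_anova(
      curves[curves$quantity == qt,
             c("subject", "trial", "condition", "node", "value")],
      alpha = config$alpha, n_permutations = config$n_permutations,
      seed = config$stats_seed
    )
  }
  result <- structure(list(
    curves = curves,
    spm = spm,
    residuals = dplyr::bind_rows(resid_rows),
    solver_status = dplyr::count(dplyr::bind_rows(status_rows),
                                 .data$condition, .data$status),
    cohort = cohort,
    config = config
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  result
}

# Write curves, SPM summaries and a hash manifest to out_dir.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_curves(result$curves, file.path(out_dir, "curves.tsv"))
  jsonlite::write_json(
    lapply(result$spm, function(s) {
      list(threshold = s$threshold, alpha = s$alpha,
           n_permutations = s$n_permutations, seed = s$seed,
           clusters = s$clusters, field = s$field)
    }),
    file.path(out_dir, "spm.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns"
  )
  write_curves(result$residuals, file.path(out_dir, "residuals.tsv"))
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$cohort), " subjects x ",
      x$config$trials_per_subject, " trials x 2 variants\n", sep = "")
  cat("max residual force: ",
      sprintf("%.2f%% BW", 100 * max(x$residuals$max_residual_bw)), "\n",
      sep = "")
  for (nm in names(x$spm)) {
    s <- x$spm[[nm]]
    cat(nm, ": ", nrow(s$clusters), " suprathreshold cluster(s)\n", sep = "")
  }
  invisible(x)
}

#' Mean condition curves from a pipeline result
#' @param result a `pipeline_result`.
#' @return tibble: condition, quantity, node, mean value.
#' @export
condition_means <- function(result) {
  dplyr::summarise(
    dplyr::group_by(result$curves, .data$condition, .data$quantity,
                    .data$node),
    value = mean(.data$value), .groups = "drop"
  )
}

#' Plot mean stride curves by condition
#' @param object a `pipeline_result`.
#' @param quantities which quantities to facet (default all).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pipeline_result <- function(object, quantities = NULL, ...) {
  cm <- condition_means(object)
  if (!is.null(quantities)) cm <- cm[cm$quantity %in% quantities, ]
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$node, y = .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "stride (%)", y = NULL, colour = "hip variant") +
    ggplot2::theme_minimal()
}
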