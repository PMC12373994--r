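#' Symptom models fitted in the suite
#'
#' The 13 symptom-severity predictors modelled one at a time against
#' whole-brain V_T: CAPS-5 total, the four DSM-5 clusters, and the eight
#' clusters of the 8-factor model.
#' @return Named character vector: display label -> cohort column.
#' @export
symptom_model_set <- function() {
  c("Total" = "caps_total",
    "B-Intrusion" = "dsm5_b_intrusion",
    "C-Avoidance" = "dsm5_c_avoidance",
    "D-Mood/Cognition" = "dsm5_d_mood_cognition",
    "E-Arousal" = "dsm5_e_arousal",
    "Internal-Intrusion" = "c8_internal_intrusion",
    "External-Intrusion" = "c8_external_intrusion",
    "Avoidance" = "c8_avoidance",
    "Negative Affect" = "c8_negative_affect",
    "Anhedonia/Emotional Numbing" = "c8_anhedonia",
    "Externalizing Behavior" = "c8_externalizing",
    "Anxious Arousal" = "c8_anxious_arousal",
    "Dysphoric Arousal" = "c8_dysphoric_arousal")
}

suite_row <- function(fit, term, label_region, label_measure) {
  cf <- fit$coefficients
  r <- cf[cf$term == term, , drop = FALSE]
  data.frame(region = label_region, measure = label_measure,
             mean = r$mean, sd = r$sd,
             hpd_low = r$hpd_low, hpd_high = r$hpd_high,
             robust = r$robust, converged = fit$converged,
             failed = FALSE, stringsAsFactors = FALSE)
}

failed_row <- function(label_region, label_measure) {
  data.frame(region = label_region, measure = label_measure,
             mean = NA_real_, sd = NA_real_, hpd_low = NA_real_,
             hpd_high = NA_real_, robust = NA, converged = NA,
             failed = TRUE, stringsAsFactors = FALSE)
}

#' Run the full Bayesian model suite
#'
#' Fits the three model families over the requested regions and assembles
#' the three published-style report tables:
#' \describe{
#'   \item{confounds}{sex/age/BMI coefficients per region.}
#'   \item{group}{TC, PTSD and sex-interaction coefficients per region
#'     (healthy-control males as reference).}
#'   \item{symptom}{13 separate single-cluster models (CAPS total, 4 DSM-5
#'     clusters, 8 factor-model clusters) on whole-brain V_T.}
#' }
#' A failing fit marks its cells failed and the suite continues.
#'
#' @param cohort Cohort data.frame (see [generate_cohort()] or the pipeline's
#'   estimated-V_T records).
#' @param regions Regions for the confound and group families.
#' @param symptom_region Outcome region for the symptom family.
#' @param draws,tune,chains,seed,nu_prior Passed to [fit_model()].
#' @return Object of class \code{model_suite}: list with data.frames
#'   \code{confounds}, \code{group}, \code{symptom}.
#' @export
run_model_suite <- function(cohort,
                            regions = c("amygdala", "hippocampus", "frontal",
                                        "whole_brain"),
                            symptom_region = "whole_brain",
                            draws = 1000, tune = 1000, chains = 4, seed = 1,
                            nu_prior = "invgamma") {
  fit_one <- function(recipe, region, cluster = NULL) {
    design <- build_design(cohort, recipe, region = region, cluster = cluster)
    fit_model(design, draws = draws, tune = tune, chains = chains,
              seed = seed, nu_prior = nu_prior)
  }
  confounds <- list(); group <- list(); symptom <- list()

  for (r in regions) {
    fit <- tryCatch(suppressWarnings(fit_one("confounds", r)),
                    error = function(e) {
                      message("confound model failed for ", r, ": ",
                              conditionMessage(e)); NULL })
    rows <- if (is.null(fit))
      lapply(c("Sex", "Age", "BMI"), function(mm) failed_row(r, mm))
    else list(suite_row(fit, "sex", r, "Sex"),
              suite_row(fit, "age_z", r, "Age"),
              suite_row(fit, "bmi_z", r, "BMI"))
    confounds <- c(confounds, rows)

    gfit <- tryCatch(suppressWarnings(fit_one("group", r)),
                     error = function(e) {
                       message("group model failed for ", r, ": ",
                               conditionMessage(e)); NULL })
    grows <- if (is.null(gfit))
      lapply(c("TC", "PTSD", "Sex * TC", "Sex * PTSD"),
             function(mm) failed_row(r, mm))
    else list(suite_row(gfit, "tc", r, "TC"),
              suite_row(gfit, "ptsd", r, "PTSD"),
              suite_row(gfit, "tc_sex", r, "Sex * TC"),
              suite_row(gfit, "ptsd_sex", r, "Sex * PTSD"))
    group <- c(group, grows)
  }

  for (lab in names(symptom_model_set())) {
    cl <- symptom_model_set()[[lab]]
    sfit <- tryCatch(suppressWarnings(fit_one("symptom", symptom_region, cl)),
                     error = function(e) {
                       message("symptom model failed for ", lab, ": ",
                               conditionMessage(e)); NULL })
    symptom <- c(symptom, list(
      if (is.null(sfit)) failed_row(symptom_region, lab)
      else suite_row(sfit, cl, symptom_region, lab)))
  }
  structure(list(confounds = do.call(rbind, confounds),
                 group = do.call(rbind, group),
                 symptom = do.call(rbind, symptom)),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "model family ==\n")
    df <- x[[nm]]
    df[, 3:6] <- round(df[, 3:6], 4)
    print(df, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}
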