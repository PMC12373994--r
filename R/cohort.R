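#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults reproduce
#' the study-cohort structure: 19 chronic-PTSD subjects, 27 trauma-exposed
#' controls (TC) and 16 healthy controls (HC), with group-specific sex
#' ratios, age and body-mass-index distributions, and CAPS-5 severity for
#' the two trauma-exposed groups. True regional volumes of distribution
#' (V_T) are built as regional baseline + linear predictor effects +
#' heavy-tailed subject residual, so downstream regression stages have a
#' known ground truth.
#'
#' @param n_ptsd,n_tc,n_hc Group sizes (default 19 / 27 / 16).
#' @param p_male Named vector (hc, tc, ptsd): probability a subject is male.
#' @param age_mean,age_sd Named vectors (hc, tc, ptsd): age distribution, years.
#' @param bmi_mean,bmi_sd Named vectors (hc, tc, ptsd): BMI distribution, kg/m^2.
#' @param caps_mean,caps_sd Named vectors (tc, ptsd): CAPS-5 total severity.
#'   HC subjects carry no CAPS scores.
#' @param effect_sizes Named numeric vector mapping predictor names to slopes
#'   in V_T units per predictor unit. Recognised names: \code{group_tc},
#'   \code{group_ptsd}, \code{sex_female}, \code{age}, \code{bmi},
#'   \code{caps_total}, any DSM-5 cluster (\code{dsm5_b_intrusion},
#'   \code{dsm5_c_avoidance}, \code{dsm5_d_mood_cognition},
#'   \code{dsm5_e_arousal}) or 8-factor cluster (\code{c8_internal_intrusion},
#'   \code{c8_external_intrusion}, \code{c8_avoidance},
#'   \code{c8_negative_affect}, \code{c8_anhedonia}, \code{c8_externalizing},
#'   \code{c8_anxious_arousal}, \code{c8_dysphoric_arousal}). The default
#'   plants only an anhedonia/emotional-numbing effect of 0.014 V_T units
#'   per CAPS point.
#' @param baseline_vt Named vector of regional baseline V_T values.
#' @param residual_scale Scale of the subject-level Student-t (5 df) residual,
#'   V_T units. May be 0 for a noise-free cohort.
#' @param regional_scale SD of the independent Gaussian regional residual;
#'   \code{NULL} (default) means \code{residual_scale / 3}.
#' @param outlier_fraction Probability that a subject's residual is grossly
#'   contaminated (shifted by 5-10 residual scales); default 0.
#' @param cluster_cor Correlation between latent CAPS cluster scores.
#' @param lobe_weights Named weights used to form the whole-brain composite
#'   from the lobar/cerebellar columns (normalised internally).
#' @param seed Optional integer seed stored with the config.
#' @return An object of class \code{cohort_config}.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_ptsd = 19, n_tc = 27, n_hc = 16,
                          p_male = c(hc = 9 / 16, tc = 25 / 27, ptsd = 10 / 19),
                          age_mean = c(hc = 29.37, tc = 45.78, ptsd = 42.58),
                          age_sd = c(hc = 8.16, tc = 13.90, ptsd = 13.03),
                          bmi_mean = c(hc = 25.76, tc = 29.74, ptsd = 30.133),
                          bmi_sd = c(hc = 4.88, tc = 6.04, ptsd = 5.79),
                          caps_mean = c(tc = 8.72, ptsd = 38.42),
                          caps_sd = c(tc = 6.91, ptsd = 9.34),
                          effect_sizes = c(c8_anhedonia = 0.014),
                          baseline_vt = c(amygdala = 1.45, hippocampus = 1.30,
                                          frontal = 1.25, temporal = 1.30,
                                          parietal = 1.25, occipital = 1.20,
                                          cerebellum = 1.15),
                          residual_scale = 0.12,
                          regional_scale = NULL,
                          outlier_fraction = 0,
                          cluster_cor = 0.6,
                          lobe_weights = aal_lobe_weights(),
                          seed = NULL) {
  counts <- c(n_ptsd = n_ptsd, n_tc = n_tc, n_hc = n_hc)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("group sizes must be non-negative integers", call. = FALSE)
  if (any(p_male < 0 | p_male > 1))
    stop("sex probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(age_sd, bmi_sd, caps_sd) <= 0))
    stop("distribution SDs must be positive", call. = FALSE)
  if (residual_scale < 0)
    stop("residual_scale must be non-negative", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("outlier_fraction must lie in [0, 1]", call. = FALSE)
  if (is.null(regional_scale)) regional_scale <- residual_scale / 3
  for (nm in c("p_male", "age_mean", "age_sd", "bmi_mean", "bmi_sd")) {
    v <- get(nm)
    if (!all(c("hc", "tc", "ptsd") %in% names(v)))
      stop(nm, " must be named with hc, tc, ptsd", call. = FALSE)
  }
  if (!all(c("tc", "ptsd") %in% names(caps_mean)))
    stop("caps_mean/caps_sd must be named with tc, ptsd", call. = FALSE)
  structure(list(
    n_ptsd = n_ptsd, n_tc = n_tc, n_hc = n_hc,
    p_male = p_male, age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    caps_mean = caps_mean, caps_sd = caps_sd,
    effect_sizes = effect_sizes, baseline_vt = baseline_vt,
    residual_scale = residual_scale, regional_scale = regional_scale,
    outlier_fraction = outlier_fraction, cluster_cor = cluster_cor,
    lobe_weights = lobe_weights, seed = seed
  ), class = "cohort_config")
}

# Fixed share of the CAPS-5 total carried by each 8-factor cluster; used to
# set cluster means. DSM-5 clusters and the total are sums of these, so
# cluster/total consistency is exact by construction.
caps_cluster_weights <- function() {
  c(c8_internal_intrusion = 0.12, c8_external_intrusion = 0.08,
    c8_avoidance = 0.10, c8_negative_affect = 0.18,
    c8_anhedonia = 0.17, c8_externalizing = 0.08,
    c8_anxious_arousal = 0.13, c8_dysphoric_arousal = 0.14)
}

#' Names of the 8-factor and DSM-5 CAPS cluster columns
#' @return Named list with elements \code{c8}, \code{dsm5}.
#' @export
caps_cluster_names <- function() {
  list(c8 = names(caps_cluster_weights()),
       dsm5 = c("dsm5_b_intrusion", "dsm5_c_avoidance",
                "dsm5_d_mood_cognition", "dsm5_e_arousal"))
}

# Draw correlated, truncated, rounded 8-cluster CAPS scores whose sum has
# approximately the requested total mean/SD.
draw_caps_clusters <- function(n, total_mean, total_sd, rho) {
  w <- caps_cluster_weights()
  k <- length(w)
  # scale factor so that Var(sum of latent scores) matches total_sd^2
  denom <- sum(w^2) + 2 * rho * (sum(w)^2 - sum(w^2)) / 2
  s <- w * total_sd / sqrt(denom)
  R <- matrix(rho, k, k); diag(R) <- 1
  Sigma <- diag(s) %*% R %*% diag(s)
  z <- MASS::mvrnorm(n, mu = w * total_mean, Sigma = Sigma)
  if (n == 1) z <- matrix(z, nrow = 1)
  z <- pmax(round(z), 0)
  colnames(z) <- names(w)
  z
}

#' Generate a synthetic study cohort
#'
#' Draws demographics, CAPS-5 symptom scores and true regional V_T values
#' for a cohort configured by [cohort_config()]. The true V_T of subject i
#' in region r is
#' \deqn{V_{T,ir} = b_r + \sum_p \beta_p x_{ip} + u_i + e_{ir}}
#' with regional baseline b_r, configured linear effects, a shared
#' subject-level Student-t(5) residual u_i (optionally contaminated with
#' gross outliers) and an independent Gaussian regional residual e_ir. The
#' whole-brain column is the size-weighted composite of the lobar and
#' cerebellar columns.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; overrides \code{config$seed}. Identical
#'   config+seed give an identical cohort.
#' @return A data.frame with one row per subject: \code{id}, \code{group}
#'   (factor HC/TC/PTSD), \code{sex} (factor male/female), \code{age},
#'   \code{bmi}, \code{caps_total}, DSM-5 and 8-factor cluster columns
#'   (NA for HC), and \code{vt_<region>} columns including
#'   \code{vt_whole_brain}.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  n <- c(hc = config$n_hc, tc = config$n_tc, ptsd = config$n_ptsd)
  if (sum(n) == 0) stop("cohort is empty: all group sizes are zero", call. = FALSE)
  grp <- rep(c("HC", "TC", "PTSD"), times = n[c("hc", "tc", "ptsd")])
  key <- tolower(grp)
  N <- length(grp)

  male <- stats::rbinom(N, 1, config$p_male[key]) == 1
  age <- stats::rnorm(N, config$age_mean[key], config$age_sd[key])
  age <- pmax(age, 18)
  bmi <- stats::rnorm(N, config$bmi_mean[key], config$bmi_sd[key])
  bmi <- pmax(bmi, 15)

  cl8 <- matrix(NA_real_, N, 8, dimnames = list(NULL, caps_cluster_names()$c8))
  for (g in c("tc", "ptsd")) {
    idx <- which(key == g)
    if (length(idx))
      cl8[idx, ] <- draw_caps_clusters(length(idx), config$caps_mean[[g]],
                                       config$caps_sd[[g]], config$cluster_cor)
  }
  dsm5 <- cbind(
    dsm5_b_intrusion = cl8[, "c8_internal_intrusion"] + cl8[, "c8_external_intrusion"],
    dsm5_c_avoidance = cl8[, "c8_avoidance"],
    dsm5_d_mood_cognition = cl8[, "c8_negative_affect"] + cl8[, "c8_anhedonia"],
    dsm5_e_arousal = cl8[, "c8_externalizing"] + cl8[, "c8_anxious_arousal"] +
      cl8[, "c8_dysphoric_arousal"])
  caps_total <- rowSums(dsm5)

  rec <- data.frame(
    id = sprintf("S%03d", seq_len(N)),
    group = factor(grp, levels = c("HC", "TC", "PTSD")),
    sex = factor(ifelse(male, "male", "female"), levels = c("male", "female")),
    age = age, bmi = bmi, caps_total = caps_total,
    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(dsm5), as.data.frame(cl8))

  # linear predictor from the configured effects (absent CAPS treated as 0)
  predictors <- cbind(
    group_tc = as.numeric(grp == "TC"),
    group_ptsd = as.numeric(grp == "PTSD"),
    sex_female = as.numeric(!male),
    age = age, bmi = bmi,
    caps_total = ifelse(is.na(caps_total), 0, caps_total),
    ifelse(is.na(dsm5), 0, dsm5), ifelse(is.na(cl8), 0, cl8))
  eff <- config$effect_sizes
  unknown <- setdiff(names(eff), colnames(predictors))
  if (length(unknown))
    stop("unknown effect_sizes names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lin <- if (length(eff)) drop(predictors[, names(eff), drop = FALSE] %*% eff) else 0

  u <- if (config$residual_scale > 0)
    config$residual_scale * stats::rt(N, df = 5) else numeric(N)
  if (config$outlier_fraction > 0 && config$residual_scale > 0) {
    hit <- stats::runif(N) < config$outlier_fraction
    u[hit] <- u[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) *
      stats::runif(sum(hit), 5, 10) * config$residual_scale
  }

  regions <- names(config$baseline_vt)
  for (r in regions) {
    e <- if (config$regional_scale > 0)
      stats::rnorm(N, 0, config$regional_scale) else 0
    rec[[paste0("vt_", r)]] <- config$baseline_vt[[r]] + lin + u + e
  }
  w <- config$lobe_weights
  missing_lobes <- setdiff(names(w), regions)
  if (length(missing_lobes))
    stop("lobe_weights name regions absent from baseline_vt: ",
         paste(missing_lobes, collapse = ", "), call. = FALSE)
  wb <- as.matrix(rec[paste0("vt_", names(w))]) %*% (w / sum(w))
  rec$vt_whole_brain <- drop(wb)
  attr(rec, "seed") <- seed
  rec
}
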