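#' Synthetic subject model
#'
#' A latent-variable description of one participant, sufficient to drive the
#' detector-in-the-loop measurement: a latent reflex threshold with a
#' psychometric slope governing response probability, surface-EMG noise and
#' burst parameters, and a logistic 0--10 pain-rating model.
#'
#' @param latent_threshold_mA Latent reflex threshold (> 0), mA.
#' @param psychometric_slope_mA Logistic slope in mA; 0 gives a
#'   deterministic step at the threshold.
#' @param baseline_noise_sd_mV Baseline EMG noise SD, mV (> 0).
#' @param burst_gain Envelope peak of the reflex burst at threshold, in
#'   baseline-SD units; the peak grows linearly with the suprathreshold
#'   margin (see [simulate_emg_trace()]).
#' @param burst_latency_ms Mean burst latency post onset; must lie inside
#'   (90, 150) ms.
#' @param burst_latency_jitter_ms SD of the latency jitter.
#' @param rating_center_mA Intensity at which the expected rating is 5.
#' @param rating_width_mA Logistic width of the rating curve (> 0), mA.
#' @param rating_noise_sd SD of the additive rating noise, rating units.
#' @param group_label `"FM"` (fibromyalgia) or `"HC"` (healthy control).
#' @param covariates Named list of subject-level covariate numbers
#'   (age, BMI, HADS total, PDI, EQ-5D-VAS, ...).
#' @param id Optional subject identifier.
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(latent_threshold_mA,
                          psychometric_slope_mA = 0,
                          baseline_noise_sd_mV = 0.01,
                          burst_gain = 20,
                          burst_latency_ms = 120,
                          burst_latency_jitter_ms = 8,
                          rating_center_mA = latent_threshold_mA,
                          rating_width_mA = 3,
                          rating_noise_sd = 1,
                          group_label = c("HC", "FM"),
                          covariates = list(),
                          id = NA_character_) {
  group_label <- match.arg(group_label)
  if (latent_threshold_mA <= 0) stop("`latent_threshold_mA` must be positive")
  if (psychometric_slope_mA < 0) stop("`psychometric_slope_mA` must be >= 0")
  for (p in c(baseline_noise_sd_mV, burst_gain, rating_width_mA))
    if (p <= 0) stop("scale parameters must be strictly positive")
  if (burst_latency_ms <= 90 || burst_latency_ms >= 150)
    stop("`burst_latency_ms` must lie inside (90, 150) ms")
  structure(list(latent_threshold_mA = latent_threshold_mA,
                 psychometric_slope_mA = psychometric_slope_mA,
                 baseline_noise_sd_mV = baseline_noise_sd_mV,
                 burst_gain = burst_gain,
                 burst_latency_ms = burst_latency_ms,
                 burst_latency_jitter_ms = burst_latency_jitter_ms,
                 rating_center_mA = rating_center_mA,
                 rating_width_mA = rating_width_mA,
                 rating_noise_sd = rating_noise_sd,
                 group_label = group_label,
                 covariates = covariates,
                 id = id),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model> %s [%s] T = %.2f mA (slope %.2f), rating center %.2f mA\n",
              ifelse(is.na(x$id), "subject", x$id), x$group_label,
              x$latent_threshold_mA, x$psychometric_slope_mA, x$rating_center_mA))
  invisible(x)
}

#' Latent reflex response to one stimulus
#'
#' With slope 0 the subject responds deterministically whenever the
#' intensity reaches the latent threshold; otherwise the response is
#' Bernoulli with probability
#' `1 / (1 + exp(-(intensity - threshold) / slope))`.
#'
#' Uses R's global RNG stream; seed the session before calling.
#'
#' @param subject A [subject_model()].
#' @param intensity_mA Stimulus intensity (>= 0), mA.
#' @return Logical.
#' @export
respond <- function(subject, intensity_mA) {
  stopifnot(inherits(subject, "subject_model"))
  if (!is.numeric(intensity_mA) || intensity_mA < 0)
    stop("`intensity_mA` must be non-negative")
  s <- subject$psychometric_slope_mA
  if (s == 0) return(intensity_mA >= subject$latent_threshold_mA)
  p <- stats::plogis((intensity_mA - subject$latent_threshold_mA) / s)
  stats::runif(1) < p
}

#' Simulate a stimulus-locked EMG trace
#'
#' The trace spans -100 to +200 ms around the stimulus onset. Baseline
#' activity is zero-mean Gaussian noise with SD `baseline_noise_sd_mV`
#' throughout. When the subject responded, a reflex burst is added: a
#' Gaussian envelope centred at a jittered latency inside the 90--150 ms
#' response window, carrying an EMG-like 100 Hz oscillation phase-locked to
#' the envelope centre (crest at the centre), so the realised burst peak
#' equals the programmed envelope peak
#' `burst_gain * baseline_sd * (1 + max(0, I - T) / T)` up to sampling and
#' additive noise. Envelope centres jittered outside the window are clipped
#' back to its edge minus the envelope half-width.
#'
#' @param subject A [subject_model()].
#' @param intensity_mA Delivered intensity, mA.
#' @param responded Logical: did the latent reflex occur?
#' @param fs Sampling rate, Hz (>= 500).
#' @return An [emg_trace()] with onset 100 ms into the sweep.
#' @export
simulate_emg_trace <- function(subject, intensity_mA, responded, fs = 2000) {
  stopifnot(inherits(subject, "subject_model"), fs >= 500)
  pre_ms <- 100; post_ms <- 200
  n_pre <- round(pre_ms * fs / 1000)
  n_post <- round(post_ms * fs / 1000)
  n <- n_pre + n_post
  onset <- n_pre + 1L
  sd0 <- subject$baseline_noise_sd_mV
  x <- stats::rnorm(n, 0, sd0)
  if (isTRUE(responded)) {
    env_sd_ms <- 6  # envelope SD; burst spans ~25 ms
    lat <- subject$burst_latency_ms +
      stats::rnorm(1, 0, subject$burst_latency_jitter_ms)
    half_width <- 2 * env_sd_ms
    lat <- min(max(lat, 90 + half_width), 150 - half_width)
    t_ms <- ((seq_len(n) - onset) / fs) * 1000
    margin <- max(0, intensity_mA - subject$latent_threshold_mA) /
      subject$latent_threshold_mA
    amp <- subject$burst_gain * sd0 * (1 + margin)
    env <- exp(-(t_ms - lat)^2 / (2 * env_sd_ms^2))
    carrier <- cos(2 * pi * 100 * (t_ms - lat) / 1000)
    x <- x + amp * env * carrier
  }
  emg_trace(x, sampling_rate = fs, onset_index = onset)
}

#' Rate the painfulness of one stimulus on the 0--10 scale
#'
#' A rounded, noisy logistic in intensity:
#' `round(10 * plogis((I - center) / width) + N(0, noise))`, clipped to
#' 0..10. The expectation is non-decreasing in intensity; 4 is the
#' conventional liminal value for pain on this scale (metadata only, not
#' used in simulation logic).
#'
#' @param subject A [subject_model()].
#' @param intensity_mA Stimulus intensity (>= 0), mA.
#' @return Integer rating in 0..10.
#' @export
rate_pain <- function(subject, intensity_mA) {
  stopifnot(inherits(subject, "subject_model"))
  if (!is.numeric(intensity_mA) || intensity_mA < 0)
    stop("`intensity_mA` must be non-negative")
  mu <- 10 * stats::plogis((intensity_mA - subject$rating_center_mA) /
                             subject$rating_width_mA)
  r <- round(mu + stats::rnorm(1, 0, subject$rating_noise_sd))
  as.integer(min(10, max(0, r)))
}

#' Cohort specification
#'
#' Per-group sampling distributions for the synthetic cohort. Defaults are
#' calibrated to the study conditions the measurement was designed for:
#' 29 fibromyalgia (FM) and 21 healthy-control (HC) subjects, latent
#' reflex thresholds Normal(14.4, 6.4) mA in FM and Normal(14.7, 5.4) mA
#' in HC (truncated to the operable 0.5--29.5 mA range), rating-curve
#' centres shifted lower in FM so patients rate matched intensities as
#' more painful (ordinal medians near 7 vs 5), and covariate means/SDs
#' matching the groups' clinical characteristics. `rating_threshold_rho`
#' links the latent threshold and the rating centre within a group through
#' a Gaussian copula.
#'
#' @param n_fm,n_hc Group sizes.
#' @param fm,hc Named lists overriding group parameter entries:
#'   `threshold_mean`, `threshold_sd`, `rating_center_offset_mA` (rating
#'   centre = offset + copula-correlated normal deviate around the group
#'   threshold mean), `rating_center_sd`, `rating_width_mA`,
#'   `rating_noise_sd`, `rating_threshold_rho`, `psychometric_slope_mA`,
#'   `covariate_means`, `covariate_sds`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_fm = 29L, n_hc = 21L, fm = list(), hc = list()) {
  if (n_fm < 1L || n_hc < 1L) stop("group sizes must be at least 1")
  defaults <- list(
    FM = list(threshold_mean = 14.4, threshold_sd = 6.4,
              rating_center_offset_mA = -8, rating_center_sd = 3,
              rating_width_mA = 2.5, rating_noise_sd = 1,
              rating_threshold_rho = 0.5, psychometric_slope_mA = 0,
              covariate_means = c(age = 38.9, height_m = 1.65, weight_kg = 81.2,
                                  bp_systolic = 122, bp_diastolic = 81,
                                  current_pain = 5.5, hads_total = 13.3,
                                  pdi = 37.3, eq5d_vas = 52.7),
              covariate_sds = c(age = 11.7, height_m = 0.06, weight_kg = 19.8,
                                bp_systolic = 12.8, bp_diastolic = 10.8,
                                current_pain = 2.1, hads_total = 6.5,
                                pdi = 11.3, eq5d_vas = 19.7)),
    HC = list(threshold_mean = 14.7, threshold_sd = 5.4,
              rating_center_offset_mA = -4, rating_center_sd = 3,
              rating_width_mA = 2.5, rating_noise_sd = 1,
              rating_threshold_rho = 0, psychometric_slope_mA = 0,
              covariate_means = c(age = 41.2, height_m = 1.69, weight_kg = 69.4,
                                  bp_systolic = 114, bp_diastolic = 76,
                                  current_pain = 0, hads_total = 3.8,
                                  pdi = 7.8, eq5d_vas = 86.3),
              covariate_sds = c(age = 11.0, height_m = 0.06, weight_kg = 11.8,
                                bp_systolic = 8.0, bp_diastolic = 8.4,
                                current_pain = 0, hads_total = 3.4,
                                pdi = 2.0, eq5d_vas = 6.4)))
  defaults$FM[names(fm)] <- fm
  defaults$HC[names(hc)] <- hc
  for (g in c("FM", "HC")) {
    p <- defaults[[g]]
    if (p$threshold_sd <= 0 || p$rating_center_sd <= 0)
      stop("distribution SDs must be positive")
    if (abs(p$rating_threshold_rho) > 1)
      stop("`rating_threshold_rho` must lie in [-1, 1]")
  }
  structure(list(n_fm = as.integer(n_fm), n_hc = as.integer(n_hc),
                 groups = defaults,
                 trunc_range_mA = c(0.5, 29.5)),
            class = "cohort_spec")
}

# inverse-CDF draw from Normal(mean, sd) truncated to [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-6)
    stop("degenerate truncation: distribution has negligible mass in range")
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws latent thresholds from each group's truncated normal, rating-curve
#' centres correlated with the threshold through a Gaussian copula at the
#' group's `rating_threshold_rho`, and subject covariates from independent
#' normals (non-negative scores clipped at 0). Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List of [subject_model()]s, FM subjects first.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  lo <- spec$trunc_range_mA[1]; hi <- spec$trunc_range_mA[2]
  out <- list()
  for (g in c("FM", "HC")) {
    p <- spec$groups[[g]]
    n <- if (g == "FM") spec$n_fm else spec$n_hc
    p_lo <- stats::pnorm(lo, p$threshold_mean, p$threshold_sd)
    p_hi <- stats::pnorm(hi, p$threshold_mean, p$threshold_sd)
    if (p_hi - p_lo < 1e-6)
      stop("degenerate truncation: threshold distribution for ", g,
           " has negligible mass in the operable range")
    z1 <- stats::rnorm(n)  # threshold copula margin
    thr <- stats::qnorm(p_lo + stats::pnorm(z1) * (p_hi - p_lo),
                        p$threshold_mean, p$threshold_sd)
    rho <- p$rating_threshold_rho
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    center <- p$threshold_mean + p$rating_center_offset_mA +
      p$rating_center_sd * z2
    for (i in seq_len(n)) {
      covs <- as.list(p$covariate_means +
                        p$covariate_sds * stats::rnorm(length(p$covariate_means)))
      names(covs) <- names(p$covariate_means)
      for (k in setdiff(names(covs), c("height_m")))
        covs[[k]] <- max(0, covs[[k]])
      covs$bmi <- covs$weight_kg / covs$height_m^2
      out[[length(out) + 1L]] <- subject_model(
        latent_threshold_mA = thr[i],
        psychometric_slope_mA = p$psychometric_slope_mA,
        rating_center_mA = center[i],
        rating_width_mA = p$rating_width_mA,
        rating_noise_sd = p$rating_noise_sd,
        group_label = g,
        covariates = covs,
        id = sprintf("%s%02d", g, i))
    }
  }
  out
}
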