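#' Stimulus train parameters
#'
#' The electrical stimulus is a train of square-wave pulses delivered at
#' jittered inter-stimulus intervals; these parameters are recorded in
#' session logs (they do not alter the staircase logic).
#'
#' @param n_pulses Pulses per train (default 5).
#' @param pulse_width_ms Pulse width, ms (default 1).
#' @param frequency_hz Intra-train pulse rate, Hz (default 200).
#' @param isi_range_s Inter-stimulus interval range, s (default `c(8, 12)`).
#' @return An object of class `stimulus_train`.
#' @export
stimulus_train <- function(n_pulses = 5L, pulse_width_ms = 1,
                           frequency_hz = 200, isi_range_s = c(8, 12)) {
  stopifnot(n_pulses >= 1L, isi_range_s[1] < isi_range_s[2])
  structure(list(n_pulses = as.integer(n_pulses),
                 pulse_width_ms = pulse_width_ms,
                 frequency_hz = frequency_hz,
                 isi_range_s = as.numeric(isi_range_s)),
            class = "stimulus_train")
}

# deterministic 32-bit mix of master seed and stream ordinal; stays < 2^31
derive_seed <- function(master_seed, ordinal) {
  s <- (as.numeric(master_seed) %% 2147483647) + 1
  for (k in seq_len(2)) {
    s <- (s * 48271 + as.numeric(ordinal) * 2654435761) %% 2147483647
  }
  as.integer(s)
}

#' Run one measurement session on a simulated subject
#'
#' Closes the loop the measurement relies on: at each staircase intensity a
#' latent reflex is drawn ([respond()]), a stimulus-locked EMG trace is
#' simulated ([simulate_emg_trace()]), the detector's Z-score verdict
#' ([detect_reflex()]) drives [staircase_advance()], and a pain rating
#' ([rate_pain()]) is logged. Simulated stimulus times carry uniform 8--12 s
#' jitter. Fully reproducible from `seed`.
#'
#' @param subject A [subject_model()].
#' @param limb `"first"` or `"second"`.
#' @param seed Integer seed for this session.
#' @param detection A [detection_config()].
#' @param staircase A [staircase_config()].
#' @param train A [stimulus_train()].
#' @param fs Sampling rate of the simulated EMG, Hz.
#' @return An object of class `session_record`: subject id, limb, seed,
#'   stimulus log (data frame: ordinal, time_s, intensity_mA, z_score,
#'   is_response, rating), the `threshold_result`, and the mean rating.
#' @export
run_session <- function(subject, limb = c("first", "second"), seed = 1L,
                        detection = detection_config(),
                        staircase = staircase_config(),
                        train = stimulus_train(), fs = 2000) {
  limb <- match.arg(limb)
  set.seed(as.integer(seed))
  sim_time <- 0
  responder <- function(i_mA) {
    sim_time <<- sim_time + stats::runif(1, train$isi_range_s[1], train$isi_range_s[2])
    hit <- respond(subject, i_mA)
    tr <- simulate_emg_trace(subject, i_mA, hit, fs = fs)
    det <- detect_reflex(tr, detection)
    list(response = det$is_response,
         rating = rate_pain(subject, i_mA),
         z_score = det$z_score,
         time_s = sim_time)
  }
  times <- numeric(0)
  wrapped <- function(i_mA) {
    out <- responder(i_mA)
    times[length(times) + 1L] <<- out$time_s
    out
  }
  res <- run_staircase(wrapped, staircase)
  log <- res$history
  log$ordinal <- seq_len(nrow(log))
  log$time_s <- times[seq_len(nrow(log))]
  log <- log[, c("ordinal", "time_s", "intensity_mA", "z_score",
                 "is_response", "rating")]
  structure(list(subject_id = subject$id,
                 group = subject$group_label,
                 limb = limb,
                 seed = as.integer(seed),
                 stimulus_log = log,
                 result = res,
                 mean_rating = if (nrow(log)) mean(log$rating) else NA_real_),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s (%s limb, seed %d): %d stimuli, status %s, threshold %s mA, mean rating %.2f\n",
              x$subject_id, x$limb, x$seed, nrow(x$stimulus_log),
              x$result$status,
              if (is.na(x$result$threshold_mA)) "-" else
                format(round(x$result$threshold_mA, 4)),
              x$mean_rating))
  invisible(x)
}

#' Serialize a session record to the versioned JSON schema
#'
#' Sessions are written under the `nwr-session-1` schema (shipped at
#' `system.file("extdata", "nwr-session-1.schema.json", package =
#' "nwreflex")`).
#'
#' @param session A `session_record`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_json <- function(session, path) {
  stopifnot(inherits(session, "session_record"))
  obj <- list(
    schema = "nwr-session-1",
    subject_id = session$subject_id,
    group = session$group,
    limb = session$limb,
    seed = session$seed,
    stimuli = session$stimulus_log,
    status = session$result$status,
    success_intensities_mA = session$result$success_intensities_mA,
    threshold_mA = session$result$threshold_mA,
    mean_rating = session$mean_rating)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Validate a session JSON against the shipped schema
#'
#' Checks the schema tag, required fields, field types and the per-stimulus
#' record structure declared in `nwr-session-1.schema.json`.
#'
#' @param path Path to a session JSON.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- jsonlite::read_json(
    system.file("extdata", "nwr-session-1.schema.json", package = "nwreflex"),
    simplifyVector = TRUE)
  if (!identical(obj$schema, schema$schema))
    stop("session schema tag is not ", schema$schema)
  for (f in schema$required)
    if (is.null(obj[[f]]) && !(f %in% schema$nullable))
      stop("session JSON missing required field `", f, "`")
  if (length(obj$stimuli)) {
    for (f in schema$stimulus_fields)
      if (!f %in% names(obj$stimuli))
        stop("stimulus log missing field `", f, "`")
    if (is.unsorted(obj$stimuli$time_s, strictly = TRUE))
      stop("stimulus times must be strictly increasing")
  }
  if (!obj$status %in% schema$statuses) stop("unknown status ", obj$status)
  invisible(TRUE)
}

#' Experiment configuration
#'
#' Everything needed to simulate a full bilateral two-group study: the
#' cohort specification, detector and staircase settings, per-group
#' per-limb dropout probabilities, and the master seed from which all
#' per-session seeds are derived.
#'
#' Dropout defaults mirror a realistic attrition pattern: a small
#' probability of not completing the first limb and a larger one of
#' stopping after it, higher in patients.
#'
#' @param cohort A [cohort_spec()].
#' @param detection A [detection_config()].
#' @param staircase A [staircase_config()].
#' @param train A [stimulus_train()].
#' @param fs EMG sampling rate, Hz.
#' @param dropout Named list of per-limb dropout probabilities:
#'   `fm_limb1`, `fm_limb2`, `hc_limb1`, `hc_limb2`.
#' @param master_seed Integer master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              detection = detection_config(),
                              staircase = staircase_config(),
                              train = stimulus_train(),
                              fs = 2000,
                              dropout = list(fm_limb1 = 1 / 32, fm_limb2 = 5 / 32,
                                             hc_limb1 = 0, hc_limb2 = 1 / 29),
                              master_seed = 1L) {
  stopifnot(all(unlist(dropout) >= 0), all(unlist(dropout) <= 1))
  structure(list(cohort = cohort, detection = detection,
                 staircase = staircase, train = train, fs = fs,
                 dropout = dropout, master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Simulate a complete two-group bilateral experiment
#'
#' Generates the cohort, runs first- and second-limb sessions per subject
#' (each limb independently skipped with its group's dropout probability),
#' assembles the per-subject cohort table with the bilateral averaging rule
#' (the subject's threshold and rating are the means over the limbs that
#' were measured), and runs the group analysis. Per-session seeds are
#' derived deterministically from the master seed, so the whole experiment
#' is reproducible.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, writes `cohort.csv`,
#'   `report.json` and per-session JSONs under `sessions/`.
#' @return List: `cohort_table` (data frame, one row per subject),
#'   `sessions` (list of `session_record`), `report` (see
#'   [analyze_cohort()]).
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "sessions"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  }
  subjects <- generate_cohort(config$cohort,
                              seed = derive_seed(config$master_seed, 0))
  sessions <- list()
  rows <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    gkey <- tolower(sub$group_label)
    limb_rec <- list(first = NULL, second = NULL)
    for (li in 1:2) {
      limb <- c("first", "second")[li]
      seed_d <- derive_seed(config$master_seed, si * 4L + li)
      set.seed(seed_d)
      dropped <- stats::runif(1) < config$dropout[[paste0(gkey, "_limb", li)]]
      if (dropped) next
      rec <- run_session(sub, limb = limb,
                         seed = derive_seed(config$master_seed, si * 4L + li + 2L),
                         detection = config$detection,
                         staircase = config$staircase,
                         train = config$train, fs = config$fs)
      sessions[[length(sessions) + 1L]] <- rec
      limb_rec[[limb]] <- rec
    }
    thr <- c(first = NA_real_, second = NA_real_)
    rat <- c(first = NA_real_, second = NA_real_)
    for (limb in c("first", "second")) {
      r <- limb_rec[[limb]]
      if (!is.null(r) && r$result$status == "OK") thr[[limb]] <- r$result$threshold_mA
      if (!is.null(r)) rat[[limb]] <- r$mean_rating
    }
    covs <- sub$covariates
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sub$id, group = sub$group_label,
      threshold_limb1_mA = thr[["first"]], threshold_limb2_mA = thr[["second"]],
      subject_threshold_mA = if (all(is.na(thr))) NA_real_ else mean(thr, na.rm = TRUE),
      rating_limb1 = rat[["first"]], rating_limb2 = rat[["second"]],
      subject_rating = if (all(is.na(rat))) NA_real_ else mean(rat, na.rm = TRUE),
      age = covs$age, height_m = covs$height_m, weight_kg = covs$weight_kg,
      bmi = covs$bmi, bp_systolic = covs$bp_systolic,
      bp_diastolic = covs$bp_diastolic, current_pain = covs$current_pain,
      hads_total = covs$hads_total, pdi = covs$pdi, eq5d_vas = covs$eq5d_vas)
  }
  cohort_table <- do.call(rbind, rows)
  report <- analyze_cohort(cohort_table)
  if (!is.null(out_dir)) {
    write_cohort_csv(cohort_table, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (s in sessions)
      write_session_json(s, file.path(out_dir, "sessions",
                                      sprintf("%s_%s.json", s$subject_id, s$limb)))
  }
  list(cohort_table = cohort_table, sessions = sessions, report = report)
}

#' Group analysis of a per-subject cohort table
#'
#' Computes, per group, summaries of the covariates and the measured
#' reflex threshold (mean, t-based 95% CI, SD, median, IQR) with pooled
#' t-tests for between-group differences (Levene's test reported
#' alongside), the Mann-Whitney comparison of the subjective pain ratings,
#' Spearman correlations between threshold and rating (per group and
#' overall), and the bilateral subset's limb comparison: per-limb
#' summaries, per-subject percent change, between-group pooled t on the
#' percent changes, and within-group paired t / Wilcoxon signed-rank tests.
#'
#' @param cohort_table Data frame as produced by [run_experiment()] or
#'   [read_cohort_csv()].
#' @return A nested list shaped like the study's summary tables.
#' @export
analyze_cohort <- function(cohort_table) {
  ct <- cohort_table
  stopifnot(all(c("group", "subject_threshold_mA", "subject_rating") %in% names(ct)))
  fm <- ct[ct$group == "FM", , drop = FALSE]
  hc <- ct[ct$group == "HC", , drop = FALSE]
  covariate_cols <- intersect(
    c("age", "height_m", "weight_kg", "bmi", "bp_systolic", "bp_diastolic",
      "current_pain", "hads_total", "pdi", "eq5d_vas"), names(ct))

  summarize_pair <- function(col) {
    a <- fm[[col]]; b <- hc[[col]]
    res <- list(fm = tryCatch(unclass(describe_sample(a)), error = function(e) NULL),
                hc = tryCatch(unclass(describe_sample(b)), error = function(e) NULL))
    res$t_test <- tryCatch(two_sample_t(a, b), error = function(e) NULL)
    res$levene <- tryCatch({
      keep <- !is.na(ct[[col]])
      lv <- suppressWarnings(
        car::leveneTest(ct[[col]][keep] ~ factor(ct$group[keep])))
      list(F = lv$`F value`[1], p = lv$`Pr(>F)`[1])
    }, error = function(e) NULL)
    res$normality <- list(
      fm = tryCatch(normality_flag(a), error = function(e) NULL),
      hc = tryCatch(normality_flag(b), error = function(e) NULL))
    res
  }

  characteristics <- lapply(stats::setNames(covariate_cols, covariate_cols),
                            summarize_pair)
  thresholds <- summarize_pair("subject_threshold_mA")
  ratings <- list(
    fm = tryCatch(unclass(describe_sample(fm$subject_rating)),
                  error = function(e) NULL),
    hc = tryCatch(unclass(describe_sample(hc$subject_rating)),
                  error = function(e) NULL),
    mann_whitney = tryCatch(
      mann_whitney_u(fm$subject_rating[!is.na(fm$subject_rating)],
                     hc$subject_rating[!is.na(hc$subject_rating)]),
      error = function(e) NULL))
  corr <- function(d) tryCatch(
    spearman_rho(d$subject_threshold_mA, d$subject_rating),
    error = function(e) NULL)
  correlations <- list(fm = corr(fm), hc = corr(hc), all = corr(ct))

  limb_block <- function(d) {
    bi <- d[!is.na(d$threshold_limb1_mA) & !is.na(d$threshold_limb2_mA), ,
            drop = FALSE]
    if (nrow(bi) < 2L) return(list(n = nrow(bi)))
    pc_thr <- percent_change(bi$threshold_limb1_mA, bi$threshold_limb2_mA)
    pc_rat <- tryCatch(percent_change(bi$rating_limb1, bi$rating_limb2),
                       error = function(e) NULL)
    list(n = nrow(bi),
         limb1 = unclass(describe_sample(bi$threshold_limb1_mA)),
         limb2 = unclass(describe_sample(bi$threshold_limb2_mA)),
         percent_change = unclass(describe_sample(pc_thr)),
         percent_change_rating = if (is.null(pc_rat)) NULL else
           unclass(describe_sample(pc_rat)),
         paired = tryCatch(paired_tests(bi$threshold_limb1_mA,
                                        bi$threshold_limb2_mA),
                           error = function(e) NULL))
  }
  limbs <- list(fm = limb_block(fm), hc = limb_block(hc))
  pc_t <- tryCatch({
    bif <- fm[!is.na(fm$threshold_limb1_mA) & !is.na(fm$threshold_limb2_mA), ]
    bih <- hc[!is.na(hc$threshold_limb1_mA) & !is.na(hc$threshold_limb2_mA), ]
    two_sample_t(percent_change(bif$threshold_limb1_mA, bif$threshold_limb2_mA),
                 percent_change(bih$threshold_limb1_mA, bih$threshold_limb2_mA))
  }, error = function(e) NULL)

  list(n = list(fm = nrow(fm), hc = nrow(hc)),
       characteristics = characteristics,
       thresholds = thresholds,
       ratings = ratings,
       correlations = correlations,
       limb_comparison = c(limbs, list(percent_change_t = pc_t)))
}

#' Write / read the per-subject cohort table as CSV
#'
#' The canonical on-disk form is a long-format CSV with one row per
#' measured limb (`subject_id, group, limb, threshold_mA, mean_rating,`
#' covariates); missing values are empty fields. [read_cohort_csv()]
#' rebuilds the wide per-subject table, applying the bilateral averaging
#' rule (a subject with one measured limb keeps that limb's values).
#' Unknown columns are preserved. Writing then reading a table is the
#' identity on its canonical form.
#'
#' @param cohort_table Wide per-subject data frame (see [run_experiment()]).
#' @param path CSV path.
#' @return `read_cohort_csv`: the wide data frame; `write_cohort_csv`:
#'   `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort_table, path) {
  ct <- cohort_table
  covariate_cols <- setdiff(names(ct),
                            c("subject_id", "group", "threshold_limb1_mA",
                              "threshold_limb2_mA", "subject_threshold_mA",
                              "rating_limb1", "rating_limb2", "subject_rating"))
  long <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
    r <- ct[i, ]
    do.call(rbind, lapply(1:2, function(li) {
      cbind(data.frame(subject_id = r$subject_id, group = r$group,
                       limb = c("first", "second")[li],
                       threshold_mA = r[[paste0("threshold_limb", li, "_mA")]],
                       mean_rating = r[[paste0("rating_limb", li)]]),
            r[covariate_cols])
    }))
  }))
  # a limb with neither threshold nor rating was not measured: drop its row
  measured <- !(is.na(long$threshold_mA) & is.na(long$mean_rating))
  utils::write.csv(long[measured, ], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  long <- utils::read.csv(path, na.strings = "")
  req <- c("subject_id", "group", "limb", "threshold_mA", "mean_rating")
  missing_cols <- setdiff(req, names(long))
  if (length(missing_cols))
    stop("cohort CSV missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("threshold_mA", "mean_rating")) {
    bad <- !is.na(long[[col]]) & is.na(suppressWarnings(as.numeric(long[[col]])))
    if (any(bad))
      stop(sprintf("non-numeric `%s` at line %d of %s",
                   col, which(bad)[1] + 1L, path))
    long[[col]] <- as.numeric(long[[col]])
  }
  if (!all(long$limb %in% c("first", "second")))
    stop("`limb` must be 'first' or 'second'")
  covariate_cols <- setdiff(names(long), req)
  rows <- lapply(split(long, long$subject_id), function(d) {
    get_limb <- function(limb, col) {
      v <- d[[col]][d$limb == limb]
      if (length(v)) v[1] else NA_real_
    }
    thr <- c(get_limb("first", "threshold_mA"), get_limb("second", "threshold_mA"))
    rat <- c(get_limb("first", "mean_rating"), get_limb("second", "mean_rating"))
    base <- data.frame(
      subject_id = d$subject_id[1], group = d$group[1],
      threshold_limb1_mA = thr[1], threshold_limb2_mA = thr[2],
      subject_threshold_mA = if (all(is.na(thr))) NA_real_ else mean(thr, na.rm = TRUE),
      rating_limb1 = rat[1], rating_limb2 = rat[2],
      subject_rating = if (all(is.na(rat))) NA_real_ else mean(rat, na.rm = TRUE))
    cbind(base, d[1, covariate_cols, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}
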