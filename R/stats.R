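#' @title Workload correlation statistics and pipeline
#' @description Assembles the per-session metric table, correlates every
#'   physiological metric with the pilot-inceptor-workload baseline via
#'   Pearson and repeated-measures correlation, and computes inter-pilot
#'   variability.
#' @name workload-stats
NULL

# the physiological metrics correlated against PIW, report order
.PHYSIO_METRICS <- c("stddev_pd_left", "stddev_pd_right", "fixation_rate",
                     "mean_fixation_duration", "nni", "tli", "tei")

#' All cognitive-load metrics for one session
#'
#' Runs the ocular, EEG and inceptor metric computations for a single
#' session; a failed stream yields flagged-missing (`NA`) cells for its
#' metrics, never silent zeros.
#'
#' @param session A `session_data` list.
#' @param tei_montage TEI montage name or electrode vector.
#' @return One-row data frame: participant, condition, the seven
#'   physiological metrics, duty_cycle, aggressiveness, piw.
#' @export
session_metrics <- function(session, tei_montage = "frontal_f") {
  oc <- tryCatch(ocular_metrics(session), error = function(e) {
    warning("ocular metrics failed for session (", session$participant, ",",
            session$condition, "): ", conditionMessage(e), call. = FALSE)
    list(stddev_pd_left = NA_real_, stddev_pd_right = NA_real_,
         fixation_rate = NA_real_, mean_fixation_duration = NA_real_,
         nni = NA_real_)
  })
  ee <- tryCatch(eeg_metrics(session, tei_montage), error = function(e) {
    warning("EEG metrics failed for session (", session$participant, ",",
            session$condition, "): ", conditionMessage(e), call. = FALSE)
    list(tli = NA_real_, tei = NA_real_, tei_montage = NA_character_)
  })
  ic <- tryCatch(inceptor_metrics(session), error = function(e) {
    warning("inceptor metrics failed for session (", session$participant,
            ",", session$condition, "): ", conditionMessage(e), call. = FALSE)
    list(duty_cycle = NA_real_, aggressiveness = NA_real_, piw = NA_real_)
  })
  data.frame(participant = session$participant,
             condition = session$condition,
             stddev_pd_left = oc$stddev_pd_left,
             stddev_pd_right = oc$stddev_pd_right,
             fixation_rate = oc$fixation_rate,
             mean_fixation_duration = oc$mean_fixation_duration,
             nni = oc$nni,
             tli = ee$tli, tei = ee$tei,
             duty_cycle = ic$duty_cycle,
             aggressiveness = ic$aggressiveness,
             piw = ic$piw)
}

#' Build the participant-by-condition metric table
#'
#' One row per session (participant x condition); duplicate cells are an
#' error.
#'
#' @param sessions A `study_data` object or a list of `session_data`.
#' @param tei_montage TEI montage passed through to [session_metrics()].
#' @return Data frame of class `metric_table`.
#' @export
build_metric_table <- function(sessions, tei_montage = "frontal_f") {
  if (inherits(sessions, "study_data")) sessions <- sessions$sessions
  rows <- lapply(sessions, session_metrics, tei_montage = tei_montage)
  tab <- do.call(rbind, rows)
  key <- paste(tab$participant, tab$condition)
  if (anyDuplicated(key))
    stop("duplicate (participant, condition) cell(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  tab <- tab[order(tab$participant, tab$condition), ]
  rownames(tab) <- NULL
  class(tab) <- c("metric_table", "data.frame")
  tab
}

#' Pearson product-moment correlation
#'
#' Pairwise-complete Pearson correlation with the degrees of freedom
#' reported as n - 2 and a two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs dropped.
#' @return List `r`, `df`, `p`, `n`. Zero variance in either variable
#'   yields `r = NA` (flagged undefined).
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, df = n - 2L, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, n = n)
}

#' Repeated-measures correlation
#'
#' Common within-subject association estimated by analysis of covariance:
#' a linear model with one intercept per subject and a shared slope for
#' `x`. The coefficient is
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, where `SS_x` is
#' the sum of squares attributable to `x` after the subject intercepts
#' (on a balanced design this equals the Type-III SS), with
#' `df = N_obs - k_subjects - 1` and an F-based p-value. Between-subject
#' offsets in `y` do not inflate the coefficient. Subjects with fewer than
#' two complete observations are dropped with a warning.
#'
#' @param subject Subject identifiers (coerced to factor).
#' @param x,y Numeric vectors.
#' @return List `r_rm`, `df`, `p`, `n_obs`, `n_subjects`, `slope`.
#' @export
rmcorr <- function(subject, x, y) {
  ok <- is.finite(x) & is.finite(y) & !is.na(subject)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  counts <- table(subject)
  few <- names(counts)[counts < 2]
  if (length(few)) {
    warning("dropping subject(s) with < 2 observations: ",
            paste(few, collapse = ", "), call. = FALSE)
    keep <- !(subject %in% few)
    subject <- droplevels(subject[keep]); x <- x[keep]; y <- y[keep]
  }
  k <- nlevels(subject)
  n <- length(x)
  if (k < 2) stop("rmcorr needs at least 2 subjects")
  full <- stats::lm(y ~ subject + x)
  red <- stats::lm(y ~ subject)
  ss_err <- sum(stats::residuals(full)^2)
  ss_x <- sum(stats::residuals(red)^2) - ss_err
  df <- n - k - 1L
  if (df < 1) stop("not enough observations for rmcorr (df < 1)")
  slope <- unname(stats::coef(full)[["x"]])
  if (ss_x + ss_err <= 0 || !is.finite(slope))
    return(list(r_rm = NA_real_, df = df, p = NA_real_,
                n_obs = n, n_subjects = k, slope = slope))
  r_rm <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  Fstat <- ss_x / (ss_err / df)
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  list(r_rm = r_rm, df = df, p = p, n_obs = n, n_subjects = k, slope = slope)
}

#' Correlate every physiological metric with PIW
#'
#' Produces the study's comparison table: for each of the seven
#' physiological cognitive-load metrics (left/right low-frequency pupil
#' variability, fixation rate, mean fixation duration, NNI, TLI, TEI), the
#' Pearson coefficient against PIW and the repeated-measures coefficient,
#' with their degrees of freedom and p-values. Missing cells are dropped
#' pairwise per metric; no multiple-testing correction is applied
#' (p-values are descriptive).
#'
#' @param tab A `metric_table`.
#' @param exclude_nni_below Optional flagged exclusion: drop metric-table
#'   rows whose NNI falls below this value before correlating NNI (an
#'   explicit outlier rule, never automatic; default `NULL` = keep all).
#' @return Data frame: metric, r, df, p, r_rm, df_rm, p_rm, n.
#' @export
correlate_with_piw <- function(tab, exclude_nni_below = NULL) {
  stopifnot(is.data.frame(tab), "piw" %in% names(tab))
  rows <- lapply(.PHYSIO_METRICS, function(m) {
    v <- tab[[m]]
    pw <- tab$piw
    sub <- tab$participant
    if (m == "nni" && !is.null(exclude_nni_below)) {
      keep <- is.na(v) | v >= exclude_nni_below
      v <- v[keep]; pw <- pw[keep]; sub <- sub[keep]
    }
    pr <- pearson(v, pw)
    rm <- rmcorr(sub, v, pw)
    data.frame(metric = m, r = pr$r, df = pr$df, p = pr$p,
               r_rm = rm$r_rm, df_rm = rm$df, p_rm = rm$p, n = pr$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-pilot variability of the cognitive-load metrics
#'
#' Sample standard deviation of each metric across the conditions flown by
#' each participant. Participants with a single condition get `NA`.
#'
#' @param tab A `metric_table`.
#' @param metrics Metric columns to summarise (default: the seven
#'   physiological metrics plus PIW).
#' @return Data frame: one row per participant, one column per metric.
#' @export
pilot_variability <- function(tab, metrics = c(.PHYSIO_METRICS, "piw")) {
  stopifnot(is.data.frame(tab))
  parts <- sort(unique(tab$participant))
  out <- data.frame(participant = parts)
  for (m in metrics) {
    out[[m]] <- vapply(parts, function(p) {
      v <- tab[[m]][tab$participant == p]
      v <- v[is.finite(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v)
    }, numeric(1))
  }
  out
}

#' Render the comparison table as fixed-width text
#'
#' @param ct Output of [correlate_with_piw()].
#' @return Character vector of report lines.
#' @export
format_correlation_report <- function(ct) {
  fmt <- function(x, d = 3) ifelse(is.na(x), "NA", formatC(x, digits = d, format = "f"))
  header <- sprintf("%-24s %8s %4s %9s %8s %6s %9s",
                    "Cognitive load metric", "r", "df", "p", "r_rm",
                    "df_rm", "p_rm")
  lines <- vapply(seq_len(nrow(ct)), function(i) {
    sprintf("%-24s %8s %4d %9s %8s %6d %9s",
            ct$metric[i], fmt(ct$r[i]), ct$df[i], fmt(ct$p[i], 4),
            fmt(ct$r_rm[i]), ct$df_rm[i], fmt(ct$p_rm[i], 4))
  }, character(1))
  c(header, strrep("-", nchar(header)), lines)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Generates (or loads) a study, computes the metric table, correlates
#' every physiological metric against PIW (Pearson + repeated-measures),
#' and computes inter-pilot variability. With an `out_dir`, writes
#' `metric_table.csv`, `correlations.csv`, `correlation_report.txt` and
#' `pilot_variability.csv`; outputs are deterministic given the design
#' seed.
#'
#' @param design A [study_design()], or `NULL` when `session_dir` is given.
#' @param effects An [effect_profile()].
#' @param session_dir Optional directory of session CSVs (from
#'   [write_study_csv()]) to load instead of generating.
#' @param out_dir Optional output directory.
#' @param tei_montage TEI montage selection.
#' @param verbose Log per-stage progress to stderr.
#' @return List: `metric_table`, `correlations`, `variability`, `report`
#'   (text lines).
#' @export
run_pipeline <- function(design = study_design(), effects = effect_profile(),
                         session_dir = NULL, out_dir = NULL,
                         tei_montage = "frontal_f", verbose = FALSE) {
  log_ <- function(...) if (verbose) message("[pipeline] ", ...)
  if (!is.null(session_dir)) {
    log_("loading sessions from ", session_dir)
    study <- read_study_csv(session_dir)
  } else {
    log_("generating synthetic study (seed ", design$seed, ")")
    study <- generate_study(design, effects)
  }
  log_("computing per-session metrics (", length(study$sessions), " sessions)")
  tab <- build_metric_table(study, tei_montage = tei_montage)
  log_("correlating metrics with PIW")
  ct <- correlate_with_piw(tab)
  vt <- pilot_variability(tab)
  rep_lines <- format_correlation_report(ct)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "metric_table.csv"), row.names = FALSE)
    utils::write.csv(ct, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    writeLines(rep_lines, file.path(out_dir, "correlation_report.txt"))
    utils::write.csv(vt, file.path(out_dir, "pilot_variability.csv"), row.names = FALSE)
    log_("wrote outputs to ", out_dir)
  }
  list(metric_table = tab, correlations = ct, variability = vt,
       report = rep_lines)
}
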