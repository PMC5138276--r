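#' Statistical pipeline for the cooling experiment
#'
#' Summaries follow the animal-study convention: 1 Hz recordings are
#' moving-average smoothed; the per-animal "baseline" value is the smoothed
#' temperature at collar activation and the "60 min" value the smoothed
#' temperature 3600 s later; cooling rates are the per-animal endpoint
#' differences expressed per hour. Normality is screened with the
#' Shapiro-Wilk W test and before/after comparisons use a two-tailed paired
#' Student t test.
#'
#' @name cooling-stats
NULL

#' Centered moving average with truncated edges
#'
#' Smooths a regularly sampled series with a centered window of
#' `window_s + 1` samples (`window_s / 2` on each side); windows are
#' truncated at the series boundaries, so the output has the same length
#' and no missing values.
#'
#' @param x numeric series (1 sample per second in the intended use).
#' @param window_s window span in samples; `<= 1` returns `x` unchanged.
#' @return smoothed series of the same length.
#' @export
moving_average <- function(x, window_s = 60) {
  n <- length(x)
  if (n == 0) stop("empty series")
  if (window_s <= 1) return(x)
  h <- floor(window_s / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Two-tailed paired Student t test
#'
#' @param before,after paired measurements of equal length `n >= 2`.
#' @return list with `t`, `df` (`n - 1`) and `p` (two-tailed).
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- before - after
  if (stats::sd(d) == 0)
    stop("degenerate paired test: differences have zero variance")
  ht <- stats::t.test(before, after, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk requires at least 3 observations")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

record_endpoints <- function(rec, window_s) {
  n <- length(rec$brain_C)
  sm_brain <- moving_average(rec$brain_C, window_s)
  sm_body <- moving_average(rec$body_C, window_s)
  hours <- (rec$time_s[n] - rec$time_s[1]) / 3600
  c(brain_baseline = sm_brain[1], brain_final = sm_brain[n],
    body_baseline = sm_body[1], body_final = sm_body[n],
    brain_rate = (sm_brain[1] - sm_brain[n]) / hours,
    body_rate = (sm_body[1] - sm_body[n]) / hours)
}

#' Summarize a cohort of cooling recordings
#'
#' Computes per-animal baseline and end-of-cooling values of brain and body
#' temperature (moving-average smoothed endpoints), cooling rates, group
#' means and sample SDs, Shapiro-Wilk normality screens, and paired
#' two-tailed t tests of baseline versus end of cooling.
#'
#' @param records list of experiment records (see [generate_cohort()] /
#'   [table1_records()]).
#' @param window_s moving-average window (s), default 60.
#' @return an object of class `stats_report`: list with `per_animal` (data
#'   frame), `group` (means/SDs), `normality` (per variable W and p),
#'   `paired` (brain and body test results) and `window_s`.
#' @export
summarize_cohort <- function(records, window_s = 60) {
  stopifnot(length(records) >= 2)
  len <- vapply(records, function(r) length(r$brain_C), 0L)
  if (length(unique(len)) != 1) stop("records have unequal lengths")
  ep <- t(vapply(records, record_endpoints, numeric(6), window_s = window_s))
  per_animal <- data.frame(
    animal = vapply(records, function(r) r$animal_id, ""),
    ep, row.names = NULL, check.names = FALSE)
  vars <- colnames(ep)
  group <- data.frame(
    variable = vars,
    mean = apply(ep, 2, mean),
    sd = apply(ep, 2, stats::sd),
    row.names = NULL)
  na_test <- list(W = NA_real_, p = NA_real_)
  normality <- lapply(setNames(nm = vars), function(v) {
    if (length(records) < 3) return(na_test)
    tryCatch(shapiro_wilk(ep[, v]), error = function(e) na_test)
  })
  safe_paired <- function(before, after) {
    tryCatch(paired_t(before, after),
             error = function(e) list(t = NA_real_,
                                      df = length(before) - 1L,
                                      p = NA_real_, degenerate = TRUE))
  }
  paired <- list(
    brain = safe_paired(ep[, "brain_baseline"], ep[, "brain_final"]),
    body = safe_paired(ep[, "body_baseline"], ep[, "body_final"]))
  normality_flag <- all(vapply(normality, function(z) {
    is.na(z$p) || z$p > 0.05
  }, TRUE))
  structure(list(per_animal = per_animal, group = group,
                 normality = normality, paired = paired,
                 normality_flag = normality_flag, window_s = window_s),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, digits = 3, ...) {
  cat("<stats_report>\n")
  print(cbind(x$per_animal[1],
              round(x$per_animal[-1], digits)), row.names = FALSE)
  g <- x$group
  cat("\nGroup mean (SD):\n")
  for (k in seq_len(nrow(g)))
    cat(sprintf("  %-14s %.1f (%.1f)\n", g$variable[k], g$mean[k], g$sd[k]))
  cat(sprintf("\nPaired t (baseline vs 60 min): brain t=%.2f df=%d p=%.4f; body t=%.2f df=%d p=%.4f\n",
              x$paired$brain$t, x$paired$brain$df, x$paired$brain$p,
              x$paired$body$t, x$paired$body$df, x$paired$body$p))
  cat(sprintf("All endpoint variables pass Shapiro-Wilk at 0.05: %s\n",
              x$normality_flag))
  invisible(x)
}

#' Compare a simulated trace with experimental recordings
#'
#' On a decimated time grid over the cooling hour, computes the cohort mean
#' and 95% confidence interval (t-based) of the experimental brain and body
#' temperatures and flags whether the simulated trace falls inside the
#' interval, returning the within-CI fraction per channel.
#'
#' @param trace a `temperature_trace` whose cooling phase covers 3600 s;
#'   brain = node `"head"`, body = node `"body"`.
#' @param records list of experiment records covering the same hour.
#' @param window_s moving-average window applied to the recordings (s).
#' @param grid_interval_s spacing of comparison points (s).
#' @return list with `grid_s`, per-channel data frames (`brain`, `body`:
#'   mean, lower, upper, simulated, inside) and `fraction_inside` (named,
#'   plus `overall`).
#' @export
compare_sim_to_experiment <- function(trace, records, window_s = 60,
                                      grid_interval_s = 60) {
  t0 <- attr(trace, "phase_marks")[1]
  rel <- trace$time_s - t0
  if (max(rel) < 3600) stop("trace does not cover the cooling hour")
  grid <- seq(0, 3600, by = grid_interval_s)
  n <- length(records)
  rec_t <- records[[1]]$time_s
  if (any(vapply(records, function(r) length(r$time_s), 0L) != length(rec_t)))
    stop("records have unequal lengths")
  if (min(rec_t) > 0 || max(rec_t) < 3600) stop("records do not cover the hour")
  channel <- function(field, node) {
    sm <- vapply(records, function(r) moving_average(r[[field]], window_s),
                 numeric(length(rec_t)))
    ix_rec <- vapply(grid, function(g) which.min(abs(rec_t - g)), 0L)
    m <- rowMeans(sm[ix_rec, , drop = FALSE])
    s <- apply(sm[ix_rec, , drop = FALSE], 1, stats::sd)
    half <- stats::qt(0.975, n - 1) * s / sqrt(n)
    ix_tr <- vapply(grid, function(g) which.min(abs(rel - g)), 0L)
    simv <- trace[[node]][ix_tr]
    data.frame(time_s = grid, mean = m, lower = m - half, upper = m + half,
               simulated = simv,
               inside = simv >= m - half & simv <= m + half)
  }
  brain <- channel("brain_C", "head")
  body <- channel("body_C", "body")
  fr <- c(brain = mean(brain$inside), body = mean(body$inside))
  list(grid_s = grid, brain = brain, body = body,
       fraction_inside = c(fr, overall = mean(c(brain$inside, body$inside))))
}
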