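#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] for a single group: right censoring handled,
#' events precede censorings at tied times (the standard convention), and
#' the curve starts at 1 and is non-increasing.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1/TRUE = death, 0/FALSE = censored).
#' @return Data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 1, 0, 0, 0))
#' km$surv[km$time == 2] # (4/5) * (3/4) = 0.6
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected log-rank with hypergeometric variance
#' (via [survival::survdiff()]); the statistic is referred to a chi-square
#' law with `n_groups - 1` degrees of freedom. Per-group KM curves are
#' attached.
#'
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @param times Positive follow-up times.
#' @param events Event indicators; at least one event overall.
#' @return An object of class `survival_result`: `statistic`, `df`, `p`,
#'   `n_per_group`, `obs`, `exp`, `km_curves` (named list of KM
#'   data.frames).
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.character(groups)
  stopifnot(length(groups) == length(times), length(times) == length(events))
  if (length(unique(groups)) < 2L) {
    stop("log-rank needs at least 2 groups", call. = FALSE)
  }
  events <- as.integer(as.logical(events))
  if (sum(events) < 1L) stop("log-rank needs at least 1 event", call. = FALSE)
  g <- factor(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  km_curves <- lapply(split(seq_along(times), g), function(i) {
    km_estimate(times[i], events[i])
  })
  structure(
    list(statistic = sd$chisq, df = length(levels(g)) - 1L,
         p = stats::pchisq(sd$chisq, length(levels(g)) - 1L, lower.tail = FALSE),
         n_per_group = table(g), obs = sd$obs, exp = sd$exp,
         km_curves = km_curves),
    class = "survival_result"
  )
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> log-rank chi-square %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Log-rank (Nelson-Aalen residual) scores
#'
#' `a_i = event_i - cumulative hazard at time_i`, the linear scores
#' underlying maximally selected log-rank statistics.
#' @noRd
logrank_scores <- function(times, events) {
  ord <- order(times, -events) # events precede censorings at ties
  t_s <- times[ord]; e_s <- events[ord]
  n <- length(t_s)
  at_risk <- n - seq_len(n) + 1L
  haz_inc <- ifelse(e_s == 1L, 1 / at_risk, 0)
  # at tied times every subject shares the cumulative hazard through the tie
  cumhaz_sorted <- cumsum(haz_inc)
  cumhaz_at <- vapply(times, function(t) max(cumhaz_sorted[t_s <= t]), numeric(1))
  events - cumhaz_at
}

#' Maximally selected log-rank cutoff for a continuous score
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' score values that fall inside the quantile window (default the 10th-90th
#' percentile restriction of the maximally-selected-rank-statistics
#' literature). Each candidate split is scored by the standardized linear
#' log-rank statistic: with Nelson-Aalen residual scores `a_i`,
#' `M(c) = |S - E| / sqrt(V)` where `S` sums the scores of the low group and
#' `E`, `V` are the permutation (hypergeometric sampling) moments of that
#' sum. The maximizing cutoff is returned; ties break toward the more
#' balanced split. The p-value of the two-group log-rank test at the
#' selected cutoff is reported as `p_uncorrected` (the selection effect
#' inflates significance); `n_perm > 0` adds a permutation-adjusted p
#' obtained by re-maximizing on score-permuted data.
#'
#' @param scores Per-sample numeric scores (not all equal).
#' @param times,events Survival data; at least one event.
#' @param quantile_window Length-2 window of score quantiles searched
#'   (default `c(0.1, 0.9)`).
#' @param n_perm Number of permutations for the adjusted p (default 0 =
#'   skip).
#' @return A list: `cutoff`, `std_statistic` (the maximal standardized
#'   statistic M), `statistic` (two-group log-rank chi-square at the
#'   cutoff), `p_uncorrected`, `selected_under_null` (TRUE when even the
#'   maximal M is below the two-sided normal 95% bound), `candidates`
#'   (data.frame of all cutoffs and M values), and `p_permutation` when
#'   requested.
#' @export
maxstat_cutoff <- function(scores, times, events, quantile_window = c(0.1, 0.9),
                           n_perm = 0L) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  events <- as.integer(as.logical(events))
  if (sum(events) < 1L) stop("no events: cutoff selection undefined", call. = FALSE)
  if (length(unique(scores)) < 2L) stop("all scores equal", call. = FALSE)

  a <- logrank_scores(times, events)
  n <- length(a)
  a_bar <- mean(a)
  ss <- sum((a - a_bar)^2)

  search_max <- function(sc) {
    u <- sort(unique(sc))
    cand <- (u[-1] + u[-length(u)]) / 2
    win <- stats::quantile(sc, quantile_window, names = FALSE)
    cand <- cand[cand >= win[1] & cand <= win[2]]
    if (length(cand) == 0L) return(NULL)
    stats_at <- vapply(cand, function(cc) {
      m <- sum(sc <= cc)
      if (m == 0L || m == n) return(NA_real_)
      s <- sum(a[sc <= cc])
      v <- m * (n - m) / (n * (n - 1)) * ss
      if (v <= 0) return(NA_real_)
      abs(s - m * a_bar) / sqrt(v)
    }, numeric(1))
    balance <- vapply(cand, function(cc) abs(n - 2 * sum(sc <= cc)), numeric(1))
    ok <- which(!is.na(stats_at))
    if (length(ok) == 0L) return(NULL)
    best <- ok[order(-stats_at[ok], balance[ok])][1L]
    list(cand = cand, stats = stats_at, best = best)
  }

  sm <- search_max(scores)
  if (is.null(sm) || length(sm$cand) < 2L) {
    stop("fewer than 2 candidate cutoffs inside the quantile window", call. = FALSE)
  }
  best_m <- sm$stats[sm$best]
  cutoff <- sm$cand[sm$best]
  hi <- scores > cutoff
  sd <- survival::survdiff(survival::Surv(times, events) ~ hi)
  out <- list(
    cutoff = cutoff,
    std_statistic = best_m,
    statistic = sd$chisq,
    p_uncorrected = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
    selected_under_null = best_m < stats::qnorm(0.975),
    candidates = data.frame(cutoff = sm$cand, std_statistic = sm$stats)
  )
  if (n_perm > 0L) {
    null_max <- vapply(seq_len(n_perm), function(i) {
      pm <- search_max(sample(scores))
      if (is.null(pm)) 0 else max(pm$stats, na.rm = TRUE)
    }, numeric(1))
    out$p_permutation <- (1 + sum(null_max >= best_m)) / (1 + n_perm)
  }
  out
}

#' Stratified prognosis over signature x TMB cross-classes
#'
#' Cross-classifies samples by an nCTPS high/low factor and a TMB high/low
#' factor and runs the k-group log-rank test over the non-empty classes
#' (empty classes are dropped with a message). When `tmb_group` is numeric
#' it is dichotomized by its own maximally selected cutoff
#' ([maxstat_cutoff()]) unless an explicit `tmb_threshold` is given.
#'
#' @param nctps_group "high"/"low" label per sample.
#' @param tmb_group "high"/"low" labels, or numeric TMB values.
#' @param times,events Survival data.
#' @param tmb_threshold Optional numeric threshold used when `tmb_group` is
#'   numeric.
#' @return A `survival_result` over the cross-classes, with extra fields
#'   `classes` (per-sample labels) and `tmb_cutoff` when dichotomization was
#'   performed.
#' @export
stratified_prognosis <- function(nctps_group, tmb_group, times, events,
                                 tmb_threshold = NULL) {
  tmb_cutoff <- NULL
  if (is.numeric(tmb_group)) {
    if (is.null(tmb_threshold)) {
      cut <- maxstat_cutoff(tmb_group, times, events)
      tmb_cutoff <- cut$cutoff
    } else {
      tmb_cutoff <- tmb_threshold
    }
    tmb_group <- ifelse(tmb_group > tmb_cutoff, "high", "low")
  }
  cls <- paste0("nCTPS_", nctps_group, ".TMB_", tmb_group)
  present <- table(cls)
  all_classes <- as.vector(outer(c("nCTPS_high", "nCTPS_low"),
                                 c("TMB_high", "TMB_low"), paste, sep = "."))
  empty <- setdiff(all_classes, names(present))
  if (length(empty) > 0L) {
    message("dropping empty cross-class(es): ", paste(empty, collapse = ", "))
  }
  if (length(present) < 2L) {
    stop("fewer than 2 non-empty cross-classes", call. = FALSE)
  }
  res <- logrank_test(cls, times, events)
  res$classes <- cls
  res$tmb_cutoff <- tmb_cutoff
  res
}
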