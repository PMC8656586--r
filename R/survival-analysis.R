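#' Dichotomize a cohort on an expression z-score cutoff
#'
#' Labels patients `"low"` when the target-gene expression z-score falls
#' strictly below the cutoff (in SD from the cohort mean), else `"high"`.
#' Records without an expression value are dropped with a message.
#'
#' @param cohort data.frame with at least `expression_z`; typically also
#'   `time_months`, `event`, `chemo_treated`, `er_status`, `her2_status`.
#' @param cutoff_sd cutoff in SD units (default -0.82, the disease-free
#'   survival cutoff; use -0.75 for disease-specific survival).
#' @return the cohort with an added factor column `expr_group`
#'   (levels `"low"`, `"high"`); group counts in attribute `group_n`,
#'   excluded-record count in attribute `n_excluded`.
#' @export
dichotomize <- function(cohort, cutoff_sd = -0.82) {
  if (is.null(cohort$expression_z)) stop("cohort is missing column: expression_z")
  drop <- is.na(cohort$expression_z)
  if (any(drop)) {
    message(sum(drop), " record(s) without expression data excluded")
    cohort <- cohort[!drop, ]
  }
  cohort$expr_group <- factor(ifelse(cohort$expression_z < cutoff_sd, "low", "high"),
                              levels = c("low", "high"))
  attr(cohort, "group_n") <- table(cohort$expr_group)
  attr(cohort, "n_excluded") <- sum(drop)
  attr(cohort, "cutoff_sd") <- cutoff_sd
  cohort
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator; ties at a time are handled as
#' simultaneous events, and events precede censorings at the same time.
#'
#' @param time_months non-negative follow-up times.
#' @param event event indicator (1/TRUE = event, 0/FALSE = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`. The underlying
#'   `survival::survfit` object is attached as attribute `fit`.
#' @export
km_estimate <- function(time_months, event) {
  stopifnot(length(time_months) == length(event), all(time_months >= 0))
  fit <- survival::survfit(survival::Surv(time_months, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, survival = fit$surv)
  attr(out, "fit") <- fit
  out
}

#' Log-rank test between two groups
#'
#' Standard (unweighted) log-rank chi-square with 1 degree of freedom,
#' expected events taken from the pooled risk sets. A comparison with no
#' events in either group is degenerate and flagged rather than tested.
#'
#' @param time_months follow-up times.
#' @param event event indicators.
#' @param group two-level grouping (factor, character or logical).
#' @return list: `chisq`, `p_value`, `n` (per group), `observed`,
#'   `expected` (events per group), `degenerate`.
#' @export
logrank_test <- function(time_months, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("log-rank test requires exactly two non-empty groups")
  }
  group <- droplevels(group)
  event <- as.integer(event)
  n <- table(group)
  if (sum(event) == 0) {
    return(list(chisq = 0, p_value = 1, n = n,
                observed = tapply(event, group, sum),
                expected = tapply(event, group, sum), degenerate = TRUE))
  }
  sd_ <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd_$chisq), p_value = p, n = n,
       observed = sd_$obs, expected = sd_$exp, degenerate = FALSE)
}

#' Expression-dichotomized survival comparison
#'
#' Dichotomizes a cohort at the given z-score cutoff and runs the
#' low-vs-high log-rank test, returning the KM curves of both groups.
#'
#' @inheritParams dichotomize
#' @return list: `test` (from [logrank_test()]), `km_low`, `km_high`,
#'   `group_n`, `cutoff_sd`.
#' @export
survival_comparison <- function(cohort, cutoff_sd = -0.82) {
  cohort <- dichotomize(cohort, cutoff_sd)
  if (any(table(cohort$expr_group) == 0)) {
    stop("dichotomization produced an empty group at cutoff ", cutoff_sd)
  }
  low <- cohort[cohort$expr_group == "low", ]
  high <- cohort[cohort$expr_group == "high", ]
  list(
    test = logrank_test(cohort$time_months, cohort$event, cohort$expr_group),
    km_low = km_estimate(low$time_months, low$event),
    km_high = km_estimate(high$time_months, high$event),
    group_n = attr(cohort, "group_n"),
    cutoff_sd = cutoff_sd
  )
}

#' Subgroup survival analyses
#'
#' Repeats the dichotomized log-rank comparison independently within
#' treatment or receptor-status subgroups (z-scores stay cohort-level;
#' only the comparison is subset). Records with unknown status for the
#' chosen split are excluded and counted; a subgroup with an empty
#' low or high arm, or no events, is reported but not tested.
#'
#' @inheritParams dichotomize
#' @param split one of `"chemo"`, `"er"`, `"her2"`.
#' @return data.frame with one row per subgroup level: `subgroup`, `n`,
#'   `n_low`, `n_high`, `events`, `chisq`, `p_value`, `tested`;
#'   excluded-record count in attribute `n_excluded`.
#' @export
subgroup_analysis <- function(cohort, split = c("chemo", "er", "her2"),
                              cutoff_sd = -0.82) {
  split <- match.arg(split)
  var <- switch(split, chemo = "chemo_treated", er = "er_status",
                her2 = "her2_status")
  if (is.null(cohort[[var]])) stop("cohort is missing column: ", var)
  v <- cohort[[var]]
  if (is.logical(v)) v <- ifelse(is.na(v), NA, ifelse(v, "treated", "untreated"))
  v[v %in% c("unknown", "")] <- NA
  excluded <- is.na(v)
  cohort <- cohort[!excluded, ]
  v <- v[!excluded]
  rows <- lapply(sort(unique(v)), function(lev) {
    sub <- dichotomize(cohort[v == lev, ], cutoff_sd)
    n_low <- sum(sub$expr_group == "low")
    n_high <- sum(sub$expr_group == "high")
    testable <- n_low > 0 && n_high > 0 && sum(sub$event) > 0
    if (testable) {
      t <- logrank_test(sub$time_months, sub$event, sub$expr_group)
      data.frame(subgroup = lev, n = nrow(sub), n_low = n_low, n_high = n_high,
                 events = sum(sub$event), chisq = t$chisq, p_value = t$p_value,
                 tested = !t$degenerate, stringsAsFactors = FALSE)
    } else {
      data.frame(subgroup = lev, n = nrow(sub), n_low = n_low, n_high = n_high,
                 events = sum(sub$event), chisq = NA_real_, p_value = NA_real_,
                 tested = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(excluded)
  attr(out, "split") <- split
  out
}
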