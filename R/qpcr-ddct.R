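#' Validate a long-format Ct table
#'
#' Checks a matched-pair qPCR array export: one row per (miRNA, case,
#' timepoint) with a cycle-threshold value. Ct values at or beyond the
#' detection limit, and missing values, are both treated as undetected
#' (array exports differ in which convention they use) and recoded to `NA`.
#'
#' @param ct data.frame with columns `mirna_id`, `case_id`, `timepoint`
#'   (`"pre"` or `"post"`) and `ct` (numeric cycles; `NA` = undetected).
#' @param detection_limit_ct theoretical limit of detection in cycles
#'   (default 40). Values `>= detection_limit_ct` are recoded undetected.
#' @return the validated table with `ct` recoded, invisibly classed
#'   `"ct_pair_matrix"`.
#' @export
ct_pair_matrix <- function(ct, detection_limit_ct = 40) {
  required <- c("mirna_id", "case_id", "timepoint", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(ct$ct)) ct$ct <- suppressWarnings(as.numeric(ct$ct))
  bad_tp <- setdiff(unique(ct$timepoint), c("pre", "post"))
  if (length(bad_tp)) {
    stop("timepoint must be 'pre' or 'post'; found: ", paste(bad_tp, collapse = ", "))
  }
  key <- paste(ct$mirna_id, ct$case_id, ct$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (mirna, case, timepoint) entry: ", gsub("\r", " / ", dup))
  }
  # all cases must share the same panel
  panels <- tapply(ct$mirna_id, paste(ct$case_id, ct$timepoint),
                   function(x) paste(sort(unique(x)), collapse = "\r"))
  if (length(unique(panels)) != 1L) {
    stop("all samples must share the same miRNA panel")
  }
  ct$ct[!is.na(ct$ct) & ct$ct >= detection_limit_ct] <- NA_real_
  attr(ct, "detection_limit_ct") <- detection_limit_ct
  class(ct) <- c("ct_pair_matrix", class(ct))
  ct
}

#' Global-mean normalization of one sample
#'
#' Centres each detected Ct on the mean Ct of all miRNAs detected within
#' that sample. Undetected entries (`NA`) stay undetected; they contribute
#' nothing to the mean.
#'
#' @param ct numeric vector of Ct values for one sample, `NA` = undetected.
#' @param sample_id label used in error messages.
#' @return numeric vector of delta-Ct values, `NA` where undetected.
#' @examples
#' normalize_sample(c(24, 26))        # -1, +1
#' normalize_sample(c(20, 30, NA))    # -5, +5, NA
#' @export
normalize_sample <- function(ct, sample_id = "sample") {
  detected <- !is.na(ct)
  if (!any(detected)) {
    stop("no detected miRNAs in sample '", sample_id, "'; cannot normalize")
  }
  ct - mean(ct[detected])
}

#' Convert an expression ratio to the signed-fold display convention
#'
#' Ratios below 1 are reported as negative reciprocals (0.5 becomes -2) so
#' that every fold has magnitude at least 1 and its sign gives the
#' direction of change.
#'
#' @param ratio positive post/pre expression ratio(s).
#' @return signed fold(s), `|fold| >= 1`.
#' @export
signed_fold <- function(ratio) {
  bad <- !is.na(ratio) & ratio <= 0
  if (any(bad)) stop("ratio must be positive; got ", ratio[bad][1])
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Convert a signed fold back to a post/pre ratio
#'
#' Inverse of [signed_fold()]: positive folds are already ratios; a
#' negative fold -f maps to 1/f.
#'
#' @param fold signed fold(s) with `|fold| >= 1`.
#' @return positive ratio(s).
#' @export
fold_to_ratio <- function(fold) {
  bad <- !is.na(fold) & abs(fold) < 1
  if (any(bad)) stop("signed folds must satisfy |fold| >= 1; got ", fold[bad][1])
  ifelse(fold >= 0, fold, -1 / fold)
}

#' Per-pair delta-delta Ct folds with detection-limit imputation
#'
#' For every (miRNA, case) pair computes the post/pre expression change by
#' the delta-delta Ct method: each sample is global-mean normalized
#' ([normalize_sample()]), then `ddCt = dCt_post - dCt_pre` and
#' `ratio = 2^(-ddCt)`. When a miRNA is undetected in exactly one of the
#' paired samples its Ct is imputed at the detection limit, the resulting
#' fold is a bound and is flagged `is_estimate`. Imputed Cts never enter
#' the normalization mean (they are bounds, not measurements). Pairs
#' undetected on both sides carry no direction evidence and are flagged
#' `is_missing`.
#'
#' @param ct a table accepted by [ct_pair_matrix()].
#' @param detection_limit_ct detection limit in cycles (default 40).
#' @return data.frame with columns `mirna_id`, `case_id`, `ratio`,
#'   `signed_fold`, `is_estimate`, `is_missing`.
#' @export
ddct_folds <- function(ct, detection_limit_ct = 40) {
  if (!inherits(ct, "ct_pair_matrix")) {
    ct <- ct_pair_matrix(ct, detection_limit_ct)
  } else {
    detection_limit_ct <- attr(ct, "detection_limit_ct")
  }
  mirnas <- sort(unique(ct$mirna_id))
  cases <- sort(unique(ct$case_id))
  out <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[i]
    pre <- ct[ct$case_id == cs & ct$timepoint == "pre", ]
    post <- ct[ct$case_id == cs & ct$timepoint == "post", ]
    pre <- pre[match(mirnas, pre$mirna_id), ]
    post <- post[match(mirnas, post$mirna_id), ]
    dct_pre <- normalize_sample(pre$ct, paste0(cs, "/pre"))
    dct_post <- normalize_sample(post$ct, paste0(cs, "/post"))
    # impute undetected side at the detection limit, centred on the
    # detected-only mean of its sample
    imp_pre <- detection_limit_ct - mean(pre$ct, na.rm = TRUE)
    imp_post <- detection_limit_ct - mean(post$ct, na.rm = TRUE)
    und_pre <- is.na(pre$ct)
    und_post <- is.na(post$ct)
    dct_pre[und_pre] <- imp_pre
    dct_post[und_post] <- imp_post
    ddct <- dct_post - dct_pre
    ratio <- 2^(-ddct)
    is_missing <- und_pre & und_post
    is_estimate <- xor(und_pre, und_post)
    ratio[is_missing] <- NA_real_
    out[[i]] <- data.frame(
      mirna_id = mirnas, case_id = cs, ratio = ratio,
      signed_fold = ifelse(is.na(ratio), NA_real_, signed_fold(ratio)),
      is_estimate = is_estimate, is_missing = is_missing,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate-excluded mean signed fold
#'
#' Aggregates per-case folds on the ratio scale: signed folds are converted
#' to post/pre ratios, averaged arithmetically, and the mean converted back
#' to a signed fold. Folds flagged as estimates (detection-limit bounds)
#' are excluded from the mean.
#'
#' @param fold signed folds (`|fold| >= 1`), `NA` allowed (dropped).
#' @param is_estimate logical flags, same length as `fold`.
#' @return mean signed fold.
#' @examples
#' mean_signed_fold(c(3.46, 1.84, 1.70, 1.33, 4.50))              # 2.57
#' mean_signed_fold(c(-2.33, -1.42, -14.4, -1.27, -1.36))         # -1.83
#' mean_signed_fold(c(1.70, 1.32, 1.11, 1.82, 30),
#'                  is_estimate = c(rep(FALSE, 4), TRUE))         # 1.49
#' @export
mean_signed_fold <- function(fold, is_estimate = rep(FALSE, length(fold))) {
  stopifnot(length(fold) == length(is_estimate))
  keep <- !is_estimate & !is.na(fold)
  if (!any(keep)) {
    stop("no non-estimate fold values available; mean fold undefined")
  }
  signed_fold(mean(fold_to_ratio(fold[keep])))
}

#' Consistency filter: same-direction change in every case
#'
#' Retains miRNAs whose signed folds point the same way, with
#' `|fold| > 1`, in every case. Estimated (bound) folds participate at
#' their bound value; a pair undetected on both sides disqualifies the
#' miRNA (no direction evidence).
#'
#' @param folds fold table from [ddct_folds()], or any data.frame with
#'   columns `mirna_id`, `case_id`, `signed_fold` (optional `is_missing`).
#' @return character vector of retained miRNA ids, sorted.
#' @export
consistency_filter <- function(folds) {
  sp <- split(folds, folds$mirna_id)
  keep <- vapply(sp, function(d) {
    if (!is.null(d$is_missing) && any(d$is_missing)) return(FALSE)
    f <- d$signed_fold
    if (anyNA(f)) return(FALSE)
    all(abs(f) > 1) && (all(f > 0) || all(f < 0))
  }, logical(1))
  sort(names(keep)[keep])
}

#' Magnitude filter: minimum fold change in every case
#'
#' Retains miRNAs with `|signed_fold| >= min_fold` in every case.
#' Estimated folds participate at their bound value. Intended to run on
#' miRNAs that already pass [consistency_filter()].
#'
#' @param folds fold table (see [consistency_filter()]).
#' @param min_fold minimum fold, `>= 1` (default 1.3).
#' @param mirnas optional subset of miRNA ids to consider (e.g. the
#'   consistency survivors); defaults to all in `folds`.
#' @return character vector of retained miRNA ids, sorted.
#' @export
magnitude_filter <- function(folds, min_fold = 1.3, mirnas = NULL) {
  if (min_fold < 1) stop("min_fold must be >= 1")
  if (!is.null(mirnas)) folds <- folds[folds$mirna_id %in% mirnas, ]
  sp <- split(folds, folds$mirna_id)
  keep <- vapply(sp, function(d) {
    f <- d$signed_fold
    if (anyNA(f)) return(FALSE)
    if (!is.null(d$is_missing) && any(d$is_missing)) return(FALSE)
    all(abs(f) >= min_fold)
  }, logical(1))
  sort(names(keep)[keep])
}

#' Summarize matched-pair folds, Table-style
#'
#' One row per consistency-passing miRNA: per-case signed folds (wide),
#' which cases were estimated, the estimate-excluded mean fold, direction,
#' and whether the miRNA passes the magnitude filter. Rows ordered by
#' `|mean_fold|` descending, ties by id.
#'
#' @param folds fold table with columns `mirna_id`, `case_id`,
#'   `signed_fold`, `is_estimate` (optional `is_missing`).
#' @param min_fold magnitude-filter threshold (default 1.3).
#' @return data.frame summary.
#' @export
fold_summary <- function(folds, min_fold = 1.3) {
  if (is.null(folds$is_estimate)) folds$is_estimate <- FALSE
  consistent <- consistency_filter(folds)
  passing <- magnitude_filter(folds, min_fold, mirnas = consistent)
  cases <- sort(unique(folds$case_id))
  rows <- lapply(consistent, function(m) {
    d <- folds[folds$mirna_id == m, ]
    d <- d[match(cases, d$case_id), ]
    mean_fold <- tryCatch(mean_signed_fold(d$signed_fold, d$is_estimate),
                          error = function(e) NA_real_)
    row <- data.frame(mirna_id = m, stringsAsFactors = FALSE)
    for (i in seq_along(cases)) row[[paste0("fold_", cases[i])]] <- d$signed_fold[i]
    row$mean_fold <- mean_fold
    row$estimate_flags <- paste(ifelse(d$is_estimate, "*", "."), collapse = "")
    row$direction <- if (all(d$signed_fold > 0)) "up" else "down"
    row$passes_filter <- m %in% passing
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(-abs(out$mean_fold), out$mirna_id), ]
  rownames(out) <- NULL
  out
}

#' Summarize a Ct matrix end to end
#'
#' Convenience wrapper: [ddct_folds()] then [fold_summary()].
#'
#' @inheritParams ddct_folds
#' @inheritParams fold_summary
#' @return data.frame summary (see [fold_summary()]).
#' @export
ddct_summary <- function(ct, detection_limit_ct = 40, min_fold = 1.3) {
  fold_summary(ddct_folds(ct, detection_limit_ct), min_fold = min_fold)
}
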