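#' Relative survival versus vehicle control
#'
#' First normalization of a viability plate: technical replicates are
#' averaged within each biological replicate, then every dose is divided
#' by the vehicle (dose 0) mean of the same biological replicate. The
#' per-dose summary carries SD and SEM across biological replicates.
#'
#' @param plate data.frame with columns `condition`, `dose_nM`, `bio_rep`,
#'   `tech_rep`, `signal` (absorbance, arbitrary units).
#' @param condition the transfection condition to extract.
#' @return list with `per_rep` (one row per biological replicate x dose:
#'   `bio_rep`, `dose_nM`, `rel_survival`) and `curve` (per dose:
#'   `dose_nM`, `mean_rel`, `sd_rel`, `sem_rel`, `n`).
#' @export
relative_survival <- function(plate, condition) {
  required <- c("condition", "dose_nM", "bio_rep", "tech_rep", "signal")
  missing_cols <- setdiff(required, names(plate))
  if (length(missing_cols)) {
    stop("plate table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- plate[plate$condition == condition, ]
  if (!nrow(d)) stop("no wells for condition '", condition, "'")
  if (!any(d$dose_nM == 0)) stop("no vehicle (dose 0) wells for condition '", condition, "'")
  agg <- stats::aggregate(signal ~ bio_rep + dose_nM, data = d, FUN = mean)
  per_rep <- do.call(rbind, lapply(split(agg, agg$bio_rep), function(b) {
    veh <- b$signal[b$dose_nM == 0]
    if (!length(veh) || veh <= 0) {
      stop("vehicle mean signal must be positive (bio_rep ", b$bio_rep[1], ")")
    }
    data.frame(bio_rep = b$bio_rep, dose_nM = b$dose_nM,
               rel_survival = b$signal / veh, stringsAsFactors = FALSE)
  }))
  rownames(per_rep) <- NULL
  per_rep <- per_rep[order(per_rep$bio_rep, per_rep$dose_nM), ]
  curve <- do.call(rbind, lapply(split(per_rep, per_rep$dose_nM), function(g) {
    data.frame(dose_nM = g$dose_nM[1], mean_rel = mean(g$rel_survival),
               sd_rel = stats::sd(g$rel_survival),
               sem_rel = stats::sd(g$rel_survival) / sqrt(nrow(g)),
               n = nrow(g))
  }))
  curve <- curve[order(curve$dose_nM), ]
  rownames(curve) <- NULL
  list(condition = condition, per_rep = per_rep, curve = curve)
}

#' Relative survival versus the control transfection
#'
#' Second normalization: per biological replicate and dose, the
#' vehicle-relative survival of the targeted condition divided by that of
#' its scrambled/control condition. Raw-signal units cancel, so the ratio
#' is invariant to rescaling any one biological replicate.
#'
#' @param target,control outputs of [relative_survival()].
#' @return list with `per_rep` (`bio_rep`, `dose_nM`, `ratio`) and
#'   `curve` (per-dose mean/SD/SEM of the ratio).
#' @export
relative_to_control <- function(target, control) {
  a <- target$per_rep
  b <- control$per_rep
  if (!setequal(unique(a$dose_nM), unique(b$dose_nM))) {
    stop("dose grids differ between target and control conditions")
  }
  m <- merge(a, b, by = c("bio_rep", "dose_nM"), suffixes = c("_target", "_control"))
  if (!nrow(m)) stop("no shared (bio_rep, dose) pairs between conditions")
  m$ratio <- m$rel_survival_target / m$rel_survival_control
  per_rep <- m[order(m$bio_rep, m$dose_nM), c("bio_rep", "dose_nM", "ratio")]
  rownames(per_rep) <- NULL
  curve <- do.call(rbind, lapply(split(per_rep, per_rep$dose_nM), function(g) {
    data.frame(dose_nM = g$dose_nM[1], mean_ratio = mean(g$ratio),
               sd_ratio = stats::sd(g$ratio),
               sem_ratio = stats::sd(g$ratio) / sqrt(nrow(g)), n = nrow(g))
  }))
  curve <- curve[order(curve$dose_nM), ]
  rownames(curve) <- NULL
  list(target = target$condition, control = control$condition,
       per_rep = per_rep, curve = curve)
}

#' Paired one-tailed t test
#'
#' Paired t test on biological-replicate means, one-tailed in the stated
#' direction (`"greater"`: target exceeds control, the mimic/siRNA
#' hypothesis; `"less"`: the inhibitor hypothesis). When the paired
#' differences have zero variance the test is degenerate: p is 0.5 for
#' identical vectors, else 0 or 1 by the sign of the common difference.
#'
#' @param target,control equal-length paired numeric vectors (n >= 2).
#' @param direction `"greater"` or `"less"`.
#' @return list: `statistic`, `df`, `p_value`, `direction`, `degenerate`.
#' @export
paired_t_one_tailed <- function(target, control, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(target) != length(control)) stop("paired vectors must have equal length")
  if (length(target) < 2) stop("need at least 2 pairs")
  d <- target - control
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 0.5
         else if ((mean(d) > 0) == (direction == "greater")) 0 else 1
    return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1, p_value = p,
                direction = direction, degenerate = TRUE))
  }
  tt <- stats::t.test(target, control, paired = TRUE, alternative = direction)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, direction = direction, degenerate = FALSE)
}

#' Clonogenic surviving fraction
#'
#' Plating efficiency is colonies/seeded (a colony being >30 cells); the
#' surviving fraction is the treated plating efficiency relative to the
#' vehicle's.
#'
#' @param colonies_treated,seeded_treated treated-arm colony and seeded
#'   counts.
#' @param colonies_vehicle,seeded_vehicle vehicle-arm counts.
#' @return list: `pe_treated`, `pe_vehicle`, `surviving_fraction`.
#' @export
surviving_fraction <- function(colonies_treated, seeded_treated,
                               colonies_vehicle, seeded_vehicle) {
  stopifnot(seeded_treated > 0, seeded_vehicle > 0,
            colonies_treated >= 0, colonies_vehicle >= 0,
            colonies_treated <= seeded_treated,
            colonies_vehicle <= seeded_vehicle)
  pe_t <- colonies_treated / seeded_treated
  pe_v <- colonies_vehicle / seeded_vehicle
  if (pe_v == 0) stop("vehicle plating efficiency is zero; surviving fraction undefined")
  list(pe_treated = pe_t, pe_vehicle = pe_v, surviving_fraction = pe_t / pe_v)
}

#' Interpolated IC estimate from a dose-response curve
#'
#' ICxx is the dose at which relative survival equals 1 - xx/100.
#' Survival is interpolated linearly against log10(dose) between the
#' bracketing observed doses; no parametric curve is fitted and no
#' extrapolation beyond the observed range is performed. An exact grid
#' hit returns that dose.
#'
#' @param dose_nM ascending positive doses (vehicle dose 0, if present,
#'   is ignored for the log-dose interpolation).
#' @param survival relative survival (fraction of vehicle) at each dose.
#' @param ic the xx of ICxx (default 50).
#' @return interpolated dose, in the units of `dose_nM`.
#' @examples
#' estimate_ic(c(1, 100), c(1, 0), ic = 50)  # 10
#' @export
estimate_ic <- function(dose_nM, survival, ic = 50) {
  stopifnot(length(dose_nM) == length(survival), ic > 0, ic < 100)
  keep <- dose_nM > 0 & !is.na(survival)
  dose <- dose_nM[keep]
  surv <- survival[keep]
  ord <- order(dose)
  dose <- dose[ord]
  surv <- surv[ord]
  if (length(dose) < 2) stop("need at least two positive doses")
  target <- 1 - ic / 100
  hit <- which(surv == target)
  if (length(hit)) return(dose[hit[1]])
  cross <- which((surv[-length(surv)] - target) * (surv[-1] - target) < 0)
  if (!length(cross)) {
    stop("IC", ic, " outside the observed survival range; no extrapolation")
  }
  i <- cross[1]
  ld <- log10(dose[i]) +
    (target - surv[i]) / (surv[i + 1] - surv[i]) * (log10(dose[i + 1]) - log10(dose[i]))
  10^ld
}

#' Fold resistance between two IC estimates
#'
#' @param ic_resistant,ic_parental positive IC values in the same units.
#' @return ratio resistant/parental.
#' @export
resistance_ratio <- function(ic_resistant, ic_parental) {
  stopifnot(ic_resistant > 0, ic_parental > 0)
  ic_resistant / ic_parental
}
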