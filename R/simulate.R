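#' Simulate matched pre/post qPCR miRNA Ct arrays
#'
#' Emulates a 377-miRNA array card run on matched pre/post-treatment
#' samples: per-miRNA baseline Cts, Gaussian cycle noise on every
#' measurement, and detection dropout at the array's limit. Planted
#' miRNAs have their post-treatment Ct shifted by -log2(true ratio), so
#' the delta-delta Ct pipeline should recover the planted fold.
#'
#' @param n_mirnas panel size (default 377).
#' @param n_pairs number of matched case pairs (default 5).
#' @param planted_ratios named numeric vector: true post/pre expression
#'   ratio per planted miRNA id (ids outside the panel are an error;
#'   ratios must be positive). Ratios apply to every case.
#' @param ct_noise_sd per-measurement Ct noise in cycles (default 0.15).
#' @param detection_limit_ct dropout threshold (default 40).
#' @param baseline_mean,baseline_sd per-miRNA baseline Ct distribution.
#' @param n_dropout_mirnas number of low-abundance miRNAs whose baseline
#'   sits just below the detection limit, producing realistic dropout.
#' @param seed optional integer seed.
#' @return long-format Ct table accepted by [ct_pair_matrix()].
#' @export
sim_ct_arrays <- function(n_mirnas = 377, n_pairs = 5, planted_ratios = NULL,
                          ct_noise_sd = 0.15, detection_limit_ct = 40,
                          baseline_mean = 28, baseline_sd = 3,
                          n_dropout_mirnas = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mirnas <- sprintf("miR-sim-%03d", seq_len(n_mirnas))
  if (!is.null(planted_ratios)) {
    if (is.null(names(planted_ratios)) || any(!nzchar(names(planted_ratios)))) {
      stop("planted_ratios must be a named vector of miRNA ids")
    }
    if (any(planted_ratios <= 0)) stop("planted ratios must be positive")
    if (!all(names(planted_ratios) %in% mirnas)) {
      stop("planted miRNA id(s) outside the simulated panel")
    }
  }
  baseline <- stats::rnorm(n_mirnas, baseline_mean, baseline_sd)
  names(baseline) <- mirnas
  if (n_dropout_mirnas > 0) {
    lowq <- utils::tail(seq_len(n_mirnas), n_dropout_mirnas)
    baseline[lowq] <- stats::rnorm(n_dropout_mirnas, detection_limit_ct - 0.5, 0.7)
  }
  shift <- rep(0, n_mirnas)
  names(shift) <- mirnas
  if (!is.null(planted_ratios)) {
    shift[names(planted_ratios)] <- -log2(planted_ratios)
  }
  rows <- vector("list", n_pairs * 2)
  k <- 0
  for (case in sprintf("case-%d", seq_len(n_pairs))) {
    for (tp in c("pre", "post")) {
      mu <- baseline + if (tp == "post") shift else 0
      ctv <- mu + stats::rnorm(n_mirnas, 0, ct_noise_sd)
      ctv[ctv >= detection_limit_ct] <- NA_real_
      k <- k + 1
      rows[[k]] <- data.frame(mirna_id = mirnas, case_id = case, timepoint = tp,
                              ct = ctv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate pulldown/input RNA-seq count tables
#'
#' Emulates a biotin-mimic pulldown experiment: four libraries (pulldown
#' and input for the miRNA mimic and the scrambled control), Poisson
#' counts at a configured depth. Planted target genes are enriched by the
#' configured fold in the miRNA pulldown only; all other libraries share
#' the same expression profile.
#'
#' @param n_genes gene universe size (default 5020).
#' @param planted_folds named numeric vector: true pulldown enrichment
#'   fold per planted gene id (e.g. `gene-0001`). Must exceed 1.
#' @param depth expected library size per sample (default 1e6).
#' @param planted_base_count expected control-pulldown count of planted
#'   genes (default 50); keeps their enrichment call clear of shot noise.
#' @param base_shape gamma shape for the background abundance profile.
#' @param mirna_id condition label for the mimic (default "miR-sim").
#' @param seed optional integer seed.
#' @return long count table accepted by [rpm_normalize()].
#' @export
sim_pulldown_counts <- function(n_genes = 5020, planted_folds = NULL,
                                depth = 1e6, planted_base_count = 50,
                                base_shape = 0.7, mirna_id = "miR-sim",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene-%04d", seq_len(n_genes))
  if (!is.null(planted_folds)) {
    if (is.null(names(planted_folds))) stop("planted_folds must be named by gene id")
    if (!all(names(planted_folds) %in% genes)) {
      stop("planted gene id(s) outside the simulated universe")
    }
    if (any(planted_folds <= 1)) stop("planted enrichment folds must exceed 1")
  }
  w <- stats::rgamma(n_genes, shape = base_shape, rate = 1)
  names(w) <- genes
  lambda <- w / sum(w) * depth
  if (!is.null(planted_folds)) {
    lambda[names(planted_folds)] <- planted_base_count
  }
  lambda_mir_pd <- lambda
  if (!is.null(planted_folds)) {
    lambda_mir_pd[names(planted_folds)] <-
      lambda[names(planted_folds)] * planted_folds
  }
  samples <- list(
    list(id = "pulldown_control", role = "pulldown", condition = "control", l = lambda),
    list(id = paste0("pulldown_", mirna_id), role = "pulldown",
         condition = mirna_id, l = lambda_mir_pd),
    list(id = "input_control", role = "input", condition = "control", l = lambda),
    list(id = paste0("input_", mirna_id), role = "input",
         condition = mirna_id, l = lambda)
  )
  do.call(rbind, lapply(samples, function(s) {
    data.frame(gene_id = genes, sample_id = s$id, role = s$role,
               condition = s$condition, count = stats::rpois(n_genes, s$l),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a 5-algorithm target-prediction table
#'
#' Emulates a binding-site prediction export: each gene is predicted by a
#' random subset of the five algorithms, with configurable support-count
#' distribution; designated genes can be forced to an exact support count
#' (e.g. 5-of-5 or 4-of-5).
#'
#' @param genes character vector of gene ids to cover.
#' @param mirna_id miRNA the predictions are for.
#' @param forced_k named integer vector (0-5): exact number of supporting
#'   algorithms for specific genes.
#' @param k_prob probabilities of 0..5 supporting algorithms for
#'   non-forced genes (length 6; normalized internally).
#' @param seed optional integer seed.
#' @return data.frame `gene_id`, `mirna_id`, `algorithm` — one row per
#'   prediction, accepted by [consensus_targets()].
#' @export
sim_predictions <- function(genes, mirna_id, forced_k = NULL,
                            k_prob = c(0.45, 0.25, 0.13, 0.08, 0.05, 0.04),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(k_prob) == 6)
  k_prob <- k_prob / sum(k_prob)
  k <- sample(0:5, length(genes), replace = TRUE, prob = k_prob)
  names(k) <- genes
  if (!is.null(forced_k)) {
    if (is.null(names(forced_k))) stop("forced_k must be named by gene id")
    if (any(forced_k < 0 | forced_k > 5)) stop("forced_k must be between 0 and 5")
    k[names(forced_k)] <- forced_k
  }
  rows <- lapply(genes[k > 0], function(g) {
    data.frame(gene_id = g, mirna_id = mirna_id,
               algorithm = sample(PREDICTION_ALGORITHMS, k[[g]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), mirna_id = character(),
                      algorithm = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a survival cohort with a treatment-restricted marker effect
#'
#' Emulates a breast-cancer expression/survival export: standard-normal
#' expression z-scores, exponential event times, independent exponential
#' censoring, and treatment/receptor annotations. The hazard of patients
#' with low marker expression (z below `cutoff_sd`) is multiplied by
#' `hazard_ratio_low` in the chemotherapy arm only — the pattern expected
#' of a chemoresistance effector.
#'
#' @param n cohort size (default 2000).
#' @param chemo_fraction fraction treated with chemotherapy (default
#'   0.21, the scale of curated breast-cancer cohorts).
#' @param hazard_ratio_low hazard multiplier for low-expression patients
#'   in the chemo arm; must be >= 1 (1 = null cohort).
#' @param baseline_hazard events per month (default 0.012).
#' @param censoring_rate target fraction censored under the null
#'   (default 0.3); implemented as independent exponential censoring.
#' @param cutoff_sd z-score cutoff defining "low" (default -0.82).
#' @param seed optional integer seed.
#' @return data.frame with columns `patient_id`, `time_months`, `event`,
#'   `expression_z`, `chemo_treated`, `er_status`, `her2_status`.
#' @export
sim_cohort <- function(n = 2000, chemo_fraction = 0.21, hazard_ratio_low = 2,
                       baseline_hazard = 0.012, censoring_rate = 0.3,
                       cutoff_sd = -0.82, seed = NULL) {
  if (hazard_ratio_low < 1) stop("hazard_ratio_low must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(n)
  chemo <- stats::runif(n) < chemo_fraction
  low <- z < cutoff_sd
  hz <- baseline_hazard * ifelse(low & chemo, hazard_ratio_low, 1)
  t_event <- stats::rexp(n, hz)
  hz_cens <- baseline_hazard * censoring_rate / (1 - censoring_rate)
  t_cens <- stats::rexp(n, hz_cens)
  data.frame(
    patient_id = sprintf("pt-%04d", seq_len(n)),
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    expression_z = z,
    chemo_treated = chemo,
    er_status = sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                       prob = c(0.74, 0.24, 0.02)),
    her2_status = sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                         prob = c(0.14, 0.84, 0.02)),
    stringsAsFactors = FALSE
  )
}

#' Simulate MTT plates and clonogenic counts
#'
#' Generates viability signals from a logistic dose-response,
#' `survival(d) = 1 / (1 + (d / IC50)^hill)`, with multiplicative
#' log-normal replicate noise, plus matching clonogenic colony counts
#' drawn binomially from a plating efficiency scaled by the same
#' survival curve.
#'
#' @param ic50_by_condition named positive vector: true IC50 (nM) per
#'   transfection condition.
#' @param doses dose grid in nM including vehicle 0.
#' @param hill logistic slope (default 1.3).
#' @param n_bio,n_tech biological and technical replicate counts.
#' @param noise_cv log-normal noise sdlog on signals (default 0.05).
#' @param vehicle_signal mean vehicle absorbance (default 1).
#' @param seeded_cells,pe_vehicle clonogenic seeding and vehicle plating
#'   efficiency.
#' @param seed optional integer seed.
#' @return list: `plate` (accepted by [relative_survival()]) and
#'   `clonogenic` (`condition`, `dose_nM`, `seeded`, `colonies`).
#' @export
sim_viability <- function(ic50_by_condition = c(control = 30, mimic = 60),
                          doses = c(0, 1, 3, 10, 30, 100, 300),
                          hill = 1.3, n_bio = 3, n_tech = 3, noise_cv = 0.05,
                          vehicle_signal = 1, seeded_cells = 200,
                          pe_vehicle = 0.5, seed = NULL) {
  if (any(ic50_by_condition <= 0)) stop("IC50 values must be positive")
  if (!is.null(seed)) set.seed(seed)
  logistic_surv <- function(d, ic50) ifelse(d == 0, 1, 1 / (1 + (d / ic50)^hill))
  plate <- do.call(rbind, lapply(names(ic50_by_condition), function(cond) {
    grid <- expand.grid(bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
                        dose_nM = doses)
    mu <- vehicle_signal * logistic_surv(grid$dose_nM, ic50_by_condition[[cond]])
    data.frame(condition = cond, dose_nM = grid$dose_nM, bio_rep = grid$bio_rep,
               tech_rep = grid$tech_rep,
               signal = mu * exp(stats::rnorm(nrow(grid), 0, noise_cv)),
               stringsAsFactors = FALSE)
  }))
  clono <- do.call(rbind, lapply(names(ic50_by_condition), function(cond) {
    sv <- logistic_surv(doses, ic50_by_condition[[cond]])
    data.frame(condition = cond, dose_nM = doses, seeded = seeded_cells,
               colonies = stats::rbinom(length(doses), seeded_cells,
                                        pmin(1, pe_vehicle * sv)),
               stringsAsFactors = FALSE)
  }))
  list(plate = plate, clonogenic = clono)
}
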