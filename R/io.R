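#' Read a schema-checked TSV
#'
#' All pipeline tables share one dialect: tab-separated, header row,
#' UTF-8, `NA` for missing. Fails with the offending column name when a
#' required column is absent.
#'
#' @param path file path.
#' @param required_cols character vector of required column names.
#' @param numeric_cols columns coerced to numeric (coercion failure is an
#'   error naming the column).
#' @return data.frame.
#' @export
read_tsv_checked <- function(path, required_cols = character(),
                             numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop("'", basename(path), "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad)) {
        stop("'", basename(path), "' column '", col,
             "': non-numeric value in row ", bad[1])
      }
      df[[col]] <- coerced
    }
  }
  df
}

#' Write a pipeline TSV
#'
#' @param df data.frame.
#' @param path destination path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_tsv_checked
#' @export
read_ct_table <- function(path) {
  read_tsv_checked(path, c("mirna_id", "case_id", "timepoint", "ct"), "ct")
}

#' @rdname read_tsv_checked
#' @export
read_count_table <- function(path) {
  read_tsv_checked(path, c("gene_id", "sample_id", "role", "condition", "count"),
                   "count")
}

#' @rdname read_tsv_checked
#' @export
read_prediction_table <- function(path) {
  read_tsv_checked(path, c("gene_id", "mirna_id", "algorithm"))
}

#' @rdname read_tsv_checked
#' @export
read_cohort_table <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "time_months", "event",
                                 "expression_z"),
                         c("time_months", "event", "expression_z"))
  if (!is.null(df$chemo_treated) && !is.logical(df$chemo_treated)) {
    df$chemo_treated <- as.logical(df$chemo_treated)
  }
  df
}

#' @rdname read_tsv_checked
#' @export
read_plate_table <- function(path) {
  read_tsv_checked(path, c("condition", "dose_nM", "bio_rep", "tech_rep", "signal"),
                   c("dose_nM", "signal"))
}

#' @rdname read_tsv_checked
#' @export
read_clonogenic_table <- function(path) {
  read_tsv_checked(path, c("condition", "dose_nM", "seeded", "colonies"),
                   c("dose_nM", "seeded", "colonies"))
}

#' Bundled matched-pair miRNA fold-change matrix
#'
#' The per-case post/pre signed fold differences for the 12 miRNAs found
#' consistently up- or down-regulated across 5 matched pre/post
#' neoadjuvant-chemotherapy ER-positive breast cancer cases, as published
#' for that cohort. Entries estimated via detection-limit imputation
#' (the miRNA undetected in one sample of the pair) are stored at their
#' bound value with `is_estimate = TRUE`; such bounds participate in the
#' consistency and magnitude filters but are excluded from mean folds.
#'
#' @return data.frame: `mirna_id`, `case_id`, `signed_fold`, `is_estimate`.
#' @export
nac_fold_matrix <- function() {
  path <- system.file("extdata", "nac_mirna_folds.tsv", package = "chemomir",
                      mustWork = TRUE)
  df <- read_tsv_checked(path, c("mirna_id", "case_id", "signed_fold", "is_estimate"),
                         "signed_fold")
  df$is_estimate <- as.logical(df$is_estimate)
  df
}

#' Run the full discovery pipeline on simulated inputs
#'
#' Seeded end-to-end demonstration run: simulates every input, executes
#' the four analysis stages in discovery order (matched-pair miRNA fold
#' analysis, chemoresponse quantification, pulldown + consensus target
#' nomination, dichotomized survival), writes each stage's tables and a
#' run manifest into `out_dir`, and returns the in-memory results.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving all generators (sub-seeds are derived
#'   from it, one per generator).
#' @param min_fold magnitude-filter threshold (default 1.3).
#' @param enrichment_threshold pulldown over-representation threshold
#'   (default 100).
#' @param consensus_k algorithms required for consensus (default 4).
#' @param cutoff_sd dichotomization cutoff (default -0.82).
#' @param sim_args optional named list overriding generator arguments
#'   (elements `ct`, `pulldown`, `predictions`, `cohort`, `viability`).
#' @return invisibly, a list with each stage's results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1, min_fold = 1.3,
                         enrichment_threshold = 100, consensus_k = 4,
                         cutoff_sd = -0.82, sim_args = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 5)

  planted_mirnas <- c("miR-sim-001" = 2.5, "miR-sim-002" = 4, "miR-sim-003" = 0.4)
  ct_args <- utils::modifyList(
    list(planted_ratios = planted_mirnas, seed = sub_seeds[1]), sim_args$ct %||% list())
  ct <- do.call(sim_ct_arrays, ct_args)
  folds <- ddct_folds(ct)
  summary_tab <- fold_summary(folds, min_fold = min_fold)
  write_tsv(ct, file.path(out_dir, "ct_arrays.tsv"))
  write_tsv(summary_tab, file.path(out_dir, "mirna_fold_summary.tsv"))

  via_args <- utils::modifyList(list(seed = sub_seeds[2]), sim_args$viability %||% list())
  via <- do.call(sim_viability, via_args)
  conds <- unique(via$plate$condition)
  rs <- lapply(conds, function(cc) relative_survival(via$plate, cc))
  names(rs) <- conds
  write_tsv(via$plate, file.path(out_dir, "viability_plate.tsv"))
  curves <- do.call(rbind, lapply(rs, function(r) cbind(condition = r$condition, r$curve)))
  write_tsv(curves, file.path(out_dir, "dose_response_curves.tsv"))

  planted_genes <- c("gene-0001" = 200, "gene-0002" = 300, "gene-0003" = 150)
  pd_args <- utils::modifyList(
    list(planted_folds = planted_genes, seed = sub_seeds[3]), sim_args$pulldown %||% list())
  counts <- do.call(sim_pulldown_counts, pd_args)
  mirna_id <- unique(counts$condition[counts$condition != "control"])[1]
  enr <- enrichment_table(counts, mirna_id, threshold = enrichment_threshold)
  pulldown_set <- call_candidates(enr)
  write_tsv(enr, file.path(out_dir, "pulldown_enrichment.tsv"))

  pred_args <- utils::modifyList(
    list(genes = unique(counts$gene_id), mirna_id = mirna_id,
         forced_k = stats::setNames(c(5L, 4L, 2L), names(planted_genes)),
         seed = sub_seeds[4]),
    sim_args$predictions %||% list())
  preds <- do.call(sim_predictions, pred_args)
  consensus <- consensus_targets(preds, mirna_id, k = consensus_k)
  final_targets <- intersect_candidates(consensus, pulldown_set)
  write_tsv(preds, file.path(out_dir, "predictions.tsv"))
  write_candidate_set(final_targets, file.path(out_dir, "final_targets.tsv"))

  cohort_args <- utils::modifyList(list(seed = sub_seeds[5]), sim_args$cohort %||% list())
  cohort <- do.call(sim_cohort, cohort_args)
  surv_all <- survival_comparison(cohort, cutoff_sd = cutoff_sd)
  surv_sub <- subgroup_analysis(cohort, "chemo", cutoff_sd = cutoff_sd)
  write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
  write_tsv(surv_sub, file.path(out_dir, "survival_subgroups.tsv"))

  manifest <- data.frame(
    key = c("seed", "min_fold", "enrichment_threshold", "consensus_k",
            "cutoff_sd", "stages"),
    value = c(seed, min_fold, enrichment_threshold, consensus_k, cutoff_sd,
              "ddct;chemoresponse;pulldown;targets;survival"),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(
    folds = folds, summary = summary_tab, dose_response = rs,
    enrichment = enr, pulldown_set = pulldown_set, consensus = consensus,
    final_targets = final_targets, cohort = cohort,
    survival_overall = surv_all, survival_subgroups = surv_sub,
    manifest = manifest
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
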