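#' Reads-per-million normalization of a pulldown count table
#'
#' Normalizes raw gene counts to library depth. A pseudocount (default
#' 0.5) is added to every raw count before computing sample totals and
#' RPM, so downstream enrichment ratios are defined even when the control
#' pulldown yielded zero reads for a gene.
#'
#' @param counts data.frame with columns `gene_id`, `sample_id`, `role`
#'   (`"pulldown"` or `"input"`), `condition` (`"control"` or a miRNA id)
#'   and `count` (non-negative integers).
#' @param pseudocount added to every raw count (default 0.5).
#' @return the table with an added `rpm` column.
#' @export
rpm_normalize <- function(counts, pseudocount = 0.5) {
  required <- c("gene_id", "sample_id", "role", "condition", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("count table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(counts$count < 0, na.rm = TRUE)) stop("counts must be non-negative")
  key <- paste(counts$gene_id, counts$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, sample) entry: ",
         gsub("\r", " / ", key[duplicated(key)][1]))
  }
  raw_totals <- tapply(counts$count, counts$sample_id, sum)
  if (any(raw_totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(names(raw_totals)[raw_totals == 0], collapse = ", "))
  }
  adj <- counts$count + pseudocount
  totals <- tapply(adj, counts$sample_id, sum)
  counts$rpm <- adj / as.numeric(totals[counts$sample_id]) * 1e6
  counts
}

#' Pulldown enrichment ratios against the scrambled-control pulldown
#'
#' For one miRNA condition, computes per-gene enrichment as the RPM in the
#' miRNA pulldown divided by the RPM in the control pulldown, and flags
#' candidates at the over-representation threshold (default 100-fold).
#' Input-sample RPMs are carried through for reporting but do not gate
#' candidacy. Genes whose control pulldown had zero raw reads are flagged
#' `pseudocount_dominated`: their ratio rests on the pseudocount alone.
#'
#' @param counts raw count table (see [rpm_normalize()]); normalized
#'   internally if no `rpm` column is present.
#' @param mirna_id the miRNA condition to contrast against `"control"`.
#' @param threshold candidate threshold on the enrichment ratio
#'   (default 100); must be > 1.
#' @param pseudocount passed to [rpm_normalize()] when needed.
#' @return data.frame ordered by `enrichment_ratio` descending with
#'   columns `gene_id`, `rpm_control_pulldown`, `rpm_mirna_pulldown`,
#'   input RPMs where available, `enrichment_ratio`, `is_candidate`,
#'   `pseudocount_dominated`.
#' @export
enrichment_table <- function(counts, mirna_id, threshold = 100, pseudocount = 0.5) {
  if (threshold <= 1) stop("threshold must be > 1")
  if (is.null(counts$rpm)) counts <- rpm_normalize(counts, pseudocount)
  pd <- counts[counts$role == "pulldown", ]
  ctrl <- pd[pd$condition == "control", ]
  mir <- pd[pd$condition == mirna_id, ]
  if (!nrow(mir)) stop("no pulldown sample for condition '", mirna_id, "'")
  genes <- sort(unique(ctrl$gene_id))
  if (!setequal(genes, unique(mir$gene_id))) {
    stop("pulldown samples do not share the same gene universe")
  }
  ctrl <- ctrl[match(genes, ctrl$gene_id), ]
  mir <- mir[match(genes, mir$gene_id), ]
  out <- data.frame(
    gene_id = genes,
    rpm_control_pulldown = ctrl$rpm,
    rpm_mirna_pulldown = mir$rpm,
    stringsAsFactors = FALSE
  )
  inp <- counts[counts$role == "input", ]
  if (nrow(inp)) {
    for (cond in unique(inp$condition)) {
      v <- inp[inp$condition == cond, ]
      out[[paste0("rpm_input_", cond)]] <- v$rpm[match(genes, v$gene_id)]
    }
  }
  out$enrichment_ratio <- out$rpm_mirna_pulldown / out$rpm_control_pulldown
  out$is_candidate <- out$enrichment_ratio >= threshold
  out$pseudocount_dominated <- ctrl$count == 0
  out <- out[order(-out$enrichment_ratio, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "mirna_id") <- mirna_id
  attr(out, "threshold") <- threshold
  out
}

#' Call pulldown candidate targets
#'
#' Genes at least `threshold`-fold over-represented in the miRNA pulldown
#' relative to the scrambled-control pulldown, ordered by enrichment ratio
#' descending.
#'
#' @param enrichment table from [enrichment_table()].
#' @param threshold over-representation threshold (> 1); defaults to the
#'   threshold the table was built with.
#' @return a [candidate_set()] with `source = "pulldown"`.
#' @export
call_candidates <- function(enrichment, threshold = attr(enrichment, "threshold")) {
  if (is.null(threshold)) threshold <- 100
  if (threshold <= 1) stop("threshold must be > 1")
  genes <- enrichment$gene_id[enrichment$enrichment_ratio >= threshold]
  candidate_set(attr(enrichment, "mirna_id"), "pulldown", genes)
}
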