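#' The five binding-site prediction algorithms
#'
#' Fixed algorithm universe for k-of-5 consensus calling.
#' @export
PREDICTION_ALGORITHMS <- c("miRanda", "PicTar", "TargetScan", "RNA22", "PITA")

#' Construct a candidate gene set
#'
#' Lightweight container tying an ordered gene set to the miRNA it was
#' called for and the evidence source.
#'
#' @param mirna_id miRNA identifier.
#' @param source one of `"pulldown"`, `"consensus"`, `"intersection"`.
#' @param genes character vector of gene symbols (order preserved,
#'   duplicates dropped).
#' @param k_required consensus support level, 1-5 (consensus sets only).
#' @return object of class `"candidate_set"`.
#' @export
candidate_set <- function(mirna_id, source, genes, k_required = NA_integer_) {
  source <- match.arg(source, c("pulldown", "consensus", "intersection"))
  structure(
    list(mirna_id = mirna_id, source = source,
         genes = unique(as.character(genes)), k_required = k_required),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d gene(s) for %s [%s%s]\n",
              length(x$genes), x$mirna_id, x$source,
              if (!is.na(x$k_required)) paste0(", k>=", x$k_required) else ""))
  if (length(x$genes)) cat(" ", paste(utils::head(x$genes, 20), collapse = ", "),
                           if (length(x$genes) > 20) "..." else "", "\n")
  invisible(x)
}

normalize_symbol <- function(x) toupper(trimws(as.character(x)))

#' k-of-5 prediction consensus targets
#'
#' Genes predicted as targets of a miRNA by at least `k` of the five
#' binding-site algorithms (miRanda, PicTar, TargetScan, RNA22, PITA).
#' Gene symbols are matched case-insensitively after whitespace stripping.
#'
#' @param predictions data.frame with columns `gene_id`, `mirna_id`,
#'   `algorithm`; one row per predicted (gene, miRNA, algorithm).
#' @param mirna_id miRNA to call targets for.
#' @param k minimum number of supporting algorithms, 1-5 (default 5).
#' @return a [candidate_set()] with `source = "consensus"`, genes ordered
#'   by support count descending then symbol; the per-gene support counts
#'   are attached as attribute `support`.
#' @export
consensus_targets <- function(predictions, mirna_id, k = 5) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 5) {
    stop("k must be an integer between 1 and 5")
  }
  required <- c("gene_id", "mirna_id", "algorithm")
  missing_cols <- setdiff(required, names(predictions))
  if (length(missing_cols)) {
    stop("prediction table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(predictions$algorithm), PREDICTION_ALGORITHMS)
  if (length(bad)) {
    stop("unknown prediction algorithm(s): ", paste(bad, collapse = ", "))
  }
  p <- predictions[predictions$mirna_id == mirna_id, ]
  p$gene <- normalize_symbol(p$gene_id)
  p <- unique(p[, c("gene", "algorithm")])
  support <- table(p$gene)
  support <- sort(support, decreasing = TRUE)
  genes <- names(support)[support >= k]
  # order: support desc, then symbol
  ord <- order(-as.integer(support[genes]), genes)
  cs <- candidate_set(mirna_id, "consensus", genes[ord], k_required = as.integer(k))
  attr(cs, "support") <- support
  cs
}

#' Intersect consensus and pulldown candidate sets
#'
#' The strongest candidates: genes both computationally predicted (k-of-5
#' consensus) and experimentally recovered in the biotin-mimic pulldown.
#' Both sets must refer to the same miRNA.
#'
#' @param a,b [candidate_set()] objects for the same miRNA.
#' @return a [candidate_set()] with `source = "intersection"`, genes
#'   sorted alphabetically.
#' @export
intersect_candidates <- function(a, b) {
  stopifnot(inherits(a, "candidate_set"), inherits(b, "candidate_set"))
  if (!identical(a$mirna_id, b$mirna_id)) {
    stop("candidate sets refer to different miRNAs: ",
         a$mirna_id, " vs ", b$mirna_id)
  }
  genes <- sort(intersect(normalize_symbol(a$genes), normalize_symbol(b$genes)))
  k <- if (!is.na(a$k_required)) a$k_required else b$k_required
  candidate_set(a$mirna_id, "intersection", genes, k_required = k)
}

#' Write / read a candidate set as TSV
#'
#' @param x a [candidate_set()].
#' @param path file path.
#' @return `write_candidate_set` returns `path` invisibly;
#'   `read_candidate_set` returns the reconstructed [candidate_set()].
#' @export
write_candidate_set <- function(x, path) {
  stopifnot(inherits(x, "candidate_set"))
  df <- data.frame(
    mirna_id = rep(x$mirna_id, length.out = max(1, length(x$genes))),
    source = x$source,
    k_required = x$k_required,
    gene_id = if (length(x$genes)) x$genes else NA_character_,
    stringsAsFactors = FALSE
  )
  if (!length(x$genes)) df <- df[0, ]
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_candidate_set
#' @export
read_candidate_set <- function(path) {
  df <- read_tsv_checked(path, c("mirna_id", "source", "k_required", "gene_id"))
  if (!nrow(df)) stop("empty candidate set file: ", path)
  candidate_set(df$mirna_id[1], df$source[1], df$gene_id[!is.na(df$gene_id)],
                k_required = df$k_required[1])
}
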