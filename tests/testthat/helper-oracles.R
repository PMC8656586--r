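# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementation paths.

# Product-limit survival by direct risk-set tabulation.
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

# Unweighted log-rank chi-square by observed-minus-expected over pooled
# risk sets, hypergeometric variance.
oracle_logrank <- function(time, event, group) {
  group <- factor(group)
  lev <- levels(droplevels(group))
  stopifnot(length(lev) == 2)
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Delta-delta Ct folds from first principles on a complete (no-dropout)
# wide Ct matrix: mirnas x 2 columns (pre, post) for one case.
oracle_ddct_case <- function(ct_pre, ct_post) {
  dpre <- ct_pre - mean(ct_pre)
  dpost <- ct_post - mean(ct_post)
  2^(-(dpost - dpre))
}

# Enrichment calls from first principles on a small count table.
oracle_enrichment_calls <- function(counts, mirna_id, threshold,
                                    pseudocount = 0.5) {
  pd <- counts[counts$role == "pulldown", ]
  ctrl <- pd[pd$condition == "control", ]
  mir <- pd[pd$condition == mirna_id, ]
  genes <- sort(unique(ctrl$gene_id))
  rpm <- function(d) {
    d <- d[match(genes, d$gene_id), ]
    (d$count + pseudocount) / sum(d$count + pseudocount) * 1e6
  }
  ratio <- rpm(mir) / rpm(ctrl)
  sort(genes[ratio >= threshold])
}

# Exact sign-flip permutation p-value for the paired one-tailed t test.
oracle_paired_perm_p <- function(x, y, direction = "greater") {
  d <- x - y
  n <- length(d)
  tstat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  obs <- tstat(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  perm <- apply(signs, 1, function(s) tstat(d * s))
  if (direction == "greater") mean(perm >= obs) else mean(perm <= obs)
}

# Small deterministic plate builder for chemoresponse tests.
make_plate <- function(conditions, doses, bio_reps = 2, signal_fun) {
  grid <- expand.grid(condition = conditions, dose_nM = doses,
                      bio_rep = seq_len(bio_reps), tech_rep = 1:2,
                      stringsAsFactors = FALSE)
  grid$signal <- signal_fun(grid)
  grid
}
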