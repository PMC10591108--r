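# Independent brute-force oracles used across test files. These stay
# deliberately naive: direct evaluation of definitions, no shared code with
# the implementation.

# Benjamini-Hochberg step-up, evaluated literally from the definition:
# q_i = min over j with p_(j) >= p_(i) of min(1, m p_(j) / rank(j)).
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Set of genome bases covered by a set of 0-based half-open intervals on one
# chromosome, as integer base indices.
bf_bases <- function(starts, ends) {
  unique(unlist(mapply(function(s, e) seq.int(s, e - 1L), starts, ends,
                       SIMPLIFY = FALSE)))
}

# Two-sided Fisher exact p for table [[a, b], [c, d]] by full enumeration
# with exact binomial coefficients (minimum-likelihood rule).
bf_fisher_p <- function(a, b, c, d) {
  K <- a + c
  n <- a + b
  N <- a + b + c + d
  support <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  obs <- choose(K, a) * choose(N - K, n - a) / choose(N, n)
  sum(probs[probs <= obs * (1 + 1e-07)])
}

# Event-time-by-event-time two-group log-rank tabulation.
bf_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Direct simulation of a just-identified IV problem without the cohort
# generator: binary instrument z, endogenous x confounded with the outcome
# error through u.
sim_iv <- function(n, beta1, a1 = 1.5, gamma = 0.8, delta = 0.8,
                   p_mut = 0.3) {
  z <- stats::rbinom(n, 1, p_mut)
  u <- stats::rnorm(n)
  expr <- stats::rnorm(n)
  x <- 2 + a1 * z + 0.5 * expr + gamma * u + stats::rnorm(n, sd = 0.5)
  y <- 1 + beta1 * x + delta * u + stats::rnorm(n, sd = 0.5)
  list(y = y, x = x, z = z,
       exog = cbind(`(Intercept)` = 1, expression = expr))
}

# Small synthetic peak_set built directly from a coordinate table.
make_peak_set <- function(df, sample_id = "CL1", factor_id = "F1",
                          factor_class = "TF", dialect = "narrowPeak") {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(df$name)) df$name <- sprintf("p%d", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  structure(list(sample_id = sample_id, factor_id = factor_id,
                 factor_class = factor_class, dialect = dialect,
                 intervals = df[, c("chrom", "start", "end", "name",
                                    "score", "strand", "signal")]),
            class = "peak_set")
}

# Compact generator configuration for simulation-heavy tests.
small_config <- function(n = 200, beta1 = 1.5, gamma = 0.8, delta = 0.8,
                         seed = 1L, n_cancer_types = 3) {
  generator_config(
    n_cell_lines = n, n_cancer_types = n_cancer_types, n_tfs = 2, n_hms = 1,
    planted_pairs = data.frame(tf = 1L, hm = 1L, beta1 = beta1),
    confounder_strengths = c(gamma = gamma, delta = delta),
    n_genes = 20, n_drugs = 4, n_patients = 20, seed = seed)
}

# Raw-scale IV fit of the planted pair of a cohort: returns the pieces the
# simulation tests need.
fit_planted_pair <- function(cohort) {
  tf <- cohort$truth$planted_pairs$tf[1]
  hm <- cohort$truth$planted_pairs$hm[1]
  ct <- factor(cohort$cancer_type)
  exog <- cbind(`(Intercept)` = 1, expression = cohort$expression[, tf])
  if (nlevels(ct) >= 2) {
    d <- stats::model.matrix(~ ct)[, -1, drop = FALSE]
    exog <- cbind(exog, d)
  }
  fit_2sls(cohort$hm_activity[, hm], cohort$tf_activity[, tf], exog,
           cohort$mutation[, tf])
}

ols_planted_slope <- function(cohort) {
  tf <- cohort$truth$planted_pairs$tf[1]
  hm <- cohort$truth$planted_pairs$hm[1]
  ct <- factor(cohort$cancer_type)
  X <- cbind(`(Intercept)` = 1, tf = cohort$tf_activity[, tf],
             expression = cohort$expression[, tf])
  if (nlevels(ct) >= 2) {
    X <- cbind(X, stats::model.matrix(~ ct)[, -1, drop = FALSE])
  }
  unname(fit_ols(cohort$hm_activity[, hm], X)$coefficients["tf"])
}
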