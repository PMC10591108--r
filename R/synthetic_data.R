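# Synthetic cohorts with a known mutation -> TF activity -> histone mark
# causal chain, latent confounding, and all downstream assets (dependency
# scores, gene sets, drug response, survival, interaction network).

HISTONE_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3",
                   "H3K79me2", "H3K9ac", "H4K20me1")

#' Configuration for the synthetic cohort generator
#'
#' Encodes the structural causal model the analysis assumes. For every cell
#' line i, transcription factor j and histone mark k:
#' \deqn{TF_{ij} = \mu_{TF} + a_1 Mut_{ij} + a_2 E_{ij} + \gamma U_{ip} + c_{T(i)j} + \epsilon_{ij}}
#' \deqn{HM_{ik} = \mu_{HM} + \beta_1 TF_{ij} + \delta U_{ip} + c_{T(i)k} + \eta_{ik}}
#' where `Mut` is Bernoulli mutation status (the instrument), `E` expression,
#' `U_p` a latent standard-normal confounder shared by the TF and mark of
#' planted pair p (one independent confounder per planted pair), `c` a
#' cancer-type effect, and the noise terms Gaussian. Unplanted pairs have
#' `beta1 = 0` and no shared confounder, so the only honest signal is the
#' planted causal chain.
#'
#' @param n_cell_lines,n_cancer_types,n_tfs,n_hms cohort dimensions.
#' @param planted_pairs data frame (or list of length-3 vectors) with columns
#'   `tf`, `hm` (1-based factor indices) and `beta1`, the true causal effect
#'   on the activity scale.
#' @param mutation_prob per-(cell line, TF) Bernoulli mutation probability.
#' @param instrument_strength effect `a1` of mutation on TF activity.
#' @param confounder_strengths named vector `c(gamma=, delta=)`: effect of the
#'   latent confounder on TF and mark activity respectively.
#' @param expression_effect effect `a2` of expression on TF activity.
#' @param cancer_effect_sd sd of per-(cancer type, factor) random shifts.
#' @param noise_sd_tf,noise_sd_hm sd of the Gaussian noise terms.
#' @param n_loci_per_pair co-bound loci planted per causal pair.
#' @param n_private_loci peaks unique to each factor (no cross-factor overlap).
#' @param n_genes,n_drugs,n_patients sizes of the downstream assets.
#' @param censoring_rate fraction of survival records censored, in `[0, 1)`.
#' @param hazard_ratio planted mutated-vs-wildtype hazard ratio for survival.
#' @param tf_intercept,hm_intercept activity baselines; kept well above zero
#'   so peak signal values (`2^activity - 1`) stay positive.
#' @param n_chroms,chrom_length toy genome used for peak coordinates.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(n_cell_lines = 60, n_cancer_types = 4,
                             n_tfs = 12, n_hms = 3,
                             planted_pairs = data.frame(
                               tf = c(1L, 2L), hm = c(1L, 2L),
                               beta1 = c(1.5, 1.5)),
                             mutation_prob = 0.3,
                             instrument_strength = 1.5,
                             confounder_strengths = c(gamma = 0.8, delta = 0.8),
                             expression_effect = 0.5,
                             cancer_effect_sd = 0.3,
                             noise_sd_tf = 0.5, noise_sd_hm = 0.5,
                             n_loci_per_pair = 25, n_private_loci = 15,
                             n_genes = 400, n_drugs = 40, n_patients = 300,
                             censoring_rate = 0.2, hazard_ratio = 2,
                             tf_intercept = 5, hm_intercept = 1,
                             n_chroms = 2, chrom_length = 1e6,
                             seed = 1L) {
  if (is.list(planted_pairs) && !is.data.frame(planted_pairs)) {
    planted_pairs <- do.call(rbind, lapply(planted_pairs, function(v) {
      data.frame(tf = as.integer(v[1]), hm = as.integer(v[2]), beta1 = v[3])
    }))
  }
  cfg <- list(
    n_cell_lines = as.integer(n_cell_lines),
    n_cancer_types = as.integer(n_cancer_types),
    n_tfs = as.integer(n_tfs), n_hms = as.integer(n_hms),
    planted_pairs = planted_pairs,
    mutation_prob = mutation_prob,
    instrument_strength = instrument_strength,
    confounder_strengths = confounder_strengths,
    expression_effect = expression_effect,
    cancer_effect_sd = cancer_effect_sd,
    noise_sd_tf = noise_sd_tf, noise_sd_hm = noise_sd_hm,
    n_loci_per_pair = as.integer(n_loci_per_pair),
    n_private_loci = as.integer(n_private_loci),
    n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
    n_patients = as.integer(n_patients),
    censoring_rate = censoring_rate, hazard_ratio = hazard_ratio,
    tf_intercept = tf_intercept, hm_intercept = hm_intercept,
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  counts <- c("n_cell_lines", "n_cancer_types", "n_tfs", "n_hms",
              "n_loci_per_pair", "n_genes", "n_drugs", "n_patients")
  for (nm in counts) {
    assert_that(length(cfg[[nm]]) == 1 && !is.na(cfg[[nm]]) && cfg[[nm]] >= 1,
                "configuration error: %s must be a count >= 1", nm)
  }
  assert_that(cfg$mutation_prob > 0 && cfg$mutation_prob < 1,
              "configuration error: mutation_prob must lie in (0, 1)")
  assert_that(cfg$noise_sd_tf > 0 && cfg$noise_sd_hm > 0,
              "configuration error: noise sds must be positive")
  assert_that(cfg$censoring_rate >= 0 && cfg$censoring_rate < 1,
              "configuration error: censoring_rate must lie in [0, 1)")
  assert_that(cfg$n_hms <= length(HISTONE_MARKS),
              "configuration error: at most %d histone marks supported",
              length(HISTONE_MARKS))
  pp <- cfg$planted_pairs
  assert_that(is.data.frame(pp) && all(c("tf", "hm", "beta1") %in% names(pp)),
              "configuration error: planted_pairs needs tf, hm, beta1 columns")
  assert_that(all(pp$tf >= 1 & pp$tf <= cfg$n_tfs) &&
              all(pp$hm >= 1 & pp$hm <= cfg$n_hms),
              "configuration error: planted pair indices out of range")
  invisible(cfg)
}

#' Expected OLS bias of the mark-on-TF slope under planted confounding
#'
#' For a planted pair, ordinary least squares of mark activity on TF activity
#' (controlling expression and cancer type) converges to
#' `beta1 + gamma*delta*Var(U) / Var_resid(TF)`, where `Var_resid(TF)` is the
#' TF activity variance left after partialling out the controlled covariates:
#' `a1^2 p(1-p) + gamma^2 + noise_sd_tf^2` (Var(U) = 1 by construction).
#'
#' @param config a [generator_config()].
#' @return the asymptotic bias (a positive number when `gamma*delta > 0`).
#' @export
expected_ols_bias <- function(config) {
  p <- config$mutation_prob
  g <- config$confounder_strengths[["gamma"]]
  d <- config$confounder_strengths[["delta"]]
  var_tf <- config$instrument_strength^2 * p * (1 - p) + g^2 +
    config$noise_sd_tf^2
  g * d / var_tf
}

# Deterministic genomic layout for peaks: non-overlapping anchor positions on
# the toy genome, split into shared loci (per planted pair) and private loci
# (per factor). Uses its own substream so cohort draws are unaffected.
peak_layout <- function(config) {
  set.seed(child_seed(config$seed, 1))
  n_pairs <- nrow(config$planted_pairs)
  n_anchor <- n_pairs * config$n_loci_per_pair +
    (config$n_tfs + config$n_hms) * config$n_private_loci
  slot_w <- 2500L
  per_chrom <- (config$chrom_length - slot_w) %/% slot_w
  assert_that(n_anchor <= per_chrom * config$n_chroms,
              "configuration error: toy genome too small for requested loci")
  chrom <- paste0("chr", rep(seq_len(config$n_chroms), each = per_chrom))
  pos <- rep(seq(0L, by = slot_w, length.out = per_chrom), config$n_chroms)
  pick <- sample(length(pos), n_anchor)
  anchors <- data.frame(chrom = chrom[pick], pos = pos[pick],
                        stringsAsFactors = FALSE)
  i <- 0L
  shared <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    shared[[p]] <- anchors[i + seq_len(config$n_loci_per_pair), ]
    i <- i + config$n_loci_per_pair
  }
  private_tf <- vector("list", config$n_tfs)
  for (j in seq_len(config$n_tfs)) {
    private_tf[[j]] <- anchors[i + seq_len(config$n_private_loci), ]
    i <- i + config$n_private_loci
  }
  private_hm <- vector("list", config$n_hms)
  for (k in seq_len(config$n_hms)) {
    private_hm[[k]] <- anchors[i + seq_len(config$n_private_loci), ]
    i <- i + config$n_private_loci
  }
  list(shared = shared, private_tf = private_tf, private_hm = private_hm)
}

#' Generate a synthetic cohort from the structural causal model
#'
#' Draws mutation status, expression, latent confounders, cancer-type effects
#' and noise, then builds TF and histone-mark activity matrices according to
#' the model documented in [generator_config()]. All realized latent values
#' are recorded in `$truth` so expected biases can be recomputed analytically.
#'
#' @param config a [generator_config()].
#' @return a `synthetic_cohort` list: `tf_activity`, `hm_activity` (cell line
#'   x factor matrices), `mutation` (binary), `expression`, `cancer_type`
#'   (named factor), and `truth` (config, realized confounders, layout).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_cell_lines
  cells <- sprintf("CL%03d", seq_len(n))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  hms <- HISTONE_MARKS[seq_len(config$n_hms)]
  cancer <- factor(sprintf("cancer%02d",
                           rep_len(seq_len(config$n_cancer_types), n)))
  names(cancer) <- cells

  mut <- matrix(stats::rbinom(n * config$n_tfs, 1, config$mutation_prob),
                n, config$n_tfs, dimnames = list(cells, tfs))
  expr <- matrix(stats::rnorm(n * config$n_tfs), n, config$n_tfs,
                 dimnames = list(cells, tfs))
  pp <- config$planted_pairs
  U <- matrix(stats::rnorm(n * max(1L, nrow(pp))), n, max(1L, nrow(pp)))
  rownames(U) <- cells

  ct_tf <- matrix(stats::rnorm(config$n_cancer_types * config$n_tfs,
                               sd = config$cancer_effect_sd),
                  config$n_cancer_types, config$n_tfs)
  ct_hm <- matrix(stats::rnorm(config$n_cancer_types * config$n_hms,
                               sd = config$cancer_effect_sd),
                  config$n_cancer_types, config$n_hms)
  eps_tf <- matrix(stats::rnorm(n * config$n_tfs, sd = config$noise_sd_tf),
                   n, config$n_tfs)
  eps_hm <- matrix(stats::rnorm(n * config$n_hms, sd = config$noise_sd_hm),
                   n, config$n_hms)

  g <- config$confounder_strengths[["gamma"]]
  d <- config$confounder_strengths[["delta"]]
  ci <- as.integer(cancer)

  tf_act <- config$tf_intercept +
    config$instrument_strength * mut +
    config$expression_effect * expr +
    ct_tf[ci, , drop = FALSE] + eps_tf
  for (p in seq_len(nrow(pp))) {
    tf_act[, pp$tf[p]] <- tf_act[, pp$tf[p]] + g * U[, p]
  }

  hm_act <- config$hm_intercept +
    ct_hm[ci, , drop = FALSE] + eps_hm
  for (p in seq_len(nrow(pp))) {
    hm_act[, pp$hm[p]] <- hm_act[, pp$hm[p]] +
      pp$beta1[p] * tf_act[, pp$tf[p]] + d * U[, p]
  }
  dimnames(tf_act) <- list(cells, tfs)
  dimnames(hm_act) <- list(cells, hms)

  cohort <- list(
    tf_activity = tf_act, hm_activity = hm_act,
    mutation = mut, expression = expr, cancer_type = cancer,
    truth = list(config = config, confounder = U,
                 cancer_effect_tf = ct_tf, cancer_effect_hm = ct_hm,
                 noise_tf = eps_tf, noise_hm = eps_hm,
                 planted_pairs = data.frame(
                   tf = tfs[pp$tf], hm = hms[pp$hm], beta1 = pp$beta1,
                   stringsAsFactors = FALSE),
                 layout = peak_layout(config)))
  class(cohort) <- "synthetic_cohort"
  cohort
}

# One synthetic peak table. TF peaks are 400 bp centered inside the 1 kb
# histone peak at shared anchors, so each planted locus yields a 400 bp
# co-bound intersection. Signal is constant within a file and chosen so the
# mean log2(1 + signal) equals the cohort activity exactly.
peak_table <- function(anchors, width, offset, activity, factor_id) {
  if (activity <= 0) {
    warning("activity <= 0 for ", factor_id,
            "; peak signal floored at 1e-06", call. = FALSE)
  }
  signal <- max(2^activity - 1, 1e-06)
  ord <- order(anchors$chrom, anchors$pos)
  anchors <- anchors[ord, , drop = FALSE]
  data.frame(chrom = anchors$chrom,
             start = anchors$pos + offset,
             end = anchors$pos + offset + width,
             name = sprintf("%s_peak%d", factor_id, seq_len(nrow(anchors))),
             score = as.integer(pmin(1000, round(signal))),
             strand = ".",
             signalValue = signal,
             pValue = -1, qValue = -1,
             stringsAsFactors = FALSE)
}

#' Write narrowPeak / broadPeak files for a synthetic cohort
#'
#' Emits one narrowPeak file per (cell line, TF) and one broadPeak file per
#' (cell line, histone mark) on the toy genome, 0-based half-open. Planted
#' pairs share co-bound anchors; every factor also carries private peaks.
#' Reading the files back and applying [activity_score()] reproduces the
#' cohort's activity values exactly.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir writable directory (created if missing).
#' @return manifest data frame: cell_line, factor_id, factor_class, dialect,
#'   path, n_peaks.
#' @export
generate_peak_files <- function(cohort, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  assert_that(ok && file.access(out_dir, 2) == 0,
              "I/O error: cannot write to %s", out_dir)
  cfg <- cohort$truth$config
  layout <- cohort$truth$layout
  pp <- cfg$planted_pairs
  tfs <- colnames(cohort$tf_activity)
  hms <- colnames(cohort$hm_activity)
  rows <- list()
  for (cell in rownames(cohort$tf_activity)) {
    for (j in seq_along(tfs)) {
      anchors <- layout$private_tf[[j]]
      for (p in which(pp$tf == j)) {
        anchors <- rbind(anchors, layout$shared[[p]])
      }
      tab <- peak_table(anchors, width = 400L, offset = 300L,
                        activity = cohort$tf_activity[cell, j],
                        factor_id = tfs[j])
      tab$peak <- -1L  # narrowPeak point-source column
      path <- file.path(out_dir, sprintf("%s__%s.narrowPeak", cell, tfs[j]))
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell, factor_id = tfs[j], factor_class = "TF",
        dialect = "narrowPeak", path = path, n_peaks = nrow(tab),
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(hms)) {
      anchors <- layout$private_hm[[k]]
      for (p in which(pp$hm == k)) {
        anchors <- rbind(anchors, layout$shared[[p]])
      }
      tab <- peak_table(anchors, width = 1000L, offset = 0L,
                        activity = cohort$hm_activity[cell, k],
                        factor_id = hms[k])
      path <- file.path(out_dir, sprintf("%s__%s.broadPeak", cell, hms[k]))
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell, factor_id = hms[k], factor_class = "HM",
        dialect = "broadPeak", path = path, n_peaks = nrow(tab),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate downstream characterization assets for a synthetic cohort
#'
#' Builds every input the post-IV stages consume, each with a planted,
#' recoverable signal: (i) a gene x cell-line CERES matrix whose dependency
#' block is centered below zero; (ii) gene sets (GMT-style) including one
#' enriched in the planted target genes; (iii) a drug x cell-line IC50 matrix
#' linearly coupled to mean target-gene expression for one drug class;
#' (iv) a survival table whose hazard depends on mutation status of the first
#' planted TF; (v) an interaction score table (0-1000) with a planted hub of
#' degree >= 5 above score 700. A gene annotation places planted target gene
#' TSSs at the planted co-bound loci so target-gene assignment recovers them.
#'
#' @param cohort a [generate_cohort()] result.
#' @param ic50_coupling slope of IC50 on mean planted-target expression for
#'   the coupled drug class.
#' @return named list of assets plus `planted` ground truth.
#' @export
generate_downstream_assets <- function(cohort, ic50_coupling = 1) {
  cfg <- cohort$truth$config
  set.seed(child_seed(cfg$seed, 2))
  cells <- rownames(cohort$tf_activity)
  n <- length(cells)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  dep_block <- genes[seq_len(min(40L, cfg$n_genes))]
  target_genes <- genes[seq_len(min(60L, cfg$n_genes))]

  ceres <- matrix(stats::rnorm(cfg$n_genes * n, mean = 0, sd = 0.2),
                  cfg$n_genes, n, dimnames = list(genes, cells))
  ceres[dep_block, ] <- ceres[dep_block, ] - 1

  # gene sets: one enriched in planted targets, the rest random draws
  set_size <- min(40, cfg$n_genes)
  sets <- list(PLANTED_TARGET_PROGRAM = sample(target_genes,
                                               min(set_size,
                                                   length(target_genes))))
  for (s in 2:8) {
    sets[[sprintf("RANDOM_SET_%02d", s)]] <- sample(genes, set_size)
  }
  collection <- gene_set_collection(sets, universe = genes)

  # annotation: planted targets sit on planted co-bound anchors
  shared <- do.call(rbind, cohort$truth$layout$shared)
  tss <- sample.int(cfg$chrom_length - 1L, cfg$n_genes)
  chrom <- paste0("chr", sample.int(cfg$n_chroms, cfg$n_genes, replace = TRUE))
  idx <- seq_along(target_genes)
  anchor_idx <- rep_len(seq_len(nrow(shared)), length(idx))
  chrom[idx] <- shared$chrom[anchor_idx]
  tss[idx] <- shared$pos[anchor_idx] + 500L
  annotation <- data.frame(gene_id = genes, chrom = chrom, tss = tss,
                           strand = sample(c("+", "-"), cfg$n_genes,
                                           replace = TRUE),
                           stringsAsFactors = FALSE)

  gene_expr <- matrix(stats::rnorm(n * cfg$n_genes), n, cfg$n_genes,
                      dimnames = list(cells, genes))
  mean_target <- rowMeans(gene_expr[, target_genes, drop = FALSE])

  drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))
  n_coupled <- max(1L, cfg$n_drugs %/% 4L)
  drug_classes <- data.frame(
    drug = drugs,
    class = c(rep("PLANTED_CLASS", n_coupled),
              rep_len(c("CLASS_B", "CLASS_C", "CLASS_D"),
                      cfg$n_drugs - n_coupled)),
    stringsAsFactors = FALSE)
  ic50 <- matrix(stats::rnorm(cfg$n_drugs * n, mean = 1, sd = 0.5),
                 cfg$n_drugs, n, dimnames = list(drugs, cells))
  coupled <- drug_classes$class == "PLANTED_CLASS"
  ic50[coupled, ] <- ic50[coupled, ] +
    matrix(rep(ic50_coupling * mean_target, sum(coupled)),
           sum(coupled), n, byrow = TRUE)

  # survival: exponential times, hazard scaled by mutation of the first
  # planted TF; censored records get a uniform fraction of their event time
  planted_tf <- cohort$truth$planted_pairs$tf[1]
  mut <- stats::rbinom(cfg$n_patients, 1, cfg$mutation_prob)
  rate <- log(2) / 60 * cfg$hazard_ratio^mut  # wildtype median 60 months
  time <- stats::rexp(cfg$n_patients, rate)
  censored <- stats::rbinom(cfg$n_patients, 1, cfg$censoring_rate) == 1
  time[censored] <- time[censored] * stats::runif(sum(censored))
  survival <- data.frame(
    id = sprintf("P%04d", seq_len(cfg$n_patients)),
    time = time, event = as.integer(!censored),
    mutated = mut,
    group = ifelse(mut == 1, "mutated", "wildtype"),
    cancer_type = sample(levels(cohort$cancer_type), cfg$n_patients,
                         replace = TRUE),
    stringsAsFactors = FALSE)

  # interaction table with a planted hub (gene 1, degree 6 above 700)
  hub <- genes[1]
  n_edges <- 3L * cfg$n_genes
  p1 <- sample(genes, n_edges, replace = TRUE)
  p2 <- sample(genes, n_edges, replace = TRUE)
  keep <- p1 != p2
  interactions <- data.frame(protein1 = p1[keep], protein2 = p2[keep],
                             combined_score = round(stats::runif(sum(keep),
                                                                 150, 1000)),
                             stringsAsFactors = FALSE)
  interactions <- rbind(
    data.frame(protein1 = hub, protein2 = genes[2:7], combined_score = 900,
               stringsAsFactors = FALSE),
    interactions)

  list(ceres = ceres, gene_sets = collection, gene_annotation = annotation,
       gene_expression = gene_expr, ic50 = ic50, drug_classes = drug_classes,
       survival = survival, interactions = interactions,
       planted = list(target_genes = target_genes, dependency_genes = dep_block,
                      enriched_set = "PLANTED_TARGET_PROGRAM",
                      coupled_class = "PLANTED_CLASS",
                      ic50_coupling = ic50_coupling,
                      hub = hub, survival_tf = planted_tf,
                      hazard_ratio = cfg$hazard_ratio))
}
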