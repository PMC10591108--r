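# End-to-end orchestration: activity quantification -> OLS screen -> IV
# stage -> downstream characterization, in synthetic or files mode, with
# deterministic outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read user
#'   tables).
#' @param out_dir output directory for stage tables and the manifest.
#' @param generator a [generator_config()] (synthetic mode).
#' @param seed overrides the generator seed when given.
#' @param stages character subset of
#'   `c("activity", "screen", "iv", "enrichment", "phenotype", "survival",
#'   "network")`; later stages silently require the earlier ones.
#' @param q FDR gate used for both the screen and the dual IV gate.
#' @param score_threshold interaction-score cutoff (default 700).
#' @param min_degree hub degree threshold (default 5).
#' @param ceres_bin_width dependency bin width (default 0.4).
#' @param horizon_months fixed survival horizon (default 60, i.e. 5 years).
#' @param promoter_window,enhancer_window TSS half-windows (bp) for target
#'   gene assignment; defaults are sized for the generator's compact toy
#'   genome, not for a real genome.
#' @param write_peaks materialize per-sample peak files and re-derive the
#'   activity matrices from them (synthetic mode; exercises the full I/O
#'   path, default TRUE).
#' @param paths named list of input paths (files mode): `tf_activity`,
#'   `hm_activity`, `expression`, `mutation`, `metadata` (TSV with
#'   cell_line, cancer_type), optional `interactions`, `survival`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            out_dir = tempfile("epidriver_run_"),
                            generator = generator_config(),
                            seed = NULL,
                            stages = c("activity", "screen", "iv",
                                       "enrichment", "phenotype",
                                       "survival", "network"),
                            q = 0.1, score_threshold = 700, min_degree = 5,
                            ceres_bin_width = 0.4, horizon_months = 60,
                            promoter_window = 2000, enhancer_window = 2000,
                            write_peaks = TRUE, paths = list()) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
  }
  cfg <- list(mode = mode, out_dir = out_dir, generator = generator,
              stages = stages, q = q, score_threshold = score_threshold,
              min_degree = min_degree, ceres_bin_width = ceres_bin_width,
              horizon_months = horizon_months,
              promoter_window = promoter_window,
              enhancer_window = enhancer_window,
              write_peaks = write_peaks, paths = paths)
  class(cfg) <- "pipeline_config"
  assert_that(q > 0 && score_threshold > 0 && min_degree > 0 &&
              ceres_bin_width > 0 && horizon_months > 0,
              "config error: thresholds must be positive")
  cfg
}

#' Validate pipeline inputs
#'
#' Collects all findings (fatal and warnings) rather than stopping at the
#' first: matrix index consistency, file existence, dialect/score sanity.
#'
#' @param config a [pipeline_config()].
#' @return data frame (level, message); zero rows means a clean bundle.
#' @export
validate_inputs <- function(config) {
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (config$mode == "files") {
    need <- c("tf_activity", "hm_activity", "expression", "mutation",
              "metadata")
    for (nm in need) {
      p <- config$paths[[nm]]
      if (is.null(p)) {
        note("fatal", paste0("missing input path: ", nm))
      } else if (!file.exists(p)) {
        note("fatal", paste0("input path does not exist: ", p))
      }
    }
    fatal <- length(findings) > 0
    if (!fatal) {
      mats <- lapply(config$paths[need[1:4]], read_matrix_tsv)
      cells <- rownames(mats$tf_activity)
      for (nm in c("hm_activity", "expression", "mutation")) {
        missing <- setdiff(cells, rownames(mats[[nm]]))
        if (length(missing)) {
          note("fatal", paste0(nm, " missing cell line(s): ",
                               paste(missing, collapse = ", ")))
        }
      }
      if (!all(mats$mutation %in% c(0, 1), na.rm = TRUE)) {
        note("fatal", "mutation matrix must be binary")
      }
      if (!is.null(config$paths$interactions)) {
        df <- read_tsv(config$paths$interactions)
        sc <- suppressWarnings(as.numeric(df$combined_score))
        bad <- which(is.na(sc) | sc < 0 | sc > 1000)
        if (length(bad)) {
          note("fatal", sprintf(
            "interaction combined_score outside [0, 1000] at line %d",
            bad[1] + 1L))
        }
      }
    }
  } else {
    chk <- try(validate_generator_config(config$generator), silent = TRUE)
    if (inherits(chk, "try-error")) {
      note("fatal", conditionMessage(attr(chk, "condition")))
    }
  }
  if (!length(findings)) {
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Run the full driver-discovery pipeline
#'
#' Executes the enabled stages in order, writes one TSV per stage plus a
#' JSON run manifest into `config$out_dir`, and returns the in-memory
#' results. Reruns with the same configuration (and seed) reproduce the
#' output tables byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  findings <- validate_inputs(config)
  fatal <- findings[findings$level == "fatal", , drop = FALSE]
  if (nrow(fatal)) {
    stop_usage("config error:\n%s", paste(fatal$message, collapse = "\n"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("epidriver")),
                   mode = config$mode, stages = list(), counts = list())
  res <- list()
  on <- function(stage) stage %in% config$stages
  record <- function(stage, status) {
    manifest$stages[[stage]] <<- status
  }

  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$generator)
    assets <- generate_downstream_assets(cohort)
    manifest$seed <- config$generator$seed
  } else {
    mats <- lapply(config$paths[c("tf_activity", "hm_activity",
                                  "expression", "mutation")],
                   read_matrix_tsv)
    meta <- read_tsv(config$paths$metadata)
    cancer <- factor(meta$cancer_type)
    names(cancer) <- meta$cell_line
    cohort <- list(tf_activity = mats$tf_activity,
                   hm_activity = mats$hm_activity,
                   expression = mats$expression,
                   mutation = mats$mutation,
                   cancer_type = cancer)
    assets <- NULL
  }
  res$cohort <- cohort

  # --- activity -----------------------------------------------------------
  tf_act <- cohort$tf_activity
  hm_act <- cohort$hm_activity
  peak_sets <- NULL
  if (on("activity") && config$mode == "synthetic" && config$write_peaks) {
    peak_dir <- file.path(config$out_dir, "peaks")
    man <- generate_peak_files(cohort, peak_dir)
    peak_sets <- lapply(seq_len(nrow(man)), function(i) {
      read_peak_file(man$path[i], man$dialect[i])
    })
    act <- build_activity_matrix(peak_sets, normalize = TRUE)
    cls <- attr(act, "factor_class")
    tf_act <- act[, names(cls)[cls == "TF"], drop = FALSE]
    hm_act <- act[, names(cls)[cls == "HM"], drop = FALSE]
    res$peak_manifest <- man
  } else if (on("activity")) {
    # activities arrive as matrices; z-score per factor for comparability
    tf_act <- scale(tf_act)
    hm_act <- scale(hm_act)
  }
  if (on("activity")) {
    write_matrix_tsv(tf_act, file.path(config$out_dir, "tf_activity.tsv"),
                     "cell_line")
    write_matrix_tsv(hm_act, file.path(config$out_dir, "hm_activity.tsv"),
                     "cell_line")
    record("activity", "ok")
    manifest$counts$cell_lines <- nrow(tf_act)
    manifest$counts$tfs <- ncol(tf_act)
    manifest$counts$hms <- ncol(hm_act)
  } else {
    record("activity", "skipped")
  }
  res$tf_activity <- tf_act
  res$hm_activity <- hm_act

  # --- screen + IV --------------------------------------------------------
  if (on("screen")) {
    candidates <- screen_candidates(tf_act, hm_act, cohort$expression,
                                    cohort$cancer_type,
                                    q_threshold = config$q)
    write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))
    res$candidates <- candidates
    record("screen", "ok")
    manifest$counts$candidates <- sum(candidates$selected)
  } else record("screen", "skipped")

  if (on("iv") && on("screen")) {
    drivers <- run_iv_stage(res$candidates, tf_act, hm_act,
                            cohort$expression, cohort$mutation,
                            cohort$cancer_type, q = config$q)
    write_tsv(drivers, file.path(config$out_dir, "drivers.tsv"))
    res$drivers <- drivers
    record("iv", "ok")
    manifest$counts$drivers <- sum(drivers$driver)
  } else record("iv", "skipped")

  driver_pairs <- if (!is.null(res$drivers))
    res$drivers[res$drivers$driver, , drop = FALSE] else NULL

  # --- target genes per driver pair (synthetic peak route only) ----------
  targets <- list()
  if (!is.null(driver_pairs) && nrow(driver_pairs) > 0 &&
      !is.null(peak_sets) && !is.null(assets)) {
    by_factor <- split(peak_sets,
                       vapply(peak_sets, function(p) p$factor_id, ""))
    for (i in seq_len(nrow(driver_pairs))) {
      tf <- driver_pairs$tf[i]
      hm <- driver_pairs$hm[i]
      tf_sets <- by_factor[[tf]]
      hm_sets <- by_factor[[hm]]
      names(tf_sets) <- vapply(tf_sets, function(p) p$sample_id, "")
      names(hm_sets) <- vapply(hm_sets, function(p) p$sample_id, "")
      loci <- pool_cobound_loci(tf_sets, hm_sets)
      targets[[paste0(tf, ":", hm)]] <- list(
        loci = loci,
        genes = assign_target_genes(loci, assets$gene_annotation, hm = hm,
                                    promoter_window = config$promoter_window,
                                    enhancer_window = config$enhancer_window))
    }
    res$targets <- targets
  }

  # --- enrichment ---------------------------------------------------------
  if (on("enrichment") && length(targets) && !is.null(assets)) {
    bins <- bin_genes_by_ceres(assets$ceres, width = config$ceres_bin_width)
    enr <- list()
    for (pair in names(targets)) {
      tg <- targets[[pair]]$genes
      if (!length(tg)) next
      fr <- lapply(setdiff(names(bins), "other"), function(b) {
        if (!length(bins[[b]])) return(NULL)
        row <- fisher_enrichment(tg, bins[[b]], rownames(assets$ceres))
        cbind(pair = pair, bin = b, row, stringsAsFactors = FALSE)
      })
      fr <- do.call(rbind, fr)
      hg <- hypergeom_enrichment(tg, assets$gene_sets)
      hg <- cbind(pair = pair, hg, stringsAsFactors = FALSE)
      enr[[pair]] <- list(ceres_bins = fr, hallmark = hg)
    }
    if (length(enr)) {
      write_tsv(do.call(rbind, lapply(enr, `[[`, "ceres_bins")),
                file.path(config$out_dir, "ceres_bin_enrichment.tsv"))
      write_tsv(do.call(rbind, lapply(enr, `[[`, "hallmark")),
                file.path(config$out_dir, "gene_set_enrichment.tsv"))
    }
    res$enrichment <- enr
    record("enrichment", "ok")
  } else record("enrichment", "skipped")

  # --- phenotype: per-cancer correlation + drug response ------------------
  if (on("phenotype") && length(targets) && !is.null(assets)) {
    cors <- lapply(names(targets), function(pair) {
      loci <- targets[[pair]]$loci
      if (!nrow(loci)) return(NULL)
      cbind(pair = pair,
            pearson_by_cancer(loci, cohort$cancer_type),
            stringsAsFactors = FALSE)
    })
    cors <- do.call(rbind, cors)
    if (!is.null(cors)) {
      write_tsv(cors, file.path(config$out_dir, "pair_cancer_correlation.tsv"))
    }
    drug <- lapply(names(targets), function(pair) {
      tg <- intersect(targets[[pair]]$genes, colnames(assets$gene_expression))
      if (length(tg) < 1) return(NULL)
      me <- rowMeans(assets$gene_expression[, tg, drop = FALSE])
      rows <- drug_response_assoc(assets$ic50, me, cohort$cancer_type)
      cbind(pair = pair, rows, stringsAsFactors = FALSE)
    })
    drug <- do.call(rbind, drug)
    if (!is.null(drug)) {
      write_tsv(drug, file.path(config$out_dir, "drug_association.tsv"))
      cls <- lapply(split(drug, drug$pair), function(sub) {
        cbind(pair = sub$pair[1],
              class_level_summary(sub, assets$drug_classes),
              stringsAsFactors = FALSE)
      })
      write_tsv(do.call(rbind, cls),
                file.path(config$out_dir, "drug_class_summary.tsv"))
      res$drug <- drug
    }
    res$correlation <- cors
    record("phenotype", "ok")
  } else record("phenotype", "skipped")

  # --- survival -----------------------------------------------------------
  if (on("survival") && !is.null(assets)) {
    surv <- assets$survival
    lr <- logrank(surv, surv$group)
    curves <- lapply(split(surv, surv$group), km_estimate)
    horizon <- lapply(curves, survival_at, t = config$horizon_months)
    summary <- data.frame(
      group = names(curves),
      n = as.vector(table(surv$group)[names(curves)]),
      os_at_horizon = vapply(horizon, `[[`, 0, "estimate"),
      ci_lower = vapply(horizon, `[[`, 0, "lower"),
      ci_upper = vapply(horizon, `[[`, 0, "upper"),
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      stringsAsFactors = FALSE)
    write_tsv(summary, file.path(config$out_dir, "survival_summary.tsv"))
    res$survival <- list(curves = curves, logrank = lr, summary = summary)
    record("survival", "ok")
  } else record("survival", "skipped")

  # --- network ------------------------------------------------------------
  if (on("network") && !is.null(assets)) {
    graph <- load_interactions(assets$interactions,
                               score_threshold = config$score_threshold)
    hubs <- hub_nodes(graph, min_degree = config$min_degree)
    clusters <- filter_clusters(graph, min_degree = config$min_degree)
    write_tsv(data.frame(hub = hubs, stringsAsFactors = FALSE),
              file.path(config$out_dir, "network_hubs.tsv"))
    res$network <- list(graph = graph, hubs = hubs, clusters = clusters)
    record("network", "ok")
    manifest$counts$hubs <- length(hubs)
  } else record("network", "skipped")

  manifest$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
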