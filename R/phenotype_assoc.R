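# Phenotype association: per-cancer Pearson correlation of co-bound locus
# signals, and the drug-sensitivity model (IC50 regressed on mean
# target-gene expression with cancer-type covariates).

#' Per-cancer Pearson correlation of co-bound locus signals
#'
#' Pools a pair's co-bound loci across the cell lines of each cancer type
#' and correlates TF signal with histone-mark signal. p comes from the usual
#' t transform on `n - 2` df. Cancers with fewer than `min_loci` loci, or
#' with zero-variance signals, are reported but flagged not-evaluable.
#'
#' @param loci locus table from [intersect_peaks()] / [pool_cobound_loci()]
#'   (needs tf_signal, hm_signal, cell_line columns).
#' @param cancer_of_cell_line named vector mapping cell line id to cancer
#'   type.
#' @param min_loci evaluation floor (default 3).
#' @return data frame (cancer, n_loci, r, r_squared, p_value, evaluable).
#' @export
pearson_by_cancer <- function(loci, cancer_of_cell_line, min_loci = 3) {
  cancer <- as.character(cancer_of_cell_line[loci$cell_line])
  assert_that(!anyNA(cancer), "loci reference cell lines with no cancer type")
  rows <- lapply(sort(unique(cancer)), function(ca) {
    sub <- loci[cancer == ca, , drop = FALSE]
    n <- nrow(sub)
    out <- data.frame(cancer = ca, n_loci = n, r = NA_real_,
                      r_squared = NA_real_, p_value = NA_real_,
                      evaluable = FALSE, stringsAsFactors = FALSE)
    if (n < min_loci) return(out)
    if (stats::sd(sub$tf_signal) == 0 || stats::sd(sub$hm_signal) == 0) {
      return(out)
    }
    r <- stats::cor(sub$tf_signal, sub$hm_signal)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    out$r <- r
    out$r_squared <- r^2
    out$p_value <- 2 * stats::pt(-abs(tt), df = n - 2)
    out$evaluable <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Drug-sensitivity association with target-gene expression
#'
#' Per drug, OLS of IC50 on the mean target-gene expression plus cancer-type
#' dummies. `beta1` is the raw-scale slope; `or_value = exp(beta1_std)`
#' summarizes the slope per standard deviation of expression on a ratio
#' scale (a resistance direction > 1 means IC50 rises with target
#' expression). p-values are identical on either scale.
#'
#' @param ic50 drug x cell-line matrix.
#' @param mean_target_expr named vector per cell line (mean expression of
#'   the pair's target genes, log scale).
#' @param cancer_type named factor per cell line.
#' @return data frame (drug, beta1, se, p_value, or_value, n); drugs with
#'   constant IC50 or too few complete cases are skipped with a warning.
#' @export
drug_response_assoc <- function(ic50, mean_target_expr, cancer_type) {
  cells <- intersect(colnames(ic50), names(mean_target_expr))
  assert_that(length(cells) >= 4, "too few shared cell lines")
  expr <- mean_target_expr[cells]
  expr_sd <- stats::sd(expr)
  if (expr_sd == 0) {
    stop_usage("constant target expression across cell lines")
  }
  ct <- factor(as.character(cancer_type[cells]))
  exog <- cbind(`(Intercept)` = 1, expr = expr)
  if (nlevels(ct) >= 2) {
    dummies <- stats::model.matrix(~ ct)[, -1, drop = FALSE]
    colnames(dummies) <- paste0("cancer_", levels(ct)[-1])
    exog <- cbind(exog, dummies)
  }
  rows <- list()
  skipped <- character()
  for (drug in rownames(ic50)) {
    y <- ic50[drug, cells]
    ok <- !is.na(y)
    if (sum(ok) < ncol(exog) + 2 || stats::sd(y[ok]) == 0) {
      skipped <- c(skipped, drug)
      next
    }
    fit <- fit_ols(y[ok], exog[ok, , drop = FALSE])
    b1 <- unname(fit$coefficients["expr"])
    rows[[length(rows) + 1L]] <- data.frame(
      drug = drug, beta1 = b1,
      se = unname(fit$se["expr"]), p_value = unname(fit$p["expr"]),
      or_value = exp(b1 * expr_sd), n = sum(ok),
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " drug(s) with constant IC50 or too few cases", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Drug-class level summary
#'
#' Per class: median of per-drug `or_value`, drug count, and Fisher's
#' combined p (`-2 sum log p ~ chi^2_{2m}`).
#'
#' @param rows output of [drug_response_assoc()].
#' @param class_map data frame with `drug` and `class` columns covering
#'   every drug in `rows`.
#' @return data frame (class, n_drugs, median_or, combined_p).
#' @export
class_level_summary <- function(rows, class_map) {
  cls <- class_map$class[match(rows$drug, class_map$drug)]
  assert_that(!anyNA(cls), "every drug must be mapped to a class")
  out <- lapply(sort(unique(cls)), function(ca) {
    sub <- rows[cls == ca, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("class ", ca, " has no drugs; omitted", call. = FALSE)
      return(NULL)
    }
    stat <- -2 * sum(log(pmax(sub$p_value, .Machine$double.xmin)))
    data.frame(class = ca, n_drugs = nrow(sub),
               median_or = stats::median(sub$or_value),
               combined_p = stats::pchisq(stat, df = 2 * nrow(sub),
                                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
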