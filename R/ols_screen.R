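# Pan-cancer OLS screen: histone-mark activity regressed on TF activity
# (with a +/-1 activated/silent multiplier), TF expression, and cancer-type
# dummies. FDR-gated pairs become candidates for the IV stage.

#' Build the screening design matrix
#'
#' Columns: intercept, `TF_C` (TF activity times the mark-class code,
#' +1 activated / -1 silent), expression, and treatment-coded cancer-type
#' dummies (reference = lexicographically first level). The design is
#' checked for full column rank.
#'
#' @param tf TF activity vector.
#' @param hm_class `"activated"` or `"silent"` for the mark being modeled.
#' @param expression TF expression vector.
#' @param cancer_type factor (or character) of cancer types; pass
#'   `drop_cancer = TRUE` to omit the term when only one type is present.
#' @param drop_cancer drop cancer dummies.
#' @return numeric design matrix with named columns.
#' @export
build_design <- function(tf, hm_class = c("activated", "silent"),
                         expression, cancer_type, drop_cancer = FALSE) {
  hm_class <- match.arg(hm_class)
  n <- length(tf)
  assert_that(length(expression) == n && length(cancer_type) == n,
              "design inputs must have equal length")
  code <- if (hm_class == "activated") 1 else -1
  X <- cbind(`(Intercept)` = rep(1, n), TF_C = code * tf,
             expression = expression)
  if (!drop_cancer) {
    ct <- factor(cancer_type)
    assert_that(nlevels(ct) >= 2,
                "need >= 2 cancer types (or drop_cancer = TRUE)")
    dummies <- stats::model.matrix(~ ct)[, -1, drop = FALSE]
    colnames(dummies) <- paste0("cancer_", levels(ct)[-1])
    X <- cbind(X, dummies)
  }
  rownames(X) <- NULL
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_usage("collinearity error: design is rank deficient; dependent columns: %s",
               paste(dropped, collapse = ", "))
  }
  X
}

#' Ordinary least squares with classical inference
#'
#' QR-based OLS returning coefficients, classical standard errors
#' (`sigma2 * (X'X)^-1` with `sigma2 = RSS/(n-k)`), t statistics and
#' two-sided p-values on `n - k` degrees of freedom.
#'
#' @param y response vector.
#' @param X design matrix (include the intercept yourself).
#' @return an `ols_fit` list: coefficients, se, t, p, sigma2, df, n,
#'   residuals, fitted, terms (column names).
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  assert_that(length(y) == n, "length(y) must match nrow(X)")
  assert_that(n > k, "need more observations than design columns")
  qrX <- qr(X)
  if (qrX$rank < k) {
    stop_usage("collinearity error: singular design (rank %d < %d columns)",
               qrX$rank, k)
  }
  coef <- qr.coef(qrX, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  names(coef) <- names(se) <- names(tval) <- names(pval) <- colnames(X)
  structure(list(coefficients = coef, se = se, t = tval, p = pval,
                 sigma2 = sigma2, df = n - k, n = n,
                 residuals = resid, fitted = fitted,
                 terms = colnames(X), xtx_inv = xtx_inv),
            class = "ols_fit")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. `NA` entries are excluded from the family with a
#' warning and reinserted as `NA`.
#'
#' @param p vector of p-values in `[0, 1]` (NAs tolerated).
#' @return vector of adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)),
              "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(!ok)) {
    warning(sum(!ok), " NA p-value(s) excluded from the BH family",
            call. = FALSE)
  }
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' OLS screen over all TF x histone-mark pairs
#'
#' Fits one regression per (TF, mark) pair over the cell lines where both
#' activities are observed, extracts the TF-effect p-value, applies
#' Benjamini-Hochberg across all tested pairs jointly, and flags candidates
#' at `fdr < q_threshold`. Pairs with too few complete cases are skipped and
#' excluded from the BH family.
#'
#' @param tf_activity,hm_activity cell-line x factor matrices sharing row
#'   names.
#' @param expression cell-line x TF expression matrix.
#' @param cancer_type named factor of cancer types per cell line.
#' @param hm_class named vector mapping each mark to `"activated"` or
#'   `"silent"`; unlisted marks default to `"activated"` (none of the seven
#'   in-scope marks is repressive).
#' @param q_threshold candidate FDR gate (default 0.1).
#' @return data frame (tf, hm, beta, p_value, fdr, selected, n), one row per
#'   tested pair; skipped pairs recorded in the `skipped` attribute.
#' @export
screen_candidates <- function(tf_activity, hm_activity, expression,
                              cancer_type, hm_class = NULL,
                              q_threshold = 0.1) {
  cells <- rownames(tf_activity)
  assert_that(identical(cells, rownames(hm_activity)),
              "activity matrices must share cell-line rows")
  rows <- list()
  skipped <- character()
  for (tf in colnames(tf_activity)) {
    for (hm in colnames(hm_activity)) {
      cls <- if (!is.null(hm_class) && hm %in% names(hm_class))
        hm_class[[hm]] else "activated"
      ok <- stats::complete.cases(tf_activity[, tf], hm_activity[, hm],
                                  expression[, tf])
      X <- try(build_design(tf_activity[ok, tf], cls,
                            expression[ok, tf],
                            cancer_type[cells[ok]]), silent = TRUE)
      if (inherits(X, "try-error") || sum(ok) < ncol(X) + 2) {
        skipped <- c(skipped, paste0(tf, ":", hm))
        next
      }
      fit <- fit_ols(hm_activity[ok, hm], X)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, hm = hm,
        beta = unname(fit$coefficients["TF_C"]),
        p_value = unname(fit$p["TF_C"]),
        n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " pair(s) with unusable designs: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  assert_that(length(rows) >= 1, "no testable TF-mark pair")
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res$selected <- res$fdr < q_threshold
  res <- res[order(res$tf, res$hm), c("tf", "hm", "beta", "p_value",
                                      "fdr", "selected", "n")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
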