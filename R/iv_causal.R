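# Two-stage least-squares estimation of the causal effect of TF binding
# activity on histone-mark activity, instrumented by binary TF mutation
# status, with weak-instrument and Wu-Hausman diagnostics and the dual
# FDR / FDRweak driver gate.

#' Two-stage least squares (just-identified)
#'
#' Stage 1 regresses the endogenous regressor on the exogenous covariates
#' plus the excluded instrument; stage 2 regresses the outcome on the
#' exogenous covariates plus the stage-1 fitted values. Standard errors use
#' residuals computed with the ORIGINAL endogenous regressor (the standard
#' 2SLS correction), in a classical and an HC1-robust flavor. In the
#' just-identified case the estimate equals the instrument-moment closed
#' form `(Z'X)^-1 Z'y`.
#'
#' @param y outcome vector.
#' @param endog endogenous regressor (TF activity).
#' @param exog exogenous design including an intercept column.
#' @param instrument excluded instrument (binary mutation status).
#' @return an `iv_fit` list: beta0, beta1, coefficients, se (classical),
#'   se_robust, wald_p (classical t on beta1), wald_p_robust, first_stage
#'   ([fit_ols()] of the first stage), weak_F, weak_p, wu_hausman_stat,
#'   wu_hausman_p, n, df.
#' @export
fit_2sls <- function(y, endog, exog, instrument) {
  exog <- as.matrix(exog)
  n <- length(y)
  assert_that(length(endog) == n && nrow(exog) == n &&
              length(instrument) == n, "input lengths differ")
  if (length(unique(instrument)) < 2) {
    stop_usage("no-identification error: instrument is constant")
  }
  Z <- cbind(exog, instrument = instrument)
  X <- cbind(exog, endog = endog)
  k <- ncol(X)
  assert_that(n > k + 2, "too few observations for 2SLS")
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    stop_usage("identification error: instrument collinear with exogenous covariates")
  }

  first <- fit_ols(endog, Z)
  endog_hat <- first$fitted
  X_hat <- cbind(exog, endog = endog_hat)
  qr2 <- qr(X_hat)
  if (qr2$rank < k) {
    stop_usage("identification error: second-stage design rank deficient")
  }
  coef <- qr.coef(qr2, y)
  # residuals with the ORIGINAL endogenous regressor
  resid <- y - drop(X %*% coef)
  sigma2 <- sum(resid^2) / (n - k)
  # (Z'X)^-1 Z'Z (X'Z)^-1 sandwich for the just-identified case
  ZX_inv <- solve(crossprod(Z, X))
  vc_classical <- sigma2 * ZX_inv %*% crossprod(Z) %*% t(ZX_inv)
  meat <- crossprod(Z * resid, Z * resid)
  vc_robust <- (n / (n - k)) * ZX_inv %*% meat %*% t(ZX_inv)
  se <- sqrt(diag(vc_classical))
  se_robust <- sqrt(diag(vc_robust))
  names(coef) <- names(se) <- names(se_robust) <- colnames(X)

  b1 <- unname(coef["endog"])
  t1 <- b1 / se["endog"]
  wald_p <- 2 * stats::pt(-abs(t1), df = n - k)
  wald_p_robust <- 2 * stats::pt(-abs(b1 / se_robust["endog"]), df = n - k)

  wk <- weak_instrument_F(endog, exog, instrument)
  wh <- wu_hausman(y, endog, exog, instrument)

  structure(list(beta0 = unname(coef["(Intercept)"]), beta1 = b1,
                 coefficients = coef, se = se, se_robust = se_robust,
                 wald_p = unname(wald_p),
                 wald_p_robust = unname(wald_p_robust),
                 first_stage = first,
                 weak_F = wk$F, weak_p = wk$p,
                 wu_hausman_stat = wh$stat, wu_hausman_p = wh$p,
                 n = n, df = n - k, residuals = resid),
            class = "iv_fit")
}

#' Robust first-stage (weak instrument) F statistic
#'
#' With one endogenous regressor and one excluded instrument, the
#' Kleibergen-Paap rank Wald F reduces to the squared
#' heteroskedasticity-robust (HC1) t statistic of the instrument coefficient
#' in the first-stage regression; p is taken from `F(1, n - k)`.
#'
#' @param endog endogenous regressor.
#' @param exog exogenous design including intercept.
#' @param instrument excluded instrument.
#' @return list with elements `F` and `p`.
#' @export
weak_instrument_F <- function(endog, exog, instrument) {
  Z <- cbind(as.matrix(exog), instrument = instrument)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    stop_usage("identification error: first stage rank deficient")
  }
  fit <- fit_ols(endog, Z)
  vc <- hc1_cov(Z, fit$residuals)
  j <- ncol(Z)
  t_rob <- fit$coefficients[j] / sqrt(vc[j, j])
  Fstat <- unname(t_rob^2)
  list(F = Fstat, p = stats::pf(Fstat, 1, fit$df, lower.tail = FALSE))
}

#' Wu-Hausman endogeneity test (control-function form)
#'
#' Appends the first-stage residuals to an OLS of the outcome on the
#' exogenous covariates and the original endogenous regressor, and F-tests
#' the residual coefficient (1 numerator df). A significant statistic means
#' OLS and 2SLS disagree, i.e. the regressor is endogenous.
#'
#' @inheritParams fit_2sls
#' @return list with `stat` and `p`; both `NA` (with a warning) when the
#'   instrument spans the endogenous regressor so the residuals vanish.
#' @export
wu_hausman <- function(y, endog, exog, instrument) {
  exog <- as.matrix(exog)
  Z <- cbind(exog, instrument = instrument)
  first <- fit_ols(endog, Z)
  v <- first$residuals
  if (max(abs(v)) < 1e-10) {
    warning("first-stage residuals numerically zero; Wu-Hausman undefined",
            call. = FALSE)
    return(list(stat = NA_real_, p = NA_real_))
  }
  X_aux <- cbind(exog, endog = endog, vhat = v)
  aux <- fit_ols(y, X_aux)
  stat <- unname(aux$t["vhat"]^2)
  list(stat = stat, p = stats::pf(stat, 1, aux$df, lower.tail = FALSE))
}

#' Convert a causal effect to the reported odds-ratio-style value
#'
#' The driver table reports `exp(beta1)` under an `or` column: one plausible
#' summary of a linear activity effect on a positive ratio scale. It is NOT
#' an odds ratio from a logistic model; treat it as a labeled transform.
#'
#' @param beta1 causal effect estimate.
#' @return `exp(beta1)`.
#' @export
effect_to_or <- function(beta1) {
  assert_that(is.finite(beta1), "beta1 must be finite")
  exp(beta1)
}

#' IV stage over the candidate pairs: the driver table
#'
#' Fits one 2SLS model per candidate (TF, mark) pair with that TF's mutation
#' status as instrument, then applies Benjamini-Hochberg separately to the
#' Wald p family (-> `fdr`) and the weak-instrument p family (-> `fdr_weak`).
#' A pair is a driver when both adjusted values fall below `q`. Candidates
#' whose TF never (or always) carries a mutation are skipped and excluded
#' from both BH families.
#'
#' @param candidates data frame from [screen_candidates()]; only rows with
#'   `selected == TRUE` are tested (set `selected_only = FALSE` to test all).
#' @param tf_activity,hm_activity,expression,mutation cell-line x factor
#'   matrices sharing row names.
#' @param cancer_type named factor per cell line.
#' @param q dual FDR gate (default 0.1).
#' @param selected_only test only screen-selected candidates.
#' @return data frame with one row per tested pair: tf, hm, beta1, or
#'   (`exp(beta1)`), p_value (classical Wald), wald_p (robust Wald), weak_p,
#'   wu_hausman_p, fdr, fdr_weak, driver, n; sorted by (tf, hm). Skipped
#'   pairs are listed in the `skipped` attribute. Zero testable candidates
#'   yield a zero-row frame with attribute `status = "ran, nothing testable"`.
#' @export
run_iv_stage <- function(candidates, tf_activity, hm_activity, expression,
                         mutation, cancer_type, q = 0.1,
                         selected_only = TRUE) {
  assert_that(nrow(candidates) >= 1, "candidates must be non-empty")
  test_set <- if (selected_only)
    candidates[candidates$selected, , drop = FALSE] else candidates
  cells <- rownames(tf_activity)
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(test_set))) {
    tf <- test_set$tf[i]
    hm <- test_set$hm[i]
    ok <- stats::complete.cases(tf_activity[, tf], hm_activity[, hm],
                                expression[, tf], mutation[, tf])
    inst <- mutation[ok, tf]
    if (length(unique(inst)) < 2) {
      skipped <- c(skipped, paste0(tf, ":", hm))
      next
    }
    ct <- factor(cancer_type[cells[ok]])
    exog <- cbind(`(Intercept)` = 1, expression = expression[ok, tf])
    if (nlevels(ct) >= 2) {
      dummies <- stats::model.matrix(~ ct)[, -1, drop = FALSE]
      colnames(dummies) <- paste0("cancer_", levels(ct)[-1])
      exog <- cbind(exog, dummies)
    }
    fit <- try(fit_2sls(hm_activity[ok, hm], tf_activity[ok, tf], exog, inst),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      skipped <- c(skipped, paste0(tf, ":", hm))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, hm = hm, beta1 = fit$beta1, or = effect_to_or(fit$beta1),
      p_value = fit$wald_p, wald_p = fit$wald_p_robust,
      weak_p = fit$weak_p, wu_hausman_p = fit$wu_hausman_p,
      n = fit$n, stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message("IV stage skipped ", length(skipped), " pair(s): ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  if (!length(rows)) {
    out <- data.frame(tf = character(), hm = character(), beta1 = numeric(),
                      or = numeric(), p_value = numeric(), wald_p = numeric(),
                      weak_p = numeric(), wu_hausman_p = numeric(),
                      fdr = numeric(), fdr_weak = numeric(),
                      driver = logical(), n = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "status") <- "ran, nothing testable"
    attr(out, "skipped") <- skipped
    return(out)
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res$fdr_weak <- bh_adjust(res$weak_p)
  res$driver <- res$fdr < q & res$fdr_weak < q
  res <- res[order(res$tf, res$hm),
             c("tf", "hm", "beta1", "or", "p_value", "wald_p", "weak_p",
               "wu_hausman_p", "fdr", "fdr_weak", "driver", "n")]
  rownames(res) <- NULL
  attr(res, "status") <- "ok"
  attr(res, "skipped") <- skipped
  res
}
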