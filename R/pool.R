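# Inverse-variance pooling of log odds ratios: fixed-effect and
# DerSimonian-Laird random-effects, with the heterogeneity-driven switching
# rule, leave-one-out sensitivity, subgroup analysis, meta-regression and
# publication-bias diagnostics.

extract_yi_sei <- function(effects) {
  yi <- vapply(effects, function(e) e$log_or, numeric(1))
  sei <- vapply(effects, function(e) e$se, numeric(1))
  if (any(!is.finite(yi)) || any(!is.finite(sei)) || any(sei <= 0))
    stop("all effects must have finite log-OR and positive SE")
  list(yi = yi, sei = sei)
}

heterogeneity <- function(yi, sei) {
  w <- 1 / sei^2
  yhat <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - yhat)^2)
  df <- length(yi) - 1L
  p_q <- pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, df = df, p_q = p_q, i2 = i2)
}

new_pooled <- function(yi, sei, w, het, tau2, method, model = NA_character_,
                       stratum = NA_character_) {
  mu <- sum(w * yi) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(list(
    model = model, stratum = stratum,
    effect = effect_estimate(mu, se),
    het = c(het, list(tau2 = tau2)),
    method = method, k = length(yi),
    weights = w / sum(w), yi = yi, sei = sei
  ), class = "pooled_result")
}

#' Fixed-effect (inverse-variance) pooling of log odds ratios
#'
#' Weights w = 1/SE^2; pooled log-OR = sum(w y)/sum(w); pooled
#' SE = sqrt(1/sum(w)). Cochran's Q (against the fixed-effect mean), its
#' p-value and I^2 are attached; tau2 is 0 by definition under the
#' fixed-effect model.
#'
#' @param effects list of [effect_estimate()]s (at least two).
#' @param model optional genetic-model label carried into the result.
#' @param stratum optional stratum label.
#' @return A `pooled_result`: `effect`, `het` (`q`, `df`, `p_q`, `i2`,
#'   `tau2`), `method`, `k`, normalized `weights`.
#' @export
pool_fixed <- function(effects, model = NA_character_, stratum = NA_character_) {
  if (length(effects) < 2) stop("at least two studies are required")
  d <- extract_yi_sei(effects)
  het <- heterogeneity(d$yi, d$sei)
  new_pooled(d$yi, d$sei, 1 / d$sei^2, het, tau2 = 0, method = "fixed",
             model = model, stratum = stratum)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w))) with
#' fixed-effect weights w = 1/SE^2, then re-weighting by w* = 1/(SE^2 + tau2).
#' When Q <= df the estimate collapses to the fixed-effect result
#' (tau2 = 0). The reported Q/I^2 are the fixed-weight statistics.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result` with `method = "random"` and the DL `tau2`.
#' @export
pool_random <- function(effects, model = NA_character_, stratum = NA_character_) {
  if (length(effects) < 2) stop("at least two studies are required")
  d <- extract_yi_sei(effects)
  w <- 1 / d$sei^2
  het <- heterogeneity(d$yi, d$sei)
  tau2 <- max(0, (het$q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  new_pooled(d$yi, d$sei, 1 / (d$sei^2 + tau2), het, tau2 = tau2,
             method = "random", model = model, stratum = stratum)
}

#' Pool with the heterogeneity-driven model switch
#'
#' Computes Q and I^2 from the fixed-effect fit, then uses the fixed-effect
#' model when p(Q) > 0.1 and I^2 < 50% (both strictly), and the
#' DerSimonian-Laird random-effects model otherwise.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result`; `method` records which branch fired.
#' @export
choose_and_pool <- function(effects, model = NA_character_,
                            stratum = NA_character_) {
  fx <- pool_fixed(effects, model = model, stratum = stratum)
  if (fx$het$p_q > 0.1 && fx$het$i2 < 50) fx
  else pool_random(effects, model = model, stratum = stratum)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s-effect pooled OR (k = %d%s%s): %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$method, x$k,
              if (!is.na(x$model)) paste0(", ", x$model) else "",
              if (!is.na(x$stratum)) paste0(", ", x$stratum) else "",
              x$effect$or, x$effect$ci_low, x$effect$ci_high, x$effect$p_value))
  cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
              x$het$q, x$het$df, x$het$p_q, x$het$i2, x$het$tau2))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs [choose_and_pool()] k times, omitting one study each time.
#'
#' @param effects list of at least three `effect_estimate`s.
#' @return List of `pooled_result`s named by the omitted study (names of
#'   `effects` if present, else indices).
#' @export
leave_one_out <- function(effects) {
  k <- length(effects)
  if (k < 3) stop("leave-one-out requires at least three studies")
  nm <- names(effects)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  out <- lapply(seq_len(k), function(i) choose_and_pool(effects[-i]))
  names(out) <- nm
  out
}

#' Subgroup analysis with a between-stratum heterogeneity test
#'
#' Pools each stratum separately, then tests for differences between strata
#' with Q_between = sum over strata of w_s (y_s - ybar)^2 on (S - 1) df,
#' where y_s are the stratum-pooled log-ORs with weights w_s = 1/SE_s^2.
#' Strata with a single study are reported descriptively and excluded from
#' the test.
#'
#' @param effects list of `effect_estimate`s.
#' @param labels stratum label per study.
#' @param pooling `"random"` (default; every stratum pooled by
#'   random-effects, matching forest-plot subgroup practice) or `"switch"`
#'   ([choose_and_pool()] per stratum).
#' @return List of class `subgroup_result`: `strata` (named list of
#'   `pooled_result`s or single-study `effect_estimate`s flagged
#'   `descriptive_only`), `between` (`q`, `df`, `p`) or NULL when fewer than
#'   two testable strata.
#' @export
subgroup_analysis <- function(effects, labels, pooling = c("random", "switch")) {
  pooling <- match.arg(pooling)
  stopifnot(length(labels) == length(effects))
  labels <- as.character(labels)
  strata <- list()
  ys <- ses <- numeric(0)
  for (s in unique(labels)) {
    idx <- which(labels == s)
    if (length(idx) >= 2) {
      pr <- if (pooling == "random") pool_random(effects[idx], stratum = s)
            else choose_and_pool(effects[idx], stratum = s)
      strata[[s]] <- pr
      ys <- c(ys, pr$effect$log_or)
      ses <- c(ses, pr$effect$se)
    } else {
      e <- effects[[idx]]
      e$descriptive_only <- TRUE
      strata[[s]] <- e
    }
  }
  between <- NULL
  if (length(ys) >= 2) {
    w <- 1 / ses^2
    ybar <- sum(w * ys) / sum(w)
    qb <- sum(w * (ys - ybar)^2)
    dfb <- length(ys) - 1L
    between <- list(q = qb, df = dfb, p = pchisq(qb, dfb, lower.tail = FALSE))
  }
  structure(list(strata = strata, between = between, pooling = pooling),
            class = "subgroup_result")
}

#' Mixed-effects meta-regression on a categorical moderator
#'
#' Delegates to [metafor::rma()] with `method = "DL"` (method-of-moments
#' residual tau2) and a dummy-coded moderator, with Wald z-tests per
#' coefficient.
#'
#' @param effects list of at least four `effect_estimate`s.
#' @param covariate factor (or coercible) with at least two observed levels.
#' @return List of class `meta_regression`: `coefficients` (data frame:
#'   estimate, se, z, p per term), `tau2` (residual), `qe` (residual Q),
#'   `qm_p` (omnibus moderator test p-value), `fit` (the `rma` object).
#' @export
meta_regression <- function(effects, covariate) {
  if (length(effects) < 4) stop("meta-regression requires at least four studies")
  covariate <- factor(covariate)
  if (nlevels(droplevels(covariate)) < 2)
    stop("covariate must have at least two observed levels")
  d <- extract_yi_sei(effects)
  fit <- metafor::rma(yi = d$yi, sei = d$sei, mods = ~ covariate,
                      method = "DL", test = "z")
  structure(list(
    coefficients = data.frame(term = rownames(fit$beta),
                              estimate = as.numeric(fit$beta),
                              se = fit$se, z = fit$zval, p = fit$pval),
    tau2 = fit$tau2, qe = fit$QE, qm_p = fit$QMp, fit = fit
  ), class = "meta_regression")
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect y/SE on precision 1/SE; the intercept
#' estimates asymmetry and is tested with a t-test on k - 2 df. Not computed
#' for fewer than `min_k` studies.
#'
#' @param effects list of `effect_estimate`s.
#' @param min_k minimum number of studies (default 10).
#' @return List of class `bias_test`: `applicable`, and when applicable
#'   `intercept`, `se`, `p`.
#' @export
egger_test <- function(effects, min_k = 10) {
  k <- length(effects)
  if (k < min_k)
    return(structure(list(test = "egger", applicable = FALSE, k = k),
                     class = "bias_test"))
  d <- extract_yi_sei(effects)
  z <- d$yi / d$sei
  prec <- 1 / d$sei
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)$coefficients
  structure(list(test = "egger", applicable = TRUE, k = k,
                 intercept = sm[1, 1], se = sm[1, 2], p = sm[1, 4]),
            class = "bias_test")
}

#' Begg and Mazumdar's rank correlation test
#'
#' Kendall's tau (tau-b, normal approximation) between the standardized
#' deviates from the fixed-effect pooled estimate,
#' (y - yhat)/sqrt(v - 1/sum(w)), and the variances v. Not computed for
#' fewer than `min_k` studies.
#'
#' @inheritParams egger_test
#' @return List of class `bias_test`: `applicable`, and when applicable
#'   `tau`, `p`.
#' @export
begg_test <- function(effects, min_k = 10) {
  k <- length(effects)
  if (k < min_k)
    return(structure(list(test = "begg", applicable = FALSE, k = k),
                     class = "bias_test"))
  d <- extract_yi_sei(effects)
  v <- d$sei^2
  w <- 1 / v
  yhat <- sum(w * d$yi) / sum(w)
  vstar <- v - 1 / sum(w)
  dev <- (d$yi - yhat) / sqrt(vstar)
  ct <- suppressWarnings(stats::cor.test(dev, v, method = "kendall",
                                         exact = FALSE))
  structure(list(test = "begg", applicable = TRUE, k = k,
                 tau = unname(ct$estimate), p = ct$p.value),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("%s test not applicable (k = %d < 10)\n", x$test, x$k))
  } else if (x$test == "egger") {
    cat(sprintf("Egger intercept %.4f (SE %.4f), p = %.4g (k = %d)\n",
                x$intercept, x$se, x$p, x$k))
  } else {
    cat(sprintf("Begg tau %.4f, p = %.4g (k = %d)\n", x$tau, x$p, x$k))
  }
  invisible(x)
}

#' Forest-plot data for a pooled result
#'
#' @param pooled a `pooled_result`.
#' @param study_ids optional study labels.
#' @return Data frame: study, weight (%), or, ci_low, ci_high, with a final
#'   "Pooled" row.
#' @export
forest_data <- function(pooled, study_ids = NULL) {
  k <- pooled$k
  if (is.null(study_ids)) study_ids <- paste0("study_", seq_len(k))
  rows <- data.frame(
    study = c(study_ids, "Pooled"),
    weight = c(100 * pooled$weights, 100),
    or = c(exp(pooled$yi), pooled$effect$or),
    ci_low = c(exp(pooled$yi - Z95 * pooled$sei), pooled$effect$ci_low),
    ci_high = c(exp(pooled$yi + Z95 * pooled$sei), pooled$effect$ci_high))
  rows
}
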