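# Diagnostic-accuracy meta-analysis of a risk-genotype dichotomization:
# per-study accuracy statistics, logit-scale pooling, the Moses-Littenberg
# SROC regression with numerically integrated AUC, and the Spearman
# threshold-effect test.

#' Build a diagnostic 2x2 from a genetic-model contrast
#'
#' Re-reads the contrast 2x2 as a diagnostic table: TP = cases carrying the
#' risk grouping, FP = controls carrying it, FN/TN the complements.
#'
#' @param study one row of a `genotype_studies` data frame.
#' @param model a genetic model name (see [genetic_models()]).
#' @return List of class `diagnostic_study`: `tp`, `fp`, `fn`, `tn`.
#' @export
diagnostic_study <- function(study, model) {
  tb <- build_contrast(study, model)
  structure(list(tp = tb$a, fn = tb$b, fp = tb$c, tn = tb$d, model = model),
            class = "diagnostic_study")
}

correct_cells <- function(d) {
  cells <- c(d$tp, d$fp, d$fn, d$tn)
  if (cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0)
    stop("empty case or control margin")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
       corrected = corrected)
}

#' Per-study diagnostic accuracy statistics
#'
#' Sensitivity tp/(tp+fn), specificity tn/(fp+tn), likelihood ratios
#' +LR = sens/(1-spec) and -LR = (1-sens)/spec, and the diagnostic odds
#' ratio DOR = +LR/-LR = (tp tn)/(fp fn), each with a 95% CI (Wilson-free,
#' log/logit Wald intervals). Zero cells receive a 0.5 correction
#' (flagged).
#'
#' @param study a `diagnostic_study` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return List of class `accuracy_stats` with elements `sens`, `spec`,
#'   `plr`, `nlr`, `dor` (each `list(est, ci_low, ci_high)`), and
#'   `corrected`.
#' @examples
#' accuracy_stats(list(tp = 30, fp = 10, fn = 30, tn = 70))
#' @export
accuracy_stats <- function(study) {
  cc <- correct_cells(study)
  sens <- cc$tp / (cc$tp + cc$fn)
  spec <- cc$tn / (cc$fp + cc$tn)
  logit_ci <- function(p, n) {
    l <- log(p / (1 - p)); se <- sqrt(1 / (n * p) + 1 / (n * (1 - p)))
    list(est = p, ci_low = plogis(l - Z95 * se), ci_high = plogis(l + Z95 * se))
  }
  log_ci <- function(est, se)
    list(est = est, ci_low = exp(log(est) - Z95 * se),
         ci_high = exp(log(est) + Z95 * se))
  plr <- sens / (1 - spec)
  nlr <- (1 - sens) / spec
  se_plr <- sqrt((1 - sens) / (cc$tp + cc$fn) / sens + spec / (cc$fp + cc$tn) / (1 - spec))
  se_nlr <- sqrt(sens / (cc$tp + cc$fn) / (1 - sens) + (1 - spec) / (cc$fp + cc$tn) / spec)
  dor <- (cc$tp * cc$tn) / (cc$fp * cc$fn)
  se_dor <- sqrt(1 / cc$tp + 1 / cc$fp + 1 / cc$fn + 1 / cc$tn)
  structure(list(
    sens = logit_ci(sens, cc$tp + cc$fn),
    spec = logit_ci(spec, cc$fp + cc$tn),
    plr = log_ci(plr, se_plr), nlr = log_ci(nlr, se_nlr),
    dor = log_ci(dor, se_dor), corrected = cc$corrected
  ), class = "accuracy_stats")
}

logit_effect <- function(p, n) effect_estimate(log(p / (1 - p)),
                                               sqrt(1 / (n * p) + 1 / (n * (1 - p))))

#' Pool diagnostic accuracy across studies
#'
#' Sensitivity and specificity are pooled on the logit scale and the DOR and
#' likelihood ratios on the log scale, each by inverse variance with the
#' heterogeneity-driven fixed/random switch of [choose_and_pool()] (or
#' forced random effects), then back-transformed.
#'
#' @param studies list of `diagnostic_study`s (at least two).
#' @param pooling `"switch"` (default) or `"random"`.
#' @return List of class `pooled_accuracy`: `sens`, `spec`, `plr`, `nlr`,
#'   `dor`, each a list with `est`, `ci_low`, `ci_high`, `method`, `i2`, and
#'   `log_dor_pooled` (the `pooled_result` for the DOR, for cross-checks).
#' @export
pool_accuracy <- function(studies, pooling = c("switch", "random")) {
  pooling <- match.arg(pooling)
  if (length(studies) < 2) stop("at least two studies are required")
  pool1 <- function(effects, trans) {
    pr <- if (pooling == "switch") choose_and_pool(effects)
          else pool_random(effects)
    list(est = trans(pr$effect$log_or), ci_low = trans(pr$effect$log_or - Z95 * pr$effect$se),
         ci_high = trans(pr$effect$log_or + Z95 * pr$effect$se),
         method = pr$method, i2 = pr$het$i2, pooled = pr)
  }
  cells <- lapply(studies, correct_cells)
  sens_eff <- lapply(cells, function(cc) logit_effect(cc$tp / (cc$tp + cc$fn), cc$tp + cc$fn))
  spec_eff <- lapply(cells, function(cc) logit_effect(cc$tn / (cc$fp + cc$tn), cc$fp + cc$tn))
  dor_eff <- lapply(cells, function(cc) effect_estimate(
    log(cc$tp * cc$tn / (cc$fp * cc$fn)),
    sqrt(1 / cc$tp + 1 / cc$fp + 1 / cc$fn + 1 / cc$tn)))
  plr_eff <- lapply(cells, function(cc) {
    sens <- cc$tp / (cc$tp + cc$fn); spec <- cc$tn / (cc$fp + cc$tn)
    effect_estimate(log(sens / (1 - spec)),
                    sqrt((1 - sens) / (cc$tp + cc$fn) / sens + spec / (cc$fp + cc$tn) / (1 - spec)))
  })
  nlr_eff <- lapply(cells, function(cc) {
    sens <- cc$tp / (cc$tp + cc$fn); spec <- cc$tn / (cc$fp + cc$tn)
    effect_estimate(log((1 - sens) / spec),
                    sqrt(sens / (cc$tp + cc$fn) / (1 - sens) + (1 - spec) / (cc$fp + cc$tn) / spec))
  })
  dor_pool <- pool1(dor_eff, exp)
  structure(list(
    sens = pool1(sens_eff, plogis), spec = pool1(spec_eff, plogis),
    plr = pool1(plr_eff, exp), nlr = pool1(nlr_eff, exp), dor = dor_pool,
    log_dor_pooled = dor_pool$pooled, k = length(studies)
  ), class = "pooled_accuracy")
}

#' @export
print.pooled_accuracy <- function(x, ...) {
  cat(sprintf("Pooled diagnostic accuracy (k = %d):\n", x$k))
  for (nm in c("sens", "spec", "plr", "nlr", "dor")) {
    e <- x[[nm]]
    cat(sprintf("  %-4s %.3f (95%% CI %.3f-%.3f) [%s, I2 %.1f%%]\n",
                nm, e$est, e$ci_low, e$ci_high, e$method, e$i2))
  }
  invisible(x)
}

#' Moses-Littenberg SROC regression with AUC
#'
#' Per study, D = logit(TPR) - logit(FPR) and S = logit(TPR) + logit(FPR);
#' unweighted least squares of D on S gives intercept `a` and slope `b`
#' (b = 0 means a symmetric SROC). The summary curve is
#' logit(TPR) = (a + (1 + b) logit(FPR)) / (1 - b), and the AUC is its
#' trapezoid integral over FPR in (0, 1) on an `npoints`-point grid. The AUC
#' standard error is a nonparametric bootstrap over studies.
#'
#' @param studies list of at least three `diagnostic_study`s.
#' @param npoints quadrature points (default 2001).
#' @param boot bootstrap replicates for `se_auc` (default 200; 0 skips it).
#' @param seed seed for the bootstrap.
#' @return List of class `sroc_model`: `a_intercept`, `b_slope`, `auc`,
#'   `se_auc`, `points` (per-study TPR/FPR), `curve` (function of FPR),
#'   `degenerate_s` (TRUE when the S spread was too small to estimate a
#'   slope, which is then fixed at 0).
#' @export
sroc_moses <- function(studies, npoints = 2001, boot = 200, seed = 1) {
  if (length(studies) < 3) stop("SROC regression requires at least three studies")
  cells <- lapply(studies, correct_cells)
  tpr <- vapply(cells, function(cc) cc$tp / (cc$tp + cc$fn), numeric(1))
  fpr <- vapply(cells, function(cc) cc$fp / (cc$fp + cc$tn), numeric(1))
  stopifnot(all(tpr > 0 & tpr < 1), all(fpr > 0 & fpr < 1))
  fit_ab <- function(tpr, fpr) {
    D <- qlogis(tpr) - qlogis(fpr)
    S <- qlogis(tpr) + qlogis(fpr)
    if (stats::sd(S) < 1e-8) return(c(a = mean(D), b = 0, degen = 1))
    cf <- stats::coef(stats::lm(D ~ S))
    c(a = unname(cf[1]), b = unname(cf[2]), degen = 0)
  }
  auc_of <- function(a, b, npts) {
    x <- seq(1 / (npts + 1), npts / (npts + 1), length.out = npts)
    y <- plogis((a + (1 + b) * qlogis(x)) / (1 - b))
    # trapezoid over (0,1) with boundary values 0 and 1 pinned
    xs <- c(0, x, 1); ys <- c(0, y, 1)
    sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  }
  ab <- unlist(fit_ab(tpr, fpr))
  names(ab) <- c("a", "b", "degen")
  if (ab["degen"] == 1)
    warning("degenerate S variance: slope fixed at 0 (symmetric SROC)")
  if (abs(1 - ab["b"]) < 1e-8) stop("SROC slope of 1: curve undefined")
  auc <- auc_of(ab["a"], ab["b"], npoints)
  se_auc <- NA_real_
  if (boot > 0) {
    k <- length(tpr)
    aucs <- with_seed(seed, vapply(seq_len(boot), function(i) {
      idx <- sample.int(k, k, replace = TRUE)
      abi <- fit_ab(tpr[idx], fpr[idx])
      if (abs(1 - abi["b"]) < 1e-8) return(NA_real_)
      auc_of(abi["a"], abi["b"], 501)
    }, numeric(1)))
    se_auc <- stats::sd(aucs, na.rm = TRUE)
  }
  structure(list(
    a_intercept = unname(ab["a"]), b_slope = unname(ab["b"]),
    auc = auc, se_auc = se_auc,
    points = data.frame(tpr = tpr, fpr = fpr),
    curve = local({
      a0 <- unname(ab["a"]); b0 <- unname(ab["b"])
      function(f) plogis((a0 + (1 + b0) * qlogis(f)) / (1 - b0))
    }),
    degenerate_s = ab["degen"] == 1
  ), class = "sroc_model")
}

#' @export
print.sroc_model <- function(x, ...) {
  cat(sprintf("Moses-Littenberg SROC: a = %.4f, b = %.4f%s\n",
              x$a_intercept, x$b_slope,
              if (x$degenerate_s) " (slope fixed: degenerate S)" else ""))
  cat(sprintf("  AUC = %.4f (SE %.4f), k = %d\n", x$auc, x$se_auc,
              nrow(x$points)))
  invisible(x)
}

#' Spearman test for a threshold effect
#'
#' Rank correlation between logit(TPR) and logit(FPR) across studies; a
#' strong positive correlation suggests that between-study heterogeneity is
#' driven by an implicit threshold. Exact p-value for k <= 9 (no ties),
#' t-approximation otherwise (ties get average ranks).
#'
#' @param studies list of at least three `diagnostic_study`s.
#' @return List: `rho`, `p`.
#' @export
spearman_threshold <- function(studies) {
  if (length(studies) < 3) stop("threshold test requires at least three studies")
  cells <- lapply(studies, correct_cells)
  ltpr <- vapply(cells, function(cc) qlogis(cc$tp / (cc$tp + cc$fn)), numeric(1))
  lfpr <- vapply(cells, function(cc) qlogis(cc$fp / (cc$fp + cc$tn)), numeric(1))
  ct <- suppressWarnings(stats::cor.test(ltpr, lfpr, method = "spearman",
                                         exact = length(studies) <= 9))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Export SROC plot data
#'
#' @param model an `sroc_model`.
#' @param ncurve number of fitted-curve samples (default 101).
#' @return Data frame with columns `type` ("study" or "curve"), `fpr`, `tpr`.
#' @export
sroc_plot_data <- function(model, ncurve = 101) {
  f <- seq(0.005, 0.995, length.out = ncurve)
  rbind(data.frame(type = "study", fpr = model$points$fpr, tpr = model$points$tpr),
        data.frame(type = "curve", fpr = f, tpr = model$curve(f)))
}
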