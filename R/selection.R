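# Inheritance-model selection: Thakkinstian's pairwise-OR decision rules,
# Wacholder's false positive report probability, and the composite
# candidate -> definitive classification.

sig_ne_1 <- function(e) e$ci_low > 1 || e$ci_high < 1
ci_contains_1 <- function(e) !sig_ne_1(e)

# z-test that two log-ORs are equal (used for "OR1 = OR3" style judgements)
z_equal <- function(e1, e2, alpha = 0.05) {
  z <- (e1$log_or - e2$log_or) / sqrt(e1$se^2 + e2$se^2)
  2 * pnorm(-abs(z)) >= alpha
}

# z-test that log(or2) + log(or3) = 0, i.e. OR2 = 1/OR3
z_reciprocal <- function(e2, e3, alpha = 0.05) {
  z <- (e2$log_or + e3$log_or) / sqrt(e2$se^2 + e3$se^2)
  2 * pnorm(-abs(z)) >= alpha
}

#' Thakkinstian's genetic-model decision rules
#'
#' Given three pooled genotype contrasts for one SNP - OR1 (variant vs
#' common homozygote, 22 vs 11), OR2 (heterozygote vs common homozygote,
#' 12 vs 11) and OR3 (variant homozygote vs heterozygote, 22 vs 12) - the
#' rules are evaluated in order, first match wins:
#' \enumerate{
#'   \item OR1 = OR3 != 1 and OR2 = 1: recessive.
#'   \item OR1 = OR2 != 1 and OR3 = 1: dominant.
#'   \item OR2 = 1/OR3 != 1 and OR1 = 1: complete over-dominant.
#'   \item OR1 > OR2 > 1 and OR1 > OR3 > 1 (or the all-protective mirror
#'     OR1 < OR2 < 1 and OR1 < OR3 < 1): codominant.
#' }
#' "= 1" is judged by the 95% CI containing 1 and "!= 1" by it excluding 1;
#' equality between two ORs (and OR2 = 1/OR3) by a two-sided z-test on the
#' log scale at level `alpha`; the codominant inequality chains by point
#' estimates with all three ORs individually significant in the same
#' direction. No match returns "undetermined".
#'
#' @param or1,or2,or3 [effect_estimate()]s pooled from the same study set.
#' @param alpha level of the equality z-tests (default 0.05).
#' @return List of class `model_verdict`: `proposed` (one of "recessive",
#'   "dominant", "complete_overdominant", "codominant", "undetermined") and
#'   `rule_fired`.
#' @export
thakkinstian_decide <- function(or1, or2, or3, alpha = 0.05) {
  verdict <- function(p, rule) structure(list(proposed = p, rule_fired = rule),
                                         class = "model_verdict")
  if (sig_ne_1(or1) && sig_ne_1(or3) && z_equal(or1, or3, alpha) &&
      ci_contains_1(or2))
    return(verdict("recessive", "OR1 = OR3 != 1 and OR2 = 1"))
  if (sig_ne_1(or1) && sig_ne_1(or2) && z_equal(or1, or2, alpha) &&
      ci_contains_1(or3))
    return(verdict("dominant", "OR1 = OR2 != 1 and OR3 = 1"))
  if (ci_contains_1(or1) && sig_ne_1(or2) && sig_ne_1(or3) &&
      z_reciprocal(or2, or3, alpha))
    return(verdict("complete_overdominant", "OR2 = 1/OR3 != 1 and OR1 = 1"))
  up <- or1$ci_low > 1 && or2$ci_low > 1 && or3$ci_low > 1 &&
    or1$or > or2$or && or1$or > or3$or
  down <- or1$ci_high < 1 && or2$ci_high < 1 && or3$ci_high < 1 &&
    or1$or < or2$or && or1$or < or3$or
  if (up || down)
    return(verdict("codominant",
                   "OR1 > OR2 > 1 and OR1 > OR3 > 1 (or mirrored)"))
  verdict("undetermined", "no rule matched")
}

#' @export
print.model_verdict <- function(x, ...) {
  cat(sprintf("Thakkinstian verdict: %s (%s)\n", x$proposed, x$rule_fired))
  invisible(x)
}

#' False positive report probability of an association
#'
#' Wacholder's FPRP = alpha (1 - pi) / (alpha (1 - pi) + (1 - beta) pi),
#' where alpha is the observed two-sided p-value of the effect, 1 - beta the
#' power to detect an odds ratio of `threshold_or` at that alpha level, and
#' pi the prior probability of a true association. With z_obs =
#' |log OR| / SE and delta = |log(threshold_or)| (protective effects are
#' handled by symmetry), power = pnorm(delta/SE - z_obs) +
#' pnorm(-delta/SE - z_obs). An association is noteworthy when
#' FPRP < `noteworthy_cut` at pi = 0.01.
#'
#' @param effect an [effect_estimate()] (e.g. a pooled result's `effect`, or
#'   [effect_from_ci()] on a published OR and CI).
#' @param threshold_or odds ratio the power is computed against (default 1.5).
#' @param priors prior probabilities (default 0.1, 0.01, 0.001, 1e-4, 1e-5).
#' @param noteworthy_cut FPRP cutoff for noteworthiness (default 0.2).
#' @param alpha_level `"observed"` (default: the alpha entering the power is
#'   the observed p-value) or a fixed numeric level such as 0.05.
#' @return List of class `fprp_result`: `alpha_obs`, `power`,
#'   `fprp_by_prior` (named by prior), `noteworthy`.
#' @examples
#' fprp(effect_from_ci(0.69, 0.56, 0.85))  # FPRP ~ 0.072 at pi = 0.01
#' @export
fprp <- function(effect, threshold_or = 1.5,
                 priors = c(0.1, 0.01, 0.001, 1e-4, 1e-5),
                 noteworthy_cut = 0.2, alpha_level = "observed") {
  stopifnot(effect$se > 0, threshold_or > 0, threshold_or != 1,
            all(priors > 0), all(priors <= 1))
  z_obs <- abs(effect$log_or) / effect$se
  alpha_obs <- 2 * pnorm(-z_obs)
  z_crit <- if (identical(alpha_level, "observed")) z_obs
            else qnorm(1 - as.numeric(alpha_level) / 2)
  delta <- abs(log(threshold_or)) / effect$se
  power <- pnorm(delta - z_crit) + pnorm(-delta - z_crit)
  f <- alpha_obs * (1 - priors) / (alpha_obs * (1 - priors) + power * priors)
  names(f) <- format(priors, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  at_01 <- f[which.min(abs(priors - 0.01))]
  structure(list(alpha_obs = alpha_obs, power = power, fprp_by_prior = f,
                 noteworthy = unname(at_01) < noteworthy_cut,
                 threshold_or = threshold_or),
            class = "fprp_result")
}

#' @export
print.fprp_result <- function(x, ...) {
  cat(sprintf("FPRP (threshold OR %.2f): observed p = %.4g, power = %.3f\n",
              x$threshold_or, x$alpha_obs, x$power))
  for (nm in names(x$fprp_by_prior))
    cat(sprintf("  prior %-8s FPRP %.4f\n", nm, x$fprp_by_prior[nm]))
  cat(sprintf("  noteworthy at prior 0.01: %s\n",
              if (x$noteworthy) "yes" else "no"))
  invisible(x)
}

#' Composite candidate-to-definitive genetic-model decision
#'
#' For one SNP within one stratum: candidate models are the genetic models
#' significant in the pairwise meta-analysis that are also proposed by the
#' network meta-analysis (highest SUCRA) or by Thakkinstian's algorithm (or
#' both), provided at least `min_k` studies contributed. Definitive models
#' are the candidates whose pooled effect is FPRP-noteworthy. If several
#' models satisfy all criteria they are all retained. The Thakkinstian
#' verdicts "recessive"/"dominant" map onto the corresponding pairwise
#' models; "complete_overdominant" onto the over-dominant model;
#' "codominant" onto the homozygote contrast.
#'
#' @param pooled named list of `pooled_result`s, one per genetic model (at
#'   least the six of [genetic_models()] that could be computed).
#' @param nma_best highest-SUCRA model name from [rank_models()], or NULL if
#'   no NMA was run.
#' @param thakkinstian a `model_verdict`, or NULL.
#' @param fprp_results named list of `fprp_result`s per model (must cover
#'   the candidates).
#' @param snp_id,stratum labels carried into the record.
#' @param k number of studies behind the pooled results.
#' @param min_k minimum studies for model assessment (default 2).
#' @return List of class `model_decision`: `snp_id`, `stratum`, `k`,
#'   `significant_models`, `nma_best`, `thakkinstian_proposed`, `candidates`,
#'   `fprp_at_0.01` (named), `definitive`, `direction` ("hazardous",
#'   "protective" or "none"), `incomplete` (TRUE when both NMA and
#'   Thakkinstian stages are missing).
#' @export
decide_models <- function(pooled, nma_best = NULL, thakkinstian = NULL,
                          fprp_results = list(), snp_id = NA_character_,
                          stratum = "Both", k = NULL, min_k = 2) {
  if (is.null(k)) k <- max(vapply(pooled, function(p) p$k, numeric(1)))
  significant <- names(pooled)[vapply(pooled, function(p)
    sig_ne_1(p$effect), logical(1))]
  thak_model <- if (!is.null(thakkinstian)) switch(thakkinstian$proposed,
    recessive = "recessive", dominant = "dominant",
    complete_overdominant = "overdominant", codominant = "homozygote",
    undetermined = NULL) else NULL
  proposed <- union(nma_best, thak_model)
  incomplete <- is.null(nma_best) && is.null(thakkinstian)
  candidates <- if (k >= min_k) intersect(significant, proposed) else character(0)
  fprp01 <- vapply(candidates, function(m) {
    fr <- fprp_results[[m]]
    if (is.null(fr)) NA_real_
    else unname(fr$fprp_by_prior[which.min(abs(as.numeric(names(fr$fprp_by_prior)) - 0.01))])
  }, numeric(1))
  definitive <- candidates[!is.na(fprp01) & vapply(candidates, function(m)
    isTRUE(fprp_results[[m]]$noteworthy), logical(1))]
  direction <- if (!length(definitive)) "none"
  else if (mean(vapply(definitive, function(m) pooled[[m]]$effect$or,
                       numeric(1))) > 1) "hazardous" else "protective"
  structure(list(
    snp_id = snp_id, stratum = stratum, k = k,
    significant_models = significant, nma_best = nma_best,
    thakkinstian_proposed = if (is.null(thakkinstian)) NA_character_
                            else thakkinstian$proposed,
    candidates = candidates, fprp_at_0.01 = fprp01,
    definitive = definitive, direction = direction, incomplete = incomplete
  ), class = "model_decision")
}

#' @export
print.model_decision <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "/"
  cat(sprintf("%s [%s], k = %d%s\n", x$snp_id, x$stratum, x$k,
              if (x$incomplete) " (INCOMPLETE: no model-selection stage)" else ""))
  cat("  significant: ", fmt(x$significant_models), "\n", sep = "")
  cat("  NMA best: ", fmt(x$nma_best), "; Thakkinstian: ",
      x$thakkinstian_proposed, "\n", sep = "")
  cat("  candidates: ", fmt(x$candidates), "\n", sep = "")
  if (length(x$candidates))
    cat("  FPRP@0.01: ", paste(sprintf("%s=%.3f", x$candidates, x$fprp_at_0.01),
                               collapse = ", "), "\n", sep = "")
  cat("  definitive: ", fmt(x$definitive), " (", x$direction, ")\n", sep = "")
  invisible(x)
}

#' Flatten model decisions into a decision table
#'
#' One row per (SNP, stratum) in the shape of a published screening table:
#' study count, significant models, the NMA and Thakkinstian proposals,
#' candidates, FPRP at prior 0.01, definitive models and direction.
#'
#' @param decisions list of `model_decision`s.
#' @return Data frame.
#' @export
decision_table <- function(decisions) {
  fmt <- function(v) if (length(v)) paste(v, collapse = "; ") else "/"
  do.call(rbind, lapply(decisions, function(d) data.frame(
    snp_id = d$snp_id, stratum = d$stratum, k = d$k,
    significant_models = fmt(d$significant_models),
    nma_best = if (is.null(d$nma_best)) "/" else d$nma_best,
    thakkinstian = d$thakkinstian_proposed,
    candidates = fmt(d$candidates),
    fprp_0.01 = if (length(d$fprp_at_0.01))
      paste(sprintf("%.3g", d$fprp_at_0.01), collapse = "; ") else "/",
    definitive = fmt(d$definitive), direction = d$direction)))
}
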