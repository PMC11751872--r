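# End-to-end orchestration: screen -> contrasts -> pairwise pooling ->
# network meta-analysis -> model selection -> diagnostics, with a report
# bundle of CSV/JSON tables and a run manifest.

#' Configuration for a full pipeline run
#'
#' Defaults mirror standard practice for this analysis: FPRP threshold OR
#' 1.5 with priors 0.1 ... 1e-5, HWE alpha 0.05, minimum sample size 300,
#' NMA with 4 chains / 20,000 burn-in / 50,000 iterations. `nma` can be set
#' to a lighter [nma_config()] (or NULL to skip the NMA stage; model
#' selection then rests on Thakkinstian's algorithm alone).
#'
#' @param strata strata to analyze in addition to the pooled "Both" set.
#' @param models genetic models to fit.
#' @param nma an [nma_config()] or NULL.
#' @param fprp_or FPRP threshold odds ratio.
#' @param priors FPRP prior probabilities.
#' @param alpha_hwe HWE screening level.
#' @param min_n minimum combined sample size.
#' @param seed integer seed for stochastic stages.
#' @param diagnose_all run the diagnostic meta-analysis for every definitive
#'   model (default FALSE: hazardous definitive models only).
#' @return List of class `run_config`.
#' @export
run_config <- function(strata = c("Asian", "Caucasian"),
                       models = genetic_models(),
                       nma = nma_config(),
                       fprp_or = 1.5,
                       priors = c(0.1, 0.01, 0.001, 1e-4, 1e-5),
                       alpha_hwe = 0.05, min_n = 300, seed = 1,
                       diagnose_all = FALSE) {
  structure(list(strata = strata, models = models, nma = nma,
                 fprp_or = fprp_or, priors = priors, alpha_hwe = alpha_hwe,
                 min_n = min_n, seed = as.integer(seed),
                 diagnose_all = diagnose_all),
            class = "run_config")
}

pool_snp_models <- function(studies, models) {
  pooled <- list()
  for (m in models) {
    eff <- study_effects(studies, m)
    if (length(eff) >= 2) pooled[[m]] <- choose_and_pool(eff, model = m)
  }
  pooled
}

analyze_snp_stratum <- function(studies, cfg, snp, stratum) {
  k <- nrow(studies)
  if (k < 2) return(NULL)
  pooled <- pool_snp_models(studies, cfg$models)
  thak <- thakkinstian_decide(
    or1 = choose_and_pool(study_effects(studies, "homozygote"))$effect,
    or2 = choose_and_pool(study_effects(studies, "heterozygote"))$effect,
    or3 = choose_and_pool(study_effects(studies, "or3"))$effect)
  ranks <- NULL
  if (!is.null(cfg$nma)) {
    nma_cfg <- cfg$nma
    nma_cfg$seed <- cfg$seed + sum(utf8ToInt(paste0(snp, stratum))) %% 10000L
    post <- fit_nma(studies, nma_cfg)
    ranks <- rank_models(post)
  }
  fprps <- lapply(pooled, function(p)
    fprp(p$effect, threshold_or = cfg$fprp_or, priors = cfg$priors))
  decision <- decide_models(pooled,
                            nma_best = if (is.null(ranks)) NULL else ranks$best,
                            thakkinstian = thak, fprp_results = fprps,
                            snp_id = snp, stratum = stratum, k = k)
  list(pooled = pooled, thakkinstian = thak, ranks = ranks, fprp = fprps,
       decision = decision,
       loo = if (k >= 3) lapply(cfg$models, function(m)
         leave_one_out(study_effects(studies, m))) else NULL)
}

#' Run the full combined-evaluation pipeline
#'
#' Screens the studies, then for each SNP (overall and per ethnicity
#' stratum with at least two studies) pools all genetic models with the
#' fixed/random switch, runs leave-one-out, ethnicity/genotyping subgroup
#' analyses and publication-bias tests, fits the Bayesian genotype-node NMA
#' with SUCRA ranking, applies Thakkinstian's algorithm and the FPRP
#' criterion, and combines them into the candidate/definitive decision
#' table. A diagnostic-accuracy meta-analysis is run for definitive
#' hazardous models (all definitive models with `diagnose_all`). Reports
#' are written under `out_dir` together with a machine-readable manifest;
#' if a stage fails, the bundle contains everything up to the failure plus
#' an error record.
#'
#' @param studies a `genotype_studies` data frame (or path to a CSV for
#'   [parse_studies()]).
#' @param config a [run_config()].
#' @param out_dir output directory for the report bundle (NULL: no files).
#' @return List of class `pipeline_result`: `screening`, `analyses` (per
#'   SNP/stratum), `decisions` (decision table data frame), `bias`,
#'   `subgroups`, `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(studies, config = run_config(), out_dir = NULL) {
  t_start <- Sys.time()
  if (is.character(studies)) studies <- parse_studies(studies)
  manifest <- list(config = unclass(config), seed = config$seed,
                   started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
                   r_version = as.character(getRversion()),
                   stages = list(), error = NULL)
  result <- list(screening = NULL, analyses = list(), decisions = NULL,
                 bias = list(), subgroups = list(), diagnostics = list())
  emit <- function() {
    result$manifest <- manifest
    class(result) <- "pipeline_result"
    if (!is.null(out_dir)) write_bundle(result, out_dir)
    result
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- expr
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    val
  }
  tryCatch({
    result$screening <- stage("screen", apply_inclusion_filters(
      studies, alpha_hwe = config$alpha_hwe, min_n = config$min_n))
    kept <- result$screening$kept
    if (nrow(kept) == 0) stop("no studies left after screening")
    for (snp in unique(kept$snp_id)) {
      snp_studies <- kept[kept$snp_id == snp, , drop = FALSE]
      result$analyses[[paste0(snp, "|Both")]] <- stage(
        paste0("analyze:", snp, ":Both"),
        analyze_snp_stratum(snp_studies, config, snp, "Both"))
      for (st in config$strata) {
        sub <- snp_studies[snp_studies$ethnicity == st, , drop = FALSE]
        if (nrow(sub) >= 2)
          result$analyses[[paste0(snp, "|", st)]] <- stage(
            paste0("analyze:", snp, ":", st),
            analyze_snp_stratum(sub, config, snp, st))
      }
      # bias tests and subgroup analysis on the full per-SNP study set
      eff_all <- study_effects(snp_studies, "allelic")
      result$bias[[snp]] <- list(egger = egger_test(eff_all),
                                 begg = begg_test(eff_all))
      if (length(unique(snp_studies$ethnicity)) >= 2)
        result$subgroups[[snp]] <- subgroup_analysis(
          eff_all, snp_studies$ethnicity)
    }
    result$analyses <- Filter(Negate(is.null), result$analyses)
    result$decisions <- decision_table(
      lapply(result$analyses, `[[`, "decision"))
    for (key in names(result$analyses)) {
      dec <- result$analyses[[key]]$decision
      run_diag <- dec$definitive[
        config$diagnose_all | dec$direction == "hazardous"]
      if (length(run_diag) && dec$k >= 3) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        sub <- kept[kept$snp_id == parts[1] &
                      (parts[2] == "Both" | kept$ethnicity == parts[2]), ,
                    drop = FALSE]
        diags <- lapply(seq_len(nrow(sub)), function(i)
          diagnostic_study(sub[i, ], run_diag[1]))
        result$diagnostics[[key]] <- stage(paste0("diagnose:", key), list(
          model = run_diag[1],
          accuracy = pool_accuracy(diags, pooling = "random"),
          sroc = sroc_moses(diags, seed = config$seed),
          threshold = spearman_threshold(diags)))
      }
    }
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    emit()
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    warning("pipeline stopped: ", conditionMessage(e), call. = FALSE)
    emit()
  })
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$screening))
    write_screening_report(result$screening, out_dir)
  if (!is.null(result$decisions))
    utils::write.csv(result$decisions, file.path(out_dir, "decisions.csv"),
                     row.names = FALSE)
  pooled_rows <- list()
  sucra_rows <- list()
  for (key in names(result$analyses)) {
    an <- result$analyses[[key]]
    for (m in names(an$pooled)) {
      p <- an$pooled[[m]]
      pooled_rows[[paste(key, m)]] <- data.frame(
        key = key, model = m, k = p$k, method = p$method,
        or = p$effect$or, ci_low = p$effect$ci_low,
        ci_high = p$effect$ci_high, p = p$effect$p_value,
        q = p$het$q, p_q = p$het$p_q, i2 = p$het$i2, tau2 = p$het$tau2)
    }
    if (!is.null(an$ranks))
      sucra_rows[[key]] <- data.frame(key = key,
                                      model = names(an$ranks$sucra),
                                      sucra = unname(an$ranks$sucra))
  }
  if (length(pooled_rows))
    utils::write.csv(do.call(rbind, pooled_rows),
                     file.path(out_dir, "pooled_results.csv"), row.names = FALSE)
  if (length(sucra_rows))
    utils::write.csv(do.call(rbind, sucra_rows),
                     file.path(out_dir, "sucra.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Combined-evaluation pipeline run\n")
  if (!is.null(x$screening))
    cat(sprintf("  screened: %d kept / %d dropped\n",
                nrow(x$screening$kept), nrow(x$screening$dropped)))
  cat(sprintf("  analyses: %d SNP-stratum sets; diagnostics: %d\n",
              length(x$analyses), length(x$diagnostics)))
  if (!is.null(x$manifest$error))
    cat("  ERROR: ", x$manifest$error, "\n", sep = "")
  if (!is.null(x$decisions)) print(x$decisions)
  invisible(x)
}
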