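# Case-control genotype simulator with known generative truth.
#
# Controls are drawn from exact Hardy-Weinberg proportions at a chosen
# variant-allele frequency; case genotype probabilities are obtained by
# tilting the control distribution with per-genotype odds multipliers
# determined by the generative genetic model and a (possibly study-specific)
# odds ratio. Because the tilt acts on genotype odds directly, the target
# contrast's odds ratio is exact by construction under case-control
# sampling, which makes sharp parameter-recovery tests possible.

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf variant allele frequency q, strictly inside (0, 1).
#' @return Probability triple ((1-q)^2, 2q(1-q), q^2).
#' @examples
#' hwe_probs(0.3)  # 0.49 0.42 0.09
#' @export
hwe_probs <- function(maf) {
  if (!is.finite(maf) || maf <= 0 || maf >= 1)
    stop("maf must lie strictly inside (0, 1)")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Case genotype probabilities under a generative genetic model
#'
#' Case probabilities are proportional to the control probabilities times
#' per-genotype odds multipliers m = (m11, m12, m22):
#' recessive (1, 1, psi); dominant (1, psi, psi); overdominant (1, psi, 1);
#' homozygote/codominant (1, psi^h, psi) with heterozygote exponent `h`
#' (default 0.5, log-additive); allelic (1, psi, psi^2).
#'
#' @param control_probs genotype probability triple (e.g. [hwe_probs()]).
#' @param model generative model: one of [genetic_models()] or "codominant"
#'   (alias of homozygote with exponent `h`).
#' @param or_study odds ratio psi (> 0) for this study.
#' @param h heterozygote exponent for the homozygote/codominant tilt.
#' @return Case genotype probability triple.
#' @examples
#' case_probs(hwe_probs(0.3), "recessive", 2)
#' @export
case_probs <- function(control_probs, model, or_study, h = 0.5) {
  stopifnot(length(control_probs) == 3, all(control_probs >= 0),
            abs(sum(control_probs) - 1) < 1e-8, or_study > 0)
  psi <- or_study
  m <- switch(match.arg(model, c(genetic_models(), "codominant")),
    recessive = c(1, 1, psi),
    dominant = c(1, psi, psi),
    overdominant = c(1, psi, 1),
    homozygote = c(1, psi^h, psi),
    codominant = c(1, psi^h, psi),
    heterozygote = c(1, psi, 1),
    allelic = c(1, psi, psi^2)
  )
  w <- control_probs * m
  w / sum(w)
}

#' Simulation settings for a synthetic study corpus
#'
#' Defaults emulate a typical candidate-SNP literature: around ten studies
#' per SNP, per-arm sample sizes spanning a few hundred subjects (totals in
#' the low-to-mid hundreds through low thousands), a common variant
#' (MAF 0.3), modest between-study heterogeneity on the log-OR scale, and a
#' roughly 70/30 Asian/Caucasian split.
#'
#' @param snp_id SNP label.
#' @param k_studies number of studies.
#' @param n_cases,n_controls per-study arm sizes: a single integer or a
#'   range `c(lo, hi)` sampled uniformly per study.
#' @param maf control variant-allele frequency in (0, 1).
#' @param true_model generative genetic model.
#' @param true_or generative odds ratio psi.
#' @param tau between-study SD of the log odds ratio.
#' @param ethnicity_split named proportions over ethnicity strata.
#' @param h heterozygote exponent for codominant generation.
#' @param seed integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(snp_id = "rs0000001", k_studies = 10,
                       n_cases = c(160, 1200), n_controls = c(160, 1200),
                       maf = 0.3, true_model = "recessive", true_or = 1.5,
                       tau = 0.1, ethnicity_split = c(Asian = 0.7, Caucasian = 0.3),
                       h = 0.5, seed = 1) {
  stopifnot(k_studies >= 1, maf > 0, maf < 1, true_or > 0, tau >= 0,
            all(ethnicity_split > 0))
  structure(list(snp_id = snp_id, k_studies = as.integer(k_studies),
                 n_cases = n_cases, n_controls = n_controls, maf = maf,
                 true_model = match.arg(true_model,
                                        c(genetic_models(), "codominant")),
                 true_or = true_or, tau = tau,
                 ethnicity_split = ethnicity_split / sum(ethnicity_split),
                 h = h, seed = as.integer(seed)),
            class = "sim_config")
}

draw_n <- function(spec, k) {
  if (length(spec) == 1) rep(as.integer(spec), k)
  else as.integer(round(stats::runif(k, spec[1], spec[2])))
}

#' Simulate a corpus of case-control genotype studies
#'
#' Per study: a study-level log-OR is drawn from
#' Normal(log(true_or), tau^2); control genotypes are multinomial at the
#' exact HWE probabilities; case genotypes are multinomial at the tilted
#' probabilities of [case_probs()] evaluated at the study OR. Fully
#' reproducible under the config seed, which is consumed locally (the
#' session RNG stream is untouched).
#'
#' @param config a [sim_config()].
#' @return List of class `sim_corpus`: `studies` (a `genotype_studies` data
#'   frame in the same schema [parse_studies()] reads, with quality and
#'   genotyping metadata filled in) and `truth` (`sim_config` echo,
#'   per-study realized log-ORs, control genotype probabilities).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    k <- config$k_studies
    p_ctrl <- hwe_probs(config$maf)
    log_ors <- stats::rnorm(k, log(config$true_or), config$tau)
    n_ca <- draw_n(config$n_cases, k)
    n_co <- draw_n(config$n_controls, k)
    eth <- sample(names(config$ethnicity_split), k, replace = TRUE,
                  prob = config$ethnicity_split)
    gmeth <- sample(GENOTYPING_METHODS, k, replace = TRUE,
                    prob = c(0.5, 0.35, 0.15))
    qual <- sample(7:15, k, replace = TRUE,
                   prob = c(rep(3, 4), rep(2, 5)))  # medium-heavy, like real corpora
    rows <- lapply(seq_len(k), function(i) {
      p_case <- case_probs(p_ctrl, config$true_model, exp(log_ors[i]),
                           h = config$h)
      ca <- as.integer(stats::rmultinom(1, n_ca[i], p_case))
      co <- as.integer(stats::rmultinom(1, n_co[i], p_ctrl))
      data.frame(study_id = sprintf("sim%02d", i),
                 first_author = sprintf("Author%02d", i),
                 year = 2010L + (i %% 14L), country = "simulated",
                 ethnicity = eth[i], control_source = "population",
                 genotyping_method = gmeth[i],
                 snp_id = config$snp_id, gene = "simGene",
                 case_11 = ca[1], case_12 = ca[2], case_22 = ca[3],
                 ctrl_11 = co[1], ctrl_12 = co[2], ctrl_22 = co[3],
                 quality_total = qual[i])
    })
    studies <- as_genotype_studies(do.call(rbind, rows))
    structure(list(
      studies = studies,
      truth = list(config = config, log_ors = log_ors,
                   control_probs = p_ctrl)
    ), class = "sim_corpus")
  })
}

#' @export
print.sim_corpus <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Simulated corpus: %d studies of %s (%s model, OR %.2f, tau %.2f, MAF %.2f)\n",
              cfg$k_studies, cfg$snp_id, cfg$true_model, cfg$true_or,
              cfg$tau, cfg$maf))
  invisible(x)
}

#' Write a simulated corpus to disk
#'
#' Emits the CSV schema [parse_studies()] consumes plus a JSON sidecar with
#' the generative truth.
#'
#' @param corpus a `sim_corpus`.
#' @param path output CSV path; the truth sidecar gets extension
#'   `.truth.json`.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(corpus, path) {
  write_studies(corpus$studies, path)
  truth_path <- sub("\\.csv$", "", path)
  truth_path <- paste0(truth_path, ".truth.json")
  cfg <- corpus$truth$config
  jsonlite::write_json(list(
    config = unclass(cfg), log_ors = corpus$truth$log_ors,
    control_probs = corpus$truth$control_probs
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, truth_path))
}
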