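# Bayesian random-effects network meta-analysis over genotype nodes.
#
# Each study contributes up to three "arms" (genotypes 11, 12, 22) with a
# binomial case-membership outcome: events = cases with that genotype,
# trials = all subjects (cases + controls) with it. The hierarchical
# logistic model is
#   logit(p_ig) = mu_i + delta_ig,  delta_i,11 = 0,
#   delta_ig ~ Normal(d_g, tau^2) for g in {12, 22},  d_11 = 0,
# so d_12 and d_22 are the population log odds ratios of the heterozygote
# and variant-homozygote genotypes against the common homozygote (invariant
# to the case-control sampling fractions). Composite genetic models are
# derived per posterior draw from (d_12, d_22) and the pooled control
# genotype mixture.

NMA_MODEL_STRING <- "
model {
  for (k in 1:Nobs) {
    r[k] ~ dbin(p[k], n[k])
    logit(p[k]) <- mu[s[k]] + delta[s[k], g[k]]
  }
  for (i in 1:K) {
    delta[i, 1] <- 0
    for (j in 2:3) { delta[i, j] ~ dnorm(d[j], prec.tau) }
    mu[i] ~ dnorm(0, 0.01)
  }
  d[1] <- 0
  for (j in 2:3) { d[j] ~ dnorm(0, 0.01) }
  tau ~ dnorm(0, 1) T(0,)
  prec.tau <- pow(tau, -2)
}
"

#' Configuration for the Bayesian network meta-analysis
#'
#' Defaults follow common practice for genotype-node networks: four parallel
#' chains, 20,000 burn-in iterations and 50,000 sampling iterations; vague
#' Normal(0, 10^2) priors on the basic log-ORs and study baselines and a
#' half-Normal(0, 1) prior on the between-study SD.
#'
#' @param chains number of MCMC chains (>= 2, required for PSRF).
#' @param burn_in burn-in iterations per chain.
#' @param iterations retained iterations per chain.
#' @param seed integer seed; per-chain RNG seeds are derived from it.
#' @param thin thinning interval.
#' @return List of class `nma_config`.
#' @export
nma_config <- function(chains = 4, burn_in = 20000, iterations = 50000,
                       seed = 1, thin = 1) {
  stopifnot(iterations > 0, burn_in >= 0, thin >= 1)
  if (chains < 2) stop("at least two chains are required (PSRF undefined otherwise)")
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 thin = as.integer(thin),
                 priors = list(d = "Normal(0, 10^2)", mu = "Normal(0, 10^2)",
                               tau = "half-Normal(0, 1)")),
            class = "nma_config")
}

#' Fit the genotype-node network meta-analysis for one SNP
#'
#' @param studies a `genotype_studies` data frame (all rows assumed to be
#'   the same SNP; at least two studies).
#' @param config an [nma_config()].
#' @return Object of class `nma_posterior`: `d_het`, `d_hom`, `tau` (pooled
#'   posterior draws across chains), `chains` (per-chain draws for PSRF),
#'   `psrf` (named: d_het, d_hom, tau), `converged` (all PSRF <= 1.1),
#'   `control_mix` (pooled control genotype proportions), `config`,
#'   `dropped_nodes`.
#' @export
fit_nma <- function(studies, config = nma_config()) {
  studies <- as.data.frame(studies)
  K <- nrow(studies)
  if (K < 2) stop("network meta-analysis requires at least two studies")
  # long-format arms: events = cases, trials = cases + controls per genotype
  r <- n <- s <- g <- integer(0)
  for (i in seq_len(K)) {
    ca <- as.numeric(studies[i, c("case_11", "case_12", "case_22")])
    co <- as.numeric(studies[i, c("ctrl_11", "ctrl_12", "ctrl_22")])
    for (j in 1:3) {
      if (ca[j] + co[j] > 0) {
        r <- c(r, ca[j]); n <- c(n, ca[j] + co[j]); s <- c(s, i); g <- c(g, j)
      }
    }
  }
  dropped <- setdiff(1:3, unique(g))
  if (length(dropped)) {
    warning("genotype node(s) absent from all studies: ",
            paste(c("11", "12", "22")[dropped], collapse = ", "))
  }
  inits <- lapply(seq_len(config$chains), function(ch)
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (config$seed * 1000L + ch) %% 2147483647L))
  jm <- rjags::jags.model(textConnection(NMA_MODEL_STRING),
                          data = list(Nobs = length(r), K = K, r = r, n = n,
                                      s = s, g = g),
                          n.chains = config$chains, inits = inits, quiet = TRUE)
  if (config$burn_in > 0) update(jm, config$burn_in, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("d", "tau"), n.iter = config$iterations,
                             thin = config$thin, progress.bar = "none")
  per_chain <- lapply(sam, function(m)
    list(d_het = as.numeric(m[, "d[2]"]), d_hom = as.numeric(m[, "d[3]"]),
         tau = as.numeric(m[, "tau"])))
  psrf_val <- c(
    d_het = psrf(lapply(per_chain, `[[`, "d_het")),
    d_hom = psrf(lapply(per_chain, `[[`, "d_hom")),
    tau = psrf(lapply(per_chain, `[[`, "tau")))
  if (any(psrf_val > 1.1))
    warning("PSRF above 1.1 for: ",
            paste(names(psrf_val)[psrf_val > 1.1], collapse = ", "),
            " - chains may not have converged")
  ctrl_tot <- colSums(studies[, c("ctrl_11", "ctrl_12", "ctrl_22")])
  structure(list(
    d_het = unlist(lapply(per_chain, `[[`, "d_het")),
    d_hom = unlist(lapply(per_chain, `[[`, "d_hom")),
    tau = unlist(lapply(per_chain, `[[`, "tau")),
    chains = per_chain, psrf = psrf_val, converged = all(psrf_val <= 1.1),
    control_mix = as.numeric(ctrl_tot / sum(ctrl_tot)),
    config = config, dropped_nodes = dropped
  ), class = "nma_posterior")
}

#' @export
print.nma_posterior <- function(x, ...) {
  cat(sprintf("Genotype-node NMA: %d draws x %d chains\n",
              length(x$chains[[1]]$d_het), length(x$chains)))
  cat(sprintf("  d_het (12 vs 11): mean %.4f; d_hom (22 vs 11): mean %.4f; tau: mean %.4f\n",
              mean(x$d_het), mean(x$d_hom), mean(x$tau)))
  cat(sprintf("  PSRF: d_het %.3f, d_hom %.3f, tau %.3f -> %s\n",
              x$psrf["d_het"], x$psrf["d_hom"], x$psrf["tau"],
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Derive the six genetic-model log-ORs from basic NMA parameters
#'
#' Per posterior draw: the homozygote and heterozygote contrasts are the
#' basic parameters themselves. The composite models (dominant, recessive,
#' over-dominant, allelic) are obtained by tilting the pooled control
#' genotype mixture: case genotype probabilities are proportional to
#' control_mix * exp(d_g) (d_11 = 0), and each composite model's log-OR is
#' that of the implied 2x2 table.
#'
#' @param post an `nma_posterior`, or a list with numeric vectors `d_het`
#'   and `d_hom`.
#' @param control_mix genotype probability triple (defaults to the pooled
#'   control mixture stored in `post`).
#' @return Matrix (draws x 6) of log-ORs, columns named by
#'   [genetic_models()]. Composite columns are NA (with a warning) when
#'   `control_mix` has a zero component that makes them degenerate.
#' @export
derive_model_contrasts <- function(post, control_mix = post$control_mix) {
  d_het <- post$d_het
  d_hom <- post$d_hom
  stopifnot(length(d_het) == length(d_hom), length(control_mix) == 3,
            all(control_mix >= 0), abs(sum(control_mix) - 1) < 1e-6)
  p <- control_mix
  if (any(p == 0))
    warning("degenerate control mixture (zero component): composite models set to NA")
  w11 <- p[1]
  w12 <- p[2] * exp(d_het)
  w22 <- p[3] * exp(d_hom)
  tot <- w11 + w12 + w22
  c11 <- w11 / tot; c12 <- w12 / tot; c22 <- w22 / tot
  lor <- function(pe_case, pe_ctrl)
    log(pe_case / (1 - pe_case)) - log(pe_ctrl / (1 - pe_ctrl))
  # allelic: variant allele frequency in each group
  qa_case <- c22 + c12 / 2
  qa_ctrl <- p[3] + p[2] / 2
  out <- cbind(
    allelic = lor(qa_case, qa_ctrl),
    homozygote = d_hom,
    heterozygote = d_het,
    dominant = lor(c12 + c22, p[2] + p[3]),
    recessive = lor(c22, p[3]),
    overdominant = lor(c12, p[2]))
  if (any(p == 0))  # composite models are undefined; identities are kept
    out[, c("allelic", "dominant", "recessive", "overdominant")] <- NA_real_
  out
}

#' Rank probabilities of the genetic models over posterior draws
#'
#' Models are ranked per draw by descending association strength |log-OR|
#' (direction-agnostic, so protective and hazardous effects rank alike);
#' rank 1 = strongest.
#'
#' @param contrasts matrix of per-draw log-ORs (draws x models), e.g. from
#'   [derive_model_contrasts()]. Columns with any NA are dropped.
#' @return Row-stochastic matrix (model x rank) of rank probabilities.
#' @export
rank_probabilities <- function(contrasts) {
  keep <- colSums(is.na(contrasts)) == 0
  m <- contrasts[, keep, drop = FALSE]
  K <- ncol(m)
  if (K < 2) stop("need at least two non-degenerate models to rank")
  counts <- matrix(0, K, K, dimnames = list(colnames(m), paste0("rank", 1:K)))
  for (i in seq_len(nrow(m))) {
    rk <- rank(-abs(m[i, ]), ties.method = "first")
    counts[cbind(seq_len(K), rk)] <- counts[cbind(seq_len(K), rk)] + 1
  }
  counts / nrow(m)
}

#' SUCRA scores from a rank-probability matrix
#'
#' Surface under the cumulative ranking curve:
#' SUCRA_k = sum over r = 1..K-1 of P(model k ranks in top r) / (K - 1).
#' 1 means certainly best-ranked, 0 certainly worst; the mean over models is
#' exactly 0.5 for any valid rank matrix.
#'
#' @param rank_probabilities row-stochastic matrix (model x rank).
#' @return Named numeric vector of SUCRA scores in \[0, 1\].
#' @export
sucra <- function(rank_probabilities) {
  rp <- as.matrix(rank_probabilities)
  if (any(abs(rowSums(rp) - 1) > 1e-6))
    stop("rank probability rows must sum to 1")
  K <- ncol(rp)
  cum <- t(apply(rp, 1, cumsum))
  out <- if (K == 1) rep(1, nrow(rp)) else rowSums(cum[, 1:(K - 1), drop = FALSE]) / (K - 1)
  names(out) <- rownames(rp)
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' PSRF = sqrt((W (n-1)/n + B/n) / W) for m chains of length n, with W the
#' mean within-chain variance and B the between-chain variance (n * variance
#' of chain means). Values near 1 indicate convergence.
#'
#' @param chains list of >= 2 equal-length numeric vectors (length >= 10).
#' @return The PSRF (positive scalar). Identical constant chains return 1 by
#'   convention; constant but unequal chains are an error.
#' @export
psrf <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("PSRF requires at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 10) stop("chains must have equal length >= 10")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    if (B == 0) return(1)
    stop("zero within-chain variance with differing chains: PSRF undefined")
  }
  sqrt((W * (n - 1) / n + B / n) / W)
}

# Per-draw standardized association strength |log-OR|/SE of each model's
# implied 2x2, with the Woolf SE evaluated at the draw's case mixture and
# the control mixture on a unit-subject scale (equal arms; the common
# sample-size factor cancels in the ranking). Standardization matters:
# under, e.g., a strictly recessive data-generating process the recessive
# and homozygote contrasts share the same true log-OR, and only the
# information content of their dichotomizations separates them.
model_z_scores <- function(post, control_mix) {
  lors <- derive_model_contrasts(post, control_mix)
  p <- control_mix
  w12 <- p[2] * exp(post$d_het)
  w22 <- p[3] * exp(post$d_hom)
  tot <- p[1] + w12 + w22
  c11 <- p[1] / tot; c12 <- w12 / tot; c22 <- w22 / tot
  woolf <- function(a, b, cc, d) sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  qa_case <- c22 + c12 / 2; qa_ctrl <- p[3] + p[2] / 2
  se <- cbind(
    allelic = woolf(2 * qa_case, 2 * (1 - qa_case), 2 * qa_ctrl, 2 * (1 - qa_ctrl)),
    homozygote = woolf(c22, c11, p[3], p[1]),
    heterozygote = woolf(c12, c11, p[2], p[1]),
    dominant = woolf(c12 + c22, c11, p[2] + p[3], p[1]),
    recessive = woolf(c22, c11 + c12, p[3], p[1] + p[2]),
    overdominant = woolf(c12, c11 + c22, p[2], p[1] + p[3]))
  abs(lors) / se[, colnames(lors), drop = FALSE]
}

#' Summarize an NMA fit as a SUCRA ranking of the six genetic models
#'
#' Models are ranked per posterior draw by standardized association
#' strength: |log-OR| divided by the Woolf standard error of the model's
#' implied 2x2 table at that draw's case-genotype mixture (equal unit
#' arms). This is direction-agnostic like a plain |log-OR| ranking but
#' additionally credits dichotomizations that use the sample more
#' efficiently, which breaks the structural ties between composite models
#' and the basic contrasts they coincide with.
#'
#' @param post an `nma_posterior` from [fit_nma()].
#' @param control_mix optional override of the control genotype mixture.
#' @param criterion `"z"` (default, standardized) or `"lor"` (rank by plain
#'   |log-OR|).
#' @return List of class `rank_summary`: `rank_probabilities`, `sucra`
#'   (sorted decreasing), `best` (highest-SUCRA model).
#' @export
rank_models <- function(post, control_mix = post$control_mix,
                        criterion = c("z", "lor")) {
  criterion <- match.arg(criterion)
  scores <- if (criterion == "z") model_z_scores(post, control_mix)
            else derive_model_contrasts(post, control_mix)
  rp <- rank_probabilities(scores)
  sc <- sucra(rp)
  structure(list(rank_probabilities = rp, sucra = sc,
                 best = names(sc)[which.max(sc)]),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("SUCRA ranking of genetic models (higher = more suitable):\n")
  sc <- sort(x$sucra, decreasing = TRUE)
  for (nm in names(sc)) cat(sprintf("  %-13s %.3f\n", nm, sc[nm]))
  invisible(x)
}
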