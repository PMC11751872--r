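or_ci <- function(or, lo, hi) effect_from_ci(or, lo, hi)

test_that("Thakkinstian's rules propose the documented models", {
  rec <- thakkinstian_decide(or_ci(2.0, 1.5, 2.7), or_ci(1.0, 0.8, 1.3),
                             or_ci(2.0, 1.5, 2.7))
  expect_equal(rec$proposed, "recessive")

  dom <- thakkinstian_decide(or_ci(2.0, 1.5, 2.7), or_ci(2.0, 1.5, 2.7),
                             or_ci(1.0, 0.8, 1.3))
  expect_equal(dom$proposed, "dominant")

  cod <- thakkinstian_decide(or_ci(2.5, 1.8, 3.5), or_ci(1.6, 1.2, 2.1),
                             or_ci(1.5, 1.1, 2.0))
  expect_equal(cod$proposed, "codominant")

  od <- thakkinstian_decide(or_ci(1.0, 0.8, 1.25), or_ci(2.0, 1.5, 2.7),
                            or_ci(0.5, 0.37, 0.67))
  expect_equal(od$proposed, "complete_overdominant")

  none <- thakkinstian_decide(or_ci(1.1, 0.9, 1.35), or_ci(1.0, 0.8, 1.25),
                              or_ci(1.1, 0.9, 1.35))
  expect_equal(none$proposed, "undetermined")
})

test_that("Thakkinstian verdicts are invariant to jointly inverting all three ORs", {
  invert <- function(e) effect_estimate(-e$log_or, e$se)
  set.seed(41)
  for (i in 1:60) {
    ors <- lapply(1:3, function(j)
      effect_estimate(rnorm(1, 0, 0.6), runif(1, 0.05, 0.3)))
    v1 <- thakkinstian_decide(ors[[1]], ors[[2]], ors[[3]])
    v2 <- thakkinstian_decide(invert(ors[[1]]), invert(ors[[2]]),
                              invert(ors[[3]]))
    expect_equal(v2$proposed, v1$proposed)
  }
})

test_that("FPRP reproduces spreadsheet-style hand computations", {
  # OR 2.0, CI (1.2, 3.33): se = ln(3.33/1.2)/3.92, alpha ~ 0.00776,
  # power ~ 0.135 -> FPRP ~ 0.851 at prior 0.01
  f <- fprp(or_ci(2.0, 1.2, 3.33))
  expect_equal(f$alpha_obs, 0.0078, tolerance = 0.01)
  expect_equal(f$power, 0.135, tolerance = 0.01)
  expect_equal(unname(f$fprp_by_prior["0.01"]), 0.851, tolerance = 0.001)
  expect_false(f$noteworthy)

  strong <- fprp(or_ci(1.58, 1.32, 1.89))
  expect_true(strong$noteworthy)
  expect_lt(unname(strong$fprp_by_prior["0.01"]), 0.001)
})

test_that("FPRP is monotone in the prior and in the association strength", {
  set.seed(43)
  for (i in 1:15) {
    e <- effect_estimate(runif(1, 0.1, 1.2), runif(1, 0.05, 0.4))
    f <- fprp(e)$fprp_by_prior
    expect_true(all(diff(f) > 0))  # priors are listed decreasing
  }
  # FPRP falls as |z| grows at fixed SE
  se <- 0.15
  vals <- vapply(seq(0.1, 1.5, by = 0.1), function(b)
    unname(fprp(effect_estimate(b, se))$fprp_by_prior["0.01"]), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("FPRP limits: certainty prior gives 0, vanishing prior gives 1, null effect is finite", {
  e <- effect_estimate(0.4, 0.15)
  expect_equal(unname(fprp(e, priors = 1)$fprp_by_prior), 0)
  expect_gt(unname(fprp(e, priors = 1e-12)$fprp_by_prior), 0.999)
  nul <- fprp(effect_estimate(0, 0.2))
  expect_equal(nul$alpha_obs, 1)
  expect_equal(nul$power, 1)  # at z = 0 the two power tails sum to one
  expect_true(all(is.finite(nul$fprp_by_prior)))
})

test_that("protective and hazardous effects of equal magnitude get identical FPRP", {
  a <- fprp(effect_estimate(log(1.5), 0.1))
  b <- fprp(effect_estimate(-log(1.5), 0.1))
  expect_equal(a$fprp_by_prior, b$fprp_by_prior)
})

test_that("the fixed-alpha power convention is available as an option", {
  e <- or_ci(0.69, 0.56, 0.85)
  obs <- fprp(e)
  fixed <- fprp(e, alpha_level = 0.05)
  expect_gt(fixed$power, obs$power)  # z_crit 1.96 < observed z here
  expect_false(isTRUE(all.equal(obs$fprp_by_prior, fixed$fprp_by_prior)))
})

test_that("the composite decision combines pairwise, NMA/Thakkinstian and FPRP", {
  eff_rec <- make_effects(rep(log(1.6), 4), rep(0.1, 4))
  eff_hom <- make_effects(rep(log(1.7), 4), rep(0.12, 4))
  eff_null <- make_effects(rep(0.01, 4), rep(0.1, 4))
  pooled <- list(recessive = choose_and_pool(eff_rec, model = "recessive"),
                 homozygote = choose_and_pool(eff_hom, model = "homozygote"),
                 dominant = choose_and_pool(eff_null, model = "dominant"))
  thak <- structure(list(proposed = "recessive", rule_fired = "test"),
                    class = "model_verdict")
  fprps <- lapply(pooled, function(p) fprp(p$effect))
  dec <- decide_models(pooled, nma_best = "overdominant", thakkinstian = thak,
                       fprp_results = fprps, snp_id = "rs895819",
                       stratum = "Asian", k = 4)
  expect_setequal(dec$significant_models, c("recessive", "homozygote"))
  expect_equal(dec$candidates, "recessive")
  expect_equal(dec$definitive, "recessive")
  expect_equal(dec$direction, "hazardous")
  expect_true(all(dec$definitive %in% dec$candidates))
  expect_true(all(dec$candidates %in% dec$significant_models))

  # a candidate whose FPRP is not noteworthy never becomes definitive
  weak <- make_effects(rep(log(0.86), 2), rep(0.102, 2))
  pooled_w <- list(overdominant = choose_and_pool(weak, model = "overdominant"))
  fw <- lapply(pooled_w, function(p) fprp(p$effect))
  expect_false(fw$overdominant$noteworthy)
  dec_w <- decide_models(pooled_w, nma_best = "overdominant",
                         thakkinstian = NULL, fprp_results = fw,
                         snp_id = "x", k = 2)
  expect_equal(dec_w$candidates, "overdominant")
  expect_length(dec_w$definitive, 0)
  expect_equal(dec_w$direction, "none")

  # nothing significant in pairwise: vacuous decision
  dec_v <- decide_models(list(dominant = choose_and_pool(eff_null)),
                         nma_best = "dominant", thakkinstian = NULL,
                         fprp_results = list(), snp_id = "y", k = 4)
  expect_length(dec_v$candidates, 0)
  expect_length(dec_v$definitive, 0)

  # fewer than two studies: no candidates even when proposed
  dec_k1 <- decide_models(pooled, nma_best = "recessive", thakkinstian = thak,
                          fprp_results = fprps, snp_id = "z", k = 1)
  expect_length(dec_k1$candidates, 0)

  # both selection stages missing: flagged incomplete, never silently empty
  dec_inc <- decide_models(pooled, nma_best = NULL, thakkinstian = NULL,
                           fprp_results = fprps, snp_id = "w", k = 4)
  expect_true(dec_inc$incomplete)
})

test_that("decision_table flattens decisions into one row per SNP-stratum", {
  eff <- make_effects(rep(log(1.6), 3), rep(0.1, 3))
  pooled <- list(recessive = choose_and_pool(eff, model = "recessive"))
  dec <- decide_models(pooled, nma_best = "recessive", thakkinstian = NULL,
                       fprp_results = lapply(pooled, function(p) fprp(p$effect)),
                       snp_id = "rs1", stratum = "Both", k = 3)
  tab <- decision_table(list(dec))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$definitive, "recessive")
  expect_equal(tab$direction, "hazardous")
})
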