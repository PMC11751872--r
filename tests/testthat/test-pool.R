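test_that("fixed-effect pooling matches the inverse-variance hand oracle", {
  id <- pool_fixed(make_effects(c(0.5, 0.5), c(0.2, 0.2)))
  expect_equal(id$effect$log_or, 0.5)
  expect_equal(id$effect$se, 0.2 / sqrt(2), tolerance = 1e-12)
  expect_equal(id$het$q, 0)
  expect_equal(id$het$i2, 0)

  two <- pool_fixed(make_effects(c(0, log(2)), c(0.3, 0.3)))
  expect_equal(two$effect$log_or, log(2) / 2, tolerance = 1e-12)
  expect_equal(two$het$q, 2 * (log(2) / 2 / 0.3)^2, tolerance = 1e-12)

  expect_error(pool_fixed(make_effects(0.5, 0.2)), "two studies")

  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    yi <- rnorm(k); sei <- runif(k, 0.05, 0.5)
    pr <- pool_fixed(make_effects(yi, sei))
    h <- hand_fixed(yi, sei)
    expect_equal(pr$effect$log_or, h$mu, tolerance = 1e-12)
    expect_equal(pr$effect$se, h$se, tolerance = 1e-12)
    expect_equal(pr$het$q, h$q, tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird pooling matches its moment oracle and metafor", {
  hom <- pool_random(make_effects(c(0.5, 0.5), c(0.2, 0.2)))
  expect_equal(hom$het$tau2, 0)
  expect_equal(hom$effect$log_or,
               pool_fixed(make_effects(c(0.5, 0.5), c(0.2, 0.2)))$effect$log_or)

  hetero <- pool_random(make_effects(c(0, 1), c(0.1, 0.1)))
  expect_equal(hetero$het$q, 50, tolerance = 1e-12)
  expect_equal(hetero$het$tau2, 49 / (200 - 20000 / 200), tolerance = 1e-12)
  expect_gt(hetero$effect$se,
            pool_fixed(make_effects(c(0, 1), c(0.1, 0.1)))$effect$se)

  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    yi <- rnorm(k, 0.3, 0.4); sei <- runif(k, 0.05, 0.5)
    pr <- pool_random(make_effects(yi, sei))
    h <- hand_dl(yi, sei)
    expect_equal(pr$effect$log_or, h$mu, tolerance = 1e-12)
    expect_equal(pr$het$tau2, h$tau2, tolerance = 1e-12)
    # cross-check against metafor's DL implementation
    mf <- metafor::rma(yi = yi, sei = sei, method = "DL")
    expect_equal(pr$effect$log_or, as.numeric(mf$beta), tolerance = 1e-10)
    expect_equal(pr$het$tau2, mf$tau2, tolerance = 1e-10)
    # random-effects CI is never narrower than fixed-effect
    expect_gte(pr$effect$se, pool_fixed(make_effects(yi, sei))$effect$se)
  }
})

test_that("pooled estimates are invariant to study permutation", {
  set.seed(17)
  yi <- rnorm(6); sei <- runif(6, 0.1, 0.4)
  ref <- pool_random(make_effects(yi, sei))
  for (i in 1:5) {
    p <- sample(6)
    pr <- pool_random(make_effects(yi[p], sei[p]))
    expect_equal(pr$effect$log_or, ref$effect$log_or, tolerance = 1e-12)
    expect_equal(pr$het$tau2, ref$het$tau2, tolerance = 1e-12)
  }
})

test_that("the switching rule uses fixed only when p > 0.1 and I2 < 50, strictly", {
  expect_equal(choose_and_pool(make_effects(c(0.5, 0.52), c(0.2, 0.2)))$method,
               "fixed")
  expect_equal(choose_and_pool(make_effects(c(0, 1), c(0.1, 0.1)))$method,
               "random")
  # I2 exactly 50 with p(Q) ~ 0.157 > 0.1: the strict inequality sends it random
  boundary <- choose_and_pool(make_effects(c(0, 2), c(1, 1)))
  expect_equal(boundary$het$i2, 50)
  expect_gt(boundary$het$p_q, 0.1)
  expect_equal(boundary$method, "random")
})

test_that("leave-one-out recomputes the pool without each study", {
  sym <- leave_one_out(make_effects(c(0.4, 0.4, 0.4), c(0.2, 0.2, 0.2)))
  expect_length(sym, 3)
  for (r in sym) expect_equal(r$effect$log_or, 0.4, tolerance = 1e-12)

  out <- leave_one_out(make_effects(c(0.4, 0.45, 3), c(0.2, 0.2, 0.2)))
  i2s <- vapply(out, function(r) r$het$i2, numeric(1))
  expect_equal(unname(which.min(i2s)), 3L)  # dropping the outlier kills heterogeneity
  # each result equals direct recomputation on the reduced set
  direct <- choose_and_pool(make_effects(c(0.4, 0.45), c(0.2, 0.2)))
  expect_equal(out[[3]]$effect$log_or, direct$effect$log_or, tolerance = 1e-12)

  expect_error(leave_one_out(make_effects(c(0.4, 0.4), c(0.2, 0.2))),
               "three studies")
})

test_that("subgroup analysis pools per stratum and tests between-stratum spread", {
  eq <- subgroup_analysis(make_effects(c(0.5, 0.5, 0.5, 0.5), rep(0.2, 4)),
                          c("A", "A", "B", "B"))
  expect_equal(eq$between$q, 0, tolerance = 1e-12)
  expect_equal(eq$between$p, 1, tolerance = 1e-9)

  diff <- subgroup_analysis(make_effects(c(0, 0.02, 1, 0.98), rep(0.05, 4)),
                            c("A", "A", "B", "B"))
  expect_lt(diff$between$p, 0.05)
  # hand oracle on the two pooled points
  ya <- diff$strata$A$effect$log_or; sa <- diff$strata$A$effect$se
  yb <- diff$strata$B$effect$log_or; sb <- diff$strata$B$effect$se
  w <- c(1 / sa^2, 1 / sb^2); ybar <- sum(w * c(ya, yb)) / sum(w)
  expect_equal(diff$between$q, sum(w * (c(ya, yb) - ybar)^2), tolerance = 1e-12)

  singleton <- subgroup_analysis(make_effects(c(0.5, 0.6, 0.3), rep(0.2, 3)),
                                 c("A", "A", "B"))
  expect_true(isTRUE(singleton$strata$B$descriptive_only))
  expect_null(singleton$between)
})

test_that("meta-regression recovers a known moderator shift and rejects degenerate input", {
  expect_error(meta_regression(make_effects(rnorm(5), rep(0.1, 5)),
                               rep("A", 5)), "two observed levels")

  set.seed(23)
  null_fit <- meta_regression(make_effects(rnorm(10, 0.3, 0.02), rep(0.1, 10)),
                              rep(c("A", "B"), 5))
  expect_lt(abs(null_fit$coefficients$estimate[2]), 0.1)

  shift <- rep(c(0, 0.5), each = 10)
  yi <- rnorm(20, 0.2 + shift, 0.1)
  fit <- meta_regression(make_effects(yi, rep(0.1, 20)),
                         rep(c("ctrl", "trt"), each = 10))
  expect_lt(abs(fit$coefficients$estimate[2] - 0.5), 0.15)
  expect_lt(fit$coefficients$p[2], 0.05)
})

test_that("Egger and Begg tests follow the k >= 10 applicability guard", {
  nine <- make_effects(rnorm(9), runif(9, 0.1, 0.3))
  expect_false(egger_test(nine)$applicable)
  expect_false(begg_test(nine)$applicable)
  expect_null(egger_test(nine)$p)
})

test_that("a symmetric funnel yields a near-zero Egger intercept", {
  yi <- c(-0.5, 0.5, -0.3, 0.3, -0.2, 0.2, -0.1, 0.1, -0.05, 0.05)
  sei <- rep(c(0.5, 0.3, 0.2, 0.15, 0.1), each = 2)
  eg <- egger_test(make_effects(yi, sei))
  expect_true(eg$applicable)
  expect_lt(abs(eg$intercept), 1e-8)  # exact mirror symmetry
})

test_that("Begg tau hits +/-1 for perfectly concordant deviate-variance ranks", {
  # effects grow much faster than SE: standardized deviates and variances
  # end up perfectly concordant
  sei <- seq(0.1, 0.4, length.out = 12)
  yi <- exp(6 * sei)
  bg <- begg_test(make_effects(yi, sei))
  expect_equal(bg$tau, 1, tolerance = 1e-9)
  bg_rev <- begg_test(make_effects(-yi, sei))
  expect_equal(bg_rev$tau, -1, tolerance = 1e-9)
  # cross-check the statistic against metafor's rank correlation test
  set.seed(29)
  yr <- rnorm(12); sr <- runif(12, 0.1, 0.4)
  ours <- begg_test(make_effects(yr, sr))
  mf <- metafor::ranktest(x = yr, sei = sr, exact = FALSE)
  expect_equal(ours$tau, unname(mf$tau), tolerance = 1e-9)
  expect_equal(ours$p, mf$pval, tolerance = 1e-9)
})

test_that("95% CIs from the heterogeneity-switched pool cover a true OR of 1.5", {
  nrep <- 500
  covered <- 0
  for (i in seq_len(nrep)) {
    corpus <- simulate_corpus(sim_config(
      k_studies = 10, n_cases = 1000, n_controls = 1000, maf = 0.3,
      true_model = "recessive", true_or = 1.5, tau = 0, seed = 60000 + i))
    pr <- choose_and_pool(study_effects(corpus$studies, "recessive"))
    if (pr$effect$ci_low <= 1.5 && pr$effect$ci_high >= 1.5)
      covered <- covered + 1
  }
  expect_gte(covered / nrep, 0.90)
  expect_lte(covered / nrep, 0.98)
})

test_that("forest-plot export carries weights that sum to 100%", {
  pr <- choose_and_pool(make_effects(c(0.2, 0.4, 0.3), c(0.1, 0.2, 0.15)))
  fd <- forest_data(pr, c("a", "b", "c"))
  expect_equal(nrow(fd), 4)
  expect_equal(sum(fd$weight[1:3]), 100, tolerance = 1e-9)
  expect_equal(fd$or[4], pr$effect$or)
})
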