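test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-100, 0, 50), 200)
  expect_equal(aicc(-100, 5, 100), 210 + 60 / 94)
  for (k in 1:4) expect_gt(aicc(-10, k, 30), -2 * -10 + 2 * k)  # AICc > AIC
  expect_error(aicc(-10, 10, 11), "n_eff")
})

test_that("Akaike weights normalize and shift-invariantly rank evidence", {
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(akaike_weights(c(0, 2) + 1234), w)
  expect_equal(sum(akaike_weights(rnorm(7))), 1)
})

test_that("candidate enumeration matches an independent combinatorial count", {
  only_mand <- generate_candidates(s_optional = character(0),
                                   p_optional = character(0),
                                   time_forms_s = c("cat", "spline3", "spline4"),
                                   time_forms_p = "cat")
  expect_length(only_mand, 3L)   # time-form variants of one structure

  one_opt <- generate_candidates(s_optional = "treatment",
                                 p_optional = character(0),
                                 time_forms_s = "cat", time_forms_p = "cat")
  expect_length(one_opt, 2L)

  # oracle: count subsets of the reduced pool satisfying marginality by
  # direct enumeration over the power set
  s_opt <- c("treatment", "treatment:time", "treatment:mass")
  ok <- 0L
  for (m in 0:3) for (s in utils::combn(3, m, simplify = FALSE)) {
    sub <- s_opt[s]
    need_t <- any(c("treatment:time", "treatment:mass") %in% sub)
    if (!need_t || "treatment" %in% sub) ok <- ok + 1L
  }
  cands <- generate_candidates()   # default pools, 2 x 2 expansions
  expect_length(cands, ok * 2L * 2L)
  labs <- vapply(cands, voleCMR:::spec_label, character(1))
  expect_false(anyDuplicated(labs) > 0)
})

test_that("the term cap is enforced during enumeration", {
  few <- generate_candidates(s_optional = c("treatment", "treatment:time",
                                            "treatment:mass"),
                             p_optional = character(0),
                             time_forms_s = "cat", time_forms_p = "cat",
                             max_terms = 4L)
  # mandatory 3 + at most 1 optional term
  expect_true(all(vapply(few, function(s) length(s$surv_terms) <= 4L,
                         logical(1))))
  expect_length(few, 2L)
})

test_that("ranking screens non-estimable fits and normalizes weights", {
  sim <- simulate_captures(test_scenario(), seed = 41)
  f1 <- fit_cmr(null_spec(), sim$data)
  spec2 <- cmr_spec(surv_terms = "sex", p_terms = character(0),
                    enforce_mandatory = FALSE)
  f2 <- fit_cmr(spec2, sim$data)
  bad <- f1
  bad$boundary <- TRUE
  r <- rank_models(list(f1, f2, bad))
  expect_equal(r$n_screened_out, 1L)
  expect_equal(sum(r$table$weight), 1)
  expect_true(all(diff(r$table$AICc) >= 0))
  expect_equal(r$table$delta[1], 0)
})

test_that("model averaging reproduces a Gaussian mean and degenerate limits", {
  sim <- simulate_captures(test_scenario(), seed = 43)
  fit <- fit_cmr(null_spec(), sim$data)
  r <- rank_models(list(fit))
  avg <- model_average(r, function(beta, f) c(b1 = beta[1]),
                       n_draws = 4000, seed = 1)
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(avg$summary$estimate - unname(fit$beta[1])), 4 * se / sqrt(4000))

  # degenerate covariance: every draw sits at the MLE
  fit0 <- fit
  fit0$vcov <- matrix(0, fit$k, fit$k)
  r0 <- rank_models(list(fit0), screen = FALSE)
  avg0 <- model_average(r0, function(beta, f) c(b1 = beta[1]),
                        n_draws = 200, seed = 1)
  expect_equal(avg0$summary$lwr, avg0$summary$upr)
  expect_equal(avg0$summary$estimate, unname(fit$beta[1]))

  # two identical models split the draws but not the distribution
  r2 <- rank_models(list(fit, fit))
  avg2 <- model_average(r2, function(beta, f) c(b1 = beta[1]),
                        n_draws = 4000, seed = 1)
  expect_equal(avg2$summary$estimate, avg$summary$estimate, tolerance = 0.02)
  expect_equal(nrow(avg2$draws), nrow(avg$draws))
})

test_that("averaging is reproducible under a fixed seed", {
  sim <- simulate_captures(test_scenario(), seed = 47)
  fit <- fit_cmr(null_spec(), sim$data)
  r <- rank_models(list(fit))
  a <- model_average(r, function(beta, f) c(x = plogis(beta[1])),
                     n_draws = 500, seed = 9)
  b <- model_average(r, function(beta, f) c(x = plogis(beta[1])),
                     n_draws = 500, seed = 9)
  expect_identical(a$draws, b$draws)
})

test_that("simulation p-values follow the doubled-tail definition", {
  expect_equal(pvalue_draws(rep(1, 500), 1), 1)
  set.seed(1)
  z <- rnorm(100000)
  expect_equal(pvalue_draws(z, quantile(z, 0.025)), 0.05, tolerance = 0.01)
  expect_equal(pvalue_draws(z, 50), 2 / length(z))  # empty tail -> 2/n floor
  expect_lte(pvalue_draws(z, 0.001), 1)
})

test_that("relative survival is 1 when the arms share parameters", {
  cfg <- test_scenario()
  sim <- simulate_captures(cfg, seed = 51)
  fit <- fit_cmr(null_spec(), sim$data)
  r <- rank_models(list(fit))
  imp <- matrix(25, nrow(sim$data$ch), sim$data$design$n_sessions)
  rs <- relative_survival(r, sim$data, imp, n_draws = 400, seed = 1)
  # no treatment term in the model: the ratio is exactly 1 draw by draw
  expect_true(all(abs(rs$estimate - 1) < 1e-12))
  expect_true(all(rs$p == 1))
})

test_that("survival series honours the location split and the unit interval", {
  d <- rd_design(c("2006-01-01", "2006-03-01", "2006-05-01"), occasions = 3L)
  cfg <- sim_config(design = d, locations = c("A", "B"),
                    n0 = c(treatment = 60, control = 60), recruits = 10)
  sim <- simulate_captures(cfg, seed = 53)
  fit <- fit_cmr(cmr_spec(surv_terms = c("location", "time", "mass"),
                          time_form_s = "cat", time_form_p = "cat"),
                 sim$data, mass = impute_mass(
                   fit_latent_classes(sim$data, 2, n_restarts = 2, seed = 1),
                   sim$data))
  r <- rank_models(list(fit), screen = FALSE)
  imp <- matrix(25, nrow(sim$data$ch), d$n_sessions)
  pooled <- survival_series(r, sim$data, imp, n_draws = 300, seed = 2)
  split <- survival_series(r, sim$data, imp, by_location = TRUE,
                           n_draws = 300, seed = 2)
  expect_equal(nrow(pooled), 2L * 2L)            # interval x arm
  expect_equal(nrow(split), 2L * 2L * 2L)        # x location
  expect_true(all(pooled$estimate > 0 & pooled$estimate < 1))
  expect_true(all(split$lwr <= split$upr))
})

test_that("deterministic ratio of known survivals is recovered", {
  expect_equal(0.9 / 0.75, 1.2)
  # via draws: degenerate distributions at S_T = 0.9, S_C = 0.75
  d <- cbind(i1 = rep(0.9 / 0.75, 200))
  s <- voleCMR:::summarize_draws(d, null = 1)
  expect_equal(s$summary$estimate, 1.2)
  expect_equal(s$summary$p, 2 / 200)   # no draw reaches back to the null
})
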