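test_that("spline basis has the right shape, rank and span", {
  b3 <- spline_basis(1:7, 3)
  b4 <- spline_basis(1:7, 4)
  expect_equal(dim(b3), c(7L, 3L))
  expect_equal(dim(b4), c(7L, 4L))
  expect_true(all(is.finite(b4)))
  expect_equal(qr(b3)$rank, 3L)
  expect_equal(qr(b4)$rank, 4L)
  # a constant lies in span(basis + intercept)
  fit <- lm.fit(cbind(1, b4), rep(2.5, 7))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_error(spline_basis(1:7, 2), "df")
  expect_error(spline_basis(1:3, 4), "distinct")
})

test_that("model structures are validated", {
  expect_error(cmr_spec(surv_terms = c("location", "time")), "mass")
  expect_error(cmr_spec(p_terms = "sex"), "location:time")
  expect_error(cmr_spec(surv_terms = c("location", "time", "mass", "banana")),
               "unknown survival")
  expect_error(
    cmr_spec(surv_terms = c("location", "time", "mass", "treatment:time")),
    "requires")
  expect_error(cmr_spec(time_form_s = "quintic"), "time_form")
  s <- cmr_spec(surv_terms = c("location", "time", "mass", "treatment",
                               "treatment:mass"),
                p_terms = c("location:time", "sex"), time_form_s = "cat")
  expect_s3_class(s, "cmr_spec")
})

test_that("intercept-only design matrices are all-ones columns", {
  ed <- hand_data()
  dm <- build_design(null_spec(), ed,
                     structure(list(mass_hat = matrix(25, 4, 2)),
                               class = "imputed_mass"))
  expect_equal(unname(dm$Xs), matrix(1, 4, 1), ignore_attr = TRUE)
  expect_equal(unname(dm$Xp), matrix(1, 16, 1), ignore_attr = TRUE)
  expect_equal(dm$k, 3L)
})

test_that("the treatment covariate is zero for pre-netting intervals", {
  d <- rd_design(c("2006-01-01", "2006-03-01", "2006-05-01"), occasions = 2L,
                 treatment_start = 2L)
  cfg <- sim_config(design = d, locations = "L1",
                    n0 = c(treatment = 40, control = 40), recruits = 5,
                    s_treatment = 0.5)
  sim <- simulate_captures(cfg, seed = 13)
  m <- fit_latent_classes(sim$data, K = 1, n_restarts = 1, seed = 1)
  imp <- impute_mass(m, sim$data)
  spec <- cmr_spec(surv_terms = c("location", "time", "mass", "treatment",
                                  "treatment:time"),
                   p_terms = "location:time", time_form_s = "cat")
  dm <- build_design(spec, sim$data, imp)
  n <- dm$n
  treated <- sim$data$individuals$treatment == "treatment"
  tcol <- dm$Xs[, "treatment"]
  expect_true(all(tcol[seq_len(n)] == 0))                  # interval 1
  expect_equal(unname(tcol[n + seq_len(n)]), as.numeric(treated))  # interval 2
  # and every interaction column with treatment vanishes in interval 1
  icol <- grep("treatment:", colnames(dm$Xs))
  expect_true(all(dm$Xs[seq_len(n), icol] == 0))
})

test_that("design rows match hand enumeration for a 2-individual case", {
  d <- rd_design(c("2006-01-01", "2006-03-01", "2006-05-01"), occasions = 1L)
  ind <- tibble::tibble(id = c("a", "b"), sex = c("F", "M"),
                        location = c("A", "B"),
                        plot = c("A.treatment", "B.control"),
                        treatment = c("treatment", "control"))
  ch <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L))
  mass <- rbind(c(20, 25, NA), c(30, NA, 35))
  ed <- encounter_data(ind, ch, mass, d)
  imp <- structure(list(mass_hat = rbind(c(20, 25, 27), c(30, 32, 35))),
                   class = "imputed_mass")
  spec <- cmr_spec(surv_terms = c("location", "time", "mass", "treatment"),
                   p_terms = "location:time", time_form_s = "cat",
                   time_form_p = "cat")
  dm <- build_design(spec, ed, imp)
  # survival rows: interval-major (i1k1, i2k1, i1k2, i2k2)
  expect_equal(unname(dm$Xs[, "mass_c"]), c(-0.5, 0.5, 0, 0.7))
  expect_equal(unname(dm$Xs[, "locationB"]), c(0, 1, 0, 1))
  expect_equal(unname(dm$Xs[, "treatment"]), c(0, 0, 1, 0))
  expect_equal(unname(dm$Xs[, "tsf2"]), c(0, 0, 1, 1))
  # capture rows: occasion-major, location x session factor structure
  expect_equal(nrow(dm$Xp), 6L)
  expect_equal(unname(dm$Xp[, "(Intercept)"]), rep(1, 6))
})

test_that("a lone Bernoulli trial contributes -log(0.5) at p = 0.5", {
  d <- rd_design("2006-01-01", occasions = 2L)
  ind <- tibble::tibble(id = "a", sex = "F", location = "A",
                        plot = "A.control", treatment = "control")
  ed <- encounter_data(ind, matrix(c(1L, 0L), 1), matrix(20, 1, 1), d)
  b <- tiny_dm_obs(ed, surv_terms = character(0), p_terms = character(0))
  expect_equal(negloglik(c(0, 0, 0), b$dm, b$obs), -log(0.5))
  # captured on both occasions at p = 0.5: same contribution
  ed2 <- encounter_data(ind, matrix(c(1L, 1L), 1), matrix(20, 1, 1), d)
  b2 <- tiny_dm_obs(ed2, surv_terms = character(0), p_terms = character(0))
  expect_equal(negloglik(c(0, 0, 0), b2$dm, b2$obs), -log(0.5))
})

test_that("the forward recursion equals exhaustive state enumeration", {
  set.seed(42)
  for (rep in 1:12) {
    ed <- random_tiny_data()
    b <- tiny_dm_obs(ed)
    beta <- rnorm(b$dm$k, 0, 0.8)
    expect_equal(negloglik(beta, b$dm, b$obs), brute_nll(beta, b$dm, b$obs),
                 tolerance = 1e-12)
  }
})

test_that("gamma -> 0 reduces to the two-state CJS likelihood", {
  set.seed(99)
  for (rep in 1:8) {
    ed <- random_tiny_data(n_max = 6, t_max = 4)
    b <- tiny_dm_obs(ed)
    beta <- c(rnorm(b$dm$k - 1, 0, 0.8), -30)   # gamma ~ 1e-13
    expect_equal(negloglik(beta, b$dm, b$obs), cjs_nll(beta, b$dm, b$obs),
                 tolerance = 1e-10)
  }
})

test_that("single-session capture model equals a conditional logistic fit", {
  d <- rd_design("2006-01-01", occasions = 5L)
  set.seed(17)
  n <- 300
  sex <- sample(c("F", "M"), n, replace = TRUE)
  p <- plogis(-0.3 + 0.8 * (sex == "M"))
  repeat {
    ch <- matrix(rbinom(n * 5, 1, rep(p, 5)), n)
    if (all(rowSums(ch) > 0)) break
  }
  ind <- tibble::tibble(id = paste0("i", 1:n), sex = sex, location = "A",
                        plot = "A.control", treatment = "control")
  ed <- encounter_data(ind, ch, matrix(25, n, 1), d)
  spec <- cmr_spec(surv_terms = character(0), p_terms = "sex",
                   enforce_mandatory = FALSE)
  fit <- fit_cmr(spec, ed)
  # oracle: logistic regression on the post-first-capture Bernoulli trials
  fo <- apply(ch == 1, 1, which.max)
  y <- x <- NULL
  for (i in 1:n) if (fo[i] < 5) {
    y <- c(y, ch[i, (fo[i] + 1):5])
    x <- c(x, rep(sex[i] == "M", 5 - fo[i]))
  }
  g <- glm(y ~ x, family = binomial())
  bp <- fit$beta[fit$dm$k_s + seq_len(fit$dm$k_p)]
  expect_equal(unname(bp), unname(coef(g)), tolerance = 1e-4)
})

test_that("estimates recover the generating values on simulated data", {
  cfg <- test_scenario()
  sim <- simulate_captures(cfg, seed = 19)
  fit <- fit_cmr(null_spec(), sim$data)
  expect_true(fit$converged)
  s_hat <- plogis(fit$beta[1])
  p_hat <- plogis(fit$beta[fit$dm$k_s + 1])
  se_s <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(qlogis(s_hat) - qlogis(0.8)), 3 * se_s + 0.05)
  expect_equal(unname(p_hat), 0.45, tolerance = 0.1)
})

test_that("a saturated capture pattern is flagged as a boundary fit", {
  d <- rd_design("2006-01-01", occasions = 3L)
  ind <- tibble::tibble(id = paste0("i", 1:20), sex = "F", location = "A",
                        plot = "A.control", treatment = "control")
  ed <- encounter_data(ind, matrix(1L, 20, 3), matrix(25, 20, 1), d)
  fit <- fit_cmr(null_spec(), ed)
  expect_true(fit$boundary)
  p_hat <- plogis(fit$beta[fit$dm$k_s + 1])
  expect_gt(p_hat, 0.999)
})

test_that("a zero covariate column leaves the maximized likelihood unchanged", {
  sim <- simulate_captures(test_scenario(), seed = 23)
  fit0 <- fit_cmr(null_spec(), sim$data)
  # mass term with all-constant imputed mass = a zero column after centering
  imp <- structure(list(mass_hat = matrix(25, nrow(sim$data$ch),
                                          sim$data$design$n_sessions)),
                   class = "imputed_mass")
  spec <- cmr_spec(surv_terms = "mass", p_terms = character(0),
                   enforce_mandatory = FALSE)
  fit1 <- fit_cmr(spec, sim$data, mass = imp)
  expect_equal(fit1$loglik, fit0$loglik, tolerance = 1e-4)
})

test_that("survival scales between interval and monthly rates", {
  d <- rd_design(c("2006-01-01", "2006-03-02"), occasions = 2L)  # 60 days
  cfg <- sim_config(design = d, locations = "L1",
                    n0 = c(treatment = 50, control = 50), recruits = 0)
  sim <- simulate_captures(cfg, seed = 3)
  fit <- fit_cmr(null_spec(), sim$data)
  s_m <- monthly_survival(fit, 1, "L1")
  s_i <- interval_survival(fit, 1, "L1")
  expect_equal(s_i, s_m^2)
  expect_equal(0.64^(30 / 60), 0.8)
  # link monotonicity
  b2 <- fit$beta
  b2[1] <- b2[1] + 1
  expect_gt(monthly_survival(fit, 1, "L1", beta = b2), s_m)
})

test_that("Horvitz-Thompson abundance matches its closed forms", {
  d <- rd_design("2006-01-01", occasions = 1L)
  ind <- tibble::tibble(id = paste0("i", 1:10), sex = "F", location = "A",
                        plot = "A.control", treatment = "control")
  ed <- encounter_data(ind, matrix(1L, 10, 1), matrix(25, 10, 1), d)
  b <- tiny_dm_obs(ed, surv_terms = character(0), p_terms = character(0))
  fit <- structure(list(dm = b$dm, beta = c(0, 0, 0)), class = "cmr_fit")
  expect_equal(population_size(fit, ed, 1), 20)   # p* = 0.5 -> N = 10/0.5
  expect_equal(population_size(fit, ed, 1, beta = c(0, 20, 0)), 10,
               tolerance = 1e-6)                  # census limit p -> 1
})
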