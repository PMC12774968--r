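test_that("a single class reduces to per-sex-session sample means", {
  sim <- simulate_captures(test_scenario(), seed = 2)
  m <- fit_latent_classes(sim$data, K = 1, n_restarts = 1, seed = 1)
  expect_true(all(abs(rowSums(m$posterior) - 1) < 1e-9))
  expect_true(all(m$posterior == 1))
  mass <- sim$data$mass
  sex <- sim$data$individuals$sex
  for (s in c("F", "M")) for (t in seq_len(ncol(mass))) {
    v <- mass[sex == s, t]
    if (any(!is.na(v))) {
      expect_equal(unname(m$means[1, s, t]), mean(v, na.rm = TRUE),
                   tolerance = 1e-8)
    }
  }
})

test_that("well-separated classes are recovered almost perfectly", {
  Tn <- 4L
  mc <- list(pi = c(0.5, 0.5),
             means = array(rep(c(18, 35), 2 * Tn), c(2, 2, Tn),
                           dimnames = list(NULL, c("F", "M"), NULL)),
             sd = 1)
  cfg <- test_scenario(mass_classes = mc)
  sim <- simulate_captures(cfg, seed = 31)
  m <- fit_latent_classes(sim$data, K = 2, n_restarts = 3, seed = 1)
  truth_class <- sim$truth$roster$class[
    match(sim$data$individuals$id, sim$truth$roster$id)]
  fitted_class <- max.col(m$posterior)
  acc <- max(mean(fitted_class == truth_class),
             mean(3L - fitted_class == truth_class))  # label switching
  expect_gte(acc, 0.95)
  expect_true(is.finite(m$bic))
})

test_that("more classes never fit worse than one", {
  sim <- simulate_captures(test_scenario(), seed = 4)
  m1 <- fit_latent_classes(sim$data, K = 1, n_restarts = 1, seed = 1)
  m2 <- fit_latent_classes(sim$data, K = 2, n_restarts = 3, seed = 1)
  expect_gte(m2$loglik, m1$loglik - 1e-6)
})

test_that("BIC weights follow the evidence formula", {
  fake <- function(bic) structure(list(bic = bic), class = "latent_class_model")
  expect_equal(bic_weights(list(fake(10), fake(10))), c(0.5, 0.5))
  expect_equal(bic_weights(list(fake(1)))[1], 1)
  w <- bic_weights(list(fake(100), fake(102)))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(sum(w), 1)
})

test_that("class-probability-weighted means match the hand calculation", {
  d <- rd_design("2006-01-01", occasions = 1L)
  ind <- tibble::tibble(id = c("a", "b", "c"), sex = "F", location = "A",
                        plot = "A.control", treatment = "control")
  ed <- encounter_data(ind, matrix(1L, 3, 1), matrix(c(20, 24, 30), 3, 1), d)
  model <- structure(
    list(K = 2L, pi = c(1 / 3, 2 / 3),
         posterior = cbind(c(0.5, 0.25, 0.25), c(0.5, 0.75, 0.75)),
         individuals = ind$id),
    class = "latent_class_model")
  cm <- class_session_means(model, ed)
  expect_equal(unname(cm[1, "F", 1]), 23.5)   # (10 + 6 + 7.5) / 1
  # equal weights reduce to the unweighted mean
  model$posterior <- matrix(0.5, 3, 2)
  cm <- class_session_means(model, ed)
  expect_equal(unname(cm[1, "F", 1]), mean(c(20, 24, 30)))
  expect_equal(unname(cm[2, "F", 1]), mean(c(20, 24, 30)))
})

test_that("empty sex-session cells are interpolated and flagged", {
  d <- rd_design(c("2006-01-01", "2006-03-01", "2006-05-01"), occasions = 1L)
  ind <- tibble::tibble(id = c("a", "b"), sex = "F", location = "A",
                        plot = "A.control", treatment = "control")
  ch <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L))
  mass <- rbind(c(20, NA, 30), c(22, NA, 32))
  ed <- encounter_data(ind, ch, mass, d)
  model <- structure(list(K = 1L, pi = 1, posterior = matrix(1, 2, 1),
                          individuals = ind$id),
                     class = "latent_class_model")
  cm <- class_session_means(model, ed)
  expect_equal(unname(cm[1, "F", 2]), mean(c(21, 31)))   # linear midpoint
  expect_true(attr(cm, "filled")[1, 1, 2])
  expect_false(attr(cm, "filled")[1, 1, 1])
})

test_that("imputation identities hold exactly", {
  sim <- simulate_captures(test_scenario(), seed = 6)
  m <- fit_latent_classes(sim$data, K = 2, n_restarts = 2, seed = 1)
  imp <- impute_mass(m, sim$data)
  obs <- !is.na(sim$data$mass)
  resid <- (imp$mass_hat - sim$data$mass)[obs]
  per_ind <- rowSums(ifelse(obs, imp$mass_hat - sim$data$mass, 0),
                     na.rm = TRUE) / rowSums(obs)
  expect_true(all(abs(per_ind) < 1e-10))   # mean residual identically zero
  expect_true(all(is.finite(imp$mass_hat)))

  # single capture passes through exactly
  once <- which(rowSums(obs) == 1)
  for (i in utils::head(once, 20)) {
    t <- which(obs[i, ])
    expect_equal(imp$mass_hat[i, t], sim$data$mass[i, t])
  }
})

test_that("an identical duplicate model leaves the averaged imputation unchanged", {
  sim <- simulate_captures(test_scenario(), seed = 8)
  m <- fit_latent_classes(sim$data, K = 2, n_restarts = 2, seed = 1)
  one <- impute_mass(m, sim$data)
  two <- impute_mass(list(m, m), sim$data)
  expect_equal(two$weights, c(0.5, 0.5))
  expect_equal(two$mass_hat, one$mass_hat)
})
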