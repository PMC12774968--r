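#' Fit a latent-class body-mass trajectory model
#'
#' Approximates each individual's body-mass change over the study by a finite
#' Gaussian mixture over sex-by-session mean trajectories: class `g` assigns
#' sex `s` at session `t` the mean `m[g, s, t]` with class-specific residual
#' s.d., and an individual's observed masses at its capture sessions are
#' conditionally independent given its class. Fitted by EM, restarted from
#' random soft assignments, best restart by log-likelihood. Deliverables are
#' the class mean trajectories, the mixing proportions, the posterior
#' membership probabilities `P(c_i = g)`, and BIC
#' (`-2 logL + k log(n_individuals)`).
#'
#' @param data an [encounter_data]; every individual needs at least one
#'   observed mass.
#' @param K number of latent classes (>= 1).
#' @param n_restarts random restarts of EM.
#' @param seed integer seed for the restarts.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below `tol`, or after `max_iter` iterations
#'   (then the best iterate is returned with `converged = FALSE`).
#'
#' @return An object of class `latent_class_model` with elements `K`, `pi`,
#'   `means` (K x 2 x sessions, sexes F/M), `sigma`, `posterior`
#'   (individuals x K), `loglik`, `n_par`, `bic`, `converged`, `n_restarts`,
#'   `seed`.
#' @export
fit_latent_classes <- function(data, K, n_restarts = 5L, seed = 1L,
                               max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(data, "encounter_data"), K >= 1L)
  mass <- data$mass
  n <- nrow(mass)
  Tn <- ncol(mass)
  if (any(rowSums(!is.na(mass)) < 1L)) {
    stop("every individual must have at least one observed mass")
  }
  sex_idx <- match(data$individuals$sex, c("F", "M"))
  obs <- !is.na(mass)
  # cells (sex, session) with any observation: class means defined there
  cell_obs <- vapply(1:2, function(s)
    colSums(obs[sex_idx == s, , drop = FALSE]) > 0L, logical(Tn))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  m_step <- function(post) {
    pi_g <- colMeans(post)
    means <- array(NA_real_, c(K, 2L, Tn), dimnames = list(NULL, c("F", "M"), NULL))
    sigma <- numeric(K)
    for (g in seq_len(K)) {
      w <- post[, g]
      for (s in 1:2) {
        rows <- sex_idx == s
        wm <- colSums(w[rows] * ifelse(obs[rows, , drop = FALSE],
                                       mass[rows, , drop = FALSE], 0), na.rm = TRUE)
        ww <- colSums(w[rows] * obs[rows, , drop = FALSE])
        mg <- wm / ww
        # cells with no effective weight fall back to the pooled sex-session mean
        pooled <- colSums(ifelse(obs[rows, , drop = FALSE],
                                 mass[rows, , drop = FALSE], 0), na.rm = TRUE) /
          pmax(colSums(obs[rows, , drop = FALSE]), 1)
        bad <- !is.finite(mg)
        mg[bad] <- pooled[bad]
        mg[!cell_obs[, s]] <- NA_real_
        means[g, s, ] <- mg
      }
      resid2 <- (mass - means[g, , ][cbind(rep(sex_idx, Tn),
                                           rep(seq_len(Tn), each = n))])^2
      num <- sum(w * rowSums(ifelse(obs, resid2, 0), na.rm = TRUE))
      den <- sum(w * rowSums(obs))
      sigma[g] <- max(sqrt(num / den), 1e-3)
    }
    list(pi = pi_g, means = means, sigma = sigma)
  }

  e_step <- function(par) {
    logf <- matrix(0, n, K)
    for (g in seq_len(K)) {
      mu <- par$means[g, , ][cbind(rep(sex_idx, Tn), rep(seq_len(Tn), each = n))]
      ll <- stats::dnorm(mass, matrix(mu, n, Tn), par$sigma[g], log = TRUE)
      logf[, g] <- rowSums(ifelse(obs, ll, 0), na.rm = TRUE) +
        log(pmax(par$pi[g], 1e-300))
    }
    mx <- apply(logf, 1L, max)
    lse <- mx + log(rowSums(exp(logf - mx)))
    list(post = exp(logf - lse), loglik = sum(lse))
  }

  # pooled sex-session means used to build start values
  pooled_means <- vapply(1:2, function(s) {
    rows <- sex_idx == s
    colSums(ifelse(obs[rows, , drop = FALSE],
                   mass[rows, , drop = FALSE], 0), na.rm = TRUE) /
      pmax(colSums(obs[rows, , drop = FALSE]), 1)
  }, numeric(Tn))
  ind_mean <- rowSums(ifelse(obs, mass, 0), na.rm = TRUE) / rowSums(obs)
  grand_sd <- stats::sd(mass[obs])

  best <- NULL
  for (r in seq_len(n_restarts)) {
    # seed each class's trajectory from a randomly chosen individual: the
    # pooled sex-session curve shifted to that individual's mean level
    for (attempt in 1:5) {
      seeds <- sample.int(n, K)
      par <- list(pi = rep(1 / K, K),
                  means = array(NA_real_, c(K, 2L, Tn),
                                dimnames = list(NULL, c("F", "M"), NULL)),
                  sigma = rep(max(grand_sd, 1e-2), K))
      for (g in seq_len(K)) {
        shift <- ind_mean[seeds[g]] - mean(ind_mean)
        par$means[g, 1L, ] <- pooled_means[, 1L] + shift
        par$means[g, 2L, ] <- pooled_means[, 2L] + shift
      }
      post <- e_step(par)$post
      ll_prev <- -Inf
      converged <- FALSE
      collapsed <- FALSE
      for (it in seq_len(max_iter)) {
        par <- m_step(post)
        if (any(par$pi < 1e-8)) { collapsed <- TRUE; break }
        es <- e_step(par)
        post <- es$post
        if (is.finite(ll_prev) &&
            abs(es$loglik - ll_prev) < tol * (abs(ll_prev) + 1)) {
          converged <- TRUE; ll_prev <- es$loglik; break
        }
        ll_prev <- es$loglik
      }
      if (!collapsed) break
    }
    if (collapsed) next
    if (is.null(best) || ll_prev > best$loglik) {
      best <- list(par = par, post = post, loglik = ll_prev, converged = converged)
    }
  }
  if (is.null(best)) stop("all EM restarts collapsed to an empty class")

  n_par <- (K - 1L) + K * sum(cell_obs) + K
  structure(
    list(K = K, pi = best$par$pi, means = best$par$means,
         sigma = best$par$sigma, posterior = best$post,
         individuals = data$individuals$id,
         loglik = best$loglik, n_par = n_par,
         bic = -2 * best$loglik + n_par * log(n),
         converged = best$converged, n_restarts = n_restarts, seed = seed),
    class = "latent_class_model"
  )
}

#' @export
print.latent_class_model <- function(x, ...) {
  cat("Latent-class mass model: K =", x$K,
      "| logLik =", format(x$loglik), "| BIC =", format(x$bic),
      if (!x$converged) "| NOT converged" else "", "\n")
  cat("  mixing proportions:", paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.latent_class_model <- function(x, ...) {
  Tn <- dim(x$means)[3]
  tidyr::expand_grid(class = seq_len(x$K), sex = c("F", "M"),
                     session = seq_len(Tn)) |>
    dplyr::mutate(mean_mass = x$means[cbind(class, match(sex, c("F", "M")),
                                            session)],
                  sigma = x$sigma[class], pi = x$pi[class])
}

#' @export
#' @importFrom generics glance
glance.latent_class_model <- function(x, ...) {
  tibble::tibble(K = x$K, logLik = x$loglik, n_par = x$n_par, bic = x$bic,
                 converged = x$converged)
}

#' BIC evidence weights for a set of latent-class models
#'
#' `w_m = exp(-dBIC_m / 2) / sum(exp(-dBIC / 2))`.
#'
#' @param models list of `latent_class_model` objects fitted to the same data.
#' @return Numeric weights summing to 1.
#' @export
bic_weights <- function(models) {
  if (inherits(models, "latent_class_model")) models <- list(models)
  stopifnot(length(models) >= 1L)
  bic <- vapply(models, function(m) m$bic, numeric(1))
  d <- bic - min(bic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Probability-weighted class mean masses per sex and session
#'
#' For class `g`, sex `s`, session `t`, the mean of observed masses of
#' individuals of sex `s` captured at `t`, each weighted by its posterior
#' membership probability `P(c_i = g)`. Cells where no individual of that sex
#' was captured are filled by linear interpolation across sessions within
#' `(g, s)` (nearest value beyond the ends) and flagged in the `filled`
#' attribute.
#'
#' @param model a `latent_class_model`.
#' @param data the [encounter_data] it was fitted to.
#' @return Array K x 2 x sessions with attribute `filled` (same shape,
#'   logical).
#' @export
class_session_means <- function(model, data) {
  stopifnot(inherits(model, "latent_class_model"),
            identical(model$individuals, data$individuals$id))
  mass <- data$mass
  n <- nrow(mass)
  Tn <- ncol(mass)
  K <- model$K
  sex_idx <- match(data$individuals$sex, c("F", "M"))
  obs <- !is.na(mass)
  out <- array(NA_real_, c(K, 2L, Tn), dimnames = list(NULL, c("F", "M"), NULL))
  for (g in seq_len(K)) {
    w <- model$posterior[, g]
    for (s in 1:2) {
      rows <- sex_idx == s
      num <- colSums(w[rows] * ifelse(obs[rows, , drop = FALSE],
                                      mass[rows, , drop = FALSE], 0), na.rm = TRUE)
      den <- colSums(w[rows] * obs[rows, , drop = FALSE])
      out[g, s, ] <- ifelse(den > 0, num / den, NA_real_)
    }
  }
  filled <- is.na(out)
  for (g in seq_len(K)) for (s in 1:2) {
    v <- out[g, s, ]
    if (anyNA(v) && !all(is.na(v))) {   # a sex absent from the data stays NA
      out[g, s, ] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                                   xout = seq_len(Tn), rule = 2)$y
    }
  }
  attr(out, "filled") <- filled
  out
}

#' Impute a complete body-mass covariate
#'
#' Builds `m_hat[i, t]` for every individual and session: the posterior-
#' weighted average of the class mean trajectories for the individual's sex
#' (BIC-averaged over models), shifted by the individual's mean deviation of
#' observed mass from that baseline over its capture sessions. The shift makes
#' the mean residual at captured sessions exactly zero, and an individual
#' captured once is recovered exactly at that session.
#'
#' @param models a `latent_class_model` or list of them (same data).
#' @param data the [encounter_data].
#' @param weights BIC weights; computed by [bic_weights] when `NULL`.
#' @return Object of class `imputed_mass`: list with `mass_hat` (matrix
#'   individuals x sessions), `base` (the pre-shift baseline), `offset`, and
#'   the model `weights`.
#' @export
impute_mass <- function(models, data, weights = NULL) {
  if (inherits(models, "latent_class_model")) models <- list(models)
  if (is.null(weights)) weights <- bic_weights(models)
  stopifnot(abs(sum(weights) - 1) < 1e-8, length(weights) == length(models))
  mass <- data$mass
  n <- nrow(mass)
  Tn <- ncol(mass)
  sex_idx <- match(data$individuals$sex, c("F", "M"))
  base <- matrix(0, n, Tn)
  for (m in seq_along(models)) {
    mod <- models[[m]]
    cm <- class_session_means(mod, data)
    bm <- matrix(0, n, Tn)
    for (g in seq_len(mod$K)) {
      bm <- bm + mod$posterior[, g] *
        matrix(cm[g, , ][cbind(rep(sex_idx, Tn), rep(seq_len(Tn), each = n))],
               n, Tn)
    }
    base <- base + weights[m] * bm
  }
  obs <- !is.na(mass)
  offset <- rowSums(ifelse(obs, mass - base, 0), na.rm = TRUE) / rowSums(obs)
  mass_hat <- base + offset
  dimnames(mass_hat) <- dimnames(mass)
  structure(list(mass_hat = mass_hat, base = base, offset = offset,
                 weights = weights),
            class = "imputed_mass")
}

#' @export
print.imputed_mass <- function(x, ...) {
  cat("Imputed mass:", nrow(x$mass_hat), "individuals x",
      ncol(x$mass_hat), "sessions\n")
  invisible(x)
}

#' @export
tidy.imputed_mass <- function(x, ...) {
  tibble::as_tibble(x$mass_hat, rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "session_label",
                        values_to = "mass_hat") |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(session = dplyr::row_number()) |>
    dplyr::ungroup()
}
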