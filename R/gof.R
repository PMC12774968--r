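# simulate one replicate of every individual's post-first-capture history
# from fitted real-scale parameters, holding each first capture fixed at its
# observed session and occasion (the support of the conditional likelihood)
simulate_histories <- function(real, dm, obs) {
  n <- dm$n
  Tn <- dm$Tn
  O <- dm$O
  osess <- occ_session(dm$design)
  ch <- matrix(0L, n, O)
  ch[cbind(seq_len(n), obs$first_occ)] <- 1L

  alive <- avail <- rep(TRUE, n)   # state at the first-capture session
  for (t in seq_len(Tn)) {
    cur <- obs$fi <= t
    if (!any(cur)) next
    if (t > 1L) {
      trans <- obs$fi < t
      phi <- real$S[, t - 1L] ^ dm$Lpow[t - 1L]
      alive[trans] <- alive[trans] &
        (stats::runif(sum(trans)) < phi[trans])
      avail[trans] <- stats::runif(sum(trans)) < (1 - real$gamma)
    }
    occ <- which(osess == t)
    for (o in occ) {
      atrisk <- cur & alive & avail & (o > obs$first_occ)
      ch[atrisk, o] <- as.integer(stats::runif(sum(atrisk)) < real$p[atrisk, o])
    }
  }
  ch
}

#' Parametric-bootstrap goodness of fit and overdispersion
#'
#' Simulates capture histories for each individual in the original sample
#' from the fitted model's real-scale parameters (each first capture held at
#' its observed position), refits the same model structure to every
#' replicate, and records the deviance (-2 x maximized log conditional
#' likelihood; no saturated-model correction). The goodness-of-fit p-value is
#' the proportion of bootstrap deviances at or above the observed deviance;
#' the overdispersion factor is `c_hat = observed deviance / mean(bootstrap
#' deviances)`.
#'
#' @param fit a converged `cmr_fit`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return Object of class `gof_result`: `deviance_obs`, `deviance_boot`,
#'   `p`, `c_hat`, `n_boot`, `n_failed`, `unreliable` (more than 20% of
#'   refits failed), `seed`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 100L, seed = 1L) {
  stopifnot(inherits(fit, "cmr_fit"))
  if (!fit$converged) stop("the fitted model did not converge")
  dm <- fit$dm
  real <- real_params(fit$beta, dm)
  dev_obs <- -2 * fit$loglik

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  dev_boot <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    ch_b <- simulate_histories(real, dm, fit$obs)
    obs_b <- obs_stats(ch_b, dm$design)
    ref <- tryCatch(
      fit_cmr_dm(dm, obs_b, n_eff = fit$n_eff, start = fit$beta,
                 hessian = FALSE),
      error = function(e) NULL)
    if (is.null(ref) || !ref$converged) {
      n_failed <- n_failed + 1L
    } else {
      dev_boot <- c(dev_boot, -2 * ref$loglik)
    }
  }
  if (!length(dev_boot)) stop("every bootstrap refit failed")
  structure(
    list(deviance_obs = dev_obs, deviance_boot = dev_boot,
         p = mean(dev_boot >= dev_obs),
         c_hat = dev_obs / mean(dev_boot),
         n_boot = n_boot, n_failed = n_failed,
         unreliable = n_failed > 0.2 * n_boot, seed = seed),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Parametric-bootstrap GOF:", length(x$deviance_boot), "replicates",
      if (x$n_failed) paste0("(", x$n_failed, " failed)"), "\n")
  cat("  deviance", format(x$deviance_obs), "| p =", format(x$p),
      "| c-hat =", format(round(x$c_hat, 3)),
      if (x$unreliable) "| UNRELIABLE" else "", "\n")
  invisible(x)
}

#' @export
glance.gof_result <- function(x, ...) {
  tibble::tibble(deviance = x$deviance_obs, p = x$p, c_hat = x$c_hat,
                 n_boot = x$n_boot, n_failed = x$n_failed,
                 unreliable = x$unreliable)
}
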