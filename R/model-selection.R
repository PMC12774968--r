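#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n_eff - k - 1)`. The effective
#' sample size defaults to the number of individuals elsewhere in the
#' package, since the conditional likelihood treats individuals as the
#' exchangeable unit.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n_eff effective sample size; must exceed `k + 1`.
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, k, n_eff) {
  if (n_eff <= k + 1) stop("n_eff must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_eff - k - 1)
}

#' Akaike evidence weights
#'
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` with
#' `delta_m = AICc_m - min(AICc)`; invariant to adding a constant.
#'
#' @param aicc_values numeric vector of AICc values (at least one finite).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(any(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Enumerate candidate model structures
#'
#' All subsets of the optional term pools on top of the mandatory terms,
#' respecting interaction marginality (an interaction enters only with its
#' main effects / lower-order interactions), expanded over the requested
#' time forms, capped at `max_terms` listed terms per component, in a
#' deterministic order.
#'
#' The default pools give a desk-scale candidate set (treatment main effect
#' and its time and mass interactions for S; sex for p; categorical and
#' 3-df-spline time) of 20 models. `reduced = FALSE` opens the full term
#' pools and all four time forms.
#'
#' @param s_optional,p_optional optional term pools (see [cmr_spec]).
#' @param time_forms_s,time_forms_p time forms to expand over.
#' @param max_terms per-component cap on listed terms.
#' @return List of [cmr_spec] objects.
#' @export
generate_candidates <- function(s_optional = c("treatment", "treatment:time",
                                               "treatment:mass"),
                                p_optional = "sex",
                                time_forms_s = c("cat", "spline3"),
                                time_forms_p = "spline3",
                                max_terms = 11L) {
  mandatory_s <- c("location", "time", "mass")
  mandatory_p <- "location:time"
  subsets_ok <- function(pool, mandatory, requires) {
    if (!length(pool)) return(list(character(0)))
    idx <- unlist(lapply(0:length(pool), function(m)
      utils::combn(seq_along(pool), m, simplify = FALSE)), recursive = FALSE)
    subs <- lapply(idx, function(i) pool[i])
    keep <- vapply(subs, function(s) {
      all_terms <- c(mandatory, s)
      for (tm in intersect(all_terms, names(requires))) {
        if (!all(requires[[tm]] %in% all_terms)) return(FALSE)
      }
      length(all_terms) <= max_terms
    }, logical(1))
    subs[keep]
  }
  s_subs <- subsets_ok(s_optional, mandatory_s, s_requires)
  p_subs <- subsets_ok(p_optional, mandatory_p, p_requires)
  out <- list()
  for (fs in time_forms_s) for (fp in time_forms_p) {
    for (ss in s_subs) for (ps in p_subs) {
      out[[length(out) + 1L]] <- cmr_spec(
        surv_terms = c(mandatory_s, ss), p_terms = c(mandatory_p, ps),
        time_form_s = fs, time_form_p = fp, max_terms = max_terms)
    }
  }
  out
}

#' @rdname generate_candidates
#' @param reduced use the desk-scale pools (default) or the full ones.
#' @export
default_candidates <- function(reduced = TRUE) {
  if (reduced) return(generate_candidates())
  generate_candidates(
    s_optional = c("treatment", "cohort", "sex", "location:treatment",
                   "location:time", "treatment:time", "treatment:mass",
                   "time:mass"),
    p_optional = c("location", "sex", "location:day", "location:time:day"),
    time_forms_s = c("cat", "cat_r", "spline3", "spline4"),
    time_forms_p = c("cat", "spline3", "spline4"))
}

#' Rank fitted models by AICc
#'
#' Applies the estimability screen (non-converged or boundary fits are set
#' aside before ranking), computes delta-AICc and Akaike weights over the
#' screened set, and marks the retained subset (`weight > retain`) used for
#' model averaging.
#'
#' @param fits list of `cmr_fit` objects on the same data.
#' @param retain retention threshold on the Akaike weight.
#' @param screen drop non-estimable (boundary / non-converged) fits before
#'   ranking.
#' @return Object of class `ranked_models` with a selection `table` (tibble)
#'   and the screened `fits`, sorted by AICc.
#' @export
rank_models <- function(fits, retain = 0.001, screen = TRUE) {
  stopifnot(length(fits) >= 1L)
  ok <- vapply(fits, function(f) !screen || (f$converged && !f$boundary),
               logical(1))
  if (!any(ok)) {
    warning("all models failed the estimability screen; ranking unscreened")
    ok <- rep(TRUE, length(fits))
  }
  kept <- fits[ok]
  a <- vapply(kept, function(f) f$aicc, numeric(1))
  ord <- order(a)
  kept <- kept[ord]
  a <- a[ord]
  w <- akaike_weights(a)
  table <- tibble::tibble(
    model = vapply(kept, function(f) spec_label(f$spec), character(1)),
    k = vapply(kept, function(f) f$k, numeric(1)),
    logLik = vapply(kept, function(f) f$loglik, numeric(1)),
    AICc = a, delta = a - min(a), weight = w,
    cum_weight = cumsum(w), retained = w > retain)
  structure(list(table = table, fits = kept, retain = retain,
                 n_screened_out = sum(!ok)),
            class = "ranked_models")
}

#' @export
print.ranked_models <- function(x, ...) {
  cat("Model selection (", nrow(x$table), " models, ",
      x$n_screened_out, " screened out):\n", sep = "")
  print(x$table, n = 10)
  invisible(x)
}

#' @export
tidy.ranked_models <- function(x, ...) x$table

#' Simulation-based multimodel averaging of a derived quantity
#'
#' Draws coefficient vectors from each retained model's Gaussian sampling
#' distribution `N(beta_hat, vcov)`, with the number of replicates per model
#' proportional to its Akaike weight, evaluates the derived quantity on every
#' draw, and pools. Point estimate is the draw mean; the interval the
#' 2.5/97.5 percentiles; the p-value (when `null` is given) twice the
#' proportion of draws at least as far from the draw mean as the null, on the
#' null's side.
#'
#' @param ranked a [rank_models] result.
#' @param quantity `function(beta, fit)` returning a (named) numeric vector.
#' @param n_draws total pooled draws.
#' @param seed integer seed.
#' @param null null value(s) for p-value calculation, or `NULL`.
#' @param prepare optional `function(fit)` returning a `function(beta)`; when
#'   given it replaces `quantity` and lets per-model constants (design rows,
#'   masks) be built once instead of once per draw.
#' @return Object of class `averaged_prediction`: pooled `draws` matrix and a
#'   summary tibble (`estimate`, `lwr`, `upr`, `p`).
#' @export
model_average <- function(ranked, quantity, n_draws = 10000L, seed = 1L,
                          null = NULL, prepare = NULL) {
  stopifnot(inherits(ranked, "ranked_models"))
  sel <- ranked$table$retained
  fits <- ranked$fits[sel]
  w <- ranked$table$weight[sel]
  if (!length(fits)) stop("no retained models to average over")

  usable <- vapply(fits, function(f) !anyNA(f$vcov), logical(1))
  if (!all(usable)) {
    warning(sum(!usable), " model(s) with singular covariance skipped")
    fits <- fits[usable]
    w <- w[usable]
    if (!length(fits)) stop("no model with a valid covariance to draw from")
  }
  w <- w / sum(w)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  draws <- NULL
  for (m in seq_along(fits)) {
    nm <- round(w[m] * n_draws)
    if (nm < 1L) next
    f <- fits[[m]]
    V <- (f$vcov + t(f$vcov)) / 2
    k <- length(f$beta)
    R <- if (max(abs(V)) < 1e-12) NULL else
      tryCatch(chol(V), error = function(e)
        tryCatch(chol(V + diag(1e-8, k)), error = function(e2) NULL))
    B <- if (is.null(R)) {
      # degenerate covariance: all draws at the MLE
      matrix(f$beta, nm, k, byrow = TRUE)
    } else {
      matrix(stats::rnorm(nm * k), nm, k) %*% R +
        matrix(f$beta, nm, k, byrow = TRUE)
    }
    qf <- if (is.null(prepare)) function(b) quantity(b, f) else prepare(f)
    q <- apply(B, 1L, qf)
    q <- if (is.matrix(q)) t(q) else
      if (nm == 1L) matrix(q, nrow = 1L) else matrix(q, ncol = 1L)
    draws <- rbind(draws, q)
  }
  summarize_draws(draws, null)
}

summarize_draws <- function(draws, null = NULL) {
  est <- unname(colMeans(draws))
  ci <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  pv <- if (is.null(null)) rep(NA_real_, ncol(draws)) else {
    null <- rep_len(null, ncol(draws))
    vapply(seq_len(ncol(draws)), function(j)
      pvalue_draws(draws[, j], null[j]), numeric(1))
  }
  nm <- colnames(draws) %||% paste0("q", seq_len(ncol(draws)))
  structure(
    list(draws = draws,
         summary = tibble::tibble(quantity = nm, estimate = est,
                                  lwr = ci[1, ], upr = ci[2, ], p = pv)),
    class = "averaged_prediction")
}

#' @export
print.averaged_prediction <- function(x, ...) {
  cat("Model-averaged prediction (", nrow(x$draws), " pooled draws):\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.averaged_prediction <- function(x, ...) x$summary

#' Simulation p-value against a null value
#'
#' Twice the proportion of draws lying on the null's side of the draw mean at
#' a distance from the mean at least `|mean - null|`, capped at 1. With no
#' draw in the tail the resolution bound `2 / n` is returned, so p stays in
#' (0, 1].
#'
#' @param draws numeric vector (>= 100 draws recommended).
#' @param null null value.
#' @return Scalar p-value.
#' @export
pvalue_draws <- function(draws, null) {
  m <- mean(draws)
  d <- abs(m - null)
  n <- length(draws)
  tail_n <- if (null <= m) sum(draws <= m - d) else sum(draws >= m + d)
  max(min(1, 2 * tail_n / n), 2 / n)
}

# covariate profile at a prediction point: mean imputed mass and sex ratio of
# the individuals captured at the given session (optionally within plots)
profile_at <- function(data, imp, session, plots = NULL) {
  sc <- session_captures(data$ch, data$design)
  sel <- sc[, session] > 0L
  if (!is.null(plots)) sel <- sel & data$individuals$plot %in% plots
  if (!any(sel)) sel <- sc[, session] > 0L
  mh <- if (inherits(imp, "imputed_mass")) imp$mass_hat else imp
  list(mass = mean(mh[sel, session]),
       frac_m = mean(data$individuals$sex[sel] == "M"))
}

# expected monthly survival at the profile of a prediction point, mixing the
# sexes by the observed sex ratio
survival_at_profile <- function(beta, fit, interval, location, treatment,
                                prof) {
  sf <- monthly_survival(fit, interval, location, treatment, prof$mass, "F",
                         beta)
  sm <- monthly_survival(fit, interval, location, treatment, prof$mass, "M",
                         beta)
  (1 - prof$frac_m) * sf + prof$frac_m * sm
}

# prepared-quantity builder for survival prediction points: expands each
# grid row over its locations and both sexes, builds the design rows once
# per model, and aggregates plogis(X beta_S) with location/sex-ratio weights
survival_prepare <- function(grid, profs) {
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    locs <- unlist(grid$location[r])
    tidyr::expand_grid(.r = r, location = locs, sex = c("F", "M")) |>
      dplyr::mutate(
        interval = grid$interval[r], treatment = grid$treatment[r],
        mass = profs[[r]]$mass,
        w = ifelse(sex == "M", profs[[r]]$frac_m, 1 - profs[[r]]$frac_m) /
          length(locs))
  })
  function(fit) {
    X <- survival_rows(fit$dm, rows)
    A <- matrix(0, nrow(grid), nrow(rows))
    A[cbind(rows$.r, seq_len(nrow(rows)))] <- rows$w
    ks <- fit$dm$k_s
    function(beta) drop(A %*% stats::plogis(drop(X %*% beta[seq_len(ks)])))
  }
}

#' Model-averaged monthly survival per interval and treatment group
#'
#' For every interval and treatment role (optionally per location), the
#' model-averaged monthly apparent survival at the profile of that prediction
#' point: the mean imputed body mass and sex ratio of the individuals
#' captured at the interval's origin session in the relevant plots.
#'
#' @param ranked a [rank_models] result.
#' @param data the [encounter_data].
#' @param imp the [impute_mass] result used for fitting.
#' @param by_location keep locations separate (default averages over them).
#' @param n_draws,seed passed to [model_average].
#' @return Tibble: interval, treatment (, location), estimate, lwr, upr.
#' @export
survival_series <- function(ranked, data, imp, by_location = FALSE,
                            n_draws = 4000L, seed = 1L) {
  design <- data$design
  locs <- sort(unique(data$individuals$location))
  grid <- tidyr::expand_grid(
    interval = seq_len(design$n_sessions - 1L),
    treatment = c("treatment", "control"),
    location = if (by_location) locs else list(locs)) |>
    dplyr::mutate(label = paste0("i", .data$interval, ".", .data$treatment,
                                 if (by_location) paste0(".", .data$location)
                                 else ""))
  profs <- lapply(seq_len(nrow(grid)), function(r) {
    plots <- paste(unlist(grid$location[r]), grid$treatment[r], sep = ".")
    profile_at(data, imp, grid$interval[r], plots)
  })
  avg <- model_average(ranked, NULL, n_draws = n_draws, seed = seed,
                       prepare = survival_prepare(grid, profs))
  colnames(avg$draws) <- grid$label
  avg$summary$quantity <- grid$label
  out <- dplyr::bind_cols(grid[setdiff(names(grid), c("label", "location"))],
                          avg$summary[c("estimate", "lwr", "upr")])
  if (by_location) out$location <- grid$location
  attr(out, "draws") <- avg$draws
  out
}

#' Model-averaged relative survival (treatment / control)
#'
#' The ratio of treatment to control monthly survival per interval, computed
#' draw-by-draw from the pooled model-averaging sample so the interval and
#' p-value (against the null ratio 1) propagate all model and parameter
#' uncertainty. Survival in each arm is the mean over locations at the
#' prediction point's own covariate profile.
#'
#' @inheritParams survival_series
#' @return Tibble: interval, estimate, lwr, upr, p (null ratio = 1).
#' @export
relative_survival <- function(ranked, data, imp, n_draws = 4000L, seed = 1L) {
  design <- data$design
  locs <- sort(unique(data$individuals$location))
  n_int <- design$n_sessions - 1L
  profs_t <- lapply(seq_len(n_int), function(k)
    profile_at(data, imp, k, paste(locs, "treatment", sep = ".")))
  profs_c <- lapply(seq_len(n_int), function(k)
    profile_at(data, imp, k, paste(locs, "control", sep = ".")))
  grid_t <- tibble::tibble(interval = seq_len(n_int), treatment = "treatment",
                           location = rep(list(locs), n_int))
  grid_c <- tibble::tibble(interval = seq_len(n_int), treatment = "control",
                           location = rep(list(locs), n_int))
  prep_t <- survival_prepare(grid_t, profs_t)
  prep_c <- survival_prepare(grid_c, profs_c)
  prepare <- function(fit) {
    ft <- prep_t(fit)
    fc <- prep_c(fit)
    function(beta) {
      sc <- fc(beta)
      ifelse(sc > 0, ft(beta) / sc, NA_real_)
    }
  }
  avg <- model_average(ranked, NULL, n_draws = n_draws, seed = seed, null = 1,
                       prepare = prepare)
  colnames(avg$draws) <- paste0("i", seq_len(n_int))
  avg$summary$quantity <- paste0("i", seq_len(n_int))
  out <- tibble::tibble(interval = seq_len(n_int)) |>
    dplyr::bind_cols(avg$summary[c("estimate", "lwr", "upr", "p")])
  attr(out, "draws") <- avg$draws
  out
}

#' Model-averaged population size per session and plot
#'
#' Horvitz-Thompson abundance (see [population_size]) evaluated on every
#' model-averaging draw, pooled into estimates, intervals, and
#' treatment-minus-control differences per location.
#'
#' @inheritParams survival_series
#' @return List of tibbles: `abundance` (session, plot, estimate, lwr, upr,
#'   n_caught) and `difference` (session, location, estimate, lwr, upr).
#' @export
abundance_series <- function(ranked, data, n_draws = 4000L, seed = 1L) {
  design <- data$design
  plots <- sort(unique(data$individuals$plot))
  grid <- tidyr::expand_grid(session = seq_len(design$n_sessions),
                             plot = plots)
  sc <- session_captures(data$ch, design)
  grid$n_caught <- vapply(seq_len(nrow(grid)), function(r)
    sum(sc[data$individuals$plot == grid$plot[r], grid$session[r]] > 0L),
    numeric(1))
  # prepared quantity: one p-matrix per draw, then Horvitz-Thompson sums
  # over the caught-in-session-and-plot masks
  prepare <- function(fit) {
    dm <- fit$dm
    masks <- lapply(seq_len(nrow(grid)), function(r)
      which(sc[, grid$session[r]] > 0L &
              data$individuals$plot == grid$plot[r]))
    ks <- dm$k_s
    kp <- dm$k_p
    function(beta) {
      p <- stats::plogis(matrix(drop(dm$Xp %*% beta[ks + seq_len(kp)]),
                                dm$n, dm$O))
      pstar <- -expm1(log1p(-p) %*% dm$sagg)
      vapply(seq_len(nrow(grid)), function(r) {
        m <- masks[[r]]
        if (!length(m)) return(0)
        sum(1 / pstar[m, grid$session[r]])
      }, numeric(1))
    }
  }
  avg <- model_average(ranked, NULL, n_draws = n_draws, seed = seed,
                       prepare = prepare)
  colnames(avg$draws) <- paste0("s", grid$session, ".", grid$plot)
  avg$summary$quantity <- colnames(avg$draws)
  abundance <- dplyr::bind_cols(grid,
                                avg$summary[c("estimate", "lwr", "upr")])

  # treatment - control per location, draw-wise
  locs <- sort(unique(data$individuals$location))
  dgrid <- tidyr::expand_grid(session = seq_len(design$n_sessions),
                              location = locs)
  dcols <- lapply(seq_len(nrow(dgrid)), function(r) {
    it <- which(grid$session == dgrid$session[r] &
                  grid$plot == paste(dgrid$location[r], "treatment", sep = "."))
    ic <- which(grid$session == dgrid$session[r] &
                  grid$plot == paste(dgrid$location[r], "control", sep = "."))
    avg$draws[, it] - avg$draws[, ic]
  })
  dmat <- do.call(cbind, dcols)
  difference <- dplyr::bind_cols(
    dgrid,
    tibble::tibble(estimate = colMeans(dmat),
                   lwr = apply(dmat, 2, stats::quantile, 0.025, names = FALSE),
                   upr = apply(dmat, 2, stats::quantile, 0.975, names = FALSE)))
  list(abundance = abundance, difference = difference)
}
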