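#' B-spline basis for a smooth time effect
#'
#' Cubic B-spline basis over primary-session (or interval) index with 3 or 4
#' degrees of freedom, interior knots at quantiles, no intercept column (the
#' model supplies the intercept).
#'
#' @param x numeric vector of session/interval indices to evaluate at.
#' @param df 3 or 4.
#' @return Matrix `length(x)` x `df`.
#' @export
spline_basis <- function(x, df) {
  if (!df %in% c(3L, 4L)) stop("df must be 3 or 4")
  if (length(unique(x)) < df + 1L) stop("need at least df + 1 distinct points")
  b <- splines::bs(x, df = df, degree = 3L, intercept = FALSE)
  unname(b[, , drop = FALSE])
}

s_pool <- c("location", "treatment", "time", "mass", "cohort", "sex",
            "location:treatment", "location:time", "treatment:time",
            "treatment:mass", "time:mass")
p_pool <- c("location", "sex", "location:time", "location:day",
            "location:time:day")
s_requires <- list(
  "location:treatment" = c("location", "treatment"),
  "location:time" = c("location", "time"),
  "treatment:time" = c("treatment", "time"),
  "treatment:mass" = c("treatment", "mass"),
  "time:mass" = c("time", "mass"))
# lower-order main effects are added automatically when the design matrix is
# built, so only cross-term marginality is demanded of the listed terms
p_requires <- list(
  "location:time:day" = c("location:time", "location:day"))

#' Specify a robust-design Huggins model structure
#'
#' Terms for the monthly-survival (S) and capture-probability (p) components.
#' Capture and recapture probabilities are always equal (no trap response) and
#' temporary emigration is always uniformly random with a single probability
#' (gamma' = gamma''), so neither is part of the term language. The time
#' effect enters either categorically (optionally with the last two levels
#' merged, for end-of-study estimability) or as a cubic B-spline with 3 or 4
#' degrees of freedom; S and p may use different forms.
#'
#' @param surv_terms subset of `location, treatment, time, mass, cohort, sex,
#'   location:treatment, location:time, treatment:time, treatment:mass,
#'   time:mass`.
#' @param p_terms subset of `location, sex, location:time, location:day,
#'   location:time:day` (`day` is the linear day-within-session covariate).
#' @param time_form_s,time_form_p one of `"cat"`, `"cat_r"` (last two levels
#'   merged), `"spline3"`, `"spline4"`.
#' @param enforce_mandatory require the always-included terms (S: location,
#'   time, mass; p: location:time) and interaction marginality. Turn off for
#'   deliberately minimal models (e.g. intercept-only simulations).
#' @param max_terms cap on the number of listed terms per component.
#' @return An object of class `cmr_spec`.
#' @export
cmr_spec <- function(surv_terms = c("location", "time", "mass"),
                     p_terms = "location:time",
                     time_form_s = "spline3", time_form_p = time_form_s,
                     enforce_mandatory = TRUE, max_terms = 11L) {
  forms <- c("cat", "cat_r", "spline3", "spline4")
  stopifnot(time_form_s %in% forms, time_form_p %in% forms)
  bad <- setdiff(surv_terms, s_pool)
  if (length(bad)) stop("unknown survival term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(p_terms, p_pool)
  if (length(bad)) stop("unknown capture term(s): ", paste(bad, collapse = ", "))
  if (length(surv_terms) > max_terms || length(p_terms) > max_terms) {
    stop("more than ", max_terms, " terms in a component")
  }
  if (enforce_mandatory) {
    if (!all(c("location", "time", "mass") %in% surv_terms)) {
      stop("survival component must include location, time and mass")
    }
    if (!"location:time" %in% p_terms) {
      stop("capture component must include location:time")
    }
    for (tm in intersect(surv_terms, names(s_requires))) {
      if (!all(s_requires[[tm]] %in% surv_terms)) {
        stop("term ", tm, " requires ", paste(s_requires[[tm]], collapse = ", "))
      }
    }
    for (tm in intersect(p_terms, names(p_requires))) {
      if (!all(p_requires[[tm]] %in% p_terms)) {
        stop("term ", tm, " requires ", paste(p_requires[[tm]], collapse = ", "))
      }
    }
  }
  structure(list(surv_terms = surv_terms, p_terms = p_terms,
                 time_form_s = time_form_s, time_form_p = time_form_p),
            class = "cmr_spec")
}

#' @export
print.cmr_spec <- function(x, ...) {
  cat("S ~", spec_label_part(x$surv_terms, x$time_form_s), "\n")
  cat("p ~", spec_label_part(x$p_terms, x$time_form_p), "\n")
  invisible(x)
}

spec_label_part <- function(terms, form) {
  if (!length(terms)) return(paste0("1 [", form, "]"))
  paste0(paste(terms, collapse = " + "), " [", form, "]")
}

spec_label <- function(spec) {
  paste0("S(", spec_label_part(spec$surv_terms, spec$time_form_s),
         ") p(", spec_label_part(spec$p_terms, spec$time_form_p), ")")
}

# time columns for a given form evaluated at index grid 1..m:
# a list(df = covariate columns keyed by index, sym = formula symbol)
time_columns <- function(form, m, prefix) {
  if (form %in% c("cat", "cat_r")) {
    lev <- as.character(seq_len(m))
    val <- lev
    if (form == "cat_r" && m >= 2L) val[m] <- val[m - 1L]
    f <- factor(val, levels = unique(val))
    df <- stats::setNames(data.frame(f), paste0(prefix, "f"))
    list(df = df, sym = paste0(prefix, "f"))
  } else {
    dfree <- if (form == "spline3") 3L else 4L
    B <- spline_basis(seq_len(m), dfree)
    colnames(B) <- paste0(prefix, seq_len(dfree))
    list(df = as.data.frame(B),
         sym = paste0("(", paste(colnames(B), collapse = " + "), ")"))
  }
}

# translate a spec term list into a model formula string, adding the main
# effects an interaction needs for a full-rank, marginality-respecting matrix
component_formula <- function(terms, time_sym, day_sym = "day0") {
  sub1 <- function(tm) {
    tm <- gsub("\\btime\\b", time_sym, tm)
    tm <- gsub("\\bday\\b", day_sym, tm)
    gsub("\\bmass\\b", "mass_c", tm)
  }
  out <- character(0)
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    # all non-empty subsets of the interaction's components, low order first
    for (ord in seq_along(parts)) {
      for (cmb in utils::combn(parts, ord, simplify = FALSE)) {
        out <- c(out, sub1(paste(cmb, collapse = ":")))
      }
    }
  }
  out <- unique(out)
  if (!length(out)) out <- "1"
  stats::as.formula(paste("~", paste(out, collapse = " + ")))
}

# drop formula terms that reference a constant factor (e.g. a single-location
# study): such terms carry no information and would break the contrasts
prune_formula <- function(form, df) {
  tt <- stats::terms(form)
  labs <- attr(tt, "term.labels")
  if (!length(labs)) return(form)
  const <- names(df)[vapply(df, function(v)
    is.factor(v) && nlevels(droplevels(v)) < 2L, logical(1))]
  if (!length(const)) return(form)
  keep <- vapply(labs, function(l) {
    vars <- all.vars(stats::as.formula(paste("~", l)))
    !any(vars %in% const)
  }, logical(1))
  labs <- labs[keep]
  if (!length(labs)) return(stats::as.formula("~ 1"))
  stats::as.formula(paste("~", paste(labs, collapse = " + ")))
}

#' Build design matrices for a robust-design Huggins model
#'
#' One survival row per individual x interval (interval-major order) and one
#' capture row per individual x occasion (occasion-major order). The
#' treatment covariate is 0 for every interval originating before the session
#' in which the exclusion netting went up, so all plots share the control
#' parameters there. Body mass enters standardized as `(mass - 25) / 10`
#' using the imputed value at the interval's origin session; `day` enters p
#' as the linear day-within-session index minus 1.
#'
#' @param spec a [cmr_spec].
#' @param data an [encounter_data].
#' @param mass an [impute_mass] result (or a complete individuals x sessions
#'   matrix); may be `NULL` when `mass` is not in the model.
#' @param design an [rd_design]; defaults to the one inside `data`.
#' @return An object of class `cmr_design` holding `Xs`, `Xp`, the formulas
#'   and factor levels needed to rebuild rows for prediction, and layout
#'   constants.
#' @export
build_design <- function(spec, data, mass = NULL, design = data$design) {
  stopifnot(inherits(spec, "cmr_spec"), inherits(data, "encounter_data"))
  n <- nrow(data$ch)
  Tn <- design$n_sessions
  n_int <- Tn - 1L
  O <- n_occasions(design)

  mass_mat <- NULL
  if (inherits(mass, "imputed_mass")) mass_mat <- mass$mass_hat
  else if (is.matrix(mass)) mass_mat <- mass
  if ("mass" %in% spec$surv_terms && is.null(mass_mat)) {
    stop("spec includes mass but no imputed mass was supplied")
  }
  if (!is.null(mass_mat) && (nrow(mass_mat) != n || ncol(mass_mat) != Tn ||
                             anyNA(mass_mat))) {
    stop("imputed mass must be complete over individuals x sessions")
  }

  loc_lev <- sort(unique(data$individuals$location))
  coh_lev <- unique(data$individuals$cohort)

  # time columns are only materialised when a term mentions time, so minimal
  # models stay fittable on designs too short for a spline basis
  need_ts <- any(grepl("time", spec$surv_terms)) && n_int > 0L
  need_tp <- any(grepl("time", spec$p_terms))
  ts <- if (need_ts) time_columns(spec$time_form_s, n_int, "ts") else
    list(df = NULL, sym = "1")
  tp <- if (need_tp) time_columns(spec$time_form_p, Tn, "tp") else
    list(df = NULL, sym = "1")

  surv_df <- NULL
  if (n_int > 0L) {
    surv_df <- tibble::tibble(
      interval = rep(seq_len(n_int), each = n),
      id = rep(data$individuals$id, n_int),
      location = factor(rep(data$individuals$location, n_int), loc_lev),
      sex = factor(rep(data$individuals$sex, n_int), c("F", "M")),
      cohort = factor(rep(data$individuals$cohort, n_int), coh_lev),
      treatment = as.numeric(
        rep(data$individuals$treatment == "treatment", n_int) &
          rep(seq_len(n_int), each = n) >= design$treatment_start),
      mass_c = if (is.null(mass_mat)) 0 else
        (as.vector(mass_mat[, seq_len(n_int)]) - 25) / 10
    )
    if (!is.null(ts$df)) {
      surv_df <- cbind(surv_df, ts$df[surv_df$interval, , drop = FALSE])
    }
  }
  sform <- component_formula(spec$surv_terms, ts$sym)
  if (n_int > 0L) sform <- prune_formula(sform, surv_df)
  Xs <- if (n_int > 0L) stats::model.matrix(sform, surv_df) else
    matrix(0, 0L, 1L)

  os <- occ_session(design)
  p_df <- tibble::tibble(
    occ = rep(seq_len(O), each = n),
    session = rep(os, each = n),
    location = factor(rep(data$individuals$location, O), loc_lev),
    sex = factor(rep(data$individuals$sex, O), c("F", "M")),
    day0 = rep(occ_day(design) - 1L, each = n)
  )
  if (!is.null(tp$df)) p_df <- cbind(p_df, tp$df[p_df$session, , drop = FALSE])
  pform <- prune_formula(component_formula(spec$p_terms, tp$sym), p_df)
  Xp <- stats::model.matrix(pform, p_df)

  structure(
    list(spec = spec, design = design, n = n, Tn = Tn, n_int = n_int, O = O,
         Xs = Xs, Xp = Xp, k_s = ncol(Xs), k_p = ncol(Xp),
         k = ncol(Xs) + ncol(Xp) + 1L,
         Lpow = if (n_int > 0L) design$interval_days / 30 else numeric(0),
         sagg = session_agg(design),
         sform = sform, pform = pform, ts = ts, tp = tp,
         loc_lev = loc_lev, coh_lev = coh_lev,
         beta_names = c(paste0("S:", colnames(Xs)), paste0("p:", colnames(Xp)),
                        "logit_gamma")),
    class = "cmr_design"
  )
}

# capture-history summaries the likelihood needs; separated from the design
# matrices so bootstrap replicates can swap histories without rebuilding X
obs_stats <- function(ch, design) {
  fc <- first_capture(ch, design)
  O <- ncol(ch)
  list(ch = ch, fi = fc$session, first_occ = fc$occasion,
       sc = session_captures(ch, design),
       after_first = outer(fc$occasion, seq_len(O), `<`))
}

# O x T aggregation matrix (occasion -> session)
session_agg <- function(design) {
  s <- occ_session(design)
  outer(s, seq_len(design$n_sessions), `==`) * 1
}

#' Negative log conditional likelihood of a robust-design Huggins model
#'
#' Each individual contributes the probability of its capture history
#' strictly after its first capture, conditional on that first capture.
#' Remaining occasions of the first-capture session are independent
#' Bernoulli(p); between sessions a forward recursion marginalizes the hidden
#' states (alive-available, alive-unavailable, dead) with per-interval
#' survival `S_monthly^(interval_days/30)` and independent
#' Bernoulli(1 - gamma) availability (uniformly random temporary emigration).
#' An available animal emits its within-session Bernoulli history; an
#' unavailable or dead one emits 1 if the session holds no captures and 0
#' otherwise.
#'
#' @param beta coefficient vector: survival block, capture block, then the
#'   single logit-gamma parameter.
#' @param dm a [build_design] result.
#' @param obs capture-history summaries (internal; built from the data by
#'   [fit_cmr]).
#' @return Scalar negative log-likelihood (a large penalty on numerical
#'   failure).
#' @export
negloglik <- function(beta, dm, obs) {
  if (any(!is.finite(beta))) return(1e10)
  n <- dm$n
  b_s <- beta[seq_len(dm$k_s)]
  b_p <- beta[dm$k_s + seq_len(dm$k_p)]
  gam <- stats::plogis(beta[dm$k])

  eta_p <- drop(dm$Xp %*% b_p)
  logp <- stats::plogis(eta_p, log.p = TRUE)
  log1mp <- stats::plogis(-eta_p, log.p = TRUE)
  C <- obs$ch * matrix(logp, n, dm$O) + (1 - obs$ch) * matrix(log1mp, n, dm$O)
  C[!obs$after_first] <- 0
  logPA <- C %*% dm$sagg
  eA <- exp(logPA)
  y0 <- obs$sc == 0L

  if (dm$n_int > 0L) {
    S <- stats::plogis(matrix(drop(dm$Xs %*% b_s), n, dm$n_int))
    phi <- S ^ matrix(dm$Lpow, n, dm$n_int, byrow = TRUE)
  }

  aA <- aU <- aD <- numeric(n)
  for (t in seq_len(dm$Tn)) {
    if (t > 1L) {
      upd <- obs$fi < t
      if (any(upd)) {
        ph <- phi[upd, t - 1L]
        alive <- (aA[upd] + aU[upd]) * ph
        dead <- aD[upd] + (aA[upd] + aU[upd]) * (1 - ph)
        e0 <- y0[upd, t]
        aA[upd] <- alive * (1 - gam) * eA[upd, t]
        aU[upd] <- alive * gam * e0
        aD[upd] <- dead * e0
      }
    }
    init <- obs$fi == t
    aA[init] <- eA[init, t]
    aU[init] <- 0
    aD[init] <- 0
  }
  tot <- aA + aU + aD
  if (any(!is.finite(tot)) || any(tot <= 0)) return(1e10)
  -sum(log(tot))
}

# central-difference Hessian with relative step (default 1e-5)
num_hessian <- function(fn, x, rel_step = 1e-5) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- xm <- x
        xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- xpm <- xmp <- xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit a robust-design Huggins model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of the conditional likelihood on the
#' logit scale, starting from zero (optionally multi-started from jittered
#' zeros), with covariance from the inverse numerical Hessian (central
#' differences, relative step 1e-5). A model is flagged `boundary` when any
#' fitted real-scale probability lies outside `[1e-6, 1 - 1e-6]` or any
#' coefficient variance falls below 1e-10 or above 1e6 — the estimability
#' screen used before model ranking.
#'
#' @param spec a [cmr_spec].
#' @param data an [encounter_data].
#' @param mass an [impute_mass] result (required when `mass` is a survival
#'   term).
#' @param design an [rd_design].
#' @param n_starts optimizer starts (first from zero, others jittered).
#' @param n_eff effective sample size for AICc; defaults to the number of
#'   individuals (the exchangeable unit of the conditional likelihood).
#' @param seed seed for the start jitter.
#' @return An object of class `cmr_fit`.
#' @export
fit_cmr <- function(spec, data, mass = NULL, design = data$design,
                    n_starts = 1L, n_eff = NULL, seed = 1L) {
  dm <- build_design(spec, data, mass, design)
  obs <- obs_stats(data$ch, design)
  fit <- fit_cmr_dm(dm, obs, n_starts = n_starts, seed = seed,
                    n_eff = n_eff %||% dm$n)
  fit$data_ids <- data$individuals$id
  fit
}

# the optimizer core; reused by the parametric bootstrap with fresh obs
# (which skips the Hessian: bootstrap needs only the maximized deviance)
fit_cmr_dm <- function(dm, obs, n_starts = 1L, seed = 1L, n_eff = dm$n,
                       start = NULL, hessian = TRUE) {
  k <- dm$k
  fn <- function(b) negloglik(b, dm, obs)
  starts <- list(start %||% rep(0, k))
  if (n_starts > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    for (j in seq_len(n_starts - 1L)) {
      starts[[j + 1L]] <- stats::rnorm(k, 0, 0.5)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, fn, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  beta <- best$par
  if (hessian) {
    H <- num_hessian(fn, beta)
    vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
    if (anyNA(vc)) {
      vc <- tryCatch(solve(H + diag(1e-8, k)), error = function(e)
        matrix(NA_real_, k, k))
    }
  } else {
    vc <- matrix(NA_real_, k, k)
  }
  dimnames(vc) <- list(dm$beta_names, dm$beta_names)
  names(beta) <- dm$beta_names

  real <- real_params(beta, dm)
  eps <- 1e-6
  bound <- any(real$p < eps | real$p > 1 - eps) ||
    (dm$n_int > 0L && any(real$S < eps | real$S > 1 - eps)) ||
    real$gamma > 1 - eps
  if (hessian) {
    v <- diag(vc)
    bound <- bound || anyNA(v) || any(v < 1e-10 | v > 1e6)
  }

  ll <- -best$value
  structure(
    list(beta = beta, vcov = vc, loglik = ll, k = k,
         aicc = aicc(ll, k, n_eff), n_eff = n_eff,
         converged = best$convergence == 0L, boundary = bound,
         spec = dm$spec, dm = dm, obs = obs),
    class = "cmr_fit"
  )
}

# fitted real-scale parameters over the observed design rows
real_params <- function(beta, dm) {
  p <- stats::plogis(drop(dm$Xp %*% beta[dm$k_s + seq_len(dm$k_p)]))
  S <- if (dm$n_int > 0L) {
    stats::plogis(matrix(drop(dm$Xs %*% beta[seq_len(dm$k_s)]), dm$n, dm$n_int))
  } else matrix(0, 0, 0)
  list(S = S, p = matrix(p, dm$n, dm$O), gamma = stats::plogis(beta[dm$k]))
}

#' @export
print.cmr_fit <- function(x, ...) {
  cat(spec_label(x$spec), "\n")
  cat("  logLik", format(x$loglik), "| k", x$k, "| AICc", format(x$aicc),
      if (!x$converged) "| NOT converged" else "",
      if (x$boundary) "| boundary" else "", "\n")
  invisible(x)
}

#' @export
tidy.cmr_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(se))
}

#' @export
glance.cmr_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, k = x$k, AICc = x$aicc, n_eff = x$n_eff,
                 converged = x$converged, boundary = x$boundary,
                 gamma = stats::plogis(x$beta[x$k]))
}

# survival design rows for covariate profiles: profile is a data frame with
# columns interval, location, treatment ("treatment"/"control"), mass, sex,
# cohort (optional)
survival_rows <- function(dm, profile) {
  profile <- tibble::as_tibble(profile)
  if (!"sex" %in% names(profile)) profile$sex <- "F"
  if (!"cohort" %in% names(profile)) profile$cohort <- dm$coh_lev[1]
  if (!"mass" %in% names(profile)) profile$mass <- 25
  df <- tibble::tibble(
    interval = profile$interval,
    location = factor(profile$location, dm$loc_lev),
    sex = factor(profile$sex, c("F", "M")),
    cohort = factor(profile$cohort, dm$coh_lev),
    treatment = as.numeric(profile$treatment == "treatment" &
                             profile$interval >= dm$design$treatment_start),
    mass_c = (profile$mass - 25) / 10
  )
  if (!is.null(dm$ts$df)) df <- cbind(df, dm$ts$df[df$interval, , drop = FALSE])
  stats::model.matrix(dm$sform, df)
}

#' Monthly apparent survival at a covariate profile
#'
#' Fitted survival on the 30-day scale for given interval(s) and covariates.
#' The model is parameterised directly on the monthly scale, so no interval
#' rescaling is applied here; [interval_survival] powers it by
#' `interval_days / 30`.
#'
#' @param fit a `cmr_fit`.
#' @param interval interval index (vectorised with the other arguments).
#' @param location location name.
#' @param treatment `"treatment"` or `"control"` (automatically inactive for
#'   pre-netting intervals).
#' @param mass body mass in grams.
#' @param sex `"F"` or `"M"`.
#' @param beta optional coefficient vector overriding the MLE (used by the
#'   model-averaging draws).
#' @return Numeric vector of monthly survival probabilities.
#' @export
monthly_survival <- function(fit, interval, location, treatment = "control",
                             mass = 25, sex = "F", beta = NULL) {
  beta <- beta %||% fit$beta
  X <- survival_rows(fit$dm, tibble::tibble(
    interval = interval, location = location, treatment = treatment,
    mass = mass, sex = sex))
  stats::plogis(drop(X %*% beta[seq_len(fit$dm$k_s)]))
}

#' @rdname monthly_survival
#' @export
interval_survival <- function(fit, interval, location, treatment = "control",
                              mass = 25, sex = "F", beta = NULL) {
  s <- monthly_survival(fit, interval, location, treatment, mass, sex, beta)
  s ^ (fit$dm$design$interval_days[interval] / 30)
}

#' Horvitz-Thompson abundance from per-occasion capture probabilities
#'
#' The Huggins derived estimand: for every individual captured in the
#' session, `p*_i = 1 - prod(1 - p_io)` over the session's occasions, and
#' `N_hat = sum(1 / p*_i)`.
#'
#' @param fit a `cmr_fit`.
#' @param data the [encounter_data] the model was fitted to.
#' @param session session index.
#' @param plot plot label (`NULL` pools all plots).
#' @param beta optional coefficient vector overriding the MLE.
#' @return Abundance estimate (scalar).
#' @export
population_size <- function(fit, data, session, plot = NULL, beta = NULL) {
  beta <- beta %||% fit$beta
  dm <- fit$dm
  p <- stats::plogis(matrix(drop(dm$Xp %*% beta[dm$k_s + seq_len(dm$k_p)]),
                            dm$n, dm$O))
  sc <- session_captures(data$ch, dm$design)
  caught <- sc[, session] > 0L
  if (!is.null(plot)) caught <- caught & data$individuals$plot == plot
  if (!any(caught)) return(0)
  occ <- occ_session(dm$design) == session
  log_miss <- rowSums(log1p(-p[caught, occ, drop = FALSE]))
  pstar <- -expm1(log_miss)
  sum(1 / pstar)
}
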