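#' Simulation scenario for robust-design capture histories
#'
#' Defines the generating process for a synthetic avian-exclusion trapping
#' study: paired treatment/control plots at several locations, Bernoulli
#' captures within closed 5-day sessions, apparent survival between sessions
#' on the logit scale (treatment, location, interval and body-mass effects),
#' uniformly random temporary emigration (the availability of each individual
#' at each session is an independent Bernoulli(1 - gamma) draw), deterministic
#' recruitment counts per interval, and body masses following a small number
#' of latent trajectory classes.
#'
#' Survival is parameterised on the 30-day (monthly) scale and powered by
#' `interval_days / 30` per interval. The body-mass effect acts on logit
#' monthly survival per gram of (mass - 25); masses are recorded to 0.5 g as a
#' field balance would.
#'
#' @param design an [rd_design].
#' @param locations character vector of location names; each location gets a
#'   paired treatment and control plot.
#' @param n0 named numeric `c(treatment = , control = )`: initial abundance
#'   per plot at session 1.
#' @param recruits recruits entering each plot at each session after the
#'   first (a scalar, or a matrix plots x (n_sessions - 1)). Deterministic, so
#'   true abundance is known exactly.
#' @param s_monthly baseline monthly apparent survival (control, mean mass).
#' @param s_treatment additive effect of active netting on logit monthly
#'   survival (0 = no treatment effect).
#' @param s_location additive logit effects per location (first is reference).
#' @param s_time additive logit effect per interval (length n_sessions - 1).
#' @param s_mass effect on logit monthly survival per gram of mass above 25 g.
#' @param p_capture baseline per-occasion capture probability.
#' @param p_day additive effect on logit p per day within session (day 1 = 0).
#' @param p_sex additive logit-p effect for males.
#' @param gamma temporary-emigration probability per session.
#' @param mass_classes list describing the latent mass trajectories:
#'   `pi` (mixing proportions), `means` (array K x 2 x n_sessions, second
#'   dimension F/M, grams), `sd` (residual s.d. per class, grams).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(design = default_design(),
                       locations = c("Barwik", "Losiowka", "Gugny"),
                       n0 = c(treatment = 74, control = 65),
                       recruits = 25,
                       s_monthly = 0.8,
                       s_treatment = 0,
                       s_location = rep(0, length(locations)),
                       s_time = rep(0, design$n_sessions - 1L),
                       s_mass = 0,
                       p_capture = 0.4,
                       p_day = 0,
                       p_sex = 0,
                       gamma = 0.1,
                       mass_classes = default_mass_classes(design$n_sessions)) {
  stopifnot(inherits(design, "rd_design"))
  if (s_monthly < 0 || s_monthly > 1) stop("s_monthly must be in [0, 1]")
  if (p_capture < 0 || p_capture > 1) stop("p_capture must be in [0, 1]")
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)")
  if (any(n0 < 0)) stop("n0 must be >= 0")
  if (abs(sum(mass_classes$pi) - 1) > 1e-8) stop("mass class proportions must sum to 1")
  if (length(s_location) != length(locations)) stop("one s_location per location")
  if (length(s_time) != design$n_sessions - 1L) stop("one s_time per interval")
  n_plots <- 2L * length(locations)
  if (is.matrix(recruits)) {
    stopifnot(nrow(recruits) == n_plots, ncol(recruits) == design$n_sessions - 1L)
  } else {
    recruits <- matrix(recruits, n_plots, max(design$n_sessions - 1L, 0L))
  }
  structure(
    list(design = design, locations = locations, n0 = n0, recruits = recruits,
         s_monthly = s_monthly, s_treatment = s_treatment,
         s_location = s_location, s_time = s_time, s_mass = s_mass,
         p_capture = p_capture, p_day = p_day, p_sex = p_sex, gamma = gamma,
         mass_classes = mass_classes),
    class = "sim_config"
  )
}

#' Default latent body-mass trajectory classes
#'
#' Three trajectories spanning the 16-44 g range typical of root voles:
#' small overwintering animals, large stable adults, and a cohort that grows
#' rapidly from subadult to adult mass over the study. Males run ~1.5 g
#' heavier than females.
#'
#' @param n_sessions number of primary sessions.
#' @return A list with elements `pi`, `means` (K x 2 x n_sessions), `sd`.
#' @export
default_mass_classes <- function(n_sessions) {
  tgrid <- seq(0, 1, length.out = n_sessions)
  f <- rbind(
    20 + 2 * tgrid,        # small, near-stable
    32 + 3 * tgrid,        # large adults
    18 + 17 * tgrid        # fast spring growth
  )
  means <- array(NA_real_, c(3L, 2L, n_sessions),
                 dimnames = list(NULL, c("F", "M"), NULL))
  means[, "F", ] <- f
  means[, "M", ] <- f + 1.5
  list(pi = c(0.45, 0.35, 0.20), means = means, sd = 1.5)
}

#' Read a simulation scenario from YAML
#'
#' Scenario files carry the scalar fields of [sim_config] plus the design
#' (`start_dates`, `occasions`, `treatment_start`); unlisted fields keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
#' @examples
#' cfg <- read_scenario(system.file("extdata", "example_scenario.yaml",
#'                                  package = "voleCMR"))
#' cfg$s_monthly
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) {
    rd_design(y$design$start_dates,
              occasions = y$design$occasions %||% 5L,
              treatment_start = y$design$treatment_start %||% 2L)
  } else default_design()
  args <- y[setdiff(names(y), "design")]
  if (!is.null(args$n0)) args$n0 <- unlist(args$n0)
  do.call(sim_config, c(list(design = design), args))
}

logit_s_monthly <- function(config, loc_idx, treated_active, interval, mass) {
  stats::qlogis(config$s_monthly) +
    config$s_treatment * treated_active +
    config$s_location[loc_idx] +
    config$s_time[interval] +
    config$s_mass * (mass - 25)
}

#' Simulate a robust-design capture study with known truth
#'
#' Draws individual alive/available states, latent mass classes and capture
#' histories under a [sim_config], returning both the observed
#' [encounter_data] (never-captured individuals dropped) and a `sim_truth`
#' object holding the generating states for recovery tests: birth session,
#' death interval, availability, true class and mass per session, true
#' per-plot abundance (alive, and alive-and-available), and the generating
#' monthly survival per covariate profile.
#'
#' Random draws are blocked so that the per-occasion capture uniforms are
#' drawn last: raising `p_capture` under the same seed can only turn
#' non-captures into captures.
#'
#' @param config a [sim_config].
#' @param seed integer seed.
#' @return A list with elements `data` ([encounter_data]) and `truth`.
#' @export
simulate_captures <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  Tn <- design$n_sessions
  n_int <- Tn - 1L
  K <- length(config$mass_classes$pi)

  plots <- tidyr::expand_grid(location = config$locations,
                              treatment = c("treatment", "control")) |>
    dplyr::mutate(plot = paste(.data$location, .data$treatment, sep = "."))

  # roster: one row per (ever-existing) individual
  roster <- purrr::map_dfr(seq_len(nrow(plots)), function(j) {
    nb <- c(config$n0[[plots$treatment[j]]],
            if (n_int > 0L) config$recruits[j, ] else numeric(0))
    tibble::tibble(
      plot = plots$plot[j], location = plots$location[j],
      treatment = plots$treatment[j],
      birth = rep(seq_len(Tn), times = round(nb))
    )
  })
  n <- nrow(roster)
  if (n == 0L) stop("zero population: no individuals to simulate")
  roster$id <- sprintf("v%05d", seq_len(n))
  loc_idx <- match(roster$location, config$locations)
  treated_plot <- roster$treatment == "treatment"

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  roster$sex <- sample(c("F", "M"), n, replace = TRUE)
  roster$class <- sample.int(K, n, replace = TRUE, prob = config$mass_classes$pi)

  # true mass per session: class curve + N(0, sd), 0.5 g grid
  mu <- config$mass_classes$means[cbind(
    rep(roster$class, Tn), rep(match(roster$sex, c("F", "M")), Tn),
    rep(seq_len(Tn), each = n))]
  sdc <- rep_len(config$mass_classes$sd, K)[roster$class]
  mass_true <- matrix(mu + stats::rnorm(n * Tn, 0, sdc), n, Tn)
  mass_true <- round(mass_true * 2) / 2

  # survival and availability draws
  u_surv <- matrix(stats::runif(n * max(n_int, 1L)), n)
  u_avail <- matrix(stats::runif(n * Tn), n)
  alive <- matrix(FALSE, n, Tn)
  death_interval <- rep(NA_integer_, n)
  for (t in seq_len(Tn)) alive[roster$birth == t, t] <- TRUE
  if (n_int > 0L) {
    for (k in seq_len(n_int)) {
      cur <- alive[, k]
      if (!any(cur)) { alive[roster$birth == k + 1L, k + 1L] <- TRUE; next }
      sm <- stats::plogis(logit_s_monthly(
        config, loc_idx[cur],
        as.numeric(treated_plot[cur] & (k >= design$treatment_start)),
        k, mass_true[cur, k]))
      phi <- sm ^ (design$interval_days[k] / 30)
      srv <- u_surv[cur, k] < phi
      alive[cur, k + 1L] <- srv
      died <- which(cur)[!srv]
      death_interval[died] <- k
      alive[roster$birth == k + 1L, k + 1L] <- TRUE
    }
  }
  avail <- alive & (u_avail < 1 - config$gamma)

  # captures, drawn last so raising p is monotone under the same seed
  O <- n_occasions(design)
  u_cap <- matrix(stats::runif(n * O), n)
  dayc <- occ_day(design) - 1L
  logit_p <- stats::qlogis(config$p_capture) +
    outer(as.numeric(roster$sex == "M") * config$p_sex, dayc * config$p_day, `+`)
  p_occ <- stats::plogis(logit_p)
  at_risk <- avail[, occ_session(design), drop = FALSE]
  ch <- matrix(as.integer(at_risk & (u_cap < p_occ)), n, O)

  sc <- session_captures(ch, design)
  mass_obs <- mass_true
  mass_obs[sc == 0L] <- NA_real_

  abundance <- tibble::tibble(
    plot = rep(roster$plot[1], 0), session = integer(0),
    n_alive = integer(0), n_available = integer(0))
  abundance <- tidyr::expand_grid(plot = plots$plot, session = seq_len(Tn)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_alive = sum(alive[roster$plot == .data$plot, .data$session]),
      n_available = sum(avail[roster$plot == .data$plot, .data$session])) |>
    dplyr::ungroup()

  truth <- structure(
    list(roster = tibble::as_tibble(roster[c("id", "plot", "location",
                                             "treatment", "sex", "class",
                                             "birth")]),
         death_interval = death_interval,
         alive = alive, available = avail, mass_true = mass_true,
         abundance = abundance, config = config, seed = seed),
    class = "sim_truth"
  )

  seen <- rowSums(ch) > 0L
  if (!any(seen)) stop("no individual was ever captured under this scenario")
  data <- encounter_data(
    roster[seen, c("id", "sex", "location", "plot", "treatment")],
    ch[seen, , drop = FALSE], mass_obs[seen, , drop = FALSE], design)
  list(data = data, truth = truth)
}

#' True generating monthly survival for a covariate profile
#'
#' @param truth a `sim_truth`.
#' @param interval interval index.
#' @param location location name.
#' @param treatment `"treatment"` or `"control"`.
#' @param mass body mass in grams.
#' @return Monthly survival probability.
#' @export
true_monthly_survival <- function(truth, interval, location,
                                  treatment = "control", mass = 25) {
  config <- truth$config
  active <- as.numeric(treatment == "treatment" &
                         interval >= config$design$treatment_start)
  stats::plogis(logit_s_monthly(config, match(location, config$locations),
                                active, interval, mass))
}
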