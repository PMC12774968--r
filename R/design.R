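#' Robust-design study layout
#'
#' Describes the temporal layout of a robust-design live-trapping study:
#' widely spaced primary sessions (the population is open between them), each
#' holding a run of consecutive daily secondary occasions (the population is
#' treated as closed within a session). Intervals between sessions are
#' measured in days from session start to session start; survival is reported
#' on a 30-day scale and powered by `interval_days / 30` per interval.
#'
#' @param start_dates `Date` vector (or coercible strings), one per session,
#'   strictly increasing.
#' @param occasions integer: trapping occasions (days) per session; recycled
#'   to the number of sessions.
#' @param treatment_start index of the first session with the exclusion
#'   netting active. Survival intervals originating before this session carry
#'   no treatment effect, so all plots share the control parameters there.
#' @param session_labels optional character labels; defaults to `"S1"...`.
#'
#' @return An object of class `rd_design`.
#' @export
#' @examples
#' d <- rd_design(c("2005-11-15", "2006-01-15", "2006-03-15"), occasions = 5)
#' d$interval_days
rd_design <- function(start_dates, occasions = 5L, treatment_start = 2L,
                      session_labels = NULL) {
  start_dates <- as.Date(start_dates)
  n <- length(start_dates)
  if (n < 1L) stop("at least one session is required")
  if (n > 1L && any(diff(start_dates) <= 0)) {
    stop("session start dates must be strictly increasing")
  }
  occasions <- as.integer(rep_len(occasions, n))
  if (any(occasions < 1L)) stop("occasions_per_session must be >= 1")
  if (is.null(session_labels)) session_labels <- paste0("S", seq_len(n))
  structure(
    list(
      n_sessions = n,
      session_labels = session_labels,
      start_dates = start_dates,
      occasions = occasions,
      interval_days = if (n > 1L) as.numeric(diff(start_dates)) else numeric(0),
      treatment_start = as.integer(treatment_start)
    ),
    class = "rd_design"
  )
}

#' Default study layout: seven bimonthly five-day sessions
#'
#' Mirrors a November-to-November small-mammal trapping design: seven primary
#' sessions at roughly two-month intervals, five daily occasions each, with
#' the exclusion treatment active from the second session onwards (the first
#' session is pre-experimental).
#'
#' @return An `rd_design`.
#' @export
default_design <- function() {
  rd_design(
    start_dates = c("2005-11-15", "2006-01-15", "2006-03-15", "2006-05-15",
                    "2006-07-15", "2006-09-15", "2006-11-15"),
    occasions = 5L,
    treatment_start = 2L
  )
}

#' @export
print.rd_design <- function(x, ...) {
  cat("Robust design:", x$n_sessions, "sessions,",
      paste(range(x$occasions), collapse = "-"), "occasions/session\n")
  cat("  starts:", paste(format(x$start_dates), collapse = ", "), "\n")
  if (length(x$interval_days)) {
    cat("  interval days:", paste(x$interval_days, collapse = ", "), "\n")
  }
  cat("  treatment active from session", x$treatment_start, "\n")
  invisible(x)
}

# total secondary occasions
n_occasions <- function(design) sum(design$occasions)

# session index of each global occasion (1-based)
occ_session <- function(design) rep(seq_len(design$n_sessions), design$occasions)

# day-within-session (1-based) of each global occasion
occ_day <- function(design) {
  unlist(lapply(design$occasions, seq_len), use.names = FALSE)
}

# calendar date of each global occasion: session start + (day - 1)
occ_date <- function(design) {
  design$start_dates[occ_session(design)] + (occ_day(design) - 1L)
}
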