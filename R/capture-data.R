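#' Encounter-history container
#'
#' Bundles a validated binary individuals-by-occasions capture matrix with the
#' per-individual covariates and the sparse observed body masses of a
#' robust-design study. Rows of all components align.
#'
#' @param individuals tibble/data frame with columns `id`, `sex` (`"F"`/`"M"`),
#'   `location`, `plot`, `treatment` (`"treatment"`/`"control"`), `cohort`
#'   (label of the first-capture session; derived if absent).
#' @param ch binary integer matrix, individuals x total occasions, occasions
#'   grouped by session in design order.
#' @param mass numeric matrix, individuals x sessions, grams; `NA` where no
#'   mass was observed. A value may only be present where the individual was
#'   captured in that session.
#' @param design an [rd_design].
#'
#' @return An object of class `encounter_data`.
#' @export
encounter_data <- function(individuals, ch, mass, design) {
  individuals <- tibble::as_tibble(individuals)
  ch <- as.matrix(ch)
  storage.mode(ch) <- "integer"
  mass <- as.matrix(mass)
  n <- nrow(individuals)
  stopifnot(inherits(design, "rd_design"))
  if (nrow(ch) != n || nrow(mass) != n) {
    stop("individuals, ch and mass must have the same number of rows")
  }
  if (ncol(ch) != n_occasions(design)) {
    stop("ch must have ", n_occasions(design), " columns (total occasions)")
  }
  if (ncol(mass) != design$n_sessions) {
    stop("mass must have one column per session")
  }
  req <- c("id", "sex", "location", "plot", "treatment")
  miss <- setdiff(req, names(individuals))
  if (length(miss)) stop("missing individual columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(individuals$id)) stop("duplicated individual ids")
  if (!all(ch %in% c(0L, 1L))) stop("encounter matrix must be binary")
  if (any(rowSums(ch) < 1L)) {
    bad <- individuals$id[rowSums(ch) < 1L]
    stop("individuals with no captures: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(individuals$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(individuals$treatment %in% c("treatment", "control"))) {
    stop("treatment must be 'treatment' or 'control'")
  }
  sc <- session_captures(ch, design)
  if (any(!is.na(mass) & sc == 0L)) {
    stop("observed mass present in a session without a capture")
  }
  if (!"cohort" %in% names(individuals)) {
    first <- apply(sc > 0L, 1L, which.max)
    individuals$cohort <- design$session_labels[first]
  }
  rownames(ch) <- rownames(mass) <- individuals$id
  structure(
    list(individuals = individuals, ch = ch, mass = mass, design = design),
    class = "encounter_data"
  )
}

#' @export
print.encounter_data <- function(x, ...) {
  cat("Encounter data:", nrow(x$ch), "individuals,",
      x$design$n_sessions, "sessions,", ncol(x$ch), "occasions,",
      sum(x$ch), "captures\n")
  invisible(x)
}

# n x n_sessions matrix of per-session capture counts
session_captures <- function(ch, design) {
  s <- occ_session(design)
  out <- vapply(seq_len(design$n_sessions),
                function(t) rowSums(ch[, s == t, drop = FALSE]),
                numeric(nrow(ch)))
  matrix(as.integer(out), nrow = nrow(ch),
         dimnames = list(rownames(ch), design$session_labels))
}

# index of first capture: list(session, occasion) per individual
first_capture <- function(ch, design) {
  occ1 <- apply(ch == 1L, 1L, which.max)
  list(session = occ_session(design)[occ1], occasion = occ1)
}

#' Read long-format capture records
#'
#' Reads a long CSV with one row per capture event and assembles a validated
#' [encounter_data]. Required columns: `id`, `location`, `treatment`,
#' `session`, `occasion`, `sex`, `mass_g`; optional: `plot` (defaults to
#' `location.treatment`), `cohort`. `session` and `occasion` are 1-based; the
#' occasion index counts days within its session. Duplicate `(id, occasion)`
#' rows collapse to a single capture; the body mass recorded for a session is
#' the first one listed for that individual in that session.
#'
#' @param path CSV file path.
#' @param design an [rd_design] the indices must be consistent with.
#' @return An `encounter_data`.
#' @export
read_long_csv <- function(path, design) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  long_records_to_encounter(df, design)
}

#' Assemble encounter data from a long records frame
#'
#' Same contract as [read_long_csv] but starting from an in-memory data
#' frame, so capture records can flow straight from dplyr pipelines.
#'
#' @param df data frame of capture records (see [read_long_csv]).
#' @param design an [rd_design].
#' @return An `encounter_data`.
#' @export
long_records_to_encounter <- function(df, design) {
  df <- tibble::as_tibble(df)
  req <- c("id", "location", "treatment", "session", "occasion", "sex", "mass_g")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"plot" %in% names(df)) df$plot <- paste(df$location, df$treatment, sep = ".")
  bad <- which(df$session < 1 | df$session > design$n_sessions)
  if (length(bad)) stop("unknown session in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(df$occasion < 1 | df$occasion > design$occasions[df$session])
  if (length(bad)) stop("unknown occasion in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  two <- df |>
    dplyr::distinct(.data$id, .data$plot) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(two)) stop("individual(s) appearing in two plots: ",
                      paste(utils::head(two$id, 5), collapse = ", "))

  ids <- unique(df$id)
  n <- length(ids)
  occ_offset <- c(0L, cumsum(design$occasions))[seq_len(design$n_sessions)]
  ch <- matrix(0L, n, n_occasions(design))
  gocc <- occ_offset[df$session] + df$occasion
  ch[cbind(match(df$id, ids), gocc)] <- 1L

  mass <- matrix(NA_real_, n, design$n_sessions)
  first_mass <- df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::filter(!is.na(.data$mass_g)) |>
    dplyr::group_by(.data$id, .data$session) |>
    dplyr::slice_min(.data$.row, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  mass[cbind(match(first_mass$id, ids), first_mass$session)] <- first_mass$mass_g

  cov <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      sex = dplyr::first(.data$sex),
      location = dplyr::first(.data$location),
      plot = dplyr::first(.data$plot),
      treatment = dplyr::first(.data$treatment),
      cohort = if ("cohort" %in% names(df)) dplyr::first(.data$cohort) else
        NA_character_,
      .groups = "drop"
    )
  cov <- cov[match(ids, cov$id), ]
  if (all(is.na(cov$cohort))) cov$cohort <- NULL
  encounter_data(cov, ch, mass, design)
}

#' Write / read MARK-style encounter histories
#'
#' `write_encounter_histories()` writes one line per individual: the
#' concatenated 0/1 capture string over all occasions followed by the
#' covariate columns and the per-session masses (comma-separated, empty where
#' unobserved), tab-separated with a header. `read_encounter_histories()`
#' inverts it exactly.
#'
#' @param data an [encounter_data].
#' @param path output file path.
#' @return `path`, invisibly (writer); an `encounter_data` (reader).
#' @export
write_encounter_histories <- function(data, path) {
  stopifnot(inherits(data, "encounter_data"))
  chs <- apply(data$ch, 1L, paste, collapse = "")
  masss <- apply(data$mass, 1L, function(m) {
    paste(ifelse(is.na(m), "", format(m, trim = TRUE, scientific = FALSE)),
          collapse = ",")
  })
  out <- tibble::tibble(
    ch = chs,
    id = data$individuals$id,
    sex = data$individuals$sex,
    location = data$individuals$location,
    plot = data$individuals$plot,
    treatment = data$individuals$treatment,
    cohort = data$individuals$cohort,
    mass = masss
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_encounter_histories
#' @param design an [rd_design] matching the occasion count of the file.
#' @export
read_encounter_histories <- function(path, design) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  ch <- do.call(rbind, lapply(strsplit(df$ch, ""), as.integer))
  mass <- do.call(rbind, lapply(strsplit(df$mass, ",", fixed = TRUE), function(v) {
    v <- c(v, rep("", design$n_sessions - length(v)))
    suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  }))
  encounter_data(df[c("id", "sex", "location", "plot", "treatment", "cohort")],
                 ch, mass, design)
}

#' Descriptive summary of a capture data set
#'
#' Computes the standard descriptive counts of a robust-design trapping data
#' set: capture and individual totals, recapture fraction, per session-plot
#' caught counts, per-individual session/occasion means, the single-session
#' fraction, and capture spans in calendar days (occasion date = session start
#' + day-within-session - 1).
#'
#' @param data an [encounter_data].
#' @return A one-row tibble.
#' @export
summarize_captures <- function(data) {
  stopifnot(inherits(data, "encounter_data"))
  design <- data$design
  ch <- data$ch
  sc <- session_captures(ch, design)
  n <- nrow(ch)
  total <- sum(ch)
  occ_per_ind <- rowSums(ch)
  sess_per_ind <- rowSums(sc > 0L)
  n_recap <- sum(occ_per_ind >= 2L)

  caught <- tibble::tibble(
    plot = rep(data$individuals$plot, design$n_sessions),
    session = rep(seq_len(design$n_sessions), each = n),
    caught = as.vector(sc > 0L)
  ) |>
    dplyr::group_by(.data$plot, .data$session) |>
    dplyr::summarise(n = sum(.data$caught), .groups = "drop")

  dts <- occ_date(design)
  span <- apply(ch == 1L, 1L, function(h) {
    d <- dts[h]
    as.numeric(max(d) - min(d))
  })

  tibble::tibble(
    total_captures = total,
    n_individuals = n,
    n_recaptured = n_recap,
    frac_recaptured = n_recap / n,
    session_plot_mean = mean(caught$n),
    session_plot_sd = stats::sd(caught$n),
    session_plot_min = min(caught$n),
    session_plot_max = max(caught$n),
    mean_sessions_per_ind = mean(sess_per_ind),
    mean_occasions_per_ind = mean(occ_per_ind),
    n_single_session = sum(sess_per_ind == 1L),
    frac_single_session = mean(sess_per_ind == 1L),
    mean_span_days = mean(span),
    max_span_days = max(span)
  )
}
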