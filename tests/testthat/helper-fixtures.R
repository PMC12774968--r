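# hand-enumerable 4-individual fixture on a 2-session x 2-occasion design
# (sessions start 2006-01-01 and 2006-03-01, one occasion per day)
hand_design <- function() {
  rd_design(c("2006-01-01", "2006-03-01"), occasions = 2L)
}

hand_data <- function() {
  ch <- rbind(
    i1 = c(1L, 1L, 0L, 0L),
    i2 = c(1L, 0L, 1L, 0L),
    i3 = c(0L, 0L, 0L, 1L),
    i4 = c(0L, 1L, 0L, 0L))
  mass <- rbind(c(20, NA), c(22, 24.5), c(NA, 30), c(18, NA))
  ind <- tibble::tibble(
    id = rownames(ch),
    sex = c("F", "M", "F", "M"),
    location = "A", plot = "A.control", treatment = "control")
  encounter_data(ind, ch, mass, hand_design())
}

# small well-behaved simulated scenario for module tests
test_scenario <- function(...) {
  d <- rd_design(c("2006-01-01", "2006-03-01", "2006-05-01", "2006-07-01"),
                 occasions = 4L)
  args <- list(design = d, locations = "L1",
               n0 = c(treatment = 120, control = 120), recruits = 15,
               s_monthly = 0.8, p_capture = 0.45, gamma = 0.1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# an intercept-only model structure (for data simulated without covariate
# effects)
null_spec <- function() {
  cmr_spec(surv_terms = character(0), p_terms = character(0),
           enforce_mandatory = FALSE)
}
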