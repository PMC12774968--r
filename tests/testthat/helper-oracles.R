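# Independent likelihood oracles. Both are deliberately written in a
# different style from the package's vectorised forward recursion: the brute
# force enumerates every hidden-state sequence per individual, the CJS
# version runs a two-state (alive/dead) recursion with no emigration state.

# exhaustive enumeration over {available, unavailable, dead} sequences
brute_nll <- function(beta, dm, obs) {
  n <- dm$n
  Tn <- dm$Tn
  bs <- beta[seq_len(dm$k_s)]
  bp <- beta[dm$k_s + seq_len(dm$k_p)]
  gam <- plogis(beta[dm$k])
  p <- plogis(matrix(drop(dm$Xp %*% bp), n, dm$O))
  S <- if (dm$n_int > 0) plogis(matrix(drop(dm$Xs %*% bs), n, dm$n_int))
  osess <- rep(seq_len(Tn), dm$design$occasions)
  total <- 0
  for (i in seq_len(n)) {
    f <- obs$fi[i]
    emitA <- function(t, post_first) {
      occ <- which(osess == t)
      if (post_first) occ <- occ[occ > obs$first_occ[i]]
      if (!length(occ)) return(1)
      prod(ifelse(obs$ch[i, occ] == 1, p[i, occ], 1 - p[i, occ]))
    }
    emit0 <- function(t) as.numeric(obs$sc[i, t] == 0)
    rest <- if (f < Tn) (f + 1):Tn else integer(0)
    grids <- if (length(rest)) {
      expand.grid(rep(list(c("A", "U", "D")), length(rest)),
                  stringsAsFactors = FALSE)
    } else data.frame(row.names = 1)
    lik <- 0
    for (r in seq_len(nrow(grids))) {
      pr <- emitA(f, TRUE)
      st <- "A"
      for (j in seq_along(rest)) {
        t <- rest[j]
        z <- grids[r, j]
        phi <- S[i, t - 1]^(dm$design$interval_days[t - 1] / 30)
        tr <- if (st == "D") {
          if (z == "D") 1 else 0
        } else switch(z, A = phi * (1 - gam), U = phi * gam, D = 1 - phi)
        em <- if (z == "A") emitA(t, FALSE) else emit0(t)
        pr <- pr * tr * em
        st <- z
        if (pr == 0) break
      }
      lik <- lik + pr
    }
    total <- total - log(lik)
  }
  total
}

# two-state CJS-with-binomial-sessions likelihood (no temporary emigration)
cjs_nll <- function(beta, dm, obs) {
  n <- dm$n
  Tn <- dm$Tn
  bs <- beta[seq_len(dm$k_s)]
  bp <- beta[dm$k_s + seq_len(dm$k_p)]
  p <- plogis(matrix(drop(dm$Xp %*% bp), n, dm$O))
  S <- if (dm$n_int > 0) plogis(matrix(drop(dm$Xs %*% bs), n, dm$n_int))
  osess <- rep(seq_len(Tn), dm$design$occasions)
  total <- 0
  for (i in seq_len(n)) {
    f <- obs$fi[i]
    emitA <- function(t, post_first) {
      occ <- which(osess == t)
      if (post_first) occ <- occ[occ > obs$first_occ[i]]
      if (!length(occ)) return(1)
      prod(ifelse(obs$ch[i, occ] == 1, p[i, occ], 1 - p[i, occ]))
    }
    a_alive <- emitA(f, TRUE)
    a_dead <- 0
    if (f < Tn) for (t in (f + 1):Tn) {
      phi <- S[i, t - 1]^(dm$design$interval_days[t - 1] / 30)
      no_cap <- as.numeric(obs$sc[i, t] == 0)
      a_dead <- (a_dead + a_alive * (1 - phi)) * no_cap
      a_alive <- a_alive * phi * emitA(t, FALSE)
    }
    total <- total - log(a_alive + a_dead)
  }
  total
}

# random tiny encounter data set within given bounds (all individuals kept
# capturable: histories redrawn until everyone has a capture)
random_tiny_data <- function(n_max = 4, t_max = 3, occ_max = 3) {
  Tn <- sample(2:t_max, 1)
  occ <- sample(1:occ_max, Tn, replace = TRUE)
  d <- rd_design(as.Date("2006-01-01") +
                   cumsum(c(0, sample(30:70, Tn - 1, replace = TRUE))),
                 occasions = occ)
  n <- sample(1:n_max, 1)
  repeat {
    ch <- matrix(rbinom(n * sum(occ), 1, 0.5), n)
    if (all(rowSums(ch) > 0)) break
  }
  ind <- tibble::tibble(id = paste0("i", seq_len(n)),
                        sex = sample(c("F", "M"), n, replace = TRUE),
                        location = "L1", plot = "L1.control",
                        treatment = "control")
  mass <- matrix(NA_real_, n, Tn)
  sc <- t(vapply(seq_len(n), function(i) {
    tapply(ch[i, ], rep(seq_len(Tn), occ), sum)
  }, numeric(Tn)))
  mass[sc > 0] <- 25
  encounter_data(ind, ch, mass, d)
}

# minimal design+obs bundle for likelihood tests on arbitrary data
tiny_dm_obs <- function(data, surv_terms = "mass", p_terms = "sex") {
  spec <- cmr_spec(surv_terms = surv_terms, p_terms = p_terms,
                   enforce_mandatory = FALSE)
  Tn <- data$design$n_sessions
  imp <- structure(list(mass_hat = matrix(25, nrow(data$ch), Tn)),
                   class = "imputed_mass")
  dm <- build_design(spec, data, imp)
  obs <- voleCMR:::obs_stats(data$ch, data$design)
  list(dm = dm, obs = obs)
}
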