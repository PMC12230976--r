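# Shared fixture builders and independent oracles used across test files.

# Construct an individual_histories object by hand from a persons data frame
# and a residence matrix (columns named by calendar year).
make_histories <- function(persons, residence, years,
                           observed_years = years,
                           death_year_exposure = 0.5) {
  defaults <- data.frame(
    person_id = seq_len(nrow(persons)), sex = "male",
    birth_year = 1950L, birth_region = 1L,
    death_year = NA_integer_, death_age = NA_integer_,
    death_region = NA_integer_, cause = NA_character_,
    true_age_first_migration = NA_integer_, true_age_return = NA_integer_,
    stringsAsFactors = FALSE)
  for (nm in names(persons)) defaults[[nm]] <- persons[[nm]]
  structure(list(persons = defaults,
                 residence = residence,
                 years = as.integer(years),
                 observed_years = as.integer(observed_years),
                 config = list(death_year_exposure = death_year_exposure)),
            class = "individual_histories")
}

# Quick classified-bands frame for exposure-table tests when event ages are
# known exactly: fm_age is the age at first out-migration (movers), ret_age
# the age at final return (returnees).
make_bands <- function(person_id, status, fm_age = NA_real_,
                       ret_age = NA_real_,
                       leaver_breaks = c(17, 30, 60),
                       returnee_breaks = c(30, 60)) {
  cl <- data.frame(person_id = person_id, status = status,
                   stringsAsFactors = FALSE)
  ev <- rbind(
    data.frame(person_id = person_id, event = "first_migration",
               age = fm_age, stringsAsFactors = FALSE),
    data.frame(person_id = person_id, event = "return", age = ret_age,
               stringsAsFactors = FALSE))
  ev <- ev[!is.na(ev$age), ]
  assign_status_bands(cl, ev, leaver_breaks, returnee_breaks)
}

# Independent Newton/Fisher-scoring fit of a negative-binomial GLM with log
# link, fixed theta, and offset — the oracle for the unpenalized GAM limit.
nb_newton_fit <- function(X, y, offset, theta, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(sum(y) / sum(exp(offset)))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)          # Fisher weights for NB log link
    z <- eta - offset + (y - mu) / mu   # working response
    fit <- lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      return(new_beta)
    }
    beta <- new_beta
  }
  warning("nb_newton_fit did not converge")
  beta
}

# Exhaustive stepwise-replacement decomposition: average, over all orderings
# of the cells, of the change in the functional when each cell is switched
# from A to B. The independent oracle for the line-integral decomposition.
stepwise_replacement_decomposition <- function(rates_A, rates_B, functional) {
  cells <- which(!is.na(rates_A), arr.ind = TRUE)
  ncell <- nrow(cells)
  orders <- perms(ncell)
  C <- matrix(0, nrow(rates_A), ncol(rates_A), dimnames = dimnames(rates_A))
  for (o in seq_len(nrow(orders))) {
    R <- rates_A
    f_prev <- functional(rowSums(R))
    for (j in orders[o, ]) {
      R[cells[j, 1], cells[j, 2]] <- rates_B[cells[j, 1], cells[j, 2]]
      f_new <- functional(rowSums(R))
      C[cells[j, 1], cells[j, 2]] <-
        C[cells[j, 1], cells[j, 2]] + (f_new - f_prev) / nrow(orders)
      f_prev <- f_new
    }
  }
  C
}

perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Temporary expectancy from a life table built on an arbitrary grid --
# thin wrapper used by decomposition tests.
tle <- function(age_lower, width, nax = width / 2) {
  force(age_lower); force(width); force(nax)
  n <- if (length(width) == 1) rep(width, length(age_lower)) else width
  a <- if (length(nax) == 1) rep(nax, length(age_lower)) else nax
  function(mx) {
    qx <- pmin(n * mx / (1 + (n - a) * mx), 1)
    lx <- c(1, cumprod(1 - qx))
    dx <- lx[-length(lx)] * qx
    sum(n * lx[-length(lx)] - (n - a) * dx)
  }
}
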