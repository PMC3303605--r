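# Shared fixture builders: everything is generated in code, no data files.

# a minimal person tibble with full control over the matching-relevant fields
make_persons <- function(age, sex = "male", employment_status = "employee",
                         marital_status = "married", household_id = NULL,
                         weight = 1, living_resource = NA_character_) {
  n <- length(age)
  tibble::tibble(
    person_id = sprintf("P%04d", seq_len(n)),
    household_id = household_id %||% sprintf("H%04d", seq_len(n)),
    sex = rep_len(sex, n),
    age = as.integer(age),
    residential_status = "urban",
    nationality = "Han",
    education = ifelse(age < 6, "under 6", "primary"),
    employment_status = rep_len(employment_status, n),
    marital_status = rep_len(marital_status, n),
    living_resource = rep_len(living_resource, n),
    student = FALSE,
    disabled = FALSE,
    weight = rep_len(weight, n)
  )
}

make_insured <- function(age, sex = "male", employment_status = "employee",
                         marital_status = "married", monthly_income = 1000,
                         stratum = "municipal") {
  n <- length(age)
  tibble::tibble(
    record_id = sprintf("I%04d", seq_len(n)),
    person_id = sprintf("S%04d", seq_len(n)),
    stratum = rep_len(stratum, n),
    sex = rep_len(sex, n),
    age = as.integer(age),
    employment_status = rep_len(employment_status, n),
    marital_status = rep_len(marital_status, n),
    monthly_income = rep_len(monthly_income, n),
    low_income_flag = FALSE
  )
}

`%||%` <- rlang::`%||%`

# chi-square calibration objective
cal_objective <- function(w, d) sum(d * (w / d - 1)^2)

# independent minimum-norm solution of the calibration problem:
# minimise sum(d * (w/d - 1)^2) s.t. t(X) %*% w = targets.
# Substituting u = (w - d) / sqrt(d) gives the minimum-norm solution of the
# underdetermined system t(sqrt(d) * X) %*% u = targets - t(X) %*% d, computed
# here via the Moore-Penrose pseudoinverse (SVD), a different numerical route
# from the solver's normal equations.
greg_oracle <- function(d, x, targets) {
  m <- t(x * sqrt(d))
  r <- targets - as.vector(crossprod(x, d))
  u <- as.vector(MASS::ginv(m) %*% r)
  d + sqrt(d) * u
}

# total |age difference| of the best pairing, by exhaustive enumeration
best_pairing_total <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  min(vapply(perms(seq_along(b)), function(p) sum(abs(a - b[p])), numeric(1)))
}
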