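ARMS <- c("A", "B", "AB")

#' Empty per-arm sufficient statistics
#'
#' Cumulative enrolment and response counts per arm: the sufficient statistics
#' of the binomial likelihood at an interim look.
#'
#' @return A tibble with columns `arm` (`"A"`, `"B"`, `"AB"`), `n_enrolled`,
#'   `n_responses`.
#' @export
arm_counts <- function() {
  tibble(arm = ARMS, n_enrolled = 0L, n_responses = 0L)
}

as_counts_vectors <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("arm", "n_enrolled", "n_responses") %in% names(counts)))
  idx <- match(ARMS, counts$arm)
  if (anyNA(idx)) abort("`counts` must contain rows for arms A, B and AB.")
  n <- as.numeric(counts$n_enrolled[idx])
  y <- as.numeric(counts$n_responses[idx])
  if (any(y < 0) || any(y > n)) abort("responses must satisfy 0 <= y <= n per arm.")
  list(n = setNames(n, ARMS), y = setNames(y, ARMS))
}

#' Randomly assign patients to arms
#'
#' Each patient is independently assigned to one arm by a multinomial draw
#' from the current allocation probabilities (dropped arms carry probability
#' zero).
#'
#' @param n Number of patients to assign.
#' @param allocation Numeric vector of length 3 (order A, B, AB),
#'   non-negative, summing to 1 within 1e-12.
#' @return Character vector of arm labels of length `n`.
#' @export
assign_arm <- function(n, allocation) {
  stopifnot(length(allocation) == 3, all(is.finite(allocation)))
  if (any(allocation < 0)) abort("allocation probabilities must be non-negative.")
  if (all(allocation == 0)) abort("allocation must have at least one positive entry.")
  if (abs(sum(allocation) - 1) > 1e-12) {
    abort("allocation must sum to 1 (within 1e-12).")
  }
  if (n == 0) return(character(0))
  ARMS[sample.int(3L, n, replace = TRUE, prob = allocation)]
}

#' Simulate patient outcomes with a prognostic-imbalance offset
#'
#' For each patient on an arm with true log-odds `theta`, a per-patient offset
#' `epsilon ~ N(0, sigma2)` is added on the log-odds scale and the binary
#' response is drawn as `Bernoulli(expit(theta + epsilon))`. The offset
#' injects extra-binomial variability mimicking prognostic imbalance at small
#' sample sizes; the analysis models deliberately ignore it.
#'
#' @param theta Log-odds of response, recycled against `n`.
#' @param sigma2 Offset variance (>= 0).
#' @param n Number of patients.
#' @return A tibble with columns `epsilon` and `response`.
#' @export
simulate_outcome <- function(theta, sigma2, n = length(theta)) {
  if (sigma2 < 0) abort("`sigma2` must be non-negative.")
  eps <- if (sigma2 > 0) rnorm(n, 0, sqrt(sigma2)) else numeric(n)
  theta <- rep_len(theta, n)
  tibble(epsilon = eps, response = rbinom(n, 1L, plogis(theta + eps)))
}

#' Simulate an enrolment batch
#'
#' Allocates `n_patients` to arms by independent multinomial draws, simulates
#' each outcome under the arm's true effect (the combination arm uses the
#' fractional-additivity-derived `theta_AB`), and updates the cumulative
#' per-arm counts.
#'
#' @param n_patients Number of patients to enrol (>= 0).
#' @param allocation Length-3 allocation probabilities (A, B, AB).
#' @param truth An `fa_truth` from [scenario_truth()].
#' @param counts Cumulative counts tibble to update; defaults to fresh counts.
#' @return A list with `patients` (tibble: `patient`, `arm`, `epsilon`,
#'   `response`) and `counts` (updated cumulative tibble).
#' @export
simulate_batch <- function(n_patients, allocation, truth, counts = arm_counts()) {
  stopifnot(inherits(truth, "fa_truth"), n_patients >= 0)
  start <- sum(counts$n_enrolled)
  if (n_patients == 0) {
    return(list(
      patients = tibble(patient = integer(0), arm = character(0),
                        epsilon = numeric(0), response = integer(0)),
      counts = counts
    ))
  }
  arms <- assign_arm(n_patients, allocation)
  theta <- c(A = truth$theta_A, B = truth$theta_B, AB = truth$theta_AB)[arms]
  out <- simulate_outcome(unname(theta), truth$sigma2, n_patients)
  patients <- tibble(
    patient = start + seq_len(n_patients),
    arm = arms,
    epsilon = out$epsilon,
    response = out$response
  )
  add_n <- tabulate(match(arms, ARMS), 3L)
  add_y <- vapply(ARMS, function(a) sum(out$response[arms == a]), numeric(1))
  idx <- match(ARMS, counts$arm)
  counts$n_enrolled[idx] <- counts$n_enrolled[idx] + add_n
  counts$n_responses[idx] <- counts$n_responses[idx] + as.integer(add_y)
  list(patients = patients, counts = counts)
}
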