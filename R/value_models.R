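# Static valuation: utility curvature, probability weighting, Luce choice
# rule, benchmark heuristics, and gaze-regression values.

#' Power utility for gains
#'
#' `u(x) = x^alpha`. The design is gains-only, so nonpositive amounts are an
#' error.
#'
#' @param x monetary amount(s), strictly positive.
#' @param alpha curvature parameter (> 0); `alpha < 1` is risk-averse.
#' @export
utility <- function(x, alpha) {
  if (any(x <= 0)) stop("amounts must be positive (gains-only design)",
                        call. = FALSE)
  .assert_number(alpha, "alpha", lower = 1e-8)
  x^alpha
}

#' Probability weighting function
#'
#' The one-parameter inverse-S weighting
#' `pi(p) = p^gamma / (p^gamma + (1-p)^gamma)^(1/gamma)`; `gamma = 1` is the
#' identity, `gamma < 1` overweights small probabilities.
#'
#' @param p win probability in (0, 1].
#' @param gamma curvature parameter (> 0).
#' @export
prob_weight <- function(p, gamma) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  .assert_number(gamma, "gamma", lower = 1e-8)
  pg <- p^gamma
  pg / (pg + (1 - p)^gamma)^(1 / gamma)
}

#' Subjective utility of a simple lottery
#'
#' `"ev"`: `x * p`; `"eu"`: `x^alpha * p`; `"cpt"`: `x^alpha * pi(p)`.
#'
#' @param x,p lottery attributes.
#' @param model one of `"ev"`, `"eu"`, `"cpt"`.
#' @param alpha,gamma curvature parameters (used as the model requires).
#' @export
subjective_utility <- function(x, p, model = c("cpt", "ev", "eu"),
                               alpha = 1, gamma = 1) {
  model <- match.arg(model)
  switch(model,
         ev = x * p,
         eu = utility(x, alpha) * p,
         cpt = utility(x, alpha) * prob_weight(p, gamma))
}

#' Exponential Luce choice rule
#'
#' `P(choose 1) = 1 / (1 + exp(-beta * (u1 - u2)))`.
#'
#' @param u1,u2 option utilities.
#' @param beta sensitivity (>= 0); `beta = 0` gives indifference.
#' @export
luce_prob <- function(u1, u2, beta) {
  .assert_number(beta, "beta", lower = 0)
  stats::plogis(beta * (u1 - u2))
}

#' Heuristic choice rules
#'
#' Deterministic benchmark heuristics for simple gain lotteries
#' `(x, p; 0, 1 - p)`:
#' * `maximax` — choose the option with the larger maximum amount;
#' * `least_likely` — choose the option with the lower probability of its
#'   worst outcome (the worst outcome is 0 with probability `1 - p`, or `x`
#'   itself when `p = 1`);
#' * `priority` — compare minimum amounts, then probabilities of the minimum
#'   amounts, then maximum amounts, stopping as soon as the difference exceeds
#'   the termination criterion (one tenth of the largest maximum amount for
#'   amounts; .1 for probabilities).
#'
#' @param problems data.frame with `x_a`, `p_a`, `x_b`, `p_b`.
#' @param heuristic rule name.
#' @return character vector `"A"`, `"B"` or `"indifferent"`.
#' @export
heuristic_choice <- function(problems,
                             heuristic = c("maximax", "least_likely",
                                           "priority")) {
  heuristic <- match.arg(heuristic)
  x_a <- problems$x_a; p_a <- problems$p_a
  x_b <- problems$x_b; p_b <- problems$p_b
  pick <- function(a_better, b_better)
    ifelse(a_better, "A", ifelse(b_better, "B", "indifferent"))
  if (heuristic == "maximax")
    return(pick(x_a > x_b, x_b > x_a))
  # worst outcome: 0 w.p. 1-p when p < 1, else the sure amount x w.p. 1
  p_worst_a <- ifelse(p_a < 1, 1 - p_a, 1)
  p_worst_b <- ifelse(p_b < 1, 1 - p_b, 1)
  if (heuristic == "least_likely")
    return(pick(p_worst_a < p_worst_b, p_worst_b < p_worst_a))
  # priority heuristic
  min_a <- ifelse(p_a < 1, 0, x_a)
  min_b <- ifelse(p_b < 1, 0, x_b)
  amount_crit <- 0.1 * pmax(x_a, x_b)
  out <- rep(NA_character_, length(x_a))
  d1 <- min_a - min_b
  out[abs(d1) >= amount_crit] <-
    ifelse(d1[abs(d1) >= amount_crit] > 0, "A", "B")
  # probability of the minimum amount; lower is better
  pm_a <- ifelse(p_a < 1, 1 - p_a, 1)
  pm_b <- ifelse(p_b < 1, 1 - p_b, 1)
  d2 <- pm_a - pm_b
  todo <- is.na(out) & abs(d2) >= 0.1
  out[todo] <- ifelse(d2[todo] < 0, "A", "B")
  todo <- is.na(out)
  out[todo] <- pick(x_a > x_b, x_b > x_a)[todo]
  out
}

#' Gaze-regression value of an option
#'
#' The static subjective utility of an option scaled by a saturating power of
#' its gaze: `U = SU * gaze^tau`, where `gaze` is the option's fixation count
#' (`mode = "fixations"`) or total dwell in seconds (`mode = "dwell"`).
#' `tau < 1` means looking twice as long less than doubles the value. Zero
#' gaze is floored at `eps` so values stay positive (preprocessing guarantees
#' every attribute is fixated in real data).
#'
#' @param x,p lottery attributes.
#' @param gaze nonnegative fixation count or dwell seconds for the option.
#' @param base `"eu"` or `"cpt"` base utility.
#' @param alpha,gamma,tau parameters.
#' @param eps floor for zero gaze.
#' @export
fixation_regression_value <- function(x, p, gaze, base = c("eu", "cpt"),
                                      alpha = 1, gamma = 1, tau = 1,
                                      eps = 1e-3) {
  base <- match.arg(base)
  if (any(gaze < 0)) stop("gaze must be nonnegative", call. = FALSE)
  su <- subjective_utility(x, p, model = base, alpha = alpha, gamma = gamma)
  su * pmax(gaze, eps)^tau
}
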