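# Synthetic experiments: Markov gaze sequences over the four attribute AOIs,
# heterogeneous simulated participants, and complete datasets in the
# empirical CSV schema. Ground truth travels alongside the data and is never
# read by fitting code.

#' Gaze-model parameters
#'
#' A first-order Markov model over the four AOIs with no immediate repeats.
#' From a given AOI the three possible moves are one within-alternative, one
#' within-attribute and one diagonal transition; their base weights are
#' `trans_weights`. Candidate AOIs are additionally tilted (log-linearly) by
#' an amount-vs-probability bias, biases towards the higher of the two
#' amounts / probabilities, and a small value-dependence term that makes an
#' amount more likely to be fixated the larger its own win probability.
#' Fixation counts are negative binomial (truncated at `n_min`); durations
#' are log-normal.
#'
#' Defaults emulate the descriptives of the emulated experiment: about 9.05
#' fixations per trial (SD 3.56) of mean duration 407 ms (SD 244 ms), and
#' within-alternative > within-attribute > diagonal transition frequencies.
#'
#' @param trans_weights named weights for `alt`, `attr`, `diag` transitions.
#' @param first_fix first-fixation distribution over the four AOIs.
#' @param amount_bias log-tilt towards amount AOIs (0 = balanced).
#' @param higher_amount_bias log-tilt towards the higher of the two amounts.
#' @param higher_prob_bias log-tilt towards the higher of the two
#'   probabilities.
#' @param value_dep value-dependence coefficient (the amount of option i is
#'   tilted by `exp(value_dep * (p_i - mean(p)))`); small by design.
#' @param novelty_bonus log-tilt towards AOIs not yet visited in the trial;
#'   emulates the early systematic scan of all four attributes. The default
#'   (1.3) reproduces the ~4% rate of trials failing the all-AOI coverage
#'   rule seen in the emulated experiment.
#' @param ior inhibition-of-return: log-penalty on the AOI fixated two steps
#'   back. Prevents unrealistic two-AOI bouncing, so a within-alternative
#'   scanner visits one option's amount-probability pair and then the
#'   other's, as in empirical scanpaths.
#' @param n_mean,n_sd fixation-count mean and SD (negative binomial).
#' @param n_min minimum fixations per trial (4 allows full AOI coverage).
#' @param dur_meanlog,dur_sdlog log-normal duration parameters (ms).
#' @return object of class `gaze_params`.
#' @export
gaze_params <- function(trans_weights = c(alt = 0.50, attr = 0.32,
                                          diag = 0.18),
                        first_fix = c(0.4, 0.2, 0.25, 0.15),
                        amount_bias = 0, higher_amount_bias = 0,
                        higher_prob_bias = 0, value_dep = 0.05,
                        novelty_bonus = 1.3, ior = 1,
                        n_mean = 9.05, n_sd = 3.56, n_min = 4L,
                        dur_meanlog = 5.8553, dur_sdlog = 0.5540) {
  stopifnot(length(trans_weights) == 3L, all(trans_weights > 0),
            length(first_fix) == 4L, all(first_fix > 0),
            n_sd^2 > n_mean, n_min >= 1L)
  structure(list(trans_weights = trans_weights / sum(trans_weights),
                 first_fix = first_fix / sum(first_fix),
                 amount_bias = amount_bias,
                 higher_amount_bias = higher_amount_bias,
                 higher_prob_bias = higher_prob_bias,
                 value_dep = value_dep, novelty_bonus = novelty_bonus,
                 ior = ior, n_mean = n_mean, n_sd = n_sd, n_min = as.integer(n_min),
                 dur_meanlog = dur_meanlog, dur_sdlog = dur_sdlog),
            class = "gaze_params")
}

# Log-tilts of the four AOIs for one problem.
.aoi_tilts <- function(gp, problem) {
  lt <- numeric(4L)
  lt[c(1L, 3L)] <- lt[c(1L, 3L)] + gp$amount_bias
  if (problem$x_a != problem$x_b) {
    hi <- if (problem$x_a > problem$x_b) 1L else 3L
    lo <- if (hi == 1L) 3L else 1L
    lt[hi] <- lt[hi] + gp$higher_amount_bias / 2
    lt[lo] <- lt[lo] - gp$higher_amount_bias / 2
  }
  if (problem$p_a != problem$p_b) {
    hi <- if (problem$p_a > problem$p_b) 2L else 4L
    lo <- if (hi == 2L) 4L else 2L
    lt[hi] <- lt[hi] + gp$higher_prob_bias / 2
    lt[lo] <- lt[lo] - gp$higher_prob_bias / 2
  }
  pbar <- (problem$p_a + problem$p_b) / 2
  lt[1L] <- lt[1L] + gp$value_dep * (problem$p_a - pbar)
  lt[3L] <- lt[3L] + gp$value_dep * (problem$p_b - pbar)
  lt
}

# One Markov step (or the first fixation when prev is NA). `visited` marks
# AOIs already fixated this trial (novelty bonus applies to the others);
# `prev2` is the AOI two steps back (inhibition of return).
.sample_next_aoi <- function(prev, gp, problem,
                             visited = rep(TRUE, 4L), prev2 = NA_integer_) {
  lt <- .aoi_tilts(gp, problem) + gp$novelty_bonus * !visited
  if (!is.na(prev2)) lt[prev2] <- lt[prev2] - (gp$ior %||% 0)
  tilt <- exp(lt)
  if (is.na(prev)) {
    w <- gp$first_fix * tilt
    return(sample.int(4L, 1L, prob = w))
  }
  cand <- c(c(2L, 1L, 4L, 3L)[prev], .aoi_partner[prev],
            c(4L, 3L, 2L, 1L)[prev])          # alt, attr, diag neighbors
  w <- gp$trans_weights * tilt[cand]
  cand[sample.int(3L, 1L, prob = w)]
}

#' Sample a fixation sequence for one problem
#'
#' @param problem one-row data.frame with `x_a`, `p_a`, `x_b`, `p_b`.
#' @param gp a [gaze_params()].
#' @param n_fixations fixed length, or `NULL` to draw from the count
#'   distribution.
#' @return data.frame with `aoi`, `onset_ms`, `duration_ms`.
#' @export
sample_gaze_sequence <- function(problem, gp = gaze_params(),
                                 n_fixations = NULL) {
  if (is.null(n_fixations)) {
    size <- gp$n_mean^2 / (gp$n_sd^2 - gp$n_mean)
    repeat {
      n_fixations <- stats::rnbinom(1L, size = size, mu = gp$n_mean)
      if (n_fixations >= gp$n_min) break
    }
  }
  aoi <- integer(n_fixations)
  prev <- prev2 <- NA_integer_
  visited <- rep(FALSE, 4L)
  for (t in seq_len(n_fixations)) {
    nxt <- .sample_next_aoi(prev, gp, problem, visited, prev2)
    visited[nxt] <- TRUE
    prev2 <- prev
    prev <- nxt
    aoi[t] <- nxt
  }
  dur <- stats::rlnorm(n_fixations, gp$dur_meanlog, gp$dur_sdlog)
  data.frame(aoi = .aoi_label(aoi),
             onset_ms = cumsum(c(0, dur[-n_fixations])),
             duration_ms = dur, stringsAsFactors = FALSE)
}

#' Population configuration for simulated participants
#'
#' Uniform ranges for the process parameters and the heterogeneous gaze
#' biases. Process ranges sit in the interior of the fitting bounds and are
#' centered near the group-level values reported for this paradigm (notably
#' substantial leak); gaze-bias ranges are wide enough to induce the
#' individual differences the behavioral analyses target.
#'
#' @param alpha,gamma,theta,lam,beta,iota `c(lo, hi)` ranges for the process
#'   parameters.
#' @param alt_weight range of the within-alternative transition weight (the
#'   remainder is split 2:1 between within-attribute and diagonal).
#' @param amount_bias,higher_amount_bias,higher_prob_bias gaze-bias ranges.
#' @param value_dep fixed value-dependence coefficient.
#' @param systematicity_rho coupling in \[0, 1\] between a participant's
#'   within-alternative scanning weight and their choice-quality traits
#'   (attentional attenuation `theta` and sensitivity `beta`). Participants
#'   in this paradigm who organize their scanpaths by alternative also choose
#'   more in line with expected value; the accumulator itself does not
#'   generate that covariation from the scanpath, so the population model
#'   encodes it as a latent trait (0 = independent draws).
#' @param risk_orientation_rho coupling in \[0, 1\] between a participant's
#'   gaze bias towards the higher amount (and away from the higher
#'   probability) and their utility curvature `alpha`. The attentional
#'   channel already makes amount-biased gaze favor risky choices causally;
#'   this latent trait adds the preference-attention covariation seen in
#'   individual-difference data (0 = independent draws).
#' @return object of class `population_config`.
#' @export
population_config <- function(alpha = c(0.4, 1.2), gamma = c(0.4, 1.2),
                              theta = c(0.1, 0.9), lam = c(0.3, 0.9),
                              beta = c(0.3, 1.5), iota = c(0, 0),
                              alt_weight = c(0.35, 0.65),
                              amount_bias = c(-1, 1),
                              higher_amount_bias = c(-2, 2),
                              higher_prob_bias = c(-2, 2),
                              value_dep = 0.05,
                              systematicity_rho = 0.8,
                              risk_orientation_rho = 0.6) {
  structure(list(alpha = alpha, gamma = gamma, theta = theta, lam = lam,
                 beta = beta, iota = iota, alt_weight = alt_weight,
                 amount_bias = amount_bias,
                 higher_amount_bias = higher_amount_bias,
                 higher_prob_bias = higher_prob_bias,
                 value_dep = value_dep,
                 systematicity_rho = systematicity_rho,
                 risk_orientation_rho = risk_orientation_rho),
            class = "population_config")
}

.runif_range <- function(r) stats::runif(1L, r[1L], r[2L])

# n process-parameter draws as a data.frame (uses the current RNG stream).
.draw_process_params <- function(n, pop) {
  data.frame(alpha = stats::runif(n, pop$alpha[1L], pop$alpha[2L]),
             gamma = stats::runif(n, pop$gamma[1L], pop$gamma[2L]),
             theta = stats::runif(n, pop$theta[1L], pop$theta[2L]),
             lam = stats::runif(n, pop$lam[1L], pop$lam[2L]),
             beta = stats::runif(n, pop$beta[1L], pop$beta[2L]),
             iota = stats::runif(n, pop$iota[1L], pop$iota[2L]))
}

#' Sample a simulated participant
#'
#' Independent draws of process parameters and gaze-model biases from the
#' population ranges.
#'
#' @param pop a [population_config()].
#' @param id participant id.
#' @param variant generating accumulator variant.
#' @return list of class `sim_participant` with `id`, `variant`, `process`
#'   ([process_params()]) and `gaze` ([gaze_params()]).
#' @export
sample_participant <- function(pop = population_config(), id = "S01",
                               variant = "two_layer") {
  pr <- .draw_process_params(1L, pop)
  # latent systematicity trait: couples organized (within-alternative)
  # scanning with attentional evenness (theta) and choice sensitivity (beta)
  u <- stats::runif(1L)
  rho <- pop$systematicity_rho %||% 0
  w_alt <- pop$alt_weight[1L] + u * diff(pop$alt_weight)
  mix <- function(range, lat, r) {
    v <- r * lat + (1 - r) * stats::runif(1L)
    range[1L] + v * diff(range)
  }
  pr$theta <- mix(pop$theta, u, rho)
  pr$beta <- mix(pop$beta, u, rho)
  # second latent: risk orientation couples amount-directed gaze with
  # utility curvature
  u2 <- stats::runif(1L)
  rho2 <- pop$risk_orientation_rho %||% 0
  pr$alpha <- mix(pop$alpha, u2, rho2)
  hab <- mix(pop$higher_amount_bias, u2, rho2)
  hpb <- mix(rev(pop$higher_prob_bias), u2, rho2)  # reversed: negative link
  gp <- gaze_params(
    trans_weights = c(alt = w_alt, attr = 2 * (1 - w_alt) / 3,
                      diag = (1 - w_alt) / 3),
    amount_bias = .runif_range(pop$amount_bias),
    higher_amount_bias = hab,
    higher_prob_bias = hpb,
    value_dep = pop$value_dep)
  structure(list(id = id, variant = variant,
                 process = process_params(alpha = pr$alpha, gamma = pr$gamma,
                                          theta = pr$theta, lam = pr$lam,
                                          beta = pr$beta, iota = pr$iota),
                 gaze = gp),
            class = "sim_participant")
}

#' Simulate a complete experiment
#'
#' For every participant x problem: sample a fixation sequence from the
#' participant's gaze model and generate the choice from the participant's
#' accumulator. In `"step1"` mode the accumulator runs noise-free to the end
#' of the sequence and the choice is sampled from the Luce rule on the final
#' preferences; in `"step2"` mode the accumulator runs with noise
#' (`sigma = 1`) to a boundary crossing, which yields both the choice and the
#' decision time in fixations.
#'
#' @param design a [design_config()].
#' @param n_participants number of participants to draw (ignored when
#'   `participants` given).
#' @param variant generating accumulator variant.
#' @param mode `"step1"` or `"step2"`.
#' @param population a [population_config()].
#' @param participants optional list of [sample_participant()] objects.
#' @param process_override optional [process_params()] forced on every
#'   participant (used by the recovery harness).
#' @param problems optional problem table (defaults to
#'   [enumerate_problems()], trade-off plus catch trials).
#' @param bp [boundary_params()] for `"step2"` mode.
#' @param cap step cap for `"step2"` mode.
#' @param seed master seed; every stream is derived from it.
#' @return object of class `gr_dataset`: `problems`, `trials`, `fixations`,
#'   `truth` (generating parameters; not used by any fitting path).
#' @export
simulate_experiment <- function(design = design_config(),
                                n_participants = 31L,
                                variant = "two_layer",
                                mode = c("step1", "step2"),
                                population = population_config(),
                                participants = NULL,
                                process_override = NULL,
                                problems = NULL,
                                bp = NULL, cap = 100L, seed = 1L) {
  mode <- match.arg(mode)
  variant <- match.arg(variant, .variants)
  if (mode == "step2" && is.null(bp))
    stop("step2 mode requires boundary parameters", call. = FALSE)
  if (is.null(problems))
    problems <- enumerate_problems(design, seed = .subseed(seed, 2L))
  if (is.null(participants)) {
    participants <- with_seed(.subseed(seed, 3L),
      lapply(seq_len(n_participants), function(i)
        sample_participant(population, id = sprintf("S%02d", i),
                           variant = variant)))
  }
  trials <- list(); fixl <- list()
  for (s in seq_along(participants)) {
    pt <- participants[[s]]
    pp <- process_override %||% pt$process
    if (mode == "step2") pp$sigma <- 1
    with_seed(.subseed(seed, 100L + s), {
      for (j in seq_len(nrow(problems))) {
        pr <- problems[j, ]
        trial_id <- sprintf("%s_%03d", pt$id, j)
        if (mode == "step1") {
          fx <- sample_gaze_sequence(pr, pt$gaze)
          run <- run_sequence(pr, fx$aoi, pp, variant, design)
          p_a <- choice_prob_from_final(run$Y["A"], run$Y["B"], pp$beta)
          choice <- if (stats::runif(1L) < p_a) "A" else "B"
        } else {
          # simulate_to_termination manages its own RNG; hand it a subseed
          # drawn from this participant's stream
          term <- simulate_to_termination(
            pr, pp, variant, bp, fixation_source = pt$gaze, cap = cap,
            seed = sample.int(2147483646L, 1L), design = design)
          dur <- stats::rlnorm(term$n_fixations, pt$gaze$dur_meanlog,
                               pt$gaze$dur_sdlog)
          fx <- data.frame(aoi = term$aoi,
                           onset_ms = cumsum(c(0, dur[-length(dur)])),
                           duration_ms = dur, stringsAsFactors = FALSE)
          choice <- term$choice
        }
        trials[[length(trials) + 1L]] <- data.frame(
          participant_id = pt$id, trial_id = trial_id,
          problem_id = pr$problem_id, choice = choice,
          rt_ms = sum(fx$duration_ms), stringsAsFactors = FALSE)
        fixl[[length(fixl) + 1L]] <- cbind(
          data.frame(participant_id = pt$id, trial_id = trial_id,
                     stringsAsFactors = FALSE), fx)
      }
    })
  }
  structure(list(problems = problems,
                 trials = do.call(rbind, trials),
                 fixations = do.call(rbind, fixl),
                 truth = list(variant = variant, mode = mode, seed = seed,
                              participants = participants)),
            class = "gr_dataset")
}

#' @export
print.gr_dataset <- function(x, ...) {
  cat("Synthetic risky-choice dataset:",
      length(unique(x$trials$participant_id)), "participants x",
      nrow(x$problems), "problems (", x$truth$variant, ",", x$truth$mode,
      ")\n")
  invisible(x)
}
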