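# Descriptive and model-free analyses of choices and eye movements, plus
# model-based normativity comparisons.

# Merge trials with problem attributes; returns trials + x_a..p_b, delta_ev.
.merge_problems <- function(trials, problems) {
  m <- match(trials$problem_id, problems$problem_id)
  if (anyNA(m)) stop("trial references unknown problem_id", call. = FALSE)
  out <- cbind(trials,
               problems[m, c("x_a", "p_a", "x_b", "p_b", "relation",
                             "is_catch")])
  out$delta_ev <- delta_ev(out)
  rownames(out) <- NULL
  out
}

#' EV psychometrics for one participant
#'
#' Logistic slope of choosing option A on the EV difference, and the Pearson
#' correlation between response time and |EV difference| at the problem level
#' (problem-mean RTs).
#'
#' @param trials trial data.frame for one participant.
#' @param problems problem table.
#' @return list with `slope` (logistic coefficient on delta EV), `separated`
#'   (TRUE when choices are perfectly EV-ordered so the MLE diverges) and
#'   `rt_correlation`.
#' @export
ev_psychometrics <- function(trials, problems) {
  tr <- .merge_problems(trials, problems)
  tr <- tr[!tr$is_catch, , drop = FALSE]
  if (nrow(tr) < 10L) stop("need >= 10 trials", call. = FALSE)
  y <- as.integer(tr$choice == "A")
  separated <- FALSE
  slope <- NA_real_
  if (length(unique(y)) < 2L) {
    separated <- TRUE
  } else {
    fit <- suppressWarnings(stats::glm(y ~ tr$delta_ev, family =
                                         stats::binomial()))
    slope <- unname(stats::coef(fit)[2L])
    # fitted probabilities pinned at 0/1 indicate separation
    separated <- any(fit$fitted.values > 1 - 1e-8 & y == 1L) &&
      any(fit$fitted.values < 1e-8 & y == 0L) &&
      all((fit$fitted.values > 0.5) == (y == 1L))
  }
  agg_rt <- tapply(tr$rt_ms, tr$problem_id, mean)
  agg_dev <- tapply(abs(tr$delta_ev), tr$problem_id, mean)
  rt_cor <- if (stats::sd(agg_rt) == 0 || stats::sd(agg_dev) == 0) 0
            else stats::cor(agg_rt, agg_dev)
  list(slope = slope, separated = separated, rt_correlation = rt_cor)
}

#' Risky-choice fractions by probability domain
#'
#' Restricts to trade-off trials with |EV difference| at most `ev_window`
#' (default 1 ILS) and reports the fraction of choices of the riskier
#' (higher-amount) option, split into the low-probability domain (either
#' lottery has p < .25) and the medium/high domain.
#'
#' @param trials trial data.frame for one participant.
#' @param problems problem table.
#' @param ev_window half-width of the |EV difference| window.
#' @param cutoff probability-domain boundary.
#' @return named vector `low`, `medium_high`, `overall` (NA where no trials).
#' @export
risk_preference <- function(trials, problems, ev_window = 1,
                            cutoff = 0.25) {
  tr <- .merge_problems(trials, problems)
  tr <- tr[tr$relation == "tradeoff" & abs(tr$delta_ev) <= ev_window, ,
           drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials inside the EV window", call. = FALSE)
  rc <- risk_classification(tr, cutoff = cutoff)
  risky <- tr$choice == rc$riskier
  frac <- function(sel) if (any(sel)) mean(risky[sel]) else NA_real_
  c(low = frac(rc$probability_domain == "low"),
    medium_high = frac(rc$probability_domain == "medium_high"),
    overall = mean(risky))
}

#' Gaze-advantage effect on choice, corrected for value
#'
#' Residualizes choices against an expected-utility fit and contrasts the
#' mean residual between trials with a positive versus a negative final gaze
#' advantage for option A (fixation-count or dwell-time mode). Choices driven
#' only by EU give a difference near zero; gaze-weighted choices give a
#' positive difference.
#'
#' @param fd a [prepare_participant()] dataset.
#' @param eu_fit a `gr_fit` of model `"eu"` for the same participant.
#' @param mode `"count"` or `"dwell"`.
#' @param design design configuration.
#' @return the mean-residual difference (positive = gaze advantage predicts
#'   choice beyond EU), or NA (flagged by attribute) when one side is empty.
#' @export
gaze_advantage_residual <- function(fd, eu_fit, mode = c("count", "dwell"),
                                    design = design_config()) {
  mode <- match.arg(mode)
  p_a <- .choice_prob("eu", eu_fit$params, fd, design)
  resid <- as.integer(fd$choice == 1L) - p_a
  adv <- if (mode == "count") fd$count_opt[, 1L] - fd$count_opt[, 2L]
         else fd$dwell_opt[, 1L] - fd$dwell_opt[, 2L]
  pos <- adv > 0; neg <- adv < 0
  if (!any(pos) || !any(neg)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(resid[pos]) - mean(resid[neg])
}

#' Recency curve
#'
#' For backward positions 1..`k_last` from the end of the fixation sequence,
#' the fraction of trials whose fixation at that position was on the chosen
#' option. Only trials with at least `k_last` fixations enter.
#'
#' @param fd a [prepare_participant()] dataset.
#' @param k_last number of final fixations to examine (default 4).
#' @return numeric vector indexed by backward position (1 = final fixation).
#' @export
recency_curve <- function(fd, k_last = 4L) {
  keep <- fd$nfix >= k_last
  if (!any(keep)) stop("no trials with enough fixations", call. = FALSE)
  aoi <- fd$aoi[keep, , drop = FALSE]
  nf <- fd$nfix[keep]
  ch <- fd$choice[keep]
  out <- numeric(k_last)
  for (pos in seq_len(k_last)) {
    a <- aoi[cbind(seq_along(nf), nf - pos + 1L)]
    opt <- ifelse(a <= 2L, 1L, 2L)
    out[pos] <- mean(opt == ch)
  }
  names(out) <- paste0("back", seq_len(k_last))
  out
}

#' Fraction of transitivity violations
#'
#' Over all lottery triplets whose three pairwise problems are present in the
#' choice table, the fraction forming a strict preference cycle.
#'
#' @param choices data.frame with `x_a`, `p_a`, `x_b`, `p_b`, `choice`
#'   (`"A"`/`"B"`), one row per problem.
#' @return fraction of cyclic triplets; NA (flagged) when no complete triplet
#'   exists.
#' @export
transitivity_violations <- function(choices) {
  lot <- unique(rbind(
    data.frame(x = choices$x_a, p = choices$p_a),
    data.frame(x = choices$x_b, p = choices$p_b)))
  key <- function(x, p) paste(x, p, sep = "@")
  lid <- key(lot$x, lot$p)
  ia <- match(key(choices$x_a, choices$p_a), lid)
  ib <- match(key(choices$x_b, choices$p_b), lid)
  n <- length(lid)
  pref <- matrix(NA, n, n)   # pref[i, j] = TRUE if i preferred over j
  win <- ifelse(choices$choice == "A", ia, ib)
  lose <- ifelse(choices$choice == "A", ib, ia)
  pref[cbind(win, lose)] <- TRUE
  pref[cbind(lose, win)] <- FALSE
  trips <- 0L; cycles <- 0L
  if (n >= 3L) {
    cmb <- utils::combn(n, 3L)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1L, c_i]; j <- cmb[2L, c_i]; k <- cmb[3L, c_i]
      if (is.na(pref[i, j]) || is.na(pref[j, k]) || is.na(pref[i, k])) next
      trips <- trips + 1L
      # a cycle exists iff no option beats both others
      wins <- c(pref[i, j] + pref[i, k], (!pref[i, j]) + pref[j, k],
                (!pref[i, k]) + (!pref[j, k]))
      if (max(wins) < 2L) cycles <- cycles + 1L
    }
  }
  if (trips == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cycles / trips
}

#' Prediction accuracy by EV-difference quantile
#'
#' Bins trials by |EV difference| quantile and reports each fitted model's
#' prediction accuracy per bin. Bins partition all trials.
#'
#' @param fits list of `gr_fit` objects (same participant).
#' @param fd the participant's dataset.
#' @param n_quantiles number of bins.
#' @param design design configuration.
#' @return data.frame: `model`, `quantile`, `accuracy`, `n`.
#' @export
ev_quantile_accuracy <- function(fits, fd, n_quantiles = 5L,
                                 design = design_config()) {
  adev <- abs(fd$delta_ev)
  if (n_quantiles > length(unique(adev)))
    stop("more quantiles than distinct |dEV| values", call. = FALSE)
  br <- stats::quantile(adev, probs = seq(0, 1, length.out = n_quantiles +
                                            1L))
  bin <- cut(adev, breaks = unique(br), include.lowest = TRUE,
             labels = FALSE)
  rows <- list()
  for (fit in fits) {
    p_obs <- predict_choice_prob(fit, fd, design)
    acc <- (p_obs > 0.5) + 0.5 * (p_obs == 0.5)
    for (b in sort(unique(bin))) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = fit$model, quantile = b, accuracy = mean(acc[bin == b]),
        n = sum(bin == b), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normativity comparison of two fitted models
#'
#' Simulates choices under each model with the participant's fixation
#' sequences (Luce sampling on the final accumulator states) and computes two
#' normativity measures: the fraction of higher-EV choices and the fraction
#' of transitivity violations.
#'
#' @param fd the participant's dataset.
#' @param fits named list of `gr_fit` objects (accumulator models), e.g.
#'   `list(two_layer = ..., wa_normalized = ...)`; parameter lists are also
#'   accepted when paired with `variants`.
#' @param design design configuration.
#' @param seed seed for choice sampling.
#' @return data.frame: `model`, `ev_choice_fraction`,
#'   `transitivity_violations`.
#' @export
normativity_comparison <- function(fd, fits, design = design_config(),
                                   seed = 1L) {
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    p_a <- .choice_prob(fit$model %||% nm, fit$params %||% fit, fd, design)
    sim_choice <- with_seed(.subseed(seed, match(nm, names(fits))),
                            ifelse(stats::runif(fd$n) < p_a, "A", "B"))
    dev <- fd$delta_ev
    informative <- dev != 0
    ev_frac <- mean((sim_choice[informative] == "A") ==
                      (dev[informative] > 0))
    tv <- transitivity_violations(data.frame(
      x_a = fd$x[, 1L], p_a = fd$p[, 1L], x_b = fd$x[, 2L],
      p_b = fd$p[, 2L], choice = sim_choice, stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      model = nm, ev_choice_fraction = ev_frac,
      transitivity_violations = as.numeric(tv), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Participant summary table
#'
#' One row per participant with the descriptive statistics used by the
#' individual-difference analyses: EV psychometrics, risky-choice fractions,
#' fixation shares, transition proportions and the EV-choice fraction.
#'
#' @param trials,fixations cleaned dataset tables (all participants).
#' @param problems problem table.
#' @return data.frame, one row per participant.
#' @export
participant_summary <- function(trials, fixations, problems) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    fd <- prepare_participant(tr,
                              fixations[fixations$participant_id == id, ,
                                        drop = FALSE],
                              problems)
    mg <- .merge_problems(tr, problems)
    mg <- mg[!mg$is_catch, , drop = FALSE]
    psy <- tryCatch(ev_psychometrics(tr, problems),
                    error = function(e) list(slope = NA_real_,
                                             rt_correlation = NA_real_))
    rp <- tryCatch(risk_preference(tr, problems),
                   error = function(e) c(low = NA, medium_high = NA,
                                         overall = NA))
    # gaze summaries pooled over trials
    gs <- lapply(seq_len(fd$n), function(i)
      gaze_stats(fd$aoi[i, seq_len(fd$nfix[i])],
                 fd$dur[i, seq_len(fd$nfix[i])],
                 fd$x[i, 1L], fd$p[i, 1L], fd$x[i, 2L], fd$p[i, 2L]))
    trans <- Reduce(`+`, lapply(gs, `[[`, "transitions"))
    amount_share <- mean(vapply(gs, `[[`, numeric(1),
                                "amount_fixation_share"))
    ha <- vapply(gs, `[[`, numeric(1), "higher_amount_share")
    hp <- vapply(gs, `[[`, numeric(1), "higher_prob_share")
    ev_frac <- {
      inf <- fd$delta_ev != 0
      mean((fd$choice[inf] == 1L) == (fd$delta_ev[inf] > 0))
    }
    data.frame(participant_id = id,
               ev_slope = psy$slope, rt_ev_correlation = psy$rt_correlation,
               risky_low = rp[["low"]], risky_medium_high =
                 rp[["medium_high"]], risky_overall = rp[["overall"]],
               amount_fixation_share = amount_share,
               higher_amount_share = mean(ha, na.rm = TRUE),
               higher_prob_share = mean(hp, na.rm = TRUE),
               prop_within_alternative = trans[["within_alternative"]] /
                 sum(trans),
               prop_within_attribute = trans[["within_attribute"]] /
                 sum(trans),
               prop_diagonal = trans[["diagonal"]] / sum(trans),
               ev_choice_fraction = ev_frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
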