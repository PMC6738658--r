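# Two-step maximum-likelihood fitting and model comparison.

#' Model registry
#'
#' Identifies every fittable model: static benchmarks (`"ev"`, `"eu"`,
#' `"cpt"`), gaze-regression models (`"eu_fix"`, `"cpt_fix"`, `"eu_dwell"`,
#' `"cpt_dwell"`), deterministic heuristics (`"maximax"`, `"least_likely"`,
#' `"priority"`) and the accumulator variants (`"wa_normalized"`,
#' `"wa_categorical"`, `"one_layer"`, `"two_layer"`, `"hybrid"`).
#'
#' @param model model id.
#' @return list with `id`, `kind` (`static`, `regression`, `heuristic`,
#'   `accumulator`), `par_names` and the free-parameter count `k`.
#' @export
model_spec <- function(model) {
  pars <- switch(model,
    ev = "beta",
    eu = c("alpha", "beta"),
    cpt = c("alpha", "gamma", "beta"),
    eu_fix = , eu_dwell = c("alpha", "tau", "beta"),
    cpt_fix = , cpt_dwell = c("alpha", "gamma", "tau", "beta"),
    wa_normalized = , wa_categorical = c("theta", "lam", "beta"),
    one_layer = , two_layer = c("alpha", "gamma", "theta", "lam", "beta"),
    hybrid = c("alpha", "gamma", "theta", "lam", "iota", "beta"),
    maximax = , least_likely = , priority = character(0),
    stop("unknown model: ", model, call. = FALSE))
  kind <- if (model %in% c("ev", "eu", "cpt")) "static"
          else if (model %in% c("eu_fix", "cpt_fix", "eu_dwell", "cpt_dwell"))
            "regression"
          else if (model %in% c("maximax", "least_likely", "priority"))
            "heuristic"
          else "accumulator"
  list(id = model, kind = kind, par_names = pars, k = length(pars))
}

#' Default parameter bounds for fitting
#'
#' @return list with named `lower` and `upper` vectors.
#' @export
default_bounds <- function() {
  list(lower = c(alpha = 0.1, gamma = 0.2, theta = 0, lam = 0, beta = 0,
                 iota = 0, tau = 0),
       upper = c(alpha = 2, gamma = 2, theta = 1, lam = 1, beta = 50,
                 iota = 1, tau = 2))
}

# P(choose A) per trial for a model with parameter list `par`.
.choice_prob <- function(model, par, fd, design = design_config()) {
  sp <- model_spec(model)
  if (sp$kind == "heuristic") {
    pr <- data.frame(x_a = fd$x[, 1L], p_a = fd$p[, 1L],
                     x_b = fd$x[, 2L], p_b = fd$p[, 2L])
    ch <- heuristic_choice(pr, model)
    return(ifelse(ch == "A", 1, ifelse(ch == "B", 0, 0.5)))
  }
  if (sp$kind == "accumulator") {
    pp <- process_params(alpha = par$alpha %||% 1, gamma = par$gamma %||% 1,
                         theta = par$theta %||% 1, lam = par$lam %||% 0,
                         beta = par$beta, iota = par$iota %||% 0)
    Y <- .accumulate_batch(fd, pp, model, design)
    return(luce_prob(Y[, 1L], Y[, 2L], par$beta))
  }
  base <- if (grepl("^cpt", model)) "cpt" else if (grepl("^eu", model)) "eu"
          else "ev"
  ua <- subjective_utility(fd$x[, 1L], fd$p[, 1L], base,
                           alpha = par$alpha %||% 1, gamma = par$gamma %||% 1)
  ub <- subjective_utility(fd$x[, 2L], fd$p[, 2L], base,
                           alpha = par$alpha %||% 1, gamma = par$gamma %||% 1)
  if (sp$kind == "regression") {
    gaze <- if (grepl("_dwell$", model)) fd$dwell_opt else fd$count_opt
    ua <- ua * pmax(gaze[, 1L], 1e-3)^par$tau
    ub <- ub * pmax(gaze[, 2L], 1e-3)^par$tau
  }
  luce_prob(ua, ub, par$beta)
}

#' Predicted probability of each observed choice
#'
#' @param fit a `gr_fit` from [fit_choice()].
#' @param fd a [prepare_participant()] dataset (defaults to the fit's data
#'   if attached).
#' @param design design configuration.
#' @return vector of P(observed choice) per trial.
#' @export
predict_choice_prob <- function(fit, fd, design = design_config()) {
  p_a <- .choice_prob(fit$model, fit$params, fd, design)
  ifelse(fd$choice == 1L, p_a, 1 - p_a)
}

.negloglik <- function(theta_z, model, fd, design, lo, hi) {
  par <- as.list(lo + (hi - lo) * stats::plogis(theta_z))
  names(par) <- names(lo)
  p_a <- .choice_prob(model, par, fd, design)
  p_obs <- .clip_prob(ifelse(fd$choice == 1L, p_a, 1 - p_a))
  -sum(log(p_obs))
}

#' Fit a model to one participant's choices (Step 1)
#'
#' Maximum-likelihood estimation of the model's parameters from choices,
#' conditioning on the observed fixation sequences (for gaze-dependent
#' models). Bounded multi-start Nelder-Mead on a logit-transformed parameter
#' space; deterministic given `seed`. Heuristics have no free parameters and
#' are scored by accuracy only.
#'
#' @param fd a [prepare_participant()] dataset.
#' @param model model id (see [model_spec()]).
#' @param design design configuration.
#' @param bounds list with `lower`/`upper` named vectors; see
#'   [default_bounds()].
#' @param n_starts number of optimizer starts (default 20).
#' @param seed seed for start-point generation.
#' @return object of class `gr_fit` with fitted `params`, `loglik`, `aic`,
#'   `accuracy`, `k`, `n_trials` and optimizer diagnostics.
#' @export
fit_choice <- function(fd, model, design = design_config(),
                       bounds = default_bounds(), n_starts = 20, seed = 1L) {
  sp <- model_spec(model)
  if (sp$kind == "heuristic") {
    fit <- structure(list(participant_id = fd$participant_id, model = model,
                          kind = sp$kind, params = list(), loglik = NA_real_,
                          k = 0L, aic = NA_real_, n_trials = fd$n,
                          convergence = 0L), class = "gr_fit")
    fit$accuracy <- prediction_accuracy(fit, fd, design)
    return(fit)
  }
  lo <- bounds$lower[sp$par_names]
  hi <- bounds$upper[sp$par_names]
  k <- sp$k
  nll <- function(z) .negloglik(z, model, fd, design, lo, hi)
  starts <- with_seed(.subseed(seed, 11L), {
    s <- matrix(stats::runif(n_starts * k, 0.1, 0.9), n_starts, k)
    s[1L, ] <- 0.5
    stats::qlogis(s)
  })
  if (sp$kind == "accumulator" && all(c("alpha", "gamma") %in%
                                      sp$par_names) && n_starts > 1L) {
    # warm start: seed alpha/gamma from a cheap CPT fit (theta, lam at mid)
    cpt <- fit_choice(fd, "cpt", design, bounds, n_starts = 4,
                      seed = .subseed(seed, 13L))
    unit <- function(v, nm) (min(max(v, lo[nm] + 1e-6), hi[nm] - 1e-6) -
                               lo[nm]) / (hi[nm] - lo[nm])
    warm <- rep(0.5, k); names(warm) <- sp$par_names
    warm["alpha"] <- unit(cpt$params$alpha, "alpha")
    warm["gamma"] <- unit(cpt$params$gamma, "gamma")
    starts[2L, ] <- stats::qlogis(warm)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- if (k == 1L) {
      o <- stats::optimize(function(z) nll(z), interval = c(-12, 12),
                           tol = 1e-7)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(starts[i, ], nll, method = "Nelder-Mead",
                   control = list(maxit = 250L * k, reltol = 1e-8))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (k > 1L) {
    # polish: restart Nelder-Mead from the incumbent (fresh simplex)
    polish <- stats::optim(best$par, nll, method = "Nelder-Mead",
                           control = list(maxit = 250L * k, reltol = 1e-10))
    if (polish$value < best$value) best <- polish
  }
  par <- as.list(lo + (hi - lo) * stats::plogis(best$par))
  names(par) <- sp$par_names
  fit <- structure(list(participant_id = fd$participant_id, model = model,
                        kind = sp$kind, params = par,
                        loglik = -best$value, k = k,
                        aic = aic(-best$value, k), n_trials = fd$n,
                        convergence = best$convergence), class = "gr_fit")
  fit$accuracy <- prediction_accuracy(fit, fd, design)
  fit
}

#' @export
print.gr_fit <- function(x, ...) {
  cat(sprintf("gr_fit: %s, participant %s\n", x$model, x$participant_id))
  if (length(x$params))
    cat("  params:", paste(sprintf("%s=%.3f", names(x$params),
                                   unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  loglik=%.2f  AIC=%.1f  accuracy=%.3f  (n=%d)\n",
              x$loglik, x$aic, x$accuracy, x$n_trials))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 loglik`.
#' @param loglik maximized log-likelihood.
#' @param k number of fitted parameters.
#' @export
aic <- function(loglik, k) 2 * k - 2 * loglik

#' Prediction accuracy of a fitted model
#'
#' Mean over trials of an indicator that the model puts more than .5
#' probability on the observed choice; exact ties (P = .5) score one half, so
#' accuracy is symmetric under label swaps.
#'
#' @param fit a `gr_fit`.
#' @param fd the dataset to score.
#' @param design design configuration.
#' @export
prediction_accuracy <- function(fit, fd, design = design_config()) {
  p_obs <- predict_choice_prob(fit, fd, design)
  mean((p_obs > 0.5) + 0.5 * (p_obs == 0.5))
}

# Stratified fold assignment: trials ordered by |dEV|, fold labels permuted
# within consecutive blocks.
.make_folds <- function(abs_dev, k_folds, seed) {
  n <- length(abs_dev)
  ord <- order(abs_dev, seq_len(n))
  folds <- integer(n)
  with_seed(seed, {
    lab <- unlist(lapply(seq_len(ceiling(n / k_folds)), function(b)
      sample.int(k_folds)))[seq_len(n)]
    folds[ord] <- lab
  })
  folds
}

#' Cross-validate a model for one participant
#'
#' Seeded k-fold cross-validation stratified by |EV difference| quantile:
#' the model is refitted on the training folds and scored out-of-fold by
#' -2 log-likelihood (summed) and prediction accuracy (averaged over held-out
#' trials). Heuristics have nothing to fit, so their CV scores equal their
#' plain scores.
#'
#' @param fd a [prepare_participant()] dataset.
#' @param model model id.
#' @param k_folds number of folds (default 5).
#' @param seed fold-assignment and optimizer seed.
#' @param design design configuration.
#' @param n_starts optimizer starts per training fit.
#' @return list with `cv_neg2ll` and `cv_accuracy`.
#' @export
cross_validate <- function(fd, model, k_folds = 5, seed = 1L,
                           design = design_config(), n_starts = 8) {
  sp <- model_spec(model)
  if (sp$kind == "heuristic") {
    fit <- fit_choice(fd, model, design)
    return(list(cv_neg2ll = NA_real_, cv_accuracy = fit$accuracy))
  }
  folds <- .make_folds(abs(fd$delta_ev), k_folds, .subseed(seed, 23L))
  if (min(table(folds)) < 2L) stop("fold with < 2 trials", call. = FALSE)
  neg2 <- 0; hits <- 0
  for (f in sort(unique(folds))) {
    tr <- .subset_gr_data(fd, folds != f)
    te <- .subset_gr_data(fd, folds == f)
    fit <- fit_choice(tr, model, design, n_starts = n_starts,
                      seed = .subseed(seed, 100L + f))
    p_obs <- .clip_prob(predict_choice_prob(fit, te, design))
    neg2 <- neg2 - 2 * sum(log(p_obs))
    hits <- hits + sum((p_obs > 0.5) + 0.5 * (p_obs == 0.5))
  }
  list(cv_neg2ll = neg2, cv_accuracy = hits / fd$n)
}

# Row subset of a gr_data object.
.subset_gr_data <- function(fd, keep) {
  keep <- which(keep)
  out <- fd
  for (nm in c("problem_id", "relation", "is_catch", "choice", "rt_ms",
               "nfix", "delta_ev"))
    out[[nm]] <- fd[[nm]][keep]
  for (nm in c("x", "p", "aoi", "dur", "first_fix", "count_opt",
               "dwell_opt"))
    out[[nm]] <- fd[[nm]][keep, , drop = FALSE]
  out$n <- length(keep)
  out
}

#' Compare a set of models for several participants
#'
#' Fits each model to each participant and assembles a Table-1-style summary
#' (per-participant rows plus pooled sums).
#'
#' @param datasets list of [prepare_participant()] objects.
#' @param models character vector of model ids.
#' @param design design configuration.
#' @param cv run cross-validation as well?
#' @param n_starts,k_folds,seed fitting controls.
#' @return data.frame, one row per participant x model, with `loglik`, `aic`,
#'   `accuracy` and (if `cv`) `cv_neg2ll`, `cv_accuracy`.
#' @export
compare_models <- function(datasets, models, design = design_config(),
                           cv = FALSE, n_starts = 10, k_folds = 5,
                           seed = 1L) {
  rows <- list()
  for (d in seq_along(datasets)) {
    fd <- datasets[[d]]
    for (m in models) {
      fit <- fit_choice(fd, m, design, n_starts = n_starts,
                        seed = .subseed(seed, d))
      row <- data.frame(participant_id = fd$participant_id, model = m,
                        k = fit$k, loglik = fit$loglik, aic = fit$aic,
                        accuracy = fit$accuracy, stringsAsFactors = FALSE)
      if (cv) {
        cvr <- cross_validate(fd, m, k_folds = k_folds,
                              seed = .subseed(seed, d), design = design,
                              n_starts = max(4, n_starts %/% 2))
        row$cv_neg2ll <- cvr$cv_neg2ll
        row$cv_accuracy <- cvr$cv_accuracy
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Parameter-recovery harness
#'
#' For each generative parameter set: simulate one participant's choices over
#' the design's trade-off problems with model-generated fixations, refit the
#' model, and report generative vs recovered values with per-parameter
#' Pearson correlations and mean bias.
#'
#' @param truth data.frame of generative parameter sets (columns `alpha`,
#'   `gamma`, `theta`, `lam`, `beta`), or `NULL` to draw `n_sets` from the
#'   recovery population.
#' @param variant generating (and refitted) accumulator variant.
#' @param n_sets number of simulated participants when `truth` is NULL.
#' @param design design configuration.
#' @param seed master seed.
#' @param n_starts optimizer starts per refit.
#' @param population population configuration for parameter draws and gaze;
#'   the default spans the interior of the fitting bounds.
#' @param min_consistency generative sets must imply at least this mean
#'   choice consistency on the design (default 0.75, the weakest accuracy a
#'   fitted compensatory model attains on data of this kind): recovery is
#'   defined for parameter regimes that resemble fitted participants, and a
#'   near-random chooser's parameters are not estimable from any finite
#'   sample.
#' @return list with `report` (data.frame of generative `*_gen` and recovered
#'   `*_rec` columns) and `correlations` (named vector).
#' @export
recover_parameters <- function(truth = NULL, variant = "two_layer",
                               n_sets = 30, design = design_config(),
                               seed = 1L, n_starts = 8,
                               population = NULL,
                               min_consistency = 0.75) {
  population <- population %||% population_config(
    alpha = c(0.2, 1.8), gamma = c(0.3, 1.8), theta = c(0.05, 0.95),
    lam = c(0.05, 0.95), beta = c(0.3, 1.5))
  if (is.null(truth)) {
    truth <- with_seed(.subseed(seed, 37L), {
      acc <- list(); tries <- 0L
      while (length(acc) < n_sets && tries < 200L * n_sets) {
        tries <- tries + 1L
        d <- .draw_process_params(1L, population)
        if (.design_consistency(d, variant, design) >= min_consistency)
          acc[[length(acc) + 1L]] <- d
      }
      if (length(acc) < n_sets)
        stop("could not draw enough generative sets above the ",
             "consistency floor", call. = FALSE)
      do.call(rbind, acc)
    })
  }
  sp <- model_spec(variant)
  problems <- enumerate_problems(design, seed = .subseed(seed, 1L))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    pp <- do.call(process_params, as.list(truth[i, sp$par_names]))
    sim <- simulate_experiment(design, n_participants = 1L,
                               variant = variant, mode = "step1",
                               population = population,
                               process_override = pp,
                               problems = problems,
                               seed = .subseed(seed, 1000L + i))
    fd <- prepare_participant(sim$trials, sim$fixations, sim$problems)
    fit <- fit_choice(fd, variant, design, n_starts = n_starts,
                      seed = .subseed(seed, 2000L + i))
    row <- c(as.list(truth[i, sp$par_names]), fit$params)
    names(row) <- c(paste0(sp$par_names, "_gen"),
                    paste0(sp$par_names, "_rec"))
    rows[[i]] <- as.data.frame(row)
  }
  report <- do.call(rbind, rows)
  cors <- vapply(sp$par_names, function(pn)
    stats::cor(report[[paste0(pn, "_gen")]], report[[paste0(pn, "_rec")]]),
    numeric(1))
  list(report = report, correlations = cors)
}

# Mean Luce choice consistency max(P, 1-P) a parameter set implies over the
# design's trade-off problems, under a canonical balanced scan.
.design_consistency <- function(par, variant, design) {
  pr <- enumerate_problems(design, seed = 1L)
  pr <- pr[!pr$is_catch, , drop = FALSE]
  n <- nrow(pr)
  scan <- rep(c(1L, 2L, 3L, 4L), length.out = 9L)
  fd <- list(n = n, x = cbind(pr$x_a, pr$x_b), p = cbind(pr$p_a, pr$p_b),
             aoi = matrix(scan, n, length(scan), byrow = TRUE),
             nfix = rep(length(scan), n),
             first_fix = matrix(rep(1:4, each = n), n, 4L))
  pp <- process_params(alpha = par$alpha, gamma = par$gamma,
                       theta = par$theta, lam = par$lam, beta = par$beta,
                       iota = par$iota %||% 0)
  Y <- .accumulate_batch(fd, pp, variant, design)
  p_a <- luce_prob(Y[, 1L], Y[, 2L], par$beta)
  mean(pmax(p_a, 1 - p_a))
}
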