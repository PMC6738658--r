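# Integration-to-boundary layer: boundary families, stochastic termination,
# Monte-Carlo (choice, decision time) likelihoods and Vincentized quantiles.
# Decision time is measured in fixation steps.

#' Decision-boundary parameters
#'
#' `"fixed"` uses a constant boundary `b0`. `"collapsing"` decays
#' exponentially from `b0` towards the asymptote `b_inf` with time constant
#' `tau_c` (in fixation steps): `b(t) = b_inf + (b0 - b_inf) exp(-t/tau_c)`.
#'
#' @param family `"fixed"` or `"collapsing"`.
#' @param b0 initial boundary (> 0).
#' @param b_inf asymptotic boundary (collapsing; `0 <= b_inf <= b0`).
#' @param tau_c collapse time constant in fixation steps (> 0).
#' @export
boundary_params <- function(family = c("fixed", "collapsing"), b0,
                            b_inf = NULL, tau_c = NULL) {
  family <- match.arg(family)
  .assert_number(b0, "b0", lower = 1e-12)
  if (family == "collapsing") {
    .assert_number(b_inf, "b_inf", lower = 0)
    .assert_number(tau_c, "tau_c", lower = 1e-12)
    if (b_inf > b0) stop("b_inf must not exceed b0", call. = FALSE)
  }
  structure(list(family = family, b0 = b0, b_inf = b_inf, tau_c = tau_c),
            class = "boundary_params")
}

#' Boundary value at a fixation step
#'
#' @param t fixation step(s), >= 1.
#' @param bp a [boundary_params()].
#' @export
boundary_value <- function(t, bp) {
  stopifnot(inherits(bp, "boundary_params"), all(t >= 1))
  if (bp$family == "fixed") rep(bp$b0, length(t))
  else bp$b_inf + (bp$b0 - bp$b_inf) * exp(-t / bp$tau_c)
}

#' Extend a fixation sequence by its own transition statistics
#'
#' Continues an AOI sequence by sampling transition categories
#' (within-alternative / within-attribute / diagonal) from the observed
#' sequence's Laplace-smoothed category proportions; each category determines
#' the next AOI uniquely given the current one.
#'
#' @param aoi observed AOI sequence (codes or labels).
#' @param n_extra number of additional fixations.
#' @return integer AOI codes of length `length(aoi) + n_extra`.
#' @export
extend_fixation_seq <- function(aoi, n_extra) {
  code <- .aoi_code(aoi)
  tc <- classify_transitions(code)
  w <- (tc + 1) / sum(tc + 1)
  cur <- code[length(code)]
  out <- integer(n_extra)
  # neighbor of `cur` per category: alt, attr, diag
  neigh <- function(cur) c(alt = c(2L, 1L, 4L, 3L)[cur],
                           attr = .aoi_partner[cur],
                           diag = c(4L, 3L, 2L, 1L)[cur])
  for (i in seq_len(n_extra)) {
    cur <- neigh(cur)[sample.int(3L, 1L, prob = w)]
    out[i] <- cur
  }
  c(code, out)
}

#' Simulate an accumulation race to boundary crossing
#'
#' Runs the accumulator with per-step noise until the larger of the two
#' alternative accumulators reaches the boundary. The winner is the larger
#' accumulator at crossing; an exact tie is resolved by a (seeded) coin flip.
#' If the boundary is not crossed within `cap` steps the trial is flagged
#' censored.
#'
#' @param problem one-row data.frame with `x_a`, `p_a`, `x_b`, `p_b`.
#' @param params a [process_params()] (with `sigma > 0` unless crossing is
#'   guaranteed).
#' @param variant accumulator variant.
#' @param bp a [boundary_params()].
#' @param fixation_source either a `gaze_params` object (fixations sampled
#'   from the gaze model), an AOI vector (extended by its own transition
#'   statistics if exhausted), or a `function(t, prev_aoi)` returning the next
#'   AOI code.
#' @param cap maximum number of fixation steps.
#' @param seed seed (noise and fixation sampling).
#' @param design design configuration.
#' @return list with `choice` (`"A"`/`"B"`), `n_fixations`, `censored`, and
#'   the AOI sequence used.
#' @export
simulate_to_termination <- function(problem, params, variant, bp,
                                    fixation_source, cap = 100L,
                                    seed = 1L, design = design_config()) {
  variant <- match.arg(variant, .variants)
  with_seed(seed, {
    next_aoi <- .as_fixation_source(fixation_source, problem)
    inp <- init_inputs(problem, params, design, variant)
    seen <- rep(FALSE, 4L)
    state <- list(layer1 = rep(0, 4L), Y = c(0, 0), step = 0L)
    aoi_used <- integer(0)
    prev <- NA_integer_
    for (t in seq_len(cap)) {
      a <- next_aoi(t, prev)
      prev <- a
      aoi_used[t] <- a
      seen[a] <- TRUE
      vals <- ifelse(seen, inp$true, inp$default)
      state <- accumulator_step(state, a, vals, params, variant,
                                noise = params$sigma * stats::rnorm(2L))
      if (max(state$Y) >= boundary_value(t, bp)) {
        winner <- if (state$Y[1L] > state$Y[2L]) "A"
                  else if (state$Y[2L] > state$Y[1L]) "B"
                  else sample(c("A", "B"), 1L)
        return(list(choice = winner, n_fixations = t, censored = FALSE,
                    aoi = .aoi_label(aoi_used)))
      }
    }
    list(choice = if (state$Y[1L] >= state$Y[2L]) "A" else "B",
         n_fixations = cap, censored = TRUE, aoi = .aoi_label(aoi_used))
  })
}

.as_fixation_source <- function(src, problem) {
  if (inherits(src, "gaze_params")) {
    visited <- rep(FALSE, 4L)
    prev2 <- NA_integer_
    return(function(t, prev) {
      a <- .sample_next_aoi(prev, src, problem, visited, prev2)
      visited[a] <<- TRUE
      prev2 <<- prev
      a
    })
  }
  if (is.function(src)) return(src)
  code <- .aoi_code(src)
  full <- code
  function(t, prev) {
    # lazily extend using the observed sequence's transition statistics
    while (t > length(full)) full <<- extend_fixation_seq(full, 16L)
    full[t]
  }
}

# Precompute M noisy accumulator paths for every trial of a participant,
# conditioned on the observed AOI prefix and gaze-statistics extension.
# Returns per-trial list(Ymax M x cap, lead M x cap in {1,2,0}).
.simulate_trial_paths <- function(fd, params, variant, design, M, cap,
                                  seed) {
  out <- vector("list", fd$n)
  for (i in seq_len(fd$n)) {
    obs <- fd$aoi[i, seq_len(fd$nfix[i])]
    aoi_mat <- with_seed(.subseed(seed, 5000L + i), {
      t(vapply(seq_len(M), function(m) {
        if (cap <= length(obs)) obs[seq_len(cap)]
        else extend_fixation_seq(obs, cap - length(obs))
      }, integer(cap)))
    })
    noise <- with_seed(.subseed(seed, 6000L + i),
                       array(params$sigma * stats::rnorm(M * cap * 2L),
                             dim = c(M, cap, 2L)))
    first_fix <- matrix(Inf, M, 4L)
    for (k in 1:4) {
      hit <- aoi_mat == k
      any_hit <- rowSums(hit) > 0
      first_fix[any_hit, k] <- apply(hit[any_hit, , drop = FALSE], 1L,
                                     which.max)
    }
    pseudo <- list(n = M,
                   x = matrix(fd$x[i, ], M, 2L, byrow = TRUE),
                   p = matrix(fd$p[i, ], M, 2L, byrow = TRUE),
                   aoi = aoi_mat, nfix = rep(cap, M),
                   first_fix = first_fix)
    res <- .accumulate_batch(pseudo, params, variant, design, noise = noise,
                             paths = TRUE)
    lead <- matrix(0L, M, cap)
    lead[res$Y_A > res$Y_B] <- 1L
    lead[res$Y_B > res$Y_A] <- 2L
    out[[i]] <- list(Ymax = pmax(res$Y_A, res$Y_B), lead = lead)
  }
  out
}

# -2 log-likelihood of observed (choice, n_fixations) across trials for
# boundary `bp`, given precomputed paths.
.boundary_neg2ll <- function(paths, fd, bp, cap) {
  b <- boundary_value(seq_len(cap), bp)
  M <- nrow(paths[[1L]]$Ymax)
  ll <- 0
  for (i in seq_along(paths)) {
    C <- sweep(paths[[i]]$Ymax, 2L, b, ">=")
    first <- max.col(cbind(C, TRUE), ties.method = "first")
    t_obs <- fd$nfix[i]
    hit <- if (t_obs <= cap) {
      at <- first == t_obs
      ld <- paths[[i]]$lead[cbind(seq_len(M), pmin(first, cap))]
      sum(at & ld == fd$choice[i]) + 0.5 * sum(at & ld == 0L)
    } else 0
    ll <- ll + log((hit + 1) / (M + 2))
  }
  -2 * ll
}

#' Monte-Carlo likelihood of a (choice, decision time) observation
#'
#' Estimates the probability that the accumulation race, conditioned on the
#' trial's observed AOI sequence (extended by its own transition statistics
#' when exhausted), first crosses the boundary at exactly the observed
#' fixation count with the observed winner. Laplace smoothing
#' `(hits + 1) / (M + 2)` keeps the log-likelihood finite.
#'
#' @param problem one-row data.frame with `x_a`, `p_a`, `x_b`, `p_b`.
#' @param aoi observed AOI sequence.
#' @param choice observed choice, `"A"` or `"B"`.
#' @param params [process_params()] with `sigma > 0`.
#' @param variant accumulator variant.
#' @param bp [boundary_params()].
#' @param M Monte-Carlo sample count (>= 100).
#' @param cap step cap.
#' @param seed seed.
#' @param design design configuration.
#' @export
choice_rt_likelihood <- function(problem, aoi, choice, params, variant, bp,
                                 M = 200L, cap = 50L, seed = 1L,
                                 design = design_config()) {
  if (M < 1L) stop("M must be positive", call. = FALSE)
  code <- .aoi_code(aoi)
  fd <- list(n = 1L,
             x = cbind(problem$x_a, problem$x_b),
             p = cbind(problem$p_a, problem$p_b),
             aoi = matrix(code, 1L), nfix = length(code),
             choice = match(choice, c("A", "B")))
  paths <- .simulate_trial_paths(fd, params, variant, design, M, cap, seed)
  exp(-0.5 * .boundary_neg2ll(paths, fd, bp, cap))
}

#' Fit boundary parameters to choices and decision times (Step 2)
#'
#' Holding the Step-1 process parameters fixed (with `sigma = 1`; the noise
#' scale is absorbed by the boundary), maximizes the summed Monte-Carlo
#' log-likelihood of each trial's observed (choice, fixation count) over the
#' boundary parameters. Common random numbers: accumulator paths are
#' simulated once per trial and reused for every boundary evaluation, which
#' makes the likelihood a deterministic function of the boundary.
#'
#' @param fd a [prepare_participant()] dataset.
#' @param step1 a `gr_fit` for an accumulator model (or a parameter list).
#' @param variant accumulator variant (defaults to the fit's model).
#' @param family boundary family.
#' @param M Monte-Carlo paths per trial.
#' @param cap step cap (decision times above it are censored).
#' @param seed seed for the common random numbers.
#' @param design design configuration.
#' @return list of class `gr_boundary_fit`: `bp` (fitted
#'   [boundary_params()]), `neg2ll`, `k`, `aic`, frozen `step1_params`.
#' @export
fit_boundary <- function(fd, step1, variant = NULL,
                         family = c("fixed", "collapsing"), M = 100L,
                         cap = 50L, seed = 1L, design = design_config()) {
  family <- match.arg(family)
  if (inherits(step1, "gr_fit")) {
    variant <- variant %||% step1$model
    p1 <- step1$params
  } else p1 <- step1
  if (is.null(variant) || !variant %in% .variants)
    stop("fit_boundary requires an accumulator variant", call. = FALSE)
  params <- process_params(alpha = p1$alpha %||% 1, gamma = p1$gamma %||% 1,
                           theta = p1$theta %||% 1, lam = p1$lam %||% 0,
                           beta = p1$beta %||% 1, iota = p1$iota %||% 0,
                           sigma = 1)
  paths <- .simulate_trial_paths(fd, params, variant, design, M, cap, seed)
  bmax <- max(vapply(paths, function(p) max(p$Ymax), numeric(1)))
  if (family == "fixed") {
    opt <- stats::optimize(function(b0)
      .boundary_neg2ll(paths, fd, boundary_params("fixed", b0 = b0), cap),
      interval = c(1e-3, bmax), tol = 1e-4 * bmax)
    bp <- boundary_params("fixed", b0 = opt$minimum)
    val <- opt$objective
    k <- 1L
  } else {
    obj <- function(z) {
      b0 <- exp(z[1L])
      bi <- b0 * stats::plogis(z[2L])
      tc <- exp(z[3L])
      .boundary_neg2ll(paths, fd,
                       boundary_params("collapsing", b0 = b0, b_inf = bi,
                                       tau_c = tc), cap)
    }
    start <- c(log(bmax / 2), 0, log(cap / 4))
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-8))
    bp <- boundary_params("collapsing", b0 = exp(opt$par[1L]),
                          b_inf = exp(opt$par[1L]) *
                            stats::plogis(opt$par[2L]),
                          tau_c = exp(opt$par[3L]))
    val <- opt$value
    k <- 3L
  }
  structure(list(participant_id = fd$participant_id, variant = variant,
                 family = family, bp = bp, neg2ll = val, k = k,
                 aic = 2 * k + val, step1_params = p1, M = M, cap = cap),
            class = "gr_boundary_fit")
}

#' @export
print.gr_boundary_fit <- function(x, ...) {
  cat(sprintf("gr_boundary_fit: %s boundary for %s (participant %s)\n",
              x$family, x$variant, x$participant_id))
  cat(sprintf("  b0=%.3f%s  -2LL=%.1f AIC=%.1f\n", x$bp$b0,
              if (x$family == "collapsing")
                sprintf(" b_inf=%.3f tau_c=%.2f", x$bp$b_inf, x$bp$tau_c)
              else "", x$neg2ll, x$aic))
  invisible(x)
}

#' Vincentized group quantiles
#'
#' Computes the requested quantiles for each participant's decision-time
#' sample and averages them across participants.
#'
#' @param samples list with one numeric vector per participant.
#' @param probs quantile levels (default `c(.1, .3, .5, .7, .9, .99)`).
#' @return named numeric vector of group quantiles.
#' @export
vincentized_quantiles <- function(samples,
                                  probs = c(.1, .3, .5, .7, .9, .99)) {
  if (!length(samples)) stop("no participants", call. = FALSE)
  q <- vapply(samples, function(s) {
    if (!length(s)) stop("empty sample", call. = FALSE)
    stats::quantile(s, probs = probs, names = FALSE, type = 7)
  }, numeric(length(probs)))
  out <- rowMeans(matrix(q, nrow = length(probs)))
  names(out) <- paste0("q", probs)
  out
}
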