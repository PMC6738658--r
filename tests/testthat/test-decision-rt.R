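dc <- design_config()

test_that("boundary families", {
  bf <- boundary_params("fixed", b0 = 2.5)
  expect_equal(boundary_value(c(1, 5, 50), bf), rep(2.5, 3))
  bc <- boundary_params("collapsing", b0 = 2, b_inf = 1, tau_c = 1)
  expect_equal(boundary_value(1, bc), 1 + exp(-1), tolerance = 1e-12)
  expect_equal(boundary_value(1e6, bc), 1, tolerance = 1e-9)
  # b_inf = b0 recovers the fixed boundary exactly
  bc2 <- boundary_params("collapsing", b0 = 2.5, b_inf = 2.5, tau_c = 3)
  t <- 1:40
  expect_equal(boundary_value(t, bc2), boundary_value(t, bf))
  expect_error(boundary_params("collapsing", b0 = 1, b_inf = 2, tau_c = 1),
               "b_inf")
})

test_that("sequence extension preserves the no-repeat invariant", {
  set.seed(2)
  s <- c(1L, 2L, 1L, 2L, 3L)
  ext <- extend_fixation_seq(s, 40L)
  expect_equal(length(ext), 45L)
  expect_identical(ext[1:5], s)
  expect_true(all(diff(ext) != 0))
})

test_that("termination: immediate crossing, censoring, racing", {
  pr <- data.frame(x_a = 6, p_a = .8, x_b = 24, p_b = .2)
  par <- process_params(alpha = .8, gamma = .7, theta = .5, lam = .5,
                        beta = 1, sigma = 0)
  src <- c(1L, 2L, 3L, 4L)
  # boundary below the first step input terminates at t = 1
  out <- simulate_to_termination(pr, par, "one_layer",
                                 boundary_params("fixed", b0 = 1e-9), src,
                                 seed = 1)
  expect_equal(out$n_fixations, 1L)
  expect_false(out$censored)
  # unreachable boundary -> censored at cap
  out2 <- simulate_to_termination(pr, par, "one_layer",
                                  boundary_params("fixed", b0 = 1e9), src,
                                  cap = 30L, seed = 1)
  expect_true(out2$censored)
  expect_equal(out2$n_fixations, 30L)
  # the winner matches the larger accumulator at crossing (replay the trace)
  out3 <- simulate_to_termination(pr, par, "two_layer",
                                  boundary_params("fixed", b0 = 3),
                                  gaze_params(), cap = 60L, seed = 4)
  if (!out3$censored) {
    run <- run_sequence(pr, out3$aoi, par, "two_layer", dc)
    win <- if (run$trace$Y_A[out3$n_fixations] >=
                 run$trace$Y_B[out3$n_fixations]) "A" else "B"
    expect_equal(out3$choice, win)
  }
})

test_that("raising the boundary stochastically increases decision time", {
  pr <- data.frame(x_a = 24, p_a = .2, x_b = 6, p_b = .8)
  par <- process_params(alpha = .9, gamma = .9, theta = .5, lam = .4,
                        beta = 1, sigma = 1)
  nf_low <- nf_high <- numeric(30)
  for (i in 1:30) {
    # coupled seeds: same noise stream under both boundaries
    nf_low[i] <- simulate_to_termination(
      pr, par, "two_layer", boundary_params("fixed", b0 = 2),
      gaze_params(), cap = 80L, seed = i)$n_fixations
    nf_high[i] <- simulate_to_termination(
      pr, par, "two_layer", boundary_params("fixed", b0 = 8),
      gaze_params(), cap = 80L, seed = i)$n_fixations
  }
  expect_true(all(nf_high >= nf_low))
  expect_gt(mean(nf_high), mean(nf_low))
})

test_that("Monte-Carlo likelihood behaves over outcomes", {
  pr <- data.frame(x_a = 24, p_a = .5, x_b = 6, p_b = .8)
  par <- process_params(alpha = .9, gamma = .9, theta = .5, lam = .4,
                        beta = 1, sigma = 1)
  bp <- boundary_params("fixed", b0 = 4)
  s <- c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L)
  M <- 150L; cap <- 25L
  # exhaustive bookkeeping on one common path ensemble: every path crosses
  # at exactly one (choice, t) outcome or is censored
  fd <- list(n = 1L, x = cbind(pr$x_a, pr$x_b), p = cbind(pr$p_a, pr$p_b),
             aoi = matrix(s, 1L), nfix = length(s), choice = 1L)
  paths <- gazerisk:::.simulate_trial_paths(fd, par, "two_layer", dc,
                                            M = M, cap = cap, seed = 77)
  hits_total <- 0
  for (ch in 1:2) for (t in seq_len(cap)) {
    fd2 <- fd; fd2$nfix <- t; fd2$choice <- ch
    lik <- exp(-0.5 * gazerisk:::.boundary_neg2ll(paths, fd2, bp, cap))
    hits_total <- hits_total + (lik * (M + 2) - 1)
  }
  b <- boundary_value(seq_len(cap), bp)
  crossed <- apply(paths[[1]]$Ymax, 1, function(y) any(y >= b))
  expect_equal(hits_total, sum(crossed), tolerance = 1e-6)
  expect_lte(hits_total, M + 1e-6)
  # an impossible observation sits at the smoothing floor
  lik0 <- choice_rt_likelihood(pr, s, "A", par, "two_layer",
                               boundary_params("fixed", b0 = 1e9),
                               M = M, cap = cap, seed = 77)
  expect_equal(lik0, 1 / (M + 2), tolerance = 1e-12)
})

test_that("choice_rt_likelihood uses nfix of the observation", {
  # near-deterministic crossing at the observed step gives a probability
  # close to its ceiling M / (M + 2)
  pr <- data.frame(x_a = 24, p_a = .8, x_b = 3, p_b = .1)
  par <- process_params(alpha = 1, gamma = 1, theta = 1, lam = 0, beta = 1,
                        sigma = 1e-9)
  bp <- boundary_params("fixed", b0 = 1e-6)
  lik <- choice_rt_likelihood(pr, c(1L, 2L), "A", par, "one_layer", bp,
                              M = 100L, cap = 10L, seed = 3)
  # crossing is forced at t = 1, so observing t = 2 is impossible...
  expect_equal(lik, 1 / 102, tolerance = 1e-12)
  # ...and observing t = 1 with the dominant winner is certain
  lik1 <- choice_rt_likelihood(pr, 1L, "A", par, "one_layer", bp,
                               M = 100L, cap = 10L, seed = 3)
  expect_equal(lik1, 101 / 102, tolerance = 1e-12)
})

test_that("boundary fitting recovers a generative fixed boundary", {
  set.seed(10)
  problems <- enumerate_problems(dc, seed = 2)
  pop <- population_config()
  pt <- with_seed(42, sample_participant(pop, id = "S1"))
  b_true <- 4
  ds <- simulate_experiment(dc, participants = list(pt), mode = "step2",
                            bp = boundary_params("fixed", b0 = b_true),
                            problems = problems[!problems$is_catch, ][1:40, ],
                            cap = 60L, seed = 21)
  fd <- prepare_participant(ds$trials, ds$fixations, ds$problems)
  fit <- fit_boundary(fd, pt$process, variant = "two_layer",
                      family = "fixed", M = 100L, cap = 40L, seed = 5)
  expect_lt(abs(fit$bp$b0 - b_true) / b_true, 0.2)
  # collapsing fit on fixed-boundary data keeps b_inf near b0 (no collapse)
  fitc <- fit_boundary(fd, pt$process, variant = "two_layer",
                       family = "collapsing", M = 100L, cap = 40L, seed = 5)
  expect_lte(fitc$neg2ll, fit$neg2ll + 1e-6)
})

test_that("Vincentized quantiles average per-participant quantiles", {
  expect_equal(unname(vincentized_quantiles(list(c(4, 4, 4), c(6, 6, 6)),
                                            probs = c(.1, .5, .9))),
               c(5, 5, 5))
  x <- rlnorm(200, 2, .4)
  expect_equal(vincentized_quantiles(list(x), probs = c(.3, .7)),
               c(q0.3 = unname(quantile(x, .3)),
                 q0.7 = unname(quantile(x, .7))))
  expect_error(vincentized_quantiles(list()), "no participants")
  expect_error(vincentized_quantiles(list(numeric(0))), "empty")
})
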