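dc <- design_config()
problems <- enumerate_problems(dc, seed = 1)

test_that("EV psychometrics: slope sign, separation flag, RT correlation", {
  tr <- data.frame(participant_id = "P1",
                   trial_id = sprintf("t%03d", seq_len(nrow(problems))),
                   problem_id = problems$problem_id,
                   choice = "A", rt_ms = 3000, stringsAsFactors = FALSE)
  dev <- delta_ev(problems)
  # perfectly EV-consistent chooser -> separation flagged
  tr$choice <- ifelse(dev > 0, "A", "B")
  psy <- ev_psychometrics(tr, problems)
  expect_true(psy$separated)
  # noisy but EV-sensitive chooser -> positive bounded slope
  set.seed(12)
  p <- plogis(0.5 * dev)
  tr$choice <- ifelse(runif(nrow(tr)) < p, "A", "B")
  psy2 <- ev_psychometrics(tr, problems)
  expect_false(psy2$separated)
  expect_gt(psy2$slope, 0)
  # RT decreasing in |dEV| -> negative correlation; constant RT -> zero
  tr$rt_ms <- 5000 - 300 * abs(dev) + rnorm(nrow(tr), 0, 50)
  expect_lt(ev_psychometrics(tr, problems)$rt_correlation, -0.9)
  tr$rt_ms <- 4000
  expect_equal(ev_psychometrics(tr, problems)$rt_correlation, 0)
})

test_that("risk preference splits by probability domain", {
  tro <- problems[problems$relation == "tradeoff", ]
  rc <- risk_classification(tro)
  tr <- data.frame(participant_id = "P1",
                   trial_id = sprintf("t%03d", seq_len(nrow(tro))),
                   problem_id = tro$problem_id,
                   choice = rc$riskier, rt_ms = 3000,
                   stringsAsFactors = FALSE)
  rp <- risk_preference(tr, problems)
  expect_equal(unname(rp[c("low", "medium_high")]), c(1, 1))
  # always-safe chooser
  tr$choice <- ifelse(rc$riskier == "A", "B", "A")
  rp0 <- risk_preference(tr, problems)
  expect_equal(unname(rp0[["overall"]]), 0)
  # the window restricts to near-equal-EV problems
  dev <- delta_ev(tro)
  expect_error(risk_preference(tr[abs(dev) > 5, ], problems,
                               ev_window = 0.001), "window")
  # the canonical low-probability example lands in the low domain
  ex <- data.frame(x_a = 24, p_a = .1, x_b = 6, p_b = .5)
  expect_equal(risk_classification(ex)$probability_domain, "low")
})

test_that("gaze-advantage residual: null under EU, positive under gaze model", {
  sim <- simulate_experiment(dc, n_participants = 1, variant = "one_layer",
                             process_override = process_params(
                               alpha = 1, gamma = 1, theta = 0.1,
                               lam = 0.3, beta = 2),
                             problems = problems, seed = 31)
  fd <- prepare_participant(sim$trials, sim$fixations, sim$problems)
  eu_fit <- fit_choice(fd, "eu", dc, n_starts = 6, seed = 2)
  adv_gaze <- gaze_advantage_residual(fd, eu_fit, mode = "count")
  expect_gt(adv_gaze, 0)
  # EU-generated choices (gaze-independent): residual difference near zero
  set.seed(41)
  ua <- subjective_utility(fd$x[, 1], fd$p[, 1], "eu", alpha = .9)
  ub <- subjective_utility(fd$x[, 2], fd$p[, 2], "eu", alpha = .9)
  p_a <- luce_prob(ua, ub, 0.8)
  fd_null <- fd
  fd_null$choice <- ifelse(runif(fd$n) < p_a, 1L, 2L)
  eu_fit2 <- fit_choice(fd_null, "eu", dc, n_starts = 6, seed = 2)
  adv_null <- gaze_advantage_residual(fd_null, eu_fit2, mode = "count")
  expect_lt(abs(adv_null), abs(adv_gaze))
  expect_lt(abs(adv_null), 0.15)
  # antisymmetry under flipping the gaze advantage
  fd_flip <- fd
  fd_flip$count_opt <- fd$count_opt[, 2:1]
  fd_flip$dwell_opt <- fd$dwell_opt[, 2:1]
  expect_equal(gaze_advantage_residual(fd_flip, eu_fit, mode = "count"),
               -adv_gaze, tolerance = 1e-12)
})

test_that("recency curve endpoints", {
  fix <- make_fixture_dataset(problems[1:30, ])
  fd <- prepare_participant(fix$trials, fix$fixations, problems,
                            include_catch = TRUE)
  # chooser that always picks the final fixation's option
  fd$choice <- ifelse(fd$aoi[cbind(seq_len(fd$n), fd$nfix)] <= 2, 1L, 2L)
  rc <- recency_curve(fd, k_last = 4)
  expect_equal(unname(rc[1]), 1)
  # choice independent of gaze stays near one half
  set.seed(3)
  fd$choice <- sample(1:2, fd$n, replace = TRUE)
  rc2 <- recency_curve(fd, k_last = 2)
  expect_true(all(rc2 >= 0.2 & rc2 <= 0.8))
})

test_that("transitivity violations count strict cycles", {
  # one cyclic triplet
  cyc <- data.frame(x_a = c(10, 20, 30), p_a = c(.9, .8, .7),
                    x_b = c(20, 30, 10), p_b = c(.8, .7, .9),
                    choice = c("A", "A", "A"))
  expect_equal(transitivity_violations(cyc), 1)
  # transitive pattern
  tra <- cyc; tra$choice <- c("A", "A", "B")
  expect_equal(transitivity_violations(tra), 0)
  # no complete triplet -> flagged NA
  expect_true(is.na(transitivity_violations(cyc[1:2, ])))
  # a deterministic fixed-utility chooser cannot cycle
  tro <- problems[problems$relation == "tradeoff", ]
  su_a <- subjective_utility(tro$x_a, tro$p_a, "cpt", alpha = .8,
                             gamma = .7)
  su_b <- subjective_utility(tro$x_b, tro$p_b, "cpt", alpha = .8,
                             gamma = .7)
  det <- data.frame(tro[, c("x_a", "p_a", "x_b", "p_b")],
                    choice = ifelse(su_a >= su_b, "A", "B"))
  expect_equal(transitivity_violations(det), 0)
})

test_that("EV-quantile accuracy partitions trials", {
  fix <- make_fixture_dataset(problems[problems$relation == "tradeoff", ])
  fd <- prepare_participant(fix$trials, fix$fixations, problems)
  fd <- gazerisk:::.subset_gr_data(fd, fd$delta_ev != 0)  # drop exact ties
  # a perfect oracle model scores 1 in every bin
  fd$choice <- ifelse(fd$delta_ev > 0, 1L, 2L)
  oracle <- structure(list(model = "ev", kind = "static",
                           params = list(beta = 50)), class = "gr_fit")
  tab <- ev_quantile_accuracy(list(oracle), fd, n_quantiles = 5)
  expect_equal(sum(tab$n), fd$n)
  expect_true(all(tab$accuracy == 1))
  expect_error(ev_quantile_accuracy(list(oracle), fd, n_quantiles = 1000),
               "quantiles")
})

test_that("normativity: EV-maximizer limit and model identity", {
  # the EV-maximizer limit (beta large, alpha = gamma = 1, theta = 1,
  # lam = 0) approaches EV choice as integration washes out the mid-range
  # defaults, so use long balanced sequences
  tro <- problems[problems$relation == "tradeoff", ]
  nf <- 40L
  trials <- data.frame(participant_id = "P1",
                       trial_id = sprintf("t%03d", seq_len(nrow(tro))),
                       problem_id = tro$problem_id, choice = "A",
                       rt_ms = 3000, stringsAsFactors = FALSE)
  aoi_seq <- rep(c("amount_a", "prob_a", "amount_b", "prob_b"),
                 length.out = nf)
  fx <- do.call(rbind, lapply(seq_len(nrow(tro)), function(i)
    data.frame(participant_id = "P1", trial_id = trials$trial_id[i],
               aoi = aoi_seq, onset_ms = seq(0, by = 400, length.out = nf),
               duration_ms = 350, stringsAsFactors = FALSE)))
  fd <- prepare_participant(trials, fx, problems)
  evmax <- structure(list(model = "two_layer", kind = "accumulator",
                          params = list(alpha = 1, gamma = 1, theta = 1,
                                        lam = 0, beta = 50)),
                     class = "gr_fit")
  out <- normativity_comparison(fd, list(m1 = evmax, m2 = evmax), dc,
                                seed = 4)
  expect_gt(out$ev_choice_fraction[1], 0.97)
  expect_lte(out$transitivity_violations[1], 0.02)
})
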