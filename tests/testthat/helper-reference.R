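# Independent oracles and fixture builders shared by the tests.

# Naive reference simulator for all accumulator variants: plain scalar loops,
# written directly from the model definitions and kept independent of the
# package's accumulation code paths.
ref_accumulate <- function(x_a, p_a, x_b, p_b, aoi_codes, par, variant,
                           amount_levels = c(3, 6, 15, 24, 30),
                           prob_levels = c(0.1, 0.2, 0.5, 0.8, 1),
                           noise = NULL) {
  `%||%` <- function(a, b) if (is.null(a)) b else a
  alpha <- par$alpha %||% 1; gamma <- par$gamma %||% 1
  theta <- par$theta %||% 1; lam <- par$lam %||% 0
  iota <- par$iota %||% 0
  lam1 <- par$lam1 %||% lam
  wfun <- function(p) p^gamma / (p^gamma + (1 - p)^gamma)^(1 / gamma)
  mid_x <- (min(amount_levels) + max(amount_levels)) / 2
  mid_p <- (min(prob_levels) + max(prob_levels)) / 2
  if (variant %in% c("one_layer", "two_layer", "hybrid")) {
    s_true <- c(x_a^alpha, wfun(p_a), x_b^alpha, wfun(p_b))
    s_def <- c(mid_x^alpha, wfun(mid_p), mid_x^alpha, wfun(mid_p))
  } else if (variant == "wa_normalized") {
    nx <- function(v) (v - min(amount_levels)) /
      (max(amount_levels) - min(amount_levels))
    np <- function(v) (v - min(prob_levels)) /
      (max(prob_levels) - min(prob_levels))
    s_true <- c(nx(x_a), np(p_a), nx(x_b), np(p_b))
    s_def <- c(nx(mid_x), np(mid_p), nx(mid_x), np(mid_p))
  } else {
    s_true <- c(x_a, p_a, x_b, p_b)
    s_def <- c(mid_x, mid_p, mid_x, mid_p)
  }
  partner <- c(3, 4, 1, 2)
  seen <- rep(FALSE, 4)
  A <- rep(0, 4)
  YA <- 0; YB <- 0
  for (t in seq_along(aoi_codes)) {
    a <- aoi_codes[t]
    seen[a] <- TRUE
    v <- ifelse(seen, s_true, s_def)
    nz <- if (is.null(noise)) c(0, 0) else noise[t, ]
    if (variant == "one_layer") {
      su_a <- v[1] * v[2]; su_b <- v[3] * v[4]
      if (a <= 2) {
        YA <- (1 - lam) * YA + su_a + nz[1]
        YB <- (1 - lam) * YB + theta * su_b + nz[2]
      } else {
        YA <- (1 - lam) * YA + theta * su_a + nz[1]
        YB <- (1 - lam) * YB + su_b + nz[2]
      }
    } else if (variant %in% c("two_layer", "hybrid")) {
      Aold <- A
      for (m in 1:4) {
        w <- if (m == a) 1 else theta
        A[m] <- (1 - lam1) * Aold[m] + w * v[m]
        if (variant == "hybrid") {
          A[m] <- A[m] - iota * Aold[partner[m]]
          if (A[m] < 0) A[m] <- 0
        }
      }
      YA <- (1 - lam) * YA + A[1] * A[2] + nz[1]
      YB <- (1 - lam) * YB + A[3] * A[4] + nz[2]
    } else {
      vi <- v[a]; vj <- v[partner[a]]
      if (variant == "wa_normalized") {
        d <- vi - theta * vj
        if (a <= 2) {
          YA <- (1 - lam) * YA + d + nz[1]
          YB <- (1 - lam) * YB - d + nz[2]
        } else {
          YA <- (1 - lam) * YA - d + nz[1]
          YB <- (1 - lam) * YB + d + nz[2]
        }
      } else {
        wi <- as.numeric(vi > theta * vj)
        wj <- as.numeric(theta * vj > vi)
        if (a <= 2) {
          YA <- (1 - lam) * YA + wi + nz[1]
          YB <- (1 - lam) * YB + wj + nz[2]
        } else {
          YA <- (1 - lam) * YA + wj + nz[1]
          YB <- (1 - lam) * YB + wi + nz[2]
        }
      }
    }
  }
  c(A = YA, B = YB)
}

# Random problem from the default grid (trade-off not guaranteed).
rand_problem <- function() {
  data.frame(x_a = sample(c(3, 6, 15, 24, 30), 1),
             p_a = sample(c(.1, .2, .5, .8, 1), 1),
             x_b = sample(c(3, 6, 15, 24, 30), 1),
             p_b = sample(c(.1, .2, .5, .8, 1), 1))
}

# Random AOI code sequence with no immediate repeats.
rand_aoi_seq <- function(n) {
  out <- integer(n)
  out[1] <- sample.int(4, 1)
  for (t in seq_len(n - 1)) {
    out[t + 1] <- sample(setdiff(1:4, out[t]), 1)
  }
  out
}

# Random process parameters inside the fitting bounds.
rand_params <- function(sigma = 0) {
  process_params(alpha = runif(1, 0.2, 1.8), gamma = runif(1, 0.3, 1.8),
                 theta = runif(1, 0, 1), lam = runif(1, 0, 1),
                 beta = runif(1, 0.1, 2), iota = runif(1, 0, 0.5),
                 sigma = sigma)
}

# Tiny deterministic fixture: trials + fixations for one participant over a
# given problem table, with an arbitrary but valid AOI pattern.
make_fixture_dataset <- function(problems, participant_id = "P1",
                                 nfix = 6L, rt_ms = 3000) {
  trials <- data.frame(participant_id = participant_id,
                       trial_id = sprintf("t%03d", seq_len(nrow(problems))),
                       problem_id = problems$problem_id,
                       choice = rep(c("A", "B"),
                                    length.out = nrow(problems)),
                       rt_ms = rt_ms, stringsAsFactors = FALSE)
  fx <- do.call(rbind, lapply(seq_len(nrow(problems)), function(i) {
    aoi <- c("amount_a", "prob_a", "amount_b", "prob_b",
             "amount_a", "prob_b")[seq_len(nfix)]
    data.frame(participant_id = participant_id,
               trial_id = trials$trial_id[i], aoi = aoi,
               onset_ms = seq(0, by = 400, length.out = nfix),
               duration_ms = rep(350, nfix), stringsAsFactors = FALSE)
  }))
  list(trials = trials, fixations = fx)
}
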