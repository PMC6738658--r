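# Vectorized accumulator core: advances all trials of a participant in
# lockstep, one fixation index at a time. Must agree with run_sequence()
# exactly (tested); exists because the likelihood is evaluated thousands of
# times inside the optimizer.

# Subjective/normalized/raw attribute values for all trials: list(S n x 4,
# S0 length 4 defaults).
.batch_values <- function(fd, params, variant, design) {
  al <- design$amount_levels; pl <- design$prob_levels
  mid_x <- (min(al) + max(al)) / 2
  mid_p <- (min(pl) + max(pl)) / 2
  x <- fd$x; p <- fd$p
  if (variant %in% c("one_layer", "two_layer", "hybrid")) {
    S <- cbind(utility(x[, 1L], params$alpha),
               prob_weight(p[, 1L], params$gamma),
               utility(x[, 2L], params$alpha),
               prob_weight(p[, 2L], params$gamma))
    S0 <- c(utility(mid_x, params$alpha), prob_weight(mid_p, params$gamma),
            utility(mid_x, params$alpha), prob_weight(mid_p, params$gamma))
  } else if (variant == "wa_normalized") {
    nx <- function(v) (v - min(al)) / (max(al) - min(al))
    np <- function(v) (v - min(pl)) / (max(pl) - min(pl))
    S <- cbind(nx(x[, 1L]), np(p[, 1L]), nx(x[, 2L]), np(p[, 2L]))
    S0 <- c(nx(mid_x), np(mid_p), nx(mid_x), np(mid_p))
  } else {
    S <- cbind(x[, 1L], p[, 1L], x[, 2L], p[, 2L])
    S0 <- c(mid_x, mid_p, mid_x, mid_p)
  }
  list(S = S, S0 = S0)
}

# Final (Y_A, Y_B) for every trial in fd under `params`/`variant`.
# noise: optional n x Tmax x 2 array of raw additive noise.
# paths = TRUE additionally returns the full n x Tmax accumulator paths.
.accumulate_batch <- function(fd, params, variant, design = design_config(),
                              noise = NULL, paths = FALSE) {
  variant <- match.arg(variant, .variants)
  n <- fd$n
  Tmax <- ncol(fd$aoi)
  if (paths) { PA <- matrix(NA_real_, n, Tmax); PB <- matrix(NA_real_, n, Tmax) }
  sv <- .batch_values(fd, params, variant, design)
  S <- sv$S
  S0mat <- matrix(sv$S0, n, 4L, byrow = TRUE)
  lam <- params$lam
  lam1 <- params$lam1 %||% lam
  th <- params$theta
  iota <- params$iota %||% 0
  YA <- numeric(n); YB <- numeric(n)
  two_layerish <- variant %in% c("two_layer", "hybrid")
  if (two_layerish) A1 <- matrix(0, n, 4L)
  for (t in seq_len(Tmax)) {
    idx <- which(fd$nfix >= t)
    if (!length(idx)) break
    a <- fd$aoi[idx, t]
    V <- S[idx, , drop = FALSE]
    notav <- fd$first_fix[idx, , drop = FALSE] > t
    V[notav] <- S0mat[idx, , drop = FALSE][notav]
    nz <- if (is.null(noise)) NULL else noise[idx, t, , drop = FALSE]
    nzA <- if (is.null(nz)) 0 else nz[, , 1L]
    nzB <- if (is.null(nz)) 0 else nz[, , 2L]
    fix_a <- a <= 2L
    if (variant == "one_layer") {
      sua <- V[, 1L] * V[, 2L]
      sub <- V[, 3L] * V[, 4L]
      YA[idx] <- (1 - lam) * YA[idx] + ifelse(fix_a, sua, th * sua) + nzA
      YB[idx] <- (1 - lam) * YB[idx] + ifelse(fix_a, th * sub, sub) + nzB
    } else if (two_layerish) {
      W <- matrix(th, length(idx), 4L)
      W[cbind(seq_along(idx), a)] <- 1
      Aold <- A1[idx, , drop = FALSE]
      Anew <- (1 - lam1) * Aold + W * V
      if (variant == "hybrid") {
        Anew <- Anew - iota * Aold[, .aoi_partner, drop = FALSE]
        Anew[Anew < 0] <- 0
      }
      A1[idx, ] <- Anew
      YA[idx] <- (1 - lam) * YA[idx] + Anew[, 1L] * Anew[, 2L] + nzA
      YB[idx] <- (1 - lam) * YB[idx] + Anew[, 3L] * Anew[, 4L] + nzB
    } else {
      ii <- cbind(seq_along(idx), a)
      jj <- cbind(seq_along(idx), .aoi_partner[a])
      vi <- V[ii]; vj <- V[jj]
      if (variant == "wa_normalized") {
        d <- vi - th * vj
        YA[idx] <- (1 - lam) * YA[idx] + ifelse(fix_a, d, -d) + nzA
        YB[idx] <- (1 - lam) * YB[idx] + ifelse(fix_a, -d, d) + nzB
      } else {
        win_i <- as.numeric(vi > th * vj)
        win_j <- as.numeric(th * vj > vi)
        YA[idx] <- (1 - lam) * YA[idx] + ifelse(fix_a, win_i, win_j) + nzA
        YB[idx] <- (1 - lam) * YB[idx] + ifelse(fix_a, win_j, win_i) + nzB
      }
    }
    if (paths) { PA[idx, t] <- YA[idx]; PB[idx, t] <- YB[idx] }
  }
  if (paths) list(final = cbind(A = YA, B = YB), Y_A = PA, Y_B = PB)
  else cbind(A = YA, B = YB)
}
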