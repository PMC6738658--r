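# Gaze-driven leaky-accumulation dynamics. Five variants:
#   wa_normalized  - within-attribute, normalized value differences
#   wa_categorical - within-attribute, categorical (ordinal) differences
#   one_layer      - within-alternative, attentionally gated subjective
#                    utilities accumulated per alternative
#   two_layer      - cascade: four attribute-level leaky units feeding two
#                    alternative-level units that integrate the product of
#                    their paired attribute activations
#   hybrid         - two_layer plus mutual inhibition between same-attribute
#                    units of the two options (rectified at zero)
#
# All variants substitute mid-range default values for attributes that have
# not yet been fixated; the true subjective value enters from an attribute's
# first fixation onward.

.variants <- c("wa_normalized", "wa_categorical", "one_layer", "two_layer",
               "hybrid")

#' Process-model parameters
#'
#' @param alpha utility curvature (> 0).
#' @param gamma probability-weighting curvature (> 0).
#' @param theta attentional attenuation of unattended inputs, in \[0, 1\].
#' @param lam activation leak in \[0, 1\]; accumulators decay by `1 - lam`
#'   per fixation. `lam = 0` is perfect (drift-diffusion-like) integration.
#' @param beta Luce choice sensitivity (>= 0).
#' @param iota mutual inhibition between same-attribute units (hybrid only).
#' @param sigma per-step Gaussian noise scale on the alternative-level
#'   accumulators; 0 for Step-1 (choice-only) fitting.
#' @param lam1 optional separate leak for the first layer of the two-layer /
#'   hybrid cascade; defaults to `lam` (single shared leak).
#' @return a named list of class `process_params`.
#' @export
process_params <- function(alpha = 1, gamma = 1, theta = 1, lam = 0,
                           beta = 1, iota = 0, sigma = 0, lam1 = NULL) {
  .assert_number(alpha, "alpha", lower = 1e-8)
  .assert_number(gamma, "gamma", lower = 1e-8)
  .assert_number(theta, "theta", lower = 0, upper = 1)
  .assert_number(lam, "lam", lower = 0, upper = 1)
  .assert_number(beta, "beta", lower = 0)
  .assert_number(iota, "iota", lower = 0)
  .assert_number(sigma, "sigma", lower = 0)
  if (!is.null(lam1)) .assert_number(lam1, "lam1", lower = 0, upper = 1)
  structure(list(alpha = alpha, gamma = gamma, theta = theta, lam = lam,
                 beta = beta, iota = iota, sigma = sigma, lam1 = lam1),
            class = "process_params")
}

# Variant-appropriate attribute values (true and default) for one problem.
# Values are ordered (amount_a, prob_a, amount_b, prob_b).
.attr_values <- function(x_a, p_a, x_b, p_b, params, variant, design) {
  al <- design$amount_levels; pl <- design$prob_levels
  mid_x <- (min(al) + max(al)) / 2
  mid_p <- (min(pl) + max(pl)) / 2
  if (variant %in% c("one_layer", "two_layer", "hybrid")) {
    s <- c(utility(x_a, params$alpha), prob_weight(p_a, params$gamma),
           utility(x_b, params$alpha), prob_weight(p_b, params$gamma))
    s0 <- c(utility(mid_x, params$alpha), prob_weight(mid_p, params$gamma),
            utility(mid_x, params$alpha), prob_weight(mid_p, params$gamma))
  } else if (variant == "wa_normalized") {
    nx <- function(x) (x - min(al)) / (max(al) - min(al))
    np <- function(p) (p - min(pl)) / (max(pl) - min(pl))
    s <- c(nx(x_a), np(p_a), nx(x_b), np(p_b))
    s0 <- c(nx(mid_x), np(mid_p), nx(mid_x), np(mid_p))  # = 0.5
  } else {  # wa_categorical: raw values
    s <- c(x_a, p_a, x_b, p_b)
    s0 <- c(mid_x, mid_p, mid_x, mid_p)
  }
  list(true = s, default = s0)
}

#' Initialize attribute inputs for an accumulation run
#'
#' All four attributes start at the subjective value of the design mid-range
#' defaults ((min + max) / 2 of the amount and probability levels); an
#' attribute's true subjective value replaces the default at its first
#' fixation.
#'
#' @param problem one-row data.frame (or list) with `x_a`, `p_a`, `x_b`,
#'   `p_b`.
#' @param params a [process_params()].
#' @param design a [design_config()].
#' @param variant model variant (see package overview).
#' @return list with `true` and `default` value vectors (AOI order
#'   `amount_a, prob_a, amount_b, prob_b`) and the logical `seen` state.
#' @export
init_inputs <- function(problem, params, design = design_config(),
                        variant = "two_layer") {
  variant <- match.arg(variant, .variants)
  v <- .attr_values(problem$x_a, problem$p_a, problem$x_b, problem$p_b,
                    params, variant, design)
  v$seen <- rep(FALSE, 4L)
  names(v$true) <- names(v$default) <- names(v$seen) <- .aoi_levels
  v
}

#' One accumulation step
#'
#' Advances the accumulator state by one fixation. `values` must already
#' reflect default substitution for the current step (i.e. the fixated
#' attribute's true value is visible from this step on).
#'
#' @param state list with `layer1` (4 activations; used by two_layer/hybrid)
#'   and `Y` (2 alternative preferences).
#' @param aoi fixated AOI (label or code 1..4).
#' @param values length-4 attribute input vector for this step.
#' @param params a [process_params()].
#' @param variant model variant.
#' @param noise length-2 noise draws added to the alternative accumulators
#'   (scaled by `sigma` internally when generated upstream; pass raw
#'   additive terms here).
#' @return updated state.
#' @export
accumulator_step <- function(state, aoi, values, params,
                             variant = "two_layer", noise = c(0, 0)) {
  variant <- match.arg(variant, .variants)
  a <- .aoi_code(aoi)
  lam <- params$lam
  lam1 <- params$lam1 %||% lam
  th <- params$theta
  Y <- state$Y
  A1 <- state$layer1
  if (variant == "one_layer") {
    su <- c(values[1L] * values[2L], values[3L] * values[4L])
    w <- if (a <= 2L) c(1, th) else c(th, 1)
    Y <- (1 - lam) * Y + w * su + noise
  } else if (variant %in% c("two_layer", "hybrid")) {
    w <- rep(th, 4L); w[a] <- 1
    A1new <- (1 - lam1) * A1 + w * values
    if (variant == "hybrid") {
      A1new <- A1new - params$iota * A1[.aoi_partner]
      A1new <- pmax(A1new, 0)
    }
    A1 <- A1new
    Y <- (1 - lam) * Y + c(A1[1L] * A1[2L], A1[3L] * A1[4L]) + noise
  } else {
    # within-attribute: comparison on the fixated attribute
    vi <- values[a]; vj <- values[.aoi_partner[a]]
    fix_a <- a <= 2L
    if (variant == "wa_normalized") {
      d <- vi - th * vj
      inc <- if (fix_a) c(d, -d) else c(-d, d)
    } else {
      win_i <- vi > th * vj
      win_j <- th * vj > vi
      inc <- if (fix_a) c(win_i, win_j) else c(win_j, win_i)
      inc <- as.numeric(inc)
    }
    Y <- (1 - lam) * Y + inc + noise
  }
  list(layer1 = unname(A1), Y = unname(Y),
       step = (state$step %||% 0L) + 1L)
}

#' Run the accumulator over a fixation sequence
#'
#' Applies [init_inputs()] and then one [accumulator_step()] per fixation,
#' with default substitution at each attribute's first fixation. Returns the
#' final alternative preferences and the full trace.
#'
#' @param problem one-row data.frame with `x_a`, `p_a`, `x_b`, `p_b`.
#' @param aoi AOI sequence (labels or codes).
#' @param params a [process_params()].
#' @param variant model variant.
#' @param design a [design_config()].
#' @param noise optional `length(aoi) x 2` matrix of additive noise for the
#'   alternative accumulators (already scaled); defaults to none.
#' @return list with `Y` (named final preferences), and `trace` (data.frame
#'   with step, aoi, the four layer-1 activations and `Y_A`, `Y_B`).
#' @export
run_sequence <- function(problem, aoi, params, variant = "two_layer",
                         design = design_config(), noise = NULL) {
  variant <- match.arg(variant, .variants)
  code <- .aoi_code(aoi)
  n <- length(code)
  if (n == 0L) stop("empty fixation sequence", call. = FALSE)
  if (is.null(noise)) noise <- matrix(0, n, 2L)
  inp <- init_inputs(problem, params, design, variant)
  seen <- rep(FALSE, 4L)
  state <- list(layer1 = rep(0, 4L), Y = c(0, 0), step = 0L)
  trace <- matrix(NA_real_, n, 6L)
  for (t in seq_len(n)) {
    seen[code[t]] <- TRUE
    vals <- ifelse(seen, inp$true, inp$default)
    state <- accumulator_step(state, code[t], vals, params, variant,
                              noise[t, ])
    trace[t, ] <- c(state$layer1, state$Y)
  }
  colnames(trace) <- c(paste0("a_", .aoi_levels), "Y_A", "Y_B")
  list(Y = c(A = state$Y[1L], B = state$Y[2L]),
       trace = data.frame(step = seq_len(n), aoi = .aoi_label(code), trace,
                          stringsAsFactors = FALSE))
}

#' Choice probability from final accumulator states
#'
#' Step-1 (noise-free) mode: the exponential Luce rule applied to the final
#' preference difference.
#'
#' @param y_a,y_b final accumulator values.
#' @param beta Luce sensitivity.
#' @export
choice_prob_from_final <- function(y_a, y_b, beta) luce_prob(y_a, y_b, beta)
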