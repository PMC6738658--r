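# Experimental design: the amount x probability lottery grid, dominance
# classification, problem enumeration and risk taxonomy.

#' Design configuration for the lottery grid
#'
#' Describes the stimulus space of a two-alternative risky-choice experiment:
#' each lottery is a single gain `x` obtained with probability `p` (otherwise
#' nothing), and lotteries live on the Cartesian grid of `amount_levels` by
#' `prob_levels`. Defaults reproduce the 5x5 grid of the experiment the
#' package emulates: amounts 3, 6, 15, 24, 30 ILS and win probabilities
#' .1, .2, .5, .8, 1.
#'
#' @param amount_levels strictly increasing positive monetary amounts (ILS).
#' @param prob_levels strictly increasing win probabilities in (0, 1].
#' @param n_catch number of dominated catch trials to include.
#' @param problem_subset optional character vector of problem ids restricting
#'   the trade-off problems (for replicating a published subset).
#' @return an object of class `design_config`.
#' @examples
#' dc <- design_config()
#' nrow(build_grid(dc))  # 25
#' @export
design_config <- function(amount_levels = c(3, 6, 15, 24, 30),
                          prob_levels = c(0.1, 0.2, 0.5, 0.8, 1),
                          n_catch = 10L,
                          problem_subset = NULL) {
  if (length(amount_levels) < 1L || length(prob_levels) < 1L)
    stop("level lists must be non-empty", call. = FALSE)
  if (anyDuplicated(amount_levels) || anyDuplicated(prob_levels))
    stop("duplicate levels in design", call. = FALSE)
  if (is.unsorted(amount_levels, strictly = TRUE) ||
      is.unsorted(prob_levels, strictly = TRUE))
    stop("levels must be strictly increasing", call. = FALSE)
  if (any(amount_levels <= 0))
    stop("amounts must be strictly positive", call. = FALSE)
  if (any(prob_levels <= 0) || any(prob_levels > 1))
    stop("probabilities must lie in (0, 1]", call. = FALSE)
  structure(list(amount_levels = as.numeric(amount_levels),
                 prob_levels = as.numeric(prob_levels),
                 n_catch = as.integer(n_catch),
                 problem_subset = problem_subset),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("Risky-choice design:",
      length(x$amount_levels), "amounts x",
      length(x$prob_levels), "probabilities,",
      x$n_catch, "catch trials\n")
  cat("  amounts (ILS):", paste(x$amount_levels, collapse = ", "), "\n")
  cat("  probabilities:", paste(x$prob_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Build the lottery grid
#'
#' One lottery per (amount, probability) pair of the design levels.
#'
#' @param config a [design_config()].
#' @return data.frame with columns `lottery_id`, `amount`, `prob`, one row per
#'   grid cell (amount varying fastest within probability).
#' @export
build_grid <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  g <- expand.grid(amount = config$amount_levels, prob = config$prob_levels,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(lottery_id = sprintf("L%02d", seq_len(nrow(g))),
             amount = g$amount, prob = g$prob,
             stringsAsFactors = FALSE)
}

#' Classify a pair of lotteries by dominance
#'
#' A lottery stochastically dominates another when both its amount and its
#' probability are at least as high, with at least one strictly higher.
#'
#' @param amount_a,prob_a,amount_b,prob_b lottery attributes (vectorized).
#' @return character vector: `"tradeoff"`, `"a_dominates"`, `"b_dominates"`
#'   or `"equal"`.
#' @examples
#' classify_pair(20, .5, 10, .5)  # "a_dominates"
#' classify_pair(24, .1, 6, .5)   # "tradeoff"
#' @export
classify_pair <- function(amount_a, prob_a, amount_b, prob_b) {
  ge_a <- amount_a >= amount_b & prob_a >= prob_b
  ge_b <- amount_b >= amount_a & prob_b >= prob_a
  eq <- amount_a == amount_b & prob_a == prob_b
  out <- rep("tradeoff", length(ge_a))
  out[ge_a & !eq] <- "a_dominates"
  out[ge_b & !eq] <- "b_dominates"
  out[eq] <- "equal"
  out
}

#' Enumerate choice problems from a design
#'
#' All unordered trade-off pairs of grid lotteries (or the configured subset),
#' plus `n_catch` dominated pairs sampled with the seed as catch trials. The
#' first lottery in grid order is labeled option A; in catch trials the
#' dominant option may be either A or B.
#'
#' @param config a [design_config()].
#' @param seed integer seed used only for catch-trial sampling.
#' @return data.frame with columns `problem_id`, `x_a`, `p_a`, `x_b`, `p_b`,
#'   `relation`, `is_catch`.
#' @export
enumerate_problems <- function(config = design_config(), seed = 1L) {
  grid <- build_grid(config)
  n <- nrow(grid)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  rel <- classify_pair(grid$amount[i], grid$prob[i],
                       grid$amount[j], grid$prob[j])
  pairs <- data.frame(x_a = grid$amount[i], p_a = grid$prob[i],
                      x_b = grid$amount[j], p_b = grid$prob[j],
                      relation = rel, stringsAsFactors = FALSE)
  trade <- pairs[pairs$relation == "tradeoff", , drop = FALSE]
  trade$problem_id <- sprintf("T%03d", seq_len(nrow(trade)))
  if (!is.null(config$problem_subset)) {
    missing <- setdiff(config$problem_subset, trade$problem_id)
    if (length(missing))
      stop("problem_subset ids not in enumeration: ",
           paste(missing, collapse = ", "), call. = FALSE)
    trade <- trade[trade$problem_id %in% config$problem_subset, , drop = FALSE]
  }
  trade$is_catch <- FALSE

  dom <- pairs[pairs$relation %in% c("a_dominates", "b_dominates"), ,
               drop = FALSE]
  if (config$n_catch > nrow(dom))
    stop("n_catch exceeds the number of dominated pairs", call. = FALSE)
  if (config$n_catch > 0L) {
    pick <- with_seed(seed, sample.int(nrow(dom), config$n_catch))
    catch <- dom[pick, , drop = FALSE]
    catch$problem_id <- sprintf("C%03d", seq_len(nrow(catch)))
    catch$is_catch <- TRUE
    out <- rbind(trade, catch)
  } else {
    out <- trade
  }
  rownames(out) <- NULL
  out[, c("problem_id", "x_a", "p_a", "x_b", "p_b", "relation", "is_catch")]
}

#' Expected value of a lottery and EV difference of a problem
#'
#' @param amount,prob lottery attributes (vectorized).
#' @return `expected_value`: `amount * prob`.
#' @examples
#' expected_value(30, .5)  # 15
#' @export
expected_value <- function(amount, prob) amount * prob

#' @rdname expected_value
#' @param problems data.frame with columns `x_a`, `p_a`, `x_b`, `p_b`.
#' @return `delta_ev`: EV(A) - EV(B) per problem.
#' @export
delta_ev <- function(problems) {
  problems$x_a * problems$p_a - problems$x_b * problems$p_b
}

#' Risk classification of a trade-off problem
#'
#' The riskier option of a trade-off pair is the higher-amount /
#' lower-probability one. The probability domain is `"low"` when either
#' lottery has `p < cutoff` (default .25, matching the prospect-theory
#' fourfold-pattern boundary), else `"medium_high"`.
#'
#' @param problems data.frame with `x_a`, `p_a`, `x_b`, `p_b` (and optionally
#'   `relation`; recomputed if absent).
#' @param cutoff low-probability domain boundary.
#' @return data.frame with `riskier` (`"A"`/`"B"`) and `probability_domain`.
#' @export
risk_classification <- function(problems, cutoff = 0.25) {
  rel <- classify_pair(problems$x_a, problems$p_a, problems$x_b, problems$p_b)
  if (any(rel != "tradeoff"))
    stop("risk classification is defined only for trade-off pairs",
         call. = FALSE)
  riskier <- ifelse(problems$x_a > problems$x_b, "A", "B")
  domain <- ifelse(pmin(problems$p_a, problems$p_b) < cutoff,
                   "low", "medium_high")
  data.frame(riskier = riskier, probability_domain = domain,
             stringsAsFactors = FALSE)
}
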