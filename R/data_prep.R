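# Compact per-participant representation used by the fitting and simulation
# code: trial attribute matrices plus a padded AOI matrix.

#' Prepare one participant's trials for model fitting
#'
#' Merges the trial table with the problem table and packs the cleaned
#' fixation sequences into padded matrices. Catch trials are excluded by
#' default (models are fitted on trade-off problems).
#'
#' @param trials trial data.frame (`participant_id`, `trial_id`,
#'   `problem_id`, `choice`, `rt_ms`) for a single participant.
#' @param fixations cleaned fixation data.frame for the same participant.
#' @param problems problem table from [enumerate_problems()].
#' @param include_catch keep dominated catch trials?
#' @return an object of class `gr_data`: lists `x`, `p` (n x 2 matrices),
#'   `choice` (1 = A, 2 = B), `rt_ms`, `aoi` (n x Tmax integer matrix, 0
#'   padded), `nfix`, `first_fix` (n x 4, Inf when never fixated), per-option
#'   fixation counts and dwell (seconds), and `delta_ev`.
#' @export
prepare_participant <- function(trials, fixations, problems,
                                include_catch = FALSE) {
  pid <- unique(trials$participant_id)
  if (length(pid) != 1L)
    stop("prepare_participant expects a single participant", call. = FALSE)
  m <- match(trials$problem_id, problems$problem_id)
  if (anyNA(m)) stop("trial references unknown problem_id", call. = FALSE)
  tr <- cbind(trials, problems[m, c("x_a", "p_a", "x_b", "p_b", "relation",
                                    "is_catch")])
  if (!include_catch) tr <- tr[!tr$is_catch, , drop = FALSE]
  n <- nrow(tr)
  if (n == 0L) stop("no usable trials", call. = FALSE)

  fkey <- paste(fixations$participant_id, fixations$trial_id, sep = "\r")
  tkey <- paste(tr$participant_id, tr$trial_id, sep = "\r")
  seqs <- lapply(tkey, function(k) {
    f <- fixations[fkey == k, , drop = FALSE]
    list(aoi = .aoi_code(f$aoi), dur = f$duration_ms)
  })
  nfix <- vapply(seqs, function(s) length(s$aoi), integer(1))
  if (any(nfix == 0L)) stop("trial without fixations", call. = FALSE)
  Tmax <- max(nfix)
  aoi <- matrix(0L, n, Tmax)
  dur <- matrix(0, n, Tmax)
  for (i in seq_len(n)) {
    aoi[i, seq_len(nfix[i])] <- seqs[[i]]$aoi
    dur[i, seq_len(nfix[i])] <- seqs[[i]]$dur
  }
  first_fix <- matrix(Inf, n, 4L)
  for (k in 1:4) {
    hit <- aoi == k
    any_hit <- rowSums(hit) > 0
    first_fix[any_hit, k] <- apply(hit[any_hit, , drop = FALSE], 1L,
                                   which.max)
  }
  count_opt <- cbind(A = rowSums(aoi == 1L | aoi == 2L),
                     B = rowSums(aoi == 3L | aoi == 4L))
  dwell_opt <- cbind(A = rowSums(dur * (aoi == 1L | aoi == 2L)) / 1000,
                     B = rowSums(dur * (aoi == 3L | aoi == 4L)) / 1000)
  choice <- match(tr$choice, c("A", "B"))
  if (anyNA(choice)) stop("choice must be 'A' or 'B'", call. = FALSE)
  structure(list(
    participant_id = pid, n = n,
    problem_id = tr$problem_id,
    x = cbind(a = tr$x_a, b = tr$x_b),
    p = cbind(a = tr$p_a, b = tr$p_b),
    relation = tr$relation, is_catch = tr$is_catch,
    choice = choice, rt_ms = tr$rt_ms,
    aoi = aoi, dur = dur, nfix = nfix, first_fix = first_fix,
    count_opt = count_opt, dwell_opt = dwell_opt,
    delta_ev = tr$x_a * tr$p_a - tr$x_b * tr$p_b
  ), class = "gr_data")
}

#' @export
print.gr_data <- function(x, ...) {
  cat("Participant", x$participant_id, "-", x$n, "trials,",
      "median fixations/trial:", stats::median(x$nfix), "\n")
  invisible(x)
}
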