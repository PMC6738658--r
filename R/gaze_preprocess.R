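# Fixation preprocessing: AOI assignment, cleaning, trial filtering,
# transition taxonomy and per-trial gaze summaries.

#' Assign a gaze point to an area of interest
#'
#' Maps screen coordinates to one of the four attribute regions (amount and
#' probability of each option). A point is assigned to the nearest AOI center
#' within `radius_px`; ties are broken by the fixed AOI order
#' `amount_a, prob_a, amount_b, prob_b`.
#'
#' @param x_px,y_px gaze coordinates (vectorized).
#' @param layout data.frame with columns `aoi`, `x_px`, `y_px` giving the four
#'   distinct attribute centers.
#' @param radius_px assignment radius in pixels (default 100).
#' @return character vector of AOI labels, `NA` where no center is in range.
#' @export
assign_aoi <- function(x_px, y_px, layout, radius_px = 100) {
  stopifnot(all(c("aoi", "x_px", "y_px") %in% names(layout)))
  if (nrow(layout) != 4L || anyDuplicated(layout[, c("x_px", "y_px")]))
    stop("layout must give four distinct AOI centers", call. = FALSE)
  ord <- match(.aoi_levels, layout$aoi)
  if (anyNA(ord)) stop("layout must name all four AOIs", call. = FALSE)
  layout <- layout[ord, , drop = FALSE]
  d2 <- outer(x_px, layout$x_px, "-")^2 + outer(y_px, layout$y_px, "-")^2
  best <- max.col(-d2, ties.method = "first")
  hit <- d2[cbind(seq_along(best), best)] <= radius_px^2
  ifelse(hit, .aoi_levels[best], NA_character_)
}

#' Clean a fixation sequence
#'
#' Drops fixations shorter than `min_duration_ms`, then joins consecutive
#' fixations to the same AOI into one fixation (durations summed, earliest
#' onset kept). Dropping precedes merging: the duration threshold expresses
#' validity of individual fixations, not of merged runs.
#'
#' @param fixations data.frame with columns `aoi`, `onset_ms`, `duration_ms`,
#'   time-ordered by onset.
#' @param min_duration_ms minimum valid fixation duration (default 50 ms).
#' @return cleaned fixation data.frame (possibly zero rows).
#' @examples
#' f <- data.frame(aoi = c("amount_a", "amount_a"), onset_ms = c(0, 120),
#'                 duration_ms = c(120, 200))
#' clean_fixations(f)$duration_ms  # 320
#' @export
clean_fixations <- function(fixations, min_duration_ms = 50) {
  stopifnot(all(c("aoi", "onset_ms", "duration_ms") %in% names(fixations)))
  if (is.unsorted(fixations$onset_ms))
    stop("fixations must be ordered by onset", call. = FALSE)
  keep <- fixations$duration_ms >= min_duration_ms
  f <- fixations[keep, , drop = FALSE]
  if (nrow(f) == 0L) { rownames(f) <- NULL; return(f) }
  run <- cumsum(c(TRUE, f$aoi[-1L] != f$aoi[-nrow(f)]))
  out <- f[!duplicated(run), , drop = FALSE]
  out$duration_ms <- as.numeric(tapply(f$duration_ms, run, sum))
  rownames(out) <- NULL
  out
}

#' Filter trials by duration and AOI coverage
#'
#' Excludes trials with response times above `max_rt_ms` (10 s) or below
#' `min_rt_ms` (500 ms), and trials whose cleaned fixation sequence does not
#' visit all four AOIs. Duration exclusions are applied first; the report
#' additionally gives the counts under the reverse ordering, since the source
#' procedure's ordering of the two 4% exclusion rules is unstated.
#'
#' @param trials data.frame with `participant_id`, `trial_id`, `rt_ms`, ...
#' @param fixations cleaned fixation data.frame with `participant_id`,
#'   `trial_id`, `aoi`.
#' @param max_rt_ms,min_rt_ms duration bounds in ms.
#' @return list with `retained` (trial data.frame), `excluded` (with a
#'   `reason` column, `"duration"` or `"coverage"`), and `report` (counts per
#'   reason under both orderings).
#' @export
filter_trials <- function(trials, fixations,
                          max_rt_ms = 10000, min_rt_ms = 500) {
  key <- function(d) paste(d$participant_id, d$trial_id, sep = "\r")
  tk <- key(trials)
  cov_ok_keys <- {
    fk <- key(fixations)
    n_aoi <- tapply(fixations$aoi, fk, function(a) length(unique(a)))
    names(n_aoi)[n_aoi == 4L]
  }
  bad_dur <- trials$rt_ms > max_rt_ms | trials$rt_ms < min_rt_ms
  bad_cov <- !(tk %in% cov_ok_keys)

  reason <- rep(NA_character_, nrow(trials))
  reason[bad_cov] <- "coverage"
  reason[bad_dur] <- "duration"   # duration applied first takes precedence
  retained <- trials[is.na(reason), , drop = FALSE]
  excluded <- trials[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  rownames(retained) <- rownames(excluded) <- NULL

  report <- data.frame(
    ordering = c("duration_first", "duration_first",
                 "coverage_first", "coverage_first"),
    reason = c("duration", "coverage", "coverage", "duration"),
    n = c(sum(bad_dur), sum(bad_cov & !bad_dur),
          sum(bad_cov), sum(bad_dur & !bad_cov)),
    stringsAsFactors = FALSE)
  list(retained = retained, excluded = excluded, report = report)
}

#' Classify gaze transitions of a fixation sequence
#'
#' Adjacent fixation pairs fall into three categories: within-alternative
#' (same option, different attribute), within-attribute (same attribute,
#' different option) and diagonal (different option and attribute).
#'
#' @param aoi character or integer AOI sequence (cleaned, no immediate
#'   repeats).
#' @return named integer vector `within_alternative`, `within_attribute`,
#'   `diagonal`; sums to `length(aoi) - 1`.
#' @export
classify_transitions <- function(aoi) {
  code <- .aoi_code(aoi)
  n <- length(code)
  out <- c(within_alternative = 0L, within_attribute = 0L, diagonal = 0L)
  if (n < 2L) return(out)
  from <- code[-n]; to <- code[-1L]
  if (any(from == to))
    stop("sequence contains immediate AOI repeats; clean it first",
         call. = FALSE)
  same_opt <- (from <= 2L) == (to <= 2L)
  same_att <- (from %% 2L) == (to %% 2L)
  out["within_alternative"] <- sum(same_opt & !same_att)
  out["within_attribute"] <- sum(!same_opt & same_att)
  out["diagonal"] <- sum(!same_opt & !same_att)
  out
}

#' Per-trial gaze summary
#'
#' Fixation counts and dwell time per option and attribute, the share of
#' amount (probability) fixations directed at the larger amount (probability),
#' the option of the final fixation, and the gaze advantage of option A.
#'
#' @param aoi cleaned AOI sequence.
#' @param duration_ms fixation durations aligned with `aoi`.
#' @param x_a,p_a,x_b,p_b the trial's lottery attributes.
#' @return named list of summary statistics.
#' @export
gaze_stats <- function(aoi, duration_ms, x_a, p_a, x_b, p_b) {
  code <- .aoi_code(aoi)
  if (length(code) == 0L) stop("empty fixation sequence", call. = FALSE)
  is_a <- code <= 2L
  is_amount <- code %% 2L == 1L
  n_opt <- c(A = sum(is_a), B = sum(!is_a))
  dwell_opt <- c(A = sum(duration_ms[is_a]), B = sum(duration_ms[!is_a]))
  n_att <- c(amount = sum(is_amount), prob = sum(!is_amount))

  share_on <- function(on_att, fav_a) {
    m <- sum(on_att)
    if (m == 0L) return(NA_real_)
    if (is.na(fav_a)) return(0.5)      # tie: neither is "higher"
    sum(on_att & (is_a == fav_a)) / m
  }
  fav_amt <- if (x_a == x_b) NA else x_a > x_b
  fav_prb <- if (p_a == p_b) NA else p_a > p_b
  list(
    n_fixations = length(code),
    count_option = n_opt,
    dwell_option = dwell_opt,
    count_attribute = n_att,
    amount_fixation_share = n_att[["amount"]] / length(code),
    higher_amount_share = share_on(is_amount, fav_amt),
    higher_prob_share = share_on(!is_amount, fav_prb),
    final_option = if (is_a[length(code)]) "A" else "B",
    gaze_advantage_count = n_opt[["A"]] - n_opt[["B"]],
    gaze_advantage_dwell = dwell_opt[["A"]] - dwell_opt[["B"]],
    transitions = classify_transitions(code)
  )
}

#' Preprocess a raw dataset
#'
#' Applies [clean_fixations()] per trial, then [filter_trials()].
#'
#' @param trials,fixations raw trial and fixation tables (interface schema).
#' @param min_duration_ms,max_rt_ms,min_rt_ms thresholds.
#' @return list `trials` (retained), `fixations` (cleaned, retained trials
#'   only), `excluded`, `report`.
#' @export
preprocess_dataset <- function(trials, fixations, min_duration_ms = 50,
                               max_rt_ms = 10000, min_rt_ms = 500) {
  key <- paste(fixations$participant_id, fixations$trial_id, sep = "\r")
  parts <- split(fixations, factor(key, levels = unique(key)))
  cleaned <- do.call(rbind, lapply(parts, clean_fixations,
                                   min_duration_ms = min_duration_ms))
  rownames(cleaned) <- NULL
  flt <- filter_trials(trials, cleaned, max_rt_ms = max_rt_ms,
                       min_rt_ms = min_rt_ms)
  keep <- paste(cleaned$participant_id, cleaned$trial_id, sep = "\r") %in%
    paste(flt$retained$participant_id, flt$retained$trial_id, sep = "\r")
  list(trials = flt$retained, fixations = cleaned[keep, , drop = FALSE],
       excluded = flt$excluded, report = flt$report)
}
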