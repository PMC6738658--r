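# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.aoi_levels <- c("amount_a", "prob_a", "amount_b", "prob_b")

# partner AOI = same attribute, other option (index form)
.aoi_partner <- c(3L, 4L, 1L, 2L)

.aoi_code <- function(aoi) {
  if (is.numeric(aoi)) {
    code <- as.integer(aoi)
  } else {
    code <- match(as.character(aoi), .aoi_levels)
  }
  if (anyNA(code) || any(code < 1L | code > 4L))
    stop("invalid AOI label; expected one of: ",
         paste(.aoi_levels, collapse = ", "), call. = FALSE)
  code
}

.aoi_label <- function(code) .aoi_levels[code]

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
.subseed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7907) %%
               2147483647)
}

.assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s]", name, format(lower),
                 format(upper)), call. = FALSE)
  invisible(x)
}

.clip_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)
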