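#' @keywords internal
"_PACKAGE"

# Shared small helpers: validation, time handling, AUC.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower) stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower) stop_field(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper) stop_field(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

# Hour-of-day as a real number in [0, 24), from POSIXct or numeric seconds.
hour_of_day <- function(time) {
  s <- as.numeric(time) %% 86400
  s / 3600
}

# Clock hour 0-23 of a timestamp (time-zone-naive local clock convention:
# all timestamps are handled in UTC so the printed clock time is the clock).
clock_hour <- function(time) as.integer(floor(hour_of_day(time)))

# Rank-based AUC of scores for binary labels (1 = positive); equals the
# Mann-Whitney U statistic scaled to [0, 1].
auc_score <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))

# Derive a child seed stream from a master seed (stays well below 2^31).
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}
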