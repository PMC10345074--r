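# Propensity-score matching of good vs unfavorable outcome groups on age
# and NIHSS: logistic propensity, greedy 1:1 nearest-neighbour on the logit
# scale without replacement, caliper 0.2 SD of the logit propensity.

#' Estimate propensity scores for group membership
#'
#' Logistic regression of group membership (unfavorable = 1) on the given
#' covariates. Under (quasi-)separation the plain fit is replaced by a
#' lightly ridge-penalized fit so that finite propensities are always
#' returned.
#'
#' @param covariates Data frame with a `group` column
#'   (`good`/`unfavorable`) and the matching covariates.
#' @param vars Covariate names to model on (default `c("age", "nihss")`).
#' @param ridge_penalty Penalty used by the separation fallback.
#' @return Numeric vector of fitted probabilities in (0, 1), aligned with
#'   the rows of `covariates`.
#' @export
estimate_propensity <- function(covariates, vars = c("age", "nihss"),
                                ridge_penalty = 1e-4) {
  y <- as.integer(covariates$group == "unfavorable")
  X <- as.matrix(covariates[, vars, drop = FALSE])
  fit_sep <- FALSE
  p <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    pr <- fit$fitted.values
    # NA coefficients from collinear columns are harmless; diverging fits
    # (propensities pinned at 0/1) indicate separation
    if (any(!is.finite(pr)) || any(pr > 1 - 1e-10) || any(pr < 1e-10))
      fit_sep <- TRUE
    pr
  }, error = function(e) { fit_sep <<- TRUE; NULL })
  if (fit_sep) {
    warning("separation in propensity model; using ridge-penalized fallback")
    # glmnet needs >= 2 columns; duplicate a column if necessary
    Xf <- if (ncol(X) == 1L) cbind(X, X) else X
    fit <- glmnet::glmnet(Xf, y, family = "binomial", alpha = 0,
                          lambda = ridge_penalty, standardize = TRUE)
    p <- as.numeric(stats::predict(fit, Xf, type = "response"))
  }
  pmin(pmax(p, 1e-8), 1 - 1e-8)
}

#' Greedy 1:1 propensity-score matching without replacement
#'
#' Matches each minority-group patient (iterated in seeded random order) to
#' its nearest unmatched majority-group patient on the logit propensity
#' scale. Pairs whose logit distance exceeds `caliper` times the SD of the
#' logit propensity (Austin's convention; set `caliper_scale = "raw"` for a
#' raw-probability caliper) are discarded.
#'
#' @param covariates Data frame with `patient_id` and `group`.
#' @param propensity Propensities from [estimate_propensity()].
#' @param caliper Caliper multiplier (default 0.2).
#' @param caliper_scale `"logit_sd"` (default) or `"raw"`.
#' @param seed Seed for the minority processing order.
#' @param match_vars Covariates reported in the balance table.
#' @return List of class `circdip_match`: `pairs` (data frame of matched
#'   ids and their propensities), `propensity`, `caliper_used` (absolute
#'   threshold on the matching scale), `balance` (from [balance_report()]),
#'   `matched_ids`.
#' @export
match_pairs <- function(covariates, propensity, caliper = 0.2,
                        caliper_scale = c("logit_sd", "raw"), seed = 1,
                        match_vars = c("age", "nihss")) {
  caliper_scale <- match.arg(caliper_scale)
  stopifnot(nrow(covariates) == length(propensity))
  grp <- covariates$group
  stopifnot(all(grp %in% c("good", "unfavorable")),
            any(grp == "good"), any(grp == "unfavorable"))
  score <- if (caliper_scale == "logit_sd") stats::qlogis(propensity) else propensity
  thr <- if (caliper_scale == "logit_sd") caliper * stats::sd(score) else caliper
  if (!is.finite(thr) || thr == 0) thr <- Inf  # degenerate: identical scores

  minority <- if (sum(grp == "good") <= sum(grp == "unfavorable"))
    "good" else "unfavorable"
  mi <- which(grp == minority)
  ma <- which(grp != minority)
  set.seed(seed)
  mi <- mi[sample.int(length(mi))]
  used <- rep(FALSE, length(ma))
  pair_min <- pair_maj <- integer(0)
  for (i in mi) {
    d <- abs(score[ma] - score[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= thr) {
      used[j] <- TRUE
      pair_min <- c(pair_min, i)
      pair_maj <- c(pair_maj, ma[j])
    }
  }
  good_idx <- if (minority == "good") pair_min else pair_maj
  unf_idx <- if (minority == "good") pair_maj else pair_min
  pairs <- data.frame(patient_id_good = covariates$patient_id[good_idx],
                      patient_id_unfavorable = covariates$patient_id[unf_idx],
                      propensity_good = propensity[good_idx],
                      propensity_unfavorable = propensity[unf_idx],
                      stringsAsFactors = FALSE)
  matched_ids <- c(pairs$patient_id_good, pairs$patient_id_unfavorable)
  bal <- balance_report(covariates, matched_ids, vars = match_vars)
  structure(list(pairs = pairs, propensity = propensity, caliper_used = thr,
                 balance = bal, matched_ids = matched_ids),
            class = "circdip_match")
}

#' Standardized mean differences before and after matching
#'
#' SMD = (mean_unfavorable - mean_good) / pooled SD, with the pooled SD
#' computed on the pre-match cohort; covariates with zero pooled SD are
#' reported as SMD 0 and flagged degenerate.
#'
#' @param covariates Full cohort with `patient_id`, `group` and covariates.
#' @param matched_ids Patient ids retained by matching.
#' @param vars Covariates to report.
#' @return Data frame `covariate`, `smd_before`, `smd_after`, `degenerate`.
#' @export
balance_report <- function(covariates, matched_ids,
                           vars = c("age", "nihss")) {
  smd <- function(d) {
    g1 <- d$group == "unfavorable"
    vapply(vars, function(v) {
      x1 <- d[[v]][g1]; x0 <- d[[v]][!g1]
      s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
      if (!is.finite(s) || s == 0) 0 else (mean(x1) - mean(x0)) / s
    }, 0)
  }
  before <- smd(covariates)
  after <- smd(covariates[covariates$patient_id %in% matched_ids, , drop = FALSE])
  pooled_sd0 <- vapply(vars, function(v) {
    g1 <- covariates$group == "unfavorable"
    s <- sqrt((stats::var(covariates[[v]][g1]) +
               stats::var(covariates[[v]][!g1])) / 2)
    !is.finite(s) || s == 0
  }, TRUE)
  data.frame(covariate = vars, smd_before = unname(before),
             smd_after = unname(after), degenerate = unname(pooled_sd0),
             stringsAsFactors = FALSE)
}
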