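#' Rank features by association p-value
#'
#' Converts per-feature association results into integer significance ranks
#' over the full feature universe: rank 1 is the smallest p-value. Ties are
#' broken lexicographically by feature id, so the ranks are a deterministic
#' bijection onto 1..N.
#'
#' @param assocs A `feature_association` data.frame with one finite p-value
#'   per feature.
#' @param stratum optional stratum label (e.g. `"male"`, `"female"`).
#' @return An object of class `stratified_ranking`: list with `stratum`, `n`
#'   and `rank`, a named integer vector (feature id -> rank).
#' @export
rank_by_pvalue <- function(assocs, stratum = NULL) {
  if (!all(c("feature_id", "p_value") %in% names(assocs)))
    stopf("assocs must have feature_id and p_value columns")
  if (anyDuplicated(assocs$feature_id))
    stopf("duplicate feature ids in association list")
  if (any(!is.finite(assocs$p_value)))
    stopf("all p-values must be finite")
  n <- nrow(assocs)
  ord <- order(assocs$p_value, assocs$feature_id)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  names(rk) <- assocs$feature_id
  structure(list(stratum = stratum, n = n, rank = rk),
            class = "stratified_ranking")
}

#' Rank differences between sex-stratified analyses
#'
#' For each candidate feature, the signed difference
#' `d = rank_male - rank_female` of its significance ranks in the two
#' stratified analyses. Positive `d` means the feature is more significant
#' (better ranked) in females.
#'
#' @param rank_m,rank_f `stratified_ranking` objects over the same feature
#'   universe.
#' @param candidates feature ids to evaluate (a subset of the universe).
#' @return A data.frame of class `rank_difference` with columns `feature_id`,
#'   `rank_m`, `rank_f`, `d`.
#' @export
compute_rank_differences <- function(rank_m, rank_f, candidates) {
  if (!inherits(rank_m, "stratified_ranking") ||
      !inherits(rank_f, "stratified_ranking"))
    stopf("rank_m and rank_f must be stratified_ranking objects")
  if (rank_m$n != rank_f$n ||
      !setequal(names(rank_m$rank), names(rank_f$rank)))
    stopf("the two rankings must share the same feature universe")
  missing <- setdiff(candidates, names(rank_m$rank))
  if (length(missing))
    stopf("candidate(s) absent from the rankings: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  rm_ <- unname(rank_m$rank[candidates])
  rf_ <- unname(rank_f$rank[candidates])
  out <- data.frame(feature_id = candidates, rank_m = rm_, rank_f = rf_,
                    d = rm_ - rf_, stringsAsFactors = FALSE)
  class(out) <- c("rank_difference", "data.frame")
  out
}

#' Fit the Gaussian null of candidate rank differences
#'
#' The null model for rank differences is a Gaussian fitted to the candidate
#' set's own differences: under the null hypothesis that feature rankings are
#' not sex-related, the candidate differences form a steep unimodal
#' distribution whose mean and spread calibrate the test. The default
#' estimator is the maximum-likelihood fit (sample mean; SD with divisor n).
#' `robust = TRUE` uses median and MAD instead, which resists contamination
#' by genuinely sex-specific candidates.
#'
#' @param diffs A `rank_difference` data.frame (or a numeric vector of
#'   differences); at least 3 values, not all identical.
#' @param robust logical; use median/MAD instead of mean/MLE-SD.
#' @return An object of class `gaussian_null`: list with `mu`, `sigma`, `n`,
#'   `robust`.
#' @export
fit_gaussian_null <- function(diffs, robust = FALSE) {
  d <- if (is.data.frame(diffs)) diffs$d else diffs
  if (is.null(d) || !is.numeric(d)) stopf("diffs must contain numeric differences")
  if (length(d) < 3)
    stopf("need at least 3 rank differences to fit the null (got %d)", length(d))
  if (robust) {
    mu <- stats::median(d)
    sigma <- stats::mad(d)
  } else {
    mu <- mean(d)
    sigma <- sqrt(mean((d - mu)^2))
  }
  if (sigma <= 0)
    stopf("degenerate rank differences: zero spread")
  structure(list(mu = mu, sigma = sigma, n = length(d), robust = robust),
            class = "gaussian_null")
}

#' @export
print.gaussian_null <- function(x, ...) {
  cat(sprintf("Gaussian rank-difference null (%s fit on %d candidates): mu = %.2f, sigma = %.2f\n",
              if (x$robust) "median/MAD" else "ML", x$n, x$mu, x$sigma))
  invisible(x)
}

#' Call sex-specific features from rank differences
#'
#' Evaluates each candidate's rank difference against the fitted Gaussian
#' null using the survival function (complementary CDF): for `d >= mu` the
#' upper-tail probability is reported and the direction is
#' `female_specific`; for `d < mu` the lower-tail probability, direction
#' `male_specific`. A candidate is flagged when its tail probability falls
#' below `alpha`. A diagnostic histogram of all candidate tail probabilities
#' (bin width 0.05) is attached as attribute `"histogram"` (see
#' [p_diff_histogram()]).
#'
#' @param diffs A `rank_difference` data.frame.
#' @param null A `gaussian_null` from [fit_gaussian_null()].
#' @param alpha per-feature significance threshold in (0, 1).
#' @return A data.frame of class `sex_specific_call` with columns
#'   `feature_id`, `rank_m`, `rank_f`, `d`, `p_diff`, `direction`, `flagged`.
#' @export
call_sex_specific <- function(diffs, null, alpha = 0.05) {
  if (!inherits(null, "gaussian_null")) stopf("null must be a gaussian_null")
  if (null$sigma <= 0) stopf("null sigma must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  d <- diffs$d
  if (is.null(d)) stopf("diffs must contain a d column")
  z <- (d - null$mu) / null$sigma
  upper <- d >= null$mu
  p_diff <- ifelse(upper,
                   stats::pnorm(z, lower.tail = FALSE),
                   stats::pnorm(z, lower.tail = TRUE))
  out <- data.frame(
    feature_id = diffs$feature_id,
    rank_m = diffs$rank_m, rank_f = diffs$rank_f, d = d,
    p_diff = p_diff,
    direction = ifelse(upper, "female_specific", "male_specific"),
    flagged = p_diff < alpha,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sex_specific_call", "data.frame")
  attr(out, "histogram") <- p_diff_histogram(out)
  out
}

#' Histogram bins of rank-difference tail probabilities
#'
#' Diagnostic binning of the candidate tail probabilities on (0, 1] with a
#' fixed bin width; an excess in the lowest bin relative to the rest signals
#' sub-groups of candidates with genuinely sex-related rankings.
#'
#' @param calls A `sex_specific_call` data.frame (or numeric p values).
#' @param width bin width, default 0.05.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
p_diff_histogram <- function(calls, width = 0.05) {
  p <- if (is.data.frame(calls)) calls$p_diff else calls
  if (width <= 0 || width > 1) stopf("width must lie in (0, 1]")
  breaks <- seq(0, 1, by = width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- as.integer(table(cut(p, breaks = breaks, include.lowest = TRUE)))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = counts)
}
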