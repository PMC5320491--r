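#' Specification of the balanced female-resampling check
#'
#' The sex-balance robustness check repeatedly redraws the analysis
#' population using all males and an equal number of randomly sampled
#' females, preserving the female population's cohort x smoking-status
#' proportions. By default the draw is made within the analysis population
#' (current + never smokers); `population = "all"` resamples within the full
#' design including former smokers.
#'
#' @param rounds number of resampling rounds (default 10).
#' @param seed integer seed; each round is deterministic given seed and round
#'   index.
#' @param population `"current_never"` or `"all"`.
#' @return An object of class `subsample_spec`.
#' @export
subsample_spec <- function(rounds = 10L, seed = 1L,
                           population = c("current_never", "all")) {
  population <- match.arg(population)
  if (rounds < 1) stopf("rounds must be >= 1")
  structure(list(rounds = as.integer(rounds), seed = seed,
                 population = population),
            class = "subsample_spec")
}

# Largest-remainder allocation of `total` draws across strata proportional
# to `weights` (ties broken by stratum order).
largest_remainder_ <- function(weights, total) {
  if (total == 0) return(rep(0L, length(weights)))
  quota <- weights / sum(weights) * total
  alloc <- floor(quota)
  short <- total - sum(alloc)
  if (short > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1
  }
  as.integer(alloc)
}

#' Draw one sex-balanced subsample
#'
#' Returns the subject ids of one balanced round: every male in the target
#' population, plus an equal total number of females sampled at random, with
#' the female draw stratified by cohort x smoking status so that the sampled
#' females keep the full female population's stratum proportions
#' (largest-remainder rounding).
#'
#' @param phenotypes A phenotype table.
#' @param spec A [subsample_spec()].
#' @param round_index round number in 1..rounds.
#' @return Character vector of subject ids.
#' @export
draw_balanced_subsample <- function(phenotypes, spec, round_index) {
  if (!inherits(spec, "subsample_spec")) stopf("spec must be a subsample_spec")
  if (round_index < 1 || round_index > spec$rounds)
    stopf("round_index must lie in 1..%d", spec$rounds)
  validate_phenotypes(phenotypes)
  ph <- phenotypes
  if (spec$population == "current_never")
    ph <- ph[ph$smoking_status %in% c("current", "never"), , drop = FALSE]

  males <- ph[ph$sex == "male", , drop = FALSE]
  females <- ph[ph$sex == "female", , drop = FALSE]
  n_target <- nrow(males)
  if (n_target > nrow(females))
    stopf("infeasible subsample: %d males but only %d females available",
          n_target, nrow(females))

  stratum <- interaction(females$cohort, females$smoking_status, drop = TRUE)
  sizes <- table(stratum)
  alloc <- largest_remainder_(as.numeric(sizes), n_target)
  names(alloc) <- names(sizes)
  over <- alloc > as.integer(sizes)
  if (any(over))
    stopf("infeasible stratum '%s': allocation exceeds available females",
          names(alloc)[which(over)[1]])

  with_seed(sub_seed(spec$seed, 100L + round_index), {
    fem_ids <- unlist(lapply(names(alloc), function(s) {
      pool <- females$subject_id[stratum == s]
      sample(pool, alloc[[s]])
    }), use.names = FALSE)
    c(males$subject_id, fem_ids)
  })
}

#' Overlap of per-round calls with the full-population calls
#'
#' For each resampling round, the percentage of the full-population flagged
#' list recovered by that round's flagged list, together with the mean and SD
#' over rounds and the cumulative overlap curve (the union of rounds 1..k
#' intersected with the full list).
#'
#' @param full_flagged feature ids flagged in the full-population analysis.
#' @param per_round_flagged list of per-round flagged feature id vectors.
#' @return An object of class `overlap_summary`: list with `per_round` (%),
#'   `mean`, `sd`, `cumulative` (%).
#' @export
resampling_overlap <- function(full_flagged, per_round_flagged) {
  if (length(full_flagged) == 0)
    stopf("full-population flagged list is empty")
  if (!is.list(per_round_flagged) || length(per_round_flagged) < 1)
    stopf("need at least one resampling round")
  full <- unique(full_flagged)
  per_round <- vapply(per_round_flagged, function(r)
    100 * length(intersect(r, full)) / length(full), numeric(1))
  cum <- numeric(length(per_round_flagged))
  acc <- character(0)
  for (k in seq_along(per_round_flagged)) {
    acc <- union(acc, per_round_flagged[[k]])
    cum[k] <- 100 * length(intersect(acc, full)) / length(full)
  }
  structure(list(per_round = per_round, mean = mean(per_round),
                 sd = stats::sd(per_round), cumulative = cum),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Resampling overlap over %d rounds: mean %.1f%% (SD %s%%), cumulative %.1f%%\n",
              length(x$per_round), x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.1f", x$sd),
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}
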