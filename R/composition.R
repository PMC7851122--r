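# Per-ego network composition metrics. Composition summarises the people
# around the ego, so it uses the FULL roster (the name interpreter covers
# all network members, not just the ten entering the tie section). Every
# metric uses a non-missing denominator: alters with the relevant
# attribute missing drop out of that metric only.

#' Index of qualitative variation
#'
#' \eqn{IQV = \frac{K}{K-1}\,(1 - \sum_k p_k^2)} over per-category counts:
#' 0 when a single category holds all members, 1 at exact uniformity.
#'
#' @param counts Non-negative per-category counts.
#' @param K Number of categories (defaults to `length(counts)`).
#' @return Index in `[0, 1]`; `NA` when the counts sum to zero.
#' @export
iqv <- function(counts, K = length(counts)) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  if (K < 2) stop("iqv needs at least two categories", call. = FALSE)
  p <- counts / n
  (K / (K - 1)) * (1 - sum(p^2))
}

.alters_of <- function(x) {
  if (inherits(x, "ego_record")) x$alters else .as_alters(x)
}

#' Diversity of sex (two-category IQV)
#'
#' 0 when all network members are one sex; 1 with an equal number of men
#' and women.
#'
#' @param alters Alter roster (data.frame, list, or an [ego_record()]).
#' @return Index in `[0, 1]`; `NA` when no alter has a recorded sex.
#' @export
diversity_of_sex <- function(alters) {
  a <- .alters_of(alters)
  counts <- c(sum(a$sex == "male", na.rm = TRUE),
              sum(a$sex == "female", na.rm = TRUE))
  iqv(counts, K = 2)
}

#' Diversity of race (three-category IQV)
#'
#' 0 when all persons are the same race; 1 at an equal proportion of each
#' racial category (White, Black, Other).
#'
#' @inheritParams diversity_of_sex
#' @return Index in `[0, 1]`; `NA` when no alter has a recorded race.
#' @export
diversity_of_race <- function(alters) {
  a <- .alters_of(alters)
  counts <- vapply(.races, function(rc) sum(a$race == rc, na.rm = TRUE), 0L)
  iqv(counts, K = 3)
}

#' Percentage of alters satisfying a predicate
#'
#' `100 * (# TRUE) / (# non-missing)`. Backs percentage of kin, distant
#' (>15 miles), non-exercising (< 3-4x/week), negative-influence, and the
#' football-affiliation metrics.
#'
#' @param values Logical vector (one entry per alter; `NA` = missing).
#' @return Percentage in `[0, 100]`; `NA` when every value is missing.
#' @export
percentage_metric <- function(values) {
  values <- as.logical(values)
  if (all(is.na(values))) return(NA_real_)
  100 * mean(values, na.rm = TRUE)
}

#' Standard deviation of alter ages
#'
#' Sample standard deviation (n-1 denominator) over alters with a
#' recorded age; summarises the age range of the network.
#'
#' @inheritParams diversity_of_sex
#' @return Years; `NA` with fewer than two recorded ages.
#' @export
sd_of_ages <- function(alters) {
  ages <- .alters_of(alters)$age
  ages <- ages[!is.na(ages)]
  if (length(ages) < 2) return(NA_real_)
  sd(ages)
}

#' Majority-male score
#'
#' (number of men - number of women) / number of members with recorded
#' sex; ranges from -1 (majority female) to 1 (majority male).
#'
#' @inheritParams diversity_of_sex
#' @return Score in `[-1, 1]`; `NA` when no alter has a recorded sex.
#' @export
majority_male_score <- function(alters) {
  a <- .alters_of(alters)
  nm <- sum(a$sex == "male", na.rm = TRUE)
  nf <- sum(a$sex == "female", na.rm = TRUE)
  if (nm + nf == 0) return(NA_real_)
  (nm - nf) / (nm + nf)
}

#' Proportion of network members with the same race as the participant
#'
#' Homogeneity score from 0 (all different race, heterogeneous) to 1 (all
#' same race, homogeneous). Rosters of fewer than two alters are excluded
#' (scored `NA`), matching the homogeneity-montage convention.
#'
#' @param record An [ego_record()] (the ego's race is required).
#' @return Proportion in `[0, 1]`; `NA` when the ego race is unknown, the
#'   roster has fewer than two alters, or no alter has a recorded race.
#' @export
same_race_proportion <- function(record) {
  if (n_alters(record) < 2) return(NA_real_)
  if (is.na(record$race)) return(NA_real_)
  race <- record$alters$race
  race <- race[!is.na(race)]
  if (!length(race)) return(NA_real_)
  mean(race == record$race)
}

#' All composition metrics for one record
#'
#' Football-affiliation percentages are only defined for the players
#' cohort (the survey never asks them of controls) and are `NA` otherwise.
#'
#' @param record A validated [ego_record()].
#' @return Named list: `pct_kin`, `diversity_sex`, `diversity_race`,
#'   `pct_distant`, `sd_ages`, `pct_non_exercising`, `pct_negative`,
#'   `pct_played_football`, `pct_nfl_with_participant`,
#'   `majority_male_score`, `same_race_proportion`.
#' @export
compute_composition <- function(record) {
  a <- record$alters
  player <- record$group == "player"
  list(
    pct_kin = percentage_metric(a$kin),
    diversity_sex = diversity_of_sex(a),
    diversity_race = diversity_of_race(a),
    pct_distant = percentage_metric(a$distant),
    sd_ages = sd_of_ages(a),
    pct_non_exercising = percentage_metric(a$non_exercising),
    pct_negative = percentage_metric(a$negative_influence),
    pct_played_football = if (player) percentage_metric(a$played_football) else NA_real_,
    pct_nfl_with_participant = if (player) {
      percentage_metric(a$nfl_with_participant)
    } else NA_real_,
    majority_male_score = majority_male_score(a),
    same_race_proportion = same_race_proportion(record)
  )
}
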