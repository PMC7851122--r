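# Programmatic fixtures: quick ego-record and roster builders.

make_alters <- function(n, sex = rep("male", n), race = rep("White", n),
                        age = rep(40, n), kin = rep(FALSE, n),
                        distant = rep(FALSE, n),
                        non_exercising = rep(FALSE, n),
                        negative_influence = rep(FALSE, n),
                        played_football = rep(NA, n),
                        nfl_with_participant = rep(NA, n)) {
  list(sex = sex, race = race, age = age, kin = kin, distant = distant,
       non_exercising = non_exercising,
       negative_influence = negative_influence,
       played_football = played_football,
       nfl_with_participant = nfl_with_participant)
}

make_record <- function(id = "p1", group = "player", n = 3,
                        ties = c("full", "none", "missing"),
                        alters = make_alters(n), race = "White", ...) {
  if (is.character(ties)) {
    ties <- match.arg(ties)
    k <- min(n, 10)
    ties <- switch(ties,
      full = if (k >= 1) complete_egonet(k) else NULL,
      none = if (k >= 1) star_egonet(k) else NULL,
      missing = NULL
    )
  }
  ego_record(
    participant_id = id, group = group, age = 50, race = race,
    education = "Bachelor's degree", employment = "employed",
    income = 60000, domestic_status = "married",
    living_situation = "with others", chronic_condition = FALSE,
    alters = alters, ties = ties, ...
  )
}

# A small cohort data.frame of independent covariates for regression tests.
make_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    age = round(runif(n, 25, 75)),
    race = sample(c("White", "Black", "Other"), n, replace = TRUE,
                  prob = c(.7, .2, .1)),
    education = sample(education_levels(), n, replace = TRUE),
    employment = sample(c("employed", "student", "retired", "unemployed"),
                        n, replace = TRUE, prob = c(.6, .1, .2, .1)),
    income = round(rlnorm(n, log(65000), .4)),
    domestic_status = sample(c("married", "not married"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
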