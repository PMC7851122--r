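# Controlled vocabularies for the survey dialect. Race is fixed to the
# three analysis categories; finer input races are mapped by .race_map.
.groups <- c("player", "control")
.races <- c("White", "Black", "Other")
.sexes <- c("male", "female")
.education_levels <- c(
  "High school or less", "Some college", "Associate degree",
  "Bachelor's degree", "Graduate degree"
)
.employment_levels <- c("employed", "student", "retired", "unemployed")
.domestic_levels <- c("married", "not married")
.living_levels <- c("with others", "alone")
.chronic_types <- c("neurocognitive", "pain", "cardiometabolic", "sleep")

# Declared dictionary mapping free-text race codes onto the three
# analysis categories (lower-cased lookup).
.race_map <- c(
  "white" = "White", "caucasian" = "White",
  "black" = "Black", "african american" = "Black",
  "african-american" = "Black",
  "other" = "Other", "asian" = "Other", "hispanic" = "Other",
  "latino" = "Other", "native american" = "Other",
  "pacific islander" = "Other", "mixed" = "Other", "multiracial" = "Other"
)

# Per-alter attribute fields and their storage types. Order fixes the
# column layout of the wide survey dialect and of alter rosters.
.alter_fields <- c(
  sex = "character", race = "character", age = "numeric",
  kin = "logical", distant = "logical", non_exercising = "logical",
  negative_influence = "logical", played_football = "logical",
  nfl_with_participant = "logical"
)

# Number of roster members entering the tie (inter-relater) section.
.tie_cap <- 10L

.empty_alters <- function(n = 0L) {
  out <- lapply(.alter_fields, function(type) {
    switch(type,
      character = rep(NA_character_, n),
      numeric = rep(NA_real_, n),
      logical = rep(NA, n)
    )
  })
  names(out) <- names(.alter_fields)
  out
}

.as_alters <- function(x) {
  if (is.null(x)) return(.empty_alters())
  if (is.data.frame(x)) x <- as.list(x)
  if (!is.list(x)) stop("alters must be a data.frame or named list", call. = FALSE)
  n <- if (length(x)) max(lengths(x)) else 0L
  out <- .empty_alters(n)
  for (f in names(.alter_fields)) {
    if (is.null(x[[f]])) next
    v <- x[[f]]
    if (length(v) != n) stop("alter field lengths differ: ", f, call. = FALSE)
    out[[f]] <- switch(.alter_fields[[f]],
      character = as.character(v),
      numeric = as.numeric(v),
      logical = as.logical(v)
    )
  }
  out
}

#' Construct a single ego-network record
#'
#' An `ego_record` holds one participant: ego covariates, the ordered
#' alter roster produced by the name generator, and the symmetric
#' alter-alter tie matrix collected for the first ten roster members.
#'
#' @param participant_id Opaque identifier, unique within a cohort.
#' @param group `"player"` or `"control"`.
#' @param age Ego age in years.
#' @param race One of `"White"`, `"Black"`, `"Other"`.
#' @param education One of the five ordered education levels (see
#'   [education_levels()]).
#' @param employment `"employed"`, `"student"`, `"retired"` or `"unemployed"`.
#' @param income Yearly income in dollars; may be `NA`.
#' @param domestic_status `"married"` or `"not married"`.
#' @param living_situation `"with others"` or `"alone"`.
#' @param chronic_condition Logical; any chronic health condition. For
#'   players this is derived as "any chronic type present".
#' @param chronic_types Character subset of
#'   `c("neurocognitive", "pain", "cardiometabolic", "sleep")`; players only.
#' @param alters Alter roster: a data.frame (or named list of parallel
#'   vectors) with columns among `sex`, `race`, `age`, `kin`, `distant`,
#'   `non_exercising`, `negative_influence`, `played_football`,
#'   `nfl_with_participant`. Roster order is meaningful: it determines
#'   which ten alters enter the tie section.
#' @param ties Symmetric `k x k` numeric matrix of tie strengths among the
#'   first `k = min(n_alters, 10)` alters, entries in `{0, 1, 2}`
#'   (0 = no tie, 1 = tie, 2 = especially close), diagonal undefined
#'   (`NA`). `NULL` when the tie section is missing.
#' @param inaccurate Logical QC flag: record verified inaccurate by staff
#'   review.
#'
#' @return An object of class `ego_record`.
#' @export
ego_record <- function(participant_id, group,
                       age = NA_real_, race = NA_character_,
                       education = NA_character_, employment = NA_character_,
                       income = NA_real_, domestic_status = NA_character_,
                       living_situation = NA_character_,
                       chronic_condition = NA, chronic_types = character(),
                       alters = NULL, ties = NULL, inaccurate = FALSE) {
  group <- match.arg(group, .groups)
  alters <- .as_alters(alters)
  n <- length(alters$sex)
  k <- min(n, .tie_cap)
  if (!is.null(ties)) {
    ties <- as.matrix(ties)
    if (nrow(ties) != ncol(ties) || nrow(ties) > k) {
      stop("ties must be a square matrix over the first min(n, 10) alters",
           call. = FALSE)
    }
    off <- ties[row(ties) != col(ties)]
    if (any(!is.na(off) & !(off %in% 0:2))) {
      stop("tie strengths must be in {0, 1, 2}", call. = FALSE)
    }
    ties[is.na(ties) & row(ties) != col(ties)] <- 0
    # conservative presence coding: disagreements keep the stronger tie
    repaired <- any(ties != t(ties))
    ties <- pmax(ties, t(ties))
    diag(ties) <- NA_real_
  } else {
    repaired <- FALSE
  }
  if (length(chronic_types)) {
    chronic_types <- match.arg(chronic_types, .chronic_types, several.ok = TRUE)
  }
  structure(
    list(
      participant_id = as.character(participant_id), group = group,
      age = as.numeric(age), race = race, education = education,
      employment = employment, income = as.numeric(income),
      domestic_status = domestic_status, living_situation = living_situation,
      chronic_condition = as.logical(chronic_condition),
      chronic_types = chronic_types,
      alters = alters, ties = ties,
      tie_repaired = isTRUE(repaired), inaccurate = isTRUE(inaccurate)
    ),
    class = "ego_record"
  )
}

#' Number of alters in the roster (uncapped network size)
#' @param record An [ego_record()].
#' @return Integer roster length.
#' @export
n_alters <- function(record) length(record$alters$sex)

#' Alter roster as a data.frame
#' @param record An [ego_record()].
#' @return One row per alter, in roster order.
#' @export
alter_roster <- function(record) {
  as.data.frame(record$alters, stringsAsFactors = FALSE)
}

#' The five ordered education levels of the survey dialect
#' @return Character vector, lowest to highest.
#' @export
education_levels <- function() .education_levels

#' @export
print.ego_record <- function(x, ...) {
  cat("<ego_record> ", x$participant_id, " (", x$group, ")\n", sep = "")
  cat("  alters:", n_alters(x),
      if (is.null(x$ties)) "| ties: missing" else
        paste0("| ties: ", nrow(x$ties), "x", nrow(x$ties)), "\n")
  invisible(x)
}

#' @export
print.ego_cohort <- function(x, ...) {
  grp <- table(vapply(x, `[[`, "", "group"))
  cat("<ego_cohort> ", length(x), " records (",
      paste(names(grp), grp, sep = ": ", collapse = ", "), ")\n", sep = "")
  err <- attr(x, "parse_errors")
  if (!is.null(err) && nrow(err)) cat("  parse errors:", nrow(err), "rows skipped\n")
  invisible(x)
}
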