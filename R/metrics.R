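# Fixed column order of the per-ego metrics table.
.metric_columns <- c(
  "network_size", "density", "constraint", "effective_size",
  "max_degree", "mean_degree",
  "pct_kin", "diversity_sex", "diversity_race", "pct_distant", "sd_ages",
  "pct_non_exercising", "pct_negative", "pct_played_football",
  "pct_nfl_with_participant", "majority_male_score", "same_race_proportion"
)
.covariate_columns <- c(
  "age", "race", "education", "employment", "income", "domestic_status",
  "living_situation", "chronic_condition"
)

#' Names of the per-ego network metrics
#' @param which `"all"`, `"structure"` or `"composition"`.
#' @return Character vector in table order.
#' @export
persnet_metric_names <- function(which = c("all", "structure", "composition")) {
  which <- match.arg(which)
  switch(which,
    all = .metric_columns,
    structure = .metric_columns[1:6],
    composition = .metric_columns[7:17]
  )
}

#' Compute the full per-ego metrics table for a cohort
#'
#' Validates each record, drops unusable ones (the exclusions are
#' reported in the `validation` attribute together with any parse
#' errors), and computes all structure and composition metrics plus the
#' ego covariates needed downstream. Rosters longer than ten are flagged
#' `ties_truncated`: their tie-based metrics cover only the first-ten
#' subnetwork, the only tie data the survey collects.
#'
#' @param x An `ego_cohort`, a survey data.frame, or a CSV path.
#' @param keep_unusable Keep rows failing validation (default drops them).
#' @inheritParams compute_structure
#' @return data.frame, one row per usable participant: id, group,
#'   covariates, chronic-condition detail, and the 17 metrics.
#' @export
compute_metrics <- function(x, keep_unusable = FALSE,
                            constraint_weighted = TRUE,
                            effective_size_method = "binary") {
  records <- .as_cohort(x)
  val <- validate_cohort(records)
  keep <- if (keep_unusable) rep(TRUE, length(records)) else val$usable
  kept <- records[keep]
  rows <- lapply(kept, function(r) {
    s <- compute_structure(r, constraint_weighted = constraint_weighted,
                           effective_size_method = effective_size_method)
    cmp <- compute_composition(r)
    c(
      list(participant_id = r$participant_id, group = r$group,
           age = r$age, race = r$race, education = r$education,
           employment = r$employment, income = r$income,
           domestic_status = r$domestic_status,
           living_situation = r$living_situation,
           chronic_condition = r$chronic_condition,
           n_chronic = if (r$group == "player") length(r$chronic_types) else NA_integer_,
           chronic_neurocognitive = if (r$group == "player") "neurocognitive" %in% r$chronic_types else NA,
           chronic_pain = if (r$group == "player") "pain" %in% r$chronic_types else NA,
           chronic_cardiometabolic = if (r$group == "player") "cardiometabolic" %in% r$chronic_types else NA,
           chronic_sleep = if (r$group == "player") "sleep" %in% r$chronic_types else NA,
           ties_truncated = n_alters(r) > .tie_cap),
      s, cmp
    )
  })
  out <- if (length(rows)) {
    as.data.frame(do.call(rbind, lapply(rows, function(r) {
      lapply(r, function(v) if (is.null(v)) NA else v)
    })))
  } else {
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 16 + length(.metric_columns))),
      c("participant_id", "group", .covariate_columns, "n_chronic",
        paste0("chronic_", .chronic_types), "ties_truncated", .metric_columns)
    )
  }
  out[] <- lapply(out, function(col) unlist(col, use.names = FALSE))
  rownames(out) <- NULL
  attr(out, "validation") <- list(
    report = val,
    excluded = val$participant_id[!val$usable],
    parse_errors = attr(records, "parse_errors")
  )
  out
}

#' Write a per-ego metrics table to CSV
#'
#' One row per participant in a stable column order; missing metrics are
#' written as empty cells. All bundles must share a schema.
#'
#' @param metrics A metrics data.frame from [compute_metrics()], or a
#'   list of per-ego metric bundles (named lists) sharing one schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  if (!is.data.frame(metrics)) {
    if (!length(metrics)) stop("no metric bundles to write", call. = FALSE)
    schemas <- lapply(metrics, names)
    if (!all(vapply(schemas, identical, TRUE, schemas[[1]]))) {
      stop("schema mismatch across metric bundles", call. = FALSE)
    }
    metrics <- as.data.frame(do.call(rbind, lapply(metrics, function(r) {
      lapply(r, function(v) if (is.null(v)) NA else v)
    })))
    metrics[] <- lapply(metrics, unlist, use.names = FALSE)
  }
  write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return data.frame with empty cells restored as `NA`.
#' @export
read_metrics_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  # all-missing columns come back logical; restore the schema types
  for (cn in intersect(c(.metric_columns, "age", "income", "n_chronic"),
                       names(out))) {
    out[[cn]] <- as.numeric(out[[cn]])
  }
  for (cn in intersect(c("chronic_condition", "ties_truncated",
                         paste0("chronic_", .chronic_types)), names(out))) {
    out[[cn]] <- as.logical(out[[cn]])
  }
  out
}
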