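# Two-cohort comparison machinery: descriptive tables, univariate tests,
# and covariate-adjusted linear models. No multiplicity correction is
# applied to the primary p-values; a Benjamini-Hochberg column is emitted
# as supplementary output only.

#' Covariate specification for adjusted comparisons
#'
#' The default six covariates and their codings: age (years, continuous);
#' race (binary, non-White vs White); education (ordered integer 1-5);
#' employment (three dummies, employed as reference); income (continuous,
#' $1000s); domestic status (binary, not married vs married).
#'
#' @param covariates Subset of the six covariate names, in model order.
#' @return A `covariate_spec` object.
#' @export
covariate_spec <- function(covariates = c("age", "race", "education",
                                          "employment", "income",
                                          "domestic_status")) {
  known <- c("age", "race", "education", "employment", "income",
             "domestic_status")
  bad <- setdiff(covariates, known)
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(covariates = covariates), class = "covariate_spec")
}

# Numeric design columns for the requested covariates. `data` holds the
# raw covariate columns as produced by compute_metrics().
.build_design <- function(spec, data) {
  cols <- list()
  for (cv in spec$covariates) {
    if (!cv %in% names(data)) {
      stop("missing covariate column: ", cv, call. = FALSE)
    }
    cols <- c(cols, switch(cv,
      age = list(age = as.numeric(data$age)),
      race = list(race_nonwhite = as.numeric(data$race != "White")),
      education = list(education_rank = {
        e <- data$education
        if (is.numeric(e)) as.numeric(e) else as.numeric(match(e, .education_levels))
      }),
      employment = list(
        employment_student = as.numeric(data$employment == "student"),
        employment_retired = as.numeric(data$employment == "retired"),
        employment_unemployed = as.numeric(data$employment == "unemployed")
      ),
      income = list(income_k = as.numeric(data$income) / 1000),
      domestic_status = list(
        not_married = as.numeric(data$domestic_status != "married"))
    ))
  }
  as.data.frame(cols)
}

#' Two-sided Mann-Whitney test
#'
#' Normal approximation with tie correction (no continuity correction) by
#' default; exact enumeration when both sides have at most
#' `exact_threshold` observations and the data are tie-free.
#'
#' @param x,y Numeric samples (both must be nonempty after `NA` removal).
#' @param exact_threshold Per-side size at or below which the exact
#'   distribution is used.
#' @return Two-sided p-value, with the Mann-Whitney `U` of the first
#'   sample as attribute `statistic`.
#' @export
mann_whitney <- function(x, y, exact_threshold = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  use_exact <- length(x) <= exact_threshold && length(y) <= exact_threshold &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  p <- unname(wt$p.value)
  attr(p, "statistic") <- unname(wt$statistic)
  attr(p, "exact") <- use_exact
  p
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction by default (general r x c case); set
#' `yates = TRUE` for the corrected 2 x 2 variant.
#'
#' @param x A count matrix/table, or a factor to cross-tabulate with `y`.
#' @param y Second factor when `x` is a factor.
#' @param yates Apply the continuity correction (2 x 2 only).
#' @return p-value with attributes `statistic` and `df`.
#' @export
chi_square <- function(x, y = NULL, yates = FALSE) {
  tab <- if (is.matrix(x) || is.table(x)) as.matrix(x) else table(x, y)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margin in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  if (any(ct$expected <= 0)) stop("expected count of zero", call. = FALSE)
  p <- unname(ct$p.value)
  attr(p, "statistic") <- unname(ct$statistic)
  attr(p, "df") <- unname(ct$parameter)
  p
}

.summaries <- function(values, group) {
  lapply(split(values, group), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    q <- unname(quantile(v, c(.25, .5, .75), type = 7))
    list(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  })
}

#' Covariate-adjusted two-group comparison of one metric
#'
#' Ordinary least squares of the metric on a group indicator plus the
#' coded covariates, on complete cases; the adjusted p-value is the
#' two-sided t-test on the group coefficient. Group medians/IQRs and the
#' univariate Mann-Whitney p are reported alongside.
#'
#' @param values Numeric metric, one entry per participant.
#' @param group Two-level grouping vector.
#' @param covariate_data data.frame with the raw covariate columns.
#' @param spec A [covariate_spec()].
#' @param ref Reference group level (the coefficient is the shift of the
#'   other level relative to this one).
#' @param metric Optional metric name carried into the result.
#' @return A `comparison_result`: list with `metric`, `group_summaries`,
#'   `estimate`, `p_univariate`, `p_adjusted`, `n_used`.
#' @export
adjusted_comparison <- function(values, group, covariate_data,
                                spec = covariate_spec(), ref = "control",
                                metric = NULL) {
  group <- as.character(group)
  lev <- unique(group[!is.na(group)])
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (!ref %in% lev) ref <- lev[1]
  other <- setdiff(lev, ref)
  ind <- as.numeric(group == other)
  design <- .build_design(spec, covariate_data)
  # constant columns (an unused dummy level in this subset) carry no
  # information and are dropped, as lm() would drop an unused factor level
  keep_cols <- vapply(design, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1
  }, TRUE)
  design <- design[, keep_cols, drop = FALSE]
  dat <- cbind(data.frame(.y = values, .group = ind), design)
  cc <- complete.cases(dat)
  n_used <- sum(cc)
  if (n_used < ncol(design) + 3) {
    stop("too few complete cases (", n_used, ") for the adjusted model",
         call. = FALSE)
  }
  X <- as.matrix(cbind(`(Intercept)` = 1, dat[cc, -1]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- lm(.y ~ ., data = dat[cc, ])
  co <- summary(fit)$coefficients
  structure(list(
    metric = metric,
    groups = c(ref, other),
    group_summaries = .summaries(values, group),
    estimate = unname(co[".group", "Estimate"]),
    p_univariate = as.numeric(mann_whitney(values[group == ref],
                                           values[group == other])),
    p_adjusted = unname(co[".group", "Pr(>|t|)"]),
    n_used = n_used
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  fmt <- function(s) sprintf("%.2f [%.2f, %.2f]", s$median, s$q1, s$q3)
  cat("<comparison_result>", x$metric %||% "", "\n")
  for (g in x$groups) cat("  ", g, ": ", fmt(x$group_summaries[[g]]), "\n", sep = "")
  cat(sprintf("  estimate %.3f | p_univariate %.4g | p_adjusted %.4g | n %d\n",
              x$estimate, x$p_univariate, x$p_adjusted, x$n_used))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.result_row <- function(res) {
  s1 <- res$group_summaries[[res$groups[1]]]
  s2 <- res$group_summaries[[res$groups[2]]]
  data.frame(
    metric = res$metric %||% NA_character_,
    group_ref = res$groups[1], group_alt = res$groups[2],
    median_ref = s1$median, q1_ref = s1$q1, q3_ref = s1$q3,
    median_alt = s2$median, q1_alt = s2$q1, q3_alt = s2$q3,
    estimate = res$estimate, p_univariate = res$p_univariate,
    p_adjusted = res$p_adjusted, n_used = res$n_used,
    stringsAsFactors = FALSE
  )
}

#' Compare every network metric between two cohorts
#'
#' Runs [adjusted_comparison()] for each metric in a per-ego metrics
#' table. Metrics defined in only one cohort (the football affiliations)
#' are summarised for that cohort with `NA` p-values, mirroring how they
#' are reported. A Benjamini-Hochberg column over the adjusted p-values
#' is appended as supplementary output.
#'
#' @param metrics data.frame from [compute_metrics()] (or
#'   [read_metrics_table()]).
#' @param metric_names Metrics to compare; default all seventeen.
#' @param spec A [covariate_spec()].
#' @param ref Reference group level.
#' @return data.frame, one row per metric, with group medians/IQRs,
#'   `p_univariate`, `p_adjusted`, `n_used`, `p_adjusted_bh`.
#' @export
compare_metrics <- function(metrics, metric_names = persnet_metric_names(),
                            spec = covariate_spec(), ref = "control") {
  lev <- unique(metrics$group)
  if (length(lev) < 2) stop("need two groups in the metrics table", call. = FALSE)
  rows <- lapply(metric_names, function(mn) {
    if (!mn %in% names(metrics)) return(NULL)
    v <- metrics[[mn]]
    by_grp <- tapply(!is.na(v), metrics$group, sum)
    if (any(by_grp == 0)) {
      s <- .summaries(v, metrics$group)
      have <- names(by_grp)[by_grp > 0]
      res <- structure(list(
        metric = mn, groups = c(ref, setdiff(lev, ref)),
        group_summaries = s, estimate = NA_real_,
        p_univariate = NA_real_, p_adjusted = NA_real_,
        n_used = sum(!is.na(v))
      ), class = "comparison_result")
      return(.result_row(res))
    }
    .result_row(adjusted_comparison(v, metrics$group, metrics, spec = spec,
                                    ref = ref, metric = mn))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted_bh <- p.adjust(out$p_adjusted, method = "BH")
  rownames(out) <- NULL
  out
}

#' Baseline descriptive table for a cohort
#'
#' Continuous characteristics as median \[IQR\] with Mann-Whitney
#' p-values; categorical characteristics as count (% of non-missing) per
#' level with chi-squared p-values.
#'
#' @param x An `ego_cohort`, or a data.frame with one row per participant
#'   carrying a `group` column and the baseline columns.
#' @return data.frame: `variable`, `level`, then per group `n_<g>` /
#'   `pct_<g>` (categorical) or `median_<g>` / `q1_<g>` / `q3_<g>`
#'   (continuous), a formatted `summary_<g>` column, and `p`.
#' @export
descriptive_table <- function(x) {
  if (!is.data.frame(x)) x <- .as_cohort(x)
  df <- if (!is.data.frame(x)) {
    x <- unclass(x)
    data.frame(
      group = vapply(x, `[[`, "", "group"),
      age = vapply(x, function(r) as.numeric(r$age), 0),
      race = vapply(x, function(r) as.character(r$race), ""),
      education = vapply(x, function(r) as.character(r$education), ""),
      employment = vapply(x, function(r) as.character(r$employment), ""),
      income = vapply(x, function(r) as.numeric(r$income), 0),
      domestic_status = vapply(x, function(r) as.character(r$domestic_status), ""),
      living_situation = vapply(x, function(r) as.character(r$living_situation), ""),
      chronic_condition = vapply(x, function(r) as.logical(r$chronic_condition), NA),
      stringsAsFactors = FALSE
    )
  } else x
  groups <- sort(unique(df$group[!is.na(df$group)]))
  if (length(groups) != 2) {
    stop("descriptive_table needs two nonempty groups", call. = FALSE)
  }
  continuous <- intersect(c("age", "income"), names(df))
  categorical <- intersect(
    c("race", "education", "employment", "domestic_status",
      "living_situation", "chronic_condition"), names(df))
  rows <- list()
  for (v in continuous) {
    s <- .summaries(df[[v]], df$group)
    row <- data.frame(variable = v, level = NA_character_, stringsAsFactors = FALSE)
    for (g in groups) {
      sg <- s[[g]]
      row[[paste0("median_", g)]] <- sg$median
      row[[paste0("q1_", g)]] <- sg$q1
      row[[paste0("q3_", g)]] <- sg$q3
      row[[paste0("summary_", g)]] <- if (sg$n) {
        sprintf("%.2f [%.2f, %.2f]", sg$median, sg$q1, sg$q3)
      } else ""
    }
    row$p <- if (all(vapply(s, `[[`, 0L, "n") > 0)) {
      as.numeric(mann_whitney(df[[v]][df$group == groups[1]],
                              df[[v]][df$group == groups[2]]))
    } else NA_real_
    rows[[length(rows) + 1]] <- row
  }
  for (v in categorical) {
    vals <- df[[v]]
    if (is.logical(vals)) vals <- ifelse(vals, "present", "not present")
    levs <- if (v == "education") .education_levels else
      if (v == "employment") .employment_levels else sort(unique(vals[!is.na(vals)]))
    levs <- intersect(levs, vals)
    tab <- table(factor(vals, levels = levs), df$group)[, groups, drop = FALSE]
    p <- if (nrow(tab) >= 2) tryCatch(as.numeric(chi_square(t(tab))),
                                      error = function(e) NA_real_) else NA_real_
    denom <- colSums(tab)
    for (lv in levs) {
      row <- data.frame(variable = v, level = lv, stringsAsFactors = FALSE)
      for (g in groups) {
        n <- tab[lv, g]
        pct <- if (denom[[g]] > 0) 100 * n / denom[[g]] else NA_real_
        row[[paste0("n_", g)]] <- n
        row[[paste0("pct_", g)]] <- pct
        row[[paste0("summary_", g)]] <- if (denom[[g]] > 0) {
          sprintf("%d (%.1f)", n, pct)
        } else ""
      }
      row$p <- p
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  rownames(out) <- NULL
  out
}

#' Stratified comparisons within the players cohort
#'
#' Re-runs the adjusted comparison over strata of the players cohort:
#' `race_2way` (White vs Black/Other, each also contrasted with
#' controls); `illness_count` (0 / 1 / 2 / 3+ chronic conditions, each
#' ill stratum vs the no-condition stratum); `illness_type` (none vs
#' sleep apnea / pain / cardiometabolic; type strata may overlap since a
#' player can carry several afflictions). Empty strata are skipped with a
#' message.
#'
#' @param metrics data.frame from [compute_metrics()].
#' @param strata_rule One of `"race_2way"`, `"illness_count"`,
#'   `"illness_type"`.
#' @param metric_names Metrics to compare.
#' @param spec A [covariate_spec()]; for within-player race contrasts the
#'   race covariate is dropped automatically when it coincides with the
#'   stratification.
#' @return data.frame of comparison rows with `strata_rule` and
#'   `contrast` columns.
#' @export
stratified_comparison <- function(metrics,
                                  strata_rule = c("race_2way", "illness_count",
                                                  "illness_type"),
                                  metric_names = persnet_metric_names(),
                                  spec = covariate_spec()) {
  strata_rule <- match.arg(strata_rule)
  players <- metrics[metrics$group == "player", , drop = FALSE]
  controls <- metrics[metrics$group == "control", , drop = FALSE]
  run <- function(sub, label_col, contrast, use_spec) {
    counts <- table(sub[[label_col]])
    if (length(counts) < 2 || any(counts == 0)) {
      message("skipping contrast (empty stratum): ", contrast)
      return(NULL)
    }
    rows <- lapply(metric_names, function(mn) {
      if (!mn %in% names(sub)) return(NULL)
      v <- sub[[mn]]
      ok <- tapply(!is.na(v), sub[[label_col]], sum)
      if (any(ok == 0)) return(NULL)
      res <- tryCatch(
        adjusted_comparison(v, sub[[label_col]], sub, spec = use_spec,
                            ref = levels(factor(sub[[label_col]]))[1],
                            metric = mn),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      cbind(data.frame(strata_rule = strata_rule, contrast = contrast,
                       stringsAsFactors = FALSE), .result_row(res))
    })
    do.call(rbind, rows)
  }
  out <- NULL
  if (strata_rule == "race_2way") {
    players$race_stratum <- ifelse(players$race == "White", "White", "Black/Other")
    no_race <- covariate_spec(setdiff(spec$covariates, "race"))
    sub <- players; sub$.lab <- sub$race_stratum
    out <- rbind(out, run(sub, ".lab", "players White vs Black/Other", no_race))
    for (stratum in c("White", "Black/Other")) {
      sub <- rbind(
        cbind(players[players$race_stratum == stratum,
                      setdiff(names(players), "race_stratum"), drop = FALSE]),
        controls)
      sub$.lab <- ifelse(sub$group == "control", "control", stratum)
      out <- rbind(out, run(sub, ".lab",
                            paste0("players ", stratum, " vs controls"), spec))
    }
  } else if (strata_rule == "illness_count") {
    players$.count <- cut(players$n_chronic, c(-1, 0, 1, 2, Inf),
                          labels = c("0", "1", "2", "3+"))
    for (stratum in c("1", "2", "3+")) {
      sub <- players[players$.count %in% c("0", stratum), , drop = FALSE]
      sub$.lab <- as.character(sub$.count)
      out <- rbind(out, run(sub, ".lab",
                            paste0("players ", stratum, " conditions vs 0"), spec))
    }
  } else {
    none <- players[players$n_chronic %in% 0, , drop = FALSE]
    for (ty in c("sleep", "pain", "cardiometabolic")) {
      col <- paste0("chronic_", ty)
      sub <- rbind(none, players[players[[col]] %in% TRUE, , drop = FALSE])
      sub$.lab <- ifelse(sub$n_chronic == 0, "none", ty)
      out <- rbind(out, run(sub, ".lab",
                            paste0("players ", ty, " vs no condition"), spec))
    }
  }
  if (!is.null(out)) rownames(out) <- NULL
  out
}
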