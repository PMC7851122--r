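# Vectorised field coercers. Each returns list(value, bad): `bad` marks
# cells whose input was non-missing but could not be interpreted, so the
# offending row can be skipped with a per-row parse error.

.coerce_num <- function(v) {
  if (is.numeric(v)) return(list(value = as.numeric(v), bad = rep(FALSE, length(v))))
  s <- trimws(as.character(v))
  s[s == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(s))
  list(value = out, bad = !is.na(s) & is.na(out))
}

.coerce_bool <- function(v) {
  if (is.logical(v)) return(list(value = v, bad = rep(FALSE, length(v))))
  if (is.numeric(v)) {
    bad <- !is.na(v) & !(v %in% c(0, 1))
    return(list(value = v == 1, bad = bad))
  }
  s <- tolower(trimws(as.character(v)))
  s[s == ""] <- NA_character_
  tru <- s %in% c("1", "true", "t", "yes", "y")
  fal <- s %in% c("0", "false", "f", "no", "n")
  out <- rep(NA, length(s))
  out[tru] <- TRUE
  out[fal] <- FALSE
  list(value = out, bad = !is.na(s) & !tru & !fal)
}

.coerce_cat <- function(v, levels, map = NULL, ordinal = FALSE) {
  s <- trimws(as.character(v))
  s[s == ""] <- NA_character_
  low <- tolower(s)
  idx <- match(low, tolower(levels))
  if (ordinal) {
    num <- match(low, as.character(seq_along(levels)))
    idx[is.na(idx)] <- num[is.na(idx)]
  }
  if (!is.null(map)) {
    mapped <- match(tolower(unname(map[low])), tolower(levels))
    idx[is.na(idx)] <- mapped[is.na(idx)]
  }
  list(value = levels[idx], bad = !is.na(s) & is.na(idx))
}

.ego_coercers <- function() list(
  age = .coerce_num,
  race = function(v) .coerce_cat(v, .races, map = .race_map),
  education = function(v) .coerce_cat(v, .education_levels, ordinal = TRUE),
  employment = function(v) .coerce_cat(v, .employment_levels),
  income = .coerce_num,
  domestic_status = function(v) .coerce_cat(v, .domestic_levels),
  living_situation = function(v) .coerce_cat(v, .living_levels),
  chronic_condition = .coerce_bool,
  chronic_neurocognitive = .coerce_bool,
  chronic_pain = .coerce_bool,
  chronic_cardiometabolic = .coerce_bool,
  chronic_sleep = .coerce_bool,
  qc_inaccurate = .coerce_bool
)

.alter_coercer <- function(field) {
  switch(.alter_fields[[field]],
    character = if (field == "sex") {
      function(v) .coerce_cat(v, .sexes)
    } else {
      function(v) .coerce_cat(v, .races, map = .race_map)
    },
    numeric = .coerce_num,
    logical = .coerce_bool
  )
}

#' Parse a wide-format personal-network survey table
#'
#' Reads the flat wide-CSV dialect (one row per participant): ego columns,
#' then `alter{i}_<field>` blocks for each roster slot, then `tie_{i}_{j}`
#' strengths (`0` none, `1` tie, `2` especially close) for `1 <= i < j <= 10`.
#' The roster is unlimited; tie entries beyond the first ten alters are
#' ignored. An alter slot is part of the roster when any of its attribute
#' cells is non-missing. If both `tie_i_j` and `tie_j_i` are present and
#' disagree, the stronger value is kept and the record is flagged
#' `asymmetric_ties_repaired`.
#'
#' Rows with malformed categorical or numeric codes are skipped and
#' collected in the `parse_errors` attribute of the result; duplicate
#' participant ids are an error.
#'
#' @param x Path to a CSV file, or a data.frame laid out in the dialect.
#' @return A list of [ego_record()] objects (class `ego_cohort`) with a
#'   `parse_errors` attribute (data.frame: `row`, `participant_id`,
#'   `message`).
#' @seealso [write_survey_table()], [validate_record()]
#' @export
parse_survey_table <- function(x) {
  df <- if (is.character(x)) {
    read.csv(x, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("", "NA"), colClasses = "character")
  } else if (is.data.frame(x)) x else {
    stop("x must be a file path or a data.frame", call. = FALSE)
  }
  nr <- nrow(df)
  if (!"participant_id" %in% names(df) || !"group" %in% names(df)) {
    stop("survey table must have participant_id and group columns", call. = FALSE)
  }
  ids <- trimws(as.character(df$participant_id))
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  grp <- .coerce_cat(df$group, .groups)

  ego <- list(); ego_bad <- matrix(FALSE, nr, 0)
  for (f in names(.ego_coercers())) {
    if (f %in% names(df)) {
      co <- .ego_coercers()[[f]](df[[f]])
      ego[[f]] <- co$value
      ego_bad <- cbind(ego_bad, co$bad)
      colnames(ego_bad)[ncol(ego_bad)] <- f
    }
  }

  # alter slot discovery and columnwise coercion into per-field matrices
  pat <- paste0("^alter([0-9]+)_(", paste(names(.alter_fields), collapse = "|"), ")$")
  hits <- regmatches(names(df), regexec(pat, names(df)))
  slots <- sort(unique(as.integer(vapply(
    hits[lengths(hits) == 3], `[`, "", 2
  ))))
  amat <- abad <- list()
  for (f in names(.alter_fields)) {
    cols <- paste0("alter", slots, "_", f)
    vm <- matrix(if (.alter_fields[[f]] == "character") NA_character_ else
                 if (.alter_fields[[f]] == "numeric") NA_real_ else NA,
                 nr, length(slots))
    bm <- matrix(FALSE, nr, length(slots))
    for (s in seq_along(slots)) {
      if (cols[s] %in% names(df)) {
        co <- .alter_coercer(f)(df[[cols[s]]])
        vm[, s] <- co$value
        bm[, s] <- co$bad
      }
    }
    amat[[f]] <- vm
    abad[[f]] <- bm
  }
  present <- Reduce(`|`, c(lapply(amat, function(m) !is.na(m)),
                           lapply(abad, identity)))
  if (is.null(present)) present <- matrix(FALSE, nr, 0)
  any_alter_bad <- Reduce(`|`, lapply(abad, function(m) rowSums(m) > 0),
                          accumulate = FALSE)
  if (is.null(any_alter_bad)) any_alter_bad <- rep(FALSE, nr)

  # tie columns for pairs among the first .tie_cap slots (both orientations)
  pairs <- which(upper.tri(matrix(0, .tie_cap, .tie_cap)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  tie_fwd <- tie_rev <- matrix(NA_real_, nr, nrow(pairs))
  tie_bad <- matrix(FALSE, nr, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    for (orient in 1:2) {
      cn <- if (orient == 1) paste0("tie_", i, "_", j) else paste0("tie_", j, "_", i)
      if (cn %in% names(df)) {
        co <- .coerce_num(df[[cn]])
        bad <- co$bad | (!is.na(co$value) & !(co$value %in% 0:2))
        if (orient == 1) tie_fwd[, p] <- co$value else tie_rev[, p] <- co$value
        tie_bad[, p] <- tie_bad[, p] | bad
      }
    }
  }

  records <- vector("list", nr)
  errors <- list()
  fail <- function(r, msg) {
    errors[[length(errors) + 1]] <<- data.frame(
      row = r, participant_id = ids[r], message = msg,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nr)) {
    if (is.na(grp$value[r])) { fail(r, "malformed or missing group"); next }
    if (ncol(ego_bad) && any(ego_bad[r, ])) {
      fail(r, paste("malformed value in:",
                    paste(colnames(ego_bad)[ego_bad[r, ]], collapse = ", ")))
      next
    }
    m <- if (ncol(present)) {
      w <- which(present[r, ])
      if (length(w)) max(w) else 0L
    } else 0L
    if (any_alter_bad[r]) { fail(r, "malformed alter attribute"); next }
    alters <- lapply(amat, function(vm) vm[r, seq_len(m)])
    k <- min(m, .tie_cap)
    ties <- NULL
    repaired <- FALSE
    if (k >= 1) {
      sel <- pairs[, 2] <= k
      if (any(tie_bad[r, sel])) { fail(r, "malformed tie strength"); next }
      fwd <- tie_fwd[r, sel]; rev <- tie_rev[r, sel]
      if (k == 1) {
        ties <- matrix(NA_real_, 1, 1)
      } else if (any(!is.na(fwd)) || any(!is.na(rev))) {
        repaired <- any(!is.na(fwd) & !is.na(rev) & fwd != rev)
        v <- pmax(fwd, rev, na.rm = TRUE)
        v[is.na(v)] <- 0
        ties <- matrix(0, k, k)
        ties[cbind(pairs[sel, 1], pairs[sel, 2])] <- v
        ties <- pmax(ties, t(ties))
        diag(ties) <- NA_real_
      }
    }
    g <- function(f) if (is.null(ego[[f]])) NA else ego[[f]][r]
    types <- .chronic_types[c(isTRUE(g("chronic_neurocognitive")),
                              isTRUE(g("chronic_pain")),
                              isTRUE(g("chronic_cardiometabolic")),
                              isTRUE(g("chronic_sleep")))]
    chronic <- g("chronic_condition")
    if (grp$value[r] == "player" && is.na(chronic)) chronic <- length(types) > 0
    rec <- ego_record(
      participant_id = ids[r], group = grp$value[r],
      age = g("age"), race = g("race"), education = g("education"),
      employment = g("employment"), income = g("income"),
      domestic_status = g("domestic_status"),
      living_situation = g("living_situation"),
      chronic_condition = chronic,
      chronic_types = if (grp$value[r] == "player") types else character(),
      alters = alters, ties = ties,
      inaccurate = isTRUE(g("qc_inaccurate"))
    )
    rec$tie_repaired <- rec$tie_repaired || repaired
    records[[r]] <- rec
  }
  keep <- !vapply(records, is.null, TRUE)
  out <- records[keep]
  class(out) <- "ego_cohort"
  attr(out, "parse_errors") <- if (length(errors)) {
    do.call(rbind, errors)
  } else {
    data.frame(row = integer(), participant_id = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Serialize ego records back to the wide survey dialect
#'
#' Inverse of [parse_survey_table()]: the round trip
#' parse -> `survey_table` -> parse is lossless.
#'
#' @param records An `ego_cohort` or list of [ego_record()] objects.
#' @return A data.frame in the wide survey dialect.
#' @export
survey_table <- function(records) {
  m_max <- max(c(0L, vapply(records, n_alters, 0L)))
  nr <- length(records)
  lgl_chr <- function(v) ifelse(is.na(v), NA_integer_, as.integer(v))
  df <- data.frame(
    participant_id = vapply(records, `[[`, "", "participant_id"),
    group = vapply(records, `[[`, "", "group"),
    stringsAsFactors = FALSE
  )
  for (f in c("age", "income")) df[[f]] <- vapply(records, function(r) as.numeric(r[[f]]), 0)
  for (f in c("race", "education", "employment", "domestic_status",
              "living_situation")) {
    df[[f]] <- vapply(records, function(r) as.character(r[[f]]), "")
  }
  df <- df[, c("participant_id", "group", "age", "race", "education",
               "employment", "income", "domestic_status", "living_situation")]
  df$chronic_condition <- lgl_chr(vapply(records, `[[`, NA, "chronic_condition"))
  for (ct in .chronic_types) {
    df[[paste0("chronic_", ct)]] <- vapply(records, function(r) {
      if (r$group != "player") NA_integer_ else as.integer(ct %in% r$chronic_types)
    }, 0L)
  }
  df$qc_inaccurate <- vapply(records, function(r) as.integer(r$inaccurate), 0L)
  for (i in seq_len(m_max)) {
    for (f in names(.alter_fields)) {
      col <- paste0("alter", i, "_", f)
      df[[col]] <- vapply(records, function(r) {
        if (n_alters(r) < i) return(NA_character_)
        v <- r$alters[[f]][i]
        if (is.logical(v)) v <- as.integer(v)
        if (is.na(v)) NA_character_ else as.character(v)
      }, "")
    }
  }
  for (i in seq_len(max(min(m_max, .tie_cap) - 1L, 0L))) {
    for (j in seq(i + 1L, min(m_max, .tie_cap))) {
      df[[paste0("tie_", i, "_", j)]] <- vapply(records, function(r) {
        if (is.null(r$ties) || nrow(r$ties) < j) NA_real_ else r$ties[i, j]
      }, 0)
    }
  }
  df
}

#' Write a survey table (or cohort) to CSV
#' @param x A survey data.frame or an `ego_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  if (!is.data.frame(x)) x <- survey_table(x)
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

# Coerce any cohort-like input (ego_cohort, bare list of ego_records,
# survey data.frame, or CSV path) to an ego_cohort.
.as_cohort <- function(x) {
  if (inherits(x, "ego_cohort")) return(x)
  if (is.list(x) && !is.data.frame(x) &&
      length(x) && all(vapply(x, inherits, TRUE, "ego_record"))) {
    class(x) <- "ego_cohort"
    return(x)
  }
  parse_survey_table(x)
}

#' Quality-control validation of an ego record
#'
#' Classifies a parsed record following the survey's quality-control
#' procedure for incomplete, inaccurate, or non-existent network data:
#' `nonexistent_network` when the roster is empty; `incomplete` when any
#' alter lacks sex, race *and* kin, or when the tie section is absent for
#' a roster of two or more; `inaccurate` when the staff QC flag is set;
#' `asymmetric_ties_repaired` when conflicting tie orientations were
#' reconciled on read; `size_lt_2` (informational) for one-alter rosters,
#' which are excluded from homogeneity montage scoring. A record is
#' `usable` unless incomplete, inaccurate, or nonexistent.
#'
#' Always returns a report; never raises.
#'
#' @param record An [ego_record()].
#' @return List with `participant_id`, `flags` (character vector) and
#'   `usable` (logical).
#' @export
validate_record <- function(record) {
  flags <- character()
  m <- n_alters(record)
  if (m == 0) flags <- c(flags, "nonexistent_network")
  if (m >= 1) {
    a <- record$alters
    bare <- is.na(a$sex) & is.na(a$race) & is.na(a$kin)
    if (any(bare)) flags <- c(flags, "incomplete")
    if (m >= 2 && is.null(record$ties)) flags <- c(flags, "incomplete")
  }
  if (isTRUE(record$inaccurate)) flags <- c(flags, "inaccurate")
  if (isTRUE(record$tie_repaired)) flags <- c(flags, "asymmetric_ties_repaired")
  if (m == 1) flags <- c(flags, "size_lt_2")
  flags <- unique(flags)
  list(
    participant_id = record$participant_id,
    flags = flags,
    usable = !any(flags %in% c("incomplete", "inaccurate", "nonexistent_network"))
  )
}

#' Validate every record in a cohort
#' @param records An `ego_cohort`.
#' @return data.frame with `participant_id`, comma-separated `flags`, and
#'   `usable`.
#' @export
validate_cohort <- function(records) {
  reps <- lapply(records, validate_record)
  data.frame(
    participant_id = vapply(reps, `[[`, "", "participant_id"),
    flags = vapply(reps, function(r) paste(r$flags, collapse = ","), ""),
    usable = vapply(reps, `[[`, TRUE, "usable"),
    stringsAsFactors = FALSE
  )
}
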