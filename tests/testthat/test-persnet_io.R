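test_that("parsing recovers rosters, caps the tie section at ten, and handles empty rosters", {
  # three alters with a full 3x3 tie section
  recs <- parse_survey_table(survey_table(list(make_record(n = 3, ties = "full"))))
  expect_length(recs, 1)
  expect_equal(n_alters(recs[[1]]), 3)
  expect_equal(dim(recs[[1]]$ties), c(3, 3))
  expect_equal(recs[[1]]$ties[1, 2], 1)

  # twelve alters: the roster is uncapped but ties cover the first ten
  r12 <- make_record(n = 12, ties = complete_egonet(10))
  recs <- parse_survey_table(survey_table(list(r12)))
  expect_equal(n_alters(recs[[1]]), 12)
  expect_equal(dim(recs[[1]]$ties), c(10, 10))

  # empty roster: no alters, ties missing
  df <- survey_table(list(make_record(n = 3, ties = "full")))
  empty <- df[1, ]
  empty[grep("^(alter|tie_)", names(empty))] <- NA
  rec <- parse_survey_table(empty)[[1]]
  expect_equal(n_alters(rec), 0)
  expect_null(rec$ties)
})

test_that("parse -> write -> parse round trip is lossless on a synthetic cohort", {
  tab <- simulate_cohort(default_synthetic_config(25, 20), seed = 11)
  recs <- parse_survey_table(tab)
  expect_equal(nrow(attr(recs, "parse_errors")), 0)
  recs2 <- parse_survey_table(survey_table(recs))
  expect_equal(length(recs2), length(recs))
  for (i in seq_along(recs)) {
    expect_equal(recs2[[i]], recs[[i]])
  }
})

test_that("asymmetric tie orientations are repaired to the stronger value and flagged", {
  df <- survey_table(list(make_record(n = 3, ties = "none")))
  df$tie_1_2 <- 2
  df$tie_2_1 <- 0
  rec <- parse_survey_table(df)[[1]]
  expect_equal(rec$ties[1, 2], 2)
  expect_equal(rec$ties[2, 1], 2)
  expect_true("asymmetric_ties_repaired" %in% validate_record(rec)$flags)
  expect_true(validate_record(rec)$usable)
})

test_that("duplicate ids abort; malformed categorical rows are skipped and logged", {
  df <- survey_table(list(make_record(id = "a"), make_record(id = "a")))
  expect_error(parse_survey_table(df), "duplicate participant_id")

  df <- survey_table(list(make_record(id = "a"), make_record(id = "b")))
  df$race[2] <- "martian"
  recs <- parse_survey_table(df)
  expect_length(recs, 1)
  err <- attr(recs, "parse_errors")
  expect_equal(err$participant_id, "b")
  expect_match(err$message, "race")
})

test_that("race synonyms are mapped onto the three analysis categories", {
  df <- survey_table(list(make_record(n = 1)))
  df$race <- "African American"
  df$alter1_race <- "caucasian"
  rec <- parse_survey_table(df)[[1]]
  expect_equal(rec$race, "Black")
  expect_equal(rec$alters$race, "White")
})

test_that("validation classifies nonexistent, tiny, and incomplete networks", {
  rep0 <- validate_record(make_record(n = 0, ties = "missing"))
  expect_equal(rep0$flags, "nonexistent_network")
  expect_false(rep0$usable)

  rep1 <- validate_record(make_record(n = 1, ties = "none"))
  expect_equal(rep1$flags, "size_lt_2")
  expect_true(rep1$usable)

  rep5 <- validate_record(make_record(n = 5, ties = "missing"))
  expect_true("incomplete" %in% rep5$flags)
  expect_false(rep5$usable)

  # an alter with sex, race and kin all missing makes the record incomplete
  a <- make_alters(3)
  a$sex[2] <- NA; a$race[2] <- NA; a$kin[2] <- NA
  repb <- validate_record(make_record(n = 3, alters = a, ties = "full"))
  expect_true("incomplete" %in% repb$flags)

  # QC-inaccurate records are unusable but still classified
  repq <- validate_record(make_record(n = 3, ties = "full", inaccurate = TRUE))
  expect_false(repq$usable)
  expect_true(validate_record(make_record(n = 3, ties = "full"))$usable)
})

test_that("graph export produces stars, triangles, and first-ten-only edges", {
  g <- export_graph(make_record(n = 3, ties = "none"), include_ego = TRUE)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)

  g <- export_graph(make_record(n = 3, ties = "full"), include_ego = FALSE)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)

  g <- export_graph(make_record(n = 12, ties = complete_egonet(10)),
                    include_ego = FALSE)
  expect_equal(igraph::vcount(g), 12)
  expect_equal(igraph::ecount(g), choose(10, 2))

  expect_error(export_graph(make_record(n = 0, ties = "missing")), "empty")

  # graphml written files are readable and carry alter attributes
  path <- withr_local_tempfile <- tempfile(fileext = ".graphml")
  on.exit(unlink(path))
  export_graph(make_record(n = 3, ties = "full"), path = path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), 4)
  expect_true("sex" %in% igraph::vertex_attr_names(g2))
})

test_that("metrics tables round-trip through CSV with empty cells for missing values", {
  recs <- list(make_record(id = "a", n = 4, ties = "full"),
               make_record(id = "b", n = 1, ties = "none"))
  met <- compute_metrics(recs)
  expect_equal(nrow(met), 2)
  expect_true(is.na(met$density[met$participant_id == "b"]))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_metrics_table(met, path)
  met2 <- read_metrics_table(path)
  expect_equal(met2[, persnet_metric_names()], met[, persnet_metric_names()],
               tolerance = 1e-12)

  # bundle-list input with a schema mismatch is rejected
  b1 <- list(participant_id = "a", network_size = 3)
  b2 <- list(participant_id = "b", density = 0.5)
  expect_error(write_metrics_table(list(b1, b2), path), "schema mismatch")
  expect_silent(write_metrics_table(list(b1, b1), path))
})
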