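test_that("dichotomization maps strengths {0,1,2} to presence {0,1,1}", {
  m <- matrix(c(NA, 0, 1, 0, NA, 2, 1, 2, NA), 3, 3)
  b <- dichotomize_ties(m)
  expect_equal(b[1, 3], 1)
  expect_equal(b[2, 3], 1)
  expect_equal(b[1, 2], 0)
  expect_equal(dichotomize_ties(complete_egonet(4, strength = 2)),
               complete_egonet(4) |> (\(x) { diag(x) <- 0; x })())
  expect_true(all(dichotomize_ties(star_egonet(4)) == 0))
})

test_that("network size is the uncapped roster length", {
  expect_equal(network_size(make_record(n = 0, ties = "missing")), 0)
  expect_equal(network_size(make_record(n = 7)), 7)
  expect_equal(network_size(make_record(n = 12, ties = complete_egonet(10))), 12)
})

test_that("density counts actual over possible alter-alter connections", {
  expect_equal(tie_density(star_egonet(4)), 0)
  expect_equal(tie_density(complete_egonet(4)), 1)
  m <- star_egonet(4)
  m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 2; m[2, 3] <- m[3, 2] <- 1
  expect_equal(tie_density(m), 0.5)
  expect_true(is.na(tie_density(matrix(NA_real_, 1, 1))))
})

test_that("constraint hits its closed forms: single contact, star, and complete egonets", {
  expect_equal(burt_constraint(matrix(NA_real_, 1, 1)), 100)
  for (k in 2:10) {
    expect_equal(burt_constraint(star_egonet(k)), 100 / k, tolerance = 1e-12)
    expect_equal(burt_constraint(complete_egonet(k)),
                 100 * (2 * k - 1)^2 / k^3, tolerance = 1e-12)
  }
})

test_that("constraint and effective size agree with brute-force Burt oracles", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:10, 1)
    m <- rand_egonet(k)
    expect_equal(burt_constraint(m, weighted = TRUE),
                 oracle_constraint(m, weighted = TRUE), tolerance = 1e-9)
    expect_equal(burt_constraint(m, weighted = FALSE),
                 oracle_constraint(m, weighted = FALSE), tolerance = 1e-9)
    expect_equal(effective_size(m), oracle_effective_size_binary(m),
                 tolerance = 1e-9)
    expect_equal(effective_size(m, method = "burt"),
                 oracle_effective_size_burt(m), tolerance = 1e-9)
  }
})

test_that("binary constraint matches igraph on ego-included graphs", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:10, 1)
    m <- rand_egonet(k, strengths = 0:1)
    edges <- c()
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      if (m[a, b] >= 1) edges <- c(edges, a + 1, b + 1)
    }
    g <- igraph::make_empty_graph(k + 1, directed = FALSE)
    g <- igraph::add_edges(g, c(rbind(1, 2:(k + 1)), edges))
    expect_equal(burt_constraint(m, weighted = FALSE),
                 100 * unname(igraph::constraint(g)[1]), tolerance = 1e-9)
  }
})

test_that("effective size follows the binary simplification k - 2t/k", {
  expect_equal(effective_size(star_egonet(5)), 5)
  expect_equal(effective_size(complete_egonet(5)), 1)
  m <- star_egonet(4)
  m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 2
  expect_equal(effective_size(m), 3)
})

test_that("degrees are computed on the alter-only dichotomized subgraph", {
  expect_equal(degree_stats(complete_egonet(4)),
               list(max_degree = 3, mean_degree = 3))
  expect_equal(degree_stats(star_egonet(4)),
               list(max_degree = 0, mean_degree = 0))
  path <- star_egonet(3)
  path[1, 2] <- path[2, 1] <- 1; path[2, 3] <- path[3, 2] <- 1
  expect_equal(degree_stats(path), list(max_degree = 2, mean_degree = 4 / 3))
})

test_that("compute_structure bundles metrics with first-ten ties but uncapped size", {
  s <- compute_structure(make_record(n = 12, ties = complete_egonet(10)))
  expect_equal(s$network_size, 12)
  expect_equal(s$density, 1)

  s0 <- compute_structure(make_record(n = 0, ties = "missing"))
  expect_equal(s0$network_size, 0)
  expect_true(all(is.na(unlist(s0[-1]))))

  m <- star_egonet(4)
  m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 1; m[2, 3] <- m[3, 2] <- 1
  s4 <- compute_structure(make_record(n = 4, ties = m))
  expect_equal(s4$density, 0.5)
  expect_equal(s4$effective_size, 2.5)
})

test_that("adding a tie never decreases density nor increases effective size", {
  # NOTE: Burt constraint is deliberately absent here. It is not monotone
  # in added ties: a new tie redistributes the proportional weights of its
  # endpoints, which can shrink other alters' indirect contributions by
  # more than the new dyad adds (e.g. densifying one corner of a sparse
  # egonet). Constraint does increase on the star -> complete path, which
  # the closed-form tests cover.
  set.seed(99)
  for (i in 1:40) {
    k <- sample(3:10, 1)
    m <- rand_egonet(k)
    zeros <- which(upper.tri(m) & m == 0, arr.ind = TRUE)
    if (!nrow(zeros)) next
    pick <- zeros[sample(nrow(zeros), 1), ]
    m2 <- m
    m2[pick[1], pick[2]] <- m2[pick[2], pick[1]] <- sample(1:2, 1)
    expect_gte(tie_density(m2), tie_density(m))
    expect_lte(effective_size(m2), effective_size(m))
  }
})

test_that("constraint increases along the star-to-complete densification path", {
  for (k in c(3, 5, 8)) {
    m <- star_egonet(k)
    prev <- burt_constraint(m)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    # fill ties one alter at a time so closure accumulates globally
    for (p in seq_len(nrow(pairs))) {
      m[pairs[p, 1], pairs[p, 2]] <- m[pairs[p, 2], pairs[p, 1]] <- 1
    }
    expect_gt(burt_constraint(m), prev)
  }
})

test_that("structure metric bounds hold on random egonets", {
  set.seed(123)
  for (i in 1:60) {
    k <- sample(1:10, 1)
    m <- rand_egonet(k)
    s <- compute_structure(make_record(n = k, ties = m))
    if (k >= 2) expect_true(s$density >= 0 && s$density <= 1)
    expect_true(s$effective_size >= 1 - 1e-12 && s$effective_size <= k)
    expect_lte(s$max_degree, k - 1 + 1e-12)
    expect_lte(s$mean_degree, s$max_degree)
  }
})
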