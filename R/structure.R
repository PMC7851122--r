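# Per-ego network structure metrics. All tie-based metrics operate on the
# inter-relater subnetwork (first min(n, 10) alters); network size alone
# uses the full, uncapped roster.

#' Dichotomize a tie-strength matrix
#'
#' Presence coding for density, degrees and effective size: an alter-alter
#' tie is present iff its strength is at least 1 ("especially close" ties
#' count once).
#'
#' @param ties Symmetric strength matrix with entries in `{0, 1, 2}`,
#'   diagonal undefined.
#' @return Binary symmetric matrix of the same dimension, zero diagonal.
#' @export
dichotomize_ties <- function(ties) {
  b <- (ties >= 1) * 1
  b[is.na(b)] <- 0
  b
}

#' Network size: the uncapped roster length
#'
#' The number of individuals named in the network, excluding the
#' participant. The name generator places no ceiling on the roster, so
#' size is computed on the full roster even though ties are only
#' collected for the first ten members.
#'
#' @param record An [ego_record()].
#' @return Integer count.
#' @export
network_size <- function(record) n_alters(record)

#' Density of the alter-alter network
#'
#' Actual connections among network members divided by possible
#' connections, excluding the participant, on dichotomized ties.
#'
#' @param ties Strength matrix over `k` alters.
#' @return Fraction in `[0, 1]`; `NA` when `k < 2`.
#' @export
tie_density <- function(ties) {
  if (is.null(ties) || nrow(ties) < 2) return(NA_real_)
  k <- nrow(ties)
  b <- dichotomize_ties(ties)
  sum(b[upper.tri(b)]) / (k * (k - 1) / 2)
}

# Proportional-weight matrix over the ego-included node set.
# Row 1 is the ego, tied to every alter with unit weight; the alter block
# carries raw strengths (weighted = TRUE) or presence (FALSE).
.ego_weights <- function(ties, weighted = TRUE) {
  k <- nrow(ties)
  z <- matrix(0, k + 1, k + 1)
  z[1, -1] <- 1
  z[-1, 1] <- 1
  if (k >= 2) {
    a <- if (weighted) ties else dichotomize_ties(ties)
    a[is.na(a)] <- 0
    z[-1, -1] <- a
  }
  z
}

#' Burt constraint of the ego
#'
#' The degree to which the ego's contacts are connected to each other,
#' incorporating strength of ties. Computed on the ego-included graph over
#' the first ten alters with unit ego-alter weights: with symmetrized
#' proportional weights
#' \eqn{p_{ij} = (z_{ij} + z_{ji}) / \sum_q (z_{iq} + z_{qi})}, the dyadic
#' constraint is
#' \eqn{c_{ej} = (p_{ej} + \sum_{q \ne e,j} p_{eq} p_{qj})^2} and the
#' reported score is \eqn{100 \sum_j c_{ej}} (a 0 to ~140 percent-like
#' scale; an isolated single contact gives exactly 100).
#'
#' @param ties Strength matrix over `k >= 1` alters.
#' @param weighted Use raw strengths for the alter-alter weights
#'   (default); `FALSE` dichotomizes them first.
#' @return Constraint score; `NA` for an empty network.
#' @export
burt_constraint <- function(ties, weighted = TRUE) {
  if (is.null(ties) || nrow(ties) < 1) return(NA_real_)
  z <- .ego_weights(ties, weighted)
  s <- z + t(z)
  p <- s / rowSums(s)
  k <- nrow(ties)
  # indirect term for all alters at once: (p %*% p)[1, j] sums over every
  # q; remove the q = e and q = j contributions (p[e, e] = p[j, j] = 0).
  indirect <- (p %*% p)[1, -1] - p[1, -1] * diag(p[-1, -1, drop = FALSE])
  100 * sum((p[1, -1] + indirect)^2)
}

#' Effective size of the ego network
#'
#' The number of nonredundant network members. The default is the binary
#' simplification `k - 2t/k` (roster-in-ties size minus the mean
#' alter-alter degree, on dichotomized ties); `method = "burt"` evaluates
#' the weighted redundancy sum
#' \eqn{\sum_j (1 - \sum_{q \ne e,j} p_{eq} m_{qj})} with
#' \eqn{m_{qj} = (z_{qj} + z_{jq}) / \max_w (z_{qw} + z_{wq})}, which
#' coincides with the binary form on dichotomized complete data.
#'
#' @param ties Strength matrix over `k >= 1` alters.
#' @param method `"binary"` (default) or `"burt"`.
#' @return Real in `[1, k]`; `NA` for an empty network.
#' @export
effective_size <- function(ties, method = c("binary", "burt")) {
  method <- match.arg(method)
  if (is.null(ties) || nrow(ties) < 1) return(NA_real_)
  k <- nrow(ties)
  if (method == "binary") {
    if (k == 1) return(1)
    b <- dichotomize_ties(ties)
    t_count <- sum(b[upper.tri(b)])
    return(k - 2 * t_count / k)
  }
  z <- .ego_weights(ties, weighted = TRUE)
  s <- z + t(z)
  p <- s / rowSums(s)
  mx <- apply(s, 1, max)
  m <- s / mx  # marginal strength of each contact's relations
  total <- 0
  for (j in 2:(k + 1)) {
    q <- setdiff(2:(k + 1), j)
    total <- total + (1 - sum(p[1, q] * m[q, j]))
  }
  total
}

#' Maximum and mean alter degree
#'
#' Degrees on the dichotomized alter-alter subgraph; the ego is excluded
#' both as a node and from the counts.
#'
#' @param ties Strength matrix over `k >= 1` alters.
#' @return Named list `max_degree`, `mean_degree`; both `NA` for an empty
#'   network.
#' @export
degree_stats <- function(ties) {
  if (is.null(ties) || nrow(ties) < 1) {
    return(list(max_degree = NA_real_, mean_degree = NA_real_))
  }
  b <- dichotomize_ties(ties)
  deg <- rowSums(b)
  list(max_degree = max(deg), mean_degree = mean(deg))
}

#' All six structure metrics for one record
#'
#' Network size uses the full roster; density, constraint, effective size
#' and degrees are computed on the first-ten subnetwork for which ties
#' were collected. Records whose roster exceeds ten are marked
#' `ties_truncated` in the metrics table.
#'
#' @param record A validated [ego_record()].
#' @param constraint_weighted Passed to [burt_constraint()].
#' @param effective_size_method Passed to [effective_size()].
#' @return Named list: `network_size`, `density`, `constraint`,
#'   `effective_size`, `max_degree`, `mean_degree`.
#' @export
compute_structure <- function(record, constraint_weighted = TRUE,
                              effective_size_method = "binary") {
  ties <- record$ties
  deg <- degree_stats(ties)
  list(
    network_size = network_size(record),
    density = if (is.null(ties)) NA_real_ else tie_density(ties),
    constraint = burt_constraint(ties, weighted = constraint_weighted),
    effective_size = effective_size(ties, method = effective_size_method),
    max_degree = deg$max_degree,
    mean_degree = deg$mean_degree
  )
}
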