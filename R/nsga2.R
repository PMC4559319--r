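# NSGA-II machinery: dominance, non-dominated sorting, crowding distance,
# crowding tournament selection.  All objectives are minimized.

#' Pareto dominance between two objective vectors
#'
#' \code{a} dominates \code{b} when \code{a} is superior or equal in every
#' objective and differs in at least one; \code{a} strongly dominates
#' \code{b} when it is strictly superior in every objective.  The strong
#' variant underlies \emph{weak} Pareto optimality: the weak Pareto set is
#' everything not strongly dominated.
#'
#' @param a,b numeric objective vectors (minimized).
#' @param strong use strong dominance.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
dominates <- function(a, b, strong = FALSE) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  if (strong) all(a < b) else all(a <= b) && any(a != b)
}

#' Non-dominated sorting of a population
#'
#' Rank 1 is the non-dominated subset; rank k the non-dominated subset once
#' ranks below k are removed.  With \code{strong = TRUE} the sort uses
#' strong dominance, yielding weak-Pareto fronts.
#'
#' @param obj numeric matrix, one row per individual, one column per
#'   objective (minimized).
#' @param strong use strong dominance.
#' @return Integer vector of ranks.
#' @export
nondominated_sort <- function(obj, strong = FALSE) {
  n <- nrow(obj)
  if (n == 0) return(integer(0))
  dom <- matrix(FALSE, n, n)   # dom[i, j]: i dominates j
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dom[i, j] <- dominates(obj[i, ], obj[j, ], strong = strong)
    }
  }
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    idx <- which(remaining)
    front <- idx[!vapply(idx, function(j) any(dom[idx, j]), logical(1))]
    if (!length(front)) stop("dominance cycle (impossible for valid vectors)")
    rank[front] <- r
    remaining[front] <- FALSE
  }
  rank
}

#' Crowding distance within one front
#'
#' For each objective the front is sorted; boundary individuals receive
#' infinite distance, interior ones the sum over objectives of the
#' normalized gap between their neighbours.  Objectives with zero range
#' contribute nothing.
#'
#' @param obj numeric matrix of the front's objective vectors.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n == 0) return(numeric(0))
  d <- numeric(n)
  if (n <= 2) return(rep(Inf, n))
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[1]] <- Inf
    d[o[n]] <- Inf
    if (rng > 0) {
      for (k in 2:(n - 1))
        d[o[k]] <- d[o[k]] + (obj[o[k + 1], m] - obj[o[k - 1], m]) / rng
    }
  }
  d
}

# ranks + crowding for a whole population matrix
.rank_and_crowd <- function(obj, strong = FALSE) {
  rank <- nondominated_sort(obj, strong = strong)
  crowd <- numeric(length(rank))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  list(rank = rank, crowd = crowd)
}

# binary crowding tournament: lower rank wins; tie -> larger crowding
# distance wins; full tie -> fair coin
.tournament <- function(rank, crowd, n_pick) {
  n <- length(rank)
  vapply(seq_len(n_pick), function(k) {
    ij <- sample.int(n, 2L, replace = TRUE)
    i <- ij[1]; j <- ij[2]
    if (rank[i] < rank[j]) i
    else if (rank[j] < rank[i]) j
    else if (crowd[i] > crowd[j]) i
    else if (crowd[j] > crowd[i]) j
    else if (runif(1) < 0.5) i else j
  }, integer(1))
}

# truncate a population (list of evaluated individuals with $rank/$crowd)
# to n_keep by (rank asc, crowding desc)
.truncate_pop <- function(pop, n_keep) {
  if (length(pop) <= n_keep) return(pop)
  rank <- vapply(pop, `[[`, numeric(1), "rank")
  crowd <- vapply(pop, `[[`, numeric(1), "crowd")
  pop[order(rank, -crowd)][seq_len(n_keep)]
}
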