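# Built-in toy folding engine.  Pair scores GC = -3, AU = -2, GU = -1
# (toy energy units), minimum hairpin loop 3 nt, kT = 1.  Nested structures
# only.  Non-physical by design: it exists so designs, tests and demos run
# hermetically; it makes no attempt to reproduce nearest-neighbour free
# energies.

# Convert an rna_structure used as a folding constraint into the partner
# vector the DP consumes: pairs forced, '.' positions forced unpaired,
# wildcard positions free.
.constraint_partner <- function(constraint, n) {
  if (is.null(constraint)) return(rep(-1L, n))
  if (is.character(constraint)) constraint <- parse_dotbracket(constraint)
  stopifnot(inherits(constraint, "rna_structure"), constraint$length == n)
  con <- integer(n)                      # 0 = forced unpaired
  con[constraint$wildcard] <- -1L
  p <- constraint$pairs
  if (nrow(p)) {
    con[p[, 1]] <- p[, 2]
    con[p[, 2]] <- p[, 1]
  }
  con
}

#' Toy engine: minimum free energy structure
#'
#' Dynamic-programming minimum over all nested structures under the toy
#' energy model.  When a constraint structure is supplied, its base pairs are
#' forced, its explicitly unpaired positions are kept unpaired, and wildcard
#' (\code{'*'}) positions are left free; the result is the lowest-energy
#' structure in the constrained ensemble (the standard model of, e.g., a
#' ligand-bound aptamer state).
#'
#' @param seq RNA sequence.
#' @param constraint optional [rna_structure()] or dot-bracket string.
#' @return List with \code{structure} ([rna_structure()]) and \code{energy}.
#' @export
toy_mfe <- function(seq, constraint = NULL) {
  s <- seq_to_codes(seq)
  con <- .constraint_partner(constraint, length(s))
  res <- .toy_mfe_cpp(s, con)
  if (!isTRUE(res$feasible))
    stop("constraint is incompatible with the sequence (empty structure space)")
  partner <- res$partner
  idx <- which(partner > seq_along(partner))
  pairs <- cbind(idx, partner[idx])
  list(structure = rna_structure(pairs, length(s)), energy = res$energy)
}

#' Toy engine: ensemble free energy
#'
#' \code{G = -kT ln Z} (kT = 1) over the same nested-structure space as
#' [toy_mfe()]; \code{G <= E(theta)} for every structure theta the sequence
#' can form, in particular \code{G <=} the MFE.
#'
#' @inheritParams toy_mfe
#' @return Ensemble free energy (toy units).
#' @export
toy_ensemble <- function(seq, constraint = NULL) {
  s <- seq_to_codes(seq)
  g <- .toy_pf_cpp(s, .constraint_partner(constraint, length(s)))
  if (!is.finite(g)) stop("constraint is incompatible with the sequence")
  g
}

#' Toy engine: energy of a given structure
#'
#' Sum of the pair scores of the structure's base pairs.  Because the model
#' is additive over pairs this also evaluates pseudoknotted structures.
#'
#' @param seq RNA sequence.
#' @param theta an [rna_structure()] or dot-bracket string.
#' @return Energy (toy units).
#' @export
toy_eval <- function(seq, theta) {
  s <- seq_to_codes(seq)
  if (is.character(theta)) theta <- parse_dotbracket(theta)
  stopifnot(inherits(theta, "rna_structure"))
  if (theta$length != length(s)) stop("sequence/structure length mismatch")
  p <- theta$pairs
  if (!nrow(p)) return(0)
  if (any(p[, 2] - p[, 1] - 1 < 3))
    stop("structure violates the minimum hairpin loop (3 nt)")
  sc <- .toy_pair_score(s[p[, 1]], s[p[, 2]])
  if (any(sc == 0)) stop("structure contains a pair the sequence cannot form")
  sum(sc)
}

.toy_pair_score <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  unname(c("1 4" = -2, "2 3" = -3, "3 4" = -1)[key]) -> sc
  sc[is.na(sc)] <- 0
  sc
}

#' Toy engine: k lowest-energy distinct structures
#'
#' @param seq RNA sequence.
#' @param k number of structures.
#' @return List of lists with \code{structure} and \code{energy}, energies
#'   non-decreasing; fewer than \code{k} when the structure space is smaller.
#' @export
toy_subopt <- function(seq, k = 2) {
  s <- seq_to_codes(seq)
  res <- .toy_kbest_cpp(s, as.integer(k))
  lapply(res, function(r) {
    idx <- which(r$partner > seq_along(r$partner))
    list(structure = rna_structure(cbind(idx, r$partner[idx]), length(s)),
         energy = r$energy)
  })
}

#' Toy engine: direct-path energy barrier
#'
#' Beam-search direct-path heuristic between two structures the sequence can
#' form: every move adds or removes one base pair, removals drawn from
#' \code{theta_a \\ theta_b} and additions from \code{theta_b \\ theta_a}
#' (an addition requires both positions free and no crossing with the current
#' structure), so every path has the same length.  The \code{lookahead} best
#' partial paths (by their running saddle) are retained at each step.  The
#' returned value, max energy along the best path minus \code{E(theta_a)},
#' is an upper bound on the true saddle height.
#'
#' @param seq RNA sequence.
#' @param theta_a,theta_b structures or dot-bracket strings.
#' @param lookahead beam width (default 10).
#' @return Barrier height \code{>= 0} (toy units).
#' @export
toy_barrier <- function(seq, theta_a, theta_b, lookahead = 10) {
  if (is.character(theta_a)) theta_a <- parse_dotbracket(theta_a)
  if (is.character(theta_b)) theta_b <- parse_dotbracket(theta_b)
  s <- seq_to_codes(seq)
  pk <- function(x) paste(x$pairs[, 1], x$pairs[, 2])
  key_a <- if (nrow(theta_a$pairs)) pk(theta_a) else character(0)
  key_b <- if (nrow(theta_b$pairs)) pk(theta_b) else character(0)
  e_of <- function(keys) {
    if (!length(keys)) return(0)
    ij <- do.call(rbind, strsplit(keys, " "))
    sum(.toy_pair_score(s[as.integer(ij[, 1])], s[as.integer(ij[, 2])]))
  }
  e_a <- toy_eval(seq, theta_a)
  to_remove <- setdiff(key_a, key_b)
  to_add <- setdiff(key_b, key_a)
  n_moves <- length(to_remove) + length(to_add)
  if (n_moves == 0) return(0)
  crosses_or_clashes <- function(cur_keys, add_key) {
    ij <- as.integer(strsplit(add_key, " ")[[1]])
    if (!length(cur_keys)) return(FALSE)
    cur <- do.call(rbind, strsplit(cur_keys, " "))
    ci <- as.integer(cur[, 1]); cj <- as.integer(cur[, 2])
    any(ci == ij[1] | cj == ij[1] | ci == ij[2] | cj == ij[2]) ||
      any((ci < ij[1] & ij[1] < cj & cj < ij[2]) |
          (ij[1] < ci & ci < ij[2] & ij[2] < cj))
  }
  # beam state: list(keys, e, saddle)
  beam <- list(list(keys = key_a, e = e_a, saddle = e_a))
  for (step in seq_len(n_moves)) {
    nxt <- list(); seen <- character(0)
    for (st in beam) {
      rem <- intersect(st$keys, to_remove)
      add <- setdiff(to_add, st$keys)
      moves <- c(lapply(rem, function(k) list(op = "rm", k = k)),
                 lapply(add, function(k) list(op = "add", k = k)))
      for (mv in moves) {
        if (mv$op == "add" && crosses_or_clashes(st$keys, mv$k)) next
        keys2 <- if (mv$op == "rm") setdiff(st$keys, mv$k) else c(st$keys, mv$k)
        e2 <- e_of(keys2)
        id <- paste(sort(keys2), collapse = ";")
        if (id %in% seen) next
        seen <- c(seen, id)
        nxt[[length(nxt) + 1L]] <- list(keys = keys2, e = e2,
                                        saddle = max(st$saddle, e2))
      }
    }
    if (!length(nxt)) stop("no valid move sequence between the two structures")
    ord <- order(vapply(nxt, `[[`, numeric(1), "saddle"),
                 vapply(nxt, `[[`, numeric(1), "e"))
    beam <- nxt[head(ord, lookahead)]
  }
  target_id <- paste(sort(key_b), collapse = ";")
  final <- Filter(function(st) paste(sort(st$keys), collapse = ";") == target_id,
                  beam)
  stopifnot(length(final) > 0)
  min(vapply(final, `[[`, numeric(1), "saddle")) - e_a
}
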