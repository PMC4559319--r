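# Compatibility-preserving reproduction operators.  All operators take and
# return plain sequences; the GA layer re-evaluates objectives afterwards.
# Failures caused by sequence constraints degrade to no-ops on the affected
# connected component, never to incompatible children.

# --- repair helpers ---------------------------------------------------------

# Transition repair: set position i to new_nt (same purine/pyrimidine class)
# and restore pairability by breadth-first traversal of the component rooted
# at i, visiting neighbours in ascending position order.  max_depth = 1 is
# sufficient for a plain transition; the GC-biased variant (positive design)
# may descend further, upgrading GU pairs to GC on the way.  Returns the
# updated code vector or NULL on failure (caller leaves things unchanged).
.transition_repair <- function(g, codes, i, new_nt, allowed,
                               gc_bias = FALSE, max_depth = 1L) {
  if (!allowed[new_nt, i]) return(NULL)
  if (.PURINE[new_nt] != .PURINE[codes[i]]) return(NULL)  # transitions only
  codes[i] <- new_nt
  visited <- rep(FALSE, g$n)
  visited[i] <- TRUE
  queue <- list()
  push <- function(q, v, d) c(q, list(c(v, d)))
  for (nb in g$adj[[i]]) {
    need <- !.PAIR_CODE[new_nt, codes[nb]]
    want_gc <- gc_bias && !need && !(codes[nb] %in% c(2L, 3L))
    if (need || want_gc) queue <- push(queue, nb, 1L)
  }
  while (length(queue)) {
    v <- queue[[1]][1]; d <- queue[[1]][2]
    queue <- queue[-1]
    if (visited[v]) next
    visited[v] <- TRUE
    purine <- .PURINE[codes[v]]
    cand <- .type_candidates(purine, gc_first = gc_bias)
    if (!gc_bias) cand <- unique(c(codes[v], cand))   # prefer no change
    cand <- cand[allowed[cand, v]]
    chosen <- NA_integer_
    defer <- NULL
    for (x in cand) {
      ok <- TRUE
      need_enqueue <- integer(0)
      for (m in g$adj[[v]]) {
        if (visited[m]) {
          if (!.PAIR_CODE[x, codes[m]]) { ok <- FALSE; break }
        } else if (!.PAIR_CODE[x, codes[m]]) {
          if (d < max_depth) need_enqueue <- c(need_enqueue, m)
          else { ok <- FALSE; break }
        } else if (gc_bias && d < max_depth && x != codes[v] &&
                   !(codes[m] %in% c(2L, 3L)) &&
                   ((x == 3L && codes[m] == 4L) || (x == 4L && codes[m] == 3L))) {
          need_enqueue <- c(need_enqueue, m)   # GU pair upgradeable to GC
        }
      }
      if (ok) { chosen <- x; defer <- need_enqueue; break }
    }
    if (is.na(chosen)) return(NULL)
    changed <- chosen != codes[v]
    codes[v] <- chosen
    if (changed) for (m in sort(defer)) queue <- push(queue, m, d + 1L)
  }
  codes
}

# Force a specific nucleotide at one position, repairing its component:
# same-class change -> transition repair (depth 1); class change ->
# transversion, i.e. full reassignment of the component rooted there.
.force_nt <- function(g, codes, i, new_nt, allowed) {
  if (!allowed[new_nt, i]) return(NULL)
  if (.PURINE[new_nt] == .PURINE[codes[i]]) {
    if (new_nt == codes[i]) return(codes)
    return(.transition_repair(g, codes, i, new_nt, allowed))
  }
  vs <- g$components[[g$comp[i]]]
  a <- .assign_with_root(g, vs, allowed, root = i, root_pool = new_nt)
  if (is.null(a)) return(NULL)
  codes[as.integer(names(a))] <- a
  codes
}

# assign_component wrapper usable with non-'start and end' roots: the
# algorithm must root at a 'start and end' vertex, so when the mutated
# position is an interior (degree-2) vertex the requested nucleotide is
# pinned through the constraint matrix and the component is re-rooted at a
# random 'start and end' vertex instead.
.assign_with_root <- function(g, vs, allowed, root, root_pool) {
  if (length(vs) == 1L) {
    if (!allowed[root_pool[1], root]) return(NULL)
    return(setNames(root_pool[1], root))
  }
  deg <- g$degree[vs]
  stend <- vs[deg != 2L]
  if (!length(stend)) stend <- vs[1]
  pinned <- allowed
  pinned[, root] <- FALSE
  pinned[root_pool, root] <- allowed[root_pool, root]
  if (!any(pinned[, root])) return(NULL)
  if (root %in% stend)
    return(assign_component(g, vs, pinned, root = root, root_pool = root_pool))
  assign_component(g, vs, pinned,
                   root = stend[sample.int(length(stend), 1L)])
}

# --- operators --------------------------------------------------------------

#' Point mutation preserving multi-target compatibility
#'
#' Scans the sequence 5' to 3'; each position mutates independently with
#' probability \code{p_M}.  Loop positions (dependency-graph degree 0)
#' change to a different allowed nucleotide uniformly.  Paired positions
#' apply a transversion or a transition with probability 0.5 each: a
#' transversion flips the purine/pyrimidine class of the whole connected
#' component (reassigned by the nucleotide assignment algorithm rooted at
#' the mutated position); a transition swaps within the class (A<->G,
#' C<->U) and repairs neighbours to depth 1.  When a sequence constraint
#' blocks the repair, the component is left unchanged.
#'
#' @param seq RNA sequence compatible with the targets.
#' @param g [build_graph()] of the targets.
#' @param constraint 4 x N matrix, IUPAC string, or \code{NULL}.
#' @param p_M per-position mutation probability (default 0.05).
#' @return Mutated sequence, still compatible and constraint-satisfying.
#' @export
point_mutation <- function(seq, g, constraint = NULL, p_M = 0.05) {
  allowed <- if (is.matrix(constraint)) constraint else
    sequence_constraint(constraint, n = g$n)
  codes <- seq_to_codes(seq)
  for (i in seq_len(g$n)) {
    if (runif(1) > p_M) next
    if (g$degree[i] == 0L) {
      opts <- setdiff(which(allowed[, i]), codes[i])
      if (length(opts))
        codes[i] <- if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
    } else if (runif(1) < 0.5) {            # transition
      other <- .type_candidates(.PURINE[codes[i]], gc_first = FALSE)
      other <- setdiff(other, codes[i])
      res <- .transition_repair(g, codes, i, other, allowed)
      if (!is.null(res)) codes <- res
    } else {                                # transversion
      pool <- .type_candidates(!.PURINE[codes[i]], gc_first = FALSE)
      pool <- pool[allowed[pool, i]]
      if (length(pool)) {
        if (length(pool) > 1L) pool <- pool[sample.int(length(pool))]
        vs <- g$components[[g$comp[i]]]
        a <- .assign_with_root(g, vs, allowed, root = i, root_pool = pool)
        if (!is.null(a)) codes[as.integer(names(a))] <- a
      }
    }
  }
  codes_to_seq(codes)
}

#' Negative design operator: disrupt undesired predicted base pairs
#'
#' Scans the selected predicted structure 5' to 3' for base pairs that occur
#' in no target structure and mutates their nucleotides so the two positions
#' can no longer pair, repairing components as needed.  Pairs whose
#' endpoints lie in the same connected component are skipped (disrupting
#' them would break a desired pair elsewhere); when both endpoints are
#' isolated vertices both may change, when one is isolated the isolated one
#' is changed, otherwise one endpoint is changed (upstream tried first).
#'
#' @param seq RNA sequence.
#' @param targets [target_set()].
#' @param predicted predicted structure of the method with the lowest
#'   structure similarity score (chosen by the GA layer).
#' @param g [build_graph()] of \code{targets}.
#' @param constraint constraint matrix/string or \code{NULL}.
#' @return Sequence with undesired pairs disrupted where possible.
#' @export
negative_design <- function(seq, targets, predicted, g = build_graph(targets),
                            constraint = NULL) {
  allowed <- if (is.matrix(constraint)) constraint else
    sequence_constraint(constraint, n = g$n)
  codes <- seq_to_codes(seq)
  tkeys <- unlist(lapply(targets, function(t)
    if (nrow(t$pairs)) paste(t$pairs[, 1], t$pairs[, 2]) else character(0)))
  p <- predicted$pairs
  if (!nrow(p)) return(seq)
  for (r in order(p[, 1])) {
    i <- p[r, 1]; j <- p[r, 2]
    if (paste(i, j) %in% tkeys) next                 # desired pair
    if (!.PAIR_CODE[codes[i], codes[j]]) next        # already disrupted
    ci <- g$comp[i]; cj <- g$comp[j]
    if (ci == cj) next                               # same component: skip
    size_i <- length(g$components[[ci]])
    size_j <- length(g$components[[cj]])
    disrupt_single <- function(codes, v, other_nt) {
      opts <- setdiff(which(allowed[, v] & !.PAIR_CODE[, other_nt]), codes[v])
      if (!length(opts)) return(NULL)
      codes[v] <- if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
      codes
    }
    if (size_i == 1L && size_j == 1L) {
      res <- disrupt_single(codes, i, codes[j])
      if (is.null(res)) res <- disrupt_single(codes, j, codes[i])
      if (is.null(res)) {                            # change both jointly
        for (a in which(allowed[, i])) {
          bs <- which(allowed[, j] & !.PAIR_CODE[a, ])
          if (length(bs)) {
            codes[i] <- a
            codes[j] <- bs[sample.int(length(bs), 1L)]
            res <- codes
            break
          }
        }
      }
      if (!is.null(res)) codes <- res
    } else if (size_i == 1L || size_j == 1L) {
      v <- if (size_i == 1L) i else j
      o <- if (size_i == 1L) j else i
      res <- disrupt_single(codes, v, codes[o])
      if (!is.null(res)) codes <- res
    } else {
      done <- FALSE
      for (v in c(i, j)) {
        o <- if (v == i) j else i
        cand <- which(allowed[, v] & !.PAIR_CODE[, codes[o]])
        cand <- setdiff(cand, codes[v])
        same <- cand[.PURINE[cand] == .PURINE[codes[v]]]   # transitions first
        for (x in c(same, setdiff(cand, same))) {
          res <- .force_nt(g, codes, v, x, allowed)
          if (!is.null(res) && !.PAIR_CODE[res[i], res[j]]) {
            codes <- res; done <- TRUE; break
          }
        }
        if (done) break
      }
    }
  }
  codes_to_seq(codes)
}

#' Positive design operator: stabilize missing target base pairs
#'
#' Scans the selected target structure 5' to 3' for base pairs missing from
#' the selected predicted structure and assigns a G or C (according to the
#' purine/pyrimidine class of the position) to the upstream position of each
#' missing pair, repairing the component with a GC-biased transition limited
#' to a maximum spanning-tree depth.
#'
#' @param seq RNA sequence.
#' @param target the bound target structure of the lowest-similarity method.
#' @param predicted that method's predicted structure.
#' @param g [build_graph()] of the design's targets.
#' @param constraint constraint matrix/string or \code{NULL}.
#' @param max_depth repair depth limit (default 3).
#' @return Sequence with missing target pairs GC-stabilized where possible.
#' @export
positive_design <- function(seq, target, predicted, g,
                            constraint = NULL, max_depth = 3L) {
  allowed <- if (is.matrix(constraint)) constraint else
    sequence_constraint(constraint, n = g$n)
  codes <- seq_to_codes(seq)
  pkeys <- if (nrow(predicted$pairs))
    paste(predicted$pairs[, 1], predicted$pairs[, 2]) else character(0)
  tp <- target$pairs
  if (!nrow(tp)) return(seq)
  for (r in order(tp[, 1])) {
    i <- tp[r, 1]; j <- tp[r, 2]
    if (paste(i, j) %in% pkeys) next                 # already predicted
    want <- if (.PURINE[codes[i]]) 3L else 2L        # G or C by class
    if (codes[i] == want) next
    res <- .transition_repair(g, codes, i, want, allowed,
                              gc_bias = TRUE, max_depth = max_depth)
    if (!is.null(res)) codes <- res
  }
  codes_to_seq(codes)
}

#' One-point crossover preserving multi-target compatibility
#'
#' Splits both parents at a uniformly drawn crossover point p (1 <= p <=
#' N-1) and splices the 5' half of parent L with the 3' half of parent R.
#' Any connected component with positions on both sides of the cut is
#' copied entirely from parent L, so the child stays compatible.
#'
#' @param seq_l,seq_r parent sequences (both compatible with the targets).
#' @param g [build_graph()] of the targets.
#' @return Child sequence.
#' @export
crossover <- function(seq_l, seq_r, g) {
  cl <- seq_to_codes(seq_l); cr <- seq_to_codes(seq_r)
  stopifnot(length(cl) == g$n, length(cr) == g$n)
  p <- sample.int(g$n - 1L, 1L)
  child <- c(cl[seq_len(p)], cr[(p + 1L):g$n])
  for (vs in g$components) {
    if (any(vs <= p) && any(vs > p)) child[vs] <- cl[vs]
  }
  codes_to_seq(child)
}

#' Mutate undesired sequence motifs and nucleotide tracts
#'
#' Scans for mononucleotide runs of at least \code{tract_len} and for
#' occurrences of user-prescribed IUPAC motifs; each detected region
#' triggers one compatibility-preserving point mutation at a random
#' position inside the region (loop positions change freely, paired
#' positions via transition/transversion with component repair).  Regions
#' blocked by the sequence constraint are left unchanged.
#'
#' @param seq RNA sequence.
#' @param g [build_graph()] of the targets.
#' @param constraint constraint matrix/string or \code{NULL}.
#' @param motifs character vector of IUPAC motifs to avoid.
#' @param tract_len minimum run length to scrub, or \code{NULL} to disable
#'   the tract check (default).
#' @return Scrubbed sequence.
#' @export
scrub_motifs <- function(seq, g, constraint = NULL,
                         motifs = character(0), tract_len = NULL) {
  if (!length(motifs) && is.null(tract_len)) return(seq)
  allowed <- if (is.matrix(constraint)) constraint else
    sequence_constraint(constraint, n = g$n)
  regions <- list()
  if (!is.null(tract_len)) {
    rl <- rle(strsplit(seq, "")[[1]])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$lengths >= tract_len))
      regions[[length(regions) + 1L]] <- starts[k]:ends[k]
  }
  for (mo in motifs) {
    pat <- paste(vapply(strsplit(toupper(mo), "")[[1]], function(c)
      paste0("[", paste(.IUPAC[[c]], collapse = ""), "]"), character(1)),
      collapse = "")
    mt <- gregexpr(pat, seq)[[1]]
    if (mt[1] == -1) next
    for (k in seq_along(mt))
      regions[[length(regions) + 1L]] <-
        mt[k]:(mt[k] + attr(mt, "match.length")[k] - 1L)
  }
  codes <- seq_to_codes(seq)
  for (reg in regions) {
    i <- if (length(reg) == 1L) reg else reg[sample.int(length(reg), 1L)]
    if (g$degree[i] == 0L) {
      opts <- setdiff(which(allowed[, i]), codes[i])
      if (length(opts))
        codes[i] <- if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
    } else if (runif(1) < 0.5) {
      other <- setdiff(.type_candidates(.PURINE[codes[i]], FALSE), codes[i])
      res <- .transition_repair(g, codes, i, other, allowed)
      if (!is.null(res)) codes <- res
    } else {
      pool <- .type_candidates(!.PURINE[codes[i]], FALSE)
      pool <- pool[allowed[pool, i]]
      if (length(pool)) {
        if (length(pool) > 1L) pool <- pool[sample.int(length(pool))]
        vs <- g$components[[g$comp[i]]]
        a <- .assign_with_root(g, vs, allowed, root = i, root_pool = pool)
        if (!is.null(a)) codes[as.integer(names(a))] <- a
      }
    }
  }
  codes_to_seq(codes)
}
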