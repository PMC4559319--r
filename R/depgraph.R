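#' Dependency graph of a multi-target design problem
#'
#' Vertices are sequence positions; edges are the union of the base pairs of
#' all target structures.  A compatible sequence exists if and only if every
#' connected component is bipartite (2-colorable), because every legal RNA
#' base pair (AU, GC, GU) joins a purine with a pyrimidine.  Construction
#' therefore fails with an "incompatible targets" error when the pair union
#' contains an odd cycle.
#'
#' @param targets a [target_set()] (or anything [target_set()] accepts).
#' @return An object of class \code{"dependency_graph"}: list with \code{n},
#'   \code{edges} (unique two-column matrix), \code{adj} (adjacency list),
#'   \code{comp} (component id per vertex), \code{side} (bipartition label 1/2
#'   per vertex), \code{components} (list of vertex vectors) and \code{degree}.
#' @export
build_graph <- function(targets) {
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  n <- attr(targets, "n")
  edges <- do.call(rbind, lapply(targets, `[[`, "pairs"))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  if (nrow(edges)) {
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
  comp <- integer(n); side <- integer(n)
  nc <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    nc <- nc + 1L
    comp[v] <- nc; side[v] <- 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- nc; side[w] <- 3L - side[u]
          queue <- c(queue, w)
        } else if (side[w] == side[u]) {
          stop("incompatible targets: the union of target base pairs contains ",
               "an odd cycle through position ", w, ", so the dependency graph ",
               "is not bipartite and no compatible sequence exists ",
               "(generalized intersection theorem)")
        }
      }
    }
  }
  structure(list(n = n, edges = edges, adj = adj, comp = comp, side = side,
                 components = split(seq_len(n), comp),
                 degree = lengths(adj)),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  sizes <- lengths(x$components)
  cat("Dependency graph:", x$n, "positions,", nrow(x$edges), "edges,",
      length(x$components), "components\n")
  cat("  component sizes:", paste(sort(sizes, decreasing = TRUE)[1:min(10, length(sizes))],
                                  collapse = " "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Decompose a connected component into paths
#'
#' Every component with more than one vertex decomposes into paths whose
#' endpoints ('start and end' vertices) have degree != 2; interior vertices
#' have degree 2 and belong to exactly one path.  A pure cycle has no vertex
#' of degree != 2, so one vertex is designated 'start and end' and the cycle
#' becomes a single path whose first and last vertex coincide.
#'
#' @param g a [build_graph()] result.
#' @param vertices the vertex set of one connected component (length > 1).
#' @return List with \code{paths} (list of ordered vertex vectors),
#'   \code{stend} (the 'start and end' vertices) and \code{is_cycle}.
#' @export
decompose <- function(g, vertices) {
  stopifnot(length(vertices) > 1)
  deg <- g$degree[vertices]
  stend <- vertices[deg != 2L]
  is_cycle <- length(stend) == 0L
  if (is_cycle) stend <- vertices[1]          # arbitrary 'start and end'
  paths <- list()
  used <- new.env(parent = emptyenv())        # edge keys already on a path
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  for (s in stend) {
    for (nb in g$adj[[s]]) {
      if (!is.null(used[[ekey(s, nb)]])) next
      path <- c(s, nb)
      used[[ekey(s, nb)]] <- TRUE
      prev <- s; cur <- nb
      while (!(cur %in% stend)) {
        nxt <- setdiff(g$adj[[cur]], prev)
        stopifnot(length(nxt) == 1L)          # interior vertices have degree 2
        used[[ekey(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  list(paths = paths, stend = stend, is_cycle = is_cycle)
}

#' Compatible-assignment counting tables (chi)
#'
#' For one path of the decomposition, \code{chi[k, x, s]} counts the
#' assignments of nucleotides to path positions \code{1..k} such that every
#' adjacent pair along the path is a legal base pair (AU, GC or GU), position
#' \code{k} carries nucleotide \code{x}, and the start vertex carries
#' \code{s}.  The recursion is
#' \preformatted{
#'   chi(k, A, s) = chi(k-1, U, s)
#'   chi(k, C, s) = chi(k-1, G, s)
#'   chi(k, G, s) = chi(k-1, C, s) + chi(k-1, U, s)
#'   chi(k, U, s) = chi(k-1, A, s) + chi(k-1, G, s)
#' }
#' with base case \code{chi(1, s, s) = 1} when \code{s} is allowed at the
#' start vertex.  A nucleotide disallowed by the sequence constraint at the
#' k-th vertex forces \code{chi(k, x, s) = 0}.  An all-zero table is a legal
#' result and signals infeasibility.
#'
#' @param path ordered vertex vector (as in [decompose()]).
#' @param allowed 4 x N logical constraint matrix ([sequence_constraint()]).
#' @return An \code{L x 4 x 4} integer array, dimensions (position along the
#'   path, nucleotide at that position, start nucleotide), nucleotides ordered
#'   A, C, G, U.
#' @export
chi_tables <- function(path, allowed) {
  L <- length(path)
  chi <- array(0, dim = c(L, 4, 4),
               dimnames = list(NULL, .NT, .NT))
  for (s in 1:4) if (allowed[s, path[1]]) chi[1, s, s] <- 1
  if (L > 1) for (k in 2:L) {
    for (s in 1:4) {
      chi[k, 1, s] <- chi[k - 1, 4, s]                      # A <- U
      chi[k, 2, s] <- chi[k - 1, 3, s]                      # C <- G
      chi[k, 3, s] <- chi[k - 1, 2, s] + chi[k - 1, 4, s]   # G <- C + U
      chi[k, 4, s] <- chi[k - 1, 1, s] + chi[k - 1, 3, s]   # U <- A + G
    }
    chi[k, !allowed[, path[k]], ] <- 0
  }
  chi
}

#' Endpoint-compatibility indicator (lambda)
#'
#' \code{lambda_indicator(tables, t, u)} is 1 when, for \emph{every} path
#' between two 'start and end' vertices i and j, at least one assignment
#' exists with nucleotide \code{t} at i and \code{u} at j, i.e.
#' \code{chi(L_m, u, t) > 0} for each path m oriented from i to j; otherwise 0.
#'
#' @param tables list of chi arrays, one per path between i and j, each
#'   oriented from i to j.
#' @param t,u nucleotides ("A","C","G","U" or codes 1..4) at i and j.
#' @return 0 or 1.
#' @export
lambda_indicator <- function(tables, t, u) {
  if (is.character(t)) t <- match(t, .NT)
  if (is.character(u)) u <- match(u, .NT)
  for (chi in tables) {
    L <- dim(chi)[1]
    if (chi[L, u, t] <= 0) return(0L)
  }
  1L
}

# Internal: precompute per-path chi tables for a component decomposition,
# oriented as stored, plus the reverse orientation (for lambda lookups from
# either endpoint).
.component_tables <- function(decomp, allowed) {
  lapply(decomp$paths, function(p) {
    list(path = p,
         fwd = chi_tables(p, allowed),
         rev = chi_tables(rev(p), allowed))
  })
}

# Internal: order the two same-type nucleotide candidates for a vertex.
# type: TRUE = purine {A,G}, FALSE = pyrimidine {C,U}; gc_first: priority to
# the G/C member of the class, else to the A/U member.
.type_candidates <- function(purine, gc_first) {
  cand <- if (purine) c(1L, 3L) else c(4L, 2L)   # AU-class member first
  if (gc_first) rev(cand) else cand
}

#' Assign compatible nucleotides to one connected component
#'
#' Implements the nucleotide assignment algorithm: decompose the component
#' into paths, compute the chi tables, assign a nucleotide to a root 'start
#' and end' vertex, traverse the remaining 'start and end' vertices in
#' depth-first order over the spanning tree checking lambda and backtracking
#' when no compatible assignment exists, then fill path interiors from the
#' end vertex back to the start vertex choosing nucleotides with positive chi
#' counts.  Assignment is biased: if the root receives G or C, G/C get
#' priority at every subsequent choice, otherwise A/U do, so GU pairs only
#' appear when the sequence constraint forces them.
#'
#' @param g a [build_graph()] result.
#' @param vertices vertex set of one component.
#' @param allowed 4 x N logical constraint matrix.
#' @param root root vertex \code{v_arb}; default: sampled uniformly from the
#'   'start and end' vertices.
#' @param root_pool candidate nucleotide codes for the root (default: all
#'   allowed); point-mutation transversion restricts this to the opposite
#'   purine/pyrimidine class of the current nucleotide.
#' @return Named integer vector of nucleotide codes (names = positions), or
#'   \code{NULL} when no compatible assignment exists (exhausted backtracking).
#' @export
assign_component <- function(g, vertices, allowed, root = NULL, root_pool = NULL) {
  if (length(vertices) == 1L) {
    opts <- which(allowed[, vertices])
    if (!length(opts)) return(NULL)
    nt <- if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
    return(setNames(nt, vertices))
  }
  decomp <- decompose(g, vertices)
  tabs <- .component_tables(decomp, allowed)
  stend <- decomp$stend
  if (is.null(root)) {
    root <- if (length(stend) == 1L) stend else stend[sample.int(length(stend), 1L)]
  }
  stopifnot(root %in% stend)

  # Per-path endpoint-feasibility tables: feas[[m]][u, t] is TRUE when the
  # path admits an assignment with t at its stored start and u at its end
  # (this is the lambda indicator in matrix form).
  n_paths <- length(decomp$paths)
  path_ends <- lapply(decomp$paths, function(p) c(p[1], p[length(p)]))
  feas <- lapply(seq_len(n_paths), function(m) {
    L <- length(decomp$paths[[m]])
    tabs[[m]]$fwd[L, , ] > 0      # [end nt, start nt]
  })
  if (any(!vapply(feas, any, logical(1)))) return(NULL)  # dead path

  # Spanning-tree DFS order over 'start and end' vertices; incident[[v]]
  # lists (path index, other endpoint) for lambda checks.
  pos <- match(seq_len(g$n), stend)     # vertex -> stend index (NA otherwise)
  incident <- vector("list", length(stend))
  for (m in seq_len(n_paths)) {
    e <- path_ends[[m]]
    incident[[pos[e[1]]]] <- c(incident[[pos[e[1]]]], list(c(m, e[2])))
    if (e[2] != e[1])
      incident[[pos[e[2]]]] <- c(incident[[pos[e[2]]]], list(c(m, e[1])))
  }
  order_dfs <- integer(0)
  seen <- rep(FALSE, length(stend))
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[pos[v]]) next
    seen[pos[v]] <- TRUE
    order_dfs <- c(order_dfs, v)
    for (inc in incident[[pos[v]]]) {
      if (!seen[pos[inc[2]]]) stack <- c(stack, inc[2])
    }
  }
  stopifnot(length(order_dfs) == length(stend))

  nt <- rep(NA_integer_, g$n)

  # feasibility of nucleotide x at v with respect to one incident path:
  # checked against the other endpoint when assigned; otherwise the check
  # is that some allowed nucleotide remains for the other endpoint
  # (forward checking, which prevents exponential backtracking on
  # constrained components)
  path_ok <- function(inc, v, x) {
    m <- inc[1]; other <- inc[2]
    fm <- feas[[m]]
    oriented_from_v <- path_ends[[m]][1] == v
    if (other == v) return(fm[x, x])          # pure cycle
    u <- nt[other]
    if (!is.na(u))
      return(if (oriented_from_v) fm[u, x] else fm[x, u])
    cand_u <- which(allowed[, other])
    if (oriented_from_v) any(fm[cand_u, x]) else any(fm[x, cand_u])
  }
  lam_ok <- function(v, x) {
    for (inc in incident[[pos[v]]]) if (!path_ok(inc, v, x)) return(FALSE)
    TRUE
  }

  # root candidates, in randomized order (priority class is set by whichever
  # nucleotide the root finally receives)
  rp <- root_pool
  if (is.null(rp)) rp <- 1:4
  rp <- rp[allowed[rp, root]]
  if (!length(rp)) return(NULL)
  rp <- if (length(rp) > 1) rp[sample.int(length(rp))] else rp

  k_total <- length(order_dfs)
  assign_rest <- function(idx, gc_first) {
    if (idx > k_total) return(TRUE)
    v <- order_dfs[idx]
    root_purine <- .PURINE[nt[root]]
    v_purine <- if (g$side[v] == g$side[root]) root_purine else !root_purine
    cand <- .type_candidates(v_purine, gc_first)
    cand <- cand[allowed[cand, v]]
    # constraint may force a nucleotide of the "wrong" class relative to the
    # bipartition typing only via GU pairs; those candidates are tried last
    extra <- setdiff(which(allowed[, v]), .type_candidates(v_purine, gc_first))
    for (x in c(cand, extra)) {
      if (!lam_ok(v, x)) next
      nt[v] <<- x
      if (assign_rest(idx + 1L, gc_first)) return(TRUE)
      nt[v] <<- NA_integer_
    }
    FALSE
  }

  done <- FALSE
  for (r_nt in rp) {
    if (!lam_ok(root, r_nt)) next
    nt[root] <- r_nt
    gc_first <- r_nt %in% c(2L, 3L)
    if (assign_rest(2L, gc_first)) { done <- TRUE; break }
    nt[root] <- NA_integer_
  }
  if (!done) return(NULL)

  gc_first <- nt[root] %in% c(2L, 3L)
  # fill interior vertices of each path from end back to start
  for (m in seq_along(decomp$paths)) {
    p <- decomp$paths[[m]]
    L <- length(p)
    if (L <= 2L) next
    s <- nt[p[1]]
    chi <- tabs[[m]]$fwd
    for (k in seq(L - 1L, 2L)) {
      succ <- nt[p[k + 1L]]
      cand <- which(.PAIR_CODE[, succ] & chi[k, , s] > 0)
      stopifnot(length(cand) > 0)             # guaranteed by lambda
      if (length(cand) > 1L) {
        non_gu <- cand[!((cand == 3L & succ == 4L) | (cand == 4L & succ == 3L))]
        pool <- if (length(non_gu)) non_gu else cand
        pref <- if (gc_first) pool[pool %in% c(2L, 3L)] else pool[pool %in% c(1L, 4L)]
        cand <- if (length(pref)) pref[1] else pool[1]
      }
      nt[p[k]] <- cand
    }
  }
  out <- nt[vertices]
  stopifnot(!anyNA(out))
  setNames(as.integer(out), vertices)
}

#' Sample a sequence compatible with all targets
#'
#' Generates a random RNA sequence that can form every base pair of every
#' target and satisfies the IUPAC constraint: isolated positions are drawn
#' uniformly from their allowed nucleotides; every non-trivial component is
#' assigned by [assign_component()] with a uniformly chosen root whose
#' nucleotide is drawn from all allowed codes.
#'
#' @param targets a [target_set()] or a prebuilt [build_graph()].
#' @param constraint IUPAC string, 4 x N matrix, or \code{NULL}.
#' @return RNA sequence string.
#' @export
sample_sequence <- function(targets, constraint = NULL) {
  g <- if (inherits(targets, "dependency_graph")) targets else build_graph(targets)
  allowed <- if (is.matrix(constraint)) constraint else
    sequence_constraint(constraint, n = g$n)
  if (ncol(allowed) != g$n) stop("constraint length does not match targets")
  codes <- integer(g$n)
  for (vs in g$components) {
    a <- assign_component(g, vs, allowed)
    if (is.null(a))
      stop("sequence constraint infeasible on the component containing position ",
           vs[1])
    codes[as.integer(names(a))] <- a
  }
  codes_to_seq(codes)
}
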