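# Independent brute-force oracles used across the test suite.  These
# deliberately re-derive results by enumeration, not by calling the
# package's DP/graph code paths.

NTS <- c("A", "C", "G", "U")

pairable_chr <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# all 4^L nucleotide vectors of length L
enum_seqs <- function(L) {
  if (L == 0) return(matrix(character(0), nrow = 1))
  as.matrix(do.call(expand.grid,
                    c(rep(list(NTS), L), stringsAsFactors = FALSE)))
}

# brute-force chi: number of length-L sequences along a path with every
# adjacent pair pairable, nucleotide x at position k, s at position 1,
# restricted by an allowed matrix (4 x L, rows A,C,G,U)
brute_chi_total <- function(L, allowed, k, x, s) {
  seqs <- enum_seqs(L)
  ok <- rep(TRUE, nrow(seqs))
  for (p in seq_len(L))
    ok <- ok & allowed[match(seqs[, p], NTS), p]
  if (L > 1) for (p in seq_len(L - 1))
    ok <- ok & pairable_chr(seqs[, p], seqs[, p + 1])
  sum(ok & seqs[, k] == x & seqs[, 1] == s)
}

# independent 2-coloring by depth-first search over an edge list
brute_two_colorable <- function(n, edges) {
  col <- rep(NA_integer_, n)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(NROW(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (start in seq_len(n)) {
    if (!is.na(col[start])) next
    col[start] <- 0L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (is.na(col[w])) { col[w] <- 1L - col[v]; stack <- c(stack, w) }
        else if (col[w] == col[v]) return(FALSE)
      }
    }
  }
  TRUE
}

# brute-force dominance front: indices of rows not dominated by any other
brute_front <- function(obj, strong = FALSE) {
  n <- nrow(obj)
  dominated <- vapply(seq_len(n), function(j) {
    any(vapply(seq_len(n), function(i) {
      if (i == j) return(FALSE)
      if (strong) all(obj[i, ] < obj[j, ])
      else all(obj[i, ] <= obj[j, ]) && any(obj[i, ] != obj[j, ])
    }, logical(1)))
  }, logical(1))
  which(!dominated)
}

# enumerate every nested structure (list of pair matrices) of a sequence
# under the toy rules: pairable letters, hairpin loop >= 3
brute_structures <- function(seq_chr) {
  n <- length(seq_chr)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)                         # i unpaired
    for (k in (i + 1):j) {
      if (k - i - 1 < 3) next
      if (!pairable_chr(seq_chr[i], seq_chr[k])) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(a, c(i, k), b)
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

toy_pair_score_chr <- function(a, b) {
  key <- paste0(a, b)
  sc <- c(AU = -2, UA = -2, GC = -3, CG = -3, GU = -1, UG = -1)[key]
  sc[is.na(sc)] <- 0
  unname(sc)
}

brute_structure_energy <- function(seq_chr, pairs) {
  if (NROW(pairs) == 0) return(0)
  sum(toy_pair_score_chr(seq_chr[pairs[, 1]], seq_chr[pairs[, 2]]))
}

# random nested structure of length n (from the toy MFE of a random
# sequence; retried until it has at least min_pairs pairs)
random_target <- function(n, min_pairs = 1) {
  repeat {
    seq <- paste(sample(NTS, n, replace = TRUE), collapse = "")
    st <- toy_mfe(seq)$structure
    if (nrow(st$pairs) >= min_pairs) return(st)
  }
}

# random feasible multi-target instance: 2-4 random nested targets whose
# pair union is bipartite
random_instance <- function(n, n_targets = 2, min_pairs = 1) {
  repeat {
    ts <- tryCatch(
      target_set(lapply(seq_len(n_targets), function(k)
        random_target(n, min_pairs))),
      error = function(e) NULL)
    if (is.null(ts)) next
    g <- tryCatch(build_graph(ts), error = function(e) NULL)
    if (!is.null(g)) return(list(targets = ts, graph = g))
  }
}

# enumerate all sequences compatible with a dependency graph (component by
# component), as character vector; only usable for small total spaces
brute_compatible_seqs <- function(g, max_total = 2e6) {
  per_comp <- lapply(g$components, function(vs) {
    combos <- enum_seqs(length(vs))
    keep <- rep(TRUE, nrow(combos))
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1]; j <- g$edges[r, 2]
      if (i %in% vs && j %in% vs) {
        pi <- match(i, vs); pj <- match(j, vs)
        keep <- keep & pairable_chr(combos[, pi], combos[, pj])
      }
    }
    combos[keep, , drop = FALSE]
  })
  total <- prod(vapply(per_comp, nrow, numeric(1)))
  stopifnot(total <= max_total)
  idx <- lapply(per_comp, function(m) seq_len(nrow(m)))
  grid <- do.call(expand.grid, idx)
  vapply(seq_len(nrow(grid)), function(r) {
    s <- character(g$n)
    for (c in seq_along(per_comp))
      s[g$components[[c]]] <- per_comp[[c]][grid[r, c], ]
    paste(s, collapse = "")
  }, character(1))
}
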