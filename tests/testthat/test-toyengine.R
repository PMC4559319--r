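test_that("toy MFE matches hand-checkable cases", {
  r <- toy_mfe("GGGAAACCC")
  expect_equal(to_dotbracket(r$structure), "(((...)))")
  expect_equal(r$energy, -9)
  r2 <- toy_mfe("AAAAAA")
  expect_equal(nrow(r2$structure$pairs), 0)
  expect_equal(r2$energy, 0)
  # constraint forcing everything unpaired: open chain, energy 0
  r3 <- toy_mfe("GGGAAACCC", parse_dotbracket("........."))
  expect_equal(r3$energy, 0)
  expect_equal(nrow(r3$structure$pairs), 0)
})

test_that("toy structure evaluation is additive and validates pairs", {
  expect_equal(toy_eval("AAAAA", "....."), 0)
  expect_equal(toy_eval("GGCAAAGCC", "((.....))"), -6)   # two GC pairs
  expect_equal(toy_eval("AAAAAAU", "(.....)"), -2)       # one AU pair
  expect_equal(toy_eval("GAAAAAU", "(.....)"), -1)       # one GU wobble
  expect_error(toy_eval("AAAAA", "(...)"), "cannot form")
  # consistency with the DP
  set.seed(19)
  for (k in 1:20) {
    s <- paste(sample(NTS, 12, replace = TRUE), collapse = "")
    r <- toy_mfe(s)
    expect_equal(toy_eval(s, r$structure), r$energy)
  }
})

test_that("toy DP equals brute-force enumeration (MFE, Z, constrained MFE)", {
  set.seed(101)
  for (k in 1:60) {
    n <- sample(6:12, 1)
    sv <- sample(NTS, n, replace = TRUE)
    s <- paste(sv, collapse = "")
    structs <- brute_structures(sv)
    energies <- vapply(structs, function(p) brute_structure_energy(sv, p),
                       numeric(1))
    # MFE
    expect_equal(toy_mfe(s)$energy, min(energies))
    # partition function
    expect_equal(toy_ensemble(s), -log(sum(exp(-energies))), tolerance = 1e-9)
    # constrained MFE: force the pairs of a random structure, leave rest free
    base <- structs[[sample(length(structs), 1)]]
    if (NROW(base) > 0) {
      wc <- setdiff(seq_len(n), as.vector(base))
      con <- rna_structure(base, n, wildcard = wc)
      keep <- vapply(structs, function(p) {
        if (NROW(base) == 0) return(TRUE)
        bk <- paste(base[, 1], base[, 2])
        pk <- if (NROW(p)) paste(p[, 1], p[, 2]) else character(0)
        all(bk %in% pk)
      }, logical(1))
      expect_equal(toy_mfe(s, con)$energy, min(energies[keep]))
    }
  }
})

test_that("ensemble free energy lower-bounds every structure energy", {
  set.seed(41)
  for (k in 1:25) {
    s <- paste(sample(NTS, sample(8:14, 1), replace = TRUE), collapse = "")
    g <- toy_ensemble(s)
    expect_lte(g, toy_mfe(s)$energy)
  }
  expect_equal(toy_ensemble("AAAAAA"), 0)   # only the open chain
})

test_that("suboptimal structures are distinct and energy-ordered", {
  set.seed(61)
  for (k in 1:20) {
    s <- paste(sample(NTS, 15, replace = TRUE), collapse = "")
    subs <- toy_subopt(s, k = 3)
    es <- vapply(subs, `[[`, numeric(1), "energy")
    expect_true(all(diff(es) >= 0))
    dbs <- vapply(subs, function(x) to_dotbracket(x$structure), character(1))
    expect_equal(anyDuplicated(dbs), 0L)
    expect_equal(es[1], toy_mfe(s)$energy)
    # energies agree with direct evaluation
    for (sub in subs)
      expect_equal(toy_eval(s, sub$structure), sub$energy)
  }
})

test_that("toy barrier handles trivial and single-move cases exactly", {
  s <- "GGGAAACCC"
  th <- toy_mfe(s)$structure
  expect_equal(toy_barrier(s, th, th), 0)
  # single pair difference: one move, barrier = max(E_int) - E(a)
  a <- parse_dotbracket("(((...)))")
  b <- parse_dotbracket("(((...))).")
  a9 <- parse_dotbracket("(((...)))")
  b9 <- parse_dotbracket(".((...)).")
  expect_equal(toy_barrier(s, a9, b9), toy_eval(s, b9) - toy_eval(s, a9))
  expect_gte(toy_barrier(s, b9, a9), 0)
})

test_that("toy barrier upper-bounds the exact saddle on small instances", {
  set.seed(77)
  for (k in 1:10) {
    n <- sample(9:12, 1)
    sv <- sample(NTS, n, replace = TRUE)
    s <- paste(sv, collapse = "")
    subs <- toy_subopt(s, k = 2)
    if (length(subs) < 2) next
    a <- subs[[1]]$structure; b <- subs[[2]]$structure
    # exact saddle by exhaustive search over the full move graph: states =
    # all structures, moves = single pair add/remove
    structs <- brute_structures(sv)
    keys <- vapply(structs, function(p)
      paste(sort(if (NROW(p)) paste(p[, 1], p[, 2]) else character(0)),
            collapse = ";"), character(1))
    energies <- vapply(structs, function(p) brute_structure_energy(sv, p),
                       numeric(1))
    adj_idx <- function(i) {
      ki <- strsplit(keys[i], ";")[[1]]
      which(vapply(seq_along(keys), function(j) {
        kj <- strsplit(keys[j], ";")[[1]]
        length(setdiff(ki, kj)) + length(setdiff(kj, ki)) == 1
      }, logical(1)))
    }
    ia <- match(paste(sort(paste(a$pairs[, 1], a$pairs[, 2])), collapse = ";"), keys)
    ib <- match(paste(sort(if (NROW(b$pairs)) paste(b$pairs[, 1], b$pairs[, 2])
                           else character(0)), collapse = ";"), keys)
    # binary-search the minimal saddle: connectivity under energy ceiling
    cands <- sort(unique(energies))
    exact <- NA_real_
    for (ceil in cands) {
      ok <- energies <= ceil
      if (!ok[ia] || !ok[ib]) next
      # BFS in the thresholded move graph
      seen <- logical(length(keys)); seen[ia] <- TRUE; q <- ia
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in adj_idx(v)) if (ok[w] && !seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
      }
      if (seen[ib]) { exact <- ceil - energies[ia]; break }
    }
    bar <- toy_barrier(s, a, b, lookahead = 5)
    expect_gte(bar + 1e-9, exact)
  }
})

test_that("incompatible folding constraints raise errors", {
  expect_error(toy_mfe("AAAA", rna_structure(rbind(c(1, 4)), 4)),
               "incompatible")
  expect_error(toy_ensemble("AAAA", rna_structure(rbind(c(1, 4)), 4)),
               "incompatible")
})
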