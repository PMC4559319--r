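test_that("the dependency graph is the union of target pairs", {
  g <- build_graph(target_set("(...)", ".(.)."))
  expect_equal(g$edges, rbind(c(1L, 5L), c(2L, 4L)), ignore_attr = TRUE)
  expect_equal(unname(lengths(g$components)), c(2L, 2L, 1L))
  g2 <- build_graph(target_set("....."))
  expect_equal(length(g2$components), 5L)
  expect_true(all(g2$degree == 0))
})

test_that("non-bipartite pair unions are rejected as incompatible targets", {
  expect_error(build_graph(target_set("().", ".()", "(.)")),
               "incompatible targets")
})

test_that("bipartiteness acceptance matches an independent 2-coloring", {
  set.seed(21)
  for (k in 1:60) {
    n <- sample(6:14, 1)
    n_m <- sample(2:4, 1)
    sts <- lapply(seq_len(n_m), function(m) {
      npair <- sample(1:floor(n / 2), 1)
      pos <- sample(n, 2 * npair)
      rna_structure(matrix(pos, ncol = 2), n)
    })
    ts <- target_set(sts)
    edges <- unique(do.call(rbind, lapply(sts, `[[`, "pairs")))
    ok_oracle <- brute_two_colorable(n, edges)
    got <- tryCatch({ build_graph(ts); TRUE }, error = function(e) FALSE)
    expect_identical(got, ok_oracle)
  }
})

test_that("components decompose into paths with degree != 2 endpoints", {
  # single edge
  g <- build_graph(target_set("(...)"))
  d <- decompose(g, c(1L, 5L))
  expect_equal(d$paths, list(c(1L, 5L)))
  expect_setequal(d$stend, c(1L, 5L))
  # chain i-k-j from two targets
  g2 <- build_graph(target_set("(.)..", "..(.)"))
  d2 <- decompose(g2, c(1L, 3L, 5L))
  expect_length(d2$paths, 1)
  expect_setequal(d2$stend, c(1L, 5L))
  expect_equal(sort(d2$paths[[1]]), c(1L, 3L, 5L))
  # 4-cycle: one path of length 5 whose ends coincide
  ts4 <- target_set(rna_structure(rbind(c(1, 2), c(3, 4)), 4),
                    rna_structure(rbind(c(2, 3), c(1, 4)), 4))
  g4 <- build_graph(ts4)
  d4 <- decompose(g4, 1:4)
  expect_true(d4$is_cycle)
  expect_length(d4$paths, 1)
  p <- d4$paths[[1]]
  expect_length(p, 5)
  expect_identical(p[1], p[5])
  # every edge on exactly one path, interiors have degree 2
  all_edges <- do.call(rbind, lapply(d4$paths, function(p)
    t(vapply(seq_len(length(p) - 1), function(k)
      sort(c(p[k], p[k + 1])), integer(2)))))
  expect_equal(nrow(unique(all_edges)), nrow(g4$edges))
})

test_that("chi tables satisfy the counting recursion (oracle check)", {
  al2 <- sequence_constraint(NULL, n = 2)
  chi2 <- chi_tables(c(1, 2), al2)
  # start A: only U reachable at position 2
  expect_equal(chi2[2, "U", "A"], 1)
  expect_equal(unname(chi2[2, c("A", "C", "G"), "A"]), c(0, 0, 0))
  # L = 3 unconstrained: 10 pairable triplets in total
  chi3 <- chi_tables(c(1, 2, 3), sequence_constraint(NULL, n = 3))
  expect_equal(sum(chi3[3, , ]), 10)
  # constrained end: A start cannot reach C at position 2
  alC <- sequence_constraint("NC", n = 2)
  expect_equal(chi_tables(c(1, 2), alC)[2, "C", "A"], 0)
})

test_that("chi equals brute-force enumeration for random constraints", {
  set.seed(5)
  for (rep in 1:30) {
    L <- sample(2:6, 1)
    allowed <- matrix(TRUE, 4, L, dimnames = list(NTS, NULL))
    nblock <- sample(0:(2 * L), 1)
    for (b in seq_len(nblock))
      allowed[sample(4, 1), sample(L, 1)] <- FALSE
    if (any(colSums(allowed) == 0)) next
    chi <- chi_tables(seq_len(L), allowed)
    for (x in sample(NTS, 2)) for (s in sample(NTS, 2)) {
      expect_equal(chi[L, x, s],
                   brute_chi_total(L, allowed, L, x, s),
                   info = sprintf("L=%d x=%s s=%s", L, x, s))
    }
  }
})

test_that("chi tables are orientation-symmetric up to argument transposition", {
  set.seed(9)
  for (rep in 1:20) {
    L <- sample(2:7, 1)
    allowed <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 4 * L, replace = TRUE),
                      4, L, dimnames = list(NTS, NULL))
    if (any(colSums(allowed) == 0)) next
    path <- seq_len(L)
    fwd <- chi_tables(path, allowed)
    rev_al <- allowed[, L:1, drop = FALSE]
    bwd <- chi_tables(path, rev_al)
    for (x in 1:4) for (s in 1:4)
      expect_equal(fwd[L, x, s], bwd[L, s, x])
  }
})

test_that("lambda reflects per-path endpoint feasibility", {
  al <- sequence_constraint(NULL, n = 3)
  direct <- list(chi_tables(c(1, 2), al[, 1:2]))
  expect_equal(lambda_indicator(direct, "A", "U"), 1L)
  expect_equal(lambda_indicator(direct, "A", "C"), 0L)
  chain <- list(chi_tables(c(1, 2, 3), al))
  expect_equal(lambda_indicator(chain, "A", "C"), 0L)  # no middle partner
  expect_equal(lambda_indicator(chain, "A", "A"), 1L)  # via middle U
})

test_that("unconstrained single-pair components avoid GU; constraints force it", {
  ts <- target_set("(...)")
  g <- build_graph(ts)
  set.seed(13)
  draws <- replicate(2000, {
    s <- strsplit(sample_sequence(g), "")[[1]]
    paste0(s[1], s[5])
  })
  expect_true(all(draws %in% c("AU", "UA", "GC", "CG")))
  # forcing G...U yields the wobble pair
  forced <- sample_sequence(ts, "GNNNU")
  expect_equal(substr(forced, 1, 1), "G")
  expect_equal(substr(forced, 5, 5), "U")
  expect_true(is_compatible(forced, ts))
})

test_that("constraint-directed backtracking assigns all start/end vertices", {
  # star component: hub position 3 paired in three different targets, one
  # leaf constrained to C; backtracking must still find an assignment
  ts <- target_set("(.)...", "..(.).", "..(..)")
  g <- build_graph(ts)
  al <- sequence_constraint("NNNNCN", n = 6)
  set.seed(2)
  for (k in 1:50) {
    a <- assign_component(g, g$components[[g$comp[3]]], al)
    expect_false(is.null(a))
    s <- rep("A", 6); s[as.integer(names(a))] <- NTS[a]
    expect_equal(s[5], "C")
    expect_true(is_compatible(paste(s, collapse = ""), ts))
  }
})

test_that("sampled sequences are always compatible and constraint-satisfying", {
  set.seed(31)
  for (k in 1:40) {
    inst <- random_instance(sample(10:25, 1), sample(2:4, 1))
    for (r in 1:5) {
      s <- sample_sequence(inst$graph)
      expect_true(is_compatible(s, inst$targets))
    }
  }
  # explicit forced constraint
  s <- sample_sequence(target_set("(...)"), "GNNNC")
  expect_equal(substr(s, 1, 1), "G")
  expect_equal(substr(s, 5, 5), "C")
})

test_that("reachable assignment set equals the GU-free brute-force count", {
  set.seed(17)
  for (k in 1:8) {
    inst <- random_instance(sample(8:14, 1), 2)
    g <- inst$graph
    comp <- g$components[[which.max(lengths(g$components))]]
    if (length(comp) < 2 || length(comp) > 8) next
    al <- sequence_constraint(NULL, n = g$n)
    seen <- unique(replicate(300, paste(assign_component(g, comp, al),
                                        collapse = "")))
    # GU-free compatible assignments of a connected component: one free
    # choice of nucleotide propagates deterministically => exactly 4
    expect_equal(length(seen), 4L)
  }
  # with GU allowed, chi totals on a lone path equal brute enumeration
  for (L in 2:6) {
    al <- matrix(TRUE, 4, L, dimnames = list(NTS, NULL))
    chi <- chi_tables(seq_len(L), al)
    total_brute <- sum(vapply(NTS, function(x)
      sum(vapply(NTS, function(s) brute_chi_total(L, al, L, x, s),
                 numeric(1))), numeric(1)))
    expect_equal(sum(chi[L, , ]), total_brute)
  }
})

test_that("infeasible constraints are reported with the blocking component", {
  ts <- target_set("(...)")
  expect_error(sample_sequence(ts, "ANNNC"), "infeasible")
})
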