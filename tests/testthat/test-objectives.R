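test_that("objective expressions parse, validate and evaluate", {
  o <- objective_spec("abs(r(GC:CONT) - 50)", "f3")
  expect_equal(o$refs, "GC:CONT")
  expect_equal(o$evaluator(c("GC:CONT" = 100)), 50)
  expect_equal(o$evaluator(c("GC:CONT" = 50)), 0)
  o2 <- objective_spec("r(a:FE) - 2 * r(b:EFE)")
  expect_equal(o2$evaluator(c("a:FE" = 1, "b:EFE" = 2)), -3)
  expect_error(objective_spec("r(GC:CONT); system('ls')"), "disallowed")
  expect_error(objective_spec("q(GC:CONT)"), "disallowed")
})

test_that("unresolved property references are a configuration error", {
  ts <- target_set("(...)")
  m <- list(method_spec("GC", "gc", "CONT"))
  o <- list(objective_spec("r(fold:MFE)", "bad"))
  expect_error(rna_design(ts, methods = m, objectives = o,
                          control = design_control(pop_size = 4,
                                                   max_generations = 1)),
               "unresolved")
})

test_that("method specs enforce their target-binding invariants", {
  expect_error(method_spec("m", "toy", c("SIM")), "require a bound target")
  expect_error(method_spec("m", "toy", c("BAR"), target = 1), "two bound")
  m <- method_spec("m", "toy", c("MFE", "SIM"), target = "(...)")
  expect_true(m$produces_structure)
  m2 <- method_spec("e", "rnaeval", "FE", target = "(...)")
  expect_false(m2$produces_structure)
})

test_that("evaluation fills properties, prediction and objectives", {
  ts <- target_set("(((...)))")
  prob <- multistable_problem(ts)
  methods <- mofold:::.resolve_methods(prob$methods, ts)
  ev <- evaluate_individual("GGGAAACCC", methods, prob$objectives)
  expect_equal(unname(ev$props["fold1:MFE"]), -9)
  expect_equal(unname(ev$props["fold1:SIM"]), 1)
  expect_equal(unname(ev$props["GC:CONT"]), 200 / 3, tolerance = 1e-9)
  expect_equal(to_dotbracket(ev$predicted$fold1), "(((...)))")
  # f1 = sum(E - G) >= 0 always; f2 empty sum for one target
  expect_gte(ev$obj[1], 0)
  expect_equal(ev$obj[2], 0)
  # f3 = |GC - 50|
  expect_equal(ev$obj[3], abs(200 / 3 - 50), tolerance = 1e-9)
})

test_that("f1 is non-negative for random sequences and targets", {
  set.seed(91)
  for (k in 1:15) {
    inst <- random_instance(12, 2)
    prob <- multistable_problem(inst$targets)
    methods <- mofold:::.resolve_methods(prob$methods, inst$targets)
    s <- sample_sequence(inst$graph)
    ev <- evaluate_individual(s, methods, prob$objectives)
    expect_gte(ev$obj[1], -1e-9)
  }
})

test_that("GCPAIR is the negated GC content of paired positions", {
  m <- method_spec("fold", "toy", c("MFE", "GCPAIR"))
  ev <- mofold:::.compute_method("GGGAAACCC", m)
  expect_equal(unname(ev$props["GCPAIR"]), -100)   # all paired nts are G/C
  ev0 <- mofold:::.compute_method("AAAAA", m)
  expect_equal(unname(ev0$props["GCPAIR"]), 0)     # no pairs at all
})

test_that("toy Boltzmann probabilities are consistent with the ensemble", {
  set.seed(8)
  for (k in 1:10) {
    s <- paste(sample(NTS, 10, replace = TRUE), collapse = "")
    g <- toy_ensemble(s)
    mfe <- toy_mfe(s)
    pb <- exp(g - mfe$energy)
    expect_gt(pb, 0); expect_lte(pb, 1 + 1e-9)
  }
})

test_that("device objectives hit their designed extremes", {
  # toy device: active = hairpin, inactive = open chain forced by constraint
  act <- "(((....)))"
  inact <- ".........."
  prob <- device_problem(act, inact, aptamer_constraint = "..........",
                         engine = "toy", gap = 1)
  methods <- mofold:::.resolve_methods(prob$methods, prob$targets)
  # a sequence folding exactly into the hairpin: F3 = -1 iff both SIMs are 1
  s <- "GGGAAAACCC"
  ev <- evaluate_individual(s, methods, prob$objectives)
  sim_a <- ev$props[["active:SIM"]]
  sim_i <- ev$props[["inactive:SIM"]]
  f3 <- ev$obj[3]
  expect_equal(f3, -(sim_a + sim_i) / 2)
  expect_identical(f3 == -1, sim_a == 1 && sim_i == 1)
  # F2 = 0 iff the gap is exactly the prescribed 1.0
  gap <- ev$props[["inactive:MFE"]] - ev$props[["active:MFE"]]
  expect_equal(ev$obj[2], abs(gap - 1))
})

test_that("an engine failure marks the individual with worst-case objectives", {
  ts <- target_set("(...)")
  boom <- method_spec("boom", "command", "FE", target = 1,
                      options = list(command = "false {seq}",
                                     parser = function(x) c(FE = 0)))
  o <- list(objective_spec("r(boom:FE)", "f"))
  m <- mofold:::.resolve_methods(list(boom), ts)
  expect_warning(ev <- evaluate_individual("GAAAC", m, o), "failed")
  expect_equal(ev$obj, mofold:::.WORST_OBJECTIVE)
})

test_that("the generic command adapter runs an executable and parses output", {
  stub <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "printf 'ENERGY -4.25\\n'"), stub)
  Sys.chmod(stub, "0755")
  m <- method_spec("ext", "command", "FE", target = 1,
                   options = list(
                     command = paste(stub, "{seq}"),
                     parser = function(lines) {
                       c(FE = as.numeric(strsplit(lines[1], " ")[[1]][2]))
                     }))
  ts <- target_set("(...)")
  m <- mofold:::.resolve_methods(list(m), ts)[[1]]
  res <- mofold:::.compute_method("GAAAC", m)
  expect_equal(unname(res$props["FE"]), -4.25)
})

test_that("missing external engines fail at configuration time, not mid-run", {
  ts <- target_set("(...)")
  m <- list(method_spec("nope", "command", "FE", target = 1,
                        options = list(command = "no-such-binary-xyz {seq}",
                                       parser = function(x) c(FE = 0))))
  o <- list(objective_spec("r(nope:FE)", "f"))
  expect_error(rna_design(ts, methods = m, objectives = o,
                          control = design_control(pop_size = 4,
                                                   max_generations = 1)),
               "configuration error")
})

test_that("the evaluation cache returns identical results without recompute", {
  ts <- target_set("(((...)))")
  prob <- multistable_problem(ts)
  methods <- mofold:::.resolve_methods(prob$methods, ts)
  cache <- new.env()
  e1 <- evaluate_individual("GGGAAACCC", methods, prob$objectives, cache)
  e2 <- evaluate_individual("GGGAAACCC", methods, prob$objectives, cache)
  expect_identical(e1, e2)
  expect_length(ls(cache), 1)
})
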