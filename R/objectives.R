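#' Define an objective function over method properties
#'
#' An objective is an arithmetic expression over property references
#' \code{r(METHOD:PROPERTY)} and numeric constants, using \code{+ - * /},
#' parentheses and \code{abs()}, \code{min()}, \code{max()}.  All objectives
#' are minimized.
#'
#' @param expr expression string, e.g. \code{"abs(r(GC:CONT) - 50)"}.
#' @param name objective name (defaults to the expression).
#' @return An object of class \code{"objective_spec"} carrying the compiled
#'   evaluator.
#' @export
objective_spec <- function(expr, name = expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  refs <- character(0)
  pat <- "r\\(([A-Za-z0-9_.-]+):([A-Z]+)\\)"
  mt <- gregexpr(pat, expr)[[1]]
  if (mt[1] != -1) {
    for (k in seq_along(mt)) {
      sub <- substr(expr, mt[k], mt[k] + attr(mt, "match.length")[k] - 1L)
      refs <- c(refs, sub("^r\\(", "", sub("\\)$", "", sub)))
    }
  }
  refs <- unique(refs)
  body <- expr
  for (rf in refs) {
    body <- gsub(sprintf("r(%s)", rf),
                 sprintf('.p[["%s"]]', rf), body, fixed = TRUE)
  }
  # whitelist what remains once references are replaced
  residue <- gsub('\\.p\\[\\["[A-Za-z0-9_.:-]+"\\]\\]', "", body)
  residue <- gsub("abs|min|max", "", residue)
  if (grepl("[^0-9eE.+*/() ,-]", residue))
    stop("objective expression contains disallowed tokens: ", expr)
  fn_expr <- parse(text = body)[[1]]
  env <- new.env(parent = baseenv())
  evaluator <- function(props) {
    assign(".p", as.list(props), envir = env)
    as.numeric(eval(fn_expr, env))
  }
  structure(list(name = name, expr = expr, refs = refs,
                 evaluator = evaluator),
            class = "objective_spec")
}

# Check that every r(X:Y) reference resolves against the method list.
.check_objective_refs <- function(objectives, methods) {
  avail <- unlist(lapply(methods, function(m)
    paste(m$name, m$properties, sep = ":")))
  errs <- character(0)
  for (o in objectives) {
    miss <- setdiff(o$refs, avail)
    if (length(miss))
      errs <- c(errs, paste0("objective '", o$name, "': unresolved reference ",
                             paste(miss, collapse = ", ")))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(TRUE)
}

#' Evaluate an individual: compute all properties and objectives
#'
#' Runs every method of the method list on the sequence, stores property
#' values and (for structure-producing methods) predicted structures, then
#' evaluates each objective expression.  An engine failure on a sequence
#' marks the individual with worst-case objective values and emits a
#' warning, so selection can discard it without aborting the run.
#'
#' @param seq RNA sequence.
#' @param methods list of [method_spec()] (targets already resolved).
#' @param objectives list of [objective_spec()].
#' @param cache optional environment used as a property cache keyed by
#'   sequence.
#' @return List with \code{seq}, \code{props} (named \code{"name:PROP"}),
#'   \code{predicted} (named list), \code{sims} (per-method SIM values),
#'   \code{obj} (numeric objective vector).
#' @export
evaluate_individual <- function(seq, methods, objectives, cache = NULL) {
  key <- seq
  if (!is.null(cache) && !is.null(cache[[key]])) {
    ev <- cache[[key]]
  } else {
    props <- numeric(0)
    predicted <- list()
    sims <- numeric(0)
    failed <- FALSE
    for (m in methods) {
      res <- tryCatch(.compute_method(seq, m), error = function(e) e)
      if (inherits(res, "error")) {
        warning("evaluation of method '", m$name, "' failed for a sequence: ",
                conditionMessage(res), call. = FALSE)
        failed <- TRUE
        break
      }
      pv <- setNames(res$props, paste(m$name, names(res$props), sep = ":"))
      props <- c(props, pv)
      if (!is.null(res$predicted)) predicted[[m$name]] <- res$predicted
      if ("SIM" %in% names(res$props)) sims[m$name] <- res$props[["SIM"]]
    }
    if (failed) {
      obj <- rep(.WORST_OBJECTIVE, length(objectives))
    } else {
      obj <- vapply(objectives, function(o) o$evaluator(props), numeric(1))
      obj[!is.finite(obj)] <- .WORST_OBJECTIVE
    }
    ev <- list(seq = seq, props = props, predicted = predicted,
               sims = sims, obj = obj)
    if (!is.null(cache)) cache[[key]] <- ev
  }
  ev
}

.WORST_OBJECTIVE <- 1e9

#' Standard multistable design problem
#'
#' Builds the method list and the three standard objectives for an
#' \code{n}-target design:
#' \itemize{
#'   \item \code{f1 = sum_i (E(theta_i) - G)}: how close every target's
#'     energy is to the ensemble free energy (0 would mean all targets at
#'     the ground state with probability 1);
#'   \item \code{f2 = sum_{i<j} |E(theta_i) - E(theta_j)|}: equal stability
#'     of the targets;
#'   \item \code{f3 = |GC\% - rho_target|}: target GC content.
#' }
#'
#' @param targets a [target_set()].
#' @param engine \code{"toy"} (hermetic) or \code{"rnafold"} (ViennaRNA).
#' @param rho_target target GC content in percent (default 50).
#' @return List with elements \code{methods} and \code{objectives}.
#' @export
multistable_problem <- function(targets, engine = c("toy", "rnafold"),
                                rho_target = 50) {
  engine <- match.arg(engine)
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  nt <- attr(targets, "n_target")
  methods <- lapply(seq_len(nt), function(i)
    method_spec(paste0("fold", i), engine,
                properties = c("MFE", "SIM", "FE", "EFE", "PB"),
                target = i))
  methods <- c(methods, list(method_spec("GC", "gc", "CONT")))
  fe <- sprintf("r(fold%d:FE)", seq_len(nt))
  f1 <- paste(paste(fe, collapse = " + "),
              sprintf("- %d * r(fold1:EFE)", nt))
  f2 <- if (nt < 2) "0 * r(fold1:FE)" else {
    combs <- utils::combn(nt, 2)
    paste(apply(combs, 2, function(ij)
      sprintf("abs(r(fold%d:FE) - r(fold%d:FE))", ij[1], ij[2])),
      collapse = " + ")
  }
  f3 <- sprintf("abs(r(GC:CONT) - %g)", rho_target)
  list(methods = methods,
       objectives = list(objective_spec(f1, "f1"),
                         objective_spec(f2, "f2"),
                         objective_spec(f3, "f3")))
}

#' RNA-device design problem (ON-switch style)
#'
#' Two-state device objectives: the active state is the unconstrained MFE
#' structure, the inactive (ligand-bound) state the MFE structure under an
#' aptamer structure constraint.
#' \itemize{
#'   \item \code{F1 = E(active) - G}: stability of the active ground state;
#'   \item \code{F2 = |E(inactive) - E(active) - gap|}: a prescribed energy
#'     gap (default 1 unit) between the states;
#'   \item \code{F3 = -(sim_inactive + sim_active)/2}: similarity to both
#'     target conformations (\code{-1} iff both are exactly realised);
#'   \item \code{F4 = |GC\% - rho_target|};
#'   \item optionally \code{F5}: the energy barrier between the two MFE
#'     structures.
#' }
#'
#' @param target_active,target_inactive target structures (dot-bracket,
#'   wildcards allowed).
#' @param aptamer_constraint structure-constraint string for the inactive
#'   state (dot-bracket over the full length; \code{'*'} = unconstrained).
#' @param engine \code{"toy"} or \code{"rnafold"}.
#' @param gap prescribed active/inactive energy gap (energy units).
#' @param rho_target target GC content percent.
#' @param barrier include F5 (energy barrier, findpath-style heuristic).
#' @param lookahead barrier beam width.
#' @return List with \code{targets}, \code{methods}, \code{objectives}.
#' @export
device_problem <- function(target_active, target_inactive, aptamer_constraint,
                           engine = c("toy", "rnafold"), gap = 1.0,
                           rho_target = 50, barrier = FALSE, lookahead = 10) {
  engine <- match.arg(engine)
  targets <- target_set(target_active, target_inactive)
  methods <- list(
    method_spec("active", engine, c("MFE", "SIM", "EFE"), target = 1),
    method_spec("inactive", engine, c("MFE", "SIM"), target = 2,
                str_constraint = aptamer_constraint),
    method_spec("GC", "gc", "CONT"))
  objectives <- list(
    objective_spec("r(active:MFE) - r(active:EFE)", "F1"),
    objective_spec(sprintf("abs(r(inactive:MFE) - r(active:MFE) - %g)", gap),
                   "F2"),
    objective_spec("0 - (r(inactive:SIM) + r(active:SIM)) / 2", "F3"),
    objective_spec(sprintf("abs(r(GC:CONT) - %g)", rho_target), "F4"))
  if (barrier) {
    bar_engine <- if (engine == "toy") "toy" else "findpath"
    methods <- c(methods, list(
      method_spec("bar", bar_engine, "BAR", target = 1, target2 = 2,
                  str_constraint = aptamer_constraint,
                  options = list(lookahead = lookahead, use_mfe = TRUE))))
    objectives <- c(objectives, list(objective_spec("r(bar:BAR)", "F5")))
  }
  list(targets = targets, methods = methods, objectives = objectives)
}
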