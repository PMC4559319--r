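#' Control parameters for a design run
#'
#' @param pop_size population size N_p (default 100).
#' @param max_generations generation limit l_max (default 200).
#' @param n_term stop when the number of rank-1 solutions is unchanged for
#'   this many consecutive generations (default 50).
#' @param p_M per-position point-mutation probability (default 0.05).
#' @param weak_pareto explore weak Pareto optima (strong dominance in the
#'   sort) instead of Pareto optima.
#' @param conv enable the stagnation stop rule; \code{FALSE} runs to
#'   \code{max_generations} regardless.
#' @param op_mutation,op_negative,op_positive,op_crossover operator toggles.
#' @param op_weights relative invocation weights of the enabled operators
#'   in the order mutation, negative, positive, crossover (default equal).
#' @param max_depth positive-design repair depth (default 3).
#' @param motifs IUPAC motifs to scrub after every operator application.
#' @param tract_len mononucleotide-tract scrub length, \code{NULL} = off.
#' @param seed RNG seed; every run with the same seed and inputs is
#'   reproducible.
#' @param verbose log generation progress to stderr.
#' @return A list of class \code{"design_control"}.
#' @export
design_control <- function(pop_size = 100, max_generations = 200, n_term = 50,
                           p_M = 0.05, weak_pareto = FALSE, conv = TRUE,
                           op_mutation = TRUE, op_negative = TRUE,
                           op_positive = TRUE, op_crossover = TRUE,
                           op_weights = c(1, 1, 1, 1), max_depth = 3,
                           motifs = character(0), tract_len = NULL,
                           seed = NULL, verbose = FALSE) {
  stopifnot(pop_size >= 2, max_generations >= 1, n_term >= 1,
            p_M >= 0, p_M <= 1, length(op_weights) == 4, all(op_weights >= 0))
  structure(as.list(environment()), class = "design_control")
}

#' Design RNA sequences for multiple target secondary structures
#'
#' The main fitting function: explores, with an NSGA-II multi-objective
#' genetic algorithm, the space of RNA sequences compatible with every
#' target structure, minimizing the supplied objective functions.  Every
#' individual in every generation is compatible with all targets and
#' satisfies the IUPAC sequence constraint; reproduction uses the
#' compatibility-preserving point mutation, negative design, positive
#' design and crossover operators.  The run stops when the number of
#' non-dominated solutions has not changed for \code{n_term} consecutive
#' generations (unless \code{conv = FALSE}) or at \code{max_generations}.
#'
#' @param targets a [target_set()], or one or more dot-bracket strings.
#' @param constraint optional IUPAC sequence constraint of length N.
#' @param methods list of [method_spec()]; default: the standard
#'   multistable setup of [multistable_problem()] with the toy engine.
#' @param objectives list of [objective_spec()]; default as above.
#' @param control a [design_control()].
#' @return An object of class \code{"rna_design"}; see
#'   [summary.rna_design()], [pareto_front()], [write_results()].
#' @examples
#' fit <- rna_design(c("((((....))))", "((......)).."),
#'                   control = design_control(pop_size = 20,
#'                                            max_generations = 10, seed = 1))
#' summary(fit)
#' @export
rna_design <- function(targets, constraint = NULL, methods = NULL,
                       objectives = NULL, control = design_control()) {
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  if (!is.null(control$seed)) set.seed(control$seed)
  if (is.null(methods) != is.null(objectives))
    stop("supply both 'methods' and 'objectives', or neither")
  if (is.null(methods)) {
    prob <- multistable_problem(targets)
    methods <- prob$methods
    objectives <- prob$objectives
  }
  nms <- vapply(methods, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("method names must be unique")
  methods <- .resolve_methods(methods, targets)
  .check_engines(methods)
  .check_objective_refs(objectives, methods)
  g <- build_graph(targets)              # fails early on infeasible targets
  allowed <- sequence_constraint(constraint, n = g$n)
  cache <- new.env(parent = emptyenv())
  n_p <- control$pop_size

  ops <- c("mutation", "negative", "positive", "crossover")
  on_flags <- c(control$op_mutation, control$op_negative,
                control$op_positive, control$op_crossover)
  w <- control$op_weights * on_flags
  if (sum(w) == 0) stop("all GA operators are disabled")

  eval_ind <- function(seq) evaluate_individual(seq, methods, objectives, cache)
  # the method with the lowest structure similarity, its prediction + target
  worst_sim <- function(ind) {
    if (!length(ind$sims)) return(NULL)
    nm <- names(ind$sims)[which.min(ind$sims)]
    m <- methods[[match(nm, nms)]]
    pred <- ind$predicted[[nm]]
    if (is.null(pred)) return(NULL)
    list(target = m$target, predicted = pred)
  }

  scrub <- function(seq)
    scrub_motifs(seq, g, allowed, motifs = control$motifs,
                 tract_len = control$tract_len)

  pop <- lapply(seq_len(n_p), function(k)
    eval_ind(scrub(sample_sequence(g, allowed))))

  history <- list()
  l <- 0L; c_stop <- 0L; prev_rank1 <- NA_integer_
  repeat {
    obj <- do.call(rbind, lapply(pop, `[[`, "obj"))
    rc <- .rank_and_crowd(obj, strong = control$weak_pareto)
    for (k in seq_along(pop)) {
      pop[[k]]$rank <- rc$rank[k]
      pop[[k]]$crowd <- rc$crowd[k]
    }
    n_rank1 <- sum(rc$rank == 1L)
    best <- apply(obj, 2, min)
    history[[length(history) + 1L]] <-
      c(generation = l, n_rank1 = n_rank1, setNames(best, paste0("best_f", seq_along(best))))
    if (control$verbose)
      message(sprintf("generation %d: n_rank1 = %d, best = [%s]",
                      l, n_rank1, paste(signif(best, 4), collapse = ", ")))
    if (!is.na(prev_rank1) && n_rank1 == prev_rank1) c_stop <- c_stop + 1L
    else c_stop <- 0L
    prev_rank1 <- n_rank1
    if ((control$conv && c_stop >= control$n_term) ||
        l >= control$max_generations) break

    # reproduction: parents by crowding tournament from the best N_p
    pool <- .truncate_pop(pop, n_p)
    prank <- vapply(pool, `[[`, numeric(1), "rank")
    pcrowd <- vapply(pool, `[[`, numeric(1), "crowd")
    children <- vector("list", n_p)
    for (k in seq_len(n_p)) {
      op <- sample(ops, 1L, prob = w)
      parent <- pool[[.tournament(prank, pcrowd, 1L)]]
      child_seq <- switch(op,
        mutation = point_mutation(parent$seq, g, allowed, p_M = control$p_M),
        crossover = {
          mate <- pool[[.tournament(prank, pcrowd, 1L)]]
          crossover(parent$seq, mate$seq, g)
        },
        negative = {
          ws <- worst_sim(parent)
          if (is.null(ws)) point_mutation(parent$seq, g, allowed, control$p_M)
          else negative_design(parent$seq, targets, ws$predicted, g, allowed)
        },
        positive = {
          ws <- worst_sim(parent)
          if (is.null(ws)) point_mutation(parent$seq, g, allowed, control$p_M)
          else positive_design(parent$seq, ws$target, ws$predicted, g,
                               allowed, max_depth = control$max_depth)
        })
      children[[k]] <- eval_ind(scrub(child_seq))
    }
    pop <- c(.truncate_pop(pop, n_p), children)   # |P| <= 2 N_p
    l <- l + 1L
  }

  history <- as.data.frame(do.call(rbind, history))
  out <- list(population = pop,
              history = history,
              targets = targets,
              constraint = constraint,
              methods = methods,
              objectives = objectives,
              control = control,
              generations = l,
              n_rank1 = prev_rank1)
  class(out) <- "rna_design"
  out
}

#' Extract the Pareto front (rank-1 individuals) of a design
#'
#' @param x an [rna_design()] result.
#' @return List of rank-1 individuals.
#' @export
pareto_front <- function(x) {
  stopifnot(inherits(x, "rna_design"))
  Filter(function(ind) ind$rank == 1L, x$population)
}

#' @export
print.rna_design <- function(x, ...) {
  cat("Multi-target RNA design (NSGA-II)\n")
  cat("  targets:    ", attr(x$targets, "n_target"), " structure(s), N = ",
      attr(x$targets, "n"), "\n", sep = "")
  cat("  objectives: ", paste(vapply(x$objectives, `[[`, character(1), "name"),
                              collapse = ", "), "\n", sep = "")
  cat("  generations:", x$generations,
      " | population:", length(x$population),
      " | non-dominated:", x$n_rank1, "\n")
  invisible(x)
}

#' Summarize a design run
#'
#' @param object an [rna_design()] result.
#' @param ... unused.
#' @return Invisibly, the data frame of rank-1 individuals (sequence +
#'   objective values), which is also printed.
#' @export
summary.rna_design <- function(object, ...) {
  print(object)
  df <- as.data.frame(object)
  front <- df[df$rank == 1, , drop = FALSE]
  front <- front[!duplicated(front$seq), , drop = FALSE]
  cat("\nPareto front (", nrow(front), " unique sequence(s)):\n", sep = "")
  print(utils::head(front[order(front[[4]]), ], 10), row.names = FALSE)
  invisible(front)
}

#' @export
as.data.frame.rna_design <- function(x, ...) {
  onames <- vapply(x$objectives, `[[`, character(1), "name")
  rows <- lapply(x$population, function(ind) {
    data.frame(seq = ind$seq, rank = ind$rank, crowding = ind$crowd,
               setNames(as.list(ind$obj), onames),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  props <- do.call(rbind, lapply(x$population, `[[`, "props"))
  cbind(df, as.data.frame(props, check.names = FALSE))
}

#' Plot the objective space of a design run
#'
#' Scatter plots of all objective pairs, rank-1 individuals highlighted.
#'
#' @param x an [rna_design()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rna_design <- function(x, ...) {
  obj <- do.call(rbind, lapply(x$population, `[[`, "obj"))
  onames <- vapply(x$objectives, `[[`, character(1), "name")
  colnames(obj) <- onames
  rank <- vapply(x$population, `[[`, numeric(1), "rank")
  col <- ifelse(rank == 1, "firebrick", "grey60")
  pch <- ifelse(rank == 1, 19, 1)
  if (ncol(obj) == 1) {
    graphics::plot(seq_along(obj[, 1]), sort(obj[, 1]), xlab = "individual",
                   ylab = onames[1], col = col[order(obj[, 1])], pch = 19, ...)
  } else if (ncol(obj) == 2) {
    graphics::plot(obj[, 1], obj[, 2], xlab = onames[1], ylab = onames[2],
                   col = col, pch = pch, ...)
  } else {
    graphics::pairs(obj, col = col, pch = pch, ...)
  }
  invisible(x)
}
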