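# Run configuration files and result writers.

#' Load a design run configuration
#'
#' YAML configuration with sections:
#' \preformatted{
#' targets:            # dot-bracket strings, equal length
#'   - "((((....))))"
#'   - "((......)).."
#' constraint: "NNNNNNNNNNNN"     # optional IUPAC string
#' methods:            # optional; default: standard multistable setup
#'   - {name: fold1, engine: toy, properties: [MFE, SIM, FE, EFE], target: 1}
#'   - {name: GC, engine: gc, properties: [CONT]}
#' objectives:         # optional; expressions over r(NAME:PROP)
#'   - {name: f3, expr: "abs(r(GC:CONT) - 50)"}
#' ga:                 # optional; any design_control() argument
#'   pop_size: 50
#'   seed: 1
#' }
#' Validation collects every violation before failing, so a bad file
#' reports all its problems at once.
#'
#' @param path configuration file path.
#' @return List with \code{targets}, \code{constraint}, \code{methods},
#'   \code{objectives}, \code{control}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  targets <- NULL
  if (is.null(cfg$targets) || !length(cfg$targets)) {
    note("no targets specified")
  } else {
    lens <- nchar(unlist(cfg$targets))
    if (length(unique(lens)) != 1)
      note(paste0("targets have unequal lengths: ", paste(lens, collapse = ", ")))
    targets <- tryCatch(target_set(lapply(unlist(cfg$targets), identity)),
                        error = function(e) { note(conditionMessage(e)); NULL })
  }
  constraint <- cfg$constraint
  if (!is.null(constraint)) {
    n_ref <- if (!is.null(targets)) attr(targets, "n")
             else if (length(cfg$targets)) nchar(unlist(cfg$targets)[1])
             else NULL
    if (!is.null(n_ref) && nchar(constraint) != n_ref)
      note("constraint length differs from target length")
    tryCatch(sequence_constraint(constraint),
             error = function(e) note(conditionMessage(e)))
  }
  methods <- objectives <- NULL
  if (!is.null(cfg$methods)) {
    methods <- lapply(cfg$methods, function(m)
      tryCatch(method_spec(m$name, m$engine, unlist(m$properties),
                           target = m$target, target2 = m$target2,
                           str_constraint = m$str_constraint,
                           options = m$options %||% list()),
               error = function(e) { note(conditionMessage(e)); NULL }))
    if (any(vapply(methods, is.null, logical(1)))) methods <- NULL
  }
  if (!is.null(cfg$objectives)) {
    objectives <- lapply(cfg$objectives, function(o)
      tryCatch(objective_spec(o$expr, o$name %||% o$expr),
               error = function(e) { note(conditionMessage(e)); NULL }))
    if (any(vapply(objectives, is.null, logical(1)))) objectives <- NULL
  }
  if (!is.null(methods) && !is.null(objectives)) {
    tryCatch(.check_objective_refs(objectives, methods),
             error = function(e) note(conditionMessage(e)))
  }
  control <- tryCatch(do.call(design_control, cfg$ga %||% list()),
                      error = function(e) { note(conditionMessage(e)); NULL })
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  list(targets = targets, constraint = constraint,
       methods = methods, objectives = objectives, control = control)
}

#' Write design results to FASTA and TSV files
#'
#' The FASTA file holds the rank-1 (Pareto front) sequences with IDs
#' encoding rank and index plus the objective vector on the description
#' line; the TSV file tabulates every individual with its sequence,
#' rank, crowding distance, objective values and property values.
#'
#' @param x an [rna_design()] result.
#' @param fasta,tsv output paths (\code{NULL} skips that file).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, fasta = "designs.fasta", tsv = "designs.tsv") {
  stopifnot(inherits(x, "rna_design"))
  written <- character(0)
  if (!is.null(fasta)) {
    front <- pareto_front(x)
    onames <- vapply(x$objectives, `[[`, character(1), "name")
    lines <- unlist(lapply(seq_along(front), function(k) {
      ind <- front[[k]]
      c(sprintf(">design_rank1_%03d %s", k,
                paste(sprintf("%s=%.4g", onames, ind$obj), collapse = " ")),
        ind$seq)
    }))
    writeLines(lines, fasta)
    written <- c(written, fasta)
  }
  if (!is.null(tsv)) {
    df <- as.data.frame(x)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  invisible(written)
}
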