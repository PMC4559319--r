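#' Declare a folding method and the properties it computes
#'
#' A \emph{method} is one invocation of a folding engine; its
#' \emph{properties} are the numbers it contributes to objective functions,
#' referenced in objective expressions as \code{r(NAME:PROPERTY)}.
#' Supported properties:
#' \describe{
#'   \item{MFE}{minimum free energy (the method then also attaches its
#'     predicted structure to the individual)}
#'   \item{SIM}{structure similarity between the predicted structure and the
#'     bound target (requires \code{target})}
#'   \item{FE}{free energy of the bound target structure (requires
#'     \code{target})}
#'   \item{EFE}{ensemble free energy}
#'   \item{PB}{Boltzmann probability of the bound target}
#'   \item{BAR}{energy barrier between two bound targets (requires
#'     \code{target} and \code{target2})}
#'   \item{GCPAIR}{GC content of base-paired positions of the predicted
#'     structure, multiplied by -1}
#'   \item{PF}{partition function}
#'   \item{DEF, NDEF}{(normalized) ensemble defect — external engines only}
#'   \item{CONT}{GC content of the sequence (engine \code{"gc"})}
#' }
#'
#' @param name unique method name used in \code{r(name:PROP)} references.
#' @param engine one of \code{"toy"}, \code{"gc"}, \code{"rnafold"},
#'   \code{"rnaeval"}, \code{"findpath"}, \code{"command"} (generic external
#'   adapter, see Details).
#' @param properties character vector of property names.
#' @param target,target2 bound target structure(s) (index into the design's
#'   target set, an [rna_structure()], or dot-bracket string).
#' @param str_constraint optional structure constraint applied when this
#'   method folds (models e.g. a ligand-bound aptamer domain); dot-bracket
#'   with \code{'*'} for unconstrained positions.
#' @param options engine options: \code{lookahead} (BAR beam width),
#'   \code{params} ("turner2004"/"turner1999" for ViennaRNA adapters),
#'   \code{dangles}; for \code{engine = "command"}: \code{command} (template
#'   with placeholder \code{{seq}}) and \code{parser} (function(stdout
#'   lines) -> named numeric property vector, optionally with attribute
#'   \code{"structure"} = dot-bracket).
#' @return An object of class \code{"method_spec"}.
#' @export
method_spec <- function(name, engine, properties,
                        target = NULL, target2 = NULL,
                        str_constraint = NULL, options = list()) {
  engine <- match.arg(engine,
                      c("toy", "gc", "rnafold", "rnaeval", "findpath",
                        "nupack", "fold", "command"))
  known <- c("MFE", "SIM", "FE", "EFE", "PB", "BAR", "CONT", "GCPAIR",
             "PF", "DEF", "NDEF")
  bad <- setdiff(properties, known)
  if (length(bad)) stop("unknown property: ", paste(bad, collapse = ", "))
  needs_target <- intersect(properties, c("SIM", "FE", "PB"))
  if (length(needs_target) && is.null(target))
    stop(name, ": properties ", paste(needs_target, collapse = "/"),
         " require a bound target structure")
  if ("BAR" %in% properties && (is.null(target) || is.null(target2)))
    stop(name, ": BAR requires two bound target structures")
  as_struct <- function(t)
    if (is.null(t) || is.numeric(t) || inherits(t, "rna_structure")) t
    else parse_dotbracket(t)
  produces <- any(c("MFE", "SIM", "GCPAIR") %in% properties) &&
    engine %in% c("toy", "rnafold", "nupack", "fold", "command")
  structure(list(name = name, engine = engine, properties = properties,
                 target = as_struct(target), target2 = as_struct(target2),
                 str_constraint = as_struct(str_constraint),
                 produces_structure = produces, options = options),
            class = "method_spec")
}

# Resolve numeric target references against the design's target set.
.resolve_methods <- function(methods, targets) {
  lapply(methods, function(m) {
    for (f in c("target", "target2")) {
      if (is.numeric(m[[f]])) {
        i <- as.integer(m[[f]])
        if (i < 1 || i > attr(targets, "n_target"))
          stop(m$name, ": target index ", i, " out of range")
        m[[f]] <- targets[[i]]
      }
    }
    m
  })
}

# Startup check: external engines must be resolvable before the run begins.
.check_engines <- function(methods) {
  for (m in methods) {
    if (m$engine %in% c("rnafold", "rnaeval", "findpath")) {
      if (!vienna_available())
        stop("method '", m$name, "' needs the ViennaRNA python bindings, ",
             "which were not found (configuration error)")
    } else if (m$engine %in% c("nupack", "fold", "command")) {
      cmd <- m$options$command
      if (is.null(cmd))
        cmd <- switch(m$engine, nupack = "pfunc", fold = "Fold", NULL)
      exe <- strsplit(cmd, " ")[[1]][1]
      if (Sys.which(exe) == "")
        stop("method '", m$name, "' needs executable '", exe,
             "', which is not installed (configuration error)")
    }
  }
  invisible(TRUE)
}

# Compute all properties of one method for one sequence.  Returns
# list(props = named numeric, predicted = rna_structure or NULL).
.compute_method <- function(seq, m) {
  props <- numeric(0)
  predicted <- NULL
  if (m$engine == "gc") {
    props["CONT"] <- gc_content(seq)
  } else if (m$engine == "toy") {
    need_fold <- m$produces_structure || any(c("MFE", "SIM", "GCPAIR") %in% m$properties)
    if (need_fold) {
      mfe <- toy_mfe(seq, m$str_constraint)
      predicted <- mfe$structure
      if ("MFE" %in% m$properties) props["MFE"] <- mfe$energy
      if ("SIM" %in% m$properties)
        props["SIM"] <- similarity(m$target, predicted)
      if ("GCPAIR" %in% m$properties) {
        paired <- unique(as.vector(predicted$pairs))
        props["GCPAIR"] <- if (!length(paired)) 0 else
          -100 * sum(seq_to_codes(seq)[paired] %in% c(2L, 3L)) / length(paired)
      }
    }
    if (any(c("EFE", "PB", "PF") %in% m$properties)) {
      g <- toy_ensemble(seq, m$str_constraint)
      if ("EFE" %in% m$properties) props["EFE"] <- g
      if ("PF" %in% m$properties) props["PF"] <- exp(-g)
      if ("PB" %in% m$properties)
        props["PB"] <- exp(g - toy_eval(seq, m$target))  # exp((G - E)/kT)
    }
    if ("FE" %in% m$properties) props["FE"] <- toy_eval(seq, m$target)
    if ("BAR" %in% m$properties) {
      la <- m$options$lookahead %||% 10
      if (isTRUE(m$options$use_mfe)) {
        # device style: barrier between the MFE structures with and without
        # the structure constraint
        th_a <- toy_mfe(seq)$structure
        th_b <- toy_mfe(seq, m$str_constraint)$structure
      } else {
        th_a <- m$target; th_b <- m$target2
      }
      props["BAR"] <- toy_barrier(seq, th_a, th_b, lookahead = la)
    }
  } else if (m$engine %in% c("rnafold", "rnaeval", "findpath")) {
    res <- .vienna_method(seq, m)
    props <- res$props
    predicted <- res$predicted
  } else {
    res <- .command_method(seq, m)
    props <- res$props
    predicted <- res$predicted
  }
  miss <- setdiff(m$properties, names(props))
  if (length(miss))
    stop("method '", m$name, "' did not produce propert",
         if (length(miss) > 1) "ies " else "y ", paste(miss, collapse = ", "))
  list(props = props[m$properties], predicted = predicted)
}

# Generic external-command adapter (also backs the nupack/fold placeholders).
.command_method <- function(seq, m) {
  cmd <- m$options$command
  if (is.null(cmd)) stop("engine '", m$engine, "': no command configured")
  parser <- m$options$parser
  if (is.null(parser)) stop("engine '", m$engine, "': no parser configured")
  full <- gsub("{seq}", seq, cmd, fixed = TRUE)
  parts <- strsplit(full, " +")[[1]]
  out <- suppressWarnings(
    tryCatch(system2(parts[1], parts[-1], stdout = TRUE, stderr = TRUE),
             error = function(e) structure(character(0), status = 127L)))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    stop("engine command failed (exit ", status, "): ",
         paste(utils::tail(out, 3), collapse = " | "))
  props <- parser(out)
  predicted <- attr(props, "structure")
  if (!is.null(predicted) && is.character(predicted))
    predicted <- parse_dotbracket(predicted)
  list(props = props, predicted = predicted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
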