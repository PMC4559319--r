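# Adapters for ViennaRNA, driven through the python bindings via a shipped
# helper script (inst/python/vienna_helper.py).  Requests are batched as
# JSON; each adapter call is one helper invocation.

.vienna_state <- new.env(parent = emptyenv())

#' Are the ViennaRNA python bindings available?
#'
#' @param python python executable to probe (default \code{"python"}).
#' @return \code{TRUE} or \code{FALSE} (cached per session).
#' @export
vienna_available <- function(python = getOption("mofold.python", "python")) {
  key <- paste0("avail_", python)
  if (!is.null(.vienna_state[[key]])) return(.vienna_state[[key]])
  ok <- Sys.which(python) != "" &&
    suppressWarnings(tryCatch(
      system2(python, c("-c", shQuote("import RNA")),
              stdout = FALSE, stderr = FALSE) == 0,
      error = function(e) FALSE))
  .vienna_state[[key]] <- isTRUE(ok)
  .vienna_state[[key]]
}

#' Run a batch of requests against the ViennaRNA helper
#'
#' Low-level access to the shipped python helper; each request is a list
#' with an \code{op} field (\code{"mfe"}, \code{"efe"}, \code{"eval"},
#' \code{"pb"}, \code{"findpath"}) plus its arguments.  See the helper
#' script for the request/response schema.
#'
#' @param requests list of request lists.
#' @param python python executable.
#' @return List of response lists; a failed request carries an \code{error}
#'   element.
#' @export
vienna_batch <- function(requests, python = getOption("mofold.python", "python")) {
  if (!vienna_available(python))
    stop("ViennaRNA python bindings not available (python executable '",
         python, "')")
  helper <- system.file("python", "vienna_helper.py", package = "mofold")
  if (helper == "") stop("vienna_helper.py not found in the installed package")
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(requests, infile, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2(python, shQuote(helper), stdout = TRUE, stderr = NULL,
            stdin = infile))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    stop("ViennaRNA helper failed (exit ", status, "): ",
         paste(utils::tail(out, 3), collapse = " | "))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

.vienna_one <- function(req) {
  res <- vienna_batch(list(req))[[1]]
  if (!is.null(res$error)) stop("ViennaRNA: ", res$error)
  res
}

# Structure-constraint rna_structure -> ViennaRNA constraint string:
# pairs as '()', explicitly unpaired positions as 'x', wildcards free.
.vienna_constraint <- function(constraint, n) {
  if (is.null(constraint)) return(NULL)
  if (is.character(constraint)) constraint <- parse_dotbracket(constraint)
  stopifnot(constraint$length == n)
  out <- rep("x", n)
  out[constraint$wildcard] <- "."
  p <- constraint$pairs
  if (nrow(p)) {
    if (has_pseudoknot(constraint))
      stop("ViennaRNA structure constraints cannot express crossing pairs")
    out[p[, 1]] <- "("
    out[p[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

# Property computation for the rnafold / rnaeval / findpath engines.
.vienna_method <- function(seq, m) {
  n <- nchar(seq)
  opts <- m$options
  base <- list(seq = seq,
               params = opts$params %||% "turner2004",
               dangles = opts$dangles %||% 2)
  con <- .vienna_constraint(m$str_constraint, n)
  props <- numeric(0)
  predicted <- NULL
  if (m$engine == "rnafold") {
    reqs <- list(c(base, list(op = "mfe", constraint = con)))
    need_pf <- any(c("EFE", "PB", "PF") %in% m$properties)
    if (need_pf) reqs <- c(reqs, list(c(base, list(op = "efe", constraint = con))))
    if ("FE" %in% m$properties)
      reqs <- c(reqs, list(c(base, list(op = "eval",
                                        structure = to_dotbracket(m$target)))))
    if ("PB" %in% m$properties)
      reqs <- c(reqs, list(c(base, list(op = "pb", constraint = con,
                                        structure = to_dotbracket(m$target)))))
    res <- vienna_batch(reqs)
    for (r in res) if (!is.null(r$error)) stop("ViennaRNA: ", r$error)
    mfe <- res[[1]]
    predicted <- parse_dotbracket(mfe$structure)
    props["MFE"] <- mfe$energy
    i <- 2
    if (need_pf) { props["EFE"] <- res[[i]]$efe; i <- i + 1 }
    if ("FE" %in% m$properties) { props["FE"] <- res[[i]]$energy; i <- i + 1 }
    if ("PB" %in% m$properties) props["PB"] <- res[[i]]$pb
    if ("SIM" %in% m$properties) props["SIM"] <- similarity(m$target, predicted)
    if ("PF" %in% m$properties) props["PF"] <- exp(-props[["EFE"]])
    if ("GCPAIR" %in% m$properties) {
      paired <- unique(as.vector(predicted$pairs))
      props["GCPAIR"] <- if (!length(paired)) 0 else
        -100 * sum(seq_to_codes(seq)[paired] %in% c(2L, 3L)) / length(paired)
    }
  } else if (m$engine == "rnaeval") {
    res <- .vienna_one(c(base, list(op = "eval",
                                    structure = to_dotbracket(m$target))))
    props["FE"] <- res$energy
  } else if (m$engine == "findpath") {
    if (isTRUE(opts$use_mfe)) {
      res <- vienna_batch(list(c(base, list(op = "mfe")),
                               c(base, list(op = "mfe", constraint = con))))
      for (r in res) if (!is.null(r$error)) stop("ViennaRNA: ", r$error)
      s1 <- res[[1]]$structure; s2 <- res[[2]]$structure
    } else {
      s1 <- to_dotbracket(m$target); s2 <- to_dotbracket(m$target2)
    }
    res <- .vienna_one(c(base, list(op = "findpath", s1 = s1, s2 = s2,
                                    width = opts$lookahead %||% 10)))
    props["BAR"] <- res$barrier
  }
  list(props = props, predicted = predicted)
}
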