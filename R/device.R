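# Worked example: a theophylline-responsive hammerhead-ribozyme ON-switch.
# The device couples the sTRSV hammerhead ribozyme to the theophylline
# aptamer (TCT8-4 core): without ligand it folds into the ribozyme-active
# conformation and self-cleaves; with ligand the aptamer domain folds into
# its bound conformation, the ribozyme's stem II is disrupted, and the
# transcript survives.  The ligand-bound (inactive) state is modelled as
# the MFE structure under a hard constraint fixing the aptamer domain:
# its P2 stem base pairs are enforced and its binding-core nucleotides are
# kept single-stranded (they are sequestered by the ligand).

#' Example RNA device: theophylline-aptamer ribozyme ON-switch
#'
#' Returns a 95-nt designed ON-switch sequence (hammerhead ribozyme +
#' theophylline aptamer, aptamer domain at nt 43-72) together with the
#' structure constraint that models its ligand-bound state: the aptamer P2
#' stem (pairs (50,62), (51,61), (52,60), (53,59), (54,58)) enforced, the
#' binding-core nucleotides 43-49 and 63-72 forced single-stranded, and all
#' positions outside the domain left free (wildcards).
#'
#' @return List with \code{seq} (the 95-nt sequence), \code{aptamer_domain}
#'   (nt range), and \code{constraint} (dot-bracket string with wildcards,
#'   usable as a structure constraint for [toy_mfe()] or the ViennaRNA
#'   adapters).
#' @export
device_example <- function() {
  seq <- paste0("GCUGUCUCUCUCUGUGCUUGAGGGACUGAUGAGAGUGUACCAA",
                "UACCAGCAUCGUCUUGAUGCCCUUGGCAG",
                "UGGUAUGGUGAAUUCGAAACAGC")
  stopifnot(nchar(seq) == 95)
  constraint <- paste0(strrep("*", 42),
                       ".......", "(((((", "...", ")))))", strrep(".", 10),
                       strrep("*", 23))
  stopifnot(nchar(constraint) == 95)
  list(seq = seq, aptamer_domain = c(43L, 72L), constraint = constraint)
}

#' Energy gap between the active and ligand-bound states of a device
#'
#' Computes, with ViennaRNA, the MFE structure of the sequence (the active,
#' ligand-free state) and the MFE structure under the aptamer-domain
#' constraint (the inactive, ligand-bound state), and returns the energy
#' difference \code{E(inactive) - E(active)} in kcal/mol — the quantity a
#' two-state switch design tunes via the objective
#' \code{F2 = |E(inactive) - E(active) - gap|}.
#'
#' @param seq device sequence.
#' @param constraint aptamer structure-constraint string (dot-bracket with
#'   wildcards), e.g. from [device_example()].
#' @param params energy parameter set, \code{"turner2004"} (default) or
#'   \code{"turner1999"}.
#' @param dangles dangling-end model (default 2).
#' @return List with \code{mfe} and \code{constrained} (each structure +
#'   energy) and \code{gap}.
#' @export
device_energy_gap <- function(seq, constraint,
                              params = "turner2004", dangles = 2) {
  base <- list(seq = seq, params = params, dangles = dangles)
  con <- .vienna_constraint(constraint, nchar(seq))
  res <- vienna_batch(list(c(base, list(op = "mfe")),
                           c(base, list(op = "mfe", constraint = con))))
  for (r in res) if (!is.null(r$error)) stop("ViennaRNA: ", r$error)
  list(mfe = res[[1]], constrained = res[[2]],
       gap = res[[2]]$energy - res[[1]]$energy)
}

#' Energy barrier between the two device states (findpath heuristic)
#'
#' Computes the two state structures as in [device_energy_gap()] and runs
#' the ViennaRNA findpath direct-path heuristic between them.  The result,
#' max energy along the best found path minus the energy of the start
#' (active MFE) structure, is an upper bound on the true saddle height.
#'
#' @inheritParams device_energy_gap
#' @param width findpath look-ahead (beam width), default 1000.
#' @return List with \code{barrier} (kcal/mol), \code{saddle}, and the two
#'   state structures.
#' @export
device_barrier <- function(seq, constraint, width = 1000,
                           params = "turner1999", dangles = 2) {
  base <- list(seq = seq, params = params, dangles = dangles)
  con <- .vienna_constraint(constraint, nchar(seq))
  res <- vienna_batch(list(c(base, list(op = "mfe")),
                           c(base, list(op = "mfe", constraint = con))))
  for (r in res) if (!is.null(r$error)) stop("ViennaRNA: ", r$error)
  s1 <- res[[1]]$structure; s2 <- res[[2]]$structure
  fp <- .vienna_one(c(base, list(op = "findpath", s1 = s1, s2 = s2,
                                 width = width)))
  list(barrier = fp$barrier, saddle = fp$saddle,
       active = res[[1]], inactive = res[[2]])
}
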