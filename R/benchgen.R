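# Benchmark dataset generation and design scoring for multistable design
# evaluation.

#' Score a set of designed sequences against the targets
#'
#' For each design, the target free energies \code{E(theta_i)} and the
#' ground-state (MFE) energy are computed; a design counts towards
#' \code{n1} when at least one target attains the ground-state energy and
#' towards \code{n2} ("completely multistable") when every target does.
#' \code{delta_e1}/\code{delta_e2} are the gaps between the ground state
#' and the lowest-/highest-energy target for a representative design: the
#' one with the lowest \code{delta_e2}, ties broken by the lowest
#' \code{delta_e1}.
#'
#' @param designs character vector of designed sequences.
#' @param targets a [target_set()].
#' @param engine \code{"toy"} or \code{"rnafold"}.
#' @param eps energy tie tolerance (default 1e-6).
#' @return List of class \code{"benchmark_record"}: \code{delta_e1},
#'   \code{delta_e2}, \code{n1}, \code{n2}, \code{n_designs}, \code{apsd},
#'   and the per-design gap table.
#' @export
score_designs <- function(designs, targets, engine = c("toy", "rnafold"),
                          eps = 1e-6) {
  engine <- match.arg(engine)
  if (!length(designs)) stop("empty design list")
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  per <- t(vapply(designs, function(s) {
    if (engine == "toy") {
      fe <- vapply(targets, function(t) toy_eval(s, t), numeric(1))
      mfe <- toy_mfe(s)$energy
    } else {
      reqs <- c(lapply(targets, function(t)
        list(op = "eval", seq = s, structure = to_dotbracket(t))),
        list(list(op = "mfe", seq = s)))
      res <- vienna_batch(reqs)
      for (r in res) if (!is.null(r$error)) stop("ViennaRNA: ", r$error)
      fe <- vapply(res[seq_along(targets)], `[[`, numeric(1), "energy")
      mfe <- res[[length(res)]]$energy
    }
    c(de1 = min(fe) - mfe, de2 = max(fe) - mfe)
  }, numeric(2)))
  n1 <- sum(per[, "de1"] <= eps)
  n2 <- sum(per[, "de2"] <= eps)
  rep_idx <- order(per[, "de2"], per[, "de1"])[1]
  structure(list(delta_e1 = per[rep_idx, "de1"],
                 delta_e2 = per[rep_idx, "de2"],
                 n1 = n1, n2 = n2, n_designs = length(designs),
                 apsd = if (attr(targets, "n_target") >= 2) apsd(targets) else NA_real_,
                 per_design = per),
            class = "benchmark_record")
}

#' @export
print.benchmark_record <- function(x, ...) {
  cat(sprintf("designs: %d | n1 = %d | n2 = %d | de1 = %.2f | de2 = %.2f",
              x$n_designs, x$n1, x$n2, x$delta_e1, x$delta_e2))
  if (!is.na(x$apsd)) cat(sprintf(" | APSD = %.2f", x$apsd))
  cat("\n")
  invisible(x)
}

#' Generate a random two-target benchmark set
#'
#' Rejection-samples random sequences, takes the two lowest-energy distinct
#' structures from the engine's suboptimal list, and accepts the pair when
#' (i) the bracket-string Hamming distance over the length is at least
#' \code{min_div} (avoids near-identical targets), and (ii) the fraction of
#' base-paired nucleotides over both structures is at least
#' \code{min_paired} (avoids mostly-unpaired targets).  A third criterion —
#' at least one pseudoknot in one structure — applies only to
#' pseudoknot-capable engines and is waived (and flagged) for the built-in
#' nested-only toy engine.
#'
#' @param length target length in nucleotides.
#' @param engine \code{"toy"} (suboptimals from the k-best DP).
#' @param min_div criterion (i) threshold (default 0.1).
#' @param min_paired criterion (ii) threshold (default 0.2).
#' @param require_pk criterion (iii); \code{NA} (default) = only when the
#'   engine supports pseudoknots.
#' @param max_attempts rejection-sampling cap.
#' @return A [target_set()] of two structures, with attribute
#'   \code{"pk_waived"} when criterion (iii) was inapplicable.
#' @export
gen_pk_target_set <- function(length, engine = "toy", min_div = 0.1,
                              min_paired = 0.2, require_pk = NA,
                              max_attempts = 1000) {
  stopifnot(engine == "toy")
  if (is.na(require_pk)) require_pk <- FALSE   # toy engine is nested-only
  for (att in seq_len(max_attempts)) {
    seq <- paste(sample(.NT, length, replace = TRUE), collapse = "")
    subs <- toy_subopt(seq, k = 2)
    if (length(subs) < 2) next
    s1 <- subs[[1]]$structure; s2 <- subs[[2]]$structure
    b1 <- to_dotbracket(s1); b2 <- to_dotbracket(s2)
    if (hamming_bracket(b1, b2) / length < min_div) next
    paired <- 2 * (nrow(s1$pairs) + nrow(s2$pairs))
    if (paired / (2 * length) < min_paired) next
    if (require_pk && !(has_pseudoknot(s1) || has_pseudoknot(s2))) next
    ts <- target_set(s1, s2)
    attr(ts, "pk_waived") <- !require_pk
    return(ts)
  }
  stop("no acceptable target pair found in ", max_attempts, " attempts")
}

#' Pair same-length structures into two-target sets
#'
#' Scans the input list in order; structure i is paired with the first
#' unused j > i of identical length whose bracket-string similarity
#' \code{(N - Hamming)/N} is below \code{max_sim}; both members are marked
#' and never reused.  Only structures with lengths in
#' \code{[min_len, max_len]} are considered.
#'
#' @param structures list of [rna_structure()] or dot-bracket strings.
#' @param max_sim similarity threshold (default 0.8).
#' @param min_len,max_len admissible length range (default 40-80).
#' @return List of [target_set()] pairs (possibly empty).
#' @export
pair_targets_le80 <- function(structures, max_sim = 0.8,
                              min_len = 40, max_len = 80) {
  brs <- vapply(structures, function(s)
    if (inherits(s, "rna_structure")) to_dotbracket(s) else s, character(1))
  lens <- nchar(brs)
  eligible <- lens >= min_len & lens <= max_len
  used <- rep(FALSE, length(brs))
  out <- list()
  for (i in seq_along(brs)) {
    if (used[i] || !eligible[i]) next
    for (j in seq_along(brs)) {
      if (j <= i || used[j] || !eligible[j] || lens[j] != lens[i]) next
      sim <- (lens[i] - hamming_bracket(brs[i], brs[j])) / lens[i]
      if (sim < max_sim) {
        out[[length(out) + 1L]] <- target_set(brs[i], brs[j])
        used[i] <- used[j] <- TRUE
        break
      }
    }
  }
  out
}

#' Average pairwise structure distance of a target set
#'
#' Mean over all target pairs of [structure_distance()] divided by the
#' length; 0 for identical targets, approaching 1 for maximally diverse
#' ones.
#'
#' @param targets a [target_set()] with at least two targets.
#' @return A fraction in \code{[0, 1]}.
#' @export
apsd <- function(targets) {
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  nt <- attr(targets, "n_target")
  if (nt < 2) stop("APSD needs at least two targets")
  n <- attr(targets, "n")
  combs <- utils::combn(nt, 2)
  mean(apply(combs, 2, function(ij)
    structure_distance(targets[[ij[1]]], targets[[ij[2]]]) / n))
}

#' Classify a design by total target Boltzmann probability
#'
#' Computes the sum over targets of their Boltzmann probabilities
#' \code{exp((G - E(theta_i))/kT)} and compares it with a threshold
#' (default 0.4, the customary cut for a "well-designed" multistable
#' sequence).
#'
#' @param design designed sequence.
#' @param targets a [target_set()].
#' @param engine \code{"toy"} or \code{"rnafold"}.
#' @param threshold classification threshold.
#' @return Logical, with attribute \code{"prob_sum"}.
#' @export
boltzmann_classification <- function(design, targets,
                                     engine = c("toy", "rnafold"),
                                     threshold = 0.4) {
  engine <- match.arg(engine)
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  if (engine == "toy") {
    g <- toy_ensemble(design)
    pb <- vapply(targets, function(t) exp(g - toy_eval(design, t)), numeric(1))
  } else {
    reqs <- lapply(targets, function(t)
      list(op = "pb", seq = design, structure = to_dotbracket(t)))
    res <- vienna_batch(reqs)
    for (r in res) if (!is.null(r$error)) stop("ViennaRNA: ", r$error)
    pb <- vapply(res, `[[`, numeric(1), "pb")
  }
  out <- sum(pb) >= threshold
  attr(out, "prob_sum") <- sum(pb)
  out
}
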