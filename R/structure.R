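#' @useDynLib mofold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames quantile
#' @importFrom utils head write.table
NULL

# Bracket alphabets for extended dot-bracket notation, in the order they are
# assigned when writing pseudoknotted structures.
.BRACKET_OPEN  <- c("(", "[", "{", "<")
.BRACKET_CLOSE <- c(")", "]", "}", ">")
.WILDCARD <- "*"

#' RNA secondary structure
#'
#' An RNA secondary structure is a set of base pairs \code{(i, j)} (1-based,
#' \code{i < j}) over positions \code{1..N}, with each position in at most one
#' pair.  Pairs from different bracket alphabets may cross, which is how
#' pseudoknots are represented.  Positions whose structure is deliberately
#' unspecified (wildcards, written \code{"*"}) are recorded in a mask and are
#' ignored when the structure is used as a comparison reference.
#'
#' @param pairs two-column integer matrix of base pairs (may have zero rows).
#' @param length sequence length \code{N}.
#' @param wildcard integer vector of positions with unspecified structure.
#' @return An object of class \code{"rna_structure"}: a list with elements
#'   \code{length}, \code{pairs} (ordered two-column matrix), \code{partner}
#'   (integer vector, 0 = unpaired) and \code{wildcard}.
#' @seealso [parse_dotbracket()], [to_dotbracket()]
#' @export
rna_structure <- function(pairs, length, wildcard = integer(0)) {
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    swap <- pairs[, 1] > pairs[, 2]
    if (any(swap)) pairs[swap, ] <- pairs[swap, c(2, 1)]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  n <- as.integer(length)
  if (n < 1L) stop("structure length must be positive")
  if (NROW(pairs) > 0) {
    if (any(pairs < 1L | pairs > n)) stop("pair index outside [1, N]")
    if (any(pairs[, 1] == pairs[, 2])) stop("a position cannot pair with itself")
    occ <- c(pairs[, 1], pairs[, 2])
    if (anyDuplicated(occ)) stop("a position occurs in more than one base pair")
  }
  partner <- integer(n)
  if (NROW(pairs) > 0) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  wildcard <- sort(unique(as.integer(wildcard)))
  if (length(wildcard) && any(wildcard < 1L | wildcard > n))
    stop("wildcard position outside [1, N]")
  structure(list(length = n, pairs = pairs, partner = partner,
                 wildcard = wildcard),
            class = "rna_structure")
}

#' Parse extended dot-bracket notation
#'
#' Accepts \code{'.'} for unpaired positions, up to four independent bracket
#' alphabets \code{() [] {} <>} (each must nest within itself; pairs of
#' different alphabets may cross, giving pseudoknots), and \code{'*'} for
#' positions whose structure is unspecified.
#'
#' @param text a single dot-bracket string.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("((..[[..))..]]")  # crossing pairs: an H-type pseudoknot
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) stop("empty dot-bracket string")
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ok <- ch %in% c(".", .WILDCARD, .BRACKET_OPEN, .BRACKET_CLOSE)
  if (!all(ok))
    stop(sprintf("invalid character '%s' at position %d", ch[which(!ok)[1]],
                 which(!ok)[1]))
  pairs <- matrix(integer(0), ncol = 2)
  for (a in seq_along(.BRACKET_OPEN)) {
    op <- .BRACKET_OPEN[a]; cl <- .BRACKET_CLOSE[a]
    stk <- integer(0)
    for (i in seq_len(n)) {
      if (ch[i] == op) {
        stk <- c(stk, i)
      } else if (ch[i] == cl) {
        if (!length(stk))
          stop(sprintf("unbalanced '%s' at position %d (alphabet '%s%s')",
                       cl, i, op, cl))
        pairs <- rbind(pairs, c(stk[length(stk)], i))
        stk <- stk[-length(stk)]
      }
    }
    if (length(stk))
      stop(sprintf("unbalanced '%s' at position %d (alphabet '%s%s')",
                   op, stk[length(stk)], op, cl))
  }
  rna_structure(pairs, n, wildcard = which(ch == .WILDCARD))
}

#' Write a structure back to dot-bracket notation
#'
#' Bracket alphabets are assigned greedily: each pair uses the first alphabet
#' in \code{() [] {} <>} order in which it does not cross an already-written
#' pair of the same alphabet.
#'
#' @param x an [rna_structure()].
#' @return A dot-bracket string.
#' @export
to_dotbracket <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  out <- rep(".", x$length)
  out[x$wildcard] <- .WILDCARD
  if (NROW(x$pairs) == 0) return(paste(out, collapse = ""))
  p <- x$pairs[order(x$pairs[, 1]), , drop = FALSE]
  placed <- vector("list", length(.BRACKET_OPEN))  # pairs per alphabet
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1]; j <- p[r, 2]
    for (a in seq_along(.BRACKET_OPEN)) {
      crosses <- FALSE
      pl <- placed[[a]]
      if (!is.null(pl) && nrow(pl)) {
        crosses <- any((pl[, 1] < i & i < pl[, 2] & pl[, 2] < j) |
                       (i < pl[, 1] & pl[, 1] < j & j < pl[, 2]))
      }
      if (!crosses) {
        placed[[a]] <- rbind(pl, c(i, j))
        out[i] <- .BRACKET_OPEN[a]; out[j] <- .BRACKET_CLOSE[a]
        break
      }
      if (a == length(.BRACKET_OPEN))
        stop("structure needs more than four mutually crossing bracket alphabets")
    }
  }
  paste(out, collapse = "")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure, N =", x$length, "\n")
  cat(" ", to_dotbracket(x), "\n")
  cat("  pairs:", nrow(x$pairs),
      if (has_pseudoknot(x)) "(pseudoknotted)" else "", "\n")
  invisible(x)
}

#' Does a structure contain crossing base pairs?
#'
#' @param x an [rna_structure()].
#' @return \code{TRUE} if any two pairs cross (pseudoknot).
#' @export
has_pseudoknot <- function(x) {
  p <- x$pairs
  if (nrow(p) < 2) return(FALSE)
  for (r in seq_len(nrow(p) - 1)) {
    i <- p[r, 1]; j <- p[r, 2]
    rest <- p[(r + 1):nrow(p), , drop = FALSE]
    if (any((rest[, 1] < i & i < rest[, 2] & rest[, 2] < j) |
            (i < rest[, 1] & rest[, 1] < j & j < rest[, 2])))
      return(TRUE)
  }
  FALSE
}

#' Ordered set of target structures
#'
#' All targets of a multi-target design problem must have the same length.
#'
#' @param ... [rna_structure()] objects or dot-bracket strings.
#' @return An object of class \code{"target_set"}: a list of structures with
#'   attributes \code{n} (common length) and \code{n_target}.
#' @export
target_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L) {
    if (is.list(xs[[1]]) && !inherits(xs[[1]], "rna_structure"))
      xs <- xs[[1]]
    else if (is.character(xs[[1]]) && length(xs[[1]]) > 1L)
      xs <- as.list(xs[[1]])
  }
  xs <- lapply(xs, function(t)
    if (inherits(t, "rna_structure")) t else parse_dotbracket(t))
  if (!length(xs)) stop("at least one target structure is required")
  lens <- vapply(xs, `[[`, integer(1), "length")
  if (length(unique(lens)) != 1L)
    stop("all target structures must have the same length (got ",
         paste(lens, collapse = ", "), ")")
  structure(xs, class = "target_set", n = lens[1], n_target = length(xs))
}

#' @export
print.target_set <- function(x, ...) {
  cat(attr(x, "n_target"), "target structure(s), N =", attr(x, "n"), "\n")
  for (t in x) cat(" ", to_dotbracket(t), "\n")
  invisible(x)
}

.check_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- strsplit(toupper(gsub("T", "U", seq)), "")[[1]]
  if (!length(s)) stop("empty sequence")
  if (!all(s %in% c("A", "C", "G", "U")))
    stop("sequence contains characters outside {A,C,G,U}")
  s
}

# canonical + wobble pairs, indexed A=1, C=2, G=3, U=4
.PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
.PAIRABLE["A", "U"] <- .PAIRABLE["U", "A"] <- TRUE
.PAIRABLE["G", "C"] <- .PAIRABLE["C", "G"] <- TRUE
.PAIRABLE["G", "U"] <- .PAIRABLE["U", "G"] <- TRUE

#' Can a sequence form every target base pair?
#'
#' A sequence is \emph{compatible} with a set of targets when every base pair
#' of every target can be realised as a canonical (AU, GC) or wobble (GU)
#' pair.  Compatibility is the invariant every individual of the genetic
#' algorithm maintains.
#'
#' @param seq RNA sequence (string over A/C/G/U).
#' @param targets a [target_set()], a single structure, or a dot-bracket
#'   string.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_compatible <- function(seq, targets) {
  if (!inherits(targets, "target_set")) targets <- target_set(targets)
  s <- .check_seq(seq)
  if (length(s) != attr(targets, "n"))
    stop("sequence length (", length(s), ") does not match target length (",
         attr(targets, "n"), ")")
  for (t in targets) {
    p <- t$pairs
    if (nrow(p) && !all(.PAIRABLE[cbind(s[p[, 1]], s[p[, 2]])]))
      return(FALSE)
  }
  TRUE
}

#' Base-pair structure distance
#'
#' The number of positions whose pairing partner differs between two
#' structures of equal length (partner = 0 when unpaired).  This partner-wise
#' count is alphabet-independent and therefore safe for pseudoknots.
#' Positions in the wildcard mask of \code{a} (the reference) are excluded.
#'
#' @param a,b [rna_structure()] objects or dot-bracket strings; \code{a} is
#'   treated as the reference whose wildcard mask applies.
#' @return Non-negative integer distance.
#' @export
structure_distance <- function(a, b) {
  if (!inherits(a, "rna_structure")) a <- parse_dotbracket(a)
  if (!inherits(b, "rna_structure")) b <- parse_dotbracket(b)
  if (a$length != b$length) stop("structures have different lengths")
  keep <- setdiff(seq_len(a$length), a$wildcard)
  sum(a$partner[keep] != b$partner[keep])
}

#' Structure similarity score
#'
#' \code{1 - d/N} where \code{d} is [structure_distance()] between the target
#' and a predicted structure and \code{N} the sequence length; 1 means the
#' structures agree at every non-wildcard position.
#'
#' @param target,predicted structures or dot-bracket strings.
#' @return A number in \code{[0, 1]}.
#' @export
similarity <- function(target, predicted) {
  if (!inherits(target, "rna_structure")) target <- parse_dotbracket(target)
  1 - structure_distance(target, predicted) / target$length
}

#' GC content of a sequence, in percent
#'
#' @param seq RNA sequence.
#' @return \code{100 * (#G + #C) / N}.
#' @export
gc_content <- function(seq) {
  s <- .check_seq(seq)
  100 * sum(s %in% c("G", "C")) / length(s)
}

#' Hamming distance between two bracket strings
#'
#' Character-wise count of differing positions.  Kept distinct from
#' [structure_distance()] because the benchmark-set selection criteria are
#' defined on the bracket notation itself.
#'
#' @param a,b equal-length strings.
#' @return Integer count.
#' @export
hamming_bracket <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) != nchar(b)) stop("strings have different lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
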