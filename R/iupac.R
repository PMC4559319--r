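# Nucleotide coding used throughout the internals: A=1, C=2, G=3, U=4.
.NT <- c("A", "C", "G", "U")

.PAIR_CODE <- matrix(FALSE, 4, 4)
.PAIR_CODE[1, 4] <- .PAIR_CODE[4, 1] <- TRUE  # AU
.PAIR_CODE[3, 2] <- .PAIR_CODE[2, 3] <- TRUE  # GC
.PAIR_CODE[3, 4] <- .PAIR_CODE[4, 3] <- TRUE  # GU wobble

.PURINE <- c(TRUE, FALSE, TRUE, FALSE)  # A, G

.IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

seq_to_codes <- function(seq) match(.check_seq(seq), .NT)
codes_to_seq <- function(codes) paste(.NT[codes], collapse = "")

#' Sequence constraint in the IUPAC nucleotide code
#'
#' Expands an IUPAC string into a 4 x N logical matrix of allowed nucleotides
#' (rows A, C, G, U).  \code{NULL} means unconstrained.
#'
#' @param iupac IUPAC string of length N, or \code{NULL}.
#' @param n sequence length (required when \code{iupac} is \code{NULL}).
#' @return A 4 x N logical matrix with rownames A, C, G, U.
#' @export
sequence_constraint <- function(iupac = NULL, n = NULL) {
  if (is.null(iupac)) {
    stopifnot(!is.null(n))
    m <- matrix(TRUE, 4, as.integer(n))
  } else {
    ch <- strsplit(toupper(iupac), "")[[1]]
    bad <- !(ch %in% names(.IUPAC))
    if (any(bad))
      stop(sprintf("invalid IUPAC code '%s' at position %d", ch[which(bad)[1]],
                   which(bad)[1]))
    m <- vapply(ch, function(c) .NT %in% .IUPAC[[c]], logical(4))
    m <- matrix(m, nrow = 4)
  }
  rownames(m) <- .NT
  if (any(colSums(m) == 0)) stop("constraint allows no nucleotide at some position")
  m
}

#' Does a sequence satisfy an IUPAC constraint?
#'
#' @param seq RNA sequence.
#' @param constraint 4 x N logical matrix from [sequence_constraint()], an
#'   IUPAC string, or \code{NULL} (always satisfied).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
satisfies_constraint <- function(seq, constraint) {
  if (is.null(constraint)) return(TRUE)
  if (is.character(constraint)) constraint <- sequence_constraint(constraint)
  codes <- seq_to_codes(seq)
  if (length(codes) != ncol(constraint)) stop("sequence/constraint length mismatch")
  all(constraint[cbind(codes, seq_along(codes))])
}
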