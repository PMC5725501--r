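# IUPAC degenerate-motif representation and both-strand genome scanning.

#' IUPAC nucleotide code table
#'
#' Mapping from each IUPAC degenerate nucleotide code to the set of
#' unambiguous bases it stands for. Note that genomic `N` in a *subject*
#' sequence is never matched by any code (including pattern `N`): an unknown
#' base cannot be asserted to be a perfect match to a consensus position.
#'
#' @format A named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' The gamma-proteobacterial BoxA consensus
#'
#' Returns the degenerate consensus `GYTCTTTAANA` (length 11) used to screen
#' genomes for putative BoxA antitermination elements. `Y` = C/T, `N` = any
#' base, so the consensus expands to 8 unambiguous 11-mers.
#'
#' @return An [iupac_pattern()] object.
#' @export
boxa_consensus <- function() iupac_pattern("GYTCTTTAANA")

#' Construct a degenerate DNA pattern
#'
#' @param pattern A string over the IUPAC nucleotide alphabet
#'   (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`). Lower case is accepted and upcased.
#' @return An object of class `iupac_pattern` with elements `pattern`,
#'   `length`, and `sets` (per-position allowed-base sets).
#' @examples
#' p <- iupac_pattern("GYTCTTTAANA")
#' p$length
#' @export
iupac_pattern <- function(pattern) {
  if (inherits(pattern, "iupac_pattern")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  pattern <- toupper(pattern)
  if (nchar(pattern) < 1L) stop("pattern must have length >= 1")
  codes <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(codes, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC code '%s' in pattern '%s'", bad[1L], pattern))
  }
  structure(
    list(pattern = pattern, length = length(codes),
         sets = IUPAC_CODES[codes]),
    class = "iupac_pattern"
  )
}

#' @export
print.iupac_pattern <- function(x, ...) {
  deg <- prod(lengths(x$sets))
  cat(sprintf("<iupac_pattern> %s (length %d, %d expansions)\n",
              x$pattern, x$length, deg))
  invisible(x)
}

#' Expand a degenerate pattern to all matching unambiguous sequences
#'
#' @param pattern A pattern string or [iupac_pattern()] object.
#' @return A sorted character vector of all A/C/G/T strings matching the
#'   pattern; its length is the product of the per-position degeneracies
#'   (8 for the BoxA consensus).
#' @examples
#' length(expand_iupac("GYTCTTTAANA")) # 8
#' @export
expand_iupac <- function(pattern) {
  p <- iupac_pattern(pattern)
  grid <- do.call(expand.grid,
                  c(rev(p$sets), list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Test a pattern match at one position
#'
#' Per-position set membership: position `pos` (0-based) of `seq` matches iff
#' every base lies in the allowed set of the corresponding pattern code.
#' A genomic `N` matches no code, including pattern `N`.
#'
#' @param seq A DNA string (A/C/G/T/N).
#' @param pos 0-based offset, `0 <= pos <= nchar(seq) - pattern length`.
#' @param pattern Pattern string or [iupac_pattern()].
#' @return `TRUE` or `FALSE`.
#' @export
matches_at <- function(seq, pos, pattern) {
  p <- iupac_pattern(pattern)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (pos < 0L || pos > nchar(seq) - p$length) {
    stop(sprintf("pos %d out of range for sequence of length %d and pattern length %d",
                 pos, nchar(seq), p$length))
  }
  bases <- strsplit(substr(seq, pos + 1L, pos + p$length), "", fixed = TRUE)[[1L]]
  all(vapply(seq_len(p$length),
             function(j) bases[j] %in% p$sets[[j]], logical(1L)))
}

# 0-based start offsets of all pattern matches on the forward strand of one
# sequence. Raw-vector membership per pattern position; linear in sequence
# length times pattern length.
.scan_forward <- function(seq, p) {
  L <- nchar(seq)
  k <- p$length
  if (L < k) return(integer(0))
  x <- charToRaw(seq)
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    allowed <- charToRaw(paste(p$sets[[j]], collapse = ""))
    ok <- ok & (x[j:(n_win + j - 1L)] %in% allowed)
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a genome for all occurrences of a degenerate pattern
#'
#' Reports every position/strand where the pattern matches exactly
#' (per-position IUPAC set membership; genomic `N` matches nothing).
#' Overlapping hits are all reported. Hits on the minus strand carry forward
#' genomic coordinates; `matched_seq` always reads 5'->3' on the hit strand,
#' i.e. for a minus-strand hit it is the reverse complement of the genomic
#' slice `[start0, end0)`.
#'
#' @param genome A [read_genome()] `Genome` object, or a named character
#'   vector of replicon sequences.
#' @param pattern Pattern string or [iupac_pattern()]; default the BoxA
#'   consensus `GYTCTTTAANA`.
#' @param strands Subset of `c("+","-")`; default both.
#' @return A data.frame with columns `replicon`, `start0`, `end0`
#'   (0-based half-open), `strand`, `matched_seq`, sorted by
#'   (`replicon`, `start0`, `strand`).
#' @examples
#' g <- list(genome_id = "g1",
#'           replicons = c(chr = "AAAGTTCTTTAATAAAA"))
#' class(g) <- "Genome"
#' scan_genome(g)
#' @export
scan_genome <- function(genome, pattern = boxa_consensus(),
                        strands = c("+", "-")) {
  p <- iupac_pattern(pattern)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  replicons <- if (inherits(genome, "Genome")) genome$replicons else genome
  if (is.null(names(replicons)) || anyNA(names(replicons))) {
    stop("replicon sequences must be named")
  }
  rows <- vector("list", 0L)
  for (rid in names(replicons)) {
    s <- replicons[[rid]]
    L <- nchar(s)
    if ("+" %in% strands) {
      st <- .scan_forward(s, p)
      if (length(st) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = rid, start0 = st, end0 = st + p$length, strand = "+",
          matched_seq = substring(s, st + 1L, st + p$length),
          stringsAsFactors = FALSE)
      }
    }
    if ("-" %in% strands) {
      rc <- .revcomp(s)
      st_rc <- .scan_forward(rc, p)
      if (length(st_rc) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = rid,
          start0 = L - (st_rc + p$length), end0 = L - st_rc, strand = "-",
          matched_seq = substring(rc, st_rc + 1L, st_rc + p$length),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(replicon = character(), start0 = integer(), end0 = integer(),
               strand = character(), matched_seq = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$replicon, out$start0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
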