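# Base-composition analysis for Rut (Rho utilization) localization. Rut
# sites are characteristically pyrimidine-rich (C+T) and G-poor; the module
# counts bases over printed 1-based inclusive intervals and slides a
# thresholded window along a sequence to flag Rut-like segments.

#' Base composition of a sequence interval
#'
#' Counts bases over a 1-based inclusive interval, matching the convention of
#' printed coordinates such as "positions 2-22". `N` (or any non-ACGT
#' character) is counted as `n_other`. Pyrimidines are C + T.
#'
#' @param seq A DNA string.
#' @param start_1based,end_1based Interval bounds, 1-based inclusive;
#'   defaults cover the whole sequence.
#' @return A list of class `composition_report` with `interval`, `length`,
#'   `n_A`, `n_C`, `n_G`, `n_T`, `n_other`, `n_pyrimidine`.
#' @examples
#' base_composition("CCTTGT", 1, 6)$n_pyrimidine # 5
#' @export
base_composition <- function(seq, start_1based = 1L, end_1based = nchar(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (start_1based < 1L || end_1based > n || start_1based > end_1based) {
    stop(sprintf("interval %d-%d out of bounds for sequence of length %d",
                 start_1based, end_1based, n))
  }
  bases <- strsplit(substr(seq, start_1based, end_1based), "", fixed = TRUE)[[1L]]
  cnt <- function(b) sum(bases == b)
  nA <- cnt("A"); nC <- cnt("C"); nG <- cnt("G"); nT <- cnt("T")
  structure(list(
    interval = c(start = as.integer(start_1based), end = as.integer(end_1based)),
    length = length(bases),
    n_A = nA, n_C = nC, n_G = nG, n_T = nT,
    n_other = length(bases) - (nA + nC + nG + nT),
    n_pyrimidine = nC + nT
  ), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf(
    "<composition_report> positions %d-%d (%d nt): %d pyrimidines (C=%d, T=%d), %d G, %d A, %d other\n",
    x$interval["start"], x$interval["end"], x$length,
    x$n_pyrimidine, x$n_C, x$n_T, x$n_G, x$n_A, x$n_other))
  invisible(x)
}

#' Scan a sequence for pyrimidine-rich, G-poor (Rut-like) windows
#'
#' Slides a window of `window` nt along the sequence and flags windows with
#' at least `min_pyrimidines` pyrimidines and at most `max_g` G residues.
#' The defaults (21 nt, >= 16 pyrimidines, <= 1 G) are calibrated so that a
#' 21-nt segment with 17 pyrimidines and one G — the composition of the
#' E. coli suhB 5' UTR positions 2-22 — passes. There is no published formal
#' Rut score; the thresholds are explicit configuration and are echoed in the
#' result.
#'
#' @param seq A DNA string.
#' @param window Window length in nt (default 21).
#' @param min_pyrimidines Minimum C+T count for a passing window (default 16).
#' @param max_g Maximum G count for a passing window (default 1).
#' @return A list of class `rut_scan`: `windows` (data.frame `start`, `end`
#'   1-based inclusive, `n_pyrimidine`, `n_G`, `passes`), `runs` (merged
#'   maximal intervals covered by passing windows), and `thresholds`.
#'   A window longer than the sequence yields an empty result with a warning.
#' @export
rut_candidate_windows <- function(seq, window = 21L, min_pyrimidines = 16L,
                                  max_g = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L, window >= 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  thresholds <- list(window = as.integer(window),
                     min_pyrimidines = as.integer(min_pyrimidines),
                     max_g = as.integer(max_g))
  empty <- structure(list(
    windows = data.frame(start = integer(), end = integer(),
                         n_pyrimidine = integer(), n_G = integer(),
                         passes = logical(), stringsAsFactors = FALSE),
    runs = data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE),
    thresholds = thresholds), class = "rut_scan")
  if (window > n) {
    warning(sprintf("window (%d) longer than sequence (%d): no windows scored",
                    window, n))
    return(empty)
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  # cumulative indicator sums give every window count in O(n)
  cpy <- cumsum(bases %in% c("C", "T"))
  cg <- cumsum(bases == "G")
  starts <- seq_len(n - window + 1L)
  ends <- starts + window - 1L
  wpy <- cpy[ends] - c(0L, cpy)[starts]
  wg <- cg[ends] - c(0L, cg)[starts]
  passes <- wpy >= min_pyrimidines & wg <= max_g
  windows <- data.frame(start = starts, end = ends,
                        n_pyrimidine = as.integer(wpy), n_G = as.integer(wg),
                        passes = passes, stringsAsFactors = FALSE)
  runs <- .merge_intervals(windows$start[passes], windows$end[passes])
  structure(list(windows = windows, runs = runs, thresholds = thresholds),
            class = "rut_scan")
}

# merge overlapping/adjacent 1-based inclusive intervals (inputs sorted by
# start, as produced by the window scan)
.merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  rs <- start[1L]; re <- end[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= re + 1L) {
      re <- max(re, end[i])
    } else {
      out_s <- c(out_s, rs); out_e <- c(out_e, re)
      rs <- start[i]; re <- end[i]
    }
  }
  data.frame(start = c(out_s, rs), end = c(out_e, re), stringsAsFactors = FALSE)
}

#' @export
print.rut_scan <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "<rut_scan> window=%d, min_pyrimidines=%d, max_g=%d: %d/%d windows pass, %d merged run(s)\n",
    th$window, th$min_pyrimidines, th$max_g,
    sum(x$windows$passes), nrow(x$windows), nrow(x$runs)))
  invisible(x)
}
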