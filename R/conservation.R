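# Per-column conservation of an upstream-region multiple alignment against a
# reference row. For each reference (non-gap) column the score is
# 100 * (n_match + 1) / n_rows: the number of non-reference rows matching the
# reference base, plus one for the reference itself, over the number of
# aligned sequences. With 19 non-reference species this is exactly the
# "+1, divide by 20" percentage plotted along the E. coli coordinate.

#' Construct an upstream-region alignment
#'
#' @param rows Named character vector of aligned sequences over
#'   `A,C,G,T,-` (case-insensitive; stored upper case), all the same length.
#' @param reference_id Name of the reference row (the sequence whose
#'   coordinates the conservation track follows).
#' @return An object of class `upstream_alignment`.
#' @export
alignment <- function(rows, reference_id) {
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == "")) {
    stop("alignment rows must be named")
  }
  if (anyDuplicated(names(rows))) stop("duplicate sequence id in alignment")
  if (length(rows) < 2L) stop("alignment needs at least 2 rows")
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1L) {
    stop("ragged alignment: rows differ in length")
  }
  bad <- grepl("[^ACGT-]", rows)
  if (any(bad)) {
    stop(sprintf("row '%s' contains characters outside {A,C,G,T,-}",
                 names(rows)[bad][1L]))
  }
  if (!reference_id %in% names(rows)) {
    stop(sprintf("reference id '%s' not present in alignment", reference_id))
  }
  structure(list(rows = rows, reference_id = reference_id,
                 n_rows = length(rows), width = nchar(rows[[1L]])),
            class = "upstream_alignment")
}

#' @export
print.upstream_alignment <- function(x, ...) {
  cat(sprintf("<upstream_alignment> %d rows x %d columns, reference '%s'\n",
              x$n_rows, x$width, x$reference_id))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA (equal-length rows, gaps as `-`).
#' @param reference_id Reference row id; default the first record.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(path, reference_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  rows <- as.character(seqs)
  names(rows) <- ids
  if (is.null(reference_id)) reference_id <- ids[1L]
  alignment(rows, reference_id)
}

#' Per-column percent match to the reference
#'
#' For every alignment column where the reference is not gapped:
#' `n_match` counts the non-reference rows whose character equals the
#' reference character (a gap never matches), and
#' `pct = 100 * (n_match + 1) / n_rows`, so the track is bounded in
#' `[100 / n_rows, 100]`. Columns where the reference is gapped are omitted
#' from the track and listed in the `ref_gap_columns` attribute.
#' Comparison is case-insensitive ([alignment()] upcases on construction).
#'
#' @param aln An [alignment()] object.
#' @return A data.frame (the conservation track) with columns `ref_pos`
#'   (1-based position along the ungapped reference), `column` (alignment
#'   column index), `ref_base`, `n_match`, `pct`; attribute
#'   `ref_gap_columns` holds the omitted column indices.
#' @export
column_match_percent <- function(aln) {
  stopifnot(inherits(aln, "upstream_alignment"))
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  ref <- m[aln$reference_id, ]
  others <- m[setdiff(rownames(m), aln$reference_id), , drop = FALSE]
  keep <- ref != "-"
  n_match <- colSums(others[, keep, drop = FALSE] ==
                       matrix(ref[keep], nrow = nrow(others),
                              ncol = sum(keep), byrow = TRUE))
  track <- data.frame(
    ref_pos = seq_len(sum(keep)),
    column = which(keep),
    ref_base = ref[keep],
    n_match = as.integer(n_match),
    pct = 100 * (n_match + 1) / aln$n_rows,
    stringsAsFactors = FALSE)
  rownames(track) <- NULL
  attr(track, "ref_gap_columns") <- which(!keep)
  attr(track, "n_rows") <- aln$n_rows
  track
}

#' Centered moving average of a conservation track
#'
#' Smooths `pct` with a centered window; positions near the edges use the
#' truncated window that fits. `window = 1` is the identity. Off by default
#' in all reports — provided only for plotting.
#'
#' @param track A conservation track from [column_match_percent()], or a
#'   plain numeric vector.
#' @param window Odd positive integer window width.
#' @return For a numeric input, the smoothed numeric vector; for a track, the
#'   track with an added `pct_smooth` column.
#' @export
windowed_mean <- function(track, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1L) {
    stop("window must be a positive integer")
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  smooth_vec <- function(v) {
    n <- length(v)
    half <- (window - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      mean(v[max(1L, i - half):min(n, i + half)])
    }, numeric(1L))
  }
  if (is.numeric(track)) return(smooth_vec(track))
  stopifnot(is.data.frame(track), "pct" %in% names(track))
  track$pct_smooth <- smooth_vec(track$pct)
  track
}
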