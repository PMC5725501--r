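# Genus-level collapse of per-genome hits: the bias control for the uneven
# distribution of sequenced genomes across genera. A gene function is
# credited to a genus once, however many species, strains or loci support it.

#' Normalize a gene-function label
#'
#' Function identity is the supplied label string after case-folding and
#' whitespace normalization; empty or missing labels map to `"unannotated"`.
#' No ontology reasoning is performed.
#'
#' @param x Character vector of labels.
#' @return Normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  x[is.na(x) | x == ""] <- "unannotated"
  x
}

.hit_labels <- function(upstream_hits, function_map) {
  if (!is.null(function_map)) {
    lbl <- function_map$function_label[
      match(upstream_hits$gene_id, function_map$gene_id)]
  } else if ("function_label" %in% names(upstream_hits)) {
    lbl <- upstream_hits$function_label
  } else {
    lbl <- rep("", nrow(upstream_hits))
  }
  normalize_label(lbl)
}

.hit_genera <- function(upstream_hits, metadata) {
  idx <- match(upstream_hits$genome_id, metadata$genome_id)
  if (anyNA(idx)) {
    stop(sprintf("hit genome '%s' absent from metadata",
                 upstream_hits$genome_id[is.na(idx)][1L]))
  }
  metadata$genus[idx]
}

#' Aggregate upstream hits to genus-level function presence
#'
#' One summary per distinct (normalized) function label: the number of genera
#' in which at least one species has at least one upstream hit on a gene with
#' that label. Operon-derived rows are excluded by default (the direct screen
#' defines function presence; the operon extension is reported separately).
#'
#' @param upstream_hits Output of [screen_genomes()] (optionally after
#'   [extend_to_operon()]).
#' @param metadata Metadata data.frame (`genome_id`, `species`, `genus`).
#' @param function_map Optional (`gene_id`, `function_label`) table
#'   overriding the labels carried by the hits.
#' @param include_operon Count operon-derived flagged rows too
#'   (default `FALSE`).
#' @return A data.frame sorted by descending `n_genera` then label, with
#'   columns `function_label`, `n_genera`, `genera` (list column of genus
#'   names) and `example_genes` (list column of up to 5 `genome_id:gene_id`
#'   strings).
#' @export
aggregate_by_genus <- function(upstream_hits, metadata, function_map = NULL,
                               include_operon = FALSE) {
  stopifnot(is.data.frame(upstream_hits), is.data.frame(metadata))
  h <- upstream_hits
  if (!include_operon && "operon_flag" %in% names(h)) {
    h <- h[!h$operon_flag, , drop = FALSE]
  }
  if (nrow(h) == 0L) {
    return(data.frame(function_label = character(), n_genera = integer(),
                      genera = I(list()), example_genes = I(list()),
                      stringsAsFactors = FALSE))
  }
  lab <- .hit_labels(h, function_map)
  gen <- .hit_genera(h, metadata)
  sp <- split(seq_len(nrow(h)), lab)
  out <- lapply(names(sp), function(l) {
    i <- sp[[l]]
    genera <- sort(unique(gen[i]))
    ex <- unique(paste0(h$genome_id[i], ":", h$gene_id[i]))
    data.frame(function_label = l, n_genera = length(genera),
               genera = I(list(genera)),
               example_genes = I(list(utils::head(ex, 5L))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$n_genera, out$function_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genus coverage of one target function
#'
#' How many genera contain at least one species with an upstream hit on a
#' gene carrying `target_label`, out of all genera present in the metadata
#' (genera with no screened genome are not in the denominator because they
#' are not in the metadata).
#'
#' @inheritParams aggregate_by_genus
#' @param target_label Function label of interest (normalized before
#'   comparison), e.g. `"suhB"`.
#' @return A list `n_genera_with_hit`, `n_genera_total`.
#' @export
genus_coverage <- function(upstream_hits, metadata, target_label,
                           function_map = NULL, include_operon = FALSE) {
  stopifnot(length(target_label) == 1L)
  total <- length(unique(metadata$genus))
  h <- upstream_hits
  if (!include_operon && "operon_flag" %in% names(h)) {
    h <- h[!h$operon_flag, , drop = FALSE]
  }
  if (nrow(h) == 0L) {
    return(list(n_genera_with_hit = 0L, n_genera_total = total))
  }
  lab <- .hit_labels(h, function_map)
  gen <- .hit_genera(h, metadata)
  hitters <- unique(gen[lab == normalize_label(target_label)])
  list(n_genera_with_hit = length(hitters), n_genera_total = total)
}
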