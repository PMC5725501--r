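# Reading genomes (FASTA), annotations (GFF3) and tabular metadata into the
# internal data model, and writing all tabular outputs.
#
# Convention: internal coordinates are 0-based half-open everywhere
# (`start0`, `end0`); conversion to/from the 1-based inclusive coordinates of
# GFF3 and printed reports happens only at I/O boundaries.

#' Construct a Genome object
#'
#' @param genome_id Identifier for the genome.
#' @param replicons Named character vector of replicon sequences
#'   (A/C/G/T/N, upper case).
#' @return An object of class `Genome`: a list with `genome_id` and
#'   `replicons`.
#' @export
new_genome <- function(genome_id, replicons) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (length(replicons) == 0L) stop("genome has no replicons")
  ids <- names(replicons)
  if (is.null(ids) || any(ids == "") || anyNA(ids)) {
    stop("every replicon needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate replicon id '%s' in genome '%s'",
                 ids[duplicated(ids)][1L], genome_id))
  }
  if (any(nchar(replicons) == 0L)) {
    stop(sprintf("empty sequence for replicon '%s'",
                 ids[nchar(replicons) == 0L][1L]))
  }
  bad <- grepl("[^ACGTN]", replicons)
  if (any(bad)) {
    stop(sprintf("replicon '%s' contains characters outside {A,C,G,T,N}",
                 ids[bad][1L]))
  }
  structure(list(genome_id = genome_id, replicons = replicons),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome> %s: %d replicon(s), %s bp total\n", x$genome_id,
              length(x$replicons),
              format(sum(nchar(x$replicons)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' One replicon per FASTA record; the header token before the first
#' whitespace is the replicon id. Sequences are upper-cased and `U` is
#' normalized to `T`; any residue outside `{A,C,G,T,N}` is an error naming
#' the offending record.
#'
#' @param fasta_path Path to a FASTA file.
#' @param genome_id Genome identifier; default the file name without
#'   extension.
#' @return A `Genome` object.
#' @export
read_genome <- function(fasta_path,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  if (!file.exists(fasta_path)) stop(sprintf("no such file: %s", fasta_path))
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop(sprintf("empty FASTA file: %s", fasta_path))
  ids <- sub("\\s.*$", "", names(seqs))
  s <- chartr("u", "t", as.character(seqs))
  s <- chartr("U", "T", toupper(s))
  names(s) <- ids
  new_genome(genome_id, s)
}

#' Write a genome to FASTA
#'
#' @param genome A `Genome` object.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "Genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$replicons), path, width = 70L)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Extracts protein-coding gene records from a GFF3 file. CDS features are
#' used when present (grouped by gene id, so a multi-CDS gene yields one
#' record spanning its extremes); otherwise `gene` features are used.
#' GFF3 1-based inclusive coordinates become 0-based half-open. The
#' translational start of a record is its leftmost coordinate on `+` and the
#' base before its rightmost coordinate on `-` (see [gene_start0()]).
#'
#' @param gff3_path Path to a GFF3 file.
#' @param genome `Genome` the annotations refer to; seqids must name its
#'   replicons and features must fit inside them.
#' @param function_attribute Attribute key supplying the function label
#'   (default `"product"`, falling back to the gene name, then `""`). The
#'   annotation source defines function granularity, so this is
#'   configuration, not a fixed rule.
#' @return A data.frame of gene records with columns `gene_id`, `replicon`,
#'   `start0`, `end0`, `strand`, `function_label`.
#' @export
read_annotations <- function(gff3_path, genome, function_attribute = "product") {
  stopifnot(inherits(genome, "Genome"))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  if (length(gr) == 0L) stop(sprintf("no CDS or gene features in %s", gff3_path))
  mc <- S4Vectors::mcols(gr)
  pick_attr <- function(key) {
    if (!key %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[key]]
    if (is(v, "CharacterList") || is.list(v)) {
      v <- vapply(v, function(x) if (length(x) > 0L) x[[1L]] else NA_character_,
                  character(1L))
    }
    as.character(v)
  }
  gene_id <- pick_attr("ID")
  for (alt in c("Parent", "locus_tag", "gene", "Name")) {
    miss <- is.na(gene_id)
    if (!any(miss)) break
    gene_id[miss] <- pick_attr(alt)[miss]
  }
  gene_id[is.na(gene_id)] <- paste0("feature_", which(is.na(gene_id)))
  fun <- pick_attr(function_attribute)
  fun[is.na(fun)] <- pick_attr("gene")[is.na(fun)]
  fun[is.na(fun)] <- ""
  df <- data.frame(
    gene_id = gene_id,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    function_label = fun,
    stringsAsFactors = FALSE)
  # collapse multi-CDS genes: span of all parts, translational extremes
  if (anyDuplicated(df$gene_id)) {
    sp <- split(df, df$gene_id)
    df <- do.call(rbind, lapply(sp, function(d) {
      d$start0[1L] <- min(d$start0); d$end0[1L] <- max(d$end0); d[1L, ]
    }))
    rownames(df) <- NULL
  }
  bad_rep <- !df$replicon %in% names(genome$replicons)
  if (any(bad_rep)) {
    stop(sprintf("seqid '%s' (gene '%s') not present in genome '%s'",
                 df$replicon[bad_rep][1L], df$gene_id[bad_rep][1L],
                 genome$genome_id))
  }
  lens <- nchar(genome$replicons)[df$replicon]
  oob <- df$start0 < 0L | df$end0 > lens | df$start0 >= df$end0
  if (any(oob)) {
    stop(sprintf("feature '%s' out of bounds for replicon '%s'",
                 df$gene_id[oob][1L], df$replicon[oob][1L]))
  }
  short <- (df$end0 - df$start0) < 3L
  if (any(short)) {
    stop(sprintf("CDS '%s' is shorter than one codon", df$gene_id[short][1L]))
  }
  unstranded <- !df$strand %in% c("+", "-")
  if (any(unstranded)) {
    stop(sprintf("gene '%s' must have strand '+' or '-'",
                 df$gene_id[unstranded][1L]))
  }
  df <- df[order(df$replicon, df$start0), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' 0-based coordinate of a gene's translational start
#'
#' The first base of the annotated start codon: `start0` for a `+` strand
#' gene, `end0 - 1` for a `-` strand gene.
#'
#' @param genes A gene-record data.frame.
#' @return Integer vector of 0-based positions.
#' @export
gene_start0 <- function(genes) {
  ifelse(genes$strand == "+", genes$start0, genes$end0 - 1L)
}

#' Write gene records to GFF3
#'
#' Emits one CDS feature per record with `ID` and `product` attributes,
#' converting internal 0-based half-open coordinates back to GFF3's 1-based
#' inclusive convention.
#'
#' @param genes Gene-record data.frame as from [read_annotations()].
#' @param path Output path.
#' @export
write_annotations_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start0 + 1L, end = genes$end0),
    strand = genes$strand)
  gr$source <- "boxascan"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$product <- genes$function_label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read the genome metadata table
#'
#' Tab-separated with columns `genome_id`, `species`, `genus`. Genome ids
#' must be unique and every genus non-empty.
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species", "genus")
  if (!all(need %in% names(md))) {
    stop(sprintf("metadata must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(md$genome_id)) {
    stop(sprintf("duplicate genome_id '%s' in metadata",
                 md$genome_id[duplicated(md$genome_id)][1L]))
  }
  if (any(is.na(md$genus) | md$genus == "")) stop("every genus must be non-empty")
  md
}

#' Read the gene-function mapping table
#'
#' Tab-separated with columns `gene_id`, `function_label` (COG-style labels
#' or product names; the label source is configuration).
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_function_map <- function(path) {
  fm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "function_label") %in% names(fm))) {
    stop("function map must have columns gene_id, function_label")
  }
  fm
}

#' Write a records table as TSV
#'
#' Tab-separated with a header row, no quoting. Rows are stably sorted by
#' whichever of `genome_id`, `replicon`, `motif_start0`/`start0` are present,
#' so identical inputs give byte-identical files. List columns are collapsed
#' with commas.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, character(1L), collapse = ",")
    }
  }
  keys <- intersect(c("genome_id", "replicon", "motif_start0", "start0",
                      "gene_id", "strand"), names(df))
  if (length(keys) > 0L && nrow(df) > 1L) {
    df <- df[do.call(order, df[keys]), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop(sprintf("cannot write table to '%s': %s",
                                      path, conditionMessage(e))))
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
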