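# Independent brute-force oracles and small fixture builders.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1L]]])), collapse = "")
}

# Brute-force scan: enumerate every k-mer on both strands and test set
# membership in the full pattern expansion. Independent of .scan_forward.
oracle_scan <- function(seq, pattern = "GYTCTTTAANA", replicon = "chr") {
  words <- expand_iupac(pattern)
  k <- nchar(words[1L])
  L <- nchar(seq)
  if (L < k) {
    return(data.frame(replicon = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  subs <- substring(seq, 1:(L - k + 1L), k:L)
  fw <- which(subs %in% words) - 1L
  rc_subs <- vapply(subs, revcomp_chr, character(1L), USE.NAMES = FALSE)
  rv <- which(rc_subs %in% words) - 1L
  out <- rbind(
    if (length(fw) > 0L) data.frame(replicon = replicon, start0 = fw,
                                    end0 = fw + k, strand = "+",
                                    matched_seq = subs[fw + 1L],
                                    stringsAsFactors = FALSE),
    if (length(rv) > 0L) data.frame(replicon = replicon, start0 = rv,
                                    end0 = rv + k, strand = "-",
                                    matched_seq = rc_subs[rv + 1L],
                                    stringsAsFactors = FALSE))
  if (is.null(out)) {
    return(data.frame(replicon = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$replicon, out$start0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force screen: every (motif, gene) pair, distance predicate applied
# directly. Independent of screen_genome's per-gene vectorization.
oracle_screen <- function(genome, genes, pattern = "GYTCTTTAANA",
                          distance_nt = 50L, mode = "containment",
                          same_strand_only = TRUE) {
  k <- nchar(iupac_pattern(pattern)$pattern)
  hits <- do.call(rbind, lapply(names(genome$replicons), function(rid) {
    oracle_scan(genome$replicons[[rid]], pattern, rid)
  }))
  pairs <- list()
  if (!is.null(hits) && nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      for (j in seq_len(nrow(genes))) {
        h <- hits[i, ]; g <- genes[j, ]
        if (h$replicon != g$replicon) next
        if (same_strand_only && h$strand != g$strand) next
        gap <- if (g$strand == "+") g$start0 - h$end0 else h$start0 - g$end0
        if (is.na(gap) || gap < 0L) next
        limit <- if (mode == "containment") distance_nt - k else distance_nt
        if (gap > limit) next
        pairs[[length(pairs) + 1L]] <-
          data.frame(replicon = h$replicon, motif_start0 = h$start0,
                     strand = h$strand, gene_id = g$gene_id, gap_nt = gap,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(replicon = character(), motif_start0 = integer(),
                      strand = character(), gene_id = character(),
                      gap_nt = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  out <- out[order(out$replicon, out$motif_start0, out$strand, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# A tiny genome with one gene and one motif planted at a chosen gap.
planted_genome <- function(gap, strand = "+", gene_len = 300L,
                           word = "GTTCTTTAATA", flank = 200L,
                           genome_id = "tg") {
  total <- 2L * flank + gene_len
  bases <- strsplit(strrep("A", total), "", fixed = TRUE)[[1L]]
  bases[seq(2, total, by = 2)] <- "C"  # no spurious consensus matches
  s <- flank
  if (strand == "+") {
    bases[(s + 1):(s + 3)] <- c("A", "T", "G")
    bases[(s + gene_len - 2):(s + gene_len)] <- c("T", "A", "A")
    m_start <- s - gap - nchar(word)
    bases[(m_start + 1):(m_start + nchar(word))] <-
      strsplit(word, "", fixed = TRUE)[[1L]]
  } else {
    bases[(s + 1):(s + 3)] <- c("T", "T", "A")
    bases[(s + gene_len - 2):(s + gene_len)] <- c("C", "A", "T")
    m_start <- s + gene_len + gap
    bases[(m_start + 1):(m_start + nchar(word))] <-
      strsplit(revcomp_chr(word), "", fixed = TRUE)[[1L]]
  }
  genome <- new_genome(genome_id, stats::setNames(paste(bases, collapse = ""), "chr"))
  genes <- data.frame(gene_id = "gene1", replicon = "chr",
                      start0 = s, end0 = s + gene_len, strand = strand,
                      function_label = "suhB", stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, motif_start0 = m_start)
}
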