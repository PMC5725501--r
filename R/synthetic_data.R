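# Synthetic annotated genomes with planted ground truth. The generator
# emulates the screened population: bacterial genomes with annotated
# single-CDS genes, BoxA consensus matches planted at controlled gaps on the
# gene's strand, and one-mismatch decoys that must never be reported.
# Everything is reproducible from one master seed via per-genome substreams,
# so adding a genome never perturbs earlier genomes.

#' Simulation configuration
#'
#' Defaults describe one desk-scale study population: 20 genera of 5 genomes
#' each (100 genomes), one 50-kb replicon per genome at GC 0.5, 20
#' single-CDS genes per genome, 1-7 planted consensus matches per genome at
#' gaps 0-39 nt from the start codon (so each lies wholly inside the 50-nt
#' upstream window), and 3 one-mismatch decoys per genome placed in windows
#' of non-target genes.
#'
#' @param seed Master seed (integer).
#' @param genera_plan Named integer vector: genus name -> number of genomes.
#' @param replicon_length Length of the single replicon per genome (nt).
#' @param gc GC content of the background sequence, in (0, 1).
#' @param n_genes Genes per genome.
#' @param gene_length_range Min/max CDS length (nt; rounded to codons).
#' @param n_motifs_range Min/max planted motifs per genome (drawn uniformly).
#' @param gap_range Min/max gap (nt) between a planted element's 3' end and
#'   the start codon.
#' @param n_decoys One-mismatch decoys per genome.
#' @param pattern The consensus to plant; default [boxa_consensus()].
#' @param planted_labels Function labels cycled over a genome's motif target
#'   genes (the first target in every genome gets the first label).
#' @param background_label Function label of all other genes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genera_plan = stats::setNames(rep(5L, 20L),
                                                     sprintf("Genus%02d", 1:20)),
                       replicon_length = 50000L,
                       gc = 0.5,
                       n_genes = 20L,
                       gene_length_range = c(300L, 900L),
                       n_motifs_range = c(1L, 7L),
                       gap_range = c(0L, 39L),
                       n_decoys = 3L,
                       pattern = boxa_consensus(),
                       planted_labels = c("suhB", "prsA", "rpsJ",
                                          "ParE-like toxin", "ribH"),
                       background_label = "hypothetical protein") {
  p <- iupac_pattern(pattern)
  stopifnot(gc > 0, gc < 1, n_genes >= 1L, n_decoys >= 0L,
            length(gene_length_range) == 2L, length(n_motifs_range) == 2L,
            length(gap_range) == 2L, gap_range[1L] >= 0L,
            n_motifs_range[1L] >= 0L,
            n_motifs_range[2L] + n_decoys <= n_genes,
            all(names(genera_plan) != ""), all(genera_plan >= 1L))
  margin <- max(as.integer(gap_range[2L]) + p$length, 60L) + 50L
  slot <- as.integer(replicon_length) %/% as.integer(n_genes)
  if (slot < gene_length_range[2L] + 2L * margin) {
    stop(sprintf(paste0(
      "infeasible placement: replicon_length/n_genes = %d nt per gene slot, ",
      "but max gene length %d plus 2 x %d nt flanks is required"),
      slot, gene_length_range[2L], margin))
  }
  structure(list(
    seed = as.integer(seed), genera_plan = genera_plan,
    replicon_length = as.integer(replicon_length), gc = gc,
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_motifs_range = as.integer(n_motifs_range),
    gap_range = as.integer(gap_range), n_decoys = as.integer(n_decoys),
    pattern = p, planted_labels = planted_labels,
    background_label = background_label, margin = margin, slot = slot
  ), class = "sim_config")
}

# deterministic per-genome substream seed below 2^31
.sub_seed <- function(seed, i) {
  s0 <- seed %% 2147483647
  as.integer((s0 * 1009 + i * 7919) %% 2147483646) + 1L
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# one-mismatch decoy: a concrete expansion with one non-N consensus position
# mutated to a base outside that position's allowed set
.make_decoy <- function(p, expansions) {
  word <- strsplit(sample(expansions, 1L), "", fixed = TRUE)[[1L]]
  mutable <- which(lengths(p$sets) < 4L)
  pos <- if (length(mutable) == 1L) mutable else sample(mutable, 1L)
  forbidden <- setdiff(c("A", "C", "G", "T"), p$sets[[pos]])
  word[pos] <- if (length(forbidden) == 1L) forbidden else sample(forbidden, 1L)
  paste(word, collapse = "")
}

.simulate_one_genome <- function(config, genome_id, replicon_id, sub_seed) {
  set.seed(sub_seed)
  p <- config$pattern
  L <- config$replicon_length
  expansions <- expand_iupac(p)
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
             (1 - config$gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs)

  # non-overlapping genes, one per slot, flanks >= margin on both sides
  n <- config$n_genes
  codon_range <- floor(config$gene_length_range / 3)
  genes <- data.frame(gene_id = sprintf("%s_g%02d", genome_id, seq_len(n)),
                      replicon = replicon_id,
                      start0 = NA_integer_, end0 = NA_integer_,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      function_label = config$background_label,
                      stringsAsFactors = FALSE)
  for (g in seq_len(n)) {
    slot_start <- (g - 1L) * config$slot
    len <- 3L * sample(seq(codon_range[1L], codon_range[2L]), 1L)
    free <- config$slot - len - 2L * config$margin
    off <- if (free > 0L) sample(0:free, 1L) else 0L
    s <- slot_start + config$margin + off
    genes$start0[g] <- s
    genes$end0[g] <- s + len
    if (genes$strand[g] == "+") {
      bases[(s + 1L):(s + 3L)] <- c("A", "T", "G")
      bases[(s + len - 2L):(s + len)] <- c("T", "A", "A")
    } else {
      bases[(s + 1L):(s + 3L)] <- c("T", "T", "A")
      bases[(s + len - 2L):(s + len)] <- c("C", "A", "T")
    }
  }

  n_motifs <- if (config$n_motifs_range[1L] == config$n_motifs_range[2L]) {
    config$n_motifs_range[1L]
  } else {
    sample(seq(config$n_motifs_range[1L], config$n_motifs_range[2L]), 1L)
  }
  targets <- if (n_motifs > 0L) sort(sample.int(n, n_motifs)) else integer(0)
  decoy_pool <- setdiff(seq_len(n), targets)
  decoys <- if (config$n_decoys > 0L) {
    sort(sample(decoy_pool, config$n_decoys))
  } else integer(0)

  plant <- function(gene_row, word, gap) {
    # place `word` (read 5'->3' on the gene's strand) ending `gap` nt before
    # the start codon; returns the genomic interval
    k <- nchar(word)
    w <- strsplit(word, "", fixed = TRUE)[[1L]]
    if (gene_row$strand == "+") {
      m_start <- gene_row$start0 - gap - k
      bases[(m_start + 1L):(m_start + k)] <<- w
    } else {
      m_start <- gene_row$end0 + gap
      bases[(m_start + 1L):(m_start + k)] <<- rev(unname(.complement[w]))
    }
    c(m_start, m_start + k)
  }

  truth <- vector("list", length(targets) + length(decoys))
  ti <- 0L
  for (j in seq_along(targets)) {
    g <- targets[j]
    gap <- sample(seq(config$gap_range[1L], config$gap_range[2L]), 1L)
    word <- sample(expansions, 1L)
    iv <- plant(genes[g, ], word, gap)
    genes$function_label[g] <-
      config$planted_labels[(j - 1L) %% length(config$planted_labels) + 1L]
    ti <- ti + 1L
    truth[[ti]] <- data.frame(
      genome_id = genome_id, replicon = replicon_id,
      start0 = iv[1L], end0 = iv[2L], strand = genes$strand[g],
      kind = "motif", gene_id = genes$gene_id[g], gap_nt = gap,
      planted_seq = word, stringsAsFactors = FALSE)
  }
  for (g in decoys) {
    gap <- sample(seq(config$gap_range[1L], config$gap_range[2L]), 1L)
    word <- .make_decoy(p, expansions)
    iv <- plant(genes[g, ], word, gap)
    ti <- ti + 1L
    truth[[ti]] <- data.frame(
      genome_id = genome_id, replicon = replicon_id,
      start0 = iv[1L], end0 = iv[2L], strand = genes$strand[g],
      kind = "decoy", gene_id = genes$gene_id[g], gap_nt = gap,
      planted_seq = word, stringsAsFactors = FALSE)
  }

  seqs <- paste(bases, collapse = "")
  names(seqs) <- replicon_id
  list(genome = new_genome(genome_id, seqs), genes = genes,
       truth = do.call(rbind, truth))
}

# consecutive same-strand genes grouped into operons of at most 3 members
.build_operons <- function(genes) {
  n <- nrow(genes)
  op <- integer(n); rank <- integer(n)
  cur <- 0L; r <- 0L
  for (i in seq_len(n)) {
    new_run <- i == 1L || genes$strand[i] != genes$strand[i - 1L] || r >= 3L
    if (new_run) { cur <- cur + 1L; r <- 0L }
    r <- r + 1L
    op[i] <- cur; rank[i] <- r
  }
  data.frame(gene_id = genes$gene_id,
             operon_id = sprintf("%s_op%02d",
                                 sub("_g[0-9]+$", "", genes$gene_id), op),
             rank = rank, stringsAsFactors = FALSE)
}

#' Simulate a population of annotated genomes with planted truth
#'
#' Generates, per genome: an i.i.d. background sequence at the configured GC
#' content; non-overlapping single-CDS genes on random strands with start and
#' stop codons written into the sequence; planted consensus matches — each a
#' uniformly chosen member of `expand_iupac(pattern)` written at the
#' configured gap on the gene's strand — and one-mismatch decoys that violate
#' the consensus at one position. Spontaneous background matches can occur in
#' addition to the planted ones; ground truth for recovery testing is the
#' truth table (planted elements), while the full match set is defined by
#' rescanning the emitted sequence.
#'
#' @param config A [sim_config()].
#' @return A list of class `boxa_simulation`: `genomes` (named list of
#'   `Genome`), `annotations` (named list of gene-record data.frames),
#'   `metadata`, `function_map`, `operons`, `truth` (the planted-element
#'   table), and `config`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genera <- rep(names(config$genera_plan), config$genera_plan)
  n_genomes <- length(genera)
  genome_ids <- sprintf("G%03d", seq_len(n_genomes))
  within <- stats::ave(seq_len(n_genomes), genera, FUN = seq_along)
  species <- sprintf("%s sp%02d", genera, within)

  genomes <- vector("list", n_genomes)
  annotations <- vector("list", n_genomes)
  truths <- vector("list", n_genomes)
  operons <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    one <- .simulate_one_genome(config, genome_ids[i],
                                paste0(genome_ids[i], "_chr"),
                                .sub_seed(config$seed, i))
    genomes[[i]] <- one$genome
    annotations[[i]] <- one$genes
    truths[[i]] <- one$truth
    operons[[i]] <- .build_operons(one$genes)
  }
  names(genomes) <- genome_ids
  names(annotations) <- genome_ids
  truth <- do.call(rbind, truths[!vapply(truths, is.null, logical(1L))])
  if (is.null(truth)) {
    truth <- data.frame(genome_id = character(), replicon = character(),
                        start0 = integer(), end0 = integer(),
                        strand = character(), kind = character(),
                        gene_id = character(), gap_nt = integer(),
                        planted_seq = character(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  function_map <- do.call(rbind, lapply(annotations, function(a) {
    a[, c("gene_id", "function_label")]
  }))
  rownames(function_map) <- NULL
  structure(list(
    genomes = genomes, annotations = annotations,
    metadata = data.frame(genome_id = genome_ids, species = species,
                          genus = genera, stringsAsFactors = FALSE),
    function_map = function_map,
    operons = do.call(rbind, operons),
    truth = truth, config = config
  ), class = "boxa_simulation")
}

#' @export
print.boxa_simulation <- function(x, ...) {
  cat(sprintf(
    "<boxa_simulation> %d genomes in %d genera; %d planted motifs, %d decoys\n",
    length(x$genomes), length(unique(x$metadata$genus)),
    sum(x$truth$kind == "motif"), sum(x$truth$kind == "decoy")))
  invisible(x)
}

#' Write a simulation to disk in standard formats
#'
#' Emits per-genome FASTA and GFF3 plus the metadata, function-map, operon
#' and truth TSVs — the same dialects the pipeline reads for real data.
#'
#' @param sim A [simulate_genomes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "boxa_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(sim$genomes)) {
    write_genome_fasta(sim$genomes[[gid]], file.path(dir, paste0(gid, ".fa")))
    write_annotations_gff3(sim$annotations[[gid]],
                           file.path(dir, paste0(gid, ".gff3")))
  }
  write_table(sim$metadata, file.path(dir, "metadata.tsv"))
  write_table(sim$function_map, file.path(dir, "function_map.tsv"))
  write_table(sim$operons, file.path(dir, "operons.tsv"))
  write_table(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate a reference-anchored multiple alignment
#'
#' Starting from an ungapped reference row, each non-reference row mutates
#' every column independently: with probability `p_gap` the column becomes a
#' gap, with probability `p_sub` it substitutes to a uniformly chosen
#' different base, otherwise it copies the reference. A fixture for
#' conservation scoring; it does not emulate indel-aware alignment.
#'
#' @param ref_seq Reference sequence (A/C/G/T string).
#' @param n_rows Total rows including the reference (default 20, as in a
#'   19-species-plus-reference upstream alignment).
#' @param p_sub,p_gap Per-column substitution and gap probabilities;
#'   `p_sub + p_gap <= 1`.
#' @param seed RNG seed.
#' @param reference_id Name of the reference row.
#' @return An [alignment()] object.
#' @export
simulate_alignment <- function(ref_seq, n_rows = 20L, p_sub = 0.2,
                               p_gap = 0, seed = 1L, reference_id = "REF") {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L, n_rows >= 2L)
  if (p_sub < 0 || p_gap < 0 || p_sub + p_gap > 1) {
    stop("need p_sub >= 0, p_gap >= 0 and p_sub + p_gap <= 1")
  }
  ref_seq <- toupper(ref_seq)
  if (grepl("[^ACGT]", ref_seq)) stop("reference must be over {A,C,G,T}")
  set.seed(seed %% 2147483647)
  ref <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  L <- length(ref)
  alphabet <- c("A", "C", "G", "T")
  rows <- character(n_rows - 1L)
  for (r in seq_len(n_rows - 1L)) {
    u <- stats::runif(L)
    out <- ref
    gap <- u < p_gap
    sub <- !gap & u < p_gap + p_sub
    out[gap] <- "-"
    if (any(sub)) {
      shift <- sample.int(3L, sum(sub), replace = TRUE)
      out[sub] <- alphabet[(match(ref[sub], alphabet) - 1L + shift) %% 4L + 1L]
    }
    rows[r] <- paste(out, collapse = "")
  }
  all_rows <- c(ref_seq, rows)
  names(all_rows) <- c(reference_id, sprintf("sp%02d", seq_len(n_rows - 1L)))
  alignment(all_rows, reference_id)
}
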