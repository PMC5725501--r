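test_that("upstream_gap measures the motif-to-start distance on both strands", {
  gp <- function(ms, me, mstrand, gs, ge, gstrand, rep_m = "chr", rep_g = "chr") {
    upstream_gap(list(replicon = rep_m, start0 = ms, end0 = me, strand = mstrand),
                 list(gene_id = "g", replicon = rep_g, start0 = gs, end0 = ge,
                      strand = gstrand))
  }
  # + strand gene start s=100, motif [85,96): 100 - 96 = 4
  expect_identical(gp(85L, 96L, "+", 100L, 400L, "+"), 4L)
  # - strand gene CDS [200,500), motif [505,516): 505 - 500 = 5
  expect_identical(gp(505L, 516L, "-", 200L, 500L, "-"), 5L)
  # motif downstream of a + gene start: undefined
  expect_true(is.na(gp(120L, 131L, "+", 100L, 400L, "+")))
  # strand mismatch: undefined unless the requirement is lifted
  expect_true(is.na(gp(85L, 96L, "-", 100L, 400L, "+")))
  m <- list(replicon = "chr", start0 = 85L, end0 = 96L, strand = "-")
  g <- list(gene_id = "g", replicon = "chr", start0 = 100L, end0 = 400L,
            strand = "+")
  expect_identical(upstream_gap(m, g, require_same_strand = FALSE), 4L)
  expect_error(gp(85L, 96L, "+", 100L, 400L, "+", rep_g = "other"), "replicon")
})

test_that("minus-strand gap equals the plus-strand rule on the mirrored genome", {
  # derived check: reverse-complement the replicon, mirror the coordinates,
  # and the + strand rule must give the same gap
  pg <- planted_genome(gap = 5L, strand = "-")
  L <- nchar(pg$genome$replicons[["chr"]])
  hits <- scan_genome(pg$genome)
  expect_identical(nrow(hits), 1L)
  gap_minus <- upstream_gap(as.list(hits[1, ]), as.list(pg$genes[1, ]))
  mir_genome <- new_genome("mir", c(chr = revcomp_chr(pg$genome$replicons[["chr"]])))
  mir_gene <- list(gene_id = "g", replicon = "chr",
                   start0 = L - pg$genes$end0, end0 = L - pg$genes$start0,
                   strand = "+")
  mh <- scan_genome(mir_genome)
  gap_plus <- upstream_gap(as.list(mh[1, ]), mir_gene)
  expect_identical(gap_minus, 5L)
  expect_identical(gap_plus, gap_minus)
})

test_that("containment vs gap mode draw the boundary where the window ends", {
  for (strand in c("+", "-")) {
    r39 <- screen_genome(planted_genome(39L, strand)$genome,
                         planted_genome(39L, strand)$genes)
    expect_identical(nrow(r39), 1L)
    expect_identical(r39$gap_nt, 39L)
    r40 <- screen_genome(planted_genome(40L, strand)$genome,
                         planted_genome(40L, strand)$genes)
    expect_identical(nrow(r40), 0L)
    g50 <- planted_genome(50L, strand)
    expect_identical(nrow(screen_genome(g50$genome, g50$genes)), 0L)
    expect_identical(
      nrow(screen_genome(g50$genome, g50$genes,
                         config = screen_config(mode = "gap"))), 1L)
    g51 <- planted_genome(51L, strand)
    expect_identical(
      nrow(screen_genome(g51$genome, g51$genes,
                         config = screen_config(mode = "gap"))), 0L)
  }
})

test_that("a motif upstream of two overlapping gene models yields two rows but one locus", {
  pg <- planted_genome(30L, "+")
  genes2 <- rbind(pg$genes,
                  data.frame(gene_id = "gene2", replicon = "chr",
                             start0 = pg$genes$start0 + 6L,
                             end0 = pg$genes$end0 + 6L, strand = "+",
                             function_label = "prsA", stringsAsFactors = FALSE))
  res <- screen_genome(pg$genome, genes2)
  expect_identical(nrow(res), 2L)
  expect_setequal(res$gene_id, c("gene1", "gene2"))
  md <- data.frame(genome_id = "tg", species = "s", genus = "Gx",
                   stringsAsFactors = FALSE)
  expect_identical(per_genome_counts(res, md)$n_motif_loci, 1L)
})

test_that("per_genome_counts reports zeros and rejects unknown genomes", {
  md <- data.frame(genome_id = c("g1", "g2", "g3"), species = letters[1:3],
                   genus = c("A", "A", "B"), stringsAsFactors = FALSE)
  empty <- screen_genome(planted_genome(45L)$genome, planted_genome(45L)$genes)
  counts <- per_genome_counts(empty, md)
  expect_identical(counts$n_motif_loci, c(0L, 0L, 0L))
  bad <- data.frame(genome_id = "ghost", replicon = "chr", motif_start0 = 1L,
                    strand = "+", operon_flag = FALSE, stringsAsFactors = FALSE)
  expect_error(per_genome_counts(bad, md), "ghost")
})

test_that("screen_genome equals the brute-force pair oracle on synthetic genomes", {
  sim <- simulate_genomes(sim_config(seed = 42, genera_plan = c(A = 3, B = 2),
                                     replicon_length = 60000L))
  for (gid in names(sim$genomes)) {
    got <- screen_genome(sim$genomes[[gid]], sim$annotations[[gid]])
    want <- oracle_screen(sim$genomes[[gid]], sim$annotations[[gid]])
    expect_identical(got[, c("replicon", "motif_start0", "strand",
                             "gene_id", "gap_nt")], want)
  }
})

test_that("screening is invariant under reverse-complementing the genome", {
  sim <- simulate_genomes(sim_config(seed = 9, genera_plan = c(A = 1)))
  g <- sim$genomes[[1]]
  genes <- sim$annotations[[1]]
  L <- nchar(g$replicons[[1]])
  fwd <- screen_genome(g, genes)
  mir <- new_genome(g$genome_id,
                    stats::setNames(revcomp_chr(g$replicons[[1]]),
                                    names(g$replicons)))
  mir_genes <- genes
  mir_genes$start0 <- L - genes$end0
  mir_genes$end0 <- L - genes$start0
  mir_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  rev_res <- screen_genome(mir, mir_genes)
  back <- data.frame(motif_start0 = L - rev_res$motif_end0,
                     strand = ifelse(rev_res$strand == "+", "-", "+"),
                     gene_id = rev_res$gene_id, gap_nt = rev_res$gap_nt,
                     stringsAsFactors = FALSE)
  o <- order(back$motif_start0, back$strand, back$gene_id)
  expect_identical(back[o, ]$motif_start0, fwd$motif_start0)
  expect_identical(back[o, ]$strand, fwd$strand)
  expect_identical(back[o, ]$gene_id, fwd$gene_id)
  expect_identical(back[o, ]$gap_nt, fwd$gap_nt)
})

test_that("extend_to_operon flags downstream members without touching counts", {
  pg <- planted_genome(10L, "+")
  res <- screen_genome(pg$genome, pg$genes)
  ops <- data.frame(gene_id = c("gene1", "geneB", "geneC"),
                    operon_id = "op1", rank = 1:3, stringsAsFactors = FALSE)
  ext <- extend_to_operon(res, ops,
                          function_map = data.frame(
                            gene_id = c("geneB", "geneC"),
                            function_label = c("rpsJ", "nusB"),
                            stringsAsFactors = FALSE))
  expect_identical(nrow(ext), 3L)
  expect_identical(sum(ext$operon_flag), 2L)
  expect_setequal(ext$gene_id[ext$operon_flag], c("geneB", "geneC"))
  expect_identical(ext$function_label[ext$gene_id == "geneB"], "rpsJ")
  expect_identical(ext[!ext$operon_flag, ], res)
  # monocistronic gene: nothing added; absent gene: passes through
  expect_identical(nrow(extend_to_operon(res, ops[1, ])), 1L)
  expect_identical(nrow(extend_to_operon(res, ops[2:3, ])), 1L)
  md <- data.frame(genome_id = "tg", species = "s", genus = "G",
                   stringsAsFactors = FALSE)
  expect_identical(per_genome_counts(ext, md)$n_motif_loci,
                   per_genome_counts(res, md)$n_motif_loci)
})
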