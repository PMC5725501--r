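small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, genera_plan = c(GenA = 2, GenB = 1), ...)
}

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_genomes(small_cfg(seed = 5)), d1)
  write_simulation(simulate_genomes(small_cfg(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     info = f)
  }
  # and a different seed changes the sequences
  s3 <- simulate_genomes(small_cfg(seed = 6))
  s1 <- simulate_genomes(small_cfg(seed = 5))
  expect_false(identical(s1$genomes[[1]]$replicons, s3$genomes[[1]]$replicons))
})

test_that("per-genome substreams make earlier genomes stable when genomes are added", {
  a <- simulate_genomes(sim_config(seed = 8, genera_plan = c(GenA = 2)))
  b <- simulate_genomes(sim_config(seed = 8, genera_plan = c(GenA = 2, GenB = 2)))
  expect_identical(b$genomes[["G001"]], a$genomes[["G001"]])
  expect_identical(b$genomes[["G002"]], a$genomes[["G002"]])
  expect_identical(b$annotations[["G001"]], a$annotations[["G001"]])
})

test_that("planted motifs match the consensus and decoys never do", {
  sim <- simulate_genomes(small_cfg(seed = 13))
  p <- boxa_consensus()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    s <- sim$genomes[[tr$genome_id]]$replicons[[tr$replicon]]
    on_strand <- if (tr$strand == "+") {
      substr(s, tr$start0 + 1, tr$end0)
    } else {
      revcomp_chr(substr(s, tr$start0 + 1, tr$end0))
    }
    if (tr$kind == "motif") {
      expect_true(matches_at(on_strand, 0, p), info = paste("row", i))
    } else {
      expect_false(matches_at(on_strand, 0, p), info = paste("row", i))
      expect_false(on_strand %in% expand_iupac(p))
    }
  }
})

test_that("a genome configured with 7 planted motifs counts 7 distinct loci", {
  cfg <- sim_config(seed = 2, genera_plan = c(GenA = 1),
                    n_motifs_range = c(7L, 7L), n_decoys = 0L)
  sim <- simulate_genomes(cfg)
  hits <- screen_genomes(sim$genomes, sim$annotations)
  counts <- per_genome_counts(hits, sim$metadata)
  expect_identical(counts$n_motif_loci, 7L)
})

test_that("an oracle rescan of emitted genomes recovers every planted motif", {
  sim <- simulate_genomes(small_cfg(seed = 17))
  for (gid in names(sim$genomes)) {
    oh <- oracle_scan(sim$genomes[[gid]]$replicons[[1]],
                      replicon = names(sim$genomes[[gid]]$replicons))
    key_o <- paste(oh$replicon, oh$start0, oh$strand)
    tm <- sim$truth[sim$truth$kind == "motif" & sim$truth$genome_id == gid, ]
    expect_true(all(paste(tm$replicon, tm$start0, tm$strand) %in% key_o))
    td <- sim$truth[sim$truth$kind == "decoy" & sim$truth$genome_id == gid, ]
    expect_false(any(paste(td$replicon, td$start0, td$strand) %in% key_o))
  }
})

test_that("genes carry valid start and stop codons on their strand", {
  sim <- simulate_genomes(small_cfg(seed = 23))
  g <- sim$genomes[[1]]
  ann <- sim$annotations[[1]]
  s <- g$replicons[[1]]
  for (i in seq_len(nrow(ann))) {
    cds <- substr(s, ann$start0[i] + 1, ann$end0[i])
    if (ann$strand[i] == "-") cds <- revcomp_chr(cds)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_identical(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")
    expect_identical(nchar(cds) %% 3L, 0L)
  }
  # intervals are non-overlapping and within bounds
  o <- order(ann$start0)
  expect_true(all(ann$start0[o][-1] >= ann$end0[o][-nrow(ann)]))
  expect_true(all(ann$end0 <= nchar(s)))
})

test_that("emitted files feed back through the readers unchanged", {
  sim <- simulate_genomes(small_cfg(seed = 29))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  g <- read_genome(file.path(d, "G001.fa"), genome_id = "G001")
  expect_identical(g$replicons, sim$genomes[["G001"]]$replicons)
  ann <- read_annotations(file.path(d, "G001.gff3"), g)
  cols <- c("gene_id", "replicon", "start0", "end0", "strand", "function_label")
  expect_identical(ann[order(ann$gene_id), cols],
                   sim$annotations[["G001"]][order(sim$annotations[["G001"]]$gene_id), cols])
  md <- read_metadata(file.path(d, "metadata.tsv"))
  expect_identical(md, sim$metadata[order(sim$metadata$genome_id), ])
})

test_that("background motif density is near the binomial expectation", {
  # 16 matching (position, strand) pairs per 4^11 positions at GC 0.5
  cfg <- sim_config(seed = 31, genera_plan = c(GenA = 10), n_genes = 2L,
                    n_motifs_range = c(0L, 0L), n_decoys = 0L,
                    replicon_length = 100000L)
  sim <- simulate_genomes(cfg)
  n_hits <- sum(vapply(sim$genomes, function(g) {
    nrow(scan_genome(g))
  }, integer(1)))
  n_pos <- 10 * (100000 - 10)
  expected <- n_pos * 16 / 4^11
  # binomial 99.9% bounds around the expectation
  bound <- qbinom(c(5e-4, 1 - 5e-4), n_pos, 16 / 4^11)
  expect_gte(n_hits, bound[1])
  expect_lte(n_hits, bound[2])
})

test_that("simulate_alignment honours its probability contract", {
  aln0 <- simulate_alignment("ACGTACGTAC", 5, 0, 0, seed = 1)
  expect_true(all(column_match_percent(aln0)$pct == 100))
  aln1 <- simulate_alignment(strrep("ACGT", 50), 20, 1, 0, seed = 1)
  expect_true(all(column_match_percent(aln1)$pct == 5))
  alng <- simulate_alignment(strrep("ACGT", 50), 4, 0, 1, seed = 1)
  expect_true(all(grepl("^-+$", alng$rows[-1])))
  expect_error(simulate_alignment("ACGT", 5, 0.7, 0.5), "p_sub")
  # reproducibility
  expect_identical(simulate_alignment("ACGTACGT", 6, 0.3, 0.1, seed = 4),
                   simulate_alignment("ACGTACGT", 6, 0.3, 0.1, seed = 4))
})
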