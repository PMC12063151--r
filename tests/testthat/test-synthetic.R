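test_that("generation is seed-deterministic, on-target and feasible", {
  a <- generate_genome_annotation(55, n_chrom = 1, chrom_len = 120000,
                                  n_genes = 18, n_lnc = 5, n_nc = 2)
  b <- generate_genome_annotation(55, n_chrom = 1, chrom_len = 120000,
                                  n_genes = 18, n_lnc = 5, n_nc = 2)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$reference$transcripts, b$reference$transcripts)
  # every requested positional class is planted at least once
  expect_true(all(c("antisense_exonic", "divergent", "convergent",
                    "upstream_sense", "downstream_sense") %in%
                    a$truth$lncs$class))
  # realised GC within +-0.02 of the 0.41 target at 120 kb
  gc <- Biostrings::letterFrequency(a$genome[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.41), 0.02)
  # packing an impossible request errors
  expect_error(generate_genome_annotation(1, n_chrom = 1, chrom_len = 30000,
                                          n_genes = 20, n_lnc = 2),
               "infeasible")
})

test_that("coding genes carry real ORFs and candidates carry their flaws", {
  ds <- default_synth()$ds
  seqs <- extract_sequences(ds$reference, ds$genome,
                            paste0(ds$truth$genes$gene_id[1:8], ".t1"))
  for (s in as.character(seqs)) {
    orf <- find_longest_orf(s, min_aa = 100)
    expect_false(is.null(orf))
    expect_gte(orf$aa_length, 150)
  }
  dec <- ds$truth$decoys
  expect_setequal(dec$intended_filter,
                  c("length_ok", "no_sense_overlap", "noncoding_vote",
                    "expressed", "known_rna_ok"))
  short <- ds$candidates$transcripts["DEC_short.t1", "spliced_length"]
  expect_lt(short, 200)
  cseq <- extract_sequences(ds$candidates, ds$genome, "DEC_coding.t1")
  expect_gt(find_longest_orf(as.character(cseq[[1]]), 100)$aa_length, 100)
})

test_that("triplex planting writes recoverable complementary tracts", {
  ds0 <- generate_genome_annotation(60, n_chrom = 1, chrom_len = 150000,
                                    n_genes = 22, n_lnc = 5)
  none <- plant_triplex_sites(ds0, 61, n_sites = 0)
  expect_identical(as.character(none$genome), as.character(ds0$genome))
  expect_null(none$truth$triplex)
  ds <- plant_triplex_sites(ds0, 61, n_sites = 3)
  tp <- ds$truth$triplex
  expect_equal(nrow(tp), 3)
  # the planted purine tract is literally present on the plus strand
  for (i in 1:3) {
    got <- as.character(Biostrings::subseq(ds$genome[[tp$chrom[i]]],
                                           tp$tts_start[i], tp$tts_end[i]))
    expect_equal(got, tp$seq[i])
    gfrac <- Biostrings::letterFrequency(Biostrings::DNAString(got), "G",
                                         as.prob = TRUE)
    expect_gte(unname(gfrac), 0.4)
    expect_gte(nchar(got), 25)
  }
  # and the TFO sits at the recorded transcript position of its lncRNA
  lseqs <- extract_sequences(ds$candidates, ds$genome,
                             paste0(unique(tp$lnc_id), ".t1"))
  for (i in 1:3) {
    rna <- as.character(lseqs[[paste0(tp$lnc_id[i], ".t1")]])
    tfo <- substr(rna, tp$tfo_start[i], tp$tfo_end[i])
    expect_equal(tfo, paste(rev(strsplit(tp$seq[i], "")[[1]]), collapse = ""))
  }
})

test_that("expression simulation: design, determinism, lncRNA levels", {
  synth <- default_synth()
  ds <- synth$ds
  e1 <- synth$expr
  e2 <- simulate_expression(ds, 103)
  expect_identical(e1$counts, e2$counts)
  expect_equal(nrow(e1$design), 15)          # 5 conditions x 3 replicates
  expect_setequal(unique(e1$design$condition),
                  c("C0.1", "0.025", "R3", "R6", "R10"))
  expect_true(all(e1$counts >= 0))
  expect_true(all(e1$counts == floor(e1$counts)))
  # silent decoy is never expressed; its TPM can never exceed 1
  expect_true(all(e1$counts["DEC_silent.t1", ] == 0))
  expect_true(all(e1$tpm["DEC_silent.t1", ] == 0))
  # lncRNAs sit below coding genes on average
  tx <- ds$candidates$transcripts
  lnc_ids <- paste0(ds$truth$lncs$lnc_id, ".t1")
  cod_ids <- paste0(ds$truth$genes$gene_id, ".t1")
  expect_lt(mean(e1$counts[lnc_ids, ]), mean(e1$counts[cod_ids, ]))
  expect_error(simulate_expression(ds, 1, rho_pairs = data.frame(
    lnc_id = "LNC01", gene_id = "G0001", rho = 1)), "rho")
})

test_that("planted correlations are recovered on transformed counts", {
  synth <- default_synth()
  gc <- aggregate_to_gene(synth$expr$counts, synth$expr$tx2gene)
  vst <- normalize_and_transform(gc)
  rp <- synth$expr$truth$rho_pairs
  got <- correlate_genes(vst, rp[, c("lnc_id", "gene_id")])
  expect_equal(sign(got$r), sign(rp$rho))
  expect_true(all(abs(got$r - rp$rho) < 0.35))
})

test_that("synthetic outputs round-trip through the on-disk formats", {
  synth <- default_synth()
  dir <- tempfile()
  write_synthetic_dataset(synth$ds, synth$expr, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "reference.gtf", "candidates.gtf", "hits.tsv",
    "truth.json", "counts.tsv", "tpm.tsv", "design.tsv", "de.tsv")))))
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(synth$ds$genome))
  cand <- read_annotation(file.path(dir, "candidates.gtf"),
                          chrom_lengths = synth$ds$candidates$chrom_lengths)
  expect_equal(sort(cand$transcripts$transcript_id),
               sort(synth$ds$candidates$transcripts$transcript_id))
  d <- read_design(file.path(dir, "design.tsv"))
  expect_equal(d$sample, synth$expr$design$sample)
  expect_equal(d$condition, synth$expr$design$condition)
  fl <- read_de_flags(file.path(dir, "de.tsv"))
  expect_true(all(fl[synth$expr$truth$de_genes]))
  h <- read_hit_table(file.path(dir, "hits.tsv"))
  expect_equal(h$query_id, synth$ds$hits$query_id)
})
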