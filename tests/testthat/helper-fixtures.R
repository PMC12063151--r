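# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

# AnnotationSet from a compact exon table:
# list(c(chrom, start, end, strand, transcript_id, gene_id[, biotype]))
make_ann <- function(rows, chrom_lengths) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), strand = r[[4]],
               transcript_id = r[[5]], gene_id = r[[6]],
               biotype = if (length(r) >= 7) r[[7]] else "coding",
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcript_id = df$transcript_id, gene_id = df$gene_id,
    biotype = df$biotype)
  AnnotationSet(gr, chrom_lengths = chrom_lengths)
}

# deterministic random DNA
rand_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# a cached default synthetic dataset (built once per test run)
default_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_genome_annotation(101)
      ds <- plant_triplex_sites(ds, 102, n_sites = 5)
      expr <- simulate_expression(ds, 103)
      cache <<- list(ds = ds, expr = expr)
    }
    cache
  }
})

# planted profile groups for the clustering tests
planted_profiles <- function(n_per = 30, noise = 0.25, seed = 77, k = 4) {
  set.seed(seed)
  shapes <- rbind(c(2, 1, 0, -1, -2),    # down
                  c(-2, -1, 0, 1, 2),    # up
                  c(-2, 2, 1, -1, -2),   # early peak
                  c(2, -2, -1, 1, 2))[seq_len(k), , drop = FALSE]
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rep(shapes[i, ], each = n_per), n_per) +
      matrix(rnorm(n_per * 5, 0, noise), n_per)))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  colnames(x) <- paste0("p", 1:5)
  list(profiles = t(apply(x, 1, function(r) (r - mean(r)) / sd(r))),
       truth = rep(seq_len(k), each = n_per))
}

# adjusted Rand index between two hard labelings (hand implementation of
# the Hubert-Arabie formula)
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
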