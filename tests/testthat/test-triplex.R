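p20 <- triplex_params()

test_that("TFO tract examples behave per the motif definitions", {
  # pure alternating purine, 20 nt: one R tract, no errors, G fraction 0.5
  tr <- find_tracts(strrep("GA", 10), p20, kind = "TFO_on_rna")
  r <- tr[tr$motif == "R", ]
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end, r$errors), c(1, 20, 0))
  expect_equal(r$guanine_fraction, 0.5)
  # 19 nt pure purine: below min_length
  expect_equal(nrow(find_tracts(strrep("A", 19), p20, "TFO_on_rna")), 0)
  # U is accepted in RNA and treated as T (Y and M motifs)
  tr_u <- find_tracts(strrep("GU", 12), p20, "TFO_on_rna")
  expect_true("M" %in% tr_u$motif)
})

test_that("TTS detection sees both strands as potential purine strands", {
  purine <- strrep("GGA", 10)
  tr <- find_tracts(purine, p20, "TTS_on_duplex")
  expect_true(any(tr$purine_strand == "+" & tr$errors == 0))
  # the complement: purine strand is the minus strand, same coordinates
  compl <- chartr("GA", "CT", purine)
  tr2 <- find_tracts(compl, p20, "TTS_on_duplex")
  expect_true(any(tr2$purine_strand == "-" & tr2$errors == 0))
  expect_equal(tr$start, tr2$start)
  expect_equal(tr$end, tr2$end)
})

test_that("24 nt purine tract with 3 consecutive pyrimidines splits", {
  s <- paste0(strrep("A", 12), "TTT", strrep("G", 9))   # 24 nt
  tr <- find_tracts(s, p20, "TTS_on_duplex")
  # no window may contain the 3-error run; both sides are < 20 nt alone
  expect_false(any(tr$purine_strand == "+" & tr$start <= 12 & tr$end >= 15))
  bigger <- paste0(strrep("GA", 12), "TTT", strrep("GA", 12))
  tr2 <- find_tracts(bigger, p20, "TTS_on_duplex")
  plus <- tr2[tr2$purine_strand == "+", ]
  expect_equal(nrow(plus), 2)                            # one tract per side
  expect_true(all(plus$errors == 0))
})

test_that("reported tracts always satisfy all constraints (re-validated)", {
  set.seed(5)
  for (k in 1:20) {
    s <- rand_dna(200, probs = c(A = .35, C = .15, G = .35, T = .15))
    for (kind in c("TFO_on_rna", "TTS_on_duplex")) {
      tr <- find_tracts(s, p20, kind)
      if (nrow(tr) == 0) next
      expect_true(all(tr$length >= p20$min_length))
      expect_true(all(tr$errors / tr$length <= p20$max_error_rate + 1e-9))
      expect_true(all(tr$guanine_fraction >= p20$min_guanine - 1e-9))
      for (i in seq_len(nrow(tr))) {
        piece <- strsplit(substr(s, tr$start[i], tr$end[i]), "")[[1]]
        al <- if (kind == "TFO_on_rna") {
          list(R = c("G", "A"), Y = c("C", "T"), M = c("G", "T"))[[tr$motif[i]]]
        } else if (tr$purine_strand[i] == "+") c("A", "G") else c("C", "T")
        err <- !(piece %in% al)
        expect_true(piece[1] %in% al && piece[length(piece)] %in% al)
        runs <- rle(err)
        expect_lte(max(c(0, runs$lengths[runs$values])), p20$max_consecutive_errors)
      }
    }
  }
})

test_that("reverse-complementing a chromosome leaves the TTS set invariant", {
  set.seed(6)
  s <- paste0(rand_dna(60), strrep("GAAGGA", 5), rand_dna(60),
              strrep("TCCTTC", 5), rand_dna(40))
  n <- nchar(s)
  tts <- find_tts_tracts(c(chr = s), p20)
  tts_rc <- find_tts_tracts(c(chr = revcomp(s)), p20)
  # map the revcomp coordinates back and flip the purine strand label
  mapped <- data.frame(start = n - tts_rc$end + 1, end = n - tts_rc$start + 1,
                       purine_strand = ifelse(tts_rc$purine_strand == "+", "-", "+"))
  o1 <- order(tts$start, tts$purine_strand)
  o2 <- order(mapped$start, mapped$purine_strand)
  expect_equal(tts$start[o1], mapped$start[o2])
  expect_equal(tts$end[o1], mapped$end[o2])
  expect_equal(tts$purine_strand[o1], mapped$purine_strand[o2])
})

test_that("triplex matching pairs TFOs with TTSs under Hoogsteen rules", {
  # identity match: polyG TFO vs polyG purine tract
  tfos <- data.frame(lnc_id = "l1", start = 11, end = 30, length = 20,
                     motif = "R", errors = 0, guanine_fraction = 1,
                     seq = strrep("G", 20), stringsAsFactors = FALSE)
  ttss <- data.frame(chrom = "chr1", start = 101, end = 120, length = 20,
                     purine_strand = "+", errors = 0, guanine_fraction = 1,
                     purine_seq = strrep("G", 20), stringsAsFactors = FALSE)
  m <- match_triplexes(tfos, ttss, p20)
  expect_equal(nrow(m), 1)
  expect_equal(m$tts_start, 101)
  expect_equal(m$tts_end, 120)
  expect_equal(m$tfo_start, 11)
  expect_equal(m$errors, 0)
  # GA-repeat TFO against GT-repeat purine strand: A:T mismatch at every
  # second position makes the R motif impossible
  tfos$seq <- strrep("GA", 10)
  ttss$purine_seq <- strrep("GT", 10)
  expect_equal(nrow(match_triplexes(tfos, ttss, p20)), 0)
  # empty inputs
  expect_equal(nrow(match_triplexes(tfos[0, ], ttss, p20)), 0)
  expect_equal(nrow(match_triplexes(tfos, ttss[0, ], p20)), 0)
})

test_that("antiparallel motifs reverse the TFO; minus purine strands map back", {
  # TTS on the minus purine strand: genome shows the pyrimidine face
  pur <- paste0(strrep("GA", 8), "GGGG")  # 20 nt purine 5'->3'
  genome <- c(chr1 = paste0(rand_dna(30), revcomp(pur), rand_dna(30)))
  lnc <- c(l1 = paste0(rand_dna(25), paste(rev(strsplit(pur, "")[[1]]), collapse = ""),
                       rand_dna(25)))
  res <- predict_triplexes(lnc, genome, p20)
  r <- res[res$motif == "R", ]
  expect_gte(nrow(r), 1)
  # a reported match covers the planted site on the minus purine strand
  expect_true(any(r$purine_strand == "-" & r$tts_start <= 31 & r$tts_end >= 50))
})

test_that("planted synthetic triplex sites are recovered end to end", {
  synth <- default_synth()
  ds <- synth$ds
  tp <- ds$truth$triplex
  lncs <- subset_annotation(ds$candidates, paste0(unique(tp$lnc_id), ".t1"))
  seqs <- extract_sequences(lncs, ds$genome)
  names(seqs) <- sub("\\.t1$", "", names(seqs))
  res <- predict_triplexes(seqs, ds$genome, p20)
  for (i in seq_len(nrow(tp))) {
    hit <- res$lnc_id == tp$lnc_id[i] & res$chrom == tp$chrom[i] &
      res$tts_start <= tp$tts_start[i] & res$tts_end >= tp$tts_end[i]
    expect_true(any(hit), label = paste("site", tp$site_id[i]))
  }
  # a 19 nt planted tract is a negative control at min_length 20
  neg <- find_tracts(paste0(strrep("C", 40), strrep("A", 19), strrep("C", 40)),
                     p20, "TTS_on_duplex")
  expect_false(any(neg$purine_strand == "+"))
})

test_that("genome context partitions every base with the stated priority", {
  # single 1-exon gene on a toy chromosome
  ann <- make_ann(list(list("chr1", 4001, 5000, "+", "g.t1", "g", "coding")),
                  c(chr1 = 10000))
  ctx <- classify_genome_context(ann)
  expect_equal(sum(ctx$fractions), 1, tolerance = 1e-12)
  # promoter = [3001, 4250) .. i.e. 1000 up + 250 down including the TSS
  expect_equal(ctx$fractions[["promoter"]], 1250 / 10000)
  expect_equal(ctx$fractions[["exon"]], 750 / 10000)  # 4251..5000
  expect_equal(ctx$fractions[["intron"]], 0)
  # base inside both promoter and exon is promoter (4001..4250)
  expect_false(any(IRanges::overlapsAny(ctx$classes$exon,
                                        GenomicRanges::GRanges("chr1", IRanges::IRanges(4100, 4100)))))
  # empty annotation: all intergenic
  empty <- classify_genome_context(
    structure(list(exons = GenomicRanges::GRanges(),
                   transcripts = make_ann(list(list("chr1", 1, 10, "+", "t", "g")),
                                          c(chr1 = 100))$transcripts[0, ],
                   chrom_lengths = c(chr1 = 5000)), class = "AnnotationSet"))
  expect_equal(empty$fractions[["intergenic"]], 1)
})

test_that("interaction context takes the highest-priority overlap", {
  ann <- make_ann(list(
    list("chr1", 4001, 4600, "+", "g.t1", "g", "coding"),    # exon 1
    list("chr1", 4801, 5600, "+", "g.t1", "g", "coding")     # exon 2
  ), c(chr1 = 10000))
  ctx <- classify_genome_context(ann)
  mk <- function(s, e) data.frame(lnc_id = "l", tfo_start = 1, tfo_end = 20,
                                  chrom = "chr1", tts_start = s, tts_end = e,
                                  purine_strand = "+", motif = "R", length = e - s + 1,
                                  errors = 0, guanine_fraction = .5,
                                  stringsAsFactors = FALSE)
  # spanning promoter (ends 4250) and exon -> promoter
  expect_equal(assign_interaction_context(mk(4200, 4300), ctx)$context, "promoter")
  # spanning exon and intron (intron = 4601..4800) -> exon
  expect_equal(assign_interaction_context(mk(4550, 4650), ctx)$context, "exon")
  expect_equal(assign_interaction_context(mk(4650, 4700), ctx)$context, "intron")
  expect_equal(assign_interaction_context(mk(9000, 9100), ctx)$context, "intergenic")
  expect_error(assign_interaction_context(mk(9990, 10050), ctx), "outside")
})

test_that("interaction pairs deduplicate per scope", {
  ann <- make_ann(list(
    list("chr1", 5000, 6000, "+", "gA.t1", "gA", "coding"),
    list("chr1", 20000, 21000, "+", "gB.t1", "gB", "coding"),
    list("chr2", 5000, 6000, "+", "gC.t1", "gC", "coding")
  ), c(chr1 = 30000, chr2 = 30000))
  mk <- function(chrom, s, e, lnc = "l1")
    data.frame(lnc_id = lnc, tfo_start = 1, tfo_end = 20, chrom = chrom,
               tts_start = s, tts_end = e, purine_strand = "+", motif = "R",
               length = e - s + 1, errors = 0, guanine_fraction = .5,
               stringsAsFactors = FALSE)
  # two TTSs in gA's promoter: one unique pair, two interactions;
  # one TFO hitting promoters of three genes: three pairs
  ints <- rbind(mk("chr1", 4000, 4020), mk("chr1", 4400, 4420),
                mk("chr1", 19000, 19020), mk("chr2", 4000, 4020),
                mk("chr1", 5500, 5520))   # exon of gA
  ip <- interaction_pairs(ints, ann)
  expect_equal(nrow(ip$Promoter$pairs), 3)
  expect_equal(sort(ip$Promoter$pairs$gene_id), c("gA", "gB", "gC"))
  expect_equal(ip$Promoter$n_interactions, 4)
  expect_equal(unname(ip$Promoter$per_gene[["gA"]]), 2)
  expect_equal(ip$Exon$pairs$gene_id, "gA")
  expect_true(all(c("gA", "gB", "gC") %in% ip$GenePromoter$pairs$gene_id))
})
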