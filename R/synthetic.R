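my_sample <- function(x, n, replace = FALSE, prob = NULL) {
  # sample() with the surprising length-1 behaviour removed
  if (length(x) == 1L) return(rep(x, n))
  sample(x, n, replace = replace, prob = prob)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- do.call(paste0, expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1])
  sort(setdiff(all, c("TAA", "TAG", "TGA")))
}

# Deterministic codon usage bias shared by every synthetic coding gene: an
# exponential decay over the alphabetically sorted sense codons. This gives
# coding sequence a strong, learnable hexamer signature without moving GC
# content far from genomic background.
codon_weights <- function() {
  cod <- sense_codons()
  w <- exp(-seq.int(0L, length(cod) - 1L) / 18)
  setNames(w / sum(w), cod)
}

biased_orf <- function(n_codons) {
  w <- codon_weights()
  paste0("ATG",
         paste(sample(names(w), n_codons - 1L, replace = TRUE, prob = w),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

noncoding_seq <- function(len, gc, max_tries = 25L) {
  # random sequence re-drawn until it would not trip the built-in coding
  # classifier (no ORF > 100 aa, Fickett below the default cutoff)
  for (i in seq_len(max_tries)) {
    s <- random_dna(len, gc)
    if (is.null(find_longest_orf(s, min_aa = 100)) &&
        suppressWarnings(fickett_score(s)) < 0.95) return(s)
  }
  stop("could not draw a non-coding sequence of length ", len)
}

str_assign <- function(s, at, replacement) {
  # write `replacement` into string s starting at 1-based position `at`
  paste0(substr(s, 1L, at - 1L), replacement,
         substr(s, at + nchar(replacement), nchar(s)))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Synthetic genome, reference annotation and candidate transcripts
#'
#' Builds, from a single seed, a multi-chromosome random genome at a target
#' GC content containing: protein-coding genes (ATG...stop ORFs of at least
#' 150 codons drawn from a fixed biased codon table, a fraction of them
#' two-exon), a few short ncRNAs, planted novel lncRNA transcripts of every
#' positional class (antisense_exonic, divergent, convergent,
#' upstream_sense, downstream_sense), and decoy candidates each designed to
#' be removed by one specific filter (too short; sense-exon overlap; strong
#' coding ORF; never expressed; known-RNA database hit). All coordinates
#' and intended outcomes are recorded in the returned truth object; the
#' same seed reproduces the dataset bit-identically.
#'
#' @param seed Integer seed.
#' @param n_chrom,chrom_len Number and length of chromosomes (default 2 x
#'   200 kb).
#' @param n_genes Number of coding genes (default 60), split evenly across
#'   chromosomes.
#' @param gc Target GC content of the genomic background (default 0.41).
#' @param n_lnc Number of planted lncRNAs (default 15), cycled over the
#'   five positional classes.
#' @param n_nc Number of reference ncRNA genes (default 4).
#' @return List of class `synthetic_dataset`: `genome` (DNAStringSet),
#'   `reference` and `candidates` ([AnnotationSet]s), `hits` (synthetic
#'   external-hit table), and `truth` (planted lncRNA classes and partners,
#'   decoys with their intended filter, whitelist, seed and parameters).
#' @export
generate_genome_annotation <- function(seed, n_chrom = 2, chrom_len = 200000,
                                       n_genes = 60, gc = 0.41,
                                       n_lnc = 15, n_nc = 4) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  genome <- setNames(vapply(chroms, function(x) random_dna(chrom_len, gc),
                            character(1)), chroms)

  per_chrom <- rep(n_genes %/% n_chrom, n_chrom)
  if (n_genes %% n_chrom) per_chrom[seq_len(n_genes %% n_chrom)] <-
    per_chrom[seq_len(n_genes %% n_chrom)] + 1L

  genes <- list()   # per gene: chrom, start, end, strand, exon offsets, mrna
  gidx <- 0L
  for (ci in seq_len(n_chrom)) {
    cursor <- 3000L
    for (k in seq_len(per_chrom[ci])) {
      gidx <- gidx + 1L
      n_cod <- sample(150:400, 1L)
      utr5 <- random_dna(sample(30:80, 1L), gc)
      utr3 <- random_dna(sample(50:150, 1L), gc)
      orf <- biased_orf(n_cod)
      mrna <- paste0(utr5, orf, utr3)
      strand <- sample(c("+", "-"), 1L)
      two_exon <- runif(1) < 0.2
      if (two_exon) {
        cut <- sample(seq(100L, nchar(mrna) - 100L, by = 1L), 1L)
        intron <- random_dna(sample(60:200, 1L), gc)
        pre <- paste0(substr(mrna, 1L, cut), intron,
                      substr(mrna, cut + 1L, nchar(mrna)))
        ex_tx <- rbind(c(1L, cut), c(cut + nchar(intron) + 1L, nchar(pre)))
      } else {
        pre <- mrna
        ex_tx <- rbind(c(1L, nchar(pre)))
      }
      glen <- nchar(pre)
      gap <- sample(2500:5000, 1L)
      gs <- cursor + gap
      ge <- gs + glen - 1L
      if (ge > chrom_len - 3000L)
        stop("infeasible packing: chromosome ", chroms[ci], " too short for ",
             per_chrom[ci], " genes")
      gseq <- if (strand == "+") pre else revcomp_chr(pre)
      exons <- if (strand == "+") {
        cbind(gs + ex_tx[, 1L] - 1L, gs + ex_tx[, 2L] - 1L)
      } else {
        cbind(ge - ex_tx[, 2L] + 1L, ge - ex_tx[, 1L] + 1L)
      }
      exons <- exons[order(exons[, 1L]), , drop = FALSE]
      genome[[ci]] <- str_assign(genome[[ci]], gs, gseq)
      genes[[gidx]] <- list(id = sprintf("G%04d", gidx), chrom = chroms[ci],
                            start = gs, end = ge, strand = strand,
                            exons = exons, mrna = mrna, orf = orf)
      cursor <- ge
    }
  }

  # classes cycled over planted lncRNAs; each planted element gets its own
  # partner gene (avoid first/last gene of a chromosome)
  classes <- c("antisense_exonic", "divergent", "convergent",
               "upstream_sense", "downstream_sense")
  gene_ids <- vapply(genes, `[[`, "", "id")
  gene_chrom <- vapply(genes, `[[`, "", "chrom")
  usable <- seq_along(genes)
  # drop chromosome-edge genes so flank placements stay well inside
  edge <- unlist(lapply(split(seq_along(genes), gene_chrom),
                        function(ix) c(ix[1L], ix[length(ix)])))
  usable <- setdiff(usable, edge)
  partner_pool <- usable[seq(1L, length(usable), by = 2L)]
  if (length(partner_pool) < n_lnc)
    stop("not enough genes to host ", n_lnc, " planted lncRNAs")

  lnc_rows <- list()
  cand_exons <- list()
  for (i in seq_len(n_lnc)) {
    cls <- classes[(i - 1L) %% length(classes) + 1L]
    g <- genes[[partner_pool[i]]]
    id <- sprintf("LNC%02d", i)
    if (cls == "antisense_exonic") {
      # overlap the 3'-terminal exon partially and extend into the flanking
      # gap, the way assembled antisense transcripts straddle gene ends;
      # the flank part is redrawn until the whole transcript looks
      # non-coding to the built-in classifier
      len <- sample(420:600, 1L)
      ov <- sample(60:100, 1L)
      strand <- if (g$strand == "+") "-" else "+"
      ci <- match(g$chrom, chroms)
      if (g$strand == "+") {
        ls <- g$end - ov + 1L
        le <- ls + len - 1L
        fl_at <- g$end + 1L
      } else {
        le <- g$start + ov - 1L
        ls <- le - len + 1L
        fl_at <- ls
      }
      fl_len <- len - ov
      ok <- FALSE
      for (try in seq_len(25L)) {
        genome[[ci]] <- str_assign(genome[[ci]], fl_at, random_dna(fl_len, gc))
        s <- substr(genome[[ci]], ls, le)
        if (strand == "-") s <- revcomp_chr(s)
        if (is.null(find_longest_orf(s, min_aa = 100)) &&
            suppressWarnings(fickett_score(s)) < 0.95) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not draw a non-coding antisense lncRNA for ", g$id)
    } else {
      len <- sample(250:800, 1L)
      gap <- sample(100:300, 1L)
      five_side <- cls %in% c("divergent", "upstream_sense")
      left <- if (g$strand == "+") five_side else !five_side
      if (left) {
        le <- g$start - gap - 1L
        ls <- le - len + 1L
      } else {
        ls <- g$end + gap + 1L
        le <- ls + len - 1L
      }
      strand <- if (cls %in% c("upstream_sense", "downstream_sense"))
        g$strand else (if (g$strand == "+") "-" else "+")
      s <- noncoding_seq(len, gc)
      ci <- match(g$chrom, chroms)
      genome[[ci]] <- str_assign(genome[[ci]], ls,
                                 if (strand == "+") s else revcomp_chr(s))
    }
    lnc_rows[[i]] <- data.frame(lnc_id = id, class = cls,
                                partner_gene_id = g$id, chrom = g$chrom,
                                start = ls, end = le, strand = strand,
                                stringsAsFactors = FALSE)
    cand_exons[[id]] <- data.frame(chrom = g$chrom, start = ls, end = le,
                                   strand = strand, transcript_id = paste0(id, ".t1"),
                                   gene_id = id, stringsAsFactors = FALSE)
  }
  lnc_truth <- do.call(rbind, lnc_rows)

  # decoys, one per intended filter; intergenic placements are checked
  # against genes and every previously planted feature
  spare <- setdiff(usable, partner_pool[seq_len(n_lnc)])
  placed <- lnc_truth[, c("chrom", "start", "end")]
  free_of_clash <- function(chrom, ls, le, margin = 50L) {
    gene_hit <- any(gene_chrom == chrom &
                      vapply(genes, `[[`, 0L, "start") <= le + margin &
                      vapply(genes, `[[`, 0L, "end") >= ls - margin)
    feat_hit <- nrow(placed) > 0L && any(placed$chrom == chrom &
                                           placed$start <= le + margin &
                                           placed$end >= ls - margin)
    !gene_hit && !feat_hit
  }
  place_intergenic <- function(len) {
    while (length(spare)) {
      gi <- spare[1L]; spare <<- spare[-1L]
      g <- genes[[gi]]
      ls <- g$end + 1500L
      le <- ls + len - 1L
      if (free_of_clash(g$chrom, ls, le)) {
        placed <<- rbind(placed, data.frame(chrom = g$chrom, start = ls, end = le))
        return(list(chrom = g$chrom, start = ls, end = le))
      }
    }
    stop("infeasible packing: no free intergenic slot left")
  }
  decoys <- list()
  add_decoy <- function(id, filter, chrom, start, end, strand, write_seq = NULL) {
    if (!is.null(write_seq)) {
      ci <- match(chrom, chroms)
      genome[[ci]] <<- str_assign(genome[[ci]], start,
                                  if (strand == "+") write_seq else revcomp_chr(write_seq))
    }
    decoys[[id]] <<- data.frame(transcript_id = paste0(id, ".t1"),
                                intended_filter = filter, chrom = chrom,
                                start = start, end = end, strand = strand,
                                stringsAsFactors = FALSE)
    cand_exons[[id]] <<- data.frame(chrom = chrom, start = start, end = end,
                                    strand = strand,
                                    transcript_id = paste0(id, ".t1"),
                                    gene_id = id, stringsAsFactors = FALSE)
  }
  len <- sample(120:180, 1L)
  p <- place_intergenic(len)
  add_decoy("DEC_short", "length_ok", p$chrom, p$start, p$end, "+",
            noncoding_seq(len, gc))

  g <- genes[[spare[1L]]]; spare <- spare[-1L]
  ex <- g$exons[1L, ]
  ds <- ex[1L] + 20L; de <- min(ex[2L], ds + 400L)
  add_decoy("DEC_sense", "no_sense_overlap", g$chrom, ds, de, g$strand)

  len <- 80L + 3L * 160L + 3L + 120L
  p <- place_intergenic(len)
  add_decoy("DEC_coding", "noncoding_vote", p$chrom, p$start, p$end, "+",
            paste0(random_dna(80L, gc), biased_orf(160L), random_dna(120L, gc)))

  len <- sample(300:500, 1L)
  p <- place_intergenic(len)
  add_decoy("DEC_silent", "expressed", p$chrom, p$start, p$end, "+",
            noncoding_seq(len, gc))

  len <- sample(300:500, 1L)
  p <- place_intergenic(len)
  add_decoy("DEC_knownrna", "known_rna_ok", p$chrom, p$start, p$end, "+",
            noncoding_seq(len, gc))

  # reference ncRNAs in remaining gaps
  nc_rows <- list()
  for (i in seq_len(n_nc)) {
    len <- sample(70:120, 1L)
    p <- place_intergenic(len)
    nc_rows[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                               strand = sample(c("+", "-"), 1L),
                               transcript_id = sprintf("NC%02d.t1", i),
                               gene_id = sprintf("NC%02d", i),
                               biotype = "ncRNA", stringsAsFactors = FALSE)
  }

  # assemble AnnotationSets
  ref_rows <- do.call(rbind, c(lapply(genes, function(g) {
    data.frame(chrom = g$chrom, start = g$exons[, 1L], end = g$exons[, 2L],
               strand = g$strand, transcript_id = paste0(g$id, ".t1"),
               gene_id = g$id, biotype = "coding", stringsAsFactors = FALSE)
  }), nc_rows))
  chrom_lengths <- setNames(rep(chrom_len, n_chrom), chroms)
  mk_ann <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      transcript_id = df$transcript_id, gene_id = df$gene_id,
      biotype = if (is.null(df$biotype)) "novel" else df$biotype)
    AnnotationSet(gr, chrom_lengths = chrom_lengths)
  }
  reference <- mk_ann(ref_rows)
  cand_df <- do.call(rbind, cand_exons)
  cand_df$biotype <- "novel"
  candidates <- mk_ann(cand_df)

  # synthetic external hit table: a real RFAM hit for DEC_knownrna, plus a
  # whitelisted high-identity RNAcentral hit on a planted lncRNA (a
  # manual-inspection rescue) and a weak descriptive-only hit
  wl_lnc <- paste0(lnc_truth$lnc_id[2L], ".t1")
  hits <- data.frame(
    query_id = c("DEC_knownrna.t1", wl_lnc, paste0(lnc_truth$lnc_id[3L], ".t1")),
    subject_id = c("RF00005", "URS000001", "URS000002"),
    subject_class = c("RFAM", "RNAcentral", "RNAcentral"),
    identity = c(98, 95, 60),
    evalue = c(1e-10, 1e-6, 1e-3),
    coverage = c(90, 80, 60),
    stringsAsFactors = FALSE)

  structure(list(
    genome = Biostrings::DNAStringSet(genome),
    reference = reference,
    candidates = candidates,
    hits = hits,
    truth = list(lncs = lnc_truth,
                 decoys = do.call(rbind, decoys),
                 whitelist = wl_lnc,
                 genes = data.frame(gene_id = gene_ids,
                                    chrom = gene_chrom,
                                    start = vapply(genes, `[[`, 0L, "start"),
                                    end = vapply(genes, `[[`, 0L, "end"),
                                    strand = vapply(genes, `[[`, "", "strand"),
                                    stringsAsFactors = FALSE),
                 orfs = setNames(vapply(genes, `[[`, "", "orf"), gene_ids),
                 seed = seed,
                 params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                               n_genes = n_genes, gc = gc, n_lnc = n_lnc))),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d chrom, %d reference transcripts, %d candidates\n",
              length(x$genome), nrow(x$reference$transcripts),
              nrow(x$candidates$transcripts)))
  if (!is.null(x$truth$triplex))
    cat(sprintf("  %d planted triplex sites\n", nrow(x$truth$triplex)))
  invisible(x)
}

#' Plant complementary TFO/TTS triplex tracts into a synthetic dataset
#'
#' Writes polypurine tracts (length >= 25, guanine fraction >= 0.4) into
#' promoters of coding genes and the matching R-motif TFO tracts (the
#' reversed purine sequence — antiparallel Hoogsteen pairing with G:G, A:A
#' identity) into exons of planted flank lncRNAs, recording all
#' coordinates. Host genes are chosen among genes without planted lncRNAs
#' in their flanks, preferring a different chromosome than the TFO-carrying
#' lncRNA, so planted interactions are trans.
#'
#' @param ds A [generate_genome_annotation] result.
#' @param seed Integer seed.
#' @param n_sites Number of planted TFO/TTS pairs (0 leaves the dataset
#'   untouched).
#' @param max_tries Redraw budget for rejected placements.
#' @return `ds` with a modified genome and `truth$triplex` data.frame
#'   (`site_id`, `gene_id`, `lnc_id`, `chrom`, `tts_start`, `tts_end`,
#'   `tfo_start`, `tfo_end` (transcript coordinates), `motif`, `seq`).
#' @export
plant_triplex_sites <- function(ds, seed, n_sites = 5, max_tries = 50) {
  stopifnot(inherits(ds, "synthetic_dataset"), n_sites >= 0)
  if (n_sites == 0L) {
    ds$truth$triplex <- NULL
    return(ds)
  }
  set.seed(seed)
  genome <- as.character(ds$genome)
  truth <- ds$truth
  used_partners <- unique(truth$lncs$partner_gene_id)
  hosts <- truth$genes[!truth$genes$gene_id %in% used_partners, , drop = FALSE]
  flank <- truth$lncs[truth$lncs$class != "antisense_exonic", , drop = FALSE]
  if (nrow(flank) == 0L) stop("no flank lncRNAs to carry TFOs")
  if (nrow(hosts) < n_sites) stop("not enough promoter hosts for ", n_sites, " sites")
  occ <- rbind(ds$reference$transcripts[, c("chrom", "start", "end")],
               ds$candidates$transcripts[, c("chrom", "start", "end")])
  rows <- list()
  for (s in seq_len(n_sites)) {
    lnc <- flank[(s - 1L) %% nrow(flank) + 1L, ]
    pool <- hosts[hosts$chrom != lnc$chrom, , drop = FALSE]
    if (nrow(pool) == 0L) pool <- hosts
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      g <- pool[sample.int(nrow(pool), 1L), ]
      len <- sample(25:35, 1L)
      pur <- paste(sample(c("G", "A"), len, replace = TRUE), collapse = "")
      gfrac <- sum(strsplit(pur, "")[[1L]] == "G") / len
      if (gfrac < 0.4) next
      up_off <- sample(100:800, 1L)  # within the (1000, 250) promoter window
      if (g$strand == "+") {
        tts_end <- g$start - up_off
        tts_start <- tts_end - len + 1L
      } else {
        tts_start <- g$end + up_off
        tts_end <- tts_start + len - 1L
      }
      if (tts_start < 1L || tts_end > nchar(genome[[g$chrom]])) next
      # promoters sit in intergenic gaps, but those gaps may also hold
      # planted lncRNAs, decoys, reference ncRNAs or earlier sites
      if (any(occ$chrom == g$chrom &
                occ$start <= tts_end + 20L & occ$end >= tts_start - 20L)) next
      genome[[g$chrom]] <- str_assign(genome[[g$chrom]], tts_start, pur)
      tfo <- paste(rev(strsplit(pur, "")[[1L]]), collapse = "")
      llen <- lnc$end - lnc$start + 1L
      off <- sample.int(llen - len - 40L, 1L) + 19L  # transcript position
      if (lnc$strand == "+") {
        gpos <- lnc$start + off - 1L
        genome[[lnc$chrom]] <- str_assign(genome[[lnc$chrom]], gpos, tfo)
      } else {
        gpos <- lnc$end - (off + len - 1L) + 1L
        genome[[lnc$chrom]] <- str_assign(genome[[lnc$chrom]], gpos,
                                          revcomp_chr(tfo))
      }
      rows[[s]] <- data.frame(site_id = sprintf("TPX%02d", s),
                              gene_id = g$gene_id, lnc_id = lnc$lnc_id,
                              chrom = g$chrom, tts_start = tts_start,
                              tts_end = tts_end, tfo_start = off,
                              tfo_end = off + len - 1L, motif = "R",
                              seq = pur, stringsAsFactors = FALSE)
      hosts <- hosts[hosts$gene_id != g$gene_id, , drop = FALSE]
      occ <- rbind(occ, data.frame(chrom = g$chrom, start = tts_start,
                                   end = tts_end))
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place triplex site ", s, " within ", max_tries, " tries")
  }
  ds$genome <- Biostrings::DNAStringSet(genome)
  ds$truth$triplex <- do.call(rbind, rows)
  ds
}

#' Simulate a replicated multi-condition count matrix with planted truth
#'
#' Negative-binomial counts around condition-wise means for every reference
#' transcript and candidate. Growth-rate-associated (DE) genes follow a
#' monotone log2 fold-change ramp over the condition series; designated
#' (lncRNA, gene) pairs get condition-mean profiles constructed (via an
#' orthogonal-profile mixture) to yield a target Pearson correlation rho on
#' log-transformed values; lncRNA baseline means sit below coding-gene
#' means; the expression-filter decoy stays at zero counts.
#'
#' @param ds A `synthetic_dataset`.
#' @param seed Integer seed.
#' @param conditions Condition series, fastest growth first (default
#'   C0.1, 0.025, R3, R6, R10).
#' @param n_rep Replicates per condition (default 3; the default design
#'   therefore has 15 samples).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param effect_range Range of |log2FC| at the slowest growth rate for DE
#'   genes (default 1 to 3).
#' @param de_fraction Fraction of coding genes made growth-rate associated
#'   (default 0.3).
#' @param rho_pairs data.frame(`lnc_id`, `gene_id`, `rho`) of planted
#'   correlations; defaults to the planted triplex pairs with alternating
#'   rho = +0.8 / -0.8. Requires |rho| < 1.
#' @return List of class `synthetic_expression`: `counts` (transcript x
#'   sample), `tpm`, `design`, `de` (gene-level table with `padj` and
#'   `svalue`), `tx2gene`, and `truth` (`de_genes`, `rho_pairs`,
#'   `de_lncs`).
#' @export
simulate_expression <- function(ds, seed,
                                conditions = c("C0.1", "0.025", "R3", "R6", "R10"),
                                n_rep = 3, dispersion = 0.05,
                                effect_range = c(1, 3), de_fraction = 0.3,
                                rho_pairs = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"),
            length(conditions) >= 2, n_rep >= 2)
  set.seed(seed)
  K <- length(conditions)
  design <- data.frame(
    sample = paste(rep(conditions, each = n_rep), seq_len(n_rep), sep = "_"),
    condition = rep(conditions, each = n_rep),
    cultivation = ifelse(rep(conditions, each = n_rep) == "C0.1", "C", "SC"),
    replicate = rep(seq_len(n_rep), K),
    stringsAsFactors = FALSE)

  if (is.null(rho_pairs)) {
    if (!is.null(ds$truth$triplex)) {
      tp <- unique(ds$truth$triplex[, c("lnc_id", "gene_id")])
      rho_pairs <- data.frame(lnc_id = tp$lnc_id, gene_id = tp$gene_id,
                              rho = rep(c(0.8, -0.8), length.out = nrow(tp)),
                              stringsAsFactors = FALSE)
    } else {
      rho_pairs <- data.frame(lnc_id = character(), gene_id = character(),
                              rho = numeric(), stringsAsFactors = FALSE)
    }
  }
  if (any(abs(rho_pairs$rho) >= 1)) stop("|rho| must be < 1")

  tx <- rbind(ds$reference$transcripts[, c("transcript_id", "gene_id", "biotype",
                                           "spliced_length")],
              ds$candidates$transcripts[, c("transcript_id", "gene_id", "biotype",
                                            "spliced_length")])
  n_tx <- nrow(tx)
  baseline <- numeric(n_tx)
  baseline[tx$biotype == "coding"] <-
    exp(rnorm(sum(tx$biotype == "coding"), log(300), 0.8))
  baseline[tx$biotype == "ncRNA"] <-
    exp(rnorm(sum(tx$biotype == "ncRNA"), log(150), 0.5))
  novel <- tx$biotype == "novel"
  baseline[novel] <- exp(rnorm(sum(novel), log(40), 0.7))
  silent <- grepl("^DEC_silent", tx$transcript_id)
  baseline[silent] <- 0

  # condition ramp (0 at fastest growth -> 1 at slowest) and an orthogonal
  # secondary shape for the correlation mixture
  xx <- seq(0, 1, length.out = K)
  ramp <- xx
  zc <- (ramp - mean(ramp)) / sd(ramp)
  quad <- (xx - 0.5)^2
  wc <- quad - mean(quad) - sum((quad - mean(quad)) * zc) / sum(zc^2) * zc
  wc <- wc / sd(wc)

  lfc <- matrix(0, n_tx, K, dimnames = list(tx$transcript_id, conditions))
  coding_genes <- unique(tx$gene_id[tx$biotype == "coding"])
  excl <- unique(c(rho_pairs$gene_id, rho_pairs$lnc_id))
  de_pool <- setdiff(coding_genes, excl)
  de_genes <- sort(my_sample(de_pool, round(de_fraction * length(de_pool))))
  for (g in de_genes) {
    amp <- runif(1, effect_range[1L], effect_range[2L]) * sample(c(-1, 1), 1L)
    lfc[tx$gene_id == g, ] <- amp * ramp
  }
  A <- 1.5
  for (i in seq_len(nrow(rho_pairs))) {
    r <- rho_pairs$rho[i]
    lfc[tx$gene_id == rho_pairs$lnc_id[i], ] <- A * zc
    lfc[tx$gene_id == rho_pairs$gene_id[i], ] <- A * (r * zc + sqrt(1 - r^2) * wc)
  }
  de_lncs <- unique(rho_pairs$lnc_id)

  mu <- baseline * 2^lfc[, rep(seq_len(K), each = n_rep), drop = FALSE]
  colnames(mu) <- design$sample
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_tx, dimnames = dimnames(mu))
  counts[is.na(counts)] <- 0L

  lengths <- setNames(tx$spliced_length, tx$transcript_id)
  tpm <- suppressWarnings(compute_tpm(counts, lengths))

  all_genes <- unique(tx$gene_id)
  is_de <- all_genes %in% c(de_genes, de_lncs, rho_pairs$gene_id)
  de <- data.frame(gene_id = all_genes,
                   padj = ifelse(is_de, 1e-6, runif(length(all_genes), 0.2, 1)),
                   svalue = ifelse(is_de, 1e-4, runif(length(all_genes), 0.2, 1)),
                   stringsAsFactors = FALSE)

  structure(list(counts = counts, tpm = tpm, design = design, de = de,
                 tx2gene = setNames(tx$gene_id, tx$transcript_id),
                 truth = list(de_genes = de_genes, de_lncs = de_lncs,
                              rho_pairs = rho_pairs, dispersion = dispersion,
                              seed = seed)),
            class = "synthetic_expression")
}

#' One-call synthetic dataset: genome + triplex sites + expression
#'
#' @param seed Integer seed; sub-stages derive their own seeds from it.
#' @param ... Passed to [generate_genome_annotation].
#' @param n_sites Planted triplex sites (default 5).
#' @return List with elements `ds` (`synthetic_dataset`) and `expr`
#'   (`synthetic_expression`).
#' @export
synthetic_dataset <- function(seed, n_sites = 5, ...) {
  ds <- generate_genome_annotation(seed, ...)
  ds <- plant_triplex_sites(ds, seed = seed + 1L, n_sites = n_sites)
  expr <- simulate_expression(ds, seed = seed + 2L)
  list(ds = ds, expr = expr)
}

#' Write a synthetic dataset to disk in pipeline-ready formats
#'
#' FASTA genome, reference and candidate GTFs, counts/TPM/design/DE TSVs,
#' hit-table TSV and the ground truth as JSON.
#'
#' @param ds `synthetic_dataset`.
#' @param expr `synthetic_expression` (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, expr = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(ds$genome, file.path(dir, "genome.fa"))
  write_annotation(ds$reference, file.path(dir, "reference.gtf"))
  write_annotation(ds$candidates, file.path(dir, "candidates.gtf"))
  write.table(ds$hits, file.path(dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(expr)) {
    wr <- function(m, f) write.table(data.frame(feature = rownames(m), m,
                                                check.names = FALSE),
                                     file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wr(expr$counts, "counts.tsv")
    wr(expr$tpm, "tpm.tsv")
    write.table(expr$design, file.path(dir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(expr$de, file.path(dir, "de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
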