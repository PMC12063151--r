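#' Triplex search parameters
#'
#' Defaults follow the established triplex-prediction convention for
#' yeast-scale genomes: minimum triplex length 20 nt, at most 2 consecutive
#' errors, minimum guanine content 20 percent, overlapping sites merged.
#' The maximum error rate defaults to 0.05 (5 percent); it is a single
#' configurable knob.
#'
#' @param min_length Minimum tract/match length in nt (>= 10).
#' @param max_error_rate Maximum fraction of error positions (0 < x < 1).
#' @param max_consecutive_errors Longest tolerated error run.
#' @param min_guanine Minimum fraction of triad positions whose duplex base
#'   pair is G:C (G on the purine strand).
#' @param merge_overlapping When `TRUE` (default), overlapping windows of
#'   the same motif are collapsed to the single best window (longest, then
#'   fewest errors, then leftmost), so every reported record itself
#'   satisfies all constraints.
#' @return List of class `triplex_params`.
#' @export
triplex_params <- function(min_length = 20, max_error_rate = 0.05,
                           max_consecutive_errors = 2, min_guanine = 0.20,
                           merge_overlapping = TRUE) {
  stopifnot(min_length >= 10, max_error_rate > 0, max_error_rate < 1,
            max_consecutive_errors >= 0, min_guanine >= 0, min_guanine <= 1)
  structure(list(min_length = as.integer(min_length),
                 max_error_rate = max_error_rate,
                 max_consecutive_errors = as.integer(max_consecutive_errors),
                 min_guanine = min_guanine,
                 merge_overlapping = isTRUE(merge_overlapping)),
            class = "triplex_params")
}

# Maximal valid windows over a logical match vector.
#
# A window [i, j] is valid when: match[i] and match[j] are TRUE (tracts
# start and end on matching positions), j - i + 1 >= min_length, the error
# fraction is <= max_error_rate, it contains no error run longer than
# max_consecutive_errors, and the guanine fraction is >= min_guanine.
# Returned are the maximal valid windows (not contained in any other valid
# window); when merge = TRUE, overlapping maximal windows collapse to the
# best one. Long error runs partition the sequence into independent
# segments, which keeps the scan near-linear on realistic sequence.
maximal_windows <- function(match, guanine, params, merge = params$merge_overlapping) {
  n <- length(match)
  empty <- data.frame(start = integer(), end = integer(),
                      errors = integer(), guanines = integer())
  if (n < params$min_length) return(empty)
  err <- !match
  r <- rle(err)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths > params$max_consecutive_errors)
  seg_bounds <- rbind(
    cbind(c(1L, ends[long] + 1L), c(starts[long] - 1L, n)))
  out <- vector("list", nrow(seg_bounds))
  E <- cumsum(err)
  G <- cumsum(guanine)
  cs <- function(v, i) if (i == 0L) 0L else v[i]
  for (k in seq_len(nrow(seg_bounds))) {
    a <- seg_bounds[k, 1L]; b <- seg_bounds[k, 2L]
    if (b - a + 1L < params$min_length) next
    mpos <- which(match[a:b]) + a - 1L
    if (length(mpos) == 0L) next
    a <- mpos[1L]; b <- mpos[length(mpos)]
    if (b - a + 1L < params$min_length) next
    keep <- list(); best_so_far <- 0L
    for (i in mpos[mpos <= b - params$min_length + 1L]) {
      js <- mpos[mpos >= i + params$min_length - 1L]
      if (length(js) == 0L) break
      len <- js - i + 1L
      errs <- E[js] - cs(E, i - 1L)
      gs <- G[js] - cs(G, i - 1L)
      ok <- errs <= params$max_error_rate * len + 1e-9 &
        gs >= params$min_guanine * len - 1e-9
      if (!any(ok)) next
      j <- max(js[ok])
      if (j > best_so_far) {
        best_so_far <- j
        keep[[length(keep) + 1L]] <- c(i, j, E[j] - cs(E, i - 1L),
                                       G[j] - cs(G, i - 1L))
      }
    }
    if (length(keep)) {
      w <- do.call(rbind, keep)
      df <- data.frame(start = w[, 1L], end = w[, 2L],
                       errors = w[, 3L], guanines = w[, 4L])
      out[[k]] <- if (merge) merge_best(df) else df
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

# Collapse chains of mutually overlapping windows to the single best window
# (longest, then fewest errors, then leftmost).
merge_best <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(df$start[-1L] > cummax(df$end)[-nrow(df)])))
  picked <- lapply(split(df, grp), function(g) {
    len <- g$end - g$start + 1L
    g[order(-len, g$errors, g$start)[1L], , drop = FALSE]
  })
  res <- do.call(rbind, picked)
  rownames(res) <- NULL
  res
}

motif_sets <- list(
  R = list(match = c("G", "A"), guanine = "G"),  # purine motif, antiparallel
  Y = list(match = c("C", "T"), guanine = "C"),  # pyrimidine motif, parallel
  M = list(match = c("G", "T"), guanine = "G")   # mixed motif, antiparallel
)

# TFO base -> purine-strand base it reads (Hoogsteen pairing)
motif_pairing <- list(
  R = c(G = "G", A = "A"),
  Y = c(C = "G", T = "A"),
  M = c(G = "G", T = "A")
)
motif_orientation <- c(R = "antiparallel", Y = "parallel", M = "antiparallel")

seq_chars <- function(seq) {
  s <- chartr("u", "t", chartr("U", "T", toupper(as.character(seq))))
  strsplit(s, "", fixed = TRUE)[[1L]]
}

#' Candidate triplex tracts in a single sequence
#'
#' For `kind = "TFO_on_rna"`, maximal windows over the three triplex motif
#' alphabets — R \{G,A\}, Y \{C,T/U\}, M \{G,T/U\} — are reported;
#' positions outside the motif alphabet count as errors, and the guanine
#' fraction counts triad positions pairing with a duplex G:C (G for R/M,
#' C for Y). For `kind = "TTS_on_duplex"`, both strands are examined as the
#' potential purine strand (the given sequence, and per-position its
#' complement), with pyrimidine interruptions on the purine strand counted
#' as errors; coordinates always refer to the input strand.
#'
#' @param seq Character scalar or `DNAString`.
#' @param params [triplex_params].
#' @param kind `"TFO_on_rna"` or `"TTS_on_duplex"`.
#' @return data.frame: `start`, `end` (1-based on the input sequence),
#'   `length`, `motif` (R/Y/M for TFOs, `NA` for TTSs), `purine_strand`
#'   (`"+"`/`"-"` for TTSs, `NA` for TFOs), `errors`, `guanine_fraction`.
#' @export
find_tracts <- function(seq, params = triplex_params(),
                        kind = c("TFO_on_rna", "TTS_on_duplex")) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "triplex_params"))
  chars <- seq_chars(seq)
  if (length(chars) == 0L) stop("empty sequence")
  rows <- list()
  if (kind == "TFO_on_rna") {
    for (m in names(motif_sets)) {
      ms <- motif_sets[[m]]
      w <- maximal_windows(chars %in% ms$match, chars == ms$guanine, params)
      if (nrow(w)) {
        w$motif <- m; w$purine_strand <- NA_character_
        rows[[m]] <- w
      }
    }
  } else {
    views <- list(`+` = list(match = c("A", "G"), guanine = "G"),
                  `-` = list(match = c("C", "T"), guanine = "C"))
    for (v in names(views)) {
      vs <- views[[v]]
      w <- maximal_windows(chars %in% vs$match, chars == vs$guanine, params)
      if (nrow(w)) {
        w$motif <- NA_character_; w$purine_strand <- v
        rows[[v]] <- w
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      motif = character(), purine_strand = character(),
                      errors = integer(), guanine_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start + 1L
  out$guanine_fraction <- out$guanines / out$length
  rownames(out) <- NULL
  out[order(out$start, out$end, out$motif, out$purine_strand, na.last = TRUE),
      c("start", "end", "length", "motif", "purine_strand", "errors",
        "guanine_fraction")]
}

#' TFO tracts across a set of lncRNA sequences
#' @param seqs Named character vector or `DNAStringSet` of RNA-sense
#'   lncRNA sequences.
#' @param params [triplex_params].
#' @return data.frame with a leading `lnc_id` column (plus the sequence of
#'   each tract in `seq`).
#' @export
find_tfo_tracts <- function(seqs, params = triplex_params()) {
  seqs <- setNames(as.character(seqs), names(seqs))
  stopifnot(!is.null(names(seqs)))
  res <- lapply(names(seqs), function(id) {
    tr <- find_tracts(seqs[[id]], params, kind = "TFO_on_rna")
    if (nrow(tr) == 0L) return(NULL)
    tr$lnc_id <- id
    tr$seq <- substring(chartr("Uu", "Tt", toupper(seqs[[id]])), tr$start, tr$end)
    tr
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(), length = integer(),
                      motif = character(), purine_strand = character(),
                      errors = integer(), guanine_fraction = numeric(),
                      lnc_id = character(), seq = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[, c("lnc_id", "start", "end", "length", "motif", "errors",
          "guanine_fraction", "seq")]
}

#' TTS tracts across a genome
#' @param genome `DNAStringSet` or named character vector of chromosomes.
#' @param params [triplex_params].
#' @return data.frame with a leading `chrom` column and the purine-strand
#'   sequence of each tract (5'->3') in `purine_seq`.
#' @export
find_tts_tracts <- function(genome, params = triplex_params()) {
  genome <- setNames(as.character(genome), names(genome))
  stopifnot(!is.null(names(genome)))
  res <- lapply(names(genome), function(chrom) {
    tr <- find_tracts(genome[[chrom]], params, kind = "TTS_on_duplex")
    if (nrow(tr) == 0L) return(NULL)
    tr$chrom <- chrom
    plus <- substring(toupper(genome[[chrom]]), tr$start, tr$end)
    tr$purine_seq <- ifelse(
      tr$purine_strand == "+", plus,
      vapply(plus, function(x)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
        character(1), USE.NAMES = FALSE))
    tr
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(), length = integer(),
                      motif = character(), purine_strand = character(),
                      errors = integer(), guanine_fraction = numeric(),
                      chrom = character(), purine_seq = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "length", "purine_strand", "errors",
          "guanine_fraction", "purine_seq")]
}

# All valid alignment windows of one TFO tract against one TTS tract under
# one motif's pairing rule. tfo_seq and purine_seq are plain upper-case
# character scalars; returns transcript/genome-free local coordinates.
align_tfo_tts <- function(tfo_seq, purine_seq, motif, params) {
  pair <- motif_pairing[[motif]]
  tchars <- seq_chars(tfo_seq)
  pchars <- seq_chars(purine_seq)
  expected <- unname(pair[tchars])          # NA where TFO base outside motif
  antip <- motif_orientation[[motif]] == "antiparallel"
  if (antip) expected <- rev(expected)
  nt <- length(expected); np <- length(pchars)
  if (nt < params$min_length || np < params$min_length) return(NULL)
  rows <- list()
  # offset o: expected[i] aligned to pchars[i + o]
  for (o in seq.int(-(nt - params$min_length), np - params$min_length)) {
    i1 <- max(1L, 1L - o); i2 <- min(nt, np - o)
    if (i2 - i1 + 1L < params$min_length) next
    idx <- i1:i2
    pidx <- idx + o
    mvec <- !is.na(expected[idx]) & expected[idx] == pchars[pidx]
    gvec <- pchars[pidx] == "G"
    w <- maximal_windows(mvec, gvec, params)
    if (nrow(w) == 0L) next
    # local coordinates: on the (possibly reversed) TFO and the purine seq
    w$tfo_lo <- idx[w$start]; w$tfo_hi <- idx[w$end]
    w$tts_lo <- pidx[w$start]; w$tts_hi <- pidx[w$end]
    if (antip) {  # map back to 5'->3' TFO coordinates
      lo <- nt - w$tfo_hi + 1L; hi <- nt - w$tfo_lo + 1L
      w$tfo_lo <- lo; w$tfo_hi <- hi
    }
    rows[[length(rows) + 1L]] <- w
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Match TFO tracts against TTS tracts into triplex interactions
#'
#' A pair is reported when an alignment of the TFO against the TTS purine
#' strand under the motif's Hoogsteen pairing rule — R: G:G, A:A
#' (antiparallel); Y: C:G, T:A (parallel); M: G:G, T:A (antiparallel) —
#' has length >= `min_length` and satisfies the error, consecutive-error
#' and guanine constraints. With `merge_overlapping`, reported matches of
#' one (lncRNA, motif) pair overlapping on the genome collapse to the best
#' match.
#'
#' @param tfos data.frame from [find_tfo_tracts].
#' @param ttss data.frame from [find_tts_tracts].
#' @param params [triplex_params] (use the same params the tracts were
#'   produced with).
#' @return data.frame of interactions: `lnc_id`, `tfo_start`, `tfo_end`
#'   (transcript coordinates), `chrom`, `tts_start`, `tts_end` (genome
#'   coordinates on the input strand), `purine_strand`, `motif`, `length`,
#'   `errors`, `guanine_fraction`.
#' @export
match_triplexes <- function(tfos, ttss, params = triplex_params()) {
  empty <- data.frame(lnc_id = character(), tfo_start = integer(),
                      tfo_end = integer(), chrom = character(),
                      tts_start = integer(), tts_end = integer(),
                      purine_strand = character(), motif = character(),
                      length = integer(), errors = integer(),
                      guanine_fraction = numeric(), stringsAsFactors = FALSE)
  if (is.null(tfos) || nrow(tfos) == 0L || is.null(ttss) || nrow(ttss) == 0L)
    return(empty)
  rows <- list()
  for (i in seq_len(nrow(tfos))) {
    for (j in seq_len(nrow(ttss))) {
      w <- align_tfo_tts(tfos$seq[i], ttss$purine_seq[j], tfos$motif[i], params)
      if (is.null(w)) next
      np <- nchar(ttss$purine_seq[j])
      # purine-seq coordinates -> genome coordinates on the input strand
      if (ttss$purine_strand[j] == "+") {
        g_lo <- ttss$start[j] + w$tts_lo - 1L
        g_hi <- ttss$start[j] + w$tts_hi - 1L
      } else {  # purine strand read 5'->3' is the reverse complement
        g_lo <- ttss$end[j] - w$tts_hi + 1L
        g_hi <- ttss$end[j] - w$tts_lo + 1L
      }
      len <- w$end - w$start + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_id = tfos$lnc_id[i],
        tfo_start = tfos$start[i] + w$tfo_lo - 1L,
        tfo_end = tfos$start[i] + w$tfo_hi - 1L,
        chrom = ttss$chrom[j],
        tts_start = g_lo, tts_end = g_hi,
        purine_strand = ttss$purine_strand[j],
        motif = tfos$motif[i],
        length = len, errors = w$errors,
        guanine_fraction = w$guanines / len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- unique(out)
  if (params$merge_overlapping) {
    key <- paste(out$lnc_id, out$motif, out$chrom, out$purine_strand)
    merged <- lapply(split(out, key), function(g) {
      if (nrow(g) == 1L) return(g)
      g <- g[order(g$tts_start, g$tts_end), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(
        g$tts_start[-1L] > cummax(g$tts_end)[-nrow(g)])))
      do.call(rbind, lapply(split(g, grp), function(h) {
        h[order(-h$length, h$errors, h$tts_start)[1L], , drop = FALSE]
      }))
    })
    out <- do.call(rbind, merged)
  }
  out <- out[order(out$chrom, out$tts_start, out$lnc_id, out$motif), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end triplex prediction for a lncRNA set against a genome
#'
#' @param lnc_seqs Named sequences (RNA sense) of the lncRNAs, e.g. from
#'   [extract_sequences].
#' @param genome `DNAStringSet` / named character vector of chromosomes.
#' @param params [triplex_params].
#' @return Interactions data.frame as from [match_triplexes].
#' @export
predict_triplexes <- function(lnc_seqs, genome, params = triplex_params()) {
  tfos <- find_tfo_tracts(lnc_seqs, params)
  ttss <- find_tts_tracts(genome, params)
  match_triplexes(tfos, ttss, params)
}

#' Promoter windows around every transcription start site
#' @param annotation AnnotationSet.
#' @param upstream,downstream Window extent in bases; the TSS itself counts
#'   as the first downstream base, so the window covers
#'   `[TSS - upstream, TSS + downstream - 1]` in transcript orientation,
#'   clipped to the chromosome.
#' @return `GRanges` (strand-less) with a `gene_id` column, one window per
#'   transcript.
#' @export
promoter_ranges <- function(annotation, upstream = 1000, downstream = 250) {
  tx <- annotation$transcripts
  tss <- ifelse(tx$strand == "-", tx$end, tx$start)
  lo <- ifelse(tx$strand == "-", tss - downstream + 1, tss - upstream)
  hi <- ifelse(tx$strand == "-", tss + upstream, tss + downstream - 1)
  lo <- pmax(lo, 1)
  hi <- pmin(hi, annotation$chrom_lengths[tx$chrom])
  gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(lo, hi), strand = "*")
  S4Vectors::mcols(gr)$gene_id <- tx$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tx$transcript_id
  gr
}

#' Strand-independent priority partition of the genome
#'
#' Every base of every chromosome is assigned exactly one class with
#' priority promoter > exon > intron > intergenic. Promoters are windows of
#' `promoter_def["upstream"]` bases upstream and
#' `promoter_def["downstream"]` bases downstream (TSS included) of every
#' transcript's transcription start; introns are transcript-span bases not
#' covered by exons.
#'
#' @param annotation AnnotationSet with chromosome lengths.
#' @param promoter_def Named vector `c(upstream=, downstream=)`; default
#'   `c(1000, 250)`.
#' @return List of class `genome_context`: `classes` (named list of
#'   strand-less, reduced `GRanges` partitioning the genome), `fractions`
#'   (named numeric summing to 1), `promoter_def`, `chrom_lengths`.
#' @export
classify_genome_context <- function(annotation,
                                    promoter_def = c(upstream = 1000, downstream = 250)) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  cl <- annotation$chrom_lengths
  genome_gr <- GenomicRanges::GRanges(names(cl), IRanges::IRanges(1, unname(cl)))
  strip <- function(gr) {
    gr <- GenomicRanges::granges(gr)
    GenomicRanges::strand(gr) <- "*"
    GenomeInfoDb::seqlevels(gr) <- names(cl)
    GenomicRanges::reduce(gr)
  }
  if (nrow(annotation$transcripts) == 0L) {
    prom <- exon <- intron <- GenomicRanges::GRanges()
    intergenic <- genome_gr
  } else {
    prom <- strip(promoter_ranges(annotation, promoter_def[["upstream"]],
                                  promoter_def[["downstream"]]))
    ex_all <- strip(annotation$exons)
    spans <- strip(transcript_ranges(annotation))
    exon <- GenomicRanges::setdiff(ex_all, prom)
    intron <- GenomicRanges::setdiff(
      GenomicRanges::setdiff(spans, ex_all), prom)
    covered <- GenomicRanges::reduce(c(prom, ex_all, spans))
    intergenic <- GenomicRanges::setdiff(genome_gr, covered)
  }
  classes <- list(promoter = prom, exon = exon, intron = intron,
                  intergenic = intergenic)
  total <- sum(cl)
  fractions <- vapply(classes, function(g) sum(as.numeric(GenomicRanges::width(g))) / total,
                      numeric(1))
  structure(list(classes = classes, fractions = fractions,
                 promoter_def = promoter_def, chrom_lengths = cl),
            class = "genome_context")
}

#' @export
print.genome_context <- function(x, ...) {
  cat("genome_context fractions:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Label interactions with their highest-priority genomic context
#'
#' Each interaction's TTS takes the single highest-priority class it
#' overlaps (promoter > exon > intron > intergenic): a TTS spanning both a
#' promoter and an exon is classed as promoter only.
#'
#' @param interactions data.frame from [match_triplexes] /
#'   [predict_triplexes].
#' @param context_map A [classify_genome_context] result covering all TTS
#'   chromosomes.
#' @return `interactions` with a `context` column appended.
#' @export
assign_interaction_context <- function(interactions, context_map) {
  stopifnot(inherits(context_map, "genome_context"))
  if (nrow(interactions) == 0L) {
    interactions$context <- character(0)
    return(interactions)
  }
  missing <- setdiff(unique(interactions$chrom), names(context_map$chrom_lengths))
  if (length(missing)) stop("context map lacks chromosome(s): ",
                            paste(missing, collapse = ", "))
  if (any(interactions$tts_start < 1 |
          interactions$tts_end > context_map$chrom_lengths[interactions$chrom]))
    stop("TTS outside genome bounds")
  tts <- GenomicRanges::GRanges(interactions$chrom,
                                IRanges::IRanges(interactions$tts_start,
                                                 interactions$tts_end))
  ctx <- rep("intergenic", nrow(interactions))
  for (class in c("intron", "exon", "promoter")) {  # ascending priority
    hit <- IRanges::overlapsAny(tts, context_map$classes[[class]],
                                      ignore.strand = TRUE)
    ctx[hit] <- class
  }
  interactions$context <- ctx
  interactions
}

#' Unique interacting lncRNA-gene pairs per genomic scope
#'
#' For each scope the set of distinct (lncRNA, gene) pairs whose TTS lies in
#' the gene's scope region: `Promoter` (windows around the gene's
#' transcription starts, default 1500 up / 250 down), `Exon` (the gene's
#' exons) and `GenePromoter` (gene span plus promoter). Overlap is
#' strand-independent. A gene may pair with many lncRNAs and vice versa.
#'
#' @param interactions data.frame of triplex interactions.
#' @param annotation AnnotationSet of (coding) genes; only transcripts with
#'   biotype `"coding"` define scope regions when any are present.
#' @param promoter_def Promoter window for the pairing scope, default
#'   `c(upstream = 1500, downstream = 250)`.
#' @return List of class `interaction_pairs` with one element per scope,
#'   each a list: `pairs` (data.frame `lnc_id`, `gene_id`),
#'   `n_interactions`, `per_lnc` and `per_gene` pair counts.
#' @export
interaction_pairs <- function(interactions, annotation,
                              promoter_def = c(upstream = 1500, downstream = 250)) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  ann <- annotation
  if (any(ann$transcripts$biotype == "coding")) {
    ann <- subset_annotation(
      ann, ann$transcripts$transcript_id[ann$transcripts$biotype == "coding"])
  }
  prom <- promoter_ranges(ann, promoter_def[["upstream"]], promoter_def[["downstream"]])
  exons <- GenomicRanges::granges(ann$exons)
  S4Vectors::mcols(exons)$gene_id <- S4Vectors::mcols(ann$exons)$gene_id
  genes <- gene_ranges(ann)
  gene_prom <- c(GenomicRanges::granges(genes), GenomicRanges::granges(prom))
  S4Vectors::mcols(gene_prom)$gene_id <- c(S4Vectors::mcols(genes)$gene_id,
                                           S4Vectors::mcols(prom)$gene_id)
  scopes <- list(Promoter = prom, Exon = exons, GenePromoter = gene_prom)
  tts <- if (nrow(interactions)) {
    GenomicRanges::GRanges(interactions$chrom,
                           IRanges::IRanges(interactions$tts_start,
                                            interactions$tts_end))
  } else GenomicRanges::GRanges()
  out <- lapply(scopes, function(region) {
    hits <- GenomicRanges::findOverlaps(tts, region, ignore.strand = TRUE)
    if (length(hits) == 0L) {
      return(list(pairs = data.frame(lnc_id = character(), gene_id = character(),
                                     stringsAsFactors = FALSE),
                  n_interactions = 0L,
                  per_lnc = integer(0), per_gene = integer(0)))
    }
    df <- data.frame(
      lnc_id = interactions$lnc_id[S4Vectors::queryHits(hits)],
      gene_id = S4Vectors::mcols(region)$gene_id[S4Vectors::subjectHits(hits)],
      interaction = S4Vectors::queryHits(hits),
      stringsAsFactors = FALSE)
    pairs <- unique(df[, c("lnc_id", "gene_id")])
    pairs <- pairs[order(pairs$lnc_id, pairs$gene_id), , drop = FALSE]
    rownames(pairs) <- NULL
    list(pairs = pairs,
         n_interactions = length(unique(df$interaction)),
         per_lnc = table(unique(df[, c("lnc_id", "interaction")])$lnc_id),
         per_gene = table(unique(df[, c("gene_id", "interaction")])$gene_id))
  })
  structure(out, class = "interaction_pairs")
}

#' Write interactions (or tracts) as a BED-like TSV
#' @param x data.frame.
#' @param path Output TSV.
#' @export
write_triplex_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
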