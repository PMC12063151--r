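#' @importFrom methods is
#' @importFrom stats median sd cor pt setNames quantile ks.test rnbinom runif
#'   rnorm density dist
#' @importFrom utils read.delim write.table head
#' @importFrom graphics hist
NULL

#' Annotation set: transcripts, their exons and chromosome lengths
#'
#' The central genomic container of the package. Exons are held as a
#' [GenomicRanges::GRanges] (1-based, closed intervals — the Bioconductor
#' convention; GTF/BED conversions happen only at the I/O boundary) carrying
#' `transcript_id`, `gene_id` and `biotype` metadata columns. A transcript's
#' span is the hull of its exons.
#'
#' @param exons A `GRanges` of exon intervals with metadata columns
#'   `transcript_id`, `gene_id` and optionally `biotype` (one of `"coding"`,
#'   `"ncRNA"`, `"novel"`, `"lncRNA"`; default `"novel"`).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bases).
#'   If `NULL`, lengths are taken from `seqlengths(exons)` when set, else
#'   inferred as the maximum exon end per chromosome (a lower bound).
#'
#' @return An object of class `AnnotationSet`: a list with elements `exons`
#'   (sorted `GRanges`), `transcripts` (data.frame with one row per
#'   transcript: `transcript_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `n_exons`, `spliced_length`) and `chrom_lengths`.
#' @export
AnnotationSet <- function(exons, chrom_lengths = NULL) {
  stopifnot(is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("every exon needs a transcript_id")
  if (is.null(mc$gene_id)) mc$gene_id <- mc$transcript_id
  if (is.null(mc$biotype)) mc$biotype <- "novel"
  bad <- !mc$biotype %in% c("coding", "ncRNA", "novel", "lncRNA")
  if (any(bad)) stop("unknown biotype: ", paste(unique(mc$biotype[bad]), collapse = ", "))
  S4Vectors::mcols(exons) <- mc[, c("transcript_id", "gene_id", "biotype")]
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)

  # per-transcript consistency: single chrom and strand
  tid <- as.character(mc <- S4Vectors::mcols(exons)$transcript_id)
  chrom <- as.character(GenomicRanges::seqnames(exons))
  strand <- as.character(GenomicRanges::strand(exons))
  if (any(vapply(split(chrom, tid), function(x) length(unique(x)) > 1L, logical(1)))) {
    stop("exons of one transcript on multiple chromosomes")
  }
  if (any(vapply(split(strand, tid), function(x) length(unique(x)) > 1L, logical(1)))) {
    stop("exons of one transcript on multiple strands")
  }
  ir <- split(IRanges::ranges(exons), tid)
  if (any(!vapply(as.list(ir), IRanges::isDisjoint, logical(1)))) {
    stop("overlapping exons within one transcript")
  }

  first <- !duplicated(tid)
  spl <- vapply(split(GenomicRanges::width(exons), tid), sum, numeric(1))
  nex <- vapply(split(tid, tid), length, integer(1))
  st <- vapply(split(GenomicRanges::start(exons), tid), min, numeric(1))
  en <- vapply(split(GenomicRanges::end(exons), tid), max, numeric(1))
  ids <- tid[first]
  transcripts <- data.frame(
    transcript_id = ids,
    gene_id = as.character(S4Vectors::mcols(exons)$gene_id[first]),
    chrom = chrom[first],
    start = unname(st[ids]),
    end = unname(en[ids]),
    strand = strand[first],
    biotype = as.character(S4Vectors::mcols(exons)$biotype[first]),
    n_exons = unname(nex[ids]),
    spliced_length = unname(spl[ids]),
    stringsAsFactors = FALSE
  )
  rownames(transcripts) <- transcripts$transcript_id

  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb::seqlengths(exons)
    if (all(!is.na(sl))) {
      chrom_lengths <- sl
    } else {
      chrom_lengths <- vapply(split(en, chrom[match(ids, tid)]), max, numeric(1))
    }
  }
  chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  missing <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(missing)) stop("no chromosome length for: ", paste(missing, collapse = ", "))
  if (any(transcripts$end > chrom_lengths[transcripts$chrom]))
    stop("transcript extends beyond chromosome length")

  structure(list(exons = exons, transcripts = transcripts,
                 chrom_lengths = chrom_lengths),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d transcripts (%d genes) on %d chromosome(s)\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              length(x$chrom_lengths)))
  print(table(x$transcripts$biotype))
  invisible(x)
}

#' @export
length.AnnotationSet <- function(x) nrow(x$transcripts)

#' Subset an AnnotationSet by transcript ids
#' @param x AnnotationSet.
#' @param ids Character vector of transcript ids to keep.
#' @return AnnotationSet restricted to `ids`.
#' @export
subset_annotation <- function(x, ids) {
  stopifnot(inherits(x, "AnnotationSet"))
  missing <- setdiff(ids, x$transcripts$transcript_id)
  if (length(missing)) stop("unknown transcript ids: ", paste(head(missing), collapse = ", "))
  keep <- S4Vectors::mcols(x$exons)$transcript_id %in% ids
  AnnotationSet(x$exons[keep], chrom_lengths = x$chrom_lengths)
}

#' Transcript spans as a GRanges
#' @param x AnnotationSet.
#' @return `GRanges` of transcript spans (hull of exons), named by
#'   transcript id, with `transcript_id`, `gene_id`, `biotype` columns.
#' @export
transcript_ranges <- function(x) {
  stopifnot(inherits(x, "AnnotationSet"))
  tx <- x$transcripts
  gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                               strand = tx$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id, biotype = tx$biotype)
  names(gr) <- tx$transcript_id
  gr
}

#' Gene spans (hull over all member transcripts) as a GRanges
#' @param x AnnotationSet.
#' @return `GRanges` named by gene id with a `gene_id` column.
#' @export
gene_ranges <- function(x) {
  tr <- transcript_ranges(x)
  sp <- S4Vectors::split(tr, S4Vectors::mcols(tr)$gene_id)
  gr <- unlist(GenomicRanges::reduce(sp, min.gapwidth = 1e9), use.names = TRUE)
  S4Vectors::mcols(gr)$gene_id <- names(gr)
  gr
}

validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop(sprintf("malformed GTF record at line %d: expected 9 tab-separated fields, got %d",
                 idx[which(nf < 9L)[1L]], nf[which(nf < 9L)[1L]]))
  }
  types <- vapply(fields, `[[`, "", 3L)
  attrs <- vapply(fields, `[[`, "", 9L)
  ex <- types == "exon"
  noid <- ex & !grepl("transcript_id", attrs, fixed = TRUE)
  if (any(noid)) {
    stop(sprintf("exon without transcript_id attribute at line %d", idx[which(noid)[1L]]))
  }
  invisible(TRUE)
}

#' Read a GTF/GFF3 annotation into an AnnotationSet
#'
#' Exon features are grouped into transcripts; the transcript span is the
#' hull of its exons. GTF's 1-based closed coordinates map directly onto the
#' internal `GRanges` representation.
#'
#' @param path GTF or GFF3 file.
#' @param chrom_lengths Optional named vector, or a two-column file
#'   (chrom, length) readable by [utils::read.delim].
#' @return [AnnotationSet].
#' @export
read_annotation <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gtf$", path, ignore.case = TRUE)) validate_gtf_lines(path)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  ex <- gr[!is.na(mc$type) & mc$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (is.null(S4Vectors::mcols(ex)$transcript_id) ||
      anyNA(S4Vectors::mcols(ex)$transcript_id))
    stop("exon feature lacking a transcript_id attribute in ", path)
  bt <- S4Vectors::mcols(ex)$transcript_biotype
  if (is.null(bt)) bt <- rep(NA_character_, length(ex))
  bt[is.na(bt)] <- "novel"
  S4Vectors::mcols(ex)$biotype <- bt
  if (is.character(chrom_lengths) && length(chrom_lengths) == 1L &&
      file.exists(chrom_lengths)) {
    tab <- read.delim(chrom_lengths, header = FALSE, stringsAsFactors = FALSE)
    chrom_lengths <- setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
  }
  AnnotationSet(ex, chrom_lengths = chrom_lengths)
}

#' Write an AnnotationSet as GTF
#'
#' Emits one `transcript` feature plus its `exon` features per transcript,
#' with `transcript_id`, `gene_id` and `transcript_biotype` attributes.
#' Round-trips through [read_annotation] coordinate-exactly.
#'
#' @param x AnnotationSet.
#' @param path Output file.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "AnnotationSet"))
  tr <- transcript_ranges(x)
  S4Vectors::mcols(tr)$type <- "transcript"
  ex <- x$exons
  S4Vectors::mcols(ex)$type <- "exon"
  ord <- order(match(S4Vectors::mcols(ex)$transcript_id, names(tr)))
  ex <- ex[ord]
  all <- c(tr, ex)
  all <- all[order(match(S4Vectors::mcols(all)$transcript_id, names(tr)),
                   S4Vectors::mcols(all)$type == "exon",
                   GenomicRanges::start(all))]
  names(all) <- NULL
  S4Vectors::mcols(all)$transcript_biotype <- S4Vectors::mcols(all)$biotype
  S4Vectors::mcols(all)$biotype <- NULL
  S4Vectors::mcols(all)$source <- "lncscout"
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Write intervals as BED6
#' @param gr GRanges (names used as the BED name column when present).
#' @param path Output file.
#' @export
write_bed6 <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a multi-record (possibly line-wrapped) FASTA genome
#' @param path FASTA file.
#' @return `DNAStringSet` named by the first whitespace-separated token of
#'   each header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#' @param genome DNAStringSet.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Spliced, RNA-sense transcript sequences
#'
#' Exon sequences are concatenated 5'-to-3' in transcript orientation;
#' minus-strand transcripts are reverse-complemented.
#'
#' @param x AnnotationSet.
#' @param genome `DNAStringSet` (or named character vector) of chromosome
#'   sequences.
#' @param ids Transcript ids to extract (default: all).
#' @return `DNAStringSet` named by transcript id.
#' @export
extract_sequences <- function(x, genome, ids = NULL) {
  stopifnot(inherits(x, "AnnotationSet"))
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(ids)) ids <- x$transcripts$transcript_id
  ex <- x$exons
  tid <- S4Vectors::mcols(ex)$transcript_id
  out <- lapply(ids, function(id) {
    e <- ex[tid == id]
    if (length(e) == 0L) stop("unknown transcript id: ", id)
    chrom <- as.character(GenomicRanges::seqnames(e))[1L]
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    clen <- length(genome[[chrom]])
    if (any(GenomicRanges::end(e) > clen))
      stop("exon of ", id, " beyond end of chromosome ", chrom)
    pieces <- Biostrings::extractAt(genome[[chrom]], IRanges::ranges(e))
    s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (as.character(GenomicRanges::strand(e))[1L] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  res <- Biostrings::DNAStringSet(out)
  names(res) <- ids
  res
}

#' Overlap length of two genomic intervals
#'
#' @param a,b `GRanges` of length 1.
#' @param mode `"same_strand"`, `"opposite_strand"` or `"any"`. Strand `*`
#'   satisfies both strand conditions.
#' @return Number of overlapping bases (0 when on different chromosomes,
#'   when the strand condition is unmet, or when disjoint).
#' @export
overlap_length <- function(a, b, mode = c("any", "same_strand", "opposite_strand")) {
  mode <- match.arg(mode)
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))) return(0L)
  sa <- as.character(GenomicRanges::strand(a))
  sb <- as.character(GenomicRanges::strand(b))
  if (mode == "same_strand" && sa != "*" && sb != "*" && sa != sb) return(0L)
  if (mode == "opposite_strand" && sa != "*" && sb != "*" && sa == sb) return(0L)
  max(0L, min(GenomicRanges::end(a), GenomicRanges::end(b)) -
        max(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L)
}

#' Genes within a window of a query transcript
#'
#' Gap distance between spans (0 when overlapping), signed negative when the
#' target lies upstream (lower genomic coordinates) of the query. Results are
#' sorted by |distance|, ties broken by smaller target start.
#'
#' @param query A transcript id present in `query_set`, or a length-1
#'   `GRanges`.
#' @param query_set AnnotationSet containing `query` (ignored when `query`
#'   is a `GRanges`).
#' @param targets AnnotationSet of target genes.
#' @param window Maximum gap in bases (>= 0).
#' @return data.frame with `gene_id`, `distance`, `start`, `end`, `strand`.
#' @export
nearest_neighbors <- function(query, targets, query_set = NULL, window = 2000) {
  stopifnot(window >= 0)
  if (is.character(query)) {
    stopifnot(inherits(query_set, "AnnotationSet"))
    q <- transcript_ranges(query_set)[query]
  } else {
    q <- query
  }
  stopifnot(is(q, "GRanges"), length(q) == 1L)
  g <- gene_ranges(targets)
  same <- as.character(GenomicRanges::seqnames(g)) ==
    as.character(GenomicRanges::seqnames(q))
  g <- g[same]
  if (length(g) == 0L) {
    return(data.frame(gene_id = character(), distance = numeric(),
                      start = numeric(), end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  qs <- GenomicRanges::start(q); qe <- GenomicRanges::end(q)
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  dist <- ifelse(ge < qs, -(qs - ge - 1L),          # target upstream
                 ifelse(gs > qe, gs - qe - 1L, 0L)) # downstream / overlap
  keep <- abs(dist) <= window
  out <- data.frame(gene_id = names(g)[keep], distance = dist[keep],
                    start = gs[keep], end = ge[keep],
                    strand = as.character(GenomicRanges::strand(g))[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$distance), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
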