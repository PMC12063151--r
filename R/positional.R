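#' Positional classification of a lncRNA relative to coding genes
#'
#' Categories relative to the nearest protein-coding gene:
#' \describe{
#'   \item{antisense_exonic}{an exon of the lncRNA overlaps an exon of a
#'     coding gene on the opposite strand; the partner is the gene with the
#'     largest total exon overlap.}
#'   \item{upstream_sense / downstream_sense}{same strand as the partner,
#'     located on the partner's 5' / 3' side (in partner orientation).}
#'   \item{divergent}{opposite strand, on the 5' side of the partner's
#'     transcription start (head-to-head, transcribed away from each other).}
#'   \item{convergent}{opposite strand, on the 3' side of the partner's
#'     transcription end (tail-to-tail).}
#'   \item{intergenic_unassigned}{no coding gene within `max_window`.}
#' }
#' The partner (when not antisense-exonic) is the nearest coding gene by
#' span gap, ties broken by smaller gene start. A lncRNA overlapping the
#' partner's span without exon overlap (e.g. antisense-intronic) is sided by
#' comparing span midpoints; a midpoint tie counts as the 5' side.
#' Same-strand exon overlap is an error: such transcripts should have been
#' removed by the sense-overlap filter.
#'
#' @param lnc A transcript id in `lncs`, or a length-1 `GRanges` span (then
#'   exon-level antisense overlap is assessed on the span).
#' @param coding AnnotationSet of protein-coding genes.
#' @param lncs AnnotationSet containing `lnc` when given as an id.
#' @param max_window Maximum span gap to a partner gene (default 10000).
#' @return List of class `positional_call`: `lnc_id`, `partner_gene_id`
#'   (`NA` when unassigned), `category`, `distance` (gap in bases, 0 when
#'   overlapping).
#' @export
classify_position <- function(lnc, coding, lncs = NULL, max_window = 10000) {
  stopifnot(inherits(coding, "AnnotationSet"))
  if (nrow(coding$transcripts) == 0L) stop("empty coding annotation")
  if (is.character(lnc)) {
    stopifnot(inherits(lncs, "AnnotationSet"))
    lnc_id <- lnc
    span <- transcript_ranges(lncs)[lnc_id]
    lexons <- lncs$exons[S4Vectors::mcols(lncs$exons)$transcript_id == lnc_id]
  } else {
    stopifnot(is(lnc, "GRanges"), length(lnc) == 1L)
    span <- lnc
    lnc_id <- if (!is.null(names(lnc))) names(lnc) else "query"
    lexons <- lnc
  }
  if (any(coding$transcripts$biotype == "coding")) {
    coding <- subset_annotation(
      coding, coding$transcripts$transcript_id[coding$transcripts$biotype == "coding"])
  }
  cod <- coding$exons

  # sense exon overlap should not reach this stage
  sh <- GenomicRanges::findOverlaps(lexons, cod, ignore.strand = FALSE)
  if (length(sh) > 0L)
    stop(lnc_id, " overlaps a coding exon in sense; it should have been filtered")

  inv <- GenomicRanges::invertStrand(lexons)
  ah <- GenomicRanges::findOverlaps(inv, cod, ignore.strand = FALSE)
  if (length(ah) > 0L) {
    ov <- GenomicRanges::pintersect(inv[S4Vectors::queryHits(ah)],
                                    cod[S4Vectors::subjectHits(ah)])
    gene <- as.character(S4Vectors::mcols(cod)$gene_id[S4Vectors::subjectHits(ah)])
    tot <- vapply(split(GenomicRanges::width(ov), gene), sum, numeric(1))
    partner <- names(tot)[order(-tot, names(tot))][1L]
    return(structure(list(lnc_id = lnc_id, partner_gene_id = partner,
                          category = "antisense_exonic", distance = 0L),
                     class = "positional_call"))
  }

  nb <- nearest_neighbors(span, coding, window = max_window)
  if (nrow(nb) == 0L) {
    return(structure(list(lnc_id = lnc_id, partner_gene_id = NA_character_,
                          category = "intergenic_unassigned", distance = NA_integer_),
                     class = "positional_call"))
  }
  p <- nb[1L, ]
  lnc_strand <- as.character(GenomicRanges::strand(span))
  # which genomic side of the partner does the lncRNA lie on?
  ls <- GenomicRanges::start(span); le <- GenomicRanges::end(span)
  left_of <- if (le < p$start) TRUE else if (ls > p$end) FALSE else
    (ls + le) <= (p$start + p$end)  # overlap: decide by midpoints
  # 5' side of the partner in partner orientation
  on_5prime <- if (p$strand == "+") left_of else !left_of
  category <- if (lnc_strand == p$strand) {
    if (on_5prime) "upstream_sense" else "downstream_sense"
  } else {
    if (on_5prime) "divergent" else "convergent"
  }
  structure(list(lnc_id = lnc_id, partner_gene_id = p$gene_id,
                 category = category, distance = abs(p$distance)),
            class = "positional_call")
}

#' @export
print.positional_call <- function(x, ...) {
  cat(sprintf("%s: %s (partner %s, distance %s)\n", x$lnc_id, x$category,
              x$partner_gene_id, x$distance))
  invisible(x)
}

#' Classify every transcript of an AnnotationSet
#'
#' @param lncs AnnotationSet of lncRNAs.
#' @param coding AnnotationSet of protein-coding genes.
#' @param max_window Passed to [classify_position].
#' @return data.frame: `lnc_id`, `partner_gene_id`, `category`, `distance`;
#'   attribute `summary` holds per-category counts.
#' @export
classify_positions <- function(lncs, coding, max_window = 10000) {
  stopifnot(inherits(lncs, "AnnotationSet"))
  calls <- lapply(lncs$transcripts$transcript_id, classify_position,
                  coding = coding, lncs = lncs, max_window = max_window)
  out <- data.frame(
    lnc_id = vapply(calls, `[[`, "", "lnc_id"),
    partner_gene_id = vapply(calls, `[[`, "", "partner_gene_id"),
    category = vapply(calls, `[[`, "", "category"),
    distance = vapply(calls, function(x) as.numeric(x$distance), numeric(1)),
    stringsAsFactors = FALSE)
  lv <- c("antisense_exonic", "divergent", "convergent",
          "upstream_sense", "downstream_sense", "intergenic_unassigned")
  attr(out, "summary") <- table(factor(out$category, levels = lv))
  out
}
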