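#' Length filter
#'
#' Flags transcripts whose spliced (exon-sum) length meets the minimum
#' lncRNA length. The 200 nt convention refers to transcript (not genomic)
#' length, so the spliced length is used.
#'
#' @param candidates AnnotationSet of candidate transcripts.
#' @param min_len Minimum spliced length in nucleotides (default 200;
#'   transcripts shorter than this are discarded, i.e. the flag is
#'   `length >= min_len`).
#' @return Named logical vector (`length_ok`), one entry per candidate.
#' @export
filter_length <- function(candidates, min_len = 200) {
  stopifnot(inherits(candidates, "AnnotationSet"), min_len > 0)
  setNames(candidates$transcripts$spliced_length >= min_len,
           candidates$transcripts$transcript_id)
}

#' Sense exon-overlap filter
#'
#' A candidate fails when any of its exons overlaps (>= 1 base) an exon of
#' any reference gene — coding or non-coding — on the same strand. Antisense
#' (opposite strand) overlap does not fail the filter: antisense-exonic
#' lncRNAs are a recognised class and survive this step.
#'
#' @param candidates AnnotationSet of candidate transcripts.
#' @param reference AnnotationSet of already-annotated genes.
#' @return Named logical vector (`no_sense_overlap`).
#' @export
filter_sense_exon_overlap <- function(candidates, reference) {
  stopifnot(inherits(candidates, "AnnotationSet"),
            inherits(reference, "AnnotationSet"))
  if (nrow(reference$transcripts) == 0L) stop("empty reference annotation")
  hits <- GenomicRanges::findOverlaps(candidates$exons, reference$exons,
                                      ignore.strand = FALSE)
  bad <- unique(S4Vectors::mcols(candidates$exons)$transcript_id[
    S4Vectors::queryHits(hits)])
  setNames(!candidates$transcripts$transcript_id %in% bad,
           candidates$transcripts$transcript_id)
}

#' Transcripts-per-million normalisation
#'
#' `TPM_ij = (count_ij / length_i) / sum_k(count_kj / length_k) * 1e6`.
#' Every sample column with any signal sums to 1e6.
#'
#' @param counts Numeric matrix, transcripts x samples.
#' @param lengths Named numeric vector of effective transcript lengths
#'   (> 0), covering all rows of `counts`.
#' @return TPM matrix with the dimensions and dimnames of `counts`.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(rownames(counts)))
  if (is.null(names(lengths))) {
    stopifnot(length(lengths) == nrow(counts))
    names(lengths) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) stop("no length for: ", paste(head(missing), collapse = ", "))
  len <- lengths[rownames(counts)]
  stopifnot(all(len > 0))
  rate <- counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Expression filter
#'
#' A transcript passes when its TPM is strictly greater than `min_tpm` in at
#' least `min_samples` samples. The strict inequality follows the convention
#' "not greater than 1 TPM in any sample" = discarded; a transcript at
#' exactly 1 TPM everywhere fails.
#'
#' @param tpm TPM matrix (transcripts x samples).
#' @param min_tpm Threshold (default 1, strict `>`).
#' @param min_samples Number of samples that must exceed the threshold.
#' @return Named logical vector (`expressed`).
#' @export
filter_expression <- function(tpm, min_tpm = 1, min_samples = 1) {
  tpm <- as.matrix(tpm)
  stopifnot(all(tpm >= 0), min_samples >= 1)
  setNames(rowSums(tpm > min_tpm) >= min_samples, rownames(tpm))
}

#' Default thresholds for the external-hit filters
#'
#' @param rfam_evalue RFAM hits below this E-value mark known structured
#'   RNAs (excluded).
#' @param rnacentral_evalue,rnacentral_identity An RNAcentral hit excludes a
#'   transcript only when E-value < `rnacentral_evalue` AND identity >
#'   `rnacentral_identity` (percent).
#' @param protein_evalue SWISSPROT/PFAM ORF hits below this E-value are
#'   recorded as annotations.
#' @param strict_protein When `TRUE`, significant protein hits also exclude
#'   the transcript (`domain_ok = FALSE`); by default they are flag-only.
#' @param descriptive_coverage,descriptive_evalue Relaxed thresholds for the
#'   purely descriptive reporting pass (no filtering).
#' @param whitelist Query ids exempt from exclusion (manual-inspection
#'   rescues).
#' @return List of class `hit_policy`.
#' @export
hit_policy <- function(rfam_evalue = 1e-5,
                       rnacentral_evalue = 1e-5, rnacentral_identity = 90,
                       protein_evalue = 1e-5, strict_protein = FALSE,
                       descriptive_coverage = 50, descriptive_evalue = 1e-2,
                       whitelist = character()) {
  structure(list(rfam_evalue = rfam_evalue,
                 rnacentral_evalue = rnacentral_evalue,
                 rnacentral_identity = rnacentral_identity,
                 protein_evalue = protein_evalue,
                 strict_protein = strict_protein,
                 descriptive_coverage = descriptive_coverage,
                 descriptive_evalue = descriptive_evalue,
                 whitelist = whitelist), class = "hit_policy")
}

#' Read an external hit table (TSV)
#'
#' Expected columns: `query_id`, `subject_id`, `subject_class` (one of RFAM,
#' RNAcentral, SWISSPROT, PFAM), `identity` (percent), `evalue`, `coverage`
#' (percent query coverage).
#' @param path TSV file with the header above.
#' @return data.frame.
#' @export
read_hit_table <- function(path) {
  h <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "subject_class", "identity", "evalue", "coverage")
  missing <- setdiff(need, names(h))
  if (length(missing)) stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  h
}

#' Known-RNA and protein-domain hit filters
#'
#' Exclusion rules: an RFAM hit with E-value < 1e-5, or an RNAcentral hit
#' with identity > 90 percent and E-value < 1e-5, marks a transcript as a
#' known RNA (`known_rna_ok = FALSE`) unless the query is whitelisted.
#' Significant SWISSPROT/PFAM hits on translated ORFs are recorded as
#' annotations; by default they do not exclude (`domain_ok = TRUE`) — an
#' opt-in strict mode excludes them. A separate descriptive pass reports
#' hits at relaxed thresholds (coverage, E-value) without filtering.
#'
#' @param hits data.frame as returned by [read_hit_table] (may be empty).
#' @param candidates Character vector of all candidate transcript ids, or an
#'   AnnotationSet.
#' @param policy A [hit_policy].
#' @return List: `known_rna_ok` and `domain_ok` named logical vectors over
#'   all candidates, `annotations` (significant protein hits),
#'   `descriptive` (relaxed-threshold report).
#' @export
apply_hits_filters <- function(hits, candidates, policy = hit_policy()) {
  if (inherits(candidates, "AnnotationSet"))
    candidates <- candidates$transcripts$transcript_id
  stopifnot(is.character(candidates), inherits(policy, "hit_policy"))
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(query_id = character(), subject_id = character(),
                       subject_class = character(), identity = numeric(),
                       evalue = numeric(), coverage = numeric(),
                       stringsAsFactors = FALSE)
  }
  known <- c("RFAM", "RNAcentral", "SWISSPROT", "PFAM")
  bad <- setdiff(unique(hits$subject_class), known)
  if (length(bad)) stop("unknown subject_class: ", paste(bad, collapse = ", "))

  rfam_bad <- hits$subject_class == "RFAM" & hits$evalue < policy$rfam_evalue
  rnac_bad <- hits$subject_class == "RNAcentral" &
    hits$evalue < policy$rnacentral_evalue &
    hits$identity > policy$rnacentral_identity
  excl <- unique(hits$query_id[rfam_bad | rnac_bad])
  excl <- setdiff(excl, policy$whitelist)
  known_rna_ok <- setNames(!candidates %in% excl, candidates)

  prot <- hits[hits$subject_class %in% c("SWISSPROT", "PFAM") &
                 hits$evalue < policy$protein_evalue, , drop = FALSE]
  domain_ok <- setNames(rep(TRUE, length(candidates)), candidates)
  if (policy$strict_protein && nrow(prot)) {
    domain_ok[candidates %in% prot$query_id] <- FALSE
  }

  descriptive <- hits[hits$subject_class %in% c("RFAM", "RNAcentral") &
                        hits$coverage > policy$descriptive_coverage &
                        hits$evalue < policy$descriptive_evalue, , drop = FALSE]
  list(known_rna_ok = known_rna_ok, domain_ok = domain_ok,
       annotations = prot, descriptive = descriptive)
}

#' Intersect per-filter flags into a FilterReport
#'
#' The final retained set is the conjunction (AND) of all per-filter flags;
#' the conjunction is commutative, so filter order never matters. The report
#' additionally counts, per filter, the transcripts that filter alone
#' removes (fail it but pass everything else) and its total removals.
#'
#' @param flags Named list of named logical vectors, one per filter, all
#'   covering the identical transcript set.
#' @return data.frame of class `filter_report` with one row per transcript,
#'   one logical column per filter plus `retained`; attribute `summary`
#'   holds per-filter removal counts.
#' @export
intersect_filters <- function(flags) {
  stopifnot(is.list(flags), length(flags) >= 1L, !is.null(names(flags)))
  ids <- sort(names(flags[[1L]]))
  for (f in flags) {
    if (!setequal(names(f), ids))
      stop("filter flag vectors cover different transcript sets")
  }
  mat <- vapply(flags, function(f) unname(f[ids]), logical(length(ids)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(ids),
                                       dimnames = list(ids, names(flags)))
  retained <- apply(mat, 1L, all)
  rep_df <- data.frame(transcript_id = ids, mat, retained = retained,
                       stringsAsFactors = FALSE, row.names = NULL)
  fails <- !mat
  summary <- data.frame(
    filter = colnames(mat),
    removed_total = colSums(fails),
    removed_alone = vapply(seq_len(ncol(mat)), function(j) {
      sum(fails[, j] & rowSums(fails[, -j, drop = FALSE]) == 0L)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(rep_df, "summary") <- summary
  class(rep_df) <- c("filter_report", "data.frame")
  rep_df
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d candidates, %d retained\n",
              nrow(x), sum(x$retained)))
  print(attr(x, "summary"))
  invisible(x)
}

#' Write a FilterReport as TSV (per-transcript flags; summary as comments)
#' @param report filter_report.
#' @param path Output TSV.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- attr(report, "summary")
  writeLines(sprintf("# %s: removed_total=%d removed_alone=%d",
                     s$filter, s$removed_total, s$removed_alone), con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
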