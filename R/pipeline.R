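#' Run the full lncRNA filter cascade
#'
#' Applies, in one call, the length, sense-exon-overlap, coding-potential
#' (built-in ensemble vote), known-RNA / domain-hit and expression filters
#' and intersects them into a [intersect_filters] report. The hexamer model
#' for the coding vote is trained on the fly from the reference annotation:
#' coding transcripts provide in-frame ORF hexamers, and dinucleotide-
#' preserving noncoding background comes from the reference ncRNAs plus the
#' candidates themselves when too few ncRNAs exist.
#'
#' @param candidates AnnotationSet of candidate transcripts.
#' @param reference AnnotationSet of annotated genes (coding + ncRNA).
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param tpm TPM matrix covering all candidate transcripts.
#' @param hits External hit table (data.frame; may be `NULL`).
#' @param policy [hit_policy].
#' @param external_votes Optional data.frame of external classifier labels
#'   (rownames = transcript ids, each column `"coding"`/`"noncoding"`).
#' @param min_len,min_tpm Filter thresholds.
#' @param hexamer_model Optional pre-trained [train_hexamer_model]; when
#'   `NULL` one is trained from `reference` ORFs vs candidate sequences.
#' @return List: `report` ([intersect_filters] result), `retained`
#'   (AnnotationSet of surviving transcripts, biotype set to `"lncRNA"`),
#'   `features` (per-candidate coding features), `hit_detail`.
#' @export
run_filter_cascade <- function(candidates, reference, genome, tpm,
                               hits = NULL, policy = hit_policy(),
                               external_votes = NULL,
                               min_len = 200, min_tpm = 1,
                               hexamer_model = NULL) {
  cand_seqs <- extract_sequences(candidates, genome)
  if (is.null(hexamer_model)) {
    ref_coding <- reference$transcripts$transcript_id[
      reference$transcripts$biotype == "coding"]
    coding_seqs <- extract_sequences(reference, genome, ref_coding)
    # training ORFs: longest ORF of each coding transcript
    orfs <- vapply(as.character(coding_seqs), function(s) {
      o <- find_longest_orf(s, min_aa = 50)
      if (is.null(o)) NA_character_ else substr(s, o$start, o$end)
    }, character(1))
    orfs <- orfs[!is.na(orfs)]
    noncod <- as.character(cand_seqs)
    nc_ids <- reference$transcripts$transcript_id[
      reference$transcripts$biotype == "ncRNA"]
    if (length(nc_ids))
      noncod <- c(noncod, as.character(extract_sequences(reference, genome, nc_ids)))
    hexamer_model <- suppressWarnings(train_hexamer_model(orfs, noncod))
  }

  ids <- candidates$transcripts$transcript_id
  feats <- lapply(setNames(ids, ids), function(id)
    suppressWarnings(coding_features(cand_seqs[[id]], model = hexamer_model)))
  votes <- vapply(ids, function(id) {
    ext <- if (!is.null(external_votes) && id %in% rownames(external_votes))
      unlist(external_votes[id, , drop = TRUE]) else character()
    classify_and_vote(feats[[id]], external_votes = ext)$vote
  }, character(1))

  hit_res <- apply_hits_filters(hits, ids, policy)
  flags <- list(
    length_ok = filter_length(candidates, min_len = min_len),
    no_sense_overlap = filter_sense_exon_overlap(candidates, reference),
    noncoding_vote = setNames(votes == "noncoding", ids),
    known_rna_ok = hit_res$known_rna_ok,
    domain_ok = hit_res$domain_ok,
    expressed = filter_expression(tpm[ids, , drop = FALSE], min_tpm = min_tpm)
  )
  report <- intersect_filters(flags)
  kept <- report$transcript_id[report$retained]
  retained <- NULL
  if (length(kept)) {
    retained <- subset_annotation(candidates, kept)
    S4Vectors::mcols(retained$exons)$biotype <- "lncRNA"
    retained$transcripts$biotype <- "lncRNA"
  }
  list(report = report, retained = retained, features = feats,
       hit_detail = hit_res)
}

#' End-to-end analysis of a synthetic dataset
#'
#' Chains every stage on generated data: filter cascade, positional
#' classification, triplex prediction with genomic-context assignment and
#' pair extraction, pair labelling, correlation and DE-stratified
#' summaries. Used by the package's smoke tests and the acceptance script.
#'
#' @param ds A `synthetic_dataset`.
#' @param expr A `synthetic_expression` for the same dataset.
#' @param params [triplex_params].
#' @return List: `cascade`, `positions`, `interactions` (context-labelled),
#'   `context`, `pairs_by_scope`, `labels` (pair records with r/p/n),
#'   `group_summary`, `de_flags`.
#' @export
run_synthetic_pipeline <- function(ds, expr, params = triplex_params()) {
  stopifnot(inherits(ds, "synthetic_dataset"),
            inherits(expr, "synthetic_expression"))
  cascade <- run_filter_cascade(
    ds$candidates, ds$reference, ds$genome, expr$tpm,
    hits = ds$hits, policy = hit_policy(whitelist = ds$truth$whitelist))
  retained <- cascade$retained
  if (is.null(retained)) stop("no transcript survived the cascade")

  positions <- classify_positions(retained, ds$reference)

  lnc_seqs <- extract_sequences(retained, ds$genome)
  interactions <- predict_triplexes(lnc_seqs, ds$genome, params)
  # report interactions at gene level (the lncRNA gene id)
  interactions$lnc_id <- sub("\\.t\\d+$", "", interactions$lnc_id)
  context <- classify_genome_context(ds$reference)
  interactions <- assign_interaction_context(interactions, context)
  pairs_by_scope <- interaction_pairs(interactions, ds$reference)

  gene_counts <- aggregate_to_gene(expr$counts, expr$tx2gene)
  vst <- normalize_and_transform(gene_counts)
  labels <- label_pairs(retained, ds$reference, pairs_by_scope)
  keep <- labels$lnc_id %in% rownames(vst) & labels$gene_id %in% rownames(vst)
  labels <- correlate_genes(vst, labels[keep, , drop = FALSE])

  de_flags <- setNames(expr$de$padj < 0.0005, expr$de$gene_id)
  group_summary <- suppressWarnings(
    summarize_by_group(labels, de_flags))

  list(cascade = cascade, positions = positions, interactions = interactions,
       context = context, pairs_by_scope = pairs_by_scope, labels = labels,
       group_summary = group_summary, de_flags = de_flags)
}
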