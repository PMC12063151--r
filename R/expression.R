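#' Aggregate transcript-level values to gene level
#'
#' Member transcript values are summed per gene; when `round_counts` is
#' `TRUE` (the convention for estimated counts), sums are rounded to the
#' nearest integer, half away from zero.
#'
#' @param mat Numeric matrix, transcripts x samples.
#' @param tx2gene Named character vector mapping every row of `mat` to a
#'   gene id, or a data.frame with columns `transcript_id`, `gene_id`.
#' @param round_counts Round the aggregated values (default `TRUE`).
#' @return Gene x sample matrix.
#' @export
aggregate_to_gene <- function(mat, tx2gene, round_counts = TRUE) {
  mat <- as.matrix(mat)
  if (is.data.frame(tx2gene))
    tx2gene <- setNames(tx2gene$gene_id, tx2gene$transcript_id)
  unmapped <- setdiff(rownames(mat), names(tx2gene))
  if (length(unmapped)) stop("unmapped transcript(s): ",
                             paste(head(unmapped), collapse = ", "))
  g <- factor(tx2gene[rownames(mat)])
  out <- rowsum(mat, g)
  if (round_counts) out <- sign(out) * floor(abs(out) + 0.5)
  out[order(rownames(out)), , drop = FALSE]
}

#' Library-size normalisation and log transformation
#'
#' A design-blind stand-in for a variance-stabilising transformation:
#' median-of-ratios size factors followed by `log2(count / size_factor + 1)`.
#' The geometric-mean reference is computed over features with all-positive
#' counts from the column proportions (each sample divided by its library
#' size) scaled to a nominal library of 1e6, which makes the reference —
#' and hence every other sample's transform — exactly invariant to
#' rescaling any one sample; transformed values are on a log2-CPM-like
#' scale. Rows with identical values across all samples after
#' transformation are removed, as such rows are uninformative artefacts of
#' abundance estimation. A hook for an externally produced transformed
#' matrix: pass it straight to downstream functions instead of this one.
#'
#' @param counts Non-negative matrix, features x samples.
#' @return Transformed matrix; attributes `size_factors` (named numeric)
#'   and `removed` (ids of dropped uniform rows).
#' @export
normalize_and_transform <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature with all-positive counts; supply a pseudo-reference")
  prop <- sweep(counts, 2L, colSums(counts), "/")
  loggeo <- rowMeans(log(prop[pos, , drop = FALSE])) + log(1e6)
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(col)
    exp(median(log(col) - loggeo)))
  trans <- log2(sweep(counts, 2L, sf, "/") + 1)
  uniform <- apply(trans, 1L, function(r) max(r) - min(r) == 0)
  out <- trans[!uniform, , drop = FALSE]
  attr(out, "size_factors") <- sf
  attr(out, "removed") <- rownames(trans)[uniform]
  out
}

zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  sweep(sweep(mat, 1L, mu, "-"), 1L, s, "/")
}

#' Pearson correlation between feature pairs
#'
#' Rows are z-scored (mean 0, sd 1) before computing the Pearson
#' correlation coefficient; two-sided p-values come from the t distribution
#' with n - 2 degrees of freedom. Zero-variance rows yield `NA` for r and p.
#'
#' @param mat Transformed matrix, features x samples (n >= 3 samples).
#' @param pairs data.frame with columns `a` and `b` (row ids of `mat`), or
#'   any data.frame whose first two columns hold the ids.
#' @return `pairs` with `r`, `p` and `n` columns appended.
#' @export
correlate_genes <- function(mat, pairs) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  stopifnot(n >= 3)
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  missing <- setdiff(c(a, b), rownames(mat))
  if (length(missing)) stop("pair feature(s) not in matrix: ",
                            paste(head(missing), collapse = ", "))
  z <- suppressWarnings(zscore_rows(mat))
  r <- vapply(seq_along(a), function(i) {
    za <- z[a[i], ]; zb <- z[b[i], ]
    if (anyNA(za) || anyNA(zb)) return(NA_real_)
    sum(za * zb) / (n - 1)
  }, numeric(1))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- pairs
  out$r <- r
  out$p <- p
  out$n <- n
  out
}

#' Exclusive labelling of lncRNA-gene pairs
#'
#' Every (lncRNA, coding gene) pair receives exactly one label under the
#' precedence Neighbouring > Interacting > Independent:
#' `Neighbouring` when the span gap is within `window` bases (on the same
#' chromosome); otherwise `Interacting_Promoter` when a triplex TTS linked
#' to a TFO of the lncRNA lies in the gene's promoter; otherwise
#' `Independent`. Alternative labelings using the Exon and Gene+Promoter
#' interaction scopes are returned alongside for supplementary-style
#' analyses.
#'
#' @param lncs AnnotationSet of lncRNAs (gene level: pairs are formed per
#'   lncRNA gene id).
#' @param coding AnnotationSet of coding genes.
#' @param pairs_by_scope An [interaction_pairs] result (or `NULL` for none).
#' @param window Neighbouring distance in bases (default 2000).
#' @return data.frame of class `pair_records`: `lnc_id`, `gene_id`,
#'   `distance` (span gap, `NA` when on different chromosomes), `label`
#'   (primary labelling), `label_exon`, `label_gene_promoter`.
#' @export
label_pairs <- function(lncs, coding, pairs_by_scope = NULL, window = 2000) {
  stopifnot(inherits(lncs, "AnnotationSet"), inherits(coding, "AnnotationSet"))
  lg <- gene_ranges(lncs)
  cod <- coding
  if (any(cod$transcripts$biotype == "coding")) {
    cod <- subset_annotation(
      cod, cod$transcripts$transcript_id[cod$transcripts$biotype == "coding"])
  }
  cg <- gene_ranges(cod)
  grid <- expand.grid(lnc_id = names(lg), gene_id = names(cg),
                      stringsAsFactors = FALSE)
  li <- match(grid$lnc_id, names(lg)); ci <- match(grid$gene_id, names(cg))
  same_chrom <- as.character(GenomicRanges::seqnames(lg))[li] ==
    as.character(GenomicRanges::seqnames(cg))[ci]
  ls <- GenomicRanges::start(lg)[li]; le <- GenomicRanges::end(lg)[li]
  gs <- GenomicRanges::start(cg)[ci]; ge <- GenomicRanges::end(cg)[ci]
  gap <- pmax(pmax(gs - le, ls - ge) - 1L, 0L)
  grid$distance <- ifelse(same_chrom, gap, NA_real_)

  in_scope <- function(scope) {
    if (is.null(pairs_by_scope) || is.null(pairs_by_scope[[scope]]))
      return(rep(FALSE, nrow(grid)))
    p <- pairs_by_scope[[scope]]$pairs
    paste(grid$lnc_id, grid$gene_id) %in% paste(p$lnc_id, p$gene_id)
  }
  neighbouring <- !is.na(grid$distance) & grid$distance <= window
  lab <- function(interacting, name) {
    ifelse(neighbouring, "Neighbouring",
           ifelse(interacting, name, "Independent"))
  }
  grid$label <- lab(in_scope("Promoter"), "Interacting_Promoter")
  grid$label_exon <- lab(in_scope("Exon"), "Interacting_Exon")
  grid$label_gene_promoter <- lab(in_scope("GenePromoter"),
                                  "Interacting_GenePromoter")
  class(grid) <- c("pair_records", "data.frame")
  grid
}

bimodality_indicator <- function(r, edge = 0.25) {
  r <- r[!is.na(r)]
  if (length(r) < 5L) return(NA_real_)
  br <- seq(-1, 1, by = 0.25)
  h <- hist(r, breaks = br, plot = FALSE)$density
  mid <- h[findInterval(0, br, rightmost.closed = TRUE)]
  left <- max(h[br[-length(br)] < -edge])
  right <- max(h[br[-1L] > edge])
  lo <- min(left, right)
  if (lo <= 0) return(0)
  max(0, 1 - mid / lo)
}

#' Per-group summaries of pair correlation distributions
#'
#' Pairs are grouped by label and the lncRNA's differential-expression (DE)
#' status. Per group: n, mean, median and quartiles of r, a kernel-density
#' export for plotting, the two-sample Kolmogorov-Smirnov statistic against
#' the corresponding Independent group, and a simple bimodality indicator
#' (1 minus the ratio of the histogram density near r = 0 to the smaller of
#' the two mode heights on either side; 0 = unimodal around one peak,
#' -> 1 = deep dip between two modes).
#'
#' @param pairs A [label_pairs] result with `r` from [correlate_genes].
#' @param de_flags Named logical vector: is each lncRNA (gene id)
#'   differentially expressed? Must cover all lncRNAs in `pairs`.
#' @param label_col Which labelling to use (default `"label"`).
#' @param min_n Groups smaller than this get summaries with a warning and
#'   no KS test (default 5).
#' @return data.frame, one row per (label, DE status) group with columns
#'   `label`, `lnc_de`, `n`, `mean_r`, `median_r`, `q25`, `q75`,
#'   `ks_vs_independent`, `bimodality`; attribute `densities` holds a list
#'   of density objects keyed by group.
#' @export
summarize_by_group <- function(pairs, de_flags, label_col = "label", min_n = 5) {
  stopifnot(label_col %in% names(pairs), "r" %in% names(pairs))
  missing <- setdiff(unique(pairs$lnc_id), names(de_flags))
  if (length(missing)) stop("no DE flag for lncRNA(s): ",
                            paste(head(missing), collapse = ", "))
  pairs$lnc_de <- unname(de_flags[pairs$lnc_id])
  pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
  key <- interaction(pairs[[label_col]], pairs$lnc_de, drop = TRUE)
  groups <- split(pairs, key)
  indep <- split(pairs$r[pairs[[label_col]] == "Independent"],
                 pairs$lnc_de[pairs[[label_col]] == "Independent"])
  dens <- list()
  rows <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    r <- g$r
    small <- length(r) < min_n
    if (small) warning("group ", k, " has n < ", min_n, "; tests skipped")
    ref <- indep[[as.character(g$lnc_de[1L])]]
    ks <- if (!small && g[[label_col]][1L] != "Independent" &&
              !is.null(ref) && length(ref) >= min_n) {
      suppressWarnings(unname(ks.test(r, ref)$statistic))
    } else NA_real_
    if (length(r) >= 2L) dens[[k]] <<- density(r, from = -1, to = 1)
    data.frame(label = g[[label_col]][1L], lnc_de = g$lnc_de[1L],
               n = length(r), mean_r = mean(r), median_r = median(r),
               q25 = unname(quantile(r, 0.25)), q75 = unname(quantile(r, 0.75)),
               ks_vs_independent = ks,
               bimodality = bimodality_indicator(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "densities") <- dens
  out
}

#' Read a sample design table
#'
#' TSV with columns `sample`, `condition` (e.g. C0.1, 0.025, R3, R6, R10),
#' optionally `cultivation` and `replicate`.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(condition = "character"))
  if (!all(c("sample", "condition") %in% names(d)))
    stop("design table needs 'sample' and 'condition' columns")
  d
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id` and at least one of `padj` (likelihood-ratio
#' test) or `svalue` (Wald/shrunken-LFC). The DE flag applied downstream is
#' `padj < padj_cutoff` when `padj` is present, else
#' `svalue < svalue_cutoff`.
#'
#' @param path TSV file.
#' @param padj_cutoff,svalue_cutoff Significance thresholds (defaults
#'   0.0005 and 0.005).
#' @return Named logical vector of DE flags per gene id.
#' @export
read_de_flags <- function(path, padj_cutoff = 0.0005, svalue_cutoff = 0.005) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(d)) stop("DE table needs a 'gene_id' column")
  if ("padj" %in% names(d)) {
    flag <- d$padj < padj_cutoff
  } else if ("svalue" %in% names(d)) {
    flag <- d$svalue < svalue_cutoff
  } else stop("DE table needs a 'padj' or 'svalue' column")
  flag[is.na(flag)] <- FALSE
  agg <- tapply(flag, d$gene_id, any)
  setNames(as.logical(agg), names(agg))[unique(d$gene_id)]
}
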