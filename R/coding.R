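#' Longest ATG-initiated, stop-terminated open reading frame
#'
#' Scans the three sense-strand frames for ATG...stop ORFs and returns the
#' longest (peptide length including the initial Met, excluding the stop).
#' Ties are broken by the 5'-most start. The ORF is reported only when the
#' peptide is strictly longer than `min_aa`.
#'
#' @param seq Character scalar or `DNAString` over A/C/G/T/N (case
#'   insensitive).
#' @param min_aa Minimum peptide length; an ORF of exactly `min_aa` amino
#'   acids is rejected (strict `>`).
#' @return `NULL` when no qualifying ORF exists, else a list with `start`,
#'   `end` (1-based nucleotide positions on the transcript, stop codon
#'   included in `end`), `aa_length` and `coverage` (fraction of the
#'   transcript covered by the ORF including its stop codon).
#' @export
find_longest_orf <- function(seq, min_aa = 100) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (frame in 0:2) {
    starts_at <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts_at) == 0L) next
    codons <- paste0(chars[starts_at], chars[starts_at + 1L], chars[starts_at + 2L])
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (length(atg) == 0L || length(stp) == 0L) next
    # first stop at or after each ATG
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    ok <- !is.na(nxt)
    atg <- atg[ok]; nxt <- nxt[ok]
    if (length(atg) == 0L) next
    # several ATGs sharing a stop: the 5'-most gives the longest peptide
    aa <- nxt - atg            # codons between ATG and stop, incl. Met
    for (i in seq_along(atg)) {
      if (aa[i] <= min_aa) next
      cand <- list(start = starts_at[atg[i]],
                   end = starts_at[nxt[i]] + 2L,
                   aa_length = aa[i])
      if (is.null(best) || cand$aa_length > best$aa_length ||
          (cand$aa_length == best$aa_length && cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$coverage <- (best$end - best$start + 1L) / n
  best
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(do.call(paste0, g))
}

hexamer_counts <- function(seqs, step) {
  hx <- all_hexamers()
  counts <- setNames(numeric(length(hx)), hx)
  for (s in seqs) {
    s <- toupper(as.character(s))
    n <- nchar(s)
    if (n < 6L) {
      warning("sequence shorter than 6 nt skipped")
      next
    }
    pos <- seq.int(1L, n - 5L, by = step)
    words <- substring(s, pos, pos + 5L)
    words <- words[!grepl("[^ACGT]", words)]
    if (length(words)) {
      tab <- table(words)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

#' Train an in-frame vs background hexamer model
#'
#' Coding sequences are counted in frame 0 (hexamers starting every third
#' base, i.e. codon-aligned on annotated ORFs); non-coding sequences in all
#' frames (every base). Add-one (Laplace) smoothing guarantees every hexamer
#' a positive frequency; each table sums to 1.
#'
#' @param coding_seqs,noncoding_seqs Character vectors or `DNAStringSet`s.
#'   Coding sequences should be ORF sequences starting at the ATG.
#' @return List of class `hexamer_model` with numeric vectors `coding` and
#'   `noncoding` over the 4096 hexamers.
#' @export
train_hexamer_model <- function(coding_seqs, noncoding_seqs) {
  stopifnot(length(coding_seqs) > 0L, length(noncoding_seqs) > 0L)
  cc <- hexamer_counts(as.character(coding_seqs), step = 3L) + 1
  nc <- hexamer_counts(as.character(noncoding_seqs), step = 1L) + 1
  structure(list(coding = cc / sum(cc), noncoding = nc / sum(nc)),
            class = "hexamer_model")
}

#' Mean hexamer log-likelihood ratio of a sequence
#'
#' Mean over sliding hexamers of `log(f_coding / f_noncoding)`. Positive
#' values indicate coding-like hexamer usage; identical tables give 0 for
#' any sequence. Hexamers containing non-ACGT letters are skipped. With
#' `step = 3` on an ORF sequence the score reads the codon frame the
#' coding table was trained on — this is how [coding_features] scores the
#' longest ORF.
#'
#' @param seq Character scalar or `DNAString`.
#' @param model A [train_hexamer_model] fit.
#' @param step Offset between successive hexamers (default 1).
#' @return Numeric scalar.
#' @export
hexamer_score <- function(seq, model, step = 1L) {
  stopifnot(inherits(model, "hexamer_model"), step >= 1L)
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 6L) stop("sequence shorter than 6 nt")
  pos <- seq.int(1L, n - 5L, by = step)
  words <- substring(s, pos, pos + 5L)
  words <- words[!grepl("[^ACGT]", words)]
  if (length(words) == 0L) return(NA_real_)
  mean(log(model$coding[words] / model$noncoding[words]))
}

# Classic TESTCODE lookup tables (position and composition parameters for
# each base, with their weights). Probabilities are indexed by threshold
# bins; the first bin matching value >= threshold wins.
fickett_tables <- list(
  position_thresholds = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
  content_thresholds = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0),
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
)

#' Fickett TESTCODE score
#'
#' The classic position/composition statistic: for each base, the position
#' parameter is `max(n1,n2,n3)/(min(n1,n2,n3)+1)` over the three codon
#' positions and the content parameter is the base's overall fraction; each
#' is converted to a coding probability through the published lookup tables
#' and combined with the published weights. Deterministic, case-insensitive;
#' `N`s are ignored in all tallies. Scores above ~0.95 indicate coding-like
#' sequence.
#'
#' @param seq Character scalar or `DNAString`.
#' @return Numeric score (roughly in (0.2, 1.9)).
#' @export
fickett_score <- function(seq) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 200) warning("TESTCODE is calibrated for sequences >= 200 nt")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  n <- length(chars)
  if (n == 0L) return(0)
  phase <- rep_len(1:3, n)
  tabs <- fickett_tables
  score <- 0
  total <- n
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) sum(chars == b & phase == p), numeric(1))
    posval <- max(cnt) / (min(cnt) + 1)
    bin <- which(posval >= tabs$position_thresholds)[1L]
    score <- score + tabs$position_prob[[b]][bin] * tabs$position_weight[[b]]
    contval <- sum(cnt) / total
    bin <- which(contval >= tabs$content_thresholds)[1L]
    score <- score + tabs$content_prob[[b]][bin] * tabs$content_weight[[b]]
  }
  score
}

#' Coding features of a transcript sequence
#'
#' The hexamer score is evaluated in-frame (step 3) on the longest ORF when
#' one exists — matching the codon frame the coding table is trained on —
#' and over the whole sequence (step 1) otherwise.
#'
#' @param seq Character scalar or `DNAString`.
#' @param model Optional [train_hexamer_model] fit (hexamer score `NA`
#'   when absent).
#' @param min_aa ORF retention threshold passed to [find_longest_orf].
#' @return List of class `coding_features`: `orf` (or `NULL`),
#'   `orf_aa`, `orf_coverage`, `fickett`, `hexamer`.
#' @export
coding_features <- function(seq, model = NULL, min_aa = 100) {
  orf <- find_longest_orf(seq, min_aa = min_aa)
  s <- toupper(as.character(seq))
  hseq <- if (is.null(orf)) s else substr(s, orf$start, orf$end)
  hstep <- if (is.null(orf)) 1L else 3L
  hx <- if (is.null(model)) NA_real_ else
    tryCatch(hexamer_score(hseq, model, step = hstep),
             error = function(e) NA_real_)
  structure(list(
    orf = orf,
    orf_aa = if (is.null(orf)) 0L else orf$aa_length,
    orf_coverage = if (is.null(orf)) 0 else orf$coverage,
    fickett = suppressWarnings(fickett_score(seq)),
    hexamer = hx), class = "coding_features")
}

#' Built-in coding call plus unanimous non-coding vote
#'
#' The built-in classifier labels a transcript coding when (longest ORF
#' peptide > `min_aa` amino acids AND hexamer score > `hexamer_cutoff`) OR
#' its Fickett score is at or above `fickett_cutoff`. The final vote is
#' `"noncoding"` only when ALL participating classifiers — the built-in one
#' plus any externally supplied label columns (e.g. from dedicated
#' coding-potential tools) — say non-coding; a single coding vote removes
#' the transcript.
#'
#' @param features A [coding_features] object.
#' @param external_votes Character vector of `"coding"`/`"noncoding"` labels
#'   from external classifiers (may be empty).
#' @param min_aa,fickett_cutoff,hexamer_cutoff Thresholds (defaults 100 aa,
#'   0.95, 0).
#' @param include_builtin Set `FALSE` to vote on external labels only.
#' @return List: `builtin` label, `vote` final label.
#' @export
classify_and_vote <- function(features, external_votes = character(),
                              min_aa = 100, fickett_cutoff = 0.95,
                              hexamer_cutoff = 0, include_builtin = TRUE) {
  stopifnot(inherits(features, "coding_features"))
  bad <- setdiff(external_votes, c("coding", "noncoding"))
  if (length(bad)) stop("invalid vote label: ", paste(bad, collapse = ", "))
  hx <- features$hexamer
  builtin <- if ((features$orf_aa > min_aa && !is.na(hx) && hx > hexamer_cutoff) ||
                 (!is.na(features$fickett) && features$fickett >= fickett_cutoff))
    "coding" else "noncoding"
  votes <- c(if (include_builtin) builtin, external_votes)
  if (length(votes) == 0L) stop("empty vote set")
  list(builtin = builtin,
       vote = if (all(votes == "noncoding")) "noncoding" else "coding")
}

#' Binary classification metrics (coding = positive class)
#'
#' Recall = TP/(TP+FN); specificity = TN/(TN+FP); precision = TP/(TP+FP);
#' balanced accuracy = (recall + specificity)/2;
#' F1 = 2 * precision * recall / (precision + recall). Ratios with a zero
#' denominator are reported as `NaN` with a warning.
#'
#' @param predicted,truth Character vectors of `"coding"`/`"noncoding"`
#'   labels; when named, they are aligned by name and must cover the same
#'   id set.
#' @return List of class `benchmark_result` with the confusion counts and
#'   derived metrics.
#' @export
benchmark_metrics <- function(predicted, truth) {
  lv <- c("coding", "noncoding")
  bad <- setdiff(unique(c(predicted, truth)), lv)
  if (length(bad)) stop("label outside {coding, noncoding}: ",
                        paste(bad, collapse = ", "))
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("predicted and truth cover different id sets")
    truth <- truth[names(predicted)]
  } else {
    stopifnot(length(predicted) == length(truth))
  }
  tp <- sum(predicted == "coding" & truth == "coding")
  tn <- sum(predicted == "noncoding" & truth == "noncoding")
  fp <- sum(predicted == "coding" & truth == "noncoding")
  fn <- sum(predicted == "noncoding" & truth == "coding")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  recall <- ratio(tp, tp + fn, "recall")
  specificity <- ratio(tn, tn + fp, "specificity")
  precision <- ratio(tp, tp + fp, "precision")
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 recall = recall, specificity = specificity,
                 precision = precision,
                 balanced_accuracy = (recall + specificity) / 2,
                 f1 = f1), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("recall=%.4f specificity=%.4f precision=%.4f balanced_acc=%.4f F1=%.4f\n",
              x$recall, x$specificity, x$precision, x$balanced_accuracy, x$f1))
  invisible(x)
}

#' Write a hexamer model as two two-column TSVs
#' @param model hexamer_model.
#' @param coding_path,noncoding_path Output files (hexamer, frequency).
#' @export
write_hexamer_model <- function(model, coding_path, noncoding_path) {
  stopifnot(inherits(model, "hexamer_model"))
  write.table(data.frame(hexamer = names(model$coding), frequency = model$coding),
              coding_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(hexamer = names(model$noncoding), frequency = model$noncoding),
              noncoding_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(model)
}

#' Read a hexamer model written by [write_hexamer_model]
#' @param coding_path,noncoding_path TSV files (hexamer, frequency).
#' @return hexamer_model.
#' @export
read_hexamer_model <- function(coding_path, noncoding_path) {
  cc <- read.delim(coding_path, stringsAsFactors = FALSE)
  nc <- read.delim(noncoding_path, stringsAsFactors = FALSE)
  structure(list(coding = setNames(cc$frequency, cc$hexamer),
                 noncoding = setNames(nc$frequency, nc$hexamer)),
            class = "hexamer_model")
}
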