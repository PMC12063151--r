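# Independent brute-force oracles. These restate the operation definitions
# directly (exhaustive enumeration, per-base loops, second implementations)
# and deliberately share no code with the package internals they check.

# ---- triplex window oracle -------------------------------------------------

# all valid windows over logical match/guanine vectors by exhaustive
# enumeration of every (start, end)
oracle_valid_windows <- function(match, guanine, p) {
  n <- length(match)
  err <- !match
  cum_e <- cumsum(err)
  cum_g <- cumsum(guanine)
  # error runs longer than allowed: any window fully containing one is out
  rl <- rle(err)
  re <- cumsum(rl$lengths)
  rs <- re - rl$lengths + 1L
  bad_runs <- cbind(rs, re)[rl$values & rl$lengths > p$max_consecutive_errors, ,
                            drop = FALSE]
  res <- list()
  for (i in seq_len(n - p$min_length + 1L)) {
    if (!match[i]) next
    js <- seq.int(i + p$min_length - 1L, n)
    js <- js[match[js]]
    if (!length(js)) next
    len <- js - i + 1L
    e <- cum_e[js] - if (i > 1L) cum_e[i - 1L] else 0L
    g <- cum_g[js] - if (i > 1L) cum_g[i - 1L] else 0L
    ok <- e <= p$max_error_rate * len + 1e-9 &
      g >= p$min_guanine * len - 1e-9
    if (nrow(bad_runs)) {
      for (r in seq_len(nrow(bad_runs))) {
        ok <- ok & !(bad_runs[r, 1L] >= i & bad_runs[r, 2L] <= js)
      }
    }
    if (any(ok)) {
      res[[length(res) + 1L]] <- data.frame(start = i, end = js[ok],
                                            errors = e[ok], guanines = g[ok])
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      errors = integer(), guanines = integer()))
  do.call(rbind, res)
}

# maximal = not contained in a different valid window
oracle_maximal <- function(valid) {
  if (nrow(valid) == 0L) return(valid)
  keep <- vapply(seq_len(nrow(valid)), function(k) {
    contained <- valid$start <= valid$start[k] & valid$end >= valid$end[k] &
      !(valid$start == valid$start[k] & valid$end == valid$end[k])
    !any(contained)
  }, logical(1))
  valid[keep, , drop = FALSE]
}

# merge overlapping windows: longest, then fewest errors, then leftmost
oracle_merge <- function(w) {
  if (nrow(w) <= 1L) return(w)
  w <- w[order(w$start, w$end), , drop = FALSE]
  out <- list()
  cur <- w[1L, , drop = FALSE]
  hi <- w$end[1L]
  for (k in seq_len(nrow(w))[-1L]) {
    if (w$start[k] <= hi) {
      cur <- rbind(cur, w[k, ])
      hi <- max(hi, w$end[k])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- w[k, , drop = FALSE]
      hi <- w$end[k]
    }
  }
  out[[length(out) + 1L]] <- cur
  picked <- lapply(out, function(g) {
    len <- g$end - g$start + 1L
    g[order(-len, g$errors, g$start)[1L], , drop = FALSE]
  })
  res <- do.call(rbind, picked)
  rownames(res) <- NULL
  res
}

oracle_windows <- function(match, guanine, p, merge = p$merge_overlapping) {
  w <- oracle_maximal(oracle_valid_windows(match, guanine, p))
  w <- w[order(w$start, w$end), , drop = FALSE]
  rownames(w) <- NULL
  if (merge) oracle_merge(w) else w
}

oracle_find_tracts <- function(seq, p, kind) {
  chars <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  alph <- if (kind == "TFO_on_rna") {
    list(R = list(m = c("G", "A"), g = "G"),
         Y = list(m = c("C", "T"), g = "C"),
         M = list(m = c("G", "T"), g = "G"))
  } else {
    list(`+` = list(m = c("A", "G"), g = "G"),
         `-` = list(m = c("C", "T"), g = "C"))
  }
  out <- list()
  for (nm in names(alph)) {
    a <- alph[[nm]]
    w <- oracle_windows(chars %in% a$m, chars == a$g, p)
    if (nrow(w)) {
      w$key <- nm
      out[[nm]] <- w
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), errors = integer(),
                      guanines = integer(), key = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end, res$key), , drop = FALSE]
}

# brute-force matching of one TFO tract sequence against one TTS purine
# sequence under one motif: every offset, every window
oracle_match_windows <- function(tfo_seq, purine_seq, motif, p) {
  pairmap <- list(R = c(G = "G", A = "A"),
                  Y = c(C = "G", T = "A"),
                  M = c(G = "G", T = "A"))[[motif]]
  antip <- motif %in% c("R", "M")
  tch <- strsplit(toupper(tfo_seq), "")[[1]]
  exp_p <- unname(pairmap[tch])
  if (antip) exp_p <- rev(exp_p)
  pch <- strsplit(toupper(purine_seq), "")[[1]]
  nt <- length(exp_p); np <- length(pch)
  res <- list()
  for (o in seq.int(-nt + 1L, np - 1L)) {
    i1 <- max(1L, 1L - o); i2 <- min(nt, np - o)
    if (i2 - i1 + 1L < p$min_length) next
    idx <- i1:i2
    m <- !is.na(exp_p[idx]) & exp_p[idx] == pch[idx + o]
    g <- pch[idx + o] == "G"
    w <- oracle_windows(m, g, p)
    if (nrow(w) == 0L) next
    w$tfo_lo <- idx[w$start]; w$tfo_hi <- idx[w$end]
    w$tts_lo <- idx[w$start] + o; w$tts_hi <- idx[w$end] + o
    if (antip) {
      lo <- nt - w$tfo_hi + 1L; hi <- nt - w$tfo_lo + 1L
      w$tfo_lo <- lo; w$tfo_hi <- hi
    }
    res[[length(res) + 1L]] <- w
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# ---- genomic context oracle ------------------------------------------------

# per-base classification of each chromosome of an AnnotationSet
oracle_context <- function(ann, promoter_def = c(upstream = 1000, downstream = 250)) {
  up <- promoter_def[["upstream"]]; dn <- promoter_def[["downstream"]]
  lapply(setNames(names(ann$chrom_lengths), names(ann$chrom_lengths)), function(ch) {
    n <- ann$chrom_lengths[[ch]]
    cls <- rep("intergenic", n)
    tx <- ann$transcripts[ann$transcripts$chrom == ch, , drop = FALSE]
    ex <- ann$exons[as.character(GenomicRanges::seqnames(ann$exons)) == ch]
    if (nrow(tx)) {
      for (k in seq_len(nrow(tx)))  # introns below exons
        cls[seq(tx$start[k], tx$end[k])] <- "intron"
      if (length(ex) > 0) {
        for (k in seq_along(ex))
          cls[seq(GenomicRanges::start(ex)[k], GenomicRanges::end(ex)[k])] <- "exon"
      }
      for (k in seq_len(nrow(tx))) {
        tss <- if (tx$strand[k] == "-") tx$end[k] else tx$start[k]
        win <- if (tx$strand[k] == "-") {
          seq(max(1, tss - dn + 1), min(n, tss + up))
        } else {
          seq(max(1, tss - up), min(n, tss + dn - 1))
        }
        cls[win] <- "promoter"
      }
    }
    cls
  })
}

# ---- independent Fickett TESTCODE implementation ---------------------------

oracle_fickett <- function(seq) {
  pos_thr <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
  cnt_thr <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
  pos_prob <- rbind(A = c(.94, .68, .84, .93, .58, .68, .45, .34, .20, .22),
                    C = c(.80, .70, .70, .81, .66, .48, .51, .33, .30, .23),
                    G = c(.90, .88, .74, .64, .53, .48, .27, .16, .08, .08),
                    T = c(.97, .97, .91, .68, .69, .44, .54, .20, .09, .09))
  cnt_prob <- rbind(A = c(.28, .49, .44, .55, .62, .49, .67, .65, .81, .21),
                    C = c(.82, .64, .51, .64, .59, .59, .43, .44, .39, .31),
                    G = c(.40, .54, .47, .64, .64, .73, .41, .41, .33, .29),
                    T = c(.28, .24, .39, .40, .55, .75, .56, .69, .51, .58))
  pos_w <- c(A = .26, C = .18, G = .31, T = .33)
  cnt_w <- c(A = .11, C = .12, G = .15, T = .14)
  ch <- strsplit(toupper(seq), "")[[1]]
  keep <- ch %in% c("A", "C", "G", "T")
  ch <- ch[keep]
  codpos <- ((seq_along(ch) - 1) %% 3) + 1
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- sapply(1:3, function(p) sum(ch == b & codpos == p))
    pv <- max(cnt) / (min(cnt) + 1)
    total <- total + pos_prob[b, match(TRUE, pv >= pos_thr)] * pos_w[b]
    cv <- sum(cnt) / length(ch)
    total <- total + cnt_prob[b, match(TRUE, cv >= cnt_thr)] * cnt_w[b]
  }
  unname(total)
}
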