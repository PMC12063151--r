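test_that("longest ORF obeys the strict > 100 aa rule", {
  expect_null(find_longest_orf("CCTTTCCCTTTCCCTTT"))          # no ATG
  orf101 <- paste0("ATG", strrep("GCT", 100), "TAA")           # 101 aa
  got <- find_longest_orf(orf101)
  expect_equal(got$aa_length, 101)
  expect_equal(got$start, 1)
  expect_equal(got$end, 306)
  orf100 <- paste0("ATG", strrep("GCT", 99), "TAA")            # exactly 100 aa
  expect_null(find_longest_orf(orf100))
  expect_equal(find_longest_orf(orf100, min_aa = 50)$aa_length, 100)
  # unterminated ORF does not count
  expect_null(find_longest_orf(paste0("ATG", strrep("GCT", 150))))
  # longest wins across frames; ties break to the 5'-most start
  seq2 <- paste0("G", orf101, "CC", paste0("ATG", strrep("GCA", 120), "TGA"))
  expect_equal(find_longest_orf(seq2)$aa_length, 121)
})

test_that("hexamer model training smooths and normalises", {
  m <- suppressWarnings(train_hexamer_model("AAAAAA", c("ACGTAC", "GGGTTT")))
  expect_equal(sum(m$coding), 1)
  expect_equal(sum(m$noncoding), 1)
  # toy corpus: the single observed hexamer has count 1 + 1 over 4096 + 1
  expect_equal(unname(m$coding[["AAAAAA"]]), 2 / 4097)
  expect_equal(unname(m$coding[["CCCCCC"]]), 1 / 4097)
  expect_true(all(m$noncoding > 0))                  # smoothing
  # identical inputs give identical tables (hexamer-long sequences, where
  # the in-frame and all-frame counting coincide)
  m2 <- train_hexamer_model(c("ACGTAC", "GGGGGG"), c("ACGTAC", "GGGGGG"))
  expect_equal(m2$coding, m2$noncoding)
  expect_warning(train_hexamer_model(c("AAAAAA", "ACG"), "ACGTAC"), "skipped")
})

test_that("hexamer score is a mean log-likelihood ratio", {
  eq <- structure(list(coding = setNames(rep(1/4096, 4096), lncscout:::all_hexamers()),
                       noncoding = setNames(rep(1/4096, 4096), lncscout:::all_hexamers())),
                  class = "hexamer_model")
  expect_equal(hexamer_score("ACGTACGTACGT", eq), 0)
  expect_error(hexamer_score("ACGTA", eq), "shorter")
  m <- suppressWarnings(train_hexamer_model(strrep("AC", 60), strrep("GT", 60)))
  expect_gt(hexamer_score(strrep("AC", 10), m), 0)
  expect_lt(hexamer_score(strrep("GT", 10), m), 0)
  # direct evaluation on a toy 12-mer: mean of the 7 sliding hexamer ratios
  s <- "ACGTACGTACGT"
  words <- substring(s, 1:7, 6:12)
  expect_equal(hexamer_score(s, m),
               mean(log(m$coding[words] / m$noncoding[words])))
})

test_that("Fickett TESTCODE matches an independent implementation", {
  expect_equal(suppressWarnings(fickett_score(strrep("A", 300))),
               oracle_fickett(strrep("A", 300)))
  set.seed(11)
  for (k in 1:20) {
    pr <- runif(4, 0.5, 2)
    s <- rand_dna(sample(200:600, 1),
                  probs = setNames(pr / sum(pr), c("A", "C", "G", "T")))
    expect_equal(fickett_score(s), oracle_fickett(s))
  }
  # case-insensitive; Ns ignored
  s <- rand_dna(300)
  expect_equal(fickett_score(tolower(s)), fickett_score(s))
  expect_equal(fickett_score(paste0(s, "NNN")), fickett_score(s))
})

test_that("vote is unanimous non-coding", {
  m <- suppressWarnings(train_hexamer_model(
    vapply(1:5, function(i) paste0("ATG", rand_dna(300), "TAA"), ""),
    vapply(1:5, function(i) rand_dna(300), "")))
  f <- suppressWarnings(coding_features(rand_dna(300), m))
  expect_equal(classify_and_vote(f, external_votes = c("noncoding", "noncoding"))$vote,
               if (classify_and_vote(f)$builtin == "noncoding") "noncoding" else "coding")
  f_nc <- structure(list(orf = NULL, orf_aa = 0L, orf_coverage = 0,
                         fickett = 0.5, hexamer = -1), class = "coding_features")
  expect_equal(classify_and_vote(f_nc)$vote, "noncoding")
  expect_equal(classify_and_vote(f_nc, external_votes = "coding")$vote, "coding")
  f_cd <- structure(list(orf = NULL, orf_aa = 150L, orf_coverage = 0.9,
                         fickett = 0.5, hexamer = 2), class = "coding_features")
  expect_equal(classify_and_vote(f_cd)$builtin, "coding")
  expect_equal(classify_and_vote(f_cd, external_votes = rep("noncoding", 3))$vote,
               "coding")
  expect_error(classify_and_vote(f_nc, include_builtin = FALSE), "empty vote")
  expect_error(classify_and_vote(f_nc, external_votes = "maybe"), "invalid vote")
})

test_that("benchmark metrics reproduce the confusion-matrix formulas", {
  pred <- c(rep("coding", 9), rep("noncoding", 11))
  truth <- c(rep("coding", 8), "noncoding",
             rep("coding", 2), rep("noncoding", 9))
  b <- benchmark_metrics(pred, truth)
  expect_equal(c(b$TP, b$TN, b$FP, b$FN), c(8, 9, 1, 2))
  expect_equal(b$recall, 0.8)
  expect_equal(b$specificity, 0.9)
  expect_equal(b$balanced_accuracy, 0.85)
  expect_equal(b$precision, 8 / 9)
  expect_equal(b$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  # permutation invariance (named alignment)
  nm <- paste0("s", seq_along(pred))
  b2 <- benchmark_metrics(setNames(pred, nm), setNames(truth, nm)[sample(nm)])
  expect_equal(unclass(b), unclass(b2))
  # swapping the positive class swaps recall and specificity
  swap <- function(x) ifelse(x == "coding", "noncoding", "coding")
  b3 <- benchmark_metrics(swap(pred), swap(truth))
  expect_equal(b3$recall, b$specificity)
  expect_equal(b3$specificity, b$recall)
  # degenerate case: nothing predicted coding
  expect_warning(b4 <- benchmark_metrics(rep("noncoding", 4),
                                         c("coding", "coding", "noncoding", "noncoding")),
                 "precision")
  expect_equal(b4$recall, 0)
  expect_true(is.nan(b4$precision))
  expect_error(benchmark_metrics("yes", "coding"), "label outside")
})

test_that("planted coding/noncoding sequences are separated (seeded)", {
  set.seed(202)
  codons <- lncscout:::sense_codons()
  w <- exp(-seq.int(0, 60) / 15)
  mk_coding <- function() paste0(rand_dna(40), "ATG",
                                 paste(sample(codons, 200, TRUE, prob = w), collapse = ""),
                                 "TAA", rand_dna(60))
  train_c <- vapply(1:40, function(i) mk_coding(), "")
  train_n <- vapply(1:40, function(i) rand_dna(500), "")
  model <- suppressWarnings(train_hexamer_model(
    vapply(train_c, function(s) {
      o <- find_longest_orf(s, min_aa = 50); substr(s, o$start, o$end)
    }, ""), train_n))
  test_c <- vapply(1:100, function(i) mk_coding(), "")
  test_n <- vapply(1:100, function(i) rand_dna(500), "")
  pred <- vapply(c(test_c, test_n), function(s)
    classify_and_vote(suppressWarnings(coding_features(s, model)))$builtin, "")
  truth <- rep(c("coding", "noncoding"), each = 100)
  b <- benchmark_metrics(unname(pred), truth)
  expect_gte(b$balanced_accuracy, 0.9)
})
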