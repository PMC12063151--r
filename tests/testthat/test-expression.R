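test_that("gene aggregation sums and rounds half away from zero", {
  m <- rbind(t1 = c(1.4, 2.5), t2 = c(2.4, 2.0), t3 = c(5, 7))
  colnames(m) <- c("s1", "s2")
  g <- aggregate_to_gene(m, c(t1 = "gA", t2 = "gA", t3 = "gB"))
  expect_equal(unname(g["gA", ]), c(4, 5))   # 3.8 -> 4, 4.5 -> 5
  expect_equal(unname(g["gB", ]), c(5, 7))
  expect_error(aggregate_to_gene(m, c(t1 = "gA", t2 = "gA")), "unmapped")
  # identity plus rounding when one transcript per gene
  one <- aggregate_to_gene(rbind(t1 = c(0.4, 0.6)), c(t1 = "g"))
  expect_equal(unname(one["g", ]), c(0, 1))
})

test_that("median-of-ratios transform absorbs library size", {
  set.seed(31)
  base <- matrix(rpois(60, 100) + 1, 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  # identical samples: equal size factors, so B = 2A gives factor ratio 2
  t1 <- normalize_and_transform(cbind(base[, 1, drop = FALSE],
                                      s2 = base[, 1] * 2))
  sf <- attr(t1, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(t1[, 1], t1[, 2])              # transformed values equal
  same <- normalize_and_transform(cbind(base[, 1, drop = FALSE],
                                        s2 = base[, 1]))
  sf_same <- attr(same, "size_factors")
  expect_equal(unname(sf_same[1]), unname(sf_same[2]))
  # scaling any sample leaves the transform unchanged
  t2 <- normalize_and_transform(base)
  scaled <- base; scaled[, 2] <- scaled[, 2] * 7
  t3 <- normalize_and_transform(scaled)
  expect_equal(t2, t3, tolerance = 1e-12, ignore_attr = TRUE)
  # constant rows removed; all-zero reference impossible
  withcst <- rbind(base, cst = c(0, 0, 0))
  t4 <- normalize_and_transform(withcst)
  expect_false("cst" %in% rownames(t4))
  expect_equal(attr(t4, "removed"), "cst")
  expect_error(normalize_and_transform(rbind(a = c(1, 0), b = c(0, 1))),
               "pseudo-reference")
})

test_that("correlations use z-scored rows and the t distribution", {
  x <- c(1, 2, 3, 4)
  m <- rbind(x = x, y = c(2, 1, 4, 3), same = x * 3 + 2, anti = -x,
             flat = rep(1, 4))
  colnames(m) <- paste0("s", 1:4)
  pr <- data.frame(a = c("x", "x", "x", "x"),
                   b = c("same", "anti", "y", "flat"))
  got <- correlate_genes(m, pr)
  expect_equal(got$r, c(1, -1, 0.6, NA))
  expect_equal(got$n, rep(4, 4))
  expect_equal(got$p[3], cor.test(x, c(2, 1, 4, 3))$p.value)
  # z-scored rows have mean 0 and sd 1
  z <- lncscout:::zscore_rows(m[1:4, ])
  expect_equal(unname(rowMeans(z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 4), tolerance = 1e-9)
  expect_error(correlate_genes(m, data.frame(a = "x", b = "nope")), "not in matrix")
})

test_that("pair labels are exclusive and partition all pairs", {
  lncs <- make_ann(list(
    list("chr1", 3000, 3400, "+", "l1.t1", "l1", "lncRNA"),
    list("chr1", 50000, 50400, "+", "l2.t1", "l2", "lncRNA")
  ), c(chr1 = 100000))
  coding <- make_ann(list(
    list("chr1", 4901, 6000, "+", "gA.t1", "gA", "coding"),  # gap to l1: 1500
    list("chr1", 80000, 81000, "+", "gB.t1", "gB", "coding"),
    list("chr1", 20000, 21000, "+", "gC.t1", "gC", "coding")
  ), c(chr1 = 100000))
  scopes <- structure(list(
    Promoter = list(pairs = data.frame(lnc_id = c("l2", "l1"),
                                       gene_id = c("gB", "gA"))),
    Exon = list(pairs = data.frame(lnc_id = "l2", gene_id = "gC")),
    GenePromoter = list(pairs = data.frame(lnc_id = c("l2", "l2"),
                                           gene_id = c("gB", "gC")))),
    class = "interaction_pairs")
  lab <- label_pairs(lncs, coding, scopes, window = 2000)
  expect_equal(nrow(lab), 2 * 3)               # full lnc x gene grid
  get <- function(l, g) lab$label[lab$lnc_id == l & lab$gene_id == g]
  expect_equal(get("l1", "gA"), "Neighbouring")          # gap 1500, beats scope
  expect_equal(get("l2", "gB"), "Interacting_Promoter")  # far but linked
  expect_equal(get("l2", "gC"), "Independent")
  expect_equal(lab$label_exon[lab$lnc_id == "l2" & lab$gene_id == "gC"],
               "Interacting_Exon")
  expect_equal(lab$label_gene_promoter[lab$lnc_id == "l2" & lab$gene_id == "gC"],
               "Interacting_GenePromoter")
  # partition: label counts sum to the number of pairs, for every labelling
  for (col in c("label", "label_exon", "label_gene_promoter")) {
    expect_equal(sum(table(lab[[col]])), nrow(lab))
  }
})

test_that("group summaries: KS endpoints and bimodality flagging", {
  mk_pairs <- function(label, r, lnc) data.frame(
    lnc_id = lnc, gene_id = paste0("g", seq_along(r)), distance = NA,
    label = label, r = r, stringsAsFactors = FALSE)
  set.seed(9)
  ind <- mk_pairs("Independent", runif(60, -0.3, 0.3), "lA")
  de <- c(lA = FALSE)
  # disjoint supports -> KS = 1
  pairs2 <- rbind(mk_pairs("Independent", runif(40, -0.95, -0.5), "lA"),
                  mk_pairs("Interacting_Promoter", runif(40, 0.5, 0.95), "lA"))
  s2 <- summarize_by_group(pairs2, de)
  expect_equal(s2$ks_vs_independent[s2$label == "Interacting_Promoter"], 1)
  # bimodal +-0.8 group flagged, unimodal near-zero group not
  bi <- mk_pairs("Interacting_Promoter",
                 c(rnorm(40, 0.8, 0.05), rnorm(40, -0.8, 0.05)), "lB")
  uni <- mk_pairs("Independent", rnorm(80, 0, 0.1), "lB")
  s3 <- summarize_by_group(rbind(bi, uni), c(lB = TRUE))
  expect_gt(s3$bimodality[s3$label == "Interacting_Promoter"], 0.5)
  expect_lt(s3$bimodality[s3$label == "Independent"], 0.5)
  # small groups warn and skip the test
  expect_warning(
    s4 <- summarize_by_group(rbind(ind, mk_pairs("Neighbouring", c(.1, .2), "lA")), de),
    "n < 5")
  expect_true(is.na(s4$ks_vs_independent[s4$label == "Neighbouring"]))
  expect_error(summarize_by_group(ind, c(zz = TRUE)), "no DE flag")
})

test_that("KS statistic is exactly 0 on identical groups", {
  r <- seq(-0.9, 0.9, length.out = 25)
  pairs <- rbind(
    data.frame(lnc_id = "l", gene_id = paste0("a", 1:25), distance = NA,
               label = "Independent", r = r),
    data.frame(lnc_id = "l", gene_id = paste0("b", 1:25), distance = NA,
               label = "Neighbouring", r = r))
  s <- suppressWarnings(summarize_by_group(pairs, c(l = FALSE)))
  expect_equal(s$ks_vs_independent[s$label == "Neighbouring"], 0)
})

test_that("DE flags come from padj or s-value tables", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("a", "b", "c"),
                         padj = c(1e-6, 0.5, NA)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- read_de_flags(f)
  expect_equal(unname(fl[c("a", "b", "c")]), c(TRUE, FALSE, FALSE))
  write.table(data.frame(gene_id = c("a", "b"), svalue = c(0.004, 0.006)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  fl2 <- read_de_flags(f)
  expect_equal(unname(fl2[c("a", "b")]), c(TRUE, FALSE))
})
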