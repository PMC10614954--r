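test_that("housekeeping normalization anchors each cell's hk sum", {
  prof <- matrix(c(2, 4), 2, 1, dimnames = list(c("hk1", "o1"), "c1"))
  out <- housekeepingNormalize(prof, "hk1")
  expect_equal(unname(out[, 1]), c(1, 2))

  # cells differing by a global scalar become identical
  prof2 <- cbind(c1 = c(2, 4), c2 = c(6, 12))
  rownames(prof2) <- c("hk1", "o1")
  out2 <- housekeepingNormalize(prof2, "hk1")
  expect_equal(out2[, 1], out2[, 2])

  # hk set = all genes is depth normalization to the constant
  prof3 <- cbind(c1 = c(1, 3))
  rownames(prof3) <- c("g1", "g2")
  expect_equal(unname(housekeepingNormalize(prof3, c("g1", "g2"))[, 1]),
               c(0.25, 0.75))

  prof4 <- cbind(c1 = c(0, 5), c2 = c(1, 1))
  rownames(prof4) <- c("hk1", "o1")
  expect_warning(out4 <- housekeepingNormalize(prof4, "hk1"),
                 "zero housekeeping")
  expect_equal(colnames(out4), "c2")
  expect_error(housekeepingNormalize(prof4, "zz"), "no housekeeping gene")
})

test_that("per-cell log2FC medians recover multiplicative effects", {
  a <- matrix(2, 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  b <- a / 2
  expect_equal(unname(perCellLog2FC(a, b, eps = 0)), rep(1, 3))
  expect_equal(unname(perCellLog2FC(a, a, eps = 0)), rep(0, 3))

  a2 <- matrix(c(1, 2, 100), 1, 3)
  b2 <- matrix(1, 1, 3)
  expect_equal(unname(perCellLog2FC(a2, b2, eps = 0)), 1)

  # antisymmetry
  set.seed(71)
  ra <- matrix(rexp(20), 4, 5); rb <- matrix(rexp(20), 4, 5)
  expect_equal(perCellLog2FC(ra, rb), -perCellLog2FC(rb, ra))

  expect_error(perCellLog2FC(ra, rb[, 1:3]), "mismatched cell sets")
})

test_that("log2FC is invariant to shared per-cell scalings after hk normalization", {
  set.seed(72)
  a <- matrix(rexp(40) + 0.1, 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
  b <- matrix(rexp(40) + 0.1, 8, 5, dimnames = dimnames(a))
  sc <- runif(5, 0.5, 2)
  hk <- c("g1", "g2")
  fc0 <- perCellLog2FC(housekeepingNormalize(a, hk),
                       housekeepingNormalize(b, hk), eps = 0)
  fc1 <- perCellLog2FC(housekeepingNormalize(sweep(a, 2, sc, "*"), hk),
                       housekeepingNormalize(sweep(b, 2, sc, "*"), hk),
                       eps = 0)
  expect_equal(fc0, fc1, tolerance = 1e-12)
})

test_that("X-linkage groups follow the chromosome patterns", {
  ann <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    mouse = c("chrX", "chrX", "chr2", "chrX", NA),
                    opossum = c("chr4", "chrX", "chr1", "chr3", "chr1"),
                    chicken = c("chr1", "chr4", "chr3", "chrX", "chr2"))
  g <- assignGeneGroups(ann, "mouse", "opossum", "chicken")
  expect_equal(g$group, c("XAR", "XCR", "autosomal", "excluded", "excluded"))
  expect_equal(g$reason[5], "missing annotation")
  # pure function of rows: permutation permutes output
  p <- c(3, 1, 5, 2, 4)
  g2 <- assignGeneGroups(ann[p, ], "mouse", "opossum", "chicken")
  expect_equal(g2$group, g$group[p])
})

test_that("signed-rank group test matches exact enumeration", {
  # 20 identical values one unit above the null: p = 2^-20
  r <- testGroupShift(rep(0, 20), -1, "greater")
  expect_equal(r$p.value, 2^-20)
  expect_equal(r$n_used, 20L)

  # symmetric sample about the null: p near one half
  set.seed(81)
  sym <- c(-(1:10), 1:10) / 10
  expect_gt(testGroupShift(sym, 0, "greater")$p.value, 0.3)
  expect_lt(testGroupShift(sym, 0, "greater")$p.value, 0.7)

  # random n = 8 instances against full sign enumeration
  for (i in 1:10) {
    v <- rnorm(8, 0.3)
    for (alt in c("greater", "less")) {
      expect_equal(testGroupShift(v, 0, alt)$p.value,
                   oracle_signed_rank(v, 0, alt),
                   tolerance = 1e-12,
                   label = paste("instance", i, alt))
    }
  }

  tied <- testGroupShift(rep(-1, 8), -1, "greater")
  expect_equal(tied$p.value, 1)
  expect_true(tied$all_tied)
  expect_error(testGroupShift(c(0, 0, 0, 1, 1), 0, "greater"),
               "fewer than 5")
})

test_that("BH adjustment matches hand computation", {
  expect_equal(adjustPvalues(0.02), 0.02)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(adjustPvalues(p) >= p))
  expect_error(adjustPvalues(c(0.5, 1.2)))
})

test_that("GGACH motifs are counted with IUPAC H and per-kb frequency", {
  expect_equal(countGGACH("GGACA")$count, 1)
  expect_equal(countGGACH("GGACG")$count, 0)
  expect_equal(countGGACH("GGACAGGACT")$count, 2)
  expect_equal(countGGACH("ggacu")$count, 1)        # RNA, lowercase
  expect_equal(countGGACH("GGACC")$count, 1)
  expect_equal(countGGACH(Biostrings::DNAString("TTGGACTTT"))$count, 1)
  expect_equal(countGGACH("GGACAGGACT")$per_kb, 2 * 1000 / 10)
  expect_error(countGGACH(""), "empty")
})

test_that("motif-shift comparison flags X-specific motif loss", {
  set.seed(82)
  groups <- rep(c("XCR", "autosomal"), each = 100)
  f2 <- rnorm(200, 5)
  # identical delta distributions: no signal
  f1_null <- f2 + rnorm(200, 0, 0.5)
  expect_gt(compareMotifShift(f1_null, f2, groups, "XCR")[["XCR"]], 0.05)

  # X group loses one motif per kb
  rej <- 0
  for (i in 1:30) {
    shift <- ifelse(groups == "XCR", -1, 0)
    f1 <- f2 + shift + rnorm(200)
    p <- compareMotifShift(f1, f2, groups, "XCR")[["XCR"]]
    rej <- rej + (p < 0.01)
  }
  expect_gte(rej / 30, 0.9)

  # agrees with a direct rank-sum call on a fixed instance
  d1 <- rnorm(10); d0 <- rnorm(10)
  p_pkg <- compareMotifShift(c(d1, d0), rep(0, 20), groups[c(1:10, 101:110)],
                             "XCR")[["XCR"]]
  p_ref <- wilcox.test(d1, d0, alternative = "less")$p.value
  expect_equal(p_pkg, p_ref)
  expect_error(compareMotifShift(1:6, 1:6, c(rep("XCR", 3), rep("autosomal", 3))),
               "fewer than 5")
})

test_that("disease log2FC uses the 10,000 scale with +1 pseudocount", {
  expect_equal(unname(diseaseLog2FC(19, 9)), 1)
  expect_equal(unname(diseaseLog2FC(c(5, 2), c(5, 2))), c(0, 0))
  expect_equal(unname(diseaseLog2FC(0, 0)), 0)

  case <- toy_counts(matrix(c(19, 1, 9, 11), 2, 2))
  ctrl <- toy_counts(matrix(c(9, 11, 19, 1), 2, 2))
  fc <- diseaseLog2FC(case, ctrl)
  pbc <- Matrix::rowMeans(depthNormalize(case, 10000))
  pbk <- Matrix::rowMeans(depthNormalize(ctrl, 10000))
  expect_equal(unname(fc), log2((pbc + 1) / (pbk + 1)), ignore_attr = TRUE)
  expect_error(diseaseLog2FC(case[, 0], ctrl), "empty group")
})

test_that("transfer evaluation scores predicted against observed alterations", {
  set.seed(83)
  genes <- 60
  obs_case <- matrix(rexp(genes * 2, 1 / 50), genes, 2,
                     dimnames = list(NULL, c("ct1", "ct2")))
  ctrl <- matrix(rexp(genes * 2, 1 / 50), genes, 2,
                 dimnames = list(NULL, c("ct1", "ct2")))
  # prediction identical to the observation: correlation 1
  res <- transferEval(obs_case, ctrl, obs_case, obs_case, ctrl)
  expect_equal(res$prediction_cor, c(1, 1))
  # a prediction whose log2FC vector is a permutation of the observed
  # one carries no gene-level signal: near-zero correlation
  obs_fc <- sapply(colnames(obs_case), function(ct)
    log2((obs_case[, ct] + 1) / (ctrl[, ct] + 1)))
  perm <- sapply(colnames(obs_case), function(ct)
    (ctrl[, ct] + 1) * 2^(obs_fc[sample(genes), ct]) - 1)
  colnames(perm) <- colnames(obs_case)
  res2 <- transferEval(perm, ctrl, obs_case, obs_case, ctrl)
  expect_lt(max(abs(res2$prediction_cor)), 0.45)
  expect_equal(res2$baseline_cor, c(1, 1))
})
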