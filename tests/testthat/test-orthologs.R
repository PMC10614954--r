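edge_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_a = r[[1]], species_a = r[[2]], gene_b = r[[3]],
               species_b = r[[4]], percent_identity = as.numeric(r[[5]]))))
}

test_that("greedy matching picks maximal-score one-to-one pairs", {
  g <- OrthologGraph(edge_df(
    list("A", "mouse", "X", "opossum", 90),
    list("A", "mouse", "Y", "opossum", 85),
    list("B", "mouse", "X", "opossum", 80),
    list("B", "mouse", "Y", "opossum", 70)))
  m <- greedyOneToOne(g, "mouse", "opossum")
  expect_equal(m[order(m$gene_a), c("gene_a", "gene_b")],
               data.frame(gene_a = c("A", "B"), gene_b = c("X", "Y")),
               ignore_attr = TRUE)

  g1 <- OrthologGraph(edge_df(list("A", "mouse", "X", "opossum", 50)))
  expect_equal(greedyOneToOne(g1, "mouse", "opossum")$gene_a, "A")

  # vertex taken by the higher-scoring edge blocks the lower one
  g2 <- OrthologGraph(edge_df(list("A", "mouse", "X", "opossum", 90),
                              list("B", "mouse", "X", "opossum", 95)))
  m2 <- greedyOneToOne(g2, "mouse", "opossum")
  expect_equal(m2$gene_a, "B")
  expect_equal(nrow(m2), 1)

  # orientation: first species argument owns gene_a
  m3 <- greedyOneToOne(g1, "opossum", "mouse")
  expect_equal(m3$gene_a, "X")
})

test_that("graph validity rejects same-species edges and bad scores", {
  expect_error(OrthologGraph(edge_df(list("A", "mouse", "B", "mouse", 50))),
               "within one species")
  expect_error(OrthologGraph(edge_df(list("A", "mouse", "X", "opossum", 101))),
               "percent identity")
})

test_that("transitivity triangles fill missing hub edges", {
  # hub A--B accepted, B--C mapped, C untouched: A--C added
  acc <- list(mouse = data.frame(gene_a = "A", gene_b = "B",
                                 percent_identity = 90))
  pw <- list("mouse|chicken" = data.frame(gene_a = "B", gene_b = "C",
                                          percent_identity = 70))
  acc$chicken <- data.frame(gene_a = character(), gene_b = character(),
                            percent_identity = numeric())
  out <- fillTransitive(acc, pw, "hub", list(c("mouse", "chicken")))
  expect_equal(out$chicken$gene_a, "A")
  expect_equal(out$chicken$gene_b, "C")
  expect_true(out$chicken$transitive)

  # C already matched: nothing added
  acc2 <- acc
  acc2$chicken <- data.frame(gene_a = "A2", gene_b = "C",
                             percent_identity = 60)
  out2 <- fillTransitive(acc2, pw, "hub", list(c("mouse", "chicken")))
  expect_equal(nrow(out2$chicken), 1)
  expect_false(any(out2$chicken$transitive))

  # two candidate triangles sharing C: only the higher B--C score fires
  acc3 <- list(
    mouse = data.frame(gene_a = c("A1", "A2"), gene_b = c("B1", "B2"),
                       percent_identity = c(90, 91)),
    chicken = data.frame(gene_a = character(), gene_b = character(),
                         percent_identity = numeric()))
  pw3 <- list("mouse|chicken" = data.frame(
    gene_a = c("B1", "B2"), gene_b = c("C", "C"),
    percent_identity = c(80, 95)))
  out3 <- fillTransitive(acc3, pw3, "hub", list(c("mouse", "chicken")))
  expect_equal(out3$chicken$gene_a, "A2")
  expect_equal(out3$chicken$percent_identity, 95)
})

test_that("buildOneToOne assembles direct and transitive rows", {
  # complete consistent triangle: one row, all species, no transitivity
  g <- OrthologGraph(edge_df(
    list("M1", "mouse", "O1", "opossum", 90),
    list("M1", "mouse", "C1", "chicken", 85),
    list("O1", "opossum", "C1", "chicken", 80)))
  map <- buildOneToOne(g, "mouse", c("mouse", "opossum", "chicken"))
  tb <- orthologTable(map)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$opossum, "O1")
  expect_equal(tb$chicken, "C1")
  expect_equal(unname(unlist(tb[, c("provenance_opossum",
                                    "provenance_chicken")])),
               c("direct", "direct"))

  # hub--B plus B--C only: the chicken slot is completed transitively
  g2 <- OrthologGraph(edge_df(
    list("M1", "mouse", "O1", "opossum", 90),
    list("O1", "opossum", "C1", "chicken", 80)))
  tb2 <- orthologTable(buildOneToOne(g2, "mouse",
                                     c("mouse", "opossum", "chicken")))
  expect_equal(tb2$chicken, "C1")
  expect_equal(tb2$provenance_chicken, "transitive")
  expect_equal(sum(tb2$provenance_chicken == "transitive"), 1)

  # lineage-specific loss is representable
  g3 <- OrthologGraph(edge_df(list("M1", "mouse", "C1", "chicken", 50)))
  tb3 <- orthologTable(buildOneToOne(g3, "mouse",
                                     c("mouse", "opossum", "chicken")))
  expect_true(is.na(tb3$opossum))
  expect_equal(tb3$chicken, "C1")
})

test_that("reconciliation matches the brute-force oracle on random graphs", {
  species <- c("mouse", "opossum", "chicken")
  for (trial in 1:200) {
    g <- simulateOrthologGraph(
      stats::setNames(sample(1:8, 3, replace = TRUE), species),
      edge_density = runif(1, 0.1, 0.9), seed = trial)
    map <- buildOneToOne(g, "mouse", species)
    tb <- map@table
    oracle <- oracle_one_to_one(orthologEdges(g), "mouse", species)
    expect_equal(tb[order(tb$hub), , drop = FALSE],
                 oracle[order(oracle$hub), , drop = FALSE],
                 ignore_attr = TRUE, label = paste("trial", trial))
    # degree constraint: every gene at most once per foreign species
    for (cc in setdiff(colnames(tb), "hub")) {
      v <- tb[[cc]][!is.na(tb[[cc]])]
      expect_false(anyDuplicated(v) > 0)
    }
  }
})

test_that("reconciliation is deterministic", {
  g <- simulateOrthologGraph(c(mouse = 6, opossum = 6, chicken = 6),
                             edge_density = 0.5, seed = 99)
  m1 <- orthologTable(buildOneToOne(g, "mouse"))
  m2 <- orthologTable(buildOneToOne(g, "mouse"))
  expect_identical(m1, m2)
})
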