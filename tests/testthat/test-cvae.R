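# small shared fixture: 2-species toy data and an untrained model
make_toy_model <- function(n = 30, G = 12, seed = 21) {
  sim <- simulateMultispecies(n_cells_per_species = n / 2, n_genes = G,
                              n_cell_types = 2, species = c("sp1", "sp2"),
                              dropout_rate = 0.05, seed = seed)
  cfg <- cvaeConfig(n_latent = 4, hidden_width = 16, seed = seed)
  list(x = sim$counts,
       model = newCVAE(G, c("sp1", "sp2"), config = cfg))
}

test_that("encoding is deterministic and respects dimensions", {
  tm <- make_toy_model()
  e1 <- encodeCells(tm$model, tm$x)
  e2 <- encodeCells(tm$model, tm$x)
  expect_identical(e1, e2)
  expect_equal(dim(e1$mu), c(30, 4))
  expect_true(all(is.finite(e1$mu)), all(is.finite(e1$logvar)))

  # identical counts + identical factors give identical embeddings
  m <- matrix(c(3, 1, 0, 2, 0, 1, 3, 1, 0, 2, 0, 1), 12, 2)
  x2 <- toy_counts(m, species = c("sp1", "sp1"))
  e <- encodeCells(tm$model, x2)
  expect_equal(e$mu[1, ], e$mu[2, ])

  expect_error(encodeCells(tm$model, tm$x[1:5, ]), "dimension mismatch")
})

test_that("decoder output satisfies the ZINB-head invariants", {
  tm <- make_toy_model()
  set.seed(1)
  z <- matrix(rnorm(10 * 4), 10, 4)
  cells <- data.frame(species = rep(c("sp1", "sp2"), 5))
  d <- decodeCells(tm$model, z, cells)
  expect_equal(rowSums(d$mu_prime), rep(1, 10), tolerance = 1e-6)
  expect_true(all(d$size > 0))
  expect_true(all(abs(d$dropout_logit) <= 15))

  # the species factor is live: same z, different code, different profile
  same_z <- z[c(1, 1), ]
  d2 <- decodeCells(tm$model, same_z,
                    data.frame(species = c("sp1", "sp2")))
  expect_gt(max(abs(d2$mu_prime[1, ] - d2$mu_prime[2, ])), 0)

  expect_error(decodeCells(tm$model, z[, 1:2], cells), "dimension mismatch")
  expect_error(decodeCells(tm$model, z,
                           data.frame(species = rep("other", 10))),
               "dictionary")
})

test_that("the cVAE loss composes reconstruction and KL exactly", {
  tm <- make_toy_model()
  ls <- cvaeLoss(tm$model, tm$x)
  expect_equal(unname(ls["cvae"]), unname(ls["reconstr"] + ls["kl"]))
  expect_gte(unname(ls["kl"]), 0)
  expect_gte(unname(ls["cvae"]), unname(ls["reconstr"]))

  # hand-composed from the exported pieces
  enc <- encodeCells(tm$model, tm$x)
  cd <- as.data.frame(SummarizedExperiment::colData(tm$x))
  dec <- decodeCells(tm$model, enc$mu, cd)
  Xc <- t(as.matrix(SummarizedExperiment::assay(tm$x, "counts")))
  d <- rowSums(Xc)
  ll <- 0
  for (i in seq_len(nrow(Xc))) {
    ll <- ll + sum(zinbLogLik(Xc[i, ], d[i] * dec$mu_prime[i, ],
                              dec$size[i, ], dec$dropout_logit[i, ]))
  }
  rec <- -ll / nrow(Xc)
  kl <- mean(sapply(seq_len(nrow(Xc)), function(i)
    klDiagGaussian(enc$mu[i, ], enc$logvar[i, ])))
  expect_equal(unname(ls["reconstr"]), rec, tolerance = 1e-10)
  expect_equal(unname(ls["kl"]), kl, tolerance = 1e-10)
})

test_that("discriminator cross-entropy matches direct computation", {
  tm <- make_toy_model()
  model <- tm$model
  # zero parameters: uniform softmax, loss = ln K
  model@params$cW[] <- 0
  model@params$cb[] <- 0
  z <- matrix(rnorm(20 * 4), 20, 4)
  sp <- rep(c("sp1", "sp2"), 10)
  expect_equal(discriminatorLoss(model, z, sp), log(2))

  # near-perfect predictions approach zero loss
  model@params$cW[] <- 0
  model@params$cb <- c(30, -30)
  expect_lt(discriminatorLoss(model, z, rep("sp1", 20)), 1e-8)

  # generic parameters against a hand-rolled softmax CE
  set.seed(3)
  model@params$cW <- matrix(rnorm(8), 4, 2)
  model@params$cb <- rnorm(2)
  logits <- z %*% model@params$cW +
    matrix(model@params$cb, 20, 2, byrow = TRUE)
  p <- exp(logits) / rowSums(exp(logits))
  ce <- -mean(log(p[cbind(1:20, match(sp, c("sp1", "sp2")))]))
  expect_equal(discriminatorLoss(model, z, sp), ce, tolerance = 1e-12)

  expect_error(discriminatorLoss(model, z, rep("dog", 20)), "dictionary")
})

test_that("the adversarial objective is the component difference", {
  tm <- make_toy_model()
  m_off <- tm$model
  expect_equal(adversarialObjective(m_off, tm$x),
               unname(cvaeLoss(m_off, tm$x)["cvae"]))

  m_on <- tm$model
  m_on@config$use_discriminator <- TRUE
  m_on@config$adv_weight <- 1
  enc <- encodeCells(m_on, tm$x)
  expected <- unname(cvaeLoss(m_on, tm$x)["cvae"]) -
    discriminatorLoss(m_on, enc$mu, speciesLabels(tm$x))
  expect_equal(adversarialObjective(m_on, tm$x), expected)
})

test_that("generator gradients never touch discriminator parameters", {
  ns <- asNamespace("scross")
  tm <- make_toy_model()
  Xc <- t(as.matrix(SummarizedExperiment::assay(tm$x, "counts")))
  d <- rowSums(Xc)
  cd <- as.data.frame(SummarizedExperiment::colData(tm$x))
  Fh <- ns$.factor_block(tm$model, cd)
  E <- ns$.encoder_input(Xc, d, "lognorm")
  Y <- ns$.onehot(cd$species, c("sp1", "sp2"))
  st <- ns$.cvae_step(tm$model@params, Xc, E, Fh, d,
                      eps = matrix(0, nrow(Xc), 4),
                      disc = list(Y = Y, weight = 1))
  expect_false(any(c("cW", "cb") %in% names(st$grads)))
  ds <- ns$.disc_step(tm$model@params, st$Z, Y)
  expect_setequal(names(ds$grads), c("cW", "cb"))
})

test_that("checkpoints round-trip through plain-text files", {
  tm <- make_toy_model()
  dir <- withr::local_tempdir()
  saveCVAE(tm$model, file.path(dir, "ckpt"))
  m2 <- loadCVAE(file.path(dir, "ckpt"))
  e1 <- encodeCells(tm$model, tm$x)
  e2 <- encodeCells(m2, tm$x)
  expect_equal(e1$mu, e2$mu, tolerance = 1e-12)
  expect_equal(m2@levels$species, c("sp1", "sp2"))
  expect_equal(m2@config$n_latent, 4L)
})
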