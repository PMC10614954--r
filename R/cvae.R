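#' Configuration for the conditional VAE
#'
#' Collects every tunable of the model and its training loop. The
#' encoder and decoder have exactly two hidden ReLU layers; the latent
#' dimension and the optional species discriminator are the two
#' hyperparameters scanned by \code{\link{gridSearchCVAE}}.
#'
#' @param n_latent bottleneck dimension (grid values 25/50/100).
#' @param hidden_width units per hidden layer.
#' @param use_discriminator adversarially encourage species-invariant
#'   embeddings via a single-layer softmax discriminator.
#' @param adv_weight weight on the "fool the discriminator" term of the
#'   generator objective.
#' @param encoder_input \code{"lognorm"} feeds the encoder
#'   log1p(depth-normalized counts x 10,000); \code{"raw"} feeds raw
#'   counts. The likelihood always scores raw counts.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs hard epoch cap.
#' @param patience stop after this many consecutive epochs without a new
#'   validation-loss minimum (45 by default).
#' @param val_fraction,val_cap fraction of non-test cells assigned to
#'   validation, and the absolute cap on validation cells.
#' @param seed integer seed driving initialization, splitting, shuffling
#'   and reparameterization noise.
#' @return named list.
#' @export
cvaeConfig <- function(n_latent = 25, hidden_width = 128,
                       use_discriminator = FALSE, adv_weight = 1,
                       encoder_input = c("lognorm", "raw"),
                       lr = 1e-3, batch_size = 128, max_epochs = 500,
                       patience = 45, val_fraction = 0.1, val_cap = 20000,
                       seed = 1) {
  stopifnot(n_latent >= 1, hidden_width >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  list(n_latent = as.integer(n_latent),
       hidden_width = as.integer(hidden_width),
       n_hidden_layers = 2L,
       use_discriminator = isTRUE(use_discriminator),
       adv_weight = adv_weight,
       encoder_input = match.arg(encoder_input),
       lr = lr, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       val_fraction = val_fraction, val_cap = as.integer(val_cap),
       seed = as.integer(seed))
}

## one-hot encode labels against a fixed level dictionary
.onehot <- function(labels, levels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), levels)
  if (length(bad))
    stop("label(s) outside the model's dictionary: ",
         paste(bad, collapse = ", "))
  m <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  m
}

## [species | batch | tissue] one-hot block for a set of cells
.factor_block <- function(model, cells) {
  lv <- model@levels
  sp <- .onehot(cells$species, lv$species)
  bt <- if ("batch" %in% colnames(cells) && length(lv$batch))
    .onehot(cells$batch, lv$batch) else
      matrix(1, nrow(cells), 1, dimnames = list(NULL, "batch1"))
  ts <- if ("tissue" %in% colnames(cells) && length(lv$tissue))
    .onehot(cells$tissue, lv$tissue) else
      matrix(1, nrow(cells), 1, dimnames = list(NULL, "tissue1"))
  cbind(sp, bt, ts)
}

## encoder conditioning input (cells x genes)
.encoder_input <- function(Xc, d, encoder_input) {
  if (encoder_input == "raw") return(Xc)
  log1p(Xc / d * 1e4)
}

## dense cells-x-genes counts from a CrossSpeciesCounts
.dense_cells <- function(x) {
  t(as.matrix(SummarizedExperiment::assay(x, "counts")))
}

#' Initialize an untrained conditional VAE
#'
#' @param n_genes number of genes (decoder output width).
#' @param species_levels character vector of species labels the model
#'   knows (one-hot dictionary).
#' @param batch_levels,tissue_levels factor dictionaries; a single level
#'   yields a constant one-hot column, appropriate when the factor does
#'   not vary.
#' @param config a \code{\link{cvaeConfig}} list.
#' @return An untrained \linkS4class{CVAEModel}; parameters are drawn
#'   reproducibly from \code{config$seed}.
#' @export
newCVAE <- function(n_genes, species_levels, batch_levels = "batch1",
                    tissue_levels = "tissue1", config = cvaeConfig()) {
  nf <- length(species_levels) + length(batch_levels) + length(tissue_levels)
  n_in_enc <- n_genes + nf
  n_in_dec <- config$n_latent + nf
  set.seed(config$seed)
  params <- .nn_init(n_in_enc, n_in_dec, n_genes, config$n_latent,
                     config$hidden_width, length(species_levels))
  methods::new("CVAEModel", params = params, config = config,
               levels = list(species = species_levels,
                             batch = batch_levels,
                             tissue = tissue_levels),
               dims = list(n_genes = as.integer(n_genes),
                           n_latent = config$n_latent,
                           hidden_width = config$hidden_width),
               history = list())
}

#' Encode cells into the latent space
#'
#' Deterministic given the model parameters and input: returns the
#' posterior mean and log-variance of each cell's embedding. Sampling
#' (reparameterized) is requested explicitly and seeded.
#'
#' @param model a \linkS4class{CVAEModel}.
#' @param x a \linkS4class{CrossSpeciesCounts}, or a cells-x-genes count
#'   matrix (then \code{cells} must be supplied).
#' @param cells optional data.frame of per-cell factors
#'   (\code{species}, optionally \code{batch}, \code{tissue}); taken from
#'   \code{colData(x)} when \code{x} is a container.
#' @param sample draw a reparameterized z instead of returning only the
#'   posterior moments.
#' @param seed RNG seed used when \code{sample = TRUE}.
#' @return list with matrices \code{mu}, \code{logvar} (cells x
#'   n_latent) and, when sampled, \code{z}.
#' @export
encodeCells <- function(model, x, cells = NULL, sample = FALSE, seed = 1) {
  if (methods::is(x, "CrossSpeciesCounts")) {
    cells <- as.data.frame(colData(x))
    Xc <- .dense_cells(x)
  } else {
    Xc <- as.matrix(x)
    if (is.null(cells)) stop("per-cell factors required for a bare matrix")
  }
  if (ncol(Xc) != model@dims$n_genes)
    stop("dimension mismatch: model expects ", model@dims$n_genes, " genes")
  d <- rowSums(Xc)
  Fh <- .factor_block(model, cells)
  enc <- .encoder_forward(model@params,
                          cbind(.encoder_input(Xc, d, model@config$encoder_input), Fh))
  out <- list(mu = enc$MU, logvar = enc$LV)
  if (sample) {
    set.seed(seed)
    eps <- matrix(stats::rnorm(length(enc$MU)), nrow(enc$MU))
    out$z <- enc$MU + eps * exp(enc$LV / 2)
  }
  out
}

#' Decode latent embeddings into ZINB parameters
#'
#' Conditions the decoder on the given factor codes; the species code is
#' "live" in the sense that changing it changes the emitted profile,
#' which is what species-factor swapping exploits.
#'
#' @param model a \linkS4class{CVAEModel}.
#' @param z cells x n_latent matrix of embeddings.
#' @param cells data.frame of per-cell factors (\code{species},
#'   optionally \code{batch}, \code{tissue}).
#' @return list of cells x genes matrices: \code{mu_prime} (each row a
#'   simplex: depth-corrected mean rates summing to 1), \code{size}
#'   (dispersion, > 0) and \code{dropout_logit}.
#' @export
decodeCells <- function(model, z, cells) {
  z <- as.matrix(z)
  if (ncol(z) != model@dims$n_latent)
    stop("dimension mismatch: model expects n_latent = ", model@dims$n_latent)
  Fh <- .factor_block(model, cells)
  dec <- .decoder_forward(model@params, z, Fh)
  list(mu_prime = dec$MUp, size = dec$R, dropout_logit = dec$P)
}

#' Conditional-VAE loss on a batch of cells
#'
#' Reconstruction term: negative ZINB log-likelihood of the raw counts
#' under mean depth x mu', summed over genes and averaged over cells.
#' KL term: closed-form divergence of the diagonal-Gaussian posterior
#' from the standard normal, averaged over cells. The total is their
#' unweighted sum.
#'
#' @inheritParams encodeCells
#' @return named numeric: \code{reconstr}, \code{kl}, \code{cvae}.
#' @export
cvaeLoss <- function(model, x, cells = NULL, sample = FALSE, seed = 1) {
  if (methods::is(x, "CrossSpeciesCounts")) {
    cells <- as.data.frame(colData(x))
    Xc <- .dense_cells(x)
  } else {
    Xc <- as.matrix(x)
    if (is.null(cells)) stop("per-cell factors required for a bare matrix")
  }
  d <- rowSums(Xc)
  Fh <- .factor_block(model, cells)
  E <- .encoder_input(Xc, d, model@config$encoder_input)
  eps <- NULL
  if (sample) {
    set.seed(seed)
    eps <- matrix(stats::rnorm(nrow(Xc) * model@dims$n_latent), nrow(Xc))
  }
  st <- .cvae_step(model@params, Xc, E, Fh, d, eps = eps)
  c(reconstr = st$loss_rec, kl = st$loss_kl, cvae = st$loss_cvae)
}

#' Species-discriminator cross-entropy
#'
#' Mean cross-entropy of the single-layer softmax discriminator's species
#' predictions from cell embeddings.
#'
#' @param model a \linkS4class{CVAEModel}.
#' @param z cells x n_latent embedding matrix.
#' @param species character vector of true species labels.
#' @return numeric(1).
#' @export
discriminatorLoss <- function(model, z, species) {
  Y <- .onehot(species, model@levels$species)
  .disc_step(model@params, as.matrix(z), Y)$loss
}

#' Adversarial generator objective
#'
#' The quantity the encoder/decoder minimize during the generator step
#' when the discriminator is enabled: loss_cVAE - w * loss_dis, with the
#' discriminator parameters held fixed. Without a discriminator this is
#' just loss_cVAE.
#'
#' @inheritParams cvaeLoss
#' @return numeric(1).
#' @export
adversarialObjective <- function(model, x, cells = NULL, sample = FALSE,
                                 seed = 1) {
  ls <- cvaeLoss(model, x, cells = cells, sample = sample, seed = seed)
  if (!isTRUE(model@config$use_discriminator)) return(unname(ls["cvae"]))
  if (methods::is(x, "CrossSpeciesCounts")) cells <- as.data.frame(colData(x))
  enc <- encodeCells(model, x, cells = cells, sample = sample, seed = seed)
  z <- if (sample) enc$z else enc$mu
  unname(ls["cvae"]) -
    model@config$adv_weight * discriminatorLoss(model, z, cells$species)
}
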