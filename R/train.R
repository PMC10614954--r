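#' Split cells into train / validation / test sets
#'
#' The test set is whatever \code{held_out} selects (typically all cells
#' of one cell type or tissue in the target species, mimicking an
#' uncharacterized context). Of the remaining cells, 10\% (capped at
#' 20,000) are sampled without replacement as validation; the rest train
#' the model. The three sets are disjoint and cover all cells.
#'
#' @param n total number of cells, or a
#'   \linkS4class{CrossSpeciesCounts} (its cell count is used).
#' @param held_out logical vector (length n) selecting test cells, or
#'   NULL for none.
#' @param val_fraction,val_cap validation fraction and cap.
#' @param seed RNG seed.
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
splitTrainVal <- function(n, held_out = NULL, val_fraction = 0.1,
                          val_cap = 20000, seed = 1) {
  if (methods::is(n, "CrossSpeciesCounts")) n <- ncol(n)
  if (is.null(held_out)) held_out <- rep(FALSE, n)
  stopifnot(length(held_out) == n)
  test <- which(held_out)
  rest <- which(!held_out)
  if (!length(rest)) stop("held-out selector matches every cell")
  n_val <- min(ceiling(val_fraction * length(rest)), val_cap)
  set.seed(seed)
  val <- sort(sample(rest, n_val))
  list(train = setdiff(rest, val), val = val, test = test)
}

#' Fit the conditional VAE
#'
#' Minibatch Adam with early stopping: training halts once the
#' validation loss (loss_cVAE, evaluated with the posterior mean) has not
#' reached a new minimum for \code{patience} consecutive epochs, and the
#' parameters from the minimum-validation-loss epoch are returned. With
#' the discriminator enabled, each minibatch runs one discriminator
#' update (cross-entropy on sampled embeddings) followed by one generator
#' update on loss_cVAE - w * loss_dis with the discriminator frozen.
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param config a \code{\link{cvaeConfig}}.
#' @param held_out logical selector of test cells (never seen during
#'   training), or NULL.
#' @param verbose print per-epoch losses.
#' @return A trained \linkS4class{CVAEModel}; \code{@history} holds the
#'   per-epoch loss curve, \code{best_epoch}, \code{best_val_loss} and
#'   the split indices.
#' @export
fitCVAE <- function(x, config = cvaeConfig(), held_out = NULL,
                    verbose = FALSE) {
  cd <- as.data.frame(colData(x))
  species_levels <- sort(unique(cd$species))
  batch_levels <- if ("batch" %in% colnames(cd))
    sort(unique(as.character(cd$batch))) else "batch1"
  tissue_levels <- if ("tissue" %in% colnames(cd))
    sort(unique(as.character(cd$tissue))) else "tissue1"
  model <- newCVAE(nrow(x), species_levels, batch_levels, tissue_levels,
                   config)
  split <- splitTrainVal(ncol(x), held_out, config$val_fraction,
                         config$val_cap, seed = config$seed)
  Xall <- .dense_cells(x)
  dall <- rowSums(Xall)
  if (any(dall[c(split$train, split$val)] <= 0))
    stop("zero-depth cell in the training data; filter first")
  Eall <- .encoder_input(Xall, pmax(dall, 1), config$encoder_input)
  Fall <- .factor_block(model, cd)
  Yall <- .onehot(cd$species, species_levels)
  p <- model@params
  gen_names <- grep("^[ed]", names(p), value = TRUE)
  opt_gen <- .adam_init(p[gen_names])
  opt_dis <- .adam_init(p[c("cW", "cb")])
  tr <- split$train
  va <- split$val
  best <- list(loss = Inf, epoch = 0L, params = p)
  curve <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  stall <- 0L
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(tr)
    nb <- ceiling(length(idx) / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      rows <- idx[((b - 1) * config$batch_size + 1):
                  min(b * config$batch_size, length(idx))]
      Xb <- Xall[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * config$n_latent),
                    length(rows))
      disc <- NULL
      if (config$use_discriminator) {
        # step 1: train the discriminator on sampled embeddings
        enc <- .encoder_forward(p, cbind(Eall[rows, , drop = FALSE],
                                         Fall[rows, , drop = FALSE]))
        Zb <- enc$MU + eps * exp(enc$LV / 2)
        ds <- .disc_step(p, Zb, Yall[rows, , drop = FALSE])
        up <- .adam_step(p[c("cW", "cb")], ds$grads, opt_dis, lr = config$lr)
        p[c("cW", "cb")] <- up$params
        opt_dis <- up$state
        disc <- list(Y = Yall[rows, , drop = FALSE],
                     weight = config$adv_weight)
      }
      # step 2: generator update (discriminator frozen)
      st <- .cvae_step(p, Xb, Eall[rows, , drop = FALSE],
                       Fall[rows, , drop = FALSE], dall[rows],
                       eps = eps, disc = disc)
      if (!is.finite(st$loss_cvae))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      up <- .adam_step(p[gen_names], st$grads, opt_gen, lr = config$lr)
      p[gen_names] <- up$params
      opt_gen <- up$state
      ep_loss <- ep_loss + st$loss_cvae * length(rows)
    }
    ep_loss <- ep_loss / length(idx)
    # validation loss with the posterior mean (no sampling)
    vst <- .cvae_step(p, Xall[va, , drop = FALSE],
                      Eall[va, , drop = FALSE], Fall[va, , drop = FALSE],
                      dall[va], eps = NULL)
    vloss <- vst$loss_cvae
    curve <- rbind(curve, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vloss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, ep_loss, vloss))
    if (vloss < best$loss) {
      best <- list(loss = vloss, epoch = epoch, params = p)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model@params <- best$params
  model@history <- list(curve = curve, best_epoch = best$epoch,
                        best_val_loss = best$loss, split = split)
  model
}

#' Local inverse Simpson's index (LISI) of label mixing
#'
#' For each cell, Gaussian-kernel weights over its k nearest neighbors
#' are calibrated (by binary search on the bandwidth) to a fixed
#' perplexity; summing the weights per label gives label probabilities
#' p_l, and the cell's LISI is 1 / sum(p_l^2) -- the effective number of
#' labels in its neighborhood. 1 means fully separated; the number of
#' labels means fully mixed.
#'
#' @param emb cells x dims embedding matrix.
#' @param labels per-cell labels.
#' @param perplexity neighborhood perplexity (default 30).
#' @param k neighbors used (default 3 x perplexity, reduced with a
#'   warning when fewer cells are available).
#' @return numeric vector of per-cell LISI values.
#' @export
computeLISI <- function(emb, labels, perplexity = 30, k = 3 * perplexity) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (k > n - 1) {
    warning("fewer cells than k + 1; reducing k to ", n - 1)
    k <- n - 1
  }
  perplexity <- min(perplexity, k / 3 + 1e-9)
  D2 <- as.matrix(stats::dist(emb))^2
  target <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- ord[ord != i][seq_len(k)]
    d2 <- D2[i, nb]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        pj <- w / sw
        H <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * d2)
    if (sum(w) == 0) { out[i] <- 1; next }
    pj <- w / sum(w)
    pl <- tapply(pj, labels[nb], sum)
    out[i] <- 1 / sum(pl^2)
  }
  out
}

#' Hyperparameter grid search with LISI-based selection
#'
#' Fits every combination of discriminator on/off and latent dimension,
#' then selects the fit whose validation-cell embeddings have the largest
#' mean species-LISI (best cross-species mixing). All candidates' metrics
#' are kept in the returned model's history.
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param config base \code{\link{cvaeConfig}} (its \code{n_latent} /
#'   \code{use_discriminator} are overridden by the grid).
#' @param n_latent_grid latent dimensions to scan.
#' @param discriminator_grid discriminator settings to scan.
#' @param held_out logical test-cell selector passed to
#'   \code{\link{fitCVAE}}.
#' @param perplexity LISI perplexity.
#' @return the selected trained \linkS4class{CVAEModel}; its history
#'   gains \code{grid} (per-candidate val loss and LISI) and
#'   \code{lisi_score}.
#' @export
gridSearchCVAE <- function(x, config = cvaeConfig(),
                           n_latent_grid = c(25, 50, 100),
                           discriminator_grid = c(FALSE, TRUE),
                           held_out = NULL, perplexity = 30) {
  cand <- expand.grid(use_discriminator = discriminator_grid,
                      n_latent = n_latent_grid)
  fits <- vector("list", nrow(cand))
  lisi <- numeric(nrow(cand))
  vloss <- numeric(nrow(cand))
  cd <- as.data.frame(colData(x))
  for (i in seq_len(nrow(cand))) {
    cfg <- config
    cfg$n_latent <- as.integer(cand$n_latent[i])
    cfg$use_discriminator <- cand$use_discriminator[i]
    fit <- fitCVAE(x, cfg, held_out = held_out)
    va <- fit@history$split$val
    enc <- encodeCells(fit, x[, va])
    lisi[i] <- mean(computeLISI(enc$mu, cd$species[va],
                                perplexity = perplexity))
    vloss[i] <- fit@history$best_val_loss
    fits[[i]] <- fit
  }
  if (all(!is.finite(vloss))) stop("all grid-search runs diverged")
  sel <- which.max(lisi)
  best <- fits[[sel]]
  best@history$grid <- cbind(cand, val_loss = vloss, species_lisi = lisi)
  best@history$lisi_score <- lisi[sel]
  best
}
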