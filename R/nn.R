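## Internal dense-network machinery for the conditional VAE. Everything
## operates on minibatch matrices with cells in rows. Gradients are
## derived analytically from the ZINB log-likelihood (the digamma terms
## for the dispersion head) and propagated by hand; Adam is the
## optimizer. Single-threaded BLAS matrix products keep this fast enough
## for the problem sizes the package targets.

.relu <- function(x) pmax(x, 0)

.addrow <- function(A, b) A + rep(b, each = nrow(A))

.softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

.row_softmax <- function(A) {
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.R_EPS <- 1e-4     # dispersion floor added to softplus
.P_CLAMP <- 15     # dropout logit clamp
.LV_CLAMP <- 10    # encoder log-variance clamp

## He-style initialization; heads get small weights
.nn_init <- function(n_in_enc, n_in_dec, n_genes, n_latent, width, n_species) {
  he <- function(nin, nout, scale = sqrt(2)) {
    matrix(stats::rnorm(nin * nout, 0, scale / sqrt(nin)), nin, nout)
  }
  list(
    eW1 = he(n_in_enc, width), eb1 = numeric(width),
    eW2 = he(width, width),    eb2 = numeric(width),
    eWm = he(width, n_latent, 0.1), ebm = numeric(n_latent),
    eWv = he(width, n_latent, 0.1), ebv = numeric(n_latent),
    dW1 = he(n_in_dec, width), db1 = numeric(width),
    dW2 = he(width, width),    db2 = numeric(width),
    dWmu = he(width, n_genes, 0.1), dbmu = numeric(n_genes),
    dWr  = he(width, n_genes, 0.1), dbr = numeric(n_genes),
    dWp  = he(width, n_genes, 0.1), dbp = numeric(n_genes),
    cW = he(n_latent, n_species, 0.1), cb = numeric(n_species))
}

.encoder_forward <- function(p, E) {
  H1 <- .relu(.addrow(E %*% p$eW1, p$eb1))
  H2 <- .relu(.addrow(H1 %*% p$eW2, p$eb2))
  MU <- .addrow(H2 %*% p$eWm, p$ebm)
  LVraw <- .addrow(H2 %*% p$eWv, p$ebv)
  LV <- .clamp(LVraw, -.LV_CLAMP, .LV_CLAMP)
  list(E = E, H1 = H1, H2 = H2, MU = MU, LV = LV, LVraw = LVraw)
}

.decoder_forward <- function(p, Z, Fh) {
  D <- cbind(Z, Fh)
  G1 <- .relu(.addrow(D %*% p$dW1, p$db1))
  G2 <- .relu(.addrow(G1 %*% p$dW2, p$db2))
  Amu <- .addrow(G2 %*% p$dWmu, p$dbmu)
  Ar <- .addrow(G2 %*% p$dWr, p$dbr)
  Ap <- .addrow(G2 %*% p$dWp, p$dbp)
  MUp <- .row_softmax(Amu)
  R <- .softplus(Ar) + .R_EPS
  P <- .clamp(Ap, -.P_CLAMP, .P_CLAMP)
  list(D = D, G1 = G1, G2 = G2, Amu = Amu, Ar = Ar, Ap = Ap,
       MUp = MUp, R = R, P = P)
}

## elementwise d loglik / d {mean, size, logit} for the ZINB
.zinb_grads <- function(X, M, R, P) {
  log_pi <- stats::plogis(P, log.p = TRUE)
  log_1mpi <- stats::plogis(-P, log.p = TRUE)
  pi <- exp(log_pi)
  lratio <- log(R) - log(R + M)
  pos <- X > 0
  dM <- matrix(0, nrow(X), ncol(X))
  dR <- dM; dP <- dM
  if (any(pos)) {
    dM[pos] <- (X / pmax(M, 1e-12))[pos] - ((X + R) / (R + M))[pos]
    dR[pos] <- digamma(X[pos] + R[pos]) - digamma(R[pos]) +
      lratio[pos] + 1 - ((X + R) / (R + M))[pos]
    dP[pos] <- -pi[pos]
  }
  z <- !pos
  if (any(z)) {
    a <- (R * lratio)[z]
    logS <- .logsumexp2(log_pi[z], log_1mpi[z] + a)
    w <- exp(log_1mpi[z] + a - logS)
    dM[z] <- -w * (R / (R + M))[z]
    dR[z] <- w * (lratio[z] + (M / (R + M))[z])
    # d ll / d logit at x = 0 is pi * ((1 - pi)/S - w)
    dP[z] <- pi[z] * (exp(log_1mpi[z] - logS) - w)
  }
  list(dM = dM, dR = dR, dP = dP)
}

## Full training-step loss and gradients for one minibatch.
## Xc: raw counts (cells x genes); E: encoder input; Fh: one-hot factors;
## d: depths; eps: reparameterization noise (NULL = use posterior mean);
## disc: list(Y = one-hot species, weight) to add the "fool the
## discriminator" term (discriminator parameters receive no gradient).
.cvae_step <- function(p, Xc, E, Fh, d, eps = NULL, disc = NULL) {
  n <- nrow(Xc)
  enc <- .encoder_forward(p, cbind(E, Fh))
  if (is.null(eps)) {
    Z <- enc$MU
  } else {
    Z <- enc$MU + eps * exp(enc$LV / 2)
  }
  dec <- .decoder_forward(p, Z, Fh)
  M <- dec$MUp * d              # recycles d down columns (cells)
  ll <- zinbLogLik(as.vector(Xc), as.vector(M), as.vector(dec$R),
                   as.vector(dec$P))
  loss_rec <- -sum(ll) / n
  loss_kl <- sum(0.5 * (enc$MU^2 + exp(enc$LV) - enc$LV - 1)) / n
  # gradients
  g <- .zinb_grads(Xc, M, dec$R, dec$P)
  gM <- -g$dM / n; gR <- -g$dR / n; gP <- -g$dP / n
  # heads
  U <- gM * d                                   # d mean / d mu'
  gAmu <- dec$MUp * (U - rowSums(U * dec$MUp))
  gAr <- gR * stats::plogis(dec$Ar)
  gAp <- gP * (abs(dec$Ap) < .P_CLAMP)
  # decoder trunk
  gG2 <- gAmu %*% t(p$dWmu) + gAr %*% t(p$dWr) + gAp %*% t(p$dWp)
  gPre2 <- gG2 * (dec$G2 > 0)
  gG1 <- gPre2 %*% t(p$dW2)
  gPre1 <- gG1 * (dec$G1 > 0)
  gD <- gPre1 %*% t(p$dW1)
  nl <- ncol(Z)
  gZ <- gD[, seq_len(nl), drop = FALSE]
  loss_dis <- 0
  if (!is.null(disc)) {
    logits <- .addrow(Z %*% p$cW, p$cb)
    Pd <- .row_softmax(logits)
    loss_dis <- -sum(log(pmax(Pd[disc$Y > 0], 1e-12))) / n
    # generator minimizes loss_cVAE - weight * loss_dis
    gZ <- gZ - disc$weight * ((Pd - disc$Y) %*% t(p$cW)) / n
  }
  # KL gradients + reparameterization
  gMU <- gZ + enc$MU / n
  gLV_kl <- (exp(enc$LV) - 1) / (2 * n)
  if (is.null(eps)) {
    gLV <- gLV_kl
  } else {
    gLV <- gZ * eps * exp(enc$LV / 2) * 0.5 + gLV_kl
  }
  gLV <- gLV * (abs(enc$LVraw) < .LV_CLAMP)
  # encoder trunk
  gH2 <- gMU %*% t(p$eWm) + gLV %*% t(p$eWv)
  ePre2 <- gH2 * (enc$H2 > 0)
  gH1 <- ePre2 %*% t(p$eW2)
  ePre1 <- gH1 * (enc$H1 > 0)
  grads <- list(
    eW1 = t(enc$E) %*% ePre1, eb1 = colSums(ePre1),
    eW2 = t(enc$H1) %*% ePre2, eb2 = colSums(ePre2),
    eWm = t(enc$H2) %*% gMU, ebm = colSums(gMU),
    eWv = t(enc$H2) %*% gLV, ebv = colSums(gLV),
    dW1 = t(dec$D) %*% gPre1, db1 = colSums(gPre1),
    dW2 = t(dec$G1) %*% gPre2, db2 = colSums(gPre2),
    dWmu = t(dec$G2) %*% gAmu, dbmu = colSums(gAmu),
    dWr = t(dec$G2) %*% gAr, dbr = colSums(gAr),
    dWp = t(dec$G2) %*% gAp, dbp = colSums(gAp))
  list(loss_rec = loss_rec, loss_kl = loss_kl,
       loss_cvae = loss_rec + loss_kl, loss_dis = loss_dis,
       grads = grads, Z = Z)
}

## discriminator-only step: cross-entropy loss and its gradients
.disc_step <- function(p, Z, Y) {
  n <- nrow(Z)
  logits <- .addrow(Z %*% p$cW, p$cb)
  Pd <- .row_softmax(logits)
  loss <- -sum(log(pmax(Pd[Y > 0], 1e-12))) / n
  gL <- (Pd - Y) / n
  list(loss = loss,
       grads = list(cW = t(Z) %*% gL, cb = colSums(gL)))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
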