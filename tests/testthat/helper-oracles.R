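# Independent oracle implementations and small fixture builders used
# across the suite. The oracles deliberately use different code paths
# (repeated argmax, explicit enumeration, Monte Carlo) from the package
# implementations they check.

toy_counts <- function(mat, species = rep("s1", ncol(mat)),
                       extra_cells = NULL) {
  genes <- data.frame(gene_id = paste0("g", seq_len(nrow(mat))))
  cells <- data.frame(cell_id = paste0("c", seq_len(ncol(mat))),
                      species = species)
  if (!is.null(extra_cells)) cells <- cbind(cells, extra_cells)
  CrossSpeciesCounts(Matrix::Matrix(mat, sparse = TRUE), genes, cells)
}

# --- ortholog reconciliation: brute-force re-simulation ----------------

# one-to-one matching between two species by repeated argmax
oracle_match_pair <- function(edges, sa, sb) {
  sel <- edges[(edges$species_a == sa & edges$species_b == sb) |
               (edges$species_a == sb & edges$species_b == sa), ,
               drop = FALSE]
  out <- data.frame(ga = character(), gb = character(), s = numeric())
  if (!nrow(sel)) return(out)
  df <- data.frame(
    ga = ifelse(sel$species_a == sa, sel$gene_a, sel$gene_b),
    gb = ifelse(sel$species_a == sa, sel$gene_b, sel$gene_a),
    s = sel$percent_identity, stringsAsFactors = FALSE)
  while (nrow(df)) {
    o <- order(-df$s, df$ga, df$gb)
    best <- df[o[1], ]
    out <- rbind(out, best)
    df <- df[df$ga != best$ga & df$gb != best$gb, , drop = FALSE]
  }
  out
}

# full two-phase procedure: hub matchings, then transitivity triangles
oracle_one_to_one <- function(edges, hub, species_order, pair_order = NULL) {
  others <- setdiff(species_order, hub)
  acc <- lapply(others, function(sp) {
    m <- oracle_match_pair(edges, hub, sp)
    m$transitive <- rep(FALSE, nrow(m))
    m
  })
  names(acc) <- others
  if (is.null(pair_order)) {
    pair_order <- list()
    if (length(others) >= 2)
      for (i in seq_len(length(others) - 1))
        for (j in seq(i + 1, length(others)))
          pair_order[[length(pair_order) + 1]] <- c(others[i], others[j])
  }
  has_edge <- function(sp, gene) {
    any(acc[[sp]]$gb == gene)
  }
  hub_neighbor_in <- function(sp, hubgene) {
    any(acc[[sp]]$ga == hubgene)
  }
  for (pr in pair_order) {
    pm <- oracle_match_pair(edges, pr[1], pr[2])
    repeat {
      # collect currently fireable triangles, both orientations
      cands <- data.frame(A = character(), sC = character(),
                          gC = character(), gB = character(), s = numeric())
      if (nrow(pm)) {
        for (i in seq_len(nrow(pm))) {
          for (dir in 1:2) {
            sB <- pr[dir]; sC <- pr[3 - dir]
            gB <- if (dir == 1) pm$ga[i] else pm$gb[i]
            gC <- if (dir == 1) pm$gb[i] else pm$ga[i]
            hit <- acc[[sB]][acc[[sB]]$gb == gB, , drop = FALSE]
            if (!nrow(hit)) next
            A <- hit$ga[1]
            if (has_edge(sC, gC)) next
            if (hub_neighbor_in(sC, A)) next
            cands <- rbind(cands, data.frame(A = A, sC = sC, gC = gC,
                                             gB = gB, s = pm$s[i]))
          }
        }
      }
      if (!nrow(cands)) break
      o <- order(-cands$s, cands$gB, cands$gC)
      b <- cands[o[1], ]
      acc[[b$sC]] <- rbind(acc[[b$sC]],
                           data.frame(ga = b$A, gb = b$gC, s = b$s,
                                      transitive = TRUE))
    }
  }
  # assemble into the same row shape the package uses
  hub_genes <- sort(unique(unlist(lapply(acc, function(a) a$ga))))
  tb <- data.frame(hub = hub_genes, stringsAsFactors = FALSE)
  for (sp in others) {
    idx <- match(hub_genes, acc[[sp]]$ga)
    tb[[sp]] <- acc[[sp]]$gb[idx]
  }
  tb
}

# --- exact one-sample signed-rank p by sign enumeration ----------------

oracle_signed_rank <- function(values, null_median, alternative) {
  d <- values - null_median
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  hits <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    w <- sum(r[signs == 1])
    if (alternative == "greater") {
      if (w >= W) hits <- hits + 1
    } else {
      if (w <= W) hits <- hits + 1
    }
  }
  hits / 2^n
}

# --- naive LISI --------------------------------------------------------

oracle_lisi <- function(emb, labels, perplexity = 30, k = 3 * perplexity) {
  n <- nrow(emb)
  k <- min(k, n - 1)
  perplexity <- min(perplexity, k / 3 + 1e-9)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(emb) - emb[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    dn <- d2[nb]
    f <- function(beta) {
      w <- exp(-beta * dn)
      if (sum(w) == 0) return(-log(perplexity))
      p <- w / sum(w)
      -sum(p[p > 0] * log(p[p > 0])) - log(perplexity)
    }
    lo <- 1e-12; hi <- 1e12
    while (f(lo) < 0 && lo > 1e-300) lo <- lo / 10
    for (it in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-10) break
    }
    w <- exp(-sqrt(lo * hi) * dn)
    p <- w / sum(w)
    pl <- tapply(p, labels[nb], sum)
    vals[i] <- 1 / sum(pl^2)
  }
  vals
}

# per-row direct evaluation of the demultiplexing rule
oracle_demux_row <- function(counts, frac = 0.2) {
  total <- sum(counts)
  if (total == 0) return("unassigned")
  srt <- sort(counts, decreasing = TRUE)
  if (sum(srt[-1]) / total > frac) return("doublet")
  sort(names(counts)[counts == max(counts)])[1]
}
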