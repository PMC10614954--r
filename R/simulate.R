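#' Simulate multi-species ZINB single-cell counts with known truth
#'
#' Generates cells from shared cell-type programs (per-type gene rates on
#' a simplex) modulated by per-gene per-species and per-batch
#' multiplicative effects (additive in log2). Each cell's counts are
#' drawn from a zero-inflated negative binomial with mean depth x rate,
#' where depths are log-normal with a median around 450 UMIs -- the
#' sparse combinatorial-indexing regime the model targets. The full
#' generative truth is returned for parameter-recovery checks.
#'
#' @param n_cells_per_species cells simulated per species.
#' @param n_genes number of genes (shared ortholog space).
#' @param n_cell_types number of shared cell-type programs.
#' @param species character vector of species labels; the first is the
#'   reference (zero species effect).
#' @param species_effect_sd SD (log2) of per-gene species effects on the
#'   non-reference species.
#' @param dropout_rate elementwise probability of a forced zero.
#' @param nb_size NB dispersion r (variance mean + mean^2/r).
#' @param depth_meanlog,depth_sdlog log-normal depth parameters
#'   (defaults give median exp(meanlog) = 450).
#' @param n_batches batches (assigned at random within species; the
#'   first batch carries zero effect).
#' @param batch_effect_sd SD (log2) of per-gene batch effects.
#' @param seed RNG seed; the output is bit-reproducible given the seed.
#' @return list: \code{counts} (a \linkS4class{CrossSpeciesCounts}) and
#'   \code{truth} (programs, species/batch effects in log2, per-cell
#'   type/depth, parameters, seed).
#' @export
simulateMultispecies <- function(n_cells_per_species = 2000, n_genes = 200,
                                 n_cell_types = 3,
                                 species = c("speciesA", "speciesB"),
                                 species_effect_sd = 0.5,
                                 dropout_rate = 0.1, nb_size = 2,
                                 depth_meanlog = log(450),
                                 depth_sdlog = 0.6,
                                 n_batches = 1, batch_effect_sd = 0,
                                 seed = 1) {
  stopifnot(n_cells_per_species >= 1, n_genes >= 1, n_cell_types >= 1,
            species_effect_sd >= 0, dropout_rate >= 0, dropout_rate <= 1,
            nb_size > 0, length(species) >= 1)
  set.seed(seed)
  S <- length(species)
  programs <- matrix(stats::rgamma(n_genes * n_cell_types, shape = 0.5),
                     n_genes, n_cell_types)
  programs <- sweep(programs, 2, colSums(programs), "/")
  species_effect <- matrix(0, n_genes, S,
                           dimnames = list(NULL, species))
  if (S > 1)
    species_effect[, -1] <- stats::rnorm(n_genes * (S - 1), 0,
                                         species_effect_sd)
  batches <- paste0("batch", seq_len(n_batches))
  batch_effect <- matrix(0, n_genes, n_batches,
                         dimnames = list(NULL, batches))
  if (n_batches > 1)
    batch_effect[, -1] <- stats::rnorm(n_genes * (n_batches - 1), 0,
                                       batch_effect_sd)
  n <- n_cells_per_species * S
  cell_species <- rep(species, each = n_cells_per_species)
  cell_type <- sample.int(n_cell_types, n, replace = TRUE)
  cell_batch <- sample(batches, n, replace = TRUE)
  depth <- pmax(1, round(stats::rlnorm(n, depth_meanlog, depth_sdlog)))
  counts <- matrix(0L, n_genes, n)
  rates <- matrix(0, n_genes, n)
  for (c_i in seq_len(n)) {
    rate <- programs[, cell_type[c_i]] *
      2^(species_effect[, match(cell_species[c_i], species)] +
         batch_effect[, match(cell_batch[c_i], batches)])
    rate <- rate / sum(rate)
    rates[, c_i] <- rate
    x <- stats::rnbinom(n_genes, mu = depth[c_i] * rate, size = nb_size)
    if (dropout_rate > 0)
      x[stats::runif(n_genes) < dropout_rate] <- 0L
    counts[, c_i] <- x
  }
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)))
  cells <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(n)),
    species = cell_species, batch = cell_batch, tissue = "tissue1",
    donor = paste0("donor", ((seq_len(n) - 1) %% 2) + 1),
    cell_type = paste0("type", cell_type))
  cse <- CrossSpeciesCounts(Matrix::Matrix(counts, sparse = TRUE),
                            genes, cells)
  list(counts = cse,
       truth = list(programs = programs, species_effect = species_effect,
                    batch_effect = batch_effect, rates = rates,
                    cell_type = cell_type, depth = depth,
                    dropout_rate = dropout_rate, nb_size = nb_size,
                    species = species, seed = seed))
}

#' Simulate an X-upregulation scenario with ground truth
#'
#' Two species: an "autosomal" reference (bird-like, both copies
#' autosomal) and an "X" species in which the X-group genes halved their
#' copy number and may have been compensated. X-group genes receive a
#' per-gene species effect of -1 + u + noise log2 units (u = injected
#' upregulation: u = 0 means no compensation, u = 1 full compensation);
#' autosomal genes get zero-mean noise; housekeeping genes get exactly
#' zero effect so they can anchor the normalization. Besides counts, the
#' generator returns the true per-cell rate profiles under both species
#' codes -- the "perfect decoder" output used to exercise the comparison
#' pipeline without a trained network.
#'
#' @param n_genes_x,n_genes_auto,n_genes_hk genes in the X group, the
#'   autosomal group and the housekeeping anchor set.
#' @param u injected upregulation (log2) on top of the -1 copy-number
#'   halving.
#' @param species_effect_sd per-gene SD (log2) around the group means.
#' @param n_cells_per_species,n_cell_types,dropout_rate,nb_size,seed
#'   passed to the base generator machinery.
#' @param x_species,auto_species species labels.
#' @return list: \code{counts}, \code{truth} (as in
#'   \code{\link{simulateMultispecies}}, plus \code{groups},
#'   \code{hk_genes} and \code{rate_profiles}: per-species genes x cells
#'   true normalized rates for a common set of cells).
#' @export
simulateXCU <- function(n_genes_x = 200, n_genes_auto = 150,
                        n_genes_hk = 50, u = 0.7,
                        species_effect_sd = 0.5,
                        n_cells_per_species = 2000, n_cell_types = 3,
                        dropout_rate = 0.1, nb_size = 2,
                        x_species = "mouse", auto_species = "chicken",
                        seed = 1) {
  set.seed(seed)
  n_genes <- n_genes_x + n_genes_auto + n_genes_hk
  groups <- rep(c("X", "autosomal", "housekeeping"),
                c(n_genes_x, n_genes_auto, n_genes_hk))
  eff <- numeric(n_genes)
  eff[groups == "X"] <- -1 + u +
    stats::rnorm(n_genes_x, 0, species_effect_sd)
  eff[groups == "autosomal"] <- stats::rnorm(n_genes_auto, 0,
                                             species_effect_sd)
  # housekeeping genes: exactly conserved
  species <- c(auto_species, x_species)
  programs <- matrix(stats::rgamma(n_genes * n_cell_types, shape = 0.5),
                     n_genes, n_cell_types)
  programs <- sweep(programs, 2, colSums(programs), "/")
  species_effect <- cbind(0, eff)
  colnames(species_effect) <- species
  n <- n_cells_per_species * 2
  cell_species <- rep(species, each = n_cells_per_species)
  cell_type <- sample.int(n_cell_types, n, replace = TRUE)
  depth <- pmax(1, round(stats::rlnorm(n, log(450), 0.6)))
  counts <- matrix(0L, n_genes, n)
  for (c_i in seq_len(n)) {
    rate <- programs[, cell_type[c_i]] *
      2^species_effect[, match(cell_species[c_i], species)]
    rate <- rate / sum(rate)
    x <- stats::rnbinom(n_genes, mu = depth[c_i] * rate, size = nb_size)
    if (dropout_rate > 0)
      x[stats::runif(n_genes) < dropout_rate] <- 0L
    counts[, c_i] <- x
  }
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  genes <- data.frame(gene_id = gene_id, group = groups)
  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                      species = cell_species, batch = "batch1",
                      tissue = "tissue1", donor = "donor1",
                      cell_type = paste0("type", cell_type))
  cse <- CrossSpeciesCounts(Matrix::Matrix(counts, sparse = TRUE),
                            genes, cells)
  # true normalized rate profiles of the x-species cells under both codes
  idx <- which(cell_species == x_species)
  prof <- function(sp) {
    m <- vapply(idx, function(c_i) {
      r <- programs[, cell_type[c_i]] * 2^species_effect[, sp]
      r / sum(r)
    }, numeric(n_genes))
    dimnames(m) <- list(gene_id, cells$cell_id[idx])
    m
  }
  rate_profiles <- list()
  rate_profiles[[auto_species]] <- prof(auto_species)
  rate_profiles[[x_species]] <- prof(x_species)
  list(counts = cse,
       truth = list(programs = programs, species_effect = species_effect,
                    groups = stats::setNames(groups, gene_id),
                    hk_genes = gene_id[groups == "housekeeping"],
                    rate_profiles = rate_profiles,
                    cell_type = cell_type, depth = depth, u = u,
                    species = species, seed = seed))
}

#' Simulate a many-to-many ortholog graph
#'
#' Independent cross-species edges with uniform percent-identity scores;
#' never same-species edges.
#'
#' @param n_genes_per_species named integer vector (names = species).
#' @param edge_density probability that each cross-species gene pair
#'   carries an edge.
#' @param seed RNG seed.
#' @return An \linkS4class{OrthologGraph}.
#' @export
simulateOrthologGraph <- function(n_genes_per_species, edge_density = 0.3,
                                  seed = 1) {
  stopifnot(!is.null(names(n_genes_per_species)),
            edge_density >= 0, edge_density <= 1)
  set.seed(seed)
  sp <- names(n_genes_per_species)
  ids <- lapply(sp, function(s)
    paste0(s, "_g", seq_len(n_genes_per_species[[s]])))
  names(ids) <- sp
  edges <- list()
  if (length(sp) >= 2) {
    for (i in seq_len(length(sp) - 1)) {
      for (j in seq(i + 1, length(sp))) {
        grid <- expand.grid(gene_a = ids[[i]], gene_b = ids[[j]],
                            stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(grid)) < edge_density
        if (!any(keep)) next
        grid <- grid[keep, , drop = FALSE]
        edges[[length(edges) + 1]] <- data.frame(
          gene_a = grid$gene_a, species_a = sp[i],
          gene_b = grid$gene_b, species_b = sp[j],
          percent_identity = stats::runif(nrow(grid), 0, 100))
      }
    }
  }
  if (!length(edges)) {
    return(OrthologGraph(data.frame(
      gene_a = character(), species_a = character(),
      gene_b = character(), species_b = character(),
      percent_identity = numeric())))
  }
  OrthologGraph(do.call(rbind, edges))
}

#' Simulate per-cell per-species read counts for demultiplexing
#'
#' Singlet barcodes draw 95--99\% of their reads from one species (the
#' rest spread uniformly over the others); doublets mix two species in a
#' 50/50 (+/- jitter) ratio. Truth labels are returned.
#'
#' @param n_cells number of barcodes.
#' @param species species names.
#' @param doublet_rate fraction of cross-species doublets.
#' @param purity_range singlet purity range (uniform).
#' @param total_meanlog,total_sdlog log-normal total read counts.
#' @param seed RNG seed.
#' @return list: \code{counts} (cells x species integer matrix with
#'   cell rownames) and \code{truth} (species label or
#'   \code{"doublet"}).
#' @export
simulateDemuxCounts <- function(n_cells = 1000,
                                species = c("mouse", "opossum", "chicken"),
                                doublet_rate = 0,
                                purity_range = c(0.95, 0.99),
                                total_meanlog = log(1000),
                                total_sdlog = 0.5, seed = 1) {
  stopifnot(doublet_rate >= 0, doublet_rate <= 1, length(species) >= 2)
  set.seed(seed)
  S <- length(species)
  counts <- matrix(0L, n_cells, S, dimnames = list(
    sprintf("bc%05d", seq_len(n_cells)), species))
  truth <- character(n_cells)
  total <- pmax(1, round(stats::rlnorm(n_cells, total_meanlog, total_sdlog)))
  is_doublet <- stats::runif(n_cells) < doublet_rate
  for (i in seq_len(n_cells)) {
    pr <- numeric(S)
    if (is_doublet[i]) {
      pair <- sample.int(S, 2)
      mix <- stats::runif(1, 0.4, 0.6)
      pr[pair] <- c(mix, 1 - mix)
      truth[i] <- "doublet"
    } else {
      main <- sample.int(S, 1)
      purity <- stats::runif(1, purity_range[1], purity_range[2])
      pr[] <- (1 - purity) / (S - 1)
      pr[main] <- purity
      truth[i] <- species[main]
    }
    counts[i, ] <- as.integer(stats::rmultinom(1, total[i], pr))
  }
  list(counts = counts, truth = stats::setNames(truth, rownames(counts)))
}
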