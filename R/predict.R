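#' Cross-species prediction by species-factor swapping
#'
#' Encodes each cell with its own factor codes (posterior mean, no
#' sampling), then decodes with the species code replaced by the target
#' species. The result is the depth-normalized, denoised expression
#' profile the model predicts for that cell in the target species.
#'
#' @param model a trained \linkS4class{CVAEModel}.
#' @param x a \linkS4class{CrossSpeciesCounts} of source cells.
#' @param target_species species label to decode into (must be in the
#'   model's dictionary).
#' @param scale multiply the per-gene rates (which sum to 1 per cell) by
#'   this constant, e.g. 10000 for a fixed library size.
#' @return genes x cells matrix of predicted expression; attributes
#'   \code{source_species} (per cell) and \code{target_species}.
#' @export
predictCrossSpecies <- function(model, x, target_species, scale = 1) {
  if (!target_species %in% model@levels$species)
    stop("unknown species: ", target_species)
  cd <- as.data.frame(colData(x))
  enc <- encodeCells(model, x)
  swap <- cd
  swap$species <- target_species
  dec <- decodeCells(model, enc$mu, swap)
  pred <- t(dec$mu_prime) * scale
  dimnames(pred) <- list(rownames(x), colnames(x))
  attr(pred, "source_species") <- as.character(cd$species)
  attr(pred, "target_species") <- target_species
  pred
}

#' Species baseline: identity transfer through orthologs
#'
#' Predicts that expression does not change between species: the target
#' profile equals the source profile with genes renamed through the
#' one-to-one ortholog map.
#'
#' @param source_profile named numeric vector (source-species gene ids).
#' @param map a \linkS4class{OneToOneMap}.
#' @param from_species,to_species species labels (hub or non-hub).
#' @return named numeric vector indexed by target-species gene ids.
#' @export
speciesBaseline <- function(source_profile, map, from_species, to_species) {
  tb <- map@table
  gene_col <- function(sp) {
    if (sp == map@hub_species) tb$hub
    else if (sp %in% colnames(tb)) tb[[sp]]
    else stop("species '", sp, "' not in the ortholog map")
  }
  from <- gene_col(from_species)
  to <- gene_col(to_species)
  ok <- !is.na(from) & !is.na(to)
  idx <- match(names(source_profile), from[ok])
  if (anyNA(idx))
    stop(sum(is.na(idx)), " gene(s) missing from the ortholog map, e.g. ",
         paste(utils::head(names(source_profile)[is.na(idx)], 3),
               collapse = ", "))
  stats::setNames(unname(source_profile), to[ok][idx])
}

#' Cell-type baseline: nearest profiled neighbor
#'
#' Finds the source-species cell type (excluding the held-out one) whose
#' pseudobulk profile is nearest in Euclidean distance to the held-out
#' type's source profile, and predicts the held-out target profile to be
#' that neighbor's target-species profile.
#'
#' @param held_out_ct name of the held-out cell type.
#' @param source_pb genes x cell-types matrix of depth-normalized,
#'   log-transformed pseudobulk profiles in the source species (must
#'   include the held-out type).
#' @param target_pb same, in the target species, for candidate types.
#' @return the chosen target profile (numeric vector) with attribute
#'   \code{chosen} naming the neighbor type.
#' @export
celltypeBaseline <- function(held_out_ct, source_pb, target_pb) {
  cand <- setdiff(colnames(source_pb), held_out_ct)
  cand <- intersect(cand, colnames(target_pb))
  if (!length(cand)) stop("no candidate cell types")
  ref <- source_pb[, held_out_ct]
  d <- vapply(cand, function(ct) sqrt(sum((source_pb[, ct] - ref)^2)),
              numeric(1))
  chosen <- cand[which.min(d)]
  structure(target_pb[, chosen], chosen = chosen)
}

#' Donor baseline: between-donor agreement on the held-out stratum
#'
#' Mean Pearson correlation of depth-normalized, log-transformed
#' pseudobulk profiles over all unordered donor pairs; an empirical upper
#' bound for any predictor, since it "cheats" by looking at the test set.
#'
#' @param donor_pb genes x donors matrix of pseudobulk profiles.
#' @return numeric(1); NA with a warning when fewer than two donors.
#' @export
donorBaseline <- function(donor_pb) {
  nd <- ncol(donor_pb)
  if (nd < 2) {
    warning("fewer than two donors: donor baseline undefined")
    return(NA_real_)
  }
  prs <- utils::combn(nd, 2)
  mean(apply(prs, 2, function(ij)
    stats::cor(donor_pb[, ij[1]], donor_pb[, ij[2]])))
}

#' Pearson correlation between predicted and observed pseudobulk
#'
#' The predicted pseudobulk is the linear average of the per-cell
#' predicted profiles; the observed pseudobulk averages depth-normalized
#' profiles of the held-out cells. Optionally also reports the mean
#' correlation against each donor's own pseudobulk
#' (\code{indiv_prediction}).
#'
#' @param pred genes x cells matrix of predicted profiles (e.g. from
#'   \code{\link{predictCrossSpecies}}), or an already-aggregated named
#'   vector.
#' @param truth a \linkS4class{CrossSpeciesCounts} of held-out cells, or
#'   an observed pseudobulk vector.
#' @param donors optional per-truth-cell donor labels for the
#'   \code{indiv_prediction} variant.
#' @param log_transform correlate log2(x + 1) profiles instead of linear
#'   ones.
#' @return list with \code{prediction} and (when donors are given)
#'   \code{indiv_prediction}.
#' @export
pearsonPseudobulk <- function(pred, truth, donors = NULL,
                              log_transform = FALSE) {
  pb_pred <- if (is.matrix(pred)) rowMeans(pred) else pred
  if (methods::is(truth, "CrossSpeciesCounts")) {
    norm <- depthNormalize(truth, target = 1)
    pb_true <- Matrix::rowSums(norm) / ncol(norm)
    donor_mat <- NULL
    if (!is.null(donors)) {
      stopifnot(length(donors) == ncol(norm))
      donor_mat <- vapply(unique(donors), function(dn) {
        sub <- norm[, donors == dn, drop = FALSE]
        Matrix::rowSums(sub) / ncol(sub)
      }, numeric(nrow(norm)))
    }
  } else {
    pb_true <- truth
    donor_mat <- NULL
  }
  tr <- if (log_transform) function(v) log2(v + 1) else identity
  chk <- function(v) if (stats::sd(v) == 0)
    stop("zero-variance profile") else v
  out <- list(prediction = stats::cor(chk(tr(pb_pred)), chk(tr(pb_true))))
  if (!is.null(donor_mat))
    out$indiv_prediction <- mean(apply(donor_mat, 2, function(v)
      stats::cor(chk(tr(pb_pred)), chk(tr(v)))))
  out
}

#' Per-gene relative prediction error
#'
#' |pred - target| / |source - target| on pseudobulk values: 0 means the
#' prediction recovered the target exactly, 1 means it did no better than
#' copying the source species. Genes whose source and target values
#' coincide (zero denominator) are returned as NA and counted in the
#' \code{n_undefined} attribute.
#'
#' @param pred_pb,truth_target_pb,truth_source_pb aligned per-gene
#'   pseudobulk vectors.
#' @return numeric vector (NA where undefined) with attribute
#'   \code{n_undefined}.
#' @export
relativePredictionError <- function(pred_pb, truth_target_pb,
                                    truth_source_pb) {
  stopifnot(length(pred_pb) == length(truth_target_pb),
            length(pred_pb) == length(truth_source_pb))
  den <- abs(truth_source_pb - truth_target_pb)
  out <- abs(pred_pb - truth_target_pb) / den
  out[den == 0] <- NA_real_
  attr(out, "n_undefined") <- sum(den == 0)
  out
}

#' Equal-sized quantile bins of a per-gene statistic
#'
#' Assigns genes to \code{n_bins} rank bins whose sizes differ by at most
#' one; ties are broken deterministically by original order.
#'
#' @param stat per-gene numeric statistic (e.g. mean pseudobulk
#'   expression, or across-cell variance).
#' @param n_bins number of bins.
#' @return integer bin index per gene (1 = lowest).
#' @export
binGenes <- function(stat, n_bins = 10) {
  n <- length(stat)
  stopifnot(n >= n_bins)
  r <- rank(stat, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

#' Summarize relative errors by expression bin and gene flag
#'
#' Convenience wrapper used for the "is prediction better for
#' housekeeping genes at matched expression?" analysis: bins genes by a
#' statistic and reports the median error per bin for flagged and
#' unflagged genes.
#'
#' @param errors per-gene errors (NA allowed).
#' @param stat per-gene binning statistic.
#' @param flag per-gene logical (e.g. is_housekeeping).
#' @param n_bins number of quantile bins.
#' @return data.frame: bin, flagged, n, median_error.
#' @export
binnedErrorSummary <- function(errors, stat, flag, n_bins = 10) {
  b <- binGenes(stat, n_bins)
  out <- expand.grid(bin = seq_len(n_bins), flagged = c(FALSE, TRUE))
  out$n <- NA_integer_
  out$median_error <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- b == out$bin[i] & flag == out$flagged[i] & !is.na(errors)
    out$n[i] <- sum(sel)
    if (out$n[i]) out$median_error[i] <- stats::median(errors[sel])
  }
  out
}
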