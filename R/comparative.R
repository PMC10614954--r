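#' Housekeeping-gene normalization
#'
#' Scales every cell's profile so that its summed expression over a
#' housekeeping gene set equals a fixed constant, making predicted
#' profiles comparable across species (housekeeping expression is
#' assumed conserved). Cells with zero housekeeping signal cannot be
#' scaled; they are dropped with a warning and listed in the
#' \code{excluded} attribute.
#'
#' @param profiles genes x cells numeric matrix (e.g. predicted rates).
#' @param hk_gene_ids character vector of housekeeping gene ids (at
#'   least one must be present among the rownames).
#' @param constant the per-cell housekeeping sum after scaling.
#' @return the rescaled matrix (possibly fewer columns).
#' @export
housekeepingNormalize <- function(profiles, hk_gene_ids, constant = 1) {
  hk <- intersect(rownames(profiles), hk_gene_ids)
  if (!length(hk)) stop("no housekeeping gene present in the gene space")
  s <- colSums(profiles[hk, , drop = FALSE])
  bad <- s <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero housekeeping signal excluded")
    profiles <- profiles[, !bad, drop = FALSE]
    s <- s[!bad]
  }
  out <- sweep(profiles, 2, constant / s, "*")
  attr(out, "excluded") <- names(bad)[bad]
  out
}

#' Per-gene median log2 fold change across cells
#'
#' For the same set of cells decoded under two species codes, computes
#' log2((a + eps) / (b + eps)) per cell and gene and returns the
#' per-gene median across cells. The small pseudocount stabilizes
#' near-zero denoised values without distorting well-expressed genes.
#'
#' @param pred_a,pred_b genes x cells matrices for species a and b; the
#'   columns must describe the same cells in the same order.
#' @param eps pseudocount on the normalized scale.
#' @return named numeric vector of per-gene median log2FC (a over b).
#' @export
perCellLog2FC <- function(pred_a, pred_b, eps = 1e-6) {
  if (!all(dim(pred_a) == dim(pred_b)))
    stop("mismatched cell sets")
  if (!is.null(colnames(pred_a)) && !is.null(colnames(pred_b)) &&
      !identical(colnames(pred_a), colnames(pred_b)))
    stop("mismatched cell sets")
  fc <- log2(pred_a + eps) - log2(pred_b + eps)
  apply(fc, 1, stats::median)
}

.isX <- function(chr) {
  chr <- toupper(sub("^CHR", "", toupper(as.character(chr))))
  !is.na(chr) & chr == "X"
}

#' Group genes by the evolutionary origin of their X linkage
#'
#' Uses per-species chromosome annotations of one-to-one orthologs:
#' \itemize{
#'   \item XAR (X-added region): X-linked in the eutherian species,
#'     autosomal in the metatherian and in the bird;
#'   \item XCR (X-conserved region): X-linked in both mammals, autosomal
#'     in the bird;
#'   \item autosomal: autosomal in all three;
#'   \item excluded: any other pattern, or missing annotation.
#' }
#'
#' @param ann data.frame with a gene id column plus one chromosome column
#'   per species.
#' @param eutherian,metatherian,bird names of the chromosome columns for
#'   the three lineages (e.g. mouse, opossum, chicken).
#' @param gene_id name of the gene id column (default: first column).
#' @return data.frame gene, group, with a reason column for exclusions.
#' @export
assignGeneGroups <- function(ann, eutherian, metatherian, bird,
                             gene_id = colnames(ann)[1]) {
  chrE <- ann[[eutherian]]; chrM <- ann[[metatherian]]; chrB <- ann[[bird]]
  xE <- .isX(chrE); xM <- .isX(chrM); xB <- .isX(chrB)
  missing_ann <- is.na(chrE) | is.na(chrM) | is.na(chrB) |
    chrE == "" | chrM == "" | chrB == ""
  group <- rep("excluded", nrow(ann))
  reason <- rep(NA_character_, nrow(ann))
  group[xE & !xM & !xB] <- "XAR"
  group[xE & xM & !xB] <- "XCR"
  group[!xE & !xM & !xB] <- "autosomal"
  group[missing_ann] <- "excluded"
  reason[missing_ann] <- "missing annotation"
  reason[group == "excluded" & !missing_ann] <- "inconsistent X pattern"
  data.frame(gene = as.character(ann[[gene_id]]), group = group,
             reason = reason, stringsAsFactors = FALSE)
}

#' One-sided one-sample Wilcoxon signed-rank test of a group's median
#'
#' Tests the median of a set of per-gene log2 fold changes against a null
#' value (e.g. H0: median <= -1, the no-upregulation expectation for
#' genes that halve in copy number). Exact null distribution when at most
#' 25 non-tied values remain after dropping exact ties with the null;
#' normal approximation with continuity correction otherwise.
#'
#' @param values numeric vector (per-gene median log2FCs of one group).
#' @param null_median the null median.
#' @param alternative \code{"greater"} (median > null) or \code{"less"}.
#' @return list: \code{p.value}, \code{statistic} (V), \code{n_used}
#'   (values after dropping ties), \code{all_tied} flag.
#' @export
testGroupShift <- function(values, null_median,
                           alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- values - null_median
  d <- d[d != 0]
  if (!length(d))
    return(list(p.value = 1, statistic = NA_real_, n_used = 0L,
                all_tied = TRUE))
  if (length(d) < 5)
    stop("fewer than 5 values differ from the null median")
  if (length(d) <= 25) {
    res <- .exact_signed_rank(d, alternative)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      d, mu = 0, alternative = alternative, exact = FALSE, correct = TRUE))
    res <- list(p.value = wt$p.value, statistic = unname(wt$statistic))
  }
  list(p.value = res$p.value, statistic = res$statistic,
       n_used = length(d), all_tied = FALSE)
}

## Exact one-sided signed-rank p-value under the sign-flip null,
## including tied magnitudes (midranks): the null distribution of W+ is
## built by convolution over doubled midranks, equivalent to enumerating
## all 2^n sign assignments.
.exact_signed_rank <- function(d, alternative) {
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ri <- round(2 * r)
  maxs <- sum(ri)
  f <- numeric(maxs + 1)
  f[1] <- 1
  for (x in ri) {
    g <- f
    g[(x + 1):(maxs + 1)] <- g[(x + 1):(maxs + 1)] + f[1:(maxs + 1 - x)]
    f <- g
  }
  f <- f / 2^length(ri)
  w2 <- round(2 * W)
  p <- if (alternative == "greater")
    sum(f[(w2 + 1):(maxs + 1)]) else sum(f[1:(w2 + 1)])
  list(p.value = min(1, p), statistic = W)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across the reported tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (monotone, each >= raw).
#' @export
adjustPvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Count GGACH motifs in a coding sequence
#'
#' GGACH is the m6A methylation consensus (H = A, C or T/U); a lower
#' frequency is associated with more stable transcripts. Occurrences are
#' counted at every position (the motif cannot overlap itself) and
#' reported per kilobase.
#'
#' @param cds a character string, \linkS4class{DNAString} or
#'   \linkS4class{RNAString} over A/C/G/T/U/N.
#' @return list: \code{count}, \code{per_kb}, \code{length}.
#' @export
countGGACH <- function(cds) {
  s <- toupper(as.character(cds))
  s <- gsub("U", "T", s)
  if (!nchar(s)) stop("empty sequence")
  n <- Biostrings::countPattern("GGACH", Biostrings::DNAString(s),
                                fixed = FALSE)
  list(count = n, per_kb = n * 1000 / nchar(s), length = nchar(s))
}

#' Compare motif-frequency shifts between gene groups
#'
#' For each ortholog, the change in GGACH frequency between two species
#' (species1 minus species2) is computed; a one-sided two-sample Wilcoxon
#' rank-sum test then asks whether the X group's changes are more
#' negative than the autosomal group's (i.e. X-linked transcripts lost
#' motifs when the genes became X-linked).
#'
#' @param freq_species1,freq_species2 aligned per-gene motif frequencies
#'   in the two species.
#' @param groups per-gene group labels (\code{"XAR"}, \code{"XCR"},
#'   \code{"autosomal"}, ...).
#' @param x_groups which X groups to test against the autosomal set.
#' @param alternative direction for the X group relative to autosomal
#'   (default \code{"less"}: X-group deltas more negative).
#' @return named numeric vector of p-values, one per tested X group.
#' @export
compareMotifShift <- function(freq_species1, freq_species2, groups,
                              x_groups = c("XAR", "XCR"),
                              alternative = "less") {
  stopifnot(length(freq_species1) == length(freq_species2),
            length(groups) == length(freq_species1))
  delta <- freq_species1 - freq_species2
  auto <- delta[groups == "autosomal"]
  if (length(auto) < 5) stop("autosomal group has fewer than 5 genes")
  out <- numeric(0)
  for (g in intersect(x_groups, unique(groups))) {
    dx <- delta[groups == g]
    if (length(dx) < 5) stop("group ", g, " has fewer than 5 genes")
    wt <- suppressWarnings(stats::wilcox.test(dx, auto,
                                              alternative = alternative))
    out[g] <- wt$p.value
  }
  out
}

#' Case/control log2 fold change on pseudobulk profiles
#'
#' Pseudobulk profiles normalized to a library size of 10,000 with a +1
#' pseudocount: log2((pb_case + 1) / (pb_control + 1)). The pseudocount
#' keeps lowly expressed genes from dominating the fold changes.
#'
#' @param case,control \linkS4class{CrossSpeciesCounts} objects (all
#'   cells pooled per arm) or already-computed pseudobulk vectors on the
#'   10,000 scale.
#' @return named numeric vector of per-gene log2FC.
#' @export
diseaseLog2FC <- function(case, control) {
  pb <- function(x) {
    if (methods::is(x, "CrossSpeciesCounts")) {
      if (!ncol(x)) stop("empty group")
      norm <- depthNormalize(x, target = 10000)
      Matrix::rowSums(norm) / ncol(norm)
    } else x
  }
  a <- pb(case); b <- pb(control)
  stopifnot(length(a) == length(b))
  log2(a + 1) - log2(b + 1)
}

#' Evaluate disease-signature transfer per cell type
#'
#' Correlates the predicted case-vs-control log2FC pattern with the
#' observed one in the target species, and compares it with the "use the
#' model organism's own fold changes" baseline.
#'
#' @param pred_case,control,case_truth genes x cell-types matrices of
#'   target-species pseudobulk profiles on the 10,000 scale: predicted
#'   case, observed control, observed case.
#' @param base_case,base_control same for the source species (the
#'   mouse-model baseline).
#' @return data.frame: cell_type, prediction_cor, baseline_cor.
#' @export
transferEval <- function(pred_case, control, case_truth,
                         base_case, base_control) {
  cts <- colnames(case_truth)
  stopifnot(!is.null(cts))
  out <- data.frame(cell_type = cts, prediction_cor = NA_real_,
                    baseline_cor = NA_real_)
  for (i in seq_along(cts)) {
    ct <- cts[i]
    obs <- diseaseLog2FC(case_truth[, ct], control[, ct])
    prd <- diseaseLog2FC(pred_case[, ct], control[, ct])
    bas <- diseaseLog2FC(base_case[, ct], base_control[, ct])
    if (stats::sd(obs) == 0 || stats::sd(prd) == 0 || stats::sd(bas) == 0)
      stop("zero-variance log2FC vector for cell type ", ct)
    out$prediction_cor[i] <- stats::cor(prd, obs)
    out$baseline_cor[i] <- stats::cor(bas, obs)
  }
  out
}
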