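#' Greedy one-to-one matching between two species
#'
#' Ranks all edges connecting species \code{species_a} and
#' \code{species_b} in decreasing order of percent identity and accepts an
#' edge if and only if neither endpoint already carries an accepted edge.
#' Ties in percent identity are broken lexicographically on the
#' (gene in \code{species_a}, gene in \code{species_b}) pair so the result
#' is deterministic.
#'
#' @param g an \linkS4class{OrthologGraph}.
#' @param species_a,species_b the two species to reconcile (must differ).
#' @return \code{data.frame} with columns \code{gene_a}, \code{gene_b},
#'   \code{percent_identity}; \code{gene_a} belongs to \code{species_a}.
#' @export
greedyOneToOne <- function(g, species_a, species_b) {
  stopifnot(species_a != species_b)
  e <- orthologEdges(g)
  sel <- (e$species_a == species_a & e$species_b == species_b) |
         (e$species_a == species_b & e$species_b == species_a)
  e <- e[sel, , drop = FALSE]
  out <- data.frame(gene_a = character(), gene_b = character(),
                    percent_identity = numeric())
  if (!nrow(e)) return(out)
  # orient every edge as species_a -> species_b
  flip <- e$species_a != species_a
  ga <- ifelse(flip, e$gene_b, e$gene_a)
  gb <- ifelse(flip, e$gene_a, e$gene_b)
  sc <- e$percent_identity
  o <- order(-sc, ga, gb)
  ga <- ga[o]; gb <- gb[o]; sc <- sc[o]
  used_a <- new.env(hash = TRUE, parent = emptyenv())
  used_b <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(length(ga))
  for (i in seq_along(ga)) {
    if (is.null(used_a[[ga[i]]]) && is.null(used_b[[gb[i]]])) {
      keep[i] <- TRUE
      used_a[[ga[i]]] <- TRUE
      used_b[[gb[i]]] <- TRUE
    }
  }
  data.frame(gene_a = ga[keep], gene_b = gb[keep],
             percent_identity = sc[keep])
}

#' Fill one-to-one rows through transitivity triangles
#'
#' Searches for triangles (A, B, C) where A is a hub gene, B and C are
#' genes of two distinct non-hub species, the hub--B edge is already
#' accepted, the pairwise one-to-one map of the non-hub pair connects B to
#' C, and no accepted edge touches C. Each such triangle contributes a new
#' hub edge A--C. Pairs are processed in \code{pair_order}; within a pair,
#' triangles fire greedily by decreasing B--C percent identity (ties
#' broken lexicographically on the B, C gene ids). The result keeps every
#' vertex at degree at most one per foreign species.
#'
#' @param accepted named list of accepted hub matchings, one entry per
#'   non-hub species, each a \code{data.frame(gene_a, gene_b,
#'   percent_identity)} with \code{gene_a} the hub gene.
#' @param pairwise_maps named list of non-hub pairwise matchings; names
#'   are \code{"s1|s2"} with \code{gene_a} from \code{s1}.
#' @param hub_species hub species label.
#' @param pair_order list of length-2 character vectors giving the order
#'   in which non-hub species pairs are scanned.
#' @return The \code{accepted} list with transitive edges appended; added
#'   rows carry attribute-free provenance via the \code{transitive}
#'   logical column.
#' @export
fillTransitive <- function(accepted, pairwise_maps, hub_species, pair_order) {
  for (sp in names(accepted)) {
    if (!nrow(accepted[[sp]])) {
      accepted[[sp]]$transitive <- logical(0)
    } else accepted[[sp]]$transitive <- FALSE
  }
  # degree bookkeeping: which non-hub genes are already matched (any species),
  # and which hub genes already have a neighbor in a given species
  taken <- new.env(hash = TRUE, parent = emptyenv())
  for (sp in names(accepted)) {
    for (gv in accepted[[sp]]$gene_b) taken[[paste0(sp, "\r", gv)]] <- TRUE
  }
  hub_has <- new.env(hash = TRUE, parent = emptyenv())
  for (sp in names(accepted)) {
    for (gh in accepted[[sp]]$gene_a) hub_has[[paste0(sp, "\r", gh)]] <- TRUE
  }
  # hub gene of an accepted edge into species sp, keyed by the sp gene
  hub_of <- new.env(hash = TRUE, parent = emptyenv())
  for (sp in names(accepted)) {
    a <- accepted[[sp]]
    for (i in seq_len(nrow(a))) hub_of[[paste0(sp, "\r", a$gene_b[i])]] <- a$gene_a[i]
  }
  for (pr in pair_order) {
    s1 <- pr[1]; s2 <- pr[2]
    key <- if (!is.null(pairwise_maps[[paste0(s1, "|", s2)]]))
      paste0(s1, "|", s2) else paste0(s2, "|", s1)
    pm <- pairwise_maps[[key]]
    if (is.null(pm) || !nrow(pm)) next
    if (key != paste0(s1, "|", s2)) {
      pm <- data.frame(gene_a = pm$gene_b, gene_b = pm$gene_a,
                       percent_identity = pm$percent_identity)
    }
    # candidate triangles in both roles: B in s1 with C in s2, and B in s2
    # with C in s1
    cand <- rbind(
      data.frame(sB = s1, gB = pm$gene_a, sC = s2, gC = pm$gene_b,
                 score = pm$percent_identity),
      data.frame(sB = s2, gB = pm$gene_b, sC = s1, gC = pm$gene_a,
                 score = pm$percent_identity))
    cand <- cand[order(-cand$score, cand$gB, cand$gC), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      gB <- cand$gB[i]; gC <- cand$gC[i]
      sB <- cand$sB[i]; sC <- cand$sC[i]
      A <- hub_of[[paste0(sB, "\r", gB)]]
      if (is.null(A)) next                                   # hub--B accepted?
      if (!is.null(taken[[paste0(sC, "\r", gC)]])) next      # C untouched?
      if (!is.null(hub_has[[paste0(sC, "\r", A)]])) next     # degree <= 1
      accepted[[sC]] <- rbind(accepted[[sC]],
        data.frame(gene_a = A, gene_b = gC,
                   percent_identity = cand$score[i], transitive = TRUE))
      taken[[paste0(sC, "\r", gC)]] <- TRUE
      hub_has[[paste0(sC, "\r", A)]] <- TRUE
      hub_of[[paste0(sC, "\r", gC)]] <- A
    }
  }
  accepted
}

#' Reconcile a many-to-many orthology graph to one-to-one rows
#'
#' Two phases. First, the hub species is greedily reconciled with each
#' other species by percent identity (\code{\link{greedyOneToOne}}).
#' Second, one-to-one matchings among the non-hub species are computed the
#' same way and used to fill in missing hub edges through transitivity
#' triangles (\code{\link{fillTransitive}}). Lineage-specific losses are
#' representable: a hub gene may map to one species and not another.
#'
#' @param g an \linkS4class{OrthologGraph}.
#' @param hub_species species whose genes index the output rows.
#' @param species_order character vector of all species to include (the
#'   hub may be included or not); determines column order and the default
#'   pair order.
#' @param pair_order optional list of non-hub species pairs scanned for
#'   transitivity, in order; defaults to all non-hub pairs in
#'   \code{species_order}.
#' @return A \linkS4class{OneToOneMap}.
#' @export
buildOneToOne <- function(g, hub_species,
                          species_order = NULL, pair_order = NULL) {
  e <- orthologEdges(g)
  if (is.null(species_order))
    species_order <- sort(unique(c(e$species_a, e$species_b)))
  others <- setdiff(species_order, hub_species)
  accepted <- lapply(others, function(sp) greedyOneToOne(g, hub_species, sp))
  names(accepted) <- others
  pairwise <- list()
  if (length(others) >= 2) {
    for (i in seq_len(length(others) - 1)) {
      for (j in seq(i + 1, length(others))) {
        pairwise[[paste0(others[i], "|", others[j])]] <-
          greedyOneToOne(g, others[i], others[j])
      }
    }
  }
  if (is.null(pair_order)) {
    pair_order <- list()
    if (length(others) >= 2) {
      for (i in seq_len(length(others) - 1))
        for (j in seq(i + 1, length(others)))
          pair_order[[length(pair_order) + 1]] <- c(others[i], others[j])
    }
  }
  accepted <- fillTransitive(accepted, pairwise, hub_species, pair_order)
  hub_genes <- sort(unique(unlist(lapply(accepted, function(a) a$gene_a))))
  tb <- data.frame(hub = hub_genes, stringsAsFactors = FALSE)
  prov <- data.frame(row.names = seq_along(hub_genes))
  for (sp in others) {
    a <- accepted[[sp]]
    idx <- match(hub_genes, a$gene_a)
    tb[[sp]] <- a$gene_b[idx]
    prov[[sp]] <- ifelse(is.na(idx), NA_character_,
                         ifelse(a$transitive[idx], "transitive", "direct"))
  }
  methods::new("OneToOneMap", hub_species = hub_species,
               table = tb, provenance = prov)
}

#' Read an orthology edge table
#'
#' @param path TSV with header columns \code{gene_a}, \code{species_a},
#'   \code{gene_b}, \code{species_b}, \code{percent_identity}.
#' @return An \linkS4class{OrthologGraph}.
#' @export
readOrthologGraph <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  OrthologGraph(utils::read.delim(path, stringsAsFactors = FALSE))
}
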