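#' Call the species of a single barcode
#'
#' Given per-species uniquely-mapped read counts for one cell, labels the
#' cell with the species holding the largest count unless the reads not
#' attributable to that species exceed \code{doublet_fraction} of the
#' total, in which case the cell is a cross-species doublet. With three
#' species this is exactly the rule "sum of the second- and third-largest
#' counts > 20\% of all counts"; the (T - M)/T form generalizes it to any
#' number of species. A zero total yields \code{"unassigned"}. Ties for
#' the largest count are broken lexicographically and flagged.
#'
#' @param counts named non-negative numeric vector, one entry per species.
#' @param doublet_fraction doublet threshold in [0, 1] (strict
#'   inequality; exactly the threshold is still a singlet).
#' @return character(1): a species name, \code{"doublet"} or
#'   \code{"unassigned"}; attribute \code{tie} is TRUE when the argmax was
#'   tied.
#' @examples
#' callSpecies(c(mouse = 90, opossum = 5, chicken = 5))   # "mouse"
#' callSpecies(c(mouse = 80, opossum = 15, chicken = 10)) # "doublet"
#' @export
callSpecies <- function(counts, doublet_fraction = 0.2) {
  stopifnot(doublet_fraction >= 0, doublet_fraction <= 1,
            !is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) return(structure("unassigned", tie = FALSE))
  m <- max(counts)
  if ((total - m) / total > doublet_fraction)
    return(structure("doublet", tie = FALSE))
  winners <- sort(names(counts)[counts == m])
  structure(winners[1], tie = length(winners) > 1)
}

#' Demultiplex a table of per-cell per-species read counts
#'
#' Applies \code{\link{callSpecies}} to every row and tabulates the
#' outcomes.
#'
#' @param counts data.frame or matrix: one row per cell, one column per
#'   species; row identity given by \code{cell_ids} or rownames.
#' @param doublet_fraction see \code{\link{callSpecies}}.
#' @param cell_ids optional character vector of unique cell identifiers.
#' @return list with \code{table} (data.frame cell_id, label, tie) and
#'   \code{summary} (named integer vector of outcome counts: one entry per
#'   species plus \code{doublet} and \code{unassigned}).
#' @export
demuxTable <- function(counts, doublet_fraction = 0.2, cell_ids = NULL) {
  m <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- rownames(m)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(m)))
  if (anyDuplicated(cell_ids)) stop("duplicate cell_id")
  if (nrow(m) == 0) {
    return(list(table = data.frame(cell_id = character(),
                                   label = character(), tie = logical()),
                summary = stats::setNames(integer(0), character(0))))
  }
  labs <- character(nrow(m))
  ties <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- callSpecies(stats::setNames(m[i, ], colnames(m)), doublet_fraction)
    labs[i] <- r
    ties[i] <- attr(r, "tie")
  }
  lv <- c(colnames(m), "doublet", "unassigned")
  summ <- table(factor(labs, levels = lv))
  list(table = data.frame(cell_id = cell_ids, label = labs, tie = ties,
                          stringsAsFactors = FALSE),
       summary = stats::setNames(as.integer(summ), lv))
}
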