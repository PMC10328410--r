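## Aggregation over sets of gene trees (e.g. bootstrap replicates): the
## per-branch, per-event-type support frequencies approximate reconciling
## against the whole tree set, alongside the single reconciliation of a
## designated best tree.

#' Reconcile a set of gene trees and aggregate event support
#'
#' Each tree (typically bootstrap replicates of one gene family) is
#' reconciled independently; events are then aggregated into support
#' frequencies: the fraction of trees whose optimal history contains at
#' least one event of a given type on a given branch.
#'
#' @param gene_trees List (or character vector) of newick strings /
#'   \code{phylo} objects sharing a leaf universe.
#' @param species_tree A \code{dated_tree}.
#' @param costs A \code{\link{cost_scheme}}.
#' @param best Index of the designated best tree (default 1).
#' @return A list of class \code{reconciliation_set}: \code{support}
#'   (data frame: event, branch, support), \code{mean_counts} (mean event
#'   counts per tree by type), \code{costs_per_tree}, \code{best}
#'   (the \code{reconciliation} of the designated tree) and \code{n_trees}.
#' @export
reconcile_many <- function(gene_trees, species_tree, costs = cost_scheme(),
                           best = 1L) {
  stopifnot(length(gene_trees) >= 1L, best >= 1L, best <= length(gene_trees))
  pg <- build_position_graph(time_slice(species_tree), costs)
  recs <- lapply(gene_trees, reconcile, species_tree = species_tree,
                 costs = costs, pg = pg)
  n <- length(recs)

  keys <- lapply(recs, function(r)
    unique(paste(r$events$event, r$events$branch, sep = "\r")))
  tab <- table(unlist(keys))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  support <- data.frame(
    event = vapply(parts, `[[`, "", 1),
    branch = vapply(parts, `[[`, "", 2),
    support = as.numeric(tab) / n,
    stringsAsFactors = FALSE
  )
  support <- support[order(support$event, support$branch), , drop = FALSE]
  rownames(support) <- NULL

  counts <- do.call(rbind, lapply(recs, `[[`, "counts"))
  structure(list(support = support,
                 mean_counts = colMeans(counts),
                 costs_per_tree = vapply(recs, `[[`, 0, "total_cost"),
                 best = recs[[best]],
                 n_trees = n),
            class = "reconciliation_set")
}

#' @export
print.reconciliation_set <- function(x, ...) {
  cat("Reconciliation set:", x$n_trees, "tree(s); mean counts:",
      paste(names(x$mean_counts), round(x$mean_counts, 2), collapse = ", "),
      "\n")
  invisible(x)
}
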