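## Dating inferred gene events.  Reconciliation localizes an event only to
## a branch of the chronogram: the event could have occurred anywhere
## between the branch's two nodes, so it is reported as a time range
## [t_young, t_old] with a midpoint summary.  Speciations coincide with
## nodes and get a degenerate range.  When nodes carry 95% CIs the working
## node date is the CI midpoint.

#' Date the events of a reconciliation
#'
#' @param rec A \code{\link{reconcile}} result.
#' @param tree The \code{dated_tree} the reconciliation was computed on.
#' @param mode \code{"branch"} (default): a duplication, transfer or loss
#'   is bounded by the dates of its branch's two nodes (leaf branches
#'   extend to the present, 0 Ga); \code{"slice"}: the branch range is
#'   intersected with the event's time slice, which localizes transfers
#'   more tightly.
#' @param gene Optional gene identifier copied into the output.
#' @return A data frame of dated events (class \code{dated_events}):
#'   \code{gene}, \code{event}, \code{branch}, \code{t_old},
#'   \code{t_young}, \code{midpoint} (all Ga), \code{leaf_branch}.
#'   Transfers are dated on their recipient branch.
#' @export
date_events <- function(rec, tree, mode = c("branch", "slice"),
                        gene = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "reconciliation"), inherits(tree, "dated_tree"))
  ev <- rec$events
  n_tip <- length(tree$phy$tip.label)
  root <- n_tip + 1L
  dates <- node_dates(tree)
  parent_of <- integer(n_tip + tree$phy$Nnode)
  parent_of[tree$phy$edge[, 2]] <- tree$phy$edge[, 1]

  if (nrow(ev)) {
    known <- ev$branch == "stem" | ev$branch %in% tree$edge_id
    if (any(!known))
      stop("event on branch absent from the tree: ",
           paste(unique(ev$branch[!known]), collapse = ", "))
  }

  t_old <- t_young <- numeric(nrow(ev))
  leaf_branch <- logical(nrow(ev))
  if (nrow(ev)) {
    sliced <- if (mode == "slice") time_slice(tree) else NULL
    for (r in seq_len(nrow(ev))) {
      nd <- ev$node[r]
      if (ev$event[r] == "speciation") {
        d <- dates[nd]
        t_old[r] <- d; t_young[r] <- d
      } else {
        t_old[r] <- if (nd == root) tree$root_age else dates[parent_of[nd]]
        t_young[r] <- dates[nd]          # 0 on leaf branches
        leaf_branch[r] <- nd <= n_tip
        if (mode == "slice") {
          top <- sliced$boundaries[ev$slice[r]]
          bot <- sliced$boundaries[ev$slice[r] + 1L]
          t_old[r] <- min(t_old[r], top)
          t_young[r] <- max(t_young[r], bot)
        }
      }
    }
  }
  out <- data.frame(gene = rep(gene, nrow(ev)), event = ev$event,
                    branch = ev$branch, t_old = t_old, t_young = t_young,
                    midpoint = (t_old + t_young) / 2,
                    leaf_branch = leaf_branch, stringsAsFactors = FALSE)
  class(out) <- c("dated_events", "data.frame")
  out
}

#' The earliest dated event
#'
#' The event with the oldest midpoint date; ties are broken by the larger
#' old bound, then by event-type priority speciation > duplication >
#' transfer > loss.
#'
#' @param events A \code{\link{date_events}} data frame (one or more genes).
#' @return The single earliest event row, or a zero-row frame if
#'   \code{events} is empty.
#' @export
earliest_event <- function(events) {
  if (!nrow(events)) return(events)
  prio <- match(events$event, c("speciation", "duplication", "transfer", "loss"))
  ord <- order(-events$midpoint, -events$t_old, prio)
  events[ord[1], , drop = FALSE]
}

#' Round half away from zero
#'
#' Fixed-precision rounding in which ties go away from zero (2.765 at two
#' decimals is 2.77), the convention used for reported dates.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Earliest-event summary table across genes
#'
#' One row per gene: the earliest event, its date (a single date for
#' speciations, a range otherwise) and the midpoint for range events,
#' printed at two decimals.
#'
#' @param events_by_gene Named list of \code{\link{date_events}} frames.
#' @return Data frame: \code{gene}, \code{event}, \code{date_or_range},
#'   \code{midpoint} (\code{NA} for node-dated speciations).
#' @export
earliest_event_table <- function(events_by_gene) {
  rows <- lapply(names(events_by_gene), function(g) {
    e <- earliest_event(events_by_gene[[g]])
    if (!nrow(e))
      return(data.frame(gene = g, event = NA_character_,
                        date_or_range = NA_character_, midpoint = NA_real_,
                        stringsAsFactors = FALSE))
    fmt <- function(v) sprintf("%.2f", round_half_up(v))
    if (e$event == "speciation")
      data.frame(gene = g, event = e$event, date_or_range = fmt(e$t_old),
                 midpoint = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(gene = g, event = e$event,
                 date_or_range = paste0(fmt(e$t_young), "–", fmt(e$t_old)),
                 midpoint = round_half_up(e$midpoint),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ## chronological order, oldest first
  key <- vapply(names(events_by_gene), function(g) {
    e <- earliest_event(events_by_gene[[g]])
    if (nrow(e)) e$midpoint else -Inf
  }, 0)
  out[order(-key, out$gene), , drop = FALSE]
}
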