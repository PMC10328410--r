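## Maximum-parsimony dated DTL reconciliation.
##
## For a gene node u placed at position p = (branch e, slice i), the DP is
##   C(u, p) = min over the event at u:
##     S: only where e ends in a speciation node at the slice bottom; the
##        children start on the two descendant branches in slice i+1
##        (both pairings), cost 0;
##     D: dup cost + both children start at p;
##     T: transfer cost + one child starts at p, the other on any other
##        branch alive in slice i;
##   with every "child starts at q0" term equal to
##     min over q of [ M(q0 -> q) + C(child, q) ]
##   where M is the single-lineage movement matrix of the position graph.
## Gene leaves pay M(p -> terminal position of their species).  The family
## may originate anywhere: the answer is min over p of C(root, p).
## Backtracking is deterministic (event priority S > D > T, then older
## slice, then smallest branch identifier) and movement paths are
## decomposed into explicit speciation-loss and transfer-loss events, a
## transfer-loss counting as one transfer plus one loss.

#' Reconcile a rooted gene tree with a dated species chronogram
#'
#' @param gene_tree A newick string or \pkg{ape} \code{phylo}; rooted and
#'   binary.  Leaf labels map to species either exactly or by the prefix
#'   before \code{"|"} (multi-copy families use \code{"species|copyN"}).
#'   \code{NULL} or \code{NA} denotes an empty family.
#' @param species_tree A \code{dated_tree}.
#' @param costs A \code{\link{cost_scheme}}.
#' @param pg Optional prebuilt \code{\link{build_position_graph}} result
#'   for \code{species_tree} under \code{costs} (reused across families).
#' @return An object of class \code{reconciliation}: \code{total_cost},
#'   \code{events} (data frame: \code{event}, \code{gene_node},
#'   \code{branch}, \code{donor}, \code{node}, \code{slice}), \code{counts}
#'   (named vector by event type), \code{leaf_map}, and the cost scheme.
#'   For transfers \code{branch} is the recipient branch and \code{donor}
#'   the donor branch.
#' @export
reconcile <- function(gene_tree, species_tree, costs = cost_scheme(),
                      pg = NULL) {
  stopifnot(inherits(species_tree, "dated_tree"))
  if (is.null(pg)) pg <- build_position_graph(time_slice(species_tree), costs)

  if (is.null(gene_tree) || (is.character(gene_tree) && is.na(gene_tree)))
    return(empty_reconciliation(costs))
  gt <- if (inherits(gene_tree, "phylo")) gene_tree
        else ape::read.tree(text = gene_tree)
  if (is.null(gt)) stop("could not parse gene tree")

  sp_of <- map_gene_leaves(gt$tip.label, species_tree$phy$tip.label)

  if (length(gt$tip.label) == 1L) {
    ## free origination on the species' terminal branch: cost 0, no events
    out <- empty_reconciliation(costs)
    out$leaf_map <- stats::setNames(species_tree$phy$tip.label[sp_of],
                                    gt$tip.label)
    return(out)
  }
  if (!ape::is.binary(gt)) stop("gene tree must be binary")

  P <- nrow(pg$pos)
  M <- pg$M
  n_gtip <- length(gt$tip.label)
  n_gnode <- n_gtip + gt$Nnode

  ## terminal position of each species leaf
  term_pos <- integer(length(species_tree$phy$tip.label))
  for (s in seq_along(term_pos))
    term_pos[s] <- which(pg$pos$node == s & pg$pos$slice == pg$n_slices)

  ## per-position speciation structure: child start positions (NA if the
  ## branch does not end in a speciation node at its slice bottom)
  spec_q <- spec_child_positions(pg)

  ## gene children (ape): exactly two per internal node
  gkids <- matrix(NA_integer_, n_gnode, 2)
  for (r in seq_len(nrow(gt$edge))) {
    p <- gt$edge[r, 1]
    if (is.na(gkids[p, 1])) gkids[p, 1] <- gt$edge[r, 2]
    else gkids[p, 2] <- gt$edge[r, 2]
  }

  C <- matrix(NA_real_, n_gnode, P)
  B <- matrix(NA_real_, n_gnode, P)
  slice_idx <- split(seq_len(P), pg$pos$slice)

  post <- postorder_nodes(gt)
  for (u in post) {
    if (u <= n_gtip) {
      C[u, ] <- M[, term_pos[sp_of[u]]]
    } else {
      u1 <- gkids[u, 1]; u2 <- gkids[u, 2]
      B1 <- B[u1, ]; B2 <- B[u2, ]
      cD <- costs$dup + B1 + B2
      ## transfers: best of each child over contemporaneous other branches
      om1 <- other_branch_min(B1, pg, slice_idx)
      om2 <- other_branch_min(B2, pg, slice_idx)
      cT <- costs$transfer + pmin(B1 + om2, B2 + om1)
      cS <- rep(Inf, P)
      has_s <- !is.na(spec_q[, 1])
      if (any(has_s)) {
        q1 <- spec_q[has_s, 1]; q2 <- spec_q[has_s, 2]
        cS[has_s] <- pmin(B1[q1] + B2[q2], B1[q2] + B2[q1])
      }
      C[u, ] <- pmin(cS, cD, cT)
    }
    B[u, ] <- colmin_plus(M, C[u, ])
  }

  groot <- n_gtip + 1L
  total <- min(C[groot, ])
  p0 <- which.min(C[groot, ])   # canonical order => deterministic

  ## ---- backtracking ----
  events <- list()
  emit <- function(rec) events[[length(events) + 1L]] <<- rec
  glab <- function(u) if (u <= n_gtip) gt$tip.label[u] else paste0("g", u)
  ## per-gene-node records for serialization: the chain of implied events
  ## on the edge into each node, and the node's own event
  pre_ev <- vector("list", n_gnode)
  node_ev <- vector("list", n_gnode)

  move_to <- function(u, start) {
    ## choose the position where u's event happens, decompose the path
    q <- which.min(M[start, ] + C[u, ])
    path <- decompose_path(pg, start, q)
    for (e in path) emit(e)
    pre_ev[[u]] <<- path
    q
  }

  bt <- function(u, p) {
    if (u <= n_gtip) {
      path <- decompose_path(pg, p, term_pos[sp_of[u]])
      for (e in path) emit(e)
      pre_ev[[u]] <<- c(pre_ev[[u]], path)
      node_ev[[u]] <<- list(event = "leaf",
                            branch = species_tree$phy$tip.label[sp_of[u]])
      return(invisible())
    }
    u1 <- gkids[u, 1]; u2 <- gkids[u, 2]
    B1 <- B[u1, ]; B2 <- B[u2, ]
    target <- C[u, p]
    tol <- 1e-9
    ## S
    if (!is.na(spec_q[p, 1])) {
      q1 <- spec_q[p, 1]; q2 <- spec_q[p, 2]
      if (B1[q1] + B2[q2] <= target + tol || B1[q2] + B2[q1] <= target + tol) {
        emit(list(event = "speciation", node = pg$pos$node[p],
                  branch = pg$pos$branch[p], slice = pg$pos$slice[p],
                  gene_node = glab(u)))
        node_ev[[u]] <<- list(event = "speciation", branch = pg$pos$branch[p])
        if (B1[q1] + B2[q2] <= B1[q2] + B2[q1] + tol) {
          s1 <- q1; s2 <- q2
        } else { s1 <- q2; s2 <- q1 }
        bt(u1, move_to(u1, s1)); bt(u2, move_to(u2, s2))
        return(invisible())
      }
    }
    ## D
    if (costs$dup + B1[p] + B2[p] <= target + tol) {
      emit(list(event = "duplication", node = pg$pos$node[p],
                branch = pg$pos$branch[p], slice = pg$pos$slice[p],
                gene_node = glab(u)))
      node_ev[[u]] <<- list(event = "duplication", branch = pg$pos$branch[p])
      bt(u1, move_to(u1, p)); bt(u2, move_to(u2, p))
      return(invisible())
    }
    ## T: scan recipients in canonical order, child 1 staying first
    idx <- slice_idx[[as.character(pg$pos$slice[p])]]
    idx <- idx[pg$pos$node[idx] != pg$pos$node[p]]
    for (q in idx) {
      stay1 <- costs$transfer + B1[p] + B2[q]
      stay2 <- costs$transfer + B2[p] + B1[q]
      if (stay1 <= target + tol || stay2 <= target + tol) {
        emit(list(event = "transfer", node = pg$pos$node[q],
                  branch = pg$pos$branch[q], donor = pg$pos$branch[p],
                  slice = pg$pos$slice[p], gene_node = glab(u)))
        moved <- if (stay1 <= stay2 + tol) u2 else u1
        node_ev[[u]] <<- list(event = "transfer", branch = pg$pos$branch[p],
                              recipient = pg$pos$branch[q], moved = moved)
        if (stay1 <= stay2 + tol) {
          bt(u1, move_to(u1, p)); bt(u2, move_to(u2, q))
        } else {
          bt(u2, move_to(u2, p)); bt(u1, move_to(u1, q))
        }
        return(invisible())
      }
    }
    stop("backtracking failed to reproduce the optimal cost (internal error)")
  }
  bt(groot, p0)

  ev <- events_to_frame(events)
  counts <- c(speciation = sum(ev$event == "speciation"),
              duplication = sum(ev$event == "duplication"),
              transfer = sum(ev$event == "transfer"),
              loss = sum(ev$event == "loss"))
  check <- costs$dup * counts[["duplication"]] +
    costs$transfer * counts[["transfer"]] + costs$loss * counts[["loss"]]
  if (abs(check - total) > 1e-6)
    stop("event list does not reproduce the optimal cost (internal error)")

  structure(list(total_cost = total, events = ev, counts = counts,
                 leaf_map = stats::setNames(
                   species_tree$phy$tip.label[sp_of], gt$tip.label),
                 costs = costs, origin = pg$pos[p0, , drop = FALSE],
                 gene_phylo = gt, node_events = node_ev,
                 edge_chains = pre_ev),
            class = "reconciliation")
}

empty_reconciliation <- function(costs) {
  structure(list(total_cost = 0,
                 events = events_to_frame(list()),
                 counts = c(speciation = 0L, duplication = 0L,
                            transfer = 0L, loss = 0L),
                 leaf_map = character(0), costs = costs, origin = NULL),
            class = "reconciliation")
}

events_to_frame <- function(events) {
  if (!length(events))
    return(data.frame(event = character(), gene_node = character(),
                      branch = character(), donor = character(),
                      node = integer(), slice = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    event = vapply(events, `[[`, "", "event"),
    gene_node = vapply(events, function(e)
      if (is.null(e$gene_node) || is.na(e$gene_node)) NA_character_
      else as.character(e$gene_node), ""),
    branch = vapply(events, `[[`, "", "branch"),
    donor = vapply(events, function(e)
      if (is.null(e$donor)) NA_character_ else e$donor, ""),
    node = vapply(events, function(e) as.integer(e$node), 0L),
    slice = vapply(events, function(e) as.integer(e$slice), 0L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("DTL reconciliation: cost", x$total_cost, "|",
      paste(names(x$counts), x$counts, collapse = ", "), "\n")
  invisible(x)
}

## min over q of M[p,q] + add[q], for every p
colmin_plus <- function(M, add) {
  apply(M + matrix(add, nrow(M), length(add), byrow = TRUE), 1, min)
}

## For each position p, min of v over positions in the same slice on a
## different branch (Inf when none, e.g. the stem).
other_branch_min <- function(v, pg, slice_idx) {
  out <- rep(Inf, length(v))
  for (idx in slice_idx) {
    if (length(idx) < 2L) next
    vals <- v[idx]
    j1 <- which.min(vals)
    m1 <- vals[j1]
    m2 <- if (length(vals) > 1L) min(vals[-j1]) else Inf
    out[idx] <- m1
    out[idx[j1]] <- m2
  }
  out
}

## child start positions under a speciation at each position's slice bottom
spec_child_positions <- function(pg) {
  P <- nrow(pg$pos)
  out <- matrix(NA_integer_, P, 2)
  x <- pg$sliced$tree
  kids <- node_children(x)
  bnd <- pg$sliced$boundaries
  for (p in seq_len(P)) {
    nd <- pg$pos$node[p]; i <- pg$pos$slice[p]
    if (i >= pg$n_slices) next
    if (length(kids[[nd]]) != 2L) next
    bot <- bnd[i + 1]
    is_stem <- pg$pos$branch[p] == "stem"
    if (!is_stem && abs(x$age[nd] - bot) > 1e-12) next
    ch <- kids[[nd]]
    q1 <- which(pg$pos$node == ch[1] & pg$pos$slice == i + 1L)
    q2 <- which(pg$pos$node == ch[2] & pg$pos$slice == i + 1L)
    if (length(q1) == 1L && length(q2) == 1L) out[p, ] <- c(q1, q2)
  }
  out
}

## postorder node sequence (children strictly before parents)
postorder_nodes <- function(phy) {
  ord <- reorder(phy, "postorder")
  c(ord$edge[, 2], length(phy$tip.label) + 1L)
}

## leaf label -> species tip index, by exact match or prefix before "|"
map_gene_leaves <- function(gene_labels, species_labels) {
  sp <- sub("\\|.*$", "", gene_labels)
  idx <- match(sp, species_labels)
  if (anyNA(idx))
    stop("gene leaf(s) with no matching species: ",
         paste(gene_labels[is.na(idx)], collapse = ", "))
  idx
}
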