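## Independent correctness oracle: exhaustive branch-and-bound enumeration
## of time-ordered atomic event histories.  Shares no machinery with the
## dynamic program: no movement matrix, no precomputed shortest paths --
## every history is explored move by move (descend, speciate, lose a
## descendant copy, jump by transfer-loss, duplicate, transfer) with the
## accumulated cost pruned against a cap.  Intended for tiny instances
## (<= 5 species leaves, <= 5 gene leaves).

#' Brute-force minimum reconciliation cost (oracle)
#'
#' @param gene_tree Newick string or \code{phylo}; rooted, <= 5 leaves.
#' @param species_tree A \code{dated_tree} with <= 5 leaves.
#' @param costs A \code{\link{cost_scheme}}.
#' @param cost_cap Histories costing more than this are not explored.
#' @return The minimum total cost, or \code{Inf} if no history with cost
#'   \code{<= cost_cap} exists (reported by \code{print} as \code{">cap"}).
#' @export
brute_force_reconcile <- function(gene_tree, species_tree,
                                  costs = cost_scheme(), cost_cap = 20) {
  stopifnot(inherits(species_tree, "dated_tree"))
  gt <- if (inherits(gene_tree, "phylo")) gene_tree
        else ape::read.tree(text = gene_tree)
  n_gtip <- length(gt$tip.label)
  n_stip <- length(species_tree$phy$tip.label)
  if (n_gtip > 5L || n_stip > 5L)
    stop("brute-force oracle is restricted to <= 5 leaves")
  sp_of <- map_gene_leaves(gt$tip.label, species_tree$phy$tip.label)
  if (n_gtip == 1L) return(0)

  sl <- time_slice(species_tree)
  k <- sl$n_slices
  bnd <- sl$boundaries
  x <- species_tree
  n_node <- length(x$phy$tip.label) + x$phy$Nnode
  root <- n_stip + 1L
  kids <- node_children(x)

  alive <- matrix(FALSE, n_node, k)
  for (i in seq_len(k)) alive[sl$alive[[i]], i] <- TRUE

  gkids <- vector("list", n_gtip + gt$Nnode)
  for (r in seq_len(nrow(gt$edge)))
    gkids[[gt$edge[r, 1]]] <- c(gkids[[gt$edge[r, 1]]], gt$edge[r, 2])

  dup <- costs$dup; tra <- costs$transfer; los <- costs$loss

  ## minimal completion cost for gene lineage u sitting at the top of
  ## slice i on branch e (e == root & i == 0 encodes the stem), or Inf if
  ## it exceeds `budget`
  bf <- function(u, e, i, budget) {
    if (budget < 0) return(Inf)
    best <- Inf
    is_leaf <- u <= n_gtip
    at_stem <- (i == 0L)
    bot <- bnd[i + 1]
    ## resolve a gene leaf at its species' terminal branch
    if (is_leaf && !at_stem && e == sp_of[u] && i == k) best <- 0
    ## descend on the same branch
    if (!at_stem && i < k && alive[e, i + 1L]) {
      v <- bf(u, e, i + 1L, min(budget, best))
      best <- min(best, v)
    }
    ## the branch ends in a speciation node at the slice bottom
    ends <- if (at_stem) TRUE
            else (length(kids[[e]]) == 2L && abs(x$age[e] - bot) <= 1e-12)
    if (ends && i < k) {
      ch <- kids[[if (at_stem) root else e]]
      for (j in 1:2) {   # speciation-loss into one child
        v <- los + bf(u, ch[j], i + 1L, min(budget, best) - los)
        best <- min(best, v)
      }
      if (!is_leaf) {    # cost-free co-speciation, both pairings
        for (sw in 0:1) {
          a <- gkids[[u]][1 + sw]; b <- gkids[[u]][2 - sw]
          v1 <- bf(a, ch[1], i + 1L, min(budget, best))
          if (is.finite(v1)) {
            v2 <- bf(b, ch[2], i + 1L, min(budget, best) - v1)
            best <- min(best, v1 + v2)
          }
        }
      }
    }
    if (!is_leaf) {
      ## duplication: both children continue here (allowed on the stem too:
      ## the family may duplicate before the root)
      a <- gkids[[u]][1]; b <- gkids[[u]][2]
      v1 <- bf(a, e, i, min(budget, best) - dup)
      if (is.finite(v1)) {
        v2 <- bf(b, e, i, min(budget, best) - dup - v1)
        best <- min(best, dup + v1 + v2)
      }
    }
    if (!at_stem) {
      others <- which(alive[, i])
      others <- others[others != e]
      ## transfer-loss jump to a contemporaneous branch
      for (f in others) {
        v <- tra + los + bf(u, f, i, min(budget, best) - tra - los)
        best <- min(best, v)
      }
      if (!is_leaf) {
        ## transfer: one child stays, the other restarts on another branch
        for (f in others) for (sw in 0:1) {
          a2 <- gkids[[u]][1 + sw]; b2 <- gkids[[u]][2 - sw]
          v1 <- bf(a2, e, i, min(budget, best) - tra)
          if (is.finite(v1)) {
            v2 <- bf(b2, f, i, min(budget, best) - tra - v1)
            best <- min(best, tra + v1 + v2)
          }
        }
      }
    }
    if (best > budget) Inf else best
  }

  groot <- n_gtip + 1L
  best <- bf(groot, root, 0L, cost_cap)   # origination above the root
  for (i in seq_len(k)) for (e in which(alive[, i])) {
    v <- bf(groot, e, i, min(cost_cap, best))
    best <- min(best, v)
  }
  best
}
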