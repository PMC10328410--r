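## Positions are (species branch, time slice) pairs for branches alive in
## the slice, plus a degenerate stem position above the root so that a
## gene divergence can coincide with the root speciation.  Single-lineage
## movement between positions is priced by a shortest-path matrix M over
## three arc types:
##   - same-branch descent across a slice boundary            cost 0
##   - descent through a speciation node into one child       cost loss
##     (a speciation-loss: the other child's copy is lost)
##   - within-slice jump to a contemporaneous branch          cost transfer+loss
##     (a transfer-loss: the donor copy is lost)
## Because only branches alive in a slice have positions, transfers can
## never involve an extinct or unsampled lineage.

#' Event cost scheme
#'
#' Parsimony costs for duplication, transfer and loss; speciation and
#' terminal leaf matching are free.  The defaults (duplication 2,
#' transfer 3, loss 1) are the conventional DTL defaults used by standard
#' parsimony reconciliation software.
#'
#' @param dup,transfer,loss Nonnegative event costs.
#' @return A list of class \code{cost_scheme}.
#' @export
cost_scheme <- function(dup = 2, transfer = 3, loss = 1) {
  stopifnot(dup >= 0, transfer >= 0, loss >= 0)
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "cost_scheme")
}

#' Build the (branch x slice) position graph
#'
#' @param sliced A \code{time_slices} object from \code{\link{time_slice}}.
#' @param costs A \code{\link{cost_scheme}}.
#' @return An object of class \code{position_graph}: positions table
#'   (\code{node}, \code{branch}, \code{slice}; slice 0 is the stem),
#'   shortest-path movement matrix \code{M}, next-hop matrix for path
#'   reconstruction, and lookup helpers.  Positions are ordered canonically
#'   (older slices first, then branch identifier), so first-minimum
#'   selections are deterministic.
#' @export
build_position_graph <- function(sliced, costs) {
  stopifnot(inherits(sliced, "time_slices"), inherits(costs, "cost_scheme"))
  x <- sliced$tree
  phy <- x$phy
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  k <- sliced$n_slices
  kids <- node_children(x)

  pos <- data.frame(node = root, branch = "stem", slice = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    nd <- sliced$alive[[i]]
    nd <- nd[order(x$edge_id[nd])]
    pos <- rbind(pos, data.frame(node = nd, branch = x$edge_id[nd],
                                 slice = i, stringsAsFactors = FALSE))
  }
  P <- nrow(pos)
  pid <- function(node, slice) which(pos$node == node & pos$slice == slice)

  A <- matrix(Inf, P, P)
  diag(A) <- 0
  arc_type <- matrix(0L, P, P)  # 1 descent, 2 speciation-loss, 3 transfer-loss
  arc_via <- matrix(NA_integer_, P, P)  # SL: the lost child node; TL: unused

  bnd <- sliced$boundaries
  ages <- x$age
  for (p in seq_len(P)) {
    nd <- pos$node[p]; i <- pos$slice[p]
    bot <- bnd[i + 1]          # bottom boundary of slice i (stem: root age)
    ## descent on the same branch into the next slice
    if (i < k && ages[nd] < bot - 1e-12 && nd != root) {
      q <- pid(nd, i + 1L)
      if (A[p, q] > 0) { A[p, q] <- 0; arc_type[p, q] <- 1L }
    }
    ## the branch ends in a speciation node at the slice bottom
    ends_here <- (nd == root && i == 0L) ||
      (nd != root && length(kids[[nd]]) == 2L && abs(ages[nd] - bot) <= 1e-12)
    if (ends_here && i < k) {
      ch <- kids[[if (nd == root) root else nd]]
      for (j in 1:2) {
        q <- pid(ch[j], i + 1L)
        if (costs$loss < A[p, q]) {
          A[p, q] <- costs$loss; arc_type[p, q] <- 2L
          arc_via[p, q] <- ch[3 - j]
        }
      }
    }
    ## within-slice transfer-loss jumps (stem slice has no contemporaries)
    if (i >= 1L) {
      others <- which(pos$slice == i & pos$node != nd)
      for (q in others) if (costs$transfer + costs$loss < A[p, q]) {
        A[p, q] <- costs$transfer + costs$loss
        arc_type[p, q] <- 3L
      }
    }
  }

  ## Floyd-Warshall with next-hop tracking (deterministic: strict improvement)
  M <- A
  nxt <- matrix(NA_integer_, P, P)
  nxt[is.finite(A)] <- col(A)[is.finite(A)]
  diag(nxt) <- seq_len(P)
  for (m in seq_len(P)) {
    cand <- outer(M[, m], M[m, ], `+`)
    imp <- cand < M - 1e-12
    if (any(imp)) {
      M[imp] <- cand[imp]
      nxt[imp] <- matrix(nxt[, m], P, P)[imp]
    }
  }

  structure(list(pos = pos, M = M, nxt = nxt, A = A,
                 arc_type = arc_type, arc_via = arc_via,
                 sliced = sliced, costs = costs,
                 n_slices = k, stem = 1L),
            class = "position_graph")
}

#' @export
print.position_graph <- function(x, ...) {
  cat("Position graph:", nrow(x$pos), "positions over", x$n_slices,
      "slice(s); costs D/T/L =", x$costs$dup, "/", x$costs$transfer, "/",
      x$costs$loss, "\n")
  invisible(x)
}

## Decompose the shortest path p -> q into its implied events.
## Returns a list of event records (speciation/loss pairs for SL hops,
## transfer/loss pairs for TL hops).
decompose_path <- function(pg, p, q) {
  ev <- list()
  if (p == q) return(ev)
  if (!is.finite(pg$M[p, q])) stop("unreachable movement requested")
  cur <- p
  while (cur != q) {
    nx <- pg$nxt[cur, q]
    ty <- pg$arc_type[cur, nx]
    if (ty == 2L) {
      node <- pg$pos$node[cur]
      lost <- pg$arc_via[cur, nx]
      ev <- c(ev, list(
        list(event = "speciation", node = node,
             branch = pg$pos$branch[cur],
             slice = pg$pos$slice[cur], gene_node = NA_integer_),
        list(event = "loss", node = lost,
             branch = pg$sliced$tree$edge_id[lost],
             slice = pg$pos$slice[nx], gene_node = NA_integer_)))
    } else if (ty == 3L) {
      ev <- c(ev, list(
        list(event = "transfer", node = pg$pos$node[nx],
             branch = pg$pos$branch[nx], donor = pg$pos$branch[cur],
             slice = pg$pos$slice[cur], gene_node = NA_integer_),
        list(event = "loss", node = pg$pos$node[cur],
             branch = pg$pos$branch[cur],
             slice = pg$pos$slice[cur], gene_node = NA_integer_)))
    }
    cur <- nx
  }
  ev
}
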