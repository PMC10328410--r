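## Dated species chronograms: parsing, validation, node ages, time slices.
## All temporal conventions live here: ages are in Ga before present,
## the present is 0 and time increases into the past.

#' Parse a dated species chronogram
#'
#' Reads a rooted, binary, ultrametric newick tree and returns a
#' \code{dated_tree}: the topology plus a node age (Ga before present) for
#' every node, with leaves at 0.  Optional 95\% confidence intervals on
#' internal node ages may be given as bracketed node comments of the form
#' \code{[&ci={low,high}]} placed directly after the closing parenthesis
#' (and any node label) of the clade, e.g. \code{"((A:1,B:1)[&ci={0.8,1.2}]:1,C:2);"}.
#' When a CI is present the working date of that node is the CI midpoint;
#' otherwise the point age is used.
#'
#' @param newick_text A newick string (single tree, trailing semicolon).
#' @param age_mode \code{"branch-lengths"} (default): node ages are computed
#'   from branch lengths, leaves anchored at 0; \code{"node-labels"}:
#'   internal node labels are read as absolute ages in Ga (leaves at 0) and
#'   branch lengths are ignored.
#' @param tol Relative ultrametricity tolerance (fraction of root age).
#'   Leaf depths differing from the maximum by more than this are rejected;
#'   smaller deviations are absorbed by re-projecting node ages to exact
#'   ultrametricity via leaf-depth averaging.
#' @return An object of class \code{dated_tree}: a list with elements
#'   \code{phy} (an \pkg{ape} \code{phylo}), \code{age}, \code{ci_low},
#'   \code{ci_high} (numeric vectors indexed by ape node number),
#'   \code{edge_id} (stable branch identifiers, see Details) and
#'   \code{root_age}.
#' @details Every branch is identified by the node below it.  Branch
#'   identifiers are deterministic and topology-derived: a leaf branch is
#'   named by its leaf label; an internal branch is named
#'   \code{"<smallest leaf in clade>.<clade size>"}, which is unique because
#'   clades containing the same leaf are nested and so differ in size.
#' @export
parse_chronogram <- function(newick_text,
                             age_mode = c("branch-lengths", "node-labels"),
                             tol = 1e-6) {
  age_mode <- match.arg(age_mode)
  stopifnot(is.character(newick_text), length(newick_text) == 1L)

  ci <- extract_ci_comments(newick_text)
  phy <- ape::read.tree(text = ci$newick)
  if (is.null(phy)) stop("could not parse newick text")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree contains polytomies; a binary tree is required")

  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L

  ci_low <- rep(NA_real_, n_node)
  ci_high <- rep(NA_real_, n_node)
  lab <- phy$node.label
  node_ages_from_labels <- rep(NA_real_, phy$Nnode)
  if (!is.null(lab)) {
    for (j in seq_along(lab)) {
      parts <- strsplit(lab[j], "##CI##", fixed = TRUE)[[1]]
      if (length(parts) >= 2L) {
        bounds <- as.numeric(strsplit(parts[2], "_", fixed = TRUE)[[1]])
        ci_low[n_tip + j] <- bounds[1]
        ci_high[n_tip + j] <- bounds[2]
      }
      if (nzchar(parts[1]) && !is.na(suppressWarnings(as.numeric(parts[1]))))
        node_ages_from_labels[j] <- as.numeric(parts[1])
      lab[j] <- parts[1]
    }
    phy$node.label <- lab
  }

  age <- numeric(n_node)
  if (age_mode == "branch-lengths") {
    if (is.null(phy$edge.length)) stop("newick has no branch lengths")
    depth <- node_depths(phy)
    leaf_depth <- depth[seq_len(n_tip)]
    root_age <- max(leaf_depth)
    if (root_age <= 0) stop("root age must be positive")
    ## offending leaf = largest deviation from the typical (median) depth
    ref <- stats::median(leaf_depth)
    off <- abs(leaf_depth - ref) / root_age
    if (any(off > tol)) {
      worst <- which.max(off)
      stop("tree is not ultrametric: leaf '", phy$tip.label[worst],
           "' has root-to-leaf depth ", format(leaf_depth[worst]),
           " where most leaves lie near ", format(ref))
    }
    ## re-project to exact ultrametricity: each node's age is the mean
    ## path length from the node to its descendant leaves
    age <- mean_leaf_distance(phy)
    age[seq_len(n_tip)] <- 0
  } else {
    if (anyNA(node_ages_from_labels))
      stop("age_mode = 'node-labels' requires a numeric label on every internal node")
    age[root:n_node] <- node_ages_from_labels
    age[seq_len(n_tip)] <- 0
  }

  bad_ci <- which(!is.na(ci_low) & (ci_low - age > 1e-9 | age - ci_high > 1e-9))
  if (length(bad_ci))
    stop("node age outside its confidence interval at node ", bad_ci[1])

  x <- structure(list(phy = phy, age = age, ci_low = ci_low,
                      ci_high = ci_high, root_age = age[root]),
                 class = "dated_tree")
  x$edge_id <- branch_ids(x)
  validate_dated_tree(x)
  x
}

## Pull [&ci={low,high}] comments out of newick text, splicing them into
## node labels as parseable "##CI##low_high" markers.
extract_ci_comments <- function(txt) {
  pat <- "\\[&ci=\\{([0-9.eE+-]+),([0-9.eE+-]+)\\}\\]"
  out <- gsub(pat, "##CI##\\1_\\2", txt)
  list(newick = out)
}

## Distance from the root to every node, in branch-length units.
node_depths <- function(phy) {
  n_tip <- length(phy$tip.label)
  depth <- numeric(n_tip + phy$Nnode)
  ord <- reorder(phy, "cladewise")   # parents before children
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    depth[c] <- depth[p] + ord$edge.length[k]
  }
  depth
}

## Mean path length from each node down to its descendant leaves.
mean_leaf_distance <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  n_leaves <- integer(n_node)
  total <- numeric(n_node)
  n_leaves[seq_len(n_tip)] <- 1L
  ord <- reorder(phy, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    n_leaves[p] <- n_leaves[p] + n_leaves[c]
    total[p] <- total[p] + total[c] + n_leaves[c] * ord$edge.length[k]
  }
  total / n_leaves
}

## Children of every node (list indexed by node), in canonical order:
## the child whose clade contains the lexicographically smaller smallest
## leaf comes first.
node_children <- function(x) {
  phy <- x$phy
  n_tip <- length(phy$tip.label)
  kids <- vector("list", n_tip + phy$Nnode)
  for (k in seq_len(nrow(phy$edge)))
    kids[[phy$edge[k, 1]]] <- c(kids[[phy$edge[k, 1]]], phy$edge[k, 2])
  ml <- min_leaf(phy)
  lapply(kids, function(v) if (is.null(v)) integer(0) else v[order(ml[v])])
}

## Lexicographically smallest leaf label within each node's clade.
min_leaf <- function(phy) {
  n_tip <- length(phy$tip.label)
  ml <- character(n_tip + phy$Nnode)
  ml[seq_len(n_tip)] <- phy$tip.label
  ord <- reorder(phy, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    ml[p] <- if (!nzchar(ml[p]) || ml[c] < ml[p]) ml[c] else ml[p]
  }
  ml
}

## Number of leaves under each node.
clade_sizes <- function(phy) {
  n_tip <- length(phy$tip.label)
  sz <- integer(n_tip + phy$Nnode)
  sz[seq_len(n_tip)] <- 1L
  ord <- reorder(phy, "postorder")
  for (k in seq_len(nrow(ord$edge)))
    sz[ord$edge[k, 1]] <- sz[ord$edge[k, 1]] + sz[ord$edge[k, 2]]
  sz
}

## Stable branch identifiers: branch = node below it.
branch_ids <- function(x) {
  phy <- x$phy
  n_tip <- length(phy$tip.label)
  ml <- min_leaf(phy)
  sz <- clade_sizes(phy)
  id <- character(n_tip + phy$Nnode)
  id[seq_len(n_tip)] <- phy$tip.label
  idx <- (n_tip + 1L):(n_tip + phy$Nnode)
  id[idx] <- paste0(ml[idx], ".", sz[idx])
  id
}

validate_dated_tree <- function(x) {
  phy <- x$phy
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  if (any(x$age[seq_len(n_tip)] != 0)) stop("leaf ages must be 0")
  if (x$age[root] <= 0) stop("root age must be positive")
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; c <- phy$edge[k, 2]
    if (x$age[p] <= x$age[c] + 1e-12 * max(1, x$root_age))
      stop("parent age must strictly exceed child age on branch '",
           x$edge_id[c], "'")
  }
  invisible(x)
}

#' Working node dates (CI midpoints where CIs are present)
#'
#' @param x A \code{dated_tree}.
#' @return Numeric vector of dates indexed by ape node number: the CI
#'   midpoint where a node carries a confidence interval, the point age
#'   otherwise.  Leaves are always 0.
#' @export
node_dates <- function(x) {
  d <- x$age
  has_ci <- !is.na(x$ci_low) & !is.na(x$ci_high)
  d[has_ci] <- (x$ci_low[has_ci] + x$ci_high[has_ci]) / 2
  d
}

#' Write a dated chronogram to newick
#'
#' Children are emitted in canonical order (smallest leaf label first), so
#' output is deterministic.  CI annotations, when present, are written in
#' the \code{[&ci={low,high}]} dialect that \code{\link{parse_chronogram}}
#' reads back.
#'
#' @param x A \code{dated_tree}.
#' @param digits Significant digits for branch lengths.
#' @return A newick string.
#' @export
write_chronogram <- function(x, digits = 10) {
  kids <- node_children(x)
  fmt <- function(v) format(v, digits = digits, trim = TRUE, scientific = FALSE)
  rec <- function(node, parent_age) {
    if (length(kids[[node]]) == 0L) {
      lab <- x$phy$tip.label[node]
      return(paste0(lab, ":", fmt(parent_age - x$age[node])))
    }
    inner <- paste(vapply(kids[[node]], rec, "", parent_age = x$age[node]),
                   collapse = ",")
    ci <- if (!is.na(x$ci_low[node]))
      paste0("[&ci={", fmt(x$ci_low[node]), ",", fmt(x$ci_high[node]), "}]") else ""
    blen <- if (is.na(parent_age)) "" else paste0(":", fmt(parent_age - x$age[node]))
    paste0("(", inner, ")", ci, blen)
  }
  n_tip <- length(x$phy$tip.label)
  paste0(rec(n_tip + 1L, NA_real_), ";")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated species chronogram:", length(x$phy$tip.label), "leaves, root age",
      format(x$root_age, digits = 6), "Ga\n")
  if (any(!is.na(x$ci_low))) cat("  CI annotations on",
                                 sum(!is.na(x$ci_low)), "node(s)\n")
  invisible(x)
}

#' Decompose a chronogram into time slices
#'
#' Boundaries are the distinct internal-node ages (ties merged into a
#' single boundary) plus the present (0), ordered from the root age down.
#' Slice \code{i} spans the open interval between boundary \code{i-1} and
#' boundary \code{i}; the branches alive in a slice are those whose
#' (child age, parent age) interval covers it.  Transfers are only
#' permitted between branches alive in the same slice.
#'
#' @param x A \code{dated_tree}.
#' @param tie_tol Absolute tolerance (fraction of root age) below which two
#'   internal node ages are merged into one boundary.
#' @return An object of class \code{time_slices}: list with
#'   \code{boundaries} (numeric, decreasing, first = root age, last = 0),
#'   \code{n_slices}, \code{alive} (list: branch node indices alive per
#'   slice), \code{branches} (data frame of branch id, node, parent/child
#'   ages) and the originating \code{tree}.
#' @export
time_slice <- function(x, tie_tol = 1e-9) {
  stopifnot(inherits(x, "dated_tree"))
  phy <- x$phy
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  internal_ages <- x$age[root:(n_tip + phy$Nnode)]
  b <- sort(unique(internal_ages), decreasing = TRUE)
  ## merge near-equal ages
  if (length(b) > 1L) {
    keep <- c(TRUE, diff(b) < -tie_tol * x$root_age)
    b <- b[keep]
  }
  boundaries <- c(b, 0)
  k <- length(b)

  parent_of <- integer(n_tip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  nodes <- setdiff(seq_len(n_tip + phy$Nnode), root)
  snap <- function(a) {  # snap an age onto the merged boundary grid
    i <- which.min(abs(boundaries - a))
    boundaries[i]
  }
  branches <- data.frame(
    node = nodes,
    branch = x$edge_id[nodes],
    parent_age = vapply(x$age[parent_of[nodes]], snap, 0),
    child_age = vapply(x$age[nodes], snap, 0),
    stringsAsFactors = FALSE
  )
  alive <- vector("list", k)
  for (i in seq_len(k)) {
    top <- boundaries[i]; bot <- boundaries[i + 1]
    sel <- branches$parent_age >= top & branches$child_age <= bot
    alive[[i]] <- branches$node[sel]
    if (!length(alive[[i]])) stop("empty time slice (corrupt ages)")
  }
  structure(list(boundaries = boundaries, n_slices = k, alive = alive,
                 branches = branches, tree = x),
            class = "time_slices")
}

#' @export
print.time_slices <- function(x, ...) {
  cat("Time-sliced chronogram:", x$n_slices, "slice(s), root age",
      format(x$boundaries[1], digits = 6), "Ga\n")
  invisible(x)
}
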