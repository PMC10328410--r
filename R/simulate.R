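## Synthetic data: dated pure-birth species chronograms and gene families
## evolved along them under duplication, transfer and loss, with a complete
## dated truth log.  Everything is deterministic given the seed.

#' Simulation configuration
#'
#' @param n_species Number of extant species (leaves), at least 2.
#' @param root_age Crown (root) age in Ga before present.  The default,
#'   4.05 Ga, is a commonly inferred age for the last universal common
#'   ancestor under an autocorrelated relaxed clock.
#' @param yule_rate Pure-birth speciation rate, per lineage per Ga.
#' @param r_dup,r_transfer,r_loss Gene duplication / horizontal transfer /
#'   loss rates, events per gene copy per Ga.
#' @param origin Where the gene family originates; currently \code{"root"}
#'   (a single ancestral copy present at the species root).
#' @param seed Integer RNG seed, or \code{NULL} to use the current RNG state.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 20, root_age = 4.05, yule_rate = 0.5,
                       r_dup = 0.05, r_transfer = 0.10, r_loss = 0.05,
                       origin = "root", seed = NULL) {
  stopifnot(n_species >= 2, root_age > 0, yule_rate > 0,
            r_dup >= 0, r_transfer >= 0, r_loss >= 0,
            identical(origin, "root"))
  structure(list(n_species = as.integer(n_species), root_age = root_age,
                 yule_rate = yule_rate, r_dup = r_dup,
                 r_transfer = r_transfer, r_loss = r_loss,
                 origin = origin, seed = seed),
            class = "sim_config")
}

#' Simulate a dated pure-birth species chronogram
#'
#' Draws a Yule tree conditioned on the number of extant leaves and on the
#' crown age.  Under this conditioning the ages of the non-root internal
#' nodes are i.i.d. truncated-exponential on (0, root_age) with density
#' \eqn{\lambda e^{-\lambda s} / (1 - e^{-\lambda T})} (s = age before
#' present), and the topology is built by splitting a uniformly chosen
#' extant lineage at each successive speciation time.  Leaf labels are
#' \code{s01, s02, ...} in a random assignment.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{dated_tree} with \code{n_species} leaves, root age
#'   exactly \code{root_age} and leaves at 0.
#' @export
simulate_species_chronogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_species
  T <- config$root_age
  lam <- config$yule_rate

  ages <- if (n > 2) sort(rtrunc_exp(n - 2, lam, T), decreasing = TRUE) else numeric(0)
  ages <- c(T, ages)                     # root first, then younger splits

  ## sequential construction: maintain the set of open lineages; each
  ## speciation (in decreasing age order) splits a uniformly chosen lineage
  n_node <- 2L * n - 1L
  parent <- integer(n_node); parent[] <- NA_integer_
  age <- numeric(n_node)
  root <- n + 1L
  next_internal <- root
  next_leaf <- 1L
  ## lineage bookkeeping: open lineages referenced by provisional slots;
  ## internal ids are allocated at split time, leaf ids at the end
  open <- list(list(p = NA_integer_))    # the root lineage
  nodes <- list()
  for (j in seq_along(ages)) {
    pick <- if (length(open) == 1L) 1L else sample.int(length(open), 1L)
    id <- next_internal; next_internal <- next_internal + 1L
    parent[id] <- open[[pick]]$p
    age[id] <- ages[j]
    open[[pick]] <- list(p = id)
    open[[length(open) + 1L]] <- list(p = id)
  }
  ## remaining open lineages become leaves; random label assignment
  labels <- sprintf("s%02d", seq_len(n))
  perm <- sample.int(n)
  for (j in seq_along(open)) {
    id <- next_leaf; next_leaf <- next_leaf + 1L
    parent[id] <- open[[j]]$p
    age[id] <- 0
  }
  tip.label <- labels[perm]

  nonroot <- setdiff(seq_len(n_node), root)
  edge <- cbind(parent[nonroot], nonroot)
  dimnames(edge) <- NULL
  phy <- list(edge = edge,
              edge.length = age[edge[, 1]] - age[edge[, 2]],
              tip.label = tip.label, Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- reorder(phy, "cladewise")

  x <- structure(list(phy = phy, age = age,
                      ci_low = rep(NA_real_, n_node),
                      ci_high = rep(NA_real_, n_node),
                      root_age = T),
                 class = "dated_tree")
  x$edge_id <- branch_ids(x)
  validate_dated_tree(x)
  x
}

## truncated exponential on (0, upper) with rate lam, by inversion
rtrunc_exp <- function(n, lam, upper) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-lam * upper))) / lam
}

#' CDF of non-root node ages in a conditioned Yule chronogram
#'
#' Closed-form truncated-exponential distribution of internal node ages
#' (excluding the root) for a pure-birth tree conditioned on its crown age.
#'
#' @param s Age(s) in Ga before present.
#' @param yule_rate Speciation rate per lineage per Ga.
#' @param root_age Crown age in Ga.
#' @return \eqn{P(\mathrm{age} \le s)}.
#' @export
yule_age_cdf <- function(s, yule_rate, root_age) {
  pmin(1, pmax(0, (1 - exp(-yule_rate * s)) / (1 - exp(-yule_rate * root_age))))
}

#' Simulate a gene family along a dated chronogram
#'
#' Forward Gillespie simulation from a single ancestral copy at the species
#' root.  Between species divergences each extant gene copy independently
#' experiences duplications, horizontal transfers and losses at the
#' configured rates; at each species divergence every copy on the parent
#' branch speciates into both descendant branches (logged as a speciation
#' per copy).  Transfer recipients are drawn uniformly among the species
#' branches alive at the moment of transfer, excluding the donor branch;
#' because the species tree has no extinct lineages, no transfer can
#' involve a dead lineage.  The observed gene tree is the genealogy of the
#' surviving copies with lost lineages pruned and single-child chains
#' suppressed.
#'
#' @param tree A \code{dated_tree} from \code{\link{parse_chronogram}} or
#'   \code{\link{simulate_species_chronogram}}.
#' @param config A \code{\link{sim_config}} (its \code{seed}, if non-NULL,
#'   is applied before simulating).
#' @return A list of class \code{gene_family}:
#'   \describe{
#'     \item{newick}{gene-tree newick string, leaves labelled
#'       \code{"species|copyN"}, or \code{NA} if the family went extinct;}
#'     \item{extinct}{flag: no surviving copy;}
#'     \item{truth}{data frame truth log: \code{event} (speciation,
#'       duplication, transfer, loss), \code{time_ga}, \code{donor_edge},
#'       \code{recipient_edge}, \code{copy_id}, \code{survived};}
#'     \item{n_leaves}{number of surviving copies;}
#'     \item{lineage_time}{total gene lineage-time (summed copy lifetimes,
#'       Ga) — the exposure against which event rates act.}
#'   }
#' @export
simulate_gene_family <- function(tree, config) {
  stopifnot(inherits(tree, "dated_tree"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  phy <- tree$phy
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  kids <- node_children(tree)
  eid <- tree$edge_id

  ## species divergence schedule, oldest first (root divergence included)
  internals <- root:(n_tip + phy$Nnode)
  div <- internals[order(-tree$age[internals])]

  total_rate <- config$r_dup + config$r_transfer + config$r_loss

  ## gene-copy genealogy as a growing table
  cap <- 256L
  g_parent <- integer(cap); g_birth <- numeric(cap); g_edge <- integer(cap)
  g_end <- numeric(cap); g_fate <- character(cap)
  n_copy <- 0L
  new_copy <- function(parent, birth, edge) {
    n_copy <<- n_copy + 1L
    if (n_copy > cap) {
      cap <<- cap * 2L
      length(g_parent) <<- cap; length(g_birth) <<- cap
      length(g_edge) <<- cap; length(g_end) <<- cap; length(g_fate) <<- cap
    }
    g_parent[n_copy] <<- parent; g_birth[n_copy] <<- birth
    g_edge[n_copy] <<- edge; g_end[n_copy] <<- NA_real_
    g_fate[n_copy] <<- ""
    n_copy
  }

  log_ev <- list(); n_log <- 0L
  push_log <- function(event, time_ga, donor, recipient, copy_id) {
    n_log <<- n_log + 1L
    log_ev[[n_log]] <<- list(event = event, time_ga = time_ga,
                             donor_edge = donor, recipient_edge = recipient,
                             copy_id = copy_id)
  }

  ## branches alive at time t (nodes below the branch)
  alive_at <- function(t) {
    nodes <- setdiff(seq_len(n_tip + phy$Nnode), root)
    parent_of <- integer(n_tip + phy$Nnode)
    parent_of[phy$edge[, 2]] <- phy$edge[, 1]
    nodes[tree$age[parent_of[nodes]] > t & tree$age[nodes] < t]
  }

  ## state: active copy ids and their branch; start = one copy "at the root"
  ## which immediately speciates at the root divergence
  t_now <- tree$root_age
  rk <- kids[[root]]
  c1 <- new_copy(0L, t_now, rk[1]); c2 <- new_copy(0L, t_now, rk[2])
  push_log("speciation", t_now, "root", NA_character_, 0L)
  active <- c(c1, c2)

  for (d in seq_len(length(div) + 1L)) {
    t_next <- if (d <= length(div)) tree$age[div[d]] else 0
    if (d == 1L) next   # root divergence already applied
    node <- if (d <= length(div)) div[d] else NA_integer_
    ## Gillespie events within (t_next, t_now)
    repeat {
      if (!length(active) || total_rate == 0) break
      dt <- stats::rexp(1, rate = length(active) * total_rate)
      if (t_now - dt <= t_next) break
      t_now <- t_now - dt
      i <- if (length(active) == 1L) 1L else sample.int(length(active), 1L)
      cp <- active[i]
      u <- stats::runif(1) * total_rate
      if (u < config$r_dup) {
        a <- new_copy(cp, t_now, g_edge[cp]); b <- new_copy(cp, t_now, g_edge[cp])
        g_end[cp] <- t_now; g_fate[cp] <- "duplication"
        push_log("duplication", t_now, eid[g_edge[cp]], NA_character_, cp)
        active <- c(active[-i], a, b)
      } else if (u < config$r_dup + config$r_transfer) {
        cand <- setdiff(alive_at(t_now), g_edge[cp])
        if (length(cand)) {
          tgt <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
          a <- new_copy(cp, t_now, g_edge[cp]); b <- new_copy(cp, t_now, tgt)
          g_end[cp] <- t_now; g_fate[cp] <- "transfer"
          push_log("transfer", t_now, eid[g_edge[cp]], eid[tgt], cp)
          active <- c(active[-i], a, b)
        }
      } else {
        g_end[cp] <- t_now; g_fate[cp] <- "loss"
        push_log("loss", t_now, eid[g_edge[cp]], NA_character_, cp)
        active <- active[-i]
      }
    }
    t_now <- t_next
    if (!length(active)) break
    if (!is.na(node) && d <= length(div)) {
      ## copies on the branch above `node` speciate into both children
      ch <- kids[[node]]
      on_branch <- active[g_edge[active] == node]
      for (cp in on_branch) {
        a <- new_copy(cp, t_now, ch[1]); b <- new_copy(cp, t_now, ch[2])
        g_end[cp] <- t_now; g_fate[cp] <- "speciation"
        push_log("speciation", t_now, eid[node], NA_character_, cp)
        active <- c(setdiff(active, cp), a, b)
      }
    }
  }

  survivors <- active
  for (cp in survivors) { g_end[cp] <- 0; g_fate[cp] <- "extant" }

  ## survived flag: does the copy have extant descendants?
  desc_survives <- logical(n_copy)
  desc_survives[survivors] <- TRUE
  for (cp in n_copy:1) if (desc_survives[cp] && g_parent[cp] > 0L)
    desc_survives[g_parent[cp]] <- TRUE

  truth <- if (n_log) {
    data.frame(
      event = vapply(log_ev[1:n_log], `[[`, "", "event"),
      time_ga = vapply(log_ev[1:n_log], `[[`, 0, "time_ga"),
      donor_edge = vapply(log_ev[1:n_log], `[[`, "", "donor_edge"),
      recipient_edge = vapply(log_ev[1:n_log], function(e)
        if (is.na(e$recipient_edge)) NA_character_ else e$recipient_edge, ""),
      copy_id = vapply(log_ev[1:n_log], `[[`, 0L, "copy_id"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(event = character(), time_ga = numeric(),
               donor_edge = character(), recipient_edge = character(),
               copy_id = integer(), stringsAsFactors = FALSE)
  }
  truth$survived <- truth$copy_id %in% which(desc_survives) | truth$copy_id == 0L

  ## total gene lineage-time: the summed lifetime of every copy (Ga)
  idx <- seq_len(n_copy)
  lineage_time <- sum(g_birth[idx] - g_end[idx])

  if (!length(survivors)) {
    return(structure(list(newick = NA_character_, extinct = TRUE,
                          truth = truth, n_leaves = 0L,
                          lineage_time = lineage_time),
                     class = "gene_family"))
  }

  ## leaf labels: species|copyN with per-species copy counter, assigned in
  ## genealogical (copy id) order for determinism
  survivors <- sort(survivors)
  sp <- phy$tip.label[g_edge[survivors]]
  counter <- ave(seq_along(sp), sp, FUN = seq_along)
  leaf_lab <- paste0(sp, "|copy", counter)

  newick <- build_gene_newick(survivors, leaf_lab, g_parent, g_birth,
                              g_end, n_copy)
  structure(list(newick = newick, extinct = FALSE, truth = truth,
                 n_leaves = length(survivors), lineage_time = lineage_time),
            class = "gene_family")
}

## Genealogy of surviving copies, pruned and with unary chains suppressed.
build_gene_newick <- function(survivors, leaf_lab, g_parent, g_birth,
                              g_end, n_copy) {
  keep <- logical(n_copy)
  keep[survivors] <- TRUE
  for (cp in n_copy:1) if (keep[cp] && g_parent[cp] > 0L) keep[g_parent[cp]] <- TRUE
  kids <- vector("list", n_copy)
  for (cp in which(keep)) if (g_parent[cp] > 0L)
    kids[[g_parent[cp]]] <- c(kids[[g_parent[cp]]], cp)
  lab <- character(n_copy)
  lab[survivors] <- leaf_lab
  roots <- which(keep & g_parent[1:n_copy] == 0L)
  ## the two root-speciation children share the virtual parent 0; if only
  ## one survives it is the root of the observed tree
  rec <- function(cp, top_time) {
    ks <- kids[[cp]]
    ks <- ks[keep[ks]]
    if (length(ks) == 0L)
      return(paste0(lab[cp], ":", format(top_time - g_end[cp], digits = 10)))
    if (length(ks) == 1L)           # pass-through: suppress unary node
      return(rec(ks[1], top_time))
    paste0("(", paste(vapply(ks, rec, "", top_time = g_end[cp]), collapse = ","),
           "):", format(top_time - g_end[cp], digits = 10))
  }
  if (length(survivors) == 1L)
    return(paste0("(", leaf_lab[1], ":", format(g_birth[survivors[1]]), ");"))
  if (length(roots) == 2L) {
    t0 <- g_birth[roots[1]]
    s <- paste0("(", rec(roots[1], t0), ",", rec(roots[2], t0), ");")
  } else {
    s <- paste0(sub(":[^:]*$", "", rec(roots[1], g_birth[roots[1]])), ";")
  }
  s
}

#' Write a truth log to TSV
#'
#' @param family A \code{gene_family}.
#' @param path Output file.
#' @export
write_truth_log <- function(family, path) {
  utils::write.table(family$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
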