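## Shared fixtures, all generated in code.

## 3-leaf caterpillar: ((A,B),C), node ages 1 and 2
caterpillar3 <- function() parse_chronogram("((A:1,B:1):1,C:2);")

## 4-leaf balanced chronogram whose branch endpoints reproduce the
## printed worked examples: AB branch spans 2.65-2.88, leaf branches
## under CD span 0-2.38
balanced4 <- function()
  parse_chronogram("((A:2.65,B:2.65):0.23,(C:2.38,D:2.38):0.5);")

## 4-leaf ladder: a family with leaves C and D is forced through the root
## and sheds the (A,B) clade by a loss on the branch spanning 2.65-2.88
ladder4 <- function()
  parse_chronogram("(((A:2.65,B:2.65):0.23,C:2.88):0.5,D:3.38);")

## a small random reconciliation instance (species tree + gene family)
random_instance <- function(seed, n_species = NULL,
                            r_dup = 0.15, r_transfer = 0.3, r_loss = 0.2,
                            root_age = 3) {
  set.seed(seed)
  n <- if (is.null(n_species)) sample(3:5, 1) else n_species
  cfg <- sim_config(n_species = n, root_age = root_age, r_dup = r_dup,
                    r_transfer = r_transfer, r_loss = r_loss, seed = seed)
  sp <- simulate_species_chronogram(cfg)
  fam <- simulate_gene_family(sp, cfg)
  list(species = sp, family = fam, config = cfg)
}

## price a truth log under a cost scheme (speciations are free)
truth_log_cost <- function(truth, costs = cost_scheme()) {
  costs$dup * sum(truth$event == "duplication") +
    costs$transfer * sum(truth$event == "transfer") +
    costs$loss * sum(truth$event == "loss")
}

## a reproducible batch of simulated families on one 20-species tree,
## reconciled; used by several property suites
simulated_study <- local({
  cache <- new.env(parent = emptyenv())
  function(n_families = 40, seed = 404) {
    key <- paste0("s", n_families, "_", seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sp <- simulate_species_chronogram(sim_config(n_species = 20, seed = seed))
    pg <- build_position_graph(time_slice(sp), cost_scheme())
    fams <- list(); recs <- list()
    j <- 0L; k <- 0L
    while (k < n_families) {
      j <- j + 1L
      fam <- simulate_gene_family(sp, sim_config(n_species = 20,
                                                 seed = seed * 1000L + j))
      if (fam$extinct) next
      k <- k + 1L
      fams[[k]] <- fam
      recs[[k]] <- reconcile(fam$newick, sp, pg = pg)
    }
    cache[[key]] <- list(species = sp, pg = pg, families = fams, recs = recs)
    cache[[key]]
  }
})
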