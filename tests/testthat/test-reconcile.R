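test_that("congruent gene trees reconcile at zero cost with n-1 speciations", {
  sp <- parse_chronogram("(((A:1,B:1):1,C:2):1,D:3);")
  rec <- reconcile("(((A:1,B:1):1,C:2):1,D:3);", sp)
  expect_equal(rec$total_cost, 0)
  expect_equal(rec$counts[["speciation"]], 3)
  expect_equal(rec$counts[["duplication"]], 0)
  expect_equal(rec$counts[["transfer"]], 0)
  expect_equal(rec$counts[["loss"]], 0)
})

test_that("a missing-leaf family is explained by speciation plus loss", {
  sp <- caterpillar3()
  rec <- reconcile("(A:2,C:2);", sp, cost_scheme(2, 3, 1))
  expect_equal(rec$total_cost, 1)
  expect_equal(rec$counts[["loss"]], 1)
  expect_equal(rec$counts[["transfer"]], 0)
  ## the loss falls inside the (A,B) clade
  expect_true(rec$events$branch[rec$events$event == "loss"] %in% c("A", "B"))

  ## expensive losses flip the optimum to a single transfer
  rec2 <- reconcile("(A:2,C:2);", sp, cost_scheme(2, 3, 10))
  expect_equal(rec2$total_cost, 3)
  expect_equal(rec2$counts[["transfer"]], 1)
  expect_equal(rec2$counts[["loss"]], 0)
})

test_that("single-leaf and empty families are free", {
  sp <- caterpillar3()
  rec <- reconcile("(A|copy1:1);", sp)
  expect_equal(rec$total_cost, 0)
  expect_equal(sum(rec$counts), 0)
  expect_equal(unname(rec$leaf_map), "A")

  rec0 <- reconcile(NA_character_, sp)
  expect_equal(rec0$total_cost, 0)
  expect_equal(nrow(rec0$events), 0)
})

test_that("unmappable gene leaves are rejected", {
  expect_error(reconcile("(A:1,Z:1);", caterpillar3()), "no matching species")
})

test_that("the event list always re-prices to the optimal cost", {
  ## cost = dup*D + transfer*T + loss*L across random instances and schemes
  for (seed in 1:15) {
    inst <- random_instance(seed + 300, n_species = 6)
    if (inst$family$extinct) next
    for (costs in list(cost_scheme(), cost_scheme(1, 1, 1),
                       cost_scheme(5, 2, 0.5))) {
      rec <- reconcile(inst$family$newick, inst$species, costs)
      expect_equal(costs$dup * rec$counts[["duplication"]] +
                     costs$transfer * rec$counts[["transfer"]] +
                     costs$loss * rec$counts[["loss"]],
                   rec$total_cost)
    }
  }
})

test_that("reconciliation is deterministic", {
  inst <- random_instance(77, n_species = 8)
  r1 <- reconcile(inst$family$newick, inst$species)
  r2 <- reconcile(inst$family$newick, inst$species)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$total_cost, r2$total_cost)
})

test_that("optimal cost is monotone in each event cost", {
  inst <- random_instance(41, n_species = 6, r_transfer = 0.5)
  grid <- c(0.5, 1, 2, 4)
  base <- c(dup = 2, transfer = 3, loss = 1)
  for (which_cost in names(base)) {
    prev <- -Inf
    for (v in grid) {
      cs <- as.list(base); cs[[which_cost]] <- v
      cost <- reconcile(inst$family$newick, inst$species,
                        cost_scheme(cs$dup, cs$transfer, cs$loss))$total_cost
      expect_gte(cost + 1e-9, prev)
      prev <- cost
    }
  }
})

test_that("parsimony cost never exceeds the priced true history", {
  st <- simulated_study(40)
  for (k in seq_along(st$families)) {
    expect_lte(st$recs[[k]]$total_cost,
               truth_log_cost(st$families[[k]]$truth) + 1e-9)
  }
})

test_that("every transfer connects branches alive in its slice", {
  st <- simulated_study(40)
  sl <- time_slice(st$species)
  branch_of <- setNames(sl$branches$node, sl$branches$branch)
  for (rec in st$recs) {
    tv <- rec$events[rec$events$event == "transfer", ]
    if (!nrow(tv)) next
    for (r in seq_len(nrow(tv))) {
      i <- tv$slice[r]
      expect_true(branch_of[[tv$branch[r]]] %in% sl$alive[[i]])
      expect_true(branch_of[[tv$donor[r]]] %in% sl$alive[[i]])
      expect_false(tv$branch[r] == tv$donor[r])
    }
  }
})

test_that("DP cost equals the brute-force enumerator on tiny instances", {
  checked <- 0
  seed <- 0
  while (checked < 30) {
    seed <- seed + 1
    inst <- random_instance(seed + 9000)
    if (inst$family$extinct || inst$family$n_leaves > 5) next
    checked <- checked + 1
    dp <- reconcile(inst$family$newick, inst$species)$total_cost
    bf <- brute_force_reconcile(inst$family$newick, inst$species,
                                cost_cap = dp + 3)
    expect_equal(dp, bf)
  }
})

test_that("brute force reports >cap as Inf and solves forced examples", {
  sp <- caterpillar3()
  expect_equal(brute_force_reconcile("((A:1,B:1):1,C:2);", sp), 0)
  expect_equal(brute_force_reconcile("(A:2,C:2);", sp), 1)
  expect_identical(brute_force_reconcile("(A:2,C:2);", sp, cost_cap = 0.5),
                   Inf)
})

test_that("identical gene trees aggregate to unit support", {
  sp <- caterpillar3()
  trees <- rep("((A|copy1:1,B|copy1:1):1,C|copy1:2);", 10)
  agg <- reconcile_many(trees, sp)
  expect_true(all(agg$support$support == 1))
  expect_equal(unname(agg$mean_counts[["speciation"]]), 2)
  expect_equal(agg$n_trees, 10)
})

test_that("a one-tree disagreement yields supports of 0.5 or 1 only", {
  sp <- parse_chronogram("(((A:1,B:1):1,C:2):1,D:3);")
  t1 <- "(((A:1,B:1):1,C:2):1,D:3);"
  t2 <- "(((A:1,C:1):1,B:2):1,D:3);"   # B and C swapped
  agg <- reconcile_many(list(t1, t2), sp)
  expect_true(all(agg$support$support %in% c(0.5, 1)))
})

test_that("bootstrap aggregation tracks the single-tree transfer count", {
  st <- simulated_study(40)
  ## families as replicate topologies of one "gene": mean transfer count
  ## from aggregation equals the mean of single-tree counts by definition;
  ## check the designated best tree round-trips unchanged
  trees <- lapply(st$families[1:10], `[[`, "newick")
  agg <- reconcile_many(trees, st$species, best = 3)
  single <- vapply(trees, function(tt)
    reconcile(tt, st$species)$counts[["transfer"]], 0)
  expect_equal(unname(agg$mean_counts[["transfer"]]), mean(single))
  expect_equal(agg$best$total_cost, st$recs[[3]]$total_cost)
})
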