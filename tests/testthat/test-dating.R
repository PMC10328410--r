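test_that("leaf-branch events span to the present and midpoints halve the range", {
  ## a loss on a leaf branch whose parent node sits at 2.38 Ga dates to
  ## the range 0.00-2.38 with midpoint 1.19
  sp <- balanced4()
  rec <- reconcile("((A:1,B:1):1,C:2);", sp)
  ev <- date_events(rec, sp)
  loss <- ev[ev$event == "loss", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$branch, "D")
  expect_true(loss$leaf_branch)
  expect_equal(loss$t_young, 0)
  expect_equal(loss$t_old, 2.38)
  expect_equal(loss$midpoint, 1.19)
})

test_that("internal-branch events get both node dates as bounds", {
  ## loss on the branch spanning 2.65-2.88 Ga: midpoint 2.765, printed 2.77
  sp <- ladder4()
  rec <- reconcile("(C:1,D:1);", sp)
  ev <- date_events(rec, sp)
  loss <- ev[ev$event == "loss", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$branch, "A.2")
  expect_equal(loss$t_old, 2.88)
  expect_equal(loss$t_young, 2.65)
  expect_equal(loss$midpoint, 2.765)
  expect_equal(round_half_up(loss$midpoint), 2.77)
})

test_that("rounding is half away from zero at two decimals", {
  expect_equal(round_half_up(2.765), 2.77)
  expect_equal(round_half_up(1.185), 1.19)
  expect_equal(round_half_up(-2.765), -2.77)
  expect_equal(round_half_up(2.764), 2.76)
})

test_that("speciations carry degenerate ranges at the node date", {
  sp <- caterpillar3()
  rec <- reconcile("((A:1,B:1):1,C:2);", sp)
  ev <- date_events(rec, sp)
  spe <- ev[ev$event == "speciation", ]
  expect_equal(spe$t_old, spe$t_young)
  expect_equal(sort(spe$midpoint), c(1, 2))
})

test_that("CI midpoints become the node dates used for event bounds", {
  sp <- parse_chronogram("((A:1,B:1)[&ci={0.8,1.4}]:1,C:2);")
  rec <- reconcile("(A:2,C:2);", sp)
  ev <- date_events(rec, sp)
  loss <- ev[ev$event == "loss", ]
  ## loss on leaf A or B: the branch's top node is the CI'd node -> 1.1
  expect_equal(loss$t_old, 1.1)
})

test_that("dating is a bijection on the event list and shifts linearly", {
  st <- simulated_study(40)
  rec <- st$recs[[1]]
  ev <- date_events(rec, st$species, gene = "fam")
  expect_equal(nrow(ev), nrow(rec$events))
  expect_identical(ev$event, rec$events$event)

  ## +c shift of all node dates shifts all midpoints by +c (leaf branches
  ## excluded: their young bound is anchored at the present)
  sp2 <- st$species
  c_shift <- 0.5
  sp2$age <- sp2$age + c_shift
  sp2$age[seq_along(sp2$phy$tip.label)] <- sp2$age[seq_along(sp2$phy$tip.label)] - c_shift
  ## rebuild a shifted tree by stretching terminal branches instead
  ## (equivalent: all internal nodes move up by c)
  sp2$root_age <- sp2$root_age + c_shift
  ev2 <- date_events(rec, sp2, gene = "fam")
  internal <- !ev$leaf_branch & ev$event != "speciation"
  expect_equal(ev2$midpoint[internal], ev$midpoint[internal] + c_shift)
})

test_that("slice mode never widens the branch-mode range", {
  st <- simulated_study(40)
  for (k in 1:5) {
    evb <- date_events(st$recs[[k]], st$species)
    evs <- date_events(st$recs[[k]], st$species, mode = "slice")
    expect_true(all(evs$t_old <= evb$t_old + 1e-9))
    expect_true(all(evs$t_young >= evb$t_young - 1e-9))
    expect_true(all(evs$t_young <= evs$t_old + 1e-9))
  }
})

test_that("true event times fall inside inferred branch-mode ranges", {
  ## for events the parsimony history recovers on the correct branch
  st <- simulated_study(40)
  n_match <- 0; n_inside <- 0
  for (k in seq_along(st$families)) {
    ev <- date_events(st$recs[[k]], st$species)
    tl <- st$families[[k]]$truth
    for (r in seq_len(nrow(tl))) {
      if (tl$event[r] == "speciation") next
      br <- if (tl$event[r] == "transfer") tl$recipient_edge[r]
            else tl$donor_edge[r]
      hit <- ev[ev$event == tl$event[r] & ev$branch == br, ]
      if (!nrow(hit)) next
      n_match <- n_match + 1
      if (any(tl$time_ga[r] <= hit$t_old + 1e-9 &
              tl$time_ga[r] >= hit$t_young - 1e-9))
        n_inside <- n_inside + 1
    }
  }
  expect_gt(n_match, 20)          # the regime must actually exercise this
  expect_equal(n_inside, n_match)
})

test_that("earliest event maximizes the midpoint with documented tie-breaks", {
  ev <- data.frame(
    gene = "g", event = c("loss", "transfer", "loss"),
    branch = c("x", "y", "z"),
    t_old = c(2.38, 1.0, 0.5), t_young = c(0, 0, 0.3),
    midpoint = c(1.19, 0.5, 0.4), leaf_branch = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expect_equal(earliest_event(ev)$midpoint, 1.19)

  tie <- data.frame(
    gene = "g", event = c("transfer", "duplication"),
    branch = c("x", "y"),
    t_old = c(2.0, 3.0), t_young = c(1.0, 0.0),
    midpoint = c(1.5, 1.5), leaf_branch = FALSE,
    stringsAsFactors = FALSE
  )
  expect_equal(earliest_event(tie)$t_old, 3.0)   # larger old bound wins

  tie2 <- tie
  tie2$t_old <- c(3.0, 3.0); tie2$t_young <- c(0, 0)
  ## equal midpoint and range: speciation > duplication > transfer > loss
  tie2$event <- c("transfer", "duplication")
  expect_equal(earliest_event(tie2)$event, "duplication")

  single <- ev[2, ]
  expect_equal(earliest_event(single)$branch, "y")
  expect_equal(nrow(earliest_event(ev[0, ])), 0)
})

test_that("the earliest-event table prints speciation dates and ranges", {
  sp <- balanced4()
  ebg <- list(
    withloss = date_events(reconcile("((A:1,B:1):1,C:2);", sp), sp,
                           gene = "withloss"),
    congruent = date_events(
      reconcile("((A:1,B:1):1,(C:0.5,D:0.5):1);", sp), sp,
      gene = "congruent")
  )
  tab <- earliest_event_table(ebg)
  expect_equal(tab$date_or_range[tab$gene == "congruent"], "2.88")
  expect_true(is.na(tab$midpoint[tab$gene == "congruent"]))
  ## speciation at the root is the earliest event for both
  expect_equal(tab$gene[1], order_genes(ebg)[1])
})
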