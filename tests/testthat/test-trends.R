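## build a dated-events frame directly from per-type counts or midpoints
fake_events <- function(gene, loss = 0, duplication = 0, transfer = 0,
                        speciation = 0, midpoints = NULL) {
  ev <- rep(c("loss", "duplication", "transfer", "speciation"),
            c(loss, duplication, transfer, speciation))
  m <- if (is.null(midpoints)) seq_along(ev) / max(1, length(ev)) else midpoints
  if (!length(ev)) m <- numeric(0)
  data.frame(gene = rep(gene, length(ev)), event = ev,
             branch = rep("b", length(ev)),
             t_old = m * 2, t_young = rep(0, length(ev)), midpoint = m,
             leaf_branch = rep(FALSE, length(ev)), stringsAsFactors = FALSE)
}

test_that("per-gene totals are the sum of the four event types", {
  ebg <- list(
    soxC = fake_events("soxC", loss = 17, duplication = 4, transfer = 84,
                       speciation = 32),
    dmdA = fake_events("dmdA", loss = 0, duplication = 1, transfer = 22,
                       speciation = 1),
    empty = fake_events("empty")
  )
  tab <- summarize_counts(ebg)
  expect_equal(tab$total[tab$gene == "soxC"], 137)
  expect_equal(tab$total[tab$gene == "dmdA"], 24)
  expect_equal(unlist(tab[tab$gene == "empty", -1], use.names = FALSE),
               rep(0L, 5))
  expect_equal(tab$total, tab$loss + tab$duplication + tab$transfer +
                 tab$speciation)
})

test_that("binned midpoints follow half-open bins with a closed oldest bin", {
  one <- list(g = fake_events("g", loss = 1, midpoints = 0.7))
  tt <- bin_midpoints(one, bin_width = 0.5)
  loss_row <- tt$proportions[tt$proportions$event == "loss", -(1:2)]
  expect_equal(sum(loss_row == 1), 1)
  expect_equal(sum(loss_row), 1)

  two <- list(g = fake_events("g", loss = 2, midpoints = c(0.1, 0.3)))
  tt2 <- bin_midpoints(two, bin_width = 0.25)
  pr <- unlist(tt2$proportions[tt2$proportions$event == "loss", -(1:2)])
  expect_equal(sort(unname(pr[pr > 0])), c(0.5, 0.5))
  ## 0.1 and 0.3 land in different bins
  expect_equal(sum(pr > 0), 2)

  ## boundary midpoint goes into the upper (older-closed) scheme's own bin
  edge <- list(g = fake_events("g", loss = 2, midpoints = c(0.25, 0.2499)))
  pr3 <- bin_midpoints(edge, bin_width = 0.25)$counts
  pr3 <- unlist(pr3[pr3$event == "loss", -(1:2)])
  expect_equal(unname(pr3[1:2]), c(1, 1))
})

test_that("bin counts conserve each gene's events and match a direct recount", {
  st <- simulated_study(40)
  ebg <- lapply(seq_along(st$recs), function(k)
    date_events(st$recs[[k]], st$species, gene = paste0("fam", k)))
  names(ebg) <- paste0("fam", seq_along(ebg))
  w <- 0.25
  tt <- bin_midpoints(ebg, bin_width = w)
  for (g in names(ebg)) {
    rows <- tt$counts[tt$counts$gene == g, ]
    expect_equal(sum(rows[, -(1:2)]), nrow(ebg[[g]]))
    ## independent recount: histogram each type with the same bin rule
    for (ty in c("loss", "duplication", "transfer", "speciation")) {
      m <- ebg[[g]]$midpoint[ebg[[g]]$event == ty]
      direct <- table(factor(pmin(floor(m / w + 1e-12) + 1,
                                  nrow(tt$bins)),
                             levels = seq_len(nrow(tt$bins))))
      expect_equal(unname(unlist(rows[rows$event == ty, -(1:2)])),
                   as.integer(direct))
    }
    if (nrow(ebg[[g]]) > 0) {
      prows <- tt$proportions[tt$proportions$gene == g, ]
      expect_equal(sum(prows[, -(1:2)]), 1)
    }
  }
})

test_that("genes order chronologically by earliest midpoint, ties alphabetical", {
  expect_equal(order_genes(c(g1 = 3.3, g2 = 1.19)), c("g1", "g2"))
  expect_equal(order_genes(c(b = 1, a = 1, c = 2)), c("c", "a", "b"))

  ## the printed earliest-event midpoints: sulfite/sulfide-handling genes
  ## first, organic sulfur genes last
  mids <- c(dsrA = 3.35, dsrB = 3.3, soxC = 2.77, soxA = 2.6, soxB = 2.6,
            soxX = 2.6, soxY = 2.6, soxZ = 2.6, aprA = 2.47, aprB = 2.33,
            dmsA = 2.28, mddA = 1.77, dmdA = 1.19)
  ord <- order_genes(sample(mids))
  expect_equal(ord[1], "dsrA")
  expect_equal(ord[12:13], c("mddA", "dmdA"))
  expect_equal(ord[4:8], c("soxA", "soxB", "soxX", "soxY", "soxZ"))
})

test_that("gene ordering is a permutation of the input genes", {
  st <- simulated_study(40)
  ebg <- lapply(seq_along(st$recs)[1:10], function(k)
    date_events(st$recs[[k]], st$species, gene = paste0("fam", k)))
  names(ebg) <- paste0("fam", 1:10)
  ord <- order_genes(ebg)
  expect_setequal(ord, names(ebg))
  expect_equal(length(ord), length(unique(ord)))
})

test_that("the timeline plot runs headlessly and orders genes", {
  ebg <- list(
    young = fake_events("young", transfer = 3, midpoints = c(0.2, 0.4, 0.6)),
    old = fake_events("old", speciation = 2, midpoints = c(3.0, 2.0))
  )
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  ord <- plot_event_timeline(ebg)
  expect_equal(ord, c("old", "young"))
})
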