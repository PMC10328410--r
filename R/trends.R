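## Temporal trend summaries: per-gene event-count tables, binned midpoint
## histograms, and chronological ordering of genes by their earliest event.

#' Per-gene event-count summary
#'
#' Counts of loss, duplication, transfer (HGT) and speciation events per
#' gene, with the total defined as the sum of the four types.
#'
#' @param events_by_gene Named list of \code{\link{date_events}} frames.
#' @return Data frame: \code{gene}, \code{loss}, \code{duplication},
#'   \code{transfer}, \code{speciation}, \code{total}.
#' @export
summarize_counts <- function(events_by_gene) {
  types <- c("loss", "duplication", "transfer", "speciation")
  rows <- lapply(names(events_by_gene), function(g) {
    e <- events_by_gene[[g]]
    n <- vapply(types, function(ty) sum(e$event == ty), 0L)
    data.frame(gene = g, loss = n[["loss"]], duplication = n[["duplication"]],
               transfer = n[["transfer"]], speciation = n[["speciation"]],
               total = sum(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin event midpoints into time-bin histograms
#'
#' Half-open bins \code{[lower, upper)} ascend from the present (0 Ga);
#' the oldest bin is closed so the maximum midpoint is retained.
#' Proportions are relative to the gene's total event count (all types),
#' so each gene's proportions sum to 1 across bins and types.
#'
#' @param events_by_gene Named list of \code{\link{date_events}} frames.
#' @param bin_width Bin width in Ga (default 0.25).
#' @param max_age Upper limit for the oldest bin; defaults to the smallest
#'   multiple of \code{bin_width} covering every midpoint.
#' @return A list of class \code{trend_table}: \code{bins} (data frame of
#'   \code{lower}, \code{upper}), \code{counts} and \code{proportions}
#'   (data frames: gene, event, one column per bin), \code{bin_width}.
#' @export
bin_midpoints <- function(events_by_gene, bin_width = 0.25, max_age = NULL) {
  stopifnot(bin_width > 0)
  all_mid <- unlist(lapply(events_by_gene, function(e) e$midpoint))
  if (is.null(max_age))
    max_age <- bin_width * max(1, ceiling(max(c(all_mid, 0)) / bin_width + 1e-12))
  lower <- seq(0, max_age - bin_width, by = bin_width)
  upper <- lower + bin_width
  nb <- length(lower)
  bin_of <- function(m) pmin(nb, floor(m / bin_width + 1e-12) + 1L)

  types <- c("loss", "duplication", "transfer", "speciation")
  counts <- list(); props <- list()
  for (g in names(events_by_gene)) {
    e <- events_by_gene[[g]]
    tot <- nrow(e)
    for (ty in types) {
      m <- e$midpoint[e$event == ty]
      cnt <- tabulate(bin_of(m), nbins = nb)
      counts[[paste(g, ty)]] <- data.frame(gene = g, event = ty,
                                           t(cnt), stringsAsFactors = FALSE)
      pr <- if (tot > 0) cnt / tot else rep(0, nb)
      props[[paste(g, ty)]] <- data.frame(gene = g, event = ty,
                                          t(pr), stringsAsFactors = FALSE)
    }
  }
  bin_names <- sprintf("bin_%g_%g", lower, upper)
  counts <- do.call(rbind, counts); props <- do.call(rbind, props)
  names(counts)[-(1:2)] <- bin_names
  names(props)[-(1:2)] <- bin_names
  rownames(counts) <- rownames(props) <- NULL
  structure(list(bins = data.frame(lower = lower, upper = upper),
                 counts = counts, proportions = props,
                 bin_width = bin_width),
            class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat("Trend table:", nrow(x$bins), "bins of", x$bin_width, "Ga;",
      length(unique(x$counts$gene)), "gene(s)\n")
  invisible(x)
}

#' Order genes chronologically by earliest-event midpoint
#'
#' Oldest first (descending midpoint of each gene's earliest event);
#' ties broken alphabetically.
#'
#' @param events_by_gene Named list of \code{\link{date_events}} frames,
#'   or a named numeric vector of earliest-event midpoints.
#' @return Character vector of gene names, oldest first.
#' @export
order_genes <- function(events_by_gene) {
  mid <- if (is.numeric(events_by_gene)) events_by_gene
  else vapply(events_by_gene, function(e) {
    ee <- earliest_event(e)
    if (nrow(ee)) ee$midpoint else -Inf
  }, 0)
  names(mid)[order(-mid, names(mid))]
}

#' Plot a dot timeline of dated gene events
#'
#' One horizontal band per gene (ordered chronologically), a point per
#' event at its midpoint date, coloured by event type; the time axis runs
#' from the oldest date to the present.
#'
#' @param events_by_gene Named list of \code{\link{date_events}} frames.
#' @param jitter Vertical jitter amplitude within each band.
#' @return Invisibly, the gene order used.
#' @export
plot_event_timeline <- function(events_by_gene, jitter = 0.25) {
  genes <- order_genes(events_by_gene)
  cols <- c(speciation = "#1b9e77", duplication = "#7570b3",
            transfer = "#d95f02", loss = "#666666")
  xmax <- max(unlist(lapply(events_by_gene, function(e) e$midpoint)), 0.1)
  plot(NA, xlim = c(xmax, 0), ylim = c(0.5, length(genes) + 0.5),
       xlab = "Age (Ga)", ylab = "", yaxt = "n")
  graphics::axis(2, at = seq_along(genes), labels = rev(genes), las = 1)
  for (i in seq_along(genes)) {
    e <- events_by_gene[[genes[i]]]
    y <- length(genes) + 1 - i
    graphics::points(e$midpoint,
                     y + stats::runif(nrow(e), -jitter, jitter),
                     pch = 16, cex = 0.7, col = cols[e$event])
  }
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(genes)
}
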