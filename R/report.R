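#' Relative change of a time series against a baseline window
#'
#' `100 * (x - mean(x[baseline])) / mean(x[baseline])`: the baseline window
#' (default the first 100 years) maps to 0 and later values to percentage
#' departures from it.
#'
#' @param x Numeric per-year series.
#' @param baseline Integer indices of the baseline years.
#' @return Percent series of the same length as `x`.
#' @examples
#' relative_change(c(50, 50, 60, 25), baseline = 1:2) # 0 0 20 -50
#' @export
relative_change <- function(x, baseline = 1:100) {
  stopifnot(all(baseline >= 1), all(baseline <= length(x)))
  base <- mean(x[baseline])
  if (!is.finite(base) || base == 0)
    stop("baseline mean is zero or undefined")
  100 * (x - base) / base
}

#' Size-by-age distribution of a population snapshot
#'
#' Counts individuals in an age x length-bin table. Lengths outside the
#' bin range are clamped into the boundary bins so that the table always
#' partitions the population (its grand total equals the population
#' size).
#'
#' @param pop A `fish_population`.
#' @param breaks Strictly increasing length-bin edges (cm); default 1-cm
#'   bins from 4 to 20 cm.
#' @param max_age Rows 1..`max_age` are reported.
#' @return An integer matrix: rows are ages, columns length bins.
#' @export
size_age_distribution <- function(pop, breaks = 4:20, max_age = 7) {
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  n <- population_size(pop)
  nb <- length(breaks) - 1
  out <- matrix(0L, nrow = max_age, ncol = nb,
                dimnames = list(age = seq_len(max_age),
                                length = paste0("(", breaks[-length(breaks)],
                                                ",", breaks[-1], "]")))
  if (n == 0) return(out)
  len <- pmin(pmax(pop$length, breaks[1]), breaks[length(breaks)])
  bin <- cut(len, breaks, include.lowest = TRUE, labels = FALSE)
  age <- pmin(pmax(pop$age, 1L), max_age)
  tab <- table(factor(age, levels = seq_len(max_age)),
               factor(bin, levels = seq_len(nb)))
  out[] <- as.integer(tab)
  out
}

#' Summarize replicate annual-record series
#'
#' Per-year across-replicate mean and empirical 95% percentile band
#' (2.5/97.5) for each numeric summary quantity. Replicates that went
#' extinct contribute zeros from extinction onwards (their records already
#' carry zeros) and are flagged.
#'
#' @param runs A list of per-replicate annual-record data frames (equal
#'   lengths), as returned by [run_scenario()].
#' @param quantities Column names to summarize.
#' @return A list of class `summary_series`: one data frame per quantity
#'   (`year`, `mean`, `lo`, `hi`), plus `n_replicates` and
#'   `extinct_replicates`.
#' @export
summarize_replicates <- function(runs,
                                 quantities = c("mean_l_inf", "biomass",
                                                "n_fish", "mean_k",
                                                "mean_size_mat",
                                                "mean_age_mat")) {
  stopifnot(length(runs) >= 1)
  years <- nrow(runs[[1]])
  if (!all(vapply(runs, nrow, integer(1)) == years))
    stop("replicate series have mismatched lengths")
  out <- lapply(quantities, function(q) {
    m <- vapply(runs, function(r) {
      v <- r[[q]]
      v[is.na(v)] <- 0
      v
    }, numeric(years))
    data.frame(year = runs[[1]]$year,
               mean = rowMeans(m),
               lo = apply(m, 1, quantile, 0.025, names = FALSE),
               hi = apply(m, 1, quantile, 0.975, names = FALSE))
  })
  names(out) <- quantities
  out$n_replicates <- length(runs)
  out$extinct_replicates <- which(vapply(runs, function(r)
    any(r$extinct), logical(1)))
  class(out) <- "summary_series"
  out
}

#' @export
print.summary_series <- function(x, ...) {
  qn <- setdiff(names(x), c("n_replicates", "extinct_replicates"))
  cat(sprintf("summary over %d replicates (%d extinct): %s\n",
              x$n_replicates, length(x$extinct_replicates),
              paste(qn, collapse = ", ")))
  invisible(x)
}

#' Plot a summarized quantity over time
#'
#' Convenience line plot of the replicate mean with its 95% band; carries
#' no analysis weight.
#'
#' @param summary A `summary_series`.
#' @param quantity Which quantity to plot.
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_summary <- function(summary, quantity = "biomass", ...) {
  d <- summary[[quantity]]
  plot(d$year, d$mean, type = "l", xlab = "year", ylab = quantity, ...)
  graphics::lines(d$year, d$lo, lty = 3)
  graphics::lines(d$year, d$hi, lty = 3)
  invisible(d)
}
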