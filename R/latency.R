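#' Pointwise category contrast along the BGA time series
#'
#' At every time sample, tests the target category's trials against the pooled
#' trials of all other categories with a two-tailed two-sample t-test
#' (Welch by default; `var_equal = TRUE` gives the pooled-variance Student
#' variant). Rejected trials are excluded.
#'
#' When both groups have zero variance at a sample the p-value is defined
#' as 1 (no evidence of a contrast).
#'
#' @param bga A `bga_series` from [percent_change()].
#' @param target Target category label.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A tibble with columns `time`, `statistic`, `df`, `p`.
#' @export
pointwise_contrast <- function(bga, target, var_equal = FALSE) {
  if (!inherits(bga, "bga_series")) abort("`bga` must be a <bga_series>.")
  keep <- !bga$rejected
  in_target <- keep & bga$category == target
  in_other <- keep & bga$category != target
  n1 <- sum(in_target)
  n2 <- sum(in_other)
  if (n1 < 2 || n2 < 2) abort("Need >= 2 trials in the target and pooled-other groups.")
  x <- bga$pct[in_target, , drop = FALSE]
  y <- bga$pct[in_other, , drop = FALSE]
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums(sweep(x, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(y, 2, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * pt(-abs(tstat), df)
  zero <- se == 0
  if (any(zero)) { # degenerate sample: identical constant values in both groups
    tstat[zero] <- 0
    p[zero] <- 1
    df[zero] <- NA_real_
  }
  tibble(time = bga$time, statistic = tstat, df = df, p = p)
}

#' Selectivity onset latency from sustained pointwise significance
#'
#' The onset is the first time at which the target-vs-others contrast is
#' significant (p < `alpha` after BH FDR correction across all time points in
#' `window`) and remains significant for a run of successive samples spanning
#' more than `persistence_s` (rate-aware: more than `persistence_s * fs`
#' consecutive samples).
#'
#' @inheritParams pointwise_contrast
#' @param alpha Significance level applied to the FDR-corrected p-values.
#' @param window Time window (s) searched for an onset; the FDR correction
#'   family is all samples in this window.
#' @param persistence_s Minimum significant run duration (s), exclusive.
#' @return A list of class `latency_scan`: `electrode`, `category`,
#'   `onset_s` (`NA` if no qualifying run), `trace` (tibble time/p/p_adj/
#'   significant), `alpha`, `persistence_s`.
#' @export
onset_latency <- function(bga, target, alpha = 0.05, window = c(0, 0.7),
                          persistence_s = 0.1, var_equal = FALSE) {
  ct <- pointwise_contrast(bga, target, var_equal = var_equal)
  fs <- bga$fs
  in_win <- ct$time >= window[1] & ct$time <= window[2]
  if (max(ct$time) < max(window[2], 0.5)) {
    abort("Epoch too short: the p-trace must cover the search window.")
  }
  need <- floor(persistence_s * fs) + 1L # run must span > persistence_s
  if (need > sum(in_win)) abort("`persistence_s` exceeds the searchable window.")
  tr <- ct[in_win, ]
  tr$p_adj <- p.adjust(tr$p, method = "BH")
  tr$significant <- tr$p_adj < alpha
  onset <- NA_real_
  runs <- rle(tr$significant)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= need)
  if (length(hit)) onset <- tr$time[starts[hit[1]]]
  structure(
    list(electrode = bga$electrode, category = target, onset_s = onset,
         trace = tr, alpha = alpha, persistence_s = persistence_s,
         window = window),
    class = "latency_scan"
  )
}

#' @export
print.latency_scan <- function(x, ...) {
  cat(sprintf(
    "<latency_scan> electrode %s, category %s: onset %s (alpha %.3g, persistence > %g ms)\n",
    x$electrode, x$category,
    if (is.na(x$onset_s)) "none" else sprintf("%.0f ms", 1000 * x$onset_s),
    x$alpha, 1000 * x$persistence_s
  ))
  invisible(x)
}

#' Onset latencies for every electrode and category in a dataset
#'
#' Runs [extract_bga()] and [onset_latency()] per electrode x category. When a
#' selectivity table is supplied, only significant electrode-category pairs
#' are scanned (the study convention: latency is a property of selective
#' responses).
#'
#' @param dataset A `gamma_dataset` (see [simulate_dataset()]).
#' @param selectivity Optional tibble from [selectivity_table()]; scans are
#'   restricted to rows with `significant == TRUE`.
#' @inheritParams onset_latency
#' @param ... Passed to [extract_bga()].
#' @return Tibble: `electrode`, `subject`, `region`, `hemisphere`, `category`,
#'   `onset_ms` (`NA` when no onset qualifies).
#' @export
latency_table <- function(dataset, selectivity = NULL, alpha = 0.05,
                          window = c(0, 0.7), persistence_s = 0.1, ...) {
  rows <- vector("list", 0)
  for (i in seq_len(nrow(dataset$epochs))) {
    e <- dataset$epochs[i, ]
    cats <- unique(e$data[[1]]$category)
    if (!is.null(selectivity)) {
      cats <- selectivity$category[selectivity$electrode == e$electrode &
                                     selectivity$significant]
      if (!length(cats)) next
    }
    bga <- extract_bga(e$data[[1]], ...)
    for (cat in cats) {
      sc <- onset_latency(bga, cat, alpha = alpha, window = window,
                          persistence_s = persistence_s)
      rows[[length(rows) + 1]] <- tibble(
        electrode = e$electrode, subject = e$subject, region = e$region,
        hemisphere = e$hemisphere, category = cat,
        onset_ms = 1000 * sc$onset_s
      )
    }
  }
  if (!length(rows)) {
    return(tibble(electrode = character(), subject = character(),
                  region = character(), hemisphere = character(),
                  category = character(), onset_ms = numeric()))
  }
  list_rbind(rows)
}

#' Summarize onset latencies and compare categories
#'
#' Per region x hemisphere x category cell: median and SD of detected onsets
#' (SD is `NA` for singleton cells). Within each region x hemisphere, all
#' category pairs are compared with a two-sided Wilcoxon rank-sum test, BH
#' corrected across pairs.
#'
#' @param latencies Tibble from [latency_table()] (rows with `NA` onsets are
#'   dropped).
#' @param q FDR level for the pairwise comparisons.
#' @return List of tibbles: `cells` (median/SD/n per cell) and `pairwise`
#'   (category pairs with p and BH significance per region x hemisphere).
#' @export
latency_summary <- function(latencies, q = 0.05) {
  lat <- latencies |> filter(!is.na(.data$onset_ms))
  cells <- lat |>
    group_by(.data$region, .data$hemisphere, .data$category) |>
    summarise(
      median_ms = median(.data$onset_ms),
      sd_ms = if (n() > 1) sd(.data$onset_ms) else NA_real_,
      n = n(), .groups = "drop"
    )
  pairs <- lat |>
    group_by(.data$region, .data$hemisphere) |>
    group_modify(function(d, key) {
      cats <- sort(unique(d$category))
      if (length(cats) < 2) {
        return(tibble(category1 = character(), category2 = character(),
                      p = numeric()))
      }
      cmb <- utils::combn(cats, 2)
      tibble(
        category1 = cmb[1, ], category2 = cmb[2, ],
        p = map_dbl(seq_len(ncol(cmb)), function(j) {
          a <- d$onset_ms[d$category == cmb[1, j]]
          b <- d$onset_ms[d$category == cmb[2, j]]
          # normal approximation without continuity correction: usable down to
          # the very small per-cell onset counts typical of this analysis
          suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                       correct = FALSE)$p.value)
        })
      )
    }) |>
    ungroup()
  if (nrow(pairs)) {
    fam <- paste(pairs$region, pairs$hemisphere, sep = ":")
    pairs$significant <- fdr_correct(pairs$p, fam, q = q)$significant
  }
  list(cells = cells, pairwise = pairs)
}
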