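#' d-prime sensitivity index for multi-category selectivity
#'
#' For category j among K categories, with per-category across-trial means
#' `u` and standard deviations `o`,
#' \deqn{d'_j = \frac{u_j - \frac{1}{N}\sum_{i \ne j} u_i}
#'   {\sqrt{\tfrac{1}{2}\left(o_j^2 + \frac{1}{N}\sum_{i \ne j} o_i^2\right)}}}
#' where `N = K - 1` is the number of non-target categories. One index per
#' category, so a single electrode can be selective for several categories.
#'
#' @param means Named numeric vector of per-category means of the per-trial
#'   window-mean BGA.
#' @param sds Numeric vector of per-category across-trial standard deviations
#'   (sample SD, denominator n-1), same length and order as `means`.
#' @param target Optional category name or index; if `NULL` (default) the
#'   d-prime of every category is returned as a named vector.
#' @return Numeric: one d-prime per requested category.
#' @examples
#' dprime(c(face = 1, animate = 0, place = 0, tool = 0, word = 0), rep(1, 5))
#' @export
dprime <- function(means, sds, target = NULL) {
  k <- length(means)
  if (k < 2) abort("At least 2 categories are required for a d-prime index.")
  if (length(sds) != k) abort("`means` and `sds` must have the same length.")
  if (any(!is.finite(means)) || any(!is.finite(sds))) {
    abort("Non-finite category means or SDs.")
  }
  d <- dprime_cols(matrix(means, ncol = 1), matrix(sds, ncol = 1))
  if (any(!is.finite(d))) {
    abort("Degenerate input: pooled variance is zero for at least one category.")
  }
  d <- setNames(drop(d), names(means))
  if (is.null(target)) d else unname(d[target])
}

# vectorized d-prime: u, s are K x m matrices (m independent replicates,
# e.g. permutations); returns K x m matrix of d-primes
dprime_cols <- function(u, s) {
  k <- nrow(u)
  n <- k - 1
  u_other <- sweep(-u, 2, colSums(u), "+") / n
  v <- s * s
  v_other <- sweep(-v, 2, colSums(v), "+") / n
  (u - u_other) / sqrt(0.5 * (v + v_other))
}

# per-category mean and sample SD for each column of V (n trials x m columns);
# labels is a factor of length n. Returns list(u, sd): K x m matrices.
category_column_stats <- function(V, labels) {
  n_j <- tabulate(labels, nbins = nlevels(labels))
  if (any(n_j < 2)) abort("Every category needs at least 2 trials.")
  S <- rowsum(V, labels)
  SS <- rowsum(V * V, labels)
  u <- S / n_j
  v <- (SS - n_j * u * u) / (n_j - 1)
  v[v < 0] <- 0 # guard against negative rounding residue
  list(u = u, sd = sqrt(v), n = n_j)
}

#' d-prime indices from per-trial values
#'
#' Computes the per-category summary statistics (mean, across-trial sample SD)
#' from per-trial scalar BGA values and evaluates [dprime()] for every
#' category.
#'
#' @param values Numeric vector of per-trial scalars (window-mean BGA).
#' @param labels Category label per trial (character or factor).
#' @return Named numeric vector of d-prime indices, one per category level.
#' @export
dprime_from_trials <- function(values, labels) {
  labels <- factor(labels)
  st <- category_column_stats(matrix(values, ncol = 1), labels)
  dprime(setNames(drop(st$u), levels(labels)), drop(st$sd))
}

#' Permutation null distribution of the d-prime indices
#'
#' Shuffles category labels across all trials jointly (preserving per-category
#' trial counts) and recomputes all K d-prime indices, `n_perm` times.
#'
#' @inheritParams dprime_from_trials
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @return Numeric matrix, `n_perm` rows x K category columns, of null
#'   d-prime values.
#' @export
permutation_null <- function(values, labels, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  labels <- factor(labels)
  n <- length(values)
  if (length(labels) != n) abort("`values` and `labels` lengths differ.")
  if (n < 2 * nlevels(labels)) {
    abort("Too few trials: need at least 2 per category overall.")
  }
  draw <- function() {
    V <- vapply(seq_len(n_perm), function(i) values[sample.int(n)], numeric(n))
    st <- category_column_stats(V, labels)
    t(dprime_cols(st$u, st$sd))
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(out) <- levels(labels)
  out
}

#' Permutation p-value
#'
#' One-sided p-value: the fraction of null d-prime values strictly greater
#' than the observed value (ties count as not greater). `p = 0` is possible;
#' `conservative = TRUE` applies the (count + 1)/(n + 1) correction instead.
#'
#' @param observed Observed d-prime (scalar or vector, one per category).
#' @param null Null distribution: vector, or matrix with one column per entry
#'   of `observed` (as returned by [permutation_null()]).
#' @param conservative Use the add-one small-sample correction.
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
permutation_pvalue <- function(observed, null, conservative = FALSE) {
  if (is.null(dim(null))) null <- matrix(null, ncol = 1)
  if (length(observed) != ncol(null)) {
    abort("`observed` must have one value per column of `null`.")
  }
  if (any(!is.finite(observed)) || any(!is.finite(null))) {
    abort("Non-finite values in `observed` or `null`.")
  }
  n <- nrow(null)
  cnt <- colSums(sweep(null, 2, observed, ">"))
  if (conservative) (cnt + 1) / (n + 1) else cnt / n
}

#' Benjamini-Hochberg FDR correction within families
#'
#' Applies the BH step-up procedure at level `q` separately within each
#' correction family (in the grouped electrode analysis: region x hemisphere,
#' pooling categories and electrodes within a family).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family Family label per p-value (single family if `NULL`).
#' @param q Controlled false-discovery rate, default 0.01.
#' @return A tibble with columns `p`, `family`, `significant`, and `cutoff`
#'   (the largest rejected p within the family, `NA` if none), in input order.
#' @examples
#' fdr_correct(c(0.001, 0.002, 0.5, 0.9), q = 0.01)
#' @export
fdr_correct <- function(p, family = NULL, q = 0.01) {
  if (length(p) == 0) {
    return(tibble(p = numeric(), family = character(),
                  significant = logical(), cutoff = numeric()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (is.null(family)) family <- rep("all", length(p))
  out <- tibble(p = p, family = as.character(family),
                significant = NA, cutoff = NA_real_)
  for (f in unique(out$family)) {
    i <- which(out$family == f)
    flag <- p.adjust(out$p[i], method = "BH") <= q
    out$significant[i] <- flag
    out$cutoff[i] <- if (any(flag)) max(out$p[i][flag]) else NA_real_
  }
  out$significant <- as.logical(out$significant)
  out
}

#' Electrode-by-category selectivity table
#'
#' Runs the full selectivity analysis over a simulated (or loaded) dataset:
#' BGA extraction per electrode, per-trial window-mean scalars, observed
#' d-prime per category, permutation p-values, and BH FDR flags within
#' region x hemisphere families.
#'
#' @param dataset A dataset as returned by [simulate_dataset()] or
#'   [read_dataset()]: list with `epochs` (tibble holding `epoch_set` objects
#'   in a `data` list-column) and `geometry`.
#' @param n_perm Permutations per electrode (default 10000).
#' @param q FDR level within each region x hemisphere family.
#' @param window Analysis window (s) for the window-mean BGA.
#' @param seed Integer seed; electrode e uses substream `seed + e` so any
#'   electrode subset is reproducible.
#' @param keep_null Keep each electrode's null matrix (attribute `"null"`,
#'   a named list) for reuse or diagnostics.
#' @param ... Passed on to [extract_bga()].
#' @return A tibble with one row per electrode x category: identifiers,
#'   coordinates, `d_prime`, `p_perm`, `significant`, `cutoff`, `n_perm`.
#' @export
selectivity_table <- function(dataset, n_perm = 10000, q = 0.01,
                              window = c(0.100, 0.400), seed = 1,
                              keep_null = FALSE, ...) {
  epochs_tbl <- dataset$epochs
  geometry <- dataset$geometry
  nulls <- if (keep_null) vector("list", nrow(epochs_tbl)) else NULL
  rows <- vector("list", nrow(epochs_tbl))
  for (i in seq_len(nrow(epochs_tbl))) {
    ep <- epochs_tbl$data[[i]]
    bga <- extract_bga(ep, ...)
    wm <- window_mean_bga(bga, window = window)
    labels <- factor(wm$category)
    obs <- dprime_from_trials(wm$bga, wm$category)
    null <- permutation_null(wm$bga, wm$category, n_perm = n_perm,
                             seed = (seed + i) %% .Machine$integer.max)
    pv <- permutation_pvalue(obs, null)
    rows[[i]] <- tibble(
      electrode = ep$electrode, subject = ep$subject,
      category = levels(labels), d_prime = unname(obs), p_perm = pv
    )
    if (keep_null) {
      nulls[[i]] <- null
      names(nulls)[i] <- ep$electrode
    }
  }
  tab <- list_rbind(rows) |>
    left_join(geometry, by = c("electrode", "subject"))
  all_cats <- unique(tab$category)
  miss <- tab |>
    group_by(.data$electrode) |>
    summarise(missing = list(setdiff(all_cats, .data$category)), .groups = "drop") |>
    filter(lengths(.data$missing) > 0)
  if (nrow(miss)) {
    warn(sprintf(
      "Electrodes missing categories present elsewhere (excluded from those families): %s",
      paste(sprintf("%s (%s)", miss$electrode,
                    vapply(miss$missing, paste, "", collapse = ",")),
            collapse = "; ")))
  }
  fam <- paste(tab$region, tab$hemisphere, sep = ":")
  fd <- fdr_correct(tab$p_perm, fam, q = q)
  tab$significant <- fd$significant
  tab$cutoff <- fd$cutoff
  tab$n_perm <- n_perm
  if (keep_null) attr(tab, "null") <- nulls
  tab
}

#' Summarize significant-selectivity counts
#'
#' Counts electrodes with at least one significant category per region and
#' hemisphere, plus electrodes significant for more than one category
#' (dual-selective) and per-category breakdowns.
#'
#' @param tab A selectivity table from [selectivity_table()].
#' @return A list of tibbles: `by_region` (selective / total electrodes per
#'   region x hemisphere), `by_category` (significant electrodes per
#'   category x region x hemisphere), and scalars `n_selective`, `n_total`,
#'   `n_dual`.
#' @export
selectivity_counts <- function(tab) {
  per_el <- tab |>
    group_by(.data$region, .data$hemisphere, .data$electrode) |>
    summarise(n_sig = sum(.data$significant), .groups = "drop")
  by_region <- per_el |>
    group_by(.data$region, .data$hemisphere) |>
    summarise(selective = sum(.data$n_sig > 0), total = n(), .groups = "drop")
  by_category <- tab |>
    filter(.data$significant) |>
    count(.data$region, .data$hemisphere, .data$category, name = "n_selective")
  list(
    by_region = by_region,
    by_category = by_category,
    n_selective = sum(per_el$n_sig > 0),
    n_total = nrow(per_el),
    n_dual = sum(per_el$n_sig > 1)
  )
}
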