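test_that("d-prime symmetry and unit-effect closed forms", {
  u <- rep(2.3, 5)
  o <- rep(1.7, 5)
  expect_equal(unname(dprime(u, o)), rep(0, 5))
  # u_j = 1, others 0, all SDs 1: d' = 1 / sqrt(0.5 * (1 + 1)) = 1
  expect_equal(dprime(c(1, 0, 0, 0, 0), rep(1, 5), target = 1), 1)
})

test_that("d-prime matches an independently coded evaluation of the formula", {
  direct <- function(u, o, j) {
    others <- setdiff(seq_along(u), j)
    num <- u[j] - mean(u[others])
    den <- sqrt(0.5 * (o[j]^2 + mean(o[others]^2)))
    num / den
  }
  withr::with_seed(14, {
    for (rep in 1:25) {
      u <- rnorm(5)
      o <- runif(5, 0.2, 3)
      d <- dprime(u, o)
      for (j in 1:5) {
        expect_equal(unname(d[j]), direct(u, o, j), tolerance = 1e-12)
      }
    }
  })
})

test_that("d-prime degenerate inputs raise errors", {
  expect_error(dprime(c(1, 2), c(0, 0)), "variance")
  expect_error(dprime(1, 1), "2 categories")
  expect_error(dprime(c(1, NA), c(1, 1)), "finite")
})

test_that("d-prime is invariant under common affine transforms of trial values", {
  withr::with_seed(3, {
    v <- rnorm(60)
    lab <- rep(c("face", "animate", "place", "tool", "word"), each = 12)
    d0 <- dprime_from_trials(v, lab)
    d1 <- dprime_from_trials(4.2 * v + 17, lab)
    expect_equal(d0, d1, tolerance = 1e-9)
  })
})

test_that("two-category case: d' for A equals -d' for B under equal variances", {
  withr::with_seed(8, {
    v <- c(rnorm(10, 1), rnorm(10, -1))
    lab <- rep(c("A", "B"), each = 10)
    d <- dprime_from_trials(v, lab)
    expect_equal(unname(d["A"]), -unname(d["B"]), tolerance = 1e-12)
  })
})

test_that("permutation null is deterministic under a fixed seed", {
  v <- withr::with_seed(2, rnorm(30))
  lab <- rep(c("a", "b", "c"), each = 10)
  n1 <- permutation_null(v, lab, n_perm = 50, seed = 123)
  n2 <- permutation_null(v, lab, n_perm = 50, seed = 123)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(50L, 3L))
})

test_that("Monte-Carlo null matches exhaustive enumeration (2 x 3 toy case)", {
  v <- c(0.3, 1.1, 2.9, 4.1, 5.2, 7.3)
  lab <- rep(c("A", "B"), each = 3)
  # exhaustive oracle: all C(6,3) = 20 assignments of values to category A
  combos <- utils::combn(6, 3)
  exact <- apply(combos, 2, function(ia) {
    a <- v[ia]; b <- v[-ia]
    (mean(a) - mean(b)) / sqrt(0.5 * (var(a) + var(b)))
  })
  expect_length(exact, 20)
  null <- permutation_null(v, lab, n_perm = 10000, seed = 77)[, "A"]
  # KS distance between the MC sample and the discrete exact distribution,
  # evaluated between atoms (at the atoms themselves floating-point noise in
  # the permuted recomputation makes <= ill-conditioned)
  xs <- sort(unique(exact))
  grid <- c(xs[1] - 1, (xs[-1] + xs[-length(xs)]) / 2, xs[length(xs)] + 1)
  cdf_exact <- vapply(grid, function(x) mean(exact <= x), numeric(1))
  cdf_mc <- vapply(grid, function(x) mean(null <= x), numeric(1))
  expect_lt(max(abs(cdf_exact - cdf_mc)), 0.05)
})

test_that("permutation p-values: extreme, median, and counting oracle", {
  null <- matrix(1:10 / 10, ncol = 1)
  expect_equal(permutation_pvalue(2, null), 0)
  # observed at the median of 9 distinct null values -> (9-1)/2 / 9
  null9 <- matrix(c(1:4, 6:9, 5) / 10, ncol = 1)
  expect_equal(permutation_pvalue(0.5, null9), 4 / 9)
  withr::with_seed(5, {
    null10 <- matrix(rnorm(10), ncol = 1)
    obs <- 0.2
    expect_equal(permutation_pvalue(obs, null10), sum(null10 > obs) / 10)
  })
  expect_equal(permutation_pvalue(0.5, matrix(rep(0.5, 8), ncol = 1)), 0) # ties not greater
  expect_error(permutation_pvalue(NaN, null), "finite")
})

test_that("BH flags match a hand-executed step-up and are order-invariant", {
  p <- c(0.001, 0.002, 0.5, 0.9)
  out <- fdr_correct(p, q = 0.01)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unique(out$cutoff), 0.002)

  expect_true(all(fdr_correct(rep(0, 5), q = 0.01)$significant))

  withr::with_seed(10, {
    for (i in 1:10) {
      pv <- runif(40)^2
      fam <- sample(c("f1", "f2"), 40, replace = TRUE)
      got <- fdr_correct(pv, fam, q = 0.05)
      for (f in c("f1", "f2")) {
        sel <- fam == f
        expect_equal(got$significant[sel], bh_stepup(pv[sel], 0.05))
      }
      # order invariance
      o <- sample(40)
      expect_equal(fdr_correct(pv[o], fam[o], q = 0.05)$significant,
                   got$significant[o])
    }
  })
  expect_equal(nrow(fdr_correct(numeric(0))), 0)
})

test_that("null calibration: observed d' sits at a uniform quantile of its null", {
  # exchangeable labels: the permutation p-value is ~ Uniform(0, 1)
  ps <- withr::with_seed(42, vapply(1:60, function(i) {
    v <- rnorm(40)
    lab <- rep(c("a", "b", "c", "d"), each = 10)
    obs <- dprime_from_trials(v, lab)[1]
    null <- permutation_null(v, lab, n_perm = 99)[, 1]
    permutation_pvalue(obs, null)
  }, numeric(1)))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("selectivity table recovers planted electrodes without false positives", {
  eff <- null_effect()
  eff$face <- list(base = 1.5, slope = 0) # large planted face effect
  ds <- simulate_dataset(fast_sim_config(
    n_subjects = 2, electrodes_per_subject = 5, trials_per_category = 10,
    selectivity_effect = eff, seed = 6
  ))
  tab <- selectivity_table(ds, n_perm = 1000, q = 0.01, seed = 6, notch = FALSE)
  face <- tab |> dplyr::filter(category == "face")
  expect_gte(sum(face$significant), 9) # >= 9 of 10 planted recovered
  other <- tab |> dplyr::filter(category != "face")
  expect_lte(sum(other$significant), 1) # false positives ~ 0 under FDR
})

test_that("selectivity table warns when an electrode misses a category", {
  ds <- simulate_dataset(fast_sim_config(n_subjects = 1,
                                         electrodes_per_subject = 2,
                                         trials_per_category = 5, seed = 9))
  # drop the word trials from electrode 2 only
  ep <- ds$epochs$data[[2]]
  keep <- ep$category != "word"
  ds$epochs$data[[2]] <- epoch_set(
    ep$voltages[keep, ], ep$fs, category = ep$category[keep], time = ep$time,
    electrode = ep$electrode, subject = ep$subject
  )
  expect_warning(
    tab <- selectivity_table(ds, n_perm = 20, seed = 1, notch = FALSE),
    "missing categories"
  )
  expect_equal(sum(tab$category == "word"), 1)
})
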