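# d-prime-level simulation: d = b0 + b1*c1 + b2*c2 + b3*c1*c2 + u_subj + e
make_lme_data <- function(n_subjects = 16, n_el = 94,
                          beta = c(0.1, 0.05, -0.02, 0.001),
                          subject_sd = 0.3, resid_sd = 0.4, seed = 1) {
  withr::with_seed(seed, {
    subject <- sort(sample(sprintf("s%02d", seq_len(n_subjects)), n_el,
                           replace = TRUE))
    u <- stats::setNames(rnorm(n_subjects, 0, subject_sd),
                         sprintf("s%02d", seq_len(n_subjects)))
    c1 <- runif(n_el, -15, 15); c1 <- c1 - mean(c1)
    c2 <- runif(n_el, -20, 20); c2 <- c2 - mean(c2)
    tibble::tibble(
      subject = subject, xc = c1, yc = c2,
      d_prime = beta[1] + beta[2] * c1 + beta[3] * c2 + beta[4] * c1 * c2 +
        u[subject] + rnorm(n_el, 0, resid_sd)
    )
  })
}

test_that("coordinate centering zeroes the mean within region x hemisphere", {
  ds <- simulate_dataset(fast_sim_config(n_subjects = 3, seed = 2))
  g <- center_coordinates(ds$geometry)
  chk <- g |>
    dplyr::group_by(region, hemisphere) |>
    dplyr::summarise(m = max(abs(c(mean(xc), mean(yc), mean(zc)))),
                     .groups = "drop")
  expect_lt(max(chk$m), 1e-9)
})

test_that("Spearman screen: monotone pairs, rank-formula oracle, constant axis", {
  g <- tibble::tibble(
    subject = "s", electrode = sprintf("e%d", 1:10),
    region = "VTC", hemisphere = "L",
    x = 1:10, y = (1:10)^3, z = rep(5, 10) # x-y perfectly monotone, z constant
  )
  sc <- collinearity_screen(g)
  expect_equal(sc$rho[sc$pair == "x-y"], 1)
  expect_true(is.na(sc$rho[sc$pair == "x-z"]))

  withr::with_seed(4, {
    g2 <- g
    g2$x <- rnorm(10); g2$y <- rnorm(10); g2$z <- rnorm(10)
    sc2 <- collinearity_screen(g2)
    # classical rank formula (no ties): 1 - 6 sum(d^2) / (n (n^2 - 1))
    d <- rank(g2$x) - rank(g2$y)
    expect_equal(sc2$rho[sc2$pair == "x-y"],
                 1 - 6 * sum(d^2) / (10 * 99), tolerance = 1e-10)
  })
  expect_error(collinearity_screen(g[1:2, ]), ">= 3 electrodes")
})

test_that("simulated VTC geometry reproduces strong x-z collinearity", {
  ds <- simulate_dataset(sim_config(n_subjects = 6, electrodes_per_subject = 10,
                                    trials_per_category = 2, seed = 12))
  sc <- collinearity_screen(ds$geometry)
  xz <- sc |> dplyr::filter(region == "VTC", pair == "x-z")
  expect_true(all(abs(xz$rho) > 0.8))
})

test_that("region axis rule: z dropped in VTC, x dropped in LOC", {
  expect_equal(region_axes("VTC"), c("xc", "yc"))
  expect_equal(region_axes("LOC"), c("zc", "yc"))
  expect_error(region_axes("FOO"), "Unknown region")
})

test_that("zero subject variance: mixed fit reduces to OLS and is flagged", {
  # residuals built antisymmetric within each subject, so the between-subject
  # variance component is estimated at the boundary (exactly zero)
  withr::with_seed(3, {
    n_sub <- 15
    subject <- rep(sprintf("s%02d", seq_len(n_sub)), each = 2)
    c1 <- runif(2 * n_sub, -15, 15); c1 <- c1 - mean(c1)
    c2 <- runif(2 * n_sub, -20, 20); c2 <- c2 - mean(c2)
    e <- rnorm(n_sub, 0, 0.5)
    d <- tibble::tibble(
      subject = subject, xc = c1, yc = c2,
      d_prime = 0.1 + 0.05 * c1 - 0.02 * c2 + rep(c(1, -1), n_sub) * rep(e, each = 2)
    )
  })
  fit <- fit_topology_lme(d, c("xc", "yc"))
  ols <- lm(d_prime ~ xc * yc, data = d)
  expect_true(fit$boundary)
  expect_equal(unname(tidy(fit)$estimate), unname(coef(ols)), tolerance = 1e-6)
})

test_that("REML optimum beats a grid of variance ratios (profile sanity)", {
  d <- make_lme_data(seed = 8)
  fit <- fit_topology_lme(d, c("xc", "yc"))
  dev_fun <- lme4::lmer(d_prime ~ xc * yc + (1 | subject), data = d,
                        REML = TRUE, devFunOnly = TRUE)
  theta_hat <- lme4::getME(fit$fit, "theta")
  at_hat <- dev_fun(theta_hat)
  grid <- seq(0, 10, length.out = 50)
  expect_true(all(at_hat <= vapply(grid, dev_fun, numeric(1)) + 1e-6))
})

test_that("fixed effects recover the generating coefficients (quick check)", {
  beta <- c(0.1, 0.05, -0.02, 0.001)
  d <- make_lme_data(beta = beta, seed = 5)
  td <- tidy(fit_topology_lme(d, c("xc", "yc")))
  expect_equal(unname(td$estimate), beta, tolerance = 10 * max(td$std.error))
  expect_true(all(td$std.error > 0))
  # strong slope: sign recovered and significant
  expect_lt(td$p.value[td$term == "xc"], 0.001)
  expect_gt(td$estimate[td$term == "xc"], 0)
})

test_that("slopes are invariant to shifting raw coordinates (centering)", {
  ds <- simulate_dataset(fast_sim_config(n_subjects = 5,
                                         electrodes_per_subject = 10, seed = 10))
  sel <- ds$ground_truth |>
    dplyr::transmute(electrode, subject, region, hemisphere, category,
                     d_prime = effect +
                       withr::with_seed(1, rnorm(nrow(ds$ground_truth), 0, 0.1)))
  rep1 <- topology_report(sel, ds$geometry)
  g2 <- ds$geometry
  g2$x <- g2$x + 55; g2$y <- g2$y - 12; g2$z <- g2$z + 7
  rep2 <- topology_report(sel, g2)
  a <- rep1$coefficients |> dplyr::filter(term != "(Intercept)")
  b <- rep2$coefficients |> dplyr::filter(term != "(Intercept)")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
})

test_that("one electrode per subject is flagged degenerate, not fitted blindly", {
  d <- make_lme_data(n_subjects = 12, n_el = 12, seed = 6)
  d$subject <- sprintf("s%02d", 1:12)
  fit <- fit_topology_lme(d, c("xc", "yc"))
  expect_true(fit$boundary)
  expect_true(fit$degenerate)
  expect_true(is.na(glance(fit)$sigma_subject))
})

test_that("singular designs and missing columns raise informative errors", {
  d <- make_lme_data(seed = 7)
  d$yc <- 2 * d$xc
  expect_error(fit_topology_lme(d, c("xc", "yc")), "collinear")
  expect_error(fit_topology_lme(d, c("xc", "qq")), "Missing coordinate")
  d2 <- make_lme_data(seed = 7)
  d2$subject <- "s01"
  expect_error(fit_topology_lme(d2, c("xc", "yc")), "2 subjects")
})

test_that("topology report: planted gradient sign recovered, absent cells absent", {
  ds <- simulate_dataset(sim_config(n_subjects = 5, electrodes_per_subject = 10,
                                    trials_per_category = 2, seed = 20))
  # use ground-truth effects as the response: slope sign must match injection
  sel <- ds$ground_truth |>
    dplyr::transmute(electrode, subject, region, hemisphere, category,
                     d_prime = effect)
  # drop word rows in the right hemisphere (word task is left-cohort only)
  sel <- sel |> dplyr::filter(!(category == "word" & hemisphere == "R"))
  rep <- topology_report(sel, ds$geometry)
  expect_false(any(rep$coefficients$category == "word" &
                     rep$coefficients$hemisphere == "R"))
  # face gain grows laterally: in the left hemisphere x is negative laterally,
  # so the fitted xc slope for faces must be negative in LH VTC
  face_lh <- rep$coefficients |>
    dplyr::filter(category == "face", region == "VTC", hemisphere == "L",
                  term == "xc")
  expect_lt(face_lh$estimate, 0)
  place_lh <- rep$coefficients |>
    dplyr::filter(category == "place", region == "VTC", hemisphere == "L",
                  term == "xc")
  expect_gt(place_lh$estimate, 0)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- make_lme_data(seed = 9)
  fit <- fit_topology_lme(d, c("xc", "yc"),
                          label = list(category = "face", region = "VTC"))
  td <- tidy(fit)
  expect_equal(names(td), c("category", "region", "term", "estimate",
                            "std.error", "df", "statistic", "p.value"))
  expect_equal(td$term, c("(Intercept)", "xc", "yc", "xc:yc"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 94)
  expect_true(gl$REML)
  expect_gt(gl$sigma_subject, 0)
})
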