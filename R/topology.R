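#' Mean-center electrode coordinates within region x hemisphere
#'
#' @param geometry Tibble with columns `subject`, `electrode`, `hemisphere`,
#'   `region`, `x`, `y`, `z` (Talairach mm).
#' @return The geometry tibble with added `xc`, `yc`, `zc` columns, centered
#'   within each hemisphere x region cell.
#' @export
center_coordinates <- function(geometry) {
  geometry |>
    group_by(.data$region, .data$hemisphere) |>
    mutate(xc = .data$x - mean(.data$x),
           yc = .data$y - mean(.data$y),
           zc = .data$z - mean(.data$z)) |>
    ungroup()
}

#' Spearman collinearity screen of electrode coordinates
#'
#' Pairwise Spearman rank correlations among x, y, z within each
#' region x hemisphere cell, motivating the fixed per-region axis choice of
#' [region_axes()] (in VTC the z axis tracks the lateral position along the
#' folded fusiform surface; in LOC the x axis tracks y).
#'
#' @inheritParams center_coordinates
#' @return Tibble: `region`, `hemisphere`, `pair`, `rho`, `n`. `rho` is `NA`
#'   for constant coordinates.
#' @export
collinearity_screen <- function(geometry) {
  geometry |>
    group_by(.data$region, .data$hemisphere) |>
    group_modify(function(d, key) {
      if (nrow(d) < 3) abort("Need >= 3 electrodes per region x hemisphere cell.")
      pairs <- list(c("x", "y"), c("x", "z"), c("y", "z"))
      tibble(
        pair = map_chr(pairs, paste, collapse = "-"),
        rho = map_dbl(pairs, function(p) {
          a <- d[[p[1]]]; b <- d[[p[2]]]
          if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
          cor(a, b, method = "spearman")
        }),
        n = nrow(d)
      )
    }) |>
    ungroup()
}

#' Fixed-effect coordinate axes per region
#'
#' The VTC models use x and y (z dropped for collinearity with x); the LOC
#' models use z and y (x dropped for collinearity with y). The interaction of
#' the two retained axes is always included.
#'
#' @param region `"VTC"` or `"LOC"`.
#' @return Character vector of the two centered-coordinate column names.
#' @export
region_axes <- function(region) {
  switch(region,
    VTC = c("xc", "yc"),
    LOC = c("zc", "yc"),
    abort(sprintf("Unknown region '%s' (expected VTC or LOC).", region))
  )
}

#' Random-intercept mixed model of d-prime vs electrode coordinates
#'
#' Fits `d_prime ~ c1 + c2 + c1:c2 + (1 | subject)` by REML with Satterthwaite
#' degrees of freedom for the fixed-effect t-tests. `c1`, `c2` are the
#' mean-centered coordinates retained for the region ([region_axes()]). When
#' the subject variance is estimated at the boundary (zero) the fit is
#' flagged and the fixed effects coincide with ordinary least squares.
#'
#' @param data Tibble with columns `d_prime`, `subject`, and the two centered
#'   coordinate columns named in `axes`.
#' @param axes Character vector of two coordinate column names, e.g.
#'   `c("xc", "yc")`.
#' @param label Optional named list of identifiers (category/region/hemisphere)
#'   carried into tidy output.
#' @return An object of class `topo_lme` wrapping the `lmerModLmerTest` fit,
#'   with [tidy()] and [glance()] methods.
#' @export
fit_topology_lme <- function(data, axes, label = list()) {
  if (!all(axes %in% names(data))) {
    abort(paste("Missing coordinate columns:",
                paste(setdiff(axes, names(data)), collapse = ", ")))
  }
  if (length(unique(data$subject)) < 2) {
    abort("Need >= 2 subjects to identify a subject random intercept.")
  }
  if (sd(data$d_prime) == 0) {
    abort("Degenerate response: d_prime is constant in this cell.")
  }
  mm <- cbind(1, data[[axes[1]]], data[[axes[2]]],
              data[[axes[1]]] * data[[axes[2]]])
  if (qr(mm)$rank < ncol(mm)) {
    abort(paste("Singular fixed-effect design; collinear columns among:",
                paste(c("(Intercept)", axes[1], axes[2],
                        paste0(axes[1], ":", axes[2])), collapse = ", ")))
  }
  fml <- stats::as.formula(sprintf(
    "d_prime ~ %s * %s + (1 | subject)", axes[1], axes[2]
  ))
  if (nrow(data) <= length(unique(data$subject))) {
    # one electrode per subject: subject and residual variance are jointly
    # unidentifiable -- flag the degeneracy and reduce to OLS
    fit <- stats::lm(stats::as.formula(sprintf(
      "d_prime ~ %s * %s", axes[1], axes[2])), data = data)
    return(structure(
      list(fit = fit, axes = axes, label = label, engine = "ols",
           boundary = TRUE, degenerate = TRUE, n_obs = nrow(data)),
      class = "topo_lme"
    ))
  }
  fit <- suppressMessages(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)
                   ))
  )
  structure(
    list(fit = fit, axes = axes, label = label, engine = "lmer",
         boundary = lme4::isSingular(fit, tol = 1e-6), degenerate = FALSE,
         n_obs = nrow(data)),
    class = "topo_lme"
  )
}

#' @export
print.topo_lme <- function(x, ...) {
  lbl <- paste(unlist(x$label), collapse = " / ")
  cat(sprintf("<topo_lme> %s: d_prime ~ %s * %s + (1 | subject), n = %d%s\n",
              if (nzchar(lbl)) lbl else "fit", x$axes[1], x$axes[2], x$n_obs,
              if (x$boundary) " [boundary: subject variance ~ 0]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_topology_lme
#' @param x A `topo_lme` object.
#' @param ... Unused.
#' @method tidy topo_lme
#' @export
tidy.topo_lme <- function(x, ...) {
  sm <- summary(x$fit)$coefficients # Satterthwaite df via lmerTest
  out <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    df = if (x$engine == "lmer") sm[, "df"] else x$fit$df.residual,
    statistic = sm[, "t value"],
    p.value = sm[, if (x$engine == "lmer") "Pr(>|t|)" else "Pr(>|t|)"]
  )
  for (nm in rev(names(x$label))) {
    out <- tibble(!!nm := x$label[[nm]]) |> bind_cols(out)
  }
  out
}

#' @rdname fit_topology_lme
#' @method glance topo_lme
#' @export
glance.topo_lme <- function(x, ...) {
  if (x$engine == "ols") {
    return(tibble(nobs = x$n_obs, sigma_subject = NA_real_,
                  sigma_residual = summary(x$fit)$sigma,
                  logLik = as.numeric(stats::logLik(x$fit)),
                  REML = FALSE, boundary = TRUE, degenerate = TRUE))
  }
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(
    nobs = x$n_obs,
    sigma_subject = vc$sdcor[vc$grp == "subject"],
    sigma_residual = vc$sdcor[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(x$fit)),
    REML = TRUE,
    boundary = x$boundary,
    degenerate = FALSE
  )
}

#' Per-category topology models and report
#'
#' Fits one [fit_topology_lme()] model per category x region x hemisphere cell
#' present in the selectivity table (after joining centered coordinates), and
#' assembles coefficient tables plus significant-electrode counts. Cells with
#' no data (e.g. a category never shown in one hemisphere) are absent from the
#' output, not zero-filled.
#'
#' @param selectivity Tibble from [selectivity_table()] (or any tibble with
#'   `electrode`, `subject`, `region`, `hemisphere`, `category`, `d_prime`,
#'   optionally `significant`).
#' @param geometry Geometry tibble (raw coordinates); centered internally.
#' @return A list of class `topology_report`: `coefficients` (one row per
#'   fixed-effect term per model), `fits` (named list of `topo_lme`),
#'   `screen` ([collinearity_screen()] output), and `counts` (significant
#'   electrodes per category cell, when a `significant` column is present).
#' @export
topology_report <- function(selectivity, geometry) {
  geom_c <- center_coordinates(geometry)
  dat <- selectivity |>
    left_join(geom_c |> select("electrode", "subject", "xc", "yc", "zc"),
              by = c("electrode", "subject"))
  cells <- dat |> distinct(.data$category, .data$region, .data$hemisphere)
  fits <- list()
  coefs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    d <- dat |>
      filter(.data$category == cell$category, .data$region == cell$region,
             .data$hemisphere == cell$hemisphere)
    axes <- region_axes(cell$region)
    # four fixed effects need residual degrees of freedom and >= 2 subjects
    if (nrow(d) < 6 || length(unique(d$subject)) < 2) {
      skipped <- c(skipped,
                   paste(cell$category, cell$region, cell$hemisphere, sep = ":"))
      next
    }
    fit <- fit_topology_lme(
      d, axes,
      label = list(category = cell$category, region = cell$region,
                   hemisphere = cell$hemisphere)
    )
    key <- paste(cell$category, cell$region, cell$hemisphere, sep = ":")
    fits[[key]] <- fit
    td <- tidy(fit)
    td$n_obs <- fit$n_obs
    td$boundary <- fit$boundary
    coefs[[key]] <- td
  }
  if (length(skipped)) {
    warn(paste("Cells too small for a mixed model (skipped):",
               paste(skipped, collapse = ", ")))
  }
  counts <- NULL
  if ("significant" %in% names(selectivity)) {
    counts <- selectivity |>
      filter(.data$significant) |>
      count(.data$category, .data$region, .data$hemisphere, name = "n_selective")
  }
  screen_geom <- geometry |>
    group_by(.data$region, .data$hemisphere) |>
    filter(n() >= 3) |>
    ungroup()
  coef_tbl <- if (length(coefs)) list_rbind(coefs) else
    tibble(category = character(), region = character(),
           hemisphere = character(), term = character(), estimate = numeric(),
           std.error = numeric(), df = numeric(), statistic = numeric(),
           p.value = numeric(), n_obs = integer(), boundary = logical())
  structure(
    list(coefficients = coef_tbl, fits = fits,
         screen = collinearity_screen(screen_geom), counts = counts,
         skipped = skipped),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>", length(x$fits), "mixed-effects fits\n")
  print(x$coefficients, n = 20)
  invisible(x)
}
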