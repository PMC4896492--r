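# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# short-epoch config: keeps the signal chain fast while still covering the
# baseline (-0.7..-0.2 s) and analysis (0.1..0.4 s) windows
fast_sim_config <- function(n_subjects = 2, electrodes_per_subject = 2,
                            trials_per_category = 8, seed = 7, ...) {
  sim_config(
    n_subjects = n_subjects, electrodes_per_subject = electrodes_per_subject,
    trials_per_category = trials_per_category,
    epoch_window_s = c(-0.8, 0.8), seed = seed, ...
  )
}

# config with no injected selectivity anywhere (global null)
null_effect <- function() {
  cats <- c("face", "animate", "place", "tool", "word")
  setNames(lapply(cats, function(x) list(base = 0, slope = 0)), cats)
}

# epoch_set holding a deterministic signal given by f(t), replicated per trial
signal_epochs <- function(f, fs = 1000, t = seq(-1, 2, by = 1 / fs),
                          n_trials = 3, category = NULL) {
  y <- rep_len(f(t), length(t))
  v <- matrix(rep(y, each = n_trials), nrow = n_trials)
  if (is.null(category)) category <- rep("face", n_trials)
  epoch_set(v, fs, category = category, time = t)
}

# hand-rolled bga_series (bypasses the signal chain) from a trials x samples
# percent-change matrix
fake_bga <- function(pct, time, fs, category, rejected = NULL) {
  if (is.null(rejected)) rejected <- rep(FALSE, nrow(pct))
  structure(
    list(pct = pct, mean = colMeans(pct[!rejected, , drop = FALSE]),
         sd = apply(pct[!rejected, , drop = FALSE], 2, sd),
         time = time, fs = fs, category = category, rejected = rejected,
         baseline_window = c(-0.7, -0.2),
         electrode = "fx", subject = "fs"),
    class = "bga_series"
  )
}

# independent hand-executed BH step-up (test oracle, kept free of p.adjust)
bh_stepup <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * q)
  flag <- rep(FALSE, m)
  if (length(k)) flag[o[seq_len(max(k))]] <- TRUE
  flag
}

# rms in decibels relative to a reference signal
db_ratio <- function(x, ref) 20 * log10(sqrt(mean(x^2)) / sqrt(mean(ref^2)))

# ---- MAT fixture support (written at test time by scipy, the independent
# writer; the package's reader is the code under test) ---------------------

has_scipy <- function() {
  if (!nzchar(Sys.which("python"))) return(FALSE)
  code <- suppressWarnings(system2("python", c("-c", shQuote("import scipy.io")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}

# Serialize an R list to JSON, let scipy assemble and save a MAT v5 file.
# spec entries: list(name=, value=matrix|string, kind="matrix"|"char"), or
# kind="cell" with value = list of matrices (per-subject shuffle arrays).
write_mat_fixture <- function(path, vars, compress = TRUE) {
  json <- tempfile(fileext = ".json")
  num17 <- function(x) sprintf("%.17g", as.vector(x)) # exact double transport
  payload <- lapply(vars, function(v) {
    if (v$kind == "matrix") {
      list(kind = "matrix", data = num17(v$value),
           dim = dim(v$value) %||% c(length(v$value), 1L))
    } else if (v$kind == "char") {
      list(kind = "char", data = v$value)
    } else if (v$kind == "cell_char") {
      list(kind = "cell_char", data = v$value)
    } else { # cell of numeric arrays
      list(kind = "cell", data = lapply(unname(v$value), function(a) {
        list(data = num17(a), dim = dim(a) %||% c(length(a), 1L))
      }))
    }
  })
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "import scipy.io as sio",
    sprintf("spec = json.load(open(%s))", deparse(json)),
    "out = {}",
    "for name, v in spec.items():",
    "    if v['kind'] == 'matrix':",
    "        out[name] = np.asarray(v['data'], dtype=float).reshape(v['dim'], order='F')",
    "    elif v['kind'] == 'char':",
    "        out[name] = v['data']",
    "    elif v['kind'] == 'cell_char':",
    "        c = np.empty((len(v['data']), 1), dtype=object)",
    "        for i, s in enumerate(v['data']): c[i, 0] = s",
    "        out[name] = c",
    "    else:",
    "        c = np.empty((len(v['data']), 1), dtype=object)",
    "        for i, a in enumerate(v['data']):",
    "            c[i, 0] = np.asarray(a['data'], dtype=float).reshape(a['dim'], order='F')",
    "        out[name] = c",
    sprintf("sio.savemat(%s, out, do_compression=%s)", deparse(path),
            if (compress) "True" else "False")
  ), script)
  code <- system2("python", script, stdout = FALSE, stderr = "")
  if (!identical(code, 0L)) stop("scipy fixture writer failed")
  path
}

# synthetic supplementary cohort with planted selectivity: electrodes whose
# observed d-prime exceeds every stored shuffle
make_supplementary_cohort <- function(n_el, subj_sizes, n_perm = 200,
                                      planted = integer(0), seed = 1,
                                      hemi_sign = -1, suffix = "LH_VTC") {
  stopifnot(sum(subj_sizes) == n_el)
  withr::with_seed(seed, {
    cats <- c("face", "animate", "place", "tool", "word")
    shuf <- lapply(seq_len(n_el), function(i) {
      matrix(rnorm(n_perm * 5, 0, 0.5), n_perm, 5)
    })
    dp <- t(vapply(seq_len(n_el), function(i) {
      d <- rnorm(5, 0, 0.3)
      if (i %in% planted) d[1] <- max(shuf[[i]][, 1]) + 1 # clears every shuffle
      d
    }, numeric(5)))
    coords <- cbind(hemi_sign * runif(n_el, 25, 60), runif(n_el, -75, -30),
                    runif(n_el, -15, 0))
    # per-subject cell: (n_e x n_perm x 5) arrays
    idx <- split(seq_len(n_el), rep(seq_along(subj_sizes), subj_sizes))
    cell <- lapply(idx, function(ii) {
      a <- array(0, c(length(ii), n_perm, 5))
      for (j in seq_along(ii)) a[j, , ] <- shuf[[ii[j]]]
      a
    })
    list(
      d_prime = dp, coords = coords, shuffles = shuf, cell = cell,
      categories = cats,
      vars = setNames(
        list(
          list(kind = "matrix", value = dp),
          list(kind = "matrix", value = coords),
          list(kind = "cell", value = cell),
          list(kind = "cell_char", value = cats)
        ),
        c(paste0("pt_dprime_final_", suffix), paste0("Pt_Coords_", suffix),
          paste0("pt_dprime_final_shuf_", suffix), "Categories")
      )
    )
  })
}
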