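#' Plain-text dataset serialization
#'
#' A `gamma_dataset` is written as a directory of portable text files: a JSON
#' sidecar with the full simulation configuration and a schema version,
#' tab-delimited geometry and ground-truth tables, and one tab-delimited epoch
#' file per electrode (trials x samples with `#key=value` header lines giving
#' the sampling rate and epoch start). All doubles are written with 17
#' significant digits, so `read_dataset(write_dataset(x))` is bit-identical.
#'
#' @param dataset A `gamma_dataset` from [simulate_dataset()].
#' @param path Directory to create.
#' @param overwrite Replace an existing directory.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, overwrite = FALSE) {
  if (!inherits(dataset, "gamma_dataset")) {
    abort("`dataset` must be a <gamma_dataset>.")
  }
  if (dir.exists(path)) {
    if (!overwrite) abort(sprintf("'%s' already exists (use overwrite = TRUE).", path))
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  dir.create(file.path(path, "epochs"))
  jsonlite::write_json(
    list(schema = "gammasel-dataset", schema_version = DATASET_SCHEMA_VERSION,
         config = unclass(dataset$config)),
    file.path(path, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  write_tsv17(dataset$geometry, file.path(path, "geometry.tsv"))
  write_tsv17(dataset$ground_truth, file.path(path, "ground_truth.tsv"))
  for (i in seq_len(nrow(dataset$epochs))) {
    ep <- dataset$epochs$data[[i]]
    write_epochs_tsv(ep, file.path(path, "epochs", paste0(ep$electrode, ".tsv")))
  }
  invisible(path)
}

DATASET_SCHEMA_VERSION <- "1.0"

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  cfg_path <- file.path(path, "config.json")
  if (!file.exists(cfg_path)) {
    abort(sprintf("Not a dataset directory: missing '%s'.", cfg_path))
  }
  meta <- jsonlite::fromJSON(cfg_path, simplifyVector = TRUE)
  if (!identical(meta$schema, "gammasel-dataset") ||
      !identical(meta$schema_version, DATASET_SCHEMA_VERSION)) {
    abort(sprintf(
      "Schema mismatch in '%s': found %s/%s, this package reads gammasel-dataset/%s.",
      cfg_path, meta$schema %||% "?", meta$schema_version %||% "?",
      DATASET_SCHEMA_VERSION
    ))
  }
  config <- rebuild_sim_config(meta$config)
  geometry <- read_tsv17(file.path(path, "geometry.tsv"))
  truth <- read_tsv17(file.path(path, "ground_truth.tsv"))
  files <- file.path(path, "epochs", paste0(geometry$electrode, ".tsv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort(paste("Missing epoch files:", paste(basename(missing), collapse = ", ")))
  }
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    ep <- read_epochs_tsv(files[i])
    rows[[i]] <- tibble(
      subject = ep$subject, electrode = ep$electrode,
      region = geometry$region[i], hemisphere = geometry$hemisphere[i],
      data = list(ep)
    )
  }
  structure(
    list(epochs = list_rbind(rows), geometry = geometry,
         ground_truth = truth, config = config),
    class = "gamma_dataset"
  )
}

rebuild_sim_config <- function(cfg) {
  num_fields <- c("epoch_window_s", "baseline_window_s", "gamma_band_hz",
                  "electrodes_per_subject")
  for (f in num_fields) cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  cfg$trials_per_category <- unlist(cfg$trials_per_category)
  cfg$categories <- as.character(unlist(cfg$categories))
  cfg$noise_model <- lapply(cfg$noise_model, function(x) {
    if (is.null(x)) NULL else as.numeric(unlist(x))
  })
  cfg$selectivity_effect <- lapply(cfg$selectivity_effect,
                                   function(x) lapply(x, as.numeric))
  cfg$coordinate_model <- rapply(cfg$coordinate_model,
                                 function(x) as.numeric(unlist(x)),
                                 how = "list")
  cfg$coordinate_model$vtc_fraction <- as.numeric(cfg$coordinate_model$vtc_fraction)
  do.call(sim_config, cfg)
}

# -- tab-delimited helpers (17 significant digits: doubles round-trip exactly)

fmt17 <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_tsv17 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv17 <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE,
                              stringsAsFactors = FALSE, fill = FALSE))
}

write_epochs_tsv <- function(ep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#schema=gammasel-epochs/%s", DATASET_SCHEMA_VERSION),
    sprintf("#fs=%.17g", ep$fs),
    sprintf("#t0=%.17g", ep$time[1]),
    sprintf("#electrode=%s", ep$electrode),
    sprintf("#subject=%s", ep$subject)
  ), con)
  n <- ncol(ep$voltages)
  writeLines(paste(c("category", "rejected", paste0("s", seq_len(n))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(ep$voltages))) {
    writeLines(paste(c(ep$category[i], ep$rejected[i],
                       sprintf("%.17g", ep$voltages[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a per-electrode delimited epoch file
#'
#' Reads the trials-by-samples text format written by [write_dataset()]:
#' `#key=value` header lines (`fs`, `t0`, identifiers), a column header, then
#' one row per trial (`category`, `rejected`, sample values). Truncated or
#' ragged files raise an error naming the file rather than returning silent
#' `NA`s.
#'
#' @param path Path to an epochs `.tsv` file.
#' @return An [epoch_set()].
#' @export
read_epochs_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such epoch file: '%s'.", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  meta <- setNames(as.list(vals), keys)
  if (!identical(meta$schema, paste0("gammasel-epochs/", DATASET_SCHEMA_VERSION))) {
    abort(sprintf("Schema mismatch in '%s' (found '%s').", path,
                  meta$schema %||% "none"))
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) abort(sprintf("Corrupt epoch file '%s': no trial rows.", path))
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  n_col <- length(cols)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n_col)
  if (length(bad)) {
    abort(sprintf("Corrupt/truncated epoch file '%s': row %d has %d of %d fields.",
                  path, bad[1], lengths(rows)[bad[1]], n_col))
  }
  m <- do.call(rbind, rows)
  volt <- matrix(as.numeric(m[, -(1:2), drop = FALSE]), nrow = nrow(m))
  if (anyNA(volt)) abort(sprintf("Corrupt epoch file '%s': non-numeric samples.", path))
  fs <- as.numeric(meta$fs)
  epoch_set(volt, fs, category = m[, 1], t0 = as.numeric(meta$t0),
            electrode = meta$electrode, subject = meta$subject,
            rejected = as.logical(m[, 2]))
}
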