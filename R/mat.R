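#' Read a MATLAB v5 MAT-file
#'
#' A self-contained reader for Level-5 MAT-files covering the constructs used
#' by electrode-level supplementary datasets: numeric arrays (double, single,
#' 8/16/32-bit integers), character arrays, cell arrays (arbitrarily nested),
#' and zlib-compressed (`miCOMPRESSED`) elements. Both little- and big-endian
#' files are handled. HDF5-based v7.3 containers are detected and refused with
#' an informative error; structs, sparse and complex arrays are not supported.
#'
#' @param path Path to a `.mat` file.
#' @return A named list of variables. Numeric and character data come back as
#'   R matrices/arrays (MATLAB column-major dimensions preserved; 2-D char
#'   arrays collapse to one string per row); cell arrays come back as lists
#'   with a `dim` attribute.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128) abort(sprintf("'%s' is too short to be a MAT-file.", path))
  head_txt <- rawToChar(raw[1:116][raw[1:116] != as.raw(0)])
  if (identical(as.integer(raw[1:4]), c(0x89L, 0x48L, 0x44L, 0x46L)) ||
      grepl("MATLAB 7.3", head_txt, fixed = TRUE)) {
    abort(sprintf(
      "'%s' is a MATLAB v7.3 (HDF5-based) file; this reader supports v5 only. Re-save with `save -v7` or convert (e.g. scipy.io).",
      path))
  }
  endian_tag <- rawToChar(raw[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI") "big" else
    abort(sprintf("'%s' is not a v5 MAT-file (bad endian indicator '%s').",
                  path, endian_tag))
  vars <- list()
  pos <- 129L
  n <- length(raw)
  while (pos + 7L <= n) {
    el <- mat_read_element(raw, pos, endian)
    if (el$type == 15L) { # miCOMPRESSED: payload is a zlib stream of one element
      payload <- memDecompress(el$data, type = "gzip")
      inner <- mat_read_element(payload, 1L, endian)
      v <- mat_parse_matrix(inner$data, endian)
    } else if (el$type == 14L) { # miMATRIX
      v <- mat_parse_matrix(el$data, endian)
    } else {
      abort(sprintf("Unexpected top-level element type %d in '%s'.", el$type, path))
    }
    if (!is.null(v)) vars[[v$name]] <- v$value
    pos <- el$next_pos
  }
  vars
}

# one tagged data element starting at `pos`; returns type, raw data, next_pos
mat_read_element <- function(raw, pos, endian) {
  word1 <- readBin(raw[pos:(pos + 3L)], "integer", 1, 4, endian = endian)
  small_len <- bitwAnd(bitwShiftR(word1, 16L), 0xffffL)
  if (small_len > 0L) { # small data element: type+len packed into 4 bytes
    type <- bitwAnd(word1, 0xffffL)
    data <- raw[(pos + 4L):(pos + 3L + small_len)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- word1
  nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, 4, endian = endian)
  data <- if (nbytes > 0) raw[(pos + 8L):(pos + 7L + nbytes)] else raw[0]
  nxt <- pos + 8L + nbytes
  # data elements align to 8-byte boundaries; miCOMPRESSED payloads may not
  if (type != 15L) nxt <- nxt + (-nxt + 1L) %% 8L
  list(type = type, data = data, next_pos = nxt)
}

mat_numeric_types <- list(
  `1` = list(what = "integer", size = 1, signed = TRUE),   # miINT8
  `2` = list(what = "integer", size = 1, signed = FALSE),  # miUINT8
  `3` = list(what = "integer", size = 2, signed = TRUE),   # miINT16
  `4` = list(what = "integer", size = 2, signed = FALSE),  # miUINT16
  `5` = list(what = "integer", size = 4, signed = TRUE),   # miINT32
  `6` = list(what = "integer", size = 4, signed = TRUE),   # miUINT32 (see fixup)
  `7` = list(what = "numeric", size = 4, signed = TRUE),   # miSINGLE
  `9` = list(what = "numeric", size = 8, signed = TRUE)    # miDOUBLE
)

mat_decode_numeric <- function(el, endian) {
  spec <- mat_numeric_types[[as.character(el$type)]]
  if (is.null(spec)) {
    abort(sprintf("Unsupported MAT data type %d (64-bit integers and UTF-16 payloads are not handled).",
                  el$type))
  }
  x <- readBin(el$data, spec$what, n = length(el$data) / spec$size,
               size = spec$size, signed = spec$signed, endian = endian)
  if (el$type == 6L) { # miUINT32 read as signed; fix negative wrap-around
    x <- as.numeric(x)
    x[x < 0] <- x[x < 0] + 2^32
  }
  as.numeric(x)
}

# parse the body of a miMATRIX element
mat_parse_matrix <- function(data, endian) {
  if (length(data) == 0) return(NULL) # empty element (e.g. written placeholder)
  flags_el <- mat_read_element(data, 1L, endian)
  flags <- readBin(flags_el$data[1:4], "integer", 1, 4, endian = endian)
  class_id <- bitwAnd(flags, 0xffL)
  if (bitwAnd(bitwShiftR(flags, 8L), 0x08L) != 0L) {
    abort("Complex MAT arrays are not supported.")
  }
  dims_el <- mat_read_element(data, flags_el$next_pos, endian)
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4, 4,
                  endian = endian)
  name_el <- mat_read_element(data, dims_el$next_pos, endian)
  name <- if (length(name_el$data)) {
    rawToChar(name_el$data[name_el$data != as.raw(0)])
  } else ""
  pos <- name_el$next_pos
  if (class_id == 1L) { # cell array
    n_cells <- prod(dims)
    value <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      el <- mat_read_element(data, pos, endian)
      if (el$type != 14L) abort("Malformed cell array: expected nested miMATRIX.")
      sub <- mat_parse_matrix(el$data, endian)
      value[[i]] <- if (is.null(sub)) numeric(0) else sub$value
      pos <- el$next_pos
    }
    dim(value) <- dims
  } else if (class_id == 4L) { # char array
    el <- mat_read_element(data, pos, endian)
    codes <- if (el$type %in% c(4L, 17L)) { # miUINT16 / miUTF16 code units
      readBin(el$data, "integer", length(el$data) / 2, 2, signed = FALSE,
              endian = endian)
    } else { # miUINT8 / miUTF8 / miINT8
      as.integer(el$data)
    }
    m <- matrix(codes, nrow = dims[1], ncol = prod(dims) / dims[1])
    value <- apply(m, 1, function(r) intToUtf8(r[r > 0]))
    if (length(value) == 0) value <- character(0)
  } else if (class_id %in% 5:13 && class_id != 5L) { # numeric classes
    el <- mat_read_element(data, pos, endian)
    value <- mat_decode_numeric(el, endian)
    if (length(dims) > 1 && prod(dims) == length(value)) dim(value) <- dims
  } else {
    abort(sprintf("Unsupported MAT array class %d (struct/object/sparse).",
                  class_id))
  }
  list(name = name, value = value)
}

#' Read electrode-level supplementary MAT datasets
#'
#' Parses one deposited electrode-level MAT-file (v5) holding, for one cohort
#' of subdural electrodes: per-category matrices of BGA means, BGA standard
#' deviations and observed d-prime indices (electrodes x 5), an electrode
#' coordinate matrix (electrodes x 3, Talairach mm), a category-name cell, and
#' a per-subject cell of stored shuffled d-prime indices (10,000 label
#' permutations per electrode). Variables are located by name pattern
#' (`coord`, `shuf`, `categ`, `mean`, `std`/`sd`, `dprime`) rather than exact
#' name, and electrode counts are cross-validated across variables. Subject
#' attribution is recovered from the per-subject cell lengths.
#'
#' @param path Path to one supplementary `.mat` file.
#' @param region,hemisphere Optional labels attached to the electrodes;
#'   hemisphere defaults to the sign of the x coordinate (negative = L), which
#'   also splits bilateral cohorts.
#' @return A list: `electrodes` (tibble with subject, hemisphere, region,
#'   x/y/z, and per-category columns of `d_prime`, `bga_mean`, `bga_sd`),
#'   `categories`, and `shuffles` (list, one 10,000 x 5 matrix per electrode).
#' @export
read_supplementary <- function(path, region = NA_character_, hemisphere = NULL) {
  vars <- read_mat(path)
  nms <- names(vars)
  pick <- function(pattern, multiple = FALSE) {
    hit <- grep(pattern, nms, ignore.case = TRUE, value = TRUE)
    if (!multiple && length(hit) > 1) hit <- hit[1]
    hit
  }
  coord_nm <- pick("coord")
  shuf_nm <- pick("shuf")
  cat_nm <- pick("categ")
  if (!length(coord_nm) || !length(shuf_nm)) {
    abort(sprintf(
      "'%s' does not look like a supplementary electrode dataset (no coordinate/shuffle variables among: %s).",
      path, paste(nms, collapse = ", ")))
  }
  coords <- vars[[coord_nm]]
  if (is.null(dim(coords)) || !3 %in% dim(coords)) {
    abort(sprintf("Coordinate variable '%s' is not an n x 3 matrix.", coord_nm))
  }
  if (ncol(coords) != 3) coords <- t(coords)
  n_el <- nrow(coords)
  categories <- if (length(cat_nm)) {
    as.character(unlist(vars[[cat_nm]]))
  } else {
    c("face", "animate", "place", "tool", "word")
  }
  k <- length(categories)

  shuffles <- mat_split_shuffles(vars[[shuf_nm]], n_el, k)
  per_cat <- function(pattern, exclude = character()) {
    hit <- setdiff(grep(pattern, nms, ignore.case = TRUE, value = TRUE), exclude)
    hit <- hit[vapply(vars[hit], function(v)
      is.numeric(v) && !is.null(dim(v)) && nrow(v) == n_el && ncol(v) == k,
      logical(1))]
    if (length(hit) != 1) return(NULL)
    vars[[hit]]
  }
  dp <- per_cat("dprime|d_prime", exclude = shuf_nm)
  bga_mean <- per_cat("mean")
  bga_sd <- per_cat("std|_sd")
  if (is.null(dp)) {
    abort(sprintf(
      "Schema error in '%s': no electrodes x categories d-prime matrix consistent with %d electrodes (variables: %s).",
      path, n_el, paste(nms, collapse = ", ")))
  }
  bad <- c(
    if (length(shuffles$subject) != n_el) "shuffle cell",
    if (!is.null(bga_mean) && nrow(bga_mean) != n_el) "BGA mean",
    if (!is.null(bga_sd) && nrow(bga_sd) != n_el) "BGA sd"
  )
  if (length(bad)) {
    abort(sprintf("Schema error in '%s': electrode counts disagree across variables (%s).",
                  path, paste(bad, collapse = ", ")))
  }
  if (is.null(hemisphere)) hemisphere <- ifelse(coords[, 1] < 0, "L", "R")
  el <- tibble(
    electrode = sprintf("e%03d", seq_len(n_el)),
    subject = sprintf("P%02d", shuffles$subject),
    hemisphere = rep_len(hemisphere, n_el),
    region = region,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  colnames(dp) <- categories
  out <- list(electrodes = el, d_prime = dp, categories = categories,
              shuffles = shuffles$per_electrode)
  if (!is.null(bga_mean)) { colnames(bga_mean) <- categories; out$bga_mean <- bga_mean }
  if (!is.null(bga_sd)) { colnames(bga_sd) <- categories; out$bga_sd <- bga_sd }
  out
}

# Split a per-subject cell of shuffled d-primes into one n_perm x k matrix per
# electrode, inferring which array dimension indexes electrodes / permutations
# / categories from their sizes.
mat_split_shuffles <- function(cell, n_el, k) {
  if (!is.list(cell)) abort("Shuffle variable is not a cell array.")
  cell <- cell[lengths(cell) > 0]
  per_el <- list()
  subject <- integer(0)
  for (s in seq_along(cell)) {
    a <- cell[[s]]
    d <- dim(a)
    if (is.null(d)) d <- c(length(a), 1)
    cat_dim <- which(d == k)
    if (!length(cat_dim)) {
      abort(sprintf("Shuffle cell %d has no dimension of size %d (categories).", s, k))
    }
    cat_dim <- cat_dim[length(cat_dim)]
    rest <- setdiff(seq_along(d), cat_dim)
    perm_dim <- rest[which.max(d[rest])] # permutations dominate (10,000)
    el_dim <- setdiff(rest, perm_dim)
    n_here <- if (length(el_dim)) d[el_dim] else 1L
    a <- aperm(array(a, d), c(perm_dim, cat_dim, el_dim))
    for (e in seq_len(n_here)) {
      m <- if (length(el_dim)) a[, , e] else a[, , drop = FALSE]
      per_el[[length(per_el) + 1]] <- matrix(m, ncol = k)
    }
    subject <- c(subject, rep(s, n_here))
  }
  if (length(per_el) != n_el) {
    abort(sprintf("Shuffle cell holds %d electrodes but coordinates list %d.",
                  length(per_el), n_el))
  }
  list(per_electrode = per_el, subject = subject)
}

#' Recompute selectivity and topology results from deposited matrices
#'
#' Given the deposited electrode-level MAT datasets (left VTC, right VTC, and
#' bilateral LOC cohorts), recomputes permutation p-values from the stored
#' shuffled d-prime indices, applies BH FDR at `q` within each
#' region x hemisphere family (categories and electrodes pooled), fits the
#' per-category random-intercept topology models on the stored d-prime values,
#' and runs the Spearman collinearity screen.
#'
#' @param vtc_left,vtc_right,loc Paths to the three MAT files.
#' @param q FDR level.
#' @param word_left_only Fit/flag the word category only in the left
#'   hemisphere (the word task was administered to the left cohort only).
#' @return A list: `selectivity` (electrode x category tibble with p and FDR
#'   flags), `counts` ([selectivity_counts()] output), `topology`
#'   ([topology_report()]), `screen`.
#' @export
reproduce_supplementary <- function(vtc_left, vtc_right, loc, q = 0.01,
                                    word_left_only = TRUE) {
  cohorts <- list(
    read_supplementary(vtc_left, region = "VTC", hemisphere = "L"),
    read_supplementary(vtc_right, region = "VTC", hemisphere = "R"),
    read_supplementary(loc, region = "LOC")
  )
  rows <- list()
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    el <- co$electrodes
    el$subject <- paste0("C", ci, "_", el$subject)
    el$electrode <- paste0("C", ci, "_", el$electrode)
    for (i in seq_len(nrow(el))) {
      p <- permutation_pvalue(co$d_prime[i, ], co$shuffles[[i]])
      rows[[length(rows) + 1]] <- tibble(
        electrode = el$electrode[i], subject = el$subject[i],
        hemisphere = el$hemisphere[i], region = el$region[i],
        x = el$x[i], y = el$y[i], z = el$z[i],
        category = co$categories, d_prime = co$d_prime[i, ], p_perm = p,
        n_perm = nrow(co$shuffles[[i]])
      )
    }
  }
  tab <- list_rbind(rows)
  if (word_left_only) {
    tab <- tab |> filter(!(.data$category == "word" & .data$hemisphere == "R"))
  }
  fam <- paste(tab$region, tab$hemisphere, sep = ":")
  fd <- fdr_correct(tab$p_perm, fam, q = q)
  tab$significant <- fd$significant
  tab$cutoff <- fd$cutoff
  geometry <- tab |>
    distinct(.data$electrode, .data$subject, .data$hemisphere, .data$region,
             .data$x, .data$y, .data$z)
  list(
    selectivity = tab,
    counts = selectivity_counts(tab),
    topology = topology_report(tab, geometry),
    screen = collinearity_screen(geometry)
  )
}
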