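#' Construct a spectra set
#'
#' The unit every pipeline stage consumes and produces: a shared axis, a
#' samples-by-channels intensity matrix, and a tibble of per-sample metadata.
#' Row i of the matrix is the spectrum of row i of the sample table.
#'
#' @param axis numeric, strictly monotone (wavenumber cm-1 or chemical shift
#'   ppm; instrument convention is descending, but all operations are
#'   orientation-agnostic).
#' @param intensities numeric matrix, one row per sample, `length(axis)`
#'   columns.
#' @param samples tibble/data.frame of per-sample metadata with a unique
#'   `sample_id` column.
#' @param modality free-text tag (`"ftir"`, `"nmr_medium"`, ...).
#' @param stages character record of processing stages already applied.
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(axis, intensities, samples, modality = "ftir",
                        stages = character()) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  if (length(axis) < 3L) abort("axis must have at least 3 channels")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) abort("axis must be strictly monotone")
  if (ncol(intensities) != length(axis)) {
    abort("intensity matrix must have one column per axis channel")
  }
  samples <- as_tibble(samples)
  if (nrow(samples) != nrow(intensities)) {
    abort("sample table must have one row per spectrum")
  }
  if (!"sample_id" %in% names(samples)) {
    abort("sample table must contain a 'sample_id' column")
  }
  if (anyDuplicated(samples$sample_id)) abort("sample_id values must be unique")
  rownames(intensities) <- samples$sample_id
  structure(list(axis = axis, intensities = intensities, samples = samples,
                 modality = modality, stages = stages),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d channels [%s], axis %.5g..%.5g\n",
              nrow(x$intensities), length(x$axis), x$modality,
              x$axis[1], x$axis[length(x$axis)]))
  if (length(x$stages)) cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  print(head(x$samples, 4))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$intensities)

#' Tidy a spectra set to long format
#'
#' @param x a [spectra_set()].
#' @param ... unused.
#' @return tibble with sample metadata, `axis` and `intensity` columns, one
#'   row per (sample, channel).
#' @export
as_tibble.spectra_set <- function(x, ...) {
  wide <- as_tibble(x$intensities, .name_repair = "minimal")
  names(wide) <- as.character(x$axis)
  dplyr::bind_cols(x$samples, wide) |>
    tidyr::pivot_longer(cols = -names(x$samples),
                        names_to = "axis", values_to = "intensity") |>
    dplyr::mutate(axis = as.numeric(.data$axis))
}

record_stage <- function(s, stage) {
  s$stages <- c(s$stages, stage)
  s
}

#' Write a spectra set to CSV (+ samples TSV)
#'
#' The CSV holds the axis in the first column and one column per sample; the
#' sample table goes to `<stem>_samples.tsv`. The pair round-trips through
#' [read_spectra()] to 1e-9.
#'
#' @param s a [spectra_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  m <- data.frame(axis = s$axis, t(s$intensities), check.names = FALSE)
  names(m) <- c("axis", s$samples$sample_id)
  write.csv(m, path, row.names = FALSE)
  meta_path <- sub("\\.csv$", "_samples.tsv", path)
  utils::write.table(s$samples, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read spectra from CSV or JCAMP-DX
#'
#' CSV layout: first column the axis, remaining columns one spectrum each
#' (the layout written by [write_spectra()]); a sibling
#' `<stem>_samples.tsv` is joined as sample metadata when present. JCAMP-DX
#' supports single-spectrum XYDATA `(X++(Y..Y))` records in AFFN form.
#'
#' @param path file path.
#' @param format `"csv"` or `"jcampdx"`.
#' @param modality modality tag for the returned set.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, format = c("csv", "jcampdx"),
                         modality = "ftir") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "jcampdx") return(read_jcampdx(path, modality = modality))
  m <- read.csv(path, check.names = FALSE)
  if (ncol(m) < 2L) abort("CSV must have an axis column plus >= 1 spectrum")
  axis <- m[[1]]
  if (anyNA(axis)) abort("axis column contains non-numeric values")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) {
    abort("axis must be strictly monotone (repeated or unordered values)")
  }
  x <- t(as.matrix(m[-1]))
  if (anyNA(x)) abort("ragged or non-numeric intensity columns")
  ids <- colnames(m)[-1]
  meta_path <- sub("\\.csv$", "_samples.tsv", path)
  samples <- if (file.exists(meta_path)) {
    tab <- as_tibble(read.csv(meta_path, sep = "\t"))
    if (!"sample_id" %in% names(tab)) abort("samples table lacks 'sample_id'")
    tab[match(ids, tab$sample_id), , drop = FALSE]
  } else {
    tibble(sample_id = ids)
  }
  spectra_set(axis, x, samples, modality = modality)
}

# Minimal JCAMP-DX reader: single spectrum, ##XYDATA=(X++(Y..Y)), AFFN
# (plain decimal) values only. XFACTOR/YFACTOR honored; axis rebuilt from
# FIRSTX/LASTX/NPOINTS.
read_jcampdx <- function(path, modality = "ftir") {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^##", key, "="), "", ln[[1]]))
  }
  xy <- grep("^##XYDATA=", lines)
  if (!length(xy)) abort("JCAMP-DX: no ##XYDATA record")
  form <- get_field("XYDATA")
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form)) {
    abort("JCAMP-DX: only (X++(Y..Y)) XYDATA supported")
  }
  xf <- as.numeric(get_field("XFACTOR")); if (is.na(xf)) xf <- 1
  yf <- as.numeric(get_field("YFACTOR")); if (is.na(yf)) yf <- 1
  firstx <- as.numeric(get_field("FIRSTX"))
  lastx <- as.numeric(get_field("LASTX"))
  npt <- as.integer(get_field("NPOINTS"))
  body <- lines[(xy + 1):length(lines)]
  end <- grep("^##", body)
  if (length(end)) body <- body[seq_len(end[1] - 1L)]
  ys <- lapply(strsplit(trimws(body), "[ \t]+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) abort("JCAMP-DX: non-AFFN data encountered")
    v[-1] * yf  # first token per line is the running X value
  })
  y <- unlist(ys, use.names = FALSE)
  if (!is.na(npt) && length(y) != npt) {
    abort(sprintf("JCAMP-DX: NPOINTS=%d but %d Y values read", npt, length(y)))
  }
  axis <- seq(firstx * xf, lastx * xf, length.out = length(y))
  id <- get_field("TITLE"); if (is.na(id) || !nzchar(id)) id <- "jcamp_1"
  spectra_set(axis, matrix(y, nrow = 1), tibble(sample_id = id),
              modality = modality)
}
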