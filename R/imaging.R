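#' Sum z-projection of a fluorescence stack
#'
#' Pixelwise sum of intensities over the z axis.
#'
#' @param stack numeric array indexed (z, row, col); >= 1 slice,
#'   nonnegative intensities.
#' @return matrix (row, col).
#' @export
z_project_sum <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[1] < 1L) {
    abort("stack must be a (z, row, col) array with >= 1 slice")
  }
  apply(stack, c(2, 3), sum)
}

#' Corrected total cell fluorescence of one nucleus
#'
#' `CTCF = sum(image[nucleus]) - n_nucleus_pixels * mean(image[background])`:
#' the integrated nuclear intensity minus the area-scaled mean of the
#' adjacent background. Exactly zero on a uniform image; invariant to adding
#' a constant to the whole image; linear in intensity scaling.
#'
#' @param image projected image matrix.
#' @param nucleus logical mask of the nucleus (>= 1 pixel).
#' @param background logical mask of adjacent background; must be non-empty
#'   and disjoint from `nucleus`.
#' @return CTCF value.
#' @export
compute_ctcf <- function(image, nucleus, background) {
  if (!any(background)) abort("background mask is empty")
  if (!any(nucleus)) abort("nucleus mask is empty")
  if (any(nucleus & background)) abort("nucleus and background masks overlap")
  if (!all(dim(nucleus) == dim(image)) || !all(dim(background) == dim(image))) {
    abort("masks must match the image shape")
  }
  sum(image[nucleus]) - sum(nucleus) * mean(image[background])
}

#' Default adjacent-background mask: a dilation ring
#'
#' Builds the standard automated analogue of a manually drawn "adjacent
#' background" region: the ring obtained by dilating the nucleus mask with a
#' square structuring element of the given radius and removing every nucleus
#' pixel (all nuclei if `exclude` is supplied).
#'
#' @param nucleus logical nucleus mask.
#' @param radius dilation radius in pixels (default 2).
#' @param exclude optional logical mask of all nuclei to exclude from the
#'   ring (defaults to `nucleus`).
#' @return logical background mask.
#' @export
background_annulus <- function(nucleus, radius = 2, exclude = nucleus) {
  d <- dim(nucleus)
  dil <- matrix(FALSE, d[1], d[2])
  idx <- which(nucleus, arr.ind = TRUE)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    r <- idx[, 1] + dr; c_ <- idx[, 2] + dc
    ok <- r >= 1 & r <= d[1] & c_ >= 1 & c_ <= d[2]
    dil[cbind(r[ok], c_[ok])] <- TRUE
  }
  dil & !exclude
}

#' Quantify CTCF for a set of generated or loaded stacks
#'
#' Sum-projects each stack, builds the default background ring, and computes
#' per-nucleus CTCF.
#'
#' @param stacks list as produced by [generate_nucleus_stacks()] (`$stacks`
#'   element): each item holds `stack`, `nucleus_mask`, `nucleus_id`.
#' @param truth optional tibble with per-nucleus metadata to join
#'   (`nucleus_id`, `passage`, `experiment`, ...).
#' @param annulus_radius background ring radius in pixels.
#' @return tibble with `nucleus_id`, `ctcf` and any joined metadata.
#' @export
quantify_ctcf <- function(stacks, truth = NULL, annulus_radius = 2) {
  res <- purrr::map_dfr(stacks, function(it) {
    img <- z_project_sum(it$stack)
    bg <- background_annulus(it$nucleus_mask, annulus_radius)
    tibble(nucleus_id = it$nucleus_id,
           ctcf = compute_ctcf(img, it$nucleus_mask, bg))
  })
  if (!is.null(truth)) res <- dplyr::left_join(res, truth, by = "nucleus_id")
  res
}

#' Summarize CTCF by passage
#'
#' Per-passage mean and sd plus per-(passage, experiment) counts; the table
#' handed to the group-comparison stage.
#'
#' @param df tibble with `ctcf`, `passage`, `experiment` columns.
#' @return list with `by_passage` (passage, n, mean, sd) and `counts`
#'   (passage, experiment, n).
#' @export
summarize_ctcf <- function(df) {
  for (col in c("ctcf", "passage", "experiment")) {
    if (!col %in% names(df)) abort(paste("missing column:", col))
  }
  list(
    by_passage = df |> dplyr::group_by(.data$passage) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$ctcf),
                       sd = sd(.data$ctcf), .groups = "drop"),
    counts = df |> dplyr::count(.data$passage, .data$experiment)
  )
}

#' Write / read a stack as multi-page TIFF
#'
#' Thin wrappers over the tiff package (float32 pages), for interoperability
#' with image-analysis tools; the analysis itself works on in-memory arrays.
#'
#' @param stack (z, row, col) array.
#' @param path file path.
#' @return `path` (write) or a (z, row, col) array (read).
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O")
  }
  pages <- lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ])
  mx <- max(unlist(pages), 1)
  tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                  bits.per.sample = 32L)
  attr(path, "scale") <- mx
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  out
}
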