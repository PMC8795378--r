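#' Compress a raw grayscale image to the standard LDP grid
#'
#' Block-mean pooling onto the 18 x 40 LDP grid: each source pixel is
#' assigned to one target cell (splitting each axis as evenly as possible)
#' and every cell takes the arithmetic mean of its block, rounded to an
#' integer gray value. Mean pooling preserves average brightness, which is
#' what makes gray values usable as irradiance proxies; an already-compressed
#' 18 x 40 image passes through unchanged.
#'
#' @param raw_image numeric matrix, at least `rows x cols`, gray values in
#'   `[0, 255]`.
#' @param rows,cols target grid (default 18 x 40).
#' @return Integer `rows x cols` matrix.
#' @export
compress_to_ldp <- function(raw_image, rows = 18L, cols = 40L) {
  stopifnot(is.matrix(raw_image))
  h <- nrow(raw_image); w <- ncol(raw_image)
  if (h < rows || w < cols) {
    stop(sprintf("image (%d x %d) smaller than target grid (%d x %d)",
                 h, w, rows, cols), call. = FALSE)
  }
  row_grp <- floor((seq_len(h) - 1L) * rows / h) + 1L
  col_grp <- floor((seq_len(w) - 1L) * cols / w) + 1L
  sums <- rowsum(raw_image, row_grp)
  sums <- t(rowsum(t(sums), col_grp))
  counts <- tabulate(row_grp, rows) %o% tabulate(col_grp, cols)
  out <- round(clip(sums / counts, 0, 255))
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Fit the gray-value / irradiance calibration
#'
#' Ordinary least-squares lines `gsv ~ irradiance`, one per cell
#' concentration, quantifying how faithfully gray values track irradiance.
#' Saturated readings (`gsv >= saturation`) are excluded before fitting,
#' since clipping breaks the linear response. Concentrations left with fewer
#' than 3 usable samples are flagged and excluded from the mean R-squared.
#'
#' @param samples data frame with columns `gsv`, `irradiance`,
#'   `concentration`.
#' @param saturation gray value treated as clipped (default 255).
#' @return A `gsv_calibration`: list with `per_concentration` (data frame of
#'   `concentration`, `slope`, `intercept`, `r2`, `n`, `flagged`) and
#'   `mean_r2`, the arithmetic mean R-squared over unflagged fits.
#' @export
fit_gsv_calibration <- function(samples, saturation = 255) {
  stopifnot(is.data.frame(samples),
            all(c("gsv", "irradiance", "concentration") %in% names(samples)))
  samples <- samples[samples$gsv < saturation, , drop = FALSE]
  concs <- sort(unique(samples$concentration))
  fits <- lapply(concs, function(cc) {
    sub <- samples[samples$concentration == cc, , drop = FALSE]
    if (nrow(sub) < 3L || length(unique(sub$irradiance)) < 2L) {
      return(data.frame(concentration = cc, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_,
                        n = nrow(sub), flagged = TRUE))
    }
    fit <- stats::lm(gsv ~ irradiance, data = sub)
    data.frame(concentration = cc,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               # computed directly: summary.lm() warns on perfect fits,
               # which are routine for noise-free calibration samples
               r2 = r_squared(sub$gsv, unname(stats::fitted(fit))),
               n = nrow(sub), flagged = FALSE)
  })
  per <- do.call(rbind, fits)
  structure(
    list(per_concentration = per,
         mean_r2 = mean(per$r2[!per$flagged])),
    class = "gsv_calibration")
}

#' @export
print.gsv_calibration <- function(x, ...) {
  ok <- !x$per_concentration$flagged
  cat(sprintf("gsv_calibration: %d concentrations (%d flagged), mean R2 = %.3f\n",
              nrow(x$per_concentration), sum(!ok), x$mean_r2))
  invisible(x)
}

#' Dark-area fraction of an LDP
#'
#' Fraction of pixels strictly below the dark threshold. The default
#' threshold of 25.5 gray units is 10% of the maximal 8-bit value; pixels
#' below it are considered too dark to support photosynthesis, making this
#' the standard mutual-shading statistic for an LDP.
#'
#' @param ldp gray-value matrix.
#' @param threshold dark threshold in gray units, default 25.5.
#' @return Fraction in `[0, 1]`.
#' @examples
#' dark_area_fraction(matrix(0L, 18, 40))    # 1
#' dark_area_fraction(matrix(255L, 18, 40))  # 0
#' @export
dark_area_fraction <- function(ldp, threshold = 25.5) {
  stopifnot(is.matrix(ldp), threshold > 0, threshold < 255)
  mean(ldp < threshold)
}

#' Read / write an LDP as an 8-bit grayscale PNG
#'
#' @param ldp integer gray-value matrix in `[0, 255]`.
#' @param path PNG file path.
#' @return `write_ldp_png()` returns `path` invisibly; `read_ldp_png()`
#'   returns an integer gray matrix.
#' @export
write_ldp_png <- function(ldp, path) {
  stopifnot(is.matrix(ldp), all(ldp >= 0), all(ldp <= 255))
  png::writePNG(ldp / 255, target = path)
  invisible(path)
}

#' @rdname write_ldp_png
#' @export
read_ldp_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}
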