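#' Read a grayscale image as an 8-bit integer matrix
#'
#' PNG and TIFF are supported. Multi-channel images take the requested
#' channel (default the first / red). Values are mapped to 0..255; inputs
#' of higher bit depth are rescaled by a linear min-max mapping, which is
#' recorded in the attributes.
#'
#' @param path image file path.
#' @param channel channel index for multi-channel images.
#' @return integer matrix in 0..255 with attributes `rescaled`, `from`.
#' @export
read_gray8 <- function(path, channel = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , channel]
  # png/tiff readers return [0,1]; recover the 8-bit scale
  m <- round(img * 255)
  rescaled <- FALSE
  rng <- range(m)
  if (rng[2] > 255) { # 16-bit source: linear min-max to 0..255
    m <- round((m - rng[1]) / max(rng[2] - rng[1], 1) * 255)
    rescaled <- TRUE
  }
  storage.mode(m) <- "integer"
  attr(m, "rescaled") <- rescaled
  attr(m, "from") <- rng
  m
}

#' Median filter with edge replication
#'
#' Per-pixel median over an odd square window; pixels beyond the border
#' are replicated from the nearest edge. Idempotent on constant images and
#' removes isolated hot pixels.
#'
#' @param image numeric or integer matrix (single channel).
#' @param window odd window side length (default 3).
#' @return Filtered matrix of the same dimensions and mode.
#' @export
median_filter_channel <- function(image, window = 3) {
  if (window %% 2 == 0) stop("window size must be odd", call. = FALSE)
  h <- (window - 1) %/% 2
  nr <- nrow(image)
  nc <- ncol(image)
  # edge-replicated padding
  ri <- pmin(pmax(seq_len(nr + 2 * h) - h, 1), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * h) - h, 1), nc)
  pad <- image[ri, ci, drop = FALSE]
  # stack all window offsets and take the median across the stack
  stack <- vapply(seq_len(window) - 1, function(dy) {
    vapply(seq_len(window) - 1, function(dx) {
      pad[dx + seq_len(nr), dy + seq_len(nc), drop = FALSE]
    }, matrix(0, nr, nc))
  }, array(0, c(nr, nc, window)))
  dim(stack) <- c(nr, nc, window * window)
  out <- apply(stack, c(1, 2), median)
  if (is.integer(image)) storage.mode(out) <- "integer"
  out
}

#' Pixel-intensity distribution of an 8-bit image
#'
#' Fluorescence intensity is divided into 256 bins (pixel values 0..255).
#' For each bin the raw count, the relative frequency, and a pseudocounted
#' log value `log10(1 + count/total)` are reported; absent bins therefore
#' map to 0 and every value is bounded by log10(2).
#'
#' @param image integer matrix with values in 0..255 (see [read_gray8()]).
#' @return A `pixel_distribution` tibble (intensity, count, frequency,
#'   log_pseudo).
#' @export
pixel_histogram <- function(image) {
  v <- as.vector(image)
  if (length(v) == 0) stop("empty image", call. = FALSE)
  if (any(v < 0 | v > 255)) {
    stop("pixel values outside 0..255; rescale first", call. = FALSE)
  }
  cnt <- tabulate(v + 1L, nbins = 256L)
  freq <- cnt / length(v)
  structure(tibble::tibble(intensity = 0:255, count = cnt,
                           frequency = freq,
                           log_pseudo = log10(1 + freq)),
            class = c("pixel_distribution", class(tibble::tibble())),
            n_pixels = length(v), log_base = 10)
}

#' Spatiotemporal heat-map matrix of an imaging time course
#'
#' One column per labeled day: the pseudocounted pixel-intensity
#' distribution of that day's image. Missing days between the first and
#' last label appear as all-NA gap columns.
#'
#' @param images named list of 8-bit image matrices; names are day labels
#'   (coercible to integers, e.g. `"4"` for day 4).
#' @param fill_gaps insert NA columns for unobserved intermediate days.
#' @return 256 x days numeric matrix (rownames intensities, colnames
#'   days).
#' @export
timecourse_heatmap <- function(images, fill_gaps = TRUE) {
  stopifnot(length(images) >= 1)
  days <- as.integer(names(images))
  if (anyNA(days)) stop("image names must be integer day labels",
                        call. = FALSE)
  if (anyDuplicated(days)) {
    stop("duplicate day labels: ",
         paste(unique(days[duplicated(days)]), collapse = ", "),
         call. = FALSE)
  }
  o <- order(days)
  days <- days[o]
  images <- images[o]
  all_days <- if (fill_gaps) seq(min(days), max(days)) else days
  mat <- matrix(NA_real_, nrow = 256, ncol = length(all_days),
                dimnames = list(0:255, all_days))
  for (i in seq_along(days)) {
    mat[, as.character(days[i])] <-
      pixel_histogram(images[[i]])$log_pseudo
  }
  mat
}

#' Write a heat-map matrix as TSV (and optionally render it)
#'
#' @param mat matrix from [timecourse_heatmap()].
#' @param prefix output prefix; writes `<prefix>.tsv` and, when ggplot2 is
#'   available and `render = TRUE`, `<prefix>.png`.
#' @param render render a PNG heat map.
#' @return Invisibly, the TSV path.
#' @export
write_heatmap <- function(mat, prefix, render = FALSE) {
  tsv <- paste0(prefix, ".tsv")
  write.table(mat, tsv, sep = "\t", quote = FALSE, col.names = NA)
  if (render && requireNamespace("ggplot2", quietly = TRUE)) {
    df <- expand.grid(intensity = as.integer(rownames(mat)),
                      day = as.integer(colnames(mat)))
    df$value <- as.vector(mat)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$intensity,
                                          fill = .data$value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(na.value = "grey90") +
      ggplot2::labs(x = "day", y = "fluorescence intensity (8-bit bin)",
                    fill = "log10(1 + freq)")
    ggplot2::ggsave(paste0(prefix, ".png"), p, width = 6, height = 4,
                    dpi = 150)
  }
  invisible(tsv)
}
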