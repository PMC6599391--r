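#' Ordered sorting-bin labels
#'
#' The five subpopulations cells are sorted into, ordered by fluorescence:
#' negative, low, high, top 5-10%, top 5%.
#' @export
BIN_LEVELS <- c("negative", "low", "high", "top5to10", "top5")

new_bin_scheme <- function(bin, lo, hi, ybar) {
  sch <- tibble::tibble(bin = factor(bin, levels = BIN_LEVELS),
                        lo = lo, hi = hi, ybar = ybar)
  if (any(diff(sch$ybar) <= 0)) {
    stop("per-bin mean fluorescence must be strictly increasing across bins",
         call. = FALSE)
  }
  structure(sch, class = c("bin_scheme", class(sch)))
}

#' Derive the five-gate bin scheme from sorting samples
#'
#' Mirrors the two-round sort: the negative gate sits at a high quantile of
#' an uninfected-control sample; cells above it are "fluorescence positive".
#' Among positives, the top 5% and top 5-10% gates sit at the 95th and 90th
#' percentiles, and the remaining 90% of positives are split into equal
#' low/high halves at their median. Per-bin mean fluorescence (`ybar`) is
#' the mean of the cells falling inside each gate.
#'
#' @param positive_fluor per-cell fluorescence (a.u., linear scale) of the
#'   library-infected population.
#' @param control_fluor per-cell fluorescence of the uninfected control.
#' @param neg_quantile quantile of the control sample defining the negative
#'   gate (default 0.995).
#' @return A `bin_scheme`: tibble with bin, half-open interval `[lo, hi)`,
#'   and `ybar`.
#' @export
derive_gates <- function(positive_fluor, control_fluor,
                         neg_quantile = 0.995) {
  stopifnot(length(positive_fluor) > 0, length(control_fluor) > 0)
  neg_cut <- unname(quantile(control_fluor, neg_quantile, type = 7))
  pos <- positive_fluor[positive_fluor >= neg_cut]
  if (length(pos) < 20) {
    stop("fewer than 20 fluorescence-positive cells; ",
         "5% gates are undefined", call. = FALSE)
  }
  q95 <- unname(quantile(pos, 0.95, type = 7))
  q90 <- unname(quantile(pos, 0.90, type = 7))
  rest <- pos[pos < q90]
  mid <- unname(median(rest))
  breaks <- c(neg_cut, mid, q90, q95)

  all_cells <- c(positive_fluor, control_fluor)
  lo <- c(-Inf, breaks)
  hi <- c(breaks, Inf)
  ybar <- vapply(seq_along(lo), function(i) {
    mean(all_cells[all_cells >= lo[i] & all_cells < hi[i]])
  }, numeric(1))
  if (any(!is.finite(ybar))) {
    stop("one or more gates contain no cells; cannot compute per-bin ",
         "mean fluorescence", call. = FALSE)
  }
  new_bin_scheme(BIN_LEVELS, lo, hi, ybar)
}

#' Assign fluorescence values to sorting bins
#'
#' @param fluor numeric vector of per-cell fluorescence (a.u.).
#' @param scheme a `bin_scheme`.
#' @return factor of bin labels with levels [BIN_LEVELS].
#' @export
assign_bins <- function(fluor, scheme) {
  idx <- findInterval(fluor, c(scheme$lo[1], scheme$hi))
  idx[idx < 1] <- 1
  idx[idx > nrow(scheme)] <- nrow(scheme)
  factor(as.character(scheme$bin)[idx], levels = BIN_LEVELS)
}
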