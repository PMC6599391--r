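#' Simulate per-promoter ground truth for a screen
#'
#' Each construct is either silent (reporter expression indistinguishable
#' from autofluorescence) or active with a log2 median reporter
#' fluorescence drawn uniformly over `active_range`. Non-planted constructs
#' share their activity across states; planted state-specific constructs
#' are active in their target state only, giving them a large
#' fold-difference against the silent background.
#'
#' @param n_constructs number of constructs.
#' @param states character vector of cell-state labels.
#' @param frac_active fraction of non-planted constructs that are active
#'   (in all states).
#' @param n_specific named integer vector (names in `states`): how many
#'   planted constructs are specific to each state.
#' @param active_range log2 a.u. range for active medians.
#' @param specific_range log2 a.u. range for planted-specific medians in
#'   their target state.
#' @param sigma per-cell spread of log2 fluorescence (cytometry lognormal).
#' @param bg_median,bg_sigma autofluorescence log2 median and spread.
#' @param bio_sd biological-replicate perturbation of active medians
#'   (log2 units).
#' @param seed integer seed.
#' @return A `specs_truth`: tibble (construct_id, state, log2_median with
#'   -Inf meaning silent, log2_total_median including autofluorescence,
#'   specific flag) with noise parameters as attributes.
#' @export
simulate_truth <- function(n_constructs, states = c("A", "B"),
                           frac_active = 0.4, n_specific = NULL,
                           active_range = c(7, 16),
                           specific_range = c(10.5, 15.5),
                           sigma = 0.8, bg_median = 6, bg_sigma = 0.4,
                           bio_sd = 0.5, seed = 1L) {
  set.seed(seed)
  if (is.null(n_specific)) {
    n_specific <- stats::setNames(rep(0L, length(states)), states)
  }
  stopifnot(all(names(n_specific) %in% states),
            sum(n_specific) <= n_constructs)
  ids <- sprintf("SP%05d", seq_len(n_constructs))

  m <- matrix(-Inf, nrow = n_constructs, ncol = length(states),
              dimnames = list(ids, states))
  specific_to <- rep(NA_character_, n_constructs)

  k <- 0L
  for (s in names(n_specific)) {
    if (n_specific[[s]] == 0) next
    rows <- k + seq_len(n_specific[[s]])
    m[rows, s] <- runif(length(rows), specific_range[1], specific_range[2])
    specific_to[rows] <- s
    k <- k + n_specific[[s]]
  }
  plain <- seq(k + 1L, length.out = n_constructs - k)
  active <- plain[runif(length(plain)) < frac_active]
  m[active, ] <- runif(length(active), active_range[1], active_range[2])

  truth <- tidyr::expand_grid(construct_id = ids, state = states)
  truth$log2_median <- m[cbind(truth$construct_id, truth$state)]
  truth$log2_total_median <- log2(2^truth$log2_median + 2^bg_median)
  truth$specific_to <- specific_to[match(truth$construct_id, ids)]
  structure(truth, class = c("specs_truth", class(truth)),
            sigma = sigma, bg_median = bg_median, bg_sigma = bg_sigma,
            bio_sd = bio_sd, seed = seed)
}

# per-cell total fluorescence (linear a.u.): reporter + autofluorescence
draw_cells <- function(log2_medians, n_cells, sigma, bg_median, bg_sigma) {
  n <- length(log2_medians) * n_cells
  auto <- 2^rnorm(n, rep(bg_median, n), bg_sigma)
  rep_m <- rep(log2_medians, each = n_cells)
  expr <- ifelse(is.finite(rep_m), 2^rnorm(n, rep_m, sigma), 0)
  matrix(expr + auto, ncol = n_cells, byrow = TRUE)
}

#' Simulate a FACS-binned sequencing screen
#'
#' Per cell, log2 fluorescence is Normal around the construct's true median
#' (lognormal in linear units) on top of autofluorescence; cells are
#' assigned to the five sorting bins by gates derived from a pooled
#' infected sample against an uninfected control. Each sequencing sample
#' (state x replicate x bin) draws exactly `depth` reads from a multinomial
#' over the constructs' bin occupancies. Technical replicates resample
#' sequencing only; biological replicates additionally perturb the true
#' medians by Normal(0, `bio_sd`) noise.
#'
#' @param truth a `specs_truth` from [simulate_truth()].
#' @param depth sequencing depth per sample (reads), default 1e6.
#' @param cells_per_construct sorted cells per construct per biological
#'   replicate (default 200, keeping >100-fold library coverage).
#' @param infection_rate fraction of cells carrying a construct; sets the
#'   size of the uninfected fraction used when deriving gates.
#' @param n_bio,n_tech biological replicates per state and technical
#'   (resequencing) replicates per biological replicate.
#' @param seed integer seed.
#' @return A `specs_screen`: list with `counts` (tibble construct_id,
#'   state, replicate, bio_rep, tech_rep, bin, count), `gates` (bin_scheme
#'   per state), `truth`, and the configuration.
#' @export
simulate_screen <- function(truth, depth = 1e6, cells_per_construct = 200,
                            infection_rate = 0.15, n_bio = 2, n_tech = 1,
                            seed = 1L) {
  stopifnot(inherits(truth, "specs_truth"))
  if (depth <= 0) stop("sequencing depth must be positive", call. = FALSE)
  if (cells_per_construct < 100) {
    warning("cells_per_construct < 100 drops coverage below 100-fold",
            call. = FALSE)
  }
  sigma <- attr(truth, "sigma")
  bg_median <- attr(truth, "bg_median")
  bg_sigma <- attr(truth, "bg_sigma")
  bio_sd <- attr(truth, "bio_sd")
  set.seed(seed)

  states <- unique(truth$state)
  ids <- unique(truth$construct_id)
  gates <- list()
  out <- list()

  for (s in states) {
    m <- truth$log2_median[truth$state == s][match(ids,
      truth$construct_id[truth$state == s])]

    # gate derivation: pooled infected sample vs uninfected control
    pool <- as.vector(draw_cells(m, 50L, sigma, bg_median, bg_sigma))
    n_ctrl <- max(2e4, round(length(pool) * (1 - infection_rate) /
                               max(infection_rate, 1e-3)))
    ctrl <- 2^rnorm(n_ctrl, bg_median, bg_sigma)
    neg_cut <- quantile(ctrl, 0.995)
    sch <- derive_gates(pool[pool >= neg_cut], ctrl)
    gates[[s]] <- sch

    for (b in seq_len(n_bio)) {
      m_b <- m + ifelse(is.finite(m), rnorm(length(m), 0, bio_sd), 0)
      cells <- draw_cells(m_b, cells_per_construct, sigma, bg_median,
                          bg_sigma)
      bins <- assign_bins(as.vector(t(cells)), sch)
      occ <- table(factor(rep(ids, each = cells_per_construct),
                          levels = ids), bins)
      for (tr in seq_len(n_tech)) {
        for (bn in BIN_LEVELS) {
          o <- occ[, bn]
          cnt <- if (sum(o) == 0) rep(0L, length(ids))
                 else as.integer(rmultinom(1, depth, o / sum(o)))
          out[[length(out) + 1]] <- tibble::tibble(
            construct_id = ids, state = s,
            replicate = sprintf("b%d.t%d", b, tr),
            bio_rep = b, tech_rep = tr, bin = bn, count = cnt)
        }
      }
    }
  }
  counts <- dplyr::bind_rows(out)
  counts$bin <- factor(counts$bin, levels = BIN_LEVELS)
  structure(list(counts = counts, gates = gates, truth = truth,
                 depth = depth, cells_per_construct = cells_per_construct,
                 infection_rate = infection_rate, n_bio = n_bio,
                 n_tech = n_tech, seed = seed),
            class = "specs_screen")
}

#' @exportS3Method base::print
print.specs_screen <- function(x, ...) {
  cat("<specs_screen> ", length(unique(x$counts$construct_id)),
      " constructs x ", length(x$gates), " states, ",
      x$n_bio, " bio x ", x$n_tech, " tech replicates, depth ",
      format(x$depth, scientific = FALSE), "/sample\n", sep = "")
  invisible(x)
}

#' Simulate per-cell calibration event tables
#'
#' Emulates measuring fluorescence for single promoters from the library:
#' for each chosen construct and state, draws `n_events` per-cell total
#' fluorescence values from the (unperturbed) ground truth.
#'
#' @param truth a `specs_truth`.
#' @param construct_ids constructs to measure.
#' @param n_events cells per construct per state.
#' @param seed integer seed.
#' @return tibble (construct_id, state, fluorescence); one row per cell.
#' @export
simulate_calibration <- function(truth, construct_ids, n_events = 2000,
                                 seed = 1L) {
  stopifnot(inherits(truth, "specs_truth"))
  set.seed(seed)
  sub <- truth[truth$construct_id %in% construct_ids, ]
  cells <- draw_cells(sub$log2_median, n_events, attr(truth, "sigma"),
                      attr(truth, "bg_median"), attr(truth, "bg_sigma"))
  tibble::tibble(
    construct_id = rep(sub$construct_id, each = n_events),
    state = rep(sub$state, each = n_events),
    fluorescence = as.vector(t(cells)))
}

#' Emit simulated FASTQ reads for a screen
#'
#' Writes one FASTQ per sequencing sample, one read per count. Each read is
#' the construct's variable region followed by the AscI site, barcode and
#' 3' flank, with independent per-base substitution errors; a configurable
#' fraction of reads is replaced by junk lacking the restriction site.
#' Also writes a `samples.tsv` sheet mapping files to (state, replicate,
#' bin).
#'
#' @param screen a `specs_screen`.
#' @param library a `specs_library` containing every counted construct.
#' @param dir output directory (created if missing).
#' @param error_rate per-base substitution probability.
#' @param junk_frac fraction of reads replaced by junk reads without the
#'   AscI site.
#' @param seed integer seed.
#' @return Invisibly, the sample sheet tibble (with a `file` column).
#' @export
emit_reads <- function(screen, library, dir, error_rate = 0,
                       junk_frac = 0, seed = 1L) {
  stopifnot(inherits(screen, "specs_screen"),
            inherits(library, "specs_library"))
  missing_ids <- setdiff(unique(screen$counts$construct_id),
                         library$construct_id)
  if (length(missing_ids) > 0) {
    stop("constructs absent from library: ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  tail3 <- paste0(ASCI_SITE, library$barcode, attr(library, "flank3"))
  read_of <- stats::setNames(paste0(library$variable_region, tail3),
                             library$construct_id)
  med_len <- round(median(nchar(read_of)))

  samples <- dplyr::distinct(screen$counts, .data$state, .data$replicate,
                             .data$bio_rep, .data$tech_rep, .data$bin)
  samples$file <- file.path(dir, sprintf("%s_%s_%s.fastq", samples$state,
                                         samples$replicate, samples$bin))
  for (i in seq_len(nrow(samples))) {
    sub <- screen$counts[screen$counts$state == samples$state[i] &
                           screen$counts$replicate == samples$replicate[i] &
                           screen$counts$bin == samples$bin[i], ]
    reads <- rep(read_of[sub$construct_id], sub$count)
    if (junk_frac > 0 && length(reads) > 0) {
      is_junk <- runif(length(reads)) < junk_frac
      n_junk <- sum(is_junk)
      if (n_junk > 0) {
        junk <- random_dna(n_junk, med_len)
        redo <- grepl(ASCI_SITE, junk, fixed = TRUE)
        while (any(redo)) {
          junk[redo] <- random_dna(sum(redo), med_len)
          redo <- grepl(ASCI_SITE, junk, fixed = TRUE)
        }
        reads[is_junk] <- junk
      }
    }
    reads <- mutate_reads(unname(reads), error_rate)
    dss <- Biostrings::DNAStringSet(reads)
    if (length(dss) > 0) {
      names(dss) <- sprintf("read%07d", seq_along(dss))
    }
    Biostrings::writeXStringSet(
      dss, samples$file[i], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  }
  sheet <- samples[, c("file", "state", "replicate", "bio_rep",
                       "tech_rep", "bin")]
  write.table(as.data.frame(sheet), file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sheet)
}
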