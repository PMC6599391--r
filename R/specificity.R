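#' Per-construct log2 fold-difference between two states
#'
#' @param pred prediction tibble (construct_id, state, predicted) from
#'   [predict_library()]; rows with `NA` predictions are flagged missing
#'   and excluded from ranking.
#' @param state_a,state_b the two cell states; the fold is
#'   `predicted[state_a] - predicted[state_b]` (log2).
#' @return tibble (construct_id, pred_a, pred_b, log2_fold, over_10fold,
#'   over_100fold, missing, rank) ranked by decreasing fold among
#'   non-missing constructs.
#' @export
fold_difference <- function(pred, state_a, state_b) {
  wide <- tidyr::pivot_wider(pred[, c("construct_id", "state", "predicted")],
                             names_from = "state",
                             values_from = "predicted")
  if (!all(c(state_a, state_b) %in% names(wide))) {
    stop("states not found in predictions: ",
         paste(setdiff(c(state_a, state_b), names(wide)), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(construct_id = wide$construct_id,
                        pred_a = wide[[state_a]], pred_b = wide[[state_b]])
  out$log2_fold <- out$pred_a - out$pred_b
  out$missing <- !is.finite(out$log2_fold)
  out$over_10fold <- !out$missing & out$log2_fold >= log2(10)
  out$over_100fold <- !out$missing & out$log2_fold >= log2(100)
  out$rank <- NA_integer_
  ok <- which(!out$missing)
  ord <- ok[order(-out$log2_fold[ok], out$construct_id[ok])]
  out$rank[ord] <- seq_along(ord)
  out[order(out$rank, out$construct_id), ]
}

#' Select validation candidates across the four promoter classes
#'
#' Returns `n_per_class` constructs for each class: specific to state A
#' (largest log2 folds), specific to state B (smallest), and a range of
#' predicted activity in each state (quantile-stratified along each
#' state's predicted fluorescence). Selection is deterministic; ties break
#' by construct_id.
#'
#' @param folds tibble from [fold_difference()].
#' @param n_per_class constructs per class.
#' @return tibble (construct_id, class, log2_fold, pred_a, pred_b).
#' @export
select_candidates <- function(folds, n_per_class) {
  ok <- folds[!folds$missing, ]
  n <- min(n_per_class, nrow(ok))
  if (n < n_per_class) {
    warning("only ", nrow(ok), " constructs available; classes truncated",
            call. = FALSE)
  }
  if (n == 0) {
    return(tibble::tibble(construct_id = character(0),
                          class = character(0), log2_fold = numeric(0),
                          pred_a = numeric(0), pred_b = numeric(0)))
  }
  by_fold <- ok[order(-ok$log2_fold, ok$construct_id), ]
  spec_a <- utils::head(by_fold, n)
  spec_b <- utils::head(by_fold[rev(seq_len(nrow(by_fold))), ], n)

  strat <- function(tab, col) {
    tab <- tab[order(tab[[col]], tab$construct_id), ]
    tab[unique(round(seq(1, nrow(tab), length.out = n))), ]
  }
  range_a <- strat(ok, "pred_a")
  range_b <- strat(ok, "pred_b")

  pieces <- list(`specific-to-A` = spec_a, `specific-to-B` = spec_b,
                 `range-in-A` = range_a, `range-in-B` = range_b)
  out <- dplyr::bind_rows(lapply(names(pieces), function(cl) {
    p <- pieces[[cl]][, c("construct_id", "log2_fold", "pred_a", "pred_b")]
    p$class <- cl
    p
  }))
  out[, c("construct_id", "class", "log2_fold", "pred_a", "pred_b")]
}

# exact two-sided rank-sum p by enumeration of all subset assignments of
# the pooled (tie-averaged) ranks; valid with ties
rank_sum_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  W_obs <- sum(r[seq_len(m)])
  idx <- utils::combn(length(pooled), m)
  W_all <- colSums(matrix(r[idx], nrow = m))
  center <- m * (length(pooled) + 1) / 2
  tol <- 1e-9
  mean(abs(W_all - center) >= abs(W_obs - center) - tol)
}

#' Two-sided Wilcoxon rank-sum enrichment test
#'
#' Tests whether a subset of log2 fold-differences is shifted relative to
#' the library background (the subset is removed from the background
#' before testing). Exact enumeration over all rank assignments is used
#' for combined n <= `exact_max`; otherwise the normal approximation with
#' tie correction.
#'
#' @param subset numeric values for the promoters of interest.
#' @param background numeric values for the library (may include the
#'   subset; matching values are removed once each).
#' @param exact_max combined-size threshold for the exact branch.
#' @return list with `p_value`, `method`, and the rank-sum statistic `W`
#'   of the subset.
#' @export
enrichment_test <- function(subset, background, exact_max = 12) {
  stopifnot(length(subset) > 0)
  # remove the subset from the background, one occurrence per value
  for (v in subset) {
    hit <- which(background == v)
    if (length(hit) > 0) background <- background[-hit[1]]
  }
  if (length(background) == 0) {
    stop("background empty after removing the subset", call. = FALSE)
  }
  r <- rank(c(subset, background))
  W <- sum(r[seq_along(subset)]) -
    length(subset) * (length(subset) + 1) / 2
  if (length(unique(c(subset, background))) == 1) {
    return(list(p_value = 1, method = "degenerate (all values tied)",
                W = W))
  }
  n_comb <- length(subset) + length(background)
  if (n_comb <= exact_max) {
    p <- rank_sum_exact(subset, background)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(subset, background, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal approximation with tie correction"
  }
  list(p_value = min(p, 1), method = method, W = W)
}

#' Low-coverage specificity heuristic
#'
#' Model-free shortlist for sparse screens, built from the features that
#' stay computable at low coverage: per construct and state, the total
#' raw counts over all bins, the negative-bin count, and the bin holding
#' maximal counts. A construct is a candidate specific to state A when in
#' state A its maximal-count bin is a positive bin and its negative-bin
#' count fraction is below `neg_threshold`, while in state B the
#' maximal-count bin is the negative bin (and symmetrically for B).
#' Constructs whose maximal bin is the negative bin in every state are
#' never promoted.
#'
#' @param counts raw count tibble (construct_id, state, replicate, bin,
#'   count); replicates are summed.
#' @param state_a,state_b the state pair.
#' @param neg_threshold maximal tolerated negative-bin count fraction in
#'   the "on" state (default 0.25).
#' @return tibble (construct_id, candidate_for, total_a, neg_a, argmax_a,
#'   total_b, neg_b, argmax_b, score) ranked by decreasing score within
#'   candidates; `score` is the positive-bin count fraction in the "on"
#'   state, ties broken by total counts then construct_id.
#' @export
low_coverage_rank <- function(counts, state_a, state_b,
                              neg_threshold = 0.25) {
  counts <- counts[counts$state %in% c(state_a, state_b), ]
  agg <- dplyr::summarise(
    dplyr::group_by(counts, .data$construct_id, .data$state, .data$bin),
    count = sum(.data$count), .groups = "drop")
  per_state <- dplyr::summarise(
    dplyr::group_by(agg, .data$construct_id, .data$state),
    total = sum(.data$count),
    neg = sum(.data$count[.data$bin == "negative"]),
    argmax = BIN_LEVELS[which.max(.data$count[match(BIN_LEVELS,
                                                    .data$bin)])],
    .groups = "drop")
  # constructs absent (zero counts) in one state are excluded
  seen <- dplyr::summarise(
    dplyr::group_by(per_state, .data$construct_id),
    both = dplyr::n() == 2 && all(.data$total > 0), .groups = "drop")
  keep <- seen$construct_id[seen$both]
  per_state <- per_state[per_state$construct_id %in% keep, ]

  a <- per_state[per_state$state == state_a, ]
  b <- per_state[per_state$state == state_b, ]
  b <- b[match(a$construct_id, b$construct_id), ]
  out <- tibble::tibble(
    construct_id = a$construct_id,
    total_a = a$total, neg_a = a$neg, argmax_a = a$argmax,
    total_b = b$total, neg_b = b$neg, argmax_b = b$argmax)
  on_a <- out$argmax_a != "negative" &
    out$neg_a / pmax(out$total_a, 1) < neg_threshold
  on_b <- out$argmax_b != "negative" &
    out$neg_b / pmax(out$total_b, 1) < neg_threshold
  out$candidate_for <- dplyr::case_when(
    on_a & out$argmax_b == "negative" ~ state_a,
    on_b & out$argmax_a == "negative" ~ state_b,
    TRUE ~ NA_character_)
  out$score <- ifelse(
    is.na(out$candidate_for), NA_real_,
    ifelse(out$candidate_for == state_a,
           1 - out$neg_a / pmax(out$total_a, 1),
           1 - out$neg_b / pmax(out$total_b, 1)))
  cand <- !is.na(out$candidate_for)
  ord <- order(!cand, -out$score,
               -(out$total_a + out$total_b), out$construct_id)
  out <- out[ord, ]
  out[, c("construct_id", "candidate_for", "score", "total_a", "neg_a",
          "argmax_a", "total_b", "neg_b", "argmax_b")]
}
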