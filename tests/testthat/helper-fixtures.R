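# programmatic fixtures shared across test files

random_motifs <- function(n, len_range = 6:14, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    L <- sample(len_range, 1)
    motif_matrix(matrix(runif(4 * L), ncol = 4),
                 motif_id = paste0("M", i), tf_name = paste0("TF", i))
  })
}

random_dna_fixture <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# tiny deterministic library for matching tests
toy_library <- function(n_motifs = 5, seed = 3) {
  build_library(random_motifs(n_motifs, seed = seed), seed = seed)
}

# a two-bin scheme with known mean fluorescences (for arithmetic checks)
toy_scheme2 <- function(ybar = c(10, 100)) {
  tibble::tibble(bin = c("a", "b"), lo = c(0, 50), hi = c(50, Inf),
                 ybar = ybar)
}

# count tibble from a constructs x bins matrix, single state/replicate
counts_from_matrix <- function(mat, state = "A", replicate = "b1.t1") {
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("SP%05d", seq_len(nrow(mat)))
  tibble::tibble(
    construct_id = rep(ids, times = ncol(mat)),
    state = state, replicate = replicate,
    bin = factor(rep(BIN_LEVELS[seq_len(ncol(mat))], each = nrow(mat)),
                 levels = BIN_LEVELS),
    count = as.vector(mat))
}
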