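DNA_BASES <- c("A", "C", "G", "T")

#' AscI recognition sequence
#'
#' Eight-base-cutter recognition site used to delimit the variable promoter
#' region in each construct; reads lacking it are discarded during
#' preprocessing.
#' @export
ASCI_SITE <- "GGCGCGCC"

# default fixed flanks around the variable region (configurable in
# build_library); the 3' junction carries the AscI site so that read
# trimming is testable end to end
DEFAULT_FLANK5 <- "GTAACGCCAG"
DEFAULT_FLANK3 <- "TTCGAATCCG"
DEFAULT_SPACER <- "cgt"

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", toupper(seq))
  if (any(bad)) {
    stop(what, " contains non-ACGT characters: ",
         paste(utils::head(seq[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# per-base substitution noise on a character vector of reads
mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < error_rate)
  if (length(hit) > 0) {
    # substitute with one of the three other bases
    cur <- flat[hit]
    sub <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1), USE.NAMES = FALSE)
    flat[hit] <- sub
  }
  grp <- rep.int(seq_along(reads), lens)
  vapply(split(flat, grp), paste, character(1), collapse = "")
}

# Hamming distances between one query and a character vector of references
# of the same length
hamming_to_refs <- function(query, ref_chars) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  colSums(ref_chars != q)
}
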