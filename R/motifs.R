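#' Construct a binding-site motif matrix
#'
#' A motif is a per-position nucleotide probability matrix (positions x
#' A,C,G,T). JASPAR-style count matrices are accepted and row-normalized.
#'
#' @param probs numeric matrix with one row per motif position and four
#'   columns in A, C, G, T order. Rows holding counts are normalized to
#'   probabilities.
#' @param motif_id identifier, unique within a motif collection.
#' @param tf_name transcription factor name (optional).
#' @param species source species (optional).
#' @return An object of class `motif_matrix`.
#' @export
motif_matrix <- function(probs, motif_id, tf_name = NA_character_,
                         species = NA_character_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) {
    stop("motif '", motif_id, "': expected 4 columns (A,C,G,T), got ",
         ncol(probs), call. = FALSE)
  }
  if (nrow(probs) < 4) {
    stop("motif '", motif_id, "': needs at least 4 positions, got ",
         nrow(probs), call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("motif '", motif_id, "': probabilities must be finite and >= 0",
         call. = FALSE)
  }
  rs <- rowSums(probs)
  if (any(rs <= 0)) {
    stop("motif '", motif_id, "': row ", which(rs <= 0)[1], " sums to zero",
         call. = FALSE)
  }
  # accept count matrices: normalize any row not already summing to 1
  probs <- probs / rs
  colnames(probs) <- DNA_BASES
  structure(
    list(motif_id = as.character(motif_id), tf_name = tf_name,
         species = species, probs = probs),
    class = "motif_matrix"
  )
}

#' @exportS3Method base::print
print.motif_matrix <- function(x, ...) {
  cat("<motif_matrix> ", x$motif_id, " (", x$tf_name, "), ",
      nrow(x$probs), " positions\n", sep = "")
  invisible(x)
}

validate_motif <- function(motif, tol = 1e-6) {
  stopifnot(inherits(motif, "motif_matrix"))
  rs <- rowSums(motif$probs)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    stop("motif '", motif$motif_id, "': row ", off[1],
         " is not a probability distribution (sum = ",
         format(rs[off[1]]), ")", call. = FALSE)
  }
  invisible(motif)
}

#' Read motifs from tabular files
#'
#' Each file holds one motif: a header line `>motif_id tf_name species`
#' (tf and species optional) followed by one whitespace-separated row of
#' four numbers (A C G T) per position. Count rows are normalized on load.
#'
#' @param paths character vector of motif file paths, or a directory.
#' @return list of [motif_matrix()] objects.
#' @export
read_motifs <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(txt|tsv|pwm|motif)$",
                        full.names = TRUE)
  }
  lapply(paths, function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(trimws(lines))]
    if (!startsWith(lines[1], ">")) {
      stop("motif file ", p, ": first line must be a '>' header",
           call. = FALSE)
    }
    hdr <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
    rows <- do.call(rbind, lapply(lines[-1], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    motif_matrix(rows, motif_id = hdr[1],
                 tf_name = if (length(hdr) >= 2) hdr[2] else NA_character_,
                 species = if (length(hdr) >= 3) hdr[3] else NA_character_)
  })
}

#' Consensus sequence of a motif
#'
#' Takes the maximum-probability nucleotide at each position; ties are
#' broken in fixed alphabetical order A < C < G < T so designs are
#' deterministic.
#'
#' @param motif a [motif_matrix()].
#' @return Consensus DNA sequence (character scalar of length L).
#' @export
consensus_from_pwm <- function(motif) {
  validate_motif(motif)
  idx <- apply(motif$probs, 1, which.max) # which.max takes the first max
  paste(DNA_BASES[idx], collapse = "")
}

#' Reverse complement of a DNA sequence
#'
#' @param seq character vector of sequences over A/C/G/T.
#' @return Reverse-complemented sequence(s).
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
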