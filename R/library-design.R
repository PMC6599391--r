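#' Tandem-repeat count for a binding site
#'
#' The variable region of every construct is a tandem repeat of the
#' binding site plus a 3 bp spacer, fitted into a fixed 129 bp synthesis
#' budget: `k = floor(129 / (L + 3))`. Floor is used so the variable
#' region never exceeds the budget. Sites longer than 126 bp leave no room
#' for a single unit and return `k = 0` (un-designable).
#'
#' @param tfbs_length binding-site length in bp (1..129).
#' @param budget variable-region budget in bp (default 129).
#' @param spacer_length spacer length in bp (default 3).
#' @return Integer repeat count `k`.
#' @export
tandem_repeat_count <- function(tfbs_length, budget = 129L,
                                spacer_length = 3L) {
  stopifnot(all(tfbs_length >= 1), all(tfbs_length <= budget))
  as.integer(budget %/% (tfbs_length + spacer_length))
}

generate_barcodes <- function(n, len = 17L, forbidden = ASCI_SITE,
                              max_tries = 50L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not generate ", n, " unique barcodes after ",
           max_tries, " rounds", call. = FALSE)
    }
    cand <- random_dna(2L * (n - length(out)), len)
    cand <- cand[!grepl(forbidden, cand, fixed = TRUE)]
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Build a barcoded synthetic promoter library
#'
#' For every motif the consensus sequence and its reverse complement are
#' taken; the deduplicated set of consensus sequences (a palindromic
#' consensus yields one construct, not two) is turned into tandem-repeat
#' constructs, each with a unique 17 bp random barcode. The full oligo is
#' `flank5 + variable_region + AscI site + barcode + flank3`, so trimming a
#' read at the AscI site leaves exactly the variable region.
#'
#' @param motifs list of [motif_matrix()] objects with unique `motif_id`s.
#' @param seed integer seed fixing barcode randomness.
#' @param spacer 3 bp spacer between repeats (lower case by convention).
#' @param budget variable-region budget in bp.
#' @param barcode_length barcode length in bp.
#' @param flank5,flank3 fixed flanking sequences of the oligo.
#' @return A `specs_library`: tibble of constructs (construct_id,
#'   source_motif_id, tf_name, strand, tfbs, tfbs_length, repeat_count,
#'   barcode, variable_region, full_oligo) with the variable-region index
#'   as an attribute.
#' @export
build_library <- function(motifs, seed = 1L, spacer = DEFAULT_SPACER,
                          budget = 129L, barcode_length = 17L,
                          flank5 = DEFAULT_FLANK5, flank3 = DEFAULT_FLANK3) {
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate motif_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  spacer_up <- toupper(spacer)
  assert_dna(spacer_up, "spacer")

  cons <- vapply(motifs, consensus_from_pwm, character(1))
  fwd <- tibble::tibble(source_motif_id = ids,
                        tf_name = vapply(motifs, function(m)
                          as.character(m$tf_name), character(1)),
                        strand = "forward", tfbs = cons)
  rev <- fwd
  rev$strand <- "revcomp"
  rev$tfbs <- reverse_complement(cons)
  des <- rbind(fwd, rev)
  # deduplicate on the consensus sequence itself (covers palindromes and
  # identical consensi from different motifs); first occurrence wins
  des <- des[!duplicated(des$tfbs), , drop = FALSE]

  des$tfbs_length <- nchar(des$tfbs)
  des$repeat_count <- tandem_repeat_count(des$tfbs_length, budget = budget,
                                          spacer_length = nchar(spacer_up))
  undesignable <- des$repeat_count < 1L
  if (any(undesignable)) {
    warning(sum(undesignable), " consensus sequence(s) exceed the budget ",
            "and were dropped as un-designable", call. = FALSE)
    des <- des[!undesignable, , drop = FALSE]
  }

  unit <- paste0(des$tfbs, spacer_up)
  des$variable_region <- vapply(seq_len(nrow(des)), function(i) {
    paste(rep(unit[i], des$repeat_count[i]), collapse = "")
  }, character(1))
  if (anyDuplicated(des$variable_region)) {
    stop("variable-region collision between distinct consensi; ",
         "library index would not be injective", call. = FALSE)
  }

  set.seed(seed)
  des$barcode <- generate_barcodes(nrow(des), len = barcode_length)
  des$construct_id <- sprintf("SP%05d", seq_len(nrow(des)))
  des$full_oligo <- paste0(flank5, des$variable_region, ASCI_SITE,
                           des$barcode, flank3)

  lib <- des[, c("construct_id", "source_motif_id", "tf_name", "strand",
                 "tfbs", "tfbs_length", "repeat_count", "barcode",
                 "variable_region", "full_oligo")]
  index <- stats::setNames(lib$construct_id, lib$variable_region)
  structure(lib, class = c("specs_library", class(lib)),
            index = index, spacer = spacer_up, budget = budget,
            flank5 = flank5, flank3 = flank3, seed = seed)
}

#' @exportS3Method base::print
print.specs_library <- function(x, ...) {
  cat("<specs_library> ", nrow(x), " constructs from ",
      length(unique(x$source_motif_id)), " motifs\n", sep = "")
  NextMethod()
}

#' Write a library reference to disk
#'
#' Exports a FASTA of variable regions (the alignment reference) and a TSV
#' design table.
#'
#' @param library a `specs_library`.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_design.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_library <- function(library, prefix) {
  fa <- Biostrings::DNAStringSet(library$variable_region)
  names(fa) <- library$construct_id
  fasta_path <- paste0(prefix, ".fasta")
  tsv_path <- paste0(prefix, "_design.tsv")
  Biostrings::writeXStringSet(fa, fasta_path)
  write.table(as.data.frame(library), tsv_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, design = tsv_path))
}

#' Read a library design table written by [write_library()]
#'
#' @param design_tsv path to the `_design.tsv` file.
#' @return A `specs_library`.
#' @export
read_library <- function(design_tsv) {
  lib <- tibble::as_tibble(read.table(design_tsv, sep = "\t", header = TRUE,
                                      colClasses = "character"))
  lib$tfbs_length <- as.integer(lib$tfbs_length)
  lib$repeat_count <- as.integer(lib$repeat_count)
  index <- stats::setNames(lib$construct_id, lib$variable_region)
  structure(lib, class = c("specs_library", class(lib)), index = index)
}
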