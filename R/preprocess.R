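#' Filter reads for the AscI site and trim it off
#'
#' Only reads containing the AscI recognition site (created during library
#' construction at the 3' end of the variable region) are kept; retained
#' reads are truncated at the site's 5' edge, leaving the variable
#' promoter sequence.
#'
#' @param fastq path to a FASTQ file, or a character vector of read
#'   sequences.
#' @param site restriction-site sequence (default AscI, GGCGCGCC).
#' @return list with `sequences` (trimmed reads), `kept`, `dropped`.
#' @export
filter_and_trim <- function(fastq, site = ASCI_SITE) {
  if (length(fastq) == 1 && file.exists(fastq)) {
    lines <- readLines(fastq)
    if (length(lines) %% 4 != 0) {
      stop("malformed FASTQ '", fastq, "': truncated record ",
           length(lines) %/% 4 + 1, call. = FALSE)
    }
    hdr_ok <- startsWith(lines[seq(1, length(lines), by = 4)], "@")
    sep_ok <- startsWith(lines[seq(3, length(lines), by = 4)], "+")
    if (!all(hdr_ok) || !all(sep_ok)) {
      bad <- which(!(hdr_ok & sep_ok))[1]
      stop("malformed FASTQ '", fastq, "': record ", bad,
           " lacks @/+ markers", call. = FALSE)
    }
    reads <- lines[seq(2, length(lines), by = 4)]
  } else {
    reads <- as.character(fastq)
  }
  pos <- regexpr(site, reads, fixed = TRUE)
  keep <- pos > 0
  trimmed <- substr(reads[keep], 1L, pos[keep] - 1L)
  list(sequences = unname(trimmed), kept = sum(keep),
       dropped = sum(!keep))
}

#' Collapse trimmed reads and count them per construct
#'
#' Identical sequences are collapsed first; each unique sequence is then
#' assigned to the single best-matching variable region within
#' `max_mismatches` (Hamming by default, optionally Levenshtein edit
#' distance). A sequence equidistant from two or more constructs at the
#' best distance is left unassigned, as is any sequence beyond the
#' threshold.
#'
#' @param sequences character vector of trimmed read sequences (a multiset:
#'   repeats carry their multiplicity).
#' @param library a `specs_library`.
#' @param max_mismatches assignment threshold (default 2).
#' @param method "hamming" (substitutions only; candidate references must
#'   match the read length) or "edit" (Levenshtein).
#' @return list with `counts` (tibble construct_id, count; zero rows for
#'   unseen constructs are included), `unassigned` (reads not matching any
#'   construct), `assigned`.
#' @export
collapse_and_count <- function(sequences, library, max_mismatches = 2,
                               method = c("hamming", "edit")) {
  method <- match.arg(method)
  if (nrow(library) == 0) stop("library reference is empty", call. = FALSE)
  refs <- library$variable_region
  ref_ids <- library$construct_id

  counts <- stats::setNames(rep(0, length(ref_ids)), ref_ids)
  unassigned <- 0
  if (length(sequences) > 0) {
    uniq <- table(sequences)
    useq <- names(uniq)
    mult <- as.vector(uniq)

    # fast path: exact matches against the library index
    hit <- match(useq, refs)
    exact <- !is.na(hit)
    if (any(exact)) {
      add <- tapply(mult[exact], ref_ids[hit[exact]], sum)
      counts[names(add)] <- counts[names(add)] + add
    }

    rest <- which(!exact)
    if (length(rest) > 0 && max_mismatches > 0) {
      if (method == "hamming") {
        by_len <- split(seq_along(refs), nchar(refs))
        char_cache <- list()
        for (j in rest) {
          len <- as.character(nchar(useq[j]))
          cand <- by_len[[len]]
          if (is.null(cand)) { unassigned <- unassigned + mult[j]; next }
          if (is.null(char_cache[[len]])) {
            char_cache[[len]] <- do.call(
              cbind, strsplit(refs[cand], "", fixed = TRUE))
          }
          d <- hamming_to_refs(useq[j], char_cache[[len]])
          best <- min(d)
          if (best <= max_mismatches && sum(d == best) == 1) {
            id <- ref_ids[cand[which.min(d)]]
            counts[id] <- counts[id] + mult[j]
          } else unassigned <- unassigned + mult[j]
        }
      } else {
        d_all <- utils::adist(useq[rest], refs)
        for (k in seq_along(rest)) {
          d <- d_all[k, ]
          best <- min(d)
          if (best <= max_mismatches && sum(d == best) == 1) {
            id <- ref_ids[which.min(d)]
            counts[id] <- counts[id] + mult[rest[k]]
          } else unassigned <- unassigned + mult[rest[k]]
        }
      }
    } else if (length(rest) > 0) {
      unassigned <- sum(mult[rest])
    }
  }
  list(counts = tibble::tibble(construct_id = ref_ids,
                               count = unname(counts)),
       assigned = sum(counts), unassigned = unassigned)
}

#' Count a whole screen from FASTQ files
#'
#' Runs [filter_and_trim()] and [collapse_and_count()] over every sample in
#' a sample sheet (as written by [emit_reads()]: columns file, state,
#' replicate, bin and optionally bio_rep/tech_rep).
#'
#' @param sheet sample-sheet tibble or path to a TSV.
#' @param library a `specs_library`.
#' @param max_mismatches,method passed to [collapse_and_count()].
#' @return list with `counts` (tibble construct_id, state, replicate, bin,
#'   count) and a per-sample `qc` report.
#' @export
count_screen <- function(sheet, library, max_mismatches = 2,
                         method = "hamming") {
  if (is.character(sheet)) {
    sheet <- tibble::as_tibble(read.table(sheet, sep = "\t", header = TRUE,
                                          colClasses = "character"))
  }
  out <- vector("list", nrow(sheet))
  qc <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    ft <- filter_and_trim(sheet$file[i])
    cc <- collapse_and_count(ft$sequences, library,
                             max_mismatches = max_mismatches,
                             method = method)
    cnt <- cc$counts
    cnt$state <- sheet$state[i]
    cnt$replicate <- sheet$replicate[i]
    cnt$bin <- sheet$bin[i]
    out[[i]] <- cnt
    qc[[i]] <- tibble::tibble(file = sheet$file[i], state = sheet$state[i],
                              replicate = sheet$replicate[i],
                              bin = sheet$bin[i], kept = ft$kept,
                              dropped = ft$dropped,
                              assigned = cc$assigned,
                              unassigned = cc$unassigned)
  }
  counts <- dplyr::bind_rows(out)
  counts$bin <- factor(counts$bin, levels = BIN_LEVELS)
  counts <- counts[, c("construct_id", "state", "replicate", "bin",
                       "count")]
  list(counts = counts, qc = dplyr::bind_rows(qc))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed natively: the reference for each
#' construct is its geometric mean across samples (over constructs with
#' nonzero counts everywhere); a sample's factor is the median across
#' those constructs of count/reference.
#'
#' @param mat numeric matrix, constructs x samples, raw counts.
#' @param pseudocount optional value added to all counts before the
#'   computation (default 0; set e.g. 0.5 when no construct is nonzero in
#'   every sample).
#' @return Named numeric vector of size factors, one per column.
#' @export
size_factors <- function(mat, pseudocount = 0) {
  mat <- as.matrix(mat) + pseudocount
  if (any(colSums(mat) == 0)) {
    stop("every sample needs at least one nonzero count", call. = FALSE)
  }
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    stop("no construct has nonzero counts in every sample; ",
         "consider the pseudocount option", call. = FALSE)
  }
  logref <- rowMeans(log(mat[all_pos, , drop = FALSE]))
  apply(mat[all_pos, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - logref))
  })
}

#' Normalize a screen count table by size factors
#'
#' Builds one sample per (state, replicate, bin) combination, computes
#' median-of-ratios [size_factors()], and divides raw counts by their
#' sample's factor.
#'
#' @param counts tibble (construct_id, state, replicate, bin, count).
#' @param pseudocount passed to [size_factors()].
#' @return A `count_matrix`: the input tibble with a `norm` column, plus
#'   the per-sample size factors as an attribute.
#' @export
normalize_counts <- function(counts, pseudocount = 0) {
  counts$sample <- interaction(counts$state, counts$replicate, counts$bin,
                               drop = TRUE, sep = ":")
  wide <- tidyr::pivot_wider(counts,
                             id_cols = "construct_id",
                             names_from = "sample",
                             values_from = "count", values_fill = 0)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$construct_id
  sf <- size_factors(mat, pseudocount = pseudocount)
  counts$norm <- counts$count / sf[as.character(counts$sample)]
  counts$sample <- NULL
  structure(counts, class = c("count_matrix", class(counts)),
            size_factors = sf)
}

#' Filter constructs by replicate support
#'
#' A construct is retained only if it has nonzero counts (in any bin) in at
#' least `min_replicates` replicates in every state.
#'
#' @param counts count tibble (construct_id, state, replicate, bin, count).
#' @param min_replicates minimum supporting replicates per state.
#' @return list with `counts` (filtered tibble, original attributes kept),
#'   `retained`, `dropped` (construct id vectors).
#' @export
replicate_filter <- function(counts, min_replicates = 2) {
  nrep <- tapply(counts$replicate, counts$state,
                 function(x) length(unique(x)))
  if (any(nrep < min_replicates)) {
    stop("state(s) with fewer than ", min_replicates, " replicates: ",
         paste(names(nrep)[nrep < min_replicates], collapse = ", "),
         call. = FALSE)
  }
  support <- dplyr::summarise(
    dplyr::group_by(counts, .data$construct_id, .data$state,
                    .data$replicate),
    present = sum(.data$count) > 0, .groups = "drop")
  per_state <- dplyr::summarise(
    dplyr::group_by(support, .data$construct_id, .data$state),
    n_ok = sum(.data$present), .groups = "drop")
  ok <- dplyr::summarise(
    dplyr::group_by(per_state, .data$construct_id),
    pass = all(.data$n_ok >= min_replicates), .groups = "drop")
  retained <- ok$construct_id[ok$pass]
  dropped <- ok$construct_id[!ok$pass]
  filtered <- counts[counts$construct_id %in% retained, ]
  list(counts = filtered, retained = retained, dropped = dropped)
}

#' Identify a Sanger-sequenced clone against the library
#'
#' Aligns the clone sequence to every variable region (whole reference
#' against a local window of the clone). An exact full-length hit is
#' `intact`; the best hit within `max_edits` edit operations (mismatches
#' plus inserted/deleted bases) is `mutated`; anything else is
#' `unidentifiable`.
#'
#' @param clone_seq one DNA sequence (IUPAC letters accepted).
#' @param library a `specs_library`.
#' @param max_edits edit-distance threshold for a `mutated` call.
#' @return list with `status` ("intact", "mutated", "unidentifiable"),
#'   `construct_id` (NA when unidentifiable), `edits`.
#' @export
match_sanger <- function(clone_seq, library, max_edits = 5) {
  if (!nzchar(clone_seq)) stop("empty clone sequence", call. = FALSE)
  clone_seq <- toupper(clone_seq)
  exact <- which(vapply(library$variable_region, grepl, logical(1),
                        x = clone_seq, fixed = TRUE))
  if (length(exact) > 0) {
    return(list(status = "intact",
                construct_id = library$construct_id[exact[1]], edits = 0L))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(library$variable_region),
    Biostrings::DNAString(clone_seq),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1)
  edits <- Biostrings::nmismatch(aln) +
    Biostrings::nindel(aln)@insertion[, "WidthSum"] +
    Biostrings::nindel(aln)@deletion[, "WidthSum"]
  best <- which.min(edits)
  if (edits[best] <= max_edits) {
    list(status = "mutated", construct_id = library$construct_id[best],
         edits = as.integer(edits[best]))
  } else {
    list(status = "unidentifiable", construct_id = NA_character_,
         edits = as.integer(edits[best]))
  }
}
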