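test_that("reads are kept and trimmed at the AscI site", {
  r1 <- paste0("ACGTACGT", ASCI_SITE, "TTTT")
  out <- filter_and_trim(c(r1, "ACGTACGTACGT"))
  expect_equal(out$sequences, "ACGTACGT")
  expect_equal(out$kept, 1)
  expect_equal(out$dropped, 1)

  # toy FASTQ of 10 reads, 3 without the site
  tmp <- withr::local_tempfile(fileext = ".fastq")
  seqs <- c(paste0(random_dna_fixture(7, 20), ASCI_SITE, "AAAA"),
            random_dna_fixture(3, 32))
  stopifnot(!any(grepl(ASCI_SITE, seqs[8:10], fixed = TRUE)))
  writeLines(as.vector(rbind(paste0("@r", 1:10), seqs, "+",
                             strrep("I", nchar(seqs)))), tmp)
  out <- filter_and_trim(tmp)
  expect_equal(out$kept, 7)
  expect_equal(out$dropped, 3)
  expect_true(all(nchar(out$sequences) == 20))
})

test_that("malformed FASTQ raises an informative error", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), tmp) # truncated record
  expect_error(filter_and_trim(tmp), "malformed FASTQ")
})

test_that("collapse_and_count matches exact multiplicities and the tie rule", {
  lib <- toy_library(5, seed = 20)
  seqs <- rep(lib$variable_region[c(1, 1, 2, 3)], times = c(2, 1, 4, 5))
  out <- collapse_and_count(seqs, lib)
  expect_equal(out$counts$count[match(lib$construct_id[1:3],
                                      out$counts$construct_id)],
               c(3, 4, 5))
  expect_equal(out$unassigned, 0)
  expect_error(collapse_and_count("ACGT", lib[0, ]), "empty")
})

test_that("mismatch assignment agrees with a brute-force Hamming scan", {
  lib <- toy_library(8, seed = 21)
  hamming <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  set.seed(22)
  for (i in 1:40) {
    base <- sample(lib$variable_region, 1)
    ch <- strsplit(base, "")[[1]]
    nmut <- sample(0:3, 1)
    pos <- sample(length(ch), nmut)
    ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    q <- paste(ch, collapse = "")
    d <- vapply(lib$variable_region, hamming, numeric(1), a = q)
    best <- min(d)
    expected <- if (best <= 2 && sum(d == best) == 1) {
      lib$construct_id[which.min(d)]
    } else NA_character_
    out <- collapse_and_count(q, lib)
    got <- out$counts$construct_id[out$counts$count > 0]
    if (is.na(expected)) {
      expect_equal(length(got), 0)
      expect_equal(out$unassigned, 1)
    } else {
      expect_equal(got, expected)
    }
  }
})

test_that("a sequence equidistant from two constructs stays unassigned", {
  lib <- tibble::tibble(construct_id = c("X", "Y"),
                        variable_region = c("AAAAAA", "AAAATT"))
  class(lib) <- c("specs_library", class(lib))
  out <- collapse_and_count("AAAAAT", lib) # distance 1 from both
  expect_equal(sum(out$counts$count), 0)
  expect_equal(out$unassigned, 1)
})

test_that("size factors reproduce the hand-computed median-of-ratios", {
  mat <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(mat)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples give unit factors
  expect_equal(unname(size_factors(cbind(c(5, 7, 9), c(5, 7, 9)))),
               c(1, 1))
})

test_that("size factors are scale-equivariant on random matrices", {
  set.seed(23)
  for (i in 1:20) {
    mat <- matrix(rpois(60, 50) + 1, ncol = 4)
    sf <- size_factors(mat)
    c_ <- runif(1, 0.5, 4)
    mat2 <- mat
    mat2[, 2] <- mat2[, 2] * c_
    sf2 <- size_factors(mat2)
    # multiplying one sample's counts by c multiplies its factor by c
    # relative to the others (geometric-mean reference shifts by c^(1/4))
    expect_equal(sf2[2] / sf2[1], c_ * sf[2] / sf[1], tolerance = 1e-9)
    ratio <- sf2 / sf
    expect_equal(ratio[2] / ratio[1], c_, tolerance = 1e-9)
    expect_equal(unname(ratio[c(1, 3, 4)] / ratio[1]), rep(1, 3),
                 tolerance = 1e-9)
  }
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(24)
  mat <- matrix(rpois(500, 100) + 1, ncol = 5)
  expect_equal(unname(size_factors(mat)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 1e-8)
})

test_that("size factor degenerate inputs raise the documented errors", {
  mat <- cbind(c(0, 5), c(3, 0))
  expect_error(size_factors(mat), "pseudocount")
  expect_silent(size_factors(mat, pseudocount = 0.5))
})

test_that("normalization removes sample-specific scaling", {
  set.seed(25)
  mat <- matrix(rpois(100, 80) + 1, ncol = 5,
                dimnames = list(sprintf("SP%05d", 1:20), NULL))
  cnt <- counts_from_matrix(mat)
  n1 <- normalize_counts(cnt)
  # a common constant over all samples leaves the size factors untouched
  # and passes straight through to the normalized counts
  cnt2 <- cnt
  cnt2$count <- cnt2$count * 3
  n2 <- normalize_counts(cnt2)
  expect_equal(attr(n2, "size_factors"), attr(n1, "size_factors"),
               tolerance = 1e-9)
  expect_equal(n2$norm, 3 * n1$norm, tolerance = 1e-9)
  # scaling ONE sample is absorbed by its size factor: the normalized
  # profile is unchanged up to a single global constant
  cnt3 <- cnt
  one <- cnt3$bin == "low"
  cnt3$count[one] <- cnt3$count[one] * 5
  n3 <- normalize_counts(cnt3)
  ratio <- n3$norm / n1$norm
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("replicate filter retains constructs supported in every state", {
  cnt <- tidyr::expand_grid(construct_id = sprintf("SP%05d", 1:5),
                            state = c("A", "B"),
                            replicate = c("r1", "r2", "r3"),
                            bin = factor("low", levels = BIN_LEVELS))
  cnt$count <- 10
  # SP1: zero everywhere in B -> dropped
  cnt$count[cnt$construct_id == "SP00001" & cnt$state == "B"] <- 0
  # SP2: only one replicate in A -> dropped
  cnt$count[cnt$construct_id == "SP00002" & cnt$state == "A" &
              cnt$replicate != "r1"] <- 0
  # SP3: exactly two replicates in each state -> retained
  cnt$count[cnt$construct_id == "SP00003" & cnt$replicate == "r3"] <- 0
  out <- replicate_filter(cnt, min_replicates = 2)
  expect_setequal(out$retained, c("SP00003", "SP00004", "SP00005"))
  expect_setequal(out$dropped, c("SP00001", "SP00002"))
})

test_that("replicate filter refuses single-replicate states", {
  cnt <- tidyr::expand_grid(construct_id = "SP00001", state = c("A", "B"),
                            replicate = "r1",
                            bin = factor("low", levels = BIN_LEVELS))
  cnt$count <- 5
  expect_error(replicate_filter(cnt), "fewer than 2 replicates")
})

test_that("Sanger clones are classified intact / mutated / unidentifiable", {
  lib <- toy_library(5, seed = 26)
  vr <- lib$variable_region[2]
  clone <- paste0("GTAACGCCAG", vr, ASCI_SITE, "ACGTACGTACGTACGTA")
  out <- match_sanger(clone, lib)
  expect_equal(out$status, "intact")
  expect_equal(out$construct_id, lib$construct_id[2])

  ch <- strsplit(vr, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  mut <- paste0("GTAACGCCAG", paste(ch, collapse = ""), ASCI_SITE)
  out2 <- match_sanger(mut, lib)
  expect_equal(out2$status, "mutated")
  expect_equal(out2$construct_id, lib$construct_id[2])
  expect_equal(out2$edits, 1L)

  set.seed(27)
  rnd <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  out3 <- match_sanger(rnd, lib)
  expect_equal(out3$status, "unidentifiable")
  expect_true(is.na(out3$construct_id))
  expect_error(match_sanger("", lib), "empty")
})

test_that("error-free emission round-trips to the simulated counts", {
  lib <- toy_library(6, seed = 28)
  truth <- simulate_truth(nrow(lib), seed = 29)
  scr <- simulate_screen(truth, depth = 3000, cells_per_construct = 100,
                         n_bio = 1, seed = 30)
  dir <- withr::local_tempdir()
  sheet <- emit_reads(scr, lib, dir, error_rate = 0, junk_frac = 0,
                      seed = 31)
  got <- count_screen(sheet, lib)
  mg <- dplyr::inner_join(
    scr$counts[, c("construct_id", "state", "replicate", "bin", "count")],
    got$counts, by = c("construct_id", "state", "replicate", "bin"))
  expect_equal(nrow(mg), nrow(got$counts))
  expect_identical(as.integer(mg$count.x), as.integer(mg$count.y))
})
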