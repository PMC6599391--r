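scheme5 <- function(ybar = c(1, 10, 100, 1000, 10000)) {
  tibble::tibble(bin = BIN_LEVELS, lo = 0, hi = 0, ybar = ybar)
}

test_that("activity score is the weighted mean of bin fluorescences", {
  sch <- toy_scheme2(ybar = c(10, 100))
  expect_equal(activity_score(c(3, 3), sch), 55) # equal log2 counts
  # all mass in one bin returns that bin's mean fluorescence
  sch5 <- scheme5()
  for (b in 1:5) {
    w <- rep(0, 5)
    w[b] <- 7
    expect_equal(activity_score(w, sch5), sch5$ybar[b])
  }
  expect_error(activity_score(rep(0, 5), sch5), "undefined")
})

test_that("activity score matches the arithmetic oracle on random vectors", {
  set.seed(40)
  sch <- scheme5()
  for (i in seq_len(1000)) {
    w <- runif(5, 0, 20)
    expect_equal(activity_score(w, sch), sum(sch$ybar * w) / sum(w),
                 tolerance = 1e-9)
  }
})

test_that("shifting weight to a higher bin never decreases the score", {
  set.seed(41)
  sch <- scheme5()
  for (i in seq_len(200)) {
    w <- runif(5, 0.1, 10)
    from <- sample(4, 1)
    higher <- seq(from + 1, 5)
    to <- higher[sample.int(length(higher), 1)]
    delta <- runif(1, 0, w[from])
    w2 <- w
    w2[from] <- w2[from] - delta
    w2[to] <- w2[to] + delta
    expect_gte(activity_score(w2, sch), activity_score(w, sch) - 1e-12)
  }
})

test_that("median fluorescence uses the midpoint convention and log2", {
  expect_equal(median_fluorescence(c(4, 4, 4)), 2)
  expect_equal(median_fluorescence(c(1, 2, 3, 4)), log2(2.5))
  expect_error(median_fluorescence(c(1, 2), gate = c(10, 20)), "no events")
  # lognormal sample with small sigma converges to the true median
  set.seed(42)
  x <- 2^rnorm(1e5, mean = 8, sd = 0.01)
  expect_equal(median_fluorescence(x), 8, tolerance = 1e-3)
})

test_that("feature table has p + p(p-1)/2 columns and sane invariants", {
  set.seed(43)
  mat <- matrix(rpois(100, 60) + 1, ncol = 5,
                dimnames = list(sprintf("SP%05d", 1:20), NULL))
  cnt <- normalize_counts(counts_from_matrix(mat))
  f <- build_features(cnt)
  p <- 16 # 5 log counts + total + 5 proportions + 4 ratios + argmax
  expect_equal(ncol(f) - 2, p + p * (p - 1) / 2)
  expect_true(all(is.finite(as.matrix(f[, -(1:2)]))))

  # constant counts across bins: all adjacent-bin log-ratios are zero
  flat <- counts_from_matrix(matrix(7, nrow = 2, ncol = 5,
                                    dimnames = list(c("SP00001",
                                                      "SP00002"), NULL)))
  ff <- build_features(flat, interactions = FALSE)
  ratio_cols <- grep("^ratio_", names(ff), value = TRUE)
  expect_equal(unname(as.matrix(ff[, ratio_cols])),
               matrix(0, nrow = 2, ncol = 4))

  # missing bin column errors
  bad <- cnt[cnt$bin != "top5", ]
  expect_error(build_features(bad), "missing bin")
})

test_that("doubling counts shifts totals by ~1 log2 and keeps proportions", {
  set.seed(44)
  mat <- matrix(rpois(100, 500) + 100, ncol = 5,
                dimnames = list(sprintf("SP%05d", 1:20), NULL))
  cnt <- counts_from_matrix(mat)
  cnt$norm <- cnt$count
  cnt2 <- cnt
  cnt2$norm <- cnt2$norm * 2
  f1 <- build_features(cnt, interactions = FALSE)
  f2 <- build_features(cnt2, interactions = FALSE)
  expect_equal(f2$logn_total - f1$logn_total, rep(1, 20),
               tolerance = 0.01)
  prop_cols <- grep("^prop_", names(f1), value = TRUE)
  expect_equal(as.matrix(f2[, prop_cols]), as.matrix(f1[, prop_cols]),
               tolerance = 0.01)
  expect_equal(f1$argmax_bin, f2$argmax_bin)
})

# shared small training fixture: features from a simulated screen
training_fixture <- function(n = 60, seed = 45) {
  truth <- simulate_truth(n, seed = seed)
  scr <- simulate_screen(truth, depth = 5e4, cells_per_construct = 100,
                         seed = seed + 1)
  norm <- normalize_counts(scr$counts, pseudocount = 0.5)
  list(truth = truth, screen = scr, features = build_features(norm))
}

test_that("a noiseless linear target is fit almost perfectly", {
  fx <- training_fixture()
  f <- fx$features
  x <- as.matrix(f[, -(1:2)])
  beta <- c(rep(0, ncol(x)))
  beta[1:6] <- c(0.5, -0.2, 0.3, 0.1, -0.4, 0.25)
  cal <- tibble::tibble(construct_id = f$construct_id, state = f$state,
                        target = drop(x %*% beta) + 2)
  m <- train_activity_model(f, cal, cv_repeats = 2, seed = 46)
  expect_gte(m$report$test_r2, 0.99)
})

test_that("permuted targets give near-zero held-out R2", {
  fx <- training_fixture(n = 70, seed = 47)
  f <- fx$features
  truth_m <- fx$truth$log2_total_median[
    match(paste(f$construct_id, f$state),
          paste(fx$truth$construct_id, fx$truth$state))]
  set.seed(48)
  cal <- tibble::tibble(construct_id = f$construct_id, state = f$state,
                        target = sample(truth_m))
  m <- train_activity_model(f, cal, cv_repeats = 2, seed = 49)
  expect_lte(m$report$test_r2, 0.1)
})

test_that("models survive a save/load round trip bit-identically", {
  fx <- training_fixture(n = 40, seed = 50)
  f <- fx$features
  cal <- tibble::tibble(
    construct_id = f$construct_id, state = f$state,
    target = fx$truth$log2_total_median[
      match(paste(f$construct_id, f$state),
            paste(fx$truth$construct_id, fx$truth$state))])
  m <- train_activity_model(f, cal, cv_repeats = 1, seed = 51)
  p1 <- predict_activity(m, f)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  p2 <- predict_activity(m2, f)
  expect_identical(p1$predicted, p2$predicted)

  # prediction is order-invariant
  shuf <- f[sample(nrow(f)), ]
  p3 <- predict_activity(m, shuf)
  key <- paste(p3$construct_id, p3$state)
  expect_equal(p3$predicted,
               p1$predicted[match(key, paste(p1$construct_id, p1$state))])

  # schema mismatch errors
  expect_error(predict_activity(m, f[, 1:10]), "schema mismatch")
})

test_that("training is reproducible and filtered constructs are flagged", {
  fx <- training_fixture(n = 40, seed = 52)
  f <- fx$features
  cal <- tibble::tibble(
    construct_id = f$construct_id, state = f$state,
    target = fx$truth$log2_total_median[
      match(paste(f$construct_id, f$state),
            paste(fx$truth$construct_id, fx$truth$state))])
  m1 <- train_activity_model(f, cal, cv_repeats = 2, seed = 53)
  m2 <- train_activity_model(f, cal, cv_repeats = 2, seed = 53)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$report$test_ids, m2$report$test_ids)

  all_ids <- c(unique(f$construct_id), "SP99999")
  pred <- predict_library(m1, f, all_ids = all_ids)
  expect_true(all(pred$filtered[pred$construct_id == "SP99999"]))
  expect_true(all(is.na(pred$predicted[pred$construct_id == "SP99999"])))
  expect_false(any(pred$filtered[pred$construct_id != "SP99999"]))
})
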