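test_that("the train/test split is seeded, disjoint and exhaustive", {
  x <- as.list(letters[1:10])
  sp <- split_train_test(x, 0.8, seed = 3)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), letters[1:10])
  sp2 <- split_train_test(x, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_test(list(), 0.8), "invalid-argument")
  expect_error(split_train_test(x, 1.2), "invalid-argument")
})

test_that("frequency tables count, rank and normalize per edge type", {
  ord <- build_order(3)
  e <- list(i = 9L, j = 13L, value = 1, type = classify_edge(ord, 9, 13),
            relevant = relevant_positions(9, 13))
  mk <- function(s) {
    bits <- integer(15)
    bits[12:13] <- as.integer(strsplit(s, "")[[1]])
    dmdgp:::new_bits(bits, 1L)
  }
  ft <- build_freq_table(list(mk("01"), mk("01"), mk("10")),
                         rep(list(list(e)), 3))
  g <- ft$table
  expect_equal(g$sequence, c("01", "10"))
  expect_equal(g$count, c(2L, 1L))
  expect_equal(g$probability, c(2 / 3, 1 / 3))
  expect_equal(g$rank, 1:2)
  # ties broken lexicographically
  ft2 <- build_freq_table(list(mk("10"), mk("01")), rep(list(list(e)), 2))
  expect_equal(ft2$table$sequence, c("01", "10"))
  # empty input is a valid table forcing full fallback in FBS
  ft0 <- build_freq_table(list(), list())
  expect_equal(nrow(ft0$table), 0L)
  expect_length(dmdgp:::freq_sequences(ft0, "C-5-CA"), 0L)
})

test_that("a planted sequence law is recovered from 5000 draws", {
  law <- ha10_law()
  ord <- build_order(3)
  e <- list(i = 2L, j = 11L, value = 1, type = classify_edge(ord, 2, 11),
            relevant = relevant_positions(2, 11))
  set.seed(314)
  draws <- sample(seq_along(law$sequences), 5000, replace = TRUE,
                  prob = law$probs)
  bits_list <- lapply(draws, function(k) global_with_window(law$sequences[k]))
  ft <- build_freq_table(bits_list, rep(list(list(e)), length(bits_list)))
  g <- ft$table
  expect_equal(g$sequence, law$sequences) # ranking preserved
  expect_lt(max(abs(g$probability - law$probs)), 0.03)
  cv <- accumulated_curve(ft, "HA-10-H")
  expect_true(all(cv$cumulative >= cv$index - 1e-12)) # majorizes the diagonal
  expect_equal(cv$cumulative[nrow(cv)], 1)
})

test_that("sequence-space accounting matches the edge-type lengths", {
  expect_equal(kmax("HA-10-H"), 64L)
  expect_equal(kmax("HA-7-HA"), 8L)
  expect_equal(kmax("C-5-CA"), 2L)
  expect_equal(kmax("HA-10-H", raw = TRUE), 128L)
  expect_error(kmax("C-3-CA"), "invalid-argument")
  expect_error(kmax("nonsense"), "invalid-argument")
})

test_that("accumulated curves are normalized rank maps", {
  ord <- build_order(3)
  e <- list(i = 2L, j = 11L, value = 1, type = "HA-10-H",
            relevant = relevant_positions(2, 11))
  mk <- function(s) global_with_window(s)
  # uniform counts: curve on the diagonal
  ft <- build_freq_table(lapply(c("0000000", "1000000", "0100000", "1100000"), mk),
                         rep(list(list(e)), 4))
  cv <- accumulated_curve(ft, "HA-10-H")
  expect_equal(cv$cumulative, cv$index)
  # single sequence
  ft1 <- build_freq_table(list(mk("0000000")), list(list(e)))
  expect_equal(accumulated_curve(ft1, "HA-10-H"),
               data.frame(index = 1, cumulative = 1))
  expect_error(accumulated_curve(ft1, "HA-7-HA"), "lookup error")
})

test_that("frequency tables and curves serialize to CSV", {
  ft <- build_freq_table(
    lapply(c("0000000", "0000000", "0100000"), global_with_window),
    rep(list(list(list(i = 2L, j = 11L, value = 1, type = "HA-10-H",
                       relevant = relevant_positions(2, 11)))), 3))
  p1 <- tempfile(fileext = ".csv")
  write_freq_csv(ft, p1)
  back <- read_freq_csv(p1)
  expect_equal(back$table$sequence, ft$table$sequence)
  expect_equal(back$table$count, ft$table$count)
  p2 <- tempfile(fileext = ".csv")
  write_curves_csv(ft, p2)
  cc <- utils::read.csv(p2)
  expect_equal(cc$cumulative_probability[nrow(cc)], 1)
})

test_that("inconsistent sequence lengths within a type are rejected", {
  good <- list(i = 2L, j = 11L, value = 1, type = "HA-10-H",
               relevant = relevant_positions(2, 11))
  bad <- list(i = 2L, j = 8L, value = 1, type = "HA-10-H",
              relevant = relevant_positions(2, 8))
  expect_error(
    build_freq_table(list(global_with_window("0000000"),
                          global_with_window("0000000")),
                     list(list(good), list(bad))),
    "data error")
})
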