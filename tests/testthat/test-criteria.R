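test_that("count classification follows the m/M boundary convention", {
  lim <- mab_limit()
  expect_equal(
    as.character(classify_count(c(4.2, 5.5, 6.01, 5.0, 6.0), lim)),
    c("satisfactory", "acceptable", "unsatisfactory",
      "satisfactory", "acceptable")
  )
  expect_error(classify_count(-0.1, lim), "non-negative")
  lab <- dplyr::filter(default_limits(), analyte == "LAB")
  expect_error(classify_count(3, lab), "count_limits")
})

test_that("count classification is monotone in the measured value", {
  lim <- mab_limit()
  set.seed(11)
  for (rep in 1:50) {
    v <- sort(runif(20, 0, 9))
    lv <- classify_count(v, lim)
    expect_true(all(diff(as.integer(lv)) >= 0))
  }
})

test_that("presence results map to the two extreme classes only", {
  expect_equal(as.character(classify_presence(FALSE)), "satisfactory")
  expect_equal(as.character(classify_presence(TRUE)), "unsatisfactory")
  all_clear <- classify_presence(rep(FALSE, 216))
  expect_equal(mean(all_clear == "satisfactory"), 1)
})

test_that("replicate sets follow the sampling-plan rule", {
  lim <- mab_limit()
  expect_equal(as.character(
    evaluate_replicate_set(c(4.1, 4.3, 4.0, 4.9, 4.5), lim, c = 2)),
    "satisfactory")
  expect_equal(as.character(
    evaluate_replicate_set(c(4.1, 5.5, 4.0, 4.9, 4.5), lim, c = 2)),
    "acceptable")
  expect_equal(as.character(
    evaluate_replicate_set(c(4.1, 5.5, 6.2, 4.9, 4.5), lim, c = 2)),
    "unsatisfactory")
  expect_error(evaluate_replicate_set(numeric(0), lim), "empty")
  expect_error(evaluate_replicate_set(c(4, 5), lim, c = 2), "smaller")
})

test_that("replicate-set rule agrees with a brute-force classifier", {
  lim <- mab_limit()
  set.seed(21)
  for (rep in 1:1000) {
    n <- sample(2:8, 1)
    cc <- sample.int(n - 1, 1)
    v <- runif(n, 3, 7.5)
    expect_equal(as.character(evaluate_replicate_set(v, lim, c = cc)),
                 oracle_replicate_set(v, m = 5, M = 6, c = cc))
  }
})

test_that("with c = n - 1, nothing above M and at least one compliant
           replicate, a set is never unsatisfactory", {
  lim <- mab_limit()
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    v <- c(runif(n - 1, 0, 6), runif(1, 0, 5))  # none above M, one <= m
    expect_lt(as.integer(evaluate_replicate_set(v, lim, c = n - 1)), 3)
  }
  # all replicates in (m, M] exceed any c < n, whatever c is
  expect_equal(as.character(
    evaluate_replicate_set(c(5.5, 5.6, 5.7), lim, c = 2)),
    "unsatisfactory")
})

test_that("batch verdict is the worst per-analyte class", {
  expect_equal(as.character(evaluate_batch(
    c(MAB = "satisfactory", E_COLI = "satisfactory"))), "satisfactory")
  expect_equal(as.character(evaluate_batch(
    c(MAB = "acceptable", E_COLI = "satisfactory"))), "acceptable")
  expect_equal(as.character(evaluate_batch(
    c(MAB = "acceptable", SALMONELLA = "unsatisfactory"))), "unsatisfactory")
  expect_error(evaluate_batch(character(0)), "empty")
  # single-analyte identity
  for (lv in class_levels()) {
    expect_equal(as.character(evaluate_batch(c(MAB = lv))), lv)
  }
})

test_that("class summaries count records correctly", {
  base <- tibble::tibble(
    e_coli = 1, s_aureus = 1, lab = 3,
    salmonella_present = FALSE, l_mono_present = FALSE
  )
  all_low <- dplyr::mutate(base[rep(1, 5), ], mab = 4.0)
  s1 <- summarize_classes(all_low)
  expect_equal(s1$percent_satisfactory[s1$analyte == "MAB"], 100)

  ten <- dplyr::mutate(base[rep(1, 10), ],
                       mab = c(4, 4, 4, 5.5, 5.5, 5.5, 6.5, 6.5, 6.5, 6.5))
  s2 <- summarize_classes(ten)
  row <- s2[s2$analyte == "MAB", ]
  expect_equal(unlist(row[, -1], use.names = FALSE), c(30, 30, 40))

  expect_error(summarize_classes(dplyr::select(ten, -mab)), "MAB")
  expect_error(summarize_classes(ten[0, ]), "empty")
})

test_that("class percentages sum to 100 for every analyte", {
  d <- generate_dataset(generator_config(seed = 5))
  s <- summarize_classes(d)
  sums <- s$percent_satisfactory + s$percent_acceptable +
    s$percent_unsatisfactory
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("LAB binning uses left-closed bins with a closed last bin", {
  f <- bin_lab(c(1.0, 3.0, 5.0, 6.5))
  expect_equal(f$count, c(1L, 1L, 1L, 1L))
  expect_equal(bin_lab(numeric(0))$count, rep(0L, 4))
  # edge membership: 2 belongs to [2,4); 7 to the closed last bin
  expect_equal(bin_lab(c(2, 7))$count, c(0L, 1L, 0L, 1L))
  expect_warning(f2 <- bin_lab(c(-1, 8)), "terminal")
  expect_equal(f2$count, c(1L, 0L, 0L, 1L))
  expect_error(bin_lab(1, edges = c(0, 2, 2)), "increasing")
  set.seed(41)
  v <- runif(100, 0, 7)
  expect_equal(sum(bin_lab(v)$count), 100L)
})

test_that("limits registry round-trips through YAML and JSON", {
  lim <- default_limits()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_limits(lim, path)
    expect_equal(read_limits(path), lim)
  }
  bad <- dplyr::mutate(lim, m = ifelse(analyte == "MAB", 7, m))
  expect_error(meatmicro:::validate_limits(bad), "strictly below")
})
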