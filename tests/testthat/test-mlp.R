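test_that("feature encoding produces the fixed 9-column layout", {
  x <- encode_features(tibble::tibble(storage_temp = 4, meat_temp = 6,
                                      butcher = "B", weekday = "Monday"))
  expect_equal(as.vector(x), c(4, 6, 0, 1, 0, 0, 0, 1, 0))
  x2 <- encode_features(tibble::tibble(storage_temp = 2, meat_temp = 2,
                                       butcher = "A", weekday = "Friday"))
  expect_equal(as.vector(x2), c(2, 2, 1, 0, 0, 0, 1, 0, 0))
  expect_equal(colnames(x), feature_names())
  expect_error(encode_features(tibble::tibble(
    storage_temp = 4, meat_temp = 6, butcher = "E", weekday = "Monday")),
    "unknown butcher")
})

test_that("one-hot blocks each sum to one", {
  d <- generate_dataset(generator_config(seed = 3))
  x <- encode_features(d)
  expect_true(all(rowSums(x[, 3:6]) == 1))
  expect_true(all(rowSums(x[, 7:9]) == 1))
})

test_that("forward pass matches hand-evaluated cases", {
  # zero weights: output is the output bias
  p0 <- mlp_parameters(matrix(0, 3, 2), c(1, 2, 3), matrix(0, 1, 3), 7)
  expect_equal(as.vector(mlp_forward(p0, c(5, 5))), 7)
  # logistic(0) = 0.5 through a single unit
  p1 <- mlp_parameters(matrix(0, 3, 2), rep(0, 3),
                       matrix(c(1, 0, 0), 1, 3), 0)
  expect_equal(as.vector(mlp_forward(p1, c(9, -9))), 0.5)
  # identity 2-2-1 toy net at the origin: 0.5 + 0.5
  p2 <- mlp_parameters(diag(2), c(0, 0), matrix(c(1, 1), 1, 2), 0)
  expect_equal(as.vector(mlp_forward(p2, c(0, 0))), 1.0)
  expect_error(mlp_forward(p2, c(1, 2, 3)), "feature columns")
})

test_that("forward pass is invariant to hidden-unit permutation", {
  params <- load_published_weights()
  set.seed(12)
  x <- matrix(runif(5 * 9), 5, 9)
  base <- mlp_forward(params, x)
  for (rep in 1:5) {
    perm <- sample(10)
    permuted <- mlp_parameters(params$W1[perm, ], params$B1[perm],
                               params$W2[, perm], params$B2)
    expect_equal(mlp_forward(permuted, x), base, ignore_attr = TRUE)
  }
})

test_that("published weights load with the printed spot values", {
  p <- load_published_weights()
  expect_equal(dim(p$W1), c(10L, 9L))
  expect_equal(dim(p$W2), c(4L, 10L))
  expect_equal(unname(p$W1[1, "storage_temp"]), 3.70)
  expect_equal(p$B2[1], 0.30)              # MAB output bias
  expect_equal(unname(p$W2["e_coli", 3]), 71.22)
  expect_equal(p$hidden_activation, "logistic")
  expect_equal(p$output_activation, "identity")
})

test_that("a corrupted weight file fails the checksum", {
  src <- system.file("extdata", "published_weights.json",
                     package = "meatmicro")
  tampered <- withr::local_tempfile(fileext = ".json")
  txt <- readLines(src)
  txt <- sub("3.7,", "4.7,", txt, fixed = TRUE)
  writeLines(txt, tampered)
  expect_error(read_mlp(tampered), "checksum")
})

test_that("min-max normalization round-trips and rejects constants", {
  nz <- fit_normalizer(data.frame(x = c(2, 7)), "x")
  expect_equal(normalizer_apply(nz, data.frame(x = c(2, 7)))$x, c(0, 1))
  expect_error(fit_normalizer(data.frame(x = c(4, 4, 4)), "x"), "constant")
  set.seed(13)
  d <- data.frame(a = rnorm(50), b = runif(50, -3, 9))
  nz2 <- fit_normalizer(d, c("a", "b"))
  back <- normalizer_invert(nz2, normalizer_apply(nz2, d))
  expect_equal(back, d, tolerance = 1e-9)
})

test_that("training is deterministic for a fixed seed", {
  d <- generate_dataset(generator_config(seed = 14))
  f1 <- suppressWarnings(train_mlp(d, seed = 3, max_iter = 150))
  f2 <- suppressWarnings(train_mlp(d, seed = 3, max_iter = 150))
  expect_identical(f1$params$W1, f2$params$W1)
  expect_identical(f1$performance, f2$performance)
})

test_that("splits are disjoint and cover the data", {
  d <- generate_dataset(generator_config(seed = 15))
  f <- suppressWarnings(train_mlp(d, seed = 1, max_iter = 100))
  all_idx <- sort(unlist(f$splits, use.names = FALSE))
  expect_equal(all_idx, seq_len(nrow(d)))
  expect_true(all(f$performance$r2 <= 1))
})

test_that("SOS never increases across successive BFGS segments", {
  d <- generate_dataset(generator_config(seed = 16))
  x <- encode_features(d)
  nz <- fit_normalizer(d, c("storage_temp", "meat_temp", output_names()))
  sc <- normalizer_apply(nz, d)
  x[, "storage_temp"] <- sc$storage_temp
  x[, "meat_temp"] <- sc$meat_temp
  y <- as.matrix(sc[, output_names()])
  set.seed(17)
  theta <- runif(meatmicro:::mlp_sizes(9, 10, 4), -0.1, 0.1)
  values <- meatmicro:::sos_value(theta, x, y, 9, 10, 4)
  for (seg in 1:8) {
    opt <- optim(theta, meatmicro:::sos_value, meatmicro:::sos_gradient,
                 x = x, y = y, ni = 9, nh = 10, no = 4,
                 method = "BFGS", control = list(maxit = 20))
    theta <- opt$par
    values <- c(values, meatmicro:::sos_value(theta, x, y, 9, 10, 4))
  }
  expect_true(all(diff(values) <= 1e-8))
})

test_that("training recovers a known noiseless network", {
  rec <- known_net_records(seed = 99)
  fit <- train_mlp(rec, seed = 1, max_iter = 5000,
                   check_every = 200, patience = 10)
  g <- glance(fit)
  expect_gte(g$r2_test, 0.99)
  expect_gte(g$r2_validation, 0.99)
  mt <- metrics_table(fit, rec)
  expect_true(all(mt$rmse <= 0.05))
})

test_that("model serialization round-trips a fitted model", {
  d <- generate_dataset(generator_config(seed = 18))
  f <- suppressWarnings(train_mlp(d, seed = 2, max_iter = 100))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(f, path)
  back <- read_mlp(path)
  expect_s3_class(back, "mlp_fit")
  expect_equal(back$params$W1, f$params$W1, tolerance = 1e-12)
  expect_equal(back$splits, f$splits)
  expect_equal(predict(back, d), predict(f, d), tolerance = 1e-9)
})

test_that("tidy and glance summarise a fit", {
  d <- generate_dataset(generator_config(seed = 19))
  f <- suppressWarnings(train_mlp(d, seed = 2, max_iter = 100))
  td <- tidy(f)
  expect_equal(td$split, c("train", "test", "validation"))
  expect_equal(names(glance(f)),
               c("hidden", "iterations", "converged",
                 "r2_train", "r2_test", "r2_validation"))
})
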