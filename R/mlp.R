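#' Feature and output layout of the 9-10-4 network
#'
#' The network predicts the four microbial counts from nine process
#' features in a fixed order: the two temperatures, a one-hot butcher block
#' (A-D) and a one-hot weekday block (Friday, Monday, Wednesday).
#'
#' @return Character vector of column names.
#' @export
feature_names <- function() {
  c("storage_temp", "meat_temp",
    "butcher_A", "butcher_B", "butcher_C", "butcher_D",
    "weekday_Friday", "weekday_Monday", "weekday_Wednesday")
}

#' @rdname feature_names
#' @export
output_names <- function() {
  c("mab", "lab", "e_coli", "s_aureus")
}

#' Encode sample records as network features
#'
#' Builds the 9-column design matrix: raw temperatures plus one-hot butcher
#' and weekday indicators (each block sums to one per row).
#'
#' @param records Table with `storage_temp`, `meat_temp`, `butcher`,
#'   `weekday` columns.
#' @return Numeric matrix, `nrow(records)` x 9, columns [feature_names()].
#' @export
#' @examples
#' encode_features(tibble::tibble(storage_temp = 4, meat_temp = 6,
#'                                butcher = "B", weekday = "Monday"))
encode_features <- function(records) {
  butchers <- c("A", "B", "C", "D")
  wdays <- c("Friday", "Monday", "Wednesday")
  bad_b <- setdiff(unique(records$butcher), butchers)
  if (length(bad_b) > 0) {
    abort(paste0("unknown butcher(s): ", paste(bad_b, collapse = ", ")))
  }
  bad_w <- setdiff(unique(records$weekday), wdays)
  if (length(bad_w) > 0) {
    abort(paste0("unknown weekday(s): ", paste(bad_w, collapse = ", ")))
  }
  x <- cbind(
    records$storage_temp,
    records$meat_temp,
    outer(records$butcher, butchers, `==`) * 1,
    outer(records$weekday, wdays, `==`) * 1
  )
  colnames(x) <- feature_names()
  x
}

#' Multilayer-perceptron parameter set
#'
#' Holds the weights and biases of a single-hidden-layer perceptron
#' `y = f_out(W2 f_hid(W1 x + B1) + B2)` with a logistic hidden layer and
#' identity output layer.
#'
#' @param W1 Hidden-by-input weight matrix (10 x 9 for the standard net).
#' @param B1 Hidden bias vector.
#' @param W2 Output-by-hidden weight matrix (4 x 10).
#' @param B2 Output bias vector.
#' @param hidden_activation,output_activation Activation identifiers;
#'   only `"logistic"` and `"identity"` are supported.
#' @param input_labels,output_labels Optional dimension labels.
#' @return An object of class `mlp_parameters`.
#' @export
mlp_parameters <- function(W1, B1, W2, B2,
                           hidden_activation = "logistic",
                           output_activation = "identity",
                           input_labels = NULL, output_labels = NULL) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  B1 <- as.numeric(B1); B2 <- as.numeric(B2)
  if (nrow(W1) != length(B1)) abort("W1 rows must match length(B1)")
  if (nrow(W2) != length(B2)) abort("W2 rows must match length(B2)")
  if (ncol(W2) != nrow(W1)) abort("ncol(W2) must equal nrow(W1)")
  if (!all(is.finite(W1)) || !all(is.finite(W2)) ||
      !all(is.finite(B1)) || !all(is.finite(B2))) {
    abort("all parameters must be finite")
  }
  if (!identical(hidden_activation, "logistic") ||
      !identical(output_activation, "identity")) {
    abort("only logistic hidden / identity output activations are supported")
  }
  input_labels <- input_labels %||% colnames(W1)
  output_labels <- output_labels %||% rownames(W2)
  if (!is.null(input_labels)) colnames(W1) <- input_labels
  if (!is.null(output_labels)) rownames(W2) <- output_labels
  structure(
    list(W1 = W1, B1 = B1, W2 = W2, B2 = B2,
         hidden_activation = hidden_activation,
         output_activation = output_activation,
         input_labels = input_labels,
         output_labels = output_labels),
    class = "mlp_parameters"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mlp_parameters <- function(x, ...) {
  cat(sprintf("<mlp_parameters> %d-%d-%d (hidden: %s, output: %s)\n",
              ncol(x$W1), nrow(x$W1), nrow(x$W2),
              x$hidden_activation, x$output_activation))
  invisible(x)
}

#' Forward pass through the perceptron
#'
#' Computes `identity(W2 logistic(W1 x + B1) + B2)` row-wise.
#'
#' @param params An [mlp_parameters()] object.
#' @param x Numeric vector (one sample) or matrix (samples in rows) with as
#'   many feature columns as `ncol(params$W1)`.
#' @return Numeric matrix, samples x outputs; columns carry the output
#'   labels when present.
#' @export
mlp_forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(params$W1)) {
    abort(sprintf("expected %d feature columns, got %d",
                  ncol(params$W1), ncol(x)))
  }
  h <- plogis(sweep(x %*% t(params$W1), 2, params$B1, `+`))
  y <- sweep(h %*% t(params$W2), 2, params$B2, `+`)
  colnames(y) <- params$output_labels
  y
}

#' Min-max normalizer
#'
#' Fits per-column minimum and maximum on the named columns of a table and
#' rescales them to `[0, 1]`; other columns pass through untouched.
#' `normalizer_invert()` undoes the scaling exactly (to within floating
#' point).
#'
#' @param data Data frame to fit on.
#' @param columns Columns to scale; must be non-constant.
#' @return A `minmax_normalizer` object.
#' @export
#' @examples
#' nz <- fit_normalizer(data.frame(x = c(2, 7)), "x")
#' normalizer_apply(nz, data.frame(x = c(2, 7)))$x
fit_normalizer <- function(data, columns) {
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not in data: ", paste(missing_cols, collapse = ", ")))
  }
  ranges <- purrr::map(setNames(columns, columns), function(col) {
    r <- range(data[[col]])
    if (r[1] == r[2]) {
      abort(paste0("column '", col, "' is constant; cannot min-max scale"))
    }
    r
  })
  structure(list(ranges = ranges, method = "minmax"),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `minmax_normalizer`.
#' @export
normalizer_apply <- function(normalizer, data) {
  for (col in intersect(names(normalizer$ranges), names(data))) {
    r <- normalizer$ranges[[col]]
    data[[col]] <- (data[[col]] - r[1]) / (r[2] - r[1])
  }
  data
}

#' @rdname fit_normalizer
#' @export
normalizer_invert <- function(normalizer, data) {
  for (col in intersect(names(normalizer$ranges), names(data))) {
    r <- normalizer$ranges[[col]]
    data[[col]] <- data[[col]] * (r[2] - r[1]) + r[1]
  }
  data
}

## --- parameter vector packing for optim -------------------------------

mlp_sizes <- function(ni, nh, no) ni * nh + nh + nh * no + no

mlp_unpack <- function(theta, ni, nh, no) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  B1 <- theta[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(theta[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  B2 <- theta[i + seq_len(no)]
  list(W1 = W1, B1 = B1, W2 = W2, B2 = B2)
}

mlp_pack <- function(p) c(as.vector(p$W1), p$B1, as.vector(p$W2), p$B2)

sos_value <- function(theta, x, y, ni, nh, no) {
  p <- mlp_unpack(theta, ni, nh, no)
  h <- plogis(sweep(x %*% t(p$W1), 2, p$B1, `+`))
  pred <- sweep(h %*% t(p$W2), 2, p$B2, `+`)
  sum((pred - y)^2)
}

sos_gradient <- function(theta, x, y, ni, nh, no) {
  p <- mlp_unpack(theta, ni, nh, no)
  h <- plogis(sweep(x %*% t(p$W1), 2, p$B1, `+`))
  pred <- sweep(h %*% t(p$W2), 2, p$B2, `+`)
  e <- pred - y
  d_w2 <- 2 * t(e) %*% h
  d_b2 <- 2 * colSums(e)
  dz <- (2 * (e %*% p$W2)) * h * (1 - h)
  d_w1 <- t(dz) %*% x
  d_b1 <- colSums(dz)
  c(as.vector(d_w1), d_b1, as.vector(d_w2), d_b2)
}

## --- training ----------------------------------------------------------

#' Train the perceptron on a sample table
#'
#' Fits a `9-hidden-4` network by BFGS on the sum-of-squares (SOS) error of
#' the training split, with min-max normalization of the temperatures and
#' all four outputs fitted on the full table. The data are split at random
#' (seeded) into training / testing / validation subsets; optimization runs
#' in segments of `check_every` BFGS iterations with early stopping once
#' the validation SOS has failed to improve for `patience` consecutive
#' checks, returning the parameters with the best validation error seen.
#'
#' @param data Sample table with the columns of [generate_dataset()]
#'   (at least temperatures, butcher, weekday and the four counts);
#'   at least 30 rows.
#' @param hidden Hidden-layer size; default 10.
#' @param seed Integer seed for the split and the uniform
#'   `[-init_range, init_range]` weight initialization.
#' @param split Train/test/validation fractions summing to 1;
#'   default `c(0.70, 0.15, 0.15)`.
#' @param max_iter Total BFGS iteration budget; default 10000.
#' @param check_every Iterations between validation checks; default 25.
#' @param patience Checks without validation improvement tolerated before
#'   stopping; default 3.
#' @param init_range Half-width of the uniform initial weight range.
#' @param reltol Relative convergence tolerance handed to [stats::optim()];
#'   tighten (e.g. `1e-12`) for high-precision fits on noiseless data.
#' @return An object of class `mlp_fit` with elements `params`
#'   ([mlp_parameters()]), `normalizer`, `splits` (row indices),
#'   `performance` (per-split r-squared and SOS), `iterations`, `converged`.
#'   The per-split r-squared is the mean over the four analytes of
#'   `1 - SS_res/SS_tot` on the original count scale.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' fit <- train_mlp(d, seed = 1, max_iter = 500)
#' glance(fit)
train_mlp <- function(data, hidden = 10, seed = 1L,
                      split = c(0.70, 0.15, 0.15),
                      max_iter = 10000, check_every = 25, patience = 3,
                      init_range = 0.1, reltol = 1e-8) {
  if (nrow(data) < 30) abort("need at least 30 rows to train")
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3) {
    abort("split must be three fractions summing to 1")
  }
  x_raw <- encode_features(data)
  normalizer <- fit_normalizer(data, c("storage_temp", "meat_temp",
                                       output_names()))
  scaled <- normalizer_apply(normalizer, data)
  x <- x_raw
  x[, "storage_temp"] <- scaled$storage_temp
  x[, "meat_temp"] <- scaled$meat_temp
  y <- as.matrix(scaled[, output_names()])

  n <- nrow(data)
  set.seed(seed)
  idx <- sample.int(n)
  n_tr <- round(split[1] * n)
  n_te <- round(split[2] * n)
  splits <- list(
    train = sort(idx[seq_len(n_tr)]),
    test = sort(idx[n_tr + seq_len(n_te)]),
    validation = sort(idx[(n_tr + n_te + 1):n])
  )

  ni <- ncol(x); no <- ncol(y)
  theta <- runif(mlp_sizes(ni, hidden, no), -init_range, init_range)
  x_tr <- x[splits$train, , drop = FALSE]
  y_tr <- y[splits$train, , drop = FALSE]
  x_va <- x[splits$validation, , drop = FALSE]
  y_va <- y[splits$validation, , drop = FALSE]

  best_theta <- theta
  best_va <- Inf
  stalls <- 0
  iters <- 0
  converged <- FALSE
  while (iters < max_iter) {
    opt <- optim(theta, sos_value, sos_gradient,
                 x = x_tr, y = y_tr, ni = ni, nh = hidden, no = no,
                 method = "BFGS",
                 control = list(maxit = min(check_every, max_iter - iters),
                                reltol = reltol))
    theta <- opt$par
    iters <- iters + min(check_every, max_iter - iters)
    va <- sos_value(theta, x_va, y_va, ni, hidden, no)
    if (va < best_va - 1e-10) {
      best_va <- va
      best_theta <- theta
      stalls <- 0
    } else {
      stalls <- stalls + 1
    }
    if (stalls >= patience) {
      converged <- TRUE  # stopped by validation plateau
      break
    }
    if (opt$convergence == 0) {
      if (sos_value(theta, x_tr, y_tr, ni, hidden, no) <
          sos_value(best_theta, x_tr, y_tr, ni, hidden, no) &&
          va <= best_va + 1e-10) {
        best_theta <- theta
        best_va <- va
      }
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("BFGS did not converge within %d iterations; %s",
                 max_iter, "returning best parameters found"))
  }

  p <- mlp_unpack(best_theta, ni, hidden, no)
  params <- mlp_parameters(p$W1, p$B1, p$W2, p$B2,
                           input_labels = feature_names(),
                           output_labels = output_names())

  pred_n <- mlp_forward(params, x)
  pred <- normalizer_invert(normalizer,
                            tibble::as_tibble(as.data.frame(pred_n)))
  obs <- data[, output_names()]
  performance <- purrr::map_dfr(
    setNames(names(splits), names(splits)),
    function(s) {
      rows <- splits[[s]]
      r2s <- purrr::map_dbl(output_names(), function(a) {
        o <- obs[[a]][rows]; pr <- pred[[a]][rows]
        1 - sum((o - pr)^2) / sum((o - mean(o))^2)
      })
      tibble::tibble(
        split = s,
        n = length(rows),
        r2 = mean(r2s),
        sos = sos_value(best_theta, x[rows, , drop = FALSE],
                        y[rows, , drop = FALSE], ni, hidden, no)
      )
    }
  )

  structure(
    list(params = params, normalizer = normalizer, splits = splits,
         performance = performance, iterations = iters,
         converged = converged, hidden = hidden, seed = seed),
    class = "mlp_fit"
  )
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("<mlp_fit> %d-%d-%d perceptron, %d BFGS iterations%s\n",
              ncol(x$params$W1), x$hidden, nrow(x$params$W2), x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$performance)
  invisible(x)
}

#' Predict microbial counts for new records
#'
#' @param object An `mlp_fit` from [train_mlp()].
#' @param newdata Sample table with temperature, butcher and weekday
#'   columns.
#' @param ... Unused.
#' @return Tibble of predicted counts (log10 CFU/g), one column per
#'   analyte.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  x <- encode_features(newdata)
  scaled <- normalizer_apply(object$normalizer, newdata)
  x[, "storage_temp"] <- scaled$storage_temp
  x[, "meat_temp"] <- scaled$meat_temp
  pred_n <- mlp_forward(object$params, x)
  normalizer_invert(object$normalizer,
                    tibble::as_tibble(as.data.frame(pred_n)))
}

#' @rdname train_mlp
#' @param x An `mlp_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-split performance tibble; `glance()` a
#'   one-row summary.
#' @export
tidy.mlp_fit <- function(x, ...) {
  x$performance
}

#' @rdname train_mlp
#' @export
glance.mlp_fit <- function(x, ...) {
  perf <- x$performance
  tibble::tibble(
    hidden = x$hidden,
    iterations = x$iterations,
    converged = x$converged,
    r2_train = perf$r2[perf$split == "train"],
    r2_test = perf$r2[perf$split == "test"],
    r2_validation = perf$r2[perf$split == "validation"]
  )
}
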