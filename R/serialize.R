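#' Serialize network parameters or fitted models to JSON
#'
#' A flat text format holding the layer shapes, weights, biases, activation
#' identifiers, optional labels and normalizer ranges, plus a checksum (the
#' rounded sum of absolute weight values and the value count) verified on
#' load.
#'
#' @param object An [mlp_parameters()] or `mlp_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mlp <- function(object, path) {
  if (inherits(object, "mlp_fit")) {
    params <- object$params
    extra <- list(
      normalizer = object$normalizer$ranges,
      splits = object$splits,
      performance = object$performance,
      iterations = object$iterations,
      converged = object$converged,
      seed = object$seed
    )
  } else if (inherits(object, "mlp_parameters")) {
    params <- object
    extra <- NULL
  } else {
    abort("write_mlp() expects an mlp_parameters or mlp_fit object")
  }
  values <- c(params$W1, params$B1, params$W2, params$B2)
  payload <- list(
    type = if (is.null(extra)) "mlp_parameters" else "mlp_fit",
    shape = c(ncol(params$W1), nrow(params$W1), nrow(params$W2)),
    hidden_activation = params$hidden_activation,
    output_activation = params$output_activation,
    input_labels = params$input_labels,
    output_labels = params$output_labels,
    W1 = apply(params$W1, 1, identity, simplify = FALSE),
    B1 = params$B1,
    W2 = apply(params$W2, 1, identity, simplify = FALSE),
    B2 = params$B2,
    checksum = list(abs_sum = round(sum(abs(values)), 2),
                    n_values = length(values))
  )
  payload <- c(payload, extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @return `read_mlp()` returns the stored `mlp_parameters` or `mlp_fit`.
#' @export
read_mlp <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(j$shape)
  as_mat <- function(w, nr, nc) {
    if (is.matrix(w)) {
      matrix(as.numeric(w), nr, nc)
    } else {
      matrix(unlist(w), nr, nc, byrow = TRUE)
    }
  }
  W1 <- as_mat(j$W1, shape[2], shape[1])
  W2 <- as_mat(j$W2, shape[3], shape[2])
  params <- mlp_parameters(
    W1, as.numeric(j$B1), W2, as.numeric(j$B2),
    hidden_activation = j$hidden_activation,
    output_activation = j$output_activation,
    input_labels = j$input_labels,
    output_labels = j$output_labels
  )
  values <- c(params$W1, params$B1, params$W2, params$B2)
  if (length(values) != j$checksum$n_values ||
      abs(round(sum(abs(values)), 2) - j$checksum$abs_sum) > 1e-8) {
    abort(paste0("checksum mismatch in ", path, "; file is corrupt"))
  }
  if (identical(j$type, "mlp_parameters") || is.null(j$type)) {
    return(params)
  }
  normalizer <- structure(
    list(ranges = purrr::map(j$normalizer, as.numeric), method = "minmax"),
    class = "minmax_normalizer"
  )
  structure(
    list(params = params, normalizer = normalizer,
         splits = purrr::map(j$splits, as.integer),
         performance = tibble::as_tibble(j$performance),
         iterations = j$iterations, converged = j$converged, seed = j$seed),
    class = "mlp_fit"
  )
}

#' Load the published reference weights
#'
#' Returns the 9-10-4 weight set published for the minced-beef
#' microbiological-quality network, shipped as a JSON fixture
#' (transcribed at the two-decimal precision it was printed with). The
#' original normalization ranges were not published, so these weights are
#' intended for weight-structure analyses - above all the Yoon
#' connection-weight sensitivity analysis ([yoon_importance()]) - rather
#' than physical-unit prediction.
#'
#' @return An [mlp_parameters()] object (checksum-verified on load).
#' @export
#' @examples
#' load_published_weights()
load_published_weights <- function() {
  path <- system.file("extdata", "published_weights.json",
                      package = "meatmicro")
  if (!nzchar(path)) abort("published weights fixture is missing")
  read_mlp(path)
}

#' @rdname load_published_weights
#' @return `published_weights_checksum()` returns the fixture checksum
#'   string.
#' @export
published_weights_checksum <- function() {
  path <- system.file("extdata", "published_weights.json",
                      package = "meatmicro")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sprintf("abs_sum=%.2f n=%d", j$checksum$abs_sum, j$checksum$n_values)
}
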