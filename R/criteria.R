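#' Ordered microbiological quality classes
#'
#' The three-level scheme used by food-hygiene guides: a result is
#' *satisfactory* when it does not exceed the lower limit `m`, *acceptable*
#' when it lies between `m` and the upper limit `M`, and *unsatisfactory*
#' when it exceeds `M`. The levels carry a total order
#' (satisfactory < acceptable < unsatisfactory) so that the worst level of a
#' set of analyses determines the verdict for a whole batch.
#'
#' @return Character vector of the three level names, in increasing severity.
#' @export
#' @examples
#' class_levels()
class_levels <- function() {
  c("satisfactory", "acceptable", "unsatisfactory")
}

#' @rdname class_levels
#' @param x Character vector of level names.
#' @return `as_class_level()` returns an ordered factor over the three levels.
#' @export
as_class_level <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(class_levels(), NA_character_))
  if (length(bad) > 0) {
    abort(paste0("unknown class level(s): ", paste(bad, collapse = ", ")))
  }
  factor(as.character(x), levels = class_levels(), ordered = TRUE)
}

#' Microbiological limits registry
#'
#' Default m/M limit values (log10 CFU/g) for minced meat. Mesophilic and
#' aerobic bacteria (MAB) have `m = 5`, `M = 6`; *E. coli* and *S. aureus*
#' have `m = 2`, `M = 3`. *Salmonella* spp. and *L. monocytogenes* are
#' presence-based criteria (absence in 25 g required); lactic acid bacteria
#' (LAB) are unregulated - no limit is defined for them, they are summarised
#' by frequency bins instead (see [bin_lab()]).
#'
#' @return A tibble with columns `analyte`, `mode` (one of `"count_limits"`,
#'   `"presence"`, `"unregulated"`), `m` and `M`.
#' @seealso [read_limits()] to load a registry from a YAML or JSON file.
#' @export
#' @examples
#' default_limits()
default_limits <- function() {
  lim <- tibble::tibble(
    analyte = c("MAB", "E_COLI", "S_AUREUS", "SALMONELLA", "L_MONO", "LAB"),
    mode = c("count_limits", "count_limits", "count_limits",
             "presence", "presence", "unregulated"),
    m = c(5, 2, 2, NA, NA, NA),
    M = c(6, 3, 3, NA, NA, NA)
  )
  validate_limits(lim)
}

validate_limits <- function(limits) {
  stopifnot(is.data.frame(limits))
  need <- c("analyte", "mode", "m", "M")
  missing_cols <- setdiff(need, names(limits))
  if (length(missing_cols) > 0) {
    abort(paste0("limits registry lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_mode <- setdiff(limits$mode, c("count_limits", "presence", "unregulated"))
  if (length(bad_mode) > 0) {
    abort(paste0("unknown limit mode(s): ", paste(bad_mode, collapse = ", ")))
  }
  cl <- limits$mode == "count_limits"
  if (any(is.na(limits$m[cl])) || any(is.na(limits$M[cl]))) {
    abort("count_limits analytes must have both m and M")
  }
  if (any(limits$m[cl] >= limits$M[cl])) {
    abort("m must be strictly below M for count-limit analytes")
  }
  tibble::as_tibble(limits)
}

#' Read or write a limits registry
#'
#' The registry is a small YAML or JSON file (chosen by extension) with one
#' entry per analyte: `analyte`, `mode`, and for count-limit analytes `m` and
#' `M` in log10 CFU/g.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_limits()` returns a validated limits tibble.
#' @export
read_limits <- function(path) {
  if (!file.exists(path)) abort(paste0("limits file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lim <- purrr::map_dfr(raw, function(e) {
    tibble::tibble(
      analyte = e[["analyte"]],
      mode = e[["mode"]],
      m = if (is.null(e[["m"]])) NA_real_ else as.numeric(e[["m"]]),
      M = if (is.null(e[["M"]])) NA_real_ else as.numeric(e[["M"]])
    )
  })
  validate_limits(lim)
}

#' @rdname read_limits
#' @param limits A limits tibble as returned by [default_limits()].
#' @export
write_limits <- function(limits, path) {
  limits <- validate_limits(limits)
  entries <- purrr::pmap(limits, function(analyte, mode, m, M) {
    e <- list(analyte = analyte, mode = mode)
    if (!is.na(m)) e$m <- m
    if (!is.na(M)) e$M <- M
    e
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(entries, path)
  }
  invisible(path)
}

limit_for <- function(limits, analyte) {
  row <- limits[limits$analyte == analyte, ]
  if (nrow(row) != 1) {
    abort(paste0("analyte not found in limits registry: ", analyte))
  }
  row
}

#' Classify a colony count against m/M limits
#'
#' A result at or below `m` is satisfactory, above `m` and at or below `M`
#' is acceptable, and above `M` is unsatisfactory. Boundary values belong to
#' the lower class (a result exactly equal to a limit does not exceed it).
#'
#' @param value Numeric vector of results in log10 CFU/g; must be
#'   non-negative.
#' @param limit A single row of a limits registry (see [default_limits()])
#'   with `mode == "count_limits"`, or any list with elements `mode`, `m`,
#'   `M`.
#' @return Ordered factor of class levels, same length as `value`.
#' @export
#' @examples
#' mab <- dplyr::filter(default_limits(), analyte == "MAB")
#' classify_count(c(4.2, 5.0, 5.5, 6.01), mab)
classify_count <- function(value, limit) {
  if (!identical(as.character(limit$mode), "count_limits")) {
    abort(paste0("classify_count() requires a count_limits analyte, got mode ",
                 limit$mode))
  }
  if (!is.numeric(value)) abort("value must be numeric")
  if (any(value < 0, na.rm = TRUE)) {
    abort("counts in log10 CFU/g must be non-negative")
  }
  m <- as.numeric(limit$m)
  M <- as.numeric(limit$M)
  lev <- ifelse(value <= m, "satisfactory",
                ifelse(value <= M, "acceptable", "unsatisfactory"))
  as_class_level(lev)
}

#' Classify a presence/absence result
#'
#' For presence-based criteria (absence in 25 g required) detection means
#' the batch is unsatisfactory; absence is satisfactory. No intermediate
#' class exists.
#'
#' @param detected Logical vector: was the organism detected?
#' @return Ordered factor of class levels.
#' @export
#' @examples
#' classify_presence(c(FALSE, TRUE))
classify_presence <- function(detected) {
  if (!is.logical(detected)) abort("detected must be logical")
  as_class_level(ifelse(detected, "unsatisfactory", "satisfactory"))
}

#' Classify a replicate set for one analyte
#'
#' Batch testing takes `n` replicate units (typically five). The batch is
#' unsatisfactory if any replicate exceeds `M` or if more than `c` replicates
#' fall in the `(m, M]` band; it is acceptable if between 1 and `c`
#' replicates fall in that band with all others at or below `m`; it is
#' satisfactory when every replicate is at or below `m`.
#'
#' @param values Numeric vector of replicate results (log10 CFU/g), length
#'   at least 1.
#' @param limit A count-limits registry row (see [classify_count()]).
#' @param c Maximum number of replicates tolerated in the `(m, M]` band;
#'   must be below the number of replicates. Default 2, the usual sampling
#'   plan value for five replicates.
#' @return A single class level (ordered factor of length 1).
#' @export
#' @examples
#' mab <- dplyr::filter(default_limits(), analyte == "MAB")
#' evaluate_replicate_set(c(4.1, 5.5, 4.0, 4.9, 4.5), mab, c = 2)
evaluate_replicate_set <- function(values, limit, c = 2) {
  if (length(values) == 0) abort("replicate set is empty")
  if (c >= length(values)) {
    abort("c must be smaller than the number of replicates")
  }
  per <- classify_count(values, limit)
  if (any(per == "unsatisfactory")) {
    return(as_class_level("unsatisfactory"))
  }
  n_mid <- sum(per == "acceptable")
  if (n_mid == 0) {
    as_class_level("satisfactory")
  } else if (n_mid <= c) {
    as_class_level("acceptable")
  } else {
    as_class_level("unsatisfactory")
  }
}

#' Combine per-analyte classes into a batch verdict
#'
#' A batch is as bad as its worst analyte: any unsatisfactory result makes
#' the batch unsatisfactory, otherwise any acceptable result makes it
#' acceptable, otherwise it is satisfactory.
#'
#' @param per_analyte Named character vector, factor or list of class levels,
#'   one per analyte. Must be non-empty.
#' @return A single class level.
#' @export
#' @examples
#' evaluate_batch(c(MAB = "acceptable", E_COLI = "satisfactory"))
evaluate_batch <- function(per_analyte) {
  per_analyte <- unlist(lapply(per_analyte, as.character))
  if (length(per_analyte) == 0) abort("per_analyte map is empty")
  levels <- as_class_level(per_analyte)
  max(levels)
}

#' Summarise class percentages per analyte
#'
#' Classifies every record against each regulated analyte in the registry
#' and tabulates the percentage of samples in each class - the shape of a
#' routine surveillance summary table. Count-limit analytes use
#' [classify_count()] on their count column; presence analytes use
#' [classify_presence()] on their flag column. Unregulated analytes (LAB)
#' are skipped.
#'
#' @param records Sample table with columns `mab`, `e_coli`, `s_aureus`
#'   (log10 CFU/g) and `salmonella_present`, `l_mono_present` (logical),
#'   as produced by [generate_dataset()].
#' @param limits Limits registry tibble; defaults to [default_limits()].
#' @return A tibble with one row per regulated analyte: `analyte`,
#'   `percent_satisfactory`, `percent_acceptable`, `percent_unsatisfactory`.
#'   The three percentages sum to 100 up to rounding.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' summarize_classes(d)
summarize_classes <- function(records, limits = default_limits()) {
  if (nrow(records) == 0) abort("records table is empty")
  limits <- validate_limits(limits)
  columns <- c(MAB = "mab", E_COLI = "e_coli", S_AUREUS = "s_aureus",
               SALMONELLA = "salmonella_present", L_MONO = "l_mono_present",
               LAB = "lab")
  regulated <- limits[limits$mode != "unregulated", ]
  purrr::pmap_dfr(regulated, function(analyte, mode, m, M) {
    col <- columns[[analyte]]
    if (is.null(col) || !col %in% names(records)) {
      abort(paste0("records table lacks column for analyte ", analyte))
    }
    lv <- if (mode == "count_limits") {
      classify_count(records[[col]], list(mode = mode, m = m, M = M))
    } else {
      classify_presence(records[[col]])
    }
    pct <- 100 * table(lv) / length(lv)
    tibble::tibble(
      analyte = analyte,
      percent_satisfactory = unname(pct[["satisfactory"]]),
      percent_acceptable = unname(pct[["acceptable"]]),
      percent_unsatisfactory = unname(pct[["unsatisfactory"]])
    )
  })
}

#' Frequency bins for lactic acid bacteria
#'
#' LAB carry no m/M limits, so they are summarised as a histogram over
#' concentration bands. Bins are left-closed (`[e_k, e_{k+1})`) with the last
#' bin closed on both sides. Values outside the edge range are counted in
#' the nearest terminal bin with a warning; spoilage is associated with
#' counts above 7 log10 CFU/g, the default upper edge.
#'
#' @param values Numeric vector of LAB counts in log10 CFU/g (may be empty).
#' @param edges Strictly increasing bin edges; default `c(0, 2, 4, 6, 7)`.
#' @return A tibble with columns `bin` (label), `lower`, `upper`, `count`;
#'   counts sum to `length(values)`.
#' @export
#' @examples
#' bin_lab(c(1.0, 3.0, 5.0, 6.5))
bin_lab <- function(values, edges = c(0, 2, 4, 6, 7)) {
  if (any(diff(edges) <= 0)) abort("edges must be strictly increasing")
  k <- length(edges) - 1
  labels <- paste0("[", edges[-length(edges)], ",", edges[-1],
                   c(rep(")", k - 1), "]"))
  out_of_range <- sum(values < edges[1] | values > edges[length(edges)])
  if (out_of_range > 0) {
    warn(paste0(out_of_range,
                " value(s) outside the bin range; counted in terminal bins"))
    values <- pmin(pmax(values, edges[1]), edges[length(edges)])
  }
  counts <- if (length(values) == 0) {
    rep(0L, k)
  } else {
    as.integer(table(cut(values, edges, right = FALSE, include.lowest = TRUE)))
  }
  tibble::tibble(
    bin = labels,
    lower = edges[-length(edges)],
    upper = edges[-1],
    count = counts
  )
}
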