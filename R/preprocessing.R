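#' Min-max rescale a vector to [0, 1]
#'
#' `(x - min(x)) / (max(x) - min(x))`: the normalisation applied to every
#' raw indicator (intelligence, theory-of-mind and outcome proxies) before
#' model fitting.
#'
#' @param values Numeric vector, length >= 2, not constant.
#' @return Vector in `[0, 1]` with min at 0 and max at 1; order preserved.
#' @examples
#' min_max_rescale(c(2, 4, 6))
#' @export
min_max_rescale <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("need at least two numeric values to rescale", call. = FALSE)
  }
  if (anyNA(values)) stop("missing values in rescale input", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop("degenerate column: all values equal, min-max rescale undefined",
         call. = FALSE)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Read a raw indicator table
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`/`.txt`)
#' holding one row per unit (small group, U.S. state or country) with
#' columns `unit_id`, `g_raw`, `tom_raw`, `outcome_raw` and optionally
#' `region`. An optional second intelligence column `g_raw2` (e.g. a second
#' IQ source such as international school assessments alongside a
#' quality-weighted IQ) is averaged into `g_raw` when present; if one of
#' the pair is missing for a row, the available one is used.
#'
#' Alternatively the file may already be on the model scale with columns
#' `unit_id`, `g`, `tom`, `gpsa_obs`; such tables pass through
#' [build_observation_set()] untouched by rescaling.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_raw_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tbl <- if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if ("g_raw2" %in% names(tbl)) {
    both <- cbind(tbl$g_raw, tbl$g_raw2)
    tbl$g_raw <- rowMeans(both, na.rm = TRUE)
    tbl$g_raw[is.nan(tbl$g_raw)] <- NA_real_
    tbl$g_raw2 <- NULL
  }
  tbl
}

#' Build a model-scale observation set from a raw table
#'
#' Applies the preprocessing pipeline: (1) drop rows whose `region` is in
#' `exclusions` (e.g. regions whose indicator databases carry known
#' sampling bias), (2) drop rows with any missing indicator (with a
#' message), (3) min-max rescale each indicator over the retained rows,
#' (4) multiply g and ToM by 10 so they live on `[0, 10]`, leaving the
#' outcome on `[0, 1]` as the observed GPSA. Exclusion happens before
#' rescaling, so the min and max come from the data actually fitted.
#'
#' Tables already on the model scale (columns `g`, `tom`, `gpsa_obs`) are
#' validated and filtered but not rescaled.
#'
#' @param raw A tibble/data.frame from [read_raw_table()] or built in code.
#' @param level Governance-level label, e.g. `"small_group"`, `"us_state"`,
#'   `"country"`, `"synthetic"`.
#' @param exclusions Character vector of region labels to drop.
#' @return An `observation_set`: tibble with columns `unit_id`, `g`, `tom`,
#'   `gpsa_obs` and a `level` attribute.
#' @export
build_observation_set <- function(raw, level, exclusions = character()) {
  raw <- tibble::as_tibble(raw)
  pre_scaled <- all(c("unit_id", "g", "tom", "gpsa_obs") %in% names(raw))
  if (!pre_scaled) {
    need <- c("unit_id", "g_raw", "tom_raw", "outcome_raw")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      stop("raw table is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(exclusions) && "region" %in% names(raw)) {
    raw <- raw[!(raw$region %in% exclusions), , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("all rows excluded", call. = FALSE)

  ind_cols <- if (pre_scaled) c("g", "tom", "gpsa_obs") else
    c("g_raw", "tom_raw", "outcome_raw")
  complete <- stats::complete.cases(raw[ind_cols])
  if (any(!complete)) {
    message("dropping ", sum(!complete), " row(s) with missing indicators")
    raw <- raw[complete, , drop = FALSE]
  }
  if (anyDuplicated(raw$unit_id)) stop("duplicate unit_id", call. = FALSE)

  if (pre_scaled) {
    check_range(raw$g, 0, 10, "g"); check_range(raw$tom, 0, 10, "tom")
    check_range(raw$gpsa_obs, 0, 1, "gpsa_obs")
    out <- tibble::tibble(unit_id = raw$unit_id, g = raw$g, tom = raw$tom,
                          gpsa_obs = raw$gpsa_obs)
  } else {
    if (nrow(raw) < 2L) stop("need >= 2 rows to rescale", call. = FALSE)
    out <- tibble::tibble(
      unit_id = raw$unit_id,
      g = 10 * min_max_rescale(raw$g_raw),
      tom = 10 * min_max_rescale(raw$tom_raw),
      gpsa_obs = min_max_rescale(raw$outcome_raw)
    )
  }
  observation_set(out, level)
}

#' Construct an observation set from model-scale columns
#'
#' @param data Tibble/data.frame with columns `unit_id`, `g` (`[0, 10]`),
#'   `tom` (`[0, 10]`), `gpsa_obs` (`[0, 1]`).
#' @param level Governance-level label.
#' @return An `observation_set` tibble.
#' @export
observation_set <- function(data, level = "synthetic") {
  data <- tibble::as_tibble(data)[c("unit_id", "g", "tom", "gpsa_obs")]
  check_range(data$g, 0, 10, "g")
  check_range(data$tom, 0, 10, "tom")
  check_range(data$gpsa_obs, 0, 1, "gpsa_obs")
  structure(data, level = as.character(level),
            class = c("observation_set", class(data)))
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> level = %s, n = %d\n",
              attr(x, "level"), nrow(x)))
  NextMethod()
}
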