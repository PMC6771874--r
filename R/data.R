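#' Construct a validated quantal (dichotomous) dose-response dataset
#'
#' A quantal dataset records, per dose group, the number of subjects examined
#' and the number showing the lesion or effect. Doses are oral daily doses in
#' mg/kg/day. The dataset must contain exactly one control group at dose 0,
#' at least three groups in total, strictly increasing unique doses, and
#' `affected <= n` in every group.
#'
#' @param data A data frame with columns `dose`, `n`, `affected`.
#' @param endpoint Optional endpoint name carried as an attribute.
#' @return A tibble of class `quantal_data`, sorted by dose.
#' @examples
#' as_quantal_data(data.frame(dose = c(0, 0.1, 1, 50), n = 70,
#'                            affected = c(24, 24, 19, 42)))
#' @export
as_quantal_data <- function(data, endpoint = NULL) {
  req <- c("dose", "n", "affected")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    abort(paste0("quantal data must have columns dose, n, affected; missing: ",
                 paste(miss, collapse = ", ")),
          class = "bmdtox_format_error")
  }
  out <- as_tibble(data)[req]
  out <- dplyr::arrange(out, .data$dose)
  validate_dose_groups(out$dose, n_min = 3, need_control = TRUE)
  if (any(out$n < 1) || any(out$n != round(out$n)) || any(out$affected < 0) ||
      any(out$affected != round(out$affected))) {
    abort("n must be positive integers and affected non-negative integers",
          class = "bmdtox_validation_error")
  }
  bad <- which(out$affected > out$n)
  if (length(bad) > 0) {
    abort(sprintf("affected exceeds group size at dose %g (%d/%d)",
                  out$dose[bad[1]], out$affected[bad[1]], out$n[bad[1]]),
          class = "bmdtox_validation_error")
  }
  attr(out, "endpoint") <- endpoint
  class(out) <- c("quantal_data", class(out))
  out
}

#' Construct a validated continuous dose-response dataset
#'
#' Continuous endpoints are summarized per dose group by the group size,
#' mean and standard deviation. `adverse_direction` states whether an
#' increase or a decrease of the endpoint is the adverse change; it anchors
#' benchmark responses defined as deviations from the control mean.
#'
#' @param data A data frame with columns `dose`, `n`, `mean`, `sd`.
#' @param adverse_direction `"increase"` or `"decrease"`.
#' @param endpoint Optional endpoint name.
#' @return A tibble of class `continuous_data`, sorted by dose.
#' @export
as_continuous_data <- function(data, adverse_direction = c("decrease", "increase"),
                               endpoint = NULL) {
  adverse_direction <- match.arg(adverse_direction)
  req <- c("dose", "n", "mean", "sd")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    abort(paste0("continuous data must have columns dose, n, mean, sd; missing: ",
                 paste(miss, collapse = ", ")),
          class = "bmdtox_format_error")
  }
  out <- as_tibble(data)[req]
  out <- dplyr::arrange(out, .data$dose)
  validate_dose_groups(out$dose, n_min = 2, need_control = FALSE)
  if (any(out$sd <= 0)) {
    abort("group sd must be strictly positive", class = "bmdtox_validation_error")
  }
  if (any(out$n < 2)) {
    abort("each group needs n >= 2 (sd must be estimable)",
          class = "bmdtox_validation_error")
  }
  attr(out, "endpoint") <- endpoint
  attr(out, "adverse_direction") <- adverse_direction
  class(out) <- c("continuous_data", class(out))
  out
}

validate_dose_groups <- function(dose, n_min, need_control) {
  if (any(dose < 0)) {
    abort("doses must be non-negative", class = "bmdtox_validation_error")
  }
  # exact comparison: inputs are short printed tables, not measured floats
  if (anyDuplicated(dose) > 0) {
    abort(sprintf("duplicate dose group: %g", dose[duplicated(dose)][1]),
          class = "bmdtox_validation_error")
  }
  if (length(dose) < n_min) {
    abort(sprintf("need at least %d dose groups", n_min),
          class = "bmdtox_validation_error")
  }
  if (need_control && dose[1] != 0) {
    abort("a control group at dose 0 is required",
          class = "bmdtox_validation_error")
  }
  invisible(TRUE)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a quantal dose-response table from delimited text
#'
#' Accepts comma- or tab-separated files (auto-detected from the header line)
#' with columns `dose`, `n`, `affected`.
#'
#' @param path Path to a CSV/TSV file.
#' @param endpoint Optional endpoint name.
#' @return A validated [as_quantal_data()] tibble.
#' @export
read_quantal <- function(path, endpoint = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = detect_delim(path), dec = ".",
                          check.names = TRUE, stringsAsFactors = FALSE)
  as_quantal_data(df, endpoint = endpoint %||% sub("\\.[ct]sv$", "", basename(path)))
}

#' Read a continuous dose-response summary table from delimited text
#'
#' @inheritParams read_quantal
#' @param adverse_direction `"increase"` or `"decrease"`.
#' @return A validated [as_continuous_data()] tibble.
#' @export
read_continuous <- function(path, adverse_direction = c("decrease", "increase"),
                            endpoint = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = detect_delim(path), dec = ".",
                          check.names = TRUE, stringsAsFactors = FALSE)
  as_continuous_data(df, adverse_direction = adverse_direction,
                     endpoint = endpoint %||% sub("\\.[ct]sv$", "", basename(path)))
}

#' Write a dose-response dataset as CSV
#'
#' Writing then re-reading a validated dataset is the identity.
#'
#' @param data A `quantal_data` or `continuous_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Male-rat lesion incidences of the 2-year GenX (HFPO-DA) gavage bioassay:
# doses 0, 0.1, 1, 50 mg/kg/day, 70 animals per group.
.genx_table1 <- list(
  cystic_focal_degeneration       = c(24, 24, 19, 42),
  centrilobular_hypertrophy       = c(0, 0, 0, 7),
  centrilobular_necrosis          = c(1, 0, 1, 5),
  hepatocellular_adenoma_carcinoma = c(2, 2, 1, 3),
  pancreas_adenoma_carcinoma      = c(0, 1, 0, 5),
  leydig_cell_tumors              = c(4, 4, 1, 8)
)

#' Packaged 2-year rat bioassay incidence fixtures
#'
#' `genx_fixtures()` lists the packaged endpoints; `genx_fixture(name)`
#' returns one as a validated [as_quantal_data()] tibble with doses
#' 0, 0.1, 1 and 50 mg/kg/day and 70 male rats per group. The three
#' non-neoplastic liver lesions are the modeling substrate; the tumor rows
#' are included for demonstration only (the compound is non-genotoxic and
#' tumor modeling is out of scope).
#'
#' @param name One of the names returned by `genx_fixtures()`.
#' @return `genx_fixture()`: a `quantal_data` tibble; `genx_fixtures()`:
#'   a character vector.
#' @examples
#' genx_fixture("cystic_focal_degeneration")
#' @export
genx_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.genx_table1)) {
    abort(paste0("unknown fixture '", paste(name, collapse = ","),
                 "'; available: ", paste(names(.genx_table1), collapse = ", ")),
          class = "bmdtox_lookup_error")
  }
  as_quantal_data(
    tibble(dose = c(0, 0.1, 1, 50), n = 70L, affected = .genx_table1[[name]]),
    endpoint = name
  )
}

#' @rdname genx_fixture
#' @export
genx_fixtures <- function() names(.genx_table1)
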