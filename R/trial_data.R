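#' Construct an enrichment-trial data set
#'
#' A `trial_data` object holds one row per randomized patient of an
#' enrichment-design trial: the observed right-censored follow-up time, the
#' event indicator, the treatment arm, optional extra covariates and,
#' for simulated data only, the latent true target status (hidden from all
#' estimators).
#'
#' @param time Positive numeric vector of observed follow-up times.
#' @param event Binary vector (1 = event observed, 0 = right-censored).
#' @param treatment Binary vector (1 = targeted therapy, 0 = control).
#' @param covariates Optional data frame or named matrix of additional
#'   numeric covariates, one row per patient.
#' @param true_class Optional binary vector of latent target status
#'   (1 = truly target-positive). Only available in simulations.
#'
#' @return A data frame of class `trial_data` with columns `time`, `event`,
#'   `treatment`, then any covariates, then `true_class` when present. The
#'   covariate column names are recorded in `attr(x, "covariates")`.
#' @examples
#' d <- trial_data(time = c(1, 2, 3), event = c(1, 0, 1),
#'                 treatment = c(1, 0, 1))
#' nrow(d)
#' @export
trial_data <- function(time, event, treatment, covariates = NULL,
                       true_class = NULL) {
  df <- data.frame(time = as.numeric(time), event = as.integer(event),
                   treatment = as.integer(treatment))
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(df))
      stop("covariates must have one row per patient")
    cov_names <- names(covariates)
    df <- cbind(df, covariates)
  }
  if (!is.null(true_class)) df$true_class <- as.integer(true_class)
  new_trial_data(df, cov_names)
}

new_trial_data <- function(df, cov_names) {
  attr(df, "covariates") <- cov_names
  class(df) <- c("trial_data", "data.frame")
  validate_trial_data(df)
}

validate_trial_data <- function(x) {
  check_col <- function(ok, what) {
    if (!all(ok)) {
      row <- which(!ok)[1L]
      stop(sprintf("invalid %s (row %d)", what, row), call. = FALSE)
    }
  }
  check_col(is.finite(x$time) & x$time > 0, "time: must be finite and > 0")
  check_col(x$event %in% c(0L, 1L), "event: must be 0 or 1")
  check_col(x$treatment %in% c(0L, 1L), "treatment: must be 0 or 1")
  if (!is.null(x$true_class))
    check_col(x$true_class %in% c(0L, 1L), "true_class: must be 0 or 1")
  for (nm in attr(x, "covariates"))
    check_col(is.finite(x[[nm]]), sprintf("covariate '%s': must be finite", nm))
  if (nrow(x) < 2L) stop("a trial needs at least 2 records", call. = FALSE)
  x
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Enrichment-trial data: %d patients (%d events, %d on targeted therapy)\n",
              nrow(x), sum(x$event), sum(x$treatment)))
  cv <- attr(x, "covariates")
  if (length(cv)) cat("Covariates:", paste(cv, collapse = ", "), "\n")
  if (!is.null(x$true_class))
    cat(sprintf("Latent classes recorded: %d true positives\n", sum(x$true_class)))
  NextMethod()
  invisible(x)
}

# arms/events requirements shared by the estimation routines
check_estimable <- function(data) {
  if (length(unique(data$treatment)) < 2L)
    stop("both treatment arms must be represented", call. = FALSE)
  if (sum(data$event) < 1L)
    stop("at least one event is required", call. = FALSE)
  invisible(data)
}

# design matrix: treatment first, then covariates
model_matrix_trial <- function(data) {
  cv <- attr(data, "covariates")
  X <- cbind(treatment = data$treatment)
  for (nm in cv) X <- cbind(X, data[[nm]])
  colnames(X) <- c("treatment", cv)
  storage.mode(X) <- "double"
  X
}

#' Read enrichment-trial data from a delimited file
#'
#' Reads a comma-delimited file with a header row into a [trial_data]
#' object. Canonical column names are `time`, `event`, `treatment`,
#' optional covariates, and an optional `true_class`; a `schema` mapping
#' can translate other column names.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named list/character vector mapping canonical
#'   names (`time`, `event`, `treatment`, `true_class`) to the column names
#'   used in the file, e.g. `c(time = "t", event = "status")`. Unmapped
#'   canonical names default to themselves. All remaining columns are taken
#'   as covariates, in file order.
#' @return A [trial_data] object; row order is preserved.
#' @seealso [write_trial()]
#' @export
read_trial <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- c(time = "time", event = "event", treatment = "treatment",
           true_class = "true_class")
  if (!is.null(schema)) {
    schema <- unlist(schema)
    bad <- setdiff(names(schema), names(map))
    if (length(bad))
      stop("unknown schema entries: ", paste(bad, collapse = ", "))
    map[names(schema)] <- schema
  }
  for (need in c("time", "event", "treatment"))
    if (!map[[need]] %in% names(df))
      stop(sprintf("column '%s' (for %s) not found in %s", map[[need]], need, path))
  used <- intersect(unname(map), names(df))
  cov_cols <- setdiff(names(df), used)
  trial_data(time = df[[map[["time"]]]],
             event = df[[map[["event"]]]],
             treatment = df[[map[["treatment"]]]],
             covariates = if (length(cov_cols)) df[cov_cols] else NULL,
             true_class = if (map[["true_class"]] %in% names(df))
               df[[map[["true_class"]]]] else NULL)
}

#' Write enrichment-trial data to a delimited file
#'
#' Writes a [trial_data] object as a CSV re-readable by [read_trial()] with
#' identical field values (numeric columns are written with 17 significant
#' digits so that doubles round-trip exactly).
#'
#' @param data A [trial_data] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  out <- as.data.frame(data)
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
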