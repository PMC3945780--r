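#' Construct a right-censored survival dataset
#'
#' Bundles observed times, event indicators and a covariate matrix into a
#' validated `survival_dataset` object, the container used by every fitting
#' and screening routine in the package. Each subject is a triple
#' \eqn{(t_i, \delta_i, x_i)}: a strictly positive observed time, a binary
#' event indicator (1 = event, 0 = right censored) and a row of covariates.
#'
#' @param times Numeric vector of strictly positive, finite observed times.
#' @param events Integer/numeric vector of 0/1 event indicators.
#' @param covariates Numeric matrix (n x p), no missing values.
#' @param names Optional character vector of p covariate labels; defaults to
#'   the matrix column names or `V1..Vp`.
#' @param mandatory Integer vector of covariate indices treated as mandatory
#'   (clinical) covariates: fit without penalty and never screened out.
#' @return An object of class `survival_dataset` with elements `times`,
#'   `events`, `covariates`, `names`, `mandatory`.
#' @export
survival_dataset <- function(times, events, covariates, names = NULL,
                             mandatory = integer(0)) {
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (!is.matrix(covariates)) covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(times)
  p <- ncol(covariates)
  if (n < 2L)
    stop(ss_error("at least 2 observations are required", "ss_too_few_rows"))
  if (length(events) != n || nrow(covariates) != n)
    stop(ss_error("times, events and covariates disagree in length",
                  "ss_length_mismatch"))
  if (anyNA(times) || any(!is.finite(times)) || any(times <= 0))
    stop(ss_error("observed times must be strictly positive and finite",
                  "ss_invalid_time"))
  if (anyNA(events) || !all(events %in% c(0, 1)))
    stop(ss_error("invalid event indicator: values must be 0 or 1",
                  "ss_invalid_event"))
  if (sum(events) < 1)
    stop(ss_error("at least one event is required", "ss_no_events"))
  if (anyNA(covariates) || any(!is.finite(covariates)))
    stop(ss_error("missing or non-finite covariate values",
                  "ss_missing_values"))
  if (is.null(names)) {
    names <- colnames(covariates)
    if (is.null(names)) names <- paste0("V", seq_len(p))
  }
  if (length(names) != p)
    stop(ss_error("covariate names disagree with matrix width",
                  "ss_length_mismatch"))
  mandatory <- sort(unique(as.integer(mandatory)))
  if (length(mandatory) && (min(mandatory) < 1L || max(mandatory) > p))
    stop(ss_error("mandatory indices outside 1..p", "ss_invalid_mandatory"))
  colnames(covariates) <- names
  structure(list(times = times, events = events, covariates = covariates,
                 names = names, mandatory = mandatory),
            class = "survival_dataset")
}

ss_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "survscreen_error"))
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: n = %d, p = %d, events = %d (%.1f%%)\n",
              length(x$times), ncol(x$covariates), sum(x$events),
              100 * mean(x$events)))
  if (length(x$mandatory))
    cat("  mandatory covariates:", paste(x$names[x$mandatory], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) {
  c(length(x$times), ncol(x$covariates))
}

#' Subset a survival dataset by row indices
#'
#' @param data A `survival_dataset`.
#' @param idx Integer row indices to keep.
#' @return A `survival_dataset` with the selected rows.
#' @export
subset_rows <- function(data, idx) {
  survival_dataset(data$times[idx], data$events[idx],
                   data$covariates[idx, , drop = FALSE],
                   names = data$names, mandatory = data$mandatory)
}

#' Read a survival dataset from a delimited text file
#'
#' Expects a header row; the delimiter is chosen from the file extension
#' (`.csv` is comma-, everything else tab-separated). The time and event
#' columns are named; all remaining columns become covariates in file order.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param time_col,event_col Names of the time and status columns
#'   (defaults `"time"`, `"status"`).
#' @param mandatory_cols Character vector of covariate names to flag as
#'   mandatory.
#' @return A `survival_dataset`.
#' @export
read_dataset <- function(path, time_col = "time", event_col = "status",
                         mandatory_cols = character(0)) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  for (col in c(time_col, event_col))
    if (!col %in% names(df))
      stop(ss_error(sprintf("missing column label '%s' in %s", col, path),
                    "ss_missing_column"))
  covn <- setdiff(names(df), c(time_col, event_col))
  bad <- setdiff(mandatory_cols, covn)
  if (length(bad))
    stop(ss_error(sprintf("mandatory column(s) not found: %s",
                          paste(bad, collapse = ", ")), "ss_missing_column"))
  X <- as.matrix(df[, covn, drop = FALSE])
  survival_dataset(df[[time_col]], df[[event_col]], X, names = covn,
                   mandatory = match(mandatory_cols, covn))
}

#' Write a survival dataset to a delimited text file
#'
#' Inverse of [read_dataset()]: columns `time`, `status`, then the
#' covariates under their stored names. Finite decimal values round-trip
#' exactly.
#'
#' @param data A `survival_dataset`.
#' @param path Output path; `.csv` writes comma-, otherwise tab-separated.
#' @export
write_dataset <- function(data, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(time = data$times, status = data$events,
                   data$covariates, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Draw a train/test subsample split
#'
#' Splits the rows into a training part of size `round(fraction * n)` drawn
#' without replacement and the complementary test part. A training part
#' without any event is useless for partial-likelihood fitting, so the draw
#' is repeated with an incremented seed (at most `max_redraws` times) until
#' it contains at least one event.
#'
#' @param data A `survival_dataset`.
#' @param fraction Training fraction in (0,1); the default 0.632 mirrors the
#'   subsampling convention used throughout the screening pipeline.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param max_redraws Number of redraws allowed before giving up.
#' @return A list of class `subsample_split` with integer vectors
#'   `train_idx`, `test_idx` and the `seed` actually used.
#' @export
subsample <- function(data, fraction = 0.632, seed = 1L, max_redraws = 100L) {
  n <- length(data$times)
  m <- round(fraction * n)
  if (m < 2L || m >= n)
    stop(ss_error("subsample size must lie strictly inside 2..(n-1)",
                  "ss_invalid_fraction"))
  s <- as.integer(seed)
  for (k in 0:max_redraws) {
    train <- sort(local_sample(n, m, s + k))
    if (sum(data$events[train]) >= 1) {
      return(structure(list(train_idx = train,
                            test_idx = setdiff(seq_len(n), train),
                            seed = s + k),
                       class = "subsample_split"))
    }
  }
  stop(ss_error(sprintf(
    "no subsample with an event found after %d redraws (seed %d)",
    max_redraws, s), "ss_no_event_subsample"))
}

# Seeded sampling without replacement that does not disturb the caller's RNG.
local_sample <- function(n, m, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(n, m)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic child-seed derivation: one master seed, distinct streams per
# (purpose, counter). Kept below 2^31.
derive_seed <- function(seed, ...) {
  v <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (x in v) h <- (h * 69069 + x * 2654435761 + 1013904223) %% 2147483647
  as.integer(h)
}

#' Standardize the covariates of a dataset
#'
#' Centers every covariate column to mean zero and scales it to unit sample
#' standard deviation. Constant columns cannot be scaled; their scale is
#' recorded as 1 (a warning is emitted) so the transform stays invertible.
#'
#' @param data A `survival_dataset`.
#' @return A list with `data` (the standardized dataset) and `params`
#'   (a `standardization_params` list of `means` and `scales`).
#' @export
standardize <- function(data) {
  X <- data$covariates
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  const <- !is.finite(sdv) | sdv < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant covariate column(s); scale recorded as 1",
                    sum(const)))
    sdv[const] <- 1
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  out <- data
  out$covariates <- Xs
  colnames(out$covariates) <- data$names
  list(data = out,
       params = structure(list(means = mu, scales = sdv),
                          class = "standardization_params"))
}

# Apply / invert stored standardization to a raw matrix.
apply_standardization <- function(X, params) {
  sweep(sweep(X, 2, params$means, "-"), 2, params$scales, "/")
}
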