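#' @title CSV readers and writers
#'
#' @description
#' All tabular exchange uses plain UTF-8 CSV with a header row. PRL trial
#' tables carry `participant_id,trial,choice,reward`; Dictator-game tables
#' carry `participant_id,trial,partner_return,hi_rating,si_rating,condition`.
#' Readers validate the schema and report missing columns by name.
#'
#' @name io
NULL

check_schema <- function(df, expected, path) {
  miss <- setdiff(expected, names(df))
  if (length(miss)) {
    stop("'", path, "' is missing column(s): ", paste(miss, collapse = ", "),
         "; expected header: ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  invisible(df)
}

#' Read / write PRL trial tables
#' @param data Trial tibble.
#' @param path CSV file path.
#' @export
write_prl_trials <- function(data, path) {
  check_schema(data, c("participant_id", "trial", "choice", "reward"), path)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prl_trials
#' @export
read_prl_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant_id", "trial", "choice", "reward"), path)
  out <- tibble::as_tibble(df)
  out$participant_id <- as.character(out$participant_id)
  out$trial <- as.integer(out$trial)
  out$choice <- as.integer(out$choice)
  for (pid in unique(out$participant_id)) {
    assert_prl_trials(out[out$participant_id == pid, ])
  }
  out
}

#' Read / write Dictator-game trial tables
#' @inheritParams write_prl_trials
#' @export
write_dg_trials <- function(data, path) {
  check_schema(data, c("participant_id", "trial", "partner_return",
                       "hi_rating", "si_rating", "condition"), path)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dg_trials
#' @export
read_dg_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant_id", "trial", "partner_return",
                     "hi_rating", "si_rating", "condition"), path)
  out <- tibble::as_tibble(df)
  out$participant_id <- as.character(out$participant_id)
  out$trial <- as.integer(out$trial)
  for (pid in unique(out$participant_id)) {
    assert_dg_trials(out[out$participant_id == pid, ])
  }
  out
}

#' Write / read flattened fit tables
#' @param fits A `revattr_comparison` tibble or any tibble of flattened
#'   fit rows.
#' @param path CSV file path.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(as.data.frame(fits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant_id", "model_id", "loglik", "bic", "aic"),
               path)
  tibble::as_tibble(df)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version and emitted files of a
#' pipeline run so outputs can be regenerated.
#'
#' @param path Output path (JSON).
#' @param config Configuration list (serialised as-is where possible).
#' @param seed Integer seed of the run.
#' @param files Character vector of emitted file paths.
#' @param extra Optional named list of additional fields.
#' @export
write_run_manifest <- function(path, config, seed, files, extra = list()) {
  sums <- tools::md5sum(files[file.exists(files)])
  manifest <- c(list(
    package = "revattr",
    version = as.character(utils::packageVersion("revattr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = manifest_safe(config),
    files = as.list(files),
    checksums = as.list(sums)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

# Drop non-serialisable components (functions, environments) from configs.
manifest_safe <- function(x) {
  if (is.function(x) || is.environment(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, manifest_safe)
    x[!vapply(x, is.null, logical(1))]
  } else x
}
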