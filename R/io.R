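#' Read and write the package's delimited-text schemas
#'
#' Plain-CSV readers/writers for the three tabular interchange formats:
#' PK observations (`subject,group,route,time_h,conc_ug_per_mL`), dose
#' schedules (`group,time_h,route,dose_mg_per_kg`) and biomonitoring
#' records (`survey_year,age,mean_serum_ppb,se_ppb`). Files round-trip
#' bit-identically through these functions.
#'
#' @param obs_file,dose_file,bw_file CSV paths for a PK dataset (the body
#'   weight file has columns `group,bw_kg`).
#' @return `read_pk_dataset()`: a [pk_dataset()];
#'   `read_biomonitoring()`: a tibble of records.
#' @export
read_pk_dataset <- function(obs_file, dose_file, bw_file) {
  pk_dataset(
    observations = utils::read.csv(obs_file, stringsAsFactors = FALSE),
    doses = utils::read.csv(dose_file, stringsAsFactors = FALSE),
    body_weights = utils::read.csv(bw_file, stringsAsFactors = FALSE)
  )
}

#' @rdname read_pk_dataset
#' @param dataset A [pk_dataset()].
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @export
write_pk_dataset <- function(dataset, dir, prefix = "study") {
  stopifnot(inherits(dataset, "pk_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_observations.csv",
                                           "_doses.csv", "_bw.csv")))
  utils::write.csv(dataset$observations, paths[1], row.names = FALSE)
  utils::write.csv(dataset$doses, paths[2], row.names = FALSE)
  utils::write.csv(dataset$body_weights, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @rdname read_pk_dataset
#' @param file A CSV path.
#' @export
read_biomonitoring <- function(file) {
  tibble::as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_pk_dataset
#' @param records A data frame of biomonitoring records.
#' @export
write_biomonitoring <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE)
  invisible(file)
}

#' @rdname read_pk_dataset
#' @param pod_file CSV with columns `endpoint,pod_mg_per_L`.
#' @export
read_pod_table <- function(pod_file) {
  out <- tibble::as_tibble(utils::read.csv(pod_file,
                                           stringsAsFactors = FALSE))
  stopifnot(all(c("endpoint", "pod_mg_per_L") %in% names(out)))
  out
}
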