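# Epoch container round-trip and cohort-table I/O.
#
# The on-disk epoch container is an RDS-based store with an explicit schema
# version and an integrity digest, so reads fail loudly on truncation or
# foreign content rather than silently returning garbage.

EPOCH_SCHEMA <- "tfsassay-epochs-1"

#' Write an epoch array to disk
#' @param epochs an [epoch_array()].
#' @param path output path (conventionally `.epochs.rds`).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  payload <- unclass(epochs)
  payload$schema <- EPOCH_SCHEMA
  payload$digest <- sum(epochs$data) + length(epochs$data)
  saveRDS(payload, path)
  invisible(path)
}

#' Read an epoch array written by [write_epochs()]
#'
#' Reproduces data, mask, labels and metadata exactly; truncated or foreign
#' files raise an explicit corrupt-container error, and a schema-version
#' mismatch is reported as such.
#'
#' @param path container path.
#' @return an [epoch_array()].
#' @export
read_epochs <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("corrupt epoch container: ",
                                               conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$schema))
    stop("corrupt epoch container: not a tfsassay epoch store")
  if (!identical(payload$schema, EPOCH_SCHEMA))
    stop("epoch container schema mismatch: found '", payload$schema, "'")
  chk <- sum(payload$data) + length(payload$data)
  if (!isTRUE(all.equal(chk, payload$digest)))
    stop("corrupt epoch container: integrity digest mismatch")
  epoch_array(payload$data, payload$rate, payload$tmin, payload$channels,
              labels = payload$labels, rejected = payload$rejected,
              alignment = payload$alignment)
}

#' Write a cohort table as CSV
#' @param cohort data.frame, one row per subject.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_csv()]
#' @param path CSV path.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
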