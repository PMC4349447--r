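# Plain-text readers and writers: subjects-by-exposures TSV, outcome TSV,
# the codebook sidecar dialect (tab-separated, header row, UTF-8), and the
# truth record as JSON. These are the exchange formats of the pipeline.

#' Write an exposome dataset to a directory
#'
#' Writes \code{data.tsv} (subject id + one column per exposure, missing as
#' empty), \code{outcome.tsv}, \code{codebook.tsv} (the sidecar dialect:
#' name, domain, reporter, var_type, direction, range_low, range_high) and,
#' when supplied, \code{truth.json}.
#'
#' @param em an \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param dir output directory (created if needed).
#' @param truth optional \code{truth_record}.
#' @return \code{dir}, invisibly.
#' @export
write_exposome <- function(em, outcome, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- data.frame(subject_id = em$subject_ids,
                    partner_status = em$partner_status, em$data,
                    check.names = FALSE)
  utils::write.table(dat, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(
    data.frame(subject_id = em$subject_ids, outcome = outcome),
    file.path(dir, "outcome.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE, na = "")
  write_codebook(em$codebook, file.path(dir, "codebook.tsv"))
  if (!is.null(truth)) write_truth_record(truth, file.path(dir,
                                                           "truth.json"))
  invisible(dir)
}

#' Read an exposome dataset written by \code{\link{write_exposome}}
#'
#' @param dir directory containing \code{data.tsv}, \code{outcome.tsv} and
#'   \code{codebook.tsv}.
#' @param apply_directions apply codebook coding-direction multipliers at
#'   load time (default TRUE), so higher always means more of the
#'   characteristic.
#' @return list with \code{matrix} (an \code{\link{exposome_matrix}}) and
#'   \code{outcome}.
#' @export
read_exposome <- function(dir, apply_directions = TRUE) {
  cb <- read_codebook(file.path(dir, "codebook.tsv"))
  dat <- utils::read.delim(file.path(dir, "data.tsv"), check.names = FALSE,
                           na.strings = "")
  out <- utils::read.delim(file.path(dir, "outcome.tsv"), na.strings = "")
  X <- as.matrix(dat[, cb$name, drop = FALSE])
  em <- exposome_matrix(X, cb, partner_status = dat$partner_status,
                        subject_ids = dat$subject_id)
  if (apply_directions) em <- apply_direction(em)
  list(matrix = em, outcome = out$outcome[match(dat$subject_id,
                                                out$subject_id)])
}

#' @rdname read_exposome
#' @param path codebook TSV path.
#' @export
read_codebook <- function(path) {
  cb <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cb$direction <- as.integer(cb$direction)
  cb$range_low <- as.numeric(cb$range_low)
  cb$range_high <- as.numeric(cb$range_high)
  validate_codebook(cb)
  class(cb) <- c("exposure_codebook", "data.frame")
  cb
}

#' @rdname read_exposome
#' @param codebook an \code{\link{exposure_codebook}}.
#' @export
write_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  utils::write.table(codebook, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize and restore a truth record
#'
#' The truth record round-trips losslessly through JSON: it embeds the full
#' generator spec (including the seed) and so suffices to regenerate the
#' dataset bit-identically with the same generator version.
#'
#' @param truth a \code{truth_record}.
#' @param path JSON file path.
#' @return the path (write) or the restored \code{truth_record} (read).
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  payload <- unclass(truth)
  payload$spec <- unclass(payload$spec)
  # named atomic vectors must become lists to keep their names in JSON
  payload$spec$type_mix <- as.list(payload$spec$type_mix)
  if (!is.null(payload$spec$mediator_spec))
    payload$spec$mediator_spec$loadings <-
      as.list(payload$spec$mediator_spec$loadings)
  payload$var_type <- as.list(payload$var_type)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- payload$spec
  spec$outcome_bounds <- as.numeric(spec$outcome_bounds)
  spec$type_mix <- unlist(spec$type_mix)
  spec$planted_effects <- as.data.frame(spec$planted_effects)
  if (!is.null(spec$planted_interactions) &&
      length(spec$planted_interactions))
    spec$planted_interactions <- as.data.frame(spec$planted_interactions)
  else spec$planted_interactions <- NULL
  if (!is.null(spec$mediator_spec) && length(spec$mediator_spec)) {
    spec$mediator_spec$loadings <- unlist(spec$mediator_spec$loadings)
  } else spec$mediator_spec <- NULL
  spec$seed <- as.integer(spec$seed)
  class(spec) <- "synthetic_spec"
  truth <- payload
  truth$spec <- spec
  truth$planted_effects <- as.data.frame(truth$planted_effects)
  truth$var_type <- unlist(truth$var_type)
  truth$anchor_ids <- as.integer(truth$anchor_ids)
  truth$seed <- as.integer(truth$seed)
  class(truth) <- "truth_record"
  truth
}
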