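# Data model: exposure codebook, subjects-by-exposures matrix with a
# missingness mask and partner status, and preprocessing (coding direction,
# unit-variance standardization, degenerate-variable exclusion, partner
# encoding).

#' The ten exposure domains
#'
#' Fixed domain vocabulary used throughout: every exposure belongs to exactly
#' one of ten thematic domains ranging from personal characteristics of the
#' parents to chemical and other exposures.
#'
#' @export
DOMAIN_LABELS <- c(
  "personal characteristics", "health", "development", "education",
  "socio-economic", "lifestyle", "home environment", "social environment",
  "life events", "chemical and other exposures")

#' Construct an exposure codebook
#'
#' The codebook is the sidecar metadata table for an exposome: one row per
#' exposure variable giving its domain, reporter (mother or partner), marginal
#' type, coding-direction multiplier and feasible range. Direction multipliers
#' encode the convention that, after loading, high scores reflect more (or the
#' presence) of the characteristic.
#'
#' @param name character vector of variable names (unique).
#' @param domain one of the ten \code{\link{DOMAIN_LABELS}} per variable.
#' @param reporter \code{"mother"} or \code{"partner"} per variable.
#' @param var_type \code{"binary"}, \code{"ordinal"} or \code{"continuous"}.
#' @param direction coding multiplier, +1 or -1, applied at load time.
#' @param range_low,range_high feasible range (may be \code{-Inf}/\code{Inf}).
#' @return a \code{data.frame} of class \code{exposure_codebook}.
#' @export
exposure_codebook <- function(name, domain, reporter = "mother",
                              var_type = "continuous", direction = 1L,
                              range_low = -Inf, range_high = Inf) {
  m <- length(name)
  cb <- data.frame(
    name = as.character(name),
    domain = rep_len(as.character(domain), m),
    reporter = rep_len(as.character(reporter), m),
    var_type = rep_len(as.character(var_type), m),
    direction = rep_len(as.integer(direction), m),
    range_low = rep_len(as.numeric(range_low), m),
    range_high = rep_len(as.numeric(range_high), m),
    stringsAsFactors = FALSE)
  validate_codebook(cb)
  class(cb) <- c("exposure_codebook", "data.frame")
  cb
}

validate_codebook <- function(cb) {
  stopifnot(is.data.frame(cb))
  required <- c("name", "domain", "reporter", "var_type", "direction",
                "range_low", "range_high")
  missing_cols <- setdiff(required, names(cb))
  if (length(missing_cols))
    stop("codebook is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cb$name))
    stop("codebook variable names must be unique")
  bad <- setdiff(unique(cb$domain), DOMAIN_LABELS)
  if (length(bad))
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         "; must be one of the 10 fixed labels")
  if (!all(cb$reporter %in% c("mother", "partner")))
    stop("reporter must be 'mother' or 'partner'")
  if (!all(cb$var_type %in% c("binary", "ordinal", "continuous")))
    stop("var_type must be binary, ordinal or continuous")
  if (!all(cb$direction %in% c(-1L, 1L)))
    stop("direction must be +1 or -1")
  invisible(cb)
}

#' Construct a subjects-by-exposures matrix
#'
#' Bundles the numeric data matrix (missing values as \code{NA}), its
#' codebook, the per-subject partner-status indicator (1 = no current
#' partner), and a flag matrix marking cells that were filled by the
#' partner-encoding convention rather than genuinely observed.
#'
#' @param data numeric matrix, subjects in rows, exposures in columns;
#'   column names must match \code{codebook$name}.
#' @param codebook an \code{\link{exposure_codebook}}.
#' @param partner_status integer 0/1 vector, one per subject.
#' @param subject_ids optional subject identifiers.
#' @param filled optional logical matrix marking convention-filled cells.
#' @param scale optional named vector of per-variable standard deviations
#'   recorded by \code{\link{standardize}}.
#' @return object of class \code{exposome_matrix}.
#' @export
exposome_matrix <- function(data, codebook, partner_status = NULL,
                            subject_ids = NULL, filled = NULL, scale = NULL) {
  data <- as.matrix(data)
  validate_codebook(codebook)
  if (!identical(colnames(data), codebook$name))
    stop("data column names must equal codebook$name, in order")
  n <- nrow(data)
  if (is.null(partner_status)) partner_status <- integer(n)
  if (length(partner_status) != n)
    stop("partner_status length must equal the number of subjects")
  if (is.null(subject_ids)) subject_ids <- seq_len(n)
  if (is.null(filled)) {
    filled <- matrix(FALSE, n, ncol(data), dimnames = dimnames(data))
  }
  stopifnot(identical(dim(filled), dim(data)))
  structure(list(data = data, codebook = codebook,
                 partner_status = as.integer(partner_status),
                 subject_ids = subject_ids, filled = filled, scale = scale),
            class = "exposome_matrix")
}

#' @export
print.exposome_matrix <- function(x, ...) {
  cat("exposome_matrix:", nrow(x$data), "subjects x", ncol(x$data),
      "exposures\n")
  cat("  domains:", length(unique(x$codebook$domain)),
      " partner-reported:", sum(x$codebook$reporter == "partner"),
      " partnerless subjects:", sum(x$partner_status == 1), "\n")
  cat(sprintf("  missing cells: %.1f%%  convention-filled: %.1f%%\n",
              100 * mean(is.na(x$data)), 100 * mean(x$filled)))
  if (!is.null(x$scale)) cat("  standardized (scale record present)\n")
  invisible(x)
}

#' @export
dim.exposome_matrix <- function(x) dim(x$data)

#' Restrict an exposome matrix to a variable (and subject) subset
#'
#' Keeps codebook, missingness, convention-fill flags, partner status and
#' the scale record consistent with the selection; used, for example, to
#' restrict to the stage-1 survivors before imputation.
#'
#' @param em an \code{\link{exposome_matrix}}.
#' @param vars variable names to keep (default all).
#' @param subjects subject indices to keep (default all).
#' @return the restricted \code{exposome_matrix}.
#' @export
subset_exposome <- function(em, vars = NULL, subjects = NULL) {
  if (is.null(vars)) vars <- colnames(em$data)
  if (is.null(subjects)) subjects <- seq_len(nrow(em$data))
  idx <- match(vars, colnames(em$data))
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(vars[is.na(idx)], collapse = ", "))
  cb <- em$codebook[idx, , drop = FALSE]
  class(cb) <- c("exposure_codebook", "data.frame")
  exposome_matrix(em$data[subjects, idx, drop = FALSE], cb,
                  em$partner_status[subjects], em$subject_ids[subjects],
                  em$filled[subjects, idx, drop = FALSE],
                  scale = em$scale[vars[vars %in% names(em$scale)]])
}

#' Apply coding-direction multipliers
#'
#' Multiplies each column by its codebook direction so that, after loading,
#' higher scores always reflect more (or the presence) of the characteristic.
#' Resets all directions to +1 afterwards.
#'
#' @param em an \code{\link{exposome_matrix}}.
#' @return the matrix with directions applied.
#' @export
apply_direction <- function(em) {
  flip <- em$codebook$direction == -1L
  if (any(flip)) {
    em$data[, flip] <- sweep(em$data[, flip, drop = FALSE], 2, -1, "*")
    rng <- em$codebook[flip, c("range_low", "range_high")]
    em$codebook$range_low[flip] <- -rng$range_high
    em$codebook$range_high[flip] <- -rng$range_low
    em$codebook$direction[flip] <- 1L
  }
  em
}

#' Standardize exposures to unit variance
#'
#' Rescales every column to sample variance 1, computed on observed entries
#' with the n-1 denominator. Columns are not mean-centred (the intercept
#' absorbs the mean), so raw-scale coefficients are recovered as
#' \code{B_std / SD} from the returned scale record. When a scale record from
#' a previous call is supplied it is reused unchanged, so that completed
#' (imputed) datasets share one scale and coefficients stay comparable.
#'
#' @param em an \code{\link{exposome_matrix}}.
#' @param scale optional named vector of SDs to reuse (a frozen scale record).
#' @return the standardized matrix; the scale record is in \code{$scale}.
#' @export
standardize <- function(em, scale = NULL) {
  if (is.null(scale)) {
    scale <- apply(em$data, 2, stats::sd, na.rm = TRUE)
    if (any(!is.finite(scale) | scale == 0)) {
      bad <- colnames(em$data)[!is.finite(scale) | scale == 0]
      stop("degenerate column(s) with no variation: ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; run drop_degenerate() first")
    }
  } else {
    if (!all(colnames(em$data) %in% names(scale)))
      stop("supplied scale record does not cover all variables")
    scale <- scale[colnames(em$data)]
  }
  em$data <- sweep(em$data, 2, scale, "/")
  # compose with any earlier standardization so B_std / scale is always raw
  em$scale <- if (is.null(em$scale)) scale else em$scale * scale
  em
}

#' Drop degenerate exposures
#'
#' Removes variables that are constant among subjects with an observed
#' outcome; such variables (for example, exposures whose presence was never
#' reported within the analysis sample) carry no information for the scan.
#' Variables with at least two observed levels in the outcome sample are
#' always kept.
#'
#' @param em an \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector (\code{NA} = outcome missing).
#' @return list with the reduced \code{matrix} and the \code{dropped} names.
#' @export
drop_degenerate <- function(em, outcome) {
  rows <- !is.na(outcome)
  sub <- em$data[rows, , drop = FALSE]
  n_levels <- apply(sub, 2, function(x) length(unique(x[!is.na(x)])))
  dropped <- colnames(sub)[n_levels < 2]
  keep <- setdiff(colnames(sub), dropped)
  list(matrix = subset_exposome(em, keep), dropped = dropped)
}

#' Encode partner-reported variables for partnerless subjects
#'
#' For subjects with no current partner (partner status 1), every
#' partner-reported variable is set to an arbitrary fill value, by default 0,
#' the lowest feasible value. Filled cells are flagged so they remain
#' distinguishable from genuinely observed zeros, and any model that includes
#' a filled partner variable must also include the partner-status indicator:
#' the fitted values and all non-status coefficients are then invariant to
#' the choice of fill value.
#'
#' @param em an \code{\link{exposome_matrix}}.
#' @param fill_value value assigned to partner variables of partnerless
#'   subjects (default 0).
#' @return the encoded matrix.
#' @export
encode_partner_variables <- function(em, fill_value = 0) {
  pvars <- em$codebook$reporter == "partner"
  psub <- em$partner_status == 1
  if (!any(psub) || !any(pvars)) return(em)
  low <- em$codebook$range_low[pvars]
  high <- em$codebook$range_high[pvars]
  if (any(fill_value < low | fill_value > high))
    warning("fill_value ", fill_value,
            " lies outside the feasible range of some partner variables ",
            "(the fill is arbitrary by construction)")
  # fill on the current scale of the data: if already standardized, express
  # the raw fill value on the standardized scale
  fills <- rep(fill_value, sum(pvars))
  if (!is.null(em$scale)) fills <- fill_value / em$scale[pvars]
  em$data[psub, pvars] <- rep(fills, each = sum(psub))
  em$filled[psub, pvars] <- TRUE
  em
}
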