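#' Cell-line by drug response matrix
#'
#' Light container for a continuous drug-response screen: one row per cell
#' line, one column per drug, \code{NA} marking unmeasured combinations.
#' \code{polarity} states which end of the scale means sensitive, because
#' the two summary scales in common use disagree: on activity area, high
#' values mean sensitive; on log IC50, low values mean sensitive.
#'
#' @param values numeric matrix with unique rownames (cell-line ids) and
#'   unique colnames (drug ids); non-missing entries must be finite.
#' @param polarity \code{"high_is_sensitive"} (activity-area convention) or
#'   \code{"low_is_sensitive"} (log IC50 convention).
#' @param scale_label free-text description of the response scale.
#' @return An object of class \code{response_matrix}.
#' @export
response_matrix <- function(values,
                            polarity = c("high_is_sensitive", "low_is_sensitive"),
                            scale_label = "") {
  polarity <- match.arg(polarity)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have cell-line rownames and drug colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated cell-line ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated drug ids", call. = FALSE)
  if (any(is.infinite(values)))
    stop("non-missing response values must be finite", call. = FALSE)
  structure(
    list(values = values, polarity = polarity, scale_label = scale_label),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  v <- x$values
  cat("response_matrix: ", nrow(v), " cell lines x ", ncol(v), " drugs\n", sep = "")
  cat("  polarity: ", x$polarity,
      if (nzchar(x$scale_label)) paste0("  scale: ", x$scale_label), "\n", sep = "")
  cat("  missing: ", sum(is.na(v)), " of ", length(v),
      sprintf(" (%.1f%%)\n", 100 * mean(is.na(v))), sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

cell_lines <- function(x) rownames(x$values)
drugs <- function(x) colnames(x$values)

#' Binarized sensitive/resistant calls
#'
#' @param calls character matrix with entries \code{"sensitive"},
#'   \code{"resistant"} or \code{NA}; cell-line rownames, drug colnames.
#' @param thresholds named list of \code{waterfall} threshold records
#'   (one per drug with at least one call), or \code{NULL}.
#' @return An object of class \code{sensitivity_calls}.
#' @export
sensitivity_calls <- function(calls, thresholds = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix", call. = FALSE)
  ok <- is.na(calls) | calls %in% c("sensitive", "resistant")
  if (!all(ok))
    stop("calls must be 'sensitive', 'resistant' or NA", call. = FALSE)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' must have cell-line rownames and drug colnames", call. = FALSE)
  structure(list(calls = calls, thresholds = thresholds),
            class = "sensitivity_calls")
}

#' @export
print.sensitivity_calls <- function(x, ...) {
  cat("sensitivity_calls: ", nrow(x$calls), " cell lines x ",
      ncol(x$calls), " drugs\n", sep = "")
  tab <- table(factor(x$calls, levels = c("sensitive", "resistant")),
               useNA = "ifany")
  cat("  sensitive: ", tab[["sensitive"]],
      "  resistant: ", tab[["resistant"]],
      "  missing: ", sum(is.na(x$calls)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.sensitivity_calls <- function(x) dim(x$calls)

resistant_lines <- function(calls, drug) {
  col <- call_column(calls, drug)
  names(col)[!is.na(col) & col == "resistant"]
}

call_column <- function(calls, drug) {
  if (!drug %in% colnames(calls$calls))
    stop("unknown drug id: ", drug, call. = FALSE)
  stats::setNames(calls$calls[, drug], rownames(calls$calls))
}
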