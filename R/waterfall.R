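#' Waterfall discretization threshold for one drug
#'
#' Implements the waterfall method used to split a drug's response
#' distribution into sensitive and resistant groups. The response values are
#' sorted in decreasing order and compared against a straight line: if the
#' sorted "waterfall" is close to linear (absolute Pearson correlation with
#' its rank index at least \code{linearity_cutoff}), the distribution carries
#' no inflection signal and the threshold is the median. Otherwise the
#' threshold is placed at the major inflection point, the sorted value whose
#' point is farthest (perpendicular distance, both axes min-max rescaled to
#' [0, 1]) from the chord joining the first and last sorted values.
#'
#' @param values numeric vector of response scores for one drug; \code{NA}s
#'   are dropped. At least 3 finite values, not all equal, are required.
#' @param linearity_cutoff Pearson-correlation cutoff in (0, 1) deciding
#'   between the median rule and the inflection rule. Default 0.95, the
#'   convention of the large-panel screens this method originates from.
#' @param drug_id optional drug label carried into the result.
#' @return An object of class \code{waterfall}: list with \code{drug_id},
#'   \code{n_used}, \code{linearity_r}, \code{rule} ("median" or
#'   "inflection"), \code{threshold} and \code{cutpoint_index} (NA for the
#'   median rule).
#' @examples
#' waterfall_threshold(1:11)                    # perfectly linear -> median 6
#' waterfall_threshold(c(rnorm(10), rnorm(10, 8)))
#' @export
waterfall_threshold <- function(values, linearity_cutoff = 0.95, drug_id = NA_character_) {
  if (!is.numeric(linearity_cutoff) || length(linearity_cutoff) != 1 ||
      linearity_cutoff <= 0 || linearity_cutoff >= 1)
    stop("'linearity_cutoff' must be a single value in (0, 1)", call. = FALSE)
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 3)
    stop("waterfall needs at least 3 finite values (got ", n, ")", call. = FALSE)
  if (max(v) == min(v))
    stop("degenerate distribution: all values equal", call. = FALSE)

  s <- sort(v, decreasing = TRUE)
  r <- stats::cor(seq_len(n), s)

  if (abs(r) >= linearity_cutoff) {
    rule <- "median"
    threshold <- as.numeric(stats::median(v))
    cut_idx <- NA_integer_
  } else {
    rule <- "inflection"
    d <- chord_distances(s)
    cut_idx <- which.max(d)  # which.max returns the first (smallest) index on ties
    threshold <- s[cut_idx]
  }

  structure(
    list(drug_id = drug_id, n_used = n, linearity_r = r, rule = rule,
         threshold = threshold, cutpoint_index = cut_idx),
    class = "waterfall"
  )
}

# Perpendicular distance of every sorted point to the chord joining the first
# and last points, after rescaling both axes to [0, 1] so the index axis does
# not dominate.
chord_distances <- function(s) {
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[n]) / (s[1] - s[n])
  # chord endpoints are (0, 1) and (1, 0); |(x2-x1)(y1-y) - (x1-x)(y2-y1)| / len
  abs((1 - 0) * (y[1] - y) - (0 - x) * (y[n] - y[1])) /
    sqrt((1 - 0)^2 + (y[n] - y[1])^2)
}

#' @export
print.waterfall <- function(x, ...) {
  cat("waterfall threshold",
      if (!is.na(x$drug_id)) paste0(" [", x$drug_id, "]"), "\n", sep = "")
  cat(sprintf("  n = %d, linearity r = %.4f, rule = %s\n",
              x$n_used, x$linearity_r, x$rule))
  cat(sprintf("  threshold = %g", x$threshold))
  if (!is.na(x$cutpoint_index))
    cat(" (inflection at sorted index ", x$cutpoint_index, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Apply thresholds to a response matrix
#'
#' Turns continuous responses into sensitive/resistant calls. Under
#' \code{high_is_sensitive} polarity a value \emph{at or above} the drug's
#' threshold is called sensitive and a value below it resistant; under
#' \code{low_is_sensitive} the comparison is mirrored (at or below the
#' threshold is sensitive). A value exactly at the threshold is therefore
#' always called sensitive — a fixed convention. Missing responses give
#' missing calls.
#'
#' @param x a \code{\link{response_matrix}}.
#' @param thresholds named list of \code{waterfall} records (or a named
#'   numeric vector of thresholds) covering every drug in \code{x}.
#' @return A \code{\link{sensitivity_calls}} object.
#' @export
call_sensitivity <- function(x, thresholds) {
  stopifnot(inherits(x, "response_matrix"))
  if (is.numeric(thresholds)) {
    thr <- thresholds
    records <- NULL
  } else {
    thr <- vapply(thresholds, function(w) w$threshold, numeric(1))
    records <- thresholds
  }
  missing_thr <- setdiff(drugs(x), names(thr))
  if (length(missing_thr))
    stop("no threshold for drug(s): ", paste(missing_thr, collapse = ", "),
         call. = FALSE)

  calls <- matrix(NA_character_, nrow(x$values), ncol(x$values),
                  dimnames = dimnames(x$values))
  for (d in drugs(x)) {
    v <- x$values[, d]
    sens <- if (x$polarity == "high_is_sensitive") v >= thr[[d]] else v <= thr[[d]]
    calls[, d] <- ifelse(is.na(v), NA_character_,
                         ifelse(sens, "sensitive", "resistant"))
  }
  sensitivity_calls(calls, thresholds = records)
}

#' Binarize a response matrix with the waterfall method
#'
#' Convenience wrapper: computes a \code{\link{waterfall_threshold}} per drug
#' and applies it with \code{\link{call_sensitivity}}. Drugs whose response
#' vector cannot be thresholded (fewer than 3 finite values, or all values
#' equal) get all-missing calls and no threshold record, with a warning.
#'
#' @inheritParams call_sensitivity
#' @inheritParams waterfall_threshold
#' @return A \code{\link{sensitivity_calls}} object whose \code{thresholds}
#'   slot holds one \code{waterfall} record per binarizable drug.
#' @export
binarize_response <- function(x, linearity_cutoff = 0.95) {
  stopifnot(inherits(x, "response_matrix"))
  thresholds <- list()
  skipped <- character()
  for (d in drugs(x)) {
    w <- tryCatch(
      waterfall_threshold(x$values[, d], linearity_cutoff, drug_id = d),
      error = function(e) NULL
    )
    if (is.null(w)) skipped <- c(skipped, d) else thresholds[[d]] <- w
  }
  if (length(skipped))
    warning("drug(s) not binarizable (too few or degenerate values): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(thresholds))
    stop("no drug could be binarized", call. = FALSE)

  ok <- x
  ok$values <- x$values[, names(thresholds), drop = FALSE]
  out <- call_sensitivity(ok, thresholds)
  if (length(skipped)) {
    # re-attach skipped drugs as all-missing columns, preserving column order
    calls <- matrix(NA_character_, nrow(x$values), ncol(x$values),
                    dimnames = dimnames(x$values))
    calls[, names(thresholds)] <- out$calls
    out <- sensitivity_calls(calls, thresholds = thresholds)
  }
  out
}
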