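#' Annotated gene set
#'
#' @param members character vector of gene ids (deduplicated, non-empty).
#' @param label set label, e.g. \code{"EMT"} or \code{"CSC"}.
#' @param source free-text provenance note.
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(members, label = "custom", source = "") {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (!length(members))
    stop("gene set must be non-empty", call. = FALSE)
  structure(list(label = label, members = members, source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set [", x$label, "]: ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Top upregulated genes of a co-resistance case
#'
#' Scores every gene by how much higher its expression is in the case's
#' co-resistant cell lines than in the remaining evaluable (non-co-resistant)
#' lines, and returns the top k. The default statistic is the mean difference
#' on the log-intensity scale; \code{"fold_change"} exponentiates it and
#' \code{"standardized"} divides by the pooled standard deviation. Ties are
#' broken lexicographically by gene id so the list is deterministic.
#'
#' @param expression numeric matrix, cell lines x genes.
#' @param case a \code{coresistance_pair}; its co-resistant lines form the
#'   case group, its other evaluable lines the rest group.
#' @param k number of genes to keep (default 1000).
#' @param statistic ranking statistic, see above.
#' @return An object of class \code{top_genes}: list with \code{case_id},
#'   \code{k}, \code{statistic}, \code{genes} (character, length
#'   \code{min(k, n genes)}), \code{scores} (named, non-increasing),
#'   \code{n_case}, \code{n_rest}.
#' @export
top_upregulated <- function(expression, case, k = 1000,
                            statistic = c("mean_diff", "fold_change",
                                          "standardized")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(case, "coresistance_pair"))
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("'k' must be a positive number", call. = FALSE)
  case_lines <- intersect(case$co_resistant_lines, rownames(expression))
  rest_lines <- intersect(setdiff(case$evaluable_lines, case$co_resistant_lines),
                          rownames(expression))
  if (length(case_lines) < 2 || length(rest_lines) < 2)
    stop("need >= 2 case and >= 2 rest lines with expression", call. = FALSE)

  mu_case <- colMeans(expression[case_lines, , drop = FALSE], na.rm = TRUE)
  mu_rest <- colMeans(expression[rest_lines, , drop = FALSE], na.rm = TRUE)
  score <- switch(statistic,
    mean_diff = mu_case - mu_rest,
    fold_change = exp(mu_case - mu_rest),
    standardized = {
      v_case <- apply(expression[case_lines, , drop = FALSE], 2, stats::var,
                      na.rm = TRUE)
      v_rest <- apply(expression[rest_lines, , drop = FALSE], 2, stats::var,
                      na.rm = TRUE)
      pooled <- sqrt(((length(case_lines) - 1) * v_case +
                      (length(rest_lines) - 1) * v_rest) /
                     (length(case_lines) + length(rest_lines) - 2))
      (mu_case - mu_rest) / pooled
    })
  score <- score[is.finite(score)]
  if (k > length(score)) {
    warning("k exceeds gene universe (", length(score), "); truncated",
            call. = FALSE)
    k <- length(score)
  }
  ord <- order(-score, names(score))
  top <- score[ord][seq_len(k)]
  structure(
    list(case_id = paste(case$drug_a, case$drug_b, sep = ":"),
         k = k, statistic = statistic,
         genes = names(top), scores = top,
         n_case = length(case_lines), n_rest = length(rest_lines)),
    class = "top_genes"
  )
}

#' @export
print.top_genes <- function(x, ...) {
  cat("top_genes case ", x$case_id, ": top ", x$k, " by ", x$statistic,
      " (", x$n_case, " case vs ", x$n_rest, " rest lines)\n", sep = "")
  invisible(x)
}

#' Match a top-gene list against an annotated gene set
#'
#' Reports the proportion of the annotated set found among the case's top
#' upregulated genes: |top intersect set| / |set|. The alternative
#' normalization by the top-list size k is emitted alongside.
#'
#' @param top a \code{\link{top_upregulated}} result.
#' @param annotated a \code{\link{gene_set}}.
#' @return list with \code{case_id}, \code{set_label}, \code{proportion}
#'   (over the annotated set size), \code{proportion_of_k}, and
#'   \code{intersection} (character vector).
#' @export
match_proportion <- function(top, annotated) {
  stopifnot(inherits(top, "top_genes"), inherits(annotated, "gene_set"))
  hit <- intersect(top$genes, annotated$members)
  list(case_id = top$case_id, set_label = annotated$label,
       proportion = length(hit) / length(annotated$members),
       proportion_of_k = length(hit) / top$k,
       intersection = sort(hit))
}

#' Per-case match table over several gene sets
#'
#' @param tops list of \code{top_genes} results (one per case).
#' @param sets list of \code{gene_set} objects.
#' @return data.frame with one row per (case, set): \code{case_id},
#'   \code{set_label}, \code{set_size}, \code{n_matched}, \code{proportion},
#'   \code{proportion_of_k}.
#' @export
match_table <- function(tops, sets) {
  rows <- list()
  for (top in tops) {
    for (s in sets) {
      m <- match_proportion(top, s)
      rows[[length(rows) + 1]] <- data.frame(
        case_id = m$case_id, set_label = m$set_label,
        set_size = length(s$members), n_matched = length(m$intersection),
        proportion = m$proportion, proportion_of_k = m$proportion_of_k,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
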