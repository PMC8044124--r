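#' Alteration frequencies within a co-resistance case
#'
#' For one co-resistance case (a drug pair with its co-resistant cell lines),
#' computes the fraction of co-resistant lines carrying each binary genomic
#' alteration (e.g. copy-number amplification/deletion of recurrently aberrant
#' segments, driver-gene mutation, CpG hypermethylation). Features measured in
#' none of the case's lines are omitted rather than reported as zero.
#'
#' @param features binary (0/1, \code{NA} allowed) matrix, cell lines in rows,
#'   features (genes/segments/sites) in columns.
#' @param case a \code{coresistance_pair} (see
#'   \code{\link{coresistance_count}}).
#' @param feature_kind label recorded in the profile, e.g. \code{"RACS_amp"}.
#' @return An object of class \code{alteration_profile}: list with
#'   \code{case_id}, \code{feature_kind}, \code{frequencies} (named vector)
#'   and \code{denominators} (lines with data per feature).
#' @export
case_alteration_frequency <- function(features, case, feature_kind = "alteration") {
  stopifnot(inherits(case, "coresistance_pair"))
  lines <- intersect(case$co_resistant_lines, rownames(features))
  if (!length(lines))
    stop("no co-resistant line of this case has feature data", call. = FALSE)
  sub <- features[lines, , drop = FALSE]
  denom <- colSums(!is.na(sub))
  keep <- denom > 0
  if (!any(keep))
    stop("all features are missing for this case", call. = FALSE)
  freq <- colSums(sub == 1, na.rm = TRUE)[keep] / denom[keep]
  structure(
    list(case_id = paste(case$drug_a, case$drug_b, sep = ":"),
         feature_kind = feature_kind,
         frequencies = freq, denominators = denom[keep],
         n_lines = length(lines)),
    class = "alteration_profile"
  )
}

#' @export
print.alteration_profile <- function(x, ...) {
  cat("alteration_profile [", x$feature_kind, "] case ", x$case_id, ": ",
      length(x$frequencies), " features over ", x$n_lines, " lines\n", sep = "")
  invisible(x)
}

#' Case-by-case association matrix of alteration profiles
#'
#' Correlates the per-feature alteration frequency vectors of co-resistance
#' cases over their shared features. The entry (i, j) is the correlation of
#' case i's and case j's frequencies over features present in both profiles;
#' pairs sharing fewer than 3 features, or where either shared-feature vector
#' has zero variance, are flagged missing.
#'
#' @param profiles list of \code{alteration_profile} objects (length >= 2).
#' @param method \code{"pearson"} (default), \code{"spearman"}, or
#'   \code{"jaccard"} (on profiles binarized at frequency > 0).
#' @return An object of class \code{association_matrix}: symmetric numeric
#'   matrix with unit diagonal and case ids as dimnames; attribute
#'   \code{feature_kind}.
#' @export
association_matrix <- function(profiles, method = c("pearson", "spearman", "jaccard")) {
  method <- match.arg(method)
  if (length(profiles) < 2)
    stop("need at least 2 profiles", call. = FALSE)
  ids <- vapply(profiles, `[[`, character(1), "case_id")
  n <- length(profiles)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      fi <- profiles[[i]]$frequencies
      fj <- profiles[[j]]$frequencies
      shared <- intersect(names(fi), names(fj))
      m[i, j] <- m[j, i] <- if (length(shared) < 3) {
        NA_real_
      } else if (method == "jaccard") {
        a <- fi[shared] > 0
        b <- fj[shared] > 0
        if (!any(a | b)) NA_real_ else sum(a & b) / sum(a | b)
      } else {
        a <- fi[shared]
        b <- fj[shared]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
        else stats::cor(a, b, method = method)
      }
    }
  }
  structure(m, class = c("association_matrix", "matrix"),
            feature_kind = unique(vapply(profiles, `[[`, character(1),
                                         "feature_kind")))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("association_matrix [", paste(attr(x, "feature_kind"), collapse = ","),
      "] over ", nrow(x), " cases\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Mutation-type proportions within a co-resistance case
#'
#' Tallies mutation records of the case's co-resistant lines over the four
#' canonical types (missense, nonsense, essential splicing, frameshift) and
#' returns their proportions, which sum to 1.
#'
#' @param mutations long-format data.frame with columns \code{cell_line},
#'   \code{gene}, \code{mutation_type}.
#' @inheritParams case_alteration_frequency
#' @return list with \code{case_id}, \code{counts} and \code{proportions}
#'   (both named over the four types), \code{n_records}.
#' @export
mutation_type_profile <- function(mutations, case) {
  stopifnot(inherits(case, "coresistance_pair"))
  types <- mutation_types()
  bad <- setdiff(unique(mutations$mutation_type), types)
  if (length(bad))
    stop("unknown mutation type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rec <- mutations[mutations$cell_line %in% case$co_resistant_lines, , drop = FALSE]
  if (!nrow(rec))
    stop("no mutation record among the case's co-resistant lines", call. = FALSE)
  counts <- table(factor(rec$mutation_type, levels = types))
  counts <- stats::setNames(as.numeric(counts), types)
  list(case_id = paste(case$drug_a, case$drug_b, sep = ":"),
       counts = counts, proportions = counts / sum(counts),
       n_records = nrow(rec))
}

mutation_types <- function() {
  c("missense", "nonsense", "essential_splicing", "frameshift")
}

#' Per-gene mutation frequency matrix
#'
#' Helper turning a long mutation table into gene x bin frequency vectors,
#' where a bin is a (cell line, mutation type) combination and the value is
#' the fraction of the case's lines carrying that mutation type in that gene.
#' Bins with no record for a gene anywhere in the table are reported as 0
#' within covered types; types with no record for the gene at all are NA
#' (no input data, not evidence of absence).
#'
#' @param mutations long-format mutation data.frame.
#' @param genes genes (rows of the output) to profile.
#' @param lines cell lines forming the denominator.
#' @return numeric matrix, genes x mutation types, entries = fraction of
#'   \code{lines} with that (gene, type) mutation; NA where the gene has no
#'   record of that type in the full table.
#' @export
mutation_frequency_matrix <- function(mutations, genes, lines) {
  types <- mutation_types()
  rec <- mutations[mutations$cell_line %in% lines & mutations$gene %in% genes, ,
                   drop = FALSE]
  out <- matrix(NA_real_, length(genes), length(types),
                dimnames = list(genes, types))
  # a type column is "covered" for a gene if the full table has any record of
  # that (gene, type); within covered cells, absence of a record is a true 0
  covered <- table(factor(mutations$gene, levels = genes),
                   factor(mutations$mutation_type, levels = types)) > 0
  hits <- table(factor(rec$gene, levels = genes),
                factor(rec$mutation_type, levels = types))
  out[covered] <- as.matrix(hits)[covered] / length(lines)
  out
}

#' Correlation of two genes' mutation-frequency vectors
#'
#' Pearson correlation between two rows of a mutation-frequency matrix (or
#' any two paired frequency vectors), dropping bins where either gene has no
#' data, with a two-sided p-value.
#'
#' @param freqs numeric matrix with genes as rows (e.g. from
#'   \code{\link{mutation_frequency_matrix}}), or \code{NULL} if \code{gene_a}
#'   and \code{gene_b} are given directly as numeric vectors.
#' @param gene_a,gene_b row names into \code{freqs}, or numeric vectors.
#' @return list with \code{r}, \code{n} (paired bins used), \code{p_value}.
#' @export
rtk_mutation_correlation <- function(freqs = NULL, gene_a, gene_b) {
  if (!is.null(freqs)) {
    for (g in c(gene_a, gene_b))
      if (!g %in% rownames(freqs))
        stop("gene not in frequency matrix: ", g, call. = FALSE)
    a <- freqs[gene_a, ]
    b <- freqs[gene_b, ]
  } else {
    a <- gene_a
    b <- gene_b
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 3)
    stop("fewer than 3 paired observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a frequency vector", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), n = length(a), p_value = ct$p.value)
}

#' Stratify cell lines by expression of one gene
#'
#' Splits lines into low and high strata at a raw-intensity cutoff (default 4,
#' the conventional microarray expression baseline). A value exactly at the
#' cutoff goes to the high stratum; lines with missing expression fall in
#' neither.
#'
#' @param expression numeric matrix, cell lines x genes.
#' @param gene stratifier gene (default \code{"EGFR"}).
#' @param cutoff raw log-intensity cutoff (default 4).
#' @return An object of class \code{expression_strata}: list with \code{gene},
#'   \code{cutoff}, \code{low} and \code{high} cell-line id vectors.
#' @export
stratify_by_expression <- function(expression, gene = "EGFR", cutoff = 4) {
  if (!gene %in% colnames(expression))
    stop("gene not in expression matrix: ", gene, call. = FALSE)
  v <- expression[, gene]
  ok <- !is.na(v)
  structure(
    list(gene = gene, cutoff = cutoff,
         low = rownames(expression)[ok & v < cutoff],
         high = rownames(expression)[ok & v >= cutoff]),
    class = "expression_strata"
  )
}

#' @export
print.expression_strata <- function(x, ...) {
  cat("expression_strata on ", x$gene, " at cutoff ", x$cutoff, ": ",
      length(x$low), " low, ", length(x$high), " high\n", sep = "")
  invisible(x)
}

#' Rank receptor tyrosine kinases across co-resistance cases
#'
#' For each case and expression stratum, the mean expression of each RTK over
#' the case's co-resistant lines in that stratum is z-scored across the RTK
#' list (so scores are comparable between cases), and the overall ranking is
#' the descending cross-case mean of these standardized scores. Empty
#' (case, stratum) cells are flagged missing and skipped in the averaging.
#'
#' @param expression numeric matrix, cell lines x genes.
#' @param cases list of \code{coresistance_pair} objects.
#' @param strata an \code{\link{expression_strata}} object, or \code{NULL} to
#'   use a single stratum of all lines.
#' @param rtk_list character vector of RTK gene ids, all present in
#'   \code{expression}.
#' @return An object of class \code{rtk_ranking}: list with \code{table} (long
#'   data.frame: case_id, stratum, gene, mean_expression, zscore) and
#'   \code{ranking} (data.frame: gene, mean_zscore, rank; descending).
#' @export
rank_rtks <- function(expression, cases, strata = NULL, rtk_list) {
  missing_genes <- setdiff(rtk_list, colnames(expression))
  if (length(missing_genes))
    stop("RTK(s) not in expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  strata_sets <- if (is.null(strata)) list(all = rownames(expression))
                 else list(low = strata$low, high = strata$high)

  rows <- list()
  for (case in cases) {
    cid <- paste(case$drug_a, case$drug_b, sep = ":")
    for (s in names(strata_sets)) {
      lines <- intersect(case$co_resistant_lines, strata_sets[[s]])
      lines <- intersect(lines, rownames(expression))
      if (!length(lines)) {
        rows[[length(rows) + 1]] <- data.frame(
          case_id = cid, stratum = s, gene = rtk_list,
          n_lines = 0L, mean_expression = NA_real_, zscore = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      mu <- colMeans(expression[lines, rtk_list, drop = FALSE], na.rm = TRUE)
      z <- if (stats::sd(mu) > 0) (mu - mean(mu)) / stats::sd(mu)
           else rep(0, length(mu))
      rows[[length(rows) + 1]] <- data.frame(
        case_id = cid, stratum = s, gene = rtk_list,
        n_lines = length(lines), mean_expression = unname(mu),
        zscore = unname(z), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(zscore ~ gene, data = tab, FUN = mean,
                          na.action = stats::na.omit)
  agg <- agg[order(-agg$zscore, agg$gene), , drop = FALSE]
  ranking <- data.frame(gene = agg$gene, mean_zscore = agg$zscore,
                        rank = seq_len(nrow(agg)), stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  structure(list(table = tab, ranking = ranking), class = "rtk_ranking")
}

#' @export
print.rtk_ranking <- function(x, ...) {
  cat("rtk_ranking over ", length(unique(x$table$case_id)), " case(s)\n", sep = "")
  print(utils::head(x$ranking, 5))
  invisible(x)
}
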