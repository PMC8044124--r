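#' Configuration for the synthetic GDSC-shaped data generator
#'
#' Describes a simulated pharmacogenomic screen: per drug, each cell line is
#' latently sensitive or resistant; the observed response (log IC50, so the
#' resistant state sits at the higher location) is drawn from the
#' state-conditional Gaussian; planted drug pairs share their latent
#' resistance state with probability \code{kappa}, creating known co-resistant
#' pairs. Genomic alterations and expression signals are coupled to the latent
#' co-resistance status so every downstream stage has recoverable ground
#' truth.
#'
#' Defaults mirror the GDSC panel shape (1001 cell lines, 265 drugs, 23
#' lineages, 22 RTK genes including AXL and EGFR, AXL-EGFR expression
#' correlation 0.8) with the gene universe scaled to 2000 genes to stay
#' desk-sized. Randomness is hierarchical: the single \code{seed} spawns one
#' substream per drug/gene block, so enlarging the panel does not perturb
#' existing columns.
#'
#' @param n_cell_lines,n_drugs panel dimensions.
#' @param drug_classes optional named character vector drug id -> class
#'   (\code{"RTKi"}, \code{"antimitotic"}, \code{"CTD"}, \code{"other"}).
#' @param similarity_groups optional named character vector drug id ->
#'   chemical-similarity group.
#' @param resistant_fraction per-drug probability of the resistant state
#'   (scalar recycled, or named per drug).
#' @param planted_pairs data.frame with columns \code{drug_a}, \code{drug_b},
#'   \code{kappa} (coupling in [0, 1]), or \code{NULL}.
#' @param response_means length-2 numeric \code{c(sensitive, resistant)} on
#'   the log IC50 scale; resistant must exceed sensitive.
#' @param response_sd common state-conditional standard deviation.
#' @param missing_rate fraction of response entries blanked uniformly at
#'   random.
#' @param n_genes expression/mutation gene universe size.
#' @param rtk_genes 22 RTK gene ids; must contain \code{AXL} and \code{EGFR}.
#' @param expression_coupling AXL-EGFR expression correlation rho.
#' @param expression_mean,expression_sd log-intensity baseline; the default
#'   (5, 1.5) spans the conventional stratification cutoff of 4.
#' @param rtk_case_shift named numeric: extra expression (in units of
#'   \code{expression_sd}) added to the named RTK(s) in co-resistant lines;
#'   default plants AXL 3 sd above the other RTKs there.
#' @param mutation_rate per (line, gene) mutation probability.
#' @param mutation_effect additive increase of \code{mutation_rate} in
#'   co-resistant lines.
#' @param mutation_type_proportions probabilities over missense, nonsense,
#'   essential splicing, frameshift (sums to 1; default keeps missense
#'   dominant and essential splicing rare, as in real panels).
#' @param n_alteration_features number of features in each binary alteration
#'   matrix (RACS amplification, RACS deletion, CpG hypermethylation).
#' @param alteration_base_rate,alteration_effect baseline alteration
#'   probability and its additive enrichment delta in lines co-resistant to at
#'   least one planted pair; base + delta must not exceed 1.
#' @param upregulated_set_size planted upregulated genes per planted pair.
#' @param upregulated_shift_sd their mean shift, in units of
#'   \code{expression_sd}, within the case's co-resistant lines.
#' @param n_lineages number of cancer lineages assigned uniformly.
#' @param seed integer master seed.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_cell_lines = 1001,
                       n_drugs = 265,
                       drug_classes = NULL,
                       similarity_groups = NULL,
                       resistant_fraction = 0.3,
                       planted_pairs = NULL,
                       response_means = c(sensitive = -6, resistant = -2),
                       response_sd = 1,
                       missing_rate = 0.05,
                       n_genes = 2000,
                       rtk_genes = default_rtk_genes(),
                       expression_coupling = 0.8,
                       expression_mean = 5,
                       expression_sd = 1.5,
                       rtk_case_shift = c(AXL = 3),
                       mutation_rate = 0.01,
                       mutation_effect = 0.01,
                       mutation_type_proportions = c(missense = 0.55,
                                                     nonsense = 0.20,
                                                     essential_splicing = 0.03,
                                                     frameshift = 0.22),
                       n_alteration_features = 50,
                       alteration_base_rate = 0.1,
                       alteration_effect = 0.2,
                       upregulated_set_size = 50,
                       upregulated_shift_sd = 2,
                       n_lineages = 23,
                       seed = 1L) {
  stopifnot(n_cell_lines >= 1, n_drugs >= 1, n_genes >= 1, n_lineages >= 1)
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  if (is.null(planted_pairs)) {
    if (n_drugs >= 6) {
      planted_pairs <- data.frame(
        drug_a = drug_ids[c(1, 3, 5)], drug_b = drug_ids[c(2, 4, 6)],
        kappa = 0.9, stringsAsFactors = FALSE)
    } else {
      planted_pairs <- data.frame(drug_a = character(), drug_b = character(),
                                  kappa = numeric(), stringsAsFactors = FALSE)
    }
  }
  if (nrow(planted_pairs)) {
    unknown <- setdiff(c(planted_pairs$drug_a, planted_pairs$drug_b), drug_ids)
    if (length(unknown))
      stop("planted pair references unknown drug(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(planted_pairs$kappa < 0 | planted_pairs$kappa > 1))
      stop("kappa must lie in [0, 1]", call. = FALSE)
  }
  if (length(resistant_fraction) == 1)
    resistant_fraction <- stats::setNames(rep(resistant_fraction, n_drugs), drug_ids)
  if (any(resistant_fraction <= 0 | resistant_fraction >= 1))
    stop("resistant_fraction must lie in (0, 1)", call. = FALSE)
  if (response_means[["resistant"]] <= response_means[["sensitive"]])
    stop("resistant response location must exceed the sensitive location ",
         "on the log IC50 scale", call. = FALSE)
  if (response_sd <= 0) stop("response_sd must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (abs(expression_coupling) > 1)
    stop("|expression_coupling| must not exceed 1", call. = FALSE)
  if (!all(c("AXL", "EGFR") %in% rtk_genes))
    stop("rtk_genes must include AXL and EGFR", call. = FALSE)
  if (alteration_base_rate + alteration_effect > 1)
    stop("alteration base rate + effect exceeds 1", call. = FALSE)
  if (mutation_rate + mutation_effect > 1)
    stop("mutation rate + effect exceeds 1", call. = FALSE)
  if (abs(sum(mutation_type_proportions) - 1) > 1e-8)
    stop("mutation type proportions must sum to 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single integer", call. = FALSE)

  structure(
    list(n_cell_lines = n_cell_lines, n_drugs = n_drugs,
         cell_line_ids = sprintf("CL%04d", seq_len(n_cell_lines)),
         drug_ids = drug_ids,
         drug_classes = drug_classes, similarity_groups = similarity_groups,
         resistant_fraction = resistant_fraction,
         planted_pairs = planted_pairs,
         response_means = response_means, response_sd = response_sd,
         missing_rate = missing_rate,
         n_genes = n_genes, rtk_genes = rtk_genes,
         expression_coupling = expression_coupling,
         expression_mean = expression_mean, expression_sd = expression_sd,
         rtk_case_shift = rtk_case_shift,
         mutation_rate = mutation_rate, mutation_effect = mutation_effect,
         mutation_type_proportions = mutation_type_proportions,
         n_alteration_features = n_alteration_features,
         alteration_base_rate = alteration_base_rate,
         alteration_effect = alteration_effect,
         upregulated_set_size = upregulated_set_size,
         upregulated_shift_sd = upregulated_shift_sd,
         n_lineages = n_lineages, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' The 22 receptor tyrosine kinases profiled by default
#' @return character vector of 22 gene symbols including AXL and EGFR.
#' @export
default_rtk_genes <- function() {
  c("AXL", "EGFR", "ERBB2", "ERBB3", "ERBB4", "MET", "IGF1R", "INSR",
    "PDGFRA", "PDGFRB", "KIT", "FLT1", "FLT3", "FLT4", "KDR",
    "FGFR1", "FGFR2", "FGFR3", "FGFR4", "ALK", "RET", "NTRK1")
}

# One master seed -> reproducible substreams. Seeds are drawn sequentially, so
# the first k substreams are identical whatever n is; appending drugs or genes
# leaves existing columns untouched.
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

gene_universe <- function(config) {
  n_other <- config$n_genes - length(config$rtk_genes)
  if (n_other < 0)
    stop("n_genes smaller than the RTK list", call. = FALSE)
  c(config$rtk_genes, sprintf("G%05d", seq_len(n_other)))
}

#' Generate the response matrix and its ground truth
#'
#' Draws, per drug, a latent resistant/sensitive state per cell line
#' (Bernoulli at the drug's resistant fraction), couples planted pairs
#' (drug b copies drug a's state with probability kappa, else redraws
#' independently), then draws each observed log IC50 from the Gaussian of its
#' latent state and blanks entries at the missing rate.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{response} (a \code{\link{response_matrix}},
#'   polarity \code{low_is_sensitive}) and \code{truth} (class
#'   \code{sim_truth}): \code{latent_state} logical matrix (TRUE = resistant,
#'   no missing entries), \code{true_threshold} per drug (midpoint of the two
#'   state means), \code{planted_pairs}, \code{co_resistant_lines} per planted
#'   pair plus their union \code{any_co_resistant}.
#' @export
generate_response_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cell_lines
  drugs <- config$drug_ids
  # independent substream families: per-drug draws, per-pair coupling;
  # growing the panel never re-seeds an existing column
  seeds <- substream_seeds(config$seed, config$n_drugs)
  pair_seeds <- substream_seeds(config$seed + 4L,
                                max(nrow(config$planted_pairs), 1))

  latent <- matrix(FALSE, n, length(drugs),
                   dimnames = list(config$cell_line_ids, drugs))
  for (j in seq_along(drugs)) {
    set.seed(seeds[j])
    latent[, j] <- stats::runif(n) < config$resistant_fraction[[drugs[j]]]
  }
  pp <- config$planted_pairs
  if (nrow(pp)) {
    for (k in seq_len(nrow(pp))) {
      set.seed(pair_seeds[k])
      copy <- stats::runif(n) < pp$kappa[k]
      fresh <- stats::runif(n) < config$resistant_fraction[[pp$drug_b[k]]]
      latent[, pp$drug_b[k]] <- ifelse(copy, latent[, pp$drug_a[k]], fresh)
    }
  }

  mu <- ifelse(latent, config$response_means[["resistant"]],
               config$response_means[["sensitive"]])
  values <- matrix(NA_real_, n, length(drugs), dimnames = dimnames(latent))
  n_missing <- round(config$missing_rate * n)  # per drug column
  for (j in seq_along(drugs)) {
    set.seed(seeds[j] + 1L)  # offset stream: values given states
    values[, j] <- stats::rnorm(n, mu[, j], config$response_sd)
    if (n_missing > 0) {
      set.seed(seeds[j] + 2L)
      values[sample.int(n, n_missing), j] <- NA_real_
    }
  }

  co_res <- list()
  if (nrow(pp)) {
    for (k in seq_len(nrow(pp))) {
      co_res[[paste(pp$drug_a[k], pp$drug_b[k], sep = ":")]] <-
        config$cell_line_ids[latent[, pp$drug_a[k]] & latent[, pp$drug_b[k]]]
    }
  }
  truth <- structure(
    list(latent_state = latent,
         true_threshold = stats::setNames(
           rep(mean(config$response_means), length(drugs)), drugs),
         planted_pairs = pp,
         co_resistant_lines = co_res,
         any_co_resistant = unique(unlist(co_res)),
         planted_expression_correlation = config$expression_coupling,
         planted_upregulated_genes = NULL),
    class = "sim_truth"
  )
  list(
    response = response_matrix(values, polarity = "low_is_sensitive",
                               scale_label = "log IC50 (uM)"),
    truth = truth
  )
}

#' Generate genomic feature bundles coupled to co-resistance
#'
#' Binary alteration matrices (RACS amplification, RACS deletion, CpG
#' hypermethylation) have per-entry alteration probability equal to the base
#' rate, plus the enrichment delta in cell lines co-resistant (in truth) to at
#' least one planted pair. The long mutation table gets one row per mutated
#' (line, gene), with the type drawn from the configured proportions.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth the \code{sim_truth} from
#'   \code{\link{generate_response_matrix}}.
#' @return list with \code{mutations} (data.frame: cell_line, gene,
#'   mutation_type), \code{racs_amp}, \code{racs_del}, \code{icpg} (binary
#'   matrices, lines x features).
#' @export
generate_genomic_features <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  n <- config$n_cell_lines
  enriched <- config$cell_line_ids %in% truth$any_co_resistant
  seeds <- substream_seeds(config$seed + 1L, 4)

  alt_matrix <- function(s, prefix) {
    set.seed(s)
    p <- config$alteration_base_rate + config$alteration_effect * enriched
    m <- matrix(stats::rbinom(n * config$n_alteration_features, 1,
                              rep(p, config$n_alteration_features)),
                n, config$n_alteration_features,
                dimnames = list(config$cell_line_ids,
                                sprintf("%s%03d", prefix,
                                        seq_len(config$n_alteration_features))))
    m
  }
  racs_amp <- alt_matrix(seeds[1], "AMP")
  racs_del <- alt_matrix(seeds[2], "DEL")
  icpg <- alt_matrix(seeds[3], "CPG")

  genes <- gene_universe(config)
  set.seed(seeds[4])
  p_mut <- config$mutation_rate + config$mutation_effect * enriched
  hit <- matrix(stats::runif(n * length(genes)) < rep(p_mut, length(genes)),
                n, length(genes))
  idx <- which(hit, arr.ind = TRUE)
  types <- sample(names(config$mutation_type_proportions), nrow(idx),
                  replace = TRUE, prob = config$mutation_type_proportions)
  mutations <- data.frame(
    cell_line = config$cell_line_ids[idx[, 1]],
    gene = genes[idx[, 2]],
    mutation_type = types,
    stringsAsFactors = FALSE
  )
  mutations <- mutations[order(mutations$cell_line, mutations$gene), ,
                         drop = FALSE]
  rownames(mutations) <- NULL
  list(mutations = mutations, racs_amp = racs_amp, racs_del = racs_del,
       icpg = icpg)
}

#' Generate basal expression coupled to co-resistance
#'
#' All genes are independent Gaussians on the log-intensity scale except:
#' AXL and EGFR are drawn jointly with the configured correlation rho; RTKs
#' named in \code{rtk_case_shift} get the stated extra expression in lines
#' co-resistant to at least one planted pair; and each planted pair gets a
#' disjoint set of planted upregulated genes whose mean is shifted up in that
#' case's co-resistant lines.
#'
#' @inheritParams generate_genomic_features
#' @return list with \code{expression} (matrix, lines x genes) and
#'   \code{planted_upregulated_genes} (named list per planted case).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  n <- config$n_cell_lines
  genes <- gene_universe(config)
  seeds <- substream_seeds(config$seed + 2L, length(genes) + 2)

  expr <- matrix(NA_real_, n, length(genes),
                 dimnames = list(config$cell_line_ids, genes))
  for (g in seq_along(genes)) {
    set.seed(seeds[g])
    expr[, g] <- stats::rnorm(n, config$expression_mean, config$expression_sd)
  }
  # joint AXL/EGFR: EGFR kept marginal, AXL = rho * EGFR + sqrt(1-rho^2) * z
  rho <- config$expression_coupling
  set.seed(seeds[length(genes) + 1])
  z <- stats::rnorm(n)
  e_std <- (expr[, "EGFR"] - config$expression_mean) / config$expression_sd
  expr[, "AXL"] <- config$expression_mean +
    config$expression_sd * (rho * e_std + sqrt(1 - rho^2) * z)

  if (length(config$rtk_case_shift) && length(truth$any_co_resistant)) {
    co <- rownames(expr) %in% truth$any_co_resistant
    for (g in names(config$rtk_case_shift)) {
      if (!g %in% genes) next
      expr[co, g] <- expr[co, g] +
        config$rtk_case_shift[[g]] * config$expression_sd
    }
  }

  planted <- list()
  if (nrow(config$planted_pairs) && config$upregulated_set_size > 0) {
    pool <- setdiff(genes, config$rtk_genes)
    set.seed(seeds[length(genes) + 2])
    need <- config$upregulated_set_size * nrow(config$planted_pairs)
    if (need > length(pool))
      stop("gene universe too small for the planted upregulated sets",
           call. = FALSE)
    chosen <- sample(pool, need)
    for (k in seq_len(nrow(config$planted_pairs))) {
      cid <- paste(config$planted_pairs$drug_a[k],
                   config$planted_pairs$drug_b[k], sep = ":")
      gset <- chosen[((k - 1) * config$upregulated_set_size + 1):
                       (k * config$upregulated_set_size)]
      planted[[cid]] <- sort(gset)
      lines <- truth$co_resistant_lines[[cid]]
      if (length(lines))
        expr[lines, gset] <- expr[lines, gset] +
          config$upregulated_shift_sd * config$expression_sd
    }
  }
  list(expression = expr, planted_upregulated_genes = planted)
}

#' Generate a complete synthetic bundle
#'
#' Runs all generators and assembles response, genomic features, expression,
#' lineage labels and drug annotations with a single ground-truth record.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{coresist_bundle}: list with
#'   \code{config}, \code{response}, \code{truth}, \code{mutations},
#'   \code{racs_amp}, \code{racs_del}, \code{icpg}, \code{expression},
#'   \code{lineages} (named character), \code{drug_annotations} (data.frame).
#' @export
simulate_bundle <- function(config = sim_config()) {
  rm_ <- generate_response_matrix(config)
  feats <- generate_genomic_features(config, rm_$truth)
  expr <- generate_expression(config, rm_$truth)
  truth <- rm_$truth
  truth$planted_upregulated_genes <- expr$planted_upregulated_genes

  seeds <- substream_seeds(config$seed + 3L, 1)
  set.seed(seeds[1])
  lineages <- stats::setNames(
    sprintf("lineage%02d", sample.int(config$n_lineages, config$n_cell_lines,
                                      replace = TRUE)),
    config$cell_line_ids)

  classes <- config$drug_classes
  if (is.null(classes))
    classes <- stats::setNames(rep("other", config$n_drugs), config$drug_ids)
  groups <- config$similarity_groups
  if (is.null(groups))
    groups <- stats::setNames(rep(NA_character_, config$n_drugs), config$drug_ids)
  drug_annotations <- data.frame(
    drug = config$drug_ids,
    class = unname(classes[config$drug_ids]),
    similarity_group = unname(groups[config$drug_ids]),
    stringsAsFactors = FALSE
  )
  structure(
    list(config = config, response = rm_$response, truth = truth,
         mutations = feats$mutations, racs_amp = feats$racs_amp,
         racs_del = feats$racs_del, icpg = feats$icpg,
         expression = expr$expression, lineages = lineages,
         drug_annotations = drug_annotations),
    class = "coresist_bundle"
  )
}

#' @export
print.coresist_bundle <- function(x, ...) {
  cat("coresist_bundle: ", x$config$n_cell_lines, " lines x ",
      x$config$n_drugs, " drugs, ", x$config$n_genes, " genes, seed ",
      x$config$seed, "\n", sep = "")
  cat("  planted pairs: ", nrow(x$config$planted_pairs), "\n", sep = "")
  invisible(x)
}
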