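#' Co-resistance between a drug pair
#'
#' A cell line counts toward co-resistance of a pair when it is called
#' resistant to both drugs. Lines missing the call for either drug are not
#' evaluable and are excluded from both numerator and denominator.
#'
#' @param calls a \code{\link{sensitivity_calls}} object.
#' @param drug_a,drug_b drug ids present in \code{calls}.
#' @return An object of class \code{coresistance_pair}: list with
#'   \code{drug_a}, \code{drug_b}, \code{co_resistant_lines},
#'   \code{evaluable_lines}, \code{count}, and (filled later by
#'   \code{\link{normalize_frequencies}}) \code{normalized_frequency} and
#'   \code{degree_bin}.
#' @export
coresistance_count <- function(calls, drug_a, drug_b) {
  stopifnot(inherits(calls, "sensitivity_calls"))
  ca <- call_column(calls, drug_a)
  cb <- call_column(calls, drug_b)
  evaluable <- names(ca)[!is.na(ca) & !is.na(cb)]
  co <- evaluable[ca[evaluable] == "resistant" & cb[evaluable] == "resistant"]
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         co_resistant_lines = co, evaluable_lines = evaluable,
         count = length(co),
         normalized_frequency = NA_real_, degree_bin = NA_character_),
    class = "coresistance_pair"
  )
}

#' @export
print.coresistance_pair <- function(x, ...) {
  cat("co-resistance ", x$drug_a, " <-> ", x$drug_b, ": ",
      x$count, " of ", length(x$evaluable_lines), " evaluable lines", sep = "")
  if (!is.na(x$normalized_frequency))
    cat(sprintf("  (normalized %.3f, %s)", x$normalized_frequency, x$degree_bin))
  cat("\n")
  invisible(x)
}

#' All co-resistance pairs between two drug families
#'
#' Enumerates unordered drug pairs, by default all pairs within
#' \code{drugs_a}; with \code{drugs_b} given, all cross pairs between the
#' two families (e.g. RTK inhibitors versus antimitotics).
#'
#' @inheritParams coresistance_count
#' @param drugs_a,drugs_b character vectors of drug ids.
#' @return A list of \code{coresistance_pair} objects.
#' @export
coresistance_pairs <- function(calls, drugs_a, drugs_b = NULL) {
  if (is.null(drugs_b)) {
    if (length(drugs_a) < 2) stop("need at least 2 drugs", call. = FALSE)
    idx <- utils::combn(drugs_a, 2)
    pairs <- lapply(seq_len(ncol(idx)), function(i)
      coresistance_count(calls, idx[1, i], idx[2, i]))
  } else {
    grid <- expand.grid(a = drugs_a, b = drugs_b, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    pairs <- lapply(seq_len(nrow(grid)), function(i)
      coresistance_count(calls, grid$a[i], grid$b[i]))
  }
  pairs
}

#' Min-max normalize co-resistance counts
#'
#' Rescales raw co-resistance counts across a set of pairs to [0, 1] by
#' min-max feature scaling, and bins the result with \code{\link{bin_degree}}.
#'
#' @param pairs list of \code{coresistance_pair} objects with at least two
#'   distinct counts.
#' @return The same list with \code{normalized_frequency} and
#'   \code{degree_bin} filled in.
#' @export
normalize_frequencies <- function(pairs) {
  counts <- vapply(pairs, function(p) p$count, numeric(1))
  if (length(pairs) < 2)
    stop("need at least 2 pairs to min-max scale", call. = FALSE)
  rng <- range(counts)
  if (rng[1] == rng[2])
    stop("degenerate scaling: all co-resistance counts equal", call. = FALSE)
  lapply(pairs, function(p) {
    p$normalized_frequency <- (p$count - rng[1]) / (rng[2] - rng[1])
    p$degree_bin <- bin_degree(p$normalized_frequency)
    p
  })
}

#' Degree bin of a normalized co-resistance frequency
#'
#' Bins a value in [0, 1] into low (< 0.10), mid (0.10 to < 0.60) or high
#' (>= 0.60). The high bin is closed at 0.60.
#'
#' @param x numeric vector of normalized frequencies in [0, 1].
#' @return Character vector over \code{c("low", "mid", "high")}.
#' @export
bin_degree <- function(x) {
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("normalized frequency outside [0, 1]", call. = FALSE)
  ifelse(is.na(x), NA_character_,
         ifelse(x >= 0.60, "high", ifelse(x >= 0.10, "mid", "low")))
}

#' Summarize pairs as a data frame
#'
#' @param pairs list of \code{coresistance_pair} objects.
#' @return data.frame with one row per pair.
#' @export
coresistance_table <- function(pairs) {
  data.frame(
    drug_a = vapply(pairs, `[[`, character(1), "drug_a"),
    drug_b = vapply(pairs, `[[`, character(1), "drug_b"),
    count = vapply(pairs, `[[`, numeric(1), "count"),
    n_evaluable = vapply(pairs, function(p) length(p$evaluable_lines), numeric(1)),
    normalized_frequency = vapply(pairs, `[[`, numeric(1), "normalized_frequency"),
    degree_bin = vapply(pairs, `[[`, character(1), "degree_bin"),
    stringsAsFactors = FALSE
  )
}

#' Rank a focal drug in the resistant-line panel of another drug
#'
#' The panel is the set of cell lines called resistant to \code{panel_drug}.
#' Every other drug d is scored by its conditional co-resistance frequency
#' among panel lines: (panel lines resistant to d) / (panel lines with a
#' non-missing call for d). Drugs are sorted by descending score — ties broken
#' by higher evaluable count, then lexicographic drug id — and the rank of
#' \code{focal_drug} is reported. With \code{exclude_similar = TRUE} all drugs
#' sharing the focal drug's chemical-similarity group (except the focal drug
#' itself) are removed before ranking.
#'
#' @inheritParams coresistance_count
#' @param panel_drug drug whose resistant lines define the panel.
#' @param focal_drug drug whose rank is reported; must differ from
#'   \code{panel_drug} and not be excluded.
#' @param exclusions drug ids removed before ranking.
#' @param similarity_groups optional named character vector mapping drug id to
#'   chemical-similarity group label.
#' @param exclude_similar remove drugs in the focal drug's similarity group.
#' @return An object of class \code{rank_table}: list with \code{panel_drug},
#'   \code{panel_size}, \code{focal_drug}, \code{scores} (named, sorted),
#'   \code{evaluable} (named counts), \code{rank}, \code{n_ranked},
#'   \code{exclusions}.
#' @export
rank_drug_in_panel <- function(calls, panel_drug, focal_drug,
                               exclusions = character(),
                               similarity_groups = NULL,
                               exclude_similar = FALSE) {
  stopifnot(inherits(calls, "sensitivity_calls"))
  if (focal_drug == panel_drug)
    stop("focal drug must differ from panel drug", call. = FALSE)
  panel <- resistant_lines(calls, panel_drug)
  if (!length(panel))
    stop("empty panel: no line resistant to ", panel_drug, call. = FALSE)

  if (exclude_similar) {
    if (is.null(similarity_groups))
      stop("exclude_similar requires 'similarity_groups'", call. = FALSE)
    grp <- similarity_groups[[focal_drug]]
    if (!is.null(grp) && !is.na(grp)) {
      similar <- names(similarity_groups)[similarity_groups == grp]
      exclusions <- union(exclusions, setdiff(similar, focal_drug))
    }
  }
  if (focal_drug %in% exclusions)
    stop("focal drug is excluded from ranking", call. = FALSE)

  candidates <- setdiff(colnames(calls$calls), c(panel_drug, exclusions))
  if (!focal_drug %in% candidates)
    stop("unknown drug id: ", focal_drug, call. = FALSE)

  sub <- calls$calls[panel, candidates, drop = FALSE]
  evaluable <- colSums(!is.na(sub))
  res <- colSums(!is.na(sub) & sub == "resistant")
  score <- ifelse(evaluable > 0, res / evaluable, NA_real_)

  ranked <- candidates[!is.na(score)]
  ord <- order(-score[ranked], -evaluable[ranked], ranked)
  ranked <- ranked[ord]
  if (!focal_drug %in% ranked)
    stop("focal drug has no evaluable panel line", call. = FALSE)

  structure(
    list(panel_drug = panel_drug, panel_size = length(panel),
         focal_drug = focal_drug,
         scores = score[ranked], evaluable = evaluable[ranked],
         rank = match(focal_drug, ranked), n_ranked = length(ranked),
         exclusions = exclusions),
    class = "rank_table"
  )
}

#' @export
print.rank_table <- function(x, ...) {
  cat("rank of ", x$focal_drug, " in ", x$panel_drug, "-resistant panel (",
      x$panel_size, " lines): ", x$rank, " of ", x$n_ranked, "\n", sep = "")
  if (length(x$exclusions))
    cat("  excluded: ", paste(x$exclusions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-lineage relative co-resistance frequencies
#'
#' For one drug pair, computes the co-resistance frequency (co-resistant /
#' evaluable) within each cancer lineage and relative to the pan-cancer
#' frequency over all evaluable lines. Lineages with fewer evaluable lines
#' than \code{min_evaluable} are flagged (\code{reliable = FALSE}); a lineage
#' with no evaluable line, or a zero pan-cancer frequency, yields \code{NA}
#' relative values rather than an error.
#'
#' @inheritParams coresistance_count
#' @param lineage_map named character vector: cell-line id -> lineage label,
#'   covering every evaluable line.
#' @param min_evaluable reliability floor on per-lineage evaluable count.
#' @return An object of class \code{lineage_profile}: list with the pair ids,
#'   \code{pan_cancer} frequency, and a per-lineage data.frame
#'   (\code{lineage}, \code{n_evaluable}, \code{n_co_resistant},
#'   \code{frequency}, \code{relative}, \code{reliable}).
#' @export
lineage_relative_frequencies <- function(calls, lineage_map, drug_a, drug_b,
                                         min_evaluable = 3) {
  pair <- coresistance_count(calls, drug_a, drug_b)
  ev <- pair$evaluable_lines
  unmapped <- setdiff(ev, names(lineage_map))
  if (length(unmapped))
    stop("evaluable line(s) without lineage label: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  pan <- if (length(ev)) length(pair$co_resistant_lines) / length(ev) else NA_real_

  lineages <- sort(unique(lineage_map[ev]))
  rows <- lapply(lineages, function(lg) {
    lines <- ev[lineage_map[ev] == lg]
    n_co <- sum(lines %in% pair$co_resistant_lines)
    f <- if (length(lines)) n_co / length(lines) else NA_real_
    rel <- if (!is.na(f) && !is.na(pan) && pan > 0) f / pan else NA_real_
    data.frame(lineage = lg, n_evaluable = length(lines), n_co_resistant = n_co,
               frequency = f, relative = rel,
               reliable = length(lines) >= min_evaluable,
               stringsAsFactors = FALSE)
  })
  structure(
    list(drug_a = drug_a, drug_b = drug_b, pan_cancer = pan,
         per_lineage = do.call(rbind, rows)),
    class = "lineage_profile"
  )
}

#' Build a co-resistance network
#'
#' Nodes are drugs (weight = resistant-line count, plus an optional class
#' label); edges are pairs with their normalized frequency and degree bin.
#'
#' @param pairs list of \code{coresistance_pair} objects with normalized
#'   frequencies set (see \code{\link{normalize_frequencies}}).
#' @inheritParams coresistance_count
#' @param drug_classes optional named character vector: drug id -> class.
#' @return An object of class \code{coresistance_network}: list with
#'   \code{nodes} and \code{edges} data.frames.
#' @export
build_network <- function(pairs, calls, drug_classes = NULL) {
  freq <- vapply(pairs, `[[`, numeric(1), "normalized_frequency")
  if (anyNA(freq))
    stop("normalize_frequencies() must be applied before build_network()",
         call. = FALSE)
  drug_ids <- sort(unique(unlist(lapply(pairs, function(p) c(p$drug_a, p$drug_b)))))
  nodes <- data.frame(
    drug = drug_ids,
    class = if (is.null(drug_classes)) NA_character_
            else unname(drug_classes[drug_ids]),
    n_resistant = vapply(drug_ids, function(d) length(resistant_lines(calls, d)),
                         numeric(1)),
    stringsAsFactors = FALSE
  )
  edges <- coresistance_table(pairs)
  structure(list(nodes = nodes, edges = edges), class = "coresistance_network")
}

#' @export
print.coresistance_network <- function(x, ...) {
  cat("coresistance_network: ", nrow(x$nodes), " drugs, ",
      nrow(x$edges), " edges\n", sep = "")
  print(table(x$edges$degree_bin))
  invisible(x)
}

#' Export a network as GraphML and edge-list TSV
#'
#' @param network a \code{coresistance_network}.
#' @param graphml,edgelist output paths; either may be \code{NULL} to skip.
#' @return Invisibly, the igraph object.
#' @export
write_network <- function(network, graphml = NULL, edgelist = NULL) {
  stopifnot(inherits(network, "coresistance_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("drug_a", "drug_b", "count", "normalized_frequency",
                      "degree_bin")],
    directed = FALSE, vertices = network$nodes
  )
  if (!is.null(graphml))
    igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edgelist)) {
    el <- network$edges[, c("drug_a", "drug_b", "normalized_frequency")]
    utils::write.table(el, edgelist, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(g)
}

#' Aggregate a drug's normalized co-resistance over a partner family
#'
#' Used to rank one drug family (e.g. RTK inhibitors) by co-resistance with
#' another (e.g. antimitotics). Both the mean and the sum of normalized
#' frequencies over each drug's partners are reported, since either aggregate
#' is defensible.
#'
#' @param pairs normalized \code{coresistance_pair} list where
#'   \code{drug_a} belongs to the family being ranked.
#' @return data.frame with one row per ranked drug, sorted by descending mean
#'   normalized frequency: columns \code{drug}, \code{n_partners},
#'   \code{mean_frequency}, \code{sum_frequency}.
#' @export
aggregate_family_ranking <- function(pairs) {
  tab <- coresistance_table(pairs)
  if (anyNA(tab$normalized_frequency))
    stop("normalize_frequencies() must be applied first", call. = FALSE)
  sp <- split(tab$normalized_frequency, tab$drug_a)
  out <- data.frame(
    drug = names(sp),
    n_partners = vapply(sp, length, numeric(1)),
    mean_frequency = vapply(sp, mean, numeric(1)),
    sum_frequency = vapply(sp, sum, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean_frequency, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
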