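#' Read a response matrix from CSV
#'
#' Expects a header row, cell lines as rows (first column \code{cell_line}),
#' drugs as columns. Empty cells and \code{"NA"} map to missing.
#'
#' @param path CSV file path.
#' @inheritParams response_matrix
#' @return A \code{\link{response_matrix}}.
#' @export
read_response <- function(path, polarity = "high_is_sensitive",
                          scale_label = "") {
  m <- read_numeric_matrix(path)
  response_matrix(m, polarity = polarity, scale_label = scale_label)
}

#' Read a numeric matrix from CSV
#'
#' Generic reader for expression and binary alteration matrices: header row,
#' first column holds unique row ids, remaining columns numeric. \code{""} and
#' \code{"NA"} are missing values; any other non-numeric cell is a schema
#' error naming the column.
#'
#' @param path CSV file path.
#' @return numeric matrix with row and column names.
#' @export
read_numeric_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (ncol(df) < 2)
    stop("schema error in ", path, ": need an id column plus data columns",
         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("schema error in ", path, ": duplicated id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  dat <- df[, -1, drop = FALSE]
  for (cn in colnames(dat)) {
    col <- dat[[cn]]
    if (!is.numeric(col)) {
      bad <- suppressWarnings(is.na(as.numeric(col)) & !is.na(col))
      if (any(bad))
        stop("schema error in ", path, ": non-numeric cell in column '", cn,
             "', row ", which(bad)[1], call. = FALSE)
      dat[[cn]] <- as.numeric(col)
    }
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  m
}

#' Write a numeric matrix as CSV
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_column name of the leading id column.
#' @export
write_numeric_matrix <- function(m, path, id_column = "cell_line") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Read/write sensitivity calls
#'
#' Calls are stored as a CSV of \code{sensitive}/\code{resistant}/empty cells.
#'
#' @param path CSV file path.
#' @return A \code{\link{sensitivity_calls}} (without threshold records).
#' @export
read_calls <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("schema error in ", path, ": duplicated cell-line id", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "character"
  rownames(m) <- ids
  sensitivity_calls(m)
}

#' @rdname read_calls
#' @param calls a \code{\link{sensitivity_calls}} object.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "sensitivity_calls"))
  df <- data.frame(cell_line = rownames(calls$calls), calls$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Read a long-format mutation table
#'
#' Tab-separated with header \code{cell_line}, \code{gene},
#' \code{mutation_type}; types restricted to missense, nonsense,
#' essential_splicing, frameshift.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "gene", "mutation_type")
  if (!all(need %in% colnames(df)))
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$mutation_type), mutation_types())
  if (length(bad))
    stop("schema error in ", path, ": unknown mutation type '", bad[1], "'",
         call. = FALSE)
  df[, need]
}

#' Read a gene set from a one-gene-per-line text file
#'
#' Blank lines and lines starting with \code{#} are skipped.
#'
#' @param path text file path.
#' @param label set label; defaults to the file name without extension.
#' @return A \code{\link{gene_set}}.
#' @export
read_gene_set <- function(path, label = NULL) {
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, label = label, source = path)
}

#' Write a synthetic bundle to a directory
#'
#' Emits response.csv, calls-ready matrices (expression.csv, racs_amp.csv,
#' racs_del.csv, icpg.csv), mutations.tsv, lineages.csv,
#' drug_annotations.csv, rtk_genes.txt and a manifest.json recording file
#' names, shapes and the seed. Identical bundles write byte-identical files.
#'
#' @param bundle a \code{\link{simulate_bundle}} result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "coresist_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    response = file.path(dir, "response.csv"),
    expression = file.path(dir, "expression.csv"),
    racs_amp = file.path(dir, "racs_amp.csv"),
    racs_del = file.path(dir, "racs_del.csv"),
    icpg = file.path(dir, "icpg.csv"),
    mutations = file.path(dir, "mutations.tsv"),
    lineages = file.path(dir, "lineages.csv"),
    drug_annotations = file.path(dir, "drug_annotations.csv"),
    rtk_genes = file.path(dir, "rtk_genes.txt")
  )
  write_numeric_matrix(bundle$response$values, paths$response)
  write_numeric_matrix(bundle$expression, paths$expression)
  write_numeric_matrix(bundle$racs_amp, paths$racs_amp)
  write_numeric_matrix(bundle$racs_del, paths$racs_del)
  write_numeric_matrix(bundle$icpg, paths$icpg)
  utils::write.table(bundle$mutations, paths$mutations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(
    data.frame(cell_line = names(bundle$lineages),
               lineage = unname(bundle$lineages), stringsAsFactors = FALSE),
    paths$lineages, row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$drug_annotations, paths$drug_annotations,
                   row.names = FALSE, quote = FALSE)
  writeLines(bundle$config$rtk_genes, paths$rtk_genes)

  manifest <- list(
    seed = bundle$config$seed,
    polarity = bundle$response$polarity,
    files = lapply(paths, basename),
    shapes = list(
      response = dim(bundle$response$values),
      expression = dim(bundle$expression),
      mutations = nrow(bundle$mutations)
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a bundle directory written by \code{\link{write_bundle}}
#'
#' @param dir bundle directory.
#' @return list with the same components as a \code{coresist_bundle} except
#'   \code{config} and \code{truth} (ground truth is not serialized).
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lin <- utils::read.csv(file.path(dir, "lineages.csv"),
                         stringsAsFactors = FALSE)
  list(
    response = read_response(file.path(dir, "response.csv"),
                             polarity = manifest$polarity,
                             scale_label = "log IC50 (uM)"),
    expression = read_numeric_matrix(file.path(dir, "expression.csv")),
    racs_amp = read_numeric_matrix(file.path(dir, "racs_amp.csv")),
    racs_del = read_numeric_matrix(file.path(dir, "racs_del.csv")),
    icpg = read_numeric_matrix(file.path(dir, "icpg.csv")),
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    lineages = stats::setNames(lin$lineage, lin$cell_line),
    drug_annotations = utils::read.csv(file.path(dir, "drug_annotations.csv"),
                                       stringsAsFactors = FALSE),
    rtk_genes = readLines(file.path(dir, "rtk_genes.txt")),
    manifest = manifest
  )
}

#' Run the co-resistance pipeline end to end
#'
#' Stages, in order: binarize the response matrix (waterfall), enumerate and
#' normalize co-resistance pairs between two drug families, rank the focal
#' drug in each panel-drug's resistant panel, build alteration association
#' matrices and the RTK expression ranking, and match case-specific top
#' upregulated genes against the provided gene sets. Each stage's table is
#' written under \code{out_dir} with a header comment naming the tool version
#' and config hash; a run manifest (JSON) records input checksums, per-stage
#' row counts and timestamps. Inputs are validated before any compute.
#'
#' @param config named list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{response}{path to the response CSV (required).}
#'     \item{polarity, scale_label, linearity_cutoff}{binarization settings;
#'       defaults \code{"high_is_sensitive"}, \code{""}, \code{0.95}.}
#'     \item{drug_annotations}{path to a drug annotation CSV (columns
#'       \code{drug}, \code{class}, \code{similarity_group}).}
#'     \item{class_a, class_b}{class labels whose cross pairs are analyzed
#'       (required with \code{drug_annotations}); without annotations,
#'       \code{drugs_a}/\code{drugs_b} give drug id vectors directly.}
#'     \item{focal_drug}{drug ranked within each class-a panel (optional).}
#'     \item{mutations, racs_amp, racs_del, icpg}{feature file paths
#'       (optional; enable the association stage).}
#'     \item{expression, rtk_genes}{expression CSV and RTK list (optional;
#'       enable the RTK ranking and gene-matching stages).}
#'     \item{gene_sets}{character vector of gene-set file paths.}
#'     \item{k}{top-gene list size, default 1000.}
#'     \item{min_evaluable}{lineage floor, default 3.}
#'     \item{top_cases}{number of highest-count pairs used as co-resistance
#'       cases in the association/gene-set stages, default 11.}
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{recorded in the manifest.}
#'   }
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  req <- function(name) {
    if (is.null(config[[name]]))
      stop("pipeline config misses required entry '", name, "'", call. = FALSE)
    config[[name]]
  }
  out_dir <- req("out_dir")
  response_path <- req("response")

  # fail fast: every referenced input must exist before any compute
  input_paths <- unlist(config[intersect(
    c("response", "drug_annotations", "mutations", "racs_amp", "racs_del",
      "icpg", "expression", "rtk_genes", "gene_sets", "lineages"),
    names(config))])
  missing_in <- input_paths[!file.exists(input_paths)]
  if (length(missing_in))
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  say <- function(...) if (!quiet) message("[coresist] ", ...)
  cfg_hash <- substr(tools::md5sum(response_path)[[1]], 1, 8)
  stamp <- paste0("# coresist ", as.character(utils::packageVersion("coresist")),
                  " config ", cfg_hash)
  write_stage <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  counts <- list()
  t0 <- Sys.time()

  # stage 1: binarize
  say("binarize: ", response_path)
  resp <- read_response(response_path,
                        polarity = config$polarity %||% "high_is_sensitive",
                        scale_label = config$scale_label %||% "")
  calls <- binarize_response(resp,
                             linearity_cutoff = config$linearity_cutoff %||% 0.95)
  write_calls(calls, file.path(out_dir, "calls.csv"))
  thr <- data.frame(
    drug = names(calls$thresholds),
    threshold = vapply(calls$thresholds, `[[`, numeric(1), "threshold"),
    rule = vapply(calls$thresholds, `[[`, character(1), "rule"),
    linearity_r = vapply(calls$thresholds, `[[`, numeric(1), "linearity_r"),
    n_used = vapply(calls$thresholds, `[[`, numeric(1), "n_used"),
    stringsAsFactors = FALSE)
  write_stage(thr, "thresholds.tsv")
  counts$thresholds <- nrow(thr)

  # stage 2: co-resistance
  ann <- NULL
  if (!is.null(config$drug_annotations)) {
    ann <- utils::read.csv(config$drug_annotations, stringsAsFactors = FALSE)
    drugs_a <- ann$drug[ann$class == req("class_a")]
    drugs_b <- ann$drug[ann$class == req("class_b")]
  } else {
    drugs_a <- req("drugs_a")
    drugs_b <- req("drugs_b")
  }
  drugs_a <- intersect(drugs_a, colnames(calls$calls))
  drugs_b <- intersect(drugs_b, colnames(calls$calls))
  say("coresistance: ", length(drugs_a), " x ", length(drugs_b), " drug pairs")
  pairs <- coresistance_pairs(calls, drugs_a, drugs_b)
  pairs <- normalize_frequencies(pairs)
  pair_tab <- coresistance_table(pairs)
  write_stage(pair_tab, "pairs.tsv")
  counts$pairs <- nrow(pair_tab)

  classes <- if (!is.null(ann)) stats::setNames(ann$class, ann$drug) else NULL
  net <- build_network(pairs, calls, drug_classes = classes)
  write_network(net, graphml = file.path(out_dir, "network.graphml"),
                edgelist = file.path(out_dir, "network_edges.tsv"))

  ranks <- NULL
  if (!is.null(config$focal_drug)) {
    groups <- if (!is.null(ann) && "similarity_group" %in% colnames(ann))
      stats::setNames(ann$similarity_group, ann$drug) else NULL
    rows <- list()
    for (pd in setdiff(drugs_a, config$focal_drug)) {
      rt <- tryCatch(
        rank_drug_in_panel(calls, pd, config$focal_drug,
                           similarity_groups = groups),
        error = function(e) NULL)
      if (!is.null(rt))
        rows[[pd]] <- data.frame(panel_drug = pd, focal = rt$focal_drug,
                                 rank = rt$rank, n_ranked = rt$n_ranked,
                                 panel_size = rt$panel_size,
                                 score = rt$scores[[rt$focal_drug]],
                                 stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      ranks <- do.call(rbind, rows)
      write_stage(ranks, "focal_ranks.tsv")
      counts$focal_ranks <- nrow(ranks)
    }
  }

  # co-resistance cases for the downstream stages: highest-count pairs
  n_cases <- min(config$top_cases %||% 11, length(pairs))
  cases <- pairs[order(-vapply(pairs, `[[`, numeric(1), "count"))][seq_len(n_cases)]

  # stage 3: genomic association
  assoc <- NULL
  feature_cfg <- c(RACS_amp = "racs_amp", RACS_del = "racs_del",
                   iCpG_hypermethylation = "icpg")
  have_feats <- feature_cfg[vapply(feature_cfg, function(f)
    !is.null(config[[f]]), logical(1))]
  if (length(have_feats)) {
    say("genomic association over ", length(cases), " cases")
    assoc <- list()
    for (kind in names(have_feats)) {
      feats <- read_numeric_matrix(config[[have_feats[[kind]]]])
      profs <- lapply(cases, function(cs)
        tryCatch(case_alteration_frequency(feats, cs, feature_kind = kind),
                 error = function(e) NULL))
      profs <- Filter(Negate(is.null), profs)
      if (length(profs) >= 2) {
        am <- association_matrix(profs)
        assoc[[kind]] <- am
        write_stage(as.data.frame(as.table(unclass(am)),
                                  stringsAsFactors = FALSE),
                    paste0("association_", tolower(kind), ".tsv"))
      }
    }
    counts$association_matrices <- length(assoc)
  }

  rtk_rank <- NULL
  expr <- NULL
  if (!is.null(config$expression)) {
    expr <- read_numeric_matrix(config$expression)
    if (!is.null(config$rtk_genes)) {
      rtks <- readLines(config$rtk_genes)
      say("RTK expression ranking")
      strata <- stratify_by_expression(expr, gene = config$stratifier %||% "EGFR",
                                       cutoff = config$stratifier_cutoff %||% 4)
      rtk_rank <- rank_rtks(expr, cases, strata, rtks)
      write_stage(rtk_rank$table, "rtk_expression.tsv")
      write_stage(rtk_rank$ranking, "rtk_ranking.tsv")
      counts$rtk_ranking <- nrow(rtk_rank$ranking)
    }
  }

  # stage 4: gene-set matching
  matches <- NULL
  if (!is.null(expr) && !is.null(config$gene_sets)) {
    say("gene-set matching, k = ", config$k %||% 1000)
    sets <- lapply(config$gene_sets, read_gene_set)
    tops <- lapply(cases, function(cs)
      tryCatch(top_upregulated(expr, cs, k = config$k %||% 1000),
               error = function(e) NULL))
    tops <- Filter(Negate(is.null), tops)
    if (length(tops)) {
      matches <- match_table(tops, sets)
      write_stage(matches, "geneset_matches.tsv")
      counts$geneset_matches <- nrow(matches)
    }
  }

  manifest <- list(
    tool = "coresist",
    version = as.character(utils::packageVersion("coresist")),
    seed = config$seed %||% NA,
    config = config[setdiff(names(config), "out_dir")],
    input_checksums = as.list(tools::md5sum(input_paths)),
    stage_counts = counts,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", out_dir)
  invisible(list(calls = calls, pairs = pairs, ranks = ranks, assoc = assoc,
                 rtk_ranking = rtk_rank, matches = matches,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
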