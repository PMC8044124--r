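# calls fixture used across several blocks: 5 lines x 2 drugs from the spec of
# a printed toy table: (R,R),(R,S),(S,R),(R,.),(R,R)
toy5 <- toy_calls(
  c(L1 = "RR", L2 = "RS", L3 = "SR", L4 = "R.", L5 = "RR"),
  c("dA", "dB")
)

test_that("co-resistance counts and evaluable sets follow the toy enumeration", {
  p <- coresistance_count(toy5, "dA", "dB")
  expect_equal(p$count, 2)
  expect_setequal(p$evaluable_lines, c("L1", "L2", "L3", "L5"))
  expect_setequal(p$co_resistant_lines, c("L1", "L5"))

  # a drug paired with itself counts its resistant lines
  self <- coresistance_count(toy5, "dA", "dA")
  expect_equal(self$count, 4)

  # disjoint resistant sets -> 0
  disj <- toy_calls(c(L1 = "RS", L2 = "SR", L3 = "SS"), c("d1", "d2"))
  expect_equal(coresistance_count(disj, "d1", "d2")$count, 0)

  expect_error(coresistance_count(toy5, "dA", "nope"), "unknown drug")
})

test_that("co-resistance is symmetric and matches brute force on random matrices", {
  for (s in 1:25) {
    calls <- random_calls(15, 6, seed = s)
    ds <- colnames(calls$calls)
    for (k in 1:5) {
      ab <- sample(ds, 2)
      p1 <- coresistance_count(calls, ab[1], ab[2])
      p2 <- coresistance_count(calls, ab[2], ab[1])
      expect_equal(p1$count, p2$count)
      expect_setequal(p1$co_resistant_lines, p2$co_resistant_lines)
      orc <- oracle_coresistance(calls$calls, ab[1], ab[2])
      expect_equal(p1$count, orc$count)
      expect_setequal(p1$evaluable_lines, orc$evaluable)
    }
  }
})

test_that("min-max normalization hits the endpoints and preserves order", {
  mk <- function(counts) lapply(seq_along(counts), function(i) {
    p <- coresistance_count(toy5, "dA", "dB")
    p$count <- counts[i]
    p
  })
  out <- normalize_frequencies(mk(c(0, 5, 10)))
  expect_equal(vapply(out, `[[`, numeric(1), "normalized_frequency"),
               c(0, 0.5, 1))

  # maximal pair is 1 regardless of absolute count
  out <- normalize_frequencies(mk(c(3, 17)))
  expect_equal(out[[2]]$normalized_frequency, 1)

  expect_error(normalize_frequencies(mk(c(3, 3, 3))), "degenerate")

  set.seed(9)
  counts <- sample(0:50, 12)
  norm <- vapply(normalize_frequencies(mk(counts)), `[[`, numeric(1),
                 "normalized_frequency")
  expect_identical(rank(counts), rank(norm))
  expect_equal(norm, oracle_minmax(counts))
})

test_that("degree bins follow the <10% / <60% / >=60% convention", {
  expect_identical(bin_degree(0.60), "high")
  expect_identical(bin_degree(0.0999), "low")
  expect_identical(bin_degree(0.10), "mid")
  expect_identical(bin_degree(c(0, 0.599999, 1)), c("low", "mid", "high"))
  expect_error(bin_degree(1.2), "outside")
  expect_error(bin_degree(-0.1), "outside")
})

test_that("panel ranking matches the brute-force sort oracle", {
  # 5-drug toy with hand-listed calls
  toy <- toy_calls(
    c(L1 = "RRRSS", L2 = "RRS.R", L3 = "RSRSR", L4 = "SRRRR",
      L5 = "R.SRS", L6 = "RRRRR"),
    c("p", "d1", "d2", "d3", "d4")
  )
  for (focal in c("d1", "d2", "d3", "d4")) {
    rt <- rank_drug_in_panel(toy, "p", focal)
    orc <- oracle_rank(toy$calls, "p", focal)
    expect_equal(rt$rank, orc$rank)
    expect_identical(names(rt$scores), orc$order)
  }

  # random matrices against the oracle
  for (s in 1:20) {
    calls <- random_calls(20, 8, seed = 100 + s)
    rt <- tryCatch(rank_drug_in_panel(calls, "d01", "d05"),
                   error = function(e) NULL)
    if (is.null(rt)) next
    orc <- oracle_rank(calls$calls, "d01", "d05")
    expect_equal(rt$rank, orc$rank)
  }
})

test_that("removing non-focal drugs never worsens the focal rank", {
  calls <- random_calls(25, 9, seed = 77, p_missing = 0.1)
  base <- rank_drug_in_panel(calls, "d01", "d02")
  others <- setdiff(colnames(calls$calls), c("d01", "d02"))
  for (k in 1:6) {
    drop <- sample(others, sample(1:4, 1))
    rt <- rank_drug_in_panel(calls, "d01", "d02", exclusions = drop)
    expect_lte(rt$rank, base$rank)
  }
})

test_that("panel ranking edge cases behave as specified", {
  # focal resistant in every panel line, all others in none -> rank 1
  toy <- toy_calls(c(L1 = "RRS", L2 = "RRS", L3 = "SSR"), c("p", "f", "o"))
  rt <- rank_drug_in_panel(toy, "p", "f")
  expect_equal(rt$rank, 1)

  # empty panel errors
  none <- toy_calls(c(L1 = "SS", L2 = "SS"), c("p", "f"))
  expect_error(rank_drug_in_panel(none, "p", "f"), "empty panel")

  # excluding the focal drug errors
  expect_error(rank_drug_in_panel(toy, "p", "f", exclusions = "f"), "excluded")

  # similarity-group exclusion removes chemical neighbours of the focal drug
  toy2 <- toy_calls(
    c(L1 = "RRRS", L2 = "RRRS", L3 = "RSRS"),
    c("p", "f", "sib", "o")
  )
  groups <- c(f = "egfr_tki", sib = "egfr_tki", o = "other")
  rt <- rank_drug_in_panel(toy2, "p", "f", similarity_groups = groups,
                           exclude_similar = TRUE)
  expect_true("sib" %in% rt$exclusions)
  expect_false("sib" %in% names(rt$scores))
})

test_that("lineage frequencies are relative to the pan-cancer rate", {
  calls <- toy_calls(
    c(A1 = "RR", A2 = "RR", A3 = "SS", A4 = "RS",
      B1 = "RR", B2 = "SS", B3 = "SS", B4 = "SR"),
    c("dA", "dB")
  )
  lineage <- setNames(rep(c("lung", "breast"), each = 4),
                      rownames(calls$calls))
  lp <- lineage_relative_frequencies(calls, lineage, "dA", "dB")
  # pan-cancer: 3 of 8; lung 2 of 4, breast 1 of 4 (direct counting)
  expect_equal(lp$pan_cancer, 3 / 8)
  lung <- lp$per_lineage[lp$per_lineage$lineage == "lung", ]
  expect_equal(lung$relative, (2 / 4) / (3 / 8))

  # single-lineage dataset -> relative 1
  one <- lineage_relative_frequencies(calls, setNames(rep("lung", 8),
                                                      rownames(calls$calls)),
                                      "dA", "dB")
  expect_equal(one$per_lineage$relative, 1)

  # unmapped evaluable line errors; tiny lineages flagged unreliable
  expect_error(lineage_relative_frequencies(calls, lineage[-1], "dA", "dB"),
               "without lineage")
  tiny <- setNames(c("x", rep("y", 7)), rownames(calls$calls))
  lp2 <- lineage_relative_frequencies(calls, tiny, "dA", "dB")
  expect_false(lp2$per_lineage$reliable[lp2$per_lineage$lineage == "x"])
})

test_that("network nodes and edges carry the stated attributes and round-trip", {
  calls <- random_calls(20, 5, seed = 5)
  pairs <- normalize_frequencies(
    coresistance_pairs(calls, colnames(calls$calls)))
  net <- build_network(pairs, calls,
                       drug_classes = setNames(rep("other", 5),
                                               colnames(calls$calls)))
  expect_equal(nrow(net$edges), length(pairs))
  for (i in seq_len(nrow(net$nodes)))
    expect_equal(net$nodes$n_resistant[i],
                 sum(calls$calls[, net$nodes$drug[i]] == "resistant",
                     na.rm = TRUE))

  tmp <- withr::local_tempdir()
  gml <- file.path(tmp, "net.graphml")
  el <- file.path(tmp, "net.tsv")
  write_network(net, graphml = gml, edgelist = el)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes$drug))
  expect_equal(sort(igraph::E(g)$normalized_frequency),
               sort(net$edges$normalized_frequency))
  back <- read.delim(el)
  expect_equal(nrow(back), nrow(net$edges))
})

test_that("family ranking aggregates normalized frequencies by mean and sum", {
  calls <- random_calls(30, 6, seed = 21)
  rtki <- c("d01", "d02")
  amd <- c("d03", "d04", "d05")
  pairs <- normalize_frequencies(coresistance_pairs(calls, rtki, amd))
  agg <- aggregate_family_ranking(pairs)
  expect_setequal(agg$drug, rtki)
  tab <- coresistance_table(pairs)
  for (d in rtki) {
    expect_equal(agg$mean_frequency[agg$drug == d],
                 mean(tab$normalized_frequency[tab$drug_a == d]))
    expect_equal(agg$sum_frequency[agg$drug == d],
                 sum(tab$normalized_frequency[tab$drug_a == d]))
  }
})
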