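no_pairs <- data.frame(drug_a = character(), drug_b = character(),
                       kappa = numeric(), stringsAsFactors = FALSE)

small_cfg <- function(...) {
  sim_config(n_cell_lines = 100, n_drugs = 20, n_genes = 80,
             n_alteration_features = 15, missing_rate = 0.05,
             upregulated_set_size = 5, seed = 7, ...)
}

test_that("response matrix has the configured shape and missingness", {
  cfg <- small_cfg()
  out <- generate_response_matrix(cfg)
  expect_equal(dim(out$response$values), c(100, 20))
  expect_equal(sum(is.na(out$response$values)), 20 * round(0.05 * 100))
  expect_equal(dim(out$truth$latent_state), c(100, 20))
  expect_false(anyNA(out$truth$latent_state))
  # conservation: non-missing entries = total - inserted missing
  expect_equal(sum(!is.na(out$response$values)), 2000 - 20 * round(0.05 * 100))
  # polarity: resistant latent state sits at the higher log IC50
  v <- out$response$values
  lat <- out$truth$latent_state
  expect_gt(mean(v[lat], na.rm = TRUE), mean(v[!lat], na.rm = TRUE))
  # true threshold separates the state-conditional means
  expect_true(all(out$truth$true_threshold > cfg$response_means[["sensitive"]] &
                  out$truth$true_threshold < cfg$response_means[["resistant"]]))
})

test_that("planted coupling kappa = 1 copies the latent column; kappa = 0 is independent", {
  cfg1 <- small_cfg(planted_pairs = data.frame(drug_a = "D001", drug_b = "D002",
                                               kappa = 1))
  t1 <- generate_response_matrix(cfg1)$truth
  expect_identical(t1$latent_state[, "D001"], t1$latent_state[, "D002"])

  cfg0 <- sim_config(n_cell_lines = 2000, n_drugs = 4, n_genes = 30,
                     resistant_fraction = 0.3, seed = 11,
                     planted_pairs = data.frame(drug_a = "D001",
                                                drug_b = "D002", kappa = 0))
  t0 <- generate_response_matrix(cfg0)$truth
  # brute-force count over the truth matrix; independence -> 0.3^2 = 0.09
  joint <- 0
  for (i in seq_len(2000))
    if (t0$latent_state[i, "D001"] && t0$latent_state[i, "D002"])
      joint <- joint + 1
  expect_lt(abs(joint / 2000 - 0.09), 0.03)

  expect_error(small_cfg(planted_pairs = data.frame(drug_a = "D001",
                                                    drug_b = "D999",
                                                    kappa = 0.5)),
               "unknown drug")
})

test_that("planted co-resistance count is monotone in kappa", {
  mean_count <- function(kappa) {
    counts <- vapply(1:20, function(s) {
      cfg <- sim_config(n_cell_lines = 150, n_drugs = 6, n_genes = 30,
                        seed = s, missing_rate = 0,
                        planted_pairs = data.frame(drug_a = "D001",
                                                   drug_b = "D002",
                                                   kappa = kappa))
      tr <- generate_response_matrix(cfg)$truth
      sum(tr$latent_state[, "D001"] & tr$latent_state[, "D002"])
    }, numeric(1))
    mean(counts)
  }
  m <- vapply(c(0, 0.5, 1), mean_count, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("alteration enrichment is additive on the base rate", {
  # base 0.1, delta 0.4 -> altered fraction ~0.5 in co-resistant lines
  cfg <- sim_config(n_cell_lines = 800, n_drugs = 6, n_genes = 40,
                    n_alteration_features = 40,
                    alteration_base_rate = 0.1, alteration_effect = 0.4,
                    planted_pairs = data.frame(drug_a = "D001", drug_b = "D002",
                                               kappa = 0.9),
                    seed = 3)
  out <- generate_response_matrix(cfg)
  feats <- generate_genomic_features(cfg, out$truth)
  co <- rownames(feats$racs_amp) %in% out$truth$any_co_resistant
  expect_gt(sum(co), 100)
  expect_lt(abs(mean(feats$racs_amp[co, ]) - 0.5), 0.03)
  expect_lt(abs(mean(feats$racs_amp[!co, ]) - 0.1), 0.03)

  # delta = 0: no difference between the groups
  cfg0 <- sim_config(n_cell_lines = 800, n_drugs = 6, n_genes = 40,
                     n_alteration_features = 40,
                     alteration_base_rate = 0.1, alteration_effect = 0,
                     planted_pairs = data.frame(drug_a = "D001", drug_b = "D002",
                                                kappa = 0.9),
                     seed = 3)
  out0 <- generate_response_matrix(cfg0)
  f0 <- generate_genomic_features(cfg0, out0$truth)
  co0 <- rownames(f0$racs_amp) %in% out0$truth$any_co_resistant
  expect_lt(abs(mean(f0$racs_amp[co0, ]) - mean(f0$racs_amp[!co0, ])), 0.03)

  expect_error(sim_config(alteration_base_rate = 0.8, alteration_effect = 0.4),
               "exceeds 1")
})

test_that("mutation types follow the configured proportions", {
  props <- c(missense = 0.5, nonsense = 0.2, essential_splicing = 0.1,
             frameshift = 0.2)
  cfg <- sim_config(n_cell_lines = 400, n_drugs = 4, n_genes = 300,
                    mutation_rate = 0.05, mutation_type_proportions = props,
                    planted_pairs = no_pairs, seed = 19)
  out <- generate_response_matrix(cfg)
  mut <- generate_genomic_features(cfg, out$truth)$mutations
  expect_gt(nrow(mut), 2000)
  emp <- table(mut$mutation_type) / nrow(mut)
  for (tp in names(props))
    expect_lt(abs(unname(emp[tp]) - unname(props[tp])), 0.02)
})

test_that("expression coupling between AXL and EGFR is planted at rho", {
  cfg <- sim_config(n_cell_lines = 500, n_drugs = 4, n_genes = 40,
                    expression_coupling = 0.8, rtk_case_shift = NULL,
                    planted_pairs = no_pairs, seed = 23)
  out <- generate_response_matrix(cfg)
  ex <- generate_expression(cfg, out$truth)$expression
  r <- cor(ex[, "AXL"], ex[, "EGFR"])
  expect_gte(r, 0.7)
  expect_lte(r, 0.9)

  cfg0 <- sim_config(n_cell_lines = 500, n_drugs = 4, n_genes = 40,
                     expression_coupling = 0, rtk_case_shift = NULL,
                     planted_pairs = no_pairs, seed = 23)
  ex0 <- generate_expression(cfg0, generate_response_matrix(cfg0)$truth)$expression
  expect_lt(abs(cor(ex0[, "AXL"], ex0[, "EGFR"])), 0.15)

  expect_error(sim_config(expression_coupling = 1.2), "exceed 1")
})

test_that("planted upregulated genes are elevated in their case", {
  hits <- 0
  n_rep <- 40  # scaled from the 100-seed statement; direction check per seed
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(n_cell_lines = 120, n_drugs = 6, n_genes = 60,
                      upregulated_set_size = 5, upregulated_shift_sd = 2,
                      planted_pairs = data.frame(drug_a = "D001",
                                                 drug_b = "D002", kappa = 0.9),
                      seed = 1000 + s)
    out <- generate_response_matrix(cfg)
    ex <- generate_expression(cfg, out$truth)
    g <- ex$planted_upregulated_genes[["D001:D002"]][1]
    co <- rownames(ex$expression) %in% out$truth$co_resistant_lines[["D001:D002"]]
    if (mean(ex$expression[co, g]) > mean(ex$expression[!co, g])) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("identical configs give identical bundles; substreams are stable under panel growth", {
  cfg <- small_cfg()
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$response$values, b2$response$values)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$mutations, b2$mutations)

  # adding drugs leaves existing response columns untouched
  cfg_big <- sim_config(n_cell_lines = 100, n_drugs = 25, n_genes = 80,
                        n_alteration_features = 15, missing_rate = 0,
                        upregulated_set_size = 5, seed = 7)
  cfg_small <- sim_config(n_cell_lines = 100, n_drugs = 20, n_genes = 80,
                          n_alteration_features = 15, missing_rate = 0,
                          upregulated_set_size = 5, seed = 7)
  r_small <- generate_response_matrix(cfg_small)$response$values
  r_big <- generate_response_matrix(cfg_big)$response$values
  expect_identical(r_big[, colnames(r_small)], r_small)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(resistant_fraction = 1.2), "\\(0, 1\\)")
  expect_error(sim_config(response_means = c(sensitive = 0, resistant = -1)),
               "must exceed")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(response_sd = 0), "positive")
  expect_error(sim_config(rtk_genes = c("AXL", "KIT")), "EGFR")
  expect_error(sim_config(mutation_type_proportions = c(m = 0.5, n = 0.2)),
               "sum to 1")
})
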