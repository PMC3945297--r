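# Synthetic-data generators: determinism, validity, configured rates.

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(nonsyn_retention = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(mf_boost = 0.5), "mf_boost")
  expect_error(sim_config(gc_content = 0), "gc_content")
  expect_error(sim_config(cds_length_range = c(500, 300)), "increasing")
  expect_error(sim_config(cds_length_range = c(4, 5)), "infeasible")
  expect_error(sim_config(focal_tissue = "brain"), "tissue01")
  expect_error(sim_config(germline_af_alpha_beta = c(-1, 1)), "positive")
})

test_that("generated gene models are valid and deterministic", {
  cfg <- sim_config(n_genes = 15, seed = 3)
  m1 <- generate_gene_models(cfg)
  m2 <- generate_gene_models(cfg)
  expect_identical(lapply(m1, `[[`, "cds"), lapply(m2, `[[`, "cds"))
  for (m in m1) {
    expect_true(startsWith(m$cds, "ATG"))
    expect_equal(nchar(m$cds) %% 3, 0)
    expect_true(validate_cds(m$cds))  # errors on internal stops
    expect_true(nchar(m$cds) >= 6)
  }
  expect_length(generate_gene_models(sim_config(n_genes = 0, seed = 1)), 0)
  # lengths respect the configured range (longest transcript per gene)
  one <- select_longest_transcript(m1)
  lens <- vapply(one, function(m) nchar(m$cds), 0L)
  expect_true(all(lens >= 300 & lens <= 1500))
})

test_that("functionality tables cover every possible missense change", {
  cfg <- sim_config(n_genes = 5, seed = 13)
  models <- generate_gene_models(cfg)
  tabs <- generate_functionality_tables(models, cfg)
  one <- select_longest_transcript(models)
  # completeness: MF + LF site totals equal missense-change count / 3
  sc <- count_sites(one, tabs$sift, tabs$pph)
  for (m in one) {
    want <- oracle_site_counts(
      m$cds, m$gene_id, score_fun = function(g, p, a) "MF")
    row <- sc[sc$gene_id == m$gene_id, ]
    expect_equal(row$MF_sift + row$LF_sift, want$MF, info = m$gene_id)
    expect_equal(row$MF_pph + row$LF_pph, want$MF, info = m$gene_id)
  }
})

test_that("mf_fraction and scheme agreement behave as configured", {
  cfg1 <- sim_config(n_genes = 4, mf_fraction = 1, seed = 19)
  models <- generate_gene_models(cfg1)
  tabs1 <- generate_functionality_tables(models, cfg1)
  expect_true(all(data.table::as.data.table(tabs1$sift)$func_class == "MF"))

  cfg2 <- sim_config(n_genes = 20, mf_fraction = 0.5, seed = 19)
  models2 <- generate_gene_models(cfg2)
  tabs2 <- generate_functionality_tables(models2, cfg2)
  frac <- mean(data.table::as.data.table(tabs2$sift)$func_class == "MF")
  k <- nrow(tabs2$sift)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / k))

  cfg3 <- sim_config(n_genes = 6, scheme_agreement = 1, seed = 19)
  models3 <- generate_gene_models(cfg3)
  tabs3 <- generate_functionality_tables(models3, cfg3)
  expect_identical(data.table::as.data.table(tabs3$sift)$func_class,
                   data.table::as.data.table(tabs3$pph)$func_class)
})

test_that("somatic cohorts are deterministic and honor retention settings", {
  cfg <- sim_config(n_genes = 20, n_patients = 30, seed = 29)
  models <- generate_gene_models(cfg)
  tabs <- generate_functionality_tables(models, cfg)
  c1 <- simulate_somatic_cohort(models, tabs, cfg)
  c2 <- simulate_somatic_cohort(models, tabs, cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  # nonsyn_retention = 0: only synonymous SNVs (plus any frameshift events)
  cfg0 <- sim_config(n_genes = 20, n_patients = 30, seed = 29,
                     nonsyn_retention = 0, frameshift_rate = 0)
  c0 <- simulate_somatic_cohort(models, tabs, cfg0)
  one <- select_longest_transcript(models)
  cl <- classify_substitutions(c0, one, tabs$sift, tabs$pph)
  expect_equal(nrow(cl$rejected), 0L)
  expect_true(all(cl$kept$effect == "synonymous"))

  # retention * boost > 1 is clipped with a warning
  cfg_clip <- sim_config(n_genes = 5, n_patients = 5, seed = 29,
                         nonsyn_retention = 0.9, mf_boost = 2)
  expect_warning(simulate_somatic_cohort(models, tabs, cfg_clip), "clipped")
})

test_that("planted inactivation events appear at the configured rates", {
  cfg <- sim_config(n_genes = 25, n_patients = 40, seed = 31,
                    mutation_rate = 0, nonsense_rate = 0.05,
                    frameshift_rate = 0.05, dup_rate = 0)
  models <- generate_gene_models(cfg)
  som <- simulate_somatic_cohort(models, NULL, cfg)
  expect_true(any(som$variant_class == "frameshift_indel"))
  one <- select_longest_transcript(models)
  cl <- classify_substitutions(som[som$variant_class == "SNV", ], one)
  expect_true(all(cl$kept$effect == "nonsense"))
  n_pairs <- 25 * 40
  expect_lt(abs(sum(som$variant_class == "SNV") / n_pairs - 0.05),
            4 * sqrt(0.05 * 0.95 / n_pairs))
})

test_that("germline panels have Beta-distributed frequencies and distinct sites", {
  cfg <- sim_config(n_genes = 40, seed = 37,
                    germline_af_alpha_beta = c(0.5, 0.5),
                    germline_density = 0.03)
  models <- generate_gene_models(cfg)
  g1 <- simulate_germline_panel(models, cfg)
  g2 <- simulate_germline_panel(models, cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_equal(anyDuplicated(g1[, c("transcript_id", "cds_pos", "alt")]), 0L)
  # tail above 0.1 matches the analytic Beta tail within MC error
  p_tail <- stats::pbeta(0.1, 0.5, 0.5, lower.tail = FALSE)
  obs <- mean(g1$allele_freq > 0.1)
  expect_lt(abs(obs - p_tail), 4 * sqrt(p_tail * (1 - p_tail) / nrow(g1)))
})

test_that("empty germline panels produce a header-only VCF", {
  cfg <- sim_config(n_genes = 5, germline_density = 0, seed = 41)
  models <- generate_gene_models(cfg)
  g <- simulate_germline_panel(models, cfg)
  expect_equal(nrow(g), 0L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_germline_vcf(g, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(lines[1], "##fileformat=VCFv4.2")
})

test_that("within-patient duplicates are injected and removed by dedup", {
  cfg <- sim_config(n_genes = 30, n_patients = 50, seed = 43,
                    dup_rate = 0.2, frameshift_rate = 0)
  models <- generate_gene_models(cfg)
  tabs <- generate_functionality_tables(models, cfg)
  som <- simulate_somatic_cohort(models, tabs, cfg)
  dup_count <- nrow(som) -
    nrow(unique(som[, c("patient_id", "gene_id", "cds_pos", "ref", "alt")]))
  expect_gt(dup_count, 0)
})

test_that("simulated expression matrices respect the globality structure", {
  cfg <- sim_config(n_genes = 150, global_fraction = 0.4, seed = 47)
  models <- generate_gene_models(cfg)
  expr <- simulate_expression_matrix(models, cfg)
  expect_equal(nrow(expr), length(select_longest_transcript(models)))
  prof <- compute_breadth(expr, platform = "rpkm")
  # global genes saturate at 16; the rest stay at most 13 (strict margin)
  expect_true(all(prof$breadth %in% c(0:13, 16L)))
  obs_frac <- mean(prof$is_global)
  expect_lt(abs(obs_frac - 0.4), 4 * sqrt(0.4 * 0.6 / nrow(prof)))
})
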