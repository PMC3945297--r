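# Ratio statistics, chi-square tests, group comparisons, screens,
# enrichments.

counts_of <- function(n = 0, s = 0, mf = 0, lf = 0) {
  data.frame(gene_set_id = "x", n = n, s = s, mf_sift = mf, lf_sift = lf,
             mf_pph = mf, lf_pph = lf)
}

sites_of <- function(N = 1, S = 1, MF = 1, LF = 1) {
  data.frame(gene_set_id = "x", N = N, S = S, MF_sift = MF, LF_sift = LF,
             MF_pph = MF, LF_pph = LF)
}

test_that("ratio_statistic computes the rate ratio", {
  expect_equal(
    suppressWarnings(ratio_statistic(counts_of(2, 1), sites_of(2, 1)))$ratio,
    1.0)
  expect_equal(
    suppressWarnings(ratio_statistic(counts_of(4, 1), sites_of(2, 1)))$ratio,
    2.0)
  # cohort-scale counts with synthetic sites N = 3S
  r <- ratio_statistic(counts_of(10653, 3463), sites_of(N = 3, S = 1))
  expect_equal(r$ratio, (10653 / 3463) / 3, tolerance = 1e-12)
  expect_equal(round(r$ratio, 3), 1.025)
  expect_equal(r$direction, "above_one")
})

test_that("ratio_statistic is scale invariant and flags undefined ratios", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:500, 1); s <- sample(10:500, 1)
    N <- runif(1, 100, 1e4); S <- runif(1, 100, 1e4)
    r1 <- suppressWarnings(ratio_statistic(counts_of(n, s), sites_of(N, S)))
    r2 <- suppressWarnings(
      ratio_statistic(counts_of(3 * n, 3 * s), sites_of(7 * N, 7 * S)))
    expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  }
  und <- suppressWarnings(ratio_statistic(counts_of(5, 0), sites_of(10, 10)))
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
  expect_error(ratio_statistic(counts_of(5, 5), sites_of(0, 10)), "site")
})

test_that("test_ratio_vs_one matches closed-form and chisq.test", {
  # counts proportional to sites: chi2 = 0, p = 1
  t0 <- test_ratio_vs_one(counts_of(30, 10), sites_of(3, 1))
  expect_equal(t0$chi2_stat, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$direction, "at_one")
  # worked binomial example: (200-150)^2/150 + (100-150)^2/150
  t1 <- test_ratio_vs_one(counts_of(200, 100), sites_of(100, 100))
  expect_equal(t1$chi2_stat, 50^2 / 150 + 50^2 / 150, tolerance = 1e-12)
  ref <- stats::chisq.test(c(200, 100), p = c(0.5, 0.5))
  expect_equal(t1$chi2_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(t1$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(t1$direction, "above_one")
})

test_that("test_ratio_vs_one agrees with chisq.test on random inputs", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(5:2000, 1); s <- sample(5:2000, 1)
    N <- runif(1, 50, 1e5); S <- runif(1, 50, 1e5)
    w <- c(N, S) / (N + S)
    if (any((n + s) * w < 5)) next
    got <- test_ratio_vs_one(counts_of(n, s), sites_of(N, S))
    ref <- suppressWarnings(stats::chisq.test(c(n, s), p = w))
    expect_equal(got$chi2_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("test_ratio_vs_one refuses low expected counts", {
  expect_warning(t <- test_ratio_vs_one(counts_of(3, 2), sites_of(1, 1)),
                 "refused")
  expect_true(t$refused)
  expect_true(is.na(t$p_value))
})

test_that("compare_groups reduces to the plain 2x2 chi-square when cf = 1", {
  ca <- counts_of(120, 60); cb <- counts_of(300, 240)
  sa <- sites_of(N = 400, S = 200); sb <- sites_of(N = 1000, S = 500)
  g <- compare_groups(ca, sa, cb, sb)
  expect_equal(g$cf, 1)
  expect_equal(g$corrected_n_a, 120)
  ref <- stats::chisq.test(matrix(c(120, 60, 300, 240), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(g$chi2_stat, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(g$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("compare_groups applies the site-composition correction factor", {
  sa <- sites_of(N = 800, S = 200)   # N/S = 4
  sb <- sites_of(N = 600, S = 300)   # N/S = 2
  g <- compare_groups(counts_of(200, 50), sa, counts_of(100, 50), sb)
  expect_equal(g$cf, 2)
  expect_equal(g$corrected_n_a, 100)
  # counts proportional to sites in both groups: no signal after correction
  g2 <- compare_groups(counts_of(400, 100), sa, counts_of(200, 100), sb)
  expect_equal(g2$p_value, 1, tolerance = 1e-9)
})

test_that("per_gene_screen applies inclusion rules and sorting", {
  sc <- data.table::data.table(
    gene_id = c("GA", "GB", "GC", "GD"),
    N = c(300, 300, 300, 300), S = c(100, 100, 100, 100),
    MF_sift = 0, LF_sift = 0, MF_pph = 0, LF_pph = 0,
    n_codons_counted = 100L)
  recs <- rbind(
    # GA: strong excess of non-synonymous
    make_records("P1", "GA", 1:60, "A", "C",
                 effect = c(rep("missense", 54), rep("synonymous", 6))),
    # GB: proportional to sites
    make_records("P1", "GB", 1:40, "A", "C",
                 effect = c(rep("missense", 30), rep("synonymous", 10))),
    # GC: synonymous only
    make_records("P1", "GC", 1:20, "A", "C", effect = "synonymous"),
    # GD: no synonymous -> excluded
    make_records("P1", "GD", 1:10, "A", "C", effect = "missense"))
  out <- per_gene_screen(recs, sc, alpha = 0.05)
  expect_false("GD" %in% out$gene_id)      # needs >= 1 synonymous
  expect_equal(out$gene_id[1], "GC")       # smallest p first (strong deficit)
  expect_true(all(diff(out$p_value[!out$refused]) >= 0))
  expect_true(out[out$gene_id == "GA", ]$significant_above_one)
  expect_false(out[out$gene_id == "GB", ]$significant_above_one)
  gc_row <- out[out$gene_id == "GC", ]
  expect_equal(gc_row$dn_ds, 0)            # n = 0: ratio 0, never flagged
  expect_false(gc_row$significant_above_one)
  expect_true(all(!is.na(out$q_value[!out$refused])))
})

test_that("list_enrichment reproduces the published worked example", {
  universe <- sprintf("u%05d", 1:18299)
  flagged <- universe[1:104]
  annotation <- c(universe[1:17], universe[10000:10438])  # 456 census genes
  e <- list_enrichment(flagged, annotation, universe)
  expect_equal(e$overlap, 17L)
  expect_equal(e$n_annotated, 456L)
  expect_equal(round(e$overlap_pct, 1), 16.3)
  expect_equal(round(e$annotated_unflagged_pct, 1), 96.3)
  expect_lt(e$p_value, 1e-4)
  expect_gt(e$fold_enrichment, 1)
})

test_that("list_enrichment handles degenerate annotations", {
  universe <- sprintf("u%03d", 1:500)
  flagged <- universe[1:50]
  # annotation = universe: 100% overlap, no association
  e <- list_enrichment(flagged, universe, universe)
  expect_equal(e$overlap_pct, 100)
  expect_equal(e$p_value, 1)
  # overlap exactly at the base rate: fold enrichment 1
  annotation <- c(universe[1:5], universe[51:95])  # 50 of 500 = 10%
  e2 <- list_enrichment(flagged, annotation, universe)
  expect_equal(e2$fold_enrichment, 1)
  expect_error(list_enrichment(character(), universe[1:5], universe),
               "empty")
  expect_error(list_enrichment("zzz", universe[1:5], universe), "subset")
})
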