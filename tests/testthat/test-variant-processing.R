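# Classification, deduplication, filtering and tallies of substitutions.

test_that("select_longest_transcript picks maximal CDS with lexicographic ties", {
  single <- list(gene_model("G1", "T1", "ATGTTT"))
  expect_equal(names(select_longest_transcript(single)), "G1")
  pair <- list(gene_model("G1", "TX", paste(rep("ATG", 100), collapse = "")),
               gene_model("G1", "TY", paste(rep("ATG", 101), collapse = "")))
  expect_equal(select_longest_transcript(pair)$G1$transcript_id, "TY")
  tie <- list(gene_model("G1", "T2", "ATGTTT"),
              gene_model("G1", "T1", "ATGAAA"))
  expect_equal(select_longest_transcript(tie)$G1$transcript_id, "T1")
})

test_that("classify_substitutions translates codon changes correctly", {
  models <- list(G1 = gene_model("G1", "T_G1", "ATGTTT"),
                 G2 = gene_model("G2", "T_G2", "ATGTGG"))
  tabs <- full_tables(models, mf_of = function(...) TRUE)
  recs <- rbind(
    make_records("P1", "G1", 6, "T", "C"),   # TTT -> TTC, synonymous
    make_records("P1", "G2", 6, "G", "A"),   # TGG -> TGA, nonsense
    make_records("P1", "G1", 4, "T", "C"))   # TTT -> CTT, missense
  out <- classify_substitutions(recs, models, tabs$sift, tabs$pph)
  expect_equal(nrow(out$rejected), 0L)
  expect_equal(out$kept$effect, c("synonymous", "nonsense", "missense"))
  expect_equal(out$kept$func_class_sift,
               c("not_applicable", "not_applicable", "MF"))
  expect_equal(out$kept$func_class_pph,
               c("not_applicable", "not_applicable", "MF"))
})

test_that("SIFT scores at/below 0.05 map to MF, above to LF, missing to unscored", {
  models <- list(G1 = gene_model("G1", "T_G1", "ATGTTT"))
  # score the Leu changes (TTT pos 4 T>C -> CTT = L) at 0.04, rest unscored
  sift <- functionality_table(
    data.frame(gene_id = "G1", protein_pos = 2L, alt_aa = "L",
               score = 0.04), "SIFT_like")
  recs <- rbind(make_records("P1", "G1", 4, "T", "C"),  # L, scored 0.04
                make_records("P1", "G1", 5, "T", "C"))  # TCT = S, unscored
  out <- classify_substitutions(recs, models, sift, NULL)
  expect_equal(out$kept$func_class_sift, c("MF", "unscored"))
  expect_equal(out$kept$func_class_pph, c("unscored", "unscored"))
})

test_that("classification rejects ref mismatches and out-of-range positions", {
  models <- list(G1 = gene_model("G1", "T_G1", "ATGTTT"))
  recs <- rbind(make_records("P1", "G1", 6, "A", "C"),    # ref is T
                make_records("P1", "G1", 7, "T", "C"),    # beyond CDS
                make_records("P1", "GX", 1, "A", "C"),    # unknown gene
                make_records("P1", "G1", 6, "T", "C"))    # valid
  expect_message(out <- classify_substitutions(recs, models), "rejected 3")
  expect_equal(nrow(out$kept), 1L)
  expect_setequal(out$rejected$reject_reason,
                  c("ref_mismatch", "position_out_of_range", "no_gene_model"))
})

test_that("deduplicate_within_tumor collapses within but not across patients", {
  r <- rbind(make_records("P1", "G1", 6, "T", "C"),
             make_records("P1", "G1", 6, "T", "C"),
             make_records("P2", "G1", 6, "T", "C"))
  out <- deduplicate_within_tumor(r)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$patient_id, c("P1", "P2"))
  # idempotent, and empty input passes through
  expect_equal(nrow(deduplicate_within_tumor(out)), 2L)
  expect_equal(nrow(deduplicate_within_tumor(r[0])), 0L)
})

test_that("inactivation filter removes co-occurring records per (patient, gene)", {
  r <- rbind(
    make_records("P1", "GA", 10, "A", "C", effect = "missense"),
    make_records("P1", "GA", 20, "C", "T", effect = "nonsense"),
    make_records("P1", "GB", 5, "G", "A", effect = "missense"),
    make_records("P2", "GA", 10, "A", "C", effect = "missense"))
  out <- apply_nonsense_frameshift_filter(r)
  # default: the inactivating substitution itself is retained and counted
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(r))
  expect_true(all(out$removed$gene_id == "GA" & out$removed$patient_id == "P1"))
  expect_equal(out$removed$effect, "missense")
  expect_true("nonsense" %in% out$kept$effect)
  # P2/GA and P1/GB are untouched
  expect_true(any(out$kept$patient_id == "P2" & out$kept$gene_id == "GA"))
  expect_true(any(out$kept$gene_id == "GB"))
  # strict mode drops the trigger too: no nonsense left in kept
  strict <- apply_nonsense_frameshift_filter(r, drop_trigger = TRUE)
  expect_false(any(strict$kept$effect == "nonsense", na.rm = TRUE))
  expect_equal(nrow(strict$kept), 2L)
})

test_that("frameshift events trigger removal and are never kept", {
  r <- rbind(
    make_records("P1", "GA", 10, "A", "C", effect = "synonymous"),
    make_records("P1", "GA", 12, "T", "-", frameshift = TRUE),
    make_records("P1", "GB", 5, "G", "A", effect = "missense"))
  out <- apply_nonsense_frameshift_filter(r)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(out$kept$gene_id, "GB")
  expect_setequal(out$removed$cds_pos, c(10L, 12L))
  # no triggers anywhere: identity
  clean <- r[3]
  out2 <- apply_nonsense_frameshift_filter(clean)
  expect_equal(nrow(out2$kept), 1L)
  expect_equal(nrow(out2$removed), 0L)
})

test_that("dedup and inactivation filter commute on random cohorts", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 200
    pos <- sample(1:30, n, replace = TRUE)
    # effect is a function of position, as in real data (duplicate records
    # of one substitution always agree on their classification)
    r <- make_records(
      patient = sample(paste0("P", 1:8), n, replace = TRUE),
      gene = sample(paste0("G", 1:10), n, replace = TRUE),
      pos = pos,
      ref = "A", alt = "C",
      effect = c("missense", "synonymous", "missense", "missense",
                 "nonsense")[pos %% 5 + 1])
    a <- apply_nonsense_frameshift_filter(deduplicate_within_tumor(r))$kept
    b <- deduplicate_within_tumor(apply_nonsense_frameshift_filter(r)$kept)
    setkeyv(a, c("patient_id", "gene_id", "cds_pos", "ref", "alt"))
    setkeyv(b, c("patient_id", "gene_id", "cds_pos", "ref", "alt"))
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("germline frequency filter is strict and logs missing AF", {
  r <- rbind(make_records("", "G1", 1, "A", "C", af = 0.10),
             make_records("", "G1", 2, "A", "C", af = 0.25),
             make_records("", "G1", 3, "A", "C", af = NA))
  expect_message(out <- filter_germline_by_frequency(r, 0.1), "missing")
  expect_equal(out$cds_pos, 2L)
  all_kept <- suppressMessages(filter_germline_by_frequency(r, 0))
  expect_setequal(all_kept$cds_pos, c(1L, 2L))
})

test_that("tally_group_counts counts by effect and respects the gene set", {
  r <- rbind(
    make_records("P1", "G1", 1, "A", "C", effect = "missense"),
    make_records("P1", "G1", 2, "A", "C", effect = "missense"),
    make_records("P1", "G2", 3, "A", "C", effect = "missense"),
    make_records("P1", "G1", 4, "A", "C", effect = "synonymous"),
    make_records("P1", "G3", 5, "A", "C", effect = "missense"),
    make_records("P1", "G1", 6, "A", "C", effect = "nonsense"))
  r$func_class_sift[1] <- "MF"; r$func_class_sift[2] <- "LF"
  g <- tally_group_counts(r, c("G1", "G2"), "set1")
  expect_equal(g$n, 4L)  # 3 missense + 1 nonsense in-set
  expect_equal(g$s, 1L)
  expect_equal(g$mf_sift, 1L)
  expect_equal(g$lf_sift, 1L)
  expect_true(g$mf_sift + g$lf_sift <= g$n)
  expect_warning(zero <- tally_group_counts(r, character(), "none"), "empty")
  expect_equal(zero$n + zero$s, 0L)
})

test_that("tallies are additive over disjoint gene sets", {
  set.seed(43)
  n <- 300
  r <- make_records(
    patient = "P1", gene = sample(paste0("G", 1:12), n, replace = TRUE),
    pos = seq_len(n), ref = "A", alt = "C",
    effect = sample(c("missense", "synonymous", "nonsense"), n, TRUE))
  r$func_class_sift <- ifelse(r$effect == "missense",
                              sample(c("MF", "LF", "unscored"), n, TRUE),
                              "not_applicable")
  set_a <- paste0("G", 1:6); set_b <- paste0("G", 7:12)
  ga <- tally_group_counts(r, set_a); gb <- tally_group_counts(r, set_b)
  gall <- tally_group_counts(r, c(set_a, set_b))
  for (col in c("n", "s", "mf_sift", "lf_sift"))
    expect_equal(ga[[col]] + gb[[col]], gall[[col]], info = col)
})

test_that("somatic TSV and germline VCF round-trip through the readers", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- sim_config(n_genes = 12, n_patients = 15, seed = 99,
                    frameshift_rate = 0.01)
  models <- generate_gene_models(cfg)
  tabs <- generate_functionality_tables(models, cfg)
  one <- select_longest_transcript(models)
  som <- simulate_somatic_cohort(models, tabs, cfg)
  dir <- withr::local_tempdir()
  f_som <- file.path(dir, "somatic.tsv")
  data.table::fwrite(som, f_som, sep = "\t")
  back <- read_somatic_tsv(f_som)
  expect_equal(nrow(back), nrow(som))
  out <- classify_substitutions(back, one, tabs$sift, tabs$pph)
  expect_equal(nrow(out$rejected), 0L)

  germ <- simulate_germline_panel(models, cfg)
  f_vcf <- file.path(dir, "germ.vcf")
  write_germline_vcf(germ, f_vcf)
  gback <- read_germline_vcf(f_vcf)
  expect_equal(nrow(gback), nrow(germ))
  gout <- classify_substitutions(gback, one, tabs$sift, tabs$pph)
  expect_equal(nrow(gout$rejected), 0L)
  # multi-allelic sites were split into one record per alternate
  expect_equal(anyDuplicated(gback[, c("transcript_id", "cds_pos", "alt")]), 0L)
})
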