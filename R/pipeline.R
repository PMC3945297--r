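## End-to-end pipeline: transcript selection -> site counting ->
## classification -> dedup -> inactivation filter -> germline frequency
## filter -> expression partitioning -> tallies -> statistics -> screen ->
## enrichments, with per-stage record accounting.

log_msg <- function(...) message(sprintf(...))

ratio_row <- function(counts, sites, group) {
  one <- function(metric) {
    # empty groups and refused tests propagate as NAs, never as errors
    tryCatch({
      r <- suppressWarnings(ratio_statistic(counts, sites, metric))
      list(ratio = r$ratio, p_value = r$p_value, direction = r$direction)
    }, error = function(e) {
      log_msg("ratio %s for group '%s' unavailable: %s", metric, group,
              conditionMessage(e))
      list(ratio = NA_real_, p_value = NA_real_, direction = NA_character_)
    })
  }
  dn <- one("dn_ds"); ms <- one("dmf_dlf_sift"); mp <- one("dmf_dlf_pph")
  data.frame(
    group = group,
    n = counts$n, s = counts$s, dn_ds = dn$ratio, dn_ds_p = dn$p_value,
    mf_sift = counts$mf_sift, lf_sift = counts$lf_sift,
    dmf_dlf_sift = ms$ratio, dmf_dlf_sift_p = ms$p_value,
    mf_pph = counts$mf_pph, lf_pph = counts$lf_pph,
    dmf_dlf_pph = mp$ratio, dmf_dlf_pph_p = mp$p_value)
}

comparison_rows <- function(label, counts_a, sites_a, counts_b, sites_b) {
  data.table::rbindlist(lapply(
    c("dn_ds", "dmf_dlf_sift", "dmf_dlf_pph"), function(metric) {
      gc_ <- tryCatch(
        suppressWarnings(compare_groups(counts_a, sites_a, counts_b,
                                        sites_b, metric)),
        error = function(e) {
          log_msg("comparison '%s' (%s) unavailable: %s", label, metric,
                  conditionMessage(e))
          list(ratio_a = NA_real_, ratio_b = NA_real_, cf = NA_real_,
               corrected_n_a = NA_real_, chi2_stat = NA_real_,
               p_value = NA_real_, refused = TRUE)
        })
      data.frame(comparison = label, metric = metric, ratio_a = gc_$ratio_a,
                 ratio_b = gc_$ratio_b, cf = gc_$cf,
                 corrected_n_a = gc_$corrected_n_a,
                 chi2_stat = gc_$chi2_stat, p_value = gc_$p_value,
                 refused = gc_$refused)
    }))
}

#' Classify, deduplicate and filter a somatic cohort in memory
#'
#' Convenience driver for the somatic arm of the pipeline when the inputs
#' are already in memory (e.g. straight from [simulate_somatic_cohort()]):
#' classification against the gene models, within-tumor deduplication, and
#' the nonsense/frameshift inactivation filter.
#'
#' @param somatic MAF-style data frame (as from [simulate_somatic_cohort()]
#'   or [read_somatic_tsv()]).
#' @param models Named list of per-gene models.
#' @param sift_table,pph_table Optional `functionality_table`s.
#' @param drop_trigger Passed to [apply_nonsense_frameshift_filter()].
#' @return List with `records` (analyzed substitutions), `removed`
#'   (inactivation-filtered), `rejected` (classification failures) and
#'   `n_duplicates`.
#' @export
analyze_somatic <- function(somatic, models, sift_table = NULL,
                            pph_table = NULL, drop_trigger = FALSE) {
  cl <- classify_substitutions(somatic, models, sift_table, pph_table)
  dedup <- deduplicate_within_tumor(cl$kept)
  filt <- apply_nonsense_frameshift_filter(dedup, drop_trigger = drop_trigger)
  list(records = filt$kept, removed = filt$removed, rejected = cl$rejected,
       n_duplicates = nrow(cl$kept) - nrow(dedup))
}

#' Run the full selection analysis
#'
#' Executes every stage of the analysis on a set of input files (typically
#' those written by [simulate_inputs()]): gene-model loading and
#' longest-transcript selection, site counting under both functionality
#' schemes, somatic classification, within-tumor deduplication and
#' nonsense/frameshift inactivation filtering, germline allele-frequency
#' filtering, expression-breadth partitioning, group tallies, dN/dS and
#' dMF/dLF statistics with group comparisons, the per-gene positive
#' selection screen, and enrichment tests. Record counts are logged (and
#' conservation asserted) at every filtering stage.
#'
#' @param paths Named list of input files: `cds_fasta`, `sift_tsv`,
#'   `pph_tsv`, `somatic_tsv`, `expression_tsv`, and optionally
#'   `germline_vcf`, `census_txt`, `essential_txt` (see
#'   [simulate_inputs()]).
#' @param focal_tissue Focal (tumor-origin) tissue column name.
#' @param platform Expression platform: `"rpkm"` or `"intensity"`.
#' @param relaxed Relaxed (14-16 tissue) globality rule.
#' @param min_freq Germline allele-frequency cutoff (strict, default 0.1).
#' @param alpha Screen significance level (default 0.05).
#' @param drop_trigger Passed to [apply_nonsense_frameshift_filter()].
#' @param out_dir Optional directory; when given, the report JSON and the
#'   main tables are written there.
#' @return A list of class `run_report`; see [render_report()].
#' @export
run_pipeline <- function(paths, focal_tissue = "tissue01",
                         platform = "rpkm", relaxed = FALSE,
                         min_freq = 0.1, alpha = 0.05,
                         drop_trigger = FALSE, out_dir = NULL) {
  required <- c("cds_fasta", "sift_tsv", "pph_tsv", "somatic_tsv",
                "expression_tsv")
  for (f in required) {
    if (is.null(paths[[f]]) || !file.exists(paths[[f]]))
      stop("missing required input '", f, "': ",
           if (is.null(paths[[f]])) "<unset>" else paths[[f]])
  }
  census <- if (!is.null(paths$census_txt) && file.exists(paths$census_txt))
    readLines(paths$census_txt) else character()
  essential <- if (!is.null(paths$essential_txt) &&
                   file.exists(paths$essential_txt))
    readLines(paths$essential_txt) else character()

  log_msg("reading gene models from %s", paths$cds_fasta)
  models <- read_cds_fasta(paths$cds_fasta, census_genes = census,
                           essential_genes = essential)
  one <- select_longest_transcript(models)
  log_msg("%d transcripts -> %d genes after longest-transcript selection",
          length(models), length(one))

  sift <- read_functionality_table(paths$sift_tsv, "SIFT_like")
  pph <- read_functionality_table(paths$pph_tsv, "POLYPHEN_like")
  sites <- count_sites(one, sift, pph)

  raw_somatic <- read_somatic_tsv(paths$somatic_tsv)
  cl <- classify_substitutions(raw_somatic, one, sift, pph)
  stopifnot(nrow(cl$kept) + nrow(cl$rejected) == nrow(raw_somatic))
  dedup <- deduplicate_within_tumor(cl$kept)
  n_dups <- nrow(cl$kept) - nrow(dedup)
  filt <- apply_nonsense_frameshift_filter(dedup, drop_trigger = drop_trigger)
  stopifnot(nrow(filt$kept) + nrow(filt$removed) == nrow(dedup))
  somatic <- filt$kept
  log_msg(paste0("somatic: %d raw, %d rejected, %d within-tumor duplicates, ",
                 "%d removed by inactivation filter, %d analyzed"),
          nrow(raw_somatic), nrow(cl$rejected), n_dups, nrow(filt$removed),
          nrow(somatic))

  germline <- NULL
  if (!is.null(paths$germline_vcf) && file.exists(paths$germline_vcf)) {
    raw_germ <- read_germline_vcf(paths$germline_vcf)
    clg <- classify_substitutions(raw_germ, one, sift, pph)
    germline <- filter_germline_by_frequency(clg$kept, min_freq = min_freq)
    log_msg("germline: %d sites, %d rejected, %d at AF > %.2g",
            nrow(raw_germ), nrow(clg$rejected), nrow(germline), min_freq)
  }

  expr <- read_expression_matrix(paths$expression_tsv)
  profiles <- compute_breadth(expr, platform = platform, relaxed = relaxed)
  missing_expr <- setdiff(names(one), profiles$gene_id)
  if (length(missing_expr))
    log_msg("%d gene(s) missing from the expression matrix are excluded from partitions",
            length(missing_expr))
  part <- partition_genes(profiles, focal_tissue)

  groups <- list(
    global = part$global_set,
    nonglobal = part$nonglobal_set,
    nonglobal_in_focal = part$nonglobal_expressed_in_focal,
    nonglobal_not_in_focal = part$nonglobal_not_expressed_in_focal,
    global_no_census = setdiff(part$global_set, census),
    nonglobal_no_census = setdiff(part$nonglobal_set, census),
    census = intersect(census, profiles$gene_id),
    non_census = setdiff(profiles$gene_id, census))
  empty_groups <- names(groups)[lengths(groups) == 0L]
  if (length(empty_groups))
    log_msg("empty gene group(s): %s", paste(empty_groups, collapse = ", "))
  tallies <- lapply(names(groups), function(g)
    suppressWarnings(tally_group_counts(somatic, groups[[g]], g)))
  names(tallies) <- names(groups)
  site_aggs <- lapply(names(groups), function(g)
    aggregate_site_counts(sites, groups[[g]], g))
  names(site_aggs) <- names(groups)
  table1 <- data.table::rbindlist(lapply(names(groups), function(g)
    ratio_row(tallies[[g]], site_aggs[[g]], g)))

  comparisons <- data.table::rbindlist(list(
    comparison_rows("global_vs_nonglobal",
                    tallies$global, site_aggs$global,
                    tallies$nonglobal, site_aggs$nonglobal),
    comparison_rows("global_vs_nonglobal_not_in_focal",
                    tallies$global, site_aggs$global,
                    tallies$nonglobal_not_in_focal,
                    site_aggs$nonglobal_not_in_focal),
    comparison_rows("global_vs_nonglobal_in_focal",
                    tallies$global, site_aggs$global,
                    tallies$nonglobal_in_focal,
                    site_aggs$nonglobal_in_focal),
    comparison_rows("global_no_census_vs_nonglobal_no_census",
                    tallies$global_no_census, site_aggs$global_no_census,
                    tallies$nonglobal_no_census,
                    site_aggs$nonglobal_no_census),
    comparison_rows("census_vs_non_census",
                    tallies$census, site_aggs$census,
                    tallies$non_census, site_aggs$non_census)))

  all_sites <- aggregate_site_counts(sites, NULL, "all")
  somatic_all <- tally_group_counts(somatic, NULL, "somatic_all")
  fig1 <- ratio_row(somatic_all, all_sites, "somatic")
  if (!is.null(germline)) {
    germline_all <- tally_group_counts(germline, NULL, "germline_all")
    fig1 <- rbind(fig1, ratio_row(germline_all, all_sites, "germline"))
  }

  screen <- per_gene_screen(somatic, sites, alpha = alpha)
  flagged <- screen[significant_above_one == TRUE, gene_id]
  screened <- screen$gene_id

  enrichments <- list()
  if (length(flagged) && length(census))
    enrichments$flagged_census <- list_enrichment(
      flagged, intersect(census, screened), screened)
  profiled <- profiles$gene_id
  if (length(part$global_set) && length(essential))
    enrichments$global_essential <- list_enrichment(
      part$global_set, intersect(essential, profiled), profiled)
  flagged_prof <- intersect(flagged, profiled)
  if (length(flagged_prof))
    enrichments$flagged_global <- list_enrichment(
      flagged_prof, part$global_set,
      union(intersect(screened, profiled), part$global_set))
  census_prof <- intersect(census, profiled)
  histogram <- if (length(census_prof) >= 2L)
    breadth_histogram(profiles, census_prof) else NULL

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("somaselect")),
      r_version = as.character(getRversion()),
      inputs = lapply(paths, normalizePath, mustWork = FALSE),
      parameters = list(focal_tissue = focal_tissue, platform = platform,
                        relaxed = relaxed, min_freq = min_freq,
                        alpha = alpha, drop_trigger = drop_trigger)),
    stage_counts = list(
      somatic_raw = nrow(raw_somatic), somatic_rejected = nrow(cl$rejected),
      somatic_duplicates = n_dups, somatic_removed_inactivation =
        nrow(filt$removed), somatic_analyzed = nrow(somatic),
      germline_analyzed = if (is.null(germline)) 0L else nrow(germline)),
    group_sizes = lapply(groups, length),
    table1 = table1,
    comparisons = comparisons,
    fig1 = fig1,
    screen = screen,
    n_flagged = length(flagged),
    enrichments = enrichments,
    histogram = histogram)
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report to disk
#'
#' Writes `report.json` plus TSVs of the group table, group comparisons,
#' somatic-vs-germline ratio table and the per-gene screen.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- report
  ser$screen <- as.data.frame(ser$screen)
  ser$table1 <- as.data.frame(ser$table1)
  ser$comparisons <- as.data.frame(ser$comparisons)
  if (!is.null(ser$histogram)) {
    ser$histogram <- list(table = as.data.frame(ser$histogram$table),
                          test_global = ser$histogram$test_global,
                          test_specific = ser$histogram$test_specific)
  }
  ser$enrichments <- lapply(ser$enrichments, unclass)
  jsonlite::write_json(unclass(ser), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  data.table::fwrite(report$table1, file.path(out_dir, "group_table.tsv"),
                     sep = "\t")
  data.table::fwrite(report$comparisons,
                     file.path(out_dir, "comparisons.tsv"), sep = "\t")
  data.table::fwrite(report$fig1,
                     file.path(out_dir, "somatic_vs_germline.tsv"),
                     sep = "\t")
  data.table::fwrite(report$screen, file.path(out_dir, "screen.tsv"),
                     sep = "\t")
  invisible(file.path(out_dir, "report.json"))
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

fmt_p <- function(p) {
  ifelse(is.na(p), "refused", formatC(p, digits = 3, format = "g"))
}

#' Render a run report as human-readable Markdown tables
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A character vector of Markdown lines (invisibly printed by
#'   `cat(render_report(r), sep = "\n")`).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  lines <- c("# somaselect run report", "")
  md_table <- function(df, digits = 2) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], fmt_num, digits = digits)
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }
  lines <- c(lines, "## Substitution ratios by gene group", "",
             md_table(as.data.frame(report$table1)), "")
  lines <- c(lines, "## Group comparisons (site-composition corrected)", "",
             md_table(as.data.frame(report$comparisons), digits = 3), "")
  lines <- c(lines, "## Somatic vs germline", "",
             md_table(as.data.frame(report$fig1)), "")
  lines <- c(lines, "## Per-gene positive-selection screen", "")
  if (report$n_flagged == 0L) {
    lines <- c(lines, "no genes flagged", "")
  } else {
    top <- as.data.frame(head(
      report$screen[report$screen$significant_above_one, ], 20L))
    lines <- c(lines,
               sprintf("%d gene(s) with dN/dS significantly above 1:",
                       report$n_flagged), "",
               md_table(top[, c("gene_id", "n", "s", "dn_ds", "p_value")],
                        digits = 3), "")
  }
  if (length(report$enrichments)) {
    lines <- c(lines, "## Enrichments", "")
    for (nm in names(report$enrichments)) {
      e <- report$enrichments[[nm]]
      lines <- c(lines, sprintf(
        "- %s: %d/%d (%.1f%%), fold %.2f, chi2 p = %s", nm, e$overlap,
        e$n_flagged, e$overlap_pct, e$fold_enrichment, fmt_p(e$p_value)))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
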