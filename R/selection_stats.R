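## Ratio statistics (dN/dS, dMF/dLF), chi-square tests against neutrality,
## site-composition-corrected group comparisons, per-gene screens, and
## gene-set enrichment tests.

metric_fields <- function(metric) {
  switch(metric,
    dn_ds        = list(num_count = "n",  den_count = "s",
                        num_sites = "N",  den_sites = "S"),
    dmf_dlf_sift = list(num_count = "mf_sift", den_count = "lf_sift",
                        num_sites = "MF_sift", den_sites = "LF_sift"),
    dmf_dlf_pph  = list(num_count = "mf_pph", den_count = "lf_pph",
                        num_sites = "MF_pph", den_sites = "LF_pph"),
    stop("unknown metric: ", metric))
}

extract_parts <- function(counts, sites, metric) {
  f <- metric_fields(metric)
  list(num_count = as.numeric(counts[[f$num_count]]),
       den_count = as.numeric(counts[[f$den_count]]),
       num_sites = as.numeric(sites[[f$num_sites]]),
       den_sites = as.numeric(sites[[f$den_sites]]))
}

## 1-df goodness-of-fit chi-square of observed (o1, o2) against expectation
## proportional to (w1, w2). Explicit formula (no continuity correction by
## default) so that non-integer corrected counts are handled exactly.
chi2_gof2 <- function(o1, o2, w1, w2, correct = FALSE) {
  total <- o1 + o2
  e1 <- total * w1 / (w1 + w2)
  e2 <- total * w2 / (w1 + w2)
  d1 <- abs(o1 - e1); d2 <- abs(o2 - e2)
  if (correct) { d1 <- max(0, d1 - 0.5); d2 <- max(0, d2 - 0.5) }
  stat <- d1^2 / e1 + d2^2 / e2
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = c(e1, e2))
}

## 2x2 chi-square of independence (no continuity correction by default);
## rows are groups, columns are categories. Accepts non-integer entries.
chi2_2x2 <- function(m, correct = FALSE) {
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  rs <- rowSums(m); cs <- colSums(m); tot <- sum(m)
  if (any(rs == 0) || any(cs == 0))  # degenerate margin: no association
    return(list(statistic = 0, p_value = 1, expected = m))
  e <- outer(rs, cs) / tot
  d <- abs(m - e)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = e)
}

#' Pooled substitution-rate ratio (dN/dS or dMF/dLF) for a gene group
#'
#' Computes `(count_num / sites_num) / (count_den / sites_den)`: for
#' `metric = "dn_ds"` the non-synonymous substitutions per non-synonymous
#' site over synonymous substitutions per synonymous site; the
#' `dmf_dlf_*` metrics replace synonymy by the more/less-functional
#' classification of the corresponding scheme.
#'
#' @param counts Group substitution counts ([tally_group_counts()]).
#' @param sites Aggregated site counts ([aggregate_site_counts()]).
#' @param metric `"dn_ds"`, `"dmf_dlf_sift"` or `"dmf_dlf_pph"`.
#' @param correct Apply Yates continuity correction in the test
#'   (default `FALSE`; counts are large in typical cohorts).
#' @return Object of class `ratio_result`: list with `metric`, `ratio`
#'   (`NA` with `undefined = TRUE` when the denominator count is zero),
#'   the four inputs, `chi2_stat`, `p_value`, `refused`, and `direction`
#'   (`above_one` / `below_one` / `at_one`, from the ratio's position
#'   relative to 1).
#' @export
ratio_statistic <- function(counts, sites, metric = "dn_ds",
                            correct = FALSE) {
  p <- extract_parts(counts, sites, metric)
  if (!is.finite(p$num_sites) || !is.finite(p$den_sites) ||
      p$num_sites <= 0 || p$den_sites <= 0)
    stop("zero or missing site totals for metric ", metric)
  undefined <- p$den_count == 0
  ratio <- if (undefined) NA_real_ else
    (p$num_count / p$num_sites) / (p$den_count / p$den_sites)
  test <- test_ratio_vs_one(counts, sites, metric, correct = correct)
  direction <- if (undefined || ratio == 1) "at_one" else
    if (ratio > 1) "above_one" else "below_one"
  structure(list(
    metric = metric, ratio = ratio, undefined = undefined,
    numerator_counts = p$num_count, denominator_counts = p$den_count,
    numerator_sites = p$num_sites, denominator_sites = p$den_sites,
    chi2_stat = test$chi2_stat, p_value = test$p_value,
    refused = test$refused, direction = direction),
    class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  lab <- c(dn_ds = "dN/dS", dmf_dlf_sift = "dMF/dLF(SIFT)",
           dmf_dlf_pph = "dMF/dLF(PolyPhen)")[x$metric]
  cat(sprintf("<ratio_result> %s = %s  [%d/%d subs; %.1f/%.1f sites]\n",
              lab, if (x$undefined) "undefined" else sprintf("%.3f", x$ratio),
              x$numerator_counts, x$denominator_counts,
              x$numerator_sites, x$denominator_sites))
  if (x$refused) cat("  chi-square refused (expected count < 5)\n")
  else cat(sprintf("  chi2 = %.3f, p = %.3g, direction = %s\n",
                   x$chi2_stat, x$p_value, x$direction))
  invisible(x)
}

#' Chi-square test of a substitution-rate ratio against 1
#'
#' Compares the observed split of substitutions between the two categories
#' of a metric with the split expected from the corresponding site totals
#' (1 df). The test is refused (with a warning) when either expected count
#' is below 5.
#'
#' @inheritParams ratio_statistic
#' @return List with `chi2_stat`, `p_value`, `direction`, `refused`.
#' @export
test_ratio_vs_one <- function(counts, sites, metric = "dn_ds",
                              correct = FALSE) {
  p <- extract_parts(counts, sites, metric)
  if (p$num_sites <= 0 || p$den_sites <= 0)
    stop("zero site totals for metric ", metric)
  gof <- chi2_gof2(p$num_count, p$den_count, p$num_sites, p$den_sites,
                   correct = correct)
  if (any(gof$expected < 5)) {
    warning("chi-square refused: expected count below 5 for metric ", metric)
    return(list(chi2_stat = NA_real_, p_value = NA_real_,
                direction = NA_character_, refused = TRUE))
  }
  rate_ratio <- (p$num_count / p$num_sites) /
    max(p$den_count / p$den_sites, .Machine$double.eps)
  direction <- if (gof$statistic == 0) "at_one" else
    if (rate_ratio > 1) "above_one" else "below_one"
  list(chi2_stat = gof$statistic, p_value = gof$p_value,
       direction = direction, refused = FALSE)
}

#' Compare a ratio between two gene groups, correcting for site composition
#'
#' Tests whether group A's substitution-rate ratio exceeds group B's with a
#' 2x2 chi-square on the substitution counts, after dividing group A's
#' numerator count by a correction factor
#' `cf = (sites_num_A / sites_den_A) / (sites_num_B / sites_den_B)` so that
#' a difference in site composition between the groups (e.g. a higher
#' proportion of non-synonymous sites in one group) cannot masquerade as a
#' difference in selection. When the two groups have identical site
#' composition, `cf = 1` and the test reduces to the ordinary 2x2
#' chi-square.
#'
#' @param counts_a,counts_b Group substitution counts.
#' @param sites_a,sites_b Aggregated site counts of the two groups.
#' @param metric,correct See [ratio_statistic()].
#' @return Object of class `group_comparison`: list with `ratio_a`,
#'   `ratio_b`, `cf`, `corrected_n_a`, `chi2_stat`, `p_value`, `refused`.
#' @export
compare_groups <- function(counts_a, sites_a, counts_b, sites_b,
                           metric = "dn_ds", correct = FALSE) {
  pa <- extract_parts(counts_a, sites_a, metric)
  pb <- extract_parts(counts_b, sites_b, metric)
  if (min(pa$num_sites, pa$den_sites, pb$num_sites, pb$den_sites) <= 0)
    stop("zero site totals in a group for metric ", metric)
  cf <- (pa$num_sites / pa$den_sites) / (pb$num_sites / pb$den_sites)
  corrected_n_a <- pa$num_count / cf
  m <- matrix(c(corrected_n_a, pa$den_count,
                pb$num_count, pb$den_count), nrow = 2, byrow = TRUE)
  ratio_a <- if (pa$den_count > 0)
    (pa$num_count / pa$num_sites) / (pa$den_count / pa$den_sites) else NA_real_
  ratio_b <- if (pb$den_count > 0)
    (pb$num_count / pb$num_sites) / (pb$den_count / pb$den_sites) else NA_real_
  ct <- chi2_2x2(m, correct = correct)
  refused <- any(ct$expected < 5)
  if (refused)
    warning("group comparison refused: expected count below 5 for metric ",
            metric)
  structure(list(
    metric = metric, ratio_a = ratio_a, ratio_b = ratio_b, cf = cf,
    corrected_n_a = corrected_n_a,
    chi2_stat = if (refused) NA_real_ else ct$statistic,
    p_value = if (refused) NA_real_ else ct$p_value,
    refused = refused), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: A=%.3f vs B=%.3f (cf=%.3f)\n",
              x$metric, x$ratio_a, x$ratio_b, x$cf))
  if (x$refused) cat("  chi-square refused (expected count < 5)\n")
  else cat(sprintf("  chi2 = %.3f, p = %.3g\n", x$chi2_stat, x$p_value))
  invisible(x)
}

#' Per-gene screen for dN/dS significantly above 1
#'
#' For every gene with at least `min_syn` synonymous substitutions, computes
#' the gene's dN/dS and the chi-square test against its own site
#' composition. A gene is flagged (`significant_above_one`) when its raw p
#' is below `alpha` and its ratio exceeds 1; a stricter tier at p < 0.001 is
#' reported alongside, as are Benjamini-Hochberg q-values (auxiliary only:
#' the flags use raw p). Genes whose test is refused (expected counts < 5)
#' have `NA` p and are never flagged.
#'
#' @param records Classified, filtered substitution records.
#' @param site_counts Per-gene site counts ([count_sites()]).
#' @param alpha Raw significance level (default 0.05).
#' @param min_syn Minimum synonymous substitutions for inclusion (default 1).
#' @param correct Continuity correction (default `FALSE`).
#' @return A data.table of class `screen_result`, sorted by p then gene id:
#'   `gene_id`, `n`, `s`, `N`, `S`, `dn_ds`, `chi2_stat`, `p_value`,
#'   `q_value`, `refused`, `significant_above_one`, `significant_strict`.
#' @export
per_gene_screen <- function(records, site_counts, alpha = 0.05,
                            min_syn = 1L, correct = FALSE) {
  dt <- data.table::as.data.table(records)
  dt <- dt[!is.na(effect)]
  tal <- dt[, .(n = sum(effect %in% c("missense", "nonsense")),
                s = sum(effect == "synonymous")), by = gene_id]
  sc <- data.table::as.data.table(site_counts)[, .(gene_id, N, S)]
  tal <- sc[tal, on = "gene_id"]
  tal <- tal[!is.na(N) & s >= min_syn]
  if (!nrow(tal)) {
    out <- data.table::data.table(
      gene_id = character(), n = integer(), s = integer(), N = numeric(),
      S = numeric(), dn_ds = numeric(), chi2_stat = numeric(),
      p_value = numeric(), q_value = numeric(), refused = logical(),
      significant_above_one = logical(), significant_strict = logical())
    data.table::setattr(out, "class", c("screen_result", class(out)))
    return(out)
  }
  tot <- tal$n + tal$s
  e_n <- tot * tal$N / (tal$N + tal$S)
  e_s <- tot * tal$S / (tal$N + tal$S)
  ref_flag <- e_n < 5 | e_s < 5
  d_n <- abs(tal$n - e_n); d_s <- abs(tal$s - e_s)
  if (correct) { d_n <- pmax(0, d_n - 0.5); d_s <- pmax(0, d_s - 0.5) }
  stat <- d_n^2 / e_n + d_s^2 / e_s
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tal[, dn_ds := (n / N) / (s / S)]
  tal[, chi2_stat := ifelse(ref_flag, NA_real_, stat)]
  tal[, p_value := ifelse(ref_flag, NA_real_, pval)]
  tal[, refused := ref_flag]
  tal[, q_value := {
    q <- rep(NA_real_, .N)
    ok <- !refused
    q[ok] <- stats::p.adjust(p_value[ok], method = "BH")
    q
  }]
  tal[, significant_above_one := !refused & p_value < alpha & dn_ds > 1]
  tal[, significant_strict := !refused & p_value < 0.001 & dn_ds > 1]
  data.table::setorder(tal, p_value, gene_id, na.last = TRUE)
  data.table::setcolorder(tal, c("gene_id", "n", "s", "N", "S", "dn_ds",
                                 "chi2_stat", "p_value", "q_value", "refused",
                                 "significant_above_one",
                                 "significant_strict"))
  data.table::setattr(tal, "class", c("screen_result", class(tal)))
  tal[]
}

#' Gene-set enrichment of a flagged set against an annotation
#'
#' 2x2 chi-square of flagged status against annotation membership over a
#' gene universe, with the overlap count, the percentage of flagged genes
#' carrying the annotation, and the fold enrichment over the universe-wide
#' base rate.
#'
#' @param flagged_set,annotation_set Character vectors, subsets of
#'   `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @param correct Continuity correction (default `FALSE`).
#' @return List of class `enrichment_result`: `overlap`, `n_flagged`,
#'   `n_annotated`, `n_universe`, `overlap_pct` (percentage of flagged genes
#'   annotated), `annotated_unflagged_pct` (percentage of annotated genes
#'   not flagged), `fold_enrichment`, `chi2_stat`, `p_value`.
#' @export
list_enrichment <- function(flagged_set, annotation_set, universe,
                            correct = FALSE) {
  flagged_set <- unique(flagged_set)
  annotation_set <- unique(annotation_set)
  universe <- unique(universe)
  if (!length(flagged_set)) stop("empty flagged_set")
  if (length(setdiff(flagged_set, universe)))
    stop("flagged_set is not a subset of the universe")
  if (length(setdiff(annotation_set, universe)))
    stop("annotation_set is not a subset of the universe")
  a <- length(intersect(flagged_set, annotation_set))
  b <- length(flagged_set) - a
  c_ <- length(annotation_set) - a
  d <- length(universe) - a - b - c_
  ct <- chi2_2x2(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                 correct = correct)
  base_rate <- length(annotation_set) / length(universe)
  structure(list(
    overlap = a, n_flagged = length(flagged_set),
    n_annotated = length(annotation_set), n_universe = length(universe),
    overlap_pct = 100 * a / length(flagged_set),
    annotated_unflagged_pct = 100 * c_ / max(length(annotation_set), 1L),
    fold_enrichment = (a / length(flagged_set)) / base_rate,
    chi2_stat = ct$statistic, p_value = ct$p_value),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %d/%d flagged annotated (%.1f%%), fold=%.2f, chi2=%.2f, p=%.3g\n",
    x$overlap, x$n_flagged, x$overlap_pct, x$fold_enrichment, x$chi2_stat,
    x$p_value))
  invisible(x)
}
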