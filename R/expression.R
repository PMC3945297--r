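## Expression-breadth classification across 16 tissues and the gene
## partitions compared throughout the analysis.

N_TISSUES <- 16L
DEFAULT_BREADTH_BINS <- list("0" = 0L, "1-3" = 1:3, "4-6" = 4:6, "7-9" = 7:9,
                             "10-12" = 10:12, "13-15" = 13:15, "16" = 16L)

#' Read an expression matrix
#'
#' @param path TSV with a `gene_id` column followed by 16 tissue columns.
#' @return A data.table keyed by `gene_id`.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "gene_id"))
  if (!"gene_id" %in% names(dt)) stop("expression matrix lacks gene_id column")
  dt
}

#' Compute per-gene expression breadth and globality
#'
#' A gene is expressed in a tissue when its value exceeds the platform
#' threshold: strictly above 100 for microarray `intensity` data, or at least
#' 1 for `rpkm` data. Breadth is the number of tissues (out of 16) in which
#' the gene is expressed; a gene is globally expressed when expressed in all
#' 16 tissues (strict mode), or in 14-16 tissues when `relaxed = TRUE`.
#'
#' @param expression Data frame with `gene_id` plus exactly 16 numeric,
#'   non-negative tissue columns.
#' @param platform `"rpkm"` (expressed when value >= 1) or `"intensity"`
#'   (expressed when value > 100).
#' @param relaxed Use the relaxed 14-16-tissue globality rule.
#' @return A data.table with `gene_id`, one logical column per tissue,
#'   `breadth` (0-16) and `is_global`; attribute `tissues` names the tissue
#'   columns.
#' @export
compute_breadth <- function(expression, platform = c("rpkm", "intensity"),
                            relaxed = FALSE) {
  platform <- match.arg(platform)
  dt <- data.table::as.data.table(expression)
  tissues <- setdiff(names(dt), "gene_id")
  if (length(tissues) != N_TISSUES)
    stop("expected ", N_TISSUES, " tissue columns, found ", length(tissues))
  vals <- as.matrix(dt[, tissues, with = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values")
  if (any(is.na(vals)) || any(vals < 0))
    stop("expression values must be non-negative and non-missing")
  expressed <- if (platform == "rpkm") vals >= 1 else vals > 100
  out <- data.table::data.table(gene_id = dt$gene_id)
  for (t in tissues) out[, (t) := expressed[, t]]
  out[, breadth := as.integer(rowSums(expressed))]
  min_global <- if (relaxed) 14L else N_TISSUES
  out[, is_global := breadth >= min_global]
  data.table::setattr(out, "tissues", tissues)
  out[]
}

#' Partition genes by globality and expression in a focal tissue
#'
#' Splits profiled genes into globally expressed genes and, within the
#' non-global remainder, those expressed vs not expressed in the focal
#' tissue (the tissue of origin of the tumor cohort under study).
#'
#' @param profiles Output of [compute_breadth()].
#' @param focal_tissue One of the 16 tissue column names.
#' @return A list of class `gene_partition` with character-vector elements
#'   `global_set`, `nonglobal_set`, `nonglobal_expressed_in_focal`,
#'   `nonglobal_not_expressed_in_focal` and `focal_tissue`.
#' @export
partition_genes <- function(profiles, focal_tissue) {
  tissues <- attr(profiles, "tissues")
  if (is.null(tissues))
    tissues <- setdiff(names(profiles),
                       c("gene_id", "breadth", "is_global"))
  if (!focal_tissue %in% tissues)
    stop("unknown focal tissue: ", focal_tissue)
  dt <- data.table::as.data.table(profiles)
  glob <- dt[is_global == TRUE, gene_id]
  nong <- dt[is_global == FALSE]
  in_focal <- nong[get(focal_tissue) == TRUE, gene_id]
  out_focal <- nong[get(focal_tissue) == FALSE, gene_id]
  structure(list(global_set = glob,
                 nonglobal_set = nong$gene_id,
                 nonglobal_expressed_in_focal = in_focal,
                 nonglobal_not_expressed_in_focal = out_focal,
                 focal_tissue = focal_tissue),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf(
    "<gene_partition> focal=%s: %d global, %d non-global (%d in focal, %d not)\n",
    x$focal_tissue, length(x$global_set), length(x$nonglobal_set),
    length(x$nonglobal_expressed_in_focal),
    length(x$nonglobal_not_expressed_in_focal)))
  invisible(x)
}

#' Expression-breadth histogram for a flagged gene set, with tests
#'
#' Bins genes by breadth (default bins 0, 1-3, 4-6, 7-9, 10-12, 13-15, 16)
#' and contrasts the within-bin frequencies of a flagged gene set (e.g.
#' known cancer genes) against all other profiled genes. Two 2x2 chi-square
#' tests are reported: enrichment of flagged genes in the 16-tissue
#' (globally expressed) bin and in the 0-3-tissue (tissue-specific or
#' unexpressed) bins.
#'
#' @param profiles Output of [compute_breadth()].
#' @param flag_set Non-empty character vector of flagged gene ids (subset of
#'   the profiled genes).
#' @param bins Named list of breadth values per bin.
#' @return A list of class `breadth_histogram` with elements `table`
#'   (per-bin counts and frequencies for both groups), `test_global` and
#'   `test_specific` (each a list with `chi2_stat`, `p_value`,
#'   `fold_enrichment`, or `refused = TRUE` when a group is too small).
#' @export
breadth_histogram <- function(profiles, flag_set,
                              bins = DEFAULT_BREADTH_BINS) {
  dt <- data.table::as.data.table(profiles)
  if (!length(flag_set)) stop("empty flag_set")
  extra <- setdiff(flag_set, dt$gene_id)
  if (length(extra)) stop("flag_set contains unprofiled gene(s): ",
                          paste(head(extra, 5), collapse = ", "))
  dt[, flagged := gene_id %in% flag_set]
  bin_of <- rep(NA_character_, N_TISSUES + 1L)
  for (nm in names(bins)) bin_of[bins[[nm]] + 1L] <- nm
  dt[, bin := factor(bin_of[breadth + 1L], levels = names(bins))]
  tab <- dt[, .(flagged_count = sum(flagged), other_count = sum(!flagged)),
            by = bin][order(bin)]
  tab <- tab[data.table::data.table(bin = factor(names(bins),
                                                 levels = names(bins))),
             on = "bin"]
  tab[is.na(flagged_count), flagged_count := 0L]
  tab[is.na(other_count), other_count := 0L]
  n_flag <- sum(tab$flagged_count); n_other <- sum(tab$other_count)
  tab[, `:=`(flagged_freq = flagged_count / n_flag,
             other_freq = other_count / n_other)]
  bin_test <- function(in_bin_flagged, in_bin_other) {
    if (n_flag < 2L || n_other < 2L)
      return(list(refused = TRUE,
                  reason = "fewer than 2 genes in a group"))
    m <- matrix(c(in_bin_flagged, n_flag - in_bin_flagged,
                  in_bin_other, n_other - in_bin_other), nrow = 2,
                byrow = TRUE)
    ct <- chi2_2x2(m)
    list(refused = FALSE, chi2_stat = ct$statistic, p_value = ct$p_value,
         fold_enrichment = (in_bin_flagged / n_flag) /
           (in_bin_other / n_other))
  }
  breadth_flagged <- dt[flagged == TRUE, breadth]
  breadth_other <- dt[flagged == FALSE, breadth]
  res <- list(
    table = tab[],
    test_global = bin_test(sum(breadth_flagged == 16L),
                           sum(breadth_other == 16L)),
    test_specific = bin_test(sum(breadth_flagged <= 3L),
                             sum(breadth_other <= 3L)))
  class(res) <- "breadth_histogram"
  res
}

#' @export
print.breadth_histogram <- function(x, ...) {
  cat("<breadth_histogram>\n")
  print(as.data.frame(x$table), row.names = FALSE)
  for (nm in c("test_global", "test_specific")) {
    t <- x[[nm]]
    if (isTRUE(t$refused)) cat(nm, ": refused (", t$reason, ")\n", sep = "")
    else cat(sprintf("%s: fold=%.2f chi2=%.2f p=%.3g\n", nm,
                     t$fold_enrichment, t$chi2_stat, t$p_value))
  }
  invisible(x)
}
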