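## Per-gene counting of non-synonymous/synonymous and MF/LF sites.
##
## Counting is unweighted: every coding position has three possible alternate
## bases and each possible change contributes 1/3 of a site to its effect
## class. The sum of non-synonymous (N) and synonymous (S) sites therefore
## equals the counted coding length. Stop-gain possible changes alter the
## protein and count toward N, but are outside the domain of the functional
## predictors and so contribute to neither MF nor LF.

#' Count non-synonymous and synonymous sites of a gene
#'
#' For each coding position the proportion of possible single-base changes
#' that are non-synonymous (missense or stop-gain) contributes to N and the
#' synonymous proportion to S; proportions are summed over the gene.
#' A terminal stop codon is excluded from counting; codons containing
#' ambiguity codes are skipped whole (and logged via `message`).
#'
#' @param gene A [gene_model()].
#' @return A one-row `data.frame` with columns `gene_id`, `N`, `S`,
#'   `n_codons_counted`. Always `N + S == 3 * n_codons_counted`.
#' @examples
#' g <- gene_model("G1", "T1", "ATGTTT")
#' count_syn_nonsyn_sites(g)  # ATG: N=3; TTT: N=8/3, S=1/3
#' @export
count_syn_nonsyn_sites <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  cds <- strip_terminal_stop(gene$cds)
  n_codon_total <- nchar(cds) %/% 3L
  ch <- cds_change_table(cds)
  counted <- length(unique(ch$codon_idx))
  if (counted < n_codon_total)
    message(sprintf("%s: skipped %d codon(s) with ambiguity codes",
                    gene$gene_id, n_codon_total - counted))
  data.frame(
    gene_id = gene$gene_id,
    N = sum(ch$effect %in% c("missense", "nonsense")) / 3,
    S = sum(ch$effect == "synonymous") / 3,
    n_codons_counted = counted)
}

#' Read a functionality table
#'
#' Functionality tables score every possible amino-acid alteration of a
#' protein. Two schemes are supported: `SIFT_like` tables carry a numeric
#' `score` in `[0, 1]` (a change is more functional, MF, when
#' `score <= 0.05`); `POLYPHEN_like` tables carry a `class` in
#' `benign` / `possibly_damaging` / `probably_damaging` (MF when possibly or
#' probably damaging).
#'
#' @param path TSV with columns `gene_id`, `protein_pos`, `alt_aa` and either
#'   `score` (SIFT_like) or `class` (POLYPHEN_like).
#' @param scheme `"SIFT_like"` or `"POLYPHEN_like"`.
#' @return A `functionality_table`: a keyed data.table with attribute
#'   `scheme`.
#' @export
read_functionality_table <- function(path, scheme = c("SIFT_like", "POLYPHEN_like")) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop("functionality table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "gene_id", integer = "protein_pos", character = "alt_aa"))
  functionality_table(dt, scheme)
}

#' Construct a functionality table from a data frame
#'
#' @param entries Data frame with columns `gene_id`, `protein_pos`, `alt_aa`
#'   and `score` (SIFT_like) or `class` (POLYPHEN_like).
#' @param scheme `"SIFT_like"` or `"POLYPHEN_like"`.
#' @return A `functionality_table` object.
#' @export
functionality_table <- function(entries, scheme = c("SIFT_like", "POLYPHEN_like")) {
  scheme <- match.arg(scheme)
  dt <- data.table::as.data.table(entries)
  need <- c("gene_id", "protein_pos", "alt_aa",
            if (scheme == "SIFT_like") "score" else "class")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("functionality table lacks column(s): ",
                         paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  if (scheme == "SIFT_like") {
    if (any(!is.finite(dt$score)) || any(dt$score < 0 | dt$score > 1))
      stop("SIFT_like scores must lie in [0, 1]")
    dt[, func_class := data.table::fifelse(score <= 0.05, "MF", "LF")]
  } else {
    bad <- setdiff(unique(dt$class),
                   c("benign", "possibly_damaging", "probably_damaging"))
    if (length(bad)) stop("unknown POLYPHEN_like class(es): ",
                          paste(bad, collapse = ", "))
    dt[, func_class := data.table::fifelse(class == "benign", "LF", "MF")]
  }
  data.table::setkeyv(dt, c("gene_id", "protein_pos", "alt_aa"))
  structure(dt[], class = c("functionality_table", class(dt)),
            scheme = scheme)
}

func_table_scheme <- function(table) {
  s <- attr(table, "scheme")
  if (is.null(s)) stop("not a functionality_table: missing scheme attribute")
  s
}

#' Count more-functional and less-functional sites of a gene
#'
#' Each possible missense change of each counted codon contributes 1/3 of a
#' site to MF when the functionality table classes it as more functional
#' (SIFT-like score <= 0.05, or a possibly/probably damaging PolyPhen-like
#' class), and 1/3 to LF otherwise. Synonymous and stop-gain possible changes
#' contribute to neither; missense changes without a table entry contribute
#' to neither and are logged.
#'
#' @param gene A [gene_model()].
#' @param table A `functionality_table` (see [functionality_table()]).
#' @param scheme Optional scheme check; errors if it disagrees with the
#'   table's own scheme.
#' @return One-row `data.frame` with `gene_id`, `MF`, `LF`, `n_unscored`
#'   (count of missense possible changes lacking a table entry) and `scheme`.
#' @export
count_functional_sites <- function(gene, table, scheme = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  tab_scheme <- func_table_scheme(table)
  if (!is.null(scheme) && !identical(scheme, tab_scheme))
    stop("scheme mismatch: table is ", tab_scheme, ", requested ", scheme)
  if (nrow(table) == 0L)
    warning("empty functionality table: MF = LF = 0 for ", gene$gene_id)
  cds <- strip_terminal_stop(gene$cds)
  ch <- cds_change_table(cds)[effect == "missense"]
  if (nrow(ch) == 0L)
    return(data.frame(gene_id = gene$gene_id, MF = 0, LF = 0,
                      n_unscored = 0L, scheme = tab_scheme))
  lk <- table[ch[, .(gene_id = gene$gene_id, protein_pos = aa_pos, alt_aa)],
              on = c("gene_id", "protein_pos", "alt_aa")]
  unscored <- sum(is.na(lk$func_class))
  if (unscored > 0L)
    message(sprintf("%s: %d missense change(s) unscored under %s",
                    gene$gene_id, unscored, tab_scheme))
  data.frame(
    gene_id = gene$gene_id,
    MF = sum(lk$func_class == "MF", na.rm = TRUE) / 3,
    LF = sum(lk$func_class == "LF", na.rm = TRUE) / 3,
    n_unscored = unscored,
    scheme = tab_scheme)
}

#' Count all site classes for a set of gene models
#'
#' Vectorised driver combining [count_syn_nonsyn_sites()] and
#' [count_functional_sites()] over many genes: per gene, non-synonymous (N)
#' and synonymous (S) sites, and MF/LF site totals under the SIFT-like and
#' PolyPhen-like schemes.
#'
#' @param models Named list of gene models, one per gene (see
#'   [select_longest_transcript()]).
#' @param sift_table,pph_table `functionality_table`s for the two schemes
#'   (either may be `NULL`, leaving the matching MF/LF columns `NA`).
#' @return A data.table with one row per gene: `gene_id`, `N`, `S`,
#'   `MF_sift`, `LF_sift`, `MF_pph`, `LF_pph`, `n_codons_counted`.
#' @export
count_sites <- function(models, sift_table = NULL, pph_table = NULL) {
  if (!length(models)) return(empty_site_counts())
  if (!is.null(sift_table) && func_table_scheme(sift_table) != "SIFT_like")
    stop("`sift_table` must be SIFT_like")
  if (!is.null(pph_table) && func_table_scheme(pph_table) != "POLYPHEN_like")
    stop("`pph_table` must be POLYPHEN_like")
  gc_dt <- gene_codon_dt(models)
  skipped <- gc_dt[, sum(!ok), by = gene_id]
  if (any(skipped$V1 > 0))
    message(sprintf("skipped %d codon(s) with ambiguity codes across %d gene(s)",
                    sum(skipped$V1), sum(skipped$V1 > 0)))
  gc_dt <- gc_dt[ok == TRUE]
  summ <- codon_summary_table()[gc_dt, on = "codon"]
  base <- summ[, .(N = sum(n_mis + n_non) / 3, S = sum(n_syn) / 3,
                   n_codons_counted = .N), by = gene_id]
  mis <- codon_missense_aa_table()[gc_dt, on = "codon",
                                   allow.cartesian = TRUE]
  mis <- mis[!is.na(alt_aa),
             .(gene_id, protein_pos = aa_pos, alt_aa, mult)]
  add_scheme <- function(tab, mf_col, lf_col) {
    if (is.null(tab)) {
      base[, (mf_col) := NA_real_]; base[, (lf_col) := NA_real_]
      return(invisible(NULL))
    }
    lk <- tab[mis, on = c("gene_id", "protein_pos", "alt_aa")]
    agg <- lk[, .(MF = sum(mult * (func_class == "MF"), na.rm = TRUE) / 3,
                  LF = sum(mult * (func_class == "LF"), na.rm = TRUE) / 3),
              by = gene_id]
    base[agg, (mf_col) := i.MF, on = "gene_id"]
    base[agg, (lf_col) := i.LF, on = "gene_id"]
    base[is.na(get(mf_col)), (mf_col) := 0]
    base[is.na(get(lf_col)), (lf_col) := 0]
    invisible(NULL)
  }
  add_scheme(sift_table, "MF_sift", "LF_sift")
  add_scheme(pph_table, "MF_pph", "LF_pph")
  data.table::setcolorder(base, c("gene_id", "N", "S", "MF_sift", "LF_sift",
                                  "MF_pph", "LF_pph", "n_codons_counted"))
  data.table::setorder(base, gene_id)
  base[]
}

empty_site_counts <- function() {
  data.table::data.table(
    gene_id = character(), N = numeric(), S = numeric(),
    MF_sift = numeric(), LF_sift = numeric(), MF_pph = numeric(),
    LF_pph = numeric(), n_codons_counted = integer())
}

#' Write / read per-gene site counts as TSV
#'
#' @param site_counts Output of [count_sites()].
#' @param path TSV path.
#' @return Invisibly `path` (write) or the site-counts data.table (read).
#' @export
write_site_counts <- function(site_counts, path) {
  data.table::fwrite(site_counts, path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  if (!file.exists(path)) stop("site counts file not found: ", path)
  data.table::fread(path, sep = "\t", colClasses = list(character = "gene_id"))
}
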