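## Codon-level enumeration of possible single-base changes.
## All counting in the package is unweighted: each coding position has three
## possible alternate bases, each contributing 1/3 of a site to the effect
## class of the change it produces (standard genetic code only).

BASES <- c("A", "C", "G", "T")

## cache for the 576-row (64 codons x 9 changes) lookup table
.somaselect_env <- new.env(parent = emptyenv())

#' Standard genetic code as a named character vector
#'
#' Thin wrapper around [Biostrings::GENETIC_CODE] (translation table 1);
#' stop codons translate to `"*"`.
#'
#' @return Named character vector of length 64 mapping codons to amino acids.
#' @export
standard_genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

## Full enumeration over all 64 codons: one row per (codon, offset, alt).
## Columns: codon, offset (0..2 within codon), ref, alt, alt_codon, ref_aa,
## alt_aa, effect. Effects for stop-codon references are marked "ref_stop"
## and are never used in counting (stop codons are rejected upstream).
codon_change_table <- function() {
  if (!is.null(.somaselect_env$changes)) return(.somaselect_env$changes)
  gc_tab <- standard_genetic_code()
  codons <- names(gc_tab)
  grid <- data.table::CJ(codon = codons, offset = 0:2, alt = BASES)
  grid[, ref := substr(codon, offset + 1L, offset + 1L)]
  grid <- grid[ref != alt]
  grid[, alt_codon := {
    x <- codon
    substr(x, offset + 1L, offset + 1L) <- alt
    x
  }]
  grid[, ref_aa := unname(gc_tab[codon])]
  grid[, alt_aa := unname(gc_tab[alt_codon])]
  grid[, effect := data.table::fifelse(
    ref_aa == "*", "ref_stop",
    data.table::fifelse(alt_aa == "*", "nonsense",
      data.table::fifelse(alt_aa == ref_aa, "synonymous", "missense")))]
  data.table::setkey(grid, codon)
  .somaselect_env$changes <- grid[]
  grid[]
}

#' Enumerate the possible single-base changes of a codon
#'
#' A "possible change" is any substitution of one codon base by one of the
#' three alternate bases, so every codon has exactly 9 possible changes. Each
#' change is labelled by translating the mutated codon with the standard
#' genetic code: `synonymous` (same amino acid), `missense` (different amino
#' acid) or `nonsense` (stop gained).
#'
#' @param codon Single 3-letter DNA string of unambiguous bases (A/C/G/T);
#'   must not be a stop codon.
#' @return A `data.frame` with 9 rows and columns `offset` (0-based position
#'   within the codon), `ref`, `alt` (single bases), `alt_codon`, `ref_aa`,
#'   `alt_aa`, and `effect` (one of `"synonymous"`, `"missense"`,
#'   `"nonsense"`).
#' @examples
#' enumerate_possible_changes("ATG")   # 9 changes, none synonymous
#' enumerate_possible_changes("TGG")   # includes the two stop gains
#' @export
enumerate_possible_changes <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("`codon` must be a single 3-letter DNA string")
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% BASES))
    stop("ambiguous or invalid base in codon '", codon, "': codon skipped")
  gc_tab <- standard_genetic_code()
  if (gc_tab[[codon]] == "*")
    stop("stop codon '", codon, "' rejected: not a countable reference codon")
  out <- codon_change_table()[codon]
  data.table::setDF(out[order(offset, alt),
    .(offset, ref, alt, alt_codon, ref_aa, alt_aa, effect)])
}

## Explode a CDS into its per-change table. `cds` is assumed validated
## (see validate_cds); codons containing ambiguity codes yield no rows.
## Returns a data.table with one row per possible change:
## codon_idx (1-based), cds_pos (1-based), codon, offset, ref, alt, effect,
## aa_pos, ref_aa, alt_aa.
cds_change_table <- function(cds, skip_ambiguous = TRUE) {
  stopifnot(nchar(cds) %% 3 == 0)
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) return(empty_change_table())
  cod <- substring(cds, seq(1L, by = 3L, length.out = n_codon),
                   seq(3L, by = 3L, length.out = n_codon))
  dt <- data.table::data.table(codon_idx = seq_len(n_codon), codon = cod)
  ambiguous <- !grepl("^[ACGT]{3}$", dt$codon)
  if (any(ambiguous)) {
    if (!skip_ambiguous) stop("codon with ambiguity code at codon ",
                              paste(which(ambiguous), collapse = ","))
    dt <- dt[!ambiguous]
  }
  out <- codon_change_table()[dt, on = "codon", allow.cartesian = TRUE]
  out[, cds_pos := (codon_idx - 1L) * 3L + offset + 1L]
  out[, aa_pos := codon_idx]
  out[, .(codon_idx, cds_pos, codon, offset, ref, alt, alt_codon,
          ref_aa, alt_aa, effect, aa_pos)]
}

empty_change_table <- function() {
  data.table::data.table(
    codon_idx = integer(), cds_pos = integer(), codon = character(),
    offset = integer(), ref = character(), alt = character(),
    alt_codon = character(), ref_aa = character(), alt_aa = character(),
    effect = character(), aa_pos = integer())
}

## Per-codon change-class totals (64 rows): n_syn, n_mis, n_non out of the
## 9 possible changes. Cached.
codon_summary_table <- function() {
  if (!is.null(.somaselect_env$summary)) return(.somaselect_env$summary)
  ch <- codon_change_table()
  out <- ch[, .(n_syn = sum(effect == "synonymous"),
                n_mis = sum(effect == "missense"),
                n_non = sum(effect == "nonsense")), by = codon]
  data.table::setkey(out, codon)
  .somaselect_env$summary <- out[]
  out[]
}

## Per-codon missense amino-acid alterations with nucleotide-change
## multiplicity (several single-base changes of one codon can yield the same
## amino acid). Cached; ~450 rows.
codon_missense_aa_table <- function() {
  if (!is.null(.somaselect_env$mis_aa)) return(.somaselect_env$mis_aa)
  ch <- codon_change_table()
  out <- ch[effect == "missense", .(mult = .N), by = .(codon, alt_aa)]
  data.table::setkey(out, codon)
  .somaselect_env$mis_aa <- out[]
  out[]
}

## Big (gene_id, aa_pos, codon) table over a list of gene models, terminal
## stop codons stripped; ambiguity-containing codons marked (ok = FALSE).
gene_codon_dt <- function(models) {
  cds <- vapply(models, function(m) strip_terminal_stop(m$cds), "")
  gid <- vapply(models, `[[`, "", "gene_id")
  ncod <- nchar(cds) %/% 3L
  dt <- data.table::data.table(
    gene_id = rep(gid, ncod),
    aa_pos = unlist(lapply(ncod, seq_len), use.names = FALSE))
  starts <- (dt$aa_pos - 1L) * 3L + 1L
  dt[, codon := substring(rep(cds, ncod), starts, starts + 2L)]
  dt[, ok := grepl("^[ACGT]{3}$", codon)]
  dt[]
}

## Translate a vector of codons; ambiguity codes give NA.
translate_codons <- function(codons) {
  gc_tab <- standard_genetic_code()
  out <- unname(gc_tab[codons])
  out[!grepl("^[ACGT]{3}$", codons)] <- NA_character_
  out
}
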