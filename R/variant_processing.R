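## Parsing, classification, deduplication and filtering of somatic and
## germline substitutions, and group-level tallies.
##
## Records are rows of a data.table ("substitution records") with columns:
##   patient_id (empty string for germline), gene_id, transcript_id,
##   cds_pos (1-based), ref, alt, effect (synonymous/missense/nonsense, NA
##   for frameshift events), frameshift_flag, func_class_sift,
##   func_class_pph (MF/LF/unscored/not_applicable), allele_freq (NA for
##   somatic).

record_columns <- c("patient_id", "gene_id", "transcript_id", "cds_pos",
                    "ref", "alt", "effect", "frameshift_flag",
                    "func_class_sift", "func_class_pph", "allele_freq")

empty_records <- function() {
  data.table::data.table(
    patient_id = character(), gene_id = character(),
    transcript_id = character(), cds_pos = integer(), ref = character(),
    alt = character(), effect = character(), frameshift_flag = logical(),
    func_class_sift = character(), func_class_pph = character(),
    allele_freq = numeric())
}

#' Read a minimal MAF-style somatic substitution table
#'
#' @param path TSV with columns `patient_id`, `gene_id`, `transcript_id`,
#'   `cds_pos`, `ref`, `alt`, `variant_class` (`SNV` or `frameshift_indel`).
#' @return A data.table of raw (unclassified) substitution records;
#'   frameshift rows have `frameshift_flag = TRUE` and `NA` effect.
#' @export
read_somatic_tsv <- function(path) {
  if (!file.exists(path)) stop("somatic substitution table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("patient_id", "gene_id", "transcript_id", "ref", "alt",
                  "variant_class"),
    integer = "cds_pos"))
  need <- c("patient_id", "gene_id", "transcript_id", "cds_pos", "ref",
            "alt", "variant_class")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("somatic table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$variant_class), c("SNV", "frameshift_indel"))
  if (length(bad)) stop("unknown variant_class value(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  dt[, frameshift_flag := variant_class == "frameshift_indel"]
  dt[, `:=`(effect = NA_character_,
            func_class_sift = "not_applicable",
            func_class_pph = "not_applicable",
            allele_freq = NA_real_)]
  dt[, variant_class := NULL]
  data.table::setcolorder(dt, record_columns)
  dt[]
}

#' Read a germline variant panel from VCF
#'
#' Expects a sites-only VCF 4.x whose `CHROM` is the transcript id and `POS`
#' the 1-based CDS position, with `AF` (allele frequency) and `GENE` INFO
#' fields — the coordinate convention emitted by
#' [simulate_germline_panel()]. Multi-allelic records are split into one
#' record per alternate allele, each with its own `AF`.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return A data.table of raw substitution records with `patient_id = ""`
#'   and `allele_freq` filled.
#' @note Requires the Bioconductor package \pkg{VariantAnnotation} (a
#'   suggested dependency, loaded on demand to keep package start-up light).
#' @export
read_germline_vcf <- function(path) {
  if (!file.exists(path)) stop("germline VCF not found: ", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_germline_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  if (nrow(vcf) == 0L) return(empty_records())
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  af <- info$AF
  if (is.list(af) || methods::is(af, "List")) af <- as.numeric(unlist(af))
  dt <- data.table::data.table(
    patient_id = "",
    gene_id = as.character(info$GENE),
    transcript_id = as.character(GenomeInfoDb::seqnames(rr)),
    cds_pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    effect = NA_character_,
    frameshift_flag = FALSE,
    func_class_sift = "not_applicable",
    func_class_pph = "not_applicable",
    allele_freq = as.numeric(af))
  ## indels and spanning deletions cannot be classified in CDS space
  dt <- dt[nchar(ref) == 1L & nchar(alt) == 1L & alt %in% BASES]
  dt[]
}

#' Classify substitution records against gene models
#'
#' Fills `effect` by translating the reference and mutated codon at
#' `cds_pos`, and assigns MF/LF functionality classes to missense records
#' from the SIFT-like and PolyPhen-like tables (`unscored` when a table has
#' no entry; `not_applicable` for synonymous/nonsense records and frameshift
#' events). Records whose `ref` does not match the CDS base at `cds_pos`, or
#' whose position is outside the CDS, or whose gene has no model, are
#' rejected.
#'
#' @param records Raw substitution records ([read_somatic_tsv()],
#'   [read_germline_vcf()], or a conforming data frame).
#' @param models Named list of gene models (one per gene).
#' @param sift_table,pph_table Optional `functionality_table`s.
#' @return A list with `kept` (classified records) and `rejected` (records
#'   with a `reject_reason` column). Rejections are logged via `message`.
#' @export
classify_substitutions <- function(records, models, sift_table = NULL,
                                   pph_table = NULL) {
  dt <- data.table::as.data.table(records)
  if (!nrow(dt)) return(list(kept = empty_records(),
                             rejected = cbind(empty_records(),
                                              reject_reason = character())))
  if (!"frameshift_flag" %in% names(dt)) {
    if ("variant_class" %in% names(dt)) {
      dt[, frameshift_flag := variant_class == "frameshift_indel"]
      dt[, variant_class := NULL]
    } else dt[, frameshift_flag := FALSE]
  }
  if (!"allele_freq" %in% names(dt)) dt[, allele_freq := NA_real_]
  if (!"patient_id" %in% names(dt)) dt[, patient_id := ""]
  dt[, `:=`(effect = NA_character_, alt_aa = NA_character_,
            aa_pos = NA_integer_)]
  cds_map <- vapply(models, `[[`, "", "cds")
  names(cds_map) <- vapply(models, `[[`, "", "gene_id")
  dt[, cds := cds_map[gene_id]]
  dt[, reject_reason := NA_character_]
  dt[is.na(cds), reject_reason := "no_gene_model"]
  snv <- !dt$frameshift_flag
  dt[snv & is.na(reject_reason) &
       (cds_pos < 1L | cds_pos > nchar(cds)),
     reject_reason := "position_out_of_range"]
  ok <- snv & is.na(dt$reject_reason)
  if (any(ok)) {
    idx0 <- dt$cds_pos[ok] - 1L
    codon_start <- (idx0 %/% 3L) * 3L + 1L
    dt[ok, codon := substr(cds, codon_start, codon_start + 2L)]
    dt[ok, offset := idx0 %% 3L]
    dt[ok, aa_pos := (codon_start - 1L) %/% 3L + 1L]
    ref_base <- substr(dt$codon[ok], dt$offset[ok] + 1L, dt$offset[ok] + 1L)
    mism <- ok
    mism[ok] <- ref_base != dt$ref[ok]
    dt[mism, reject_reason := "ref_mismatch"]
    ok <- snv & is.na(dt$reject_reason)
  }
  if (any(ok)) {
    alt_codon <- dt$codon[ok]
    substr(alt_codon, dt$offset[ok] + 1L, dt$offset[ok] + 1L) <- dt$alt[ok]
    aa_r <- translate_codons(dt$codon[ok])
    aa_a <- translate_codons(alt_codon)
    bad_aa <- ok
    bad_aa[ok] <- is.na(aa_r) | is.na(aa_a) | aa_r == "*"
    dt[bad_aa, reject_reason := "ambiguous_or_stop_codon"]
    keep2 <- ok & is.na(dt$reject_reason)
    sel <- keep2[ok]
    eff <- ifelse(aa_a[sel] == "*", "nonsense",
                  ifelse(aa_a[sel] == aa_r[sel], "synonymous", "missense"))
    aa_keep <- aa_a[sel]
    dt[keep2, `:=`(effect = eff, alt_aa = aa_keep)]
  }
  dt[, `:=`(func_class_sift = "not_applicable",
            func_class_pph = "not_applicable")]
  lookup_class <- function(tab) {
    mis <- which(!is.na(dt$effect) & dt$effect == "missense" &
                   is.na(dt$reject_reason))
    cls <- rep("unscored", length(mis))
    if (!is.null(tab) && length(mis)) {
      key <- dt[mis, .(gene_id, protein_pos = aa_pos, alt_aa)]
      hit <- tab[key, on = c("gene_id", "protein_pos", "alt_aa")]
      cls <- ifelse(is.na(hit$func_class), "unscored", hit$func_class)
    }
    list(idx = mis, cls = cls)
  }
  if (!is.null(sift_table)) {
    if (func_table_scheme(sift_table) != "SIFT_like")
      stop("`sift_table` must be SIFT_like")
    r <- lookup_class(sift_table)
    dt[r$idx, func_class_sift := r$cls]
  } else {
    r <- lookup_class(NULL)
    dt[r$idx, func_class_sift := "unscored"]
  }
  if (!is.null(pph_table)) {
    if (func_table_scheme(pph_table) != "POLYPHEN_like")
      stop("`pph_table` must be POLYPHEN_like")
    r <- lookup_class(pph_table)
    dt[r$idx, func_class_pph := r$cls]
  } else {
    r <- lookup_class(NULL)
    dt[r$idx, func_class_pph := "unscored"]
  }
  rejected <- dt[!is.na(reject_reason),
                 c(record_columns, "reject_reason"), with = FALSE]
  if (nrow(rejected))
    message(sprintf("classify_substitutions: rejected %d record(s) (%s)",
                    nrow(rejected),
                    paste(sprintf("%s=%d", names(table(rejected$reject_reason)),
                                  as.integer(table(rejected$reject_reason))),
                          collapse = ", ")))
  kept <- dt[is.na(reject_reason), record_columns, with = FALSE]
  list(kept = kept[], rejected = rejected[])
}

#' Deduplicate substitutions within a tumor
#'
#' A substitution reported more than once within one patient's tumor is
#' counted once: records are unique by (patient, gene, CDS position, ref,
#' alt). The same substitution observed in *different* patients recurs by
#' independent mutation and every patient's copy is retained.
#'
#' @param records Substitution records.
#' @return Deduplicated records (first occurrence kept; idempotent).
#' @export
deduplicate_within_tumor <- function(records) {
  dt <- data.table::as.data.table(records)
  if (!nrow(dt)) return(dt)
  unique(dt, by = c("patient_id", "gene_id", "cds_pos", "ref", "alt"))
}

#' Remove post-inactivation substitutions per (patient, gene)
#'
#' Once a gene copy is inactivated by a truncating event, further mutations
#' of that gene in that tumor are presumed free of selection. For every
#' (patient, gene) containing a nonsense substitution or a frameshift event,
#' all records of that (patient, gene) are removed — except, by default, the
#' inactivating nonsense substitutions themselves, which are real observed
#' substitutions and are retained (frameshift events are always moved to
#' `removed`; they are not countable substitutions). Set
#' `drop_trigger = TRUE` to also remove the triggering records.
#'
#' @param records Deduplicated somatic substitution records.
#' @param drop_trigger Also remove the triggering nonsense records
#'   (default `FALSE`).
#' @return List with `kept` and `removed`; their union is the input.
#' @export
apply_nonsense_frameshift_filter <- function(records, drop_trigger = FALSE) {
  dt <- data.table::as.data.table(records)
  if (!nrow(dt)) return(list(kept = dt, removed = dt[0]))
  dt[, trigger := (!is.na(effect) & effect == "nonsense") | frameshift_flag]
  dt[, keep := TRUE]
  dt[, keep := !any(trigger) | (trigger & !frameshift_flag & !drop_trigger),
     by = .(patient_id, gene_id)]
  kept <- dt[keep == TRUE][, c("trigger", "keep") := NULL]
  removed <- dt[keep == FALSE][, c("trigger", "keep") := NULL]
  list(kept = kept[], removed = removed[])
}

#' Filter germline records by allele frequency
#'
#' Keeps segregating sites with allele frequency strictly greater than
#' `min_freq`; rarer variants have had little time to be shaped by selection.
#' Each segregating site is counted once, irrespective of its frequency.
#'
#' @param records Germline substitution records with `allele_freq`.
#' @param min_freq Strict lower bound (default 0.1).
#' @return Filtered records; records with missing `allele_freq` are dropped
#'   with a message.
#' @export
filter_germline_by_frequency <- function(records, min_freq = 0.1) {
  dt <- data.table::as.data.table(records)
  if (!nrow(dt)) return(dt)
  n_missing <- sum(is.na(dt$allele_freq))
  if (n_missing)
    message(sprintf(
      "filter_germline_by_frequency: rejected %d record(s) with missing allele_freq",
      n_missing))
  dt[!is.na(allele_freq) & allele_freq > min_freq]
}

#' Tally substitution counts for a gene set
#'
#' Counts, over classified records restricted to `gene_set`:
#' `n` (non-synonymous substitutions: missense plus nonsense), `s`
#' (synonymous), and the MF/LF substitution counts per scheme (over scored
#' missense records only, so `mf + lf <= n`).
#'
#' @param records Classified, filtered substitution records.
#' @param gene_set Character vector of gene ids; `NULL` tallies every gene.
#' @param gene_set_id Label stored on the result.
#' @return A one-row `data.frame` of class `group_counts`.
#' @export
tally_group_counts <- function(records, gene_set = NULL,
                               gene_set_id = "all") {
  dt <- data.table::as.data.table(records)
  if (!is.null(gene_set)) {
    if (!length(gene_set))
      warning("empty gene_set '", gene_set_id, "': zero counts")
    dt <- dt[gene_id %in% gene_set]
  }
  dt <- dt[!is.na(effect)]
  out <- data.frame(
    gene_set_id = gene_set_id,
    n = sum(dt$effect %in% c("missense", "nonsense")),
    s = sum(dt$effect == "synonymous"),
    mf_sift = sum(dt$effect == "missense" & dt$func_class_sift == "MF"),
    lf_sift = sum(dt$effect == "missense" & dt$func_class_sift == "LF"),
    mf_pph = sum(dt$effect == "missense" & dt$func_class_pph == "MF"),
    lf_pph = sum(dt$effect == "missense" & dt$func_class_pph == "LF"))
  class(out) <- c("group_counts", class(out))
  out
}

#' Aggregate per-gene site counts over a gene set
#'
#' @param site_counts Per-gene site counts ([count_sites()]).
#' @param gene_set Character vector of gene ids; `NULL` uses all genes.
#' @param gene_set_id Label stored on the result.
#' @return One-row `data.frame` with summed `N`, `S`, `MF_sift`, `LF_sift`,
#'   `MF_pph`, `LF_pph`.
#' @export
aggregate_site_counts <- function(site_counts, gene_set = NULL,
                                  gene_set_id = "all") {
  dt <- data.table::as.data.table(site_counts)
  if (!is.null(gene_set)) dt <- dt[gene_id %in% gene_set]
  data.frame(
    gene_set_id = gene_set_id,
    N = sum(dt$N), S = sum(dt$S),
    MF_sift = sum(dt$MF_sift), LF_sift = sum(dt$LF_sift),
    MF_pph = sum(dt$MF_pph), LF_pph = sum(dt$LF_pph))
}
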