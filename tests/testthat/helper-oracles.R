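# Independent oracles for site counting and the chi-square statistics.
# These deliberately avoid the package's lookup-table code path: codons are
# translated with Biostrings::translate() and enumeration is done with plain
# loops, so agreement is a genuine cross-check.

.oracle_env <- new.env()

oracle_base_set <- c("A", "C", "G", "T")

# One row per (codon, pos, alt) over all 64 codons, effects labelled via
# Biostrings::translate. Built once per test session.
oracle_change_table <- function() {
  if (!is.null(.oracle_env$tab)) return(.oracle_env$tab)
  codons <- apply(expand.grid(oracle_base_set, oracle_base_set,
                              oracle_base_set), 1, paste, collapse = "")
  rows <- list()
  for (cd in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(oracle_base_set, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- alt
        rows[[length(rows) + 1L]] <- data.frame(
          codon = cd, pos = pos, alt = alt, alt_codon = mut,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  aa_of <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x), no.init.codon = TRUE))
  tab$ref_aa <- aa_of(tab$codon)
  tab$alt_aa <- aa_of(tab$alt_codon)
  tab$effect <- ifelse(tab$ref_aa == "*", "ref_stop",
                ifelse(tab$alt_aa == "*", "nonsense",
                ifelse(tab$alt_aa == tab$ref_aa, "synonymous", "missense")))
  .oracle_env$tab <- tab
  tab
}

oracle_sense_codons <- function() {
  tab <- oracle_change_table()
  sort(unique(tab$codon[tab$ref_aa != "*"]))
}

# Brute-force N/S (and optionally MF/LF) site counts for one CDS string.
# score_fun(gene_id, aa_pos, alt_aa) -> "MF"/"LF"/NA; NULL skips MF/LF.
oracle_site_counts <- function(cds, gene_id = "g", score_fun = NULL) {
  tab <- oracle_change_table()
  n_codon <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  # drop terminal stop, skip ambiguous codons
  if (length(codons) &&
      codons[n_codon] %in% tab$codon[tab$ref_aa == "*"])
    codons <- codons[-n_codon]
  valid <- grepl("^[ACGT]{3}$", codons)
  N <- S <- MF <- LF <- 0
  for (i in which(valid)) {
    ch <- tab[tab$codon == codons[i], ]
    N <- N + sum(ch$effect %in% c("missense", "nonsense")) / 3
    S <- S + sum(ch$effect == "synonymous") / 3
    if (!is.null(score_fun)) {
      mis <- ch[ch$effect == "missense", ]
      for (j in seq_len(nrow(mis))) {
        cls <- score_fun(gene_id, i, mis$alt_aa[j])
        if (is.na(cls)) next
        if (cls == "MF") MF <- MF + 1 / 3 else LF <- LF + 1 / 3
      }
    }
  }
  list(N = N, S = S, MF = MF, LF = LF, n_codons_counted = sum(valid))
}

# Random stop-free CDS of n_codons codons (ATG start for realism).
random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(setdiff(oracle_sense_codons(), "ATG"),
                             n_codons - 1, replace = TRUE), collapse = ""))
}

random_gene_model <- function(gene_id = "G1", n_codons = 20) {
  gene_model(gene_id, paste0("T_", gene_id), random_cds(n_codons))
}

# Minimal record constructor for variant-processing tests.
make_records <- function(patient, gene, pos, ref, alt,
                         effect = NA_character_, frameshift = FALSE,
                         af = NA_real_) {
  data.table::data.table(
    patient_id = patient, gene_id = gene,
    transcript_id = paste0("T_", gene), cds_pos = as.integer(pos),
    ref = ref, alt = alt, effect = effect,
    frameshift_flag = frameshift,
    func_class_sift = "not_applicable", func_class_pph = "not_applicable",
    allele_freq = af)
}

# Fully scored SIFT-like and PolyPhen-like tables for a set of models,
# with deterministic MF assignment via `mf_of(gene, pos, aa)`.
full_tables <- function(models, mf_of = function(g, p, a) TRUE) {
  tab <- oracle_change_table()
  entries <- do.call(rbind, lapply(models, function(m) {
    cds <- m$cds
    n_codon <- nchar(cds) %/% 3
    codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
    out <- list()
    for (i in seq_len(n_codon)) {
      mis <- unique(tab[tab$codon == codons[i] & tab$effect == "missense",
                        "alt_aa"])
      if (length(mis))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = m$gene_id, protein_pos = i, alt_aa = mis,
          stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }))
  is_mf <- mapply(mf_of, entries$gene_id, entries$protein_pos,
                  entries$alt_aa)
  sift <- functionality_table(
    cbind(entries, score = ifelse(is_mf, 0.01, 0.5)), "SIFT_like")
  pph <- functionality_table(
    cbind(entries, class = ifelse(is_mf, "probably_damaging", "benign")),
    "POLYPHEN_like")
  list(sift = sift, pph = pph)
}
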