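## Gene models: one coding transcript per gene.

#' Construct a gene model
#'
#' A gene model carries one coding transcript for one gene: the CDS in coding
#' orientation, identifiers, and annotation flags (cancer gene census
#' membership, predicted essentiality).
#'
#' @param gene_id,transcript_id Character scalars.
#' @param cds CDS string (A/C/G/T plus IUPAC ambiguity codes), length
#'   divisible by 3 and at least 3. A terminal stop codon is allowed (it is
#'   excluded from all site counting); an internal stop codon is an error.
#' @param is_census,is_essential Logical annotation flags.
#' @param validate Validate the CDS (default `TRUE`).
#' @return An object of class `gene_model` (a list).
#' @export
gene_model <- function(gene_id, transcript_id, cds,
                       is_census = FALSE, is_essential = FALSE,
                       validate = TRUE) {
  cds <- toupper(cds)
  if (validate) validate_cds(cds, id = transcript_id)
  structure(
    list(gene_id = as.character(gene_id),
         transcript_id = as.character(transcript_id),
         cds = cds,
         is_census = isTRUE(is_census),
         is_essential = isTRUE(is_essential)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s: %d nt CDS%s%s\n", x$gene_id,
              x$transcript_id, nchar(x$cds),
              if (x$is_census) ", census" else "",
              if (x$is_essential) ", essential" else ""))
  invisible(x)
}

#' Validate a CDS string
#'
#' Checks length (>= 3, divisible by 3), alphabet (IUPAC DNA), and absence of
#' internal stop codons. A terminal stop codon is permitted.
#'
#' @param cds CDS string.
#' @param id Identifier used in error messages.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_cds <- function(cds, id = "<cds>") {
  if (!is.character(cds) || length(cds) != 1L || !nzchar(cds))
    stop("CDS of ", id, " must be a non-empty string")
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS of ", id, " is shorter than one codon")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length of ", id, " (", nchar(cds), ") is not divisible by 3")
  if (grepl("[^ACGTRYSWKMBDHVN]", cds))
    stop("CDS of ", id, " contains non-IUPAC characters")
  n_codon <- nchar(cds) %/% 3L
  cod <- substring(cds, seq(1L, by = 3L, length.out = n_codon),
                   seq(3L, by = 3L, length.out = n_codon))
  aa <- translate_codons(cod)
  internal_stop <- which(!is.na(aa) & aa == "*")
  internal_stop <- internal_stop[internal_stop < n_codon]
  if (length(internal_stop))
    stop("CDS of ", id, " has internal stop codon(s) at codon ",
         paste(internal_stop, collapse = ","))
  invisible(TRUE)
}

## Strip a terminal stop codon, if present, before site counting.
strip_terminal_stop <- function(cds) {
  n <- nchar(cds)
  last <- substr(cds, n - 2L, n)
  aa <- translate_codons(last)
  if (!is.na(aa) && aa == "*") substr(cds, 1L, n - 3L) else cds
}

#' Read gene models from a CDS FASTA file
#'
#' Headers are expected as `>transcript_id gene=gene_id` (first token is the
#' transcript id; a `gene=` attribute names the gene; without one the
#' transcript id doubles as the gene id). Census/essentiality flags may be
#' supplied as character vectors of gene ids.
#'
#' @param path FASTA file with one CDS per transcript.
#' @param census_genes,essential_genes Character vectors of flagged gene ids.
#' @param validate Validate each CDS (default `TRUE`).
#' @return A list of [gene_model()] objects (possibly several per gene; see
#'   [select_longest_transcript()]).
#' @export
read_cds_fasta <- function(path, census_genes = character(),
                           essential_genes = character(), validate = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  tx <- sub("\\s.*$", "", headers)
  gene <- ifelse(grepl("gene=", headers),
                 sub("^.*gene=([^ ]+).*$", "\\1", headers), tx)
  lapply(seq_along(seqs), function(i) {
    gene_model(gene[i], tx[i], as.character(seqs[[i]]),
               is_census = gene[i] %in% census_genes,
               is_essential = gene[i] %in% essential_genes,
               validate = validate)
  })
}

#' Write gene models to a CDS FASTA file
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cds_fasta <- function(models, path) {
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, "", "cds"))
  names(seqs) <- vapply(models, function(m)
    sprintf("%s gene=%s", m$transcript_id, m$gene_id), "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Select the longest transcript per gene
#'
#' Keeps exactly one transcript per gene: the one with the longest CDS, so
#' that a substitution within one patient is never counted twice through
#' overlapping transcripts. Length ties break to the lexicographically
#' smallest transcript id.
#'
#' @param models List of [gene_model()] objects (at least one per gene).
#' @return A named list of gene models, one per gene (names are gene ids,
#'   sorted).
#' @export
select_longest_transcript <- function(models) {
  if (!length(models)) return(structure(list(), names = character()))
  dt <- data.table::data.table(
    idx = seq_along(models),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    cds_len = vapply(models, function(m) nchar(m$cds), 0L))
  data.table::setorder(dt, gene_id, -cds_len, transcript_id)
  pick <- dt[, .SD[1L], by = gene_id]
  out <- models[pick$idx]
  names(out) <- pick$gene_id
  out
}
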