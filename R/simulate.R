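## Synthetic-data generators: coding gene models, SIFT-like / PolyPhen-like
## functionality tables, somatic tumor cohorts, germline panels and tissue
## expression matrices, with the statistical structure the estimators assume.
##
## Selection is modeled as acceptance sampling on raw mutations: synonymous
## changes are always retained; non-synonymous changes are retained with
## probability `nonsyn_retention` (purifying strength; 1 = neutral), with
## more-functional missense changes boosted by `mf_boost` (positive
## selection). Mutations fall uniformly over coding positions with the three
## alternate bases equally likely — the same unweighted model the site
## counting assumes.
##
## Each generator reseeds the RNG from `config$seed` plus a fixed offset, so
## any generator is bit-reproducible given the same config and upstream
## objects.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generators.
#' Defaults describe a desk-scale breast-tumor-like cohort; see the methods
#' vignette for the rationale behind each value.
#'
#' @param n_genes Number of genes (default 200).
#' @param cds_length_range Min/max CDS length in nt (default 300-1500;
#'   lengths are drawn uniformly from the multiples of 3 in range).
#' @param gc_content GC fraction of generated CDS (default 0.52, typical of
#'   human coding sequence).
#' @param n_patients Number of tumors in a somatic cohort (default 300).
#' @param mutation_rate Expected raw somatic mutations per patient per Mb of
#'   CDS (default 30; desk-scale cohorts use a higher per-Mb rate than real
#'   exomes so that totals are statistically useful).
#' @param nonsyn_retention Retention probability of non-synonymous changes
#'   in the somatic cohort (1 = neutral).
#' @param mf_boost Multiplier (>= 1) on the retention of more-functional
#'   missense changes; `nonsyn_retention * mf_boost` is clipped to 1 with a
#'   warning.
#' @param mf_fraction Fraction of possible amino-acid changes scored as more
#'   functional (default 0.5).
#' @param scheme_agreement Probability that the PolyPhen-like class agrees
#'   with the SIFT-like class for a given change (default 0.9).
#' @param global_fraction Fraction of genes globally expressed (default 0.4,
#'   matching the background rate of global expression among human genes).
#' @param census_fraction Fraction of genes flagged as known cancer genes
#'   (default 0.025, the census share of the screened human gene set).
#' @param essential_fraction Fraction of genes flagged essential
#'   (default 0.2).
#' @param nonsense_rate Probability per (patient, gene) of a planted
#'   nonsense event on top of naturally arising stop gains (default 0).
#' @param frameshift_rate Probability per (patient, gene) of a planted
#'   frameshift indel (default 0.001).
#' @param dup_rate Fraction of retained somatic records duplicated within
#'   the same patient, to exercise deduplication (default 0.01).
#' @param alt_transcript_fraction Fraction of genes given an additional,
#'   shorter transcript, to exercise longest-transcript selection
#'   (default 0.1).
#' @param germline_density Expected segregating germline sites per coding
#'   bp before selection (default 0.02).
#' @param germline_nonsyn_retention Retention of non-synonymous germline
#'   variants (default 0.2: strong purifying selection, matching the
#'   germline dN/dS of common human polymorphism).
#' @param germline_af_alpha_beta Beta(alpha, beta) parameters of germline
#'   allele frequencies (default c(0.25, 2): a spectrum dominated by rare
#'   alleles).
#' @param focal_tissue Name of the tumor's tissue of origin among
#'   `tissue01..tissue16` (default `"tissue01"`).
#' @param seed Integer master seed; fully determines all outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       cds_length_range = c(300L, 1500L),
                       gc_content = 0.52,
                       n_patients = 300L,
                       mutation_rate = 30,
                       nonsyn_retention = 1,
                       mf_boost = 1,
                       mf_fraction = 0.5,
                       scheme_agreement = 0.9,
                       global_fraction = 0.4,
                       census_fraction = 0.025,
                       essential_fraction = 0.2,
                       nonsense_rate = 0,
                       frameshift_rate = 0.001,
                       dup_rate = 0.01,
                       alt_transcript_fraction = 0.1,
                       germline_density = 0.02,
                       germline_nonsyn_retention = 0.2,
                       germline_af_alpha_beta = c(0.25, 2),
                       focal_tissue = "tissue01",
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), cds_length_range = as.integer(cds_length_range),
    gc_content = gc_content, n_patients = as.integer(n_patients),
    mutation_rate = mutation_rate, nonsyn_retention = nonsyn_retention,
    mf_boost = mf_boost, mf_fraction = mf_fraction,
    scheme_agreement = scheme_agreement, global_fraction = global_fraction,
    census_fraction = census_fraction, essential_fraction = essential_fraction,
    nonsense_rate = nonsense_rate, frameshift_rate = frameshift_rate,
    dup_rate = dup_rate, alt_transcript_fraction = alt_transcript_fraction,
    germline_density = germline_density,
    germline_nonsyn_retention = germline_nonsyn_retention,
    germline_af_alpha_beta = as.numeric(germline_af_alpha_beta),
    focal_tissue = focal_tissue, seed = as.integer(seed))
  probs <- c("nonsyn_retention", "mf_fraction", "scheme_agreement",
             "global_fraction", "census_fraction", "essential_fraction",
             "nonsense_rate", "frameshift_rate", "dup_rate",
             "alt_transcript_fraction", "germline_nonsyn_retention")
  for (p in probs)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("gc_content must lie in (0, 1)")
  if (cfg$n_genes < 0L) stop("n_genes must be non-negative")
  if (cfg$mf_boost < 1) stop("mf_boost must be >= 1")
  if (cfg$mutation_rate < 0 || cfg$germline_density < 0)
    stop("rates must be non-negative")
  if (length(cfg$cds_length_range) != 2L ||
      cfg$cds_length_range[1] > cfg$cds_length_range[2])
    stop("cds_length_range must be an increasing pair")
  if (!length(seq_lengths(cfg$cds_length_range)))
    stop("infeasible cds_length_range: no multiple of 3 >= 6 in range")
  if (length(cfg$germline_af_alpha_beta) != 2L ||
      any(cfg$germline_af_alpha_beta <= 0))
    stop("germline_af_alpha_beta must be two positive reals")
  if (!grepl("^tissue(0[1-9]|1[0-6])$", cfg$focal_tissue))
    stop("focal_tissue must be one of tissue01..tissue16")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "sim_config")
}

## multiples of 3 within range, at least two codons (start + one countable)
seq_lengths <- function(range) {
  lo <- max(6L, range[1])
  if (lo > range[2]) return(integer(0))
  v <- seq.int(lo, range[2])
  v[v %% 3L == 0L]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## matrix of the 3 alternate bases per reference base
ALT_CHOICES <- local({
  m <- t(vapply(c("A", "C", "G", "T"),
                function(b) setdiff(c("A", "C", "G", "T"), b),
                character(3)))
  rownames(m) <- c("A", "C", "G", "T")
  m
})

#' Generate synthetic gene models
#'
#' Draws `n_genes` coding sequences: an ATG start codon followed by sense
#' codons with bases sampled at the configured GC content (stop codons are
#' redrawn, so no internal stops; no terminal stop codon is appended).
#' Census and essentiality flags are sampled independently at their
#' configured fractions. A fraction of genes also receive a second, shorter
#' transcript (a 5' truncation) to exercise longest-transcript selection.
#'
#' @param config A [sim_config()].
#' @return List of [gene_model()] objects (named by transcript id; use
#'   [select_longest_transcript()] to reduce to one per gene).
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0L) return(list())
  lens <- sample(seq_lengths(config$cds_length_range), n, replace = TRUE)
  gcf <- config$gc_content
  base_p <- c(A = (1 - gcf) / 2, C = gcf / 2, G = gcf / 2, T = (1 - gcf) / 2)
  draw_codons <- function(k) {
    cod <- character(0)
    while (length(cod) < k) {
      need <- k - length(cod)
      b <- sample(names(base_p), 3L * ceiling(need * 1.1), replace = TRUE,
                  prob = base_p)
      cand <- apply(matrix(b, nrow = 3L), 2L, paste, collapse = "")
      cod <- c(cod, cand[!cand %in% STOP_CODONS])
    }
    cod[seq_len(k)]
  }
  census <- runif(n) < config$census_fraction
  essential <- runif(n) < config$essential_fraction
  has_alt <- runif(n) < config$alt_transcript_fraction
  models <- vector("list", 0L)
  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    cds <- paste0("ATG", paste(draw_codons(lens[i] %/% 3L - 1L),
                               collapse = ""))
    models[[length(models) + 1L]] <-
      gene_model(gid, sprintf("T%04da", i), cds,
                 is_census = census[i], is_essential = essential[i],
                 validate = FALSE)
    if (has_alt[i] && lens[i] >= 12L) {
      short_len <- (lens[i] %/% 6L) * 3L
      models[[length(models) + 1L]] <-
        gene_model(gid, sprintf("T%04db", i),
                   substr(cds, 1L, max(6L, short_len)),
                   is_census = census[i], is_essential = essential[i],
                   validate = FALSE)
    }
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  models
}

#' Generate SIFT-like and PolyPhen-like functionality tables
#'
#' Scores every possible amino-acid alteration reachable by a single base
#' change in each gene's longest transcript. Each change is more functional
#' (MF) with probability `mf_fraction`; SIFT-like scores are drawn uniformly
#' from (0, 0.05] for MF and (0.05, 1] for LF changes, and the PolyPhen-like
#' class agrees with the SIFT-like class with probability
#' `scheme_agreement` (possibly/probably damaging split at random for MF).
#'
#' @param models Gene models (any transcript set; reduced internally to the
#'   longest per gene).
#' @param config A [sim_config()].
#' @return List with elements `sift` and `pph`, two `functionality_table`s.
#' @export
generate_functionality_tables <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  one <- select_longest_transcript(models)
  entries <- if (length(one)) {
    gc_dt <- gene_codon_dt(one)[ok == TRUE]
    mis <- codon_missense_aa_table()[gc_dt, on = "codon",
                                     allow.cartesian = TRUE]
    unique(mis[!is.na(alt_aa),
               .(gene_id, protein_pos = aa_pos, alt_aa)])
  } else empty_change_table()[, .(gene_id = character(),
                                  protein_pos = integer(),
                                  alt_aa = character())]
  if (!nrow(entries)) {
    sift <- functionality_table(
      data.frame(gene_id = character(), protein_pos = integer(),
                 alt_aa = character(), score = numeric()), "SIFT_like")
    pph <- functionality_table(
      data.frame(gene_id = character(), protein_pos = integer(),
                 alt_aa = character(), class = character()), "POLYPHEN_like")
    return(list(sift = sift, pph = pph))
  }
  k <- nrow(entries)
  is_mf <- runif(k) < config$mf_fraction
  entries[, score := data.table::fifelse(is_mf, runif(k, 0, 0.05),
                                         runif(k, 0.05 + 1e-9, 1))]
  agree <- runif(k) < config$scheme_agreement
  pph_mf <- data.table::fifelse(agree, is_mf, !is_mf)
  entries[, class := data.table::fifelse(
    pph_mf, sample(c("possibly_damaging", "probably_damaging"), k,
                   replace = TRUE), "benign")]
  sift <- functionality_table(
    entries[, .(gene_id, protein_pos, alt_aa, score)], "SIFT_like")
  pph <- functionality_table(
    entries[, .(gene_id, protein_pos, alt_aa, class)], "POLYPHEN_like")
  list(sift = sift, pph = pph)
}

## Draw raw uniform mutations over the concatenated CDS of `one` (a named
## per-gene model list): returns a raw record data.table.
draw_raw_mutations <- function(one, n_draws, patients) {
  lens <- vapply(one, function(m) nchar(m$cds), 0L)
  csum <- cumsum(lens)
  pos_global <- sample.int(csum[length(csum)], n_draws, replace = TRUE)
  gidx <- findInterval(pos_global - 1L, c(0L, csum), rightmost.closed = FALSE)
  cds_pos <- pos_global - c(0L, csum)[gidx]
  cds_vec <- vapply(one, `[[`, "", "cds")[gidx]
  ref <- substring(cds_vec, cds_pos, cds_pos)
  alt <- ALT_CHOICES[cbind(match(ref, c("A", "C", "G", "T")),
                           sample.int(3L, n_draws, replace = TRUE))]
  data.table::data.table(
    patient_id = patients,
    gene_id = vapply(one, `[[`, "", "gene_id")[gidx],
    transcript_id = vapply(one, `[[`, "", "transcript_id")[gidx],
    cds_pos = as.integer(cds_pos), ref = ref, alt = alt)
}

#' Simulate a somatic tumor cohort
#'
#' Raw mutations are placed uniformly over the coding positions of each
#' gene's longest transcript (the three alternate bases equally likely),
#' with the per-patient total Poisson-distributed at
#' `mutation_rate x CDS megabases`. Each raw mutation is then retained with
#' probability 1 (synonymous), `nonsyn_retention` (less-functional missense
#' and nonsense) or `min(1, nonsyn_retention * mf_boost)` (more-functional
#' missense, per the SIFT-like truth table). Planted nonsense and frameshift
#' events and within-patient duplicate records are injected at their
#' configured rates.
#'
#' @param models Gene models.
#' @param tables Output of [generate_functionality_tables()] (may be `NULL`
#'   when `mf_boost == 1`, in which case MF/LF status does not alter
#'   retention).
#' @param config A [sim_config()].
#' @return A MAF-style data.table with columns `patient_id`, `gene_id`,
#'   `transcript_id`, `cds_pos`, `ref`, `alt`, `variant_class`.
#' @export
simulate_somatic_cohort <- function(models, tables, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tables) && config$mf_boost != 1)
    stop("functionality tables are required when mf_boost != 1")
  set.seed(config$seed + 2L)
  one <- select_longest_transcript(models)
  empty <- data.table::data.table(
    patient_id = character(), gene_id = character(),
    transcript_id = character(), cds_pos = integer(), ref = character(),
    alt = character(), variant_class = character())
  if (!length(one) || config$n_patients == 0L) return(empty)
  total_mb <- sum(vapply(one, function(m) nchar(m$cds), 0L)) / 1e6
  n_raw <- rpois(1L, config$n_patients * config$mutation_rate * total_mb)
  patients <- sprintf("P%04d", sample.int(config$n_patients, n_raw,
                                          replace = TRUE))
  raw <- draw_raw_mutations(one, n_raw, patients)
  cl <- classify_substitutions(raw, one,
                               sift_table = if (!is.null(tables)) tables$sift,
                               pph_table = NULL)
  rec <- cl$kept
  p_mf <- min(1, config$nonsyn_retention * config$mf_boost)
  if (config$nonsyn_retention * config$mf_boost > 1)
    warning("nonsyn_retention * mf_boost > 1: clipped to 1")
  prob <- data.table::fcase(
    rec$effect == "synonymous", 1,
    rec$effect == "missense" & rec$func_class_sift == "MF", p_mf,
    default = config$nonsyn_retention)
  rec <- rec[runif(nrow(rec)) < prob]
  out <- rec[, .(patient_id, gene_id, transcript_id, cds_pos, ref, alt,
                 variant_class = "SNV")]
  ## planted gene-inactivation events
  plant <- function(rate) {
    if (rate <= 0) return(NULL)
    grid <- data.table::CJ(patient_id = sprintf("P%04d",
                                                seq_len(config$n_patients)),
                           gene_id = names(one))
    grid[runif(nrow(grid)) < rate]
  }
  np <- plant(config$nonsense_rate)
  if (!is.null(np) && nrow(np)) {
    extra <- data.table::rbindlist(lapply(seq_len(nrow(np)), function(i) {
      m <- one[[np$gene_id[i]]]
      ch <- cds_change_table(strip_terminal_stop(m$cds))[effect == "nonsense"]
      if (!nrow(ch)) return(NULL)
      j <- sample.int(nrow(ch), 1L)
      data.table::data.table(
        patient_id = np$patient_id[i], gene_id = m$gene_id,
        transcript_id = m$transcript_id, cds_pos = ch$cds_pos[j],
        ref = ch$ref[j], alt = ch$alt[j], variant_class = "SNV")
    }))
    out <- rbind(out, extra)
  }
  fs <- plant(config$frameshift_rate)
  if (!is.null(fs) && nrow(fs)) {
    pos <- vapply(fs$gene_id, function(g)
      sample.int(nchar(one[[g]]$cds), 1L), 0L)
    extra <- data.table::data.table(
      patient_id = fs$patient_id, gene_id = fs$gene_id,
      transcript_id = vapply(one[fs$gene_id], `[[`, "", "transcript_id"),
      cds_pos = as.integer(pos),
      ref = substring(vapply(one[fs$gene_id], `[[`, "", "cds"), pos, pos),
      alt = "-", variant_class = "frameshift_indel")
    out <- rbind(out, extra)
  }
  if (config$dup_rate > 0 && nrow(out)) {
    dup_idx <- which(runif(nrow(out)) < config$dup_rate)
    if (length(dup_idx)) out <- rbind(out, out[dup_idx])
  }
  data.table::setorder(out, patient_id, gene_id, cds_pos, alt)
  out[]
}

#' Simulate a germline variant panel
#'
#' Segregating sites are drawn uniformly over coding positions of each
#' gene's longest transcript, thinned by strong purifying selection
#' (`germline_nonsyn_retention` on non-synonymous draws), deduplicated to
#' one record per distinct change, and given allele frequencies drawn from
#' `Beta(alpha, beta)`.
#'
#' @param models Gene models.
#' @param config A [sim_config()].
#' @return A data.table with `gene_id`, `transcript_id`, `cds_pos`, `ref`,
#'   `alt`, `allele_freq`, suitable for [write_germline_vcf()].
#' @export
simulate_germline_panel <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  one <- select_longest_transcript(models)
  empty <- data.table::data.table(
    gene_id = character(), transcript_id = character(), cds_pos = integer(),
    ref = character(), alt = character(), allele_freq = numeric())
  if (!length(one)) return(empty)
  total_len <- sum(vapply(one, function(m) nchar(m$cds), 0L))
  n_raw <- rpois(1L, config$germline_density * total_len)
  if (n_raw == 0L) return(empty)
  raw <- draw_raw_mutations(one, n_raw, patients = "")
  cl <- classify_substitutions(raw, one)
  rec <- cl$kept
  keep_p <- data.table::fifelse(rec$effect == "synonymous", 1,
                                config$germline_nonsyn_retention)
  rec <- rec[runif(nrow(rec)) < keep_p]
  rec <- unique(rec, by = c("transcript_id", "cds_pos", "ref", "alt"))
  rec[, allele_freq := rbeta(.N, config$germline_af_alpha_beta[1],
                             config$germline_af_alpha_beta[2])]
  out <- rec[, .(gene_id, transcript_id, cds_pos, ref, alt, allele_freq)]
  data.table::setorder(out, transcript_id, cds_pos, alt)
  out[]
}

#' Write a germline panel as a sites-only VCF 4.2
#'
#' `CHROM` is the transcript id and `POS` the 1-based CDS position; `AF` and
#' `GENE` are INFO fields. Records sharing (transcript, position, ref) are
#' merged into one multi-allelic line with comma-separated ALT and AF.
#'
#' @param panel Output of [simulate_germline_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_germline_vcf <- function(panel, path) {
  dt <- data.table::as.data.table(panel)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaselect-synthetic",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  if (!nrow(dt)) {
    writeLines(header, path)
    return(invisible(path))
  }
  merged <- dt[, .(alt = paste(alt, collapse = ","),
                   af = paste(formatC(allele_freq, digits = 6,
                                      format = "f"), collapse = ","),
                   gene_id = gene_id[1L]),
               by = .(transcript_id, cds_pos, ref)]
  data.table::setorder(merged, transcript_id, cds_pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s;GENE=%s",
                  merged$transcript_id, merged$cds_pos, merged$ref,
                  merged$alt, merged$af, merged$gene_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a 16-tissue expression matrix
#'
#' Globally expressed genes (probability `global_fraction`) receive values
#' above the RPKM threshold in all 16 tissues; the remainder draw a breadth
#' uniformly from 0-13 tissues, include the focal tissue with probability
#' 0.5, and fill the rest at random. Expressed values are log-normal RPKM
#' (>= 1); unexpressed values are uniform below 1.
#'
#' @param models Gene models.
#' @param config A [sim_config()].
#' @return A data.table with `gene_id` and columns `tissue01..tissue16`.
#' @export
simulate_expression_matrix <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  genes <- names(select_longest_transcript(models))
  tissues <- sprintf("tissue%02d", 1:16)
  n <- length(genes)
  if (!n) {
    out <- data.table::as.data.table(
      c(list(gene_id = character()),
        setNames(rep(list(numeric()), 16L), tissues)))
    return(out)
  }
  is_glob <- runif(n) < config$global_fraction
  expressed <- matrix(FALSE, n, 16L, dimnames = list(NULL, tissues))
  expressed[is_glob, ] <- TRUE
  focal <- config$focal_tissue
  others <- setdiff(tissues, focal)
  for (i in which(!is_glob)) {
    b <- sample(0:13, 1L)
    if (b == 0L) next
    use_focal <- runif(1) < 0.5
    n_other <- b - as.integer(use_focal)
    n_other <- min(n_other, length(others))
    sel <- c(if (use_focal) focal, sample(others, n_other))
    expressed[i, sel] <- TRUE
  }
  vals <- matrix(runif(n * 16L, 0, 0.99), n, 16L,
                 dimnames = list(NULL, tissues))
  k <- sum(expressed)
  vals[expressed] <- pmax(1, exp(rnorm(k, mean = 2, sd = 1)))
  out <- data.table::data.table(gene_id = genes)
  for (t in tissues) out[, (t) := vals[, t]]
  out[]
}

#' Write a simulated cohort's input files
#'
#' Convenience driver: generates gene models, functionality tables, a
#' somatic cohort, a germline panel and an expression matrix from one
#' config, and writes them (FASTA, TSV, VCF, gene-list text files) under
#' `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths (`cds_fasta`, `sift_tsv`, `pph_tsv`,
#'   `somatic_tsv`, `germline_vcf`, `expression_tsv`, `census_txt`,
#'   `essential_txt`, `config_json`).
#' @export
simulate_inputs <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  models <- generate_gene_models(config)
  tables <- generate_functionality_tables(models, config)
  somatic <- simulate_somatic_cohort(models, tables, config)
  germline <- simulate_germline_panel(models, config)
  expr <- simulate_expression_matrix(models, config)
  write_cds_fasta(models, p("cds.fasta"))
  one <- select_longest_transcript(models)
  sift_out <- data.table::as.data.table(tables$sift)[
    , .(gene_id, protein_pos, alt_aa, score)]
  pph_out <- data.table::as.data.table(tables$pph)[
    , .(gene_id, protein_pos, alt_aa, class)]
  data.table::fwrite(sift_out, p("sift.tsv"), sep = "\t")
  data.table::fwrite(pph_out, p("polyphen.tsv"), sep = "\t")
  data.table::fwrite(somatic, p("somatic.tsv"), sep = "\t")
  write_germline_vcf(germline, p("germline.vcf"))
  data.table::fwrite(expr, p("expression.tsv"), sep = "\t")
  census <- names(one)[vapply(one, `[[`, TRUE, "is_census")]
  essential <- names(one)[vapply(one, `[[`, TRUE, "is_essential")]
  writeLines(census, p("census_genes.txt"))
  writeLines(essential, p("essential_genes.txt"))
  jsonlite::write_json(unclass(config), p("config.json"), auto_unbox = TRUE)
  list(cds_fasta = p("cds.fasta"), sift_tsv = p("sift.tsv"),
       pph_tsv = p("polyphen.tsv"), somatic_tsv = p("somatic.tsv"),
       germline_vcf = p("germline.vcf"), expression_tsv = p("expression.tsv"),
       census_txt = p("census_genes.txt"),
       essential_txt = p("essential_genes.txt"),
       config_json = p("config.json"))
}
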