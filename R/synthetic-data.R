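# Synthetic SMT-tagged amplicon data with a complete truth table, and the
# sample-splitting / duplicate-injection experiments built on it.
#
# The generator emulates the study design: ~1,225 targets of ~150 bp,
# deep coverage (negative-binomial per target around the configured mean),
# a random 8- or 12-base tag per template molecule, heterozygous SNPs at
# ~50% allele frequency on a configurable fraction of targets, a
# configurable PCR duplicate rate realised by resampling templates with
# replacement at constant depth, optional poly-T-enriched tag usage bias,
# and independent per-base substitution error.

#' Simulation configuration
#'
#' @param n_targets number of amplicon targets (default 1225).
#' @param insert_length insert length in bp (default 150).
#' @param smt_length tag length, 8 or 12 (default 12).
#' @param primer_length locus-specific primer length (default 25; must be
#'   at least 22 so a full matching window exists).
#' @param read_length sequenced read length (default 151).
#' @param mean_depth mean reads per target (default 1000).
#' @param depth_dispersion negative-binomial size parameter of the
#'   per-target depth law; larger is closer to Poisson (default 20).
#' @param duplicate_rate fraction of reads that are PCR duplicates, in
#'   [0, 0.9] (default 0.1, the median observed in germline samples).
#' @param het_fraction fraction of targets carrying a heterozygous SNP
#'   (default 200/1225, the designed share of common SNP targets).
#' @param error_rate per-base substitution error on the genomic reads
#'   (default 0.005).
#' @param smt_error_rate per-base substitution error on the tag read
#'   (default 0: tags are taken verbatim).
#' @param smt_bias `"none"` (uniform tags) or `"polyT"` (with probability
#'   `bias_weight` a run of `bias_run_length` T's is planted at a random
#'   offset, emulating the observed thymidine-run enrichment).
#' @param bias_weight,bias_run_length poly-T bias parameters.
#' @param gc_range per-target insert GC drawn uniformly in this range.
#' @param max_dist assignment edit-distance bound the design must support.
#' @param seed mandatory seed for every stochastic operation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_targets = 1225L, insert_length = 150L,
                       smt_length = 12L, primer_length = 25L,
                       read_length = 151L, mean_depth = 1000,
                       depth_dispersion = 20, duplicate_rate = 0.1,
                       het_fraction = 200 / 1225, error_rate = 0.005,
                       smt_error_rate = 0, smt_bias = c("none", "polyT"),
                       bias_weight = 0.02, bias_run_length = 6L,
                       gc_range = c(0.3, 0.7), max_dist = 2L, seed = NULL) {
  smt_bias <- match.arg(smt_bias)
  stopifnot(smt_length %in% c(8L, 12L), primer_length >= 22L,
            duplicate_rate >= 0, duplicate_rate <= 0.9,
            het_fraction >= 0, het_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            smt_error_rate >= 0, smt_error_rate <= 1,
            bias_weight >= 0, bias_weight <= 1,
            bias_run_length >= 1L, bias_run_length <= smt_length,
            length(gc_range) == 2L, gc_range[1] <= gc_range[2])
  structure(list(n_targets = as.integer(n_targets),
                 insert_length = as.integer(insert_length),
                 smt_length = as.integer(smt_length),
                 primer_length = as.integer(primer_length),
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 duplicate_rate = duplicate_rate,
                 het_fraction = het_fraction,
                 error_rate = error_rate,
                 smt_error_rate = smt_error_rate,
                 smt_bias = smt_bias, bias_weight = bias_weight,
                 bias_run_length = as.integer(bias_run_length),
                 gc_range = gc_range, max_dist = as.integer(max_dist),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d targets x %d bp, %d-mer SMT, ",
                     "depth ~NB(mu=%g, size=%g), duplicate rate %g, ",
                     "het fraction %.3g, error %g, bias %s\n"),
              x$n_targets, x$insert_length, x$smt_length, x$mean_depth,
              x$depth_dispersion, x$duplicate_rate, x$het_fraction,
              x$error_rate, x$smt_bias))
  invisible(x)
}

require_seed <- function(config, seed) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required for every stochastic run", call. = FALSE)
  as.integer(seed)
}

# Draw n tag sequences of length L, uniform or with planted poly-T runs.
draw_smts <- function(n, L, bias = "none", weight = 0.02, run_length = 6L) {
  if (n == 0L) return(character(0))
  cols <- lapply(seq_len(L), function(i) sample(DNA_BASES, n, replace = TRUE))
  smt <- do.call(paste0, cols)
  if (bias == "polyT" && weight > 0) {
    planted <- runif(n) < weight
    np <- sum(planted)
    if (np > 0L) {
      off <- sample.int(L - run_length + 1L, np, replace = TRUE)
      s <- smt[planted]
      substr(s, off, off + run_length - 1L) <- strrep("T", run_length)
      smt[planted] <- s
    }
  }
  smt
}

#' Generate a synthetic amplicon target design
#'
#' Random inserts with per-target GC drawn uniformly from the configured
#' range; the 22-bp matching windows of different targets are guaranteed
#' pairwise farther than `2 * max_dist` edits (so assignment is
#' unambiguous); a heterozygous SNP is placed mid-insert on the configured
#' fraction of targets.
#'
#' @param config a [sim_config()]; its `seed` is used.
#' @param seed optional override of `config$seed`.
#' @return a [target_design()].
#' @export
generate_design <- function(config, seed = NULL) {
  set.seed(require_seed(config, seed))
  n <- config$n_targets
  gc <- runif(n, config$gc_range[1], config$gc_range[2])
  targets <- data.frame(
    target_id = sprintf("T%04d", seq_len(n)),
    upstream_primer = random_dna(n, config$primer_length, 0.5),
    downstream_primer = random_dna(n, config$primer_length, 0.5),
    insert_seq = random_dna(n, config$insert_length, gc),
    stringsAsFactors = FALSE)
  # enforce window separation > 2*max_dist by regenerating offenders
  min_sep <- 2L * config$max_dist + 1L
  for (attempt in seq_len(50L)) {
    w1 <- substr(cpp_revcomp(targets$downstream_primer), 1L, 22L)
    w2 <- substr(targets$upstream_primer, 1L, 22L)
    off1 <- cpp_check_separation(w1, min_sep)
    off2 <- cpp_check_separation(w2, min_sep)
    if (length(off1) == 0L && length(off2) == 0L) break
    if (attempt == 50L) {
      stop("could not construct a design with separated primer windows", call. = FALSE)
    }
    if (length(off1) > 0L) {
      targets$downstream_primer[off1[2L]] <- random_dna(1L, config$primer_length, 0.5)
    }
    if (length(off2) > 0L) {
      targets$upstream_primer[off2[2L]] <- random_dna(1L, config$primer_length, 0.5)
    }
  }
  n_het <- round(config$het_fraction * n)
  snps <- NULL
  if (n_het > 0L) {
    het_idx <- sort(sample.int(n, n_het))
    pos <- config$insert_length %/% 2L
    ref <- substr(targets$insert_seq[het_idx], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1),
                  USE.NAMES = FALSE)
    snps <- data.frame(target_id = targets$target_id[het_idx],
                       position = pos, ref_allele = ref, alt_allele = alt,
                       stringsAsFactors = FALSE)
  }
  target_design(targets, snps, check_separation = FALSE)
}

#' Generate one synthetic SMT-tagged sample with truth
#'
#' Per target: depth `d ~ NB(mean_depth, dispersion)`; `m = round(d * (1 -
#' duplicate_rate))` unique template molecules, each with its own tag and
#' (on heterozygous targets) a Bernoulli(0.5) allele; the remaining `d - m`
#' reads are PCR duplicates resampled with replacement from the templates,
#' inheriting tag and allele. Duplicates can disagree with their template
#' only through the per-base sequencing error. Reads are emitted in a
#' random global order.
#'
#' @param design a [target_design()] (typically [generate_design()]).
#' @param config a [sim_config()].
#' @param sample_id label attached to the reads.
#' @param seed optional override of `config$seed`.
#' @param sequences generate base-level sequences and qualities (default).
#'   With `FALSE`, only the tag/truth channel is produced (reads carry
#'   empty sequences) — sufficient for tag-level studies such as collision
#'   contamination, at a fraction of the cost.
#' @return list of class `smt_sample` with elements `reads` (tagged read
#'   pairs; see [read_fastq_triplet()]) and `truth` (per read: `read_id`,
#'   `target_id`, `template_id`, `duplicate`, `allele`, `smt`).
#' @export
generate_sample <- function(design, config, sample_id = "S1", seed = NULL,
                            sequences = TRUE) {
  set.seed(require_seed(config, seed))
  tg <- design$targets
  n_t <- nrow(tg)
  depth <- rnbinom(n_t, size = config$depth_dispersion, mu = config$mean_depth)
  m <- round(depth * (1 - config$duplicate_rate))
  skip <- depth > 0L & m == 0L
  if (any(skip)) {
    warning(sprintf("%d target(s) skipped: no unique template at depth/duplicate-rate",
                    sum(skip)))
  }
  use <- which(depth > 0L & m > 0L)
  n_templates <- sum(m[use])
  smt <- draw_smts(n_templates, config$smt_length, config$smt_bias,
                   config$bias_weight, config$bias_run_length)
  has_snp <- tg$target_id %in% design$snps$target_id
  # per-target template bookkeeping
  tpl_target <- rep.int(use, m[use])
  tpl_allele <- ifelse(has_snp[tpl_target] == TRUE,
                       ifelse(rbinom(n_templates, 1L, 0.5) == 1L, "ALT", "REF"),
                       NA_character_)
  # reads: every template once, plus d - m duplicate draws with replacement
  tpl_offset <- c(0L, cumsum(m[use]))[seq_along(use)]
  read_tpl <- vector("list", length(use))
  read_dup <- vector("list", length(use))
  for (i in seq_along(use)) {
    t <- use[i]
    extra <- depth[t] - m[t]
    dups <- if (extra > 0L) sample.int(m[t], extra, replace = TRUE) else integer(0)
    read_tpl[[i]] <- tpl_offset[i] + c(seq_len(m[t]), dups)
    read_dup[[i]] <- c(rep(FALSE, m[t]), rep(TRUE, extra))
  }
  read_tpl <- unlist(read_tpl)
  read_dup <- unlist(read_dup)
  n_reads <- length(read_tpl)
  perm <- sample.int(n_reads)
  read_tpl <- read_tpl[perm]
  read_dup <- read_dup[perm]
  r_target <- tpl_target[read_tpl]
  r_allele <- tpl_allele[read_tpl]
  r_smt <- smt[read_tpl]
  if (config$smt_error_rate > 0) r_smt <- cpp_mutate_seqs(r_smt, config$smt_error_rate)
  read_id <- sprintf("%s:%07d", sample_id, seq_len(n_reads))
  if (sequences) {
    # two amplicon variants per target; reads are fixed substrings of them
    snp_i <- match(tg$target_id, design$snps$target_id)
    amp_ref <- paste0(tg$upstream_primer, tg$insert_seq, tg$downstream_primer)
    ins_alt <- tg$insert_seq
    hs <- which(!is.na(snp_i))
    if (length(hs) > 0L) {
      pos <- design$snps$position[snp_i[hs]]
      substr(ins_alt[hs], pos + 1L, pos + 1L) <- design$snps$alt_allele[snp_i[hs]]
    }
    amp_alt <- paste0(tg$upstream_primer, ins_alt, tg$downstream_primer)
    rl <- config$read_length
    r1_ref <- substr(cpp_revcomp(amp_ref), 1L, rl); r2_ref <- substr(amp_ref, 1L, rl)
    r1_alt <- substr(cpp_revcomp(amp_alt), 1L, rl); r2_alt <- substr(amp_alt, 1L, rl)
    use_alt <- !is.na(r_allele) & r_allele == "ALT"
    seq1 <- ifelse(use_alt, r1_alt[r_target], r1_ref[r_target])
    seq2 <- ifelse(use_alt, r2_alt[r_target], r2_ref[r_target])
    if (config$error_rate > 0) {
      seq1 <- cpp_mutate_seqs(seq1, config$error_rate)
      seq2 <- cpp_mutate_seqs(seq2, config$error_rate)
    }
    qual1 <- strrep("?", nchar(seq1))   # constant Q30; qualities are not used
    qual2 <- strrep("?", nchar(seq2))
  } else {
    seq1 <- seq2 <- qual1 <- qual2 <- rep("", n_reads)
  }
  reads <- data.frame(read_id = read_id, seq1 = seq1, qual1 = qual1,
                      seq2 = seq2, qual2 = qual2, smt = r_smt,
                      sample_id = sample_id, stringsAsFactors = FALSE)
  truth <- data.frame(read_id = read_id,
                      target_id = tg$target_id[r_target],
                      template_id = paste0(tg$target_id[r_target], ":", read_tpl),
                      duplicate = read_dup,
                      allele = r_allele,
                      smt = smt[read_tpl],
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth), class = "smt_sample")
}

#' @export
print.smt_sample <- function(x, ...) {
  cat(sprintf("Synthetic SMT sample: %d read pairs, %d targets, truth duplicate rate %.3f\n",
              nrow(x$reads), length(unique(x$truth$target_id)),
              mean(x$truth$duplicate)))
  invisible(x)
}

#' Randomly split reads into two pseudo-samples
#'
#' Disjoint halves of sizes `floor(n/2)` and `ceiling(n/2)` whose union is
#' the input; used to build null pairs with no real allele-frequency
#' difference.
#'
#' @param reads data.frame of reads (any per-read table).
#' @param seed RNG seed.
#' @return list with elements `a` and `b`.
#' @export
split_sample <- function(reads, seed) {
  n <- nrow(reads)
  if (n < 2L) stop("need at least two reads to split", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  na <- n %/% 2L
  list(a = reads[sort(idx[seq_len(na)]), , drop = FALSE],
       b = reads[sort(idx[(na + 1L):n]), , drop = FALSE])
}

#' Inject PCR duplicates by resampling with replacement
#'
#' With `constant_depth` (the default, as in the published simulations),
#' `m = round(n * (1 - rate))` rows are kept (sampled without replacement)
#' and `n - m` duplicates are drawn with replacement from the kept rows, so
#' total depth is preserved and the realised duplicate fraction is exactly
#' `(n - m) / n`. Without it, all `n` rows are kept and
#' `round(n * rate / (1 - rate))` duplicates are added. Duplicates copy
#' every column (tag, alleles) of their source row.
#'
#' @param reads data.frame of unique reads (any per-read table).
#' @param rate target duplicate fraction in [0, 1).
#' @param seed RNG seed.
#' @param constant_depth keep total row count fixed (default `TRUE`).
#' @return data.frame with column `injected_duplicate` appended.
#' @export
inject_duplicates <- function(reads, rate, seed, constant_depth = TRUE) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(reads)
  if (constant_depth) {
    m <- round(n * (1 - rate))
    keep <- sort(sample.int(n, m))
    dups <- if (n - m > 0L) keep[sample.int(m, n - m, replace = TRUE)] else integer(0)
  } else {
    keep <- seq_len(n)
    extra <- round(n * rate / (1 - rate))
    dups <- if (extra > 0L) sample.int(n, extra, replace = TRUE) else integer(0)
  }
  out <- reads[c(keep, dups), , drop = FALSE]
  out$injected_duplicate <- c(rep(FALSE, length(keep)), rep(TRUE, length(dups)))
  rownames(out) <- NULL
  out
}

#' Allocate experimentally identified duplicates to split halves
#'
#' Each duplicate follows the half that holds the unique read with its
#' (target, tag) pair; duplicates whose pair is in neither half are dropped
#' and counted in the `qc` attribute.
#'
#' @param half_a,half_b the two halves of the unique reads (must carry
#'   `target_id` and `smt`).
#' @param duplicates data.frame of duplicate reads with `target_id`, `smt`.
#' @return list with elements `a`, `b` (halves with their duplicates
#'   appended) and attribute `qc` = `c(n_unmatched = ...)`.
#' @export
allocate_experimental_duplicates <- function(half_a, half_b, duplicates) {
  key <- function(x) paste(x$target_id, x$smt, sep = "\r")
  in_a <- key(duplicates) %in% key(half_a)
  in_b <- key(duplicates) %in% key(half_b)
  out <- list(a = rbind(half_a, duplicates[in_a, names(half_a), drop = FALSE]),
              b = rbind(half_b, duplicates[in_b & !in_a, names(half_b), drop = FALSE]))
  attr(out, "qc") <- c(n_unmatched = sum(!in_a & !in_b))
  out
}

# Run the read-level pipeline (assign -> trim -> dedup) on one sample and
# return unique-read allele calls at QC-passing heterozygous SNPs.
pipeline_het_calls <- function(sample, design, config, min_depth = 50L,
                               band = c(0.2, 0.8)) {
  asn <- assign_reads(sample$reads, design, max_dist = config$max_dist)
  trm <- trim_reads(sample$reads, asn, design)
  ann <- mark_duplicates(trm)
  uniq <- ann[ann$label == "UNIQUE", , drop = FALSE]
  calls <- extract_alleles(uniq, design, read = 1L)
  counts <- allele_count_table(calls)
  het <- call_het_snps(counts, min_depth = min_depth, band = band)
  het <- het[het$is_het, , drop = FALSE]
  site <- paste(calls$target_id, calls$position, sep = "\r")
  keep <- site %in% paste(het$target_id, het$position, sep = "\r") &
    calls$call %in% c("REF", "ALT")
  calls <- calls[keep, , drop = FALSE]
  calls$smt <- uniq$smt[match(calls$read_id, uniq$read_id)]
  calls
}

# Per-site REF/ALT counts of a call table, on a fixed site index.
site_counts <- function(calls, site_levels) {
  si <- match(paste(calls$target_id, calls$position, sep = "\r"), site_levels)
  list(n_ref = tabulate(si[calls$call == "REF"], nbins = length(site_levels)),
       n_alt = tabulate(si[calls$call == "ALT"], nbins = length(site_levels)))
}

#' Duplicate-injection false-positive-rate experiment
#'
#' Mirrors the published simulation: per replicate, one parent sample is
#' generated and pushed through the full pipeline (assignment, trimming,
#' first-seen-tag dedup); heterozygous SNPs are called once from the unique
#' reads; the unique reads are split into two pseudo-samples; then, for
#' each duplicate rate, duplicates are injected into each half separately
#' at constant depth and a two-sided 2x2 Fisher exact test compares
#' REF/ALT counts between the halves at every het SNP. The FPR is the
#' fraction of sites with p below `alpha`.
#'
#' @param config a [sim_config()]; het targets must be present.
#' @param rates duplicate rates to inject (default `c(0, 0.25, 0.5, 0.75)`).
#' @param n_replicates replicates, each with a fresh parent sample.
#' @param seed root seed; all replicate/rate streams derive from it.
#' @param alpha significance threshold (default 0.05).
#' @param min_depth,band heterozygous-SNP calling parameters.
#' @return data.frame with columns `rate`, `replicate`, `fpr`, `n_sites`.
#' @export
fpr_experiment <- function(config, rates = c(0, 0.25, 0.5, 0.75),
                           n_replicates = 10L, seed, alpha = 0.05,
                           min_depth = 50L, band = c(0.2, 0.8)) {
  stopifnot(all(rates >= 0), all(rates < 1))
  design <- generate_design(config, seed = derive_seed(seed, 0L))
  out <- vector("list", n_replicates * length(rates))
  k <- 0L
  for (r in seq_len(n_replicates)) {
    srep <- derive_seed(seed, r)
    sample_r <- generate_sample(design, config, sample_id = sprintf("R%02d", r),
                                seed = srep)
    calls <- pipeline_het_calls(sample_r, design, config, min_depth, band)
    if (nrow(calls) == 0L) stop("no callable heterozygous SNPs", call. = FALSE)
    sites <- unique(paste(calls$target_id, calls$position, sep = "\r"))
    halves <- split_sample(calls, seed = derive_seed(srep, 1L))
    for (j in seq_along(rates)) {
      a <- inject_duplicates(halves$a, rates[j], seed = derive_seed(srep, 100L + j))
      b <- inject_duplicates(halves$b, rates[j], seed = derive_seed(srep, 200L + j))
      ca <- site_counts(a, sites)
      cb <- site_counts(b, sites)
      tested <- ca$n_ref + ca$n_alt > 0 & cb$n_ref + cb$n_alt > 0
      p <- fisher_2x2(ca$n_ref[tested], ca$n_alt[tested],
                      cb$n_ref[tested], cb$n_alt[tested])
      k <- k + 1L
      out[[k]] <- data.frame(rate = rates[j], replicate = r,
                             fpr = mean(p < alpha), n_sites = sum(tested))
    }
  }
  do.call(rbind, out)
}

#' Variance of the alternate-allele frequency under duplicate injection
#'
#' One parent sample is generated and reduced to unique-read allele calls
#' at het SNPs; for each duplicate rate, `n_injections` independent
#' constant-depth injections are performed and the per-site alternate
#' allele frequency recorded. Reported is the across-injection variance,
#' averaged over sites — the quantity whose growth with duplicate rate
#' drives the FPR inflation.
#'
#' @inheritParams fpr_experiment
#' @param n_injections injections per rate (default 100).
#' @return data.frame with columns `rate`, `mean_variance`,
#'   `median_variance`, `n_sites`.
#' @export
vaf_variance_experiment <- function(config, rates = c(0, 0.25, 0.5, 0.75),
                                    n_injections = 100L, seed,
                                    min_depth = 50L, band = c(0.2, 0.8)) {
  design <- generate_design(config, seed = derive_seed(seed, 0L))
  sample_1 <- generate_sample(design, config, sample_id = "V01",
                              seed = derive_seed(seed, 1L))
  calls <- pipeline_het_calls(sample_1, design, config, min_depth, band)
  if (nrow(calls) == 0L) stop("no callable heterozygous SNPs", call. = FALSE)
  sites <- unique(paste(calls$target_id, calls$position, sep = "\r"))
  out <- vector("list", length(rates))
  for (j in seq_along(rates)) {
    freq <- matrix(NA_real_, nrow = length(sites), ncol = n_injections)
    for (i in seq_len(n_injections)) {
      inj <- inject_duplicates(calls, rates[j],
                               seed = derive_seed(seed, 1000L * j + i))
      cc <- site_counts(inj, sites)
      freq[, i] <- ifelse(cc$n_ref + cc$n_alt > 0,
                          cc$n_alt / (cc$n_ref + cc$n_alt), NA_real_)
    }
    v <- apply(freq, 1L, var, na.rm = TRUE)
    out[[j]] <- data.frame(rate = rates[j], mean_variance = mean(v, na.rm = TRUE),
                           median_variance = stats::median(v, na.rm = TRUE),
                           n_sites = length(sites))
  }
  do.call(rbind, out)
}

#' Write a synthetic sample to FASTQ triplet + truth + design tables
#'
#' @param sample an `smt_sample` from [generate_sample()].
#' @param design the [target_design()] it was generated from.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_sample <- function(sample, design, outdir, prefix = "sim") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(outdir, paste0(prefix, c("_R1.fastq", "_R2.fastq", "_I2.fastq",
                                          "_truth.tsv", "_design.tsv")))
  write_fastq_triplet(sample$reads, p[1], p[2], p[3])
  write_results_table(sample$truth, p[4])
  write_design(design, p[5])
  invisible(p)
}
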