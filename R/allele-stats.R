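# Allele extraction at annotated SNP positions and the Fisher-test
# machinery for false-positive-rate and somatic-site analyses.
#
# Because every assigned read has a known offset within its amplicon, the
# allele at a SNP is read directly off the trimmed sequence — no alignment
# or genotyper is involved. Counts are per read pair (Read 1 only, unless
# Read 2 is requested explicitly), so no paired-read halving is needed.

#' Extract alleles at annotated SNP positions from trimmed reads
#'
#' Read 1 is sequenced from the downstream end of the amplicon, so its
#' trimmed base `j` (0-based) is the complement of insert position
#' `insert_length - 1 - j`; Read 2 runs in insert orientation. The base at
#' the SNP offset is classified as `REF`, `ALT` or `OTHER` (any other
#' character, including `N`). Reads too short to cover the position are
#' skipped and tallied in the `qc` attribute.
#'
#' @param trimmed trimmed assigned reads from [trim_reads()].
#' @param design the [target_design()] carrying the SNP annotations.
#' @param read which mate to read the allele from (1, the default, or 2).
#' @return data.frame with columns `read_id`, `sample_id`, `target_id`,
#'   `position`, `base`, `call`.
#' @export
extract_alleles <- function(trimmed, design, read = 1L) {
  stopifnot(read %in% c(1L, 2L))
  snps <- design$snps
  if (nrow(snps) == 0L || nrow(trimmed) == 0L) {
    return(structure(data.frame(read_id = character(0), sample_id = character(0),
                                target_id = character(0), position = integer(0),
                                base = character(0), call = character(0),
                                stringsAsFactors = FALSE),
                     qc = c(n_uncovered = 0L)))
  }
  if (!"sample_id" %in% names(trimmed)) trimmed$sample_id <- "S1"
  m <- merge(trimmed[, c("read_id", "sample_id", "target_id", "seq1", "seq2")],
             snps, by = "target_id", sort = FALSE)
  ins_len <- nchar(design$targets$insert_seq)[match(m$target_id,
                                                    design$targets$target_id)]
  if (read == 1L) {
    idx <- ins_len - 1L - m$position      # 0-based offset within trimmed Read 1
    seq <- m$seq1
  } else {
    idx <- m$position
    seq <- m$seq2
  }
  covered <- idx >= 0L & idx < nchar(seq)
  m <- m[covered, , drop = FALSE]
  idx <- idx[covered]
  base <- substr(if (read == 1L) m$seq1 else m$seq2, idx + 1L, idx + 1L)
  if (read == 1L) base <- complement_bases(base)
  call <- ifelse(base == m$ref_allele, "REF",
                 ifelse(base == m$alt_allele, "ALT", "OTHER"))
  out <- data.frame(read_id = m$read_id, sample_id = m$sample_id,
                    target_id = m$target_id, position = m$position,
                    base = base, call = call, stringsAsFactors = FALSE)
  attr(out, "qc") <- c(n_uncovered = sum(!covered))
  out
}

#' Per-site allele count table
#'
#' @param calls output of [extract_alleles()] (typically restricted to
#'   unique reads).
#' @return data.frame with one row per (sample, target, position) and
#'   columns `n_ref`, `n_alt`, `n_other`, `depth`.
#' @export
allele_count_table <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(sample_id = character(0), target_id = character(0),
                      position = integer(0), n_ref = integer(0),
                      n_alt = integer(0), n_other = integer(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(calls$sample_id, calls$target_id, calls$position, sep = "\r")
  uk <- unique(key)
  ki <- match(key, uk)
  nb <- length(uk)
  first <- match(uk, key)
  out <- data.frame(sample_id = calls$sample_id[first],
                    target_id = calls$target_id[first],
                    position = calls$position[first],
                    n_ref = tabulate(ki[calls$call == "REF"], nbins = nb),
                    n_alt = tabulate(ki[calls$call == "ALT"], nbins = nb),
                    n_other = tabulate(ki[calls$call == "OTHER"], nbins = nb),
                    stringsAsFactors = FALSE)
  out$depth <- out$n_ref + out$n_alt + out$n_other
  out
}

#' Drop SNP sites with an excess of third alleles
#'
#' Sites reporting an allele other than reference or alternate in more than
#' `max_other_fraction` of covering reads are unreliable (mismapped primer,
#' tri-allelic site, systematic error) and are excluded.
#'
#' @param counts an [allele_count_table()].
#' @param max_other_fraction exclusion threshold (default 0.10).
#' @return the retained rows of `counts`, with column `other_fraction`.
#' @export
snp_qc_filter <- function(counts, max_other_fraction = 0.10) {
  counts$other_fraction <- ifelse(counts$depth > 0,
                                  counts$n_other / counts$depth, NA_real_)
  keep <- !is.na(counts$other_fraction) &
    counts$other_fraction <= max_other_fraction
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call heterozygous SNPs from unique-read allele counts
#'
#' A site is heterozygous when, after [snp_qc_filter()], its depth reaches
#' `min_depth` and the alternate allele frequency `n_alt / (n_ref + n_alt)`
#' falls inside `band`. This surrogate for a genotyper is deliberately
#' conservative at ~1,000X coverage.
#'
#' @param counts an [allele_count_table()] computed from unique reads.
#' @param min_depth minimal depth (default 50).
#' @param band inclusive alternate-frequency band (default `c(0.2, 0.8)`).
#' @param max_other_fraction passed to [snp_qc_filter()].
#' @return the QC-passing rows with columns `alt_frequency`, `is_het`.
#' @export
call_het_snps <- function(counts, min_depth = 50L, band = c(0.2, 0.8),
                          max_other_fraction = 0.10) {
  out <- snp_qc_filter(counts, max_other_fraction)
  out$alt_frequency <- ifelse(out$n_ref + out$n_alt > 0,
                              out$n_alt / (out$n_ref + out$n_alt), NA_real_)
  out$is_het <- out$depth >= min_depth &
    !is.na(out$alt_frequency) &
    out$alt_frequency >= band[1L] & out$alt_frequency <= band[2L]
  out
}

#' Allele-call agreement within duplicate clusters
#'
#' A cluster (all reads of one target sharing one tag) is concordant when
#' every member reports the same allele at the target's SNP. Only clusters
#' with at least `min_size` members covering the SNP are evaluated; the
#' table is stratified by that evaluable cluster size. PCR duplicates must
#' agree up to sequencing error, so discordance in excess of the paired-read
#' error floor indicates chance tag collisions.
#'
#' @param annotations output of [mark_duplicates()].
#' @param calls output of [extract_alleles()] (Read 1) for the same reads,
#'   typically restricted to QC-passing sites.
#' @param min_size minimal evaluable cluster size (default 2).
#' @return data.frame with columns `cluster_size`, `n_clusters`,
#'   `n_concordant`, `percent_agreement`.
#' @export
cluster_concordance <- function(annotations, calls, min_size = 2L) {
  m <- merge(annotations[, c("read_id", "target_id", "smt")],
             calls[, c("read_id", "position", "call")],
             by = "read_id", sort = FALSE)
  if (nrow(m) == 0L) {
    return(data.frame(cluster_size = integer(0), n_clusters = integer(0),
                      n_concordant = integer(0), percent_agreement = numeric(0)))
  }
  key <- paste(m$target_id, m$smt, m$position, sep = "\r")
  ki <- match(key, unique(key))
  size <- tabulate(ki)
  concord <- vapply(split(m$call, ki), function(x) length(unique(x)) == 1L,
                    logical(1))
  keep <- size >= min_size
  size <- size[keep]; concord <- concord[keep]
  if (length(size) == 0L) {
    return(data.frame(cluster_size = integer(0), n_clusters = integer(0),
                      n_concordant = integer(0), percent_agreement = numeric(0)))
  }
  agg_n <- tapply(concord, size, length)
  agg_c <- tapply(concord, size, sum)
  data.frame(cluster_size = as.integer(names(agg_n)),
             n_clusters = as.integer(agg_n),
             n_concordant = as.integer(agg_c),
             percent_agreement = 100 * as.integer(agg_c) / as.integer(agg_n))
}

#' Allele-call agreement between the two mates of a pair
#'
#' Both mates of a paired-end read sequence the same molecule, so their
#' calls at an overlapped SNP disagree only through sequencing error. The
#' returned fraction is the floor against which duplicate-cluster
#' discordance is judged.
#'
#' @param calls1,calls2 outputs of [extract_alleles()] for Read 1 and
#'   Read 2 of the same read set.
#' @return fraction of pairs with identical calls, `NA` when no pair
#'   covers a SNP with both mates.
#' @export
paired_read_concordance <- function(calls1, calls2) {
  m <- merge(calls1[, c("read_id", "position", "call")],
             calls2[, c("read_id", "position", "call")],
             by = c("read_id", "position"), suffixes = c("_r1", "_r2"))
  if (nrow(m) == 0L) return(NA_real_)
  mean(m$call_r1 == m$call_r2)
}

#' Two-sided 2x2 Fisher exact test (vectorised)
#'
#' Exact two-sided p-value by summation of all hypergeometric table
#' probabilities not exceeding that of the observed table (the
#' minimum-likelihood definition used by `stats::fisher.test`). Degenerate
#' margins give p = 1. All four arguments are recycled to a common length.
#'
#' @param a_ref,a_alt,b_ref,b_alt non-negative integer allele counts of the
#'   two samples.
#' @return numeric vector of p-values.
#' @export
fisher_2x2 <- function(a_ref, a_alt, b_ref, b_alt) {
  n <- max(length(a_ref), length(a_alt), length(b_ref), length(b_alt))
  a_ref <- rep_len(a_ref, n); a_alt <- rep_len(a_alt, n)
  b_ref <- rep_len(b_ref, n); b_alt <- rep_len(b_alt, n)
  if (any(c(a_ref, a_alt, b_ref, b_alt) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    m <- a_ref[i] + b_ref[i]          # total ref
    nn <- a_alt[i] + b_alt[i]         # total alt
    k <- a_ref[i] + a_alt[i]          # sample A depth
    if (m + nn == 0 || k == 0 || k == m + nn || m == 0 || nn == 0) return(1)
    lo <- max(0L, k - nn); hi <- min(k, m)
    d <- dhyper(lo:hi, m, nn, k)
    dobs <- dhyper(a_ref[i], m, nn, k)
    min(1, sum(d[d <= dobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Two-sided 2x3 Fisher exact test
#'
#' Exact p-value by enumeration of all 2x3 tables with the observed margins
#' (two free cells; probabilities from the multivariate hypergeometric),
#' summing those with probability not exceeding the observed table's.
#' Enumeration is quadratic in the row total and is capped at
#' `max_enumeration` total counts; beyond that a seeded Monte-Carlo
#' estimate over `stats::r2dtable` margin-preserving tables is returned,
#' with its standard error in attribute `se`.
#'
#' @param g_ref,g_alt,t1_ref,t1_alt,t2_ref,t2_alt allele counts of the
#'   three samples (germline, tumor 1, tumor 2).
#' @param max_enumeration largest total count enumerated exactly.
#' @param mc_iter Monte-Carlo tables drawn beyond the cap.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return p-value (length 1).
#' @export
fisher_2x3 <- function(g_ref, g_alt, t1_ref, t1_alt, t2_ref, t2_alt,
                       max_enumeration = 5000L, mc_iter = 100000L, seed = 1L) {
  x <- c(g_ref, g_alt, t1_ref, t1_alt, t2_ref, t2_alt)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  cs <- c(g_ref + g_alt, t1_ref + t1_alt, t2_ref + t2_alt)  # per-sample depths
  R1 <- g_ref + t1_ref + t2_ref                             # total ref
  N <- sum(cs)
  if (N == 0 || R1 == 0 || R1 == N) return(1)
  lobs <- lchoose(cs[1], g_ref) + lchoose(cs[2], t1_ref) +
    lchoose(cs[3], t2_ref) - lchoose(N, R1)
  if (N <= max_enumeration) {
    x1 <- 0:min(cs[1], R1)
    x2 <- 0:min(cs[2], R1)
    g <- expand.grid(x1 = x1, x2 = x2)
    g$x3 <- R1 - g$x1 - g$x2
    g <- g[g$x3 >= 0 & g$x3 <= cs[3], , drop = FALSE]
    lp <- lchoose(cs[1], g$x1) + lchoose(cs[2], g$x2) + lchoose(cs[3], g$x3) -
      lchoose(N, R1)
    return(min(1, sum(exp(lp[lp <= lobs + 1e-7]))))
  }
  set.seed(seed)
  tabs <- r2dtable(mc_iter, c(R1, N - R1), cs)
  lp <- vapply(tabs, function(tt) {
    lchoose(cs[1], tt[1, 1]) + lchoose(cs[2], tt[1, 2]) +
      lchoose(cs[3], tt[1, 3]) - lchoose(N, R1)
  }, numeric(1))
  p <- mean(lp <= lobs + 1e-7)
  attr(p, "se") <- sqrt(p * (1 - p) / mc_iter)
  p
}

#' False positive rate of a set of null tests
#'
#' @param p_values p-values from independent tests with no true difference.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `fpr_result`: list with `fpr`, `n_tests`,
#'   `alpha`, `p_values`.
#' @export
compute_fpr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("no p-values given", call. = FALSE)
  structure(list(fpr = mean(p_values < alpha), n_tests = length(p_values),
                 alpha = alpha, p_values = p_values),
            class = "fpr_result")
}

#' @export
print.fpr_result <- function(x, ...) {
  cat(sprintf("FPR: %.3f (%d of %d tests with p < %g)\n",
              x$fpr, sum(x$p_values < x$alpha), x$n_tests, x$alpha))
  invisible(x)
}

# Benjamini-Hochberg selection at a given FDR.
bh_select <- function(p, fdr = 0.05) {
  p.adjust(p, method = "BH") < fdr
}

#' Identify somatic sites across germline and tumor samples
#'
#' Per site: an exact test of allele counts across all samples (2x2 for one
#' tumor, 2x3 for two, Monte-Carlo beyond the enumeration cap), BH
#' adjustment across sites, and a germline alternate-frequency filter. A
#' site is somatic when its BH-adjusted p-value is below `fdr`, its
#' germline alternate frequency is below `germ_alt_max`, and every sample
#' reaches `min_cov` at the site (sites failing coverage are not tested).
#'
#' @param counts data.frame with columns `site`, `sample_id`, `n_ref`,
#'   `n_alt` (one row per site per sample).
#' @param germline the `sample_id` of the germline sample.
#' @param min_cov per-site per-sample coverage floor (default 50).
#' @param germ_alt_max germline alternate-frequency ceiling (default 0.10).
#' @param fdr BH false discovery rate (default 0.05).
#' @return data.frame with one row per tested site: `site`, `p`, `q`,
#'   `germ_alt_frequency`, `somatic`.
#' @export
identify_somatic <- function(counts, germline, min_cov = 50L,
                             germ_alt_max = 0.10, fdr = 0.05) {
  stopifnot(all(c("site", "sample_id", "n_ref", "n_alt") %in% names(counts)))
  samples <- unique(counts$sample_id)
  if (length(samples) < 2L) stop("need a germline and at least one tumor sample",
                                 call. = FALSE)
  if (!germline %in% samples) stop("germline sample not present", call. = FALSE)
  tumors <- setdiff(samples, germline)
  counts$depth <- counts$n_ref + counts$n_alt
  sites <- unique(counts$site)
  res <- lapply(sites, function(s) {
    sub <- counts[counts$site == s, ]
    if (!all(samples %in% sub$sample_id) || any(sub$depth < min_cov)) return(NULL)
    g <- sub[sub$sample_id == germline, ]
    tl <- sub[match(tumors, sub$sample_id), ]
    p <- if (length(tumors) == 1L) {
      fisher_2x2(g$n_ref, g$n_alt, tl$n_ref[1], tl$n_alt[1])
    } else if (length(tumors) == 2L) {
      as.numeric(fisher_2x3(g$n_ref, g$n_alt, tl$n_ref[1], tl$n_alt[1],
                            tl$n_ref[2], tl$n_alt[2]))
    } else {
      stop("more than two tumor samples are not supported", call. = FALSE)
    }
    data.frame(site = s, p = p,
               germ_alt_frequency = g$n_alt / g$depth,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(site = character(0), p = numeric(0), q = numeric(0),
                      germ_alt_frequency = numeric(0), somatic = logical(0)))
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$somatic <- bh_select(res$p, fdr) & res$germ_alt_frequency < germ_alt_max
  res[, c("site", "p", "q", "germ_alt_frequency", "somatic")]
}
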