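# First-seen-SMT duplicate marking and tag statistics.
#
# Within one target, the first read carrying a given tag is the unique
# (molecular) read; every later read with that tag is a PCR duplicate.
# "First" is defined by input order, so permuting the input changes which
# read represents a cluster but never any count, rate or histogram.

#' Mark unique versus duplicate reads by first-seen SMT within target
#'
#' Reads whose tag contains `N` cannot certify molecular identity; they are
#' excluded from the annotation and counted in the `qc` attribute.
#'
#' @param reads data.frame with columns `read_id`, `target_id`, `smt` (and
#'   optionally `sample_id`, carried through). Rows must be in the defined
#'   input order.
#' @param merge_1mm experimental, off by default: additionally fold tags at
#'   Hamming distance 1 from an earlier-seen tag of the same target into
#'   that tag's cluster (tag-error correction). The published method treats
#'   tags verbatim.
#' @return data.frame with columns of `reads` plus `label`
#'   (`"UNIQUE"`/`"DUPLICATE"`) and `cluster_rank` (1 = first occurrence of
#'   the (target, tag) pair). Attribute `qc` holds `n_ambiguous_smt`.
#' @export
mark_duplicates <- function(reads, merge_1mm = FALSE) {
  stopifnot(all(c("read_id", "target_id", "smt") %in% names(reads)))
  has_n <- grepl("N", reads$smt, fixed = TRUE)
  ann <- reads[!has_n, , drop = FALSE]
  if (isTRUE(merge_1mm) && nrow(ann) > 0L) {
    ann$smt <- merge_one_mismatch(ann$target_id, ann$smt)
  }
  if (nrow(ann) > 0L) {
    key <- paste(ann$target_id, ann$smt, sep = "\r")
    key_id <- match(key, unique(key))
    ann$cluster_rank <- rank_in_group(key_id)
    ann$label <- ifelse(ann$cluster_rank == 1L, "UNIQUE", "DUPLICATE")
  } else {
    ann$cluster_rank <- integer(0)
    ann$label <- character(0)
  }
  rownames(ann) <- NULL
  attr(ann, "qc") <- c(n_ambiguous_smt = sum(has_n))
  ann
}

# Greedy within-target folding of tags at Hamming distance 1 from an
# earlier-seen tag. Quadratic per target in the number of distinct tags;
# intended for modest tag counts.
merge_one_mismatch <- function(target_id, smt) {
  out <- smt
  for (t in unique(target_id)) {
    idx <- which(target_id == t)
    seen <- character(0)
    for (i in idx) {
      s <- out[i]
      if (s %in% seen) next
      if (length(seen) > 0L) {
        d <- cpp_hamming(rep(s, length(seen)), seen)
        hit <- which(d == 1L)
        if (length(hit) > 0L) {
          out[i] <- seen[hit[1L]]
          next
        }
      }
      seen <- c(seen, s)
    }
  }
  out
}

#' Histogram of duplicate-cluster sizes
#'
#' A cluster is all reads of one target sharing one tag; size 1 means a
#' molecule observed once. Satisfies `sum(size * count) == nrow(annotations)`
#' and `sum(count) == number of distinct (target, tag) pairs`.
#'
#' @param annotations output of [mark_duplicates()] (one sample).
#' @return data.frame with columns `cluster_size`, `n_clusters`.
#' @export
cluster_size_histogram <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(data.frame(cluster_size = integer(0), n_clusters = integer(0)))
  }
  key <- paste(annotations$target_id, annotations$smt, sep = "\r")
  sizes <- tabulate(match(key, unique(key)))
  tab <- table(sizes)
  data.frame(cluster_size = as.integer(names(tab)),
             n_clusters = as.integer(tab))
}

#' Duplicate-rate report per sample or per target
#'
#' @param annotations output of [mark_duplicates()].
#' @param by `"sample"` or `"target"`.
#' @param design optional [target_design()]; when given with
#'   `by = "target"`, the per-target table carries insert GC, upstream- and
#'   downstream-primer GC and coverage columns as covariates for external
#'   regression of the duplicate rate.
#' @return data.frame with columns `sample_id` and/or `target_id`,
#'   `n_total`, `n_unique`, `n_duplicate`, `rate`.
#' @export
duplicate_rate_report <- function(annotations, by = c("sample", "target"),
                                  design = NULL) {
  by <- match.arg(by)
  if (!"sample_id" %in% names(annotations)) annotations$sample_id <- "S1"
  keys <- if (by == "sample") annotations["sample_id"]
          else annotations[c("sample_id", "target_id")]
  key <- do.call(paste, c(unclass(keys), sep = "\r"))
  uk <- unique(key)
  ki <- match(key, uk)
  n_total <- tabulate(ki, nbins = length(uk))
  n_dup <- tabulate(ki[annotations$label == "DUPLICATE"], nbins = length(uk))
  out <- keys[match(uk, key), , drop = FALSE]
  out$n_total <- n_total
  out$n_unique <- n_total - n_dup
  out$n_duplicate <- n_dup
  out$rate <- n_dup / n_total
  rownames(out) <- NULL
  if (by == "target" && !is.null(design)) {
    ti <- match(out$target_id, design$targets$target_id)
    out$coverage <- out$n_total
    out$insert_gc <- gc_fraction(design$targets$insert_seq)[ti]
    out$upstream_primer_gc <- gc_fraction(design$targets$upstream_primer)[ti]
    out$downstream_primer_gc <- gc_fraction(design$targets$downstream_primer)[ti]
  }
  out
}

#' Pairwise diversity of a set of SMT sequences
#'
#' Mean pairwise Hamming distance and the fraction of pairs at distance
#' exactly 1 (the signature of a tag sequencing error). When the number of
#' unordered pairs exceeds `max_pairs`, pairs are subsampled with the seed.
#'
#' @param smts character vector of same-length tags.
#' @param max_pairs cap on evaluated pairs.
#' @param seed RNG seed for pair subsampling.
#' @return list with `mean_distance`, `fraction_distance_1`, `n_pairs`.
#' @export
smt_diversity <- function(smts, max_pairs = 100000L, seed = 1L) {
  n <- length(smts)
  if (n < 2L) stop("need at least two tags", call. = FALSE)
  if (length(unique(nchar(smts))) != 1L) {
    stop("tags of mixed lengths", call. = FALSE)
  }
  n_pairs_total <- n * (n - 1) / 2
  if (n_pairs_total <= max_pairs) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1L]; j <- pairs[, 2L]
  } else {
    set.seed(seed)
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    redo <- which(i == j)
    while (length(redo) > 0L) {
      j[redo] <- sample.int(n, length(redo), replace = TRUE)
      redo <- redo[i[redo] == j[redo]]
    }
  }
  d <- cpp_hamming(smts[i], smts[j])
  list(mean_distance = mean(d),
       fraction_distance_1 = mean(d == 1L),
       n_pairs = length(d))
}

#' Positional base frequencies of a set of SMT sequences
#'
#' Tabular replacement for a sequence-logo motif plot: one row per tag
#' position, columns A/C/G/T, each row summing to 1.
#'
#' @param smts character vector of same-length tags (A/C/G/T only).
#' @return L x 4 numeric matrix of frequencies.
#' @export
smt_positional_base_frequencies <- function(smts) {
  if (length(smts) == 0L) stop("no tags given", call. = FALSE)
  if (length(unique(nchar(smts))) != 1L) {
    stop("tags of mixed lengths", call. = FALSE)
  }
  L <- nchar(smts[1L])
  m <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  chars <- matrix(unlist(strsplit(smts, "", fixed = TRUE)), nrow = L)
  for (b in DNA_BASES) m[, b] <- rowSums(chars == b)
  sw <- rowSums(m)
  if (any(sw == 0)) stop("tags contain non-ACGT characters", call. = FALSE)
  m / sw
}
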