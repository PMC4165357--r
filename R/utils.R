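# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `A/C/G/T` (case preserved); any other
#' character, including `N`, is reversed in place unchanged.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTA"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

complement_bases <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

is_dna <- function(x) grepl("^[ACGT]+$", x)

#' GC fraction of DNA strings
#'
#' @param x character vector of DNA strings.
#' @return numeric vector of G+C fractions.
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}

# Deterministic derived seeds (kept well below 2^31) so that composite
# experiments can hand independent sub-seeds to their stages.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483587 * 48271 + as.double(i) * 7919) %% 2147483587) + 1L
}

# Random DNA strings with a per-string GC fraction.
random_dna <- function(n, len, gc = 0.5) {
  gc <- rep_len(gc, n)
  vapply(seq_len(n), function(i) {
    p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# rank within groups, preserving input order (stable).
rank_in_group <- function(group_id) {
  o <- order(group_id)
  r <- integer(length(group_id))
  r[o] <- sequence(tabulate(group_id)[unique(group_id[o])])
  r
}
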