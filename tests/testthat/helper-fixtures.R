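# Shared fixtures: a small handcrafted design and error-free read builders.
# All synthetic inputs are built in code at test time.

# Deterministic random design via the package generator.
small_design <- function(n_targets = 5L, insert_length = 150L, seed = 424L,
                         het_fraction = 1) {
  cfg <- sim_config(n_targets = n_targets, insert_length = insert_length,
                    het_fraction = het_fraction, seed = seed)
  generate_design(cfg)
}

# Build an error-free read pair for target row `i` of `design`.
# allele: "REF" or "ALT" (ignored when the target carries no SNP).
make_pair <- function(design, i, smt = "ACGTACGTACGT", allele = "REF",
                      read_len = 151L, read_id = paste0("r", i),
                      sample_id = "S1") {
  tg <- design$targets[i, ]
  ins <- tg$insert_seq
  si <- which(design$snps$target_id == tg$target_id)
  if (length(si) == 1L && allele == "ALT") {
    p <- design$snps$position[si]
    substr(ins, p + 1L, p + 1L) <- design$snps$alt_allele[si]
  }
  amp <- paste0(tg$upstream_primer, ins, tg$downstream_primer)
  seq1 <- substr(revcomp(amp), 1L, read_len)
  seq2 <- substr(amp, 1L, read_len)
  data.frame(read_id = read_id, seq1 = seq1, qual1 = strrep("?", nchar(seq1)),
             seq2 = seq2, qual2 = strrep("?", nchar(seq2)), smt = smt,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

make_pairs <- function(design, idx, smts, alleles = NULL, ...) {
  if (is.null(alleles)) alleles <- rep("REF", length(idx))
  do.call(rbind, lapply(seq_along(idx), function(j) {
    make_pair(design, idx[j], smt = smts[j], allele = alleles[j],
              read_id = sprintf("r%04d", j), ...)
  }))
}

random_smts <- function(n, L = 12L) {
  smtdedup:::draw_smts(n, L)
}

# Independent Levenshtein oracle: base R's full dynamic programming.
lev_oracle <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Exhaustive 2x2 Fisher oracle: enumerate all tables with the observed
# margins, sum probabilities <= the observed table's.
fisher_2x2_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  as <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(as, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  pobs <- pr[match(a, as)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

expect_same_table <- function(x, y) {
  expect_equal(x, y, ignore_attr = TRUE)
}
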