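test_that("design generation is deterministic, separated and honours het_fraction", {
  cfg <- sim_config(n_targets = 15, het_fraction = 1, seed = 91)
  d1 <- generate_design(cfg)
  d2 <- generate_design(cfg)
  expect_identical(d1, d2)
  expect_identical(nrow(d1$snps), 15L)
  expect_true(all(d1$snps$position == 75L))
  # every SNP ref allele matches its insert base
  i <- match(d1$snps$target_id, d1$targets$target_id)
  expect_identical(substr(d1$targets$insert_seq[i], d1$snps$position + 1,
                          d1$snps$position + 1),
                   d1$snps$ref_allele)
  # matching windows pairwise farther than 2 * max_dist, by full DP oracle
  w <- smtdedup:::design_windows(d1)
  for (set in w) {
    dmat <- utils::adist(set)
    expect_true(all(dmat[upper.tri(dmat)] > 4))
  }
  expect_identical(nrow(generate_design(sim_config(n_targets = 8,
                                                   het_fraction = 0,
                                                   seed = 92))$snps), 0L)
})

test_that("sample truth matches configuration: duplicate rate and allele balance", {
  cfg0 <- sim_config(n_targets = 10, mean_depth = 500, duplicate_rate = 0,
                     het_fraction = 1, error_rate = 0, seed = 93)
  des <- generate_design(cfg0)
  s0 <- generate_sample(des, cfg0)
  expect_identical(sum(s0$truth$duplicate), 0L)
  pl0 <- run_dedup_pipeline(s0$reads, des)
  expect_equal(pl0$report$rate, 0, tolerance = 1e-4)

  cfg5 <- sim_config(n_targets = 10, mean_depth = 1000, duplicate_rate = 0.5,
                     het_fraction = 1, error_rate = 0, seed = 94)
  s5 <- generate_sample(des, cfg5)
  pl5 <- run_dedup_pipeline(s5$reads, des)
  expect_lt(abs(pl5$report$rate - 0.5), 0.03)
  # duplicates inherit their template's tag and allele; with zero error
  # every duplicate cluster is internally concordant
  calls <- extract_alleles(pl5$trimmed, des)
  conc <- cluster_concordance(pl5$annotations, calls)
  expect_true(all(conc$percent_agreement == 100))
  # alternate allele frequency across unique templates is ~0.5 per site
  uniq <- pl5$annotations[pl5$annotations$label == "UNIQUE", ]
  cnt <- allele_count_table(extract_alleles(uniq, des))
  expect_true(all(abs(cnt$n_alt / (cnt$n_ref + cnt$n_alt) - 0.5) <
                    3 * sqrt(0.25 / cnt$depth) + 0.01))
  # determinism
  s5b <- generate_sample(des, cfg5)
  expect_identical(s5, s5b)
})

test_that("tag-only generation reproduces the tag channel of the full run", {
  cfg <- sim_config(n_targets = 6, mean_depth = 100, duplicate_rate = 0.2,
                    het_fraction = 0.5, seed = 95)
  des <- generate_design(cfg)
  full <- generate_sample(des, cfg)
  tags <- generate_sample(des, cfg, sequences = FALSE)
  expect_identical(full$truth, tags$truth)
  expect_identical(full$reads$smt, tags$reads$smt)
  expect_identical(tags$reads$seq1, rep("", nrow(tags$reads)))
})

test_that("splitting gives seeded disjoint halves whose union is the input", {
  reads <- data.frame(read_id = sprintf("r%02d", 1:11), x = rnorm(11))
  h <- split_sample(reads, seed = 96)
  expect_identical(nrow(h$a), 5L)
  expect_identical(nrow(h$b), 6L)
  expect_length(intersect(h$a$read_id, h$b$read_id), 0L)
  expect_setequal(c(h$a$read_id, h$b$read_id), reads$read_id)
  h2 <- split_sample(reads, seed = 96)
  expect_identical(h, h2)
  expect_error(split_sample(reads[1, , drop = FALSE], seed = 1), "at least two")
})

test_that("duplicate injection preserves depth and realises the exact rate", {
  uniq <- data.frame(read_id = sprintf("r%03d", 1:100),
                     target_id = "T1", smt = random_smts(100),
                     stringsAsFactors = FALSE)
  out0 <- inject_duplicates(uniq, 0, seed = 97)
  expect_equal(out0[, names(uniq)], uniq, ignore_attr = TRUE)
  expect_false(any(out0$injected_duplicate))

  out <- inject_duplicates(uniq, 0.3, seed = 97)
  expect_identical(nrow(out), 100L)
  expect_identical(sum(out$injected_duplicate), 30L)
  kept <- out$smt[!out$injected_duplicate]
  expect_identical(length(kept), 70L)
  expect_true(all(out$smt[out$injected_duplicate] %in% kept))
  # dedup on the injected set reports the rate exactly (counting argument)
  ann <- mark_duplicates(out[, c("read_id", "target_id", "smt")])
  expect_identical(duplicate_rate_report(ann)$rate, 0.3)
  # determinism and error contract
  expect_identical(out, inject_duplicates(uniq, 0.3, seed = 97))
  expect_error(inject_duplicates(uniq, 1, seed = 1), "rate")

  grow <- inject_duplicates(uniq, 0.25, seed = 98, constant_depth = FALSE)
  expect_identical(nrow(grow), 133L)   # 100 kept + round(100 * 1/3) injected
})

test_that("experimental duplicates follow their unique read's half", {
  a <- data.frame(read_id = "u1", target_id = "T1", smt = "AAAA",
                  stringsAsFactors = FALSE)
  b <- data.frame(read_id = "u2", target_id = "T1", smt = "CCCC",
                  stringsAsFactors = FALSE)
  dups <- data.frame(read_id = c("d1", "d2", "d3"), target_id = "T1",
                     smt = c("AAAA", "AAAA", "GGGG"), stringsAsFactors = FALSE)
  out <- allocate_experimental_duplicates(a, b, dups)
  expect_identical(nrow(out$a), 3L)
  expect_identical(nrow(out$b), 1L)
  expect_identical(attr(out, "qc")[["n_unmatched"]], 1L)
  expect_identical(nrow(out$a) + nrow(out$b),
                   nrow(a) + nrow(b) + sum(dups$smt %in% c("AAAA", "CCCC")))
})

test_that("FPR experiment is reproducible and well-formed at small scale", {
  cfg <- sim_config(n_targets = 12, mean_depth = 150, duplicate_rate = 0,
                    het_fraction = 1, error_rate = 0, seed = 99)
  res <- fpr_experiment(cfg, rates = c(0, 0.5), n_replicates = 2, seed = 100)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$fpr >= 0 & res$fpr <= 1))
  expect_true(all(res$n_sites == 12L))
  res2 <- fpr_experiment(cfg, rates = c(0, 0.5), n_replicates = 2, seed = 100)
  expect_identical(res, res2)
})

test_that("alt-frequency variance is zero without injection and grows with it", {
  cfg <- sim_config(n_targets = 10, mean_depth = 300, duplicate_rate = 0,
                    het_fraction = 1, error_rate = 0, seed = 101)
  res <- vaf_variance_experiment(cfg, rates = c(0, 0.5), n_injections = 30,
                                 seed = 102)
  expect_equal(res$mean_variance[res$rate == 0], 0)
  expect_gt(res$mean_variance[res$rate == 0.5], 0)
})

test_that("samples round-trip to disk through the FASTQ triplet", {
  cfg <- sim_config(n_targets = 4, mean_depth = 30, het_fraction = 0.5, seed = 103)
  des <- generate_design(cfg)
  s <- generate_sample(des, cfg)
  dir <- file.path(tempdir(), "simout")
  p <- write_sample(s, des, dir)
  back <- read_fastq_triplet(p[1], p[2], p[3], sample_id = "S1")
  expect_same_table(back, s$reads)
  expect_same_table(read_results_table(p[4]), s$truth)
  des_back <- load_design(p[5])
  expect_equal(des_back$targets, des$targets)
  unlink(dir, recursive = TRUE)
})
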