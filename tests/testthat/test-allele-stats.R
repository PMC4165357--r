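test_that("allele extraction reads the SNP base off both mates", {
  des <- small_design(2)
  reads <- rbind(make_pair(des, 1, smt = "A", allele = "REF", read_id = "ref1"),
                 make_pair(des, 1, smt = "C", allele = "ALT", read_id = "alt1"))
  asn <- assign_reads(reads, des)
  trm <- trim_reads(reads, asn, des)
  for (mate in 1:2) {
    calls <- extract_alleles(trm, des, read = mate)
    expect_identical(calls$call[calls$read_id == "ref1"], "REF")
    expect_identical(calls$call[calls$read_id == "alt1"], "ALT")
  }
  # a third allele and an N are both OTHER
  snp <- des$snps[des$snps$target_id == des$targets$target_id[1], ]
  other <- setdiff(c("A", "C", "G", "T"), c(snp$ref_allele, snp$alt_allele))[1]
  t2 <- trm[trm$read_id == "ref1", ]
  ins_len <- nchar(des$targets$insert_seq[1])
  r1_off <- ins_len - 1L - snp$position
  substr(t2$seq1, r1_off + 1L, r1_off + 1L) <- smtdedup:::complement_bases(other)
  expect_identical(extract_alleles(t2, des)$call, "OTHER")
  substr(t2$seq1, r1_off + 1L, r1_off + 1L) <- "N"
  expect_identical(extract_alleles(t2, des)$call, "OTHER")
  # a read ending before the SNP is skipped and tallied
  t3 <- trm[trm$read_id == "ref1", ]
  t3$seq1 <- substr(t3$seq1, 1, r1_off)    # one base short of the SNP
  calls <- extract_alleles(t3, des)
  expect_identical(nrow(calls), 0L)
  expect_identical(attr(calls, "qc")[["n_uncovered"]], 1L)
})

test_that("third-allele QC filter and het calling behave at their thresholds", {
  counts <- data.frame(sample_id = "S", target_id = c("T1", "T2", "T3"),
                       position = 75L,
                       n_ref = c(2L, 90L, 0L), n_alt = c(1L, 90L, 0L),
                       n_other = c(1L, 10L, 0L))
  counts$depth <- counts$n_ref + counts$n_alt + counts$n_other
  kept <- snp_qc_filter(counts)
  # 25% other excluded, 5.3% retained, zero coverage never evaluated
  expect_identical(kept$target_id, "T2")

  het <- data.frame(sample_id = "S", target_id = c("H1", "H2", "H3"),
                    position = 75L,
                    n_ref = c(50L, 99L, 20L), n_alt = c(50L, 1L, 20L),
                    n_other = 0L)
  het$depth <- het$n_ref + het$n_alt + het$n_other
  out <- call_het_snps(het)
  expect_identical(out$is_het, c(TRUE, FALSE, FALSE))
})

test_that("duplicate-cluster concordance is enumerated per cluster size", {
  ann <- data.frame(read_id = sprintf("r%d", 1:6),
                    target_id = "T1",
                    smt = rep(c("AA", "CC", "GG"), each = 2),
                    stringsAsFactors = FALSE)
  calls <- data.frame(read_id = sprintf("r%d", 1:6), position = 75L,
                      call = c("ALT", "ALT", "ALT", "REF", "REF", "REF"),
                      stringsAsFactors = FALSE)
  tab <- cluster_concordance(ann, calls)
  expect_identical(tab$cluster_size, 2L)
  expect_identical(tab$n_clusters, 3L)
  expect_identical(tab$n_concordant, 2L)
  expect_equal(tab$percent_agreement, 100 * 2 / 3)

  # error-free generated data: all clusters concordant at all sizes
  cfg <- sim_config(n_targets = 10, mean_depth = 300, duplicate_rate = 0.4,
                    het_fraction = 1, error_rate = 0, seed = 81)
  des <- generate_design(cfg)
  s <- generate_sample(des, cfg)
  pl <- run_dedup_pipeline(s$reads, des)
  calls <- extract_alleles(pl$trimmed, des)
  tab <- cluster_concordance(pl$annotations, calls)
  expect_gt(nrow(tab), 0L)
  expect_true(all(tab$percent_agreement == 100))
})

test_that("paired-read concordance matches the sequencing error model", {
  cfg <- sim_config(n_targets = 30, mean_depth = 200, duplicate_rate = 0,
                    het_fraction = 1, error_rate = 0, seed = 82)
  des <- generate_design(cfg)
  s <- generate_sample(des, cfg)
  pl <- run_dedup_pipeline(s$reads, des)
  c1 <- extract_alleles(pl$trimmed, des, read = 1)
  c2 <- extract_alleles(pl$trimmed, des, read = 2)
  expect_identical(paired_read_concordance(c1, c2), 1)
  expect_true(is.na(paired_read_concordance(c1[0, ], c2[0, ])))

  e <- 0.01
  cfg_e <- sim_config(n_targets = 30, mean_depth = 200, duplicate_rate = 0,
                      het_fraction = 1, error_rate = e, seed = 83)
  s_e <- generate_sample(des, cfg_e)
  pl_e <- run_dedup_pipeline(s_e$reads, des)
  conc <- paired_read_concordance(extract_alleles(pl_e$trimmed, des, read = 1),
                                  extract_alleles(pl_e$trimmed, des, read = 2))
  # both mates err independently: P(agree) ~= (1-e)^2 + e^2/3
  expect_lt(abs(conc - ((1 - e)^2 + e^2 / 3)), 0.008)
})

test_that("2x2 Fisher test is exact against enumeration and fisher.test", {
  expect_equal(fisher_2x2(250, 250, 250, 250), 1, tolerance = 1e-9)
  expect_identical(fisher_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)

  set.seed(84)
  for (i in 1:300) {
    x <- as.integer(sample(0:15, 4, replace = TRUE))
    p <- fisher_2x2(x[1], x[2], x[3], x[4])
    expect_equal(p, fisher_2x2_oracle(x[1], x[2], x[3], x[4]), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
  expect_error(fisher_2x2(-1, 0, 0, 0), "non-negative")
})

test_that("2x3 Fisher test matches fisher.test and responds to balance", {
  expect_identical(fisher_2x3(10, 0, 20, 0, 5, 0), 1)
  tab <- matrix(c(10, 0, 0, 10, 10, 0), nrow = 2)
  expect_equal(fisher_2x3(10, 0, 0, 10, 10, 0),
               stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  set.seed(85)
  for (i in 1:25) {
    x <- as.integer(sample(0:10, 6, replace = TRUE))
    if (sum(x) == 0) next
    expect_equal(fisher_2x3(x[1], x[2], x[3], x[4], x[5], x[6]),
                 stats::fisher.test(matrix(x, nrow = 2, byrow = FALSE))$p.value,
                 tolerance = 1e-8)
  }
  # proportionally identical columns sit nearer the null than a skew
  p_prop <- fisher_2x3(20, 20, 20, 20, 20, 20)
  p_skew <- fisher_2x3(30, 10, 10, 30, 20, 20)
  expect_gt(p_prop, p_skew)
  expect_equal(p_prop, 1, tolerance = 1e-9)

  # Monte-Carlo fallback approximates the exact enumeration
  exact <- fisher_2x3(60, 40, 45, 55, 50, 50)
  mc <- fisher_2x3(60, 40, 45, 55, 50, 50, max_enumeration = 10, seed = 86)
  expect_lt(abs(as.numeric(mc) - exact), 4 * attr(mc, "se") + 1e-3)
})

test_that("FPR computation counts sub-alpha p-values", {
  r <- compute_fpr(c(0.01, 0.2, 0.04, 0.5), alpha = 0.05)
  expect_equal(r$fpr, 0.5)
  expect_identical(r$n_tests, 4L)
  expect_equal(compute_fpr(rep(1, 10))$fpr, 0)
  expect_error(compute_fpr(numeric(0)), "no p-values")
})

test_that("BH selection matches the hand-computed threshold walk", {
  p <- c(rep(0.001, 5), rep(0.04, 5), rep(0.9, 90))
  sel <- smtdedup:::bh_select(p, fdr = 0.05)
  # by hand: sorted p(i) <= 0.05 * i / 100 holds through i = 5 only
  expect_identical(which(sel), 1:5)
})

test_that("somatic sites require signal, coverage and a clean germline", {
  counts <- rbind(
    data.frame(site = "s1", sample_id = c("G", "T1", "T2"),
               n_ref = c(100L, 50L, 70L), n_alt = c(0L, 50L, 30L)),
    data.frame(site = "s2", sample_id = c("G", "T1", "T2"),
               n_ref = c(50L, 50L, 60L), n_alt = c(50L, 52L, 48L)),
    data.frame(site = "s3", sample_id = c("G", "T1", "T2"),
               n_ref = c(20L, 100L, 100L), n_alt = c(0L, 100L, 100L)))
  res <- identify_somatic(counts, germline = "G")
  expect_identical(res$site, c("s1", "s2"))     # s3 fails 50X coverage in G
  expect_true(res$somatic[res$site == "s1"])    # strong shift, clean germline
  expect_false(res$somatic[res$site == "s2"])   # germline alt 50% >= 10%
  expect_error(identify_somatic(counts[counts$sample_id == "G", ], "G"),
               "at least one tumor")
})
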