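mutate_string <- function(s, n_sub = 0L, del_at = NULL, ins_at = NULL) {
  x <- strsplit(s, "")[[1]]
  if (n_sub > 0L) {
    pos <- sample(length(x), n_sub)
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
  }
  if (!is.null(del_at)) x <- x[-del_at]
  if (!is.null(ins_at)) x <- append(x, sample(c("A", "C", "G", "T"), 1), after = ins_at)
  paste(x, collapse = "")
}

test_that("bounded matcher agrees with full dynamic-programming edit distance", {
  set.seed(21)
  for (i in 1:300) {
    a <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    op <- sample(1:4, 1)
    b <- switch(op,
                mutate_string(a, n_sub = sample(0:4, 1)),
                mutate_string(a, del_at = sample(22, 1)),
                mutate_string(a, n_sub = 1, ins_at = sample(21, 1)),
                paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = ""))
    for (k in c(2L, 3L, 6L)) {
      expect_identical(smtdedup:::cpp_bounded_levenshtein(a, b, k),
                       min(lev_oracle(a, b), k + 1L))
    }
  }
})

test_that("match_prefix returns every candidate within bound, accepting indels", {
  set.seed(22)
  cand <- setNames(replicate(8, paste(sample(c("A", "C", "G", "T"), 22, TRUE),
                                      collapse = "")),
                   paste0("T", 1:8))
  res <- match_prefix(cand[[3]], cand)
  expect_true("T3" %in% res$target_id)
  expect_identical(res$distance[res$target_id == "T3"], 0L)
  # oracle comparison over all candidates
  full <- lev_oracle(cand[[3]], unname(cand))
  expect_setequal(res$target_id, names(cand)[full <= 2])

  two_sub <- mutate_string(cand[[5]], n_sub = 2)
  res <- match_prefix(two_sub, cand)
  expect_true(all(res$distance == lev_oracle(two_sub, cand[res$target_id])))

  # 1-base deletion plus a trailing base: Levenshtein must accept it
  del <- paste0(substr(cand[[1]], 2, 22), "A")
  res <- match_prefix(del, cand)
  expect_true("T1" %in% res$target_id)
  expect_lte(res$distance[res$target_id == "T1"], 2L)

  expect_error(match_prefix("ACGT", cand), "22 bases")
})

test_that("pair assignment separates ASSIGNED, CROSS_TARGET, NO_MATCH, AMBIGUOUS", {
  des <- small_design(4)
  r_ok <- make_pair(des, 2, read_id = "ok")
  # chimera: Read 1 from target 1, Read 2 from target 3
  r1 <- make_pair(des, 1)
  r3 <- make_pair(des, 3)
  r_cross <- r1; r_cross$seq2 <- r3$seq2; r_cross$read_id <- "cross"
  r_none <- r_ok
  r_none$read_id <- "none"
  r_none$seq1 <- strrep("ACGT", 38)
  r_none$seq2 <- strrep("TGCA", 38)
  reads <- rbind(r_ok, r_cross, r_none)
  asn <- assign_reads(reads, des)
  expect_identical(asn$status, c("ASSIGNED", "CROSS_TARGET", "NO_MATCH"))
  expect_identical(asn$target_id[1], des$targets$target_id[2])
  expect_identical(asn$dist1[1], 0L)
  expect_identical(asn$dist2[1], 0L)
  expect_true(is.na(asn$target_id[2]))
  qc <- assignment_qc(asn)
  expect_identical(qc$n[qc$status == "ASSIGNED"], 1L)
})

test_that("ties at minimal distance are AMBIGUOUS regardless of design order", {
  # two upstream windows at Hamming distance 2; a read prefix 1 edit from each
  wa <- strrep("A", 22)
  wb <- paste0(strrep("A", 20), "CC")
  mid <- paste0(strrep("A", 20), "CA")   # distance 1 from both
  base <- small_design(2)
  tg <- base$targets
  tg$upstream_primer <- c(paste0(wa, "GGG"), paste0(wb, "GGG"))
  des <- target_design(tg, check_separation = FALSE)
  rd <- make_pair(des, 1, read_id = "amb")
  rd$seq2 <- paste0(mid, substr(rd$seq2, 23, nchar(rd$seq2)))
  asn <- assign_reads(rd, des)
  expect_identical(asn$status, "AMBIGUOUS")
  # permuting the design must not resolve the tie
  des2 <- target_design(tg[2:1, ], check_separation = FALSE)
  expect_identical(assign_reads(rd, des2)$status, "AMBIGUOUS")
})

test_that("assignment does not depend on design order", {
  set.seed(23)
  cfg <- sim_config(n_targets = 10, mean_depth = 40, het_fraction = 0,
                    error_rate = 0.01, seed = 77)
  des <- generate_design(cfg)
  s <- generate_sample(des, cfg)
  a1 <- assign_reads(s$reads, des)
  perm <- sample(nrow(des$targets))
  des2 <- target_design(des$targets[perm, ], check_separation = FALSE)
  a2 <- assign_reads(s$reads, des2)
  expect_identical(a1$status, a2$status)
  expect_identical(a1$target_id, a2$target_id)
})

test_that("primer trimming yields insert-coordinate reads and filters short ones", {
  # 22-base primers, 150-base insert, 151-base reads -> 129 trimmed bases
  cfg <- sim_config(n_targets = 2, primer_length = 22, het_fraction = 0, seed = 31)
  des <- generate_design(cfg)
  reads <- make_pairs(des, 1:2, random_smts(2))
  expect_identical(unique(nchar(reads$seq1)), 151L)
  asn <- assign_reads(reads, des)
  trm <- trim_reads(reads, asn, des)
  expect_identical(unique(nchar(trm$seq1)), 129L)
  expect_identical(unique(nchar(trm$qual1)), 129L)

  # boundary: trimmed length 36 retained, 35 dropped
  short_des <- function(ins_len) {
    tg <- des$targets[1, ]
    tg$insert_seq <- substr(tg$insert_seq, 1, ins_len)
    target_design(tg, check_separation = FALSE)
  }
  for (ins_len in c(36L, 35L)) {
    d1 <- short_des(ins_len)
    rd <- make_pair(d1, 1)
    trm <- trim_reads(rd, assign_reads(rd, d1), d1)
    if (ins_len == 36L) {
      expect_identical(nrow(trm), 1L)
      expect_identical(nchar(trm$seq1), 36L)
      expect_identical(attr(trm, "qc")[["n_short"]], 0L)
    } else {
      expect_identical(nrow(trm), 0L)
      expect_identical(attr(trm, "qc")[["n_short"]], 1L)
    }
  }
})

test_that("error-free reads are fully recovered; noisy reads mostly", {
  cfg0 <- sim_config(n_targets = 25, mean_depth = 80, het_fraction = 0.2,
                     error_rate = 0, seed = 51)
  des <- generate_design(cfg0)
  s <- generate_sample(des, cfg0)
  asn <- assign_reads(s$reads, des)
  expect_true(all(asn$status == "ASSIGNED"))
  expect_identical(asn$target_id, s$truth$target_id)

  cfg1 <- sim_config(n_targets = 25, mean_depth = 200, het_fraction = 0.2,
                     error_rate = 0.005, seed = 52)
  s1 <- generate_sample(des, cfg1)
  asn1 <- assign_reads(s1$reads, des)
  frac <- mean(asn1$status == "ASSIGNED")
  expect_gte(frac, 0.9)
  # assigned reads are never mis-assigned (windows are well separated)
  ok <- asn1$status == "ASSIGNED"
  expect_identical(asn1$target_id[ok], s1$truth$target_id[ok])
})
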