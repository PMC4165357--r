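# Read-to-target assignment by bounded-edit-distance primer matching.
#
# The first 22 bases of Read 1 are compared against the reverse complement
# of each target's downstream locus-specific primer, and the first 22 bases
# of Read 2 against each upstream primer, allowing up to `max_dist`
# differences (Levenshtein, so indels are accepted). A pair is assigned
# only when both mates have the same unique minimal-distance target.

#' Match a 22-base read prefix against candidate primer windows
#'
#' Returns every candidate within `max_dist` edits (bounded Levenshtein,
#' banded dynamic programming). `N` in the read mismatches every base.
#'
#' @param prefix a 22-base string.
#' @param candidates named character vector (or data.frame with columns
#'   `target_id`, `window`) of 22-base primer-derived windows.
#' @param max_dist maximum edit distance (default 2).
#' @return data.frame with columns `target_id`, `distance`, one row per
#'   candidate within `max_dist`.
#' @export
match_prefix <- function(prefix, candidates, max_dist = 2L) {
  if (is.data.frame(candidates)) {
    ids <- candidates$target_id
    wins <- candidates$window
  } else {
    ids <- names(candidates)
    wins <- unname(candidates)
  }
  if (nchar(prefix) < 22L) {
    stop("prefix must be at least 22 bases, got ", nchar(prefix), call. = FALSE)
  }
  d <- cpp_prefix_distances(prefix, wins, as.integer(max_dist))
  keep <- d <= max_dist
  data.frame(target_id = ids[keep], distance = d[keep], stringsAsFactors = FALSE)
}

#' Assign read pairs to amplicon targets
#'
#' @param reads data.frame of tagged read pairs (see
#'   [read_fastq_triplet()]).
#' @param design a [target_design()].
#' @param max_dist maximum edit distance per mate (default 2).
#' @return data.frame with columns `read_id`, `target_id` (`NA` unless
#'   assigned), `dist1`, `dist2` (minimal distances; `NA` when no candidate
#'   is within `max_dist`) and `status`, one of `ASSIGNED` (both mates
#'   agree on one unique minimal-distance target), `CROSS_TARGET` (mates
#'   match different targets), `AMBIGUOUS` (a mate's minimal distance is
#'   tied between targets), `NO_MATCH`. Assignment is independent of the
#'   order of targets in the design.
#' @export
assign_reads <- function(reads, design, max_dist = 2L) {
  stopifnot(nrow(design$targets) > 0L)
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), target_id = character(0),
                      dist1 = integer(0), dist2 = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  if (any(nchar(reads$seq1) < 22L) || any(nchar(reads$seq2) < 22L)) {
    stop("all reads must be at least 22 bases for primer matching", call. = FALSE)
  }
  w <- design_windows(design)
  max_dist <- as.integer(max_dist)
  match_one_side <- function(prefixes, windows) {
    u <- unique(prefixes)
    m <- cpp_match_prefixes(u, windows, max_dist)
    m[match(prefixes, u), , drop = FALSE]
  }
  m1 <- match_one_side(substr(reads$seq1, 1L, 22L), w$w1)
  m2 <- match_one_side(substr(reads$seq2, 1L, 22L), w$w2)
  hit1 <- m1[, "dist"] <= max_dist
  hit2 <- m2[, "dist"] <= max_dist
  tie <- (hit1 & m1[, "tie"] == 1L) | (hit2 & m2[, "tie"] == 1L)
  status <- rep("NO_MATCH", nrow(reads))
  status[hit1 & hit2 & tie] <- "AMBIGUOUS"
  both <- hit1 & hit2 & !tie
  agree <- both & m1[, "index"] == m2[, "index"]
  status[both & !agree] <- "CROSS_TARGET"
  status[agree] <- "ASSIGNED"
  target_id <- rep(NA_character_, nrow(reads))
  target_id[agree] <- design$targets$target_id[m1[agree, "index"]]
  data.frame(read_id = reads$read_id,
             target_id = target_id,
             dist1 = ifelse(hit1, m1[, "dist"], NA_integer_),
             dist2 = ifelse(hit2, m2[, "dist"], NA_integer_),
             status = status, stringsAsFactors = FALSE)
}

#' Per-status counts of an assignment table
#'
#' @param assignments output of [assign_reads()].
#' @return data.frame with columns `status`, `n`, `fraction`.
#' @export
assignment_qc <- function(assignments) {
  lv <- c("ASSIGNED", "NO_MATCH", "CROSS_TARGET", "AMBIGUOUS")
  n <- vapply(lv, function(s) sum(assignments$status == s), integer(1))
  data.frame(status = lv, n = unname(n),
             fraction = if (sum(n) > 0) unname(n) / sum(n) else rep(NA_real_, 4L),
             stringsAsFactors = FALSE)
}

#' Trim primer sequence from assigned read pairs
#'
#' Removes the full primer-derived prefix from each mate and truncates any
#' 3' read-through beyond the insert (possible because the amplicon
#' boundaries are known from the design). Qualities are trimmed in
#' register. Pairs whose trimmed reads are not longer than `min_length`
#' bases are dropped and counted in the `qc` attribute.
#'
#' @param reads tagged read pairs.
#' @param assignments output of [assign_reads()] for the same reads.
#' @param design the [target_design()].
#' @param min_length minimal retained read length (exclusive; default 35).
#' @return data.frame of trimmed, `ASSIGNED` read pairs with their
#'   `target_id`; attribute `qc` holds `n_short` (pairs dropped as too
#'   short after trimming).
#' @export
trim_reads <- function(reads, assignments, design, min_length = 35L) {
  stopifnot(nrow(reads) == nrow(assignments))
  keep <- assignments$status == "ASSIGNED"
  r <- reads[keep, , drop = FALSE]
  ti <- match(assignments$target_id[keep], design$targets$target_id)
  len_up <- nchar(design$targets$upstream_primer)[ti]
  len_down <- nchar(design$targets$downstream_primer)[ti]
  ins_len <- nchar(design$targets$insert_seq)[ti]
  # Read 1 runs from the downstream end; its prefix is revcomp(downstream).
  r$seq1 <- substr(r$seq1, len_down + 1L, len_down + ins_len)
  r$qual1 <- substr(r$qual1, len_down + 1L, len_down + ins_len)
  r$seq2 <- substr(r$seq2, len_up + 1L, len_up + ins_len)
  r$qual2 <- substr(r$qual2, len_up + 1L, len_up + ins_len)
  r$target_id <- assignments$target_id[keep]
  long_enough <- nchar(r$seq1) > min_length & nchar(r$seq2) > min_length
  out <- r[long_enough, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- c(n_short = sum(!long_enough))
  out
}
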