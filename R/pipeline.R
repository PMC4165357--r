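#' Run the full deduplication pipeline on tagged read pairs
#'
#' Convenience wrapper chaining [assign_reads()], [trim_reads()] and
#' [mark_duplicates()], returning all intermediate tables plus the
#' per-sample duplicate-rate report and cluster-size histogram.
#'
#' @param reads tagged read pairs (see [read_fastq_triplet()]).
#' @param design a [target_design()].
#' @param max_dist assignment edit-distance bound (default 2).
#' @return list of class `smt_pipeline` with elements `assignments`,
#'   `assignment_qc`, `trimmed`, `annotations`, `report`, `histogram`.
#' @export
run_dedup_pipeline <- function(reads, design, max_dist = 2L) {
  asn <- assign_reads(reads, design, max_dist = max_dist)
  trm <- trim_reads(reads, asn, design)
  ann <- mark_duplicates(trm)
  structure(list(assignments = asn,
                 assignment_qc = assignment_qc(asn),
                 trimmed = trm,
                 annotations = ann,
                 report = duplicate_rate_report(ann, by = "sample"),
                 histogram = cluster_size_histogram(ann)),
            class = "smt_pipeline")
}

#' @export
print.smt_pipeline <- function(x, ...) {
  qc <- x$assignment_qc
  cat(sprintf("SMT dedup pipeline: %d read pairs, %.1f%% assigned\n",
              sum(qc$n), 100 * qc$fraction[qc$status == "ASSIGNED"]))
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %s: %d reads, %d unique, %d duplicates (rate %.3f)\n",
                r$sample_id[i], r$n_total[i], r$n_unique[i], r$n_duplicate[i],
                r$rate[i]))
  }
  invisible(x)
}
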