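# FASTQ triplets, design tables and result tables.
#
# Reads are represented as a plain data.frame with columns
# read_id, seq1, qual1, seq2, qual2, smt (and optionally sample_id); the
# SMT is the verbatim index-read sequence (8 or 12 bases). Parsing is
# chunked over connections so memory stays bounded by the chunk size, and
# gzip input is accepted transparently by suffix.

open_text <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

fastq_id_token <- function(header) {
  sub("\\s.*$", "", sub("^@", "", header))
}

# Read one chunk of FASTQ records from an open connection.
# Returns list(id=, seq=, qual=, lines_read=) or NULL at clean EOF.
read_fastq_chunk <- function(con, n_records, line_offset, path) {
  lines <- readLines(con, n = 4L * n_records)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ in '%s': truncated record at line %d",
                 path, line_offset + length(lines)), call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  plus <- lines[idx + 2L]
  seq <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ in '%s': expected '@' header at line %d",
                 path, line_offset + (bad[1L] - 1L) * 4L + 1L), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ in '%s': expected '+' separator at line %d",
                 path, line_offset + (bad[1L] - 1L) * 4L + 3L), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ in '%s': sequence/quality length mismatch at line %d",
                 path, line_offset + (bad[1L] - 1L) * 4L + 2L), call. = FALSE)
  }
  list(id = fastq_id_token(hdr), seq = seq, qual = qual,
       lines_read = length(lines))
}

#' Read an R1/R2/index FASTQ triplet into tagged read pairs
#'
#' The three files must contain the same records in the same order; the
#' index read carries the single molecule tag (SMT) verbatim. Records are
#' parsed in chunks, and either accumulated into one data.frame or handed
#' chunk-wise to `callback` (in which case nothing is accumulated and memory
#' use is independent of file size).
#'
#' @param r1_path,r2_path,index_path FASTQ files (plain or `.gz`).
#' @param sample_id sample label attached to every read pair.
#' @param chunk_size records parsed per chunk.
#' @param callback optional `function(chunk_df)` invoked per chunk.
#' @return data.frame with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `smt`, `sample_id` (invisibly `NULL` when `callback` is used).
#'   The tag length is recorded in attribute `smt_length`; mixing 8- and
#'   12-base tags in one run is rejected.
#' @export
read_fastq_triplet <- function(r1_path, r2_path, index_path, sample_id = "S1",
                               chunk_size = 100000L, callback = NULL) {
  con1 <- open_text(r1_path); on.exit(close(con1), add = TRUE)
  con2 <- open_text(r2_path); on.exit(close(con2), add = TRUE)
  coni <- open_text(index_path); on.exit(close(coni), add = TRUE)
  acc <- list(); off1 <- off2 <- offi <- 0L; n_seen <- 0L
  smt_len <- NULL
  repeat {
    c1 <- read_fastq_chunk(con1, chunk_size, off1, r1_path)
    c2 <- read_fastq_chunk(con2, chunk_size, off2, r2_path)
    ci <- read_fastq_chunk(coni, chunk_size, offi, index_path)
    if (is.null(c1) && is.null(c2) && is.null(ci)) break
    n1 <- if (is.null(c1)) 0L else length(c1$id)
    n2 <- if (is.null(c2)) 0L else length(c2$id)
    ni <- if (is.null(ci)) 0L else length(ci$id)
    if (n1 != n2 || n1 != ni) {
      stop(sprintf(paste0("record count mismatch between FASTQ files: ",
                          "first divergence at record %d ",
                          "(R1 has %s, R2 has %s, index has %s more records here)"),
                   n_seen + min(n1, n2, ni) + 1L, n1, n2, ni), call. = FALSE)
    }
    mism <- which(c1$id != c2$id | c1$id != ci$id)
    if (length(mism) > 0L) {
      stop(sprintf("read identifier mismatch at record %d: R1 '%s', R2 '%s', index '%s'",
                   n_seen + mism[1L], c1$id[mism[1L]], c2$id[mism[1L]],
                   ci$id[mism[1L]]), call. = FALSE)
    }
    lens <- unique(nchar(ci$seq))
    if (is.null(smt_len)) {
      if (!all(lens %in% c(8L, 12L))) {
        stop("index read (SMT) length must be 8 or 12 bases, found: ",
             paste(setdiff(lens, c(8L, 12L)), collapse = ", "), call. = FALSE)
      }
      smt_len <- lens[1L]
    }
    if (any(lens != smt_len)) {
      stop("mixed SMT lengths within one run are not supported", call. = FALSE)
    }
    chunk <- data.frame(read_id = c1$id, seq1 = c1$seq, qual1 = c1$qual,
                        seq2 = c2$seq, qual2 = c2$qual, smt = ci$seq,
                        sample_id = sample_id, stringsAsFactors = FALSE)
    if (is.null(callback)) acc[[length(acc) + 1L]] <- chunk else callback(chunk)
    n_seen <- n_seen + n1
    off1 <- off1 + c1$lines_read; off2 <- off2 + c2$lines_read
    offi <- offi + ci$lines_read
  }
  if (!is.null(callback)) return(invisible(NULL))
  out <- if (length(acc) == 0L) {
    data.frame(read_id = character(0), seq1 = character(0), qual1 = character(0),
               seq2 = character(0), qual2 = character(0), smt = character(0),
               sample_id = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, acc)
  }
  attr(out, "smt_length") <- smt_len
  out
}

#' Read paired FASTQ with the SMT embedded in the read name
#'
#' Supports demultiplexers that move the index read into the read name as
#' `name<delimiter>SMT`. The suffix is stripped from the returned
#' `read_id`.
#'
#' @inheritParams read_fastq_triplet
#' @param delimiter single character separating the name from the tag.
#' @export
read_fastq_with_header_smt <- function(r1_path, r2_path, delimiter = ":",
                                       sample_id = "S1", chunk_size = 100000L,
                                       callback = NULL) {
  stopifnot(nchar(delimiter) == 1L)
  con1 <- open_text(r1_path); on.exit(close(con1), add = TRUE)
  con2 <- open_text(r2_path); on.exit(close(con2), add = TRUE)
  acc <- list(); off1 <- off2 <- 0L; n_seen <- 0L
  repeat {
    c1 <- read_fastq_chunk(con1, chunk_size, off1, r1_path)
    c2 <- read_fastq_chunk(con2, chunk_size, off2, r2_path)
    if (is.null(c1) && is.null(c2)) break
    n1 <- if (is.null(c1)) 0L else length(c1$id)
    n2 <- if (is.null(c2)) 0L else length(c2$id)
    if (n1 != n2) {
      stop(sprintf("record count mismatch between FASTQ files: first divergence at record %d",
                   n_seen + min(n1, n2) + 1L), call. = FALSE)
    }
    pos <- regexpr(paste0("\\", delimiter, "[^", "\\", delimiter, "]*$"), c1$id)
    bad <- which(pos < 0L)
    if (length(bad) > 0L) {
      stop(sprintf("read name '%s' (record %d) carries no '%s'-delimited SMT suffix",
                   c1$id[bad[1L]], n_seen + bad[1L], delimiter), call. = FALSE)
    }
    smt <- substring(c1$id, pos + 1L)
    name <- substring(c1$id, 1L, pos - 1L)
    mism <- which(c1$id != c2$id)
    if (length(mism) > 0L) {
      stop(sprintf("read identifier mismatch at record %d: R1 '%s', R2 '%s'",
                   n_seen + mism[1L], c1$id[mism[1L]], c2$id[mism[1L]]), call. = FALSE)
    }
    chunk <- data.frame(read_id = name, seq1 = c1$seq, qual1 = c1$qual,
                        seq2 = c2$seq, qual2 = c2$qual, smt = smt,
                        sample_id = sample_id, stringsAsFactors = FALSE)
    if (is.null(callback)) acc[[length(acc) + 1L]] <- chunk else callback(chunk)
    n_seen <- n_seen + n1
    off1 <- off1 + c1$lines_read; off2 <- off2 + c2$lines_read
  }
  if (!is.null(callback)) return(invisible(NULL))
  if (length(acc) == 0L) {
    return(data.frame(read_id = character(0), seq1 = character(0),
                      qual1 = character(0), seq2 = character(0),
                      qual2 = character(0), smt = character(0),
                      sample_id = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, acc)
}

#' Write tagged read pairs as an R1/R2/index FASTQ triplet
#'
#' The index record's quality string is a constant run of Phred-33 Q30
#' (`?`), as tag qualities are not retained in the read table.
#'
#' @param reads data.frame as returned by [read_fastq_triplet()].
#' @param r1_path,r2_path,index_path output paths (plain or `.gz`).
#' @export
write_fastq_triplet <- function(reads, r1_path, r2_path, index_path) {
  write_one <- function(path, seq, qual) {
    con <- open_text(path, "wt"); on.exit(close(con))
    if (nrow(reads) > 0L) {
      writeLines(paste0("@", reads$read_id, "\n", seq, "\n+\n", qual), con)
    }
    invisible(NULL)
  }
  write_one(r1_path, reads$seq1, reads$qual1)
  write_one(r2_path, reads$seq2, reads$qual2)
  write_one(index_path, reads$smt, strrep("?", nchar(reads$smt)))
  invisible(c(r1_path, r2_path, index_path))
}

#' Write paired FASTQ with the SMT appended to the read name
#'
#' @inheritParams write_fastq_triplet
#' @param delimiter single character placed between name and tag.
#' @export
write_fastq_with_header_smt <- function(reads, r1_path, r2_path, delimiter = ":") {
  names <- paste0(reads$read_id, delimiter, reads$smt)
  write_one <- function(path, seq, qual) {
    con <- open_text(path, "wt"); on.exit(close(con))
    if (nrow(reads) > 0L) writeLines(paste0("@", names, "\n", seq, "\n+\n", qual), con)
    invisible(NULL)
  }
  write_one(r1_path, reads$seq1, reads$qual1)
  write_one(r2_path, reads$seq2, reads$qual2)
  invisible(c(r1_path, r2_path))
}

#' Construct an amplicon target design
#'
#' @param targets data.frame with columns `target_id`, `upstream_primer`,
#'   `downstream_primer`, `insert_seq`.
#' @param snps data.frame with columns `target_id`, `position` (0-based
#'   offset within the insert), `ref_allele`, `alt_allele`; may be empty.
#' @param check_separation verify that the 22-bp matching windows of
#'   different targets are mutually farther than edit distance 2, so that
#'   error-free reads can never be mis-assigned. Designs violating this are
#'   rejected.
#' @return object of class `target_design`.
#' @export
target_design <- function(targets, snps = NULL, check_separation = TRUE) {
  req <- c("target_id", "upstream_primer", "downstream_primer", "insert_seq")
  stopifnot(is.data.frame(targets), all(req %in% names(targets)))
  targets <- targets[, req]
  targets[] <- lapply(targets, as.character)
  if (anyDuplicated(targets$target_id)) {
    stop("duplicate target_id: ",
         targets$target_id[duplicated(targets$target_id)][1L], call. = FALSE)
  }
  for (col in c("upstream_primer", "downstream_primer", "insert_seq")) {
    bad <- which(!is_dna(targets[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("target '%s': %s contains a non-ACGT character",
                   targets$target_id[bad[1L]], col), call. = FALSE)
    }
  }
  short <- which(nchar(targets$upstream_primer) < 22L |
                 nchar(targets$downstream_primer) < 22L)
  if (length(short) > 0L) {
    stop(sprintf("target '%s': primers must be at least 22 bases",
                 targets$target_id[short[1L]]), call. = FALSE)
  }
  if (is.null(snps) || nrow(snps) == 0L) {
    snps <- data.frame(target_id = character(0), position = integer(0),
                       ref_allele = character(0), alt_allele = character(0),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("target_id", "position", "ref_allele", "alt_allele") %in% names(snps)))
    snps <- data.frame(target_id = as.character(snps$target_id),
                       position = as.integer(snps$position),
                       ref_allele = as.character(snps$ref_allele),
                       alt_allele = as.character(snps$alt_allele),
                       stringsAsFactors = FALSE)
    unknown <- setdiff(snps$target_id, targets$target_id)
    if (length(unknown) > 0L) {
      stop("SNP annotation for unknown target: ", unknown[1L], call. = FALSE)
    }
    ins_len <- nchar(targets$insert_seq)[match(snps$target_id, targets$target_id)]
    bad <- which(snps$position < 0L | snps$position >= ins_len)
    if (length(bad) > 0L) {
      stop(sprintf("target '%s': SNP position %d outside insert [0, %d)",
                   snps$target_id[bad[1L]], snps$position[bad[1L]], ins_len[bad[1L]]),
           call. = FALSE)
    }
    bad <- which(!(snps$ref_allele %in% DNA_BASES) | !(snps$alt_allele %in% DNA_BASES) |
                 snps$ref_allele == snps$alt_allele)
    if (length(bad) > 0L) {
      stop(sprintf("target '%s': SNP alleles must be distinct single bases",
                   snps$target_id[bad[1L]]), call. = FALSE)
    }
  }
  des <- structure(list(targets = targets, snps = snps), class = "target_design")
  if (check_separation && nrow(targets) > 1L) {
    w <- design_windows(des)
    for (set in list(w$w1, w$w2)) {
      off <- cpp_check_separation(set, 3L)
      if (length(off) > 0L) {
        stop(sprintf(paste0("targets '%s' and '%s' have matching windows within ",
                            "edit distance 2; such designs cannot be demultiplexed"),
                     targets$target_id[off[1L]], targets$target_id[off[2L]]),
             call. = FALSE)
      }
    }
  }
  des
}

#' @export
print.target_design <- function(x, ...) {
  cat(sprintf("Amplicon target design: %d targets, insert length %s bp, %d SNP annotations\n",
              nrow(x$targets),
              paste(range(nchar(x$targets$insert_seq)), collapse = "-"),
              nrow(x$snps)))
  invisible(x)
}

# The 22-bp windows each read prefix is matched against:
# Read 1 begins in the reverse complement of the downstream primer,
# Read 2 in the upstream primer.
design_windows <- function(design) {
  list(w1 = substr(cpp_revcomp(design$targets$downstream_primer), 1L, 22L),
       w2 = substr(design$targets$upstream_primer, 1L, 22L))
}

#' Load an amplicon design table
#'
#' Expects a TSV with header columns `target_id`, `upstream_primer`,
#' `downstream_primer`, `insert_seq` and optional semicolon-separated
#' `snp_positions`, `snp_ref`, `snp_alt` (0-based positions within the
#' insert).
#'
#' @param path TSV file.
#' @inheritParams target_design
#' @return object of class `target_design`.
#' @export
load_design <- function(path, check_separation = TRUE) {
  tab <- read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  req <- c("target_id", "upstream_primer", "downstream_primer", "insert_seq")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("design table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  snps <- NULL
  if ("snp_positions" %in% names(tab)) {
    rows <- which(!is.na(tab$snp_positions) & tab$snp_positions != "")
    if (length(rows) > 0L) {
      lst <- lapply(rows, function(i) {
        pos <- strsplit(tab$snp_positions[i], ";", fixed = TRUE)[[1L]]
        ref <- strsplit(tab$snp_ref[i], ";", fixed = TRUE)[[1L]]
        alt <- strsplit(tab$snp_alt[i], ";", fixed = TRUE)[[1L]]
        if (length(ref) != length(pos) || length(alt) != length(pos)) {
          stop(sprintf("target '%s': snp_positions/snp_ref/snp_alt lengths differ",
                       tab$target_id[i]), call. = FALSE)
        }
        data.frame(target_id = tab$target_id[i], position = as.integer(pos),
                   ref_allele = ref, alt_allele = alt, stringsAsFactors = FALSE)
      })
      snps <- do.call(rbind, lst)
    }
  }
  target_design(tab[, req], snps, check_separation = check_separation)
}

#' Write an amplicon design table
#'
#' Inverse of [load_design()]; round-trips losslessly.
#'
#' @param design a `target_design`.
#' @param path output TSV path.
#' @export
write_design <- function(design, path) {
  tab <- design$targets
  join <- function(f) {
    vapply(tab$target_id, function(t) {
      s <- design$snps[design$snps$target_id == t, ]
      paste(f(s), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  tab$snp_positions <- join(function(s) s$position)
  tab$snp_ref <- join(function(s) s$ref_allele)
  tab$snp_alt <- join(function(s) s$alt_allele)
  write_results_table(tab, path)
}

#' Write a results table as TSV
#'
#' Deterministic column order (as given), no quoting, no row names;
#' round-trips losslessly through [read_results_table()].
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
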