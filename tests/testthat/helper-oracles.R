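# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the code paths they check: naive string splicing instead
# of Biostrings::replaceAt, exhaustive search instead of greedy matching.

random_genome <- function(len, contig = "chr") {
  reference_genome(contig,
                   paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = ""))
}

naive_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Re-apply a truth set with plain substr/paste, editing right-to-left so
# earlier coordinates stay valid.
naive_apply_svs <- function(sequence, truth) {
  truth <- truth[order(truth$start, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    s <- truth$start[i]; e <- truth$end[i]; n <- nchar(sequence)
    left <- substr(sequence, 1, s - 1)
    sequence <- switch(truth$svtype[i],
      DEL = paste0(left, substr(sequence, e + 1, n)),
      INS = paste0(substr(sequence, 1, s), truth$inserted_seq[i],
                   substr(sequence, s + 1, n)),
      DUP = paste0(substr(sequence, 1, e), substr(sequence, s, e),
                   substr(sequence, e + 1, n)),
      INV = paste0(left, naive_revcomp(substr(sequence, s, e)),
                   substr(sequence, e + 1, n))
    )
  }
  sequence
}

# eligibility matrix truth x calls under the three matching conditions
eligibility_matrix <- function(truth, calls, criteria = match_criteria()) {
  ok <- outer(truth$contig, calls$contig, `==`) &
    outer(truth$svtype, calls$svtype, `==`) &
    abs(outer(truth$start, calls$start, `-`)) <= criteria$start_tol_bp &
    abs(outer(truth$length, calls$length, `-`)) <=
      criteria$len_tol_frac * truth$length
  ok
}

# exhaustive maximum-cardinality bipartite matching (small instances only)
max_matching_size <- function(elig) {
  nt <- nrow(elig); nc <- ncol(elig)
  if (nt == 0L || nc == 0L) return(0L)
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(elig[i, ])) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nc))
}

# random small SV table on one contig for matcher fuzzing
random_sv_table <- function(n, genome_len = 1e5, source = "x",
                            line_id = "") {
  if (n == 0L) return(empty_sv_records())
  lens <- sample(50:500, n, replace = TRUE)
  sv_records(contig = "chr",
             start = sample.int(genome_len - 600L, n, replace = TRUE),
             svtype = sample(c("INS", "DEL", "DUP", "INV"), n, TRUE),
             length = lens, source = source, line_id = line_id)
}

# strip row names for identity comparisons of SV tables
unrowname <- function(df) {
  rownames(df) <- NULL
  df
}

sv_core_cols <- c("contig", "start", "svtype", "length", "end",
                  "inserted_seq", "imprecise")
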