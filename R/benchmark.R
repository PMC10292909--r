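# Match SV call sets against a truth set and compute sensitivity, precision
# and F1. A call validates a truth record when three conditions hold: same
# SV type, start within a breakpoint tolerance, and length within a
# fractional tolerance of the truth length. Assignment is one-to-one, so an
# unmatched call counts as exactly one false positive.

#' Matching criteria for SV comparison
#'
#' The same tolerance triple drives benchmarking against simulated truth
#' (inclusive: within +/-30 bp, length differing by no more than 30\%),
#' deduplication across platforms, and recurrence clustering. Sanger-style
#' validation uses strict inequalities via [validate_call()].
#'
#' @param start_tol_bp breakpoint-start tolerance in bp (default 30;
#'   100 for validation against Sanger-resolved loci).
#' @param len_tol_frac fractional length tolerance relative to the TRUTH
#'   record's length (default 0.30).
#' @param require_same_type must SV types match (default TRUE).
#' @return an object of class `match_criteria`.
#' @export
match_criteria <- function(start_tol_bp = 30L, len_tol_frac = 0.30,
                           require_same_type = TRUE) {
  if (start_tol_bp < 0L) stop("start_tol_bp must be >= 0")
  if (len_tol_frac < 0 || len_tol_frac >= 1)
    stop("len_tol_frac must lie in [0, 1)")
  structure(list(start_tol_bp = as.integer(start_tol_bp),
                 len_tol_frac = len_tol_frac,
                 require_same_type = isTRUE(require_same_type)),
            class = "match_criteria")
}

#' Test one truth/call pair against the matching criteria
#'
#' @param truth_rec one-row SV table (the simulated/confirmed record).
#' @param call one-row SV table (the candidate call).
#' @param criteria a [match_criteria()].
#' @return list with `match` (logical) and `reason`: `"ok"`, or the first
#'   failed condition among `"type"`, `"start"`, `"length"` (contig mismatch
#'   reports `"contig"`).
#' @export
match_pair <- function(truth_rec, call, criteria = match_criteria()) {
  if (truth_rec$contig != call$contig)
    return(list(match = FALSE, reason = "contig"))
  if (criteria$require_same_type && truth_rec$svtype != call$svtype)
    return(list(match = FALSE, reason = "type"))
  if (abs(call$start - truth_rec$start) > criteria$start_tol_bp)
    return(list(match = FALSE, reason = "start"))
  if (abs(call$length - truth_rec$length) >
      criteria$len_tol_frac * truth_rec$length)
    return(list(match = FALSE, reason = "length"))
  list(match = TRUE, reason = "ok")
}

# Eligible (truth, call) pairs on one contig, as a data.frame ordered by the
# greedy priority: |dstart|, then relative length difference, then call start.
eligible_pairs <- function(truth, calls, criteria) {
  if (nrow(truth) == 0L || nrow(calls) == 0L)
    return(data.frame(ti = integer(0), ci = integer(0)))
  dstart <- abs(outer(truth$start, calls$start, `-`))
  dlen <- abs(outer(truth$length, calls$length, `-`))
  ok <- dstart <= criteria$start_tol_bp &
    dlen <= criteria$len_tol_frac * truth$length &
    outer(truth$contig, calls$contig, `==`)
  if (criteria$require_same_type)
    ok <- ok & outer(truth$svtype, calls$svtype, `==`)
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(ti = integer(0), ci = integer(0)))
  ti <- idx[, 1]; ci <- idx[, 2]
  rel <- dlen[idx] / truth$length[ti]
  ord <- order(dstart[idx], rel, calls$start[ci], ti)
  data.frame(ti = ti[ord], ci = ci[ord])
}

#' Match a call set against a truth set
#'
#' One-to-one greedy assignment: eligible pairs (all three conditions hold)
#' are taken in order of smallest start difference, ties broken by smallest
#' relative length difference, then earlier call position. Each truth record
#' matches at most one call and vice versa; multi-contig inputs are handled
#' per contig. Deterministic.
#'
#' @param truth truth SV table.
#' @param calls candidate SV table.
#' @param criteria a [match_criteria()].
#' @return a list of class `sv_assignment` with `pairs` (data.frame of
#'   matched `truth_idx`, `call_idx` row indices), `unmatched_truth` and
#'   `unmatched_calls` (integer row indices).
#' @export
match_callsets <- function(truth, calls, criteria = match_criteria()) {
  truth <- validate_sv_records(truth)
  calls <- validate_sv_records(calls)
  cand <- eligible_pairs(truth, calls, criteria)
  t_free <- rep(TRUE, nrow(truth))
  c_free <- rep(TRUE, nrow(calls))
  ti_out <- integer(0); ci_out <- integer(0)
  for (k in seq_len(nrow(cand))) {
    ti <- cand$ti[k]; ci <- cand$ci[k]
    if (t_free[ti] && c_free[ci]) {
      t_free[ti] <- FALSE
      c_free[ci] <- FALSE
      ti_out <- c(ti_out, ti)
      ci_out <- c(ci_out, ci)
    }
  }
  structure(
    list(pairs = data.frame(truth_idx = ti_out, call_idx = ci_out),
         unmatched_truth = which(t_free),
         unmatched_calls = which(c_free),
         n_truth = nrow(truth), n_calls = nrow(calls)),
    class = "sv_assignment"
  )
}

#' Confusion counts from an assignment
#'
#' @param assignment an object from [match_callsets()].
#' @return list of class `confusion_counts`: `tp` (matched pairs), `fn`
#'   (unmatched truth), `fp` (unmatched calls).
#' @export
confusion <- function(assignment) {
  stopifnot(inherits(assignment, "sv_assignment"))
  structure(list(tp = nrow(assignment$pairs),
                 fn = length(assignment$unmatched_truth),
                 fp = length(assignment$unmatched_calls)),
            class = "confusion_counts")
}

#' Sensitivity, precision and F1 from confusion counts
#'
#' sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2 * sensitivity * precision / (sensitivity + precision); each
#' component is defined as 0 when its denominator is 0.
#'
#' @param counts a `confusion_counts` object or a list with `tp`, `fn`, `fp`.
#' @return list of class `sv_metrics` with `sensitivity`, `precision`, `f1`.
#' @export
sv_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  structure(list(sensitivity = sens, precision = prec, f1 = f1),
            class = "sv_metrics")
}

#' Benchmark a call set: assignment, counts and metrics in one step
#'
#' @param truth truth SV table.
#' @param calls candidate SV table.
#' @param criteria a [match_criteria()].
#' @param by_type also compute per-SV-type rows (default TRUE).
#' @return a data.frame with one `overall` row (and one per SV type present)
#'   holding tp/fp/fn, sensitivity, precision, f1.
#' @export
benchmark_calls <- function(truth, calls, criteria = match_criteria(),
                            by_type = TRUE) {
  one <- function(tr, cl, label) {
    cc <- confusion(match_callsets(tr, cl, criteria))
    m <- sv_metrics(cc)
    data.frame(stratum = label, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               sensitivity = m$sensitivity, precision = m$precision,
               f1 = m$f1, stringsAsFactors = FALSE)
  }
  out <- one(truth, calls, "overall")
  if (by_type) {
    for (ty in intersect(SV_TYPES, unique(c(truth$svtype, calls$svtype)))) {
      out <- rbind(out, one(truth[truth$svtype == ty, , drop = FALSE],
                            calls[calls$svtype == ty, , drop = FALSE], ty))
    }
  }
  out
}
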