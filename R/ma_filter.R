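# The candidate-filtering cascade applied to MA-line call sets before
# validation: subtract ancestor-inherited variants, drop imprecise calls,
# remove SVs recurring in >= 3 lines of a platform set (systematic reference
# artifacts), merge the short- and long-read call sets per line, and classify
# candidates against Sanger-resolved loci. Every filter only removes or
# merges records; none fabricates calls, and each is idempotent.

#' A per-line call set
#'
#' @param line_id MA line identifier (non-empty; ancestors conventionally use
#'   `"ancestor"`).
#' @param calls an SV record table; `line_id` is stamped onto the records.
#' @param strain `"WT"` or `"mutS_deficient"`.
#' @param platform `"short_read"` or `"long_read"`.
#' @return an object of class `line_callset`.
#' @export
line_callset <- function(line_id, calls = empty_sv_records(),
                         strain = c("WT", "mutS_deficient"),
                         platform = c("short_read", "long_read")) {
  if (!nzchar(line_id)) stop("line_id must be non-empty")
  strain <- match.arg(strain)
  platform <- match.arg(platform)
  calls <- validate_sv_records(calls)
  if (nrow(calls) > 0L) calls$line_id <- line_id
  structure(list(line_id = line_id, strain = strain, platform = platform,
                 calls = calls),
            class = "line_callset")
}

#' @export
print.line_callset <- function(x, ...) {
  cat("<line_callset> ", x$line_id, " [", x$strain, ", ", x$platform, "]: ",
      nrow(x$calls), " calls\n", sep = "")
  invisible(x)
}

# does `call` (one row) match any row of `against` under criteria?
matches_any <- function(call, against, criteria) {
  if (nrow(against) == 0L) return(FALSE)
  same <- against$contig == call$contig &
    abs(against$start - call$start) <= criteria$start_tol_bp
  if (criteria$require_same_type) same <- same & against$svtype == call$svtype
  # tolerance relative to the reference/ancestor record being compared to
  same <- same &
    abs(against$length - call$length) <= criteria$len_tol_frac * against$length
  any(same)
}

#' Remove ancestor-inherited calls from a line
#'
#' Calls matching any ancestor call under `criteria` are removed; record
#' order is preserved. Idempotent.
#'
#' @param line a [line_callset()].
#' @param ancestor a [line_callset()] for the strain's ancestor (same
#'   platform).
#' @param criteria a [match_criteria()].
#' @return the filtered [line_callset()], with attribute `n_removed`.
#' @export
subtract_ancestor <- function(line, ancestor, criteria = match_criteria()) {
  stopifnot(inherits(line, "line_callset"), inherits(ancestor, "line_callset"))
  if (line$platform != ancestor$platform)
    stop("line and ancestor call sets must come from the same platform")
  if (nrow(line$calls) == 0L || nrow(ancestor$calls) == 0L) {
    attr(line, "n_removed") <- 0L
    return(line)
  }
  keep <- !vapply(seq_len(nrow(line$calls)), function(i) {
    matches_any(line$calls[i, ], ancestor$calls, criteria)
  }, logical(1))
  out <- line
  out$calls <- line$calls[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# single-linkage clusters over all calls of a line set, via union-find
cluster_calls <- function(all_calls, criteria) {
  n <- nrow(all_calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ctg <- all_calls$contig; ty <- all_calls$svtype
  st <- all_calls$start; ln <- all_calls$length
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    hit <- j[ctg[j] == ctg[i] & ty[j] == ty[i] &
             abs(st[j] - st[i]) <= criteria$start_tol_bp &
             abs(ln[j] - ln[i]) <= criteria$len_tol_frac * ln[j]]
    for (jj in hit) {
      ri <- find(i); rj <- find(jj)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Remove SVs recurring across MA lines
#'
#' Calls from all lines (one platform) are clustered by single linkage under
#' `criteria`; every cluster touching at least `threshold` distinct lines is
#' removed from every line. Recurrent candidates are systematic artifacts of
#' the reference or the caller, not independent mutations. Idempotent and
#' deterministic.
#'
#' @param lines list of [line_callset()] objects from one platform.
#' @param threshold minimum number of distinct lines for removal (default 3).
#' @param criteria a [match_criteria()].
#' @return list with `lines` (filtered, same order) and `removed_clusters`
#'   (data.frame: `cluster`, `n_lines`, `line_ids`, representative
#'   coordinates).
#' @export
recurrence_filter <- function(lines, threshold = 3L,
                              criteria = match_criteria()) {
  stopifnot(all(vapply(lines, inherits, logical(1), "line_callset")))
  platforms <- unique(vapply(lines, `[[`, character(1), "platform"))
  if (length(platforms) > 1L)
    stop("recurrence_filter expects lines from a single platform")
  all_calls <- do.call(rbind, lapply(lines, `[[`, "calls"))
  empty_rep <- data.frame(cluster = integer(0), n_lines = integer(0),
                          line_ids = character(0), contig = character(0),
                          start = integer(0), svtype = character(0),
                          length = integer(0), stringsAsFactors = FALSE)
  if (is.null(all_calls) || nrow(all_calls) == 0L)
    return(list(lines = lines, removed_clusters = empty_rep))
  comp <- cluster_calls(all_calls, criteria)
  lines_per_cluster <- tapply(all_calls$line_id, comp,
                              function(x) length(unique(x)))
  bad <- as.integer(names(lines_per_cluster)[lines_per_cluster >= threshold])
  drop_row <- comp %in% bad
  report <- empty_rep
  for (cl in bad) {
    rows <- all_calls[comp == cl, , drop = FALSE]
    report <- rbind(report, data.frame(
      cluster = cl, n_lines = length(unique(rows$line_id)),
      line_ids = paste(sort(unique(rows$line_id)), collapse = ","),
      contig = rows$contig[1], start = min(rows$start),
      svtype = rows$svtype[1], length = rows$length[1],
      stringsAsFactors = FALSE))
  }
  # map filtered rows back to their lines
  offsets <- c(0L, cumsum(vapply(lines, function(l) nrow(l$calls), integer(1))))
  out <- lines
  for (k in seq_along(lines)) {
    idx <- (offsets[k] + 1L):offsets[k + 1L]
    if (offsets[k + 1L] == offsets[k]) next
    keep <- !drop_row[idx]
    out[[k]]$calls <- lines[[k]]$calls[keep, , drop = FALSE]
  }
  list(lines = out, removed_clusters = report)
}

#' Drop imprecise calls
#'
#' Removes calls whose breakpoints the caller flagged as imprecise (INFO
#' IMPRECISE), the pre-validation filter applied to long-read candidates.
#'
#' @param line a [line_callset()].
#' @return the filtered [line_callset()], with attribute `n_removed`.
#' @export
drop_imprecise <- function(line) {
  stopifnot(inherits(line, "line_callset"))
  keep <- !line$calls$imprecise
  out <- line
  out$calls <- line$calls[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Merge short- and long-read call sets for one line
#'
#' Union with deduplication: when a short-read call matches a long-read call
#' under `criteria`, the long-read record is kept as the representative
#' (long-read breakpoints being the more reliable) and the merged record's
#' `source` carries both provenances. Matching is one-to-one via
#' [match_callsets()].
#'
#' @param short_calls [line_callset()] with `platform = "short_read"`.
#' @param long_calls [line_callset()] with `platform = "long_read"`; must
#'   share `line_id` with `short_calls`.
#' @param criteria a [match_criteria()].
#' @return a merged [line_callset()] (platform `"long_read"` representative
#'   coordinates; order: long-read records, then unmatched short-read ones).
#' @export
merge_platforms <- function(short_calls, long_calls,
                            criteria = match_criteria()) {
  stopifnot(inherits(short_calls, "line_callset"),
            inherits(long_calls, "line_callset"))
  if (short_calls$line_id != long_calls$line_id)
    stop("line_id mismatch: ", short_calls$line_id, " vs ",
         long_calls$line_id)
  lc <- long_calls$calls
  sc <- short_calls$calls
  asg <- match_callsets(lc, sc, criteria)
  if (nrow(asg$pairs) > 0L) {
    li <- asg$pairs$truth_idx
    si <- asg$pairs$call_idx
    lc$source[li] <- paste(lc$source[li], sc$source[si], sep = "+")
  }
  merged <- rbind(lc, sc[asg$unmatched_calls, , drop = FALSE])
  structure(list(line_id = long_calls$line_id, strain = long_calls$strain,
                 platform = "merged", calls = merged),
            class = "line_callset")
}

#' Classify a candidate against its Sanger-resolved locus
#'
#' A candidate is a true positive iff the Sanger-resolved SV has the same
#' type, the start difference is strictly below 100 bp, and the length
#' difference is strictly below 30\% of the Sanger length.
#'
#' @param call one-row SV table (the candidate).
#' @param sanger one-row SV table (the variant resolved by Sanger
#'   sequencing across the locus).
#' @param start_tol_bp strict start threshold (default 100).
#' @param len_tol_frac strict fractional length threshold (default 0.30).
#' @return list of class `validation_verdict` with `status`
#'   (`"true_positive"`/`"false_positive"`) and `reason`.
#' @export
validate_call <- function(call, sanger, start_tol_bp = 100L,
                          len_tol_frac = 0.30) {
  reason <- "ok"
  tp <- TRUE
  if (call$svtype != sanger$svtype) {
    tp <- FALSE; reason <- "type"
  } else if (!(abs(call$start - sanger$start) < start_tol_bp)) {
    tp <- FALSE; reason <- "start"
  } else if (!(abs(call$length - sanger$length) <
               len_tol_frac * sanger$length)) {
    tp <- FALSE; reason <- "length"
  }
  structure(list(call = call,
                 status = if (tp) "true_positive" else "false_positive",
                 reason = reason),
            class = "validation_verdict")
}

#' Run the default filter cascade on one platform's line set
#'
#' Applies, in order: ancestor subtraction, imprecise removal (optional),
#' and the cross-line recurrence filter. The order is configurable upstream;
#' this helper fixes the default and reports per-stage removal counts.
#'
#' @param lines list of [line_callset()] objects (one platform).
#' @param ancestor [line_callset()] of the strain ancestor on that platform.
#' @param criteria a [match_criteria()].
#' @param recurrence_threshold minimum line count for recurrence removal.
#' @param drop_imprecise_calls remove imprecise calls (default TRUE).
#' @return list with `lines` (filtered) and `report` (data.frame of counts
#'   per line per stage).
#' @export
filter_cascade <- function(lines, ancestor, criteria = match_criteria(),
                           recurrence_threshold = 3L,
                           drop_imprecise_calls = TRUE) {
  n0 <- vapply(lines, function(l) nrow(l$calls), integer(1))
  lines <- lapply(lines, subtract_ancestor, ancestor = ancestor,
                  criteria = criteria)
  n1 <- vapply(lines, function(l) nrow(l$calls), integer(1))
  if (drop_imprecise_calls) lines <- lapply(lines, drop_imprecise)
  n2 <- vapply(lines, function(l) nrow(l$calls), integer(1))
  rec <- recurrence_filter(lines, threshold = recurrence_threshold,
                           criteria = criteria)
  n3 <- vapply(rec$lines, function(l) nrow(l$calls), integer(1))
  report <- data.frame(
    line_id = vapply(lines, `[[`, character(1), "line_id"),
    input = n0, after_ancestor = n1, after_imprecise = n2,
    after_recurrence = n3, stringsAsFactors = FALSE
  )
  list(lines = rec$lines, report = report,
       removed_clusters = rec$removed_clusters)
}
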