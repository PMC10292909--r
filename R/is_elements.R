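# Attribute SVs to insertion-sequence (IS) elements. An insertion is
# IS-mediated when its inserted sequence matches a family consensus at high
# ungapped identity over most of the consensus length (both strands); a
# deletion/duplication/inversion is IS-mediated when its span covers most of
# an annotated reference copy. Near-exact IS copies dominate real bacterial
# transposition, so ungapped sliding identity suffices at the default
# thresholds; `align_fun` lets callers plug in an external aligner.

# Best ungapped sliding identity between two sequences: the shorter is slid
# along the longer with full overlap; identity is the best match fraction
# over the overlap window, coverage the window length over the consensus.
sliding_identity <- function(query, consensus) {
  q <- utf8ToInt(toupper(query))
  cns <- utf8ToInt(toupper(consensus))
  short <- if (length(q) <= length(cns)) q else cns
  long <- if (length(q) <= length(cns)) cns else q
  w <- length(short)
  best <- 0
  for (off in 0:(length(long) - w)) {
    m <- sum(short == long[(off + 1):(off + w)])
    if (m > best) best <- m
  }
  list(identity = best / w, coverage = w / length(cns))
}

is_consensus_match <- function(inserted_seq, consensus,
                               min_identity, min_cov,
                               align_fun = sliding_identity) {
  fwd <- align_fun(inserted_seq, consensus)
  best <- fwd
  if (fwd$identity < 1) {
    rev <- align_fun(revcomp(inserted_seq), consensus)
    if (rev$identity > best$identity) best <- rev
  }
  list(identity = best$identity,
       hit = best$coverage >= min_cov && best$identity >= min_identity)
}

#' Classify one SV as IS-mediated or not
#'
#' Insertions with a known payload are matched against each family consensus
#' by ungapped sliding identity on both strands; the SV is IS-mediated when
#' some consensus matches at `>= min_identity` identity over `>= min_cov` of
#' the consensus length. Span SVs (DEL/DUP/INV) are IS-mediated when the
#' affected interval covers `>= min_cov` of an annotated reference copy.
#' Insertions without a payload fall back to breakpoint proximity (within
#' 10 bp of an annotated copy edge) and are flagged low-confidence.
#'
#' @param sv one-row SV record table.
#' @param lib an [is_library()].
#' @param min_identity minimum sequence identity (default 0.90).
#' @param min_cov minimum consensus/copy coverage fraction (default 0.80).
#' @param align_fun function `(query, consensus) -> list(identity, coverage)`
#'   used for sequence evidence; defaults to the built-in ungapped sliding
#'   comparison, and may be replaced by a wrapper around an external aligner.
#' @return list of class `is_classification`: `mediated`, `family` (or
#'   `NA`), `evidence` (`"sequence_match"`, `"copy_overlap"`,
#'   `"breakpoint_proximity"`, or `NA`), `identity` (sequence evidence
#'   only), `low_confidence`.
#' @export
classify_sv <- function(sv, lib, min_identity = 0.90, min_cov = 0.80,
                        align_fun = sliding_identity) {
  stopifnot(inherits(lib, "is_library"))
  fam_names <- sort(names(lib$families))
  none <- structure(list(sv = sv, mediated = FALSE, family = NA_character_,
                         evidence = NA_character_, identity = NA_real_,
                         low_confidence = FALSE),
                    class = "is_classification")
  if (length(fam_names) == 0L) return(none)

  if (sv$svtype == "INS") {
    if (!is.na(sv$inserted_seq)) {
      best_fam <- NA_character_; best_id <- -1
      for (fam in fam_names) {
        cons <- lib$families[[fam]]$consensus
        if (is.na(cons)) next
        hit <- is_consensus_match(sv$inserted_seq, cons, min_identity,
                                  min_cov, align_fun)
        if (hit$hit && hit$identity > best_id) {
          best_id <- hit$identity; best_fam <- fam
        }
      }
      if (!is.na(best_fam)) {
        return(structure(list(sv = sv, mediated = TRUE, family = best_fam,
                              evidence = "sequence_match",
                              identity = best_id, low_confidence = FALSE),
                         class = "is_classification"))
      }
      return(none)
    }
    # no payload: breakpoint-proximity fallback, low confidence
    for (fam in fam_names) {
      cp <- lib$families[[fam]]$copies
      if (nrow(cp) == 0L) next
      near <- abs(cp$start - sv$start) <= 10L | abs(cp$end - sv$start) <= 10L
      if (any(near)) {
        return(structure(list(sv = sv, mediated = TRUE, family = fam,
                              evidence = "breakpoint_proximity",
                              identity = NA_real_, low_confidence = TRUE),
                         class = "is_classification"))
      }
    }
    return(none)
  }

  # span SVs: fraction of an annotated copy covered by the affected interval
  best_fam <- NA_character_; best_frac <- -1
  for (fam in fam_names) {
    cp <- lib$families[[fam]]$copies
    if (nrow(cp) == 0L) next
    ov <- pmax(0L, pmin(cp$end, sv$end) - pmax(cp$start, sv$start) + 1L)
    frac <- max(ov / (cp$end - cp$start + 1L))
    if (frac >= min_cov && frac > best_frac) {
      best_frac <- frac; best_fam <- fam
    }
  }
  if (!is.na(best_fam)) {
    return(structure(list(sv = sv, mediated = TRUE, family = best_fam,
                          evidence = "copy_overlap", identity = NA_real_,
                          low_confidence = FALSE),
                     class = "is_classification"))
  }
  none
}

#' Classify a table of SVs against an IS library
#'
#' @param calls SV record table.
#' @param lib an [is_library()].
#' @param ... passed to [classify_sv()].
#' @return a data.frame with one row per call: the SV columns plus
#'   `mediated`, `family`, `evidence`, `identity`, `low_confidence`.
#' @export
classify_svs <- function(calls, lib, ...) {
  calls <- validate_sv_records(calls)
  res <- lapply(seq_len(nrow(calls)),
                function(i) classify_sv(calls[i, ], lib, ...))
  cbind(calls, data.frame(
    mediated = vapply(res, `[[`, logical(1), "mediated"),
    family = vapply(res, `[[`, character(1), "family"),
    evidence = vapply(res, `[[`, character(1), "evidence"),
    identity = vapply(res, `[[`, double(1), "identity"),
    low_confidence = vapply(res, `[[`, logical(1), "low_confidence"),
    stringsAsFactors = FALSE))
}

#' Per-family IS activity summary
#'
#' For each family: its annotated copy number in the reference and the number
#' and proportion of mediated SVs attributed to it (proportions are out of
#' all mediated SVs and sum to 1 when any exist; families with zero mediated
#' SVs are kept with proportion 0).
#'
#' @param classified output of [classify_svs()] (or any data.frame with
#'   `mediated` and `family` columns).
#' @param lib the [is_library()] used for classification.
#' @return data.frame of class `is_activity_summary` with columns `family`,
#'   `reference_copy_number`, `mediated_sv_count`, `proportion`.
#' @export
activity_summary <- function(classified, lib) {
  stopifnot(inherits(lib, "is_library"))
  fams <- sort(names(lib$families))
  med <- classified[classified$mediated, , drop = FALSE]
  total <- nrow(med)
  counts <- vapply(fams, function(f) sum(med$family == f), integer(1))
  out <- data.frame(
    family = fams,
    reference_copy_number = unname(is_copy_numbers(lib)[fams]),
    mediated_sv_count = unname(counts),
    proportion = if (total > 0) unname(counts) / total else rep(0, length(fams)),
    stringsAsFactors = FALSE
  )
  attr(out, "total_mediated") <- total
  class(out) <- c("is_activity_summary", "data.frame")
  out
}

#' Correlate IS-family activity with reference copy number
#'
#' Pearson and Spearman correlations between a family's annotated copy
#' number and its proportion of all IS-mediated SVs. Spearman p-values are
#' exact for small family counts (no ties), asymptotic otherwise. With zero
#' variance in either variable the coefficients are undefined; they are
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param summary an [activity_summary()] result (>= 3 families).
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n_families`, `degenerate`.
#' @export
copy_number_correlation <- function(summary) {
  x <- summary$reference_copy_number
  y <- summary$proportion
  if (length(x) < 3L)
    stop("need >= 3 IS families for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pearson_r = 0, pearson_p = NA_real_, spearman_rho = 0,
                spearman_p = NA_real_, n_families = length(x),
                degenerate = TRUE))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n_families = length(x), degenerate = FALSE)
}
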