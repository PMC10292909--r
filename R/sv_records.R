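#' Construct a table of structural-variant records
#'
#' The package represents SVs (truth or calls) as a plain `data.frame` with
#' one row per variant. All coordinates are 1-based inclusive, the convention
#' of VCF. For insertions `start` is the base immediately to the left of the
#' insertion point and `end == start`; for deletions, tandem duplications and
#' inversions `end == start + length - 1` spans the affected interval.
#'
#' @param contig contig identifier(s).
#' @param start 1-based position of the first affected base (for INS, the
#'   base left of the insertion point).
#' @param svtype one of `"INS"`, `"DEL"`, `"DUP"`, `"INV"` (vectorised).
#' @param length SV length in bp: the inserted length for INS, the affected
#'   span for DEL/DUP/INV. Must be >= 1.
#' @param end 1-based inclusive end; computed from `start`/`length` when
#'   omitted.
#' @param inserted_seq inserted sequence for sequence-resolved insertions,
#'   `NA` otherwise.
#' @param imprecise logical: caller flagged the breakpoints as imprecise.
#' @param source free-text provenance (e.g. `"truth"`, a caller name,
#'   `"sanger"`).
#' @param line_id MA line identifier, `""` when not applicable.
#' @return a validated `data.frame` with columns `contig`, `start`, `svtype`,
#'   `length`, `end`, `inserted_seq`, `imprecise`, `source`, `line_id`.
#' @examples
#' sv_records("chr", 1000, "DEL", 500)
#' @export
sv_records <- function(contig, start, svtype, length,
                       end = NULL,
                       inserted_seq = NA_character_,
                       imprecise = FALSE,
                       source = "",
                       line_id = "") {
  n <- max(lengths(list(contig, start, svtype, length)))
  if (n == 0L) return(empty_sv_records())
  svtype <- rep_len(toupper(as.character(svtype)), n)
  start <- rep_len(as.integer(start), n)
  length <- rep_len(as.integer(length), n)
  if (is.null(end)) {
    end <- ifelse(svtype == "INS", start, start + length - 1L)
  }
  df <- data.frame(
    contig = rep_len(as.character(contig), n),
    start = start,
    svtype = svtype,
    length = length,
    end = rep_len(as.integer(end), n),
    inserted_seq = rep_len(as.character(inserted_seq), n),
    imprecise = rep_len(as.logical(imprecise), n),
    source = rep_len(as.character(source), n),
    line_id = rep_len(as.character(line_id), n),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
}

#' @rdname sv_records
#' @export
empty_sv_records <- function() {
  data.frame(
    contig = character(0), start = integer(0), svtype = character(0),
    length = integer(0), end = integer(0), inserted_seq = character(0),
    imprecise = logical(0), source = character(0), line_id = character(0),
    stringsAsFactors = FALSE
  )
}

SV_TYPES <- c("INS", "DEL", "DUP", "INV")

#' Validate an SV record table
#'
#' Checks the structural invariants of the SV table: known types, positive
#' lengths, `end >= start`, `end == start` for insertions and
#' `end == start + length - 1` otherwise.
#'
#' @param df a data.frame as produced by [sv_records()].
#' @return `df`, invisibly unchanged, or an error describing the violation.
#' @export
validate_sv_records <- function(df) {
  required <- names(empty_sv_records())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("SV table missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  bad_type <- !df$svtype %in% SV_TYPES
  if (any(bad_type))
    stop("unknown svtype: ", paste(unique(df$svtype[bad_type]), collapse = ", "))
  if (any(df$length < 1L)) stop("SV length must be >= 1")
  if (any(df$end < df$start)) stop("SV end < start")
  ins <- df$svtype == "INS"
  if (any(df$end[ins] != df$start[ins]))
    stop("INS records must have end == start")
  span <- !ins
  if (any(df$end[span] - df$start[span] + 1L != df$length[span]))
    stop("non-INS records must have end - start + 1 == length")
  df
}

#' Convert SV records to BED intervals
#'
#' Exports the 0-based half-open intervals BED expects; an insertion is
#' represented by its 1 bp anchor base. Reading the intervals back with
#' [bed_to_internal()] recovers the internal 1-based coordinates exactly.
#'
#' @param df an SV record table.
#' @return a data.frame with `chrom`, `chromStart`, `chromEnd`, `name`.
#' @export
sv_to_bed <- function(df) {
  validate_sv_records(df)
  data.frame(
    chrom = df$contig,
    chromStart = df$start - 1L,
    chromEnd = df$end,
    name = df$svtype,
    stringsAsFactors = FALSE
  )
}

#' @rdname sv_to_bed
#' @param bed a data.frame with BED columns `chrom`, `chromStart`, `chromEnd`.
#' @return for `bed_to_internal()`: a data.frame with 1-based inclusive
#'   `start`/`end` columns.
#' @export
bed_to_internal <- function(bed) {
  data.frame(
    contig = bed$chrom,
    start = as.integer(bed$chromStart) + 1L,
    end = as.integer(bed$chromEnd),
    stringsAsFactors = FALSE
  )
}
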