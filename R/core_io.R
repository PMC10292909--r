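# Readers/writers for the formats the pipeline touches: FASTA (Biostrings),
# SV VCF (vcfR for reading), and the tab-separated IS-element annotation.
# Internal coordinates are 1-based inclusive throughout, matching VCF; the
# genome is treated as linear and no SV may span the replication origin.

#' Construct a reference genome object
#'
#' @param contig_id contig name.
#' @param sequence DNA sequence over `{A,C,G,T,N}`; lower case is normalised
#'   to upper case.
#' @param circular logical; recorded as metadata only — all operations treat
#'   the sequence as linear.
#' @return an object of class `reference_genome`.
#' @export
reference_genome <- function(contig_id, sequence, circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("non-nucleotide character(s) in sequence for contig '", contig_id,
         "': ", paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(
    list(contig_id = as.character(contig_id), sequence = sequence,
         circular = isTRUE(circular)),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", x$contig_id, ": ", nchar(x$sequence), " bp",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  invisible(x)
}

#' Genome length in bp
#' @param genome a `reference_genome`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return a list of [reference_genome()] objects, one per record, in file
#'   order. Sequences are upper-cased; `N` is allowed; any other character is
#'   an error naming the offending contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  lapply(seq_along(set), function(i) {
    reference_genome(names(set)[i], as.character(set[[i]]))
  })
}

#' Write a genome to FASTA
#'
#' @param genome a [reference_genome()].
#' @param path output file path.
#' @param line_width bases per sequence line (default 60).
#' @return `path`, invisibly. Round-trips through [read_fasta()].
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  stopifnot(inherits(genome, "reference_genome"), line_width >= 1L)
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$contig_id
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

# -- SV VCF ------------------------------------------------------------------

# INFO is a semicolon-separated key[=value] list; pull one key out.
info_field <- function(info, key) {
  vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]*"), info)),
         function(x) if (length(x)) sub(paste0("^;?", key, "="), "", x[1])
                     else NA_character_,
         character(1))
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(;|$)"), info)
}

#' Read structural variants from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into an SV record table. `svtype`
#' comes from INFO/SVTYPE; length is `|SVLEN|` when present, else
#' `END - POS + 1`, else the allele-length difference for sequence-resolved
#' records. The `imprecise` column reflects the INFO/IMPRECISE flag.
#' Records of types other than INS/DEL/DUP/INV (e.g. BND) are tallied and
#' excluded with a warning, as are records whose length cannot be determined.
#'
#' @param path VCF file path.
#' @param source provenance string stamped on each record (defaults to the
#'   file name).
#' @param line_id MA line identifier stamped on each record.
#' @return an SV record table (see [sv_records()]).
#' @export
read_sv_vcf <- function(path, source = basename(path), line_id = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_sv_records())
  info <- fix[, "INFO"]
  svtype <- toupper(info_field(info, "SVTYPE"))
  # normalise the symbolic-ALT spelling of tandem duplications
  svtype[svtype == "DUP:TANDEM"] <- "DUP"
  pos <- as.integer(fix[, "POS"])
  svlen <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  endf <- suppressWarnings(as.integer(info_field(info, "END")))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  n <- length(pos)
  len <- abs(svlen)
  use_end <- is.na(len) & !is.na(endf)
  len[use_end] <- endf[use_end] - pos[use_end] + 1L
  symbolic <- grepl("[][<>]", alt) # symbolic (<DEL>) or breakend ([/]) ALTs
  resolved <- is.na(len) & !symbolic & !is.na(alt)
  len[resolved] <- abs(nchar(alt[resolved]) - nchar(ref[resolved]))

  keep_type <- svtype %in% SV_TYPES & !is.na(svtype)
  n_unknown <- sum(!keep_type)
  n_nolen <- sum(is.na(len) | len < 1L, na.rm = FALSE)
  keep <- keep_type & !is.na(len) & len >= 1L
  if (n_unknown > 0L)
    warning(n_unknown, " record(s) with SVTYPE outside INS/DEL/DUP/INV excluded")
  if (sum(keep_type & !keep) > 0L)
    warning(sum(keep_type & !keep),
            " record(s) without SVLEN/END/resolved alleles excluded")
  if (!any(keep)) return(empty_sv_records())

  inserted <- rep(NA_character_, n)
  seq_ins <- keep & svtype == "INS" & !symbolic &
    nchar(alt) > nchar(ref)
  # sequence-resolved INS: ALT = anchor base + inserted sequence
  inserted[seq_ins] <- substring(alt[seq_ins], nchar(ref[seq_ins]) + 1L)

  sv_records(
    contig = fix[keep, "CHROM"],
    start = pos[keep],
    svtype = svtype[keep],
    length = len[keep],
    inserted_seq = inserted[keep],
    imprecise = info_flag(info[keep], "IMPRECISE"),
    source = source,
    line_id = line_id
  )
}

#' Write structural variants to a VCF file
#'
#' Emits VCF 4.2 with SVTYPE/SVLEN/END (and IMPRECISE where flagged) in INFO.
#' ALT alleles are symbolic (`<DEL>`, `<DUP>`, `<INV>`, `<INS>`) except for
#' insertions whose `inserted_seq` is known, which are written
#' sequence-resolved. Round-trips through [read_sv_vcf()].
#'
#' @param calls an SV record table.
#' @param path output file path.
#' @param genome optional [reference_genome()]; supplies the REF anchor base
#'   and a contig header line, and bounds-checks the calls.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, genome = NULL) {
  calls <- validate_sv_records(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", genome$contig_id,
              genome_length(genome)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variation\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  if (nrow(calls) > 0L) {
    if (!is.null(genome) && any(calls$end > genome_length(genome)))
      stop("call(s) beyond contig bounds")
    calls <- calls[order(calls$contig, calls$start), , drop = FALSE]
    ref <- rep("N", nrow(calls))
    if (!is.null(genome))
      ref <- substring(genome$sequence, calls$start, calls$start)
    resolved <- calls$svtype == "INS" & !is.na(calls$inserted_seq)
    alt <- paste0("<", calls$svtype, ">")
    alt[resolved] <- paste0(ref[resolved], calls$inserted_seq[resolved])
    svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", calls$svtype, svlen, calls$end)
    info[calls$imprecise] <- paste0(info[calls$imprecise], ";IMPRECISE")
    body <- paste(calls$contig, calls$start, ".", ref, alt, ".", "PASS", info,
                  sep = "\t")
    header <- c(header, body)
  }
  writeLines(header, path)
  invisible(path)
}

#' Write SV records as a tab-separated truth table
#'
#' @param calls an SV record table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sv_tsv <- function(calls, path) {
  calls <- validate_sv_records(calls)
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @export
read_sv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(contig = "character",
                                            inserted_seq = "character",
                                            source = "character",
                                            line_id = "character"))
  df$inserted_seq[df$inserted_seq == ""] <- NA_character_
  validate_sv_records(df)
}

# -- IS-element annotation ---------------------------------------------------

#' Construct an IS-element library
#'
#' @param families a named list; each element is a list with `consensus`
#'   (DNA string or `NA` when unknown) and `copies` (data.frame with 1-based
#'   inclusive `start`, `end` columns of annotated reference copies).
#' @return an object of class `is_library`.
#' @export
is_library <- function(families = list()) {
  if (anyDuplicated(names(families)))
    stop("IS family names must be unique")
  for (fam in names(families)) {
    f <- families[[fam]]
    if (!is.null(f$copies) && nrow(f$copies) > 0L &&
        any(f$copies$end < f$copies$start))
      stop("IS family ", fam, ": copy interval with end < start")
    if (!is.na(f$consensus) && nchar(f$consensus) == 0L)
      stop("IS family ", fam, ": empty consensus")
  }
  structure(list(families = families), class = "is_library")
}

#' @export
print.is_library <- function(x, ...) {
  cn <- is_copy_numbers(x)
  cat("<is_library> ", length(x$families), " families; copies: ",
      paste(names(cn), cn, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reference copy number per IS family
#' @param lib an [is_library()].
#' @return named integer vector of annotated copy counts.
#' @export
is_copy_numbers <- function(lib) {
  vapply(lib$families, function(f) nrow(f$copies), integer(1))
}

#' Read an IS-element annotation table
#'
#' Expects a tab-separated table with columns `family`, `start`, `end` and
#' either a `consensus` sequence column or a companion per-family consensus
#' FASTA (headers = family names). Copies are grouped by family; the copy
#' number of a family is its interval count. Overlapping copies are allowed
#' (with a warning); a family without a consensus is kept, but
#' sequence-based classification is disabled for it.
#'
#' @param path TSV path.
#' @param consensus_fasta optional FASTA of family consensus sequences.
#' @return an [is_library()].
#' @export
read_is_annotation <- function(path, consensus_fasta = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "start", "end")
  if (!all(need %in% names(df)))
    stop("IS table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(is_library())
  bad <- which(df$end < df$start)
  if (length(bad) > 0L)
    stop("IS table row ", bad[1], ": end < start")
  cons <- NULL
  if (!is.null(consensus_fasta)) {
    gl <- read_fasta(consensus_fasta)
    cons <- stats::setNames(vapply(gl, function(g) g$sequence, character(1)),
                            vapply(gl, function(g) g$contig_id, character(1)))
  }
  fams <- lapply(split(df, df$family), function(rows) {
    seq <- NA_character_
    if ("consensus" %in% names(rows)) {
      s <- unique(rows$consensus[!is.na(rows$consensus) & rows$consensus != ""])
      if (length(s) > 0L) seq <- toupper(s[1])
    }
    if (is.na(seq) && !is.null(cons) && rows$family[1] %in% names(cons))
      seq <- cons[[rows$family[1]]]
    copies <- data.frame(start = as.integer(rows$start),
                         end = as.integer(rows$end))
    ov <- order(copies$start)
    copies <- copies[ov, , drop = FALSE]
    list(consensus = seq, copies = copies)
  })
  lib <- is_library(fams)
  for (fam in names(lib$families)) {
    cp <- lib$families[[fam]]$copies
    if (nrow(cp) > 1L && any(cp$start[-1] <= cp$end[-nrow(cp)]))
      warning("IS family ", fam, ": overlapping annotated copies")
  }
  lib
}
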