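# Implant known SVs into a reference genome and emit a truth set.
#
# The design mirrors the in-silico benchmark genomes used in bacterial MA
# studies: per-type SV counts (typically 100/200/500 of a single type),
# lengths drawn from a three-bucket mixture, breakpoints uniform along the
# chromosome, and sparse BPS/indel noise confined to the +/-100 bp flanks of
# each breakpoint. Truth coordinates are reported on the ORIGINAL reference,
# i.e. as a caller benchmarked against the reference would see them.

#' Simulation configuration
#'
#' @param n_per_type named vector/list giving the number of SVs to implant
#'   per type, over `INS`, `DEL`, `DUP`, `INV` (missing types mean 0).
#' @param length_buckets data.frame with columns `lo`, `hi` (bp, inclusive)
#'   and `weight` (mixture probabilities summing to 1). The default mixture
#'   is 70\% 50--1,000 bp, 20\% 1,001--5,000 bp, 10\% 5,001--10,000 bp. The
#'   upper cap of the third bucket is configurable; 10 kb keeps every length
#'   within the stated overall 50--10,000 bp range.
#' @param flank_bp breakpoint flank width receiving small-variant noise
#'   (default 100).
#' @param p_flank_bps per-flank probability of one base substitution
#'   (default 0.001).
#' @param p_flank_indel per-flank probability of one indel (default 0.0005);
#'   a flank receives at most one indel.
#' @param max_flank_indel_bp maximum indel length in a flank (default 20).
#' @param min_gap_bp minimum distance between implanted SVs (default
#'   `2 * flank_bp`).
#' @param is_lib optional [is_library()]; when supplied, each insertion's
#'   payload is a family consensus drawn uniformly from the library instead
#'   of random sequence, emulating IS-mediated insertions.
#' @param seed integer seed recorded in the result.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_type = c(INS = 0, DEL = 0, DUP = 0, INV = 0),
                       length_buckets = data.frame(
                         lo = c(50L, 1001L, 5001L),
                         hi = c(1000L, 5000L, 10000L),
                         weight = c(0.70, 0.20, 0.10)),
                       flank_bp = 100L,
                       p_flank_bps = 0.001,
                       p_flank_indel = 0.0005,
                       max_flank_indel_bp = 20L,
                       min_gap_bp = 2L * flank_bp,
                       is_lib = NULL,
                       seed = 1L) {
  n <- stats::setNames(rep(0L, 4), SV_TYPES)
  n[names(n_per_type)] <- as.integer(unlist(n_per_type))
  if (any(n < 0L)) stop("n_per_type counts must be >= 0")
  if (abs(sum(length_buckets$weight) - 1) > 1e-8)
    stop("length bucket weights must sum to 1")
  if (any(length_buckets$lo > length_buckets$hi))
    stop("length bucket lo > hi")
  if (any(c(p_flank_bps, p_flank_indel) < 0) ||
      any(c(p_flank_bps, p_flank_indel) > 1))
    stop("flank probabilities must lie in [0, 1]")
  structure(
    list(n_per_type = n, length_buckets = length_buckets,
         flank_bp = as.integer(flank_bp), p_flank_bps = p_flank_bps,
         p_flank_indel = p_flank_indel,
         max_flank_indel_bp = as.integer(max_flank_indel_bp),
         min_gap_bp = as.integer(min_gap_bp), is_lib = is_lib,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

draw_lengths <- function(n, buckets) {
  if (n == 0L) return(integer(0))
  b <- sample.int(nrow(buckets), n, replace = TRUE, prob = buckets$weight)
  lo <- buckets$lo[b]
  hi <- buckets$hi[b]
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

#' Plan non-overlapping SVs along a genome
#'
#' Draws SV lengths from the configured bucket mixture and start positions
#' uniformly along the genome, rejecting placements closer than `min_gap_bp`
#' to an already-placed SV (up to 1000 attempts per SV; exhausting the
#' retries is an error reporting the achieved count, never a silent
#' shortfall). Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param genome_len genome length in bp.
#' @param seed overrides `config$seed` when given.
#' @param contig contig name stamped on the records (default `"sim"`).
#' @return an SV record table sorted by start, with `source = "truth"`.
#' @export
plan_svs <- function(config, genome_len, seed = config$seed,
                     contig = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  total <- sum(config$n_per_type)
  if (total == 0L) return(empty_sv_records())
  max_len <- max(config$length_buckets$hi)
  if (genome_len < max_len + 2L * config$min_gap_bp)
    stop("genome too short for requested SV lengths")
  types <- rep(names(config$n_per_type), config$n_per_type)
  lens <- draw_lengths(total, config$length_buckets)
  starts <- integer(total)
  # occupied intervals, padded by min_gap_bp
  occ_start <- integer(0); occ_end <- integer(0)
  gap <- config$min_gap_bp
  for (i in seq_len(total)) {
    span <- if (types[i] == "INS") 1L else lens[i]
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      s <- 1L + floor(stats::runif(1) * (genome_len - span))
      e <- s + span - 1L
      if (!any(s <= occ_end + gap & e >= occ_start - gap)) {
        starts[i] <- as.integer(s)
        occ_start <- c(occ_start, as.integer(s))
        occ_end <- c(occ_end, as.integer(e))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place SV ", i, " of ", total,
           " after 1000 attempts (", i - 1L, " placed); ",
           "reduce counts or lengths")
  }
  out <- sv_records(contig = contig, start = starts, svtype = types,
                    length = lens, source = "truth")
  out[order(out$start), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Apply a truth set of SVs to a genome
#'
#' Edits are applied simultaneously on original coordinates: DEL removes the
#' span; INS inserts `inserted_seq` immediately after `start` (a uniform
#' random payload is generated — and written back into the returned truth —
#' when absent); DUP appends one extra tandem copy immediately after the
#' span; INV replaces the span with its reverse complement.
#'
#' @param genome a [reference_genome()].
#' @param truth an SV record table; must be sorted, within bounds, and
#'   pairwise non-overlapping (checked before any edit).
#' @param seed seed for generated insertion payloads.
#' @param is_lib optional [is_library()] supplying insertion payloads
#'   (uniform over families with a consensus).
#' @return a list with `genome` (the mutated [reference_genome()]) and
#'   `truth` (the input table with any generated `inserted_seq` filled in).
#'   The output genome length equals input + sum(INS) + sum(DUP) - sum(DEL).
#' @export
apply_svs <- function(genome, truth, seed = 1L, is_lib = NULL) {
  truth <- validate_sv_records(truth)
  if (nrow(truth) == 0L) return(list(genome = genome, truth = truth))
  truth <- truth[order(truth$start), , drop = FALSE]
  if (any(truth$end > genome_length(genome)) || any(truth$start < 1L))
    stop("truth record out of genome bounds")
  if (nrow(truth) > 1L &&
      any(truth$start[-1] <= truth$end[-nrow(truth)]))
    stop("overlapping truth records")
  set.seed(seed)
  need_seq <- truth$svtype == "INS" & is.na(truth$inserted_seq)
  if (any(need_seq)) {
    cons <- character(0)
    if (!is.null(is_lib))
      cons <- unlist(lapply(is_lib$families, `[[`, "consensus"))
    cons <- cons[!is.na(cons)]
    for (i in which(need_seq)) {
      if (length(cons) > 0L) {
        s <- cons[[sample.int(length(cons), 1L)]]
        truth$inserted_seq[i] <- s
        truth$length[i] <- nchar(s)
        truth$end[i] <- truth$start[i]
      } else {
        truth$inserted_seq[i] <- random_dna(truth$length[i])
      }
    }
  }
  dna <- Biostrings::DNAString(genome$sequence)
  at <- vector("list", nrow(truth))
  repl <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    s <- truth$start[i]; e <- truth$end[i]
    switch(truth$svtype[i],
      DEL = { at[[i]] <- IRanges::IRanges(s, e); repl[i] <- "" },
      INS = { at[[i]] <- IRanges::IRanges(s + 1L, s)
              repl[i] <- truth$inserted_seq[i] },
      DUP = { at[[i]] <- IRanges::IRanges(e + 1L, e)
              repl[i] <- as.character(Biostrings::subseq(dna, s, e)) },
      INV = { at[[i]] <- IRanges::IRanges(s, e)
              repl[i] <- revcomp(as.character(Biostrings::subseq(dna, s, e))) }
    )
  }
  mutated <- Biostrings::replaceAt(dna, do.call(c, at), repl)
  list(
    genome = reference_genome(paste0(genome$contig_id, "_sim"),
                              as.character(mutated),
                              circular = genome$circular),
    truth = truth
  )
}

# Map original-reference coordinates to mutated-genome coordinates for the
# breakpoint flanks, given the applied truth (sorted, non-overlapping).
# Returns per-SV junction positions on the mutated genome plus the mutated
# spans occupied by SV material (forbidden for flanking noise).
mutated_breakpoints <- function(truth) {
  shift <- 0L
  junctions <- integer(0)
  spans <- list()
  for (i in seq_len(nrow(truth))) {
    s <- truth$start[i] + shift
    type <- truth$svtype[i]
    len <- truth$length[i]
    if (type == "DEL") {
      junctions <- c(junctions, s)          # junction after s-1 / at s
      shift <- shift - len
    } else if (type == "INS") {
      junctions <- c(junctions, s, s + len + 1L)
      spans <- c(spans, list(c(s + 1L, s + len)))
      shift <- shift + len
    } else if (type == "DUP") {
      e <- truth$end[i] + shift
      junctions <- c(junctions, s, e + len + 1L)
      spans <- c(spans, list(c(s, e + len)))
      shift <- shift + len
    } else { # INV
      e <- truth$end[i] + shift
      junctions <- c(junctions, s, e + 1L)
      spans <- c(spans, list(c(s, e)))
    }
  }
  list(junctions = junctions, spans = spans)
}

#' Inject BPS/indel noise into breakpoint flanks
#'
#' Each breakpoint flank (`flank_bp` bases on each side of each SV junction
#' on the mutated genome, truncated at contig edges and excluding bases
#' inside any SV span) independently receives one substitution with
#' probability `p_flank_bps` and one indel (insertion or deletion, length
#' uniform on 1..`max_flank_indel_bp`) with probability `p_flank_indel`; a
#' flank contains at most one indel.
#'
#' @param genome the mutated [reference_genome()] after [apply_svs()].
#' @param truth the applied truth table (original-reference coordinates).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `genome` (noise applied) and `small_variants`
#'   (data.frame `pos` on the pre-noise mutated genome, `ref`, `alt`).
#' @export
inject_flanking_noise <- function(genome, truth, config, seed = config$seed) {
  set.seed(seed)
  sv_empty <- data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), stringsAsFactors = FALSE)
  if (nrow(truth) == 0L ||
      (config$p_flank_bps == 0 && config$p_flank_indel == 0))
    return(list(genome = genome, small_variants = sv_empty))
  glen <- genome_length(genome)
  bp <- mutated_breakpoints(truth[order(truth$start), , drop = FALSE])
  forbidden <- bp$spans
  in_forbidden <- function(p) {
    any(vapply(forbidden, function(sp) p >= sp[1] && p <= sp[2], logical(1)))
  }
  flanks <- list()
  for (j in bp$junctions) {
    flanks <- c(flanks,
                list(c(max(1L, j - config$flank_bp), min(glen, j - 1L)),
                     c(max(1L, j), min(glen, j + config$flank_bp - 1L))))
  }
  flanks <- Filter(function(f) f[1] <= f[2], flanks)
  pos <- integer(0); ref <- character(0); alt <- character(0)
  used <- integer(0)
  pick_pos <- function(f) {
    for (k in seq_len(50L)) {
      p <- as.integer(f[1] + floor(stats::runif(1) * (f[2] - f[1] + 1L)))
      if (!in_forbidden(p) && !p %in% used) return(p)
    }
    NA_integer_
  }
  base_at <- function(p) substring(genome$sequence, p, p)
  for (f in flanks) {
    if (stats::runif(1) < config$p_flank_bps) {
      p <- pick_pos(f)
      if (!is.na(p)) {
        b <- base_at(p)
        choices <- setdiff(c("A", "C", "G", "T"), b)
        pos <- c(pos, p); ref <- c(ref, b)
        alt <- c(alt, sample(choices, 1L))
        used <- c(used, p)
      }
    }
    if (stats::runif(1) < config$p_flank_indel) {
      p <- pick_pos(f)
      if (!is.na(p)) {
        ilen <- sample.int(config$max_flank_indel_bp, 1L)
        b <- base_at(p)
        del_span_free <- p + ilen <= min(f[2], glen) &&
          !any((p:(p + ilen)) %in% used) &&
          !any(vapply(p:(p + ilen), in_forbidden, logical(1)))
        if (stats::runif(1) < 0.5 || !del_span_free) {
          # insertion after p
          pos <- c(pos, p); ref <- c(ref, b)
          alt <- c(alt, paste0(b, random_dna(ilen)))
        } else {
          # deletion of ilen bases starting at p+1, anchored at p
          del <- substring(genome$sequence, p, p + ilen)
          pos <- c(pos, p); ref <- c(ref, del); alt <- c(alt, b)
        }
        used <- c(used, p:(p + ilen))
      }
    }
  }
  if (length(pos) == 0L)
    return(list(genome = genome, small_variants = sv_empty))
  ord <- order(pos)
  pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
  at <- IRanges::IRanges(pos, pos + nchar(ref) - 1L)
  mutated <- Biostrings::replaceAt(Biostrings::DNAString(genome$sequence),
                                   at, alt)
  list(
    genome = reference_genome(genome$contig_id, as.character(mutated),
                              circular = genome$circular),
    small_variants = data.frame(pos = pos, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
  )
}

#' Simulate a genome carrying known SVs
#'
#' Composes [plan_svs()], [apply_svs()] and [inject_flanking_noise()]; with a
#' zero-variant configuration the returned genome is byte-identical to the
#' reference. Deterministic given `config$seed`.
#'
#' @param reference a [reference_genome()].
#' @param config a [sim_config()].
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.fa`, `<prefix>.truth.vcf`, `<prefix>.truth.tsv` and
#'   `<prefix>.log`.
#' @return a list of class `sim_result` with `mutated_genome`, `truth`
#'   (original-reference coordinates), `small_variants` and `seed`.
#' @export
simulate_genome <- function(reference, config, out_prefix = NULL) {
  stopifnot(inherits(reference, "reference_genome"),
            inherits(config, "sim_config"))
  truth <- plan_svs(config, genome_length(reference), seed = config$seed,
                    contig = reference$contig_id)
  applied <- apply_svs(reference, truth, seed = config$seed + 1L,
                       is_lib = config$is_lib)
  noised <- inject_flanking_noise(applied$genome, applied$truth, config,
                                  seed = config$seed + 2L)
  res <- structure(
    list(mutated_genome = noised$genome, truth = applied$truth,
         small_variants = noised$small_variants, seed = config$seed),
    class = "sim_result"
  )
  if (!is.null(out_prefix)) {
    write_fasta(res$mutated_genome, paste0(out_prefix, ".fa"))
    write_sv_vcf(res$truth, paste0(out_prefix, ".truth.vcf"),
                 genome = reference)
    write_sv_tsv(res$truth, paste0(out_prefix, ".truth.tsv"))
    writeLines(c(
      paste0("seed: ", config$seed),
      paste0("reference: ", reference$contig_id, " (",
             genome_length(reference), " bp)"),
      paste0("svs: ", paste(names(config$n_per_type), config$n_per_type,
                            sep = "=", collapse = " ")),
      paste0("small_variants: ", nrow(res$small_variants))
    ), paste0(out_prefix, ".log"))
  }
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", nrow(x$truth), " SVs, ",
      nrow(x$small_variants), " flanking small variants; mutated genome ",
      genome_length(x$mutated_genome), " bp (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
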