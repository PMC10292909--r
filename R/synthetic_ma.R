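# Generate complete mock MA experiments: per-line true SVs (Poisson counts,
# uniform positions), ancestor-inherited variants present in every line,
# and a caller error model (false negatives, per-line false positives,
# breakpoint jitter, length noise, imprecise flags, and shared false
# positives recurring across lines). This gives the filter cascade and the
# rate estimators an end-to-end test bed with known ground truth and no
# sequencing data. Defaults mirror a typical MA design: tens of lines, a few
# thousand cell divisions each, and an SV rate of a few 1e-4 per genome per
# division.

#' Configuration for a synthetic MA experiment
#'
#' @param n_lines number of MA lines.
#' @param T_divisions cell divisions per line.
#' @param true_rate true SV rate per genome per division; per-line true SV
#'   counts are Poisson(`true_rate * T_divisions`).
#' @param type_probs multinomial probabilities over INS/DEL/DUP/INV, summing
#'   to 1. The default is insertion-dominated, the spectrum bacterial MA
#'   lines show.
#' @param ancestor_sv_count variants carried by the ancestor and therefore
#'   present identically in every line's observed calls.
#' @param fn_rate probability a true SV is missed by the caller.
#' @param fp_per_line expected number of random false positives per line
#'   (Poisson).
#' @param jitter_sd_bp SD of breakpoint jitter, rounded Normal truncated at
#'   +/- 3 SD so tolerance guarantees are testable.
#' @param len_noise_frac multiplicative length noise: observed length is
#'   uniform within `+/- len_noise_frac` of truth.
#' @param p_imprecise probability an observed call is flagged imprecise.
#' @param shared_fp_count number of shared false positives (reference
#'   artifacts) injected identically into `shared_fp_lines` lines.
#' @param shared_fp_lines number of lines receiving each shared FP; at or
#'   above the recurrence threshold these are removed by the cascade.
#' @param length_range true SV lengths are uniform integers in this range.
#' @param seed integer seed.
#' @return an object of class `ma_sim_config`.
#' @export
ma_sim_config <- function(n_lines = 50L,
                          T_divisions = 4000,
                          true_rate = 3e-4,
                          type_probs = c(INS = 0.6, DEL = 0.3, DUP = 0.05,
                                         INV = 0.05),
                          ancestor_sv_count = 2L,
                          fn_rate = 0.02,
                          fp_per_line = 0.2,
                          jitter_sd_bp = 5,
                          len_noise_frac = 0.05,
                          p_imprecise = 0.05,
                          shared_fp_count = 2L,
                          shared_fp_lines = 5L,
                          length_range = c(50L, 1500L),
                          seed = 1L) {
  if (abs(sum(type_probs) - 1) > 1e-8) stop("type_probs must sum to 1")
  if (true_rate < 0) stop("true_rate must be >= 0")
  probs <- c(fn_rate, p_imprecise)
  if (any(probs < 0) || any(probs > 1))
    stop("fn_rate and p_imprecise must lie in [0, 1]")
  if (len_noise_frac < 0 || len_noise_frac >= 1)
    stop("len_noise_frac must lie in [0, 1)")
  structure(list(
    n_lines = as.integer(n_lines), T_divisions = T_divisions,
    true_rate = true_rate, type_probs = type_probs,
    ancestor_sv_count = as.integer(ancestor_sv_count),
    fn_rate = fn_rate, fp_per_line = fp_per_line,
    jitter_sd_bp = jitter_sd_bp, len_noise_frac = len_noise_frac,
    p_imprecise = p_imprecise, shared_fp_count = as.integer(shared_fp_count),
    shared_fp_lines = as.integer(shared_fp_lines),
    length_range = as.integer(length_range), seed = as.integer(seed)
  ), class = "ma_sim_config")
}

# random SV table: uniform positions, multinomial types, uniform lengths
random_svs <- function(n, genome_len, type_probs, length_range, source,
                       line_id = "") {
  if (n == 0L) return(empty_sv_records())
  lens <- as.integer(length_range[1] +
    floor(stats::runif(n) * (length_range[2] - length_range[1] + 1L)))
  types <- sample(names(type_probs), n, replace = TRUE, prob = type_probs)
  starts <- as.integer(1L + floor(stats::runif(n) * (genome_len -
    max(lens) - 1L)))
  sv_records(contig = "chr", start = starts, svtype = types, length = lens,
             source = source, line_id = line_id)
}

# truncated (+/- 3 SD) rounded Normal jitter
rjitter <- function(n, sd) {
  if (sd == 0 || n == 0L) return(integer(n))
  x <- stats::rnorm(n, 0, sd)
  lim <- 3 * sd
  x <- pmin(pmax(x, -lim), lim)
  as.integer(round(x))
}

# pass truth through the caller error model
observe_calls <- function(truth, config, line_id) {
  if (nrow(truth) == 0L) return(empty_sv_records())
  kept <- truth[stats::runif(nrow(truth)) >= config$fn_rate, , drop = FALSE]
  n <- nrow(kept)
  if (n == 0L) return(empty_sv_records())
  start <- pmax(1L, kept$start + rjitter(n, config$jitter_sd_bp))
  lf <- config$len_noise_frac
  length <- pmax(1L, as.integer(round(kept$length *
    stats::runif(n, 1 - lf, 1 + lf))))
  sv_records(contig = kept$contig, start = start, svtype = kept$svtype,
             length = length,
             imprecise = stats::runif(n) < config$p_imprecise,
             source = "caller", line_id = line_id)
}

#' Generate a synthetic MA experiment
#'
#' Per line: true SV count ~ Poisson(`true_rate * T_divisions`) with uniform
#' positions and multinomial types; observed calls are the truth minus
#' false-negative draws, with breakpoint jitter, length noise and imprecise
#' flags, plus per-line Poisson false positives, the ancestor's calls
#' (identical in every line), and shared false positives injected into the
#' first `shared_fp_lines` lines. Deterministic given `config$seed`.
#'
#' @param config an [ma_sim_config()].
#' @param genome_len genome length in bp (default 4.6 Mbp, an *E. coli*-sized
#'   chromosome).
#' @return a list of class `synthetic_experiment` with `truth` (list of SV
#'   tables per line), `observed` (list of [line_callset()]s), `ancestor`
#'   (a [line_callset()]), `shared_fps` (SV table), and `config`.
#' @export
generate_experiment <- function(config, genome_len = 4.6e6) {
  stopifnot(inherits(config, "ma_sim_config"))
  set.seed(config$seed)
  line_ids <- sprintf("line%03d", seq_len(config$n_lines))

  ancestor_calls <- random_svs(config$ancestor_sv_count, genome_len,
                               config$type_probs, config$length_range,
                               source = "ancestor")
  shared_fps <- random_svs(config$shared_fp_count, genome_len,
                           config$type_probs, config$length_range,
                           source = "shared_fp")
  fp_lines <- line_ids[seq_len(min(config$shared_fp_lines, config$n_lines))]

  truth <- vector("list", config$n_lines)
  observed <- vector("list", config$n_lines)
  names(truth) <- line_ids
  for (k in seq_len(config$n_lines)) {
    id <- line_ids[k]
    n_true <- stats::rpois(1, config$true_rate * config$T_divisions)
    tr <- random_svs(n_true, genome_len, config$type_probs,
                     config$length_range, source = "truth", line_id = id)
    truth[[k]] <- tr
    obs <- observe_calls(tr, config, id)
    n_fp <- stats::rpois(1, config$fp_per_line)
    fps <- random_svs(n_fp, genome_len, config$type_probs,
                      config$length_range, source = "random_fp",
                      line_id = id)
    extra <- rbind(ancestor_calls,
                   if (id %in% fp_lines) shared_fps else empty_sv_records())
    if (nrow(extra) > 0L) extra$line_id <- id
    obs <- rbind(obs, fps, extra)
    observed[[k]] <- line_callset(id, obs, strain = "WT",
                                  platform = "long_read")
  }
  structure(list(
    truth = truth,
    observed = observed,
    ancestor = line_callset("ancestor", ancestor_calls, strain = "WT",
                            platform = "long_read"),
    shared_fps = shared_fps,
    genome_len = genome_len,
    config = config
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> ", x$config$n_lines, " lines, T=",
      x$config$T_divisions, ", true rate ", x$config$true_rate, "; ",
      sum(vapply(x$truth, nrow, integer(1))), " true SVs\n", sep = "")
  invisible(x)
}

#' Run the filter cascade and rate recovery on a synthetic experiment
#'
#' Applies ancestor subtraction, optional imprecise-call removal, and the
#' cross-line recurrence filter; benchmarks each line's surviving calls
#' against that line's truth; and estimates the per-genome SV rate from the
#' surviving true positives.
#'
#' @param experiment a [generate_experiment()] result.
#' @param criteria a [match_criteria()].
#' @param recurrence_threshold lines required for recurrence removal
#'   (default 3).
#' @param drop_imprecise_calls drop imprecise calls before the recurrence
#'   filter (default FALSE: imprecise breakpoints still witness a real event
#'   for rate counting; enable to mimic the pre-validation triage).
#' @return list of class `recovery_report`: `estimate` (a `rate_estimate`),
#'   `true_rate`, `covered` (does the CI cover the true rate), `tp`, `fp`,
#'   `fn`, `n_true`, and the cascade `report`.
#' @export
run_recovery <- function(experiment, criteria = match_criteria(),
                         recurrence_threshold = 3L,
                         drop_imprecise_calls = FALSE) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  cfg <- experiment$config
  cascade <- filter_cascade(experiment$observed, experiment$ancestor,
                            criteria = criteria,
                            recurrence_threshold = recurrence_threshold,
                            drop_imprecise_calls = drop_imprecise_calls)
  tp <- fp <- fn <- 0L
  for (k in seq_along(cascade$lines)) {
    cc <- confusion(match_callsets(experiment$truth[[k]],
                                   cascade$lines[[k]]$calls, criteria))
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  est <- rate_per_genome(tp, cfg$n_lines, cfg$T_divisions)
  structure(list(
    estimate = est,
    true_rate = cfg$true_rate,
    covered = est$ci_low <= cfg$true_rate && cfg$true_rate <= est$ci_high,
    tp = tp, fp = fp, fn = fn,
    n_true = sum(vapply(experiment$truth, nrow, integer(1))),
    report = cascade$report
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> true rate %.3g, estimate %.3g (CI %.3g-%.3g, %s); tp=%d fp=%d fn=%d\n",
    x$true_rate, x$estimate$rate, x$estimate$ci_low, x$estimate$ci_high,
    if (x$covered) "covered" else "missed", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Writes one VCF per line, the ancestor VCF, a combined truth TSV and a
#' config echo, the layout a filtering run expects.
#'
#' @param experiment a [generate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lc in experiment$observed)
    write_sv_vcf(lc$calls, file.path(dir, paste0(lc$line_id, ".vcf")))
  write_sv_vcf(experiment$ancestor$calls, file.path(dir, "ancestor.vcf"))
  write_sv_tsv(do.call(rbind, experiment$truth),
               file.path(dir, "truth.tsv"))
  cfg <- experiment$config
  writeLines(paste(names(unclass(cfg)),
                   vapply(unclass(cfg), function(v)
                     paste(format(v), collapse = ","), character(1)),
                   sep = ": "),
             file.path(dir, "config.txt"))
  invisible(dir)
}
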