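test_that("plan_svs delivers requested counts, bucket lengths, gaps, determinism", {
  cfg <- sim_config(n_per_type = c(DEL = 100), seed = 5)
  truth <- plan_svs(cfg, 4.6e6)
  expect_equal(nrow(truth), 100L)
  expect_true(all(truth$svtype == "DEL"))
  expect_true(all(truth$length >= 50 & truth$length <= 10000))
  # sorted, pairwise separated by min_gap_bp
  expect_true(all(diff(truth$start) > 0))
  expect_true(all(truth$start[-1] - truth$end[-nrow(truth)] > cfg$min_gap_bp))
  expect_identical(truth, plan_svs(cfg, 4.6e6))

  expect_equal(nrow(plan_svs(sim_config(), 1e6)), 0L)
  expect_error(plan_svs(sim_config(n_per_type = c(DEL = 50)), 20000),
               "genome too short|could not place")
})

test_that("bucket occupancy at 500 SVs sits within binomial 99% bounds", {
  cfg <- sim_config(n_per_type = c(DEL = 500), seed = 11)
  truth <- plan_svs(cfg, 4.6e6)
  b <- cfg$length_buckets
  for (i in seq_len(nrow(b))) {
    n_i <- sum(truth$length >= b$lo[i] & truth$length <= b$hi[i])
    expect_gte(n_i, qbinom(0.005, 500, b$weight[i]))
    expect_lte(n_i, qbinom(0.995, 500, b$weight[i]))
  }
  expect_equal(sum(truth$length < 50 | truth$length > 10000), 0L)
})

test_that("apply_svs reproduces hand-applied edits", {
  g <- reference_genome("t", "ACGTACGTAC")
  del <- apply_svs(g, sv_records("t", 3L, "DEL", 4L))
  expect_equal(del$genome$sequence, "ACGTAC")
  dup <- apply_svs(g, sv_records("t", 3L, "DUP", 4L))
  expect_equal(dup$genome$sequence, "ACGTACGTACGTAC")
  inv <- apply_svs(g, sv_records("t", 2L, "INV", 4L))
  expect_equal(inv$genome$sequence, "ATACGCGTAC")
  ins <- apply_svs(g, sv_records("t", 4L, "INS", 3L, inserted_seq = "TTT"))
  expect_equal(ins$genome$sequence, "ACGTTTTACGTAC")

  overlapping <- sv_records("t", c(2L, 4L), "DEL", c(4L, 4L))
  expect_error(apply_svs(g, overlapping), "overlap")
})

test_that("truth re-application reconstructs the mutated genome (randomized)", {
  set.seed(101)
  for (trial in 1:25) {
    ref <- random_genome(sample(20000:40000, 1))
    cfg <- sim_config(
      n_per_type = c(INS = sample(0:4, 1), DEL = sample(0:4, 1),
                     DUP = sample(0:3, 1), INV = sample(0:3, 1)),
      length_buckets = data.frame(lo = 50L, hi = 800L, weight = 1),
      p_flank_bps = 0, p_flank_indel = 0,
      seed = sample.int(1e6, 1)
    )
    sim <- simulate_genome(ref, cfg)
    expect_identical(sim$mutated_genome$sequence,
                     naive_apply_svs(ref$sequence, sim$truth))
    # length bookkeeping
    delta <- sum(sim$truth$length[sim$truth$svtype %in% c("INS", "DUP")]) -
      sum(sim$truth$length[sim$truth$svtype == "DEL"])
    expect_equal(genome_length(sim$mutated_genome),
                 genome_length(ref) + delta)
  }
})

test_that("zero-variant config leaves the genome byte-identical", {
  set.seed(3)
  ref <- random_genome(30000)
  sim <- simulate_genome(ref, sim_config(seed = 9))
  expect_identical(sim$mutated_genome$sequence, ref$sequence)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(sim$small_variants), 0L)
})

test_that("simulate_genome is deterministic and writes parseable outputs", {
  set.seed(13)
  ref <- random_genome(50000)
  cfg <- sim_config(n_per_type = c(INS = 8),
                    length_buckets = data.frame(lo = 50L, hi = 400L,
                                                weight = 1),
                    seed = 21)
  a <- simulate_genome(ref, cfg)
  b <- simulate_genome(ref, cfg)
  expect_identical(a$mutated_genome$sequence, b$mutated_genome$sequence)
  expect_identical(unrowname(a$truth), unrowname(b$truth))

  prefix <- file.path(withr::local_tempdir(), "sim1")
  simulate_genome(ref, cfg, out_prefix = prefix)
  back <- read_sv_vcf(paste0(prefix, ".truth.vcf"))
  expect_equal(nrow(back), 8L)
  expect_true(all(back$svtype == "INS"))
  expect_true(all(!is.na(back$inserted_seq)))
  expect_equal(nchar(back$inserted_seq), back$length)
  expect_true(file.exists(paste0(prefix, ".log")))
})

test_that("flanking noise respects per-flank semantics and indel cap", {
  set.seed(77)
  ref <- random_genome(60000)
  base_cfg <- function(...) {
    sim_config(n_per_type = c(DEL = 10),
               length_buckets = data.frame(lo = 100L, hi = 400L, weight = 1),
               seed = 31, ...)
  }
  # zero probabilities: no noise at all
  sim0 <- simulate_genome(ref, base_cfg(p_flank_bps = 0, p_flank_indel = 0))
  expect_equal(nrow(sim0$small_variants), 0L)

  # p_flank_indel = 1: exactly one indel per flank, none longer than 20 bp
  sim1 <- simulate_genome(ref, base_cfg(p_flank_bps = 0, p_flank_indel = 1))
  n_flanks <- 2L * nrow(sim1$truth) # one junction per DEL, two flanks each
  expect_equal(nrow(sim1$small_variants), n_flanks)
  indel_len <- abs(nchar(sim1$small_variants$ref) -
                   nchar(sim1$small_variants$alt))
  expect_true(all(indel_len >= 1 & indel_len <= 20))

  # substitution count over many flanks within binomial 99.9% bounds
  cfgN <- sim_config(n_per_type = c(DEL = 100),
                     length_buckets = data.frame(lo = 100L, hi = 300L,
                                                 weight = 1),
                     p_flank_bps = 0.05, p_flank_indel = 0, seed = 41)
  ref2 <- random_genome(500000)
  simN <- simulate_genome(ref2, cfgN)
  n_flanks <- 200L
  n_subs <- nrow(simN$small_variants)
  expect_gte(n_subs, qbinom(0.0005, n_flanks, 0.05))
  expect_lte(n_subs, qbinom(0.9995, n_flanks, 0.05))
  # substitutions really substitute
  expect_true(all(nchar(simN$small_variants$ref) == 1L &
                  nchar(simN$small_variants$alt) == 1L))
  expect_true(all(simN$small_variants$ref != simN$small_variants$alt))
})

test_that("small variants fall within a flank of some breakpoint", {
  set.seed(55)
  ref <- random_genome(200000)
  cfg <- sim_config(n_per_type = c(DEL = 20, INS = 20),
                    length_buckets = data.frame(lo = 60L, hi = 500L,
                                                weight = 1),
                    p_flank_bps = 1, p_flank_indel = 0, seed = 61)
  truth <- plan_svs(cfg, genome_length(ref))
  applied <- apply_svs(ref, truth, seed = 62)
  noised <- inject_flanking_noise(applied$genome, applied$truth, cfg,
                                  seed = 63)
  # recompute mutated-genome junctions from the truth with a running offset
  truth <- applied$truth[order(applied$truth$start), ]
  shift <- 0L
  junctions <- integer(0)
  for (i in seq_len(nrow(truth))) {
    s <- truth$start[i] + shift
    if (truth$svtype[i] == "DEL") {
      junctions <- c(junctions, s)
      shift <- shift - truth$length[i]
    } else { # INS
      junctions <- c(junctions, s, s + truth$length[i] + 1L)
      shift <- shift + truth$length[i]
    }
  }
  dist <- vapply(noised$small_variants$pos,
                 function(p) min(abs(p - junctions)), numeric(1))
  expect_true(all(dist <= cfg$flank_bp))
})

test_that("breakpoint positions are consistent with a uniform distribution", {
  glen <- 4.6e6
  starts <- unlist(lapply(1:10, function(s) {
    plan_svs(sim_config(n_per_type = c(DEL = 100), seed = 1000 + s),
             glen)$start
  }))
  bins <- table(cut(starts, breaks = seq(0, glen, length.out = 21)))
  p <- chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("IS-payload insertions draw a family consensus", {
  set.seed(9)
  lib <- is_library(list(
    ISX = list(consensus = paste(sample(c("A", "C", "G", "T"), 700,
                                        replace = TRUE), collapse = ""),
               copies = data.frame(start = 1000L, end = 1699L))
  ))
  ref <- random_genome(50000)
  truth <- sv_records("chr", 20000L, "INS", 999L)
  applied <- apply_svs(ref, truth, seed = 2, is_lib = lib)
  expect_equal(applied$truth$inserted_seq, lib$families$ISX$consensus)
  expect_equal(applied$truth$length, 700L)
})
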