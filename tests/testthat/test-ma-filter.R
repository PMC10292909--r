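mk_line <- function(id, calls, platform = "long_read") {
  line_callset(id, calls, strain = "WT", platform = platform)
}

test_that("subtract_ancestor removes tolerant matches and is idempotent", {
  crit <- match_criteria()
  anc_calls <- sv_records("chr", c(1000L, 8000L), "DEL", c(300L, 500L),
                          source = "ancestor")
  line_calls <- rbind(
    sv_records("chr", 1020L, "DEL", 330L),   # within 30 bp / 10% of ancestor
    sv_records("chr", 8000L, "DEL", 500L),   # identical to ancestor
    sv_records("chr", 20000L, "INS", 700L)   # de novo
  )
  line <- mk_line("l1", line_calls)
  anc <- mk_line("ancestor", anc_calls)
  out <- subtract_ancestor(line, anc, crit)
  expect_equal(nrow(out$calls), 1L)
  expect_equal(out$calls$svtype, "INS")
  expect_equal(attr(out, "n_removed"), 2L)
  # idempotent
  again <- subtract_ancestor(out, anc, crit)
  expect_equal(unrowname(again$calls), unrowname(out$calls))
  # empty ancestor: unchanged
  none <- subtract_ancestor(line, mk_line("ancestor", empty_sv_records()),
                            crit)
  expect_equal(nrow(none$calls), 3L)
  # platform mismatch is an error
  expect_error(subtract_ancestor(line, mk_line("ancestor", anc_calls,
                                               "short_read"), crit),
               "platform")
})

test_that("recurrence_filter removes clusters touching >= threshold lines", {
  crit <- match_criteria()
  shared <- sv_records("chr", 5000L, "DEL", 400L)
  lines <- lapply(1:10, function(i) {
    calls <- if (i <= 5) {
      # jittered copies of the shared artifact, still within tolerance
      rbind(sv_records("chr", 5000L + i, "DEL", 400L + i),
            sv_records("chr", 100000L + 1000L * i, "INS", 600L))
    } else {
      sv_records("chr", 100000L + 1000L * i, "INS", 600L)
    }
    mk_line(sprintf("l%02d", i), calls)
  })
  res <- recurrence_filter(lines, threshold = 3L, criteria = crit)
  # removed everywhere, reported with the 5 carrier line ids
  expect_equal(nrow(res$removed_clusters), 1L)
  expect_equal(res$removed_clusters$n_lines, 5L)
  expect_equal(res$removed_clusters$line_ids,
               paste(sprintf("l%02d", 1:5), collapse = ","))
  for (l in res$lines) {
    expect_true(all(l$calls$svtype == "INS"))
    expect_equal(nrow(l$calls), 1L)
  }
  # idempotent
  res2 <- recurrence_filter(res$lines, threshold = 3L, criteria = crit)
  expect_equal(nrow(res2$removed_clusters), 0L)

  # two carriers only: retained
  two <- lapply(1:2, function(i) mk_line(paste0("a", i), shared))
  kept <- recurrence_filter(two, threshold = 3L, criteria = crit)
  expect_equal(vapply(kept$lines, function(l) nrow(l$calls), integer(1)),
               c(1L, 1L))

  # all-empty input passes through
  empty <- lapply(1:3, function(i) mk_line(paste0("e", i),
                                           empty_sv_records()))
  expect_equal(recurrence_filter(empty)$lines, empty)
})

test_that("drop_imprecise keeps only precise calls", {
  calls <- sv_records("chr", seq(1000L, 5000L, by = 1000L), "DEL", 200L,
                      imprecise = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  out <- drop_imprecise(mk_line("l1", calls))
  expect_equal(nrow(out$calls), 2L)
  expect_equal(attr(out, "n_removed"), 3L)
  expect_true(all(!out$calls$imprecise))
  # idempotent; empty passes through
  expect_equal(nrow(drop_imprecise(out)$calls), 2L)
  expect_equal(nrow(drop_imprecise(mk_line("l1",
                                           empty_sv_records()))$calls), 0L)
})

test_that("merge_platforms deduplicates with the long-read representative", {
  crit <- match_criteria()
  long <- mk_line("l1", sv_records("chr", c(1000L, 5000L), "DEL",
                                   c(400L, 300L), source = "sniffles"))
  short_disjoint <- line_callset(
    "l1", sv_records("chr", c(20000L, 30000L, 40000L), "INS", 100L,
                     source = "manta"), platform = "short_read")
  m1 <- merge_platforms(short_disjoint, long, crit)
  expect_equal(nrow(m1$calls), 5L)

  # near-duplicate: dstart 20, dlen 5% -> merged, dual provenance,
  # long-read coordinates kept
  short_dup <- line_callset(
    "l1", sv_records("chr", 1020L, "DEL", 420L, source = "manta"),
    platform = "short_read")
  m2 <- merge_platforms(short_dup, long, crit)
  expect_equal(nrow(m2$calls), 2L)
  merged_row <- m2$calls[m2$calls$start == 1000L, ]
  expect_equal(merged_row$source, "sniffles+manta")
  expect_equal(merged_row$length, 400L)

  # line_id mismatch
  other <- line_callset("l2", empty_sv_records(), platform = "short_read")
  expect_error(merge_platforms(other, long), "line_id")
})

test_that("validate_call uses strict Sanger thresholds", {
  sanger <- sv_records("chr", 1000L, "INS", 768L, source = "sanger")
  ok <- validate_call(sv_records("chr", 1040L, "INS", 768L), sanger)
  expect_equal(ok$status, "true_positive")

  at_100 <- validate_call(sv_records("chr", 1100L, "INS", 768L), sanger)
  expect_equal(at_100$status, "false_positive")
  expect_equal(at_100$reason, "start")
  at_99 <- validate_call(sv_records("chr", 1099L, "INS", 768L), sanger)
  expect_equal(at_99$status, "true_positive")

  wrong <- validate_call(sv_records("chr", 1000L, "DEL", 768L), sanger)
  expect_equal(wrong$status, "false_positive")
  expect_equal(wrong$reason, "type")

  # length threshold is strict: 30% of 768 is 230.4, so dlen 231 passes
  # (< 230.4 is false) and 230 passes
  near <- validate_call(sv_records("chr", 1000L, "INS", 998L), sanger)
  expect_equal(near$status, "true_positive") # dlen 230 < 230.4
  over <- validate_call(sv_records("chr", 1000L, "INS", 999L), sanger)
  expect_equal(over$status, "false_positive") # dlen 231 >= 230.4
})

test_that("filter_cascade composes stages and reports per-line counts", {
  crit <- match_criteria()
  anc_calls <- sv_records("chr", 2000L, "DEL", 300L, source = "ancestor")
  shared <- sv_records("chr", 9000L, "INS", 500L)
  lines <- lapply(1:4, function(i) {
    calls <- rbind(
      anc_calls,
      shared,
      sv_records("chr", 50000L + 10000L * i, "DEL", 200L,
                 imprecise = (i == 1L))
    )
    mk_line(paste0("l", i), calls)
  })
  res <- filter_cascade(lines, mk_line("ancestor", anc_calls),
                        criteria = crit, recurrence_threshold = 3L,
                        drop_imprecise_calls = TRUE)
  expect_equal(res$report$input, rep(3L, 4))
  expect_equal(res$report$after_ancestor, rep(2L, 4))
  expect_equal(res$report$after_imprecise, c(1L, 2L, 2L, 2L))
  expect_equal(res$report$after_recurrence, c(0L, 1L, 1L, 1L))
  # no stage fabricates records
  expect_true(all(res$report$after_recurrence <= res$report$input))
})
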