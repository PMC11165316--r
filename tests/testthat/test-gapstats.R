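test_that("BTOP decoding handles identities, mismatches and merged gaps", {
  ev <- decode_btop("259")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "match")
  expect_equal(sum(ev$length), 259)

  ev2 <- decode_btop("10AG5")
  expect_equal(sum(ev2$length), 16)                       # align_len
  expect_equal(sum(ev2$length[ev2$type == "match"]), 15)  # identities

  ev3 <- decode_btop("4-A-A2")
  gaps <- ev3[ev3$type %in% c("qgap", "sgap"), ]
  expect_equal(nrow(gaps), 1)          # two -A tokens merged
  expect_equal(gaps$type, "qgap")
  expect_equal(gaps$length, 2L)
  expect_equal(sum(ev3$length[ev3$type == "match"]), 6)

  expect_error(decode_btop("4-"), "offset 2")
  expect_error(decode_btop("2--3"), "offset 2")
})

test_that("re-encoding a decoded event list reproduces the canonical string", {
  # gap-merged inputs survive encode(decode(.)) byte-identically
  for (b in c("259", "10AG5", "4-A-A2", "100-A-A100", "3K-R-2-W5AG"))
    expect_identical(encode_btop(decode_btop(b)), b)
  # and re-encoding is idempotent for any legal input
  for (b in c("0", "5A-A-3", "-C-C-C2"))
    expect_identical(encode_btop(decode_btop(encode_btop(decode_btop(b)))),
                     encode_btop(decode_btop(b)))
})

test_that("alignment summaries carry identity, gap events and max gap", {
  s <- summarize_alignment(list(btop = "100", align_len = 100L))
  expect_equal(s$max_gap, 0L)
  expect_equal(s$percent_identity, 100)
  # a 96%-identical alignment with a single 104-residue subject insertion
  # (gap in the query): identity 2496/2600
  btop <- paste0("1248", strrep("-A", 104), "1248")
  s2 <- summarize_alignment(list(btop = btop))
  expect_equal(s2$max_gap, 104L)
  expect_equal(s2$percent_identity, 100 * 2496 / 2600)
  # gaps of 3 and 7 on opposite sides
  s3 <- summarize_alignment(list(btop = paste0("10", strrep("-A", 3), "10",
                                               strrep("C-", 7), "10")))
  expect_equal(s3$n_gaps_ge(5), 1L)
  expect_equal(s3$max_gap, 7L)
  expect_setequal(s3$gap_events$side, c("query", "subject"))
  # conservation: events always span align_len
  expect_error(summarize_alignment(list(btop = "10", align_len = 11L)),
               "align_len")
  expect_warning(summarize_alignment(list(btop = "8AG1",
                                          align_len = 10L,
                                          percent_identity = 50)),
                 "disagrees")
})

test_that("best-hit filtering applies length and E-value cutoffs strictly", {
  h <- function(q, s, e, bits, qlen) data.frame(
    query_acc = q, subject_acc = s, percent_identity = 100,
    align_len = 50L, mismatches = 0L, gap_opens = 0L, q_start = 1L,
    q_end = 50L, s_start = 1L, s_end = 50L, e_value = e, bit_score = bits,
    btop = "50", query_len = qlen, subject_len = 50L,
    stringsAsFactors = FALSE)
  hits <- rbind(h("Q1", "S1", 1e-8, 100, 80),     # too short: dropped
                h("Q2", "S2", 1e-6, 100, 200),    # E == 1e-6: dropped
                h("Q3", "S3", 1e-8, 100, 200),
                h("Q3", "S4", 1e-12, 90, 200),    # better E wins
                h("Q4", "S5", 1e-9, 50, 200),
                h("Q4", "S6", 1e-9, 80, 200))     # tie on E: bit score
  best <- best_hit_filter(hits)
  expect_equal(nrow(best), 2)
  expect_equal(best$subject_acc[best$query_acc == "Q3"], "S4")
  expect_equal(best$subject_acc[best$query_acc == "Q4"], "S6")
})

test_that("pair statistics recover planted fractions and honor half-open bins", {
  # constructed fixture: 10 alignments above 90% identity, 2 of them with
  # a gap of at least 5 -> 20% in the >90% subset
  mk <- function(pid, gap) data.frame(
    query_acc = "q", subject_acc = "s", align_len = 100L,
    n_identical = pid, percent_identity = pid, n_gaps = as.integer(gap > 0),
    max_gap = gap, stringsAsFactors = FALSE)
  summ <- do.call(rbind, c(
    lapply(1:8, function(i) mk(95, 0)),
    list(mk(97, 12), mk(98, 7)),
    lapply(1:5, function(i) mk(70, 10))))
  st <- proteome_pair_stats(summ)
  expect_equal(st$n, 15L)
  expect_equal(st$frac_gt90, 10 / 15)
  expect_equal(st$gt90$fraction[st$gt90$threshold == 5], 0.2)
  # gapless input: every fraction zero
  st0 <- proteome_pair_stats(do.call(rbind, lapply(1:4, function(i)
    mk(80, 0))))
  expect_true(all(st0$bins$frac_ge_5 == 0, na.rm = TRUE))
  # boundary: identity exactly at an edge lands in the upper bin
  stb <- proteome_pair_stats(mk(90, 0))
  expect_equal(stb$bins$n[stb$bins$lo == 90], 1L)
  expect_equal(stb$bins$n[stb$bins$lo == 89], 0L)
  expect_equal(stb$frac_gt90, 0)       # '>90%' is strict
  # empty input: empty tables
  ste <- proteome_pair_stats(summ[0, ])
  expect_equal(ste$n, 0L)
  expect_equal(nrow(ste$bins), 0L)
})

test_that("planted m8+BTOP files close the loop through parsing and stats", {
  hits <- generate_pair_hits(200, frac_gt90 = 0.5, frac_gap_ge5_gt90 = 0.2,
                             seed = 77)
  f <- tempfile()
  write_m8_btop(hits, f)
  qlen <- stats::setNames(hits$query_len, hits$query_acc)
  back <- read_m8_btop(f, query_lengths = qlen)
  expect_equal(back$btop, hits$btop)
  best <- best_hit_filter(back)
  expect_equal(nrow(best), 200L)
  st <- proteome_pair_stats(best)
  planted <- attr(hits, "planted")
  expect_equal(st$frac_gt90, planted$frac_gt90)
  expect_equal(st$gt90$fraction[st$gt90$threshold == 5],
               planted$frac_gap_ge5_gt90)
  # a single planted 104-residue gap dominates the file's maximum
  hits2 <- generate_pair_hits(20, frac_gt90 = 1, frac_gap_ge5_gt90 = 0.05,
                              max_gap_range = c(104, 104), seed = 78)
  st2 <- summarize_hits(hits2)
  expect_equal(max(st2$max_gap), 104L)
  expect_equal(nrow(generate_pair_hits(0)), 0L)
})
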