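test_that("detection filter keeps transcripts detected at enough days", {
  # 4 transcripts x 13 days engineered to be above a 0 threshold at
  # {6, 5, 13, 0} days respectively -> 2 survivors at min = 6
  n_above <- c(6, 5, 13, 0)
  vals <- t(sapply(n_above, function(k) c(rep(1, k), rep(-1, 13 - k))))
  ds <- make_ds(vals, days = long_days)
  kept <- detection_filter(ds, min_timepoints = 6, detect_thr = 0)
  expect_equal(transcript_ids(kept), c("T01", "T03"))

  # everything above threshold at all days -> identity
  all_on <- make_ds(matrix(5, 4, 13), days = long_days)
  expect_equal(transcript_ids(detection_filter(all_on, 6, 0)),
               transcript_ids(all_on))

  # asking for more days than exist is an error
  expect_error(detection_filter(ds, min_timepoints = 14, detect_thr = 0),
               "distinct days")
})

test_that("raising min_timepoints never enlarges the detection survivor set", {
  set.seed(5)
  ds <- make_ds(matrix(rnorm(60 * 13, 5, 2), 60), days = long_days)
  prev <- transcript_ids(detection_filter(ds, 1))
  for (m in 2:13) {
    cur <- transcript_ids(detection_filter(ds, m))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("segmental fold change implements the inclusive informative window", {
  days <- c(0, 2, 4, 6, 8, 15, 30)
  sch <- segments_short()
  flat <- mk_profile("flat", rep(2, 7))
  # log2 2 at day 0 -> log2 3 at day 4, the mesoderm segment endpoints
  doubling <- mk_profile("dbl", c(2, 2.5, 3, 3, 3, 3, 3))
  calls <- segmental_fold_change(list(flat, doubling), sch)
  f <- calls[calls$transcript_id == "flat", ]
  expect_true(all(f$fold_change == 1))
  expect_true(all(f$direction == "flat"))
  expect_false(any(f$informative))
  d1 <- calls[calls$transcript_id == "dbl" & calls$segment == "mesoderm", ]
  expect_equal(d1$fold_change, 2)  # log2 2.0 -> 3.0 across the segment
  expect_equal(d1$direction, "up")
  expect_true(d1$informative)

  # boundaries are inclusive: exactly 1.2 and 0.8 are informative,
  # 1.19 and 0.81 are not
  mk <- function(id, delta) mk_profile(id, c(1, 1, 1 + delta, 1 + delta, 2, 2, 2))
  bounds <- segmental_fold_change(list(
    mk("hi", log2(1.2)), mk("hi_in", log2(1.19)),
    mk("lo", log2(0.8)), mk("lo_in", log2(0.81))), sch)
  meso <- bounds[bounds$segment == "mesoderm", ]
  expect_equal(meso$informative[match(c("hi", "hi_in", "lo", "lo_in"),
                                      meso$transcript_id)],
               c(TRUE, FALSE, TRUE, FALSE))

  # log2 1.0 -> 1.585 across a segment: FC = 2^0.585 ~ 1.500, informative
  p <- mk_profile("x", c(1, 1.2, 1.585, 1.585, 1.585, 1.585, 1.585))
  cx <- segmental_fold_change(list(p), sch)
  expect_equal(cx$fold_change[cx$segment == "mesoderm"], 2^0.585,
               tolerance = 1e-12)
  expect_true(cx$informative[cx$segment == "mesoderm"])
})

test_that("segmental fold change is invariant to adding a constant in log2", {
  set.seed(8)
  profs <- lapply(1:5, function(i) mk_profile(paste0("P", i), rnorm(7, 5)))
  shifted <- lapply(profs, function(p)
    time_profile(p$transcript_id, p$days, p$mean_log2 + 3.7))
  a <- segmental_fold_change(profs, segments_short())
  b <- segmental_fold_change(shifted, segments_short())
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
  expect_equal(a$informative, b$informative)
})

test_that("widening the informative window never shrinks the informative set", {
  set.seed(9)
  profs <- lapply(1:40, function(i) mk_profile(paste0("P", i), rnorm(7, 5, .3)))
  narrow <- informative_ids(segmental_fold_change(profs, segments_short(),
                                                  low_thr = 0.7, high_thr = 1.4))
  wide <- informative_ids(segmental_fold_change(profs, segments_short(),
                                                low_thr = 0.9, high_thr = 1.1))
  expect_true(all(narrow %in% wide))
})

test_that("a segment with fewer than 2 sampled days is an error naming it", {
  p <- mk_profile("x", 1:7)
  bad <- segment_scheme(c("a", "b"), c(0, 9), c(8, 12))  # no days in [9,12]
  expect_error(segmental_fold_change(list(p), bad), "b")
})

test_that("segment overlap reproduces exact Venn cells and partitions the union", {
  # planted memberships: A in all 3; B in meso only; C in meso+mat; D none
  days <- c(0, 2, 4, 6, 8, 15, 30)
  jump <- log2(2)  # one doubling: informative
  mk <- function(id, meso, spec, mat) {
    # increments between consecutive days; jumps land inside the segments
    # [0,4] (day 0->2), [5,8] (day 6->8) and [9,30] (day 15->30)
    inc <- c(if (meso) jump else 0, 0, 0,
             if (spec) jump else 0, 0,
             if (mat) jump else 0)
    time_profile(id, days, cumsum(c(5, inc)))
  }
  profs <- list(mk("A", TRUE, TRUE, TRUE), mk("B", TRUE, FALSE, FALSE),
                mk("C", TRUE, FALSE, TRUE), mk("D", FALSE, FALSE, FALSE))
  calls <- segmental_fold_change(profs, segments_short())
  ov <- segment_overlap(calls)
  sets <- attr(ov, "sets")
  expect_equal(sets[["mesoderm+specification+maturation"]], "A")
  expect_equal(sets[["mesoderm"]], "B")
  expect_equal(sets[["mesoderm+maturation"]], "C")
  expect_equal(sum(ov$n_transcripts), 3)  # D is nowhere
  # cells partition the union: no transcript in two cells
  all_members <- unlist(sets)
  expect_false(anyDuplicated(all_members) > 0)
  expect_setequal(all_members, informative_ids(calls))

  # disjoint informative sets leave multi-segment cells empty
  disj <- list(mk("E", TRUE, FALSE, FALSE), mk("F", FALSE, TRUE, FALSE))
  ov2 <- segment_overlap(segmental_fold_change(disj, segments_short()))
  expect_false(any(grepl("\\+", ov2$segments)))
})
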