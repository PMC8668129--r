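# Signature detectors and clone profiling.

test_that("large-insert fraction counts eligible pairs only", {
  region <- genomic_interval("chrT", 0, 60000)
  small <- do.call(rbind, lapply(seq(1000, 8000, by = 1000) - 1000,
                                 function(s) make_pair(s, s + 300)))
  big <- rbind(make_pair(9000, 10000), make_pair(11000, 12500))
  res <- fraction_large_inserts(rbind(small, big), region)
  expect_equal(res$fraction, 0.2)
  expect_equal(res$n_eligible, 10L)

  res0 <- fraction_large_inserts(small, region)
  expect_equal(res0$fraction, 0)

  # zero eligible pairs is an explicit no-data state, not zero
  none <- fraction_large_inserts(small, genomic_interval("chrT", 50000, 59999))
  expect_true(none$no_data)
  expect_true(is.na(none$fraction))

  # duplicates and secondaries are excluded
  dup <- make_pair(1000, 2500, duplicate = TRUE)
  expect_equal(fraction_large_inserts(rbind(small, dup), region)$n_eligible,
               8L)
})

test_that("mean depth counts each mate's bases", {
  iv <- genomic_interval("chrT", 10000, 10150)
  one <- make_pair(10000, 10300)  # mate1 exactly covers the interval
  expect_equal(mean_depth(one, iv)$mean_depth, 1)
  expect_equal(mean_depth(one[0, ], iv)$mean_depth, 0)
  both <- make_pair(10000, 10000)
  expect_equal(mean_depth(both, iv)$mean_depth, 2)
  expect_error(mean_depth(one, genomic_interval("chrT", 5, 5,
                                                allow_empty = TRUE)),
               "non-empty")
})

test_that("J/V junction pairs are detected by mate overlap", {
  loc <- toy_locus()
  # mate1 in IGHJ1, mate2 in IGHV3-23
  hit <- make_pair(2900, 20100)
  a <- detect_vdj_pairs(hit, loc)
  expect_equal(a, data.frame(j_name = "IGHJ1", v_name = "IGHV3-23",
                             stringsAsFactors = FALSE))
  # orientation-independent: V mate first
  swapped <- make_pair(20100, 2900)
  swapped$insert_size <- abs(swapped$insert_size)
  expect_equal(nrow(detect_vdj_pairs(swapped, loc)), 1L)

  # both mates in the V region: no assignment
  expect_equal(nrow(detect_vdj_pairs(make_pair(20050, 40100), loc)), 0L)
  # J + D is not a V(D)J junction pair
  expect_equal(nrow(detect_vdj_pairs(make_pair(2900, 4450), loc)), 0L)
  # mapping-quality and flag filters
  expect_equal(nrow(detect_vdj_pairs(make_pair(2900, 20100, mapq2 = 5),
                                     loc, min_mapq = 20)), 0L)
  expect_equal(nrow(detect_vdj_pairs(make_pair(2900, 20100,
                                               secondary = TRUE), loc)), 0L)
})

test_that("multi-segment overlaps resolve to the larger overlap, then name", {
  # two J segments close enough for one read to span both
  seg <- gene_segments(c("IGHJ8", "IGHJ9", "IGHV6-1"), "chrT",
                       c(1000, 1100, 8000), c(1060, 1160, 8300))
  loc <- locus_definition("chrT", genomic_interval("chrT", 0, 60000),
                          genomic_interval("chrT", 0, 3000),
                          genomic_interval("chrT", 3000, 8000),
                          genomic_interval("chrT", 8000, 60000), seg)
  # read [1030, 1180): 30 bp on IGHJ8, 60 bp on IGHJ9 -> IGHJ9
  a <- detect_vdj_pairs(make_pair(1030, 8100), loc)
  expect_equal(a$j_name, "IGHJ9")
  # read [1010, 1160): 50 bp on IGHJ8, 60 bp on IGHJ9 -> IGHJ9 still
  expect_equal(detect_vdj_pairs(make_pair(1010, 8100), loc)$j_name, "IGHJ9")
  # read [1040, 1190): 20 on IGHJ8, 60 on IGHJ9
  expect_equal(detect_vdj_pairs(make_pair(1040, 8100), loc)$j_name, "IGHJ9")
  # symmetric overlaps tie-break alphabetically: read covering both fully
  a3 <- detect_vdj_pairs(make_pair(1000, 8100, width1 = 160), loc)
  expect_equal(a3$j_name, "IGHJ8")
})

test_that("detector matches the brute-force enumeration on crafted pairs", {
  loc <- toy_locus()
  set.seed(42)
  starts1 <- sample(0:59000, 40)
  gap <- sample(150:500, 40, replace = TRUE)
  pairs <- do.call(rbind, mapply(function(s, g) {
    make_pair(s, min(s + g, 59000))
  }, starts1, gap, SIMPLIFY = FALSE))
  # seed some guaranteed junction hits and edge cases
  pairs <- rbind(pairs, make_pair(2950, 8100), make_pair(1550, 55200),
                 make_pair(2250, 40300), make_pair(2999, 8000, width1 = 1),
                 make_pair(2900, 20100, duplicate = TRUE))
  got <- detect_vdj_pairs(pairs, loc)
  want <- brute_force_vdj(pairs, loc)
  expect_equal(got[order(got$j_name, got$v_name), ],
               want[order(want$j_name, want$v_name), ], ignore_attr = TRUE)
  expect_gt(nrow(want), 2)
})

test_that("clonality profiles count unique J/V pairs and their support", {
  loc <- toy_locus()
  a <- data.frame(j_name = c(rep("IGHJ1", 3), "IGHJ3"),
                  v_name = c(rep("IGHV3-23", 3), "IGHV1-69"),
                  stringsAsFactors = FALSE)
  p <- profile_clonality(a, loc, "S1")
  expect_equal(p$n_clones, 2L)
  expect_equal(p$dominant_fraction, 0.75)
  expect_equal(p$dominant_j, "IGHJ1")
  expect_equal(sum(p$events$support), nrow(a))
  expect_equal(sum(p$events$fraction), 1)
  expect_equal(p$del_size, 20000 - 3000)

  mono <- profile_clonality(a[1, , drop = FALSE], loc, "S1")
  expect_equal(mono$n_clones, 1L)
  expect_equal(mono$dominant_fraction, 1)

  undet <- profile_clonality(a[0, , drop = FALSE], loc, "S1")
  expect_equal(undet$status, "undetermined")
  expect_equal(undet$n_clones, 0L)
  expect_true(is.na(undet$dominant_fraction))
})

test_that("dominant ties prefer the larger deletion", {
  loc <- toy_locus()
  a <- data.frame(j_name = c("IGHJ1", "IGHJ1"),
                  v_name = c("IGHV3-23", "IGHV1-69"),
                  stringsAsFactors = FALSE)
  p <- profile_clonality(a, loc, "S1")
  expect_equal(p$dominant_v, "IGHV1-69")  # 37 kb beats 17 kb
  expect_equal(p$dominant_fraction, 0.5)
})

test_that("cohort summary counts dominance thresholds correctly", {
  loc <- toy_locus()
  mk <- function(fracs, id) {
    n <- round(fracs * 20)
    a <- data.frame(
      j_name = rep(c("IGHJ1", "IGHJ2", "IGHJ3")[seq_along(n)], n),
      v_name = rep(c("IGHV3-23", "IGHV1-69", "IGHV6-1")[seq_along(n)], n),
      stringsAsFactors = FALSE)
    profile_clonality(a, loc, id)
  }
  profs <- list(mk(1.0, "A"), mk(c(0.6, 0.4), "B"), mk(c(0.2, 0.35, 0.45), "C"))
  s <- cohort_summary(profs)$stats
  expect_equal(s$n_monoclonal, 1L)
  expect_equal(s$n_dom_gt50, 2L)   # the monoclonal sample counts here too
  expect_equal(s$n_dom_gt75, 1L)
  expect_equal(s$mean_n_clones, 2)

  one <- cohort_summary(profs[1])$stats
  expect_equal(one$min_dominant_fraction, one$max_dominant_fraction)
})

test_that("event support is conserved through profiling", {
  loc <- toy_locus()
  for (s in 1:5) {
    cfg <- toy_config(seed = s, n_clones = 4)
    germ <- simulate_germline(cfg, loc)
    tr <- simulate_sample(cfg, loc, germ, 1)
    pr <- simulate_read_pairs(tr, cfg, loc)
    a <- detect_vdj_pairs(pr, loc)
    if (nrow(a) == 0) next
    p <- profile_clonality(a, loc)
    expect_equal(p$total_support, nrow(a))
    expect_equal(sum(p$events$support), nrow(a))
    expect_equal(p$dominant_fraction, max(p$events$fraction))
    expect_true(p$dominant_fraction > 0 && p$dominant_fraction <= 1)
    expect_equal(p$dominant_fraction == 1, p$n_clones == 1L)
  }
})

test_that("the true clone's read share estimates its fraction unbiasedly", {
  # single-sample estimates carry multinomial noise at ~7 supporting pairs,
  # so the contract tested is accuracy of the mean over a dozen streams;
  # the share of the *known* dominant (J,V) event is the unbiased reading
  # of the clone-frequency definition (the max-share profile adds the
  # order-statistic bias discussed in the vignette)
  loc <- igh_locus()
  counts <- vapply(1:24, function(s) {
    cfg <- sim_config(seed = 100 + s, n_clones = 10, dominant_fraction = 0.7)
    germ <- simulate_germline(cfg, loc)
    tr <- simulate_sample(cfg, loc, germ, 1)
    a <- detect_vdj_pairs(simulate_read_pairs(tr, cfg, loc), loc)
    c(sum(a$j_name == tr$dominant_j & a$v_name == tr$dominant_v), nrow(a))
  }, c(0, 0))
  pooled_share <- sum(counts[1, ]) / sum(counts[2, ])
  expect_lt(abs(pooled_share - 0.7), 0.10)
})

test_that("monoclonal simulations resolve to the single true clone", {
  loc <- igh_locus()
  for (s in 1:4) {
    cfg <- sim_config(seed = 200 + s, n_clones = 1)
    germ <- simulate_germline(cfg, loc)
    tr <- simulate_sample(cfg, loc, germ, 1)
    p <- profile_sample(simulate_read_pairs(tr, cfg, loc), loc)
    expect_equal(p$n_clones, 1L)
    expect_equal(c(p$dominant_j, p$dominant_v),
                 c(tr$dominant_j, tr$dominant_v))
    expect_equal(c(p$del_start, p$del_end), unname(tr$deletion))
  }
})
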