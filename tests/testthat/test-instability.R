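# Allele-specific instability scoring: worked examples, boundary rules,
# invariance properties, and agreement with the naive scan oracle.

test_that("ploidy and WGD follow the length-weighted autosomal rules", {
  g <- test_genome()
  p <- diploid_profile(g)
  pw <- ploidy_wgd(sample_segments(p, "s1"), g)
  expect_equal(pw$ploidy, 2)
  expect_false(pw$wgd)
  # half the autosomal length total 2, half total 4 -> ploidy 3; exactly 50%
  # at major >= 2 does not satisfy the strict >50% WGD rule
  p2 <- segment_profiles(data.frame(
    sample = "s1", chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0, 100e6, 0, 50e6), end = c(100e6, 200e6, 50e6, 100e6),
    total_cn = c(2L, 4L, 2L, 4L), major_cn = c(1L, 2L, 1L, 2L),
    minor_cn = c(1L, 2L, 1L, 2L)))
  pw2 <- ploidy_wgd(sample_segments(p2, "s1"), g)
  expect_equal(pw2$ploidy, 3)
  expect_false(pw2$wgd)  # 150 of 300 Mb: not more than 50%
  # doubling every allele doubles ploidy and forces WGD
  pd <- sample_segments(p, "s1")
  pd$major_cn <- 2L; pd$minor_cn <- 2L; pd$total_cn <- 4L
  pwd <- ploidy_wgd(pd, g)
  expect_equal(pwd$ploidy, 4)
  expect_true(pwd$wgd)
  expect_error(ploidy_wgd(pd[0, ], g), "no autosomal segments")
})

test_that("CIN counts gains, losses and LOH over merged segments", {
  g <- test_genome()
  p <- make_profile(c(0, 50e6, 1, 1), c(50e6, 120e6, 3, 2), c(120e6, 200e6, 1, 0))
  cs <- cin_score(sample_segments(p, "s1"), g)
  expect_equal(cs$n_gain, 1)            # total 5
  expect_equal(cs$n_loss, 1)            # total 1
  expect_equal(cs$n_loh_segments, 1)    # (1,0)
  expect_equal(cs$cin, 3)
  # multi-category counting: total 1 with minor 0 is loss + LOH
  expect_equal(cin_score(make_profile(c(0, 200e6, 1, 0)), g)$cin, 2)
  expect_equal(cin_score(make_profile(c(0, 200e6, 1, 0)), g, exclusive = TRUE)$cin, 1)
  # diploid heterozygous genome scores zero
  expect_equal(cin_score(sample_segments(diploid_profile(g), "s1"), g)$cin, 0)
})

test_that("splitting segments without changing state never changes scores", {
  g <- test_genome()
  p <- make_profile(c(0, 30e6, 2, 1), c(30e6, 90e6, 1, 1), c(110e6, 150e6, 2, 0),
                    c(150e6, 200e6, 1, 1))
  ps <- sample_segments(p, "s1")
  # split every segment at its midpoint
  split_rows <- do.call(rbind, lapply(seq_len(nrow(ps)), function(i) {
    mid <- floor((ps$start[i] + ps$end[i]) / 2)
    rbind(transform(ps[i, ], end = mid), transform(ps[i, ], start = mid))
  }))
  split_p <- segment_profiles(split_rows)
  for (fn in list(cin_score, function(x, g) hrd_loh_count(x, g),
                  function(x, g) lst_count(x, g), function(x, g) tai_count(x, g))) {
    expect_equal(fn(sample_segments(split_p, "s1"), g), fn(ps, g))
  }
  # input order invariance
  shuf <- segment_profiles(ps[sample(nrow(ps)), ])
  expect_equal(hrd_score(sample_segments(shuf, "s1"), g), hrd_score(ps, g))
})

test_that("HRD-LOH counts large interstitial LOH only", {
  g <- test_genome()
  # 20 Mb LOH inside chr1 -> 1
  expect_equal(hrd_loh_count(make_profile(c(0, 40e6, 1, 1), c(40e6, 60e6, 2, 0),
                                          c(60e6, 200e6, 1, 1)), g), 1)
  # LOH spanning a whole chromosome -> 0
  whole <- segment_profiles(data.frame(sample = "s1", chrom = "chr2", start = 0,
                                       end = 100e6, total_cn = 1L, major_cn = 1L,
                                       minor_cn = 0L))
  expect_equal(hrd_loh_count(whole, g), 0)
  # 12 Mb is below the >15 Mb threshold
  expect_equal(hrd_loh_count(make_profile(c(0, 40e6, 1, 1), c(40e6, 52e6, 2, 0),
                                          c(52e6, 200e6, 1, 1)), g), 0)
  # exactly 15 Mb does not exceed the threshold
  expect_equal(hrd_loh_count(make_profile(c(0, 40e6, 1, 1), c(40e6, 55e6, 2, 0),
                                          c(55e6, 200e6, 1, 1)), g), 0)
  # touching runs of different LOH states merge into one run
  expect_equal(hrd_loh_count(make_profile(c(0, 40e6, 1, 1), c(40e6, 50e6, 2, 0),
                                          c(50e6, 60e6, 1, 0),
                                          c(60e6, 200e6, 1, 1)), g), 1)
})

test_that("LST junction counting applies flank, gap and smoothing rules", {
  g <- test_genome()
  # 20 Mb total-2 adjacent to 30 Mb total-3 on one arm -> 1 junction
  p1 <- make_profile(c(0, 20e6, 1, 1), c(20e6, 50e6, 2, 1), c(50e6, 90e6, 1, 1))
  expect_equal(lst_count(sample_segments(p1, "s1"), g), 2)  # both flanks qualify
  # restrict to exactly the quoted example: two long segments only
  p2 <- make_profile(c(0, 20e6, 1, 1), c(20e6, 50e6, 2, 1))
  expect_equal(lst_count(sample_segments(p2, "s1"), g), 1)
  # interposed 2 Mb segment is smoothed away (gap 2 Mb <= 3 Mb): still 1
  p3 <- make_profile(c(0, 20e6, 1, 1), c(20e6, 22e6, 2, 2), c(22e6, 52e6, 2, 1))
  expect_equal(lst_count(sample_segments(p3, "s1"), g), 1)
  # interposed 5 Mb segment survives smoothing and breaks both flanks -> 0
  p4 <- make_profile(c(0, 20e6, 1, 1), c(20e6, 25e6, 2, 2), c(25e6, 55e6, 2, 1))
  expect_equal(lst_count(sample_segments(p4, "s1"), g), 0)
  # copy-neutral LOH does not create a junction (state is total copy number)
  p5 <- make_profile(c(0, 40e6, 1, 1), c(40e6, 60e6, 2, 0), c(60e6, 90e6, 1, 1))
  expect_equal(lst_count(sample_segments(p5, "s1"), g), 0)
})

test_that("TAI requires telomere contact and respects the centromere", {
  g <- test_genome()  # chr2: 100 Mb, centromere [45, 55] Mb
  tele <- function(...) {
    segment_profiles(do.call(rbind, lapply(list(...), function(r) {
      data.frame(sample = "s1", chrom = "chr2", start = r[1], end = r[2],
                 total_cn = r[3] + r[4], major_cn = r[3], minor_cn = r[4])
    })))
  }
  # telomeric imbalanced segment, not crossing the centromere -> 1
  expect_equal(tai_count(tele(c(0, 30e6, 2, 1), c(30e6, 100e6, 1, 1)), g), 1)
  # crossing the whole centromere -> 0
  expect_equal(tai_count(tele(c(0, 60e6, 2, 1), c(60e6, 100e6, 1, 1)), g), 0)
  # ending exactly at the centromere edge counts as non-crossing
  expect_equal(tai_count(tele(c(0, 55e6, 2, 1), c(55e6, 100e6, 1, 1)), g), 1)
  # balanced telomeric segment -> 0
  expect_equal(tai_count(tele(c(0, 30e6, 2, 2), c(30e6, 100e6, 1, 1)), g), 0)
  # whole-chromosome imbalance -> 0
  expect_equal(tai_count(tele(c(0, 100e6, 2, 1)), g), 0)
  # interstitial imbalance -> 0
  expect_equal(tai_count(tele(c(0, 20e6, 1, 1), c(20e6, 40e6, 2, 1),
                              c(40e6, 100e6, 1, 1)), g), 0)
  # q-arm telomere also counts
  expect_equal(tai_count(tele(c(0, 70e6, 1, 1), c(70e6, 100e6, 2, 1)), g), 1)
})

test_that("hrd is exactly the sum of its components and monotone in LOH", {
  g <- test_genome()
  expect_true(all(hrd_score(sample_segments(diploid_profile(g), "s1"), g)[
    , c("cin", "hrd_loh", "lst", "tai", "hrd")] == 0))
  base <- make_profile(c(0, 20e6, 1, 1), c(20e6, 50e6, 2, 1), c(50e6, 200e6, 1, 1))
  s_base <- hrd_score(sample_segments(base, "s1"), g)
  # add one qualifying LOH segment on the untouched chr2
  plus <- segment_profiles(rbind(
    as.data.frame(base),
    data.frame(sample = "s1", chrom = "chr2", start = c(0, 20e6, 40e6),
               end = c(20e6, 40e6, 100e6), total_cn = c(2L, 2L, 2L),
               major_cn = c(1L, 2L, 1L), minor_cn = c(1L, 0L, 1L))))
  s_plus <- hrd_score(sample_segments(plus, "s1"), g)
  expect_equal(s_plus$hrd_loh, s_base$hrd_loh + 1)
  expect_equal(s_plus$lst, s_base$lst)
  expect_equal(s_plus$tai, s_base$tai)
  expect_equal(s_plus$hrd, s_plus$hrd_loh + s_plus$lst + s_plus$tai)
})

test_that("sex chromosomes are excluded from every instability score", {
  g <- test_genome()
  p <- segment_profiles(data.frame(
    sample = "s1", chrom = c("chr1", "chr2", "chrX", "chrX"),
    start = c(0, 0, 0, 50e6), end = c(200e6, 100e6, 50e6, 150e6),
    total_cn = c(2L, 2L, 5L, 1L), major_cn = c(1L, 1L, 4L, 1L),
    minor_cn = c(1L, 1L, 1L, 0L)))
  sc <- hrd_score(sample_segments(p, "s1"), g)
  expect_equal(sc$cin, 0)
  expect_equal(sc$hrd, 0)
  expect_equal(sc$ploidy, 2)
})

test_that("scores agree exactly with the naive scan oracle on random profiles", {
  g <- bundled_genome()
  for (seed in 1:120) {
    p <- random_profile(g, seed)
    ps <- sample_segments(p, "s1")
    pw <- ploidy_wgd(ps, g)
    o_pw <- orc_ploidy_wgd(ps, g)
    expect_equal(pw$ploidy, o_pw$ploidy, info = paste("seed", seed))
    expect_identical(pw$wgd, o_pw$wgd, info = paste("seed", seed))
    expect_equal(unclass(cin_score(ps, g)), orc_cin(ps, g),
                 info = paste("seed", seed))
    expect_equal(hrd_loh_count(ps, g), orc_hrd_loh(ps, g),
                 info = paste("seed", seed))
    expect_equal(lst_count(ps, g), orc_lst(ps, g), info = paste("seed", seed))
    expect_equal(tai_count(ps, g), orc_tai(ps, g), info = paste("seed", seed))
  }
})
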