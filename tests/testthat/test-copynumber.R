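# Depth fixtures here use the tiny 6-interval panel: chr1 x3, chr2 x2, chrX.

track_for <- function(tumor, normal, spec = norm_spec(), blacklist = NULL,
                      tumor_extra = NULL) {
  db <- tiny_db(blacklist = blacklist)
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  import_depths(db, "S1", tiny_depth_table(tumor, extra_cols = tumor_extra),
                tiny_depth_table(normal))
  compute_ratio_track(db, "S1", spec)
}

test_that("normalization_factor averages depths on selected chromosomes", {
  d <- data.frame(chrom = c("chr1", "chr1", "chr1"), depth = c(10, 20, 30))
  expect_equal(normalization_factor(d, norm_spec()), 20)

  d2 <- data.frame(chrom = c("chr1", "chr1", "chr2"), depth = c(10, 10, 40))
  expect_equal(normalization_factor(d2, norm_spec("user_chromosomes", "chr2")),
               40)
  expect_error(
    normalization_factor(d2, norm_spec("user_chromosomes", "chrX")),
    "no intervals")
  expect_error(normalization_factor(data.frame(chrom = "chr1", depth = 0),
                                    norm_spec()), "zero")
})

test_that("compute_ratio_track applies R = (T/T_nf)/(N/N_nf)", {
  # autosome factors: T over chr1+chr2 = mean(10,10,40,20,20) = 20; N = 10
  tr <- track_for(c(10, 10, 40, 20, 20, 20), rep(10, 6))
  expect_equal(tr$tumor_norm_factor, 20)
  expect_equal(tr$normal_norm_factor, 10)
  expect_equal(tr$entries$ratio, c(0.5, 0.5, 2.0, 1.0, 1.0, 1.0))

  # identity: T = N element-wise
  x <- c(13, 7, 22, 5, 90, 31)
  expect_equal(track_for(x, x)$entries$ratio, rep(1, 6))

  # uniform doubling is normalized away
  expect_equal(track_for(2 * x, x)$entries$ratio, rep(1, 6),
               tolerance = 1e-12)
})

test_that("ratio track handles provider ratios, zero normals and blacklist", {
  tr <- track_for(rep(10, 6), rep(10, 6), spec = norm_spec("provider_ratio"),
                  tumor_extra = list(name = "ratio",
                                     values = c(0.5, 1, 2, 1, 1.5, 1)))
  expect_equal(tr$entries$ratio, c(0.5, 1, 2, 1, 1.5, 1))
  expect_true(is.na(tr$tumor_norm_factor))
  expect_error(track_for(rep(10, 6), rep(10, 6),
                         spec = norm_spec("provider_ratio")),
               "precomputed ratio")

  # zero-depth normal intervals dropped with a report, not infinite ratios
  expect_message(tr0 <- track_for(rep(10, 6), c(10, 0, 10, 10, 10, 10)),
                 "zero normal depth")
  expect_equal(nrow(tr0$entries), 5)
  expect_equal(nrow(tr0$dropped), 1)
  expect_true(all(is.finite(tr0$entries$ratio)))

  # blacklisted intervals excluded from entries AND normalization factors
  bl <- write_lines_tmp("chr1\t100\t200\tBL", ".bed")
  tr_bl <- track_for(c(1000, 10, 10, 10, 10, 10), rep(10, 6), blacklist = bl)
  expect_equal(nrow(tr_bl$entries), 5)
  expect_equal(tr_bl$tumor_norm_factor, 10)  # the 1000 is blacklisted

  expect_error(track_for(rep(10, 6), rep(0, 6)), "zero")
})

test_that("ratio invariances hold over randomized panels", {
  set.seed(11)
  for (rep_i in 1:10) {
    tumor <- round(runif(6, 5, 500), 3)
    normal <- round(runif(6, 5, 500), 3)
    base <- track_for(tumor, normal)

    # scale invariance in either sample
    c1 <- round(runif(1, 0.1, 9), 4)
    expect_equal(track_for(c1 * tumor, normal)$entries$ratio,
                 base$entries$ratio, tolerance = 1e-12)
    expect_equal(track_for(tumor, c1 * normal)$entries$ratio,
                 base$entries$ratio, tolerance = 1e-12)

    # explicit autosome list reproduces the default exactly
    full <- track_for(tumor, normal,
                      spec = norm_spec("user_chromosomes", paste0("chr", 1:22)))
    expect_identical(full$entries$ratio, base$entries$ratio)

    # post-normalization identity over the normalization set
    auto <- base$entries$chrom != "chrX"
    expect_equal(mean(base$entries$tumor_depth[auto] / base$tumor_norm_factor),
                 1, tolerance = 1e-12)
    expect_equal(mean(base$entries$normal_depth[auto] / base$normal_norm_factor),
                 1, tolerance = 1e-12)

    # matches the independent brute-force oracle
    expect_equal(base$entries$ratio,
                 oracle_ratios(base$entries$chrom, base$entries$tumor_depth,
                               base$entries$normal_depth, paste0("chr", 1:22)),
                 tolerance = 1e-12)
  }
})

test_that("auto_cn_calls applies inclusive thresholds", {
  tr <- track_for(c(10, 20, 40, 15, 20, 20), rep(20, 6),
                  spec = norm_spec("user_chromosomes", "chr2"))
  # factors: T_nf = mean(15,20) = 17.5, N_nf = 20 -> R = T/17.5 * 20/20...
  expect_equal(tr$entries$ratio, c(10, 20, 40, 15, 20, 20) / 17.5,
               tolerance = 1e-12)

  calls <- auto_cn_calls(tr, loss_max = 0.75, gain_min = 1.25)
  expect_equal(calls$state,
               ifelse(calls$ratio <= 0.75, "deleted",
                      ifelse(calls$ratio >= 1.25, "gained", "neutral")))

  flat <- track_for(rep(7, 6), rep(7, 6))
  expect_equal(auto_cn_calls(flat, 0.2, 3)$state, rep("neutral", 6))
  # boundary inclusive on the aberrant side
  b <- auto_cn_calls(flat, loss_max = 1.0, gain_min = 1.5)
  expect_equal(b$state, rep("deleted", 6))
  b2 <- auto_cn_calls(flat, loss_max = 0.5, gain_min = 1.0)
  expect_equal(b2$state, rep("gained", 6))

  expect_error(auto_cn_calls(flat, 1.25, 0.75), "loss_max < gain_min")
})

test_that("auto_cn_group_calls summarizes members by median", {
  # chr1 = ALPHA(2) + BETA(1), chr2 = GAMMA(2), chrX = DELTA(1)
  tr <- track_for(c(5, 5.2, 4.8, 10, 10, 10), rep(10, 6),
                  spec = norm_spec("user_chromosomes", "chr2"))
  db <- tiny_db(); on.exit(close_panel_db(db))
  groups <- panel_groups(db)
  g <- auto_cn_group_calls(tr, groups, 0.75, 1.25)
  expect_equal(g$group_name, c("ALPHA", "BETA", "GAMMA", "DELTA"))
  expect_equal(g$summary_ratio[g$group_name == "ALPHA"], median(c(0.5, 0.52)))
  expect_equal(g$state[g$group_name == "ALPHA"], "deleted")
  expect_equal(g$n_intervals, c(2L, 1L, 2L, 1L))
  expect_equal(g$state[g$group_name == "GAMMA"], "neutral")

  # median robust to one outlier each way
  tr2 <- track_for(c(5, 10, 15, 10, 10, 10), rep(10, 6),
                   spec = norm_spec("user_chromosomes", "chr2"))
  g2 <- auto_cn_group_calls(tr2, groups)
  expect_equal(g2$summary_ratio[g2$group_name == "ALPHA"], 0.75)

  # group with no scored members is uncallable
  grp_extra <- rbind(groups, data.frame(group_name = "EMPTY",
                                        target_id = NA, chrom = NA,
                                        start = NA, end = NA, label = NA))
  g3 <- auto_cn_group_calls(tr, grp_extra)
  expect_equal(g3$state[g3$group_name == "EMPTY"], "uncallable")
  expect_equal(g3$n_intervals[g3$group_name == "EMPTY"], 0L)

  # mean alternative
  g4 <- auto_cn_group_calls(tr2, groups, summary = "mean")
  expect_equal(g4$summary_ratio[g4$group_name == "ALPHA"], 0.75)
})

test_that("compute_baf derives VAFs and the heterozygosity flag", {
  rec <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                    normal_ref = c(10, 20, 0), normal_alt = c(10, 0, 0),
                    tumor_ref = c(18, 20, 10), tumor_alt = c(2, 0, 10))
  baf <- compute_baf(rec, het_band = c(0.4, 0.6))
  expect_equal(nrow(baf), 2)  # zero normal depth excluded
  expect_equal(baf$normal_vaf, c(0.5, 0))
  expect_equal(baf$tumor_vaf, c(0.1, 0))
  expect_equal(baf$heterozygous_in_normal, c(TRUE, FALSE))

  expect_error(compute_baf(rec, het_band = c(0.6, 0.4)), "het_band")
})
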