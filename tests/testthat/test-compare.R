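# Plant a degraded copy of a region of `a` inside `b`; returns the modified
# b and the exact planted identity (mutations are substitutions at distinct
# positions, so the bookkeeping is exact).
plant_homology <- function(a, b, a_start, len, b_start, divergence) {
    region <- substr(a, a_start, a_start + len - 1L)
    n_mut <- round(divergence * len)
    chars <- strsplit(region, "")[[1]]
    pos <- sample(len, n_mut)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[p]), 1)
    list(b = splice_at(b, b_start, paste(chars, collapse = "")),
         identity = 100 * (len - n_mut) / len)
}

test_that("self-comparison covers everything at full identity", {
    set.seed(50)
    x <- random_dna(10000, 64)
    segs <- find_shared_segments(x, x)
    summ <- summarize_sharing(segs, 10000, 10000)
    expect_equal(summ$n_segments, 1L)
    expect_equal(summ$coverage_a_percent, 100)
    expect_equal(summ$coverage_b_percent, 100)
    expect_equal(summ$length_weighted_identity, 100)
})

test_that("a planted 12 kb segment at 92% identity is recovered on either strand", {
    set.seed(51)
    a <- random_dna(30000, 64)
    b0 <- random_dna(50000, 64)
    planted <- plant_homology(a, b0, 5001, 12000, 20001, 0.08)
    segs <- find_shared_segments(a, planted$b)
    expect_equal(nrow(segs), 1L)
    expect_lte(abs(segs$length_bp - 12000), 2L * 21L)
    expect_lte(abs(segs$identity_percent - planted$identity), 2)
    expect_equal(segs$strand, "+")
    # reverse-complement the planted region: found on the minus strand
    rc_b <- paste0(substr(planted$b, 1, 20000),
                   revcomp(substr(planted$b, 20001, 32000)),
                   substr(planted$b, 32001, 50000))
    segs_rc <- find_shared_segments(a, rc_b)
    expect_equal(nrow(segs_rc), 1L)
    expect_equal(segs_rc$strand, "-")
    expect_lte(abs(segs_rc$length_bp - 12000), 2L * 21L)
})

test_that("unrelated sequences share nothing above chance", {
    set.seed(52)
    expect_equal(nrow(find_shared_segments(random_dna(20000, 64),
                                           random_dna(20000, 64),
                                           min_segment = 500)), 0L)
    expect_equal(nrow(find_shared_segments("", random_dna(1000, 50))), 0L)
})

test_that("sharing summaries do the arithmetic stated on the tin", {
    one <- data.frame(a_start = 1, a_end = 50, b_start = 11, b_end = 60,
                      strand = "+", length_bp = 50, identity_percent = 90)
    s <- summarize_sharing(one, 100, 200)
    expect_equal(s$coverage_a_percent, 50)
    expect_equal(s$coverage_b_percent, 25)
    expect_equal(s$shared_bp_a, 50)
    expect_equal(s$length_weighted_identity, 90)
    empty <- summarize_sharing(one[0, ], 100, 200)
    expect_equal(empty$n_segments, 0L)
    expect_equal(empty$coverage_a_percent, 0)
    # overlapping B intervals are merged before B coverage
    two <- rbind(one, data.frame(a_start = 60, a_end = 109, b_start = 31,
                                 b_end = 80, strand = "+", length_bp = 50,
                                 identity_percent = 100))
    s2 <- summarize_sharing(two, 200, 200)
    expect_equal(s2$coverage_b_percent, 100 * 70 / 200)
    expect_equal(s2$length_weighted_identity, 95)
})

test_that("shared totals are symmetric within anchor resolution", {
    set.seed(53)
    a <- random_dna(20000, 64)
    b0 <- random_dna(30000, 64)
    planted <- plant_homology(a, b0, 2001, 8000, 10001, 0.06)
    s_ab <- summarize_sharing(find_shared_segments(a, planted$b),
                              20000, 30000)
    s_ba <- summarize_sharing(find_shared_segments(planted$b, a),
                              30000, 20000)
    expect_lte(abs(s_ab$shared_bp_a - s_ba$shared_bp_a), 2L * 21L)
})

test_that("lowering the identity threshold never loses coverage", {
    set.seed(54)
    a <- random_dna(15000, 64)
    b0 <- random_dna(20000, 64)
    planted <- plant_homology(a, b0, 3001, 6000, 8001, 0.08)
    cov <- vapply(c(95, 85, 70), function(th)
        summarize_sharing(find_shared_segments(a, planted$b,
                                               min_identity = th),
                          15000, 20000)$coverage_a_percent, numeric(1))
    expect_true(all(diff(cov) >= 0))
})
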