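test_that("a constructed palindrome is found as one full-length inverted pair", {
    set.seed(42)
    x <- random_dna(60, 50)
    s <- paste0(x, revcomp(x))
    got <- find_repeats(s, "inverted", min_len = 20, min_identity = 100)
    expect_equal(nrow(got), 1L)
    expect_equal(got$arm1_start, 1L)
    expect_equal(got$arm1_end, 60L)
    expect_equal(got$arm2_start, 61L)
    expect_equal(got$arm2_end, 120L)
    expect_equal(got$length_bp, 60L)
    expect_equal(got$identity_percent, 100)
})

test_that("finder matches the brute-force oracle on random sequences", {
    set.seed(7)
    for (i in 1:3) {
        s <- random_dna(1200, 55)
        for (orient in c("direct", "inverted")) {
            expect_same_pairs(
                find_repeats(s, orient, min_len = 20, min_identity = 100),
                oracle_find_repeats(s, orient, 20, 100))
        }
    }
    for (i in 1:3) {
        s <- random_dna(300, 45)
        for (orient in c("direct", "inverted")) {
            expect_same_pairs(
                find_repeats(s, orient, min_len = 20, min_identity = 90),
                oracle_find_repeats(s, orient, 20, 90))
        }
    }
})

test_that("finder matches the oracle on repeat-rich constructions", {
    set.seed(13)
    core <- random_dna(80, 60)
    s <- paste0(random_dna(150, 60), core, random_dna(120, 60),
                core, random_dna(60, 60), revcomp(core), random_dna(90, 60))
    for (orient in c("direct", "inverted")) {
        for (p in c(100, 90)) {
            expect_same_pairs(find_repeats(s, orient, min_len = 20,
                                           min_identity = p),
                              oracle_find_repeats(s, orient, 20, p))
        }
    }
})

test_that("planted terminal inverted repeats are recovered exactly", {
    lp <- generate_linear_plasmid(length = 21616L, tir_len = 489L,
                                  tir_identity = 100, seed = 7L)
    tir <- find_terminal_inverted_repeats(lp$replicon, min_identity = 100)
    expect_equal(tir$length_bp, 489L)
    expect_equal(tir$identity_percent, 100)
    expect_equal(tir$arm1_start, 1L)
    expect_equal(tir$arm1_end, 489L)
    expect_equal(tir$arm2_start, 21616L - 488L)
    expect_equal(tir$arm2_end, 21616L)
})

test_that("a degraded TIR is recovered with identity in [99, 100)", {
    lp <- generate_linear_plasmid(length = 6000L, tir_len = 101L,
                                  tir_identity = 99, seed = 3L)
    tir <- find_terminal_inverted_repeats(lp$replicon, min_identity = 99)
    expect_equal(tir$length_bp, 101L)
    expect_gte(tir$identity_percent, 99)
    expect_lt(tir$identity_percent, 100)
})

test_that("duplicated (direct) termini do not masquerade as a TIR", {
    cp <- generate_circular_plasmid(length = 8000L, end_overlap = 120L,
                                    n_spanning_pairs = 0L, seed = 9L)
    expect_null(find_terminal_inverted_repeats(cp$replicon))
})

test_that("inverted pairs of the reverse complement are the mirrored pairs", {
    lp <- generate_linear_plasmid(length = 5000L, tir_len = 150L, seed = 15L)
    s <- lp$replicon$sequence
    n <- nchar(s)
    a <- find_repeats(s, "inverted", min_len = 50, min_identity = 100)
    b <- find_repeats(revcomp(s), "inverted", min_len = 50,
                      min_identity = 100)
    mirrored <- data.frame(arm1_start = n - b$arm2_end + 1L,
                           arm1_end = n - b$arm2_start + 1L,
                           arm2_start = n - b$arm1_end + 1L,
                           arm2_end = n - b$arm1_start + 1L)
    o1 <- order(a$arm1_start)
    o2 <- order(mirrored$arm1_start)
    expect_equal(a[o1, names(mirrored)], mirrored[o2, ],
                 ignore_attr = TRUE)
})

test_that("arms never overlap, swapped duplicates never appear, and short input is empty", {
    set.seed(21)
    for (i in 1:4) {
        s <- paste0(random_dna(400, 50), substr(random_dna(400, 50), 1, 120))
        for (orient in c("direct", "inverted")) {
            df <- find_repeats(s, orient, min_len = 20, min_identity = 90)
            if (nrow(df) == 0) next
            expect_true(all(df$arm2_start > df$arm1_end))
            key <- paste(df$arm1_start, df$arm1_end, df$arm2_start,
                         df$arm2_end)
            expect_equal(anyDuplicated(key), 0L)
            expect_true(all(df$identity_percent >= 90))
        }
    }
    expect_equal(nrow(find_repeats(random_dna(150, 50), "direct",
                                   min_len = 100)), 0L)
})

test_that("N never matches, even against itself", {
    x <- strrep("N", 40)
    s <- paste0(x, random_dna(30, 50), x)
    expect_equal(nrow(find_repeats(s, "direct", min_len = 20,
                                   min_identity = 100)), 0L)
})
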