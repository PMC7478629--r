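test_that("generation is deterministic under a fixed seed", {
    a <- generate_linear_plasmid(length = 5000L, tir_len = 120L, seed = 77L)
    b <- generate_linear_plasmid(length = 5000L, tir_len = 120L, seed = 77L)
    expect_identical(a$replicon$sequence, b$replicon$sequence)
    expect_identical(a$truth, b$truth)
    c1 <- generate_circular_plasmid(length = 6000L, end_overlap = 77L,
                                    n_spanning_pairs = 20L,
                                    noise_rate = 0.1, seed = 5L)
    c2 <- generate_circular_plasmid(length = 6000L, end_overlap = 77L,
                                    n_spanning_pairs = 20L,
                                    noise_rate = 0.1, seed = 5L)
    expect_identical(c1$replicon$sequence, c2$replicon$sequence)
    expect_identical(c1$links, c2$links)
    expect_false(identical(
        c1$replicon$sequence,
        generate_circular_plasmid(length = 6000L, end_overlap = 77L,
                                  n_spanning_pairs = 20L, noise_rate = 0.1,
                                  seed = 6L)$replicon$sequence))
})

test_that("backgrounds meet their GC target and are repeat-free at scoring length", {
    lp <- generate_linear_plasmid(length = 20000L, tir_len = 200L,
                                  gc = 64, seed = 19L)
    expect_lte(abs(gc_content(lp$replicon$sequence) - 64), 1.1)
    # outside the planted TIR there is no >= 50 bp perfect repeat
    inner <- substr(lp$replicon$sequence, 201, 19800)
    expect_equal(nrow(find_repeats(inner, "direct", min_len = 50)), 0L)
    expect_equal(nrow(find_repeats(inner, "inverted", min_len = 50)), 0L)
})

test_that("truth records score the finder's output without re-derivation", {
    lp <- generate_linear_plasmid(length = 9000L, tir_len = 250L, seed = 23L)
    tir <- find_terminal_inverted_repeats(lp$replicon, min_identity = 100)
    expect_equal(c(tir$arm1_start, tir$arm1_end), lp$truth$tir$arm1)
    expect_equal(c(tir$arm2_start, tir$arm2_end), lp$truth$tir$arm2)
    ice <- generate_ice(length = 130000L, seed = 27L)
    drs <- find_repeats(ice$replicon$sequence, "direct", min_len = 100,
                        min_identity = 100)
    for (dr in ice$truth$dr) {
        hit <- drs[drs$arm1_start == dr$arm1[1], ]
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$length_bp, dr$length_bp)
        expect_equal(c(hit$arm2_start, hit$arm2_end), dr$arm2)
        expect_equal(hit$identity_percent, 100)
    }
})

test_that("planted link counts partition into clean and noisy", {
    cp <- generate_circular_plasmid(length = 8000L, end_overlap = 77L,
                                    n_spanning_pairs = 100L,
                                    noise_rate = 0.05, seed = 31L)
    expect_equal(cp$truth$n_spanning_planted + cp$truth$n_noise, 100L)
    expect_equal(nrow(cp$links), 100L)
    expect_gte(count_spanning_pairs(cp$replicon, cp$links),
               cp$truth$n_spanning_planted)
})

test_that("infeasible requests fail loudly", {
    expect_error(generate_linear_plasmid(length = 200L, tir_len = 150L),
                 "infeasible")
    expect_error(generate_ice(length = 20000L, cargo_span = 19000L,
                              dr_len = 600L), "infeasible|too small")
    expect_error(generate_ice(length = 50000L, cargo_span = 40000L,
                              seed = 2L), "too small")
})

test_that("contradictory backbone requests are generated as asked", {
    sim <- generate_ice(length = 100000L, cargo_span = 30000L,
                        dr2_len = 0L,
                        esx_signatures = list(),
                        backbone = "repA", seed = 41L)
    prof <- profile_for(sim)
    expect_true(prof$flags[["repA"]])
    expect_equal(prof$classification, "cryptic_plasmid")
})

test_that("fixtures serialize completely", {
    dir <- withr::local_tempdir()
    cp <- generate_circular_plasmid(length = 6000L, end_overlap = 60L,
                                    n_spanning_pairs = 12L, seed = 3L)
    paths <- write_fixture(cp, dir)
    expect_true(all(file.exists(paths)))
    truth <- yaml::read_yaml(paths[["truth"]])
    expect_equal(truth$end_overlap, 60L)
    links <- read_read_links(paths[["links"]])
    expect_equal(nrow(links), 12L)
})
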