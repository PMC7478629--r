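test_that("the four element-table-shaped fixtures get the expected flags and classes", {
    for (nm in names(TABLE1_EXPECTED_FLAGS)) {
        sim <- table1_fixture(nm)
        prof <- profile_for(sim)
        on <- sort(names(prof$flags)[prof$flags])
        expect_identical(on, sort(TABLE1_EXPECTED_FLAGS[[nm]]),
                         label = paste(nm, "flags"))
        expect_equal(prof$classification, TABLE1_EXPECTED_CLASS[[nm]],
                     label = paste(nm, "class"))
        expect_equal(prof$topology, TABLE1_EXPECTED_TOPOLOGY[[nm]],
                     label = paste(nm, "topology"))
    }
})

test_that("an empty element is all-negative and unclassified", {
    prof <- build_profile(AnnotatedReplicon("e", strrep("ACGT", 100)))
    expect_false(any(prof$flags))
    expect_equal(prof$classification, "unclassified")
})

test_that("classification is a pure function of the flag vector", {
    expect_equal(classify_element(flags_profile(
        c("relaxase", "virB4", "transposase"))), "putative_ICE")
    expect_equal(classify_element(flags_profile(
        c("relaxase", "virD4", "integrase"))), "putative_ICE")
    # repA vetoes the ICE call, replication + conjugation wins
    expect_equal(classify_element(flags_profile(
        c("repA", "relaxase", "virD4", "integrase"))),
        "conjugative_plasmid")
    expect_equal(classify_element(flags_profile(
        c("helicase", "relaxase", "virB4"))), "conjugative_plasmid")
    expect_equal(classify_element(flags_profile("repA")), "cryptic_plasmid")
    expect_equal(classify_element(flags_profile(c("helicase", "virB4"))),
                 "cryptic_plasmid")
    expect_equal(classify_element(flags_profile("relaxase")), "unclassified")
    expect_equal(classify_element(flags_profile()), "unclassified")
})

test_that("feature order never changes a profile", {
    sim <- table1_fixture("pCBMA213_2")
    rep <- sim$replicon
    set.seed(3)
    shuffled <- AnnotatedReplicon(rep$id, rep$sequence,
                                  rep$features[sample(nrow(rep$features)), ])
    p1 <- profile_for(sim)
    p2 <- build_profile(shuffled, call_topology(shuffled),
                        call_esx_loci(shuffled))
    expect_identical(p1$flags, p2$flags)
    expect_identical(p1$classification, p2$classification)
})

test_that("toxin-antitoxin needs adjacency, not mere co-occurrence", {
    seqs <- strrep("ACGT", 3000)
    near <- rbind(feature_row(100, 400, product = "toxin", tags = "TA_toxin"),
                  feature_row(500, 800, product = "antitoxin",
                              tags = "TA_antitoxin"))
    far <- rbind(feature_row(100, 400, tags = "TA_toxin"),
                 feature_row(1000, 1300),
                 feature_row(2000, 2300),
                 feature_row(3000, 3300),
                 feature_row(9000, 9300, tags = "TA_antitoxin"))
    expect_true(build_profile(
        AnnotatedReplicon("a", seqs, near))$flags[["toxin_antitoxin"]])
    expect_false(build_profile(
        AnnotatedReplicon("b", seqs, far))$flags[["toxin_antitoxin"]])
    # one intervening gene is still adjacent
    mid <- rbind(near[1, ], feature_row(420, 470), near[2, ])
    expect_true(build_profile(
        AnnotatedReplicon("c", seqs, mid))$flags[["toxin_antitoxin"]])
})

test_that("integrated regions are delimited by DR pairs with cargo and adjacent IS", {
    sim <- table1_fixture("ICEMyc226")
    rep <- sim$replicon
    drs <- find_repeats(rep$sequence, "direct", min_len = 100,
                        min_identity = 100)
    loci <- call_esx_loci(rep)
    calls <- delimit_integrated_regions(rep, drs, loci = loci)
    truth_dr1 <- sim$truth$dr[[1]]
    hit <- calls[calls$dr_length_bp == 167L, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$region_start, truth_dr1$arm1[2] + 1L)
    expect_equal(hit$region_end, truth_dr1$arm2[1] - 1L)
    expect_false(is.na(hit$adjacent_transposase))
    expect_gte(hit$n_cds, 1L)
    expect_equal(hit$n_esx_loci, 1L)
    # regions never extend into their arms
    expect_true(all(calls$region_start > calls$arm1_end))
    expect_true(all(calls$region_end < calls$arm2_start))
    # sorted longest (outermost) first
    expect_true(!is.unsorted(rev(calls$region_len)))
})

test_that("a DR pair without cargo produces no call; nested pairs report outer first", {
    # constructed 5 kb example, repeats planted by hand
    set.seed(40)
    s <- random_dna(5000, 55)
    outer_arm <- random_dna(120, 55)
    inner_arm <- random_dna(100, 55)
    s <- splice_at(s, 500, outer_arm)
    s <- splice_at(s, 4500, outer_arm)
    s <- splice_at(s, 1000, inner_arm)
    s <- splice_at(s, 3000, inner_arm)
    drs <- data.frame(
        arm1_start = c(500L, 1000L), arm1_end = c(619L, 1099L),
        arm2_start = c(4500L, 3000L), arm2_end = c(4619L, 3099L),
        orientation = "direct", length_bp = c(120L, 100L),
        identity_percent = 100)
    cds <- feature_row(1500, 2400, product = "cargo protein")
    rep <- AnnotatedReplicon("nested", s, cds)
    calls <- delimit_integrated_regions(rep, drs)
    expect_equal(nrow(calls), 2L)
    # outer region (620..4499) comes before inner (1100..2999)
    expect_equal(calls$region_start, c(620L, 1100L))
    expect_equal(calls$region_end, c(4499L, 2999L))
    # no CDS between the arms -> no call
    empty_rep <- AnnotatedReplicon("empty", s)
    expect_equal(nrow(delimit_integrated_regions(empty_rep, drs)), 0L)
})
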