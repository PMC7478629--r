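esx_features <- function(tags, starts, gene_len = 900L) {
    do.call(rbind, mapply(function(tag, st)
        feature_row(st, st + gene_len - 1L, "+", "CDS",
                    product = paste("ESX component", tag), tags = tag),
        tags, starts, SIMPLIFY = FALSE))
}

test_that("four core genes within clustering range form exactly one locus", {
    f <- esx_features(c("EccC", "EccB", "EccD", "MycP"),
                      c(1000, 3000, 5000, 7000))
    rep <- AnnotatedReplicon("r", random_dna(20000, 60), f)
    loci <- call_esx_loci(rep)
    expect_length(loci, 1L)
    expect_equal(loci[[1]]$n_core, 4L)
    expect_equal(loci[[1]]$signature, "eccC/eccB/eccD/mycP")
})

test_that("three core genes never form a locus", {
    f <- esx_features(c("EccB", "EccC", "EccD"), c(1000, 3000, 5000))
    rep <- AnnotatedReplicon("r", random_dna(10000, 60), f)
    expect_length(call_esx_loci(rep), 0L)
})

test_that("distant clusters stay separate and never share members", {
    sim <- generate_ice(length = 130000L, dr_len = 167L,
                        cargo_span = 40000L, dr2_len = 0L, seed = 31L)
    loci <- call_esx_loci(sim$replicon)
    expect_length(loci, 2L)
    expect_lt(loci[[1]]$span_end, loci[[2]]$span_start)
    members <- unlist(lapply(loci, function(l) l$members$feature))
    expect_equal(anyDuplicated(members), 0L)
    expect_true(all(vapply(loci, function(l) l$n_core, integer(1)) >= 4L))
})

test_that("planted signatures are reproduced verbatim, with the distal eccA marked", {
    sim <- generate_ice(length = 130000L, dr_len = 167L,
                        cargo_span = 40000L, dr2_len = 648L, seed = 11L)
    loci <- call_esx_loci(sim$replicon)
    sigs <- sort(vapply(loci, function(l) l$signature, character(1)))
    expect_identical(sigs,
                     sort(c("eccE/eccB/eccD/eccC/eccD/mycP/-//-/eccA",
                            "eccC/eccB/eccD/mycP/eccE/-//-/eccA")))
})

test_that("signature typing assigns the mobile-element types and rejects degenerates", {
    expect_equal(classify_esx_type("eccE/eccB/eccD/eccC/eccD/mycP/-//-/eccA"),
                 "ESX-4-bis")
    expect_equal(classify_esx_type("eccC/eccB/eccD/mycP/eccE/-//-/eccA"),
                 "ESX-2-like")
    expect_equal(classify_esx_type("eccA"), "untyped")
    expect_equal(classify_esx_type("eccA/eccB/eccC/eccD/mycP/eccE"),
                 "ESX-3-like")
    expect_equal(classify_esx_type("eccB/eccC/eccD/mycP"), "ESX-4")
    # reversed gene order types identically (genomic orientation is arbitrary)
    expect_equal(classify_esx_type("eccA/-//-/eccE/mycP/eccD/eccC/eccD/eccB/eccE"),
                 "ESX-4-bis")
})

test_that("calling is strand-symmetric and typing orientation-invariant", {
    sim <- generate_ice(length = 130000L, dr_len = 167L,
                        cargo_span = 40000L, dr2_len = 0L, seed = 12L)
    loci_f <- call_esx_loci(sim$replicon)
    loci_r <- call_esx_loci(reverse_replicon(sim$replicon))
    expect_length(loci_r, length(loci_f))
    n <- nchar(sim$replicon$sequence)
    spans_f <- t(vapply(loci_f, function(l) c(l$span_start, l$span_end),
                        numeric(2)))
    spans_r <- t(vapply(rev(loci_r), function(l)
        c(n - l$span_end + 1L, n - l$span_start + 1L), numeric(2)))
    expect_equal(spans_f, spans_r)
    types_f <- sort(vapply(loci_f, function(l) l$assigned_type, character(1)))
    types_r <- sort(vapply(loci_r, function(l) l$assigned_type, character(1)))
    expect_identical(types_f, types_r)
    # gene order reads back-to-front on the reversed replicon
    tokens <- function(l) {
        x <- strsplit(l$signature, "/")[[1]]
        x[!x %in% c("-", "")]
    }
    expect_identical(lapply(loci_f, tokens),
                     lapply(rev(loci_r), function(l) rev(tokens(l))))
})

test_that("a three-gene decoy cluster is rejected while true loci are kept", {
    sim <- generate_ice(length = 130000L, dr_len = 167L,
                        cargo_span = 40000L, dr2_len = 0L, seed = 33L)
    rep <- sim$replicon
    decoy <- esx_features(c("EccB", "EccC", "EccD"),
                          c(120000, 122000, 124000))
    rep2 <- AnnotatedReplicon(rep$id, rep$sequence,
                              rbind(rep$features, decoy))
    loci <- call_esx_loci(rep2)
    expect_length(loci, 2L)
    expect_true(all(vapply(loci, function(l) l$span_end, numeric(1)) <
                    120000))
})

test_that("product strings map onto controlled tags", {
    f <- rbind(feature_row(1, 900, product = "MOB-family relaxase"),
               feature_row(1000, 1900, product = "IS110 family transposase"),
               feature_row(2000, 2900, product = "DDE-type integrase/transposase/recombinase"),
               feature_row(3000, 3900, product = "type II toxin-antitoxin system antitoxin"),
               feature_row(4000, 4900, product = "VapC family toxin"),
               feature_row(5000, 5900, product = "mycosin protease MycP"),
               feature_row(6000, 6900, product = "replicative DNA helicase (DnaB-like)"))
    tagged <- assign_domain_tags(f)
    tl <- strsplit(tagged$domain_tags, ";")
    expect_true("relaxase" %in% tl[[1]])
    expect_true("transposase" %in% tl[[2]])
    # DDE products count as transposase, not integrase
    expect_true("transposase" %in% tl[[3]])
    expect_false("integrase" %in% tl[[3]])
    expect_true("TA_antitoxin" %in% tl[[4]])
    expect_true("TA_toxin" %in% tl[[5]])
    expect_true("MycP" %in% tl[[6]])
    expect_true("DnaB_helicase" %in% tl[[7]])
})
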