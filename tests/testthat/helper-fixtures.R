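# Shared fixture builders. The four element-table-shaped fixtures are
# expensive enough to build once and cache for the whole test run.

ESX_SIG_4BIS <- c("eccE", "eccB", "eccD", "eccC", "eccD", "mycP", "-//-", "eccA")
ESX_SIG_2LIKE <- c("eccC", "eccB", "eccD", "mycP", "eccE", "-//-", "eccA")
ESX_SIG_3LIKE <- c("eccA", "eccB", "eccC", "eccD", "mycP", "eccE")

TABLE1_EXPECTED_FLAGS <- list(
    pCBMA213_1 = c("virB4", "helicase", "dna_polymerase", "integrase",
                   "transposase", "trna_genes", "t7ss", "toxin_antitoxin"),
    pCBMA213_2 = c("repA", "relaxase", "virD4", "virB4", "tcpC",
                   "transposase", "t7ss", "toxin_antitoxin"),
    pCBMA213_3 = c("repA"),
    ICEMyc226 = c("relaxase", "virD4", "virB4", "tcpC", "helicase",
                  "transposase", "t7ss", "toxin_antitoxin"))

TABLE1_EXPECTED_CLASS <- c(pCBMA213_1 = "cryptic_plasmid",
                           pCBMA213_2 = "conjugative_plasmid",
                           pCBMA213_3 = "cryptic_plasmid",
                           ICEMyc226 = "putative_ICE")

TABLE1_EXPECTED_TOPOLOGY <- c(pCBMA213_1 = "linear", pCBMA213_2 = "circular",
                              pCBMA213_3 = "linear", ICEMyc226 = "circular")

.fixture_cache <- new.env(parent = emptyenv())

table1_fixture <- function(which) {
    key <- paste0("t1_", which)
    if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
    sim <- switch(which,
        pCBMA213_1 = generate_ice(
            length = 70000L, dr_len = 0L, dr2_len = 0L, tir_len = 145L,
            end_overlap = 0L, esx_signatures = list(ESX_SIG_3LIKE),
            backbone = c("virB4", "helicase", "dna_polymerase", "integrase",
                         "transposase", "trna_genes", "toxin_antitoxin"),
            seed = 101L),
        pCBMA213_2 = generate_ice(
            length = 60000L, dr_len = 0L, dr2_len = 0L, tir_len = 0L,
            end_overlap = 77L, esx_signatures = list(ESX_SIG_2LIKE),
            backbone = c("repA", "relaxase", "virD4", "virB4", "tcpC",
                         "transposase", "toxin_antitoxin"),
            seed = 102L),
        pCBMA213_3 = generate_ice(
            length = 21616L, dr_len = 0L, dr2_len = 0L, tir_len = 489L,
            end_overlap = 0L, esx_signatures = list(),
            backbone = "repA", seed = 103L),
        ICEMyc226 = generate_ice(
            length = 130000L, dr_len = 167L, cargo_span = 40000L,
            dr2_len = 648L, end_overlap = 100L,
            esx_signatures = list(ESX_SIG_4BIS, ESX_SIG_2LIKE),
            backbone = c("relaxase", "virD4", "virB4", "tcpC", "helicase",
                         "transposase", "toxin_antitoxin"),
            seed = 104L),
        stop("unknown fixture"))
    .fixture_cache[[key]] <- sim
    sim
}

profile_for <- function(sim, links = NULL) {
    topo <- call_topology(sim$replicon, links)
    loci <- call_esx_loci(sim$replicon)
    build_profile(sim$replicon, topo, loci)
}

# A bare profile from a flag vector, for classification-rule tests that
# need no sequence at all.
flags_profile <- function(on = character()) {
    flags <- setNames(rep(FALSE, 12L),
                      c("repA", "relaxase", "virD4", "virB4", "tcpC",
                        "helicase", "dna_polymerase", "integrase",
                        "transposase", "trna_genes", "t7ss",
                        "toxin_antitoxin"))
    flags[on] <- TRUE
    flags
}

splice_at <- function(s, start, piece) {
    paste0(substr(s, 1, start - 1), piece,
           substr(s, start + nchar(piece), nchar(s)))
}

write_mini_fasta <- function(seqs, path) {
    lines <- unlist(lapply(names(seqs), function(id)
        c(paste0(">", id), seqs[[id]])))
    writeLines(lines, path)
    path
}
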