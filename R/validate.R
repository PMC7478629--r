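## Validation against the four deposited reference elements of the CBMA
## mobilome. The records are not redistributed with the package; the user
## downloads them once (GenBank nucleotide FASTA, and optionally a feature
## table) into a directory and points this function at it.

REFERENCE_ELEMENTS <- data.frame(
    element = c("pCBMA213_1", "pCBMA213_2", "pCBMA213_3", "ICEMyc226"),
    accession = c("MF600313.1", "KY349138.1", "MN587875", "MN587876"),
    length_bp = c(274124L, 160489L, 21616L, 388440L),
    gc_percent = c(62L, 65L, 64L, 64L),
    stringsAsFactors = FALSE)

#' Validate the pipeline against the deposited reference elements
#'
#' Recomputes the published characteristics of the four deposited CBMA
#' mobilome records from local copies and compares them to the deposited
#' values: sequence lengths and rounded GC for all four; CDS count (364) for
#' ICEMyc226 and tRNA count (32) for pCBMA213_1 when feature tables are
#' present; terminal inverted repeat lengths 145 (pCBMA213_1) and 489
#' (pCBMA213_3); direct repeats of 167 and 648 bp within ICEMyc226; and the
#' pCBMA213_2 vs ICEMyc226 sharing summary (about 70% coverage at about 90%
#' identity, checked to within 5 points since the deposited characterization
#' reports them approximately).
#'
#' Expected files in `dir`: `<accession>.fasta` per record, and optionally
#' `<accession>_features.tsv` (TSV dialect) or `<accession>.gff3`.
#'
#' @param dir Directory holding the downloaded records.
#' @param params Parameters from [mge_params()].
#' @return Data frame of checks: `check`, `expected`, `observed`, `pass`.
#'   Missing inputs are a fatal error, not a silent skip.
#' @export
validate_reference_elements <- function(dir, params = mge_params()) {
    refs <- REFERENCE_ELEMENTS
    fasta <- file.path(dir, paste0(refs$accession, ".fasta"))
    missing <- !file.exists(fasta)
    if (any(missing))
        stop("missing reference record(s) in ", dir, ": ",
             paste(refs$accession[missing], collapse = ", "),
             "\nDownload the GenBank nucleotide FASTA for each accession ",
             "into that directory as <accession>.fasta", call. = FALSE)
    seqs <- lapply(fasta, function(f) read_replicon_fasta(f)[[1]])
    names(seqs) <- refs$element
    checks <- list()
    add <- function(check, expected, observed, tol = 0) {
        checks[[length(checks) + 1L]] <<- data.frame(
            check = check, expected = expected, observed = observed,
            pass = abs(observed - expected) <= tol, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(refs))) {
        el <- refs$element[i]
        add(paste0(el, "_length_bp"), refs$length_bp[i], nchar(seqs[[el]]))
        add(paste0(el, "_gc_percent"), refs$gc_percent[i],
            round_half_up(gc_content(seqs[[el]])))
    }
    ## feature counts when annotation is available
    for (i in seq_len(nrow(refs))) {
        feat <- file.path(dir, paste0(refs$accession[i], "_features.tsv"))
        gff <- file.path(dir, paste0(refs$accession[i], ".gff3"))
        path <- if (file.exists(feat)) feat else if (file.exists(gff)) gff
                else next
        rep <- load_annotated_replicon(fasta[i], path)[[1]]
        if (refs$element[i] == "ICEMyc226")
            add("ICEMyc226_n_cds", 364L, count_features(rep, "CDS"))
        if (refs$element[i] == "pCBMA213_1")
            add("pCBMA213_1_n_trna", 32L, count_features(rep, "tRNA"))
    }
    ## terminal inverted repeats
    tir1 <- find_terminal_inverted_repeats(
        seqs[["pCBMA213_1"]], max_offset = params$tir$max_offset,
        min_len = params$tir$min_len, min_identity = 100)
    add("pCBMA213_1_tir_bp", 145L, if (is.null(tir1)) 0L else tir1$length_bp)
    tir3 <- find_terminal_inverted_repeats(
        seqs[["pCBMA213_3"]], max_offset = params$tir$max_offset,
        min_len = params$tir$min_len, min_identity = 100)
    add("pCBMA213_3_tir_bp", 489L, if (is.null(tir3)) 0L else tir3$length_bp)
    ## direct repeats within the ICE
    drs <- find_repeats(seqs[["ICEMyc226"]], "direct",
                        min_len = params$classify$dr_min_len,
                        min_identity = params$classify$dr_min_identity)
    add("ICEMyc226_dr1_bp", 167L,
        if (any(drs$length_bp == 167L)) 167L else 0L)
    add("ICEMyc226_dr2_bp", 648L,
        if (any(drs$length_bp == 648L)) 648L else 0L)
    ## sharing between the circular plasmid and the ICE
    segs <- find_shared_segments(seqs[["pCBMA213_2"]], seqs[["ICEMyc226"]],
                                 k = params$compare$k,
                                 min_segment = params$compare$min_segment,
                                 min_identity = params$compare$min_identity,
                                 max_gap = params$compare$max_gap)
    summ <- summarize_sharing(segs, nchar(seqs[["pCBMA213_2"]]),
                              nchar(seqs[["ICEMyc226"]]))
    add("pCBMA213_2_vs_ICEMyc226_coverage_a", 70, summ$coverage_a_percent,
        tol = 5)
    add("pCBMA213_2_vs_ICEMyc226_identity", 90,
        summ$length_weighted_identity, tol = 5)
    do.call(rbind, checks)
}
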