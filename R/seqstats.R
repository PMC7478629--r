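#' GC content of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`. `N` (assembly gaps, ambiguity) is
#' excluded from both numerator and denominator. Full precision is returned;
#' report output rounds half-up to the integer percent (the convention of
#' published element tables).
#'
#' @param sequence Nucleotide string, or an [AnnotatedReplicon()].
#' @return GC percentage in `[0, 100]`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(sequence) {
    s <- as_sequence(sequence)
    counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
    acgt <- counts[c("A", "C", "G", "T")]
    denom <- sum(acgt)
    if (denom == 0L)
        stop("GC content undefined: sequence has no A/C/G/T bases",
             call. = FALSE)
    unname(100 * (acgt[["G"]] + acgt[["C"]]) / denom)
}

#' Count features of a given type
#'
#' @param replicon An [AnnotatedReplicon()].
#' @param ftype One of `"CDS"`, `"tRNA"`, `"other"`.
#' @return Integer count; an unknown type counts 0 with a warning.
#' @export
count_features <- function(replicon, ftype = "CDS") {
    stopifnot(inherits(replicon, "AnnotatedReplicon"))
    if (!ftype %in% c("CDS", "tRNA", "other")) {
        warning("unknown feature type '", ftype, "'; returning 0",
                call. = FALSE)
        return(0L)
    }
    sum(replicon$features$ftype == ftype)
}

#' Per-replicon summary statistics
#'
#' @param replicon An [AnnotatedReplicon()].
#' @return One-row data frame: `replicon_id`, `length_bp`, `gc_percent`
#'   (full precision), `n_cds`, `n_trna`.
#' @export
replicon_stats <- function(replicon) {
    data.frame(replicon_id = replicon$id,
               length_bp = nchar(replicon$sequence),
               gc_percent = gc_content(replicon),
               n_cds = count_features(replicon, "CDS"),
               n_trna = count_features(replicon, "tRNA"),
               stringsAsFactors = FALSE)
}
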