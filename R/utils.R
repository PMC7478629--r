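`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' `N` is its own complement.
#'
#' @param x A single nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Uppercase and coerce a raw sequence string to the {A,C,G,T,N} alphabet.
## Ambiguity codes and gaps become N (draft assemblies contain both); the
## caller decides whether to warn.
clean_sequence <- function(x, warn = TRUE, what = "sequence") {
    x <- toupper(x)
    bad <- gsub("[ACGTN]", "", x)
    if (nzchar(bad)) {
        if (warn) {
            warning(sprintf("%s: %d non-ACGTN character(s) replaced with N",
                            what, nchar(bad)), call. = FALSE)
        }
        x <- gsub("[^ACGTN]", "N", x)
    }
    x
}

## Overwrite s[start .. start+nchar(piece)-1] with piece (1-based).
splice_in <- function(s, start, piece) {
    n <- nchar(s)
    end <- start + nchar(piece) - 1L
    stopifnot(start >= 1L, end <= n)
    paste0(substr(s, 1L, start - 1L), piece, substr(s, end + 1L, n))
}

## Half-up rounding to integer, the convention used for report percentages.
round_half_up <- function(x) floor(x + 0.5)

## Distance in bp between two closed intervals; 0 if they touch or overlap.
interval_gap <- function(s1, e1, s2, e2) {
    if (e1 < s2) s2 - e1 - 1L else if (e2 < s1) s1 - e2 - 1L else 0L
}

as_sequence <- function(x) {
    if (inherits(x, "AnnotatedReplicon")) x$sequence
    else if (is.character(x) && length(x) == 1L) x
    else stop("expected an AnnotatedReplicon or a single sequence string")
}
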