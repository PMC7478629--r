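## Maximal repeat-pair finder: the engine behind terminal-inverted-repeat
## detection, circularity overlaps and direct-repeat element boundaries.

## Shortest exact run a repeat meeting (min_len, min_identity) is guaranteed
## to contain, by the pigeonhole distribution of its mismatch budget; used to
## size the k-mer seed so the seeded scan misses nothing it promises to find.
guaranteed_seed_length <- function(min_len, min_identity, horizon = 10000L) {
    if (min_identity >= 100) return(min_len)
    lens <- seq.int(min_len, max(horizon, min_len))
    e <- floor((100 - min_identity) / 100 * lens + 1e-9)
    min(ceiling((lens - e) / (e + 1)))
}

## Deterministic arm-overlap dedup: pairs sorted by length (desc), then
## arm1_start, then arm2_start; a pair is dropped when both of its arms
## overlap both arms of an already-kept pair — i.e. it restates the same
## repeat. Keeps the longest, then leftmost, representative.
dedupe_repeat_pairs <- function(df) {
    if (nrow(df) <= 1L) {
        rownames(df) <- NULL
        return(df)
    }
    o <- order(-df$length_bp, df$arm1_start, df$arm2_start)
    df <- df[o, , drop = FALSE]
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
        ki <- which(keep)
        clash <- FALSE
        for (j in ki) {
            if (df$arm1_start[i] <= df$arm1_end[j] &&
                df$arm1_end[i] >= df$arm1_start[j] &&
                df$arm2_start[i] <= df$arm2_end[j] &&
                df$arm2_end[i] >= df$arm2_start[j]) { clash <- TRUE; break }
        }
        keep[i] <- !clash
    }
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Find maximal direct or inverted repeat pairs
#'
#' Reports every maximal pair of equal-length, non-overlapping arms whose
#' ungapped (Hamming) identity meets `min_identity`. *Maximal* means the pair
#' cannot be extended by one base at either end of both arms — onto a
#' mismatch, past the sequence boundary, or into arm overlap — without
#' dropping below the identity threshold. `N` never matches anything,
#' including `N`. Arms never overlap (`arm2_start > arm1_end`), and no pair
#' is reported twice in swapped-arm order.
#'
#' Small sequences (up to 4 kb) are scanned exhaustively over every
#' (anti)diagonal; larger ones by exact k-mer seeding with a seed length
#' chosen so that any repeat meeting the thresholds must contain a seed.
#' Overlapping reports of the same repeat are collapsed to the longest, then
#' leftmost, representative.
#'
#' @param sequence Nucleotide string or [AnnotatedReplicon()].
#' @param orientation `"inverted"` (arm2 matches the reverse complement of
#'   arm1) or `"direct"`.
#' @param min_len Minimum arm length in bp (default 100, the window size
#'   commonly used for genome-wide repeat scans).
#' @param min_identity Minimum percent identity in `[80, 100]`.
#' @param k Exact seed length for the seeded scan (capped by what the
#'   thresholds guarantee).
#' @return Data frame of repeat pairs: `arm1_start`, `arm1_end`,
#'   `arm2_start`, `arm2_end`, `orientation`, `length_bp`,
#'   `identity_percent`, sorted by length (desc) then `arm1_start`. A
#'   sequence shorter than `2 * min_len` yields zero rows.
#' @examples
#' x <- strrep("ACGTT", 12)
#' find_repeats(paste0(x, "GGGGGGGGGGGGGGGGGGGG", revcomp(x)),
#'              orientation = "inverted", min_len = 20)
#' @export
find_repeats <- function(sequence, orientation = c("inverted", "direct"),
                         min_len = 100L, min_identity = 100, k = 21L) {
    orientation <- match.arg(orientation)
    s <- clean_sequence(as_sequence(sequence), warn = FALSE)
    stopifnot(min_len >= 8L, min_identity >= 80, min_identity <= 100)
    empty <- cbind(data.frame(arm1_start = integer(), arm1_end = integer(),
                              arm2_start = integer(), arm2_end = integer()),
                   orientation = character(),
                   data.frame(length_bp = integer(),
                              identity_percent = numeric()))
    n <- nchar(s)
    if (n < 2L * min_len) return(empty)
    exhaustive <- n <= 4000L
    seed_k <- max(6L, min(as.integer(k),
                          guaranteed_seed_length(min_len, min_identity), 31L))
    df <- find_repeats_cpp(s, orientation == "inverted", as.integer(min_len),
                           as.numeric(min_identity), seed_k, exhaustive)
    df$orientation <- rep(orientation, nrow(df))
    df <- df[, c("arm1_start", "arm1_end", "arm2_start", "arm2_end",
                 "orientation", "length_bp", "identity_percent")]
    dedupe_repeat_pairs(df)
}

#' Detect a terminal inverted repeat (TIR)
#'
#' Linear actinomycete plasmids carry reverse-complement repeats at their two
#' termini. This returns the longest inverted repeat pair whose first arm
#' starts within `max_offset` bp of position 1 and whose second arm ends
#' within `max_offset` bp of the sequence end — the tolerance absorbs ragged
#' assembly ends.
#'
#' @param replicon [AnnotatedReplicon()] or sequence string.
#' @param max_offset Maximum distance of each arm from its terminus (bp).
#' @param min_len Minimum TIR arm length (default 50, shorter than the
#'   genome-wide scan default so short termini are caught).
#' @param min_identity Minimum percent identity.
#' @return One-row repeat-pair data frame (as [find_repeats()]), or `NULL`
#'   when no qualifying TIR exists.
#' @export
find_terminal_inverted_repeats <- function(replicon, max_offset = 100L,
                                           min_len = 50L, min_identity = 95) {
    s <- as_sequence(replicon)
    n <- nchar(s)
    df <- find_repeats(s, "inverted", min_len = min_len,
                       min_identity = min_identity)
    df <- df[df$arm1_start - 1L <= max_offset &
             n - df$arm2_end <= max_offset, , drop = FALSE]
    if (nrow(df) == 0L) return(NULL)
    o <- order(-df$length_bp, -df$identity_percent, df$arm1_start)
    out <- df[o[1], , drop = FALSE]
    rownames(out) <- NULL
    out
}
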