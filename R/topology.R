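## Replicon topology: circular / linear / unresolved, from three evidence
## channels — exact terminal sequence redundancy, read pairs spanning the
## contig ends, and terminal inverted repeats.

#' Detect exact end overlap (terminal redundancy)
#'
#' Assemblers present a circular replicon as a linear contig whose start is
#' duplicated at its end. This returns the largest `L` in
#' `[min_overlap, max_overlap]` for which the first `L` bases equal the last
#' `L` bases exactly (`N` never matches), or 0 when there is none. Matching
#' is exact: assembler-duplicated termini are exact copies, and a mismatch
#' model is deliberately out of scope. `L` is capped at half the sequence
#' length.
#'
#' @param sequence Nucleotide string or [AnnotatedReplicon()].
#' @param min_overlap Smallest overlap considered meaningful (>= 15).
#' @param max_overlap Largest overlap searched.
#' @return Integer overlap length (0 if none).
#' @export
detect_end_overlap <- function(sequence, min_overlap = 20L,
                               max_overlap = 2000L) {
    stopifnot(min_overlap >= 15L)
    s <- clean_sequence(as_sequence(sequence), warn = FALSE)
    n <- nchar(s)
    hi <- min(as.integer(max_overlap), n %/% 2L)
    if (hi < min_overlap) return(0L)
    head_raw <- charToRaw(substr(s, 1L, hi))
    tail_raw <- charToRaw(substr(s, n - hi + 1L, n))
    nN <- charToRaw("N")[1]
    for (L in seq.int(hi, min_overlap)) {
        a <- head_raw[seq_len(L)]
        b <- tail_raw[seq.int(hi - L + 1L, hi)]
        if (all(a == b & a != nN)) return(L)
    }
    0L
}

#' Count read pairs spanning the contig ends
#'
#' A pair supports circularity when one mate maps inside the first
#' `end_window` bases pointing outward to the left (`-`) and the other
#' inside the last `end_window` bases pointing outward to the right (`+`) —
#' the footprint an insert spanning the circular junction leaves on the
#' linearized sequence. Mates may appear in either column order. Links
#' belonging to other contigs are ignored.
#'
#' @param replicon An [AnnotatedReplicon()].
#' @param links Read-link data frame ([read_read_links()]).
#' @param end_window Window size at each end (bp, must be < length/2).
#' @return Integer count of spanning pairs.
#' @export
count_spanning_pairs <- function(replicon, links, end_window = 500L) {
    n <- nchar(replicon$sequence)
    stopifnot(end_window < n / 2)
    if (is.null(links) || nrow(links) == 0L) return(0L)
    links <- links[links$contig == replicon$id, , drop = FALSE]
    if (nrow(links) == 0L) return(0L)
    left <- function(p, o) p >= 1L & p <= end_window & o == "-"
    right <- function(p, o) p >= n - end_window + 1L & p <= n & o == "+"
    spans <- (left(links$pos1, links$orient1) & right(links$pos2, links$orient2)) |
             (left(links$pos2, links$orient2) & right(links$pos1, links$orient1))
    sum(spans)
}

#' Call replicon topology
#'
#' Combines the three evidence channels into a verdict. Circular requires
#' end overlap at/above `min_overlap` *or* at least `spanning_threshold`
#' spanning read pairs; linear requires a terminal inverted repeat with no
#' circular evidence; otherwise unresolved. When a TIR co-occurs with
#' circular evidence the verdict is circular — read-pair and overlap
#' evidence is physical, and inverted repeats can occur in circular
#' molecules — with the conflict recorded in `evidence_notes`.
#'
#' @param replicon An [AnnotatedReplicon()].
#' @param links Optional read-link data frame.
#' @param params Parameter list from [mge_params()].
#' @return A `TopologyCall`: list with `replicon_id`, `verdict`,
#'   `end_overlap_bp`, `spanning_pairs`, `tir` (repeat-pair row or `NULL`)
#'   and `evidence_notes`.
#' @export
call_topology <- function(replicon, links = NULL, params = mge_params()) {
    tp <- params$topology
    overlap <- detect_end_overlap(replicon$sequence,
                                  min_overlap = tp$min_overlap,
                                  max_overlap = tp$max_overlap)
    spanning <- if (is.null(links)) 0L else
        count_spanning_pairs(replicon, links, end_window = tp$end_window)
    tir <- find_terminal_inverted_repeats(
        replicon, max_offset = params$tir$max_offset,
        min_len = params$tir$min_len, min_identity = params$tir$min_identity)
    circ <- overlap >= tp$min_overlap || spanning >= tp$spanning_threshold
    notes <- character()
    if (overlap > 0L)
        notes <- c(notes, sprintf("end overlap of %d bp", overlap))
    if (spanning > 0L)
        notes <- c(notes, sprintf("%d spanning read pair(s)", spanning))
    if (!is.null(tir))
        notes <- c(notes, sprintf("terminal inverted repeat of %d bp at %.1f%% identity",
                                  tir$length_bp, tir$identity_percent))
    verdict <- if (circ) {
        if (!is.null(tir))
            notes <- c(notes,
                       "conflict: TIR present but circular evidence prevails")
        "circular"
    } else if (!is.null(tir)) "linear" else "unresolved"
    structure(list(replicon_id = replicon$id, verdict = verdict,
                   end_overlap_bp = as.integer(overlap),
                   spanning_pairs = as.integer(spanning),
                   tir = tir, evidence_notes = notes),
              class = "TopologyCall")
}

#' @export
print.TopologyCall <- function(x, ...) {
    cat(sprintf("<TopologyCall> %s: %s (overlap %d bp, %d spanning pairs, TIR %s)\n",
                x$replicon_id, x$verdict, x$end_overlap_bp, x$spanning_pairs,
                if (is.null(x$tir)) "none" else
                    sprintf("%d bp", x$tir$length_bp)))
    invisible(x)
}

#' @export
as.data.frame.TopologyCall <- function(x, ...) {
    data.frame(replicon_id = x$replicon_id, verdict = x$verdict,
               end_overlap_bp = x$end_overlap_bp,
               spanning_pairs = x$spanning_pairs,
               tir_length_bp = if (is.null(x$tir)) 0L else x$tir$length_bp,
               tir_identity = if (is.null(x$tir)) NA_real_ else
                   x$tir$identity_percent,
               notes = paste(x$evidence_notes, collapse = "; "),
               stringsAsFactors = FALSE)
}
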