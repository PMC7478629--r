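## Shared-segment detection between two elements: exact k-mer anchors merged
## into exact blocks, blocks chained collinearly with a bounded gap, chains
## resolved greedily by anchored length, identities computed ungapped over
## the chained spans.

## Merge same-diagonal anchors (a, b 1-based starts of exact k-mer matches)
## into maximal exact blocks.
anchors_to_blocks <- function(a, b, k) {
    d <- b - a
    o <- order(d, a)
    a <- a[o]; d <- d[o]
    new_block <- c(TRUE, diff(d) != 0L | diff(a) > k)
    id <- cumsum(new_block)
    astart <- tapply(a, id, min)
    aend <- tapply(a, id, max) + k - 1L
    data.frame(a_start = as.integer(astart), a_end = as.integer(aend),
               diag = as.integer(tapply(d, id, function(x) x[1])))
}

## Chain blocks (sorted by a_start) maximizing summed block length; gaps in
## both sequences bounded by max_gap, small overlaps (< k) tolerated.
## Returns list of integer vectors of block indices, best chain first,
## blocks used at most once.
chain_blocks <- function(blocks, k, max_gap) {
    nb <- nrow(blocks)
    o <- order(blocks$a_start, blocks$a_end)
    blocks <- blocks[o, , drop = FALSE]
    len <- blocks$a_end - blocks$a_start + 1L
    b_start <- blocks$a_start + blocks$diag
    b_end <- blocks$a_end + blocks$diag
    avail <- rep(TRUE, nb)
    chains <- list()
    repeat {
        idx <- which(avail)
        if (!length(idx)) break
        score <- rep(-Inf, nb); prev <- rep(NA_integer_, nb)
        for (ii in idx) {
            score[ii] <- len[ii]
            for (jj in idx[idx < ii]) {
                ga <- blocks$a_start[ii] - blocks$a_end[jj] - 1L
                gb <- b_start[ii] - b_end[jj] - 1L
                if (ga < -(k - 1L) || ga > max_gap) next
                if (gb < -(k - 1L) || gb > max_gap) next
                cand <- score[jj] + len[ii]
                if (cand > score[ii]) { score[ii] <- cand; prev[ii] <- jj }
            }
        }
        endi <- idx[which.max(score[idx])]
        chain <- integer()
        i <- endi
        while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
        chains[[length(chains) + 1L]] <- o[chain]
        avail[chain] <- FALSE
    }
    chains
}

## Ungapped identity over a chained span. Single-diagonal chains are compared
## base by base over the whole span; across diagonal shifts the collinear
## pieces are compared and the shifted remainder counts as unaligned.
chain_identity <- function(seq_a, seq_b, blocks, chain_rows, k) {
    bl <- blocks[chain_rows, , drop = FALSE]
    bl <- bl[order(bl$a_start), , drop = FALSE]
    diags <- unique(bl$diag)
    if (length(diags) == 1L) {
        a1 <- min(bl$a_start); a2 <- max(bl$a_end)
        len <- a2 - a1 + 1L
        m <- hamming_matches_cpp(substr(seq_a, a1, a2), 1L,
                                 substr(seq_b, a1 + diags, a2 + diags), 1L, len)
        return(list(matches = m, aligned = len))
    }
    matches <- 0L; aligned <- 0L
    for (i in seq_len(nrow(bl))) {
        len <- bl$a_end[i] - bl$a_start[i] + 1L
        matches <- matches + len; aligned <- aligned + len
        if (i < nrow(bl)) {
            ga <- bl$a_start[i + 1L] - bl$a_end[i] - 1L
            gb <- (bl$a_start[i + 1L] + bl$diag[i + 1L]) -
                  (bl$a_end[i] + bl$diag[i]) - 1L
            if (ga > 0L && ga == gb) {
                m <- hamming_matches_cpp(
                    substr(seq_a, bl$a_end[i] + 1L, bl$a_start[i + 1L] - 1L), 1L,
                    substr(seq_b, bl$a_end[i] + bl$diag[i] + 1L,
                           bl$a_start[i + 1L] + bl$diag[i + 1L] - 1L), 1L, ga)
                matches <- matches + m; aligned <- aligned + ga
            } else {
                aligned <- aligned + max(0L, min(ga, gb))
            }
        }
    }
    list(matches = matches, aligned = aligned)
}

## Ungapped X-drop extension from (pos_a, pos_b) in direction dir (+1/-1):
## +1 per match, -2 per mismatch, stop when the running score falls `xdrop`
## below its maximum; returns the extension length at the score maximum.
xdrop_extend <- function(seq_a, seq_b, pos_a, pos_b, dir, xdrop = 20L) {
    na <- nchar(seq_a); nb <- nchar(seq_b)
    best <- 0; best_i <- 0L; score <- 0; i <- 0L
    repeat {
        i <- i + 1L
        ia <- pos_a + dir * i; ib <- pos_b + dir * i
        if (ia < 1L || ib < 1L || ia > na || ib > nb) break
        ca <- substr(seq_a, ia, ia)
        score <- score +
            (if (ca != "N" && ca == substr(seq_b, ib, ib)) 1 else -2)
        if (score > best) { best <- score; best_i <- i }
        if (score < best - xdrop) break
    }
    best_i
}

## Extend a span outward on its terminal diagonals.
extend_span <- function(seq_a, seq_b, a1, a2, d1, d2) {
    a1 <- a1 - xdrop_extend(seq_a, seq_b, a1, a1 + d1, -1L)
    a2 <- a2 + xdrop_extend(seq_a, seq_b, a2, a2 + d2, +1L)
    c(a1, a2)
}

empty_segments <- function() {
    data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
               b_end = integer(), strand = character(), length_bp = integer(),
               identity_percent = numeric(), score = integer(),
               stringsAsFactors = FALSE)
}

find_segments_one_strand <- function(seq_a, seq_b, k, min_segment,
                                     min_identity, max_gap, max_occ) {
    anch <- kmer_anchors_cpp(seq_a, seq_b, as.integer(k), as.integer(max_occ))
    if (nrow(anch) == 0L) return(empty_segments())
    blocks <- anchors_to_blocks(anch$a_start, anch$b_start, k)
    if (nrow(blocks) > 20000L) {
        blocks <- blocks[order(-(blocks$a_end - blocks$a_start)), ,
                         drop = FALSE][seq_len(20000L), ]
    }
    chains <- chain_blocks(blocks, k, max_gap)
    segs <- lapply(chains, function(rows) {
        bl <- blocks[rows, , drop = FALSE]
        bl <- bl[order(bl$a_start), , drop = FALSE]
        a1 <- min(bl$a_start); a2 <- max(bl$a_end)
        d1 <- bl$diag[1]; d2 <- bl$diag[nrow(bl)]
        ext <- extend_span(seq_a, seq_b, a1, a2, d1, d2)
        if (a2 - a1 + 1L < min_segment &&
            ext[2] - ext[1] + 1L < min_segment) return(NULL)
        if (length(unique(bl$diag)) == 1L) {
            ## single diagonal: identity directly over the extended span
            a1 <- ext[1]; a2 <- ext[2]
            len <- a2 - a1 + 1L
            m <- hamming_matches_cpp(substr(seq_a, a1, a2), 1L,
                                     substr(seq_b, a1 + d1, a2 + d1), 1L, len)
            idp <- 100 * m / len
        } else {
            idt <- chain_identity(seq_a, seq_b, blocks, rows, k)
            lext <- a1 - ext[1]; rext <- ext[2] - a2
            mext <- 0L
            if (lext > 0L)
                mext <- mext + hamming_matches_cpp(
                    substr(seq_a, ext[1], a1 - 1L), 1L,
                    substr(seq_b, ext[1] + d1, a1 + d1 - 1L), 1L, lext)
            if (rext > 0L)
                mext <- mext + hamming_matches_cpp(
                    substr(seq_a, a2 + 1L, ext[2]), 1L,
                    substr(seq_b, a2 + 1L + d2, ext[2] + d2), 1L, rext)
            idp <- 100 * (idt$matches + mext) /
                   (idt$aligned + lext + rext)
            a1 <- ext[1]; a2 <- ext[2]
        }
        if (a2 - a1 + 1L < min_segment) return(NULL)
        if (idp < min_identity) return(NULL)
        data.frame(a_start = a1, a_end = a2,
                   b_start = a1 + bl$diag[1], b_end = a2 + bl$diag[nrow(bl)],
                   strand = "+", length_bp = a2 - a1 + 1L,
                   identity_percent = idp,
                   score = sum(bl$a_end - bl$a_start + 1L),
                   stringsAsFactors = FALSE)
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (!length(segs)) return(empty_segments())
    do.call(rbind, segs)
}

#' Find shared segments between two sequences
#'
#' Anchor-and-chain homology detection: exact `k`-mer matches between A and B
#' (both strands) are merged into exact blocks, blocks are chained
#' collinearly with gaps up to `max_gap` in either sequence, overlapping
#' chains are resolved greedily by anchored length (ties to the leftmost in
#' A), and each chain's identity is computed ungapped over its span plus
#' exact outward extensions. Segments shorter than `min_segment` in A, or
#' below `min_identity`, are dropped; surviving segments never overlap in A.
#'
#' @param seq_a,seq_b Nucleotide strings (or [AnnotatedReplicon()]s).
#' @param k Anchor k-mer length (>= 15).
#' @param min_segment Minimum segment length in A (bp).
#' @param min_identity Minimum percent identity.
#' @param max_gap Maximum chaining gap (bp).
#' @param max_occ Maximum occurrences per anchor k-mer in B (repeat guard).
#' @return Data frame of segments: `a_start`, `a_end`, `b_start`, `b_end`
#'   (always given on the forward strand of B), `strand`, `length_bp`
#'   (length in A), `identity_percent`.
#' @export
find_shared_segments <- function(seq_a, seq_b, k = 21L, min_segment = 1000L,
                                 min_identity = 70, max_gap = 2000L,
                                 max_occ = 50L) {
    stopifnot(k >= 15L)
    a <- clean_sequence(as_sequence(seq_a), warn = FALSE)
    b <- clean_sequence(as_sequence(seq_b), warn = FALSE)
    if (nchar(a) == 0L || nchar(b) == 0L) {
        out <- empty_segments(); out$score <- NULL; return(out)
    }
    fwd <- find_segments_one_strand(a, b, k, min_segment, min_identity,
                                    max_gap, max_occ)
    brc <- revcomp(b)
    rev_ <- find_segments_one_strand(a, brc, k, min_segment, min_identity,
                                     max_gap, max_occ)
    if (nrow(rev_)) {
        nb <- nchar(b)
        bs <- nb - rev_$b_end + 1L
        be <- nb - rev_$b_start + 1L
        rev_$b_start <- bs; rev_$b_end <- be
        rev_$strand <- "-"
    }
    segs <- rbind(fwd, rev_)
    if (nrow(segs) == 0L) { segs$score <- NULL; return(segs) }
    ## greedy resolution: best score first, drop anything overlapping in A
    segs <- segs[order(-segs$score, segs$a_start), , drop = FALSE]
    keep <- logical(nrow(segs))
    for (i in seq_len(nrow(segs))) {
        ki <- which(keep)
        keep[i] <- !any(segs$a_start[i] <= segs$a_end[ki] &
                        segs$a_end[i] >= segs$a_start[ki])
    }
    segs <- segs[keep, , drop = FALSE]
    segs <- segs[order(segs$a_start), , drop = FALSE]
    segs$score <- NULL
    rownames(segs) <- NULL
    segs
}

#' Summarize sharing between two elements
#'
#' @param segments Segment data frame from [find_shared_segments()]
#'   (non-overlapping in A).
#' @param len_a,len_b Lengths of the two elements (bp).
#' @return One-row data frame: `shared_bp_a` (total shared bases in A),
#'   `coverage_a_percent`, `coverage_b_percent` (B-side overlaps merged
#'   before computing coverage), `length_weighted_identity`, `n_segments`.
#' @examples
#' summarize_sharing(data.frame(a_start = 1, a_end = 50, b_start = 11,
#'                              b_end = 60, strand = "+", length_bp = 50,
#'                              identity_percent = 100), 100, 200)
#' @export
summarize_sharing <- function(segments, len_a, len_b) {
    if (is.null(segments) || nrow(segments) == 0L)
        return(data.frame(shared_bp_a = 0L, coverage_a_percent = 0,
                          coverage_b_percent = 0,
                          length_weighted_identity = 0, n_segments = 0L))
    shared_a <- sum(segments$length_bp)
    ## merge B intervals before coverage
    b <- segments[order(segments$b_start), c("b_start", "b_end")]
    merged <- 0L; cur_s <- b$b_start[1]; cur_e <- b$b_end[1]
    if (nrow(b) > 1L) for (i in 2:nrow(b)) {
        if (b$b_start[i] <= cur_e + 1L) cur_e <- max(cur_e, b$b_end[i])
        else { merged <- merged + cur_e - cur_s + 1L
               cur_s <- b$b_start[i]; cur_e <- b$b_end[i] }
    }
    merged <- merged + cur_e - cur_s + 1L
    data.frame(shared_bp_a = shared_a,
               coverage_a_percent = 100 * shared_a / len_a,
               coverage_b_percent = 100 * merged / len_b,
               length_weighted_identity =
                   sum(segments$identity_percent * segments$length_bp) / shared_a,
               n_segments = nrow(segments))
}
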