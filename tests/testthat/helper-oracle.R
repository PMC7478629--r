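# Brute-force oracles, written straight from the definitions and independent
# of the package's seeded/banded scanning path.
#
# Two definition-level reductions keep the enumeration honest but feasible:
# extending a window onto a MATCH always keeps identity at or above the
# threshold (matches/len <= (matches+1)/(len+1)), so a maximal window's
# first position is either 1 or preceded by a mismatch, and its last is
# either the end or followed by one. Windows at the arm-contact cap (direct
# orientation, length == diagonal offset) have no legal extension and are
# maximal whenever they pass the threshold.

# All one-step-maximal windows on a logical match vector; returns a matrix
# with columns a, b, matches (possibly 0 rows).
oracle_enum_windows <- function(m, min_len, p, cap = Inf) {
    M <- length(m)
    none <- matrix(integer(), ncol = 3)
    if (M < min_len) return(none)
    S <- c(0L, cumsum(m))
    out <- none
    if (p >= 100) {
        r <- rle(as.logical(m))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (i in which(r$values & r$lengths >= min_len)) {
            if (r$lengths[i] <= cap) {
                out <- rbind(out, c(starts[i], ends[i], r$lengths[i]))
            } else {
                # every cap-length window inside the run is maximal; the
                # arm-overlap dedup keeps the leftmost
                for (a in starts[i]:(ends[i] - cap + 1L))
                    out <- rbind(out, c(a, a + cap - 1L, cap))
            }
        }
        return(out)
    }
    A <- which(c(TRUE, !m[-M]))
    B <- which(c(!m[-1L], TRUE))
    MT <- outer(A, B, function(a, b) S[b + 1L] - S[a])
    LEN <- outer(A, B, function(a, b) b - a + 1L)
    ok <- MT * 100 >= p * LEN - 1e-7
    ext_keeps <- MT * 100 >= p * (LEN + 1L) - 1e-7
    no_ext <- outer(A == 1L, B == M, "&")
    maximal <- ok & LEN >= min_len & LEN < cap & (no_ext | !ext_keeps)
    idx <- which(maximal, arr.ind = TRUE)
    if (nrow(idx)) {
        out <- rbind(out, cbind(A[idx[, 1]], B[idx[, 2]],
                                MT[idx]))
    }
    if (is.finite(cap) && cap >= min_len && cap <= M) {
        for (a in seq_len(M - cap + 1L)) {
            mt <- S[a + cap] - S[a]
            if (mt * 100 >= p * cap - 1e-7)
                out <- rbind(out, c(a, a + cap - 1L, mt))
        }
    }
    out
}

# Same output contract as find_repeats(), computed by visiting every
# (anti)diagonal. Feasible up to ~2 kb (100%) / ~500 bp (90%).
oracle_find_repeats <- function(s, orientation, min_len, min_identity) {
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
    rows <- list()
    push <- function(w, a1s_off, d_or_C, direct) {
        if (nrow(w) == 0L) return()
        a <- a1s_off + w[, 1] - 1L
        b <- a1s_off + w[, 2] - 1L
        if (direct) {
            df <- data.frame(arm1_start = a, arm1_end = b,
                             arm2_start = a + d_or_C, arm2_end = b + d_or_C)
        } else {
            df <- data.frame(arm1_start = a, arm1_end = b,
                             arm2_start = d_or_C - b, arm2_end = d_or_C - a)
        }
        df$orientation <- orientation
        df$length_bp <- b - a + 1L
        df$identity_percent <- 100 * w[, 3] / df$length_bp
        rows[[length(rows) + 1L]] <<- df
    }
    if (orientation == "direct") {
        for (d in seq_len(n - 1L)) {
            if (d < min_len) next
            M <- n - d
            m <- v[1:M] == v[(1 + d):n] & v[1:M] != "N"
            push(oracle_enum_windows(m, min_len, min_identity, cap = d),
                 1L, d, TRUE)
        }
    } else {
        for (C in 3:(2L * n - 1L)) {
            tmin <- max(1L, C - n)
            tmax <- ceiling(C / 2) - 1L
            if (tmax - tmin + 1L < min_len) next
            t <- tmin:tmax
            m <- v[t] == unname(comp[v[C - t]])
            push(oracle_enum_windows(m, min_len, min_identity),
                 tmin, C, FALSE)
        }
    }
    if (!length(rows)) {
        return(data.frame(arm1_start = integer(), arm1_end = integer(),
                          arm2_start = integer(), arm2_end = integer(),
                          orientation = character(), length_bp = integer(),
                          identity_percent = numeric(),
                          stringsAsFactors = FALSE))
    }
    oracle_dedupe(do.call(rbind, rows))
}

# Arm-overlap dedup rule, restated: longest first (ties by leftmost arm1,
# then arm2); drop a pair when both arms overlap both arms of a kept pair.
oracle_dedupe <- function(df) {
    df <- df[order(-df$length_bp, df$arm1_start, df$arm2_start), ,
             drop = FALSE]
    kept <- df[0, ]
    for (i in seq_len(nrow(df))) {
        dup <- FALSE
        if (nrow(kept)) {
            o1 <- df$arm1_start[i] <= kept$arm1_end &
                  df$arm1_end[i] >= kept$arm1_start
            o2 <- df$arm2_start[i] <= kept$arm2_end &
                  df$arm2_end[i] >= kept$arm2_start
            dup <- any(o1 & o2)
        }
        if (!dup) kept <- rbind(kept, df[i, ])
    }
    rownames(kept) <- NULL
    kept
}

# Largest exact prefix/suffix overlap, by definition.
oracle_end_overlap <- function(s, min_overlap, max_overlap) {
    n <- nchar(s)
    best <- 0L
    for (L in seq_len(min(max_overlap, n %/% 2L))) {
        if (L < min_overlap) next
        pre <- substr(s, 1L, L)
        suf <- substr(s, n - L + 1L, n)
        if (pre == suf && !grepl("N", pre, fixed = TRUE)) best <- L
    }
    best
}

expect_same_pairs <- function(found, expected) {
    cols <- c("arm1_start", "arm1_end", "arm2_start", "arm2_end", "length_bp")
    expect_equal(nrow(found), nrow(expected))
    if (nrow(found) == 0L) return(invisible())
    o1 <- do.call(order, found[cols])
    o2 <- do.call(order, expected[cols])
    expect_equal(found[o1, cols, drop = FALSE],
                 expected[o2, cols, drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(found$identity_percent[o1], expected$identity_percent[o2],
                 tolerance = 1e-9, ignore_attr = TRUE)
}
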