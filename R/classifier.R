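## Element feature matrix, classification cascade, and delimitation of
## integrated regions by flanking direct repeats with adjacent transposases.

ELEMENT_FLAGS <- c("repA", "relaxase", "virD4", "virB4", "tcpC", "helicase",
                   "dna_polymerase", "integrase", "transposase", "trna_genes",
                   "t7ss", "toxin_antitoxin")

FLAG_TAG_MAP <- c(repA = "RepA", relaxase = "relaxase", virD4 = "VirD4",
                  virB4 = "VirB4", tcpC = "TcpC", helicase = "DnaB_helicase",
                  dna_polymerase = "DNA_PolI", integrase = "integrase",
                  transposase = "transposase", trna_genes = "tRNA")

#' Build an element profile (feature matrix row)
#'
#' Collects the per-element presence/absence flags from domain-tagged
#' features, together with size, GC, CDS count and topology. A flag is true
#' when at least one feature carries the corresponding tag; `trna_genes` also
#' counts `tRNA`-typed features; `t7ss` is true exactly when ESX loci were
#' called; `toxin_antitoxin` requires a toxin-tagged and an antitoxin-tagged
#' feature to be adjacent (at most `ta_max_intervening` genes between them) —
#' a deliberately simple addiction-module heuristic, weaker than dedicated
#' TA predictors, and marked as such.
#'
#' @param replicon An [AnnotatedReplicon()].
#' @param topo Optional `TopologyCall` for the replicon.
#' @param loci List of `EsxLocus` from [call_esx_loci()] (possibly empty).
#' @param ta_max_intervening Maximum genes between toxin and antitoxin.
#' @return An `ElementProfile`: list with `replicon_id`, `size_bp`,
#'   `gc_percent`, `n_cds`, `topology`, `flags` (named logical), `esx_loci`,
#'   `classification`.
#' @export
build_profile <- function(replicon, topo = NULL, loci = list(),
                          ta_max_intervening = 1L) {
    f <- replicon$features
    flags <- vapply(ELEMENT_FLAGS, function(fl) {
        if (fl == "t7ss") return(length(loci) > 0L)
        if (fl == "toxin_antitoxin") {
            tox <- which(has_tag(f, "TA_toxin"))
            anti <- which(has_tag(f, "TA_antitoxin"))
            if (!length(tox) || !length(anti)) return(FALSE)
            any(outer(tox, anti, function(i, j)
                abs(i - j) <= ta_max_intervening + 1L))
        } else if (fl == "trna_genes") {
            any(has_tag(f, "tRNA")) || any(f$ftype == "tRNA")
        } else {
            any(has_tag(f, FLAG_TAG_MAP[[fl]]))
        }
    }, logical(1))
    names(flags) <- ELEMENT_FLAGS
    profile <- structure(list(
        replicon_id = replicon$id,
        size_bp = nchar(replicon$sequence),
        gc_percent = gc_content(replicon),
        n_cds = count_features(replicon, "CDS"),
        topology = if (is.null(topo)) "unresolved" else topo$verdict,
        flags = flags,
        esx_loci = loci,
        classification = NA_character_), class = "ElementProfile")
    profile$classification <- classify_element(profile)
    profile
}

#' Classify an element from its feature flags
#'
#' Rule cascade, first match wins:
#' \enumerate{
#'   \item `putative_ICE`: relaxase, a T4SS marker (virB4 or virD4), an
#'     integrase or DDE-transposase, and *no* repA — the gene complement of a
#'     T4SS-mediated integrative conjugative element, which relies on its
#'     host replicon rather than its own replication initiator.
#'   \item `conjugative_plasmid`: replication evidence (repA, or a DnaB-like
#'     helicase for repA-less linear plasmids) plus relaxase plus a T4SS
#'     marker.
#'   \item `cryptic_plasmid`: replication evidence without a relaxase.
#'   \item `unclassified` otherwise.
#' }
#' The cascade is a pure function of the flag vector.
#'
#' @param profile An `ElementProfile` (or a named logical flag vector).
#' @return Classification string.
#' @export
classify_element <- function(profile) {
    fl <- if (inherits(profile, "ElementProfile")) profile$flags else profile
    t4ss <- fl[["virB4"]] || fl[["virD4"]]
    mobile_int <- fl[["integrase"]] || fl[["transposase"]]
    replication <- fl[["repA"]] || fl[["helicase"]]
    if (fl[["relaxase"]] && t4ss && mobile_int && !fl[["repA"]])
        return("putative_ICE")
    if (replication && fl[["relaxase"]] && t4ss)
        return("conjugative_plasmid")
    if (replication && !fl[["relaxase"]])
        return("cryptic_plasmid")
    "unclassified"
}

#' @export
print.ElementProfile <- function(x, ...) {
    on <- names(x$flags)[x$flags]
    cat(sprintf("<ElementProfile> %s: %s bp, GC %.1f%%, %d CDS, %s, %s\n  flags: %s\n",
                x$replicon_id, format(x$size_bp, big.mark = ","), x$gc_percent,
                x$n_cds, x$topology, x$classification,
                if (length(on)) paste(on, collapse = ", ") else "none"))
    invisible(x)
}

profile_report_row <- function(p) {
    stopifnot(inherits(p, "ElementProfile"))
    flags <- as.integer(p$flags)
    names(flags) <- names(p$flags)
    cbind(data.frame(element = p$replicon_id, size_bp = p$size_bp,
                     gc_percent = round_half_up(p$gc_percent),
                     n_cds = p$n_cds, topology = p$topology,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(flags)),
          data.frame(classification = p$classification,
                     stringsAsFactors = FALSE))
}

#' Delimit candidate integrated regions from direct-repeat pairs
#'
#' Integration of a mobile element leaves same-orientation repeats flanking
#' the integrated cargo. Each near-identical direct-repeat pair whose
#' inter-arm region contains at least one CDS becomes a candidate region;
#' the nearest DDE/IS-tagged feature within `max_adjacency` bp of either arm
#' is recorded as the adjacent transposase. Regions are bounded by the inner
#' edges of the arms and never extend into them; calls are sorted by region
#' length, longest (outermost, for nested pairs) first.
#'
#' @param replicon An [AnnotatedReplicon()].
#' @param drs Direct repeat pairs ([find_repeats()] output, orientation
#'   `"direct"`); rows below `min_identity` are ignored.
#' @param max_adjacency Maximum transposase-to-arm distance (bp).
#' @param loci Optional ESX loci, counted when inside a region.
#' @param min_identity Minimum arm identity for a boundary-grade repeat.
#' @return Data frame with one row per call: arm coordinates, `region_start`,
#'   `region_end`, `region_len`, cargo counts, and `adjacent_transposase`
#'   (feature index or `NA`).
#' @export
delimit_integrated_regions <- function(replicon, drs, max_adjacency = 1000L,
                                       loci = list(), min_identity = 99) {
    f <- replicon$features
    empty <- data.frame(replicon_id = character(), arm1_start = integer(),
                        arm1_end = integer(), arm2_start = integer(),
                        arm2_end = integer(), dr_length_bp = integer(),
                        region_start = integer(), region_end = integer(),
                        region_len = integer(), n_cds = integer(),
                        n_trna = integer(), n_esx_loci = integer(),
                        adjacent_transposase = integer(),
                        stringsAsFactors = FALSE)
    if (is.null(drs) || nrow(drs) == 0L) return(empty)
    drs <- drs[drs$orientation == "direct" &
               drs$identity_percent >= min_identity, , drop = FALSE]
    if (nrow(drs) == 0L) return(empty)
    tn_idx <- which(has_tag(f, "transposase"))
    calls <- lapply(seq_len(nrow(drs)), function(i) {
        rs <- drs$arm1_end[i] + 1L
        re <- drs$arm2_start[i] - 1L
        if (re < rs) return(NULL)
        inside <- f$start >= rs & f$end <= re
        n_cds <- sum(inside & f$ftype == "CDS")
        if (n_cds == 0L) return(NULL)
        adj <- NA_integer_
        if (length(tn_idx)) {
            d1 <- mapply(interval_gap, f$start[tn_idx], f$end[tn_idx],
                         MoreArgs = list(s2 = drs$arm1_start[i],
                                         e2 = drs$arm1_end[i]))
            d2 <- mapply(interval_gap, f$start[tn_idx], f$end[tn_idx],
                         MoreArgs = list(s2 = drs$arm2_start[i],
                                         e2 = drs$arm2_end[i]))
            d <- pmin(d1, d2)
            j <- which.min(d)
            if (d[j] <= max_adjacency) adj <- tn_idx[j]
        }
        n_loci <- sum(vapply(loci, function(l)
            l$span_start >= rs && l$span_end <= re, logical(1)))
        data.frame(replicon_id = replicon$id,
                   arm1_start = drs$arm1_start[i], arm1_end = drs$arm1_end[i],
                   arm2_start = drs$arm2_start[i], arm2_end = drs$arm2_end[i],
                   dr_length_bp = drs$length_bp[i],
                   region_start = rs, region_end = re,
                   region_len = re - rs + 1L,
                   n_cds = n_cds,
                   n_trna = sum(inside & f$ftype == "tRNA"),
                   n_esx_loci = n_loci,
                   adjacent_transposase = adj,
                   stringsAsFactors = FALSE)
    })
    calls <- calls[!vapply(calls, is.null, logical(1))]
    if (!length(calls)) return(empty)
    out <- do.call(rbind, calls)
    out <- out[order(-out$region_len, out$region_start), , drop = FALSE]
    rownames(out) <- NULL
    out
}
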