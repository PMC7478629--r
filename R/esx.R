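## ESX (T7SS) locus calling and signature-based typing. Loci are called by
## clustering core-component genes (EccA, EccB, EccC, EccD, EccE, MycP) along
## the replicon; a locus needs at least four core genes close to each other.
## Typing replaces phylogenetic placement with transparent gene-order
## signature matching against a bundled, user-extensible reference table.

ESX_CORE_TAGS <- c("EccA", "EccB", "EccC", "EccD", "EccE", "MycP")
ESX_GAP_MARKER <- "-//-"

esx_token <- function(tag) {
    c(EccA = "eccA", EccB = "eccB", EccC = "eccC", EccD = "eccD",
      EccE = "eccE", MycP = "mycP")[[tag]]
}

## single letters for Levenshtein distance via utils::adist
esx_letter <- function(tokens) {
    map <- c(eccA = "A", eccB = "B", eccC = "C", eccD = "D", eccE = "E",
             mycP = "P")
    paste(map[tokens], collapse = "")
}

#' Bundled ESX gene-order reference signatures
#'
#' Each row pairs an ESX type with the genomic order of its core genes.
#' The mobile-element signatures come from characterized plasmid/ICE-borne
#' loci (the ESX-4-bis order of ICEMyc226 and *Mycolicibacterium mageritense*;
#' the ESX-2-like order shared by pCBMA213_2, ICEMyc226 and the pMKMS01
#' plasmid); the chromosomal ESX-1/-3/-4 orders are the canonical
#' *Mycobacterium* locus layouts (ESX-1 with its split eccCa/eccCb, ESX-4
#' lacking eccA and eccE). `-//-` marks a gap to a distal gene. Users may
#' rbind additional rows and pass the table to [classify_esx_type()].
#'
#' @return Data frame with columns `type`, `signature`, `provenance`.
#' @export
esx_reference_signatures <- function() {
    data.frame(
        type = c("ESX-4-bis", "ESX-2-like", "ESX-1", "ESX-3-like", "ESX-4"),
        signature = c("eccE/eccB/eccD/eccC/eccD/mycP/-//-/eccA",
                      "eccC/eccB/eccD/mycP/eccE/-//-/eccA",
                      "eccA/eccB/eccC/eccC/eccD/mycP/eccE",
                      "eccA/eccB/eccC/eccD/mycP/eccE",
                      "eccB/eccC/eccD/mycP"),
        provenance = c("mobile-element locus (ICEMyc226 / M. mageritense type)",
                       "mobile-element locus (pCBMA213_2 / pMKMS01 type)",
                       "canonical chromosomal locus",
                       "canonical chromosomal locus",
                       "canonical chromosomal locus"),
        stringsAsFactors = FALSE)
}

signature_tokens <- function(signature, keep_marker = FALSE) {
    tokens <- strsplit(signature, "/", fixed = TRUE)[[1]]
    tokens <- tokens[nzchar(tokens)]
    ## "-//-" splits into "-", "", "-": re-join
    out <- character()
    i <- 1L
    while (i <= length(tokens)) {
        if (tokens[i] == "-" && i < length(tokens) && tokens[i + 1L] == "-") {
            out <- c(out, ESX_GAP_MARKER)
            i <- i + 2L
        } else {
            out <- c(out, tokens[i])
            i <- i + 1L
        }
    }
    if (!keep_marker) out <- out[out != ESX_GAP_MARKER]
    out
}

#' Call ESX (T7SS) loci on a replicon
#'
#' Core-tagged genes are clustered by single linkage along the replicon: two
#' consecutive core genes belong to the same cluster when the gap between
#' them is at most `max_gap`. Clusters with at least `min_core` members
#' become loci. A leftover (unclustered) EccA within `eccA_reach`
#' downstream of a locus (downstream in the reading direction of the
#' locus's majority strand) is appended as a distal member, marked `-//-`
#' in the signature — the arrangement seen in mobile-element ESX loci,
#' where eccA sits some 17 kb from the core cluster.
#'
#' @param replicon An [AnnotatedReplicon()] whose features carry domain tags.
#' @param max_gap Maximum gap (bp) between consecutive core genes of one
#'   cluster.
#' @param min_core Minimum core genes per locus (default 4).
#' @param eccA_reach Maximum distance (bp) at which a distal EccA is attached.
#' @return List of `EsxLocus` objects, sorted by `span_start`. Each is a list
#'   with `replicon_id`, `members` (data frame: feature index, gene, start,
#'   end), `span_start`, `span_end`, `n_core`, `signature`, `assigned_type`.
#' @export
call_esx_loci <- function(replicon, max_gap = 6000L, min_core = 4L,
                          eccA_reach = 20000L) {
    f <- replicon$features
    tl <- tag_list(f)
    core_tag <- vapply(tl, function(x) {
        hit <- intersect(ESX_CORE_TAGS, x)
        if (length(hit)) hit[1] else NA_character_
    }, character(1))
    idx <- which(!is.na(core_tag))
    if (length(idx) == 0L) return(list())
    core <- data.frame(feature = idx, tag = core_tag[idx],
                       start = f$start[idx], end = f$end[idx],
                       strand = f$strand[idx], stringsAsFactors = FALSE)
    core <- core[order(core$start, core$end), , drop = FALSE]
    gaps <- if (nrow(core) > 1L)
        core$start[-1L] - core$end[-nrow(core)] - 1L else integer()
    cluster <- cumsum(c(1L, as.integer(gaps > max_gap)))
    core$cluster <- cluster
    sizes <- table(cluster)
    locus_clusters <- as.integer(names(sizes)[sizes >= min_core])
    leftover <- core[!core$cluster %in% locus_clusters, , drop = FALSE]
    free_eccA <- leftover[leftover$tag == "EccA", , drop = FALSE]
    used_eccA <- integer()
    loci <- lapply(locus_clusters, function(cl) {
        mem <- core[core$cluster == cl, , drop = FALSE]
        ## distal eccA: nearest unclustered EccA within reach, on the
        ## locus's downstream side (majority strand decides which side
        ## that is, keeping the call strand-symmetric)
        if (nrow(free_eccA)) {
            plus <- sum(mem$strand == "+") >= sum(mem$strand == "-")
            cand <- free_eccA[!free_eccA$feature %in% used_eccA, , drop = FALSE]
            cand <- if (plus) cand[cand$start > max(mem$end), , drop = FALSE]
                    else cand[cand$end < min(mem$start), , drop = FALSE]
            if (nrow(cand)) {
                d <- mapply(interval_gap, cand$start, cand$end,
                            MoreArgs = list(s2 = min(mem$start),
                                            e2 = max(mem$end)))
                j <- which.min(d)
                if (d[j] <= eccA_reach) {
                    used_eccA <<- c(used_eccA, cand$feature[j])
                    extra <- cand[j, , drop = FALSE]
                    extra$cluster <- cl
                    mem <- rbind(mem, extra)
                    mem <- mem[order(mem$start), , drop = FALSE]
                }
            }
        }
        gp <- if (nrow(mem) > 1L)
            mem$start[-1L] - mem$end[-nrow(mem)] - 1L else integer()
        tokens <- vapply(mem$tag, esx_token, character(1))
        sig_parts <- tokens[1]
        for (i in seq_along(gp)) {
            if (gp[i] > max_gap) sig_parts <- c(sig_parts, ESX_GAP_MARKER)
            sig_parts <- c(sig_parts, tokens[i + 1L])
        }
        locus <- structure(list(
            replicon_id = replicon$id,
            members = data.frame(feature = mem$feature, gene = tokens,
                                 start = mem$start, end = mem$end,
                                 stringsAsFactors = FALSE),
            span_start = min(mem$start), span_end = max(mem$end),
            n_core = nrow(mem),
            signature = paste(sig_parts, collapse = "/"),
            assigned_type = NA_character_), class = "EsxLocus")
        locus$assigned_type <- classify_esx_type(locus)
        locus
    })
    loci[order(vapply(loci, function(l) l$span_start, numeric(1)))]
}

#' Assign an ESX type from a gene-order signature
#'
#' The locus's core-gene token sequence (gap markers removed) is compared to
#' every reference signature by Levenshtein edit distance over gene-name
#' tokens; both reading directions of the locus are tried, since the genomic
#' orientation of a mobile element is arbitrary. The type with the smallest
#' distance wins; a tie between different types, or a best distance above
#' `max_dist`, yields `"untyped"`.
#'
#' @param locus An `EsxLocus` (or a signature string).
#' @param reference Reference table as [esx_reference_signatures()].
#' @param max_dist Maximum acceptable token edit distance (default 1).
#' @return The assigned type as a string.
#' @export
classify_esx_type <- function(locus, reference = esx_reference_signatures(),
                              max_dist = 1L) {
    sig <- if (inherits(locus, "EsxLocus")) locus$signature else locus
    tokens <- signature_tokens(sig)
    if (length(tokens) == 0L) return("untyped")
    fwd <- esx_letter(tokens)
    rev_ <- esx_letter(rev(tokens))
    d <- vapply(reference$signature, function(ref) {
        r <- esx_letter(signature_tokens(ref))
        min(adist(fwd, r), adist(rev_, r))
    }, numeric(1))
    best <- min(d)
    if (best > max_dist) return("untyped")
    winners <- unique(reference$type[d == best])
    if (length(winners) > 1L) return("untyped")
    winners
}

#' @export
print.EsxLocus <- function(x, ...) {
    cat(sprintf("<EsxLocus> %s:%d-%d  %s  [%s]  (%d core genes)\n",
                x$replicon_id, x$span_start, x$span_end, x$signature,
                x$assigned_type, x$n_core))
    invisible(x)
}

#' Tabulate a list of ESX loci
#'
#' @param loci List of `EsxLocus` objects.
#' @return Data frame with one row per locus.
#' @export
esx_loci_table <- function(loci) {
    if (length(loci) == 0L)
        return(data.frame(replicon_id = character(), span_start = integer(),
                          span_end = integer(), n_core = integer(),
                          signature = character(), assigned_type = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(loci, function(l)
        data.frame(replicon_id = l$replicon_id, span_start = l$span_start,
                   span_end = l$span_end, n_core = l$n_core,
                   signature = l$signature, assigned_type = l$assigned_type,
                   stringsAsFactors = FALSE)))
}

#' Derive controlled domain tags from product strings
#'
#' A convenience for annotations that carry informative product labels but
#' no explicit `domain_tags`: a synonym table of case-insensitive patterns
#' maps common product phrasings (Prokka-style) onto the controlled
#' vocabulary. Products mentioning a DDE motif or an insertion sequence are
#' tagged `transposase` rather than `integrase`, mirroring how DDE-type
#' integrase/transposase/recombinases are scored in element tables. Existing
#' tags are kept; derived tags are added.
#'
#' @param features Feature table.
#' @return The feature table with augmented `domain_tags`.
#' @export
assign_domain_tags <- function(features) {
    if (nrow(features) == 0L) return(features)
    pats <- list(
        RepA = "\\brepA?\\b|replication initiat",
        relaxase = "relaxase|mobili[sz]ation protein|\\bmobA\\b|\\bmob\\b",
        VirD4 = "virD4|type IV coupling|T4CP",
        VirB4 = "virB4",
        TcpC = "tcpC|virB8",
        DnaB_helicase = "dnaB|replicative (DNA )?helicase",
        DNA_PolI = "DNA polymerase I\\b|\\bpolA\\b",
        transposase = "transposase|\\bIS\\d|insertion sequence|DDE",
        integrase = "integrase",
        EccA = "eccA\\d?\\b",
        EccB = "eccB\\d?\\b",
        EccC = "eccC[ab]?\\d?\\b|FtsK/SpoIIIE",
        EccD = "eccD\\d?\\b",
        EccE = "eccE\\d?\\b",
        MycP = "mycP\\d?\\b|mycosin")
    tl <- tag_list(features)
    prod <- features$product
    for (i in seq_len(nrow(features))) {
        p <- prod[i]
        tags <- tl[[i]]
        hit_transposase <- grepl(pats$transposase, p, ignore.case = TRUE,
                                 perl = TRUE)
        for (tag in names(pats)) {
            if (tag == "integrase" && hit_transposase) next
            if (grepl(pats[[tag]], p, ignore.case = TRUE, perl = TRUE))
                tags <- union(tags, tag)
        }
        ## antitoxin before toxin: "antitoxin" contains "toxin"
        if (grepl("antitoxin", p, ignore.case = TRUE))
            tags <- union(tags, "TA_antitoxin")
        else if (grepl("toxin", p, ignore.case = TRUE))
            tags <- union(tags, "TA_toxin")
        if (features$ftype[i] == "tRNA" || grepl("^tRNA", p))
            tags <- union(tags, "tRNA")
        tl[[i]] <- tags[nzchar(tags)]
    }
    features$domain_tags <- vapply(tl, paste, character(1), collapse = ";")
    features
}
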