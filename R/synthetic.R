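## Synthetic replicon generator: plants every architecture the pipeline
## detects (TIRs, terminal redundancy, spanning read pairs, direct-repeat
## flanked cargo, ESX clusters, backbone gene complements) with a fully
## known truth record, so each stage is testable offline.
##
## All randomness comes from R's Mersenne-Twister via set.seed(seed), pinned
## explicitly so truth files are reproducible from the seed alone across
## platforms.

set_sim_seed <- function(seed) {
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Random DNA sequence at a target GC content
#'
#' @param n Length in bp.
#' @param gc Target GC percent.
#' @return A nucleotide string.
#' @export
random_dna <- function(n, gc = 50) {
    p <- gc / 100
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
          collapse = "")
}

## Background sequence with no unplanted repeat >= scoring_min_len at 100%
## identity (either orientation) and GC within 1 point of target;
## rejection-sampled.
background_sequence <- function(n, gc, scoring_min_len = 50L,
                                max_tries = 25L) {
    for (try in seq_len(max_tries)) {
        s <- random_dna(n, gc)
        if (abs(gc_content(s) - gc) > 1) next
        if (nrow(find_repeats(s, "direct", min_len = scoring_min_len,
                              min_identity = 100)) > 0L) next
        if (nrow(find_repeats(s, "inverted", min_len = scoring_min_len,
                              min_identity = 100)) > 0L) next
        return(s)
    }
    stop("could not generate a repeat-free background in ", max_tries,
         " attempts", call. = FALSE)
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

set_base <- function(s, pos, avoid) {
    splice_in(s, pos, sample(setdiff(c("A", "C", "G", "T"), avoid), 1))
}

## Force the bases flanking a planted direct-repeat pair to disagree, so the
## maximal window recovered by the finder is exactly the planted arm and not
## a chance extension into the background.
break_direct_flanks <- function(s, a1, a2) {
    n <- nchar(s)
    if (a1[1] > 1L && a2[1] > 1L &&
        substr(s, a1[1] - 1L, a1[1] - 1L) == substr(s, a2[1] - 1L, a2[1] - 1L))
        s <- set_base(s, a1[1] - 1L, substr(s, a2[1] - 1L, a2[1] - 1L))
    if (a1[2] < n && a2[2] < n &&
        substr(s, a1[2] + 1L, a1[2] + 1L) == substr(s, a2[2] + 1L, a2[2] + 1L))
        s <- set_base(s, a1[2] + 1L, substr(s, a2[2] + 1L, a2[2] + 1L))
    s
}

## Same for an inverted pair: the bases just inside (and outside, when they
## exist) the arms must not be complementary.
break_inverted_flanks <- function(s, a1, a2) {
    n <- nchar(s)
    p <- a1[2] + 1L; q <- a2[1] - 1L
    if (p < q &&
        substr(s, p, p) == complement_base(substr(s, q, q)))
        s <- set_base(s, p, complement_base(substr(s, q, q)))
    p0 <- a1[1] - 1L; q0 <- a2[2] + 1L
    if (p0 >= 1L && q0 <= n &&
        substr(s, p0, p0) == complement_base(substr(s, q0, q0)))
        s <- set_base(s, p0, complement_base(substr(s, q0, q0)))
    s
}

## Degrade a string with `n_mut` substitutions at distinct positions
## (interior only when possible); returns the string and the positions.
mutate_positions <- function(s, n_mut, avoid_edges = TRUE) {
    L <- nchar(s)
    if (n_mut == 0L) return(list(seq = s, pos = integer()))
    candidates <- if (avoid_edges && L > 2L) 2:(L - 1L) else seq_len(L)
    pos <- sort(sample(candidates, n_mut))
    chars <- strsplit(s, "")[[1]]
    for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    list(seq = paste(chars, collapse = ""), pos = pos)
}

#' Generate a linear plasmid with terminal inverted repeats
#'
#' Emulates the linear-plasmid architecture of mycobacterial replicons
#' (e.g. the 21,616 bp cryptic plasmid pCBMA213_3 with its 489 bp perfect
#' TIRs): a repeat-free random background with a reverse-complement repeat
#' pair planted exactly at the termini. Identity below 100% is realized as
#' the corresponding number of interior substitutions in the second arm.
#'
#' @param length Replicon length (bp); default 21616.
#' @param tir_len TIR arm length (bp); default 489.
#' @param tir_identity Planted TIR identity percent; default 100.
#' @param gc Background GC percent; default 64.
#' @param seed Integer seed; all randomness derives from it.
#' @return List with `replicon` ([AnnotatedReplicon()]) and `truth` (a
#'   `SyntheticTruth` list recording exact arm coordinates, planted identity
#'   and mutated positions).
#' @export
generate_linear_plasmid <- function(length = 21616L, tir_len = 489L,
                                    tir_identity = 100, gc = 64, seed = 1L) {
    if (2L * tir_len >= length)
        stop("infeasible: tir_len must be < length/2", call. = FALSE)
    set_sim_seed(seed)
    s <- background_sequence(length, gc)
    arm <- random_dna(tir_len, gc)
    n_mut <- floor((1 - tir_identity / 100) * tir_len + 1e-9)
    arm2 <- mutate_positions(revcomp(arm), n_mut)
    s <- splice_in(s, 1L, arm)
    s <- splice_in(s, length - tir_len + 1L, arm2$seq)
    s <- break_inverted_flanks(s, c(1L, tir_len),
                               c(length - tir_len + 1L, length))
    truth <- structure(list(
        kind = "linear_plasmid", seed = seed, length = length,
        topology = "linear",
        tir = list(arm1 = c(1L, tir_len),
                   arm2 = c(length - tir_len + 1L, length),
                   length_bp = tir_len,
                   identity_planted = 100 * (tir_len - n_mut) / tir_len,
                   n_mismatches = n_mut)), class = "SyntheticTruth")
    list(replicon = AnnotatedReplicon(sprintf("synth_linear_s%d", seed), s),
         truth = truth)
}

#' Generate a linearized circular plasmid with spanning read pairs
#'
#' Emulates the two circularity evidence channels: the sequence ends with an
#' exact copy of its first `end_overlap` bases (assembler-duplicated
#' terminus), and `n_spanning_pairs` read-pair links join the two ends with
#' outward orientations. A fraction `noise_rate` of the pairs is mispaired:
#' both mates placed uniformly at random with random orientations.
#'
#' @param length Total (linearized) length in bp.
#' @param end_overlap Duplicated terminus length (bp, < length/10); 0 for
#'   none.
#' @param n_spanning_pairs Number of planted link pairs.
#' @param noise_rate Fraction of pairs mispaired (binomially drawn).
#' @param seed Integer seed.
#' @param end_window Window at each end within which spanning mates fall.
#' @param gc Background GC percent.
#' @return List with `replicon`, `links` (read-link data frame) and `truth`
#'   (planted overlap, clean and noisy pair counts).
#' @export
generate_circular_plasmid <- function(length = 160489L, end_overlap = 77L,
                                      n_spanning_pairs = 30L,
                                      noise_rate = 0, seed = 1L,
                                      end_window = 500L, gc = 65) {
    stopifnot(end_overlap < length / 10)
    set_sim_seed(seed)
    id <- sprintf("synth_circular_s%d", seed)
    repeat {
        s <- background_sequence(length, gc)
        if (end_overlap > 0L) {
            s <- splice_in(s, length - end_overlap + 1L,
                           substr(s, 1L, end_overlap))
            if (detect_end_overlap(s, min_overlap = 15L,
                                   max_overlap = 2L * end_overlap) ==
                end_overlap) break
        } else {
            if (detect_end_overlap(s, min_overlap = 15L,
                                   max_overlap = 2000L) == 0L) break
        }
    }
    n_noise <- if (noise_rate > 0 && n_spanning_pairs > 0L)
        rbinom(1, n_spanning_pairs, noise_rate) else 0L
    n_clean <- n_spanning_pairs - n_noise
    links <- NULL
    if (n_spanning_pairs > 0L) {
        pos1 <- sample(end_window, n_spanning_pairs, replace = TRUE)
        pos2 <- sample(seq.int(length - end_window + 1L, length),
                       n_spanning_pairs, replace = TRUE)
        orient1 <- rep("-", n_spanning_pairs)
        orient2 <- rep("+", n_spanning_pairs)
        if (n_noise > 0L) {
            noisy <- sample(n_spanning_pairs, n_noise)
            pos1[noisy] <- sample(length, n_noise, replace = TRUE)
            pos2[noisy] <- sample(length, n_noise, replace = TRUE)
            orient1[noisy] <- sample(c("+", "-"), n_noise, replace = TRUE)
            orient2[noisy] <- sample(c("+", "-"), n_noise, replace = TRUE)
        }
        links <- data.frame(pair_id = sprintf("pair%04d",
                                              seq_len(n_spanning_pairs)),
                            contig = id, pos1 = pos1, pos2 = pos2,
                            orient1 = orient1, orient2 = orient2,
                            stringsAsFactors = FALSE)
    }
    truth <- structure(list(
        kind = "circular_plasmid", seed = seed, length = length,
        topology = "circular", end_overlap = end_overlap,
        n_spanning_planted = n_clean, n_noise = n_noise,
        noise_rate = noise_rate, end_window = end_window),
        class = "SyntheticTruth")
    list(replicon = AnnotatedReplicon(id, s), links = links, truth = truth)
}

## gene/cluster placement helpers ---------------------------------------------

SYNTH_GENE_LEN <- 950L
SYNTH_GENE_GAP <- 450L
SYNTH_ESX_GENE_LEN <- 900L
SYNTH_ESX_GENE_GAP <- 600L
SYNTH_ECCA_DISTANCE <- 17000L

backbone_gene_specs <- function(flags) {
    specs <- list(
        repA = list(tags = "RepA", product = "plasmid replication initiator RepA"),
        relaxase = list(tags = "relaxase", product = "MOB-family relaxase"),
        virD4 = list(tags = "VirD4", product = "type IV secretion coupling protein VirD4"),
        virB4 = list(tags = "VirB4", product = "type IV secretion ATPase VirB4"),
        tcpC = list(tags = "TcpC", product = "VirB8-like conjugal transfer protein TcpC"),
        helicase = list(tags = "DnaB_helicase", product = "replicative DNA helicase (DnaB-like)"),
        dna_polymerase = list(tags = "DNA_PolI", product = "DNA polymerase I"),
        integrase = list(tags = "integrase", product = "site-specific integrase"),
        transposase = list(tags = "transposase", product = "DDE-type transposase"))
    specs[intersect(names(specs), flags)]
}

place_esx_cluster <- function(signature, at, cluster_id) {
    tag_of <- c(eccA = "EccA", eccB = "EccB", eccC = "EccC", eccD = "EccD",
                eccE = "EccE", mycP = "MycP")
    tokens <- signature_tokens(paste(signature, collapse = "/"),
                               keep_marker = TRUE)
    rows <- list()
    pos <- as.integer(at)
    coords <- list()
    for (tok in tokens) {
        if (tok == ESX_GAP_MARKER) {
            pos <- pos + SYNTH_ECCA_DISTANCE
            next
        }
        rows[[length(rows) + 1L]] <- feature_row(
            pos, pos + SYNTH_ESX_GENE_LEN - 1L, "+", "CDS",
            product = sprintf("ESX conserved component %s",
                              sub("^e", "E", sub("^m", "M", tok))),
            tags = tag_of[[tok]])
        coords[[length(coords) + 1L]] <- c(pos, pos + SYNTH_ESX_GENE_LEN - 1L)
        pos <- pos + SYNTH_ESX_GENE_LEN + SYNTH_ESX_GENE_GAP
    }
    list(features = do.call(rbind, rows),
         span = c(min(vapply(coords, `[`, integer(1), 1)),
                  max(vapply(coords, `[`, integer(1), 2))),
         end = pos - SYNTH_ESX_GENE_GAP,
         signature = paste(tokens, collapse = "/"),
         cluster_id = cluster_id)
}

#' Generate an annotated mobile element with planted architecture
#'
#' The general element generator, defaulting to an ICE architecture at the
#' ICEMyc226 scale: a 388,440 bp circularizable molecule whose ESX cargo
#' region (first signature) is flanked by a 167 bp direct-repeat pair with an
#' IS-tagged transposase gene adjacent to the downstream arm; a second,
#' 648 bp direct-repeat pair encloses the larger conjugative-module region
#' (remaining ESX signatures plus the backbone genes placed between the
#' outer arms); domain-tagged backbone genes realize the requested flag set.
#' Passing other backbone sets produces plasmid-shaped fixtures (the
#' generator plants exactly what is asked, including contradictory flag
#' sets — the truth records the request so classifier tests can exercise
#' contradictions).
#'
#' @param length Total length (bp).
#' @param dr_len Cargo-flanking direct repeat length (bp); 0 for none.
#' @param cargo_span Length of the region between the inner DR arms (bp).
#' @param esx_signatures List of signature token vectors (may include the
#'   `-//-` marker for a distal eccA); the first is placed in the DR cargo,
#'   the rest upstream. `list()` for no ESX loci.
#' @param backbone Character vector of flags to realize; any of
#'   `repA, relaxase, virD4, virB4, tcpC, helicase, dna_polymerase,
#'   integrase, transposase, trna_genes, toxin_antitoxin`.
#' @param seed Integer seed.
#' @param dr2_len Outer direct repeat length (bp); 0 for none.
#' @param end_overlap Duplicated terminus length (bp); 0 for none.
#' @param tir_len Terminal inverted repeat length (bp); 0 for none.
#' @param n_trna tRNA genes planted when `trna_genes` is requested.
#' @param gc Background GC percent.
#' @return List with `replicon`, `links` (`NULL`), and `truth` recording DR
#'   arm coordinates, ESX member coordinates and signatures, backbone flag
#'   set and feature placement.
#' @export
generate_ice <- function(length = 388440L, dr_len = 167L,
                         cargo_span = 40000L,
                         esx_signatures = list(
                             c("eccE", "eccB", "eccD", "eccC", "eccD", "mycP",
                               "-//-", "eccA"),
                             c("eccC", "eccB", "eccD", "mycP", "eccE",
                               "-//-", "eccA")),
                         backbone = c("relaxase", "virD4", "virB4", "tcpC",
                                      "helicase", "transposase",
                                      "toxin_antitoxin"),
                         seed = 1L, dr2_len = 648L, end_overlap = 100L,
                         tir_len = 0L, n_trna = 3L, gc = 64) {
    if (dr_len > 0L && cargo_span + 2L * dr_len >= length)
        stop("infeasible: cargo_span + 2*dr_len must be < length",
             call. = FALSE)
    set_sim_seed(seed)
    id <- sprintf("synth_element_s%d", seed)
    s <- background_sequence(length, gc)
    features <- empty_features()
    truth <- list(kind = "element", seed = seed, length = length,
                  backbone = backbone, esx = list(), dr = list(),
                  intent = list())
    add_features <- function(f) features <<- rbind(features, f)

    cursor <- max(2000L, tir_len + 500L)
    ## backbone genes
    for (nm in names(backbone_gene_specs(backbone))) {
        spec <- backbone_gene_specs(backbone)[[nm]]
        add_features(feature_row(cursor, cursor + SYNTH_GENE_LEN - 1L, "+",
                                 "CDS", spec$product, spec$tags))
        cursor <- cursor + SYNTH_GENE_LEN + SYNTH_GENE_GAP
    }
    if ("toxin_antitoxin" %in% backbone) {
        add_features(feature_row(cursor, cursor + 300L, "+", "CDS",
                                 "type II TA system toxin", "TA_toxin"))
        cursor <- cursor + 700L
        add_features(feature_row(cursor, cursor + 300L, "+", "CDS",
                                 "type II TA system antitoxin", "TA_antitoxin"))
        cursor <- cursor + 900L
    }
    if ("trna_genes" %in% backbone && n_trna > 0L) {
        for (i in seq_len(n_trna)) {
            add_features(feature_row(cursor, cursor + 75L, "+", "tRNA",
                                     "tRNA-Gly", "tRNA"))
            cursor <- cursor + 300L
        }
    }
    cursor <- cursor + 1000L
    ## outer (DR2) left arm
    dr2_arm <- NULL
    if (dr2_len > 0L) {
        dr2_arm <- random_dna(dr2_len, gc)
        s <- splice_in(s, cursor, dr2_arm)
        dr2_a1 <- c(cursor, cursor + dr2_len - 1L)
        cursor <- cursor + dr2_len + 800L
    }
    ## the first signature goes into the DR cargo when there is one; all
    ## others (or all of them, without a DR pair) are placed sequentially
    cargo_sig <- if (dr_len > 0L && length(esx_signatures))
        esx_signatures[[1]] else NULL
    seq_sigs <- if (is.null(cargo_sig)) esx_signatures
                else esx_signatures[-1]
    if (length(seq_sigs)) {
        for (i in seq_along(seq_sigs)) {
            cl <- place_esx_cluster(seq_sigs[[i]], cursor, i)
            add_features(cl$features)
            truth$esx[[length(truth$esx) + 1L]] <-
                list(signature = cl$signature,
                     span = c(min(cl$features$start), max(cl$features$end)))
            ## keep the distal eccA of this cluster out of single-linkage
            ## range of whatever comes next
            cursor <- cl$end + 8000L
        }
    }
    ## DR1 + cargo
    if (dr_len > 0L) {
        dr_arm <- random_dna(dr_len, gc)
        dr1_a1 <- c(cursor, cursor + dr_len - 1L)
        cargo_start <- cursor + dr_len
        cargo_end <- cargo_start + cargo_span - 1L
        need <- cargo_end + dr_len + 1500L + dr2_len + 1200L +
            max(end_overlap, tir_len) + 200L
        if (need > length)
            stop(sprintf(paste0("length too small for the requested ",
                                "architecture (needs >= %d bp)"), need),
                 call. = FALSE)
        s <- splice_in(s, cursor, dr_arm)
        if (!is.null(cargo_sig)) {
            cl <- place_esx_cluster(cargo_sig, cargo_start + 800L, 1L)
            if (max(cl$features$end) > cargo_end - 500L)
                stop("cargo_span too small for the first ESX signature",
                     call. = FALSE)
            add_features(cl$features)
            truth$esx[[length(truth$esx) + 1L]] <-
                list(signature = cl$signature,
                     span = c(min(cl$features$start), max(cl$features$end)))
        } else {
            add_features(feature_row(cargo_start + 500L, cargo_start + 1500L,
                                     "+", "CDS", "hypothetical protein"))
        }
        s <- splice_in(s, cargo_end + 1L, dr_arm)
        dr1_a2 <- c(cargo_end + 1L, cargo_end + dr_len)
        s <- break_direct_flanks(s, dr1_a1, dr1_a2)
        truth$dr[[length(truth$dr) + 1L]] <-
            list(name = "DR1", length_bp = dr_len, arm1 = dr1_a1,
                 arm2 = dr1_a2, identity = 100)
        ## IS-tagged transposase adjacent to the downstream arm
        is_start <- dr1_a2[2] + 200L
        add_features(feature_row(is_start, is_start + 1199L, "+", "CDS",
                                 "IS110 family transposase", "transposase"))
        cursor <- is_start + 1200L + 1000L
    } else {
        cursor <- cursor + 1000L
    }
    ## outer (DR2) right arm
    if (dr2_len > 0L) {
        s <- splice_in(s, cursor, dr2_arm)
        dr2_a2 <- c(cursor, cursor + dr2_len - 1L)
        s <- break_direct_flanks(s, dr2_a1, dr2_a2)
        truth$dr[[length(truth$dr) + 1L]] <-
            list(name = "DR2", length_bp = dr2_len, arm1 = dr2_a1,
                 arm2 = dr2_a2, identity = 100)
        cursor <- cursor + dr2_len
    }
    if (cursor >= length - max(end_overlap, tir_len) - 100L)
        stop("length too small for the requested architecture", call. = FALSE)
    ## termini
    if (tir_len > 0L) {
        arm <- random_dna(tir_len, gc)
        s <- splice_in(s, 1L, arm)
        s <- splice_in(s, length - tir_len + 1L, revcomp(arm))
        s <- break_inverted_flanks(s, c(1L, tir_len),
                                   c(length - tir_len + 1L, length))
        truth$tir <- list(arm1 = c(1L, tir_len),
                          arm2 = c(length - tir_len + 1L, length),
                          length_bp = tir_len, identity = 100)
    }
    if (end_overlap > 0L) {
        s <- splice_in(s, length - end_overlap + 1L,
                       substr(s, 1L, end_overlap))
        truth$end_overlap <- end_overlap
    }
    if ("repA" %in% backbone &&
        any(c("relaxase", "virB4", "virD4") %in% backbone) == FALSE &&
        dr_len > 0L)
        truth$intent$note <- "repA with ICE-style repeats requested as asked"
    truth$topology <- if (end_overlap > 0L) "circular" else
        if (tir_len > 0L) "linear" else "unresolved"
    truth <- structure(truth, class = "SyntheticTruth")
    list(replicon = AnnotatedReplicon(id, s, features), links = NULL,
         truth = truth)
}

#' Write a generated fixture to disk
#'
#' Serializes a generator result as FASTA + feature TSV + link TSV + truth
#' YAML, the formats the loaders read back — the round-trip used throughout
#' the tests.
#'
#' @param sim A list from one of the generators (`replicon`, optional
#'   `links`, `truth`).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (defaults to the replicon id).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir, prefix = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prefix <- prefix %||% sim$replicon$id
    paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
               features = file.path(dir, paste0(prefix, "_features.tsv")),
               links = file.path(dir, paste0(prefix, "_links.tsv")),
               truth = file.path(dir, paste0(prefix, "_truth.yaml")))
    dss <- Biostrings::DNAStringSet(sim$replicon$sequence)
    names(dss) <- sim$replicon$id
    Biostrings::writeXStringSet(dss, paths[["fasta"]])
    write_features_tsv(sim$replicon$features, paths[["features"]],
                       contig = sim$replicon$id)
    if (!is.null(sim$links)) write_tsv(sim$links, paths[["links"]])
    else paths <- paths[names(paths) != "links"]
    yaml::write_yaml(unclass(sim$truth), paths[["truth"]])
    invisible(paths)
}
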