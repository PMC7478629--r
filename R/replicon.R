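#' Controlled vocabulary of domain tags
#'
#' Domain tags are the interface between upstream annotation (Prokka product
#' strings, HMM domain hits) and every annotation-driven stage of the
#' pipeline. Backbone tags mark replication, conjugation, integration and
#' stability genes; the six `Ecc*`/`MycP` tags mark ESX (T7SS) core
#' components.
#'
#' @return Character vector of the accepted tags.
#' @seealso [assign_domain_tags()] to derive tags from free-text products.
#' @export
mge_tag_vocabulary <- function() {
    c("RepA", "relaxase", "VirD4", "VirB4", "TcpC",
      "DnaB_helicase", "DNA_PolI", "integrase", "transposase",
      "tRNA", "TA_toxin", "TA_antitoxin",
      "EccA", "EccB", "EccC", "EccD", "EccE", "MycP")
}

#' Construct an empty feature table
#'
#' @return A zero-row data frame with the feature columns used throughout the
#'   package: `start`, `end` (1-based inclusive), `strand` (`+`/`-`), `ftype`
#'   (`CDS`, `tRNA` or `other`), `product`, and `domain_tags`
#'   (semicolon-joined controlled tags, `""` for none).
#' @export
empty_features <- function() {
    data.frame(start = integer(), end = integer(), strand = character(),
               ftype = character(), product = character(),
               domain_tags = character(), stringsAsFactors = FALSE)
}

#' Construct a single feature row
#'
#' Convenience for building feature tables in code (tests, simulations,
#' small examples) without writing a GFF3 file.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param ftype `"CDS"`, `"tRNA"` or `"other"`.
#' @param product Free-text product label.
#' @param tags Character vector of controlled domain tags.
#' @return One-row feature data frame (see [empty_features()]).
#' @export
feature_row <- function(start, end, strand = "+", ftype = "CDS",
                        product = "hypothetical protein", tags = character()) {
    data.frame(start = as.integer(start), end = as.integer(end),
               strand = strand, ftype = ftype, product = product,
               domain_tags = paste(tags, collapse = ";"),
               stringsAsFactors = FALSE)
}

## Split the semicolon-joined tag column into a list of character vectors.
tag_list <- function(features) {
    if (nrow(features) == 0L) return(list())
    strsplit(ifelse(is.na(features$domain_tags), "", features$domain_tags), ";",
             fixed = TRUE)
}

## TRUE for each feature carrying `tag`.
has_tag <- function(features, tag) {
    vapply(tag_list(features), function(x) tag %in% x, logical(1))
}

sort_features <- function(features) {
    if (nrow(features) == 0L) return(features)
    o <- order(features$start, features$end, features$strand)
    f <- features[o, , drop = FALSE]
    rownames(f) <- NULL
    f
}

validate_features <- function(features, seq_len, id = "replicon") {
    if (nrow(features) == 0L) return(features)
    if (any(features$start > features$end))
        stop(sprintf("%s: feature with start > end (row %d)", id,
                     which(features$start > features$end)[1]), call. = FALSE)
    out <- which(features$start < 1L | features$end > seq_len)
    if (length(out))
        stop(sprintf(
            "%s: feature %d (%d-%d, %s) lies outside the contig (length %d)",
            id, out[1], features$start[out[1]], features$end[out[1]],
            features$product[out[1]], seq_len), call. = FALSE)
    bad_strand <- !features$strand %in% c("+", "-")
    if (any(bad_strand)) {
        warning(sprintf("%s: %d feature(s) with missing strand set to '+'",
                        id, sum(bad_strand)), call. = FALSE)
        features$strand[bad_strand] <- "+"
    }
    features$ftype[!features$ftype %in% c("CDS", "tRNA")] <- "other"
    ## unknown tags are rejected loudly, never silently dropped
    vocab <- mge_tag_vocabulary()
    tl <- tag_list(features)
    unknown <- unique(unlist(lapply(tl, setdiff, y = vocab)))
    unknown <- unknown[nzchar(unknown)]
    if (length(unknown)) {
        warning(sprintf("%s: unknown domain tag(s) rejected: %s", id,
                        paste(unknown, collapse = ", ")), call. = FALSE)
        features$domain_tags <- vapply(tl, function(x)
            paste(intersect(x, vocab), collapse = ";"), character(1))
    }
    sort_features(features)
}

#' Bundle a contig sequence with its annotated features
#'
#' The `AnnotatedReplicon` is the unit every pipeline stage consumes: one
#' contig's nucleotide sequence plus an ordered feature table. Sequences are
#' uppercased and restricted to `{A,C,G,T,N}`; features are checked against
#' the contig bounds, sorted by start (ties by end, then strand), and their
#' `domain_tags` screened against [mge_tag_vocabulary()].
#'
#' @param id Contig identifier.
#' @param sequence Nucleotide string.
#' @param features Feature table as produced by [empty_features()].
#' @param source_path Provenance string (file of origin), optional.
#' @return An object of class `AnnotatedReplicon`: a list with elements
#'   `id`, `sequence`, `features`, `source_path`.
#' @examples
#' rep <- AnnotatedReplicon("ctg1", "ACGTACGTACGT")
#' nchar(rep$sequence)
#' @export
AnnotatedReplicon <- function(id, sequence, features = empty_features(),
                              source_path = NA_character_) {
    sequence <- clean_sequence(sequence, what = id)
    features <- validate_features(features, nchar(sequence), id = id)
    structure(list(id = id, sequence = sequence, features = features,
                   source_path = source_path),
              class = "AnnotatedReplicon")
}

#' @export
print.AnnotatedReplicon <- function(x, ...) {
    cat(sprintf("<AnnotatedReplicon> %s: %s bp, %d feature(s)\n",
                x$id, format(nchar(x$sequence), big.mark = ","),
                nrow(x$features)))
    invisible(x)
}

#' @export
length.AnnotatedReplicon <- function(x) nchar(x$sequence)

#' Reverse-complement a replicon and mirror its features
#'
#' Used mainly by the strand-symmetry checks: coordinates are mirrored,
#' strands flipped, and the feature order re-sorted.
#'
#' @param replicon An [AnnotatedReplicon()].
#' @return The reversed replicon.
#' @export
reverse_replicon <- function(replicon) {
    n <- nchar(replicon$sequence)
    f <- replicon$features
    if (nrow(f) > 0L) {
        new_start <- n - f$end + 1L
        new_end <- n - f$start + 1L
        f$start <- new_start
        f$end <- new_end
        f$strand <- ifelse(f$strand == "+", "-", "+")
    }
    AnnotatedReplicon(replicon$id, revcomp(replicon$sequence), f,
                      replicon$source_path)
}
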