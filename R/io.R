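## Reading and writing the external formats: FASTA, GFF3, the TSV feature
## dialect, read-link tables, and the element report.

#' Read contigs from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_replicon_fasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
    set <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(set)
    ## keep only the first whitespace-delimited token of each header
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    vapply(seq_along(seqs), function(i)
        clean_sequence(seqs[[i]], what = names(seqs)[i]), character(1),
        USE.NAMES = FALSE) -> cleaned
    names(cleaned) <- names(seqs)
    cleaned
}

## ---- feature tables ---------------------------------------------------------

## The TSV feature dialect (v1): tab-separated with header
##   contig  start  end  strand  ftype  product  domain_tags
## domain_tags semicolon-joined, empty allowed. Lines starting with '#' are
## comments. Coordinates 1-based inclusive, as everywhere in this package.
FEATURE_TSV_COLUMNS <- c("contig", "start", "end", "strand", "ftype",
                         "product", "domain_tags")

#' Read the TSV feature dialect
#'
#' @param path Tab-separated feature file with columns `contig`, `start`,
#'   `end`, `strand`, `ftype`, `product`, `domain_tags` (semicolon-joined).
#' @return Data frame with those columns.
#' @export
read_features_tsv <- function(path) {
    if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
    df <- read.delim(path, comment.char = "#", header = TRUE,
                     colClasses = "character", blank.lines.skip = TRUE)
    missing <- setdiff(FEATURE_TSV_COLUMNS, names(df))
    if (length(missing))
        stop("feature TSV is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    df <- df[, FEATURE_TSV_COLUMNS]
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    df$domain_tags[is.na(df$domain_tags)] <- ""
    df
}

#' Read features from GFF3
#'
#' Thin wrapper over [rtracklayer::import()]. The feature type is taken from
#' the GFF3 `type` column (`CDS` and `tRNA` kept, everything else `other`),
#' the label from the `product` attribute, and controlled tags from a
#' `domain_tags` attribute (comma- or semicolon-separated).
#'
#' @param path GFF3 file.
#' @return Data frame in the same shape as [read_features_tsv()].
#' @export
read_features_gff3 <- function(path) {
    if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    get_attr <- function(name) {
        if (!name %in% names(md)) return(rep("", length(gr)))
        v <- md[[name]]
        if (is.list(v) || inherits(v, "List"))
            v <- vapply(as.list(v), function(x)
                paste(as.character(x), collapse = ","), character(1))
        v <- as.character(v)
        v[is.na(v)] <- ""
        v
    }
    strand <- as.character(BiocGenerics::strand(gr))
    strand[!strand %in% c("+", "-")] <- "+"
    tags <- gsub(",", ";", get_attr("domain_tags"), fixed = TRUE)
    data.frame(contig = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr),
               end = BiocGenerics::end(gr),
               strand = strand,
               ftype = as.character(md$type),
               product = get_attr("product"),
               domain_tags = tags,
               stringsAsFactors = FALSE)
}

#' Load annotated replicons from FASTA plus a feature file
#'
#' The main entry point for external data: one [AnnotatedReplicon()] per
#' FASTA contig, carrying the features whose `contig` column resolves to it.
#' The feature file may be GFF3 (`.gff`/`.gff3`) or the documented TSV
#' dialect; contigs with no features are kept with an empty table. A feature
#' that references an unknown contig, or whose coordinates fall outside its
#' contig, is a fatal error.
#'
#' @param fasta_path FASTA file of assembled contigs.
#' @param features_path Feature file (GFF3 or TSV), or `NULL` for none.
#' @return List of [AnnotatedReplicon()], named by contig id.
#' @export
load_annotated_replicon <- function(fasta_path, features_path = NULL) {
    seqs <- read_replicon_fasta(fasta_path)
    feats <- if (is.null(features_path)) {
        cbind(contig = character(), empty_features())
    } else if (grepl("\\.gff3?$", features_path, ignore.case = TRUE)) {
        read_features_gff3(features_path)
    } else {
        read_features_tsv(features_path)
    }
    unknown <- setdiff(unique(feats$contig), names(seqs))
    if (length(unknown)) {
        i <- which(feats$contig == unknown[1])[1]
        stop(sprintf(
            "feature row %d (%s %d-%d, %s) references unknown contig '%s'",
            i, feats$contig[i], feats$start[i], feats$end[i], feats$product[i],
            unknown[1]), call. = FALSE)
    }
    out <- lapply(names(seqs), function(id) {
        f <- feats[feats$contig == id, setdiff(names(feats), "contig"),
                   drop = FALSE]
        rownames(f) <- NULL
        AnnotatedReplicon(id, seqs[[id]], f, source_path = fasta_path)
    })
    names(out) <- names(seqs)
    out
}

#' Read paired-read linkage evidence
#'
#' Read pairs arrive as a tab-separated table (`pair_id`, `contig`, `pos1`,
#' `pos2`, `orient1`, `orient2`), one row per pair, positions 1-based. This
#' abstracts mapped mate positions without requiring SAM/BAM.
#'
#' @param path TSV file of read-pair links.
#' @return Data frame of links.
#' @export
read_read_links <- function(path) {
    if (!file.exists(path)) stop("read-link file not found: ", path, call. = FALSE)
    df <- read.delim(path, comment.char = "#", header = TRUE,
                     stringsAsFactors = FALSE)
    need <- c("pair_id", "contig", "pos1", "pos2", "orient1", "orient2")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("read-link TSV is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    df$pos1 <- as.integer(df$pos1)
    df$pos2 <- as.integer(df$pos2)
    df[, need]
}

## ---- writers ----------------------------------------------------------------

write_tsv <- function(df, path) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    ok <- try(write.table(df, path, sep = "\t", quote = FALSE,
                          row.names = FALSE, col.names = TRUE), silent = TRUE)
    if (inherits(ok, "try-error"))
        stop("cannot write to ", path, call. = FALSE)
    invisible(path)
}

#' Write a feature table in the TSV dialect
#'
#' @param features Feature table with a `contig` column (or a single
#'   replicon's table plus `contig=`).
#' @param path Output file.
#' @param contig Contig id used when `features` lacks a `contig` column.
#' @return The path, invisibly.
#' @export
write_features_tsv <- function(features, path, contig = NULL) {
    if (!"contig" %in% names(features)) {
        stopifnot(!is.null(contig))
        features$contig <- rep(contig, length.out = nrow(features))
    }
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# mgescout feature table v1", con)
    suppressWarnings(write.table(features[, FEATURE_TSV_COLUMNS], con,
                                 sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

ELEMENT_REPORT_COLUMNS <- c("element", "size_bp", "gc_percent", "n_cds",
                            "topology", "repA", "relaxase", "virD4", "virB4",
                            "tcpC", "helicase", "dna_polymerase", "integrase",
                            "transposase", "trna_genes", "t7ss",
                            "toxin_antitoxin", "classification")

#' Write the element feature-matrix report
#'
#' One row per element with the per-replicon statistics, the presence/absence
#' feature matrix (0/1), and the derived classification — the same row set a
#' mobilome summary table prints (size, GC, CDS count, topology, repA,
#' relaxase, virD4, virB4, tcpC, helicase, DNA polymerase, integrase,
#' transposase, tRNA genes, T7SS, toxin-antitoxin). GC is reported rounded
#' half-up to the integer percent.
#'
#' @param profiles List of `ElementProfile` objects from [build_profile()].
#' @param out_path Output TSV path.
#' @return The output path, invisibly.
#' @export
write_element_report <- function(profiles, out_path) {
    rows <- lapply(profiles, profile_report_row)
    df <- if (length(rows)) do.call(rbind, rows) else
        as.data.frame(setNames(rep(list(character(0)), length(ELEMENT_REPORT_COLUMNS)),
                               ELEMENT_REPORT_COLUMNS))
    write_tsv(df[, ELEMENT_REPORT_COLUMNS, drop = FALSE], out_path)
}
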