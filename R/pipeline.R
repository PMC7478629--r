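#' Pipeline parameter defaults
#'
#' All tunables in one nested list, overridable programmatically or from a
#' YAML config file. Defaults: genome-wide repeat scans report arms of at
#' least 100 bp (the conventional scan window) at 100% identity; TIR scans
#' go down to 50 bp arms within 100 bp of the termini at 95% identity
#' (assembly ends are ragged); topology calls need a 20-2000 bp exact end
#' overlap or 3 spanning pairs within 500 bp end windows; ESX clustering
#' allows 6 kb between consecutive core genes, needs 4 of them, and attaches
#' a distal eccA up to 20 kb away (mobile-element loci place it ~17 kb out);
#' element boundaries use exact (100% identity) direct repeats with a transposase
#' within 1 kb; segment comparison chains 21-mers with 2 kb gaps into
#' segments of >= 1 kb.
#'
#' @param config Optional YAML file or named list of overrides (nested,
#'   partial).
#' @return Nested parameter list.
#' @export
mge_params <- function(config = NULL) {
    p <- list(
        repeats = list(k = 21L, min_len = 100L, min_identity = 100),
        tir = list(min_len = 50L, max_offset = 100L, min_identity = 95),
        topology = list(min_overlap = 20L, max_overlap = 2000L,
                        spanning_threshold = 3L, end_window = 500L),
        esx = list(max_gap = 6000L, min_core = 4L, eccA_reach = 20000L,
                   type_max_dist = 1L),
        classify = list(ta_max_intervening = 1L, dr_min_len = 100L,
                        dr_min_identity = 100, max_adjacency = 1000L),
        compare = list(k = 21L, min_segment = 1000L, min_identity = 70,
                       max_gap = 2000L))
    if (is.null(config)) return(p)
    ov <- if (is.character(config)) yaml::read_yaml(config) else config
    modifyList(p, ov)
}

#' Run the full mobilome characterization pipeline
#'
#' For every replicon: per-replicon statistics, topology call (terminal
#' redundancy, spanning read pairs, TIR), ESX locus calling and typing,
#' the element feature matrix with classification, genome-wide direct-repeat
#' detection, and delimitation of candidate integrated regions.
#'
#' @param replicons List of [AnnotatedReplicon()] (or a single one).
#' @param links Optional read-link data frame covering any of the contigs.
#' @param params Parameters from [mge_params()].
#' @param verbose Log stage progress and counts via [message()].
#' @return List of class `mge_scan` with `profiles` (list of
#'   `ElementProfile`), `topology` (data frame), `esx` (data frame),
#'   `regions` (data frame), `repeats` (direct-repeat data frame).
#' @export
scan_mobilome <- function(replicons, links = NULL, params = mge_params(),
                          verbose = FALSE) {
    if (inherits(replicons, "AnnotatedReplicon")) replicons <- list(replicons)
    say <- function(...) if (verbose) message(sprintf(...))
    profiles <- list()
    topo_rows <- list(); esx_rows <- list(); region_rows <- list()
    repeat_rows <- list()
    for (rep in replicons) {
        say("scanning %s (%d bp, %d features)", rep$id, nchar(rep$sequence),
            nrow(rep$features))
        topo <- call_topology(rep, links, params)
        say("  topology: %s", topo$verdict)
        loci <- call_esx_loci(rep, max_gap = params$esx$max_gap,
                              min_core = params$esx$min_core,
                              eccA_reach = params$esx$eccA_reach)
        say("  ESX loci: %d", length(loci))
        prof <- build_profile(rep, topo, loci,
                              ta_max_intervening = params$classify$ta_max_intervening)
        say("  classification: %s", prof$classification)
        drs <- find_repeats(rep$sequence, "direct",
                            min_len = params$classify$dr_min_len,
                            min_identity = params$classify$dr_min_identity,
                            k = params$repeats$k)
        regions <- delimit_integrated_regions(
            rep, drs, max_adjacency = params$classify$max_adjacency,
            loci = loci, min_identity = params$classify$dr_min_identity)
        say("  direct repeats: %d; integrated-region calls: %d",
            nrow(drs), nrow(regions))
        profiles[[rep$id]] <- prof
        topo_rows[[rep$id]] <- as.data.frame(topo)
        esx_rows[[rep$id]] <- esx_loci_table(loci)
        region_rows[[rep$id]] <- regions
        if (nrow(drs))
            repeat_rows[[rep$id]] <- cbind(replicon_id = rep$id, drs)
    }
    structure(list(profiles = profiles,
                   topology = do.call(rbind, c(topo_rows,
                                               list(make.row.names = FALSE))),
                   esx = do.call(rbind, c(esx_rows,
                                          list(make.row.names = FALSE))),
                   regions = do.call(rbind, c(region_rows,
                                              list(make.row.names = FALSE))),
                   repeats = if (length(repeat_rows))
                       do.call(rbind, c(repeat_rows,
                                        list(make.row.names = FALSE)))
                   else NULL),
              class = "mge_scan")
}

#' Write all pipeline reports to a directory
#'
#' @param scan An `mge_scan` from [scan_mobilome()].
#' @param out_dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_scan_reports <- function(scan, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(element_report = file.path(out_dir, "element_report.tsv"),
               topology = file.path(out_dir, "topology.tsv"),
               esx_loci = file.path(out_dir, "esx_loci.tsv"),
               integrated_regions = file.path(out_dir,
                                              "integrated_regions.tsv"))
    write_element_report(scan$profiles, paths[["element_report"]])
    write_tsv(scan$topology, paths[["topology"]])
    write_tsv(scan$esx, paths[["esx_loci"]])
    write_tsv(scan$regions, paths[["integrated_regions"]])
    invisible(paths)
}

#' @export
print.mge_scan <- function(x, ...) {
    cat(sprintf("<mge_scan> %d replicon(s)\n", length(x$profiles)))
    for (p in x$profiles)
        cat(sprintf("  %s: %s, %s\n", p$replicon_id, p$topology,
                    p$classification))
    invisible(x)
}
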