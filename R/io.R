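## Readers and writers for the exchanged plain-text formats (bedGraph, BEDPE,
## BED segments, phased-site TSV, report JSON, YAML config) and the pipeline
## driver. All coordinates 0-based half-open; outputs sorted by (chrom, start).
##
## BEDPE dialect: columns 1-6 standard; name = orientation class; score =
## n_supporting_pairs; strands encode junction sides (head = "+", tail = "-");
## extra column 11 = median_mapq.

read_checked <- function(path, n_cols, numeric_cols, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != n_cols)
      stop(sprintf("%s:%d: expected %d tab-separated columns (%s), found %d",
                   path, i, n_cols, what, length(parts[[i]])), call. = FALSE)
    for (k in numeric_cols) {
      if (is.na(suppressWarnings(as.numeric(parts[[i]][k]))))
        stop(sprintf("%s:%d: column %d of %s must be numeric, found '%s'",
                     path, i, k, what, parts[[i]][k]), call. = FALSE)
    }
  }
  do.call(rbind, parts)
}

#' Read / write a binned read-depth track as bedGraph
#'
#' @param path File path.
#' @return `data.frame(chrom, start, end, count)`.
#' @export
read_bedgraph <- function(path) {
  m <- read_checked(path, 4L, 2:4, "bedGraph")
  if (is.null(m))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = numeric()))
  out <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                    end = as.numeric(m[, 3]), count = as.numeric(m[, 4]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname read_bedgraph
#' @param track Track `data.frame`.
#' @export
write_bedgraph <- function(track, path) {
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  utils::write.table(track[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

side_to_strand <- function(side) ifelse(side == "head", "+", "-")
strand_to_side <- function(strand) ifelse(strand == "+", "head", "tail")

#' Read / write junction calls as BEDPE
#'
#' Uses the dialect documented at the top of the package's IO layer: strand
#' columns encode the junction sides (head = `+`, tail = `-`), the name column
#' holds the orientation class, the score the supporting pair count, and an
#' 11th column the median mapping quality.
#'
#' @param path File path.
#' @return A junction-call `data.frame`.
#' @export
read_bedpe <- function(path) {
  m <- read_checked(path, 11L, c(2, 3, 5, 6, 8, 11), "BEDPE")
  if (is.null(m)) return(empty_junction_calls())
  out <- data.frame(
    chromA = m[, 1], posA = as.numeric(m[, 2]), sideA = strand_to_side(m[, 9]),
    chromB = m[, 4], posB = as.numeric(m[, 5]), sideB = strand_to_side(m[, 10]),
    class = m[, 7], n_supporting_pairs = as.numeric(m[, 8]),
    median_mapq = as.numeric(m[, 11]), stringsAsFactors = FALSE)
  bad_class <- !out$class %in% c("T-H", "H-T", "H-H", "T-T", "inter")
  if (any(bad_class))
    stop(sprintf("%s:%d: unknown junction class '%s'", path,
                 which(bad_class)[1], out$class[bad_class][1]), call. = FALSE)
  out[order(out$chromA, out$posA, out$chromB, out$posB), , drop = FALSE]
}

#' @rdname read_bedpe
#' @param calls Junction-call `data.frame`.
#' @export
write_bedpe <- function(calls, path) {
  calls <- calls[order(calls$chromA, calls$posA, calls$chromB, calls$posB), ,
                 drop = FALSE]
  support <- calls$n_supporting_pairs %||% calls$multiplicity
  mapq <- calls$median_mapq %||% rep(60, nrow(calls))
  bed <- data.frame(calls$chromA, calls$posA, calls$posA + 1,
                    calls$chromB, calls$posB, calls$posB + 1,
                    calls$class, support, side_to_strand(calls$sideA),
                    side_to_strand(calls$sideB), mapq)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write copy-number segments as BED
#'
#' Columns: chrom, start, end, name (`seg`), score = integer CN (`.` when not
#' assigned), mean, n_markers.
#'
#' @param path File path.
#' @return Segment `data.frame`.
#' @export
read_segments_bed <- function(path) {
  m <- read_checked(path, 7L, c(2, 3, 6, 7), "segments BED")
  if (is.null(m))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mean = numeric(), n_markers = integer(), cn = numeric()))
  out <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                    end = as.numeric(m[, 3]),
                    mean = as.numeric(m[, 6]),
                    n_markers = as.integer(as.numeric(m[, 7])),
                    cn = suppressWarnings(as.numeric(m[, 5])),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname read_segments_bed
#' @param segments Segment `data.frame`.
#' @export
write_segments_bed <- function(segments, path) {
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  cn <- if (is.null(segments$cn)) rep(".", nrow(segments)) else segments$cn
  bed <- data.frame(segments$chrom, segments$start, segments$end, "seg", cn,
                    segments$mean, segments$n_markers)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write phased allele counts as TSV
#'
#' Columns (with header): chrom, pos, hapA, hapB, rare (0/1).
#'
#' @param path File path.
#' @return Site `data.frame`.
#' @export
read_sites_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, "chrom\tpos\thapA\thapB\trare"))
    stop(sprintf("%s:1: expected header 'chrom pos hapA hapB rare'", path),
         call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$rare <- as.logical(d$rare)
  d[order(d$chrom, d$pos), , drop = FALSE]
}

#' @rdname read_sites_tsv
#' @param sites Site `data.frame`.
#' @export
write_sites_tsv <- function(sites, path) {
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  out <- sites[, c("chrom", "pos", "hapA", "hapB", "rare")]
  out$rare <- as.integer(out$rare)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Serialize a chromothripsis call report to JSON
#'
#' @param call A `cast_call` object.
#' @param path Output path.
#' @export
write_report_json <- function(call, path) {
  stopifnot(inherits(call, "cast_call"))
  payload <- list(schema_version = "1.0",
                  ploidy = call$ploidy,
                  chromosomes = call$table,
                  coshattered = call$coshattered,
                  config = unclass(call$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Save / load a pipeline configuration as YAML
#'
#' The configuration holds every named threshold of the pipeline plus
#' simulator/emulator parameters and seeds; `load_config(save_config(x))` is
#' the identity.
#'
#' @param config A named list (e.g. from [cast_config()], possibly extended).
#' @param path File path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run a pipeline stage
#'
#' A thin file-level driver over the package's functions, mirroring the
#' perturbation-selection-sequencing flow: `simulate` builds a genome from the
#' configured event list and writes the truth layers (event log JSON, truth CN
#' BED, truth junction BEDPE); `emit` replays the event log and writes the
#' three observable layers (bedGraph depth, BEDPE junction calls, site TSV);
#' `segment` turns depth into integer-CN segments; `call` produces the
#' chromothripsis report; `cohort` summarizes a clone table. All randomness is
#' controlled by config seeds; a line of log per stage goes to stderr.
#'
#' @param config Configuration list; see the pipeline vignette for the schema
#'   (`genome`, `events`, `emulator`, `caller`, `seed` blocks).
#' @param subcommand One of `simulate`, `emit`, `segment`, `call`, `cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(config, subcommand, out_dir = ".") {
  subcommand <- match.arg(subcommand,
                          c("simulate", "emit", "segment", "call", "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  msg <- function(...) message(sprintf("[chromocast:%s] ", subcommand),
                               sprintf(...))
  path <- function(f) file.path(out_dir, f)
  need <- function(f) {
    if (!file.exists(path(f)))
      stop(sprintf("missing input for '%s': %s", subcommand, path(f)),
           call. = FALSE)
    path(f)
  }
  spec_from_config <- function() {
    g <- config$genome
    if (is.null(g)) stop("config$genome missing", call. = FALSE)
    genome_spec(unlist(g$chrom_lengths), g$base_ploidy %||% 2L)
  }
  build_genome <- function() {
    genome <- cell_genome(spec_from_config())
    for (i in seq_along(config$events)) {
      ev <- config$events[[i]]
      ev_seed <- ev$seed %||% (seed + i)
      genome <- switch(ev$op,
        chromothripsis = simulate_chromothripsis(genome, ev$homolog,
          c(ev$region_start, ev$region_end), ev$n_breakpoints,
          ev$retention_prob, seed = ev_seed),
        bfb = simulate_bfb_cycles(genome, ev$homolog, ev$n_cycles,
          seed = ev_seed),
        wgd = apply_wgd(genome),
        simple = apply_simple_rearrangement(genome, ev$kind, ev$homolog,
          start = ev$start, end = ev$end, pos = ev$pos, partner = ev$partner,
          partner_pos = ev$partner_pos, seed = ev_seed),
        stop(sprintf("unknown event op '%s'", ev$op), call. = FALSE))
    }
    genome
  }

  written <- character()
  if (subcommand == "simulate") {
    genome <- build_genome()
    em <- config$emulator %||% list()
    bin <- em$bin_size %||% 50000
    jsonlite::write_json(genome$events, path("events.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    write_bedgraph(setNames(truth_copy_number(genome, bin)[
      , c("chrom", "start", "end", "cn_total")],
      c("chrom", "start", "end", "count")), path("truth_cn.bed"))
    write_bedpe(truth_junctions(genome), path("truth_junctions.bedpe"))
    written <- c("events.json", "truth_cn.bed", "truth_junctions.bedpe")
    msg("wrote truth layers (%d events)", length(genome$events))
  } else if (subcommand == "emit") {
    genome <- build_genome()
    em <- config$emulator %||% list()
    bin <- em$bin_size %||% 50000
    cn <- truth_copy_number(genome, bin)
    depth <- emit_read_depth(cn, em$target_coverage %||% 0.1,
                             em$read_length %||% 50,
                             genome$spec$base_ploidy, seed = seed + 101L)
    write_bedgraph(depth, path("depth.bedgraph"))
    calls <- emit_junction_calls(truth_junctions(genome),
                                 genome$spec$chrom_lengths,
                                 em$spanning_coverage %||% 25,
                                 em$position_jitter_sd %||% 300,
                                 em$fp_rate %||% 0.1,
                                 genome$spec$base_ploidy, seed = seed + 102L)
    calls <- merge_junction_calls(filter_junction_calls(calls))
    write_bedpe(calls, path("junctions.bedpe"))
    sites <- emit_phased_allele_counts(genome, em$site_density %||% 1,
                                       em$mean_depth %||% 30,
                                       seed = seed + 103L)
    write_sites_tsv(sites, path("sites.tsv"))
    written <- c("depth.bedgraph", "junctions.bedpe", "sites.tsv")
    msg("emitted depth (%d bins), %d junction calls, %d phased sites",
        nrow(depth), nrow(calls), nrow(sites))
  } else if (subcommand == "segment") {
    depth <- read_bedgraph(need("depth.bedgraph"))
    segs <- segment_read_depth(normalize_bins(depth), seed = seed + 201L)
    segs <- estimate_integer_cn(segs, config$genome$base_ploidy %||% 2L)
    write_segments_bed(segs, path("segments.bed"))
    written <- "segments.bed"
    msg("wrote %d segments", nrow(segs))
  } else if (subcommand == "call") {
    segs <- read_segments_bed(need("segments.bed"))
    jx <- read_bedpe(need("junctions.bedpe"))
    lens <- unlist(config$genome$chrom_lengths)
    cfg <- do.call(cast_config, config$caller %||% list())
    res <- call_chromothripsis(segs, jx, lens, cfg, seed = seed + 301L)
    write_report_json(res, path("report.json"))
    tsv <- res$table
    utils::write.table(tsv, path("report.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c("report.json", "report.tsv")
    msg("called %d chromothripsis chromosome(s)",
        sum(res$table$call == "chromothripsis"))
  } else if (subcommand == "cohort") {
    cohort <- utils::read.table(need("cohort.tsv"), header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    cohort$clustered <- as.logical(cohort$clustered)
    cohort$chromothripsis <- as.logical(cohort$chromothripsis)
    summ <- summarize_cohort(cohort)
    jsonlite::write_json(list(tables = summ$tables,
                              p_values = lapply(summ$tests, `[[`, "p_value")),
                         path("cohort_summary.json"), auto_unbox = TRUE,
                         digits = NA, matrix = "rowmajor")
    written <- "cohort_summary.json"
    msg("summarized %d clones", summ$n)
  }
  invisible(file.path(out_dir, written))
}
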