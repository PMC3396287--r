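# Tab-separated interchange formats. Every table written by the pipeline
# carries provenance header comments (tool version, stage, config hash);
# readers skip '#' lines.

provenance_header <- function(stage, config = NULL) {
  hash <- "none"
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(unclass_recursive(config), tf)
    hash <- unname(tools::md5sum(tf))
  }
  sprintf("# tilepeaks %s | stage=%s | config=%s",
          as.character(utils::packageVersion("tilepeaks")), stage, hash)
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  # yaml drops names on atomic vectors; serialise named vectors as maps
  if (!is.null(names(x))) return(as.list(x))
  x
}

write_tsv <- function(df, file, stage, config = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read a probe-signal table
#'
#' One file per array, tab-separated with header columns PROBE_ID,
#' CHROMOSOME, POSITION, SIGNAL_R, SIGNAL_G and optionally GC (a pair-file
#' style dialect). Positions are 0-based probe starts. On ingest, probes
#' with non-positive intensities are flagged with a warning (they are
#' rejected later by [ma_transform()]).
#'
#' @param signals probe-signal data.frame as from [simulate_array()].
#' @param file path.
#' @return `write_probe_table` returns the path; `read_probe_table` the
#'   data.frame with lower-case column names.
#' @export
write_probe_table <- function(signals, file) {
  out <- data.frame(PROBE_ID = signals$probe_id, CHROMOSOME = signals$chromosome,
                    POSITION = signals$position, SIGNAL_R = signals$signal_r,
                    SIGNAL_G = signals$signal_g)
  if (!is.null(signals$gc_fraction)) out$GC <- signals$gc_fraction
  write_tsv(out, file, "probe_table")
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(file) {
  raw <- read_tsv(file)
  needed <- c("PROBE_ID", "CHROMOSOME", "POSITION", "SIGNAL_R", "SIGNAL_G")
  if (!all(needed %in% names(raw)))
    stopf("probe file %s lacks columns: %s", file,
          paste(setdiff(needed, names(raw)), collapse = ", "))
  out <- data.frame(probe_id = as.character(raw$PROBE_ID),
                    chromosome = as.character(raw$CHROMOSOME),
                    position = as.integer(raw$POSITION),
                    signal_r = raw$SIGNAL_R, signal_g = raw$SIGNAL_G,
                    stringsAsFactors = FALSE)
  if ("GC" %in% names(raw)) out$gc_fraction <- raw$GC
  bad <- out$signal_r <= 0 | out$signal_g <= 0
  if (any(bad)) warnf("%d probe(s) in %s have non-positive intensities", sum(bad), file)
  out <- sort_by_position(out)
  rownames(out) <- NULL
  out
}

#' Write / read a promoter model table
#'
#' Tab-separated gene_id, chromosome, tss, strand and one expression column
#' per cell type. The simulation ground truth is written to a separate
#' `<file>.truth.tsv` sidecar that the analysis stages never read.
#'
#' @param model a `promoter_model` (for writing) or path (for reading).
#' @param file path of the gene table.
#' @param truth write the ground-truth sidecar too.
#' @return `write_promoter_model` the path; `read_promoter_model` a gene
#'   data.frame.
#' @export
write_promoter_model <- function(model, file, truth = TRUE) {
  g <- model$genes
  keep <- c("gene_id", "chromosome", "tss", "strand",
            grep("^expression_", names(g), value = TRUE))
  write_tsv(g[keep], file, "promoter_model", model$config)
  if (truth && !is.null(model$truth))
    write_tsv(model$truth, paste0(file, ".truth.tsv"), "ground_truth", model$config)
  invisible(file)
}

#' @rdname write_promoter_model
#' @export
read_promoter_model <- function(file) read_tsv(file)

#' Write / read a ratio track
#'
#' Tab-separated probe_id, chromosome, position, M, A, state (plus GC and
#' imputation flags when present).
#'
#' @param track a `ratio_track`; or `file` a path for reading.
#' @param file path.
#' @return `write_ratio_track` the path; `read_ratio_track` a
#'   `ratio_track`.
#' @export
write_ratio_track <- function(track, file) {
  p <- track$probes
  out <- data.frame(probe_id = p$probe_id, chromosome = p$chromosome,
                    position = p$position, M = p$m, A = p$a,
                    state = track$state)
  if (!is.null(p$gc_fraction)) out$GC <- p$gc_fraction
  if (!is.null(p$imputed)) out$imputed <- p$imputed
  attr_line <- sprintf("# array_id=%s mark=%s cell_type=%s", track$array_id,
                       track$mark, track$cell_type)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(provenance_header("ratio_track"), attr_line), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ratio_track
#' @export
read_ratio_track <- function(file) {
  hdr <- readLines(file, n = 5)
  meta <- grep("^# array_id=", hdr, value = TRUE)
  ids <- c(array_id = "track", mark = "mark", cell_type = "cellA")
  if (length(meta)) {
    kv <- regmatches(meta, gregexpr("[a-z_]+=[^ ]+", meta))[[1]]
    for (p in strsplit(kv, "=")) ids[p[1]] <- p[2]
  }
  raw <- read_tsv(file)
  probes <- data.frame(probe_id = as.character(raw$probe_id),
                       chromosome = as.character(raw$chromosome),
                       position = as.integer(raw$position),
                       m = raw$M, a = raw$A, stringsAsFactors = FALSE)
  if ("GC" %in% names(raw)) probes$gc_fraction <- raw$GC
  ratio_track(probes, unname(ids["array_id"]), unname(ids["mark"]),
              unname(ids["cell_type"]), state = raw$state[1])
}

#' Export peaks as BED6+
#'
#' Standard BED columns chrom, start, end (0-based half-open),
#' name = mark:cell_type, score = detection cutoff percentage, strand "."
#' plus extra columns n_probes, fdr, tier.
#'
#' @param peakset a `peak_set`.
#' @param file path.
#' @return The path, invisibly.
#' @export
write_peaks_bed <- function(peakset, file) {
  df <- as.data.frame(peakset)
  bed <- data.frame(chrom = df$chromosome, start = df$start, end = df$end,
                    name = paste0(attr(peakset, "mark") %||% "mark", ":",
                                  attr(peakset, "cell_type") %||% "cell"),
                    score = df$score_pct, strand = ".",
                    n_probes = df$n_probes, fdr = df$fdr, tier = df$tier)
  con <- file(file, "w")
  on.exit(close(con))
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Export assigned peaks as GFF
#'
#' GFF3-style rows (1-based inclusive coordinates) with gene, FDR and tier
#' attributes; unassigned peaks are skipped.
#'
#' @param assignment a [assign_peaks_to_tss()] result.
#' @param file path.
#' @return The path, invisibly.
#' @export
write_peaks_gff <- function(assignment, file) {
  df <- as.data.frame(assignment)
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  gff <- data.frame(
    seqid = df$chromosome, source = "tilepeaks", type = "peak",
    start = df$start + 1L, end = df$end,            # 1-based inclusive
    score = df$score_pct, strand = ".", phase = ".",
    attributes = sprintf("gene_id=%s;fdr=%.4g;tier=%s;tss_distance=%g",
                         df$gene_id, df$fdr, df$tier, df$tss_distance))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
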