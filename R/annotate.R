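#' Assign peaks uniquely to the most proximate TSS
#'
#' Promoter tiling windows overlap, so a peak can fall inside several
#' genes' tiled regions; to avoid linking one peak across numerous
#' promoters, each peak is assigned to exactly one gene. Candidate genes
#' for a peak are all genes whose strand-oriented window
#' `[tss - upstream_bp, tss + downstream_bp)` contains the peak midpoint
#' (or, with `mode = "any_overlap"`, overlaps the peak at all); among
#' candidates the gene with the smallest |midpoint - TSS| wins, with exact
#' distance ties broken deterministically in favour of the gene earlier in
#' coordinate order. Peaks with no candidate gene are reported unassigned.
#'
#' @param peakset a `peak_set` from [call_peaks()] (or a data.frame with
#'   `chromosome`, `start`, `end` and peak feature columns).
#' @param genes promoter model data.frame with `gene_id`, `chromosome`,
#'   `tss`, `strand`.
#' @param upstream_bp,downstream_bp window extents in transcription
#'   orientation (defaults tile 11.2 kb, -8.2 kb/+3 kb).
#' @param mode `"midpoint"` (default) or `"any_overlap"` window membership.
#' @return Object of class `promoter_assignment`: the peak table with
#'   added columns `gene_id` (NA when unassigned) and `tss_distance`
#'   (signed strand-oriented midpoint - TSS offset), plus the gene table
#'   and window extents in attributes.
#' @export
assign_peaks_to_tss <- function(peakset, genes, upstream_bp = 8200,
                                downstream_bp = 3000,
                                mode = c("midpoint", "any_overlap")) {
  mode <- match.arg(mode)
  if (is.null(genes) || nrow(genes) == 0) stopf("empty promoter model")
  needed <- c("gene_id", "chromosome", "tss", "strand")
  if (!all(needed %in% names(genes)))
    stopf("genes must have columns: %s", paste(needed, collapse = ", "))
  peaks <- as.data.frame(peakset)
  peaks$gene_id <- rep(NA_character_, nrow(peaks))
  peaks$tss_distance <- rep(NA_real_, nrow(peaks))
  # deterministic tie-break: earlier coordinate order wins
  genes <- genes[order(genes$chromosome, genes$tss, genes$gene_id,
                       method = "radix"), , drop = FALSE]
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chromosome == peaks$chromosome[i], , drop = FALSE]
    if (!nrow(g)) next
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    if (mode == "midpoint") {
      off <- ifelse(g$strand == "+", mid - g$tss, g$tss - mid)
      cand <- off >= -upstream_bp & off < downstream_bp
    } else {
      ws <- ifelse(g$strand == "+", g$tss - upstream_bp, g$tss - downstream_bp + 1)
      we <- ifelse(g$strand == "+", g$tss + downstream_bp, g$tss + upstream_bp + 1)
      cand <- peaks$start[i] < we & peaks$end[i] > ws
      off <- ifelse(g$strand == "+", mid - g$tss, g$tss - mid)
    }
    if (!any(cand)) next
    cg <- which(cand)
    best <- cg[which.min(abs(mid - g$tss[cg]))]  # ties: first in coord order
    peaks$gene_id[i] <- g$gene_id[best]
    peaks$tss_distance[i] <- off[best]
  }
  structure(peaks, class = c("promoter_assignment", "data.frame"),
            genes = genes, upstream_bp = upstream_bp,
            downstream_bp = downstream_bp,
            mark = attr(peakset, "mark"), cell_type = attr(peakset, "cell_type"))
}

#' Per-gene present/absent promoter calls
#'
#' Summarises an assignment into one row per gene: a promoter is called
#' enriched for the mark when it carries at least one peak at or above the
#' requested stringency tier (strict: FDR <= 0.05). Peak counts are kept
#' for reporting but are deliberately not a quantitative measure —
#' fragmentation makes them uninformative; bound area and score carry the
#' quantitative signal.
#'
#' @param assignment a [assign_peaks_to_tss()] result.
#' @param genes optional gene table (defaults to the one stored on the
#'   assignment); every gene gets a row even with zero peaks.
#' @param tier `"strict"` (FDR <= 0.05) or `"relaxed"` (FDR <= 0.2).
#' @return data.frame with one row per gene: `gene_id`, `mark`,
#'   `cell_type`, `enriched`, `n_peaks`, `total_bound_area`,
#'   `max_score_log2`, `max_score_pct`.
#' @export
call_promoter_state <- function(assignment, genes = attr(assignment, "genes"),
                                tier = c("strict", "relaxed")) {
  tier <- match.arg(tier)
  peaks <- as.data.frame(assignment)
  keep <- if (tier == "strict") peaks$tier == "strict"
          else peaks$tier %in% c("strict", "relaxed")
  peaks <- peaks[keep & !is.na(peaks$gene_id), , drop = FALSE]
  agg <- if (nrow(peaks)) {
    do.call(rbind, lapply(split(peaks, peaks$gene_id), function(p) {
      data.frame(gene_id = p$gene_id[1], n_peaks = nrow(p),
                 total_bound_area = sum(p$bound_area),
                 max_score_log2 = max(p$score_log2),
                 max_score_pct = max(p$score_pct), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(0), n_peaks = integer(0),
               total_bound_area = integer(0), max_score_log2 = numeric(0),
               max_score_pct = numeric(0))
  }
  out <- data.frame(gene_id = genes$gene_id,
                    mark = attr(assignment, "mark") %||% NA_character_,
                    cell_type = attr(assignment, "cell_type") %||% NA_character_,
                    stringsAsFactors = FALSE)
  j <- match(out$gene_id, agg$gene_id)
  out$enriched <- !is.na(j)
  out$n_peaks <- ifelse(is.na(j), 0L, agg$n_peaks[j])
  out$total_bound_area <- ifelse(is.na(j), 0L, agg$total_bound_area[j])
  out$max_score_log2 <- ifelse(is.na(j), 0, agg$max_score_log2[j])
  out$max_score_pct <- ifelse(is.na(j), 0, agg$max_score_pct[j])
  attr(out, "tier") <- tier
  out
}

#' Fraction of promoters enriched per mark
#'
#' Occupancy quality-control summary: the fraction of genes called
#' enriched, per mark and cell type, for comparison with published
#' occupancy ranges.
#'
#' @param calls promoter-call data.frame(s) from [call_promoter_state()]
#'   (a single table or a list, which is row-bound).
#' @return data.frame with `mark`, `cell_type`, `n_genes`, `n_enriched`,
#'   `fraction_enriched`.
#' @export
occupancy_summary <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  out <- do.call(rbind, lapply(
    split(calls, list(calls$mark, calls$cell_type), drop = TRUE),
    function(g) data.frame(mark = g$mark[1], cell_type = g$cell_type[1],
                           n_genes = nrow(g), n_enriched = sum(g$enriched),
                           fraction_enriched = mean(g$enriched),
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
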