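#' Default mark polarity table
#'
#' Activating marks (and RNA polymerase II) versus silencing marks; the
#' silencing marks enter the net-enrichment statistic with a negative sign.
#'
#' @return Named character vector mapping mark to
#'   `"activating"`/`"silencing"`.
#' @export
default_mark_polarity <- function() {
  c(H3K4me3 = "activating", H3ac = "activating", H3K79me2 = "activating",
    H3K36me3 = "activating", PolII = "activating",
    H3K27me3 = "silencing", H3K9me3 = "silencing")
}

#' Flatten a promoter assignment into an assigned-peak table
#'
#' Convenience for [net_enrichment()]: keeps assigned peaks of one mark
#' with the columns the integration stage consumes.
#'
#' @param assignment a [assign_peaks_to_tss()] result.
#' @return data.frame with `gene_id`, `mark`, `cell_type`, `tier`,
#'   `bound_area`, `score_log2`.
#' @export
assigned_peak_table <- function(assignment) {
  p <- as.data.frame(assignment)
  p <- p[!is.na(p$gene_id), c("gene_id", "mark", "cell_type", "tier",
                              "bound_area", "score_log2")]
  rownames(p) <- NULL
  p
}

#' Net enrichment: signed per-gene chromatin summary
#'
#' Condenses a promoter's chromatin state across all assayed marks into one
#' signed number. Every strict-tier peak contributes its bound area (bp)
#' multiplied by its log2-scale peak score; contributions are summed per
#' mark, activating-mark sums and silencing-mark sums are each divided by
#' the number of marks of that polarity present at the promoter (>= 1
#' strict peak), and the silencing side is subtracted:
#' \deqn{net = S_{act}/\max(1, n_{act}) - S_{sil}/\max(1, n_{sil})}
#' Genes bound only by activating marks therefore get positive values,
#' genes bound only by silencing marks negative values, unbound genes 0.
#' Using area x score rather than peak count makes the statistic invariant
#' to the fragmentation of one enriched region into several adjacent
#' peaks. Set `normalize = FALSE` to skip the division by the
#' per-polarity mark counts.
#'
#' @param peak_table assigned-peak table over all marks: row-bound
#'   [assigned_peak_table()] outputs (or a list of assignments, which is
#'   flattened).
#' @param genes gene table (`gene_id`, optionally an expression column);
#'   every gene gets a record.
#' @param polarity named character vector mapping each mark in
#'   `peak_table` to `"activating"`/`"silencing"`.
#' @param normalize divide each polarity sum by its number of present
#'   marks (default TRUE).
#' @param expression_col name of the expression column in `genes` to carry
#'   into the output, if present.
#' @return data.frame with one row per gene: `gene_id`, `net_enrichment`,
#'   `n_activating_present`, `n_silencing_present`, and `expression` when
#'   available.
#' @export
net_enrichment <- function(peak_table, genes, polarity = default_mark_polarity(),
                           normalize = TRUE, expression_col = NULL) {
  if (is.list(peak_table) && !is.data.frame(peak_table))
    peak_table <- do.call(rbind, lapply(peak_table, assigned_peak_table))
  unknown <- setdiff(unique(peak_table$mark), names(polarity))
  if (length(unknown))
    stopf("mark(s) with unknown polarity: %s", paste(unknown, collapse = ", "))
  p <- peak_table[peak_table$tier == "strict", , drop = FALSE]
  out <- data.frame(gene_id = genes$gene_id, net_enrichment = 0,
                    n_activating_present = 0L, n_silencing_present = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(p)) {
    p$contrib <- p$bound_area * p$score_log2
    per_mark <- stats::aggregate(contrib ~ gene_id + mark, data = p, FUN = sum)
    per_mark$polarity <- polarity[per_mark$mark]
    for (g in split(per_mark, per_mark$gene_id)) {
      i <- match(g$gene_id[1], out$gene_id)
      if (is.na(i)) next
      act <- g$contrib[g$polarity == "activating"]
      sil <- g$contrib[g$polarity == "silencing"]
      out$n_activating_present[i] <- length(act)
      out$n_silencing_present[i] <- length(sil)
      if (normalize) {
        out$net_enrichment[i] <- sum(act) / max(1, length(act)) -
          sum(sil) / max(1, length(sil))
      } else {
        out$net_enrichment[i] <- sum(act) - sum(sil)
      }
    }
  }
  if (!is.null(expression_col) && expression_col %in% names(genes))
    out$expression <- genes[[expression_col]][match(out$gene_id, genes$gene_id)]
  out
}

#' Binned correlation of net enrichment with expression
#'
#' Sorts genes by expression, groups them into consecutive bins of
#' `bin_size` genes (the last bin may be short and is flagged), and reports
#' per-bin mean expression and mean net enrichment together with the
#' Spearman rank correlation across bins — the bin-level monotone trend
#' between chromatin state and transcription.
#'
#' @param records [net_enrichment()] output carrying an `expression`
#'   column.
#' @param bin_size genes per bin.
#' @return list of class `net_expression_bins`: `bins` data.frame (`bin`,
#'   `n`, `mean_expression`, `mean_net_enrichment`, `short`) and
#'   `spearman`.
#' @export
correlate_net_with_expression <- function(records, bin_size = 100) {
  if (is.null(records$expression))
    stopf("records must carry an expression column")
  miss <- !is.finite(records$expression)
  if (mean(miss) > 0.1)
    warnf("%.1f%% of genes lack expression; they are excluded", 100 * mean(miss))
  rec <- records[!miss, , drop = FALSE]
  if (nrow(rec) < 2 * bin_size)
    stopf("need at least %d genes for bins of %d (got %d)", 2 * bin_size,
          bin_size, nrow(rec))
  rec <- rec[order(rec$expression), , drop = FALSE]
  n <- nrow(rec)
  bin <- rep(seq_len(ceiling(n / bin_size)), each = bin_size)[seq_len(n)]
  bins <- do.call(rbind, lapply(split(seq_len(n), bin), function(ix)
    data.frame(n = length(ix), mean_expression = mean(rec$expression[ix]),
               mean_net_enrichment = mean(rec$net_enrichment[ix]))))
  bins <- cbind(bin = seq_len(nrow(bins)), bins)
  bins$short <- bins$n < bin_size
  rownames(bins) <- NULL
  structure(list(
    bins = bins,
    spearman = stats::cor(bins$mean_expression, bins$mean_net_enrichment,
                          method = "spearman")
  ), class = "net_expression_bins")
}

#' @export
print.net_expression_bins <- function(x, ...) {
  cat(sprintf("net enrichment vs expression: %d bins, Spearman rho = %.3f\n",
              nrow(x$bins), x$spearman))
  print.data.frame(x$bins)
  invisible(x)
}

#' @export
plot.net_expression_bins <- function(x, ...) {
  graphics::plot(x$bins$mean_expression, x$bins$mean_net_enrichment,
                 log = "x", xlab = "bin mean expression",
                 ylab = "bin mean net enrichment", pch = 19, ...)
  invisible(x)
}

#' Peak-score change across expression fold-change categories
#'
#' Relates differential expression between two conditions to the change in
#' promoter peak scores. For each fold-change threshold t genes are
#' selected whose expression changes at least t-fold up (or down, using
#' `fc <= 1/t`), and for every mark the mean change in the promoter's
#' maximum strict-tier log2 peak score between the conditions is reported
#' (score 0 where the promoter has no strict peak). A pseudocount of
#' `pseudocount` expression units stabilises ratios near zero. Empty
#' categories are recorded with `NA`, not errors.
#'
#' @param calls1,calls2 promoter-call tables ([call_promoter_state()], all
#'   marks row-bound) for conditions 1 and 2 on a shared gene set.
#' @param expr1,expr2 named numeric vectors (names = gene ids) of
#'   expression in each condition.
#' @param thresholds fold-change thresholds; the default 1.5 to 7 in steps
#'   of 0.5 gives 12 categories per direction.
#' @param pseudocount added to expression before forming ratios.
#' @return data.frame with one row per (direction, threshold, mark):
#'   `direction`, `threshold`, `mark`, `n_genes`, `mean_delta_score`.
#' @export
fold_change_score_analysis <- function(calls1, calls2, expr1, expr2,
                                       thresholds = seq(1.5, 7, by = 0.5),
                                       pseudocount = 1) {
  if (is.list(calls1) && !is.data.frame(calls1)) calls1 <- do.call(rbind, calls1)
  if (is.list(calls2) && !is.data.frame(calls2)) calls2 <- do.call(rbind, calls2)
  genes <- intersect(names(expr1), names(expr2))
  if (!length(genes)) stopf("no shared genes between the two conditions")
  fc <- (expr2[genes] + pseudocount) / (expr1[genes] + pseudocount)
  marks <- sort(unique(c(calls1$mark, calls2$mark)))
  score_of <- function(calls, mk) {
    s <- stats::setNames(rep(0, length(genes)), genes)
    cm <- calls[calls$mark == mk & calls$enriched, , drop = FALSE]
    cm <- cm[cm$gene_id %in% genes, , drop = FALSE]
    s[cm$gene_id] <- cm$max_score_log2
    s
  }
  delta <- lapply(stats::setNames(nm = marks), function(mk)
    score_of(calls2, mk) - score_of(calls1, mk))
  out <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    do.call(rbind, lapply(thresholds, function(t) {
      sel <- if (dir == "up") fc >= t else fc <= 1 / t
      do.call(rbind, lapply(marks, function(mk) data.frame(
        direction = dir, threshold = t, mark = mk, n_genes = sum(sel),
        mean_delta_score = if (any(sel)) mean(delta[[mk]][sel]) else NA_real_,
        stringsAsFactors = FALSE)))
    }))
  }))
  rownames(out) <- NULL
  out
}
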