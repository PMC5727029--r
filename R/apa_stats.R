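#' APA statistics: 3'UTR and intronic APA calls, RE/RED, length metrics
#'
#' The central quantities: for each gene, the relative expression of two
#' isoform groups within a condition, RE = log2(distal/proximal) (with the
#' intronic PAS set playing "proximal" and the 3'UTR set "distal" in intronic
#' mode), and the relative expression difference RED = RE(treated) -
#' RE(control). Negative RED means a shift toward the proximal isoform
#' (3'UTR shortening, or intronic PAS activation). Significance of an
#' isoform switch is assessed with a replicate-pooled Fisher exact test,
#' gated by a minimum absolute change in relative isoform abundance and by
#' majority sign agreement across replicate pairs.
#'
#' @name apa_stats
NULL

#' Select the two most abundant 3'UTR PAS isoforms of a gene
#'
#' @param pos genomic positions (0-based) of the gene's 3'UTR PASs.
#' @param strand gene strand.
#' @param totals summed read counts per PAS (pooled over all samples).
#' @return list(proximal, distal): indices into `pos`, labelled by transcript
#'   orientation; NULL if fewer than two PASs. The tie for the second slot is
#'   broken toward the more distal PAS.
#' @export
select_top2_utr3 <- function(pos, strand, totals) {
  if (length(pos) < 2) return(NULL)
  # rank by reads; break ties by distal position so selection is deterministic
  distal_rank <- if (strand == "+") pos else -pos
  ord <- order(-totals, -distal_rank)
  top2 <- ord[1:2]
  upstream <- if (strand == "+") which.min(pos[top2]) else which.max(pos[top2])
  list(proximal = top2[upstream], distal = top2[3 - upstream])
}

#' RE, RED and relative-abundance change for one isoform pair
#'
#' @param prox_ctrl,dist_ctrl,prox_trt,dist_trt replicate-summed counts per
#'   condition.
#' @param pseudocount added inside the log2 ratios (default 0.5).
#' @return list(RE_ctrl, RE_trt, RED, delta_abundance); `delta_abundance` is
#'   the treated-minus-control change in the distal isoform's share of the
#'   pair (fraction points, no pseudocount); all NA when a condition has zero
#'   total.
#' @export
re_red <- function(prox_ctrl, dist_ctrl, prox_trt, dist_trt,
                   pseudocount = 0.5) {
  nc <- prox_ctrl + dist_ctrl
  nt <- prox_trt + dist_trt
  if (nc == 0 || nt == 0)
    return(list(RE_ctrl = NA_real_, RE_trt = NA_real_, RED = NA_real_,
                delta_abundance = NA_real_))
  re_c <- log2((dist_ctrl + pseudocount) / (prox_ctrl + pseudocount))
  re_t <- log2((dist_trt + pseudocount) / (prox_trt + pseudocount))
  list(RE_ctrl = re_c, RE_trt = re_t, RED = re_t - re_c,
       delta_abundance = dist_trt / nt - dist_ctrl / nc)
}

#' Test an isoform switch between conditions
#'
#' Two-sided Fisher exact test on the 2x2 table of replicate-pooled counts
#' (isoform x condition). In addition to the p-value, reports whether the
#' per-replicate-pair changes in relative abundance agree in sign with the
#' pooled change in a strict majority of pairs; callers require this
#' consistency for a significant call, which guards against single-replicate
#' artifacts that a pooled exact test cannot see.
#'
#' @param prox,dist per-sample count vectors for the two isoforms (same order
#'   as `condition`).
#' @param condition "control"/"treated" per sample.
#' @param replicate optional replicate labels pairing samples across
#'   conditions (defaults to within-condition order).
#' @return list(statistic = odds ratio, p_value, method, delta_abundance,
#'   consistent).
#' @export
test_isoform_switch <- function(prox, dist, condition, replicate = NULL) {
  ci <- condition == "control"
  ti <- condition == "treated"
  tab <- matrix(c(sum(prox[ci]), sum(dist[ci]), sum(prox[ti]), sum(dist[ti])),
                2, 2, dimnames = list(c("prox", "dist"), c("ctrl", "trt")))
  fe <- fisher_exact(tab)
  pooled <- re_red(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])$delta_abundance
  if (is.null(replicate)) {
    replicate <- integer(length(condition))
    replicate[ci] <- seq_len(sum(ci))
    replicate[ti] <- seq_len(sum(ti))
  }
  agree <- 0L; npairs <- 0L
  for (r in intersect(replicate[ci], replicate[ti])) {
    i <- which(ci & replicate == r)[1]
    j <- which(ti & replicate == r)[1]
    dc <- prox[i] + dist[i]; dt <- prox[j] + dist[j]
    if (dc == 0 || dt == 0) next
    d <- dist[j] / dt - dist[i] / dc
    npairs <- npairs + 1L
    if (!is.na(pooled) && sign(d) == sign(pooled)) agree <- agree + 1L
  }
  consistent <- npairs > 0 && agree > npairs / 2
  list(statistic = fe$statistic, p_value = fe$p_value, method = fe$method,
       delta_abundance = pooled, consistent = consistent)
}

new_apa_events <- function(df, mode, alpha, min_delta) {
  structure(df, class = c("apa_events", "data.frame"),
            mode = mode, alpha = alpha, min_delta = min_delta)
}

#' @export
print.apa_events <- function(x, ...) {
  cat("apa_events (", attr(x, "mode"), " mode): ", nrow(x), " genes tested\n",
      sep = "")
  cat("  classes:", paste(names(table(x$class)), table(x$class),
                          sep = "=", collapse = " "), "\n")
  cat("  alpha =", attr(x, "alpha"), ", min |delta abundance| =",
      attr(x, "min_delta"), "\n")
  invisible(x)
}

#' @export
summary.apa_events <- function(object, ...) {
  cls <- table(object$class)
  out <- list(mode = attr(object, "mode"), n = nrow(object), classes = cls,
              median_RED = stats::median(object$RED, na.rm = TRUE))
  class(out) <- "summary.apa_events"
  out
}

#' @export
print.summary.apa_events <- function(x, ...) {
  cat(x$mode, "APA:", x$n, "genes;",
      paste(names(x$classes), x$classes, sep = "=", collapse = " "),
      "; median RED", signif(x$median_RED, 3), "\n")
  invisible(x)
}

gene_condition_sums <- function(counts, samples) {
  ci <- samples$condition == "control"
  cbind(ctrl = rowSums(counts[, ci, drop = FALSE]),
        trt = rowSums(counts[, !ci, drop = FALSE]))
}

#' Call per-gene 3'UTR APA events
#'
#' For every gene with at least two 3'UTR PASs and `min_gene_reads` reads on
#' its top pair, tests the proximal-vs-distal switch between conditions.
#' SHORTENED: significant with increased proximal share; LENGTHENED:
#' significant with increased distal share; NC otherwise. Significance
#' requires p < `alpha`, |delta abundance| > `min_delta` and majority sign
#' consistency across replicate pairs.
#'
#' @param mat an annotated `pas_matrix`.
#' @param alpha p-value cutoff (default 0.05).
#' @param min_delta minimum absolute change in relative abundance, in
#'   fraction points (default 0.05).
#' @param min_gene_reads minimum pooled reads on the tested pair (default 20).
#' @param pseudocount log-ratio pseudocount (default 0.5).
#' @return an `apa_events` data frame, one row per tested gene.
#' @export
call_utr3_apa <- function(mat, alpha = 0.05, min_delta = 0.05,
                          min_gene_reads = 20, pseudocount = 0.5) {
  p <- mat$pas
  rows <- which(p$region == "UTR3" & !is.na(p$gene_id))
  out <- list()
  for (gid in unique(p$gene_id[rows])) {
    ix <- rows[p$gene_id[rows] == gid]
    totals <- rowSums(mat$counts[ix, , drop = FALSE])
    sel <- select_top2_utr3(p$pos[ix], p$strand[ix[1]], totals)
    if (is.null(sel)) next
    pi <- ix[sel$proximal]; di <- ix[sel$distal]
    if (sum(mat$counts[pi, ]) + sum(mat$counts[di, ]) < min_gene_reads) next
    ts <- test_isoform_switch(mat$counts[pi, ], mat$counts[di, ],
                              mat$samples$condition, mat$samples$replicate)
    cs <- gene_condition_sums(mat$counts[c(pi, di), , drop = FALSE], mat$samples)
    rr <- re_red(cs[1, "ctrl"], cs[2, "ctrl"], cs[1, "trt"], cs[2, "trt"],
                 pseudocount)
    sig <- !is.na(ts$p_value) && !is.na(ts$delta_abundance) &&
      ts$p_value < alpha && abs(ts$delta_abundance) > min_delta && ts$consistent
    cls <- if (!sig) "NC" else if (ts$delta_abundance < 0) "SHORTENED" else "LENGTHENED"
    out[[gid]] <- data.frame(
      gene_id = gid, mode = "UTR3",
      proximal_id = p$pas_id[pi], distal_id = p$pas_id[di],
      prox_ctrl = cs[1, "ctrl"], dist_ctrl = cs[2, "ctrl"],
      prox_trt = cs[1, "trt"], dist_trt = cs[2, "trt"],
      RE_ctrl = rr$RE_ctrl, RE_trt = rr$RE_trt, RED = rr$RED,
      delta_abundance = ts$delta_abundance, p_value = ts$p_value, class = cls,
      aUTR_len = abs(p$pos[di] - p$pos[pi]),
      proximal_pos = p$pos[pi], distal_pos = p$pos[di],
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0))
  rownames(df) <- NULL
  new_apa_events(df, "UTR3", alpha, min_delta)
}

#' Call per-gene intronic APA events
#'
#' All intronic PAS isoforms combined (intronic set) are compared with all
#' 3'UTR PAS isoforms combined, exactly as proximal vs distal in
#' [call_utr3_apa()]. ACTIVATED: the intronic share increases significantly;
#' REPRESSED: it decreases. `delta_abundance` here is the change in the
#' intronic set's share, so ACTIVATED corresponds to positive delta and
#' negative RED.
#'
#' @inheritParams call_utr3_apa
#' @return an `apa_events` data frame (INTRONIC mode); `intronic_rep_pos` is
#'   the position of the gene's most-used intronic PAS.
#' @export
call_intronic_apa <- function(mat, alpha = 0.05, min_delta = 0.05,
                              min_gene_reads = 20, pseudocount = 0.5) {
  p <- mat$pas
  gset <- unique(p$gene_id[!is.na(p$gene_id)])
  out <- list()
  for (gid in gset) {
    ii <- which(p$gene_id == gid & p$region == "INTRON")
    ui <- which(p$gene_id == gid & p$region == "UTR3")
    if (!length(ii) || !length(ui)) next
    int_counts <- colSums(mat$counts[ii, , drop = FALSE])
    utr_counts <- colSums(mat$counts[ui, , drop = FALSE])
    if (sum(int_counts) + sum(utr_counts) < min_gene_reads) next
    ts <- test_isoform_switch(int_counts, utr_counts,
                              mat$samples$condition, mat$samples$replicate)
    ci <- mat$samples$condition == "control"
    ic <- sum(int_counts[ci]); it <- sum(int_counts[!ci])
    uc <- sum(utr_counts[ci]); ut <- sum(utr_counts[!ci])
    rr <- re_red(ic, uc, it, ut, pseudocount)
    # delta for the intronic share = -(delta of the "distal"=UTR3 share)
    delta_int <- if (is.na(ts$delta_abundance)) NA_real_ else -ts$delta_abundance
    sig <- !is.na(ts$p_value) && !is.na(delta_int) &&
      ts$p_value < alpha && abs(delta_int) > min_delta && ts$consistent
    cls <- if (!sig) "NC" else if (delta_int > 0) "ACTIVATED" else "REPRESSED"
    rep_i <- ii[which.max(rowSums(mat$counts[ii, , drop = FALSE]))]
    out[[gid]] <- data.frame(
      gene_id = gid, mode = "INTRONIC",
      n_intronic_pas = length(ii), n_utr3_pas = length(ui),
      intronic_ctrl = ic, utr3_ctrl = uc, intronic_trt = it, utr3_trt = ut,
      RE_ctrl = rr$RE_ctrl, RE_trt = rr$RE_trt, RED = rr$RED,
      delta_abundance = delta_int, p_value = ts$p_value, class = cls,
      intronic_rep_pos = p$pos[rep_i], intronic_rep_id = p$pas_id[rep_i],
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0))
  rownames(df) <- NULL
  new_apa_events(df, "INTRONIC", alpha, min_delta)
}

#' Read-weighted mean 3'UTR length per gene and condition
#'
#' Sum(length_i * reads_i) / Sum(reads_i) over all of a gene's 3'UTR PAS
#' isoforms, per condition, using the transcript distance from the stop codon
#' to each cleavage site as the isoform's 3'UTR length.
#'
#' @param mat an annotated `pas_matrix` (utr3_len must be set).
#' @return data.frame: gene_id, wlen_ctrl, wlen_trt, length_change
#'   (treated - control, nt); NA where a condition has zero reads.
#' @export
weighted_utr3_length <- function(mat) {
  p <- mat$pas
  rows <- which(p$region == "UTR3" & !is.na(p$utr3_len) & !is.na(p$gene_id))
  cs <- gene_condition_sums(mat$counts, mat$samples)
  out <- lapply(split(rows, p$gene_id[rows]), function(ix) {
    wmean <- function(col) {
      w <- cs[ix, col]
      if (sum(w) == 0) return(NA_real_)
      sum(p$utr3_len[ix] * w) / sum(w)
    }
    data.frame(gene_id = p$gene_id[ix[1]], wlen_ctrl = wmean("ctrl"),
               wlen_trt = wmean("trt"), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$length_change <- df$wlen_trt - df$wlen_ctrl
  df
}

#' Median 3'UTR length change per APA class
#'
#' @param wlen from [weighted_utr3_length()].
#' @param events 3'UTR `apa_events`.
#' @return data.frame: class, n, median_length_change (nt).
#' @export
length_change_by_class <- function(wlen, events) {
  m <- merge(wlen, events[, c("gene_id", "class")], by = "gene_id")
  agg <- stats::aggregate(length_change ~ class, data = m,
                          FUN = stats::median, na.action = stats::na.omit)
  n <- stats::aggregate(length_change ~ class, data = m, FUN = function(v) sum(!is.na(v)))
  data.frame(class = agg$class, n = n$length_change,
             median_length_change = agg$length_change)
}

#' aUTR-size bin analysis of RED
#'
#' Genes are divided into `n_bins` groups of approximately equal size by
#' aUTR length (the distance between their proximal and distal PAS); for
#' each bin the mean RED and its standard error are reported, with a
#' two-sided Wilcoxon rank-sum test between the extreme bins. Competition
#' between adjacent PASs predicts stronger shortening (more negative RED)
#' for longer aUTRs.
#'
#' @param events 3'UTR `apa_events` (all tested genes, not only significant
#'   ones).
#' @param n_bins number of aUTR bins (default 5).
#' @return list: `bins` (bin, n, autr_min, autr_max, mean_RED, sem),
#'   `p_value` (bin 1 vs bin `n_bins`).
#' @export
autr_bin_analysis <- function(events, n_bins = 5) {
  df <- events[is.finite(events$RED) & is.finite(events$aUTR_len), ]
  if (nrow(df) < n_bins)
    return(list(bins = NULL, p_value = NA_real_))
  bin <- ceiling(rank(df$aUTR_len, ties.method = "first") * n_bins / nrow(df))
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- df$RED[bin == b]
    data.frame(bin = b, n = length(v),
               autr_min = min(df$aUTR_len[bin == b]),
               autr_max = max(df$aUTR_len[bin == b]),
               mean_RED = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  pv <- wilcoxon_rank_sum(df$RED[bin == 1], df$RED[bin == n_bins])$p_value
  list(bins = bins, p_value = pv)
}

#' Intron-position polarity profile of intronic PAS regulation
#'
#' For genes with at least `min_introns` introns, every intronic PAS isoform
#' with at least `min_reads` reads contributes a library-size-normalized
#' log2(treated/control) usage change. Isoforms are grouped by the intron
#' ordinal of their PAS (+1, +2, MIDDLE, -2, -1), group means are
#' mean-centered (the mean of the five group means is subtracted), and the
#' +1 and -1 groups are compared by a two-sided Wilcoxon rank-sum test on
#' the isoform-level values. A 5' bias (maximal +1) is the signature of
#' regulators that preferentially license first-intron PAS usage.
#'
#' @param mat an annotated `pas_matrix`.
#' @param min_introns minimum introns per gene (default 4).
#' @param min_reads minimum total reads per PAS isoform (default 2).
#' @param pseudocount log-ratio pseudocount (default 0.5).
#' @return list: `profile` (ordinal, n, mean_log2, centered, sem),
#'   `p_value` (+1 vs -1), `size_factors`.
#' @export
intron_position_profile <- function(mat, min_introns = 4, min_reads = 2,
                                    pseudocount = 0.5) {
  sf <- estimate_size_factors(gene_totals(mat))
  norm <- sweep(mat$counts, 2, sf, "/")
  p <- mat$pas
  rows <- which(p$region == "INTRON" & !is.na(p$gene_id) &
                  p$n_introns >= min_introns &
                  rowSums(mat$counts) >= min_reads)
  ci <- mat$samples$condition == "control"
  ratio <- log2((rowSums(norm[rows, !ci, drop = FALSE]) + pseudocount) /
                  (rowSums(norm[rows, ci, drop = FALSE]) + pseudocount))
  ord <- factor(p$ordinal[rows], levels = ORDINAL_LEVELS)
  means <- tapply(ratio, ord, mean)
  centered <- means - mean(means, na.rm = TRUE)
  sem <- tapply(ratio, ord, function(v) stats::sd(v) / sqrt(length(v)))
  profile <- data.frame(ordinal = ORDINAL_LEVELS,
                        n = as.integer(table(ord)),
                        mean_log2 = as.numeric(means),
                        centered = as.numeric(centered),
                        sem = as.numeric(sem))
  pv <- if (any(ord == "+1", na.rm = TRUE) && any(ord == "-1", na.rm = TRUE)) {
    wilcoxon_rank_sum(ratio[ord == "+1"], ratio[ord == "-1"])$p_value
  } else NA_real_
  list(profile = profile, p_value = pv, size_factors = sf)
}

# gene x sample total PAS reads (genes with an assignment only)
gene_totals <- function(mat) {
  keep <- !is.na(mat$pas$gene_id)
  rowsum(mat$counts[keep, , drop = FALSE], mat$pas$gene_id[keep])
}

#' Cross-tabulate 3'UTR and intronic APA classes
#'
#' The four-quadrant bookkeeping of genes tested in both modes.
#'
#' @param utr3_events,intronic_events `apa_events` from the two modes.
#' @return a table (3'UTR class x intronic class) over shared genes.
#' @export
apa_quadrants <- function(utr3_events, intronic_events) {
  shared <- intersect(utr3_events$gene_id, intronic_events$gene_id)
  u <- utr3_events$class[match(shared, utr3_events$gene_id)]
  i <- intronic_events$class[match(shared, intronic_events$gene_id)]
  table(utr3 = factor(u, c("SHORTENED", "LENGTHENED", "NC")),
        intronic = factor(i, c("ACTIVATED", "REPRESSED", "NC")))
}

#' Write an APA events table as TSV
#' @param events an `apa_events`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
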