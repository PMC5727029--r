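#' Gene-level differential expression and APA-expression coupling
#'
#' Gene expression is quantified from reads overlapping coding regions only,
#' so that 3'UTR length changes cannot leak into the expression estimate.
#' Testing uses median-of-ratios size factors, a per-gene Welch t-test on
#' log2(normalized count + 1) and Benjamini-Hochberg FDR control, with
#' significance at fold change > `fc_cut` and FDR < `fdr_cut`.
#'
#' @name expression_de
NULL

#' Median-of-ratios size factors
#'
#' Per-sample factor = median over genes of count / geometric mean across
#' samples, using genes expressed in every sample.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors, one per column.
#' @export
estimate_size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo[use])))
  sf
}

#' Count reads overlapping gene coding regions
#'
#' A read counts toward a gene iff its alignment overlaps that gene's CDS by
#' at least 1 bp on the matching strand; reads overlapping the CDS of more
#' than one gene are discarded.
#'
#' @param sam_files SAM/BAM paths named by sample id.
#' @param models a `gene_model_set`.
#' @return gene x sample integer matrix (coding genes only).
#' @export
count_cds_reads <- function(sam_files, models) {
  if (is.null(names(sam_files)))
    names(sam_files) <- sub("\\.(sam|bam)$", "", basename(sam_files))
  coding <- Filter(function(m) m$coding, models$genes)
  cds_gr <- do.call(c, unname(lapply(coding, function(m)
    GenomicRanges::GRanges(m$chrom,
                           IRanges::IRanges(m$cds[, 1] + 1L, m$cds[, 2]),
                           strand = m$strand, gene_id = m$gene_id))))
  mat <- sapply(names(sam_files), function(smp) {
    aln <- read_alignments(sam_files[[smp]])
    hits <- GenomicAlignments::findOverlaps(aln, cds_gr, ignore.strand = FALSE)
    gid <- cds_gr$gene_id[S4Vectors::subjectHits(hits)]
    per_read <- split(gid, S4Vectors::queryHits(hits))
    uniq <- vapply(per_read, function(g) {
      u <- unique(g); if (length(u) == 1L) u else NA_character_
    }, "")
    tb <- table(factor(uniq[!is.na(uniq)], levels = names(coding)))
    as.integer(tb)
  })
  rownames(mat) <- names(coding)
  mat
}

new_de_results <- function(df, fc_cut, fdr_cut) {
  structure(df, class = c("de_results", "data.frame"),
            fc_cut = fc_cut, fdr_cut = fdr_cut)
}

#' @export
print.de_results <- function(x, ...) {
  cat("de_results:", nrow(x), "genes;",
      paste(names(table(x$class)), table(x$class), sep = "=", collapse = " "),
      "\n  thresholds: fold change >", attr(x, "fc_cut"), ", FDR <",
      attr(x, "fdr_cut"), "\n")
  invisible(x)
}

#' Gene-level differential expression test
#'
#' Size-factor normalization (median-of-ratios), per-gene two-sided Welch
#' t-test on log2(normalized count + 1), BH FDR; classes UP/DOWN require
#' FDR < `fdr_cut` and |fold change| > `fc_cut`.
#'
#' @param counts gene x sample count matrix.
#' @param condition "control"/"treated" per column.
#' @param fc_cut fold-change threshold (default 1.2).
#' @param fdr_cut FDR threshold (default 0.1).
#' @return a `de_results` data frame: gene_id, base_mean, log2_ratio,
#'   p_value, fdr, class.
#' @export
de_test <- function(counts, condition, fc_cut = 1.2, fdr_cut = 0.1) {
  stopifnot(ncol(counts) == length(condition))
  if (sum(condition == "control") < 2 || sum(condition == "treated") < 2)
    stop("de_test needs >= 2 replicates per condition")
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  lg <- log2(norm + 1)
  ci <- condition == "control"
  pv <- vapply(seq_len(nrow(lg)), function(i) {
    x <- lg[i, ci]; y <- lg[i, !ci]
    if (all(counts[i, ] == 0) || (stats::var(x) == 0 && stats::var(y) == 0))
      return(NA_real_)
    stats::t.test(y, x)$p.value
  }, 0)
  l2r <- rowMeans(lg[, !ci, drop = FALSE]) - rowMeans(lg[, ci, drop = FALSE])
  fdr <- rep(NA_real_, length(pv))
  fdr[!is.na(pv)] <- bh_fdr(pv[!is.na(pv)])
  cls <- ifelse(!is.na(fdr) & fdr < fdr_cut & abs(l2r) > log2(fc_cut),
                ifelse(l2r > 0, "UP", "DOWN"), "NC")
  df <- data.frame(gene_id = rownames(counts), base_mean = rowMeans(norm),
                   log2_ratio = l2r, p_value = pv, fdr = fdr, class = cls,
                   stringsAsFactors = FALSE, row.names = NULL)
  new_de_results(df, fc_cut, fdr_cut)
}

#' Expression change distributions by APA class
#'
#' Summarizes the gene-expression log2 ratios of genes in each APA class
#' (boxplot-ready quartiles) and tests every pair of classes with a
#' two-sided Wilcoxon rank-sum test. Used to ask whether 3'UTR or intronic
#' APA regulation is coupled to expression regulation.
#'
#' @param events an `apa_events` (either mode).
#' @param de a `de_results`.
#' @return list: `summary` (class, n, median, q1, q3), `tests`
#'   (class_a, class_b, p_value).
#' @export
apa_expression_coupling <- function(events, de) {
  m <- merge(events[, c("gene_id", "class")],
             de[, c("gene_id", "log2_ratio")], by = "gene_id")
  m <- m[is.finite(m$log2_ratio), ]
  classes <- unique(m$class)
  smry <- do.call(rbind, lapply(classes, function(cl) {
    v <- m$log2_ratio[m$class == cl]
    data.frame(class = cl, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pairs <- if (length(classes) >= 2) utils::combn(sort(classes), 2) else NULL
  tests <- if (is.null(pairs)) NULL else do.call(rbind, lapply(
    seq_len(ncol(pairs)), function(j) {
      a <- m$log2_ratio[m$class == pairs[1, j]]
      b <- m$log2_ratio[m$class == pairs[2, j]]
      p <- if (length(a) >= 2 && length(b) >= 2)
        wilcoxon_rank_sum(a, b)$p_value else NA_real_
      data.frame(class_a = pairs[1, j], class_b = pairs[2, j], p_value = p,
                 stringsAsFactors = FALSE)
    }))
  list(summary = smry, tests = tests)
}

#' Expression log2 ratios restricted to sub-gene regions
#'
#' Splits a gene at an intronic PAS and computes the treated/control log2
#' ratio separately for reads wholly mapping upstream (TSS to breakpoint) and
#' downstream (breakpoint to gene 3' end) in transcript orientation. A drop
#' confined to the downstream region is the expression signature of a
#' truncating intronic APA event.
#'
#' @param sam_files SAM/BAM paths named by sample id.
#' @param model a `gene_model`.
#' @param breakpoint 0-based genomic coordinate inside the gene span.
#' @param samples sample sheet with condition per sample.
#' @param pseudocount log-ratio pseudocount (default 0.5).
#' @return list: `upstream`, `downstream` (each: counts per condition and
#'   log2_ratio; ratio NA when both conditions lack reads in the region).
#' @export
region_restricted_ratio <- function(sam_files, model, breakpoint, samples,
                                    pseudocount = 0.5) {
  gstart <- min(model$exons[, "start"]); gend <- max(model$exons[, "end"])
  if (breakpoint < gstart || breakpoint >= gend)
    stop("breakpoint ", breakpoint, " outside gene ", model$gene_id)
  # transcript-orientation split: upstream = TSS side of the breakpoint
  up_iv <- if (model$strand == "+") c(gstart, breakpoint) else c(breakpoint + 1L, gend)
  dn_iv <- if (model$strand == "+") c(breakpoint, gend) else c(gstart, breakpoint + 1L)
  if (is.null(names(sam_files)))
    names(sam_files) <- sub("\\.(sam|bam)$", "", basename(sam_files))
  count_region <- function(iv) {
    vapply(names(sam_files), function(smp) {
      aln <- read_alignments(sam_files[[smp]])
      keep <- as.character(GenomicRanges::seqnames(aln)) == model$chrom &
        as.character(BiocGenerics::strand(aln)) == model$strand &
        BiocGenerics::start(aln) - 1L >= iv[1] & BiocGenerics::end(aln) <= iv[2]
      sum(keep)
    }, 0L)
  }
  summarize <- function(cnt) {
    ci <- samples$condition[match(names(cnt), samples$sample_id)] == "control"
    c_ctrl <- sum(cnt[ci]); c_trt <- sum(cnt[!ci])
    lr <- if (c_ctrl == 0 && c_trt == 0) NA_real_ else
      log2((c_trt + pseudocount) / (c_ctrl + pseudocount))
    list(ctrl = c_ctrl, trt = c_trt, log2_ratio = lr)
  }
  list(upstream = summarize(count_region(up_iv)),
       downstream = summarize(count_region(dn_iv)))
}

#' Correlation of expression ratios between two count platforms
#'
#' Pearson correlation of per-gene treated/control log2 ratios computed from
#' 3'-end-seq gene totals against externally supplied RNA-seq log2 ratios.
#'
#' @param threads_gene_totals gene x sample matrix of 3'-end-seq totals.
#' @param rnaseq_log2_ratios named numeric vector of RNA-seq log2 ratios.
#' @param condition condition per column of `threads_gene_totals`.
#' @param genes optional gene subset.
#' @param pseudocount log-ratio pseudocount (default 0.5).
#' @return Pearson r (NA if fewer than 3 shared genes or a constant vector).
#' @export
platform_correlation <- function(threads_gene_totals, rnaseq_log2_ratios,
                                 condition, genes = NULL, pseudocount = 0.5) {
  sf <- estimate_size_factors(threads_gene_totals)
  norm <- sweep(threads_gene_totals, 2, sf, "/")
  ci <- condition == "control"
  lr <- log2((rowSums(norm[, !ci, drop = FALSE]) + pseudocount) /
               (rowSums(norm[, ci, drop = FALSE]) + pseudocount))
  shared <- intersect(names(lr), names(rnaseq_log2_ratios))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3) return(NA_real_)
  x <- lr[shared]; y <- rnaseq_log2_ratios[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
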