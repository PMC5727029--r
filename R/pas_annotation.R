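#' PAS annotation: hexamer class, gene region, census statistics
#'
#' Genuine PASs are marked by an A[A/U]UAAA-family polyadenylation signal in
#' the 40 nt upstream of the cleavage site. Each PAS is classified by the
#' highest-priority hexamer found there (AAUAAA > AUUAAA > close variants >
#' none) and by the gene region it falls in (3'UTR of the 3'-most exon,
#' intron with transcription-order ordinal, or other).
#'
#' @name pas_annotation
NULL

#' Default close-variant set: the ten single-nucleotide substitution variants
#' of AAUAAA (DNA alphabet) beyond AAUAAA and AUUAAA commonly used in poly(A)
#' signal surveys.
#' @export
default_variant_set <- function() HEX_VARIANTS

#' Classify the poly(A) hexamer upstream of a PAS
#'
#' Searches the transcript-orientation window `window` (default -40..-1)
#' upstream of the cleavage position with priority AAUAAA > AUUAAA > any
#' member of `variant_set`; within a priority tier, the match nearest the
#' cleavage site is reported. DNA is read in RNA sense (T = U); minus-strand
#' windows are reverse-complemented. Windows truncated by a contig end are
#' searched as far as they exist.
#'
#' @param genome named list of chromosome strings.
#' @param chrom,strand,pos PAS coordinates (0-based cleavage position).
#' @param window c(from, to) offsets relative to the cleavage site.
#' @param variant_set close-variant hexamers (DNA), default
#'   [default_variant_set()].
#' @return list: `label` in {AAUAAA, AUUAAA, OTHER_VARIANT, NONE},
#'   `matched_hexamer` (RNA alphabet, "" for NONE), `offset` (transcript
#'   offset of the match start, e.g. -22, NA for NONE).
#' @export
classify_hexamer <- function(genome, chrom, strand, pos, window = c(-40, -1),
                             variant_set = default_variant_set()) {
  gc <- genome[[chrom]]
  L <- nchar(gc)
  # clamp the window to the contig
  if (strand == "+") {
    from <- max(window[1], -pos)
    to <- min(window[2], L - 1 - pos)
  } else {
    from <- max(window[1], pos - (L - 1))
    to <- min(window[2], pos)
  }
  if (to - from < 5)
    return(list(label = "NONE", matched_hexamer = "", offset = NA_integer_))
  win <- if (strand == "+") {
    substr(gc, pos + from + 1, pos + to + 1)
  } else {
    paste(revcomp_chr(strsplit(substr(gc, pos - to + 1, pos - from + 1),
                               "")[[1]]), collapse = "")
  }
  tiers <- list(AAUAAA = HEX_AAUAAA, AUUAAA = HEX_AUUAAA,
                OTHER_VARIANT = variant_set)
  for (lab in names(tiers)) {
    best <- -1L; best_hex <- ""
    for (h in tiers[[lab]]) {
      m <- gregexpr(h, win, fixed = TRUE)[[1]]
      m <- m[m > 0]
      if (length(m) && max(m) > best) {  # nearest the PAS = rightmost
        best <- max(m); best_hex <- h
      }
    }
    if (best > 0)
      return(list(label = lab,
                  matched_hexamer = chartr("T", "U", best_hex),
                  offset = from + best - 1L))
  }
  list(label = "NONE", matched_hexamer = "", offset = NA_integer_)
}

#' Annotate a PAS count matrix with hexamer classes
#'
#' @param mat a `pas_matrix`.
#' @param genome named list of chromosome strings.
#' @inheritParams classify_hexamer
#' @return the matrix with `pas$hexamer` filled in.
#' @export
annotate_hexamers <- function(mat, genome, window = c(-40, -1),
                              variant_set = default_variant_set()) {
  mat$pas$hexamer <- vapply(seq_len(nrow(mat$pas)), function(i)
    classify_hexamer(genome, mat$pas$chrom[i], mat$pas$strand[i],
                     mat$pas$pos[i], window, variant_set)$label, "")
  mat
}

#' Annotate a PAS count matrix with gene and region
#'
#' Each PAS is assigned to at most one gene (containing gene on the matching
#' strand, nearest 3'-most exon on ties) and classified by
#' [classify_position()]. PASs labelled OTHER are retained in the matrix but
#' are excluded from APA testing downstream.
#'
#' @param mat a `pas_matrix`.
#' @param models a `gene_model_set`.
#' @param utr3_extension nt downstream of the 3'-most exon still counted as
#'   3'UTR.
#' @return the matrix with gene_id, region, ordinal, utr3_len, n_introns set.
#' @export
annotate_regions <- function(mat, models, utr3_extension = 1000L) {
  p <- mat$pas
  p$gene_id <- assign_genes(models, p$chrom, p$strand, p$pos, utr3_extension)
  p$region <- "OTHER"
  p$ordinal <- NA_character_
  p$utr3_len <- NA_integer_
  p$n_introns <- NA_integer_
  for (i in which(!is.na(p$gene_id))) {
    m <- models[[p$gene_id[i]]]
    rc <- classify_position(m, p$pos[i], utr3_extension)
    p$region[i] <- rc$label
    p$ordinal[i] <- rc$intron_ordinal
    p$n_introns[i] <- m$n_introns
    if (rc$label == "UTR3") p$utr3_len[i] <- utr3_isoform_length(m, p$pos[i])
  }
  mat$pas <- p
  mat
}

#' PAS census: per-gene PAS counts, hexamer fractions, region counts
#'
#' A PAS is "detected" in a condition if it has at least `min_cluster_reads`
#' reads in at least one sample of that condition.
#'
#' @param mat an annotated `pas_matrix`.
#' @param min_cluster_reads detection threshold (default 2).
#' @return list: `region_counts` (condition x region), `hexamer_fractions`
#'   (condition x class), `pas_per_gene` (histogram over detected PASs pooled
#'   across conditions).
#' @export
census <- function(mat, min_cluster_reads = 2) {
  conds <- unique(mat$samples$condition)
  detected <- sapply(conds, function(cn) {
    cols <- mat$samples$sample_id[mat$samples$condition == cn]
    apply(mat$counts[, cols, drop = FALSE] >= min_cluster_reads, 1, any)
  })
  region_counts <- t(sapply(conds, function(cn)
    table(factor(mat$pas$region[detected[, cn]],
                 levels = c("UTR3", "INTRON", "OTHER")))))
  hex_fr <- t(sapply(conds, function(cn) {
    tb <- table(factor(mat$pas$hexamer[detected[, cn]],
                       levels = c("AAUAAA", "AUUAAA", "OTHER_VARIANT", "NONE")))
    as.numeric(tb) / max(1, sum(tb))
  }))
  colnames(hex_fr) <- c("AAUAAA", "AUUAAA", "OTHER_VARIANT", "NONE")
  any_det <- apply(detected, 1, any)
  per_gene <- table(table(mat$pas$gene_id[any_det & !is.na(mat$pas$gene_id)]))
  list(region_counts = region_counts, hexamer_fractions = hex_fr,
       pas_per_gene = per_gene)
}

#' Binomial test of region-fraction shift between conditions
#'
#' Exact two-sided binomial test of the intronic PAS count in condition A
#' against the intronic fraction expected from condition B.
#'
#' @param count_intronic_a,count_utr3_a detected PAS counts in condition A.
#' @param count_intronic_b,count_utr3_b detected PAS counts in condition B.
#' @return two-sided p-value; NA if either condition has zero total.
#' @export
region_fraction_test <- function(count_intronic_a, count_utr3_a,
                                 count_intronic_b, count_utr3_b) {
  na <- count_intronic_a + count_utr3_a
  nb <- count_intronic_b + count_utr3_b
  if (na == 0 || nb == 0) return(NA_real_)
  p0 <- count_intronic_b / nb
  # binom.test returns a logical p-value at the degenerate p = 0 boundary
  as.numeric(stats::binom.test(count_intronic_a, na, p = p0)$p.value)
}
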