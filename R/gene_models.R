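#' Gene models for APA analysis
#'
#' A gene model is one gene's strand-aware exon/intron/CDS structure, with all
#' annotated isoforms merged. Internal coordinates are 0-based half-open
#' throughout the package; file I/O converts at the boundary (GTF is 1-based
#' inclusive, BED 0-based half-open). Exons and introns are stored in
#' transcription order, i.e. reversed genomic order on the minus strand.
#'
#' @name gene_models
NULL

new_gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  # genomic order first, then flip to transcription order on minus strand
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  n <- nrow(exons)
  introns <- if (n > 1) {
    cbind(exons[-n, 2], exons[-1, 1])
  } else {
    matrix(integer(0), ncol = 2)
  }
  if (strand == "-") {
    exons <- exons[rev(seq_len(n)), , drop = FALSE]
    if (nrow(introns)) introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
  }
  colnames(exons) <- c("start", "end")
  if (nrow(introns)) colnames(introns) <- c("start", "end")
  tpe <- exons[n, ]  # last exon in transcription order
  coding <- !is.null(cds) && nrow(cds) > 0
  cds_end3 <- NA_integer_  # 0-based coordinate just past the stop codon in transcript orientation
  if (coding) {
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    cds_end3 <- if (strand == "+") max(cds[, 2]) else min(cds[, 1])
  }
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exons = exons, introns = introns, n_introns = nrow(introns),
    cds = if (coding) cds else NULL, coding = coding, cds_end3 = cds_end3,
    three_prime_most_exon = c(start = unname(tpe[1]), end = unname(tpe[2]))
  ), class = "gene_model")
}

#' Load a gene annotation from GTF
#'
#' Parses exon and CDS features, merges all isoforms per gene (exon union;
#' introns are the gaps between merged exons; the 3'-most exon is the last
#' merged exon in transcription order) and converts to internal 0-based
#' half-open coordinates. Genes lacking CDS features are flagged non-coding.
#'
#' @param path path to a GTF file (1-based inclusive coordinates).
#' @return a `gene_model_set`: a named list of gene models with a span index.
#' @export
load_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in '", path, "': ", conditionMessage(e))
  )
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (!length(gr)) stop("no exon/CDS features in ", path)
  ids <- as.character(gr$gene_id)
  models <- lapply(split(seq_along(gr), ids), function(ix) {
    g <- gr[ix]
    chroms <- unique(as.character(GenomicRanges::seqnames(g)))
    if (length(chroms) > 1L)
      stop("gene ", ids[ix[1]], " spans multiple chromosomes: ",
           paste(chroms, collapse = ","))
    strand <- unique(as.character(BiocGenerics::strand(g)))
    if (length(strand) > 1L) stop("gene ", ids[ix[1]], " has mixed strands")
    ex <- GenomicRanges::reduce(g[g$type == "exon"])
    cd <- GenomicRanges::reduce(g[g$type == "CDS"])
    # GTF 1-based inclusive -> 0-based half-open
    exm <- cbind(BiocGenerics::start(ex) - 1L, BiocGenerics::end(ex))
    cdm <- if (length(cd)) cbind(BiocGenerics::start(cd) - 1L, BiocGenerics::end(cd)) else NULL
    new_gene_model(ids[ix[1]], chroms, strand, exm, cdm)
  })
  new_gene_model_set(models)
}

new_gene_model_set <- function(models) {
  names(models) <- vapply(models, `[[`, "", "gene_id")
  span <- data.frame(
    gene_id = names(models),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    start = vapply(models, function(m) min(m$exons[, "start"]), integer(1)),
    end = vapply(models, function(m) max(m$exons[, "end"]), integer(1)),
    tpe_start = vapply(models, function(m) unname(m$three_prime_most_exon["start"]), integer(1)),
    tpe_end = vapply(models, function(m) unname(m$three_prime_most_exon["end"]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(genes = models, span = span), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  ncod <- sum(vapply(x$genes, `[[`, TRUE, "coding"))
  cat("gene_model_set:", length(x$genes), "genes (", ncod, "coding ) on",
      length(unique(x$span$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
`[[.gene_model_set` <- function(x, i) x$genes[[i]]

#' @export
length.gene_model_set <- function(x) length(x$genes)

# Ordinal labels for intron i of n (transcription order). First/last take
# precedence, then second/second-to-last from each end; everything else is
# MIDDLE. A 3-intron gene's middle intron is +2.
intron_ordinal <- function(i, n) {
  stopifnot(i >= 1, i <= n)
  if (i == 1) return("+1")
  if (i == n) return("-1")
  if (i == 2) return("+2")
  if (i == n - 1) return("-2")
  "MIDDLE"
}

ORDINAL_LEVELS <- c("+1", "+2", "MIDDLE", "-2", "-1")

#' Classify a genomic position within a gene model
#'
#' A position is `UTR3` if it lies in the 3'-most exon or within
#' `utr3_extension` nt downstream of it in transcript orientation (a PAS just
#' past the annotated gene end still belongs to the terminal 3'UTR); `INTRON`
#' with its transcription-order ordinal if it falls in an intron; `OTHER`
#' otherwise (internal exons, outside the gene).
#'
#' @param model a `gene_model`.
#' @param pos 0-based genomic coordinate on the model's chromosome.
#' @param utr3_extension nt downstream of the 3'-most exon still counted as
#'   3'UTR (default 1000).
#' @return list with `label` in {UTR3, INTRON, OTHER} and `intron_ordinal`
#'   in {+1, +2, MIDDLE, -2, -1, NA}; the ordinal is non-NA iff label is INTRON.
#' @export
classify_position <- function(model, pos, utr3_extension = 1000L) {
  tpe <- model$three_prime_most_exon
  in_utr3 <- if (model$strand == "+") {
    pos >= tpe["start"] && pos < tpe["end"] + utr3_extension
  } else {
    pos < tpe["end"] && pos >= tpe["start"] - utr3_extension
  }
  if (isTRUE(unname(in_utr3)))
    return(list(label = "UTR3", intron_ordinal = NA_character_))
  if (model$n_introns > 0) {
    for (i in seq_len(model$n_introns)) {
      iv <- model$introns[i, ]
      if (pos >= iv[1] && pos < iv[2])
        return(list(label = "INTRON",
                    intron_ordinal = intron_ordinal(i, model$n_introns)))
    }
  }
  list(label = "OTHER", intron_ordinal = NA_character_)
}

# Transcript-orientation distance (nt) from the stop codon to a cleavage
# position; the 3'UTR length of the isoform ending at `pos`. NA for
# non-coding models.
utr3_isoform_length <- function(model, pos) {
  if (!model$coding) return(NA_integer_)
  if (model$strand == "+") pos - model$cds_end3 + 1L else model$cds_end3 - pos
}

#' Assign PAS positions to genes
#'
#' Each position is assigned to at most one gene: a containing gene on the
#' matching strand (gene span extended by `utr3_extension` downstream); when
#' several genes contain it, the one whose 3'-most exon lies nearest.
#'
#' @param models a `gene_model_set`.
#' @param chrom,strand,pos parallel vectors of PAS coordinates (0-based).
#' @param utr3_extension downstream slack, as in [classify_position()].
#' @return character vector of gene ids (NA where unassigned).
#' @export
assign_genes <- function(models, chrom, strand, pos, utr3_extension = 1000L) {
  sp <- models$span
  ext_start <- ifelse(sp$strand == "+", sp$start, sp$start - utr3_extension)
  ext_end <- ifelse(sp$strand == "+", sp$end + utr3_extension, sp$end)
  out <- rep(NA_character_, length(pos))
  for (k in seq_along(pos)) {
    hit <- which(sp$chrom == chrom[k] & sp$strand == strand[k] &
                   pos[k] >= ext_start & pos[k] < ext_end)
    if (!length(hit)) next
    if (length(hit) > 1L) {
      tpe_mid <- (sp$tpe_start[hit] + sp$tpe_end[hit]) / 2
      hit <- hit[which.min(abs(pos[k] - tpe_mid))]
    }
    out[k] <- sp$gene_id[hit]
  }
  out
}

#' Export 3'-most exons and introns as BED6
#'
#' One record per 3'-most exon (name `gene|UTR3`) and per intron
#' (name `gene|<ordinal>`), scores 0, in BED 0-based half-open coordinates.
#'
#' @param models a `gene_model_set`.
#' @param path output BED path.
#' @export
export_gene_features <- function(models, path) {
  rows <- lapply(models$genes, function(m) {
    tpe <- m$three_prime_most_exon
    r <- data.frame(chrom = m$chrom, start = tpe["start"], end = tpe["end"],
                    name = paste0(m$gene_id, "|UTR3"), score = 0L,
                    strand = m$strand, stringsAsFactors = FALSE)
    if (m$n_introns > 0) {
      ords <- vapply(seq_len(m$n_introns), intron_ordinal, "", n = m$n_introns)
      r <- rbind(r, data.frame(
        chrom = m$chrom, start = m$introns[, 1], end = m$introns[, 2],
        name = paste0(m$gene_id, "|", ords), score = 0L, strand = m$strand,
        stringsAsFactors = FALSE))
    }
    r
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
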