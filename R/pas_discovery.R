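#' PAS discovery: poly(A)-site reads, clustering, filtering, quantification
#'
#' 3'-end-seq reads that carry untemplated adenosines mark genuine cleavage
#' and polyadenylation junctions. A read supports a PAS iff its tail-side
#' soft-clip (transcript orientation) is a run of A/T bases of which at least
#' `min_unaligned_t` do not match the genome. Cleavage positions are clustered
#' by single linkage at 24 nt, clusters whose downstream genomic window is
#' A-rich are discarded as internal-priming artifacts, and reads are counted
#' per cluster per sample.
#'
#' @name pas_discovery
NULL

new_pas_matrix <- function(counts, pas, samples) {
  stopifnot(nrow(counts) == nrow(pas), ncol(counts) == nrow(samples))
  structure(list(counts = counts, pas = pas, samples = samples),
            class = "pas_matrix")
}

#' @export
print.pas_matrix <- function(x, ...) {
  cat("pas_matrix:", nrow(x$counts), "PASs x", ncol(x$counts), "samples;",
      "total reads", sum(x$counts), "\n")
  if (!all(is.na(x$pas$region)))
    cat("  regions:", paste(names(table(x$pas$region)), table(x$pas$region),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.pas_matrix <- function(x) dim(x$counts)

count_char <- function(x, ch) nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))

read_alignments <- function(sam) {
  bam <- if (grepl("\\.sam$", sam)) {
    Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else sam
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "seq"))
}

#' Extract PAS-supporting reads from alignments
#'
#' A read contributes iff its tail-side soft-clip, in the configured
#' orientation, is a homopolymer of A (genomic plus side) or T (minus side)
#' with at least `min_unaligned_t` bases not matching the genome (untemplated).
#' The cleavage position is the last aligned base in transcript orientation.
#'
#' @param sam_files character vector of SAM/BAM paths, named by sample id.
#' @param genome named list of chromosome strings (see [load_genome()]).
#' @param min_unaligned_t minimum untemplated tail bases (default 2).
#' @param orientation "same" if reads align on the transcript's strand,
#'   "reverse" if the library yields reverse-complemented alignments.
#' @return data.frame: sample, chrom, strand (transcript), pos (0-based
#'   cleavage coordinate), one row per accepted read.
#' @export
extract_pas_reads <- function(sam_files, genome, min_unaligned_t = 2,
                              orientation = "same") {
  if (!orientation %in% c("same", "reverse"))
    stop("unknown orientation '", orientation, "' (use 'same' or 'reverse')")
  if (is.null(names(sam_files)))
    names(sam_files) <- sub("\\.(sam|bam)$", "", basename(sam_files))
  out <- lapply(names(sam_files), function(smp) {
    aln <- read_alignments(sam_files[[smp]])
    if (!length(aln)) return(NULL)
    cig <- GenomicAlignments::cigar(aln)
    ops <- GenomicAlignments::explodeCigarOps(cig)
    lens <- GenomicAlignments::explodeCigarOpLengths(cig)
    first_s <- mapply(function(o, l) if (o[1] == "S") l[1] else 0L, ops, lens)
    last_s <- mapply(function(o, l) {
      n <- length(o); if (o[n] == "S") l[n] else 0L
    }, ops, lens)
    if (all(first_s == 0L & last_s == 0L)) {
      warning("no soft-clipped reads in sample ", smp)
      return(NULL)
    }
    alst <- as.character(BiocGenerics::strand(aln))
    txst <- if (orientation == "same") alst else chartr("+-", "-+", alst)
    chrom <- as.character(GenomicRanges::seqnames(aln))
    st1 <- BiocGenerics::start(aln); en1 <- BiocGenerics::end(aln)
    seqs <- as.character(S4Vectors::mcols(aln)$seq)
    w <- nchar(seqs)

    keep_rows <- function(plus) {
      i <- which(txst == (if (plus) "+" else "-"))
      if (!length(i)) return(NULL)
      k <- if (plus) last_s[i] else first_s[i]
      i <- i[k > 0]; k <- k[k > 0]
      if (!length(i)) return(NULL)
      clip <- if (plus) substring(seqs[i], w[i] - k + 1, w[i])
              else substring(seqs[i], 1, k)
      base <- if (plus) "A" else "T"
      pure <- count_char(clip, base) == k
      i <- i[pure]; k <- k[pure]; clip <- clip[pure]
      if (!length(i)) return(NULL)
      # untemplated = clipped bases differing from the genomic continuation
      gseq <- vapply(seq_along(i), function(j) {
        ch <- chrom[i[j]]
        if (plus) substr(genome[[ch]], en1[i[j]] + 1, en1[i[j]] + k[j])
        else substr(genome[[ch]], max(1, st1[i[j]] - k[j]), st1[i[j]] - 1)
      }, "")
      # bases beyond the contig edge are absent from gseq and count as mismatches
      templ <- count_char(gseq, base)
      unalign <- k - as.integer(templ)
      ok <- unalign >= min_unaligned_t
      i <- i[ok]
      if (!length(i)) return(NULL)
      data.frame(sample = smp, chrom = chrom[i],
                 strand = if (plus) "+" else "-",
                 pos = if (plus) en1[i] - 1L else st1[i] - 1L,
                 stringsAsFactors = FALSE)
    }
    rbind(keep_rows(TRUE), keep_rows(FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample = character(0), chrom = character(0),
                      strand = character(0), pos = integer(0))
  out
}

#' Cluster cleavage positions into poly(A) sites
#'
#' Single-linkage clustering per chromosome and strand: two positions belong
#' to the same PAS iff they are connected by a chain of steps each at most
#' `max_gap` nt. The representative position is the member with the most
#' reads, ties broken toward the transcript-3' (distal) side.
#'
#' @param reads data.frame with chrom, strand, pos and optionally sample and
#'   count columns (default count 1 per row).
#' @param max_gap maximum nt between chained members (default 24).
#' @return a `pas_clusters` object: list with `clusters` (pas_id, chrom,
#'   strand, pos, start, end, n_positions, total_reads) and `members`
#'   (position -> pas_id map).
#' @export
cluster_pas <- function(reads, max_gap = 24) {
  if (is.null(reads$count)) reads$count <- 1L
  agg <- stats::aggregate(count ~ chrom + strand + pos, data = reads, FUN = sum)
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), ]
  key <- paste(agg$chrom, agg$strand)
  cl_rows <- list(); mem_rows <- list(); cid <- 0L
  for (k in unique(key)) {
    a <- agg[key == k, ]
    brk <- c(0L, cumsum(diff(a$pos) > max_gap))
    for (b in unique(brk)) {
      cid <- cid + 1L
      m <- a[brk == b, ]
      best <- which(m$count == max(m$count))
      rep_pos <- if (m$strand[1] == "+") max(m$pos[best]) else min(m$pos[best])
      cl_rows[[cid]] <- data.frame(
        pas_id = NA_character_, chrom = m$chrom[1], strand = m$strand[1],
        pos = rep_pos, start = min(m$pos), end = max(m$pos) + 1L,
        n_positions = nrow(m), total_reads = sum(m$count),
        stringsAsFactors = FALSE)
      mem_rows[[cid]] <- data.frame(chrom = m$chrom, strand = m$strand,
                                    pos = m$pos, cluster = cid,
                                    stringsAsFactors = FALSE)
    }
  }
  clusters <- do.call(rbind, cl_rows)
  clusters$pas_id <- sprintf("pas%05d", seq_len(nrow(clusters)))
  members <- do.call(rbind, mem_rows)
  members$pas_id <- clusters$pas_id[members$cluster]
  structure(list(clusters = clusters, members = members[c("chrom", "strand", "pos", "pas_id")]),
            class = "pas_clusters")
}

#' @export
print.pas_clusters <- function(x, ...) {
  cat("pas_clusters:", nrow(x$clusters), "clusters from",
      nrow(x$members), "distinct positions\n")
  invisible(x)
}

# count of A (transcript orientation) in the `window` nt downstream of pos;
# bases beyond the contig end count as non-A
downstream_a_count <- function(genome, chrom, strand, pos, window) {
  gc <- genome[[chrom]]
  L <- nchar(gc)
  if (strand == "+") {
    s <- substr(gc, pos + 2, min(L, pos + 1 + window))
    count_char(s, "A")
  } else {
    s <- substr(gc, max(1, pos - window + 1), pos)
    count_char(s, "T")
  }
}

#' Filter internal-priming artifact clusters
#'
#' Drops clusters whose downstream genomic window (transcript orientation)
#' contains at least `min_a` adenosines: their reads' tails were likely primed
#' on a genomic A-rich tract rather than a real poly(A) tail.
#'
#' @param x a `pas_clusters` or `pas_matrix`.
#' @param genome named list of chromosome strings.
#' @param window downstream window length in nt (default 10).
#' @param min_a A count at or above which the cluster is dropped (default 6).
#' @return the filtered object; attribute `n_dropped` reports removals.
#' @export
filter_internal_priming <- function(x, genome, window = 10, min_a = 6) {
  tab <- if (inherits(x, "pas_clusters")) x$clusters else x$pas
  acount <- vapply(seq_len(nrow(tab)), function(i)
    downstream_a_count(genome, tab$chrom[i], tab$strand[i], tab$pos[i], window),
    0L)
  keep <- acount < min_a
  if (inherits(x, "pas_clusters")) {
    x$clusters <- x$clusters[keep, ]
    x$members <- x$members[x$members$pas_id %in% x$clusters$pas_id, ]
  } else {
    x$pas <- x$pas[keep, , drop = FALSE]
    x$counts <- x$counts[keep, , drop = FALSE]
  }
  attr(x, "n_dropped") <- sum(!keep)
  x
}

#' Count PAS-supporting reads per cluster per sample
#'
#' Every accepted read increments exactly one cluster in its sample's column;
#' reads at positions not covered by any cluster are assigned to new
#' singleton clusters.
#'
#' @param clusters a `pas_clusters`.
#' @param reads data.frame from [extract_pas_reads()].
#' @param samples sample sheet; every sample in `reads` must appear.
#' @return a `pas_matrix` (gene/region metadata unset; see
#'   [annotate_regions()]).
#' @export
quantify <- function(clusters, reads, samples) {
  missing <- setdiff(unique(reads$sample), samples$sample_id)
  if (length(missing))
    stop("samples in reads absent from sample sheet: ",
         paste(missing, collapse = ", "))
  mem_key <- paste(clusters$members$chrom, clusters$members$strand,
                   clusters$members$pos)
  read_key <- paste(reads$chrom, reads$strand, reads$pos)
  pid <- clusters$members$pas_id[match(read_key, mem_key)]
  tab <- clusters$clusters
  if (anyNA(pid)) {
    orphans <- unique(reads[is.na(pid), c("chrom", "strand", "pos")])
    orphans$pas_id <- sprintf("pas_s%05d", seq_len(nrow(orphans)))
    okey <- paste(orphans$chrom, orphans$strand, orphans$pos)
    pid[is.na(pid)] <- orphans$pas_id[match(read_key[is.na(pid)], okey)]
    tab <- rbind(tab, data.frame(
      pas_id = orphans$pas_id, chrom = orphans$chrom, strand = orphans$strand,
      pos = orphans$pos, start = orphans$pos, end = orphans$pos + 1L,
      n_positions = 1L, total_reads = 0L, stringsAsFactors = FALSE))
  }
  counts <- matrix(0L, nrow(tab), nrow(samples),
                   dimnames = list(tab$pas_id, samples$sample_id))
  cnt <- table(factor(pid, levels = tab$pas_id),
               factor(reads$sample, levels = samples$sample_id))
  counts[] <- as.integer(cnt)
  tab$total_reads <- as.integer(rowSums(counts))
  pas <- data.frame(tab[c("pas_id", "chrom", "strand", "pos", "start", "end")],
                    gene_id = NA_character_, region = NA_character_,
                    ordinal = NA_character_, hexamer = NA_character_,
                    utr3_len = NA_integer_, n_introns = NA_integer_,
                    stringsAsFactors = FALSE)
  new_pas_matrix(counts, pas, samples)
}

#' Export PAS clusters as BED6
#'
#' @param x a `pas_matrix` or `pas_clusters`.
#' @param path output path; name = pas_id, score = total reads.
#' @export
export_pas_bed <- function(x, path) {
  tab <- if (inherits(x, "pas_clusters")) x$clusters else
    cbind(x$pas, total_reads = rowSums(x$counts))
  bed <- data.frame(tab$chrom, tab$pos, tab$pos + 1L, tab$pas_id,
                    tab$total_reads, tab$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export per-sample bedGraph tracks of PAS read counts
#'
#' @param mat a `pas_matrix`.
#' @param dir output directory; one `<sample>.bedGraph` per sample.
#' @export
export_bedgraph <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in colnames(mat$counts)) {
    v <- mat$counts[, s]
    keep <- v > 0
    bg <- data.frame(mat$pas$chrom[keep], mat$pas$pos[keep],
                     mat$pas$pos[keep] + 1L, v[keep])
    f <- file.path(dir, paste0(s, ".bedGraph"))
    writeLines(sprintf("track type=bedGraph name=%s", s), f)
    utils::write.table(bg, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  }
  invisible(dir)
}

#' Write / read a PAS count matrix as TSV (the fast-path input format)
#'
#' Columns: pas_id, chrom, strand, pos, gene_id, region, ordinal, hexamer,
#' utr3_len, n_introns, then one column per sample.
#'
#' @param mat a `pas_matrix`.
#' @param path TSV path.
#' @export
write_pas_matrix <- function(mat, path) {
  utils::write.table(cbind(mat$pas, as.data.frame(mat$counts)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pas_matrix
#' @param samples sample sheet matching the count columns.
#' @export
read_pas_matrix <- function(path, samples) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta_cols <- c("pas_id", "chrom", "strand", "pos", "gene_id", "region",
                 "ordinal", "hexamer", "utr3_len", "n_introns")
  meta_cols <- intersect(meta_cols, names(df))
  cnt <- as.matrix(df[, samples$sample_id, drop = FALSE])
  rownames(cnt) <- df$pas_id
  pas <- df[, meta_cols, drop = FALSE]
  for (col in c("gene_id", "region", "ordinal", "hexamer", "utr3_len", "n_introns"))
    if (is.null(pas[[col]])) pas[[col]] <- NA
  new_pas_matrix(cnt, pas, samples)
}
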