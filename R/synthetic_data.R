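#' Synthetic reference, truth program and count/read simulation
#'
#' The generator builds a toy genome and annotation whose genes carry multiple
#' poly(A) sites: a proximal/distal pair (or more) in the 3'-most exon and,
#' for a configurable fraction of genes, an intronic PAS. Per-condition
#' isoform-usage fractions encode a programmed APA regulation class per gene
#' (3'UTR shortening/lengthening, intronic activation/repression, or null),
#' gene-level expression multipliers encode differential expression, and
#' negative-binomial noise with multinomial isoform apportionment emulates
#' replicated 3'-end-seq counts. True cleavage sites carry an A[A/U]UAAA-family
#' hexamer planted in the -40..-1 window; simulated reads carry untemplated
#' adenosines as soft-clips so the discovery stage is testable end to end.
#'
#' @name synthetic_data
NULL

# DNA forms; searched in RNA sense (T read as U)
HEX_AAUAAA <- "AATAAA"
HEX_AUUAAA <- "ATTAAA"
HEX_VARIANTS <- c("AGTAAA", "TATAAA", "CATAAA", "GATAAA", "AATATA",
                  "AATACA", "AATAGA", "ACTAAA", "AAGAAA", "AATGAA")

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) rev(unname(DNA_COMP[x]))

#' Reference generator configuration
#'
#' Defaults describe the simulated study conditions: 200 multi-exon genes
#' (5-8 introns), a proximal/distal PAS pair in every 3'-most exon, an
#' intronic PAS in half the genes, hexamer classes planted at the genome-wide
#' proportions 55% AAUAAA / 17% AUUAAA / 20% other variants / 8% none, and a
#' 20% 3'UTR-shortening program with an absolute usage shift of 0.3.
#'
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes genes are distributed over.
#' @param exon_count_range min/max exons per gene (introns = exons - 1).
#' @param exon_len_range,intron_len_range,last_exon_len_range nt ranges.
#' @param utr3_pas_per_gene either a single count applied to every gene or a
#'   named probability vector over counts (names "1","2",...).
#' @param p_intronic_pas probability a gene carries one intronic PAS.
#' @param intron_ordinal_weights sampling weights over the intron groups
#'   +1/+2/MIDDLE/-2/-1 for intronic PAS placement.
#' @param proximal_offset_range nt from stop codon to the proximal PAS.
#' @param autr_len_range nt between proximal and distal PAS (aUTR size).
#' @param hexamer_probs planting probabilities for AAUAAA/AUUAAA/OTHER/NONE.
#' @param hexamer_offset_range start of the planted hexamer relative to the
#'   cleavage site (must lie within -40..-6 so the 6-mer fits in -40..-1).
#' @param decoy_rate A-rich internal-priming decoy tracts per gene, planted in
#'   intergenic space.
#' @param intergenic_gap nt between consecutive genes.
#' @param prop_shortened,prop_lengthened,prop_intronic_activated,
#'   prop_intronic_repressed fractions of (eligible) genes given each
#'   programmed APA class.
#' @param apa_delta programmed absolute shift in relative isoform abundance.
#' @param prop_up,prop_down fractions of genes with programmed expression
#'   change of `expr_fold` (up) or 1/`expr_fold` (down) in the treated
#'   condition.
#' @param expr_fold programmed expression fold change.
#' @param base_pair_fracs control-condition usage split of the proximal/distal
#'   pair (must sum to 1).
#' @param base_intronic_frac control-condition usage share of an intronic PAS.
#' @return a config list for [generate_reference()].
#' @export
ref_config <- function(n_genes = 200, n_chroms = 4,
                       exon_count_range = c(6, 9),
                       exon_len_range = c(120, 300),
                       intron_len_range = c(400, 900),
                       last_exon_len_range = c(1700, 2600),
                       utr3_pas_per_gene = 2,
                       p_intronic_pas = 0.5,
                       intron_ordinal_weights = c("+1" = 0.3, "+2" = 0.2,
                                                  "MIDDLE" = 0.2, "-2" = 0.15,
                                                  "-1" = 0.15),
                       proximal_offset_range = c(150, 400),
                       autr_len_range = c(200, 1000),
                       hexamer_probs = c(AAUAAA = 0.55, AUUAAA = 0.17,
                                         OTHER = 0.20, NONE = 0.08),
                       hexamer_offset_range = c(-35, -10),
                       decoy_rate = 0.25,
                       intergenic_gap = 2000,
                       prop_shortened = 0.2, prop_lengthened = 0,
                       prop_intronic_activated = 0, prop_intronic_repressed = 0,
                       apa_delta = 0.3,
                       prop_up = 0, prop_down = 0, expr_fold = 2,
                       base_pair_fracs = c(proximal = 0.45, distal = 0.55),
                       base_intronic_frac = 0.15) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (abs(sum(cfg$hexamer_probs) - 1) > 1e-9) stop("hexamer_probs must sum to 1")
  if (abs(sum(cfg$base_pair_fracs) - 1) > 1e-9) stop("base_pair_fracs must sum to 1")
  if (cfg$hexamer_offset_range[1] < -40 || cfg$hexamer_offset_range[2] > -6)
    stop("hexamer must fit inside the -40..-1 window")
  # geometry feasibility: the 3'-most exon must hold CDS tail + PASs + hexamer room
  need <- 150 + cfg$proximal_offset_range[2] + cfg$autr_len_range[2] + 60
  if (cfg$last_exon_len_range[1] < need)
    stop("infeasible geometry: last exon (min ", cfg$last_exon_len_range[1],
         " nt) cannot hold PAS layout (needs ", need, " nt)")
  if (cfg$intron_len_range[1] < 160)
    stop("infeasible geometry: introns too short for an intronic PAS window")
  cfg
}

# write `s` into the genome char vector downstream-oriented: the first char of
# s sits at transcript offset `offset` from `pos` (offset 0 == the cleavage
# base itself). Returns the modified vector.
write_tx <- function(gchar, strand, pos, offset, s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  if (strand == "+") {
    gchar[(pos + offset + 1):(pos + offset + L)] <- ch
  } else {
    # transcript offset t maps to genomic pos - t
    gchar[(pos - offset - L + 1 + 1):(pos - offset + 1)] <- revcomp_chr(ch)
  }
  gchar
}

read_tx <- function(gchar, strand, pos, from, to) {
  if (strand == "+") {
    paste(gchar[(pos + from + 1):(pos + to + 1)], collapse = "")
  } else {
    paste(revcomp_chr(gchar[(pos - to + 1):(pos - from + 1)]), collapse = "")
  }
}

# remove chance occurrences of any PAS hexamer from a window string, leaving
# the planted interval [keep_from, keep_to] (1-based, 0 length if none) intact
scrub_hexamers <- function(win, keep_from = 0L, keep_to = -1L) {
  all_hex <- c(HEX_AAUAAA, HEX_AUUAAA, HEX_VARIANTS)
  for (iter in 1:50) {
    hit <- FALSE
    for (h in all_hex) {
      m <- gregexpr(h, win, fixed = TRUE)[[1]]
      m <- m[m > 0]
      m <- m[!(m >= keep_from - 5 & m <= keep_to)]  # overlaps planted site
      if (length(m)) {
        substr(win, m[1] + 2, m[1] + 2) <- "C"
        hit <- TRUE
        break
      }
    }
    if (!hit) return(win)
  }
  win
}

#' Generate a synthetic genome, annotation and APA truth program
#'
#' Writes a FASTA genome and a GTF annotation and returns the ground truth:
#' per-gene PAS positions with region labels, per-condition isoform-usage
#' fractions realising the programmed APA classes, expression multipliers,
#' and the planted hexamer class of every true PAS. Each true PAS is followed
#' (transcript orientation) by a 12-nt A-free guard so clipped adenosines are
#' untemplated and the internal-priming filter keeps it; decoy tracts are
#' A-rich but not pure-A so decoy reads pass the untemplated-tail rule and are
#' caught only by the downstream-window filter.
#'
#' Identical seeds give byte-identical FASTA/GTF/truth.
#'
#' @param config from [ref_config()].
#' @param seed integer seed governing all randomness.
#' @param dir output directory for `genome.fa` and `annotation.gtf`.
#' @return an `apa_truth` object: list with `genes`, `pas`, `decoys` data
#'   frames, file paths, `config` and `seed`.
#' @export
generate_reference <- function(config = ref_config(), seed = 1,
                               dir = tempfile("apakit_ref_")) {
  set.seed(seed)
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  n <- cfg$n_genes
  chrom_of <- sprintf("chr%d", (seq_len(n) - 1) %% cfg$n_chroms + 1)
  strand_of <- sample(c("+", "-"), n, replace = TRUE)

  # per-gene structural draws (transcript coordinates)
  runif_int <- function(k, r) sample(seq(r[1], r[2]), k, replace = TRUE)
  n_exons <- runif_int(n, cfg$exon_count_range)

  genes <- vector("list", n)
  cursor <- stats::setNames(rep(0L, cfg$n_chroms), sprintf("chr%d", 1:cfg$n_chroms))

  # number of UTR3 PASs per gene
  n_utr3 <- if (length(cfg$utr3_pas_per_gene) == 1 && is.null(names(cfg$utr3_pas_per_gene))) {
    rep(as.integer(cfg$utr3_pas_per_gene), n)
  } else {
    as.integer(sample(names(cfg$utr3_pas_per_gene), n, replace = TRUE,
                      prob = cfg$utr3_pas_per_gene))
  }
  has_intronic <- stats::runif(n) < cfg$p_intronic_pas

  for (g in seq_len(n)) {
    m <- n_exons[g]
    elen <- c(runif_int(m - 1, cfg$exon_len_range),
              runif_int(1, cfg$last_exon_len_range))
    ilen <- runif_int(m - 1, cfg$intron_len_range)
    # transcript-forward coordinates of exons
    starts <- cumsum(c(0L, elen[-m] + ilen))
    ex_tx <- cbind(starts, starts + elen)
    L <- ex_tx[m, 2]
    gid <- sprintf("gene%04d", g)
    chrom <- chrom_of[g]
    strand <- strand_of[g]
    g0 <- cursor[chrom] + cfg$intergenic_gap
    cursor[chrom] <- g0 + L

    # CDS: 30 nt into exon1 through 150 nt into the last exon
    cds_tx <- c(ex_tx[1, 1] + 30L, ex_tx[m, 1] + 150L)

    # UTR3 PASs (transcript coords of the last transcribed base)
    prox_off <- runif_int(1, cfg$proximal_offset_range)
    t_prox <- cds_tx[2] + prox_off
    t_pas <- t_prox
    if (n_utr3[g] >= 2) {
      autr <- runif_int(1, cfg$autr_len_range)
      t_pas <- c(t_pas, t_prox + autr)
      if (n_utr3[g] >= 3) {
        extra <- runif_int(n_utr3[g] - 2, c(60, max(61, autr - 60)))
        t_pas <- sort(unique(c(t_pas, t_prox + extra)))
      }
    }
    stopifnot(max(t_pas) + 60 <= L)

    # optional intronic PAS: pick an intron by ordinal-group weight
    intronic <- NULL
    if (has_intronic[g] && m >= 2) {
      ni <- m - 1
      ords <- vapply(seq_len(ni), intron_ordinal, "", n = ni)
      w <- cfg$intron_ordinal_weights[ords]
      w[is.na(w)] <- 0
      if (all(w == 0)) w <- rep(1, ni)
      i_pick <- sample.int(ni, 1, prob = w)
      # genomic-in-transcript-layout coordinates of intron i (between exon i and i+1)
      int_tx <- c(ex_tx[i_pick, 2], ex_tx[i_pick + 1, 1])
      off <- runif_int(1, c(60, int_tx[2] - int_tx[1] - 60))
      intronic <- list(ord = ords[i_pick], t = int_tx[1] + off, intron_idx = i_pick)
    }

    # map transcript-layout coords to genome (0-based)
    map_pos <- function(t) if (strand == "+") g0 + t else g0 + L - 1L - t
    map_iv <- function(a, b) {  # [a,b) layout -> genomic [s,e)
      if (strand == "+") c(g0 + a, g0 + b) else c(g0 + L - b, g0 + L - a)
    }
    exons_gen <- t(apply(ex_tx, 1, function(r) map_iv(r[1], r[2])))
    cds_iv <- cbind(pmax(ex_tx[, 1], cds_tx[1]), pmin(ex_tx[, 2], cds_tx[2]))
    cds_iv <- cds_iv[cds_iv[, 1] < cds_iv[, 2], , drop = FALSE]
    cds_gen <- t(apply(cds_iv, 1, function(r) map_iv(r[1], r[2])))

    pas_t <- c(t_pas, if (!is.null(intronic)) intronic$t)
    pas_region <- c(rep("UTR3", length(t_pas)), if (!is.null(intronic)) "INTRON")
    pas_ord <- c(rep(NA_character_, length(t_pas)), if (!is.null(intronic)) intronic$ord)
    genes[[g]] <- list(gid = gid, chrom = chrom, strand = strand,
                       exons = exons_gen, cds = cds_gen, n_introns = m - 1L,
                       pas_pos = vapply(pas_t, map_pos, 0),
                       pas_t = pas_t, pas_region = pas_region, pas_ord = pas_ord,
                       utr3_len = pas_t[seq_along(t_pas)] - cds_tx[2] + 1L)
  }

  # finalize chromosome lengths, build random genome
  chrom_len <- cursor + cfg$intergenic_gap
  genome_chars <- lapply(chrom_len, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  # plant hexamers, guards
  hex_class <- sample(names(cfg$hexamer_probs), sum(vapply(genes, function(g) length(g$pas_pos), 0L)),
                      replace = TRUE, prob = cfg$hexamer_probs)
  k <- 0L
  for (g in genes) {
    gc <- genome_chars[[g$chrom]]
    for (j in seq_along(g$pas_pos)) {
      k <- k + 1L
      pos <- g$pas_pos[j]
      win <- read_tx(gc, g$strand, pos, -40L, -1L)
      cls <- hex_class[k]
      if (cls == "NONE") {
        win <- scrub_hexamers(win)
      } else {
        hx <- switch(cls, AAUAAA = HEX_AAUAAA, AUUAAA = HEX_AUUAAA,
                     OTHER = sample(HEX_VARIANTS, 1))
        off <- sample(seq(cfg$hexamer_offset_range[1], cfg$hexamer_offset_range[2]), 1)
        at <- off + 41L  # 1-based index in the 40-nt window
        substr(win, at, at + 5L) <- hx
        win <- scrub_upstream_priority(win, cls, at)
      }
      gc <- write_tx(gc, g$strand, pos, -40L, win)
      # A-free downstream guard: keeps the PAS through the internal-priming
      # filter and makes clipped adenosines untemplated
      guard <- paste(sample(c("C", "G", "T"), 12, replace = TRUE), collapse = "")
      gc <- write_tx(gc, g$strand, pos, 1L, guard)
    }
    genome_chars[[g$chrom]] <- gc
  }
  # record the class actually planted
  k <- 0L
  for (gi in seq_along(genes)) {
    np <- length(genes[[gi]]$pas_pos)
    genes[[gi]]$hex_class <- hex_class[(k + 1):(k + np)]
    k <- k + np
  }

  # decoy tracts in intergenic space: A-rich but not pure-A
  n_decoys <- round(cfg$decoy_rate * n)
  decoys <- NULL
  if (n_decoys > 0) {
    dg <- sample(seq_len(n), n_decoys)
    dec <- lapply(dg, function(gi) {
      g <- genes[[gi]]
      # just past this gene's 3' end in the following intergenic gap
      pos <- if (g$strand == "+") max(g$exons) + 1200L else min(g$exons) - 1200L
      st <- sample(c("+", "-"), 1)
      genome_chars[[g$chrom]] <<- write_tx(genome_chars[[g$chrom]], st, pos, 1L,
                                           paste0("AAGACA", strrep("A", 12)))
      data.frame(chrom = g$chrom, strand = st, pos = pos, stringsAsFactors = FALSE)
    })
    decoys <- do.call(rbind, dec)
  }

  # programmed classes: draw eligible genes per class, disjointly
  utr3_count <- vapply(genes, function(g) sum(g$pas_region == "UTR3"), 0L)
  has_int <- vapply(genes, function(g) any(g$pas_region == "INTRON"), TRUE)
  cls <- rep("NULL", n)
  pick <- function(eligible, prop) {
    want <- round(prop * n)
    pool <- which(eligible & cls == "NULL")
    sample(pool, min(want, length(pool)))
  }
  cls[pick(utr3_count >= 2, cfg$prop_shortened)] <- "SHORTENED"
  cls[pick(utr3_count >= 2, cfg$prop_lengthened)] <- "LENGTHENED"
  cls[pick(has_int, cfg$prop_intronic_activated)] <- "INTRONIC_ACTIVATED"
  cls[pick(has_int, cfg$prop_intronic_repressed)] <- "INTRONIC_REPRESSED"

  expr_mult <- rep(1, n)
  de <- rep("NULL", n)
  up <- sample.int(n, round(cfg$prop_up * n))
  down <- sample(setdiff(seq_len(n), up), round(cfg$prop_down * n))
  expr_mult[up] <- cfg$expr_fold; de[up] <- "UP"
  expr_mult[down] <- 1 / cfg$expr_fold; de[down] <- "DOWN"

  # usage fractions per condition realising the program
  pas_tab <- list()
  for (g in seq_len(n)) {
    gg <- genes[[g]]
    nu <- sum(gg$pas_region == "UTR3")
    isum <- as.numeric(any(gg$pas_region == "INTRON"))
    i_ctrl <- if (isum) cfg$base_intronic_frac else 0
    i_trt <- i_ctrl
    delta <- cfg$apa_delta
    if (cls[g] == "INTRONIC_ACTIVATED") i_trt <- min(0.95, i_ctrl + delta)
    if (cls[g] == "INTRONIC_REPRESSED") { i_ctrl <- min(0.95, i_ctrl + delta) }
    # pair split among UTR3 PASs: two most abundant are first (proximal) and
    # last (distal); any extra UTR3 PASs share a minor 8% each
    minor <- if (nu > 2) 0.08 * (nu - 2) else 0
    pd_ctrl <- cfg$base_pair_fracs * (1 - minor)
    pd_trt <- pd_ctrl
    if (nu >= 2) {
      if (cls[g] == "SHORTENED")
        pd_trt <- c(pd_ctrl[1] + delta, pd_ctrl[2] - delta)
      if (cls[g] == "LENGTHENED")
        pd_trt <- c(pd_ctrl[1] - delta, pd_ctrl[2] + delta)
    }
    frac_u <- function(pd) {
      if (nu == 1) return(1)
      v <- rep(0.08, nu)
      v[1] <- pd[1]; v[nu] <- pd[2]
      v
    }
    f_ctrl <- c(frac_u(pd_ctrl) * (1 - i_ctrl), if (isum) i_ctrl)
    f_trt <- c(frac_u(pd_trt) * (1 - i_trt), if (isum) i_trt)
    pas_tab[[g]] <- data.frame(
      pas_id = sprintf("%s_pas%d", gg$gid, seq_along(gg$pas_pos)),
      gene_id = gg$gid, chrom = gg$chrom, strand = gg$strand,
      pos = gg$pas_pos, region = gg$pas_region, ordinal = gg$pas_ord,
      hexamer_class = gg$hex_class,
      utr3_len = c(gg$utr3_len, if (isum) NA_integer_),
      frac_control = f_ctrl, frac_treated = f_trt,
      stringsAsFactors = FALSE
    )
  }
  pas_df <- do.call(rbind, pas_tab)
  stopifnot(all(abs(tapply(pas_df$frac_control, pas_df$gene_id, sum) - 1) < 1e-9),
            all(abs(tapply(pas_df$frac_treated, pas_df$gene_id, sum) - 1) < 1e-9))

  gene_df <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gid"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    n_introns = vapply(genes, `[[`, 0L, "n_introns"),
    programmed_class = cls, de_class = de,
    expr_mult_control = 1, expr_mult_treated = expr_mult,
    stringsAsFactors = FALSE
  )

  # write FASTA + GTF
  fasta <- file.path(dir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(vapply(genome_chars, paste, "", collapse = ""))
  names(seqs) <- names(genome_chars)
  Biostrings::writeXStringSet(seqs, fasta)

  gtf <- file.path(dir, "annotation.gtf")
  lines <- unlist(lapply(genes, function(g) {
    attr_s <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gid, g$gid)
    ex <- sprintf("%s\tapakit\texon\t%d\t%d\t.\t%s\t.\t%s",
                  g$chrom, g$exons[, 1] + 1L, g$exons[, 2], g$strand, attr_s)
    cd <- sprintf("%s\tapakit\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                  g$chrom, g$cds[, 1] + 1L, g$cds[, 2], g$strand, attr_s)
    c(ex, cd)
  }))
  writeLines(lines, gtf)

  structure(list(genes = gene_df, pas = pas_df, decoys = decoys,
                 genome_fasta = fasta, gtf = gtf,
                 chrom_len = chrom_len, config = cfg, seed = seed),
            class = "apa_truth")
}

# after planting, remove any *equal-or-higher* priority hexamer elsewhere in
# the window so the planted class is what classify_hexamer will report
scrub_upstream_priority <- function(win, cls, at) {
  kill <- switch(cls,
                 AAUAAA = character(0),
                 AUUAAA = HEX_AAUAAA,
                 OTHER = c(HEX_AAUAAA, HEX_AUUAAA))
  for (iter in 1:50) {
    hit <- FALSE
    for (h in c(kill, switch(cls, AAUAAA = HEX_AAUAAA, AUUAAA = HEX_AUUAAA,
                             OTHER = character(0)))) {
      m <- gregexpr(h, win, fixed = TRUE)[[1]]
      m <- m[m > 0 & m != at]
      if (length(m)) {
        # mutate a base of the offending match outside the planted hexamer
        cand <- setdiff(m[1]:(m[1] + 5), at:(at + 5))
        substr(win, cand[length(cand) %/% 2 + 1], cand[length(cand) %/% 2 + 1]) <- "C"
        hit <- TRUE
        break
      }
    }
    if (!hit) break
  }
  win
}

#' @export
print.apa_truth <- function(x, ...) {
  cat("apa_truth:", nrow(x$genes), "genes,", nrow(x$pas), "true PASs",
      sprintf("(%d UTR3, %d intronic)", sum(x$pas$region == "UTR3"),
              sum(x$pas$region == "INTRON")), "\n")
  cat("  programmed:", paste(names(table(x$genes$programmed_class)),
                             table(x$genes$programmed_class),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Default sample sheet
#'
#' Three control and three treated replicates at one timepoint, matching a
#' triplicated two-condition design.
#'
#' @param n_reps replicates per condition.
#' @param timepoint label carried through outputs.
#' @return data.frame with sample_id, condition, timepoint, replicate.
#' @export
default_design <- function(n_reps = 3, timepoint = "3h") {
  data.frame(
    sample_id = c(sprintf("ctrl_%d", 1:n_reps), sprintf("trt_%d", 1:n_reps)),
    condition = rep(c("control", "treated"), each = n_reps),
    timepoint = timepoint,
    replicate = rep(1:n_reps, 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a PAS count matrix from a truth program
#'
#' Per sample, each gene's total is negative-binomial with mean
#' `depth * expression multiplier` and the given dispersion (variance
#' mean + dispersion * mean^2; dispersion 0 degrades to Poisson), then reads
#' are apportioned to the gene's PASs by a multinomial draw with the sample's
#' condition-specific usage fractions.
#'
#' @param truth an `apa_truth`.
#' @param design sample sheet (see [default_design()]).
#' @param depth mean reads per gene per sample.
#' @param dispersion NB dispersion (>= 0).
#' @param seed integer seed.
#' @param size_factors optional per-sample scaling (default 1).
#' @return a `pas_matrix` with truth-derived PAS metadata attached.
#' @export
simulate_counts <- function(truth, design = default_design(), depth = 500,
                            dispersion = 0.1, seed = 1, size_factors = NULL) {
  stopifnot(dispersion >= 0)
  set.seed(seed)
  if (is.null(size_factors)) size_factors <- rep(1, nrow(design))
  pas <- truth$pas
  gsplit <- split(seq_len(nrow(pas)), pas$gene_id)
  gmult <- stats::setNames(truth$genes$expr_mult_treated, truth$genes$gene_id)
  counts <- matrix(0L, nrow(pas), nrow(design),
                   dimnames = list(pas$pas_id, design$sample_id))
  for (s in seq_len(nrow(design))) {
    trt <- design$condition[s] == "treated"
    for (gid in names(gsplit)) {
      ix <- gsplit[[gid]]
      mu <- depth * (if (trt) gmult[[gid]] else 1) * size_factors[s]
      tot <- if (dispersion > 0) {
        stats::rnbinom(1, mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(1, mu)
      }
      fr <- if (trt) pas$frac_treated[ix] else pas$frac_control[ix]
      counts[ix, s] <- if (length(ix) == 1) tot else
        as.integer(stats::rmultinom(1, tot, fr))
    }
  }
  meta <- pas[, c("pas_id", "gene_id", "chrom", "strand", "pos", "region",
                  "ordinal", "utr3_len")]
  meta$hexamer <- pas$hexamer_class
  meta$n_introns <- truth$genes$n_introns[match(meta$gene_id, truth$genes$gene_id)]
  new_pas_matrix(counts, meta, design)
}

#' Simulate 3'-end-seq reads as SAM files
#'
#' Each PAS-supporting read aligns with its 3' end (transcript orientation) at
#' the cleavage site and carries `k` untemplated adenosines as a soft-clip,
#' with `k` drawn from `tail_probs` (default P(k >= 2) = 0.92). Cleavage
#' positions are jittered uniformly within `+/- jitter` nt. A fraction
#' `decoy_frac` of reads are internal-priming decoys ending at the planted
#' A-rich tracts. Reads are reported on the transcript's strand.
#'
#' @param truth an `apa_truth` from [generate_reference()].
#' @param design sample sheet.
#' @param depth mean reads per gene per sample.
#' @param dispersion NB dispersion of gene totals.
#' @param seed integer seed.
#' @param dir output directory; one `<sample_id>.sam` per sample.
#' @param read_len total read length (aligned + clipped).
#' @param jitter max cleavage-site jitter in nt.
#' @param decoy_frac fraction of reads emitted at decoy tracts.
#' @param tail_probs distribution of the untemplated-A tail length, names "0","1",...
#' @return list with `sam_files` (named by sample), `detectable_counts`
#'   (true-PAS x sample matrix of reads with k >= 2, i.e. recoverable by the
#'   discovery rule) and `total_counts`.
#' @export
simulate_reads <- function(truth, design = default_design(), depth = 30,
                           dispersion = 0.1, seed = 1,
                           dir = tempfile("apakit_reads_"),
                           read_len = 40, jitter = 10, decoy_frac = 0.05,
                           tail_probs = c("0" = 0.02, "1" = 0.06, "2" = 0.22,
                                          "3" = 0.30, "4" = 0.22, "5" = 0.12,
                                          "6" = 0.06)) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- load_genome(truth$genome_fasta)
  pas <- truth$pas
  gmult <- stats::setNames(truth$genes$expr_mult_treated, truth$genes$gene_id)
  gsplit <- split(seq_len(nrow(pas)), pas$gene_id)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(truth$chrom_len),
                      as.integer(truth$chrom_len)))
  ks <- as.integer(names(tail_probs))
  detect <- matrix(0L, nrow(pas), nrow(design),
                   dimnames = list(pas$pas_id, design$sample_id))
  total <- detect
  sam_files <- stats::setNames(file.path(dir, paste0(design$sample_id, ".sam")),
                               design$sample_id)

  for (s in seq_len(nrow(design))) {
    trt <- design$condition[s] == "treated"
    recs <- list()
    rid <- 0L
    qual <- strrep("I", read_len)
    # pos: 0-based last transcribed base; k clipped As at the transcript 3' end
    emit <- function(chrom, strand, pos, k) {
      m <- read_len - k
      gc <- genome[[chrom]]
      ids <- sprintf("r%07d", rid + seq_along(pos))
      rid <<- rid + length(pos)
      if (strand == "+") {
        a0 <- pos - m + 1L
        seq <- paste0(substr(rep(gc, length(pos)), a0 + 1L, pos + 1L),
                      strrep("A", k))
        cig <- ifelse(k > 0, sprintf("%dM%dS", m, k), sprintf("%dM", m))
        sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                ids, chrom, a0 + 1L, cig, seq, qual)
      } else {
        seq <- paste0(strrep("T", k),
                      substr(rep(gc, length(pos)), pos + 1L, pos + m))
        cig <- ifelse(k > 0, sprintf("%dS%dM", k, m), sprintf("%dM", m))
        sprintf("%s\t16\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                ids, chrom, pos + 1L, cig, seq, qual)
      }
    }
    for (gid in names(gsplit)) {
      ix <- gsplit[[gid]]
      mu <- depth * (if (trt) gmult[[gid]] else 1)
      tot <- if (dispersion > 0) stats::rnbinom(1, mu = mu, size = 1 / dispersion)
             else stats::rpois(1, mu)
      if (tot == 0) next
      fr <- if (trt) pas$frac_treated[ix] else pas$frac_control[ix]
      npas <- if (length(ix) == 1) tot else as.integer(stats::rmultinom(1, tot, fr))
      for (j in seq_along(ix)) {
        if (npas[j] == 0) next
        p <- pas$pos[ix[j]]; st <- pas$strand[ix[j]]; ch <- pas$chrom[ix[j]]
        kdraw <- sample(ks, npas[j], replace = TRUE, prob = tail_probs)
        jit <- if (jitter > 0) sample(seq(-jitter, jitter), npas[j], replace = TRUE)
               else rep(0L, npas[j])
        total[ix[j], s] <- total[ix[j], s] + npas[j]
        detect[ix[j], s] <- detect[ix[j], s] + sum(kdraw >= 2L)
        cp <- if (st == "+") p + jit else p - jit
        for (k in unique(kdraw))
          recs[[length(recs) + 1L]] <- emit(ch, st, cp[kdraw == k], k)
      }
    }
    if (decoy_frac > 0 && !is.null(truth$decoys) && nrow(truth$decoys)) {
      nd <- round(decoy_frac * rid)
      di <- sample.int(nrow(truth$decoys), nd, replace = TRUE)
      for (d in di)
        recs[[length(recs) + 1L]] <- emit(truth$decoys$chrom[d],
                                          truth$decoys$strand[d],
                                          truth$decoys$pos[d], 6L)
    }
    writeLines(c(header, unlist(recs)), sam_files[s])
  }
  list(sam_files = sam_files, detectable_counts = detect, total_counts = total,
       dir = dir)
}

#' Load a genome FASTA as per-chromosome character strings
#' @param path FASTA path.
#' @return named list of single strings.
#' @export
load_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.list(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
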