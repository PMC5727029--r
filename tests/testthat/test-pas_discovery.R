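# a 60-nt toy genome designed so clip templating is controlled:
# positions (0-based) 10..12 = CCC (mismatch for clipped As after aligning 0..9)
# positions 30..32 = AAA (templated continuation)
toy_genome <- function() {
  g <- paste0("GTCGTACGTG", "CCCTGCGTGC", "GTCGTGCGTG", "AAATGCGTGC",
              "GTCGTGCGTG", "CCCTGCGTGC")
  list(chr1 = g)
}

test_that("untemplated-tail rule accepts >=2 mismatching clipped As only", {
  g <- toy_genome()
  sam <- tempfile(fileext = ".sam")
  aligned10 <- substr(g$chr1, 1, 10)   # aligns 1..10 (1-based)
  aligned30 <- substr(g$chr1, 21, 30)  # aligns 21..30, genome continues AAA
  write_toy_sam(c(
    sam_record("ok3", 0, "chr1", 1, "10M3S", paste0(aligned10, "AAA")),
    sam_record("only1", 0, "chr1", 1, "10M1S", paste0(aligned10, "A")),
    sam_record("templated", 0, "chr1", 21, "10M3S", paste0(aligned30, "AAA")),
    sam_record("nonA", 0, "chr1", 1, "10M3S", paste0(aligned10, "AGA"))
  ), c(chr1 = 60L), sam)
  reads <- extract_pas_reads(c(s1 = sam), g)
  expect_equal(nrow(reads), 1)
  expect_equal(reads$pos, 9)  # 0-based last aligned base
  expect_equal(reads$strand, "+")
})

test_that("minus-strand reads use the left-side T clip and leftmost position", {
  g <- toy_genome()
  sam <- tempfile(fileext = ".sam")
  aligned <- substr(g$chr1, 14, 23)  # aligns 14..23; genome left of 14 is CCC
  write_toy_sam(c(
    sam_record("mok", 16, "chr1", 14, "3S10M", paste0("TTT", aligned)),
    sam_record("mbad", 16, "chr1", 14, "3S10M", paste0("GTT", aligned))
  ), c(chr1 = 60L), sam)
  reads <- extract_pas_reads(c(s1 = sam), g)
  expect_equal(nrow(reads), 1)
  expect_equal(reads$strand, "-")
  expect_equal(reads$pos, 13)
})

test_that("alignments with no soft clips warn and return nothing", {
  g <- toy_genome()
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam_record("r", 0, "chr1", 1, "10M", substr(g$chr1, 1, 10)),
                c(chr1 = 60L), sam)
  expect_warning(reads <- extract_pas_reads(c(s1 = sam), g), "soft-clip")
  expect_equal(nrow(reads), 0)
  expect_error(extract_pas_reads(c(s1 = sam), g, orientation = "upside"),
               "orientation")
})

test_that("clustering follows single-linkage chaining at 24 nt", {
  df <- function(p) data.frame(chrom = "chr1", strand = "+", pos = p)
  c1 <- cluster_pas(df(c(100, 110, 140)))
  expect_equal(nrow(c1$clusters), 2)  # 110 -> 140 gap is 30 > 24
  c2 <- cluster_pas(df(c(100, 120, 140)))
  expect_equal(nrow(c2$clusters), 1)  # chained 20 + 20
  # equal read support: representative is the most distal member
  expect_equal(c2$clusters$pos, 140)
  c3 <- cluster_pas(data.frame(chrom = "chr1", strand = "-", pos = c(100, 120)))
  expect_equal(c3$clusters$pos, 100)  # distal on minus = smallest coordinate
  # representative is the mode by read count when support differs
  c4 <- cluster_pas(df(c(100, 100, 100, 120)))
  expect_equal(c4$clusters$pos, 100)
})

test_that("clustering matches brute-force single-linkage on random instances", {
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    pos <- sort(sample.int(500, n))
    cl <- cluster_pas(data.frame(chrom = "chr1", strand = "+", pos = pos))
    got <- cl$members$pas_id[match(pos, cl$members$pos)]
    want <- brute_single_linkage(pos)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("clustering is input-order invariant and idempotent", {
  set.seed(2)
  pos <- sample.int(2000, 80, replace = TRUE)
  a <- cluster_pas(data.frame(chrom = "chr1", strand = "+", pos = pos))
  b <- cluster_pas(data.frame(chrom = "chr1", strand = "+", pos = rev(pos)))
  expect_equal(a$clusters, b$clusters)
  # representatives >24 nt apart re-cluster to themselves
  reps <- a$clusters$pos
  if (all(diff(sort(reps)) > 24)) {
    c2 <- cluster_pas(data.frame(chrom = "chr1", strand = "+", pos = reps))
    expect_equal(sort(c2$clusters$pos), sort(reps))
  }
})

test_that("internal-priming filter drops A-rich downstream windows", {
  # positions >24 nt apart so they stay separate clusters:
  # pos 9 -> downstream window AAAAAAAAAA; pos 59 -> ACGTACGTAC
  g <- list(chr1 = paste0("GTCGTACGTG", "AAAAAAAAAA", "GTCGTACGTG",
                          "GTCGTACGTG", "GTCGTACGTG", "GTCGTACGTG",
                          "ACGTACGTAC", "GTCGTACGTG"))
  reads <- data.frame(chrom = "chr1", strand = "+", pos = c(9, 59))
  cl <- cluster_pas(reads)
  f <- filter_internal_priming(cl, g)
  expect_equal(f$clusters$pos, 59)
  expect_equal(attr(f, "n_dropped"), 1)
  # filter is strand-aware: on minus the window lies genomically upstream
  clm <- cluster_pas(data.frame(chrom = "chr1", strand = "-", pos = c(9, 59)))
  fm <- filter_internal_priming(clm, g)
  expect_equal(nrow(fm$clusters), 2)
})

test_that("planted decoys are filtered, true PASs kept", {
  tr <- generate_reference(ref_config(n_genes = 30, decoy_rate = 0.3), seed = 5)
  sim <- simulate_reads(tr, depth = 30, seed = 6, jitter = 5, decoy_frac = 0.1)
  genome <- load_genome(tr$genome_fasta)
  reads <- extract_pas_reads(sim$sam_files, genome)
  cl <- cluster_pas(reads)
  f <- filter_internal_priming(cl, genome)
  dk <- paste(tr$decoys$chrom, tr$decoys$strand, tr$decoys$pos)
  fk <- paste(f$clusters$chrom, f$clusters$strand, f$clusters$pos)
  expect_lte(sum(dk %in% fk), 0.05 * nrow(tr$decoys))
  tk <- paste(tr$pas$chrom, tr$pas$strand, tr$pas$pos)
  # every true PAS with discovered reads survives the filter
  ck <- paste(cl$clusters$chrom, cl$clusters$strand)
  got_true <- vapply(seq_len(nrow(tr$pas)), function(i) {
    any(f$clusters$chrom == tr$pas$chrom[i] &
          f$clusters$strand == tr$pas$strand[i] &
          abs(f$clusters$pos - tr$pas$pos[i]) <= 10)
  }, TRUE)
  expect_true(all(got_true))
})

test_that("quantify conserves reads and fills singleton clusters", {
  reads <- data.frame(sample = rep("ctrl_1", 10), chrom = "chr1",
                      strand = "+", pos = rep(50, 10))
  cl <- cluster_pas(reads)
  design <- default_design()
  m <- quantify(cl, reads, design)
  expect_equal(unname(m$counts[1, "ctrl_1"]), 10)
  expect_equal(sum(m$counts), nrow(reads))
  # an orphan read (not in any cluster) becomes a singleton cluster
  reads2 <- rbind(reads, data.frame(sample = "trt_1", chrom = "chr1",
                                    strand = "+", pos = 500))
  m2 <- quantify(cl, reads2, design)
  expect_equal(nrow(m2$counts), 2)
  expect_equal(sum(m2$counts), nrow(reads2))
  expect_error(quantify(cl, transform(reads, sample = "nope"), design),
               "absent")
})

test_that("discovery closed loop at zero jitter recovers truth exactly", {
  tr <- generate_reference(ref_config(n_genes = 20, decoy_rate = 0), seed = 21)
  sim <- simulate_reads(tr, depth = 25, seed = 22, jitter = 0, decoy_frac = 0)
  genome <- load_genome(tr$genome_fasta)
  reads <- extract_pas_reads(sim$sam_files, genome)
  expect_equal(nrow(reads), sum(sim$detectable_counts))
  cl <- cluster_pas(reads)
  m <- quantify(cl, reads, default_design())
  key_t <- paste(tr$pas$chrom, tr$pas$strand, tr$pas$pos)
  key_c <- paste(m$pas$chrom, m$pas$strand, m$pas$pos)
  expect_setequal(key_t, key_c)
  ix <- match(key_t, key_c)
  expect_true(all(m$counts[ix, ] == sim$detectable_counts))
})
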