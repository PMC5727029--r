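# build a 2-PAS UTR3 gene matrix from per-sample proximal/distal counts
pair_matrix <- function(prox, dist, strand = "+", design = default_design()) {
  counts <- rbind(prox, dist)
  pas <- data.frame(
    pas_id = c("p1", "p2"), gene_id = "g1", chrom = "chr1", strand = strand,
    pos = if (strand == "+") c(1000L, 1800L) else c(1800L, 1000L),
    region = "UTR3", utr3_len = c(200L, 1000L), stringsAsFactors = FALSE)
  toy_pas_matrix(counts, pas, design)
}

test_that("top-2 selection takes the most abundant pair, ties distal", {
  sel <- select_top2_utr3(c(100, 300, 500), "+", c(50, 40, 5))
  expect_equal(sel, list(proximal = 1L, distal = 2L))
  # tie for the second slot: keep the more distal candidate
  sel2 <- select_top2_utr3(c(100, 300, 500), "+", c(50, 40, 40))
  expect_equal(sel2, list(proximal = 1L, distal = 3L))
  # minus strand: proximal is the larger coordinate
  sel3 <- select_top2_utr3(c(100, 300), "-", c(10, 50))
  expect_equal(sel3, list(proximal = 2L, distal = 1L))
  expect_null(select_top2_utr3(100, "+", 50))
})

test_that("RE/RED arithmetic matches its definition", {
  r <- re_red(100, 400, 100, 400)
  expect_equal(r$RE_ctrl, log2(400.5 / 100.5))
  expect_equal(r$RED, 0)
  expect_equal(r$delta_abundance, 0)
  # swapping conditions negates RED; swapping isoforms negates RE
  a <- re_red(100, 400, 300, 200)
  b <- re_red(300, 200, 100, 400)
  expect_equal(a$RED, -b$RED)
  s <- re_red(400, 100, 200, 300)
  expect_equal(s$RE_ctrl, -a$RE_ctrl)
  expect_true(is.na(re_red(0, 0, 10, 10)$RED))
})

test_that("isoform switch test is pooled Fisher with sign consistency", {
  cond <- default_design()$condition
  r1 <- test_isoform_switch(rep(50, 6), rep(50, 6), cond)
  expect_equal(r1$p_value, 1)
  prox <- c(30, 30, 30, 10, 20, 20)
  dist <- c(10, 10, 10, 30, 30, 40)
  r2 <- test_isoform_switch(prox, dist, cond)
  ci <- cond == "control"
  tab <- matrix(c(sum(prox[ci]), sum(dist[ci]), sum(prox[!ci]), sum(dist[!ci])), 2)
  expect_equal(r2$p_value, enum_fisher_p(tab))
  expect_true(r2$consistent)
  # a switch driven by one replicate against the others is not consistent
  prox3 <- c(30, 30, 30, 90, 28, 29)
  dist3 <- c(30, 30, 30, 2, 31, 30)
  r3 <- test_isoform_switch(prox3, dist3, cond)
  expect_false(r3$consistent)
})

test_that("significant p with sub-threshold abundance change stays NC", {
  # large counts: p is tiny but the share moves only 3 points
  prox <- c(rep(5000, 3), rep(5300, 3))
  dist <- c(rep(5000, 3), rep(4700, 3))
  m <- pair_matrix(prox, dist)
  ev <- call_utr3_apa(m)
  expect_lt(ev$p_value, 0.05)
  expect_lt(abs(ev$delta_abundance), 0.05)
  expect_equal(ev$class, "NC")
})

test_that("programmed switches are called with the right sign and RED", {
  prox <- c(rep(100, 3), rep(250, 3))
  dist <- c(rep(150, 3), rep(50, 3))
  ev <- call_utr3_apa(pair_matrix(prox, dist))
  expect_equal(ev$class, "SHORTENED")
  expect_lt(ev$RED, 0)
  expect_equal(ev$RED, ev$RE_trt - ev$RE_ctrl)
  expect_equal(ev$aUTR_len, 800)
  # condition exchange maps SHORTENED <-> LENGTHENED at identical p
  design_sw <- default_design()
  design_sw$condition <- rep(c("treated", "control"), each = 3)
  ev_sw <- call_utr3_apa(pair_matrix(prox, dist, design = design_sw))
  expect_equal(ev_sw$class, "LENGTHENED")
  expect_equal(ev_sw$p_value, ev$p_value)
  expect_equal(ev_sw$RED, -ev$RED)
})

test_that("per-gene relative abundances sum to one across isoforms", {
  m <- small_counts()
  cs <- apakit:::gene_condition_sums(m$counts, m$samples)
  for (g in unique(m$pas$gene_id)[1:8]) {
    ix <- which(m$pas$gene_id == g)
    fr <- cs[ix, "ctrl"] / sum(cs[ix, "ctrl"])
    expect_equal(sum(fr), 1)
  }
})

test_that("intronic calls oppose the UTR3 set and swap under relabeling", {
  design <- default_design()
  counts <- rbind(int = c(20, 25, 22, 80, 85, 90),
                  utr = c(180, 175, 178, 120, 115, 110))
  pas <- data.frame(pas_id = c("i1", "u1"), gene_id = "g1", chrom = "chr1",
                    strand = "+", pos = c(500L, 2000L),
                    region = c("INTRON", "UTR3"),
                    ordinal = c("+1", NA), utr3_len = c(NA, 300L),
                    stringsAsFactors = FALSE)
  m <- toy_pas_matrix(counts, pas, design)
  ev <- call_intronic_apa(m)
  expect_equal(ev$class, "ACTIVATED")
  expect_gt(ev$delta_abundance, 0)
  expect_lt(ev$RED, 0)  # shift toward the proximal (intronic) isoform
  design2 <- design; design2$condition <- rep(c("treated", "control"), each = 3)
  m2 <- toy_pas_matrix(counts, pas, design2)
  ev2 <- call_intronic_apa(m2)
  expect_equal(ev2$class, "REPRESSED")
  expect_equal(ev2$p_value, ev$p_value)
})

test_that("genes without an intronic or UTR3 PAS are excluded", {
  pas <- data.frame(pas_id = c("u1", "u2"), gene_id = "g1", chrom = "chr1",
                    strand = "+", pos = c(1000L, 1500L), region = "UTR3",
                    stringsAsFactors = FALSE)
  m <- toy_pas_matrix(matrix(50L, 2, 6), pas)
  expect_equal(nrow(call_intronic_apa(m)), 0)
})

test_that("weighted 3'UTR length is the read-weighted mean and convex", {
  prox <- c(30, 0, 0, 0, 0, 0)  # 30 reads, length 200, control only
  dist <- c(10, 0, 0, 0, 0, 0)  # 10 reads, length 1000
  m <- pair_matrix(prox, dist)
  wl <- weighted_utr3_length(m)
  expect_equal(wl$wlen_ctrl, (200 * 30 + 1000 * 10) / 40)
  expect_true(is.na(wl$wlen_trt))
  # single isoform: its own length
  m1 <- pair_matrix(c(5, 5, 5, 5, 5, 5), rep(0, 6))
  expect_equal(weighted_utr3_length(m1)$wlen_ctrl, 200)
  # convex hull property on the simulated fixture
  wl2 <- weighted_utr3_length(small_counts())
  p <- small_counts()$pas
  for (i in seq_len(min(nrow(wl2), 10))) {
    ix <- which(p$gene_id == wl2$gene_id[i] & p$region == "UTR3")
    rng <- range(p$utr3_len[ix])
    expect_gte(wl2$wlen_ctrl[i], rng[1])
    expect_lte(wl2$wlen_ctrl[i], rng[2])
  }
})

test_that("aUTR bins are balanced and track a programmed RED gradient", {
  set.seed(6)
  autr <- sample(100:5000, 100)
  ev <- structure(
    data.frame(gene_id = sprintf("g%d", 1:100), RED = -log(autr) + rnorm(100, 0, 0.05),
               aUTR_len = autr),
    class = c("apa_events", "data.frame"), mode = "UTR3")
  ab <- autr_bin_analysis(ev, n_bins = 5)
  expect_equal(ab$bins$n, rep(20, 5))
  expect_true(all(diff(ab$bins$mean_RED) < 0))  # monotone decreasing
  expect_lt(ab$p_value, 0.001)
  # too few genes
  expect_true(is.na(autr_bin_analysis(ev[1:3, ], n_bins = 5)$p_value))
})

test_that("bin1-vs-bin5 p-values are uniform when bins share a distribution", {
  set.seed(7)
  ps <- replicate(200, {
    ev <- structure(
      data.frame(gene_id = sprintf("g%d", 1:100), RED = rnorm(100),
                 aUTR_len = sample(100:5000, 100)),
      class = c("apa_events", "data.frame"), mode = "UTR3")
    autr_bin_analysis(ev, 5)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, stats::punif))$p.value, 0.01)
})

test_that("intron-position profile applies gene and read floors", {
  design <- default_design()
  mk <- function(n_introns, reads) {
    data.frame(pas_id = paste0("i", n_introns, "_", reads), gene_id = paste0("g", n_introns, reads),
               chrom = "chr1", strand = "+", pos = 100L, region = "INTRON",
               ordinal = "+1", n_introns = n_introns, stringsAsFactors = FALSE)
  }
  pas <- rbind(mk(5, 10), mk(3, 10), mk(5, 1))
  # give each isoform constant counts = reads per sample except the 1-read one
  counts <- rbind(matrix(10L, 1, 6), matrix(10L, 1, 6),
                  matrix(c(1L, rep(0L, 5)), 1, 6))
  # add UTR3 rows so size factors are defined
  pas_u <- data.frame(pas_id = c("u1", "u2", "u3"), gene_id = pas$gene_id,
                      chrom = "chr1", strand = "+", pos = 2000L,
                      region = "UTR3", ordinal = NA, n_introns = pas$n_introns,
                      stringsAsFactors = FALSE)
  m <- toy_pas_matrix(rbind(pas, pas_u)[, ],
                      counts = rbind(counts, matrix(50L, 3, 6)),
                      design = design)
  prof <- intron_position_profile(m, min_introns = 4, min_reads = 2)
  # only the 5-intron, 10-read isoform contributes to the +1 group
  expect_equal(prof$profile$n[prof$profile$ordinal == "+1"], 1)
})

test_that("doubling +1 intronic usage yields a 5'-biased centered profile", {
  design <- default_design()
  set.seed(8)
  rows <- list(); cnts <- list(); k <- 0
  for (g in 1:40) {
    ords <- c("+1", "+2", "MIDDLE", "-2", "-1")
    for (o in ords) {
      k <- k + 1
      base <- rpois(6, 40)
      if (o == "+1") base[4:6] <- rpois(3, 80)  # treated doubled
      rows[[k]] <- data.frame(pas_id = sprintf("p%d", k),
                              gene_id = sprintf("g%d", g), chrom = "chr1",
                              strand = "+", pos = k * 10L, region = "INTRON",
                              ordinal = o, n_introns = 6L,
                              stringsAsFactors = FALSE)
      cnts[[k]] <- base
    }
    k <- k + 1
    rows[[k]] <- data.frame(pas_id = sprintf("p%d", k),
                            gene_id = sprintf("g%d", g), chrom = "chr1",
                            strand = "+", pos = 100000L, region = "UTR3",
                            ordinal = NA, n_introns = 6L,
                            stringsAsFactors = FALSE)
    cnts[[k]] <- rpois(6, 200)
  }
  m <- toy_pas_matrix(do.call(rbind, cnts), do.call(rbind, rows), design)
  prof <- intron_position_profile(m)
  pr <- prof$profile
  expect_equal(pr$ordinal[which.max(pr$centered)], "+1")
  expect_lt(prof$p_value, 0.05)
  # mean-centering: the five group means average to ~zero
  expect_lt(abs(mean(pr$centered)), 1e-9)
})

test_that("quadrant bookkeeping covers shared genes exactly once", {
  m <- small_counts()
  ev_u <- call_utr3_apa(m)
  ev_i <- call_intronic_apa(m)
  q <- apa_quadrants(ev_u, ev_i)
  expect_equal(sum(q), length(intersect(ev_u$gene_id, ev_i$gene_id)))
})
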