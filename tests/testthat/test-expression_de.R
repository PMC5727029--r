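sim_gene_counts <- function(n_genes, mult, depth = 1000, dispersion = 0.05,
                            n_reps = 3, seed = 1) {
  set.seed(seed)
  cond <- rep(c("control", "treated"), each = n_reps)
  mat <- sapply(seq_along(cond), function(s) {
    mu <- depth * if (cond[s] == "treated") mult else rep(1, n_genes)
    rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  })
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  colnames(mat) <- sprintf("%s_%d", cond, rep(seq_len(n_reps), 2))
  list(counts = mat, condition = cond)
}

test_that("size factors respect identity and scaling properties", {
  set.seed(9)
  m <- matrix(rnbinom(600, mu = 200, size = 5), 100, 6)
  m2 <- cbind(m[, 1], m[, 1], m[, 2:5])
  sf <- estimate_size_factors(m2)
  expect_equal(sf[1], sf[2])
  # rescaling one column by c rescales its size factor relative to every
  # other sample by c (the geometric-mean reference absorbs c^(1/m))
  m3 <- m; m3[, 3] <- m[, 3] * 4L
  sf0 <- estimate_size_factors(m); sf3 <- estimate_size_factors(m3)
  expect_equal(sf3[3] / sf3[1], 4 * sf0[3] / sf0[1], tolerance = 1e-9)
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(10)
  m <- matrix(rnbinom(1200, mu = 150, size = 3), 200, 6) + 1L
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("de_test recovers programmed 2-fold changes in both directions", {
  # balanced program so median-of-ratios normalization is unbiased; five
  # replicates give the per-gene Welch t enough power to clear BH
  mult <- rep(1, 1000); mult[1:75] <- 2; mult[76:150] <- 0.5
  sim <- sim_gene_counts(1000, mult, dispersion = 0.02, n_reps = 5, seed = 11)
  de <- de_test(sim$counts, sim$condition)
  ids <- rownames(sim$counts)
  expect_gte(mean(ids[1:75] %in% de$gene_id[de$class == "UP"]), 0.9)
  expect_gte(mean(ids[76:150] %in% de$gene_id[de$class == "DOWN"]), 0.9)
  expect_equal(mean(de$log2_ratio[1:75]), 1, tolerance = 0.2)
  expect_equal(mean(de$log2_ratio[76:150]), -1, tolerance = 0.2)
  # observed FDR among calls near the nominal 0.1 level
  called <- de$gene_id[de$class != "NC"]
  expect_lte(mean(!(called %in% ids[1:150])), 0.15)
})

test_that("all-null and identical-matrix inputs give zero calls", {
  sim <- sim_gene_counts(500, rep(1, 500), seed = 12)
  de <- de_test(sim$counts, sim$condition)
  expect_equal(sum(de$class != "NC"), 0)
  m <- sim$counts[, 1:3]
  de2 <- de_test(cbind(m, m), rep(c("control", "treated"), each = 3))
  expect_equal(sum(de2$class != "NC"), 0)
  expect_error(de_test(sim$counts[, c(1, 4)], c("control", "treated")),
               "replicates")
})

test_that("de_test is invariant to gene order and replicate relabeling", {
  sim <- sim_gene_counts(50, c(rep(2, 10), rep(1, 40)), seed = 13)
  de1 <- de_test(sim$counts, sim$condition)
  perm <- sample(nrow(sim$counts))
  de2 <- de_test(sim$counts[perm, ], sim$condition)
  expect_equal(de2$p_value[match(de1$gene_id, de2$gene_id)], de1$p_value)
  de3 <- de_test(sim$counts[, c(2, 3, 1, 4:6)], sim$condition)
  expect_equal(de3$p_value, de1$p_value)
})

cds_toy <- function() {
  # two genes; g2's CDS overlaps g1's on the same strand for ambiguity tests
  a1 <- 'gene_id "g1"; transcript_id "g1.t1";'
  a2 <- 'gene_id "g2"; transcript_id "g2.t1";'
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    sprintf("chr1\tt\texon\t1\t300\t.\t+\t.\t%s", a1),
    sprintf("chr1\tt\tCDS\t51\t150\t.\t+\t0\t%s", a1),
    sprintf("chr1\tt\texon\t101\t400\t.\t+\t.\t%s", a2),
    sprintf("chr1\tt\tCDS\t120\t250\t.\t+\t0\t%s", a2)), gtf)
  load_annotation(gtf)
}

test_that("CDS-restricted counting excludes UTR reads and ambiguity", {
  models <- cds_toy()
  sam <- tempfile(fileext = ".sam")
  seq20 <- strrep("A", 20)
  write_toy_sam(c(
    sam_record("utr_only", 0, "chr1", 260, "20M", seq20),   # past both CDS
    sam_record("cds1bp", 0, "chr1", 32, "20M", seq20),      # ends at 51: 1 bp in g1 CDS
    sam_record("ambig", 0, "chr1", 130, "20M", seq20),      # inside both CDS
    sam_record("g2only", 0, "chr1", 200, "20M", seq20),     # g2 CDS only
    sam_record("wrongstrand", 16, "chr1", 60, "20M", seq20) # minus-strand read
  ), c(chr1 = 1000L), sam)
  cnt <- count_cds_reads(c(s1 = sam), models)
  expect_equal(cnt["g1", "s1"], 1L)
  expect_equal(cnt["g2", "s1"], 1L)
})

test_that("region-restricted ratios localize a downstream drop", {
  a <- 'gene_id "g1"; transcript_id "g1.t1";'
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(sprintf("chr1\tt\texon\t1\t2000\t.\t+\t.\t%s", a),
               sprintf("chr1\tt\tCDS\t51\t1800\t.\t+\t0\t%s", a)), gtf)
  model <- load_annotation(gtf)[["g1"]]
  design <- default_design(n_reps = 1)
  seq20 <- strrep("A", 20)
  mk_sam <- function(n_up, n_dn) {
    f <- tempfile(fileext = ".sam")
    recs <- c(
      if (n_up > 0) sapply(seq_len(n_up), function(i)
        sam_record(paste0("u", i), 0, "chr1", 100 + i, "20M", seq20)),
      if (n_dn > 0) sapply(seq_len(n_dn), function(i)
        sam_record(paste0("d", i), 0, "chr1", 1500 + i, "20M", seq20)))
    write_toy_sam(recs, c(chr1 = 3000L), f)
    f
  }
  sams <- c(ctrl_1 = mk_sam(100, 100), trt_1 = mk_sam(100, 50))
  rr <- region_restricted_ratio(sams, model, breakpoint = 1000L,
                                samples = design)
  expect_equal(rr$upstream$log2_ratio, 0, tolerance = 0.02)
  expect_equal(rr$downstream$log2_ratio, -1, tolerance = 0.05)
  # breakpoint at the gene start: downstream covers the whole gene
  rr0 <- region_restricted_ratio(sams, model, breakpoint = 0L,
                                 samples = design)
  expect_equal(rr0$downstream$ctrl, 200)
  expect_error(region_restricted_ratio(sams, model, breakpoint = 5000L,
                                       samples = design), "outside")
})

test_that("platform correlation behaves on identical/shared/independent data", {
  set.seed(14)
  cond <- rep(c("control", "treated"), each = 3)
  mult <- exp(rnorm(1000, 0, 1))  # broad expression-change program
  sim1 <- sim_gene_counts(1000, mult, depth = 500, dispersion = 0.1, seed = 15)
  sim2 <- sim_gene_counts(1000, mult, depth = 500, dispersion = 0.1, seed = 16)
  lr <- function(sim) {
    sf <- estimate_size_factors(sim$counts)
    norm <- sweep(sim$counts, 2, sf, "/")
    log2((rowSums(norm[, 4:6]) + 0.5) / (rowSums(norm[, 1:3]) + 0.5))
  }
  expect_equal(platform_correlation(sim1$counts, lr(sim1), cond), 1,
               tolerance = 1e-9)
  expect_gt(platform_correlation(sim1$counts, lr(sim2), cond), 0.8)
  simN <- sim_gene_counts(1000, rep(1, 1000), depth = 500, dispersion = 0.1,
                          seed = 17)
  expect_lt(abs(platform_correlation(sim1$counts, lr(simN), cond)), 0.15)
  expect_true(is.na(platform_correlation(sim1$counts[1:2, ], lr(sim1)[1:2], cond)))
})

test_that("coupling detects a programmed APA-expression link", {
  set.seed(18)
  ev <- structure(data.frame(
    gene_id = sprintf("g%04d", 1:300),
    class = rep(c("SHORTENED", "LENGTHENED", "NC"), each = 100)),
    class = c("apa_events", "data.frame"), mode = "UTR3")
  lr <- c(rnorm(100, 0, 0.3), rnorm(100, -1, 0.3), rnorm(100, 0, 0.3))
  de <- structure(data.frame(gene_id = ev$gene_id, log2_ratio = lr),
                  class = c("de_results", "data.frame"))
  cp <- apa_expression_coupling(ev, de)
  t_ln <- cp$tests[cp$tests$class_a == "LENGTHENED" & cp$tests$class_b == "NC", ]
  expect_lt(t_ln$p_value, 1e-6)
  expect_lt(cp$summary$median[cp$summary$class == "LENGTHENED"], -0.5)
  # a one-gene class is summarized but not tested
  ev2 <- ev[c(1, 101, 201:210), ]
  cp2 <- apa_expression_coupling(ev2, de)
  expect_true("SHORTENED" %in% cp2$summary$class)
  expect_true(is.na(cp2$tests$p_value[cp2$tests$class_a == "LENGTHENED" &
                                        cp2$tests$class_b == "SHORTENED"]))
})
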