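# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

with_fixture <- function(name, fn) {
  if (!exists(name, envir = fixture_cache))
    assign(name, fn(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

small_truth <- function() with_fixture("small_truth", function()
  generate_reference(ref_config(n_genes = 40, prop_shortened = 0.2,
                                prop_intronic_activated = 0.1,
                                p_intronic_pas = 0.6),
                     seed = 101))

small_counts <- function() with_fixture("small_counts", function()
  simulate_counts(small_truth(), depth = 300, dispersion = 0.1, seed = 102))

small_models <- function() with_fixture("small_models", function()
  load_annotation(small_truth()$gtf))

small_genome <- function() with_fixture("small_genome", function()
  load_genome(small_truth()$genome_fasta))

# a pas_matrix built directly from explicit counts + metadata
toy_pas_matrix <- function(counts, pas, design = default_design()) {
  rownames(counts) <- pas$pas_id
  colnames(counts) <- design$sample_id
  for (col in c("gene_id", "region", "ordinal", "hexamer"))
    if (is.null(pas[[col]])) pas[[col]] <- NA_character_
  for (col in c("utr3_len", "n_introns"))
    if (is.null(pas[[col]])) pas[[col]] <- NA_integer_
  apakit:::new_pas_matrix(counts, pas, design)
}

# write a SAM file from alignment records over a toy genome
write_toy_sam <- function(records, chrom_len, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len),
                      as.integer(chrom_len)))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos1, cigar, seq) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, chrom, pos1, cigar, seq, strrep("I", nchar(seq)))
}
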