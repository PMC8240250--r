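test_that("simulation is deterministic given the seed", {
  a <- sim_genome(sim_config(seed = 71, n_genes = 3, n_falsitron_loci = 2,
                             repeat_lengths = c(5, 9), depth = 15))
  b <- sim_genome(sim_config(seed = 71, n_genes = 3, n_falsitron_loci = 2,
                             repeat_lengths = c(5, 9), depth = 15))
  expect_equal(as.character(a$genome), as.character(b$genome))
  expect_equal(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
  ra <- sim_reads(a, "cDNA")
  rb <- sim_reads(b, "cDNA")
  expect_equal(as.data.frame(ra[, c("read_id", "start", "end", "seq")]),
               as.data.frame(rb[, c("read_id", "start", "end", "seq")]))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_write(a, d1, modes = "cDNA")
  sim_write(b, d2, modes = "cDNA")
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("empty configurations produce empty outputs", {
  sim <- sim_genome(sim_config(n_genes = 0, n_falsitron_loci = 0, depth = 0))
  expect_length(sim$genome, 0)
  expect_equal(nrow(sim$annotation), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(sim_reads(sim, "cDNA")), 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(p_slip = 1.5), "p_slip")
  expect_error(sim_config(n_falsitron_loci = 11, n_genes = 10), "exceed")
  expect_error(sim_config(repeat_lengths = 2), "3, 16")
  expect_error(sim_config(intron_length = c(10, 20)), "40")
})

test_that("planted repeat copies are verbatim in the genome at both flanks", {
  sim <- sim_genome(sim_config(seed = 72))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    r <- tr$repeat_length
    chrom_seq <- as.character(sim$genome[[tr$chrom]])
    if (tr$strand == "+") {
      copy1 <- substr(chrom_seq, tr$start, tr$start + r - 1)
      copy2 <- substr(chrom_seq, tr$end, tr$end + r - 1)
      expect_equal(copy1, tr$repeat_kmer)
    } else {
      copy1 <- substr(chrom_seq, tr$start - r + 2, tr$start + 1)
      copy2 <- substr(chrom_seq, tr$end - r + 2, tr$end + 1)
      expect_equal(
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(copy2))),
        tr$repeat_kmer
      )
    }
    expect_equal(copy1, copy2)
  }
})

test_that("truth boundary dinucleotides match the canonical flag", {
  default_sim <- sim_genome(sim_config(seed = 73))
  expect_false(any(default_sim$truth$canonical_boundaries))
  dn <- splice_site_dinucleotides(default_sim$truth, default_sim$genome)
  expect_false(any(dn$donor_dinucleotide == "GT" &
                     dn$acceptor_dinucleotide == "AG"))

  can_sim <- sim_genome(sim_config(n_genes = 3, n_falsitron_loci = 2,
                                   repeat_lengths = c(6, 8), depth = 10,
                                   canonical_boundaries = TRUE, seed = 74))
  expect_true(all(can_sim$truth$canonical_boundaries))
  dnc <- splice_site_dinucleotides(can_sim$truth, can_sim$genome)
  expect_true(all(dnc$donor_dinucleotide == "GT"))
  expect_true(all(dnc$acceptor_dinucleotide == "AG"))
})

read_has_truth_skip <- function(reads, tr) {
  in_tx <- reads$transcript_id == tr$transcript_id
  vapply(reads$skips[in_tx], function(m) {
    any(m[, 1] == tr$start & m[, 2] == tr$end)
  }, logical(1))
}

test_that("slippage appears only in RT-based modes, at the configured rate", {
  cfg0 <- sim_config(n_genes = 2, n_falsitron_loci = 1, repeat_lengths = 8,
                     p_slip = 0, depth = 25, seed = 75)
  sim0 <- sim_genome(cfg0)
  r0 <- sim_reads(sim0, "cDNA")
  expect_false(any(read_has_truth_skip(r0, sim0$truth[1, ])))

  cfg1 <- sim_config(n_genes = 2, n_falsitron_loci = 1, repeat_lengths = 8,
                     p_slip = 1, depth = 50, seed = 76)
  sim1 <- sim_genome(cfg1)
  r1 <- sim_reads(sim1, "cDNA")
  expect_true(all(read_has_truth_skip(r1, sim1$truth[1, ])))
  expect_equal(sum(read_has_truth_skip(r1, sim1$truth[1, ])), 50)

  # direct RNA never carries the artifact, and warns that p_slip is ignored
  expect_warning(rd <- sim_reads(sim1, "dRNA"), "slippage")
  expect_false(any(read_has_truth_skip(rd, sim1$truth[1, ])))
})

test_that("artifact read counts follow the binomial slippage model", {
  p <- 0.3; n <- 200
  counts <- vapply(1:25, function(s) {
    sim <- sim_genome(sim_config(n_genes = 1, n_falsitron_loci = 1,
                                 repeat_lengths = 8, p_slip = p, depth = n,
                                 seed = 7000 + s))
    sum(read_has_truth_skip(sim_reads(sim, "dcDNA"), sim$truth[1, ]))
  }, numeric(1))
  bounds <- qbinom(c(0.0005, 0.9995), n, p)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
  expect_gt(var(counts), 0)
})

test_that("every true intron is spliced out in all three modes", {
  sim <- small_sim(seed = 78)
  introns <- transcript_junctions(sim$annotation)
  for (mode in c("dRNA", "cDNA", "dcDNA")) {
    reads <- suppressWarnings(sim_reads(sim, mode))
    observed <- extract_junctions(reads)
    missing <- dplyr::anti_join(introns, observed,
                                by = c("chrom", "start", "end"))
    expect_equal(nrow(missing), 0)
  }
})

test_that("PCR duplication replicates slipped molecules in cDNA mode only", {
  cfg <- sim_config(n_genes = 1, n_falsitron_loci = 1, repeat_lengths = 8,
                    p_slip = 0.5, depth = 40, pcr_duplication = 3, seed = 79)
  sim <- sim_genome(cfg)
  cdna <- sim_reads(sim, "cDNA")
  dcdna <- sim_reads(sim, "dcDNA")
  expect_equal(nrow(dcdna), 40)
  n_slipped_molecules <- sum(cdna$artifact) / 3
  expect_equal(nrow(cdna), 40 + 2 * n_slipped_molecules)
})
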