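drna_exons_fixture <- function(starts, ends, strand = "+", tx = "t1") {
  tibble::tibble(
    transcript_id = tx, gene_id = "g1", chrom = "c1", strand = strand,
    start = as.integer(starts), end = as.integer(ends),
    source_label = "dRNA"
  )
}

test_that("filter 1a: containment within a single exon, boundaries included", {
  ex <- drna_exons_fixture(c(100, 500), c(400, 600))
  j <- tibble::tibble(chrom = "c1", start = 150L, end = 350L, strand = "*")
  expect_equal(contained_in_exon(j, ex)$host_transcript_id, "t1")

  j2 <- tibble::tibble(chrom = "c1", start = 150L, end = 450L, strand = "*")
  expect_true(is.na(contained_in_exon(j2, ex)$host_transcript_id))

  j3 <- tibble::tibble(chrom = "c1", start = 100L, end = 400L, strand = "*")
  expect_equal(contained_in_exon(j3, ex)$host_transcript_id, "t1")

  # strand-incompatible exon does not host
  j4 <- tibble::tibble(chrom = "c1", start = 150L, end = 350L, strand = "-")
  expect_true(is.na(contained_in_exon(j4, ex)$host_transcript_id))
})

test_that("filter 1b: junction ends must reside in two adjacent exons", {
  ex <- drna_exons_fixture(c(100, 500, 700), c(200, 600, 800))
  j <- tibble::tibble(chrom = "c1", start = 180L, end = 520L, strand = "*")
  expect_equal(spans_adjacent_exons(j, ex)$host_transcript_id, "t1")

  j2 <- tibble::tibble(chrom = "c1", start = 180L, end = 720L, strand = "*")
  expect_true(is.na(spans_adjacent_exons(j2, ex)$host_transcript_id))

  # entirely inside one exon: 1a territory, not 1b
  j3 <- tibble::tibble(chrom = "c1", start = 120L, end = 180L, strand = "*")
  expect_true(is.na(spans_adjacent_exons(j3, ex)$host_transcript_id))
})

test_that("splice-site dinucleotides respect strand orientation", {
  # intron [10, 30) on a 50-nt contig: GT...AG inside
  seq <- paste0("AAAAAAAAAA", "GTAAGTTTTTTTTTTTTTCAG", strrep("C", 19))
  g <- toy_genome(c1 = seq)
  jp <- tibble::tibble(chrom = "c1", start = 10L, end = 31L, strand = "+")
  dn <- splice_site_dinucleotides(jp, g)
  expect_equal(dn$donor_dinucleotide, "GT")
  expect_equal(dn$acceptor_dinucleotide, "AG")

  # minus strand: forward CT...AC reads GT...AG after reverse complement
  seq_m <- paste0("AAAAAAAAAA", "CTTTTTTTTTTTTTTTTTAC", strrep("C", 20))
  gm <- toy_genome(c1 = seq_m)
  jm <- tibble::tibble(chrom = "c1", start = 10L, end = 30L, strand = "-")
  dm <- splice_site_dinucleotides(jm, gm)
  expect_equal(dm$donor_dinucleotide, "GT")
  expect_equal(dm$acceptor_dinucleotide, "AG")

  # exon interior: non-canonical pair comes back verbatim
  gi <- toy_genome(c1 = paste0(strrep("A", 10), "CATTTTTTGG", strrep("A", 10)))
  ji <- tibble::tibble(chrom = "c1", start = 10L, end = 20L, strand = "+")
  di <- splice_site_dinucleotides(ji, gi)
  expect_equal(di$donor_dinucleotide, "CA")
  expect_equal(di$acceptor_dinucleotide, "GG")

  ju <- tibble::tibble(chrom = "c1", start = 10L, end = 20L, strand = "*")
  expect_error(splice_site_dinucleotides(ju, gi), "unstranded")
  je <- tibble::tibble(chrom = "c1", start = 0L, end = 1L, strand = "+")
  expect_error(splice_site_dinucleotides(je, gi), "edge")
})

test_that("detector recovers exactly the planted loci with their evidence", {
  sim <- sim_genome(sim_config(seed = 101))
  cdna <- sim_reads(sim, "cDNA")
  drna <- suppressWarnings(sim_reads(sim, "dRNA"))
  res <- detect_falsitrons(extract_junctions(cdna, "cDNA"), drna,
                           sim$annotation, sim$genome)
  expect_equal(nrow(res), nrow(sim$truth))
  got <- dplyr::arrange(tidy(res), chrom, start)
  want <- dplyr::arrange(sim$truth, chrom, start)
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  expect_true(all(got$filter_path == "1a"))
  expect_equal(got$host_transcript_id, want$transcript_id)
  expect_true(all(got$cdna_split_support >= 5))
  expect_true(all(got$drna_coverage >= 5))
  # no candidate carries a canonical splice-site pair
  expect_false(any(paste0(got$donor_dinucleotide, "-",
                          got$acceptor_dinucleotide) == "GT-AG"))
  # true introns are never reported
  introns <- transcript_junctions(sim$annotation)
  expect_equal(nrow(dplyr::semi_join(got, introns,
                                     by = c("chrom", "start", "end"))), 0)
})

test_that("junctions present in the direct-RNA data are excluded", {
  sim <- small_sim(seed = 31)
  drna <- suppressWarnings(sim_reads(sim, "dRNA"))
  # feed the dRNA junctions through as if they were cDNA evidence:
  # everything is shared, so nothing survives the absence filter
  dj <- extract_junctions(drna, "cDNA")
  res <- detect_falsitrons(dj, drna, sim$annotation, sim$genome)
  expect_equal(nrow(res), 0)
  expect_equal(unname(glance(res)$absent_in_drna), 0)
})

test_that("raising min_coverage never adds candidates", {
  sim <- small_sim(seed = 32)
  cdna <- sim_reads(sim, "cDNA")
  drna <- suppressWarnings(sim_reads(sim, "dRNA"))
  cj <- extract_junctions(cdna, "cDNA")
  lo <- detect_falsitrons(cj, drna, sim$annotation, sim$genome,
                          detector_params(min_coverage = 2))
  hi <- detect_falsitrons(cj, drna, sim$annotation, sim$genome,
                          detector_params(min_coverage = 8))
  expect_lte(nrow(hi), nrow(lo))
  expect_equal(nrow(dplyr::anti_join(tidy(hi), tidy(lo),
                                     by = c("chrom", "start", "end"))), 0)
})

test_that("the splice-site filter removes planted canonical-boundary loci", {
  sim <- sim_genome(sim_config(n_genes = 4, n_falsitron_loci = 3,
                               repeat_lengths = c(6, 8, 10), depth = 40,
                               canonical_boundaries = TRUE, seed = 33))
  expect_true(all(sim$truth$canonical_boundaries))
  cdna <- sim_reads(sim, "cDNA")
  drna <- suppressWarnings(sim_reads(sim, "dRNA"))
  res <- detect_falsitrons(extract_junctions(cdna, "cDNA"), drna,
                           sim$annotation, sim$genome)
  log <- glance(res)
  # the loci reach the splice-site stage, then all are filtered out
  expect_equal(unname(log$within_drna_exons), 3)
  expect_equal(nrow(res), 0)
})

test_that("detector validates genome completeness and parameters", {
  sim <- small_sim(seed = 34)
  cdna <- sim_reads(sim, "cDNA")
  drna <- suppressWarnings(sim_reads(sim, "dRNA"))
  cj <- extract_junctions(cdna, "cDNA")
  expect_error(
    detect_falsitrons(cj, drna, sim$annotation, sim$genome[-1]),
    "chr1"
  )
  expect_error(detector_params(min_coverage = 0), "min_coverage")
  expect_error(detector_params(canonical_pairs = "GTAG"), "GT-AG")
})
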