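test_that("splice_windows centres windows on the splice-site boundaries", {
  set.seed(99)
  seq <- rand_seq(600)
  g <- toy_genome(c1 = seq)
  j <- tibble::tibble(chrom = "c1", start = 200L, end = 300L, strand = "+")
  w <- splice_windows(j, g, window = 40)
  expect_equal(w$w5, substr(seq, 181, 220))   # genome[180:220)
  expect_equal(w$w3, substr(seq, 281, 320))   # genome[280:320)
  expect_equal(c(w$motif5_lo, w$motif5_hi), c(21, 22))
  expect_equal(c(w$motif3_lo, w$motif3_hi), c(19, 20))
  expect_equal(w$w5, paste0(substr(seq, 181, 200), substr(seq, 201, 220)))

  w4 <- splice_windows(j, g, window = 4)
  expect_equal(w4$w5, substr(seq, 199, 202))  # exactly the boundary dinucleotides
  expect_equal(c(w4$motif5_lo, w4$motif5_hi), c(3, 4))

  # minus strand: reverse complement of the mirrored plus-strand windows
  jm <- dplyr::mutate(j, strand = "-")
  wm <- splice_windows(jm, g, window = 40)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  expect_equal(wm$w5, rc(substr(seq, 281, 320)))
  expect_equal(wm$w3, rc(substr(seq, 181, 220)))
  expect_equal(c(wm$motif5_lo, wm$motif5_hi), c(21, 22))
  expect_equal(c(wm$motif3_lo, wm$motif3_hi), c(19, 20))

  # contig edge: truncated with a warning
  je <- tibble::tibble(chrom = "c1", start = 10L, end = 300L, strand = "+")
  expect_warning(we <- splice_windows(je, g, window = 40), "truncated")
  expect_equal(nchar(we$w5), 30)
  expect_equal(c(we$motif5_lo, we$motif5_hi), c(11, 12))
})

test_that("max_direct_repeat finds planted shared k-mers at the motifs", {
  # plant an 8-mer across both motifs of otherwise unrelated windows
  set.seed(4)
  repeat {
    w5 <- rand_seq(40); w3 <- rand_seq(40)
    substr(w5, 18, 25) <- "ACCTCAGT"
    substr(w3, 16, 23) <- "ACCTCAGT"
    if (oracle_max_shared_kmer(w5, w3, c(21, 22), c(19, 20)) == 8) break
  }
  res <- max_direct_repeat(w5, w3, c(21, 22), c(19, 20))
  expect_equal(res$repeat_length, 8)
  expect_equal(res$repeat_kmer, "ACCTCAGT")
  expect_equal(res$repeat_pos5, 18)
  expect_equal(res$repeat_pos3, 16)
  expect_true(res$overlaps_motifs)

  # windows sharing nothing at the motifs
  w5b <- strrep("A", 40); w3b <- strrep("C", 40)
  res0 <- max_direct_repeat(w5b, w3b, c(21, 22), c(19, 20))
  expect_equal(res0$repeat_length, 0)
  expect_false(res0$overlaps_motifs)
})

test_that("repeat search agrees with brute-force substring-pair enumeration", {
  set.seed(2024)
  plant_lens <- c(rep(NA_integer_, 120), sample(3:18, 120, replace = TRUE))
  for (pl in plant_lens) {
    wp <- random_window_pair(plant = pl)
    got <- max_direct_repeat(wp$w5, wp$w3, c(21, 22), c(19, 20),
                             repeat_params(k_min = 4, k_max = 20))
    want <- oracle_max_shared_kmer(wp$w5, wp$w3, c(21, 22), c(19, 20))
    expect_equal(got$repeat_length, want)
    if (got$repeat_length > 0) {
      # reported occurrences are verbatim and overlap the motifs
      k <- got$repeat_length
      expect_equal(substr(wp$w5, got$repeat_pos5, got$repeat_pos5 + k - 1),
                   got$repeat_kmer)
      expect_equal(substr(wp$w3, got$repeat_pos3, got$repeat_pos3 + k - 1),
                   got$repeat_kmer)
      expect_true(got$repeat_pos5 <= 22 && got$repeat_pos5 + k - 1 >= 21)
      expect_true(got$repeat_pos3 <= 20 && got$repeat_pos3 + k - 1 >= 19)
    }
  }
})

test_that("a qualifying k-mer implies a qualifying shorter k-mer (closure)", {
  set.seed(77)
  for (i in 1:150) {
    wp <- random_window_pair(plant = sample(c(NA_integer_, 5:14), 1))
    params <- repeat_params(k_min = 4, k_max = 20)
    got <- max_direct_repeat(wp$w5, wp$w3, c(21, 22), c(19, 20), params)
    if (got$repeat_length > 4) {
      shorter <- max_direct_repeat(wp$w5, wp$w3, c(21, 22), c(19, 20),
                                   repeat_params(k_min = 4,
                                                 k_max = got$repeat_length - 1))
      expect_gte(shorter$repeat_length, 4)
    }
  }
})

test_that("annotation is invariant under reverse-complementing the locus", {
  sim <- small_sim(seed = 44)
  truth <- sim$truth
  ann_fwd <- annotate_repeats(
    truth[, c("chrom", "start", "end", "strand")], sim$genome
  )
  # mirror each contig and the junction coordinates
  mirrored <- Biostrings::reverseComplement(sim$genome)
  L <- vapply(as.character(sim$genome), nchar, integer(1))[truth$chrom]
  flipped <- tibble::tibble(
    chrom = truth$chrom,
    start = as.integer(L - truth$end),
    end = as.integer(L - truth$start),
    strand = ifelse(truth$strand == "+", "-", "+")
  )
  ann_rev <- annotate_repeats(flipped, mirrored)
  expect_equal(ann_fwd$repeat_length, ann_rev$repeat_length)
  expect_equal(ann_fwd$repeat_kmer, ann_rev$repeat_kmer)
})

test_that("annotate_repeats recovers planted repeat lengths exactly", {
  sim <- sim_genome(sim_config(seed = 45))
  ann <- annotate_repeats(sim$truth[, c("chrom", "start", "end", "strand")],
                          sim$genome)
  expect_equal(ann$repeat_length, sim$truth$repeat_length)
  expect_equal(ann$repeat_kmer, sim$truth$repeat_kmer)
  # k_min = 3 also recovers a planted 3-nt repeat
  sim3 <- sim_genome(sim_config(n_genes = 2, n_falsitron_loci = 1,
                                repeat_lengths = 3, depth = 10, seed = 46))
  ann3 <- annotate_repeats(sim3$truth[, c("chrom", "start", "end", "strand")],
                           sim3$genome, repeat_params(k_min = 3))
  expect_equal(ann3$repeat_length, 3L)
})

test_that("repeat_summary reports fraction and lower-median repeat length", {
  annotated <- tibble::tibble(repeat_length = c(4, 4, 6, 8, 12, 0, 0, 0, 3, 2))
  s <- repeat_summary(annotated)
  expect_equal(s$n, 10)
  expect_equal(s$n_with_repeat, 5)
  expect_equal(s$fraction_with_repeat, 0.5)
  expect_equal(s$median_repeat_length, 6)
  expect_equal(s$max_repeat_length, 12)

  # lower-median convention for even counts
  s2 <- repeat_summary(tibble::tibble(repeat_length = c(4, 6, 8, 12)))
  expect_equal(s2$median_repeat_length, 6)

  s0 <- repeat_summary(tibble::tibble(repeat_length = numeric(0)))
  expect_true(is.na(s0$fraction_with_repeat))

  empty_ann <- annotate_repeats(
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), strand = character()),
    toy_genome(c1 = "ACGT")
  )
  expect_equal(nrow(empty_ann), 0)
})

test_that("planted falsitrons carry repeats far more often than true introns", {
  sim <- sim_genome(sim_config(seed = 47))
  fals <- annotate_repeats(sim$truth[, c("chrom", "start", "end", "strand")],
                           sim$genome)
  introns <- transcript_junctions(sim$annotation)
  intr <- annotate_repeats(introns, sim$genome)
  expect_equal(repeat_summary(fals)$fraction_with_repeat, 1)
  expect_lt(repeat_summary(intr)$fraction_with_repeat,
            repeat_summary(fals)$fraction_with_repeat)
})
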