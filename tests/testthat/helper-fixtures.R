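# Shared fixtures: everything is built in code at test time.

no_skips <- function() cbind(start = integer(0), end = integer(0))

skip_mat <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Minimal read tibble compatible with read_alignments() output.
make_reads <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(
      read_id = r$id %||% sprintf("r%02d", i),
      chrom = r$chrom %||% "c1",
      strand = r$strand %||% "+",
      start = as.integer(r$start),
      end = as.integer(r$end),
      skips = list(if (is.null(r$skips)) no_skips() else r$skips)
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_genome <- function(...) Biostrings::DNAStringSet(c(...))

# Deterministic random DNA for fixtures.
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small simulated study for fast unit tests.
small_sim <- function(seed = 11, ...) {
  sim_genome(sim_config(
    n_genes = 4, n_falsitron_loci = 2, repeat_lengths = c(6, 8),
    depth = 30, seed = seed, ...
  ))
}

# Brute-force oracle for the direct-repeat search: enumerate every
# substring pair of the two windows directly (expand.grid over all
# position pairs), independent of the package's set-intersection search.
oracle_max_shared_kmer <- function(w5, w3, m5, m3, k_min = 4, k_max = 20) {
  L5 <- nchar(w5); L3 <- nchar(w3)
  for (k in seq(min(k_max, L5, L3), k_min)) {
    p5 <- seq_len(L5 - k + 1)
    p5 <- p5[p5 + k - 1 >= m5[1] & p5 <= m5[2]]
    p3 <- seq_len(L3 - k + 1)
    p3 <- p3[p3 + k - 1 >= m3[1] & p3 <= m3[2]]
    if (length(p5) == 0 || length(p3) == 0) next
    g <- expand.grid(a = p5, b = p3)
    if (any(substring(w5, g$a, g$a + k - 1) == substring(w3, g$b, g$b + k - 1))) {
      return(k)
    }
  }
  0L
}

# Random window pair with an optional planted shared k-mer across both
# motifs (motifs at positions 21-22 and 19-20 of 40-nt windows).
random_window_pair <- function(plant = NA_integer_) {
  w5 <- rand_seq(40)
  w3 <- rand_seq(40)
  if (!is.na(plant)) {
    km <- rand_seq(plant)
    pick <- function(a, b) if (a >= b) a else sample(seq(a, b), 1)
    p5 <- pick(max(1, 22 - plant + 1), min(22, 40 - plant + 1))
    p3 <- pick(max(1, 20 - plant + 1), min(20, 40 - plant + 1))
    substr(w5, p5, p5 + plant - 1) <- km
    substr(w3, p3, p3 + plant - 1) <- km
  }
  list(w5 = w5, w3 = w3)
}
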