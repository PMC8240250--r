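#' Simulation configuration
#'
#' Parameters of the synthetic study: multi-exon genes with canonical
#' GT-AG introns and pyrimidine-rich 3' intron ends, a subset of exons
#' carrying a planted RT-slippage locus — a segment flanked by two
#' identical direct repeats, optionally holding a hairpin-forming
#' inverted repeat — and per-molecule slippage in the RT-based read
#' modes. Defaults define the reference conditions used throughout the
#' package's validation: 10 genes, 5 planted loci with repeat lengths
#' 4/6/8/12/16 nt, slippage probability 0.3, 100 reads per transcript.
#'
#' @param n_genes Number of genes (one transcript each, one contig each).
#' @param exons_per_gene Range (length-2) of exon counts per gene.
#' @param exon_length,intron_length Ranges of exon and intron lengths.
#' @param n_falsitron_loci Number of genes carrying a planted slippage
#'   locus (at most one per gene).
#' @param repeat_lengths Direct-repeat lengths, recycled over loci;
#'   values in `[3, 16]`.
#' @param interior_length Range of the repeat-enclosed segment length.
#' @param hairpin_stem Length of the inverted-repeat stem placed inside
#'   the segment (structural decoration; 0 disables).
#' @param p_slip Per-molecule, per-locus slippage probability in the
#'   cDNA-type modes.
#' @param depth Reads per transcript per mode.
#' @param substitution_error_rate Per-base substitution error rate
#'   applied to read sequences away from alignment-block edges.
#' @param pcr_duplication Integer duplication factor applied to slipped
#'   molecules in the PCR-amplified `cDNA` mode (1 = off).
#' @param canonical_boundaries Force the apparent slippage junction to
#'   begin `GT` and end `AG` (used to show the splice-site filter
#'   removes such loci); default `FALSE` forces non-canonical
#'   boundaries.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 10L,
                       exons_per_gene = c(3L, 5L),
                       exon_length = c(250L, 400L),
                       intron_length = c(150L, 300L),
                       n_falsitron_loci = 5L,
                       repeat_lengths = c(4L, 6L, 8L, 12L, 16L),
                       interior_length = c(60L, 140L),
                       hairpin_stem = 8L,
                       p_slip = 0.3,
                       depth = 100L,
                       substitution_error_rate = 0.005,
                       pcr_duplication = 1L,
                       canonical_boundaries = FALSE,
                       seed = 1L) {
  rng <- function(x) sort(as.integer(rep(x, length.out = 2)))
  cfg <- list(
    n_genes = as.integer(n_genes),
    exons_per_gene = rng(exons_per_gene),
    exon_length = rng(exon_length),
    intron_length = rng(intron_length),
    n_falsitron_loci = as.integer(n_falsitron_loci),
    repeat_lengths = as.integer(repeat_lengths),
    interior_length = rng(interior_length),
    hairpin_stem = as.integer(hairpin_stem),
    p_slip = as.numeric(p_slip),
    depth = as.integer(depth),
    substitution_error_rate = as.numeric(substitution_error_rate),
    pcr_duplication = as.integer(pcr_duplication),
    canonical_boundaries = isTRUE(canonical_boundaries),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 0) abort("n_genes must be >= 0")
  if (cfg$n_falsitron_loci > cfg$n_genes) {
    abort("n_falsitron_loci cannot exceed n_genes (one locus per gene)")
  }
  if (cfg$p_slip < 0 || cfg$p_slip > 1) abort("p_slip must be in [0, 1]")
  if (cfg$substitution_error_rate < 0 || cfg$substitution_error_rate > 0.5) {
    abort("substitution_error_rate must be in [0, 0.5]")
  }
  if (cfg$n_falsitron_loci > 0) {
    cfg$repeat_lengths <- rep(cfg$repeat_lengths,
                              length.out = cfg$n_falsitron_loci)
    if (any(cfg$repeat_lengths < 3 | cfg$repeat_lengths > 16)) {
      abort("repeat_lengths must lie in [3, 16]")
    }
  } else {
    cfg$repeat_lengths <- integer(0)
  }
  if (any(c(cfg$exon_length, cfg$intron_length, cfg$interior_length) < 1)) {
    abort("length ranges must be positive")
  }
  if (cfg$intron_length[1] < 40) {
    abort("introns shorter than 40 nt would not host the splice-site windows")
  }
  if (cfg$interior_length[1] < 2 * cfg$hairpin_stem + 10) {
    abort("interior_length too small for the configured hairpin stem")
  }
  if (cfg$depth < 0 || cfg$pcr_duplication < 1) {
    abort("depth must be >= 0 and pcr_duplication >= 1")
  }
  structure(cfg, class = "sim_config")
}

# Pyrimidine-rich tract for the 3' intron end.
ppt_dna <- function(n) {
  random_dna(n, prob = c(0.06, 0.38, 0.06, 0.50))
}

# Canonical intron: GT ... branch-like interior ... polypyrimidine ... AG
sim_intron <- function(len) {
  ppt <- min(18L, len - 8L)
  paste0("GT", random_dna(len - 4L - ppt), ppt_dna(ppt), "AG")
}

# Independent brute-force check used only to guarantee that the planted
# repeat is the *longest* shared motif-overlapping k-mer at the locus:
# enumerates every substring pair directly.
brute_shared_kmer_len <- function(w5, w3, m5, m3, k_max = 24L) {
  best <- 0L
  L5 <- nchar(w5); L3 <- nchar(w3)
  for (k in seq_len(min(k_max, L5, L3))) {
    found <- FALSE
    for (p5 in 1:(L5 - k + 1L)) {
      if (p5 + k - 1L < m5[1] || p5 > m5[2]) next
      s5 <- substr(w5, p5, p5 + k - 1L)
      for (p3 in 1:(L3 - k + 1L)) {
        if (p3 + k - 1L < m3[1] || p3 > m3[2]) next
        if (s5 == substr(w3, p3, p3 + k - 1L)) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) best <- k
  }
  best
}

# Build one planted slippage segment: repeat copy + interior + repeat copy.
# Returns the segment pieces in transcript orientation. The apparent
# junction is registered one base into the repeat, so its donor is
# repeat[2:3] and its acceptor is (interior[last], repeat[1]).
sim_segment <- function(r, interior_len, stem_len, canonical) {
  for (attempt in 1:100) {
    if (canonical) {
      if (r < 3) abort("canonical planted boundaries require repeat length >= 3")
      rep_kmer <- paste0("GGT", random_dna(r - 3L))
    } else {
      rep_kmer <- random_dna(r)
      if (substr(rep_kmer, 2L, 3L) %in% c("GT", "GC") && r >= 3) next
    }
    core_len <- interior_len - 2L * stem_len
    stem <- if (stem_len > 0) random_dna(stem_len) else ""
    pad_l <- core_len %/% 2L
    interior <- paste0(stem, random_dna(pad_l),
                       if (stem_len > 0) revcomp(stem) else "",
                       random_dna(core_len - pad_l))
    if (canonical) {
      substr(interior, interior_len, interior_len) <- "A"
    }
    return(list(repeat_kmer = rep_kmer, interior = interior))
  }
  abort("failed to sample a planted segment")
}

#' Generate a synthetic genome with planted RT-slippage loci
#'
#' Builds, deterministically for the configured seed, a toy genome (one
#' contig per gene), a transcript annotation, and a truth table of the
#' planted slippage loci. Every gene has canonical GT-AG introns; each
#' planted exon carries two identical direct-repeat copies of the
#' configured length around a segment the reverse transcriptase can
#' "skip". The truth interval for each locus is the apparent intron
#' produced by slippage, registered one base into the repeat so that the
#' repeat copies overlap both splice-site dinucleotide motifs (the
#' geometry a motif-anchored repeat search detects). Each locus is
#' checked, by exhaustive substring enumeration, to have its planted
#' repeat as the unique longest motif-overlapping shared k-mer; offending
#' genes are resampled.
#'
#' @param config A [sim_config()] list.
#' @return A `falsitron_sim` list: `genome` (named
#'   [Biostrings::DNAStringSet]), `annotation` (exon tibble as from
#'   [read_annotation()]), `truth` (one row per planted locus:
#'   `locus_id`, `gene_id`, `transcript_id`, `chrom`, `strand`, `start`,
#'   `end`, `repeat_length`, `repeat_kmer`, `p_slip`,
#'   `canonical_boundaries`), and `config`.
#' @export
sim_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pad <- 150L
  genome <- character(0)
  exon_rows <- list()
  truth_rows <- list()

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("G%02d", g)
    tx_id <- paste0(gene_id, ".T1")
    chrom <- sprintf("chr%d", g)
    strand <- sample(c("+", "-"), 1)
    has_locus <- g <= config$n_falsitron_loci
    r <- if (has_locus) config$repeat_lengths[g] else NA_integer_

    for (attempt in 1:50) {
      n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      exon_lens <- sample(seq(config$exon_length[1], config$exon_length[2]),
                          n_ex, replace = TRUE)
      intron_lens <- if (n_ex > 1) {
        sample(seq(config$intron_length[1], config$intron_length[2]),
               n_ex - 1L, replace = TRUE)
      } else integer(0)
      exon_seqs <- vapply(exon_lens, random_dna, character(1))
      intron_seqs <- vapply(intron_lens, sim_intron, character(1))

      seg <- NULL
      host <- NA_integer_
      m1 <- NA_integer_
      if (has_locus) {
        host <- if (n_ex >= 2) 2L else 1L
        interior_len <- sample(seq(config$interior_length[1],
                                   config$interior_length[2]), 1)
        seg <- sim_segment(r, interior_len, config$hairpin_stem,
                           config$canonical_boundaries)
        m1 <- 30L + sample(0:20, 1)
        needed <- m1 + 2L * r + interior_len + 30L
        host_len <- max(exon_lens[host], needed + sample(0:20, 1))
        m2 <- host_len - (m1 + 2L * r + interior_len)
        pre <- random_dna(m1)
        post <- random_dna(m2)
        # Avoid accidental extension of the repeat beyond its planted
        # length: the base before each copy and after each copy must differ.
        int_last <- substr(seg$interior, nchar(seg$interior), nchar(seg$interior))
        if (substr(pre, m1, m1) == int_last) {
          substr(pre, m1, m1) <- setdiff(c("A", "C", "G", "T"), int_last)[1]
        }
        int_first <- substr(seg$interior, 1L, 1L)
        if (substr(post, 1L, 1L) == int_first) {
          substr(post, 1L, 1L) <- setdiff(c("A", "C", "G", "T"), int_first)[1]
        }
        exon_seqs[host] <- paste0(pre, seg$repeat_kmer, seg$interior,
                                  seg$repeat_kmer, post)
        exon_lens[host] <- nchar(exon_seqs[host])
      }

      # Assemble the transcript-oriented gene region with flanking pads.
      pieces <- character(2 * n_ex - 1)
      pieces[seq(1, 2 * n_ex - 1, by = 2)] <- exon_seqs
      if (n_ex > 1) pieces[seq(2, 2 * n_ex - 2, by = 2)] <- intron_seqs
      region <- paste0(random_dna(pad), paste(pieces, collapse = ""),
                       random_dna(pad))
      # Transcript-oriented exon coordinates within the contig.
      starts <- integer(n_ex)
      pos <- pad
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        pos <- pos + exon_lens[e] + if (e < n_ex) intron_lens[e] else 0L
      }
      ends <- starts + exon_lens

      ok <- TRUE
      tr_start <- tr_end <- NA_integer_
      if (has_locus) {
        a <- starts[host] + m1            # first repeat copy start
        b <- a + r + nchar(seg$interior)  # second repeat copy start
        tr_start <- a + 1L                # junction register: 1 nt into repeat
        tr_end <- b + 1L
        w5 <- substr(region, tr_start - 19L, tr_start + 20L)
        w3 <- substr(region, tr_end - 19L, tr_end + 20L)
        # motif spans within the 40-nt windows (1-based positions 21-22
        # for the donor, 19-20 for the acceptor)
        found <- brute_shared_kmer_len(w5, w3, c(21L, 22L), c(19L, 20L))
        ok <- found == r
      }
      if (ok) break
    }
    if (!ok) abort(sprintf("could not plant locus in gene %s", gene_id))

    if (strand == "-") {
      L <- nchar(region)
      region <- revcomp(region)
      new_starts <- L - ends
      ends <- L - starts
      starts <- sort(new_starts)
      ends <- sort(ends)
      if (has_locus) {
        tmp <- L - tr_end
        tr_end <- L - tr_start
        tr_start <- tmp
      }
    }
    genome[chrom] <- region
    exon_rows[[g]] <- tibble(
      transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
      strand = strand, start = starts, end = ends,
      exon_rank = seq_along(starts), source_label = NA_character_
    )
    if (has_locus) {
      truth_rows[[g]] <- tibble(
        locus_id = sprintf("L%02d", g), gene_id = gene_id,
        transcript_id = tx_id, chrom = chrom, strand = strand,
        start = tr_start, end = tr_end, repeat_length = r,
        repeat_kmer = seg$repeat_kmer, p_slip = config$p_slip
      )
    }
  }

  genome_set <- Biostrings::DNAStringSet(genome)
  annotation <- bind_rows(exon_rows)
  if (nrow(annotation) == 0) {
    annotation <- tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      exon_rank = integer(), source_label = character()
    )
  }
  truth <- bind_rows(truth_rows)
  if (nrow(truth) > 0) {
    dn <- splice_site_dinucleotides(truth, genome_set)
    truth$canonical_boundaries <- dn$donor_dinucleotide == "GT" &
      dn$acceptor_dinucleotide == "AG"
  } else {
    truth <- tibble(
      locus_id = character(), gene_id = character(),
      transcript_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), repeat_length = integer(),
      repeat_kmer = character(), p_slip = numeric(),
      canonical_boundaries = logical()
    )
  }
  structure(
    list(genome = genome_set, annotation = annotation,
         truth = truth, config = config),
    class = "falsitron_sim"
  )
}

#' @export
print.falsitron_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic RT-slippage study: %d gene(s), %d planted locus/loci, p_slip = %g, seed = %d\n",
    x$config$n_genes, nrow(x$truth), x$config$p_slip, x$config$seed
  ))
  invisible(x)
}

# Substitute sequencing errors at positions away from block edges.
apply_substitutions <- function(seq, rate, protect) {
  len <- nchar(seq)
  if (rate <= 0 || len == 0) return(seq)
  n_err <- rbinom(1, len, rate)
  if (n_err == 0) return(seq)
  allowed <- setdiff(seq_len(len), protect)
  if (length(allowed) == 0) return(seq)
  pos <- sample(allowed, min(n_err, length(allowed)))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

#' Simulate aligned long reads for one sequencing protocol
#'
#' Emits full-length, pre-aligned reads of every simulated transcript.
#' All modes splice out the true introns (`N` skips). In the RT-based
#' modes (`cDNA`, `dcDNA`) each molecule additionally undergoes, per
#' planted locus on its transcript, slippage with probability `p_slip`,
#' which deletes one repeat copy plus the enclosed segment and appears
#' in the alignment as an `N` skip over the locus's truth interval. The
#' `dRNA` mode never produces the artifact; a non-zero `p_slip` is
#' ignored there with a warning. In `cDNA` mode, slipped molecules are
#' replicated `pcr_duplication` times. Deterministic given the
#' configuration seed and mode.
#'
#' @param sim A `falsitron_sim` object from [sim_genome()].
#' @param mode One of `"dRNA"`, `"cDNA"`, `"dcDNA"`.
#' @return A read tibble compatible with [read_alignments()] output
#'   (`read_id`, `chrom`, `strand`, `start`, `end`, `skips`), plus
#'   `transcript_id`, `artifact` (whether the read carries a slippage
#'   skip) and `seq`.
#' @export
sim_reads <- function(sim, mode = c("dRNA", "cDNA", "dcDNA")) {
  stopifnot(inherits(sim, "falsitron_sim"))
  mode <- match.arg(mode)
  config <- sim$config
  if (mode == "dRNA" && config$p_slip > 0) {
    warn("direct-RNA mode ignores p_slip: no reverse transcription, no slippage")
  }
  set.seed((config$seed %% 1000000L) * 1000L + c(dRNA = 1L, cDNA = 2L,
                                                 dcDNA = 3L)[[mode]])
  rt_based <- mode %in% c("cDNA", "dcDNA")
  chrom_cache <- lapply(as.character(sim$genome), identity)
  tx_ids <- unique(sim$annotation$transcript_id)
  out <- vector("list", length(tx_ids))

  for (t in seq_along(tx_ids)) {
    ex <- sim$annotation |>
      filter(.data$transcript_id == tx_ids[t]) |>
      arrange(.data$start)
    chrom <- ex$chrom[1]
    strand <- ex$strand[1]
    chrom_str <- chrom_cache[[chrom]]
    loci <- sim$truth |> filter(.data$transcript_id == tx_ids[t])
    rows <- vector("list", config$depth)
    for (k in seq_len(config$depth)) {
      blocks <- cbind(start = ex$start, end = ex$end)
      artifact <- FALSE
      if (rt_based && nrow(loci) > 0) {
        for (l in seq_len(nrow(loci))) {
          if (runif(1) < config$p_slip) {
            ts <- loci$start[l]; te <- loci$end[l]
            hit <- which(blocks[, 1] <= ts & te <= blocks[, 2])[1]
            blocks <- rbind(
              blocks[seq_len(hit - 1), , drop = FALSE],
              c(blocks[hit, 1], ts),
              c(te, blocks[hit, 2]),
              blocks[-seq_len(hit), , drop = FALSE]
            )
            artifact <- TRUE
          }
        }
      }
      nb <- nrow(blocks)
      skips <- if (nb > 1) {
        cbind(start = blocks[-nb, 2], end = blocks[-1, 1])
      } else {
        cbind(start = integer(0), end = integer(0))
      }
      block_lens <- blocks[, 2] - blocks[, 1]
      seq <- paste(substr(rep(chrom_str, nb), blocks[, 1] + 1L, blocks[, 2]),
                   collapse = "")
      # protect 3 nt around each block edge from substitution errors
      edges <- cumsum(block_lens)
      protect <- unique(unlist(lapply(c(0L, edges), function(e) {
        (e - 2L):(e + 3L)
      })))
      seq <- apply_substitutions(seq, config$substitution_error_rate, protect)
      n_copies <- if (mode == "cDNA" && artifact) config$pcr_duplication else 1L
      rows[[k]] <- tibble(
        read_id = sprintf("%s_%s_r%04d%s", mode, tx_ids[t], k,
                          if (n_copies > 1) paste0("_d", seq_len(n_copies)) else ""),
        chrom = chrom, strand = strand,
        start = as.integer(blocks[1, 1]), end = as.integer(blocks[nb, 2]),
        skips = rep(list(skips), n_copies),
        transcript_id = tx_ids[t], artifact = artifact, seq = seq
      )
    }
    out[[t]] <- list_rbind(rows)
  }
  reads <- list_rbind(out)
  if (is.null(reads) || nrow(reads) == 0) {
    reads <- tibble(read_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer(),
                    skips = list(), transcript_id = character(),
                    artifact = logical(), seq = character())
  }
  reads
}

#' Write simulated reads as SAM
#'
#' Serializes a simulated read tibble as a SAM file (header with `@SQ`
#' lines from the genome, one primary alignment per read, `M`/`N`-only
#' CIGARs). Round-trips through [read_alignments()].
#'
#' @param reads Read tibble from [sim_reads()].
#' @param genome Named [Biostrings::DNAStringSet] the reads were drawn
#'   from.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
  )
  body <- character(0)
  if (nrow(reads) > 0) {
    ord <- order(reads$chrom, reads$start)
    reads <- reads[ord, , drop = FALSE]
    cigars <- vapply(seq_len(nrow(reads)), function(i) {
      sk <- reads$skips[[i]]
      bounds <- c(reads$start[i],
                  if (nrow(sk) > 0) as.vector(t(sk)),
                  reads$end[i])
      lens <- diff(bounds)
      ops <- rep(c("M", "N"), length.out = length(lens))
      paste0(lens, ops, collapse = "")
    }, character(1))
    seqs <- if ("seq" %in% names(reads)) reads$seq else "*"
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    reads$read_id,
                    ifelse(reads$strand == "-", 16L, 0L),
                    reads$chrom, reads$start + 1L, cigars, seqs)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Writes `genome.fa`, `annotation.gtf`, `truth.tsv` and one SAM file
#' per requested mode into `outdir`.
#'
#' @param sim A `falsitron_sim` object.
#' @param outdir Output directory (created if needed).
#' @param modes Protocols to simulate reads for.
#' @return Named character vector of the written paths, invisibly.
#' @export
sim_write <- function(sim, outdir, modes = c("dRNA", "cDNA")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gtf"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_genome(sim$genome, paths["genome"])
  write_annotation(sim$annotation, paths["annotation"])
  readr::write_tsv(sim$truth, paths["truth"])
  for (m in modes) {
    p <- file.path(outdir, sprintf("reads_%s.sam", tolower(m)))
    write_sam(sim_reads(sim, mode = m), sim$genome, p)
    paths[paste0("reads_", tolower(m))] <- p
  }
  invisible(paths)
}
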