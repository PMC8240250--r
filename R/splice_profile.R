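#' Splice-site window sequences of an intron set
#'
#' For each stranded interval, treated as an intron, extracts the
#' 15-nt windows used for splice-site nucleotide profiles: the 5' window
#' is the last `exonic` (3) exonic bases plus the first `intronic` (12)
#' intronic bases; the 3' window is the last `intronic` intronic bases
#' plus the first `exonic` exonic bases — both in transcript orientation.
#' Intervals shorter than `intronic`, or whose windows run outside the
#' contig, are dropped with a warning.
#'
#' @param introns Stranded interval tibble (`chrom`, `start`, `end`,
#'   `strand` in `+`/`-`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param exonic,intronic Bases taken from the exonic and intronic side
#'   (defaults 3 and 12).
#' @return A tibble with one row per retained interval: the interval
#'   columns plus `window5` and `window3`.
#' @export
site_windows <- function(introns, genome, exonic = 3L, intronic = 12L) {
  check_intervals(introns, require_strand = TRUE, what = "intron")
  if (nrow(introns) > 0 && any(introns$strand == "*")) {
    abort("site_windows requires stranded intervals")
  }
  exonic <- as.integer(exonic); intronic <- as.integer(intronic)
  keep <- logical(nrow(introns))
  w5 <- w3 <- character(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    chrom <- introns$chrom[i]
    s <- introns$start[i]; e <- introns$end[i]
    len <- seq_length(genome, chrom)
    if (e - s < intronic || s - exonic < 0 || e + exonic > len) {
      keep[i] <- FALSE
      next
    }
    keep[i] <- TRUE
    if (introns$strand[i] == "+") {
      w5[i] <- seq_slice(genome, chrom, s - exonic, s + intronic)
      w3[i] <- seq_slice(genome, chrom, e - intronic, e + exonic)
    } else {
      w5[i] <- revcomp(seq_slice(genome, chrom, e - intronic, e + exonic))
      w3[i] <- revcomp(seq_slice(genome, chrom, s - exonic, s + intronic))
    }
  }
  if (any(!keep)) {
    warn(sprintf("%d interval(s) dropped: shorter than %d nt or out of bounds",
                 sum(!keep), intronic))
  }
  introns[keep, , drop = FALSE] |>
    mutate(window5 = w5[keep], window3 = w3[keep])
}

#' Position-wise nucleotide counts and frequencies
#'
#' Tabulates, for a set of equal-length sequences, the count and relative
#' frequency of each of `A`, `C`, `G`, `T` at every position. Ambiguous
#' bases (`N`) are excluded from the denominator position-wise rather
#' than dropping whole sequences.
#'
#' @param seqs Character vector of equal-length sequences over
#'   `A/C/G/T/N`.
#' @return A long tibble: `position` (1-based), `base`, `count`,
#'   `frequency` (`NaN` at positions where every sequence has `N`).
#' @export
frequency_matrix <- function(seqs) {
  if (length(seqs) == 0) {
    return(tibble(position = integer(), base = character(),
                  count = integer(), frequency = numeric()))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    abort(sprintf("sequence %d has length %d, expected %d",
                  bad, lens[bad], lens[1]))
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  purrr::map(seq_len(ncol(m)), function(pos) {
    col <- m[, pos]
    counts <- unname(vapply(bases, function(b) sum(col == b), integer(1)))
    denom <- sum(counts)
    tibble(position = pos, base = bases, count = counts,
           frequency = counts / denom)
  }) |> list_rbind()
}

#' Splice-site nucleotide profile of an intron set
#'
#' The numeric substrate of a splice-site sequence logo: position-wise
#' nucleotide counts and frequencies in the 15-nt windows (3 exonic +
#' 12 intronic) around the 5' and 3' splice sites of a set of introns.
#' Positions are labelled relative to the splice site: `-3..-1, +1..+12`
#' for the 5' site (negative = exonic) and `-12..-1, +1..+3` for the 3'
#' site (negative = intronic); there is no position 0.
#'
#' @inheritParams site_windows
#' @return A `splice_profile` tibble: `site` (`"5prime"`/`"3prime"`),
#'   `position` (labelled as above), `base`, `count`, `frequency`, with
#'   `n_sequences` attached as an attribute.
#' @export
splice_profile <- function(introns, genome, exonic = 3L, intronic = 12L) {
  win <- site_windows(introns, genome, exonic = exonic, intronic = intronic)
  label <- function(raw, left) {
    ifelse(raw <= left, raw - left - 1L, raw - left)
  }
  p5 <- frequency_matrix(win$window5) |>
    mutate(site = "5prime", position = label(.data$position, exonic))
  p3 <- frequency_matrix(win$window3) |>
    mutate(site = "3prime", position = label(.data$position, intronic))
  out <- bind_rows(p5, p3) |>
    select("site", "position", "base", "count", "frequency")
  attr(out, "n_sequences") <- nrow(win)
  attr(out, "window_spec") <- c(exonic = exonic, intronic = intronic)
  class(out) <- c("splice_profile", class(out))
  out
}

#' @export
glance.splice_profile <- function(x, ...) {
  spec <- attr(x, "window_spec")
  tibble(n_sequences = attr(x, "n_sequences"),
         exonic_nt = spec[["exonic"]], intronic_nt = spec[["intronic"]])
}

#' Plot a splice-site nucleotide profile
#'
#' Per-position nucleotide frequencies, faceted by splice site — a
#' bar-chart rendering of the information a sequence logo displays.
#'
#' @param object A `splice_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_profile <- function(object, ...) {
  d <- as_tibble(object)
  d$site <- factor(d$site, levels = c("5prime", "3prime"),
                   labels = c("5' splice site", "3' splice site"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$position),
                                  y = .data$frequency,
                                  fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~site, scales = "free_x") +
    ggplot2::labs(x = "Position relative to splice site",
                  y = "Nucleotide frequency", fill = "Base") +
    ggplot2::theme_minimal()
}
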