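# Flanking-residue extraction around pause sites and per-position
# amino-acid enrichment against the proteome background.

#' Extract residues flanking pause sites
#'
#' For each peak, reads the residues at positions `-window..+window`
#' relative to the peak codon from the gene's protein (position 0 = the
#' P-site residue, +1 = the A site; the terminal stop symbol `*` counts as
#' a residue). Positions running off either end of a protein contribute
#' nothing to that position's denominator.
#'
#' @param peaks Tibble with `gene_id` and `codon` (1-based CDS codon
#'   index), e.g. `tidy(combine_replicates(...))` filtered to one
#'   direction.
#' @param proteome A `ribo_proteome` from [build_proteome()] (supplies the
#'   protein sequences).
#' @param window Residues on each side of the peak (default 10).
#' @return A `ribo_flanks` list: `counts` (tibble `position`, `symbol`,
#'   `count`), `denominators` (tibble `position`, `n_peaks`), `n_peaks`,
#'   `window`.
#' @export
extract_flanks <- function(peaks, proteome, window = 10) {
  stopifnot(inherits(proteome, "ribo_proteome"), nrow(peaks) > 0)
  prot <- proteome$proteins[peaks$gene_id]
  if (any(is.na(prot))) {
    abort("peaks reference genes absent from the proteome")
  }
  plen <- nchar(prot)
  if (any(peaks$codon < 1 | peaks$codon > plen)) {
    abort("peak codon index beyond protein length; inconsistent inputs")
  }
  pos_grid <- seq.int(-window, window)
  rows <- lapply(pos_grid, function(k) {
    at <- peaks$codon + k
    ok <- at >= 1 & at <= plen
    sym <- substr(prot[ok], at[ok], at[ok])
    tab <- table(factor(sym, levels = AA_ALPHABET_21))
    tibble(position = k, symbol = AA_ALPHABET_21,
           count = as.integer(tab), n_peaks = sum(ok))
  })
  long <- bind_rows(rows)
  structure(
    list(counts = select(long, "position", "symbol", "count"),
         denominators = distinct(long, .data$position, .data$n_peaks),
         n_peaks = nrow(peaks), window = window),
    class = "ribo_flanks"
  )
}

#' @export
print.ribo_flanks <- function(x, ...) {
  cat("<ribo_flanks> ", x$n_peaks, " peaks, positions -", x$window, "..+",
      x$window, "\n", sep = "")
  invisible(x)
}

#' Per-position residue enrichment versus the proteome
#'
#' For every (position, symbol) cell, performs a two-sided Fisher exact
#' test of (count, peaks-at-position - count) against (background
#' occurrences, background total - occurrences), applies Benjamini-Hochberg
#' correction over the whole matrix, and reports the log2 fold difference
#' of the observed frequency versus the proteome background frequency.
#'
#' @param flanks A `ribo_flanks` from [extract_flanks()].
#' @param proteome The background `ribo_proteome`.
#' @param alpha FDR threshold for the `significant` flag.
#' @return Tibble `position`, `symbol`, `count`, `n_peaks`,
#'   `background_freq`, `log2_enrichment` (infinite when one frequency is
#'   0), `p_value`, `fdr`, `significant`.
#' @export
position_enrichment <- function(flanks, proteome, alpha = 0.05) {
  stopifnot(inherits(flanks, "ribo_flanks"), inherits(proteome, "ribo_proteome"))
  df <- flanks$counts %>%
    inner_join(flanks$denominators, by = "position") %>%
    filter(.data$n_peaks > 0)
  bg_count <- proteome$counts[df$symbol]
  bg_total <- proteome$total
  p <- fisher_exact_2x2(df$count, df$n_peaks - df$count,
                        bg_count, bg_total - bg_count)
  obs_freq <- df$count / df$n_peaks
  bg_freq <- proteome$freq[df$symbol]
  enr <- log2(obs_freq / bg_freq)
  if (any(is.infinite(enr) & obs_freq > 0)) {
    warn("symbols observed at peaks but absent from the background: infinite enrichment")
  }
  df %>%
    mutate(background_freq = unname(bg_freq),
           log2_enrichment = unname(enr),
           p_value = p,
           fdr = bh_adjust(p),
           significant = .data$fdr < alpha) %>%
    arrange(.data$position, .data$symbol)
}
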