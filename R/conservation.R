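#' PWM-weighted mean conservation over a motif site
#'
#' Each motif position j is weighted by the maximum nucleotide probability of
#' PWM column j (columns reversed for minus-strand sites; complementing is
#' unnecessary because only the column maxima enter). With per-base
#' conservation c_j the score is sum(w_j c_j) / sum(w_j).
#'
#' @param pwm Motif model (list with 4 x w matrix `mat`) or the matrix itself.
#' @param chrom,start,end Site coordinates (0-based half-open); width must
#'   equal the motif width.
#' @param strand `"+"` or `"-"`.
#' @param track A `cons_track`.
#' @return Score in \[0, 1\].
#' @export
weighted_motif_conservation <- function(pwm, chrom, start, end, strand, track) {
  mat <- if (is.list(pwm)) pwm$mat else pwm
  w <- apply(mat, 2, max)
  if (length(w) != end - start) {
    stop("site width (", end - start, ") does not match motif width (", length(w), ")")
  }
  if (identical(strand, "-")) w <- rev(w)
  cj <- cons_scores(track, chrom, seq.int(start, end - 1))
  sum(w * cj) / sum(w)
}

#' Annotate motif sites with weighted conservation
#'
#' @param sites Site data.frame (motif_id, chrom, start, end, strand, ...).
#' @param motifs Named list of motif models keyed by motif_id.
#' @param track A `cons_track`.
#' @return `sites` with a `weighted_conservation` column.
#' @export
annotate_site_conservation <- function(sites, motifs, track) {
  sites$weighted_conservation <- vapply(seq_len(nrow(sites)), function(i) {
    weighted_motif_conservation(motifs[[sites$motif_id[i]]], sites$chrom[i],
                                sites$start[i], sites$end[i], sites$strand[i], track)
  }, numeric(1))
  sites
}

#' Conserved-nucleotide enrichment within regions of one chromosome
#'
#' Classifies every base of the chromosome as conserved (score >= threshold)
#' or not, and as inside the flattened region union or not, then tests the
#' 2x2 table with Fisher's exact test (two-sided). Cell counts sum to the
#' chromosome length.
#'
#' @param regions Interval data.frame, single chromosome.
#' @param track A `cons_track`.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param conserved_threshold Conservation threshold (default 0.5, "at least").
#' @return List with `table` (a, b, c, d), `odds_ratio` (NA when undefined),
#'   `or_undefined`, and `p`.
#' @export
conservation_enrichment <- function(regions, track, chrom, chrom_length,
                                    conserved_threshold = 0.5) {
  if (conserved_threshold <= 0 || conserved_threshold > 1) {
    stop("conserved_threshold must be in (0, 1]")
  }
  if (nrow(regions) > 0 && !all(regions$chrom == chrom)) {
    stop("regions span multiple chromosomes")
  }
  flat <- if (nrow(regions) > 0) flatten_intervals(regions) else regions
  if (nrow(flat) > 0 && any(flat$end > chrom_length)) {
    stop("regions extend beyond chrom_length")
  }
  in_len <- if (nrow(flat) > 0) sum(flat$end - flat$start) else 0
  r <- track$runs[[chrom]]
  if (is.null(r)) r <- list(start = numeric(0), end = numeric(0), score = numeric(0))
  cons_idx <- which(r$score >= conserved_threshold)
  total_cons <- sum(r$end[cons_idx] - r$start[cons_idx])
  # conserved bases falling inside the region union
  a <- 0
  if (length(cons_idx) && in_len > 0) {
    for (k in seq_len(nrow(flat))) {
      ov <- pmin(r$end[cons_idx], flat$end[k]) - pmax(r$start[cons_idx], flat$start[k])
      a <- a + sum(pmax(0, ov))
    }
  }
  b <- in_len - a            # non-conserved, in-region
  cc <- total_cons - a       # conserved, outside
  d <- chrom_length - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2,
                dimnames = list(c("conserved", "non_conserved"), c("in", "out")))
  or <- if (b * cc == 0) NA_real_ else (a * d) / (b * cc)
  p <- stats::fisher.test(round(tab))$p.value
  list(chrom = chrom, table = c(a = a, b = b, c = cc, d = d),
       odds_ratio = or, or_undefined = b * cc == 0, p = p)
}
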