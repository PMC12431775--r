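#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open (BED convention) throughout the package:
#' `start` is the first base, `end` is one past the last base.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, exclusive; must satisfy `start < end`.
#' @param name Optional identifiers (recycled `NA` if missing).
#' @param strand Strand, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with columns chrom, start, end, name, strand.
#' @export
gintervals <- function(chrom, start, end, name = NA_character_, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0L || length(start) == 0L || length(end) == 0L) n <- 0L
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chrom must be non-empty")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0) || any(start >= end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = rep_len(as.character(name), n), strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  df
}

#' Do two intervals share at least `min_bp` bases?
#'
#' Shared base count for half-open intervals is
#' `max(0, min(a.end, b.end) - max(a.start, b.start))`.
#'
#' @param a,b Single-row interval data.frames (or lists with chrom/start/end).
#' @param min_bp Minimum shared bases required (>= 1).
#' @return Logical scalar.
#' @export
interval_overlap <- function(a, b, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  shared <- max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
  shared >= min_bp
}

#' Overlap pairs between two interval sets
#'
#' Finds all pairs (i, j) such that query i and subject j share at least
#' `min_bp` bases (same chromosome). Backed by IRanges.
#'
#' @param query,subject Interval data.frames (0-based half-open).
#' @param min_bp Minimum shared bases (default 1).
#' @return data.frame with columns `query`, `subject` (row indices).
#' @export
overlap_pairs <- function(query, subject, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  out <- vector("list", 0L)
  chroms <- intersect(unique(query$chrom), unique(subject$chrom))
  for (ch in chroms) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr, minoverlap = min_bp)
    out[[length(out) + 1L]] <- data.frame(
      query = qi[S4Vectors::queryHits(hits)],
      subject = si[S4Vectors::subjectHits(hits)]
    )
  }
  if (length(out) == 0L) return(data.frame(query = integer(0), subject = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$query, res$subject), , drop = FALSE]
}

#' Distance from a gene's TSS to a feature
#'
#' 0 when the TSS lies inside the feature; otherwise the distance to the
#' nearest base of the feature (the last base of a half-open interval is
#' `end - 1`).
#'
#' @param gene One-row data.frame with `chrom` and `tss`.
#' @param feature One-row interval data.frame.
#' @return Non-negative integer distance in bp.
#' @export
tss_feature_distance <- function(gene, feature) {
  if (gene$chrom[1] != feature$chrom[1]) {
    stop("gene and feature are on different chromosomes")
  }
  tss <- gene$tss[1]
  if (tss >= feature$start[1] && tss < feature$end[1]) return(0)
  min(abs(tss - feature$start[1]), abs(tss - (feature$end[1] - 1)))
}

#' Vectorised TSS-to-feature distances
#'
#' @param tss Numeric vector of TSS positions.
#' @param start,end Feature coordinates (0-based half-open), recycled against tss.
#' @return Numeric vector of distances.
#' @export
tss_feature_distances <- function(tss, start, end) {
  inside <- tss >= start & tss < end
  d <- pmin(abs(tss - start), abs(tss - (end - 1)))
  d[inside] <- 0
  d
}

#' Assign a gene to its containing TAD
#'
#' Returns the TAD whose interval contains the gene's TSS; if several TADs
#' contain it, the smallest-width one is returned (ties broken by start then
#' row order). `NULL` when no TAD contains the TSS.
#'
#' @param gene One-row data.frame with `chrom` and `tss`.
#' @param tads Interval data.frame of TADs.
#' @return One-row interval data.frame, or `NULL`.
#' @export
assign_tad <- function(gene, tads) {
  hit <- which(tads$chrom == gene$chrom[1] &
                 tads$start <= gene$tss[1] & gene$tss[1] < tads$end)
  if (length(hit) == 0L) return(NULL)
  w <- tads$end[hit] - tads$start[hit]
  hit <- hit[order(w, tads$start[hit])][1]
  tads[hit, , drop = FALSE]
}

#' Flatten intervals into a disjoint union
#'
#' Merges overlapping or touching intervals on each chromosome so no base is
#' counted twice.
#'
#' @param x Interval data.frame.
#' @return Interval data.frame of the union (name/strand dropped).
#' @export
flatten_intervals <- function(x) {
  if (nrow(x) == 0L) return(gintervals(character(0), numeric(0), numeric(0)))
  out <- lapply(split(x, x$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), name = NA_character_, strand = ".",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}
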