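#' Parse a BED file (BED3/BED6)
#'
#' Coordinates are taken verbatim as 0-based half-open. Lines starting with
#' `#`, `track` or `browser` are skipped. Malformed lines raise an error
#' naming the line number.
#'
#' @param path File path.
#' @return Interval data.frame (see [gintervals()]).
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(gintervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n_col <- vapply(fields, length, 0L)
  if (any(n_col < 3L)) {
    stop("line ", idx[which(n_col < 3L)[1]], ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) stop("line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad)) stop("line ", idx[bad[1]], ": start >= end or negative start")
  name <- ifelse(n_col >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  strand <- ifelse(n_col >= 6L, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  gintervals(chrom, start, end, name, strand)
}

#' Write intervals as BED
#'
#' Emits BED6 when any name or strand is informative, else BED3.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  has6 <- any(!is.na(x$name)) || any(x$strand != ".")
  if (has6) {
    nm <- ifelse(is.na(x$name), ".", x$name)
    out <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), nm, x$strand)
  } else {
    out <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a per-base conservation track from bedGraph
#'
#' The track is stored as per-chromosome runs (0-based half-open) with a
#' score in \[0, 1\]. Positions absent from the track score 0.
#'
#' @param path bedGraph file path.
#' @return A `cons_track` object.
#' @export
parse_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  cons_track(df)
}

#' Construct a conservation track from runs
#'
#' @param runs data.frame with chrom, start, end (0-based half-open), score.
#' @return A `cons_track` object: per-chromosome sorted run tables.
#' @export
cons_track <- function(runs) {
  if (nrow(runs) > 0 && (any(runs$score < 0) || any(runs$score > 1))) {
    stop("conservation scores must be in [0, 1]")
  }
  by_chrom <- lapply(split(runs, runs$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping runs in conservation track")
    }
    list(start = d$start, end = d$end, score = d$score)
  })
  structure(list(runs = by_chrom), class = "cons_track")
}

#' Per-base conservation scores
#'
#' @param track A `cons_track`.
#' @param chrom Chromosome name.
#' @param positions 0-based base positions.
#' @return Numeric scores; 0 for positions not covered by the track.
#' @export
cons_scores <- function(track, chrom, positions) {
  r <- track$runs[[chrom]]
  if (is.null(r) || length(r$start) == 0L) return(rep(0, length(positions)))
  i <- findInterval(positions, r$start)
  out <- rep(0, length(positions))
  ok <- i >= 1L
  ok[ok] <- positions[ok] < r$end[i[ok]]
  out[ok] <- r$score[i[ok]]
  out
}

#' Write a conservation track as bedGraph
#'
#' @param track A `cons_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- character(0)
  for (ch in sort(names(track$runs))) {
    r <- track$runs[[ch]]
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch, as.integer(r$start),
                              as.integer(r$end), formatC(r$score, digits = 6, format = "g")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with header columns gene_id, chrom, tss, strand. The TSS is
#' explicit so downstream code never re-derives it from a span.
#'
#' @param path File path.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(df))) stop("gene table must have columns: ", paste(req, collapse = ", "))
  if (any(df$tss < 0)) stop("tss must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  df[req]
}

#' Write a gene table
#' @param genes Gene data.frame.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-to-group mapping
#'
#' Tab-separated with header columns cell_id, group. Group levels are kept in
#' order of first appearance unless `levels` is given.
#'
#' @param path File path.
#' @param levels Optional ordered group labels.
#' @return data.frame with attribute `group_levels`.
#' @export
read_cell_groups <- function(path, levels = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "group") %in% names(df))) {
    stop("cell group table must have columns cell_id, group")
  }
  cell_group_map(df$cell_id, df$group, levels)
}

#' Construct a cell-to-group mapping
#'
#' @param cell_id Cell identifiers (unique).
#' @param group Group label per cell.
#' @param levels Optional ordered group labels; defaults to order of appearance.
#' @return data.frame with attribute `group_levels`.
#' @export
cell_group_map <- function(cell_id, group, levels = NULL) {
  if (anyDuplicated(cell_id)) stop("duplicate cell_id in group map")
  if (is.null(levels)) levels <- unique(group)
  if (!all(group %in% levels)) stop("group labels outside supplied levels")
  df <- data.frame(cell_id = as.character(cell_id), group = as.character(group),
                   stringsAsFactors = FALSE)
  attr(df, "group_levels") <- levels
  df
}

#' The default merged cell-group labels
#' @return Character vector of the eight merged group labels.
#' @export
default_groups <- function() {
  c("PRO1_2", "CO1_2", "GA1_2", "GA3_4", "GA5_6", "GL1_2", "GL3_4", "GL5")
}

#' Write a cells x variables matrix as MTX plus name files
#'
#' @param m Matrix (cells in rows).
#' @param prefix Path prefix; writes `<prefix>.mtx`, `<prefix>.rows.txt`,
#'   `<prefix>.cols.txt`.
#' @export
write_matrix_mtx <- function(m, prefix) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".rows.txt"))
  writeLines(colnames(m), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' Read a matrix written by [write_matrix_mtx()]
#' @param prefix Path prefix.
#' @return Dense base matrix with dimnames.
#' @export
read_matrix_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".rows.txt"))
  colnames(m) <- readLines(paste0(prefix, ".cols.txt"))
  m
}

#' Read motif models from MEME-like minimal text format
#'
#' Expects `MOTIF <motif_id> <tf_name>` headers followed by a
#' `letter-probability matrix:` line and `w` rows of 4 probabilities over
#' A, C, G, T. Columns of the returned matrices are motif positions.
#'
#' @param path File path.
#' @return Named list of motif models (`motif_id`, `tf_name`, `mat` 4 x w).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  heads <- grep("^MOTIF\\b", lines)
  if (length(heads) == 0L) stop("no MOTIF entries in ", path)
  out <- list()
  for (h in heads) {
    toks <- strsplit(trimws(lines[h]), "\\s+")[[1]]
    motif_id <- toks[2]
    tf_name <- if (length(toks) >= 3) toks[3] else toks[2]
    lp <- h + grep("letter-probability matrix", lines[(h + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1):(lp + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    mat <- t(mat)  # 4 x w, rows A C G T
    dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
    if (any(abs(colSums(mat) - 1) > 1e-6)) {
      stop("motif ", motif_id, ": columns do not sum to 1")
    }
    out[[motif_id]] <- list(motif_id = motif_id, tf_name = tf_name, mat = mat)
  }
  out
}

#' Write motif models in MEME-like minimal format
#' @param motifs Named list of motif models (as from [read_meme()]).
#' @param path Output path.
#' @export
write_meme <- function(motifs, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  for (m in motifs) {
    lines <- c(lines, sprintf("MOTIF %s %s", m$motif_id, m$tf_name),
               sprintf("letter-probability matrix: alength= 4 w= %d", ncol(m$mat)),
               apply(m$mat, 2, function(col) paste(formatC(col, digits = 8, format = "f"), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV with header
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a TSV with header
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
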