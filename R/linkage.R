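#' Spearman rank correlation
#'
#' Pearson correlation of average-rank-transformed vectors (ties receive
#' average ranks). Thin, validated wrapper over the standard estimator.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with at least two
#'   distinct values.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Select matched background features for linkage z-scoring
#'
#' Backgrounds come from the query feature's chromosome and are matched by
#' decile of mean accessibility and decile of width: candidates are ordered
#' by the summed absolute decile difference, the closest `n` are taken, and
#' ties at the cutoff are resolved by a seeded random draw.
#'
#' @param feature_meta data.frame with feature_id, chrom, width, mean_acc.
#' @param query_id Feature to match.
#' @param n Number of background features (default 200).
#' @param seed Integer seed for tie-breaking.
#' @return Character vector of background feature ids.
#' @export
select_background_features <- function(feature_meta, query_id, n = 200, seed = 1L) {
  qi <- match(query_id, feature_meta$feature_id)
  if (is.na(qi)) stop("unknown feature: ", query_id)
  pool <- feature_meta[feature_meta$chrom == feature_meta$chrom[qi] &
                         feature_meta$feature_id != query_id, , drop = FALSE]
  if (nrow(pool) < n) {
    stop("only ", nrow(pool), " candidate background features; need ", n)
  }
  all_chrom <- feature_meta[feature_meta$chrom == feature_meta$chrom[qi], , drop = FALSE]
  dec_acc <- findInterval(all_chrom$mean_acc,
                          stats::quantile(all_chrom$mean_acc, seq(0.1, 0.9, 0.1)),
                          left.open = TRUE) + 1L
  dec_w <- findInterval(all_chrom$width,
                        stats::quantile(all_chrom$width, seq(0.1, 0.9, 0.1)),
                        left.open = TRUE) + 1L
  names(dec_acc) <- names(dec_w) <- all_chrom$feature_id
  d <- abs(dec_acc[pool$feature_id] - dec_acc[query_id]) +
    abs(dec_w[pool$feature_id] - dec_w[query_id])
  ord <- order(d, pool$feature_id)
  cutoff <- d[ord[n]]
  sure <- pool$feature_id[ord][d[ord] < cutoff]
  ties <- pool$feature_id[ord][d[ord] == cutoff]
  need <- n - length(sure)
  set.seed(seed)
  c(sure, sort(sample(ties, need)))
}

#' Feature-to-gene linkage record
#'
#' Computes the Spearman correlation between a feature's accessibility and a
#' gene's expression over the cells shared by the two matrices, standardises
#' it against the correlations of background features with the same gene
#' (z = (rho_obs - mean(rho_bg)) / sd(rho_bg)), and reports the two-sided
#' normal-tail p-value of z.
#'
#' @param feature_id,gene_id Identifiers.
#' @param accessibility Cells x features matrix.
#' @param expression Cells x genes matrix (log1p scale).
#' @param background_ids Background feature ids (>= 50).
#' @return One-row data.frame: feature_id, gene_id, rho, z, p, sign.
#' @export
link_feature_gene <- function(feature_id, gene_id, accessibility, expression,
                              background_ids) {
  cells <- intersect(rownames(accessibility), rownames(expression))
  if (length(cells) < 30) stop("need >= 30 shared cells")
  frac <- length(cells) / max(nrow(accessibility), nrow(expression))
  if (frac < 0.5) warning("less than half of the cells are shared between matrices")
  if (length(background_ids) < 50) stop("need >= 50 background features")
  x <- accessibility[cells, feature_id]
  y <- expression[cells, gene_id]
  rho_obs <- spearman_rho(x, y)
  ry <- rank(y)
  bg <- accessibility[cells, background_ids, drop = FALSE]
  keep <- apply(bg, 2, function(v) length(unique(v)) >= 2)
  if (!all(keep)) {
    warning(sum(!keep), " constant background feature(s) dropped")
    bg <- bg[, keep, drop = FALSE]
  }
  rho_bg <- as.numeric(stats::cor(apply(bg, 2, rank), ry))
  s <- stats::sd(rho_bg)
  if (!is.finite(s) || s == 0) stop("degenerate background: sd of background rho is 0")
  z <- (rho_obs - mean(rho_bg)) / s
  data.frame(feature_id = feature_id, gene_id = gene_id, rho = rho_obs, z = z,
             p = 2 * stats::pnorm(-abs(z)), sign = ifelse(z >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Link all features in a gene's TAD to the gene
#'
#' @param gene One-row gene data.frame (gene_id, chrom, tss, strand).
#' @param tads TAD interval data.frame.
#' @param features Feature interval data.frame (`name` = feature_id).
#' @param accessibility Cells x features matrix.
#' @param expression Cells x genes matrix.
#' @param n_background Background features per query (default 200).
#' @param seed Integer seed (tie-breaking in background selection).
#' @return data.frame of link records with feature coordinates, or an empty
#'   data.frame (with a warning) when the gene has no TAD.
#' @export
link_gene_features <- function(gene, tads, features, accessibility, expression,
                               n_background = 200, seed = 1L) {
  empty <- data.frame(feature_id = character(0), gene_id = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      rho = numeric(0), z = numeric(0), p = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE)
  tad <- assign_tad(data.frame(chrom = gene$chrom, tss = gene$tss), tads)
  if (is.null(tad)) {
    warning("gene ", gene$gene_id, " has no containing TAD")
    return(empty)
  }
  in_tad <- features$chrom == tad$chrom & features$start >= tad$start &
    features$end <= tad$end
  feats <- features[in_tad, , drop = FALSE]
  if (nrow(feats) == 0L) return(empty)
  cells <- intersect(rownames(accessibility), rownames(expression))
  if (length(cells) < 30) stop("need >= 30 shared cells")
  if (n_background < 50) stop("need >= 50 background features")
  meta <- data.frame(feature_id = features$name, chrom = features$chrom,
                     width = features$end - features$start,
                     mean_acc = colMeans(accessibility[cells, features$name, drop = FALSE]),
                     stringsAsFactors = FALSE)
  # rank-transform every feature on the gene's chromosome once; Spearman rho
  # is then a single Pearson cross-correlation against the ranked expression
  chrom_feats <- features$name[features$chrom == tad$chrom]
  ranked <- apply(accessibility[cells, chrom_feats, drop = FALSE], 2, rank)
  y <- expression[cells, gene$gene_id]
  if (length(unique(y)) < 2) stop("undefined correlation: constant vector")
  variable <- apply(accessibility[cells, chrom_feats, drop = FALSE], 2,
                    function(v) length(unique(v)) >= 2)
  rho_all <- as.numeric(suppressWarnings(stats::cor(ranked, rank(y))))
  names(rho_all) <- chrom_feats
  out <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    fid <- feats$name[i]
    if (!variable[fid]) stop("undefined correlation: constant vector")
    bg <- select_background_features(meta, fid, n = n_background,
                                     seed = seed + i)
    drop_bg <- !variable[bg]
    if (any(drop_bg)) {
      warning(sum(drop_bg), " constant background feature(s) dropped")
      bg <- bg[!drop_bg]
    }
    rho_bg <- rho_all[bg]
    s <- stats::sd(rho_bg)
    if (!is.finite(s) || s == 0) stop("degenerate background: sd of background rho is 0")
    z <- (rho_all[fid] - mean(rho_bg)) / s
    out[[i]] <- data.frame(feature_id = fid, gene_id = gene$gene_id,
                           chrom = feats$chrom[i], start = feats$start[i],
                           end = feats$end[i], rho = unname(rho_all[fid]),
                           z = unname(z), p = 2 * stats::pnorm(-abs(z)),
                           sign = ifelse(z >= 0, "+", "-"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call cCREs from link records
#'
#' Retains links with |z| strictly above `z_threshold`, p strictly below
#' `p_threshold`, and the feature contained in the gene's TAD.
#'
#' @param links Link data.frame (from [link_gene_features()]).
#' @param tad One-row TAD interval (or NULL: returns empty set with warning).
#' @param z_threshold,p_threshold Thresholds (defaults 2 and 0.05).
#' @return Subset of `links`.
#' @export
call_ccres <- function(links, tad, z_threshold = 2, p_threshold = 0.05) {
  if (is.null(tad)) {
    warning("no TAD: empty cCRE set")
    return(links[0, , drop = FALSE])
  }
  keep <- abs(links$z) > z_threshold & links$p < p_threshold &
    links$chrom == tad$chrom & links$start >= tad$start & links$end <= tad$end
  links[keep, , drop = FALSE]
}
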