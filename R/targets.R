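#' Identify target genes of a selector TF
#'
#' A gene is a target of the TF when some feature in the gene's TAD
#' satisfies all four evidence conditions:
#' (1) the feature contains a motif site of the TF with a positive footprint
#'     in at least one of the interrogated groups (default GA1_2 / GL1_2);
#' (2) the feature is linked to the gene with |z| > `z_threshold` and
#'     p < `p_threshold` (default 2 and 0.01);
#' (3) the site's PWM-weighted conservation is > `cons_threshold`;
#' (4) a CUT&Tag peak of the TF overlaps the feature (>= 1 bp).
#' Each condition can be toggled off, which can only enlarge the call set.
#'
#' @param tf TF name.
#' @param links Link data.frame over all candidate genes (feature_id,
#'   gene_id, chrom, start, end, rho, z, p, sign), features restricted to
#'   each gene's TAD (as produced by [link_gene_features()]).
#' @param sites Site data.frame with weighted_conservation.
#' @param footprints Footprint data.frame.
#' @param peaks Named list: tf -> peak interval data.frame. An error names
#'   the TF when it has no entry (unless the peak condition is disabled).
#' @param genes Gene data.frame (gene_id, chrom, tss) for distances.
#' @param groups_use Cell groups whose footprints qualify (default
#'   `c("GA1_2", "GL1_2")`).
#' @param z_threshold,p_threshold,cons_threshold Evidence thresholds.
#' @param use_footprint,use_linkage,use_conservation,use_peak Toggles.
#' @return List with `targets` (one row per target gene: tf, gene_id,
#'   n_features, n_pos_links, n_neg_links, nearest_distance, distance_bin)
#'   and `features` (one row per supporting target feature with evidence).
#' @export
identify_targets <- function(tf, links, sites, footprints, peaks, genes,
                             groups_use = c("GA1_2", "GL1_2"),
                             z_threshold = 2, p_threshold = 0.01,
                             cons_threshold = 0.5,
                             use_footprint = TRUE, use_linkage = TRUE,
                             use_conservation = TRUE, use_peak = TRUE) {
  tf_sites <- sites[sites$tf_name == tf, , drop = FALSE]
  if (use_conservation) {
    tf_sites <- tf_sites[tf_sites$weighted_conservation > cons_threshold, , drop = FALSE]
  }
  if (use_footprint) {
    bound <- unique(unlist(lapply(groups_use, function(g) {
      bound_site_set(footprints, g)
    })))
    tf_sites <- tf_sites[tf_sites$site_id %in% bound, , drop = FALSE]
  }
  cand <- links
  if (use_linkage) {
    cand <- cand[abs(cand$z) > z_threshold & cand$p < p_threshold, , drop = FALSE]
  }
  cand <- cand[cand$feature_id %in% tf_sites$feature_id, , drop = FALSE]
  if (use_peak) {
    if (is.null(peaks[[tf]])) stop("no CUT&Tag peak set for TF: ", tf)
    pk <- peaks[[tf]]
    if (nrow(cand) > 0) {
      feats <- unique(cand[c("feature_id", "chrom", "start", "end")])
      ov <- overlap_pairs(feats, pk, min_bp = 1L)
      covered <- feats$feature_id[unique(ov$query)]
      cand <- cand[cand$feature_id %in% covered, , drop = FALSE]
    }
  }
  feat_rows <- if (nrow(cand) > 0) {
    sup <- merge(cand, tf_sites[c("site_id", "feature_id", "weighted_conservation")],
                 by = "feature_id")
    sup$tf <- tf
    sup
  } else {
    data.frame(feature_id = character(0), gene_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               rho = numeric(0), z = numeric(0), p = numeric(0),
               sign = character(0), site_id = character(0),
               weighted_conservation = numeric(0), tf = character(0),
               stringsAsFactors = FALSE)
  }
  target_genes <- sort(unique(cand$gene_id))
  tg <- lapply(target_genes, function(g) {
    d <- cand[cand$gene_id == g, , drop = FALSE]
    tss <- genes$tss[match(g, genes$gene_id)]
    dist <- min(tss_feature_distances(tss, d$start, d$end))
    data.frame(tf = tf, gene_id = g, n_features = length(unique(d$feature_id)),
               n_pos_links = sum(d$sign == "+"), n_neg_links = sum(d$sign == "-"),
               nearest_distance = dist, distance_bin = distance_bin(dist),
               stringsAsFactors = FALSE)
  })
  targets <- if (length(tg)) do.call(rbind, tg) else
    data.frame(tf = character(0), gene_id = character(0), n_features = integer(0),
               n_pos_links = integer(0), n_neg_links = integer(0),
               nearest_distance = numeric(0), distance_bin = character(0),
               stringsAsFactors = FALSE)
  list(targets = targets, features = feat_rows)
}

#' Distance bin labels
#'
#' Half-open bins \[0, 5 kb), \[5 kb, 50 kb), \[50 kb, Inf).
#' @param d Numeric distances in bp.
#' @return Character bin labels: "0-5", "5-50", ">50".
#' @export
distance_bin <- function(d) {
  ifelse(d < 5000, "0-5", ifelse(d < 50000, "5-50", ">50"))
}

#' Per-gene Wilcoxon rank-sum differential expression between two cell sets
#'
#' Two-sided rank-sum test with tie correction per gene (exact when sample
#' sizes permit and there are no ties). log2FC is computed on de-logged
#' group means with a +1 pseudocount:
#' `log2((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))`.
#'
#' @param expression Cells x genes matrix (log1p scale).
#' @param cellsA,cellsB Cell id vectors (>= 3 cells each).
#' @param adjust Multiple-testing adjustment (default "bonferroni";
#'   "BH" available).
#' @return data.frame: gene_id, log2FC, p, p_adj, pct_A, pct_B.
#' @export
de_wilcoxon <- function(expression, cellsA, cellsB, adjust = "bonferroni") {
  if (length(cellsA) < 3 || length(cellsB) < 3) stop("need >= 3 cells per group")
  A <- expression[cellsA, , drop = FALSE]
  B <- expression[cellsB, , drop = FALSE]
  p <- vapply(seq_len(ncol(A)), function(j) {
    suppressWarnings(stats::wilcox.test(A[, j], B[, j], exact = NULL)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # all-tied degenerate columns
  lfc <- log2((colMeans(expm1(A)) + 1) / (colMeans(expm1(B)) + 1))
  data.frame(gene_id = colnames(A), log2FC = lfc, p = p,
             p_adj = stats::p.adjust(p, method = adjust),
             pct_A = colMeans(A > 0), pct_B = colMeans(B > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify target genes as GABA-specific, glutamatergic-specific or neither
#'
#' GABA-specific: log2FC > `lfc` and GA mean > `expr` and GL mean < `expr`.
#' Glutamatergic-specific: log2FC < -`lfc` and GL mean > `expr` and GA mean
#' < `expr`. Otherwise unclassified.
#'
#' @param gene_ids Genes to classify.
#' @param de DE data.frame from [de_wilcoxon()] (A = GA1_2, B = GL1_2).
#' @param ga_mean,gl_mean Named vectors of group mean log1p expression.
#' @param lfc,expr Thresholds (defaults 0.5 and 0.5).
#' @return Character vector of class labels, named by gene.
#' @export
classify_targets <- function(gene_ids, de, ga_mean, gl_mean, lfc = 0.5, expr = 0.5) {
  l2 <- de$log2FC[match(gene_ids, de$gene_id)]
  ga <- ga_mean[gene_ids]
  gl <- gl_mean[gene_ids]
  out <- rep("unclassified", length(gene_ids))
  out[l2 > lfc & ga > expr & gl < expr] <- "GABA-specific"
  out[l2 < -lfc & gl > expr & ga < expr] <- "glut-specific"
  names(out) <- gene_ids
  out
}

#' Characterize a target call set
#'
#' Returns (i) counts of target features by link sign, (ii) target-gene
#' counts per nearest-distance bin, and (iii) per-gene expression
#' variability (standard deviation of per-cell-group mean expression across
#' all groups) alongside the gene's bin.
#'
#' @param target_calls `targets` data.frame from [identify_targets()].
#' @param target_features `features` data.frame from [identify_targets()].
#' @param expression Cells x genes matrix.
#' @param groups Cell-to-group data.frame.
#' @return List: `sign_counts`, `bin_counts`, `variability` (gene_id,
#'   distance_bin, variability).
#' @export
characterize_targets <- function(target_calls, target_features, expression, groups) {
  if (nrow(target_calls) == 0L) stop("no targets to characterize")
  uf <- unique(target_features[c("feature_id", "gene_id", "sign")])
  sign_counts <- c(positive = sum(uf$sign == "+"), negative = sum(uf$sign == "-"))
  bins <- c("0-5", "5-50", ">50")
  bin_counts <- vapply(bins, function(b) sum(target_calls$distance_bin == b), 0L)
  gm <- group_mean_expression(expression, groups)
  v <- apply(gm[target_calls$gene_id, , drop = FALSE], 1, stats::sd)
  variability <- data.frame(gene_id = target_calls$gene_id,
                            distance_bin = target_calls$distance_bin,
                            variability = as.numeric(v),
                            stringsAsFactors = FALSE)
  list(sign_counts = sign_counts, bin_counts = bin_counts,
       variability = variability)
}

#' Subset genes by group-mean expression (OR rule)
#'
#' Keeps genes whose GA mean or GL mean is strictly above the threshold;
#' the list is the hand-off point for external enrichment services.
#'
#' @param gene_ids Genes to subset.
#' @param ga_mean,gl_mean Named group mean vectors.
#' @param threshold Expression threshold (default 0.5 log1p).
#' @return Character vector of retained genes.
#' @export
target_expression_subset <- function(gene_ids, ga_mean, gl_mean, threshold = 0.5) {
  gene_ids[ga_mean[gene_ids] > threshold | gl_mean[gene_ids] > threshold]
}

#' Two-edge GSEA running sum
#'
#' Classic (unweighted) running enrichment score over a ranked gene list:
#' hits increment by 1/|set in ranking|, misses decrement by
#' 1/(n - |set in ranking|). Because the ranking axis is informative at both
#' ends, two leading edges are reported: edge A = set members at or before
#' the position of the curve maximum, edge B = set members at or after the
#' position of the minimum.
#'
#' @param ranked Character vector of genes ordered by descending score.
#' @param gene_set Character vector; must intersect the ranking and must not
#'   cover all of it.
#' @param weight Weighting exponent on a per-gene score (0 = classic,
#'   the default; requires `scores` when > 0).
#' @param scores Optional scores aligned with `ranked` (used when
#'   `weight > 0`).
#' @return List: curve, argmax, argmin, leading_edge_A, leading_edge_B.
#' @export
gsea_two_edge <- function(ranked, gene_set, weight = 0, scores = NULL) {
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates")
  hit <- ranked %in% gene_set
  nh <- sum(hit)
  n <- length(ranked)
  if (nh == 0L) stop("gene set is disjoint from the ranking")
  if (nh == n) stop("gene set covers the entire ranking")
  if (weight == 0) {
    inc <- rep(1 / nh, n)
  } else {
    if (is.null(scores)) stop("scores required when weight > 0")
    w <- abs(scores)^weight
    inc <- w / sum(w[hit])
  }
  step <- ifelse(hit, inc, -1 / (n - nh))
  curve <- cumsum(step)
  argmax <- which.max(curve)
  argmin <- which.min(curve)
  list(curve = curve,
       argmax = argmax, argmin = argmin,
       leading_edge_A = ranked[seq_len(argmax)][hit[seq_len(argmax)]],
       leading_edge_B = ranked[argmin:n][hit[argmin:n]])
}

#' Build the filtered GSEA ranking axis
#'
#' Genes are ranked by descending log2FC after filtering to adjusted
#' p < `p_adj` and an expressing-cell fraction of at least `min_pct` in
#' either group.
#'
#' @param de DE data.frame from [de_wilcoxon()].
#' @param p_adj Adjusted-p filter (default 0.01).
#' @param min_pct Minimum expressing fraction (default 0.1).
#' @return data.frame: gene_id, log2FC, ordered by descending log2FC.
#' @export
gsea_ranking <- function(de, p_adj = 0.01, min_pct = 0.1) {
  keep <- de$p_adj < p_adj & (de$pct_A >= min_pct | de$pct_B >= min_pct)
  d <- de[keep, c("gene_id", "log2FC")]
  d[order(-d$log2FC, d$gene_id), , drop = FALSE]
}

#' Hypergeometric similarity between two sets of cluster marker lists
#'
#' Entry (i, j) is the upper-tail hypergeometric probability of observing at
#' least the realised overlap when drawing |A_i| genes from a universe of
#' size N containing |B_j| successes. Marker genes absent from the universe
#' are dropped with a warning.
#'
#' @param markers_A,markers_B Named lists of per-cluster marker gene vectors.
#' @param universe Character vector: the shared gene pool.
#' @return List: `p` (matrix of upper-tail p-values), `neglog10` transform.
#' @export
marker_similarity <- function(markers_A, markers_B, universe) {
  N <- length(universe)
  clean <- function(lists, tag) {
    lapply(lists, function(g) {
      out <- intersect(unique(g), universe)
      if (length(out) < length(unique(g))) {
        warning(length(unique(g)) - length(out), " ", tag,
                " marker gene(s) outside universe dropped")
      }
      out
    })
  }
  markers_A <- clean(markers_A, "A")
  markers_B <- clean(markers_B, "B")
  p <- matrix(NA_real_, length(markers_A), length(markers_B),
              dimnames = list(names(markers_A), names(markers_B)))
  for (i in seq_along(markers_A)) {
    for (j in seq_along(markers_B)) {
      k <- length(intersect(markers_A[[i]], markers_B[[j]]))
      p[i, j] <- stats::phyper(k - 1, length(markers_B[[j]]),
                               N - length(markers_B[[j]]),
                               length(markers_A[[i]]), lower.tail = FALSE)
    }
  }
  list(p = p, neglog10 = -log10(p))
}

#' Per-cluster marker genes
#'
#' For each group, runs [de_wilcoxon()] of the group against all other
#' cells, filters to adjusted p < `p_adj` and positive log2FC, and keeps the
#' top `top_n` genes by log2FC.
#'
#' @param expression Cells x genes matrix.
#' @param groups Cell-to-group data.frame.
#' @param p_adj Adjusted-p filter (default 0.05).
#' @param top_n Markers per cluster (default 25).
#' @param adjust Adjustment method (default "BH").
#' @return Named list of marker gene vectors.
#' @export
cluster_markers <- function(expression, groups, p_adj = 0.05, top_n = 25,
                            adjust = "BH") {
  lv <- attr(groups, "group_levels")
  if (is.null(lv)) lv <- unique(groups$group)
  cells <- intersect(rownames(expression), groups$cell_id)
  g <- groups$group[match(cells, groups$cell_id)]
  out <- lapply(lv, function(l) {
    de <- de_wilcoxon(expression, cells[g == l], cells[g != l], adjust = adjust)
    de <- de[de$p_adj < p_adj & de$log2FC > 0, , drop = FALSE]
    de <- de[order(-de$log2FC), , drop = FALSE]
    utils::head(de$gene_id, top_n)
  })
  names(out) <- lv
  out
}
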