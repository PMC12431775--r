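#' Site ids with a positive footprint in a cell group
#'
#' A site counts as bound in a group when its footprint score is strictly
#' positive there.
#'
#' @param footprints data.frame with site_id, cell_group, footprint_score.
#' @param group Group label (must occur in `footprints$cell_group` levels).
#' @param groups Optional vector of valid group labels (defaults to the
#'   labels present in `footprints`).
#' @return Character vector of site ids.
#' @export
bound_site_set <- function(footprints, group, groups = NULL) {
  if (is.null(groups)) groups <- unique(footprints$cell_group)
  if (!group %in% groups) stop("unknown cell group: ", group)
  sel <- footprints$cell_group == group & footprints$footprint_score > 0
  unique(footprints$site_id[sel])
}

#' Per-group mean expression
#'
#' Arithmetic mean of log1p values over the cells of each group.
#'
#' @param expression Cells x genes matrix.
#' @param groups Cell-to-group data.frame (cell_id, group).
#' @return Genes x groups matrix of means.
#' @export
group_mean_expression <- function(expression, groups) {
  lv <- attr(groups, "group_levels")
  if (is.null(lv)) lv <- unique(groups$group)
  cells <- intersect(rownames(expression), groups$cell_id)
  g <- groups$group[match(cells, groups$cell_id)]
  out <- matrix(NA_real_, ncol(expression), length(lv),
                dimnames = list(colnames(expression), lv))
  for (l in lv) out[, l] <- colMeans(expression[cells[g == l], , drop = FALSE])
  out
}

#' Identify regulator TFs of a gene in a cell group
#'
#' A TF is called a regulator of the gene in the group when there exists a
#' motif site of that TF inside one of the gene's cCREs such that:
#' (1) the site has a positive footprint (bound) in the group;
#' (2) the site's PWM-weighted conservation is > `cons_threshold`;
#' (3) the TF gene's mean log1p expression in the group is > `expr_threshold`.
#' An optional fourth condition requires the mean accessibility of the
#' supporting cCRE to exceed `acc_threshold` (off by default; in the source
#' analyses this filter is applied to footprint dot plots, not the regulator
#' conditions).
#'
#' @param gene_id Selector gene.
#' @param group Cell group label.
#' @param ccres cCRE link data.frame for the gene (from [call_ccres()]).
#' @param sites Site data.frame (site_id, tf_name, feature_id,
#'   weighted_conservation).
#' @param footprints Footprint data.frame (site_id, cell_group, footprint_score).
#' @param expression Cells x genes matrix.
#' @param groups Cell-to-group data.frame.
#' @param cons_threshold,expr_threshold Thresholds (defaults 0.5 and 1.2).
#' @param use_footprint,use_conservation,use_expression Condition toggles
#'   (all TRUE by default); disabling one relaxes that condition.
#' @param acc_threshold Optional accessibility filter (NULL = off).
#' @param accessibility Cells x features matrix, required when
#'   `acc_threshold` is set.
#' @return data.frame of regulator calls with evidence columns: tf_name,
#'   gene_id, cell_group, n_sites, ccre_ids, site_ids, min_conservation,
#'   max_conservation, tf_mean_expr, min_link_p.
#' @export
identify_regulators <- function(gene_id, group, ccres, sites, footprints,
                                expression, groups,
                                cons_threshold = 0.5, expr_threshold = 1.2,
                                use_footprint = TRUE, use_conservation = TRUE,
                                use_expression = TRUE, acc_threshold = NULL,
                                accessibility = NULL) {
  empty <- data.frame(tf_name = character(0), gene_id = character(0),
                      cell_group = character(0), n_sites = integer(0),
                      ccre_ids = character(0), site_ids = character(0),
                      min_conservation = numeric(0), max_conservation = numeric(0),
                      tf_mean_expr = numeric(0), min_link_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(ccres) == 0L) return(empty)
  cand <- sites[sites$feature_id %in% ccres$feature_id, , drop = FALSE]
  if (!is.null(acc_threshold)) {
    if (is.null(accessibility)) stop("accessibility matrix required for acc_threshold")
    cells <- intersect(rownames(accessibility), groups$cell_id)
    gcells <- cells[groups$group[match(cells, groups$cell_id)] == group]
    macc <- colMeans(accessibility[gcells, unique(cand$feature_id), drop = FALSE])
    cand <- cand[macc[cand$feature_id] > acc_threshold, , drop = FALSE]
  }
  if (use_conservation) {
    cand <- cand[cand$weighted_conservation > cons_threshold, , drop = FALSE]
  }
  if (use_footprint) {
    bound <- bound_site_set(footprints, group)
    cand <- cand[cand$site_id %in% bound, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty)
  gm <- group_mean_expression(expression, groups)
  calls <- lapply(split(cand, cand$tf_name), function(d) {
    tf <- d$tf_name[1]
    if (!tf %in% rownames(gm)) {
      warning("TF gene ", tf, " absent from expression matrix; skipped")
      return(NULL)
    }
    me <- gm[tf, group]
    if (use_expression && !(me > expr_threshold)) return(NULL)
    supp <- ccres[ccres$feature_id %in% d$feature_id, , drop = FALSE]
    data.frame(tf_name = tf, gene_id = gene_id, cell_group = group,
               n_sites = nrow(d),
               ccre_ids = paste(sort(unique(d$feature_id)), collapse = ","),
               site_ids = paste(sort(d$site_id), collapse = ","),
               min_conservation = min(d$weighted_conservation),
               max_conservation = max(d$weighted_conservation),
               tf_mean_expr = me, min_link_p = min(supp$p),
               stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, TRUE)]
  if (length(calls) == 0L) return(empty)
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res[order(res$tf_name), , drop = FALSE]
}

#' Venn partition and core-regulator significance across selector genes
#'
#' Partitions the union of per-gene regulator sets by membership signature
#' and, for TFs present in the full intersection, summarises significance as
#' the maximum over genes of the minimum supporting-link p-value for that TF
#' (each gene contributes its best-supported cCRE link; the summary takes
#' the worst gene).
#'
#' @param calls_by_gene Named list (gene -> regulator call data.frame with
#'   tf_name and min_link_p), length >= 2.
#' @return List with `partition` (signature, n, tfs) and `core`
#'   (tf_name, significance).
#' @export
summarize_common_regulators <- function(calls_by_gene) {
  if (length(calls_by_gene) < 2) stop("need regulator sets for >= 2 genes")
  genes <- names(calls_by_gene)
  sets <- lapply(calls_by_gene, function(d) unique(d$tf_name))
  all_tfs <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_tfs %in% s, logical(length(all_tfs)))
  if (length(all_tfs) == 1L) member <- matrix(member, nrow = 1, dimnames = list(NULL, genes))
  sig <- apply(member, 1, function(row) paste(genes[row], collapse = "&"))
  # all 2^k - 1 regions, including empty ones
  combos <- unlist(lapply(seq_along(genes), function(k) {
    utils::combn(genes, k, paste, collapse = "&", simplify = FALSE)
  }))
  partition <- data.frame(signature = combos,
                          n = vapply(combos, function(s) sum(sig == s), 0L),
                          tfs = vapply(combos, function(s) {
                            paste(all_tfs[sig == s], collapse = ",")
                          }, ""), stringsAsFactors = FALSE, row.names = NULL)
  core_tfs <- all_tfs[rowSums(member) == length(genes)]
  core <- data.frame(tf_name = core_tfs,
                     significance = vapply(core_tfs, function(tf) {
                       max(vapply(calls_by_gene, function(d) {
                         min(d$min_link_p[d$tf_name == tf])
                       }, numeric(1)))
                     }, numeric(1)), stringsAsFactors = FALSE, row.names = NULL)
  list(partition = partition, core = core)
}

#' Permutation test for the overlap of three regulator sets
#'
#' Draws, per iteration, three uniform without-replacement sets of the given
#' sizes from the universe and records the size of their three-way
#' intersection. The empirical p-value is the proportion of iterations with
#' intersection >= the observed size; when no iteration reaches it, the
#' upper bound 1/(N+1) is reported with `upper_bound_flag = TRUE`.
#'
#' @param universe Vector of candidate TF identifiers (or a single integer,
#'   the universe size).
#' @param set_sizes Integer vector of three set sizes.
#' @param observed Observed three-way intersection size.
#' @param n_iter Number of iterations (default 1e6).
#' @param seed Integer seed.
#' @return List: observed, n_iter, exceedances, p, upper_bound_flag, seed.
#' @export
permutation_overlap_test <- function(universe, set_sizes, observed,
                                     n_iter = 1e6, seed = 1L) {
  m <- if (length(universe) == 1L && is.numeric(universe)) as.integer(universe) else length(universe)
  if (length(set_sizes) != 3L) stop("set_sizes must have length 3")
  if (any(set_sizes > m)) stop("set size exceeds universe size")
  if (observed > min(set_sizes)) stop("observed intersection exceeds the smallest set")
  if (n_iter < 1) stop("n_iter must be >= 1")
  set.seed(seed)
  exceed <- 0L
  counts <- integer(m)
  for (i in seq_len(n_iter)) {
    counts[] <- 0L
    counts[sample.int(m, set_sizes[1])] <- 1L
    s2 <- sample.int(m, set_sizes[2])
    counts[s2] <- counts[s2] + 1L
    s3 <- sample.int(m, set_sizes[3])
    inter <- sum(counts[s3] == 2L)
    if (inter >= observed) exceed <- exceed + 1L
  }
  p <- exceed / n_iter
  flag <- exceed == 0L
  if (flag) p <- 1 / (n_iter + 1)
  list(observed = observed, n_iter = n_iter, exceedances = exceed, p = p,
       upper_bound_flag = flag, seed = seed)
}
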