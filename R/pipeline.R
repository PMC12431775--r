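#' Default pipeline thresholds
#'
#' The analysis parameter set: linkage |z| > 2 with p < 0.05 for cCREs and
#' p < 0.01 for targets; weighted site conservation > 0.5; TF mean
#' expression > 1.2 (log1p); optional feature accessibility > 0.06 (off);
#' target expression subset > 0.5; cell-type log2FC 0.5; marker adjusted
#' p < 0.05 with top 25 markers; permutation iterations 1e6; 200 background
#' features; sliding-mean window 12; background quantile 0.25.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(link_z = 2, link_p_ccre = 0.05, link_p_target = 0.01,
       conservation = 0.5, tf_expression = 1.2, feature_accessibility = 0.06,
       use_accessibility_filter = FALSE, target_expression = 0.5,
       log2fc = 0.5, marker_adj_p = 0.05, top_markers = 25,
       perm_iterations = 1e6, n_background = 200,
       smooth_window = 12, background_quantile = 0.25)
}

#' Run the full analysis pipeline on a bundle
#'
#' Stages: conservation annotation of motif sites; TAD-constrained linkage
#' and cCRE calling for the selector genes; regulator identification per
#' selector and cell group with the common-regulator summary and the
#' permutation overlap test; target identification per selector TF with
#' differential expression, classification, characterization and two-edge
#' GSEA; CUT&Tag/footprint corroboration per TF; optional laminar
#' quantification when an ROI table is supplied. All tabular outputs are
#' written under `out_dir` and checksummed into a manifest; every threshold
#' actually used is recorded in the run log. Deterministic given `seed`.
#'
#' @param bundle A `synthetic_bundle` (or equivalent list of inputs).
#' @param out_dir Output directory.
#' @param thresholds Threshold list (see [default_thresholds()]; partial
#'   lists are filled with defaults).
#' @param selector_genes Selector gene ids (default: the bundle's planted
#'   selectors, else an error).
#' @param regulator_groups Cell groups for regulator calls (default
#'   CO1_2 and GA1_2).
#' @param target_groups Footprint groups qualifying target evidence
#'   (default GA1_2 and GL1_2).
#' @param perm_universe Candidate-regulator universe for the permutation
#'   test (default: seq_len(config perm_universe_size) labels).
#' @param expression_b Optional second-modality cells x genes matrix (e.g.
#'   integration-interpolated expression for accessibility-measured cells);
#'   when given, per-group cluster markers of both matrices are matched by
#'   the hypergeometric test and the similarity matrix is written.
#' @param rois Optional ROI table for the laminar stage.
#' @param vs_circle Circle (or per-image list) for the laminar stage.
#' @param seed Integer seed.
#' @return List with the stage results and the output manifest.
#' @export
run_pipeline <- function(bundle, out_dir, thresholds = list(),
                         selector_genes = NULL,
                         regulator_groups = c("CO1_2", "GA1_2"),
                         target_groups = c("GA1_2", "GL1_2"),
                         perm_universe = NULL, expression_b = NULL,
                         rois = NULL, vs_circle = NULL, seed = 1L) {
  thr <- utils::modifyList(default_thresholds(), thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(paste0(sprintf(...), "\n"), file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("ccrelink pipeline, package version %s", as.character(utils::packageVersion("ccrelink")))
  logf("seed: %d", as.integer(seed))
  for (nm in names(thr)) logf("threshold %s = %s", nm, format(thr[[nm]]))

  if (is.null(selector_genes)) selector_genes <- bundle$ground_truth$selectors
  if (is.null(selector_genes)) stop("selector_genes required")
  tf_names <- unique(bundle$sites$tf_name)

  # stage 1: conservation annotation
  logf("stage conservation: annotating %d sites", nrow(bundle$sites))
  sites <- annotate_site_conservation(bundle$sites, bundle$motifs, bundle$track)
  write_tsv_table(sites, file.path(out_dir, "sites_conservation.tsv"))

  # stage 2: linkage over every gene's TAD (cCRE threshold for selectors,
  # target threshold reuses the same records)
  logf("stage linkage: %d genes", nrow(bundle$genes))
  acc <- bundle$accessibility
  expr <- bundle$expression
  all_links <- list()
  for (i in seq_len(nrow(bundle$genes))) {
    g <- bundle$genes[i, , drop = FALSE]
    if (length(unique(expr[, g$gene_id])) < 2) {
      logf("linkage: gene %s has constant expression; skipped", g$gene_id)
      next
    }
    all_links[[g$gene_id]] <- link_gene_features(
      g, bundle$tads, bundle$features, acc, expr,
      n_background = min(thr$n_background,
                         sum(bundle$features$chrom == g$chrom) - 1),
      seed = seed + i)
  }
  links <- do.call(rbind, all_links)
  rownames(links) <- NULL
  write_tsv_table(links, file.path(out_dir, "links.tsv"))

  ccres <- list()
  for (s in selector_genes) {
    g <- bundle$genes[bundle$genes$gene_id == s, , drop = FALSE]
    tad <- assign_tad(data.frame(chrom = g$chrom, tss = g$tss), bundle$tads)
    ccres[[s]] <- call_ccres(all_links[[s]], tad,
                             z_threshold = thr$link_z, p_threshold = thr$link_p_ccre)
  }
  write_tsv_table(do.call(rbind, ccres), file.path(out_dir, "ccres.tsv"))

  # stage 3: regulators + common-regulator summary + permutation test
  logf("stage regulators: %d selectors x %d groups",
       length(selector_genes), length(regulator_groups))
  reg_calls <- list()
  for (s in selector_genes) {
    for (grp in regulator_groups) {
      acc_thr <- if (isTRUE(thr$use_accessibility_filter)) thr$feature_accessibility else NULL
      reg_calls[[paste(s, grp, sep = ".")]] <- identify_regulators(
        s, grp, ccres[[s]], sites, bundle$footprints, expr, bundle$groups,
        cons_threshold = thr$conservation, expr_threshold = thr$tf_expression,
        acc_threshold = acc_thr, accessibility = acc)
    }
  }
  regulators <- do.call(rbind, reg_calls)
  rownames(regulators) <- NULL
  write_tsv_table(regulators, file.path(out_dir, "regulators.tsv"))

  common <- list()
  perm_results <- list()
  if (is.null(perm_universe)) {
    n_u <- bundle$config$perm_universe_size %||% 1000
    perm_universe <- sprintf("U%04d", seq_len(n_u))
  }
  for (grp in regulator_groups) {
    by_gene <- lapply(selector_genes, function(s) reg_calls[[paste(s, grp, sep = ".")]])
    names(by_gene) <- selector_genes
    nonempty <- vapply(by_gene, nrow, 0L) > 0
    if (sum(nonempty) >= 2) {
      common[[grp]] <- summarize_common_regulators(by_gene[nonempty])
      write_tsv_table(common[[grp]]$partition,
                      file.path(out_dir, sprintf("common_regulators_%s.tsv", grp)))
    }
    if (length(by_gene) == 3) {
      sizes <- vapply(by_gene, function(d) length(unique(d$tf_name)), 0L)
      obs <- length(Reduce(intersect, lapply(by_gene, function(d) unique(d$tf_name))))
      if (all(sizes >= 1) && obs <= min(sizes)) {
        pr <- permutation_overlap_test(perm_universe, sizes, obs,
                                       n_iter = thr$perm_iterations, seed = seed)
        perm_results[[grp]] <- pr
        jsonlite::write_json(pr, file.path(out_dir, sprintf("overlap_test_%s.json", grp)),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  # stage 4: targets
  logf("stage targets: TFs %s", paste(selector_genes, collapse = ", "))
  gm <- group_mean_expression(expr, bundle$groups)
  cells <- intersect(rownames(expr), bundle$groups$cell_id)
  cg <- bundle$groups$group[match(cells, bundle$groups$cell_id)]
  de <- de_wilcoxon(expr, cells[cg == "GA1_2"], cells[cg == "GL1_2"])
  write_tsv_table(de, file.path(out_dir, "de_ga_vs_gl.tsv"))
  ranking <- gsea_ranking(de, p_adj = thr$link_p_target, min_pct = 0.1)
  target_out <- list()
  for (tf in selector_genes) {
    res <- identify_targets(tf, links, sites, bundle$footprints, bundle$peaks,
                            bundle$genes, groups_use = target_groups,
                            z_threshold = thr$link_z, p_threshold = thr$link_p_target,
                            cons_threshold = thr$conservation)
    if (nrow(res$targets)) {
      res$targets$class <- classify_targets(res$targets$gene_id, de,
                                            gm[, "GA1_2"], gm[, "GL1_2"],
                                            lfc = thr$log2fc, expr = thr$target_expression)
      ch <- characterize_targets(res$targets, res$features, expr, bundle$groups)
      write_tsv_table(ch$variability,
                      file.path(out_dir, sprintf("target_variability_%s.tsv", tf)))
      write_tsv_table(data.frame(metric = c(names(ch$sign_counts), names(ch$bin_counts)),
                                 value = c(ch$sign_counts, ch$bin_counts)),
                      file.path(out_dir, sprintf("target_characterization_%s.tsv", tf)))
      subset_genes <- target_expression_subset(res$targets$gene_id,
                                               gm[, "GA1_2"], gm[, "GL1_2"],
                                               threshold = thr$target_expression)
      writeLines(subset_genes, file.path(out_dir, sprintf("target_expressed_%s.txt", tf)))
      gs <- intersect(res$targets$gene_id, ranking$gene_id)
      if (length(gs) > 0 && length(gs) < nrow(ranking)) {
        gr <- gsea_two_edge(ranking$gene_id, gs)
        jsonlite::write_json(list(argmax = gr$argmax, argmin = gr$argmin,
                                  leading_edge_A = gr$leading_edge_A,
                                  leading_edge_B = gr$leading_edge_B),
                             file.path(out_dir, sprintf("gsea_%s.json", tf)),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    write_tsv_table(res$targets, file.path(out_dir, sprintf("targets_%s.tsv", tf)))
    write_tsv_table(res$features, file.path(out_dir, sprintf("target_features_%s.tsv", tf)))
    target_out[[tf]] <- res
  }

  # stage 4b (optional): cross-modality cluster-marker matching
  similarity <- NULL
  if (!is.null(expression_b)) {
    logf("stage markers: matching cluster markers across modalities")
    mk_a <- cluster_markers(expr, bundle$groups, p_adj = thr$marker_adj_p,
                            top_n = thr$top_markers)
    mk_b <- cluster_markers(expression_b, bundle$groups, p_adj = thr$marker_adj_p,
                            top_n = thr$top_markers)
    universe <- intersect(colnames(expr), colnames(expression_b))
    similarity <- marker_similarity(mk_a, mk_b, universe)
    write_tsv_table(cbind(cluster = rownames(similarity$p),
                          as.data.frame(similarity$p)),
                    file.path(out_dir, "marker_similarity.tsv"))
  }

  # stage 5: corroboration
  logf("stage corroboration: %d TFs", length(tf_names))
  cor_rows <- list()
  for (tf in tf_names) {
    bound_ids <- unique(bundle$footprints$site_id[bundle$footprints$footprint_score > 0])
    ts <- sites[sites$tf_name == tf & sites$site_id %in% bound_ids, , drop = FALSE]
    bs <- if (nrow(ts)) gintervals(ts$chrom, ts$start, ts$end, ts$site_id) else
      gintervals(character(0), numeric(0), numeric(0))
    st <- suppressWarnings(corroboration_stats(bundle$peaks[[tf]], bs))
    st$tf <- tf
    cor_rows[[tf]] <- st
    if (nrow(bundle$peaks[[tf]]) && nrow(bs)) {
      pd <- footprint_positions_in_peaks(bundle$peaks[[tf]], bs)
      write_tsv_table(data.frame(position = pd$positions),
                      file.path(out_dir, sprintf("footprint_positions_%s.tsv", tf)))
    }
  }
  corroboration <- do.call(rbind, cor_rows)[c("tf", "n_peaks", "n_bound_sites",
                                              "pct_peaks_with_site", "pct_sites_in_peak")]
  rownames(corroboration) <- NULL
  write_tsv_table(corroboration, file.path(out_dir, "corroboration.tsv"))

  # stage 6 (optional): laminar quantification
  laminar <- NULL
  if (!is.null(rois)) {
    logf("stage laminar: %d ROIs", nrow(rois))
    prof <- quantify_profile(rois, vs_circle,
                             background_quantile = thr$background_quantile)
    prof <- normalize_replicates(prof)
    smooth <- smooth_profile(prof, window = thr$smooth_window)
    write_tsv_table(prof, file.path(out_dir, "laminar_profile.tsv"))
    write_tsv_table(smooth, file.path(out_dir, "laminar_smoothed.tsv"))
    laminar <- list(profile = prof, smoothed = smooth)
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.tsv", "run_log.txt"))
  manifest <- data.frame(file = sort(files),
                         md5 = as.character(tools::md5sum(file.path(out_dir, sort(files)))),
                         row.names = NULL, stringsAsFactors = FALSE)
  write_tsv_table(manifest, file.path(out_dir, "manifest.tsv"))
  logf("done: %d output files", nrow(manifest))
  invisible(list(sites = sites, links = links, ccres = ccres,
                 regulators = regulators, common = common,
                 overlap_tests = perm_results, de = de,
                 targets = target_out, similarity = similarity,
                 corroboration = corroboration,
                 laminar = laminar, manifest = manifest, thresholds = thr))
}
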