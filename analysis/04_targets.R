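#!/usr/bin/env Rscript
# Step 4: selector-TF target genes, their classification and characterization.
#
# A gene is a target of a selector TF when a feature in the gene's TAD
# carries (i) a bound footprint of the TF in GA1_2 or GL1_2, (ii) a link to
# the gene with |z| > 2 and p < 0.01, (iii) weighted motif conservation
# > 0.5, and (iv) an overlapping CUT&Tag peak of the TF. Targets are then
# classified by GA-vs-GL differential expression, characterized by link
# sign, nearest-feature distance bins and expression variability, and run
# through a two-edge GSEA along the GA1_2 vs GL1_2 fold-change axis.

suppressMessages(library(ccrelink))

b <- read_bundle("results/bundle")
sites <- annotate_site_conservation(b$sites, b$motifs, b$track)
links <- read_tsv_table("results/links.tsv")
gm <- group_mean_expression(b$expression, b$groups)
grp <- b$groups$group
cells <- b$groups$cell_id
de <- de_wilcoxon(b$expression, cells[grp == "GA1_2"], cells[grp == "GL1_2"])
write_tsv_table(de, "results/de_ga_vs_gl.tsv")
ranking <- gsea_ranking(de, p_adj = 0.01, min_pct = 0.1)
cat(sprintf("DE axis: %d genes pass adj p < 0.01 and expression fraction >= 0.1\n",
            nrow(ranking)))

for (tf in b$ground_truth$selectors) {
  res <- identify_targets(tf, links, sites, b$footprints, b$peaks, b$genes)
  tg <- res$targets
  tg$class <- classify_targets(tg$gene_id, de, gm[, "GA1_2"], gm[, "GL1_2"])
  write_tsv_table(tg, sprintf("results/targets_%s.tsv", tf))
  write_tsv_table(res$features, sprintf("results/target_features_%s.tsv", tf))
  ch <- characterize_targets(tg, res$features, b$expression, b$groups)
  write_tsv_table(ch$variability, sprintf("results/target_variability_%s.tsv", tf))
  cat(sprintf("%s: %d target genes (%d GABA-specific, %d glut-specific); ",
              tf, nrow(tg), sum(tg$class == "GABA-specific"),
              sum(tg$class == "glut-specific")))
  cat(sprintf("links +%d/-%d; distance bins 0-5/5-50/>50 kb: %s\n",
              ch$sign_counts["positive"], ch$sign_counts["negative"],
              paste(ch$bin_counts, collapse = "/")))
  gs <- intersect(tg$gene_id, ranking$gene_id)
  if (length(gs) > 0 && length(gs) < nrow(ranking)) {
    run <- gsea_two_edge(ranking$gene_id, gs)
    cat(sprintf("  GSEA: %d set genes on the axis; leading edge A %d, edge B %d\n",
                length(gs), length(run$leading_edge_A), length(run$leading_edge_B)))
    jsonlite::write_json(list(leading_edge_A = run$leading_edge_A,
                              leading_edge_B = run$leading_edge_B,
                              argmax = run$argmax, argmin = run$argmin),
                         sprintf("results/gsea_%s.json", tf),
                         auto_unbox = TRUE, digits = NA)
  }
  expressed <- target_expression_subset(tg$gene_id, gm[, "GA1_2"], gm[, "GL1_2"])
  writeLines(expressed, sprintf("results/target_expressed_%s.txt", tf))
}

# cross-modality cluster matching: emulate integration-interpolated
# expression as a second modality and match per-group markers by the
# hypergeometric test
set.seed(20260921L)
expr_b <- pmax(b$expression + 0.15 * rnorm(length(b$expression)), 0)
mk_a <- cluster_markers(b$expression, b$groups)
mk_b <- cluster_markers(expr_b, b$groups)
sim <- marker_similarity(mk_a, mk_b, colnames(b$expression))
write_tsv_table(cbind(cluster = rownames(sim$p), as.data.frame(sim$p)),
                "results/marker_similarity.tsv")
diag_best <- vapply(rownames(sim$p), function(g) {
  if (all(is.na(sim$p[g, ]))) NA_character_ else colnames(sim$p)[which.min(sim$p[g, ])]
}, character(1))
cat(sprintf("marker matching: %d/%d groups best-match themselves across modalities\n",
            sum(diag_best == rownames(sim$p), na.rm = TRUE), nrow(sim$p)))

# truth check against the planted sets
gt <- b$ground_truth$targets
for (tf in b$ground_truth$selectors) {
  called <- read_tsv_table(sprintf("results/targets_%s.tsv", tf))$gene_id
  truth <- gt$gene_id[gt$tf == tf]
  cat(sprintf("%s: %d/%d planted targets recovered, %d extra\n", tf,
              sum(truth %in% called), length(truth), sum(!called %in% truth)))
}
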