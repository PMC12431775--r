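# shared synthetic bundles, simulated once per test run
.bundle_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.bundle_cache[[key]])) .bundle_cache[[key]] <- make()
  .bundle_cache[[key]]
}

# compact config: 12 TADs, 360 features, 200 cells; fast to simulate and link
mini_cfg <- function(seed = 11, ...) {
  synth_config(n_chroms = 2, chrom_length = 1e6, tads_per_chrom = 6,
               features_per_tad = 30, n_target_genes = 6,
               cells_per_group = 25, seed = seed, ...)
}

# links for all planted genes of a bundle (n_background sized to the config)
link_planted <- function(b, n_background = 100) {
  planted <- unique(b$ground_truth$links$gene_id)
  do.call(rbind, lapply(seq_along(planted), function(i) {
    g <- b$genes[b$genes$gene_id == planted[i], , drop = FALSE]
    link_gene_features(g, b$tads, b$features, b$accessibility, b$expression,
                       n_background = n_background, seed = i)
  }))
}

# zero-evidence-noise bundle with conservation-annotated sites and links
zero_bundle <- function() {
  cache_get("zero", function() {
    b <- simulate_bundle(zero_noise_config(mini_cfg(seed = 3)))
    b$sites <- annotate_site_conservation(b$sites, b$motifs, b$track)
    b$links <- link_planted(b)
    b
  })
}

noisy_bundle <- function(key = "noisy1", seed = 21) {
  cache_get(key, function() {
    b <- simulate_bundle(mini_cfg(seed = seed))
    b$sites <- annotate_site_conservation(b$sites, b$motifs, b$track)
    b$links <- link_planted(b)
    b
  })
}

ccres_for <- function(b, gene_id, p_threshold = 0.05) {
  g <- b$genes[b$genes$gene_id == gene_id, , drop = FALSE]
  tad <- assign_tad(data.frame(chrom = g$chrom, tss = g$tss), b$tads)
  call_ccres(b$links[b$links$gene_id == gene_id, , drop = FALSE], tad,
             p_threshold = p_threshold)
}

truth_regulators <- function(b, gene_id, group) {
  gt <- b$ground_truth$regulators
  sort(unique(gt$tf_name[gt$gene_id == gene_id & gt$cell_group == group]))
}

truth_targets <- function(b, tf) {
  gt <- b$ground_truth$targets
  sort(unique(gt$gene_id[gt$tf == tf]))
}
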