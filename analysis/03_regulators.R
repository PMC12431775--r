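#!/usr/bin/env Rscript
# Step 3: regulator identification and the common-regulator overlap test.
#
# A TF is a regulator of a selector gene in a cell group when it has a
# bound footprint (score > 0) at a conserved motif site (weighted mean
# conservation > 0.5) inside one of the gene's cCREs, and the TF gene is
# expressed > 1.2 (log1p) on average in that group. Shared regulators of
# the three selectors are summarised as a Venn partition, and the observed
# three-way overlap is tested against 1,000,000 random same-size set
# triples drawn from the candidate-regulator universe.

suppressMessages(library(ccrelink))

b <- read_bundle("results/bundle")
sites <- annotate_site_conservation(b$sites, b$motifs, b$track)
links <- read_tsv_table("results/links.tsv")
selectors <- b$ground_truth$selectors

calls <- list()
for (s in selectors) {
  g <- b$genes[b$genes$gene_id == s, , drop = FALSE]
  tad <- assign_tad(data.frame(chrom = g$chrom, tss = g$tss), b$tads)
  cc <- call_ccres(links[links$gene_id == s, ], tad)
  for (grp in c("CO1_2", "GA1_2")) {
    key <- paste(s, grp, sep = ".")
    calls[[key]] <- identify_regulators(s, grp, cc, sites, b$footprints,
                                        b$expression, b$groups)
    cat(sprintf("%s in %s: %d regulators {%s}\n", s, grp, nrow(calls[[key]]),
                paste(calls[[key]]$tf_name, collapse = ", ")))
  }
}
write_tsv_table(do.call(rbind, calls), "results/regulators.tsv")

for (grp in c("CO1_2", "GA1_2")) {
  by_gene <- lapply(selectors, function(s) calls[[paste(s, grp, sep = ".")]])
  names(by_gene) <- selectors
  if (any(vapply(by_gene, nrow, 0L) == 0)) next
  common <- summarize_common_regulators(by_gene)
  write_tsv_table(common$partition, sprintf("results/common_regulators_%s.tsv", grp))
  core <- common$core
  cat(sprintf("%s: %d TFs shared by all three selectors; worst-case linkage p %s\n",
              grp, nrow(core),
              if (nrow(core)) format(max(core$significance), digits = 3) else "-"))

  sizes <- vapply(by_gene, function(d) length(unique(d$tf_name)), 0L)
  obs <- nrow(core)
  universe <- sprintf("U%04d", seq_len(b$config$perm_universe_size))
  pt <- permutation_overlap_test(universe, sizes, obs, n_iter = 1e6,
                                 seed = 20260921L)
  cat(sprintf("  overlap test: observed %d, p %s%g (N = %g)\n", obs,
              if (pt$upper_bound_flag) "< " else "= ", pt$p, pt$n_iter))
  jsonlite::write_json(pt, sprintf("results/overlap_test_%s.json", grp),
                       auto_unbox = TRUE, digits = NA)
}
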