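#!/usr/bin/env Rscript
# Step 1: generate the synthetic multiome bundle used by all later steps.
#
# The bundle emulates a single-cell multiome study of a bifurcating neuronal
# lineage: 8 merged cell groups (progenitors, common precursors, GABAergic
# and glutamatergic branches), TADs tiling two chromosomes, accessible
# features, three selector TFs with planted cCREs and regulators, planted
# target genes, a conservation track, footprints, and CUT&Tag peaks.

suppressMessages(library(ccrelink))

cfg <- synth_config(seed = 20260921L)
bundle <- simulate_bundle(cfg)
dir.create("results", showWarnings = FALSE)
man <- write_bundle(bundle, "results/bundle")

gt <- bundle$ground_truth
cat(sprintf("bundle: %d genes, %d features in %d TADs, %d cells, %d motif sites\n",
            nrow(bundle$genes), nrow(bundle$features), nrow(bundle$tads),
            nrow(bundle$accessibility), nrow(bundle$sites)))
cat(sprintf("planted: %d feature-gene links (%d negative), %d selector genes, %d target relations\n",
            nrow(gt$links), sum(gt$links$sign == "-"),
            length(gt$selectors), nrow(gt$targets)))
cat(sprintf("wrote %d files under results/bundle (see manifest.tsv)\n", nrow(man)))
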