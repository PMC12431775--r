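target_fixture <- function(peak_overlap = TRUE, cons = 0.7, score = 0.5,
                           z = 2.5, p = 0.005) {
  links <- data.frame(feature_id = "f1", gene_id = "G1", chrom = "chr1",
                      start = 1000, end = 1500, rho = 0.6, z = z, p = p,
                      sign = "+", stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "s1", motif_id = "T.M1", tf_name = "T",
                      chrom = "chr1", start = 1100, end = 1110, strand = "+",
                      feature_id = "f1", weighted_conservation = cons,
                      stringsAsFactors = FALSE)
  fp <- data.frame(site_id = "s1", cell_group = c("GA1_2", "GL1_2"),
                   footprint_score = c(score, 0))
  pk_start <- if (peak_overlap) 1475 else 2000  # 25 bp overlap when TRUE
  peaks <- list(T = gintervals("chr1", pk_start, pk_start + 300))
  genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 4000)
  list(links = links, sites = sites, fp = fp, peaks = peaks, genes = genes)
}

test_that("target calls require the conjunction of all four evidence layers", {
  fx <- target_fixture()
  res <- identify_targets("T", fx$links, fx$sites, fx$fp, fx$peaks, fx$genes)
  expect_identical(res$targets$gene_id, "G1")
  expect_equal(res$targets$n_pos_links, 1L)
  expect_equal(res$targets$nearest_distance, 4000 - 1499)
  expect_identical(res$targets$distance_bin, "0-5")

  # removing any single layer removes the call
  no_pk <- target_fixture(peak_overlap = FALSE)
  expect_equal(nrow(identify_targets("T", no_pk$links, no_pk$sites, no_pk$fp,
                                     no_pk$peaks, no_pk$genes)$targets), 0L)
  lo_cons <- target_fixture(cons = 0.4)
  expect_equal(nrow(identify_targets("T", lo_cons$links, lo_cons$sites, lo_cons$fp,
                                     lo_cons$peaks, lo_cons$genes)$targets), 0L)
  unbound <- target_fixture(score = 0)
  expect_equal(nrow(identify_targets("T", unbound$links, unbound$sites, unbound$fp,
                                     unbound$peaks, unbound$genes)$targets), 0L)
  weak <- target_fixture(p = 0.05)
  expect_equal(nrow(identify_targets("T", weak$links, weak$sites, weak$fp,
                                     weak$peaks, weak$genes)$targets), 0L)
  # a TF without a CUT&Tag peak set is an error naming the TF
  expect_error(identify_targets("T", fx$links, fx$sites, fx$fp, list(), fx$genes),
               "T")
})

test_that("zero-noise bundles recover the planted target sets exactly", {
  b <- zero_bundle()
  for (tf in b$ground_truth$selectors) {
    res <- identify_targets(tf, b$links, b$sites, b$footprints, b$peaks, b$genes)
    expect_identical(sort(res$targets$gene_id), truth_targets(b, tf), label = tf)
  }
})

test_that("disabling any target condition yields a superset of calls", {
  for (b in list(zero_bundle(), noisy_bundle())) {
    tf <- b$ground_truth$selectors[1]
    full <- identify_targets(tf, b$links, b$sites, b$footprints, b$peaks, b$genes)
    for (toggle in c("use_footprint", "use_linkage", "use_conservation", "use_peak")) {
      args <- list(tf, b$links, b$sites, b$footprints, b$peaks, b$genes)
      args[[toggle]] <- FALSE
      relaxed <- do.call(identify_targets, args)
      expect_true(all(full$targets$gene_id %in% relaxed$targets$gene_id),
                  label = toggle)
    }
  }
})

test_that("rank-sum DE matches exhaustive enumeration and edge behaviour", {
  cells <- sprintf("c%02d", 1:10)
  A <- cells[1:5]; B <- cells[6:10]
  # identical multisets: p = 1, log2FC = 0
  e1 <- matrix(rep(c(1, 2, 3, 4, 5), 2), 10, 1, dimnames = list(cells, "g"))
  de1 <- de_wilcoxon(e1, A, B)
  expect_equal(de1$p, 1)
  expect_equal(de1$log2FC, 0)
  # expressed only in A: positive fold change, zero fraction in B
  e2 <- matrix(c(1, 2, 1, 2, 1, 0, 0, 0, 0, 0), 10, 1, dimnames = list(cells, "g"))
  de2 <- de_wilcoxon(e2, A, B)
  expect_equal(de2$pct_B, 0)
  expect_gt(de2$log2FC, 0)

  # 5-vs-5 toys: exact p from enumerating all 252 assignments
  set.seed(71)
  for (i in 1:10) {
    vals <- sample(seq(0.1, 9.9, by = 0.1), 10)  # tie-free
    em <- matrix(vals, 10, 1, dimnames = list(cells, "g"))
    got <- de_wilcoxon(em, A, B)$p
    r <- rank(vals)
    wobs <- sum(r[1:5]) - 5 * 6 / 2
    ws <- apply(utils::combn(10, 5), 2, function(idx) sum(r[idx]) - 15)
    p_enum <- min(1, 2 * min(mean(ws <= wobs), mean(ws >= wobs)))
    expect_equal(got, p_enum, tolerance = 1e-9)
  }
  expect_error(de_wilcoxon(e1, A[1:2], B), ">= 3 cells")
})

test_that("target classification follows the printed threshold rules", {
  de <- data.frame(gene_id = c("a", "b", "c"), log2FC = c(0.8, -0.8, 0))
  ga <- c(a = 0.9, b = 0.2, c = 0.6)
  gl <- c(a = 0.2, b = 0.9, c = 0.6)
  cls <- classify_targets(c("a", "b", "c"), de, ga, gl)
  expect_identical(unname(cls), c("GABA-specific", "glut-specific", "unclassified"))
})

test_that("characterization bins distances half-open and computes SD variability", {
  expect_identical(distance_bin(c(3000, 5000, 49999, 50000, 80000)),
                   c("0-5", "5-50", "5-50", ">50", ">50"))
  cells <- sprintf("c%02d", 1:9)
  groups <- cell_group_map(cells, rep(c("g1", "g2", "g3"), each = 3))
  expr <- matrix(c(rep(1, 3), rep(2, 3), rep(4, 3)), 9, 1,
                 dimnames = list(cells, "G1"))
  calls <- data.frame(tf = "T", gene_id = "G1", n_features = 1L,
                      n_pos_links = 1L, n_neg_links = 0L,
                      nearest_distance = 3000, distance_bin = "0-5")
  feats <- data.frame(feature_id = "f1", gene_id = "G1", sign = "+")
  ch <- characterize_targets(calls, feats, expr, groups)
  expect_equal(unname(ch$sign_counts), c(1, 0))
  expect_equal(unname(ch$bin_counts), c(1, 0, 0))
  expect_equal(ch$variability$variability, stats::sd(c(1, 2, 4)))  # hand oracle
  expect_equal(sum(ch$bin_counts), nrow(calls))
})

test_that("expression subset applies the strict OR rule", {
  ga <- c(a = 0.6, b = 0.5, c = 0.1)
  gl <- c(a = 0.1, b = 0.5, c = 0.2)
  expect_identical(target_expression_subset(c("a", "b", "c"), ga, gl), "a")
  expect_length(target_expression_subset(c("c"), ga, gl), 0)
})

test_that("GSEA running sum matches the hand-computed 10-gene curve", {
  ranked <- paste0("g", 1:10)
  gs <- c("g2", "g5", "g6")
  res <- gsea_two_edge(ranked, gs)
  hand <- cumsum(c(-1 / 7, 1 / 3, -1 / 7, -1 / 7, 1 / 3, 1 / 3,
                   -1 / 7, -1 / 7, -1 / 7, -1 / 7))
  expect_equal(res$curve, hand)
  expect_lt(abs(res$curve[10]), 1e-9)  # ends at zero
  expect_equal(res$argmax, 6)
  expect_identical(res$leading_edge_A, c("g2", "g5", "g6"))
  # the curve minimum is the first step (-1/7), so edge B spans the whole set
  expect_equal(res$argmin, 1)
  expect_identical(res$leading_edge_B, c("g2", "g5", "g6"))

  # a set at the very bottom puts the minimum just before the first hit
  res2 <- gsea_two_edge(paste0("g", 1:10), c("g8", "g9", "g10"))
  expect_equal(res2$argmin, 7)
  expect_identical(res2$leading_edge_B, c("g8", "g9", "g10"))
})

test_that("GSEA extremal placements and reversal behave as expected", {
  ranked <- paste0("g", 1:12)
  top <- paste0("g", 1:4)
  res <- gsea_two_edge(ranked, top)
  expect_equal(res$argmax, 4)
  expect_identical(res$leading_edge_A, top)
  bottom <- paste0("g", 9:12)
  res2 <- gsea_two_edge(ranked, bottom)
  expect_identical(res2$leading_edge_B, bottom)
  # reversing the ranking swaps the two edges
  res3 <- gsea_two_edge(rev(ranked), top)
  expect_identical(sort(res3$leading_edge_B), sort(res$leading_edge_A))
  expect_error(gsea_two_edge(ranked, "absent"), "disjoint")
  expect_error(gsea_two_edge(ranked, ranked), "entire ranking")
})

test_that("marker similarity equals the hypergeometric upper tail", {
  uni <- sprintf("u%03d", 1:100)
  A <- list(c1 = uni[1:25])
  B <- list(k1 = uni[c(1:10, 30:44)])  # overlap 10, |B| = 25
  res <- marker_similarity(A, B, uni)
  p_enum <- sum(stats::dhyper(10:25, 25, 75, 25))
  expect_equal(res$p["c1", "k1"], p_enum, tolerance = 1e-12)

  # zero overlap is certain at the upper tail of 0
  res0 <- marker_similarity(list(a = uni[1:5]), list(b = uni[6:10]), uni)
  expect_equal(unname(res0$p[1, 1]), 1)
  # saturated lists force the overlap
  uni25 <- uni[1:25]
  resS <- marker_similarity(list(a = uni25), list(b = uni25), uni25)
  expect_equal(unname(resS$p[1, 1]), 1)
  expect_warning(marker_similarity(list(a = c(uni[1:3], "zzz")),
                                   list(b = uni[1:3]), uni), "dropped")
})

test_that("GABA-only planted targets land in leading edge A", {
  b <- cache_get("gaba", function() {
    bb <- simulate_bundle(zero_noise_config(mini_cfg(seed = 13, target_mix = "gaba")))
    bb$sites <- annotate_site_conservation(bb$sites, bb$motifs, bb$track)
    bb$links <- link_planted(bb)
    bb
  })
  cells <- b$groups$cell_id
  grp <- b$groups$group
  de <- de_wilcoxon(b$expression, cells[grp == "GA1_2"], cells[grp == "GL1_2"])
  ranking <- gsea_ranking(de, p_adj = 0.01, min_pct = 0.1)
  tf <- b$ground_truth$selectors[1]
  res <- identify_targets(tf, b$links, b$sites, b$footprints, b$peaks, b$genes)
  gs <- intersect(res$targets$gene_id, ranking$gene_id)
  run <- gsea_two_edge(ranking$gene_id, gs)
  expect_gte(length(run$leading_edge_A) / length(gs), 0.9)
})
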