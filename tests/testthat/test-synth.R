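test_that("same config and seed give bit-identical bundles; seeds differ", {
  cfg <- mini_cfg(seed = 19)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$accessibility, b2$accessibility)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$footprints, b2$footprints)
  expect_identical(b1$ground_truth$links, b2$ground_truth$links)
  b3 <- simulate_bundle(mini_cfg(seed = 20))
  expect_false(identical(b1$accessibility, b3$accessibility))
})

test_that("planted ground truth is internally consistent", {
  b <- noisy_bundle()
  gt <- b$ground_truth
  expect_true(all(gt$links$feature_id %in% b$features$name))
  expect_true(all(gt$links$gene_id %in% b$genes$gene_id))
  # every planted link stays within the gene's TAD
  ftad <- b$features$tad[match(gt$links$feature_id, b$features$name)]
  gtad <- b$genes$tad[match(gt$links$gene_id, b$genes$gene_id)]
  expect_identical(ftad, gtad)
  expect_true(all(gt$bound$site_id %in% b$sites$site_id))
  expect_true(all(gt$regulators$tf_name %in% b$sites$tf_name))
  expect_true(all(gt$targets$gene_id %in% b$genes$gene_id))
  # matrices match their identifier lists
  expect_identical(colnames(b$accessibility), b$features$name)
  expect_identical(colnames(b$expression), b$genes$gene_id)
  expect_identical(rownames(b$expression), b$groups$cell_id)
  expect_true(all(b$accessibility >= 0))
  expect_true(all(b$expression >= 0))
})

test_that("footprint scores encode boundness, including exact zeros", {
  b <- noisy_bundle()
  fp <- b$footprints
  expect_identical(fp$bound, fp$footprint_score > 0)
  truth <- b$ground_truth$bound
  key_fp <- paste(fp$site_id, fp$cell_group)
  key_tr <- paste(truth$site_id, truth$cell_group)
  expect_setequal(key_fp[fp$bound], key_tr)
  expect_true(any(fp$footprint_score == 0))  # strict >0 rule is exercised
})

test_that("a single planted positive link has Spearman rho 1 at zero noise", {
  cfg <- zero_noise_config(mini_cfg(seed = 8, features_per_target = 1,
                                    target_mix = "gaba"))
  b <- simulate_bundle(cfg)
  gt <- b$ground_truth$links
  one <- gt[!gt$gene_id %in% b$ground_truth$selectors, ][1, ]
  rho <- spearman_rho(b$accessibility[, one$feature_id],
                      b$expression[, one$gene_id])
  expect_equal(rho, 1)
})

test_that("bundle write/read round-trips through standard formats", {
  b <- simulate_bundle(mini_cfg(seed = 4))
  dir <- withr::local_tempdir()
  man1 <- write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, man1$file))))
  back <- read_bundle(dir)
  expect_equal(back$genes$gene_id, b$genes$gene_id)
  expect_equal(back$features[c("chrom", "start", "end", "name")],
               b$features[c("chrom", "start", "end", "name")],
               ignore_attr = TRUE)
  expect_equal(back$accessibility, b$accessibility, tolerance = 1e-6)
  expect_equal(back$expression, b$expression, tolerance = 1e-6)
  expect_equal(back$sites, b$sites, ignore_attr = TRUE)
  expect_equal(sort(names(back$peaks)), sort(names(b$peaks)))
  expect_equal(back$ground_truth$links, b$ground_truth$links,
               ignore_attr = TRUE)
  pos <- which(b$track$runs$chr1$start >= 0)[1:50]
  expect_equal(cons_scores(back$track, "chr1", b$track$runs$chr1$start[pos]),
               cons_scores(b$track, "chr1", b$track$runs$chr1$start[pos]),
               tolerance = 1e-5)
  # checksums stable across two writes of the same bundle
  dir2 <- withr::local_tempdir()
  man2 <- write_bundle(b, dir2)
  expect_identical(man1$md5, man2$md5)
})

test_that("infeasible feature placement is a config error", {
  expect_error(synth_config(chrom_length = 1e4, tads_per_chrom = 12,
                            features_per_tad = 30),
               "infeasible placement")
})

test_that("raising the planted effect size never lowers link recovery", {
  recovery_at <- function(effect, seed) {
    b <- simulate_bundle(mini_cfg(seed = seed, effect = effect,
                                  expr_noise = 0.5))
    gt <- b$ground_truth$links
    planted <- unique(gt$gene_id)
    hits <- tot <- 0
    for (i in seq_along(planted)) {
      g <- b$genes[b$genes$gene_id == planted[i], , drop = FALSE]
      ln <- link_gene_features(g, b$tads, b$features, b$accessibility,
                               b$expression, n_background = 100, seed = i)
      cc <- call_ccres(ln, assign_tad(data.frame(chrom = g$chrom, tss = g$tss),
                                      b$tads))
      truth <- gt$feature_id[gt$gene_id == planted[i]]
      hits <- hits + sum(truth %in% cc$feature_id)
      tot <- tot + length(truth)
    }
    hits / tot
  }
  seeds <- c(31, 32, 33)
  rec <- vapply(c(0.02, 0.2, 1), function(e) {
    mean(vapply(seeds, function(s) recovery_at(e, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
})
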