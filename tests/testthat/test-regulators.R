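test_that("bound sites require a strictly positive footprint", {
  fp <- data.frame(site_id = c("s1", "s2", "s3"),
                   cell_group = "GA1_2",
                   footprint_score = c(0.3, 0, -0.2))
  expect_identical(bound_site_set(fp, "GA1_2"), "s1")
  expect_error(bound_site_set(fp, "XX"), "unknown cell group")
})

reg_fixture <- function(cons = 0.8, score = 0.5, expr_mean = 1.5) {
  cells <- sprintf("c%02d", 1:20)
  groups <- cell_group_map(cells, rep(c("GA1_2", "GL1_2"), each = 10))
  expr <- matrix(0, 20, 1, dimnames = list(cells, "TFX"))
  expr[1:10, "TFX"] <- expr_mean
  ccres <- data.frame(feature_id = "f1", gene_id = "G1", chrom = "chr1",
                      start = 0, end = 500, rho = 0.8, z = 3, p = 0.001,
                      sign = "+", stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "s1", motif_id = "TFX.M1", tf_name = "TFX",
                      chrom = "chr1", start = 10, end = 20, strand = "+",
                      feature_id = "f1", weighted_conservation = cons,
                      stringsAsFactors = FALSE)
  fp <- data.frame(site_id = "s1", cell_group = c("GA1_2", "GL1_2"),
                   footprint_score = c(score, -1))
  list(ccres = ccres, sites = sites, fp = fp, expr = expr, groups = groups)
}

test_that("regulator calls require bound + conserved + expressed, strictly", {
  fx <- reg_fixture(cons = 0.8, score = 0.5, expr_mean = 1.5)
  call <- identify_regulators("G1", "GA1_2", fx$ccres, fx$sites, fx$fp,
                              fx$expr, fx$groups)
  expect_identical(call$tf_name, "TFX")
  expect_equal(call$min_link_p, 0.001)

  # conservation exactly at the threshold is excluded (strict >)
  fx2 <- reg_fixture(cons = 0.5)
  expect_equal(nrow(identify_regulators("G1", "GA1_2", fx2$ccres, fx2$sites,
                                        fx2$fp, fx2$expr, fx2$groups)), 0L)
  # zero footprint is unbound
  fx3 <- reg_fixture(score = 0)
  expect_equal(nrow(identify_regulators("G1", "GA1_2", fx3$ccres, fx3$sites,
                                        fx3$fp, fx3$expr, fx3$groups)), 0L)
  # expression exactly at the threshold is excluded
  fx4 <- reg_fixture(expr_mean = 1.2)
  expect_equal(nrow(identify_regulators("G1", "GA1_2", fx4$ccres, fx4$sites,
                                        fx4$fp, fx4$expr, fx4$groups)), 0L)
  # TF gene absent from the expression matrix: skipped with a warning
  fx5 <- reg_fixture()
  colnames(fx5$expr) <- "OTHER"
  expect_warning(out <- identify_regulators("G1", "GA1_2", fx5$ccres, fx5$sites,
                                            fx5$fp, fx5$expr, fx5$groups),
                 "absent")
  expect_equal(nrow(out), 0L)
})

test_that("zero-noise bundles recover the planted regulator sets exactly", {
  b <- zero_bundle()
  for (s in b$ground_truth$selectors) {
    cc <- ccres_for(b, s)
    for (grp in c("CO1_2", "GA1_2")) {
      calls <- identify_regulators(s, grp, cc, b$sites, b$footprints,
                                   b$expression, b$groups)
      expect_identical(sort(calls$tf_name), truth_regulators(b, s, grp),
                       label = paste(s, grp))
    }
  }
})

test_that("relaxing any regulator condition never removes a TF", {
  for (b in list(zero_bundle(), noisy_bundle())) {
    s <- b$ground_truth$selectors[1]
    cc <- ccres_for(b, s)
    full <- identify_regulators(s, "GA1_2", cc, b$sites, b$footprints,
                                b$expression, b$groups)
    for (toggle in c("use_footprint", "use_conservation", "use_expression")) {
      args <- list(s, "GA1_2", cc, b$sites, b$footprints, b$expression, b$groups)
      args[[toggle]] <- FALSE
      relaxed <- do.call(identify_regulators, args)
      expect_true(all(full$tf_name %in% relaxed$tf_name), label = toggle)
    }
  }
})

test_that("common-regulator summary partitions sets and aggregates p-values", {
  mk <- function(tfs, ps) data.frame(tf_name = tfs, min_link_p = ps,
                                     stringsAsFactors = FALSE)
  # three identical sets: full intersection only
  same <- list(A = mk(c("x", "y"), c(0.01, 0.02)),
               B = mk(c("x", "y"), c(0.03, 0.001)),
               C = mk(c("x", "y"), c(0.002, 0.04)))
  res <- summarize_common_regulators(same)
  part <- setNames(res$partition$n, res$partition$signature)
  expect_equal(unname(part[c("A", "B", "C")]), c(0, 0, 0))
  expect_equal(unname(part["A&B&C"]), 2)
  # per-TF significance: max over genes of each gene's min p
  expect_equal(res$core$significance[res$core$tf_name == "x"], 0.03)
  expect_equal(res$core$significance[res$core$tf_name == "y"], 0.04)

  # pairwise-disjoint sets: empty full intersection
  disj <- list(A = mk("a", 0.1), B = mk("b", 0.1), C = mk("c", 0.1))
  res2 <- summarize_common_regulators(disj)
  expect_equal(res2$partition$n[res2$partition$signature == "A&B&C"], 0)
  expect_equal(nrow(res2$core), 0L)

  # constructed 3-gene toy against exhaustive min/max enumeration
  set.seed(41)
  tfs <- paste0("t", 1:6)
  toy <- lapply(1:3, function(i) {
    picked <- sort(sample(tfs, 4))
    do.call(rbind, lapply(picked, function(tf) {
      mk(rep(tf, 3), round(stats::runif(3), 4))  # 3 supporting links per TF
    }))
  })
  names(toy) <- c("gA", "gB", "gC")
  res3 <- summarize_common_regulators(toy)
  inter <- Reduce(intersect, lapply(toy, function(d) unique(d$tf_name)))
  expect_setequal(res3$core$tf_name, inter)
  for (tf in inter) {
    manual <- max(vapply(toy, function(d) min(d$min_link_p[d$tf_name == tf]),
                         numeric(1)))
    expect_equal(res3$core$significance[res3$core$tf_name == tf], manual)
  }
})

test_that("permutation overlap test saturates, bounds, and validates", {
  # all three sets drawn from a universe of their own size: intersection
  # always equals the universe, so p = 1
  r <- permutation_overlap_test(10, c(10, 10, 10), 10, n_iter = 50, seed = 1)
  expect_equal(r$p, 1)
  expect_false(r$upper_bound_flag)
  expect_error(permutation_overlap_test(10, c(2, 3, 4), 3, n_iter = 10, seed = 1),
               "exceeds the smallest set")
  r2 <- permutation_overlap_test(50, c(5, 5, 5), 5, n_iter = 200, seed = 2)
  expect_true(r2$p > 0 && r2$p <= 1)
  expect_identical(r2$upper_bound_flag, r2$exceedances == 0L)
})

test_that("empirical overlap p matches exhaustive enumeration (universe 6)", {
  # exact P(three random 2-subsets of a 6-universe share >= 1 element)
  subs <- utils::combn(6, 2, simplify = FALSE)
  hits <- 0
  for (i in seq_along(subs)) for (j in seq_along(subs)) for (k in seq_along(subs)) {
    if (length(Reduce(intersect, list(subs[[i]], subs[[j]], subs[[k]]))) >= 1) {
      hits <- hits + 1
    }
  }
  p_exact <- hits / length(subs)^3
  r <- permutation_overlap_test(6, c(2, 2, 2), 1, n_iter = 1e5, seed = 9)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(r$p - p_exact), 3 * se)
})

test_that("empirical overlap p is non-increasing in the observed size", {
  ps <- vapply(0:3, function(obs) {
    permutation_overlap_test(30, c(8, 8, 8), obs, n_iter = 2e4, seed = 77)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
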