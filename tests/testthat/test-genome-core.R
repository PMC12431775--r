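test_that("parse_bed maps fields verbatim and round-trips random intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tf1", f)
  x <- parse_bed(f)
  expect_equal(x$chrom, "chr1")
  expect_equal(x$start, 100)
  expect_equal(x$end, 200)
  expect_equal(x$name, "f1")

  writeLines(character(0), f)
  expect_equal(nrow(parse_bed(f)), 0L)

  set.seed(42)
  st <- sort(sample.int(1e6, 100))
  iv <- gintervals(sample(paste0("chr", 1:3), 100, TRUE), st,
                   st + sample.int(500, 100, TRUE),
                   sprintf("f%03d", 1:100),
                   sample(c("+", "-", "."), 100, TRUE))
  write_bed(iv, f)
  back <- parse_bed(f)
  expect_equal(back, iv, ignore_attr = TRUE)
})

test_that("parse_bed rejects malformed lines with the line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10", "chr1\tfoo\t20"), f)
  expect_error(parse_bed(f), "line 2")
  writeLines(c("# header", "chr1\t50\t40"), f)
  expect_error(parse_bed(f), "line 2")
})

test_that("interval_overlap follows the half-open >= min_bp rule", {
  a <- gintervals("chr1", 100, 200)
  expect_true(interval_overlap(a, gintervals("chr1", 199, 300), 1))   # 1 shared bp
  expect_false(interval_overlap(a, gintervals("chr1", 200, 300), 1))  # touching
  expect_error(interval_overlap(a, a, 0), "min_bp")

  # brute-force base enumeration on random pairs, plus symmetry
  set.seed(7)
  for (i in 1:200) {
    s1 <- sample.int(50, 1); e1 <- s1 + sample.int(30, 1)
    s2 <- sample.int(50, 1); e2 <- s2 + sample.int(30, 1)
    m <- sample.int(5, 1)
    x <- gintervals("c", s1, e1); y <- gintervals("c", s2, e2)
    shared <- length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1)))
    expect_identical(interval_overlap(x, y, m), shared >= m)
    expect_identical(interval_overlap(x, y, m), interval_overlap(y, x, m))
  }
})

test_that("overlap_pairs agrees with pairwise interval_overlap", {
  set.seed(13)
  q <- gintervals(sample(c("c1", "c2"), 30, TRUE), s <- sample.int(500, 30),
                  s + sample.int(80, 30, TRUE))
  s2 <- sample.int(500, 40)
  sub <- gintervals(sample(c("c1", "c2"), 40, TRUE), s2, s2 + sample.int(80, 40, TRUE))
  got <- overlap_pairs(q, sub, min_bp = 5)
  want <- expand.grid(query = 1:30, subject = 1:40)
  keep <- vapply(seq_len(nrow(want)), function(k) {
    interval_overlap(q[want$query[k], ], sub[want$subject[k], ], 5)
  }, logical(1))
  want <- want[keep, ]
  want <- want[order(want$query, want$subject), ]
  expect_equal(got$query, want$query)
  expect_equal(got$subject, want$subject)
})

test_that("tss_feature_distance handles containment, edges, and brute force", {
  g <- function(tss) data.frame(chrom = "chr1", tss = tss)
  f <- function(s, e) gintervals("chr1", s, e)
  expect_equal(tss_feature_distance(g(150), f(100, 200)), 0)
  expect_equal(tss_feature_distance(g(1000), f(6000, 6100)), 5000)
  expect_error(tss_feature_distance(data.frame(chrom = "chr2", tss = 1), f(1, 2)),
               "different chromosomes")

  set.seed(5)
  for (i in 1:100) {
    tss <- sample.int(1000, 1)
    s <- sample.int(1000, 1); e <- s + sample.int(50, 1)
    brute <- min(abs(tss - seq(s, e - 1)))
    expect_equal(tss_feature_distance(g(tss), f(s, e)), brute)
    # distance 0 iff the TSS point-interval overlaps the feature
    expect_identical(tss_feature_distance(g(tss), f(s, e)) == 0,
                     interval_overlap(gintervals("chr1", tss, tss + 1), f(s, e), 1))
  }
})

test_that("assign_tad picks the containing TAD, smallest when nested", {
  tads <- gintervals("chr1", c(0, 100, 150), c(1000, 400, 300),
                     c("outer", "mid", "inner"))
  g <- data.frame(chrom = "chr1", tss = 200)
  expect_equal(assign_tad(g, tads)$name, "inner")
  expect_null(assign_tad(data.frame(chrom = "chr1", tss = 5000), tads))
  expect_equal(assign_tad(data.frame(chrom = "chr1", tss = 50), tads)$name, "outer")

  # enumeration oracle on random nested sets
  set.seed(9)
  for (i in 1:50) {
    st <- sample.int(500, 8)
    tt <- gintervals("chr1", st, st + sample.int(400, 8, TRUE))
    tss <- sample.int(900, 1)
    hit <- which(tt$start <= tss & tss < tt$end)
    got <- assign_tad(data.frame(chrom = "chr1", tss = tss), tt)
    if (length(hit) == 0) {
      expect_null(got)
    } else {
      w <- tt$end[hit] - tt$start[hit]
      expect_equal(got$end - got$start, min(w))
    }
  }
})

test_that("conservation track lookup, bedGraph round trip, and defaults", {
  runs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(10, 20, 5), end = c(15, 25, 8),
                     score = c(0.25, 0.8, 0.5))
  tr <- cons_track(runs)
  expect_equal(cons_scores(tr, "chr1", c(9, 10, 14, 15, 22)),
               c(0, 0.25, 0.25, 0, 0.8))
  expect_equal(cons_scores(tr, "chrX", 1:3), c(0, 0, 0))  # absent scores 0
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- parse_bedgraph(f)
  expect_equal(cons_scores(back, "chr2", 4:8), cons_scores(tr, "chr2", 4:8))
  expect_error(cons_track(data.frame(chrom = "c", start = 0, end = 1, score = 1.2)),
               "\\[0, 1\\]")
})

test_that("MEME motif and gene-table readers round-trip and validate", {
  m <- list(M1 = list(motif_id = "M1", tf_name = "TFX",
                      mat = matrix(c(0.7, 0.1, 0.1, 0.1,
                                     0.25, 0.25, 0.25, 0.25), 4, 2,
                                   dimnames = list(c("A", "C", "G", "T"), NULL))))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(m, f)
  back <- read_meme(f)
  expect_equal(back$M1$tf_name, "TFX")
  expect_equal(back$M1$mat, m$M1$mat, tolerance = 1e-6)

  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(100, 5000), strand = c("+", "-"))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g, ft)
  expect_equal(read_gene_table(ft), g)
  g$strand[1] <- "."
  write_gene_table(g, ft)
  expect_error(read_gene_table(ft), "strand")
})

test_that("matrix MTX round trip preserves values and dimnames", {
  set.seed(3)
  m <- matrix(round(stats::runif(60), 4), 10, 6,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:6)))
  m[m < 0.3] <- 0
  pre <- withr::local_tempfile()
  write_matrix_mtx(m, pre)
  expect_equal(read_matrix_mtx(pre), m, tolerance = 1e-6)
})
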