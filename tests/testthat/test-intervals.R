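test_that("width normalization centers on the count maximum", {
  counts <- list(g = rep(0, 200))
  counts$g[111] <- 9                          # transcript coordinate 110
  s <- binding_site_set("g", 100, 120)
  out <- normalize_width(s, 5, counts = counts)
  expect_equal(c(out$start, out$end), c(108L, 113L))

  # already width-5 and centered: unchanged
  s2 <- binding_site_set("g", 108, 113)
  out2 <- normalize_width(s2, 5, counts = counts)
  expect_equal(c(out2$start, out2$end), c(108L, 113L))

  # no counts: centered on interval midpoint (floor)
  out3 <- normalize_width(binding_site_set("g", 100, 121), 5)
  expect_equal(c(out3$start, out3$end), c(108L, 113L))

  # clipped at transcript start: narrower, flagged
  counts$g[2] <- 99
  expect_message(out4 <- normalize_width(binding_site_set("g", 0, 10), 5,
                                         counts = counts), "clipped")
  expect_equal(c(out4$start, out4$end), c(0L, 4L))
  expect_true(out4$clipped)

  expect_error(normalize_width(s, 4), "odd")
})

test_that("jaccard index matches arithmetic and the per-nucleotide oracle", {
  A <- binding_site_set("g", 0, 10)
  B <- binding_site_set("g", 5, 15)
  expect_equal(jaccard_index(A, B), 5 / 15)
  expect_equal(jaccard_index(A, A), 1)
  expect_equal(jaccard_index(A, binding_site_set("g", 100, 110)), 0)
  set.seed(10)
  for (rep in 1:5) {
    X <- random_sites(8); Y <- random_sites(6)
    cx <- oracle_coverage(X, 1000); cy <- oracle_coverage(Y, 1000)
    expect_equal(jaccard_index(X, Y), sum(cx & cy) / sum(cx | cy))
    expect_equal(jaccard_index(X, Y), jaccard_index(Y, X))  # symmetry
  }
})

test_that("relative-distance index hits its three anchor points", {
  A <- binding_site_set("g", c(0, 100, 200, 300), c(10, 110, 210, 310))
  expect_equal(relative_distance_index(A, A), 1)           # coincident
  # perfectly even interleaving: B midpoints halfway between A midpoints
  B <- binding_site_set("g", c(50, 150, 250), c(60, 160, 260))
  expect_equal(relative_distance_index(A, B), -1)
  # uniform placement: index near 0
  set.seed(11)
  bm <- sort(sample(6:304, 10000, replace = TRUE))
  BU <- binding_site_set("g", bm - 1, bm + 1)
  idx <- relative_distance_index(A, BU)
  expect_lt(abs(idx), 0.05)
  # invariant under a common coordinate shift
  sh <- 1000L
  A2 <- binding_site_set("g", A$start + sh, A$end + sh)
  B2 <- binding_site_set("g", B$start + sh, B$end + sh)
  expect_equal(relative_distance_index(A2, B2),
               relative_distance_index(A, B))
  # genes with < 2 reference sites are skipped
  expect_message(
    r <- relative_distance_index(binding_site_set("g", 0, 10), B), "skipped")
  expect_true(is.na(r))
})

test_that("per-gene overlap matches the per-nucleotide oracle and uses a strict cutoff", {
  A <- binding_site_set("g", 0, 100)
  B <- binding_site_set("g", 50, 150)
  r <- per_gene_overlap(A, B)
  expect_equal(r$overlap_nt, 50)
  expect_false(r$classified_overlapping)       # strict > 50
  r2 <- per_gene_overlap(A, binding_site_set("g", 49, 150))
  expect_equal(r2$overlap_nt, 51)
  expect_true(r2$classified_overlapping)
  r3 <- per_gene_overlap(A, binding_site_set("g", 200, 300))
  expect_equal(r3$overlap_nt, 0)
  expect_equal(r3$jaccard, 0)
  set.seed(12)
  for (rep in 1:5) {
    X <- random_sites(10, len = 9000); Y <- random_sites(7, len = 9000)
    cx <- oracle_coverage(X, 10000); cy <- oracle_coverage(Y, 10000)
    rr <- per_gene_overlap(X, Y)
    expect_equal(rr$overlap_nt, sum(cx & cy))
    expect_equal(rr$rbp1_coverage_nt, sum(cx))
    expect_equal(rr$rbp2_coverage_nt, sum(cy))
    expect_equal(rr$union_nt, sum(cx | cy))
    expect_equal(rr$frac_coincidental_rbp1, sum(cx & cy) / sum(cx))
  }
  # genes absent from the annotation are skipped
  ann <- transcript_annotation("g", "chr1", "+", "3UTR", 0, 10000)
  X <- binding_site_set(c("g", "unknown"), c(0, 0), c(10, 10))
  expect_message(rr <- per_gene_overlap(X, X, annotation = ann), "absent")
  expect_equal(rr$gene_id, "g")
})

test_that("overlap distribution comparison behaves like a two-sample KS test", {
  t0 <- data.frame(overlap_nt = c(1, 5, 10, 20))
  expect_equal(compare_overlap_distributions(t0, t0)$D, 0)
  expect_equal(compare_overlap_distributions(t0, t0)$p, 1)
  set.seed(13)
  nt <- data.frame(overlap_nt = rpois(200, 30))
  tm <- data.frame(overlap_nt = nt$overlap_nt + 100)
  expect_lt(compare_overlap_distributions(tm, nt)$p, 0.01)
  single <- data.frame(overlap_nt = 5)
  expect_true(compare_overlap_distributions(single,
                                            data.frame(overlap_nt = 9))$D
              %in% c(0, 1))
  expect_error(compare_overlap_distributions(t0[0, , drop = FALSE], t0),
               "empty")
})
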