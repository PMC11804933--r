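test_that("MSA filtering drops low-occupancy and near-identical rows", {
  m <- rbind(ref = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C"),
             s2  = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C"),
             s3  = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "T"),
             s4  = c("T", "G", "C", "A", "T", "G", "C", "A", "T", "G"),
             s5  = c("A", "-", "-", "-", "-", "-", "-", "-", "A", "C"))
  blk <- alignment_block(m, "ref")
  out <- filter_msa(blk, rowocc = 0.4, seqid = 0.98)
  # s5: 30% non-gap -> dropped; s2 identical to ref -> dropped (later row)
  expect_false("s5" %in% rownames(out$seqs))
  expect_false("s2" %in% rownames(out$seqs))
  expect_true("ref" %in% rownames(out$seqs))
  expect_true(all(c("s3", "s4") %in% rownames(out$seqs)))
  # reference protected in identity pruning even as the later row of a pair
  m2 <- m[c("s2", "ref", "s3", "s4"), ]
  out2 <- filter_msa(alignment_block(m2, "ref"))
  expect_true("ref" %in% rownames(out2$seqs))
  expect_false("s2" %in% rownames(out2$seqs))
})

test_that("mutual information matches closed forms and the counting oracle", {
  # bijective recoding over 4 equiprobable symbols -> 2 bits
  m <- cbind(rep(c("A", "C", "G", "T"), 2), rep(c("C", "G", "T", "A"), 2))
  rownames(m) <- paste0("s", 1:8)
  mi <- mutual_information(alignment_block(m, "s1"))
  expect_equal(mi$raw[1, 2], 2)
  # constant column against anything -> 0
  m2 <- cbind(rep("A", 8), rep(c("A", "C"), 4))
  rownames(m2) <- paste0("s", 1:8)
  expect_equal(mutual_information(alignment_block(m2, "s1"))$raw[1, 2], 0)
  # random small alignments against the exhaustive-count oracle
  set.seed(31)
  for (rep in 1:6) {
    nr <- sample(5:8, 1); nc <- sample(6:12, 1)
    m3 <- matrix(sample(c("A", "C", "G", "T", "-"), nr * nc, TRUE,
                        prob = c(0.23, 0.23, 0.23, 0.23, 0.08)), nr, nc)
    m3[1, ] <- sample(c("A", "C", "G", "T"), nc, TRUE)  # ungapped reference
    rownames(m3) <- paste0("s", seq_len(nr))
    mi3 <- mutual_information(alignment_block(m3, "s1"))
    expect_equal(mi3$raw, oracle_mi_matrix(m3), tolerance = 1e-12)
    expect_equal(mi3$raw, t(mi3$raw))                   # symmetric
    expect_true(all(mi3$raw >= 0, na.rm = TRUE))
  }
})

test_that("average product correction matches the hand-computed form", {
  mk_mi <- function(raw) {
    diag(raw) <- NA
    structure(list(raw = raw, n_effective = matrix(99, nrow(raw), nrow(raw)),
                   ref_coords = seq_len(nrow(raw)) - 1L, corrected = NULL),
              class = "mi_matrix")
  }
  # constant raw matrix: corrected ~ 0 everywhere
  cst <- apc_correct(mk_mi(matrix(0.7, 5, 5)))
  expect_equal(max(abs(cst$corrected), na.rm = TRUE), 0, tolerance = 1e-12)
  # 3-column toy against explicit APC arithmetic
  raw <- matrix(c(NA, 0.4, 0.1,
                  0.4, NA, 0.3,
                  0.1, 0.3, NA), 3, 3)
  out <- apc_correct(mk_mi(raw))$corrected
  mi_bar <- c(mean(c(0.4, 0.1)), mean(c(0.4, 0.3)), mean(c(0.1, 0.3)))
  grand <- mean(c(0.4, 0.1, 0.4, 0.3, 0.1, 0.3))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_true(is.na(out[i, j]))
    else expect_equal(out[i, j],
                      raw[i, j] - mi_bar[i] * mi_bar[j] / grand,
                      tolerance = 1e-12)
  }
  expect_equal(out, t(out))                             # symmetry preserved
})

test_that("planted coevolving pairs dominate the corrected-MI distribution", {
  geom <- within(list(), {
    pp <- data.frame(col_i = c(5L, 20L, 35L, 50L, 55L),
                     col_j = c(10L, 25L, 40L, 52L, 58L), coupling = 1)
  })
  sp <- sim_spec(seed = 41, alignment_length = 60L, planted_pairs = geom$pp)
  sim <- simulate_alignment(sp)
  mi <- apc_correct(mutual_information(filter_msa(sim$block)))
  vals <- mi$corrected[upper.tri(mi$corrected)]
  thr <- quantile(vals, 0.95, na.rm = TRUE)
  planted <- mapply(function(i, j) mi$corrected[i, j],
                    geom$pp$col_i, geom$pp$col_j)
  expect_true(all(planted > thr))
})

test_that("site-pair statistic is degenerate-safe and direction-aware", {
  sp <- sim_spec(seed = 42, alignment_length = 50L, gap_rate = 0)
  mi <- apc_correct(mutual_information(simulate_alignment(sp)$block))
  # partner sites = all columns: s_i equals r_i exactly, p = 1
  r <- site_pair_statistic(mi, sitesA = 1:10, sitesB = 1:50)
  expect_equal(r$p_raw, 1)
  expect_equal(r$pair_mean, r$row_mean, tolerance = 1e-12)
  # < 4 site columns: skipped with message
  expect_message(r2 <- site_pair_statistic(mi, 1:3, 10:20), "skipped")
  expect_true(r2$skipped)
  # Bonferroni table
  tab <- site_pair_table(list(r, r2))
  expect_equal(tab$p_adj[1], 1)
  expect_true(is.na(tab$p_adj[2]))
})

test_that("shuffled-site null is seeded and bounded by the region", {
  geom <- coevo_geometry()
  pp <- data.frame(col_i = geom$a_cols, col_j = geom$b_cols, coupling = 1)
  sp <- sim_spec(seed = 43, planted_pairs = pp)
  mi <- apc_correct(mutual_information(simulate_alignment(sp)$block))
  sn <- shuffle_null(mi, geom$a_cols, geom$b_iv, iterations = 10, seed = 7)
  expect_length(sn$shuffled_means, 10)
  expect_identical(shuffle_null(mi, geom$a_cols, geom$b_iv,
                                iterations = 10, seed = 7), sn)
  # planted coupling: observed pair mean above every shuffled mean
  expect_true(sn$observed > max(sn$shuffled_means))
  expect_error(shuffle_null(mi, geom$a_cols,
                            cbind(0L, 300L), region_length = 200),
               "cannot fit")
})

test_that("stage-consistent filter keeps only sites replicated across stages", {
  s1 <- binding_site_set("g", c(100, 300, 500), c(120, 320, 520))
  s2 <- binding_site_set("g", c(110, 700), c(130, 720))
  out <- stage_consistent_sites(s1, s2, width = NULL)
  expect_equal(out$start, 100)
  out5 <- stage_consistent_sites(s1, s2, width = 5)
  expect_equal(out5$end - out5$start, 5L)
})
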