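test_that("background subtraction follows the nonsignificant-mean rule", {
  tr <- crosslink_track("g", c(10, 3, 0), c(TRUE, FALSE, FALSE))
  out <- subtract_background(tr)
  expect_equal(out$counts, c(10 - 1.5, 0, 0))   # background = mean(3, 0)

  # all positions significant: unchanged, with a warning
  tr2 <- crosslink_track("g", c(5, 7), c(TRUE, TRUE))
  expect_warning(out2 <- subtract_background(tr2), "background")
  expect_equal(out2$counts, c(5, 7))

  # significant count below background clamps at zero
  tr3 <- crosslink_track("g", c(2, 10, 10), c(TRUE, FALSE, FALSE))
  expect_equal(subtract_background(tr3)$counts, c(0, 0, 0))
})

test_that("iclip_score is correct arithmetic and scale-invariant", {
  expect_equal(iclip_score(100, 1e6, 50), 2)
  expect_equal(iclip_score(0, 1e6, 50), 0)
  expect_equal(iclip_score(100, 1e6, 50), iclip_score(200, 2e6, 50))
  # monotone in significant reads
  expect_true(iclip_score(101, 1e6, 50) > iclip_score(100, 1e6, 50))
  expect_error(iclip_score(10, 1e6, 0, tpm_floor = 0), "tpm")
  expect_error(iclip_score(10, 0, 50), "library_size")
})

test_that("hypergeometric overlap test equals exhaustive enumeration", {
  # forced total overlap: p = 1 / C(20, 5)
  expect_equal(target_overlap_significance(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(target_overlap_significance(5, 5, 0, 20), 1)
  expect_equal(target_overlap_significance(20, 7, 7, 20), 1)
  # enumeration oracle over every draw of B from a small universe
  for (cfg in list(c(12, 5, 4), c(10, 6, 3), c(14, 4, 6))) {
    u <- cfg[1]; nA <- cfg[2]; nB <- cfg[3]
    for (k in 0:min(nA, nB))
      expect_equal(target_overlap_significance(nA, nB, k, u),
                   oracle_hyper_ge(nA, nB, k, u), tolerance = 1e-12)
  }
  expect_error(target_overlap_significance(5, 5, 6, 20), "inconsistent")
})

test_that("profile filter retains structured genes and drops flat ones", {
  sp <- sim_spec(seed = 4, n_genes = 80L, gene_length = 30L)
  sim <- simulate_crosslink_tracks(sp)
  # overwrite 15 genes with flat profiles: constant mean across libraries
  flat <- sim$truth$gene_id[1:15]
  dt <- sim$tracks
  set.seed(99)
  sel <- dt$gene_id %in% flat & dt$significant
  dt$count[sel] <- rpois(sum(sel), 40)
  om <- occupancy_matrix(dt, sim$tpm, sim$library_sizes, sim$library_info)
  cr <- cluster_profiles(om, k = 4)
  expect_lt(mean(flat %in% names(cr$labels)), 0.35)
  expect_gt(mean(setdiff(sim$truth$gene_id, flat) %in% names(cr$labels)), 0.8)
  # k = 1: everything retained shares one label
  cr1 <- cluster_profiles(om, k = 1)
  expect_true(all(cr1$labels == 1L))
})

test_that("clustering is invariant to gene order", {
  sp <- sim_spec(seed = 6, n_genes = 90L, gene_length = 30L)
  sim <- simulate_crosslink_tracks(sp)
  om <- occupancy_matrix(sim$tracks, sim$tpm, sim$library_sizes,
                         sim$library_info)
  set.seed(1)
  perm <- sample(nrow(sim$tracks))
  om2 <- occupancy_matrix(sim$tracks[perm, ], sim$tpm, sim$library_sizes,
                          sim$library_info)
  cr <- cluster_profiles(om, k = 3)
  cr2 <- cluster_profiles(om2, k = 3)
  expect_equal(cr$centroids, cr2$centroids, tolerance = 1e-10)
  expect_equal(cr$labels[names(cr2$labels)], cr2$labels)
})

test_that("assign_groups classifies centroids by the stated rules", {
  mk <- function(cent) {
    structure(list(labels = setNames(rep(1L, 4), paste0("g", 1:4)),
                   centroids = cent,
                   library_info = data.frame(
                     library = c("RBP1_L1", "RBP1_L2", "RBP2_L2", "RBP2_L3"),
                     rbp = c("RBP1", "RBP1", "RBP2", "RBP2"),
                     stage = c(1, 2, 2, 3))),
              class = "cluster_result")
  }
  cent <- rbind(c(2, 2, 0.1, 0.1), c(0.1, 0.1, 3, 0.5),
                c(0.1, 0.1, 0.5, 3), c(3, 2, 0.05, 1))
  colnames(cent) <- c("RBP1_L1", "RBP1_L2", "RBP2_L2", "RBP2_L3")
  rownames(cent) <- 1:4
  res <- assign_groups(mk(cent))
  expect_equal(unname(res$group),
               c("higher_rbp1", "peak_mid_rbp2", "higher_rbp2",
                 "reduced_mid_rbp2"))
  # tie in contrast breaks deterministically with a warning
  tie <- rbind(c(1, 1, 1, 1))
  colnames(tie) <- colnames(cent); rownames(tie) <- 1
  expect_warning(assign_groups(mk(tie)), "tie")
})
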