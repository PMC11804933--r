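#' Filter a multiple sequence alignment by row occupancy and identity
#'
#' Drops rows whose non-gap fraction is below `rowocc`, then walks row pairs
#' in order and drops the later row of any pair whose identity (computed over
#' mutually non-gap columns) exceeds `seqid`. The reference row is never
#' dropped; if it falls below the occupancy threshold it is retained with a
#' warning.
#'
#' @param block an [alignment_block()].
#' @param rowocc minimum non-gap fraction, default 0.4.
#' @param seqid identity threshold above which the later row is dropped,
#'   default 0.98.
#' @return A filtered [alignment_block()]; when fewer than 4 rows remain the
#'   block carries attribute `low_power = TRUE` and a message is emitted.
#' @export
filter_msa <- function(block, rowocc = 0.4, seqid = 0.98) {
  stopifnot(inherits(block, "alignment_block"))
  seqs <- block$seqs
  if (nrow(seqs) < 2) stop("filter_msa: need >= 2 rows")
  occ <- rowMeans(seqs != "-")
  keep <- occ >= rowocc
  refi <- match(block$reference_id, rownames(seqs))
  if (!keep[refi]) {
    warning("filter_msa: reference row below occupancy threshold (",
            round(occ[refi], 3), "); retained")
    keep[refi] <- TRUE
  }
  seqs <- seqs[keep, , drop = FALSE]
  # identity pruning, reference-protected
  alive <- rep(TRUE, nrow(seqs))
  refi <- match(block$reference_id, rownames(seqs))
  for (i in seq_len(nrow(seqs) - 1L)) {
    if (!alive[i]) next
    for (j in (i + 1L):nrow(seqs)) {
      if (!alive[j]) next
      both <- seqs[i, ] != "-" & seqs[j, ] != "-"
      if (!any(both)) next
      ident <- mean(seqs[i, both] == seqs[j, both])
      if (ident > seqid) {
        drop <- if (j == refi) i else j
        alive[drop] <- FALSE
        if (drop == i) break
      }
    }
  }
  seqs <- seqs[alive, , drop = FALSE]
  out <- block
  out$seqs <- seqs
  out$species <- rownames(seqs)
  if (nrow(seqs) < 4) {
    message("filter_msa: only ", nrow(seqs),
            " row(s) remain; block flagged low-power")
    attr(out, "low_power") <- TRUE
  }
  out
}

#' Pairwise mutual information between alignment columns
#'
#' For every column pair, rows carrying a gap in either column are excluded
#' (pairwise deletion); empirical joint and marginal frequencies over
#' `{A, C, G, T}` give MI in bits:
#' \deqn{MI(i, j) = \sum_{a,b} p(a,b) \log_2 \frac{p(a,b)}{p(a) p(b)}.}
#' Pairs with fewer than `min_rows` effective rows (and the diagonal) are set
#' to missing.
#'
#' @param block a (filtered) [alignment_block()] with >= 4 rows.
#' @param min_rows minimum effective rows per pair, default 4.
#' @return An `mi_matrix`: list with `raw` (symmetric column x column matrix,
#'   bits, NA diagonal), `n_effective` (rows used per pair), `ref_coords`.
#' @export
mutual_information <- function(block, min_rows = 4L) {
  stopifnot(inherits(block, "alignment_block"))
  seqs <- block$seqs
  if (nrow(seqs) < 4) stop("mutual_information: need >= 4 rows")
  L <- ncol(seqs)
  nts <- c("A", "C", "G", "T")
  ind <- lapply(nts, function(a) (seqs == a) * 1)
  # joint counts for all column pairs at once: N_ab = t(X_a) X_b
  N <- vector("list", 16L)
  for (a in 1:4) for (b in 1:4)
    N[[(a - 1L) * 4L + b]] <- crossprod(ind[[a]], ind[[b]])
  neff <- Reduce(`+`, N)
  rowM <- lapply(1:4, function(a) Reduce(`+`, N[(a - 1L) * 4L + 1:4]))
  colM <- lapply(1:4, function(b) Reduce(`+`, N[seq(b, 16L, by = 4L)]))
  mi <- matrix(0, L, L)
  for (a in 1:4) for (b in 1:4) {
    Nab <- N[[(a - 1L) * 4L + b]]
    t <- Nab > 0
    if (any(t))
      mi[t] <- mi[t] + (Nab[t] / neff[t]) *
        log2(Nab[t] * neff[t] / (rowM[[a]][t] * colM[[b]][t]))
  }
  mi[mi < 0] <- 0           # guard against -0 from rounding
  mi[neff < min_rows] <- NA
  diag(mi) <- NA
  structure(list(raw = mi, n_effective = neff, ref_coords = block$ref_coords,
                 corrected = NULL),
            class = "mi_matrix")
}

#' Average product correction of a mutual information matrix
#'
#' Subtracts the background expected from column promiscuity:
#' `corrected(i, j) = raw(i, j) - mean_i * mean_j / overall_mean`, where
#' `mean_i` is column i's mean raw MI to all other non-missing columns and
#' `overall_mean` is the grand off-diagonal mean. Suppresses phylogenetic and
#' entropy bias shared across a column's pairs.
#'
#' @param mi an `mi_matrix` from [mutual_information()].
#' @return The `mi_matrix` with `corrected` filled in (missing stays
#'   missing); when the overall mean is 0 the correction is a no-op (with a
#'   message).
#' @export
apc_correct <- function(mi) {
  stopifnot(inherits(mi, "mi_matrix"))
  raw <- mi$raw
  mean_i <- rowMeans(raw, na.rm = TRUE)
  overall <- mean(raw, na.rm = TRUE)
  if (!is.finite(overall) || overall == 0) {
    message("apc_correct: zero grand mean; corrected = raw")
    mi$corrected <- raw
    return(mi)
  }
  corr <- raw - outer(mean_i, mean_i) / overall
  corr[is.na(raw)] <- NA
  mi$corrected <- corr
  mi
}

#' Site-pair coevolution statistic between two RBPs' binding-site columns
#'
#' For direction A-to-B: every A-site column i gets `s_i`, its mean corrected
#' MI over the B-site columns, and `r_i`, its mean corrected MI over all
#' columns (the row average). The statistic compares the paired `(s_i, r_i)`
#' by a one-sided Wilcoxon signed-rank test (elevated MI toward the partner's
#' sites). Adjust p across genes x regions x directions with
#' [site_pair_table()].
#'
#' @param mi an APC-corrected `mi_matrix` (see [apc_correct()]).
#' @param sitesA,sitesB 1-based column indices of the two RBPs' binding
#'   sites.
#' @param direction label, e.g. `"A_to_B"`.
#' @param gene_id,region labels carried into the result.
#' @return A one-row data.frame: `gene_id, region, direction, n_site_columns,
#'   pair_mean, row_mean, p_raw, skipped`. Fewer than 4 A-site columns skips
#'   the test (`skipped = TRUE`, p NA).
#' @export
site_pair_statistic <- function(mi, sitesA, sitesB, direction = "A_to_B",
                                gene_id = NA_character_,
                                region = NA_character_) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (is.null(mi$corrected))
    stop("site_pair_statistic: run apc_correct() first")
  M <- mi$corrected
  base <- data.frame(gene_id = gene_id, region = region,
                     direction = direction,
                     n_site_columns = length(sitesA),
                     pair_mean = NA_real_, row_mean = NA_real_,
                     p_raw = NA_real_, skipped = TRUE,
                     stringsAsFactors = FALSE)
  if (length(sitesA) < 4) {
    message("site_pair_statistic: < 4 site columns for ", direction,
            "; test skipped")
    return(base)
  }
  s <- vapply(sitesA, function(i) mean(M[i, sitesB], na.rm = TRUE), 0)
  r <- vapply(sitesA, function(i) mean(M[i, ], na.rm = TRUE), 0)
  ok <- is.finite(s) & is.finite(r)
  s <- s[ok]; r <- r[ok]
  if (length(s) < 4) return(base)
  d <- s - r
  p <- if (all(abs(d) < 1e-12)) 1 else
    suppressWarnings(stats::wilcox.test(s, r, paired = TRUE,
                                        alternative = "greater")$p.value)
  data.frame(gene_id = gene_id, region = region, direction = direction,
             n_site_columns = length(s), pair_mean = mean(s),
             row_mean = mean(r), p_raw = p, skipped = FALSE,
             stringsAsFactors = FALSE)
}

#' Collect site-pair results and adjust p-values
#'
#' Binds per-gene/region/direction results from [site_pair_statistic()] and
#' Bonferroni-adjusts the raw p-values across all non-skipped tests;
#' `significant` marks `p_adj < alpha`.
#'
#' @param results list of one-row data.frames from [site_pair_statistic()].
#' @param alpha significance threshold on adjusted p, default 0.01.
#' @return data.frame with `p_adj` and `significant` columns added.
#' @export
site_pair_table <- function(results, alpha = 0.01) {
  tab <- do.call(rbind, results)
  tab$p_adj <- NA_real_
  tested <- !tab$skipped
  tab$p_adj[tested] <- pmin(tab$p_raw[tested] * sum(tested), 1)
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  tab
}

#' Shuffled-binding-site null for the site-pair statistic
#'
#' Re-places the partner RBP's binding sites uniformly at random within the
#' region (widths preserved, non-overlapping), recomputes the pair mean, and
#' repeats `iterations` times; run once per direction.
#'
#' @param mi an APC-corrected `mi_matrix`.
#' @param sitesA 1-based column indices of the querying RBP's sites.
#' @param sitesB_intervals partner sites as a 2-column matrix/data.frame of
#'   0-based half-open `(start, end)` region coordinates (contiguity is
#'   preserved when shuffling).
#' @param region_length number of columns available for placement (defaults
#'   to the matrix size).
#' @param iterations shuffles, default 10.
#' @param seed integer seed.
#' @return list with `observed` (the un-shuffled pair mean) and
#'   `shuffled_means` (length `iterations`).
#' @export
shuffle_null <- function(mi, sitesA, sitesB_intervals,
                         region_length = NULL, iterations = 10L, seed = 1L) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (is.null(mi$corrected))
    stop("shuffle_null: run apc_correct() first")
  M <- mi$corrected
  if (is.null(region_length)) region_length <- ncol(M)
  iv <- as.matrix(sitesB_intervals)
  widths <- as.integer(iv[, 2] - iv[, 1])
  if (sum(widths) > region_length)
    stop("shuffle_null: partner sites cannot fit in the region")
  cols_obs <- unlist(mapply(function(s, e) (s + 1L):e, iv[, 1], iv[, 2],
                            SIMPLIFY = FALSE))
  pair_mean <- function(colsB)
    mean(vapply(sitesA, function(i) mean(M[i, colsB], na.rm = TRUE), 0),
         na.rm = TRUE)
  observed <- pair_mean(cols_obs)
  set.seed(seed)
  shuffled <- vapply(seq_len(iterations), function(it) {
    pl <- .place_sites(widths, region_length)
    cols <- unlist(mapply(function(s, e) (s + 1L):e, pl[, "start"],
                          pl[, "end"], SIMPLIFY = FALSE))
    pair_mean(cols)
  }, 0)
  list(observed = observed, shuffled_means = shuffled)
}

#' Paired summary of observed versus shuffled pair means across genes
#'
#' One-sided Wilcoxon signed-rank test comparing, gene by gene, the observed
#' pair mean with the mean of its shuffled pair means.
#'
#' @param observed numeric vector (one value per gene).
#' @param shuffled matrix, genes x iterations.
#' @return list with `p`, `n`, and `frac_observed_above` (fraction of genes
#'   whose observed value exceeds all their shuffles).
#' @export
shuffle_summary <- function(observed, shuffled) {
  stopifnot(length(observed) == nrow(shuffled))
  p <- suppressWarnings(stats::wilcox.test(observed, rowMeans(shuffled),
                                           paired = TRUE,
                                           alternative = "greater")$p.value)
  list(p = p, n = length(observed),
       frac_observed_above = mean(observed > apply(shuffled, 1, max)))
}

#' Restrict to binding sites supported at both stages
#'
#' High-confidence site filter: keeps sites from the analysis stage that
#' overlap (>= 1 nt) a site of the same RBP at the other stage, then
#' width-normalizes the survivors.
#'
#' @param sites_primary [binding_site_set()] at the analysis stage.
#' @param sites_other [binding_site_set()] at the supporting stage.
#' @param width normalization width passed to [normalize_width()]; NULL skips
#'   normalization.
#' @param ... further arguments to [normalize_width()].
#' @return Filtered (and normalized) [binding_site_set()].
#' @export
stage_consistent_sites <- function(sites_primary, sites_other, width = 5L,
                                   ...) {
  keep <- logical(nrow(sites_primary))
  for (g in unique(sites_primary$gene_id)) {
    pi <- which(sites_primary$gene_id == g)
    ot <- sites_other[sites_other$gene_id == g, , drop = FALSE]
    if (!nrow(ot)) next
    ia <- .as_iranges(sites_primary$start[pi], sites_primary$end[pi])
    ib <- .as_iranges(ot$start, ot$end)
    keep[pi] <- IRanges::countOverlaps(ia, ib) > 0
  }
  out <- sites_primary[keep, , drop = FALSE]
  if (!is.null(width) && nrow(out)) out <- normalize_width(out, width, ...)
  out
}
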