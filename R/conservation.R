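#' Conservation track constructor
#'
#' Per-position conservation scores over one gene or region; phastCons-like
#' (in `[0, 1]`) or phyloP-like (unbounded) scores are both accepted — every
#' downstream comparison is rank-based.
#'
#' @param gene_id region identifier.
#' @param scores finite numeric scores, one per position.
#' @return A `conservation_track`.
#' @export
conservation_track <- function(gene_id, scores) {
  if (any(!is.finite(scores))) stop("conservation_track: non-finite scores")
  structure(list(gene_id = gene_id, scores = as.numeric(scores)),
            class = "conservation_track")
}

#' Mean conservation score under each binding site
#'
#' @param sites a [binding_site_set()] (single region, transcript
#'   coordinates).
#' @param track a [conservation_track()] covering the region.
#' @return Numeric vector of per-site mean scores (named by site name); empty
#'   sites give an empty vector.
#' @export
site_conservation <- function(sites, track) {
  stopifnot(inherits(track, "conservation_track"))
  if (!nrow(sites)) return(stats::setNames(numeric(0), character(0)))
  n <- length(track$scores)
  if (any(sites$start < 0 | sites$end > n))
    stop("site_conservation: site outside track bounds: ",
         sites$name[which(sites$start < 0 | sites$end > n)[1]])
  means <- mapply(function(s, e) mean(track$scores[(s + 1L):e]),
                  sites$start, sites$end)
  stats::setNames(means, sites$name)
}

# place widths w uniformly at random, non-overlapping, inside [0, feat_len)
.place_sites <- function(widths, feat_len) {
  free <- feat_len - sum(widths)
  k <- length(widths)
  gaps <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
  starts <- gaps + c(0L, cumsum(widths[-k]))
  cbind(start = starts, end = starts + widths)
}

#' Shuffle binding sites within their feature
#'
#' Each iteration re-places the sites uniformly at random within the same
#' feature interval, preserving every site's width and forbidding overlaps
#' within the iteration.
#'
#' @param sites a [binding_site_set()] for one region.
#' @param feature_interval `c(start, end)` of the feature (0-based half-open).
#' @param iterations number of shuffled sets, default 10.
#' @param seed integer seed.
#' @return List of `iterations` [binding_site_set()] objects.
#' @export
shuffle_sites <- function(sites, feature_interval, iterations = 10L,
                          seed = 1L) {
  fs <- feature_interval[1]; fe <- feature_interval[2]
  widths <- sites$end - sites$start
  if (sum(widths) > fe - fs)
    stop("shuffle_sites: sites cannot fit in the feature")
  set.seed(seed)
  lapply(seq_len(iterations), function(it) {
    pl <- .place_sites(widths, fe - fs)
    out <- sites
    out$start <- as.integer(fs + pl[, "start"])
    out$end <- as.integer(fs + pl[, "end"])
    out
  })
}

#' Conservation of observed versus shuffled binding sites
#'
#' For each gene/feature: the observed statistic is the mean of per-site mean
#' conservation scores; the null re-places the sites within the same feature
#' `iterations` times and records the shuffled mean per iteration. A per-gene
#' empirical p is reported, and across genes a one-sided Mann-Whitney U test
#' compares observed means against the pooled shuffled means; when several
#' feature kinds are analyzed together (see `feature` column) the group p is
#' Bonferroni-adjusted across feature kinds.
#'
#' @param queries list of per-gene inputs, each a list with `gene_id`,
#'   `feature` (kind label), `sites` (a [binding_site_set()]),
#'   `feature_interval` (`c(start, end)`), `track` (a
#'   [conservation_track()]).
#' @param iterations shuffles per query, default 10.
#' @param seed integer seed.
#' @return list with `per_gene` (data.frame: gene_id, feature, observed_mean,
#'   shuffled columns, p_empirical) and `group_test` (data.frame per feature
#'   kind: n_genes, U, p, p_adj, observed_median, shuffled_median; features
#'   with < 3 genes are skipped with a message).
#' @export
observed_vs_shuffled <- function(queries, iterations = 10L, seed = 1L) {
  rows <- vector("list", length(queries))
  shuf_store <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    obs <- mean(site_conservation(q$sites, q$track))
    shuf_sets <- shuffle_sites(q$sites, q$feature_interval,
                               iterations = iterations,
                               seed = seed + qi)
    shuf <- vapply(shuf_sets,
                   function(s) mean(site_conservation(s, q$track)), 0)
    rows[[qi]] <- data.frame(gene_id = q$gene_id, feature = q$feature,
                             observed_mean = obs,
                             p_empirical = (1 + sum(shuf >= obs)) /
                               (1 + iterations),
                             stringsAsFactors = FALSE)
    shuf_store[[qi]] <- shuf
  }
  per_gene <- do.call(rbind, rows)
  shuf_mat <- do.call(rbind, shuf_store)
  colnames(shuf_mat) <- paste0("shuffled_", seq_len(iterations))
  per_gene <- cbind(per_gene, shuf_mat)

  feats <- unique(per_gene$feature)
  gt <- lapply(feats, function(f) {
    sel <- per_gene$feature == f
    if (sum(sel) < 3) {
      message("observed_vs_shuffled: < 3 genes for feature '", f,
              "'; group test skipped")
      return(NULL)
    }
    obs <- per_gene$observed_mean[sel]
    pooled <- as.vector(shuf_mat[sel, , drop = FALSE])
    wt <- suppressWarnings(stats::wilcox.test(obs, pooled,
                                              alternative = "greater"))
    data.frame(feature = f, n_genes = sum(sel), U = unname(wt$statistic),
               p = wt$p.value, observed_median = stats::median(obs),
               shuffled_median = stats::median(pooled),
               stringsAsFactors = FALSE)
  })
  gt <- do.call(rbind, gt)
  if (!is.null(gt)) gt$p_adj <- stats::p.adjust(gt$p, method = "bonferroni")
  list(per_gene = per_gene, group_test = gt)
}

#' Transcriptome background conservation
#'
#' Mean conservation score over all annotated feature positions, the
#' transcriptome-average reference against which binding-site conservation is
#' compared.
#'
#' @param tracks named list of [conservation_track()], one per gene.
#' @param annotation a [transcript_annotation()]; only positions inside its
#'   feature intervals contribute.
#' @return Mean score over annotated positions.
#' @export
transcriptome_background <- function(tracks, annotation) {
  vals <- numeric(0)
  for (g in unique(annotation$gene_id)) {
    tr <- tracks[[g]]
    if (is.null(tr)) next
    feats <- annotation[annotation$gene_id == g, , drop = FALSE]
    idx <- unique(unlist(mapply(function(s, e) (s + 1L):e,
                                feats$start, pmin(feats$end,
                                                  length(tr$scores)),
                                SIMPLIFY = FALSE)))
    vals <- c(vals, tr$scores[idx])
  }
  mean(vals)
}
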