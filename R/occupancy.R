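#' Cross-link track constructor
#'
#' Per-nucleotide cross-link counts over one gene, with per-position
#' significance flags (cross-link FDR < 0.01 calls from the upstream peak
#' caller) and the total usable read count of the originating library.
#'
#' @param gene_id gene identifier.
#' @param counts non-negative integer counts, one per position.
#' @param significant logical flags, same length; a significant position must
#'   carry a non-zero count.
#' @param library_size total usable reads in the library.
#' @return A `crosslink_track`.
#' @export
crosslink_track <- function(gene_id, counts, significant, library_size = NA) {
  stopifnot(length(counts) == length(significant), length(counts) >= 1)
  if (any(counts < 0)) stop("crosslink_track: negative counts")
  if (any(significant & counts == 0))
    stop("crosslink_track: significant position with zero count")
  structure(list(gene_id = gene_id, counts = as.numeric(counts),
                 significant = as.logical(significant),
                 library_size = library_size),
            class = "crosslink_track")
}

# background-subtraction kernel shared by subtract_background() and
# occupancy_matrix(): background = mean count over nonsignificant positions,
# subtracted (floored at 0) from significant positions, all else zeroed
.bg_subtract <- function(counts, significant) {
  ns <- counts[!significant]
  b <- if (length(ns)) mean(ns) else 0
  out <- numeric(length(counts))
  out[significant] <- pmax(counts[significant] - b, 0)
  out
}

#' Subtract average background from a cross-link track
#'
#' The background is the mean count over nonsignificant (cross-link FDR >
#' 0.01) positions; it is subtracted from each significant position (clamped
#' at zero) and nonsignificant positions are zeroed, leaving only
#' background-corrected significant signal.
#'
#' @param track a [crosslink_track()].
#' @return A [crosslink_track()] with corrected counts. When no nonsignificant
#'   position exists the background is 0 and a warning is emitted.
#' @export
subtract_background <- function(track) {
  stopifnot(inherits(track, "crosslink_track"))
  if (all(track$significant))
    warning("subtract_background: no nonsignificant positions in ",
            track$gene_id, "; background taken as 0")
  out <- track
  out$counts <- .bg_subtract(track$counts, track$significant)
  out
}

#' Expression-normalized iCLIP occupancy score
#'
#' Significant cross-link reads are converted to reads per million (RPM) and
#' divided by the gene's expression (TPM): score = (sig_reads / library_size
#' x 1e6) / max(tpm, tpm_floor). The score is invariant to joint rescaling of
#' reads and library size. A pseudo-count for signal-free genes belongs to the
#' plotting/export path only (see [occupancy_matrix()]), never to this score.
#'
#' @param sig_reads background-corrected significant read count.
#' @param library_size total usable reads in the library (> 0).
#' @param tpm gene expression in transcripts per million.
#' @param tpm_floor lower bound applied to `tpm` to avoid division by zero.
#' @return Numeric score (>= 0).
#' @export
iclip_score <- function(sig_reads, library_size, tpm, tpm_floor = 0.1) {
  if (any(library_size <= 0)) stop("iclip_score: library_size must be > 0")
  if (any(tpm < 0)) stop("iclip_score: negative TPM")
  if (any(tpm == 0) && tpm_floor <= 0)
    stop("iclip_score: tpm = 0 with no tpm_floor")
  rpm <- sig_reads / library_size * 1e6
  rpm / pmax(tpm, tpm_floor)
}

#' Build an occupancy matrix from cross-link tracks
#'
#' Applies background subtraction per gene/library/replicate track, sums the
#' corrected significant reads, converts to RPM, normalizes by TPM
#' ([iclip_score()]), and averages replicate scores per library.
#'
#' @param tracks long data.frame/data.table with columns
#'   `gene_id, library, replicate, pos, count, significant`.
#' @param tpm data.frame with `gene_id`, `tpm`.
#' @param library_sizes data.frame with `library`, `replicate`,
#'   `library_size`; defaults to total counts per library/replicate.
#' @param library_info data.frame with `library`, `rbp`, `stage` describing
#'   each library; defaults to parsing `<rbp>_<stage>` labels.
#' @return An `occupancy_matrix`: list with `genes`, `libraries`,
#'   `replicate_scores` (gene x library x replicate array), `aggregated`
#'   (gene x library matrix of replicate means), `library_info`, and
#'   `pseudo_count` (0.5 x smallest non-zero aggregated score, for
#'   plotting/export only).
#' @export
occupancy_matrix <- function(tracks, tpm, library_sizes = NULL,
                             library_info = NULL) {
  dt <- data.table::as.data.table(tracks)
  req <- c("gene_id", "library", "replicate", "count", "significant")
  if (!all(req %in% names(dt)))
    stop("occupancy_matrix: tracks must have columns ",
         paste(req, collapse = ", "))
  if (is.null(library_sizes))
    library_sizes <- dt[, list(library_size = sum(count)),
                        by = c("library", "replicate")]
  ls <- data.table::as.data.table(library_sizes)
  sig <- dt[, list(sig_reads = sum(.bg_subtract(count, significant)[significant])),
            by = c("gene_id", "library", "replicate")]
  sig <- merge(sig, ls, by = c("library", "replicate"))
  tpm_map <- stats::setNames(tpm$tpm, tpm$gene_id)
  miss <- setdiff(sig$gene_id, names(tpm_map))
  if (length(miss))
    stop("occupancy_matrix: genes missing from TPM table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  sig$score <- iclip_score(sig$sig_reads, sig$library_size,
                           tpm_map[sig$gene_id])

  genes <- sort(unique(sig$gene_id))
  if (is.null(library_info)) {
    libs <- sort(unique(sig$library))
    parts <- strsplit(libs, "_", fixed = TRUE)
    library_info <- data.frame(
      library = libs,
      rbp = vapply(parts, `[[`, "", 1L),
      stage = as.numeric(factor(vapply(parts, function(p) p[length(p)], ""))),
      stringsAsFactors = FALSE)
  }
  libs <- library_info$library
  reps <- sort(unique(sig$replicate))
  arr <- array(NA_real_, dim = c(length(genes), length(libs), length(reps)),
               dimnames = list(genes, libs, paste0("rep", reps)))
  at <- cbind(match(sig$gene_id, genes), match(sig$library, libs),
              match(sig$replicate, reps))
  arr[at] <- sig$score
  reads <- offsets <- arr
  reads[at] <- sig$sig_reads
  offsets[at] <- sig$library_size * pmax(tpm_map[sig$gene_id], 0.1) / 1e6
  agg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  n_missing <- sum(is.na(arr))
  if (n_missing)
    message("occupancy_matrix: ", n_missing,
            " missing replicate score(s); replicate means use available data")
  nz <- agg[agg > 0]
  structure(list(genes = genes, libraries = libs, replicate_scores = arr,
                 replicate_reads = reads, replicate_offsets = offsets,
                 aggregated = agg, library_info = library_info,
                 pseudo_count = if (length(nz)) 0.5 * min(nz) else 0),
            class = "occupancy_matrix")
}

#' Cluster expression-normalized temporal occupancy profiles
#'
#' Per gene, a quadratic profile regression over stage pseudo-time with an RBP
#' series term is fitted under a negative-binomial observation model with
#' fixed dispersion (`theta`). The regression works on background-corrected
#' significant read counts with a log(library_size x TPM) offset — the
#' count-scale formulation of the expression-normalized occupancy profile —
#' falling back to the scores themselves when reads are unavailable. Genes
#' are retained
#' when the profile-versus-flat likelihood-ratio test passes `q <= q_max`
#' (Benjamini-Hochberg across genes) and the deviance R-squared of the fit is
#' at least `r2_min`. Retained aggregated profiles are standardized per gene
#' (z-score over libraries) and clustered by Ward agglomeration cut at `k`;
#' cluster ids are renumbered by descending centroid RBP1-minus-RBP2 contrast
#' so numbering is stable.
#'
#' @param om an [occupancy_matrix()].
#' @param k number of clusters.
#' @param q_max BH-adjusted significance threshold for the profile test.
#' @param theta fixed negative-binomial dispersion.
#' @param r2_min minimum deviance R-squared of the profile fit.
#' @return A `cluster_result`: list with `labels` (named integer vector),
#'   `centroids` (k x library matrix of mean z-scored profiles), `fit_r2`,
#'   `q_value` (named, all tested genes), `group` (NA until
#'   [assign_groups()]), `library_info`.
#' @export
cluster_profiles <- function(om, k = 6, q_max = 0.01, theta = 10,
                             r2_min = 0.7) {
  stopifnot(inherits(om, "occupancy_matrix"))
  info <- om$library_info
  if (length(om$libraries) < 2) stop("cluster_profiles: need >= 2 libraries")
  fam <- MASS::negative.binomial(theta)
  nlib <- length(om$libraries)
  nrep <- dim(om$replicate_scores)[3]
  rbp_f <- factor(rep(info$rbp, nrep))
  t_num <- rep(info$stage, nrep)
  X <- stats::model.matrix(~ rbp_f + t_num + I(t_num^2))
  use_reads <- !is.null(om$replicate_reads)

  stats_g <- t(vapply(om$genes, function(g) {
    if (use_reads) {
      y <- as.vector(om$replicate_reads[g, , ])
      off <- log(as.vector(om$replicate_offsets[g, , ]))
    } else {
      y <- as.vector(om$replicate_scores[g, , ])
      off <- rep(0, length(y))
    }
    keep <- !is.na(y)
    if (sum(y[keep]) <= 0) return(c(p = 1, r2 = 0))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X[keep, , drop = FALSE], y[keep],
                                      family = fam, offset = off[keep])),
      error = function(e) NULL)
    if (is.null(fit)) return(c(p = 1, r2 = 0))
    dd <- fit$null.deviance - fit$deviance
    df <- fit$df.null - fit$df.residual
    p <- stats::pchisq(max(dd, 0), df = df, lower.tail = FALSE)
    r2 <- if (fit$null.deviance > 0) 1 - fit$deviance / fit$null.deviance else 0
    c(p = p, r2 = max(min(r2, 1), 0))
  }, c(p = 0, r2 = 0)))
  q <- stats::p.adjust(stats_g[, "p"], method = "BH")
  r2 <- stats_g[, "r2"]
  retained <- om$genes[q <= q_max & r2 >= r2_min]
  if (length(retained) < k)
    stop("cluster_profiles: only ", length(retained),
         " gene(s) pass the filters; need at least k = ", k)

  prof <- om$aggregated[retained, , drop = FALSE]
  z <- t(scale(t(prof)))
  z[!is.finite(z)] <- 0
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw_lab <- stats::cutree(hc, k = k)
  cent <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(z[raw_lab == cl, , drop = FALSE])))
  colnames(cent) <- om$libraries
  rbp_levels <- unique(info$rbp)
  contrast <- rowMeans(cent[, info$rbp == rbp_levels[1], drop = FALSE]) -
    rowMeans(cent[, info$rbp == rbp_levels[2], drop = FALSE])
  ord <- order(-contrast)
  relab <- match(raw_lab, ord)
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- seq_len(k)
  structure(list(labels = stats::setNames(relab, retained),
                 centroids = cent,
                 fit_r2 = stats::setNames(r2, om$genes),
                 q_value = stats::setNames(q, om$genes),
                 group = NULL,
                 library_info = info),
            class = "cluster_result")
}

#' Assign named binding groups to clusters
#'
#' Classifies each cluster centroid over the four binding groups: clusters
#' whose RBP1-library mean exceeds the RBP2-library mean are `higher_rbp1`
#' (converse `higher_rbp2`); a cluster whose centroid value at the second
#' RBP's shared mid stage is the strict maximum (minimum) of its profile is
#' `peak_mid_rbp2` (`reduced_mid_rbp2`), and these take precedence over the
#' higher-RBP tags.
#'
#' @param result a `cluster_result` from [cluster_profiles()].
#' @return The `cluster_result` with `group` (named character per cluster) and
#'   `gene_group` (per retained gene) filled in.
#' @export
assign_groups <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  info <- result$library_info
  rbp_levels <- unique(info$rbp)
  if (length(rbp_levels) != 2)
    stop("assign_groups: need exactly 2 RBPs, got ", length(rbp_levels))
  shared <- intersect(info$stage[info$rbp == rbp_levels[1]],
                      info$stage[info$rbp == rbp_levels[2]])
  if (!length(shared))
    stop("assign_groups: no stage shared by both RBPs")
  mid_lib <- info$library[info$rbp == rbp_levels[2] &
                            info$stage == shared[1]][1]
  cent <- result$centroids
  groups <- character(nrow(cent))
  for (cl in seq_len(nrow(cent))) {
    v <- cent[cl, ]
    mid <- v[mid_lib]
    if (mid > max(v[names(v) != mid_lib])) {
      groups[cl] <- "peak_mid_rbp2"
    } else if (mid < min(v[names(v) != mid_lib])) {
      groups[cl] <- "reduced_mid_rbp2"
    } else {
      d <- mean(v[info$rbp == rbp_levels[1]]) -
        mean(v[info$rbp == rbp_levels[2]])
      if (d == 0) {
        warning("assign_groups: tied centroid contrast for cluster ", cl,
                "; breaking tie by cluster id")
        groups[cl] <- if (cl <= nrow(cent) / 2) "higher_rbp1" else "higher_rbp2"
      } else groups[cl] <- if (d > 0) "higher_rbp1" else "higher_rbp2"
    }
  }
  result$group <- stats::setNames(groups, rownames(cent))
  result$gene_group <- stats::setNames(groups[result$labels],
                                       names(result$labels))
  result
}

#' Hypergeometric significance of a target-set overlap
#'
#' Upper-tail hypergeometric probability P(X >= nAB) of observing at least
#' `nAB` shared genes between two target sets of sizes `nA` and `nB` drawn
#' from a universe of `universe` genes.
#'
#' @param nA,nB sizes of the two target sets.
#' @param nAB observed overlap.
#' @param universe universe size.
#' @return p-value.
#' @export
target_overlap_significance <- function(nA, nB, nAB, universe) {
  if (nAB > min(nA, nB) || min(nA, nB) > universe || nA < 0 || nB < 0 ||
      nAB < 0)
    stop("target_overlap_significance: inconsistent counts")
  stats::phyper(nAB - 1, nA, universe - nA, nB, lower.tail = FALSE)
}
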