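# IRanges view of one gene's sites: converts 0-based half-open (start, end)
# to the 1-based closed coordinates IRanges uses
.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

.coverage_nt <- function(ir) sum(IRanges::width(IRanges::reduce(ir)))

#' Normalize binding sites to a fixed width
#'
#' Replaces each site by a `width`-nt window centered on its maximum
#' cross-link position (ties broken leftmost); sites without count information
#' are centered on the interval midpoint (floor). Windows are clipped at the
#' gene bounds (when `gene_lengths` is given) and at 0; clipped sites end up
#' narrower than `width` and are flagged.
#'
#' @param sites a [binding_site_set()].
#' @param width odd target width (nt), default 5.
#' @param counts optional named list of per-gene count vectors (position 1 =
#'   transcript coordinate 0) used to locate each site's maximum.
#' @param gene_lengths optional named vector of gene lengths for clipping.
#' @return A [binding_site_set()] with a logical `clipped` column.
#' @export
normalize_width <- function(sites, width = 5L, counts = NULL,
                            gene_lengths = NULL) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stop("normalize_width: width must be odd and >= 1")
  if (!nrow(sites)) { sites$clipped <- logical(0); return(sites) }
  half <- (width - 1L) %/% 2L
  center <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- sites$gene_id[i]; s <- sites$start[i]; e <- sites$end[i]
    cv <- if (!is.null(counts)) counts[[g]] else NULL
    if (!is.null(cv) && length(cv) >= e) {
      seg <- cv[(s + 1L):e]
      center[i] <- s + which.max(seg) - 1L     # ties -> leftmost
    } else {
      center[i] <- (s + e) %/% 2L
    }
  }
  new_start <- pmax(center - half, 0L)
  new_end <- center + half + 1L
  if (!is.null(gene_lengths)) {
    gl <- gene_lengths[sites$gene_id]
    new_end <- pmin(new_end, as.integer(gl))
    new_start <- pmin(new_start, new_end - 1L)
  }
  out <- sites
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  out$clipped <- (out$end - out$start) < width
  if (any(out$clipped))
    message("normalize_width: ", sum(out$clipped),
            " site(s) clipped below ", width, " nt at region bounds")
  out
}

#' Jaccard index between two binding-site sets
#'
#' Nucleotide-level intersection over union of the two sets after union-
#' merging intervals within each set, summed over genes: |A intersect B| /
#' |A union B| in nucleotides.
#'
#' @param A,B [binding_site_set()] objects in the same coordinate space.
#' @return Jaccard index in `[0, 1]`; 0 (with a message) when both sets are
#'   empty.
#' @export
jaccard_index <- function(A, B) {
  genes <- union(unique(A$gene_id), unique(B$gene_id))
  if (!length(genes)) { message("jaccard_index: both sets empty"); return(0) }
  inter <- 0; uni <- 0
  for (g in genes) {
    a <- A[A$gene_id == g, , drop = FALSE]
    b <- B[B$gene_id == g, , drop = FALSE]
    ia <- IRanges::reduce(.as_iranges(a$start, a$end))
    ib <- IRanges::reduce(.as_iranges(b$start, b$end))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) { message("jaccard_index: zero total coverage"); return(0) }
  inter / uni
}

#' Relative-distance correlation index between two site sets
#'
#' For each B-site midpoint lying within the span of A-site midpoints of the
#' same gene, the distance to the nearest A midpoint is divided by the
#' distance between its two flanking A midpoints, giving a folded relative
#' distance d in `[0, 0.5]`. The index is `1 - 4 * mean(d)`: +1 when every B
#' midpoint coincides with an A midpoint, 0 when B is uniformly placed, and -1
#' for perfectly even interleaving (every B midpoint halfway between A
#' midpoints).
#'
#' @param A,B [binding_site_set()] objects; genes with fewer than 2 A sites
#'   are skipped (with a message), as are B midpoints outside A's midpoint
#'   span.
#' @return Index in `[-1, 1]`, or NA when no B midpoint is scorable.
#' @export
relative_distance_index <- function(A, B) {
  d_all <- numeric(0)
  skipped <- 0L
  for (g in unique(B$gene_id)) {
    a <- A[A$gene_id == g, , drop = FALSE]
    if (nrow(a) < 2L) { skipped <- skipped + 1L; next }
    amid <- sort((a$start + a$end) / 2)
    b <- B[B$gene_id == g, , drop = FALSE]
    bmid <- (b$start + b$end) / 2
    bmid <- bmid[bmid >= amid[1] & bmid <= amid[length(amid)]]
    if (!length(bmid)) next
    i <- findInterval(bmid, amid, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(amid) - 1L)
    left <- amid[i]; right <- amid[i + 1L]
    d <- pmin(bmid - left, right - bmid) / (right - left)
    d_all <- c(d_all, d)
  }
  if (skipped)
    message("relative_distance_index: skipped ", skipped,
            " gene(s) with < 2 reference sites")
  if (!length(d_all)) return(NA_real_)
  1 - 4 * mean(d_all)
}

#' Per-gene footprint overlap between two RBPs
#'
#' For each gene annotated in `annotation` and covered by either set, reports
#' the merged-coverage intersection length between the two RBPs' sites, the
#' per-RBP coverages, the gene-level Jaccard index, the coincidental-coverage
#' fractions (overlap / union and overlap / per-RBP coverage), and the
#' strict `overlap_nt > cutoff` classification.
#'
#' @param A,B [binding_site_set()] objects in transcript coordinates.
#' @param annotation optional [transcript_annotation()]; genes absent from it
#'   are skipped with a message. NULL keeps all genes.
#' @param cutoff classification cutoff in nt (strict greater-than), default 50.
#' @return data.frame with one row per gene: `gene_id, overlap_nt,
#'   rbp1_coverage_nt, rbp2_coverage_nt, union_nt, jaccard,
#'   frac_coincidental_union, frac_coincidental_rbp1, frac_coincidental_rbp2,
#'   classified_overlapping`.
#' @export
per_gene_overlap <- function(A, B, annotation = NULL, cutoff = 50L) {
  genes <- sort(union(unique(A$gene_id), unique(B$gene_id)))
  if (!is.null(annotation)) {
    known <- unique(annotation$gene_id)
    drop <- setdiff(genes, known)
    if (length(drop))
      message("per_gene_overlap: skipping ", length(drop),
              " gene(s) absent from annotation")
    genes <- intersect(genes, known)
  }
  res <- lapply(genes, function(g) {
    a <- A[A$gene_id == g, , drop = FALSE]
    b <- B[B$gene_id == g, , drop = FALSE]
    ia <- IRanges::reduce(.as_iranges(a$start, a$end))
    ib <- IRanges::reduce(.as_iranges(b$start, b$end))
    ov <- sum(IRanges::width(IRanges::intersect(ia, ib)))
    ca <- sum(IRanges::width(ia)); cb <- sum(IRanges::width(ib))
    un <- sum(IRanges::width(IRanges::union(ia, ib)))
    data.frame(gene_id = g, overlap_nt = ov, rbp1_coverage_nt = ca,
               rbp2_coverage_nt = cb, union_nt = un,
               jaccard = if (un > 0) ov / un else 0,
               frac_coincidental_union = if (un > 0) ov / un else 0,
               frac_coincidental_rbp1 = if (ca > 0) ov / ca else 0,
               frac_coincidental_rbp2 = if (cb > 0) ov / cb else 0,
               classified_overlapping = ov > cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare overlap-length distributions between gene classes
#'
#' Two-sample Kolmogorov-Smirnov test on the per-gene overlap lengths of two
#' classes of genes (e.g. temporally versus nontemporally regulated).
#'
#' @param temporal,nontemporal data.frames from [per_gene_overlap()] (or any
#'   with an `overlap_nt` column); both must be non-empty.
#' @return list with `D` (KS statistic) and `p`.
#' @export
compare_overlap_distributions <- function(temporal, nontemporal) {
  if (!nrow(temporal) || !nrow(nontemporal))
    stop("compare_overlap_distributions: empty input")
  kt <- suppressWarnings(stats::ks.test(temporal$overlap_nt,
                                        nontemporal$overlap_nt))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
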