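#' Simulation specification
#'
#' Bundles every parameter of the synthetic-data generators with the defaults
#' used throughout the package's tests: 600 genes split evenly over 6 temporal
#' occupancy archetypes observed in 4 libraries (RBP1 at stages L1/L2, RBP2 at
#' L2/L3) with 3 replicates and negative-binomial noise (theta = 10); a 27-row,
#' 200-column star-phylogeny alignment with 30% per-site substitution
#' probability and optional planted coevolving column pairs; Beta-distributed
#' conservation scores elevated under binding sites; and steady-state smFISH
#' counts for a known half-life (60 min, 20 mRNA/h per locus, 2 copies).
#'
#' @param seed integer seed; every generator is a pure function of the spec.
#' @param n_genes number of genes for the cross-link track generator.
#' @param archetype_mix mixing proportions over the 6 archetypes (sum to 1).
#' @param theta negative-binomial dispersion of signal counts.
#' @param gene_length length (nt) of each simulated cross-link track.
#' @param n_peaks cross-link peak positions per gene.
#' @param bg_rate mean background (nonsignificant) count per position.
#' @param tpm_meanlog,tpm_sdlog log-normal parameters of gene expression (TPM).
#' @param n_replicates replicates per library.
#' @param n_species,alignment_length,substitution_prob,gap_rate alignment
#'   generator parameters; `gap_rate` applies per non-reference cell.
#' @param planted_pairs data.frame with columns `col_i`, `col_j`, `coupling`
#'   (1-based alignment columns; coupling probability in `[0, 1]`), or NULL.
#' @param cons_background,cons_site `c(shape1, shape2)` of the Beta laws for
#'   conservation scores outside and under binding sites.
#' @param true_half_life_min,transcription_rate,copies,chromosome_fraction,
#'   gene_length_nt,elongation,n_cells,n_probes,probe_length smFISH generator
#'   parameters; rate is mRNA per hour per locus, elongation in nt per hour.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L,
                     n_genes = 600L,
                     archetype_mix = rep(1 / 6, 6),
                     theta = 10,
                     gene_length = 60L,
                     n_peaks = 4L,
                     bg_rate = 1,
                     tpm_meanlog = log(50), tpm_sdlog = 0.6,
                     n_replicates = 3L,
                     n_species = 27L,
                     alignment_length = 200L,
                     substitution_prob = 0.3,
                     gap_rate = 0.05,
                     planted_pairs = NULL,
                     cons_background = c(1, 9),
                     cons_site = c(8, 2),
                     true_half_life_min = 60,
                     transcription_rate = 20,
                     copies = 2L,
                     chromosome_fraction = 1,
                     gene_length_nt = 20000L,
                     elongation = 90000,
                     n_cells = 50L,
                     n_probes = 48L,
                     probe_length = 20L) {
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("sim_spec: archetype_mix must sum to 1")
  if (theta <= 0) stop("sim_spec: dispersion theta must be > 0")
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("col_i", "col_j", "coupling") %in% names(planted_pairs)))
    if (any(planted_pairs$col_i == planted_pairs$col_j))
      stop("sim_spec: planted pair columns must be distinct")
    if (any(planted_pairs$coupling < 0 | planted_pairs$coupling > 1))
      stop("sim_spec: coupling probability must be in [0, 1]")
    if (any(planted_pairs$col_i < 1 | planted_pairs$col_i > alignment_length |
            planted_pairs$col_j < 1 | planted_pairs$col_j > alignment_length))
      stop("sim_spec: planted column out of range")
  }
  if (gene_length_nt <= 0) stop("sim_spec: gene_length_nt must be positive")
  if (true_half_life_min <= 0) stop("sim_spec: half-life must be positive")
  structure(as.list(environment()), class = "sim_spec")
}

# Archetype mean occupancy profiles over (RBP1_L1, RBP1_L2, RBP2_L2, RBP2_L3)
# and the binding group each archetype instantiates.
.archetype_profiles <- function() {
  p <- rbind(
    c(3.0, 1.0, 0.3, 0.2),   # early RBP1 binding, falls quickly
    c(1.8, 2.0, 0.3, 0.2),   # sustained RBP1 binding
    c(0.3, 0.2, 0.5, 3.0),   # late RBP2 binding
    c(0.2, 0.3, 1.5, 2.1),   # rising RBP2 binding
    c(0.4, 0.5, 3.0, 0.6),   # transient peak of RBP2 at the shared mid stage
    c(2.0, 1.5, 0.2, 1.8))   # dip of RBP2 at the shared mid stage
  colnames(p) <- c("RBP1_L1", "RBP1_L2", "RBP2_L2", "RBP2_L3")
  rownames(p) <- paste0("A", 1:6)
  p
}

.archetype_groups <- c("higher_rbp1", "higher_rbp1", "higher_rbp2",
                       "higher_rbp2", "peak_mid_rbp2", "reduced_mid_rbp2")

.library_info <- function() {
  data.frame(library = c("RBP1_L1", "RBP1_L2", "RBP2_L2", "RBP2_L3"),
             rbp = c("RBP1", "RBP1", "RBP2", "RBP2"),
             stage = c(1, 2, 2, 3), stringsAsFactors = FALSE)
}

#' Simulate per-nucleotide cross-link tracks with known temporal archetypes
#'
#' Generates per-gene, per-library, per-replicate cross-link count tracks.
#' Each gene draws an archetype; the total significant read count in a library
#' follows a negative binomial with mean archetype-profile x TPM, distributed
#' over a small set of fixed peak positions (flagged significant where
#' non-zero); every position additionally carries Poisson background counts
#' flagged nonsignificant.
#'
#' @param spec a [sim_spec()].
#' @return list with `tracks` (data.table: gene_id, library, replicate, pos,
#'   count, significant), `library_sizes` (library, replicate, library_size),
#'   `tpm` (gene_id, tpm), `truth` (gene_id, archetype, group) and
#'   `library_info`.
#' @export
simulate_crosslink_tracks <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$theta <= 0) stop("simulate_crosslink_tracks: dispersion <= 0")
  set.seed(spec$seed)
  prof <- .archetype_profiles()
  libs <- colnames(prof)
  G <- spec$n_genes; L <- spec$gene_length
  genes <- sprintf("g%04d", seq_len(G))
  arch <- sample.int(6, G, replace = TRUE, prob = spec$archetype_mix)
  tpm <- stats::rlnorm(G, spec$tpm_meanlog, spec$tpm_sdlog)
  # fixed peak layout per gene, shared across libraries/replicates
  peak_pos <- lapply(seq_len(G), function(i) sort(sample.int(L, spec$n_peaks)))
  peak_w <- lapply(seq_len(G), function(i) {
    w <- stats::runif(spec$n_peaks, 0.5, 1.5); w / sum(w)
  })

  out <- vector("list", length(libs) * spec$n_replicates)
  idx <- 1L
  for (l in seq_along(libs)) {
    for (r in seq_len(spec$n_replicates)) {
      counts <- matrix(stats::rpois(G * L, spec$bg_rate), nrow = G)
      sig <- matrix(FALSE, G, L)
      mu <- prof[arch, l] * tpm
      tot <- stats::rnbinom(G, size = spec$theta, mu = mu)
      for (i in seq_len(G)) {
        if (tot[i] > 0) {
          s <- stats::rmultinom(1, tot[i], peak_w[[i]])[, 1]
          counts[i, peak_pos[[i]]] <- counts[i, peak_pos[[i]]] + s
          sig[i, peak_pos[[i]]] <- s > 0
        }
      }
      out[[idx]] <- data.table::data.table(
        gene_id = rep(genes, each = L), library = libs[l], replicate = r,
        pos = rep.int(seq_len(L) - 1L, G),
        count = as.integer(t(counts)), significant = as.logical(t(sig)))
      idx <- idx + 1L
    }
  }
  tracks <- data.table::rbindlist(out)
  # library sizes are library-wide usable-read totals, of which the simulated
  # genes are a subset: nominal depth with replicate-level jitter
  lib_sizes <- tracks[, list(library_size = 0), by = c("library", "replicate")]
  lib_sizes$library_size <- round(1e6 *
    stats::rlnorm(nrow(lib_sizes), 0, 0.05))
  list(tracks = tracks,
       library_sizes = lib_sizes,
       tpm = data.frame(gene_id = genes, tpm = tpm, stringsAsFactors = FALSE),
       truth = data.frame(gene_id = genes, archetype = arch,
                          group = .archetype_groups[arch],
                          stringsAsFactors = FALSE),
       library_info = .library_info())
}

#' Simulate a reference-anchored alignment with planted coevolving columns
#'
#' Species evolve independently from a random reference sequence (star
#' phylogeny): each non-reference cell substitutes with probability
#' `substitution_prob` to a uniformly chosen different nucleotide. For a
#' planted pair `(i, j)` with coupling probability `c`, each species is
#' "coupled" with probability `c`: its column-j state is then a fixed bijective
#' recoding of its column-i state (same substitution event), so coupling 1
#' makes the two columns a bijective recoding of each other and coupling 0
#' leaves them independent. Gaps are injected per non-reference cell at
#' `gap_rate` (never at planted columns, never in the reference).
#'
#' @param spec a [sim_spec()].
#' @return list with `block` (an [alignment_block()], reference row
#'   `"reference"`) and `truth` (the planted-pairs data.frame).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_species < 4) stop("simulate_alignment: need >= 4 species")
  set.seed(spec$seed + 1L)
  nts <- c("A", "C", "G", "T")
  L <- spec$alignment_length; S <- spec$n_species
  ref <- sample(nts, L, replace = TRUE)
  m <- matrix(ref, nrow = S, ncol = L, byrow = TRUE)
  rownames(m) <- c("reference", sprintf("species_%02d", seq_len(S - 1L)))

  pp <- spec$planted_pairs
  planted_cols <- if (is.null(pp)) integer() else unique(c(pp$col_i, pp$col_j))
  # per-pair bijection between the 3 non-reference states of i and of j
  bij <- list()
  if (!is.null(pp)) {
    for (k in seq_len(nrow(pp))) {
      from <- setdiff(nts, ref[pp$col_i[k]])
      to <- sample(setdiff(nts, ref[pp$col_j[k]]))
      bij[[k]] <- stats::setNames(to, from)
    }
  }
  for (s in 2:S) {
    sub <- stats::runif(L) < spec$substitution_prob
    targ <- ref
    if (any(sub))
      targ[sub] <- vapply(ref[sub],
                          function(a) sample(setdiff(nts, a), 1L), "")
    row <- ifelse(sub, targ, ref)
    if (!is.null(pp)) {
      for (k in seq_len(nrow(pp))) {
        if (stats::runif(1) < pp$coupling[k]) {
          i <- pp$col_i[k]; j <- pp$col_j[k]
          row[j] <- if (row[i] == ref[i]) ref[j] else bij[[k]][[row[i]]]
        }
      }
    }
    if (spec$gap_rate > 0) {
      g <- stats::runif(L) < spec$gap_rate
      g[planted_cols] <- FALSE
      row[g] <- "-"
    }
    m[s, ] <- row
  }
  list(block = alignment_block(m, reference_id = "reference"),
       truth = pp)
}

#' Simulate a conservation score track with elevated scores under sites
#'
#' Background positions draw from a low-mean Beta law; positions covered by a
#' binding site draw from a high-mean Beta law.
#'
#' @param spec a [sim_spec()].
#' @param sites a [binding_site_set()] for one region (may be empty).
#' @param region_length track length (nt).
#' @param gene_id identifier stored on the track.
#' @return A `conservation_track`: list with `gene_id` and numeric `scores`.
#' @export
simulate_conservation <- function(spec, sites, region_length,
                                  gene_id = "region") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 2L)
  scores <- stats::rbeta(region_length, spec$cons_background[1],
                         spec$cons_background[2])
  if (nrow(sites)) {
    if (any(sites$end > region_length))
      stop("simulate_conservation: site outside region")
    idx <- unique(unlist(mapply(function(s, e) (s + 1L):e,
                                sites$start, sites$end, SIMPLIFY = FALSE)))
    scores[idx] <- stats::rbeta(length(idx), spec$cons_site[1],
                                spec$cons_site[2])
  }
  conservation_track(gene_id, scores)
}

#' Simulate per-cell smFISH nascent/mature counts at steady state
#'
#' Mature counts per cell are Poisson around the steady-state abundance
#' `chromosome_fraction x rate x copies / decay`; cells are transcription-site
#' positive with probability `min(chromosome_fraction, 1)`, and TS-positive
#' cells draw a nascent single-molecule-equivalent count that is Poisson around
#' `rate x (gene_length / elongation) x w`, where `w` is the probe-library
#' weighting factor of the probe set (nascent transcripts light only probes 5'
#' of the polymerase).
#'
#' @param spec a [sim_spec()].
#' @return list with `cells` (data.frame: cell, nascent_count, mature_count,
#'   ts_positive), `probes` (a [probe_set()]) and `truth` (list of generating
#'   parameters, including the steady-state mature mean).
#' @export
simulate_smfish_cells <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$gene_length_nt <= 0) stop("simulate_smfish_cells: zero gene length")
  if (spec$n_cells < 1) stop("simulate_smfish_cells: need >= 1 cell")
  set.seed(spec$seed + 3L)
  L <- spec$gene_length_nt
  step <- max((L - spec$probe_length) %/% spec$n_probes, spec$probe_length + 3L)
  pos <- seq(0L, by = step, length.out = spec$n_probes)
  pos <- pos[pos <= L - spec$probe_length]
  probes <- probe_set("simgene", pos, probe_length = spec$probe_length,
                      gene_length = L)
  w <- probe_weighting_factor(probes)
  decay <- log(2) / (spec$true_half_life_min / 60)       # h^-1
  mature_mean <- spec$chromosome_fraction * spec$transcription_rate *
    spec$copies / decay
  nascent_mean <- spec$transcription_rate * (L / spec$elongation) * w
  ts <- stats::runif(spec$n_cells) < min(spec$chromosome_fraction, 1)
  nascent <- ifelse(ts, stats::rpois(spec$n_cells, nascent_mean), 0L)
  mature <- stats::rpois(spec$n_cells, mature_mean)
  list(cells = data.frame(cell = seq_len(spec$n_cells),
                          nascent_count = as.integer(nascent),
                          mature_count = as.integer(mature),
                          ts_positive = ts),
       probes = probes,
       truth = list(half_life_min = spec$true_half_life_min,
                    decay_rate = decay,
                    transcription_rate = spec$transcription_rate,
                    weighting_factor = w,
                    mature_mean = mature_mean,
                    nascent_mean = nascent_mean))
}
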