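#' smFISH probe set
#'
#' @param gene_id gene identifier.
#' @param probe_positions 0-based transcript coordinates of the oligo 5'
#'   starts.
#' @param probe_length oligo length (nt), default 20.
#' @param gene_length transcript length (nt).
#' @return A `probe_set`.
#' @export
probe_set <- function(gene_id, probe_positions, probe_length = 20L,
                      gene_length) {
  probe_positions <- as.integer(probe_positions)
  if (!length(probe_positions)) stop("probe_set: need >= 1 probe")
  if (any(probe_positions < 0L) ||
      any(probe_positions > gene_length - probe_length))
    stop("probe_set: probe outside [0, gene_length - probe_length]")
  structure(list(gene_id = gene_id, probe_positions = probe_positions,
                 probe_length = as.integer(probe_length),
                 gene_length = as.integer(gene_length)),
            class = "probe_set")
}

#' Probe-library weighting factor
#'
#' A nascent transcript whose polymerase sits at position x only hybridizes
#' probes whose binding region lies entirely 5' of x. With the polymerase
#' uniformly distributed along the gene, the expected lit fraction of the
#' probe set is
#' \deqn{w = \frac{1}{n L} \sum_p (L - s_p - \ell),}
#' with probe starts `s_p`, oligo length `l` and gene length `L`. Dense
#' uniform probes give w -> 0.5; probes at the 5' end give w -> 1. Used to
#' convert transcription-site signal into full-transcript equivalents.
#'
#' @param probes a [probe_set()].
#' @return w in `(0, 1]`.
#' @export
probe_weighting_factor <- function(probes) {
  stopifnot(inherits(probes, "probe_set"))
  L <- probes$gene_length
  mean((L - probes$probe_positions - probes$probe_length) / L)
}

#' Transcription rate from nascent signal
#'
#' rate = (nascent / w) x elongation / gene_length, in mRNA per hour: the
#' weighting factor converts partial nascent signal to polymerase-equivalents
#' and the residence time gene_length / elongation converts standing
#' polymerases to a production rate.
#'
#' @param nascent mean nascent transcript signal (single-molecule
#'   equivalents) over transcription-site-positive cells.
#' @param w probe-library weighting factor in `(0, 1]`.
#' @param gene_length transcript length (nt).
#' @param elongation polymerase elongation rate (nt per hour), default 90
#'   kb/h.
#' @return Transcription rate (mRNA per hour).
#' @export
transcription_rate <- function(nascent, w, gene_length, elongation = 90000) {
  if (w <= 0 || w > 1) stop("transcription_rate: w must be in (0, 1]")
  if (gene_length <= 0) stop("transcription_rate: gene_length must be > 0")
  (nascent / w) * elongation / gene_length
}

#' Decay rate at steady state
#'
#' k = (chromosome_fraction x transcription rate x chromosome copies) /
#' mature transcripts per cell, in per hour: production balances decay at
#' steady state.
#'
#' @param chromosome_fraction fraction of loci (or cells) actively
#'   transcribing.
#' @param txn_rate transcription rate (mRNA per hour).
#' @param copies number of chromosome copies.
#' @param mature_per_cell mean mature transcripts per cell (> 0).
#' @return Decay rate (per hour).
#' @export
decay_rate <- function(chromosome_fraction, txn_rate, copies,
                       mature_per_cell) {
  if (mature_per_cell <= 0)
    stop("decay_rate: mature_per_cell must be > 0 (no steady state)")
  chromosome_fraction * txn_rate * copies / mature_per_cell
}

#' Half-life from decay rate
#'
#' t1/2 (min) = ln(2) / decay x 60.
#'
#' @param decay decay rate (per hour, > 0).
#' @return Half-life in minutes.
#' @export
half_life <- function(decay) {
  if (any(decay <= 0)) stop("half_life: decay must be > 0")
  log(2) / decay * 60
}

#' Estimate mRNA half-life from per-cell smFISH counts
#'
#' Chains the steady-state equations: mean nascent signal over
#' transcription-site-positive cells -> [transcription_rate()]; mean mature
#' count over all cells -> [decay_rate()]; -> [half_life()]. The chromosome
#' fraction is either fixed (`cf_mode = "fixed"`, e.g. 2 when both loci of a
#' diploid pair are scored as one unit) or estimated as the fraction of
#' TS-positive cells (`cf_mode = "ts_fraction"`). A nonparametric bootstrap
#' over cells gives the confidence interval.
#'
#' @param cells data.frame with `nascent_count`, `mature_count`,
#'   `ts_positive`.
#' @param probes a [probe_set()].
#' @param cf_mode `"ts_fraction"` or `"fixed"`.
#' @param cf_value chromosome fraction when `cf_mode = "fixed"`.
#' @param copies chromosome copies, default 2.
#' @param elongation elongation rate (nt/h), default 90000.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level, default 0.8.
#' @return A `half_life_estimate`: list with `transcription_rate`,
#'   `decay_rate`, `half_life` (min), `chromosome_fraction`, `copies`,
#'   `weighting_factor`, `n_cells`, and `ci` (percentile interval on the
#'   half-life).
#' @export
estimate_from_cells <- function(cells, probes,
                                cf_mode = c("ts_fraction", "fixed"),
                                cf_value = NULL, copies = 2L,
                                elongation = 90000, n_boot = 1000L,
                                seed = 1L, conf = 0.8) {
  cf_mode <- match.arg(cf_mode)
  if (nrow(cells) < 5) stop("estimate_from_cells: need >= 5 cells")
  if (!any(cells$ts_positive))
    stop("estimate_from_cells: no TS-positive cell; transcription unobserved")
  if (cf_mode == "fixed" && is.null(cf_value))
    stop("estimate_from_cells: cf_value required for cf_mode = 'fixed'")
  w <- probe_weighting_factor(probes)
  chain <- function(d) {
    nas <- mean(d$nascent_count[d$ts_positive])
    mat <- mean(d$mature_count)
    cf <- if (cf_mode == "fixed") cf_value else mean(d$ts_positive)
    if (mat <= 0 || !any(d$ts_positive) || cf <= 0) return(NA_real_)
    tr <- transcription_rate(nas, w, probes$gene_length, elongation)
    if (tr <= 0) return(NA_real_)
    half_life(decay_rate(cf, tr, copies, mat))
  }
  hl <- chain(cells)
  nas <- mean(cells$nascent_count[cells$ts_positive])
  mat <- mean(cells$mature_count)
  cf <- if (cf_mode == "fixed") cf_value else mean(cells$ts_positive)
  tr <- transcription_rate(nas, w, probes$gene_length, elongation)
  dk <- decay_rate(cf, tr, copies, mat)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(cells), replace = TRUE)
    chain(cells[idx, , drop = FALSE])
  }, 0)
  ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE)
  structure(list(transcription_rate = tr, decay_rate = dk, half_life = hl,
                 chromosome_fraction = cf, copies = copies,
                 weighting_factor = w, n_cells = nrow(cells),
                 ci = unname(ci)),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf(paste0("half-life estimate: %.1f min (CI %.1f-%.1f)\n",
                     "  transcription rate %.2f mRNA/h, decay %.3f /h, ",
                     "cf %.2f, copies %d, w %.3f, n = %d cells\n"),
              x$half_life, x$ci[1], x$ci[2], x$transcription_rate,
              x$decay_rate, x$chromosome_fraction, x$copies,
              x$weighting_factor, x$n_cells))
  invisible(x)
}

#' Correlate protein level with RNA half-life across cells
#'
#' Pearson correlation between per-cell protein levels of one RBP and
#' per-cell half-lives of a partner transcript.
#'
#' @param protein,halflife paired numeric vectors, n >= 3.
#' @return list with `r` and `p` (two-sided).
#' @export
correlate_protein_vs_halflife <- function(protein, halflife) {
  if (length(protein) != length(halflife) || length(protein) < 3)
    stop("correlate_protein_vs_halflife: need paired vectors of length >= 3")
  if (stats::sd(protein) == 0 || stats::sd(halflife) == 0)
    stop("correlate_protein_vs_halflife: zero variance")
  ct <- stats::cor.test(protein, halflife, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
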