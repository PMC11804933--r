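#' Binding-site set constructor
#'
#' A binding-site set holds stranded intervals for one RBP at one developmental
#' stage, in either transcript or genomic coordinates. Intervals are 0-based
#' half-open throughout the package (BED convention).
#'
#' @param gene_id character vector of gene (or chromosome) identifiers.
#' @param start,end integer vectors; 0-based half-open, `end > start`.
#' @param name optional site names.
#' @param score optional numeric scores.
#' @param strand strand characters ("+", "-" or "."); required when
#'   `coordinate_space = "genomic"`.
#' @param rbp,stage labels attached to the whole set.
#' @param coordinate_space `"transcript"` or `"genomic"`. Interval statistics
#'   are computed in transcript space; genomic sets must be projected first.
#' @return A `binding_site_set`: a data.frame with columns
#'   `gene_id, start, end, name, score, strand` and attributes `rbp`, `stage`,
#'   `coordinate_space`.
#' @export
binding_site_set <- function(gene_id, start, end, name = NULL, score = NULL,
                             strand = NULL, rbp = NA_character_,
                             stage = NA_character_,
                             coordinate_space = c("transcript", "genomic")) {
  coordinate_space <- match.arg(coordinate_space)
  start <- as.integer(start); end <- as.integer(end)
  n <- length(start)
  stopifnot(length(end) == n)
  if (length(gene_id) == 1L && n != 1L) gene_id <- rep(gene_id, n)
  stopifnot(length(gene_id) == n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("binding_site_set: NA coordinates")
  if (any(start < 0L)) stop("binding_site_set: negative start")
  bad <- which(end <= start)
  if (length(bad))
    stop("binding_site_set: end <= start for site(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(name)) name <- sprintf("site%d", seq_len(n))
  if (is.null(score)) score <- rep(0, n)
  if (length(score) == 1L && n != 1L) score <- rep(score, n)
  if (is.null(strand)) {
    if (coordinate_space == "genomic")
      stop("binding_site_set: strand is required in genomic coordinate space")
    strand <- rep(".", n)
  }
  if (length(strand) == 1L && n != 1L) strand <- rep(strand, n)
  x <- data.frame(gene_id = as.character(gene_id), start = start, end = end,
                  name = as.character(name), score = as.numeric(score),
                  strand = as.character(strand), stringsAsFactors = FALSE)
  structure(x, class = c("binding_site_set", "data.frame"),
            rbp = rbp, stage = stage, coordinate_space = coordinate_space)
}

#' @export
`[.binding_site_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "rbp") <- attr(x, "rbp")
    attr(out, "stage") <- attr(x, "stage")
    attr(out, "coordinate_space") <- attr(x, "coordinate_space")
    class(out) <- class(x)
  }
  out
}

#' Read binding sites from a BED file
#'
#' Parses BED6 (or BED3/BED4/BED5) into a [binding_site_set()]. Coordinates are
#' kept exactly as in the file: 0-based half-open.
#'
#' @param path path to a tab-separated BED file.
#' @param rbp,stage labels attached to the set.
#' @param coordinate_space `"transcript"` (default) or `"genomic"`; genomic
#'   requires a strand column.
#' @return A [binding_site_set()]. An empty file yields an empty set.
#' @export
read_bed <- function(path, rbp = NA_character_, stage = NA_character_,
                     coordinate_space = c("transcript", "genomic")) {
  coordinate_space <- match.arg(coordinate_space)
  if (!file.exists(path)) stop("read_bed: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(binding_site_set(character(), integer(), integer(),
                            rbp = rbp, stage = stage,
                            coordinate_space = coordinate_space))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("read_bed: malformed line ", which(nf < 3L)[1], " in ", path,
         " (fewer than 3 tab-separated fields)")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("read_bed: non-integer coordinate at line ",
         which(is.na(start) | is.na(end))[1], " in ", path)
  bad <- which(start >= end)
  if (length(bad))
    stop("read_bed: start >= end at line ", bad[1], " in ", path)
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5L, length(f))], ""))), 0)
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  binding_site_set(chrom, start, end,
                   name = if (all(nf >= 4L)) name else NULL,
                   score = ifelse(is.na(score), 0, score),
                   strand = strand, rbp = rbp, stage = stage,
                   coordinate_space = coordinate_space)
}

#' Write binding sites as BED6
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(x))` reproduces the intervals
#' bit-exactly. Rows are written sorted by `gene_id`, then `start`, then `end`.
#'
#' @param sites a [binding_site_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  o <- order(sites$gene_id, sites$start, sites$end)
  x <- sites[o, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$gene_id, x$start, x$end, x$name,
                   format(x$score, trim = TRUE, scientific = FALSE), x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference-anchored multiple sequence alignment
#'
#' Reads a multi-FASTA alignment, checks that all rows have equal length, and
#' re-indexes columns by reference transcript coordinate: columns where the
#' reference row carries a gap are dropped, and the mapping from retained
#' alignment column to 0-based reference position is recorded.
#'
#' @param path multi-FASTA file; gaps as `-`.
#' @param reference_id name of the reference row (must be present).
#' @param region optional region label (e.g. `"5UTR"`, `"3UTR"`).
#' @return An `alignment_block`: list with `species` (row names), `seqs`
#'   (character matrix, species x column, uppercase, `-` for gaps),
#'   `ref_coords` (0-based reference position of each retained column,
#'   strictly increasing), `reference_id`, `region`.
#' @export
read_alignment <- function(path, reference_id, region = NA_character_) {
  if (!file.exists(path)) stop("read_alignment: file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("read_alignment: fewer than 2 sequences")
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("read_alignment: ragged alignment (row lengths ",
         paste(unique(w), collapse = ", "), ")")
  m <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(m) <- names(ss)
  alignment_block(m, reference_id = reference_id, region = region)
}

#' Alignment block constructor
#'
#' @param seqs character matrix (species x alignment column) over
#'   `A,C,G,T,N,-`; rownames are species identifiers.
#' @param reference_id rowname of the reference species.
#' @param region optional region label.
#' @return An `alignment_block`; see [read_alignment()].
#' @export
alignment_block <- function(seqs, reference_id, region = NA_character_) {
  stopifnot(is.matrix(seqs), !is.null(rownames(seqs)))
  if (!reference_id %in% rownames(seqs))
    stop("alignment_block: reference row '", reference_id, "' not found")
  ref <- seqs[reference_id, ]
  keep <- ref != "-"
  # 0-based reference coordinate of each retained column: count of non-gap
  # reference positions before it
  ref_coords <- cumsum(keep)[keep] - 1L
  seqs <- seqs[, keep, drop = FALSE]
  structure(list(species = rownames(seqs), seqs = seqs,
                 ref_coords = as.integer(ref_coords),
                 reference_id = reference_id, region = region),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("alignment_block:", nrow(x$seqs), "species x", ncol(x$seqs),
      "reference columns (reference:", x$reference_id, ")\n")
  invisible(x)
}

#' Transcript annotation table
#'
#' @param gene_id,chrom,strand per-feature gene, chromosome and strand.
#' @param feature feature kind, one of `5UTR`, `CDS`, `3UTR`, `ncRNA`.
#' @param start,end 0-based half-open feature intervals (transcript or genomic,
#'   consistent within a table).
#' @param gene_length named vector of gene lengths (nt); defaults to the
#'   per-gene maximum feature end.
#' @return A `transcript_annotation` data.frame.
#' @export
transcript_annotation <- function(gene_id, chrom, strand, feature, start, end,
                                  gene_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("transcript_annotation: end <= start")
  if (any(start < 0L)) stop("transcript_annotation: negative start")
  ok <- feature %in% c("5UTR", "CDS", "3UTR", "ncRNA")
  if (!all(ok)) stop("transcript_annotation: unknown feature kind: ",
                     paste(unique(feature[!ok]), collapse = ", "))
  x <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  strand = as.character(strand), feature = as.character(feature),
                  start = start, end = end, stringsAsFactors = FALSE)
  if (is.null(gene_length))
    gene_length <- tapply(x$end, x$gene_id, max)
  if (any(x$end > gene_length[x$gene_id]))
    stop("transcript_annotation: feature outside gene span")
  structure(x, class = c("transcript_annotation", "data.frame"),
            gene_length = gene_length)
}

#' Write records as a deterministic TSV
#'
#' Writes a data.frame as tab-separated text with a header line, floats at
#' fixed precision, and rows sorted by `gene_id` then `start` (when present)
#' so that re-running on the same input yields a byte-identical file.
#'
#' @param records a data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = 6) {
  stopifnot(is.data.frame(records))
  x <- as.data.frame(records)
  keys <- intersect(c("gene_id", "start", "end"), names(x))
  if (length(keys)) x <- x[do.call(order, x[keys]), , drop = FALSE]
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], function(v) formatC(v, digits = digits,
                                               format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
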