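# TPM-like normalization of contig coverage and MAG relative abundance.

#' Contig-by-sample coverage matrix
#'
#' A light container pairing a non-negative numeric matrix (contigs in rows,
#' samples in columns) with a normalization state. The state machine admits
#' only the transition raw -> normalized, so coverage can never be scaled
#' twice.
#'
#' @param values numeric matrix with contig row names and sample column
#'   names
#' @param state `"raw"` or `"normalized"`
#' @return an object of class `coverage_matrix`
#' @export
coverage_matrix <- function(values, state = c("raw", "normalized")) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("coverage matrix needs contig row names and sample column names",
      call. = FALSE
    )
  }
  if (any(values < 0)) stop("coverage values must be >= 0", call. = FALSE)
  structure(list(values = values, state = state),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(
    "coverage_matrix (", x$state, "): ",
    nrow(x$values), " contigs x ", ncol(x$values), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$values)

#' Per-sample scaling factor
#'
#' The "per million" scale factor of the TPM-like normalization: total
#' mapped read count divided by one million. A sample with 9,171,534 mapped
#' reads has scaling factor 9.171534.
#'
#' @param total_mapped_reads positive count of reads mapped in the sample
#' @return `total_mapped_reads / 1e6`
#' @export
#' @examples
#' scaling_factor(9171534) # 9.171534
scaling_factor <- function(total_mapped_reads) {
  if (any(is.na(total_mapped_reads)) || any(total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive", call. = FALSE)
  }
  total_mapped_reads / 1e6
}

#' Raw coverage of a contig in one sample
#'
#' Coverage is the number of mapped reads divided by the contig length in
#' base pairs (a reads-per-base analogue of RPK). Set `per_kb = TRUE` for
#' reads-per-kilobase units; all downstream grouping and module arithmetic
#' is invariant to this choice when applied consistently, because the
#' grouping threshold is data-derived.
#'
#' @param mapped_reads non-negative read count
#' @param length_bp positive contig length
#' @param per_kb rescale to reads per kilobase
#' @return raw coverage value
#' @export
coverage_from_counts <- function(mapped_reads, length_bp, per_kb = FALSE) {
  if (any(length_bp <= 0)) stop("contig length must be > 0", call. = FALSE)
  if (any(mapped_reads < 0)) {
    stop("mapped_reads must be >= 0", call. = FALSE)
  }
  cov <- mapped_reads / length_bp
  if (per_kb) cov * 1000 else cov
}

#' Normalize a coverage matrix by per-sample scaling factors
#'
#' Each sample column is divided by that sample's scaling factor
#' (see [scaling_factor()]); the matrix state becomes `"normalized"`.
#' Normalizing an already-normalized matrix is an error.
#'
#' @param mat a raw [coverage_matrix()]
#' @param samples sample metadata (see [read_sample_table()]) covering every
#'   matrix column
#' @return normalized `coverage_matrix`, with attribute
#'   `"scaling_factors"` (named per-sample vector)
#' @export
normalize_coverage <- function(mat, samples) {
  stopifnot(inherits(mat, "coverage_matrix"))
  if (mat$state != "raw") {
    stop("coverage matrix is already normalized; refusing to scale twice",
      call. = FALSE
    )
  }
  idx <- match(colnames(mat$values), samples$sample_id)
  if (anyNA(idx)) {
    stop("no metadata for sample(s): ",
      paste(colnames(mat$values)[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  sf <- scaling_factor(samples$total_mapped_reads[idx])
  names(sf) <- colnames(mat$values)
  vals <- sweep(mat$values, 2L, sf, "/")
  out <- coverage_matrix(vals, state = "normalized")
  attr(out, "scaling_factors") <- sf
  out
}

#' MAG relative abundance from contig mapping ratios
#'
#' The relative abundance of a MAG in a sample is the sum of the mapping
#' ratios (fraction of the sample's read pool) of its member contigs.
#' Contigs not assigned to any MAG are ignored.
#'
#' @param ratios numeric matrix, contigs x samples, entries in `[0, 1]`
#' @param membership named character vector: contig id -> MAG id
#' @return numeric matrix, MAGs x samples, entries in `[0, 1]`
#' @export
mag_relative_abundance <- function(ratios, membership) {
  stopifnot(is.matrix(ratios))
  if (any(ratios < 0 | ratios > 1)) {
    stop("mapping ratios must lie in [0, 1]", call. = FALSE)
  }
  mags <- sort(unique(unname(membership)))
  out <- matrix(0,
    nrow = length(mags), ncol = ncol(ratios),
    dimnames = list(mags, colnames(ratios))
  )
  in_mag <- rownames(ratios) %in% names(membership)
  grp <- membership[rownames(ratios)[in_mag]]
  sub <- ratios[in_mag, , drop = FALSE]
  for (j in seq_len(ncol(sub))) {
    agg <- tapply(sub[, j], grp, sum)
    out[names(agg), j] <- as.numeric(agg)
  }
  if (any(out > 1 + 1e-9)) {
    stop("a MAG's summed mapping ratio exceeds 1; inconsistent input",
      call. = FALSE
    )
  }
  out
}
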