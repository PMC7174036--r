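# Coverage-pattern group assignment: a contig's normalized coverage profile
# across the active-layer (AL) sample and the permafrost-layer (PL) samples
# is binarized against a global median threshold and mapped to one of seven
# primary groups; PL_ALL/PL_SUB contigs with strong depth correlation are
# additionally tagged KI (increasing) or KD (decreasing).

#' Global classification threshold
#'
#' The median over all contig-by-sample entries of a normalized coverage
#' matrix. A single global threshold (rather than per-sample medians) keeps
#' presence calls comparable across samples.
#'
#' @param mat a normalized [coverage_matrix()]
#' @return scalar median
#' @export
global_threshold <- function(mat) {
  stopifnot(inherits(mat, "coverage_matrix"))
  if (mat$state != "normalized") {
    stop("global threshold is defined on normalized coverage", call. = FALSE)
  }
  if (length(mat$values) == 0L) {
    stop("empty coverage matrix", call. = FALSE)
  }
  stats::median(as.numeric(mat$values))
}

#' Assign the primary coverage-pattern group of one contig
#'
#' Each value is binarized as present iff `value >= th`. With one AL value
#' and n PL values the seven groups form a total partition of the presence
#' patterns:
#' \describe{
#'   \item{LO}{absent everywhere (low coverage)}
#'   \item{AL}{present in AL only}
#'   \item{BO}{present in AL and in all PL}
#'   \item{PL_Pi}{absent in AL, present in exactly one PL (i = that
#'     sample's position in depth order)}
#'   \item{PL_SUB}{absent in AL, present in 2..n-1 PL}
#'   \item{PL_ALL}{absent in AL, present in all PL}
#'   \item{UN}{present in AL and in a strict subset of PL}
#' }
#'
#' @param al_value normalized coverage in the AL sample
#' @param pl_values normalized coverage across the PL samples, ordered by
#'   increasing depth (n >= 2)
#' @param th global threshold (see [global_threshold()])
#' @return group label string
#' @export
assign_primary_group <- function(al_value, pl_values, th) {
  n <- length(pl_values)
  if (n < 2L) stop("need at least 2 PL samples", call. = FALSE)
  stopifnot(length(al_value) == 1L)
  al <- al_value >= th
  pl <- pl_values >= th
  k <- sum(pl)
  if (!al && k == 0L) return("LO")
  if (al && k == 0L) return("AL")
  if (al && k == n) return("BO")
  if (!al && k == 1L) return(paste0("PL_P", which(pl)))
  if (!al && k == n) return("PL_ALL")
  if (!al) return("PL_SUB")
  "UN"
}

#' Depth-trend tag of a contig
#'
#' Only contigs whose primary group is PL_ALL or PL_SUB are eligible. The
#' Pearson correlation between all PL coverages and sample depths decides
#' the tag: r >= `corr_threshold` is KI (increasing with depth),
#' r <= `-corr_threshold` is KD (decreasing). A constant PL profile has no
#' defined correlation and gets no tag.
#'
#' @param primary primary group label (see [assign_primary_group()])
#' @param pl_values PL coverages in depth order
#' @param depths_cm PL sample depths in cm, same order
#' @param corr_threshold correlation cutoff (default 0.9)
#' @return list with `tag` ("KI", "KD" or "none") and `r` (NA when
#'   undefined or ineligible)
#' @export
assign_trend <- function(primary, pl_values, depths_cm,
                         corr_threshold = 0.9) {
  stopifnot(length(pl_values) == length(depths_cm))
  if (!primary %in% c("PL_ALL", "PL_SUB")) {
    return(list(tag = "none", r = NA_real_))
  }
  if (stats::sd(pl_values) == 0 || stats::sd(depths_cm) == 0) {
    return(list(tag = "none", r = NA_real_))
  }
  r <- stats::cor(pl_values, depths_cm)
  tag <- if (r >= corr_threshold) {
    "KI"
  } else if (r <= -corr_threshold) {
    "KD"
  } else {
    "none"
  }
  list(tag = tag, r = r)
}

#' Classify every contig of a normalized coverage matrix
#'
#' Computes the global median threshold, assigns each contig its primary
#' group from the AL/PL presence pattern, and tags PL_ALL/PL_SUB contigs
#' with depth trends.
#'
#' @param mat normalized [coverage_matrix()]
#' @param samples sample metadata (one AL sample, >= 2 PL samples); PL
#'   samples are ordered by increasing depth
#' @param corr_threshold Pearson cutoff for KI/KD (default 0.9)
#' @param th optional explicit threshold, overriding the global median
#' @return data.frame with one row per contig: `contig_id`, `primary`,
#'   `trend`, `r`, and one `present_<sample>` logical column per sample;
#'   attributes `"threshold"`, `"al_sample"`, `"pl_samples"`, `"depths_cm"`
#' @export
assign_groups <- function(mat, samples, corr_threshold = 0.9, th = NULL) {
  stopifnot(inherits(mat, "coverage_matrix"))
  validate_sample_table(samples)
  idx <- match(colnames(mat$values), samples$sample_id)
  if (anyNA(idx)) {
    stop("no metadata for sample(s): ",
      paste(colnames(mat$values)[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  meta <- samples[idx, , drop = FALSE]
  al_samples <- meta$sample_id[meta$role == "AL"]
  pl_meta <- meta[meta$role == "PL", , drop = FALSE]
  pl_meta <- pl_meta[order(pl_meta$depth_cm), , drop = FALSE]
  if (length(al_samples) != 1L) {
    stop("exactly one AL sample is required, found ", length(al_samples),
      call. = FALSE
    )
  }
  if (nrow(pl_meta) < 2L) {
    stop("need at least 2 PL samples", call. = FALSE)
  }
  if (is.null(th)) th <- global_threshold(mat)
  al_col <- mat$values[, al_samples, drop = TRUE]
  pl_cols <- mat$values[, pl_meta$sample_id, drop = FALSE]
  n <- nrow(mat$values)
  primary <- character(n)
  trend <- character(n)
  r <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    primary[[i]] <- assign_primary_group(al_col[[i]], pl_cols[i, ], th)
    tr <- assign_trend(primary[[i]], pl_cols[i, ], pl_meta$depth_cm,
      corr_threshold = corr_threshold
    )
    trend[[i]] <- tr$tag
    r[[i]] <- tr$r
  }
  presence <- mat$values >= th
  colnames(presence) <- paste0("present_", colnames(mat$values))
  out <- data.frame(
    contig_id = rownames(mat$values),
    primary = primary, trend = trend, r = r,
    presence, stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- NULL
  attr(out, "threshold") <- th
  attr(out, "al_sample") <- al_samples
  attr(out, "pl_samples") <- pl_meta$sample_id
  attr(out, "depths_cm") <- pl_meta$depth_cm
  out
}

#' Summarize a group assignment table
#'
#' @param assignments output of [assign_groups()]
#' @return data.frame with one row per primary group (count and fraction of
#'   all classified contigs) plus overlay rows for KI and KD (fraction still
#'   relative to all contigs)
#' @export
group_summary <- function(assignments) {
  if (!nrow(assignments)) stop("empty assignment table", call. = FALSE)
  n <- nrow(assignments)
  tab <- table(assignments$primary)
  out <- data.frame(
    group = names(tab),
    kind = "primary",
    n_contigs = as.integer(tab),
    fraction = as.numeric(tab) / n,
    stringsAsFactors = FALSE
  )
  for (tag in c("KI", "KD")) {
    k <- sum(assignments$trend == tag)
    out <- rbind(out, data.frame(
      group = tag, kind = "trend", n_contigs = k, fraction = k / n,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}
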