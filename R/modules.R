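# KEGG Module abundance in a MAG-centric view. Each MAG is an independent
# unit: normalized contig coverage stands in for the abundance of the KOs
# that the contig's genes carry; a module's abundance in a MAG is the sum of
# its present KOs' (hit-averaged) weights divided by the module size, and a
# group's module abundance is the sum over the MAGs present in that group.

#' KO weights of one MAG
#'
#' Every annotated gene hit contributes its contig's weight (normalized
#' coverage); when the same KO hits multiple genes in the MAG, the weights
#' are averaged. Two genes with the same KO on one contig each enter the
#' average separately (per-hit averaging); set `per_contig_hits = TRUE` to
#' collapse hits to distinct contigs first.
#'
#' @param mag_contigs character vector of the MAG's contig ids
#' @param annotations data.frame from [read_ko_table()] (`gene_id`,
#'   `contig_id`, `ko_id`); rows with `ko_id` NA are ignored
#' @param contig_weights named numeric: contig id -> weight
#' @param per_contig_hits collapse multiple hits of one KO on one contig
#' @return named numeric vector: KO id -> averaged weight
#' @export
ko_weights_in_mag <- function(mag_contigs, annotations, contig_weights,
                              per_contig_hits = FALSE) {
  ann <- annotations[!is.na(annotations$ko_id), , drop = FALSE]
  outside <- setdiff(unique(ann$contig_id), mag_contigs)
  ann <- ann[ann$contig_id %in% mag_contigs, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (per_contig_hits) {
    ann <- unique(ann[, c("contig_id", "ko_id")])
  }
  w <- contig_weights[ann$contig_id]
  if (anyNA(w)) {
    stop("missing contig weight for: ",
      paste(unique(ann$contig_id[is.na(w)]), collapse = ", "),
      call. = FALSE
    )
  }
  means <- tapply(unname(w), ann$ko_id, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Module abundance within one MAG
#'
#' Sum of the weights of the module's KOs that are present in the MAG,
#' divided by the module size (count of distinct member KOs); absent KOs
#' contribute zero. E.g. a module \{K1, K2, K3\} carried on two contigs of
#' weights 2 and 4 (K1 on both, K2 on the first, K3 on the second) has
#' abundance (mean(2,4) + 2 + 4) / 3 = 3.
#'
#' @param ko_weights named numeric from [ko_weights_in_mag()]
#' @param module_kos character vector of the module's distinct KO ids
#' @return non-negative scalar
#' @export
module_abundance_in_mag <- function(ko_weights, module_kos) {
  module_kos <- unique(module_kos)
  if (!length(module_kos)) stop("module with zero KOs", call. = FALSE)
  present <- intersect(module_kos, names(ko_weights))
  sum(ko_weights[present]) / length(module_kos)
}

# Scalar contig weight under a named policy. `profile` is the contig's
# normalized coverage over all samples; the group decides which samples
# enter: AL -> the AL sample; BO -> all; PL_ALL/KI/KD -> all PL; PL_Pi ->
# PL sample i; PL_SUB -> the contig's supra-threshold PL samples (all PL if
# none); LO/UN -> all samples.
group_sample_set <- function(group, al_sample, pl_samples, profile = NULL,
                             th = NULL) {
  if (group == "AL") {
    return(al_sample)
  }
  if (group %in% c("PL_ALL", "KI", "KD")) {
    return(pl_samples)
  }
  if (grepl("^PL_P[0-9]+$", group)) {
    i <- as.integer(sub("^PL_P", "", group))
    return(pl_samples[i])
  }
  if (group == "PL_SUB") {
    supra <- pl_samples[profile[pl_samples] >= th]
    return(if (length(supra)) supra else pl_samples)
  }
  c(al_sample, pl_samples) # BO, LO, UN
}

#' Contig weight under a weighting policy
#'
#' Collapses a contig's per-sample normalized coverage profile to the single
#' scalar that weights its KO hits in group-level module abundance.
#'
#' @param profile named numeric: sample id -> normalized coverage
#' @param group group label the contig is evaluated in
#' @param al_sample AL sample id
#' @param pl_samples PL sample ids in depth order
#' @param policy `"group-mean"` (mean over the group's sample set, the
#'   default) or `"max"` (maximum over the group's sample set)
#' @param th global threshold; needed for PL_SUB's supra-threshold set
#' @return scalar weight
#' @export
weight_policy <- function(profile, group, al_sample, pl_samples,
                          policy = c("group-mean", "max"), th = NULL) {
  policy <- match.arg(policy)
  ss <- group_sample_set(group, al_sample, pl_samples, profile, th)
  vals <- profile[ss]
  switch(policy,
    "group-mean" = mean(vals),
    "max" = max(vals)
  )
}

#' Module abundance per MAG
#'
#' @param membership named character vector: contig id -> MAG id
#' @param annotations gene/KO table (see [read_ko_table()])
#' @param modules named list: module id -> KO ids
#' @param contig_weights named numeric: contig id -> scalar weight
#' @param per_contig_hits see [ko_weights_in_mag()]
#' @return numeric matrix, modules x MAGs
#' @export
module_abundance_per_mag <- function(membership, annotations, modules,
                                     contig_weights,
                                     per_contig_hits = FALSE) {
  mags <- sort(unique(unname(membership)))
  out <- matrix(0,
    nrow = length(modules), ncol = length(mags),
    dimnames = list(names(modules), mags)
  )
  for (m in mags) {
    mc <- names(membership)[membership == m]
    kw <- ko_weights_in_mag(mc, annotations, contig_weights,
      per_contig_hits = per_contig_hits
    )
    for (mod in names(modules)) {
      out[mod, m] <- module_abundance_in_mag(kw, modules[[mod]])
    }
  }
  out
}

#' Module abundance aggregated per coverage-pattern group
#'
#' For each group (every primary group present, plus KI and KD overlay
#' columns) the MAGs "present" in the group — those with at least one contig
#' assigned to it — are evaluated and their module abundances summed. Under
#' the default `scope = "group"` a MAG's KO weights are computed from its
#' contigs assigned to that group only; `scope = "whole-mag"` uses all of
#' the MAG's contigs. Contig weights come from [weight_policy()]; the
#' `"per-sample"` policy emits one column per group and sample
#' (`<group>|<sample>`), weighting each contig by its coverage in that
#' sample alone.
#'
#' @param assignments output of [assign_groups()] (its attributes supply the
#'   AL/PL sample ids and the threshold)
#' @param membership named character vector: contig id -> MAG id
#' @param annotations gene/KO table (see [read_ko_table()])
#' @param modules named list: module id -> KO ids
#' @param mat the normalized [coverage_matrix()] the assignment was made on
#' @param policy `"group-mean"`, `"max"`, or `"per-sample"`
#' @param scope `"group"` or `"whole-mag"`
#' @param per_contig_hits see [ko_weights_in_mag()]
#' @return numeric matrix, modules x groups (or group|sample columns)
#' @export
module_abundance_by_group <- function(assignments, membership, annotations,
                                      modules, mat,
                                      policy = c(
                                        "group-mean", "max", "per-sample"
                                      ),
                                      scope = c("group", "whole-mag"),
                                      per_contig_hits = FALSE) {
  policy <- match.arg(policy)
  scope <- match.arg(scope)
  stopifnot(inherits(mat, "coverage_matrix"))
  al_sample <- attr(assignments, "al_sample")
  pl_samples <- attr(assignments, "pl_samples")
  th <- attr(assignments, "threshold")
  if (is.null(al_sample) || is.null(pl_samples) || is.null(th)) {
    stop("assignments must come from assign_groups()", call. = FALSE)
  }
  groups <- c(
    intersect(
      c(
        "AL", "BO", "LO", "PL_ALL", "PL_SUB",
        sort(unique(grep("^PL_P[0-9]+$", assignments$primary,
          value = TRUE
        ))), "UN"
      ),
      unique(assignments$primary)
    ),
    intersect(c("KI", "KD"), unique(assignments$trend))
  )
  group_contigs <- function(g) {
    if (g %in% c("KI", "KD")) {
      assignments$contig_id[assignments$trend == g]
    } else {
      assignments$contig_id[assignments$primary == g]
    }
  }
  one_column <- function(g, weight_of) {
    cg <- intersect(group_contigs(g), names(membership))
    col <- stats::setNames(numeric(length(modules)), names(modules))
    if (!length(cg)) {
      return(col)
    }
    for (m in unique(unname(membership[cg]))) {
      eval_contigs <- if (scope == "group") {
        cg[membership[cg] == m]
      } else {
        names(membership)[membership == m]
      }
      w <- vapply(eval_contigs, weight_of, numeric(1))
      kw <- ko_weights_in_mag(eval_contigs, annotations, w,
        per_contig_hits = per_contig_hits
      )
      for (mod in names(modules)) {
        col[[mod]] <- col[[mod]] +
          module_abundance_in_mag(kw, modules[[mod]])
      }
    }
    col
  }
  if (policy == "per-sample") {
    all_samples <- colnames(mat$values)
    cols <- list()
    for (g in groups) {
      for (s in all_samples) {
        cols[[paste0(g, "|", s)]] <- one_column(
          g, function(cid) mat$values[cid, s]
        )
      }
    }
  } else {
    cols <- lapply(groups, function(g) {
      one_column(g, function(cid) {
        weight_policy(mat$values[cid, ], g, al_sample, pl_samples,
          policy = policy, th = th
        )
      })
    })
    names(cols) <- groups
  }
  out <- do.call(cbind, cols)
  rownames(out) <- names(modules)
  out
}
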