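# Independent oracles and small fixture builders. Everything here is coded
# from first principles (plain loops, textbook formulas) and never calls the
# package functions it is used to check.

# Textbook product-moment correlation.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Table-1 presence-pattern predicates, one per primary group. Used to check
# that exactly one group fires for any profile.
group_predicates <- function(al, pl) {
  n <- length(pl)
  k <- sum(pl)
  preds <- c(
    AL = al && k == 0,
    BO = al && k == n,
    LO = !al && k == 0,
    PL_ALL = !al && k == n,
    PL_SUB = !al && k >= 2 && k <= n - 1,
    UN = al && k >= 1 && k <= n - 1
  )
  for (i in seq_len(n)) {
    preds[[paste0("PL_P", i)]] <- !al && k == 1 && pl[[i]]
  }
  preds
}

# Brute-force recomputation of module abundance by group: nested loops over
# groups, MAGs, modules, KOs and gene hits, re-deriving sample sets and
# weights from scratch.
brute_module_abundance <- function(assignments, membership, annotations,
                                   modules, mat, policy = "group-mean",
                                   scope = "group") {
  al_sample <- attr(assignments, "al_sample")
  pl_samples <- attr(assignments, "pl_samples")
  th <- attr(assignments, "threshold")
  vals <- mat$values
  groups <- unique(assignments$primary)
  groups <- c(groups, intersect(c("KI", "KD"), assignments$trend))
  contig_weight <- function(cid, g) {
    if (g == "AL") {
      ss <- al_sample
    } else if (g %in% c("PL_ALL", "KI", "KD")) {
      ss <- pl_samples
    } else if (grepl("^PL_P[0-9]+$", g)) {
      ss <- pl_samples[as.integer(sub("^PL_P", "", g))]
    } else if (g == "PL_SUB") {
      ss <- pl_samples[vals[cid, pl_samples] >= th]
      if (!length(ss)) ss <- pl_samples
    } else {
      ss <- c(al_sample, pl_samples)
    }
    v <- vals[cid, ss]
    if (policy == "group-mean") sum(v) / length(v) else max(v)
  }
  out <- matrix(0, nrow = length(modules), ncol = length(groups),
    dimnames = list(names(modules), groups)
  )
  ann <- annotations[!is.na(annotations$ko_id), , drop = FALSE]
  for (g in groups) {
    gc <- if (g %in% c("KI", "KD")) {
      assignments$contig_id[assignments$trend == g]
    } else {
      assignments$contig_id[assignments$primary == g]
    }
    gc <- gc[gc %in% names(membership)]
    for (mag in unique(unname(membership[gc]))) {
      eval_contigs <- if (scope == "group") {
        gc[membership[gc] == mag]
      } else {
        names(membership)[membership == mag]
      }
      for (mi in seq_along(modules)) {
        total <- 0
        for (ko in modules[[mi]]) {
          hits <- ann[ann$ko_id == ko &
            ann$contig_id %in% eval_contigs, , drop = FALSE]
          if (nrow(hits) == 0) next
          ws <- numeric(0)
          for (r in seq_len(nrow(hits))) {
            ws <- c(ws, contig_weight(hits$contig_id[[r]], g))
          }
          total <- total + sum(ws) / length(ws)
        }
        out[mi, g] <- out[mi, g] + total / length(modules[[mi]])
      }
    }
  }
  out
}

# A tiny hand-built bin: 8 majority contigs sharing one lineage (NA at
# family and genus) + 2 contaminants from a different phylum.
toy_bin <- function() {
  maj <- c("Proteobacteria", "Alphaproteobacteria", "Rhizobiales",
    "NA", "NA", "Unknown species")
  con <- c("Actinobacteria", "Actinomycetia", "Streptomycetales",
    "Streptomycetaceae", "Streptomyces", "Streptomyces sp.")
  contigs <- sprintf("T%02d", 1:10)
  lineages <- c(
    stats::setNames(rep(list(maj), 8), contigs[1:8]),
    stats::setNames(rep(list(con), 2), contigs[9:10])
  )
  list(
    contigs = contigs,
    majority = contigs[1:8],
    lineages = lapply(lineages, magkit::propagate_na_labels)
  )
}

# Five-sample metadata matching the study layout.
study_samples <- function() {
  data.frame(
    sample_id = c("AL1", "PL1", "PL2", "PL3", "PL4"),
    role = c("AL", "PL", "PL", "PL", "PL"),
    depth_cm = c(7, 110, 122, 135, 170),
    total_mapped_reads = c(9171534, 1e7, 8e6, 1.2e7, 9e6),
    stringsAsFactors = FALSE
  )
}
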