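# Bin decontamination by taxonomic classification: hierarchical NA-label
# propagation, per-rank label composition, and per-rank subset emission.

#' Propagate unassigned ranks into hierarchical placeholder labels
#'
#' Taxonomic classifiers return "NA" at ranks they cannot resolve, which
#' flattens the hierarchy exactly where contamination must be assessed. This
#' rebuilds the hierarchy by synthesizing deterministic labels: scanning
#' phylum to species, an observed taxon is kept verbatim; an "NA" at phylum
#' becomes `P_NA`; an "NA" at a lower rank chains the (already propagated)
#' label of the rank above with `_NA_` and the rank letter. E.g. a lineage
#' `Proteobacteria; Alphaproteobacteria; Rhizobiales; NA; NA; Unknown species`
#' becomes `...; Rhizobiales; Rhizobiales_NA_F; Rhizobiales_NA_F_NA_G;
#' Unknown species`.
#'
#' @param raw_lineage character vector of 6 rank strings (phylum..species),
#'   "NA" marking unassigned ranks
#' @return character vector of 6 labels, none equal to the bare token "NA"
#' @export
#' @examples
#' propagate_na_labels(c(
#'   "Proteobacteria", "Alphaproteobacteria", "Rhizobiales",
#'   "NA", "NA", "Unknown species"
#' ))
propagate_na_labels <- function(raw_lineage) {
  letters_ <- unname(taxonomy_ranks())
  n <- length(letters_)
  if (length(raw_lineage) != n) {
    stop("lineage must have exactly ", n, " rank strings, got ",
      length(raw_lineage),
      call. = FALSE
    )
  }
  out <- character(n)
  for (i in seq_len(n)) {
    x <- raw_lineage[[i]]
    if (is.na(x) || identical(x, "NA")) {
      out[[i]] <- if (i == 1L) {
        paste0(letters_[[1L]], "_NA")
      } else {
        paste0(out[[i - 1L]], "_NA_", letters_[[i]])
      }
    } else {
      out[[i]] <- x
    }
  }
  out
}

#' Propagate NA labels across a whole lineage set
#'
#' @param lineages named list of raw 6-rank lineages (see
#'   [read_lineage_table()])
#' @return named list of propagated lineages
#' @export
propagate_lineages <- function(lineages) {
  lapply(lineages, propagate_na_labels)
}

#' Label composition of a bin at one taxonomic rank
#'
#' @param bin_contigs character vector of the bin's contig ids
#' @param lineages named list of propagated lineages covering the bin
#' @param rank rank name (one of `names(taxonomy_ranks())`)
#' @param weights optional named numeric (contig id -> weight, e.g. contig
#'   length); default weights each contig equally (count-based fractions)
#' @return named numeric vector: label -> fraction in `[0, 1]`, summing to 1
#' @export
rank_composition <- function(bin_contigs, lineages, rank,
                             weights = NULL) {
  ranks <- names(taxonomy_ranks())
  rank <- match.arg(rank, ranks)
  ri <- match(rank, ranks)
  missing <- setdiff(bin_contigs, names(lineages))
  if (length(missing)) {
    stop("contig(s) without lineage: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  labels <- vapply(lineages[bin_contigs], `[[`, character(1), ri)
  w <- if (is.null(weights)) {
    rep(1, length(bin_contigs))
  } else {
    unname(weights[bin_contigs])
  }
  if (anyNA(w)) stop("missing weight for a bin contig", call. = FALSE)
  tab <- tapply(w, labels, sum)
  frac <- as.numeric(tab) / sum(w)
  names(frac) <- names(tab)
  sort(frac, decreasing = TRUE)
}

#' Subset a bin by dominant labels at one rank
#'
#' Emits one subset per label whose composition fraction is strictly greater
#' than `min_fraction` (default 0.5, so at most one subset at the default).
#'
#' @inheritParams rank_composition
#' @param min_fraction keep labels with fraction strictly above this
#' @return list of subsets; each has `rank`, `label`, `contig_ids`,
#'   `fraction`
#' @export
subset_bin <- function(bin_contigs, lineages, rank, min_fraction = 0.5,
                       weights = NULL) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  ranks <- names(taxonomy_ranks())
  rank <- match.arg(rank, ranks)
  ri <- match(rank, ranks)
  comp <- rank_composition(bin_contigs, lineages, rank, weights = weights)
  keep <- names(comp)[comp > min_fraction]
  labels <- vapply(lineages[bin_contigs], `[[`, character(1), ri)
  lapply(keep, function(lab) {
    list(
      rank = rank,
      label = lab,
      contig_ids = bin_contigs[labels == lab],
      fraction = unname(comp[[lab]])
    )
  })
}

#' Refine a bin at every taxonomic rank
#'
#' Applies [subset_bin()] at all six ranks. When `contigs` (with sequences)
#' and `out_dir` are supplied, each subset is written as
#' `<bin>.<rankLetter>.<label>.fasta` and a per-bin report row is produced.
#'
#' @inheritParams subset_bin
#' @param bin_id bin name, used for output file naming
#' @param contigs optional data.frame from [read_fasta()] holding sequences
#' @param out_dir optional output directory for per-rank FASTA subsets
#' @return named list (rank -> list of subsets), with attribute `"report"`:
#'   a data.frame (bin, rank, label, n_contigs, fraction, fasta)
#' @export
refine_across_ranks <- function(bin_contigs, lineages, min_fraction = 0.5,
                                bin_id = "bin", contigs = NULL,
                                out_dir = NULL, weights = NULL) {
  ranks <- names(taxonomy_ranks())
  letters_ <- taxonomy_ranks()
  res <- list()
  rows <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  used_names <- character()
  for (rk in ranks) {
    subs <- subset_bin(bin_contigs, lineages, rk,
      min_fraction = min_fraction, weights = weights
    )
    res[[rk]] <- subs
    for (s in subs) {
      path <- NA_character_
      if (!is.null(contigs) && !is.null(out_dir)) {
        base <- paste0(bin_id, ".", letters_[[rk]], ".",
          sanitize_label(s$label))
        nm <- base
        k <- 1L
        while (nm %in% used_names) {
          k <- k + 1L
          nm <- paste0(base, "_", k)
        }
        used_names <- c(used_names, nm)
        path <- file.path(out_dir, paste0(nm, ".fasta"))
        sel <- contigs[contigs$contig_id %in% s$contig_ids, , drop = FALSE]
        write_fasta(sel, path)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bin = bin_id, rank = rk, label = s$label,
        n_contigs = length(s$contig_ids), fraction = s$fraction,
        fasta = path, stringsAsFactors = FALSE
      )
    }
  }
  report <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      bin = character(), rank = character(), label = character(),
      n_contigs = integer(), fraction = numeric(), fasta = character(),
      stringsAsFactors = FALSE
    )
  }
  attr(res, "report") <- report
  res
}

# Filename-safe label: non-alphanumeric runs -> "_"
sanitize_label <- function(label) {
  gsub("^_+|_+$", "", gsub("[^A-Za-z0-9]+", "_", label))
}

#' Rank refined subsets by externally assessed quality
#'
#' Completeness and contamination (e.g. from CheckM) are supplied by the
#' user; the toolkit never computes them. Subsets are ranked by
#' `completeness - weight * contamination`, descending; ties broken by
#' higher completeness, then by subset name.
#'
#' @param quality data.frame with columns `subset`, `completeness`,
#'   `contamination` (both percentages in `[0, 100]`)
#' @param weight contamination penalty (default 5)
#' @return the input rows reordered best-first, with a `score` column
#' @export
score_refinement <- function(quality, weight = 5) {
  stopifnot(all(c("subset", "completeness", "contamination") %in%
    names(quality)))
  comp <- quality$completeness
  cont <- quality$contamination
  if (any(comp < 0 | comp > 100) || any(cont < 0 | cont > 100)) {
    stop("completeness and contamination must lie in [0, 100]",
      call. = FALSE
    )
  }
  score <- comp - weight * cont
  ord <- order(-score, -comp, quality$subset)
  out <- quality[ord, , drop = FALSE]
  out$score <- score[ord]
  rownames(out) <- NULL
  out
}
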