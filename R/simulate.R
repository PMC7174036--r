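# Deterministic synthetic communities with machine-readable ground truth:
# bins with planted lineage contamination, coverage matrices with planted
# group structure and depth trends, and KO/module annotations. Every module
# of the toolkit is testable against these fixtures without any download.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Defaults emulate the sampling design the toolkit targets: one seasonally
#' thawing active-layer sample (AL1, 7 cm) and four permafrost samples
#' (PL1..PL4 at 110, 122, 135 and 170 cm), supra-threshold normalized
#' coverage around 2 and sub-threshold around 0.2 with 10% multiplicative
#' noise, bins carrying 20% planted lineage contamination, and a balanced
#' group design whose supra/sub entry counts pin the global median into the
#' gap between the two coverage levels.
#'
#' @param seed integer RNG seed; fully determines the community
#' @param group_design named integer vector: contigs to plant per group
#'   (primary groups plus KI/KD, which are PL_ALL contigs with exact
#'   affine-in-depth profiles)
#' @param n_mags number of MAGs the contigs are spread over
#' @param contamination_fraction fraction of each bin's contigs given a
#'   foreign lineage
#' @param depths_cm PL sample depths, increasing
#' @param al_depth_cm AL sample depth
#' @param total_mapped_reads per-sample mapped read counts (AL first)
#' @param high,low supra- and sub-threshold normalized coverage levels
#' @param noise multiplicative noise half-width within a stratum
#' @param n_modules,kos_per_module module catalogue shape
#' @param contig_length_range sampled contig lengths in bp
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 42L,
                       group_design = c(
                         AL = 5L, BO = 10L, LO = 4L, PL_SUB = 5L,
                         PL_ALL = 5L, PL_P1 = 5L, PL_P2 = 5L,
                         PL_P3 = 5L, PL_P4 = 5L, UN = 5L,
                         KI = 5L, KD = 5L
                       ),
                       n_mags = 4L,
                       contamination_fraction = 0.2,
                       depths_cm = c(110, 122, 135, 170),
                       al_depth_cm = 7,
                       total_mapped_reads = c(
                         9171534, 10254871, 8012345, 11111111, 9500000
                       ),
                       high = 2.0, low = 0.2, noise = 0.1,
                       n_modules = 8L, kos_per_module = 3L,
                       contig_length_range = c(500L, 2000L)) {
  stopifnot(
    length(depths_cm) >= 2L, !is.unsorted(depths_cm),
    length(total_mapped_reads) == length(depths_cm) + 1L,
    low * (1 + noise) < high * (1 - noise),
    contamination_fraction >= 0, contamination_fraction < 0.5
  )
  structure(
    list(
      seed = as.integer(seed), group_design = group_design,
      n_mags = as.integer(n_mags),
      contamination_fraction = contamination_fraction,
      depths_cm = depths_cm, al_depth_cm = al_depth_cm,
      total_mapped_reads = total_mapped_reads,
      high = high, low = low, noise = noise,
      n_modules = as.integer(n_modules),
      kos_per_module = as.integer(kos_per_module),
      contig_length_range = contig_length_range
    ),
    class = "sim_config"
  )
}

# Presence pattern (AL + PL) of a planted group; TRUE = supra-threshold.
planted_pattern <- function(group, n_pl) {
  pl <- rep(FALSE, n_pl)
  al <- FALSE
  if (group == "AL") {
    al <- TRUE
  } else if (group == "BO") {
    al <- TRUE
    pl[] <- TRUE
  } else if (group == "LO") {
    # all absent
  } else if (group %in% c("PL_ALL", "KI", "KD")) {
    pl[] <- TRUE
  } else if (group == "PL_SUB") {
    pl[seq(1L, n_pl, by = 2L)] <- TRUE # alternating: weak depth trend
  } else if (grepl("^PL_P[0-9]+$", group)) {
    pl[as.integer(sub("^PL_P", "", group))] <- TRUE
  } else if (group == "UN") {
    al <- TRUE
    pl[seq_len(max(1L, n_pl %/% 2L))] <- TRUE
  } else {
    stop("unknown group in design: ", group, call. = FALSE)
  }
  c(al, pl)
}

# Synthetic complete lineage for MAG i; family and genus are left "NA" so
# fixtures exercise NA-label propagation (all contigs of the MAG share the
# same raw lineage, so propagated labels agree at every rank).
mag_lineage <- function(i) {
  c(
    paste0("Phylum", i), paste0("Class", i), paste0("Order", i),
    "NA", "NA", paste0("Species", i)
  )
}

foreign_lineage <- function(i) {
  c(
    paste0("XenoPhylum", i), paste0("XenoClass", i), paste0("XenoOrder", i),
    paste0("XenoFamily", i), paste0("XenoGenus", i),
    paste0("XenoSpecies", i)
  )
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a synthetic community with ground truth
#'
#' Builds normalized coverage levels per the planted design, converts them
#' to raw coverage with the per-sample scaling factors, plants lineages with
#' per-bin contamination and KO/module annotations, and (optionally) writes
#' the whole fixture as the plain-text files the toolkit reads. Profiles of
#' KI/KD contigs are exactly affine in depth (Pearson r = +/-1); noise on
#' other PL_ALL/PL_SUB contigs is resampled until |r| < 0.85 so no planted
#' "none"-trend contig strays into a trend tag. After generation the global
#' median of the normalized matrix is checked to fall strictly between the
#' sub- and supra-threshold strata; a design for which it does not is
#' rejected as unrealizable.
#'
#' @param config a [sim_config()]
#' @param out_dir optional directory; when given, all input files and truth
#'   tables are written under it
#' @return list with `samples`, `raw` and `normalized` coverage matrices,
#'   `lineages` (raw, per contig), `membership` (contig -> MAG),
#'   `annotations`, `modules`, `contigs` (sequences), `truth` (per-contig
#'   group/trend/contaminant table), `paths` (when written)
#' @export
simulate_community <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_pl <- length(config$depths_cm)
    samples <- data.frame(
      sample_id = c("AL1", paste0("PL", seq_len(n_pl))),
      role = c("AL", rep("PL", n_pl)),
      depth_cm = c(config$al_depth_cm, config$depths_cm),
      total_mapped_reads = config$total_mapped_reads,
      stringsAsFactors = FALSE
    )
    design <- config$group_design
    groups <- rep(names(design), times = design)
    n <- length(groups)
    contig_ids <- sprintf("C%03d", seq_len(n))
    mag_ids <- paste0("MAG", rep_len(seq_len(config$n_mags), n))
    membership <- stats::setNames(mag_ids, contig_ids)

    # normalized coverage with planted presence pattern
    d <- config$depths_cm
    ramp_up <- 0.9 + 0.2 * (d - d[1]) / (d[n_pl] - d[1])
    ramp_down <- 0.9 + 0.2 * (d[n_pl] - d) / (d[n_pl] - d[1])
    vals <- matrix(0, nrow = n, ncol = n_pl + 1L,
      dimnames = list(contig_ids, samples$sample_id)
    )
    jitter1 <- function(k) stats::runif(k, 1 - config$noise, 1 + config$noise)
    for (i in seq_len(n)) {
      g <- groups[[i]]
      pat <- planted_pattern(g, n_pl)
      base <- ifelse(pat, config$high, config$low)
      if (g == "KI") {
        prof <- c(base[1] * jitter1(1), config$high * ramp_up)
      } else if (g == "KD") {
        prof <- c(base[1] * jitter1(1), config$high * ramp_down)
      } else if (g %in% c("PL_ALL", "PL_SUB")) {
        repeat {
          prof <- base * jitter1(n_pl + 1L)
          if (abs(stats::cor(prof[-1], d)) < 0.85) break
        }
      } else {
        prof <- base * jitter1(n_pl + 1L)
      }
      vals[i, ] <- prof
    }
    normalized <- coverage_matrix(vals, state = "normalized")

    # realizability: the global median must separate the strata
    th <- stats::median(as.numeric(vals))
    strata <- t(vapply(
      groups, function(g) planted_pattern(g, n_pl), logical(n_pl + 1L)
    ))
    if (any(vals[strata] < th) || any(vals[!strata] >= th)) {
      stop(
        "unrealizable design: the global median does not separate the ",
        "planted sub- and supra-threshold strata; rebalance group counts ",
        "so supra and sub entries are equally frequent",
        call. = FALSE
      )
    }

    sf <- scaling_factor(samples$total_mapped_reads)
    raw <- coverage_matrix(sweep(vals, 2L, sf, "*"), state = "raw")

    # lineages: per bin, a planted majority lineage plus foreign
    # contaminants on the last ceil(f * n_bin) contigs of the bin
    lineages <- list()
    contaminant <- logical(n)
    for (b in seq_len(config$n_mags)) {
      bin_contigs <- which(mag_ids == paste0("MAG", b))
      n_cont <- floor(config$contamination_fraction * length(bin_contigs))
      cont_idx <- utils::tail(bin_contigs, n_cont)
      for (i in bin_contigs) {
        lineages[[contig_ids[[i]]]] <- if (i %in% cont_idx) {
          foreign_lineage(b)
        } else {
          mag_lineage(b)
        }
      }
      contaminant[cont_idx] <- TRUE
    }

    # module catalogue and gene annotations: module m owns KOs
    # K<m>01..K<m>kk; each KO is planted on 1-2 contigs per MAG
    modules <- list()
    for (m in seq_len(config$n_modules)) {
      modules[[sprintf("M%03d", m)]] <-
        sprintf("K%02d%02d", m, seq_len(config$kos_per_module))
    }
    gene_rows <- list()
    gene_counter <- stats::setNames(integer(n), contig_ids)
    for (mag in unique(mag_ids)) {
      mc <- contig_ids[mag_ids == mag]
      for (ko in unlist(modules, use.names = FALSE)) {
        if (stats::runif(1) < 0.3) next # KO absent from this MAG
        hits <- sample(mc, size = sample(1:2, 1), replace = TRUE)
        for (cid in hits) {
          gene_counter[[cid]] <- gene_counter[[cid]] + 1L
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = paste0(cid, "_", gene_counter[[cid]]),
            contig_id = cid, ko_id = ko, stringsAsFactors = FALSE
          )
        }
      }
    }
    # a few unannotated genes (empty KO field)
    for (cid in utils::head(contig_ids, 3L)) {
      gene_counter[[cid]] <- gene_counter[[cid]] + 1L
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = paste0(cid, "_", gene_counter[[cid]]),
        contig_id = cid, ko_id = NA_character_, stringsAsFactors = FALSE
      )
    }
    annotations <- do.call(rbind, gene_rows)

    lens <- sample(
      config$contig_length_range[1]:config$contig_length_range[2], n,
      replace = TRUE
    )
    contigs <- data.frame(
      contig_id = contig_ids, length_bp = lens,
      sequence = vapply(lens, random_sequence, character(1)),
      bin_id = mag_ids, stringsAsFactors = FALSE
    )

    truth <- data.frame(
      contig_id = contig_ids,
      mag_id = mag_ids,
      group = ifelse(groups %in% c("KI", "KD"), "PL_ALL", groups),
      trend = ifelse(groups %in% c("KI", "KD"), groups, "none"),
      contaminant = contaminant,
      lineage = vapply(
        lineages[contig_ids], paste, character(1), collapse = "; "
      ),
      stringsAsFactors = FALSE
    )

    out <- list(
      config = config, samples = samples, raw = raw,
      normalized = normalized, lineages = lineages,
      membership = membership, annotations = annotations,
      modules = modules, contigs = contigs, truth = truth
    )
    if (!is.null(out_dir)) {
      out$paths <- write_fixture(out, out_dir)
    }
    out
  })
}

write_fixture <- function(community, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bins_dir <- file.path(out_dir, "bins")
  dir.create(bins_dir, showWarnings = FALSE)
  paths <- list(
    samples = file.path(out_dir, "samples.tsv"),
    coverage = file.path(out_dir, "coverage.tsv"),
    lineages = file.path(out_dir, "lineages.tsv"),
    ko = file.path(out_dir, "ko.tsv"),
    modules = file.path(out_dir, "modules.tsv"),
    membership = file.path(out_dir, "membership.tsv"),
    truth = file.path(out_dir, "truth_contigs.tsv"),
    bins = bins_dir
  )
  write_sample_table(community$samples, paths$samples)
  write_coverage_table(community$raw, paths$coverage)
  write_lineage_table(community$lineages, paths$lineages)
  write_ko_table(community$annotations, paths$ko)
  write_module_definitions(community$modules, paths$modules)
  write_tsv_raw(
    data.frame(
      contig_id = names(community$membership),
      mag_id = unname(community$membership), stringsAsFactors = FALSE
    ),
    paths$membership
  )
  write_tsv_raw(community$truth, paths$truth)
  for (mag in unique(community$contigs$bin_id)) {
    sel <- community$contigs[community$contigs$bin_id == mag, , drop = FALSE]
    write_fasta(sel, file.path(bins_dir, paste0(mag, ".fasta")))
  }
  paths
}

#' Two-contig micro-community illustrating module arithmetic
#'
#' One MAG ("Bin_1") with contigs C1 (weight `w1`; genes hitting K1 and K2)
#' and C2 (weight `w2`; genes hitting K1, K3 and K6), module M1 = \{K1, K2,
#' K3\} and module M2 of size 4 containing K6. With the defaults w1 = 2 and
#' w2 = 4: M1 abundance = (mean(2, 4) + 2 + 4) / 3 = 3 and M2 abundance =
#' 4 / 4 = 1.
#'
#' @param w1,w2 normalized coverage weights of contigs C1 and C2
#' @return list with `membership`, `annotations`, `modules`,
#'   `contig_weights`
#' @export
demo_module_fixture <- function(w1 = 2, w2 = 4) {
  list(
    membership = c(C1 = "Bin_1", C2 = "Bin_1"),
    annotations = data.frame(
      gene_id = c("C1_1", "C1_2", "C2_1", "C2_2", "C2_3"),
      contig_id = c("C1", "C1", "C2", "C2", "C2"),
      ko_id = c("K1", "K2", "K1", "K3", "K6"),
      stringsAsFactors = FALSE
    ),
    modules = list(
      M1 = c("K1", "K2", "K3"),
      M2 = c("K4", "K5", "K6", "K7")
    ),
    contig_weights = c(C1 = w1, C2 = w2)
  )
}
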