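test_that("NA labels chain the propagated label of the rank above", {
  # worked example: NA at family and genus under Rhizobiales
  out <- propagate_na_labels(c(
    "Proteobacteria", "Alphaproteobacteria", "Rhizobiales",
    "NA", "NA", "Unknown species"
  ))
  expect_equal(out, c(
    "Proteobacteria", "Alphaproteobacteria", "Rhizobiales",
    "Rhizobiales_NA_F", "Rhizobiales_NA_F_NA_G", "Unknown species"
  ))

  # fully unclassified lineage chains from P_NA
  expect_equal(propagate_na_labels(rep("NA", 6)), c(
    "P_NA", "P_NA_NA_C", "P_NA_NA_C_NA_O", "P_NA_NA_C_NA_O_NA_F",
    "P_NA_NA_C_NA_O_NA_F_NA_G", "P_NA_NA_C_NA_O_NA_F_NA_G_NA_S"
  ))

  expect_error(propagate_na_labels(c("A", "B")), "exactly 6")
})

test_that("propagation is the identity on complete lineages and never
          leaves a bare NA", {
  complete <- c("P1", "C1", "O1", "F1", "G1", "S1")
  expect_identical(propagate_na_labels(complete), complete)

  set.seed(11)
  for (i in 1:50) {
    raw <- ifelse(runif(6) < 0.5, "NA", paste0("T", 1:6))
    out <- propagate_na_labels(raw)
    expect_false(any(out == "NA"))
    expect_identical(out, propagate_na_labels(raw)) # deterministic
  }
})

test_that("rank composition counts contigs and nests across ranks", {
  bin <- toy_bin()
  comp <- rank_composition(bin$contigs, bin$lineages, "phylum")
  expect_equal(
    comp[c("Proteobacteria", "Actinobacteria")],
    c(Proteobacteria = 0.8, Actinobacteria = 0.2)
  )
  expect_equal(sum(comp), 1)

  one <- rank_composition(bin$contigs[1], bin$lineages, "genus")
  expect_equal(unname(one), 1)

  # nesting: a parent label's fraction is the sum over its children
  set.seed(3)
  ranks <- names(taxonomy_ranks())
  lin <- lapply(1:40, function(i) {
    # hierarchical taxonomy: each label extends its parent's; lineages are
    # truncated at a random rank (all deeper ranks unassigned), so every
    # realized label determines its parent uniquely
    path <- Reduce(
      function(parent, r) paste0(parent, ".", sample(1:2, 1)),
      1:5, accumulate = TRUE, init = paste0("T", sample(1:3, 1))
    )
    na_from <- sample(2:7, 1)
    if (na_from <= 6) path[na_from:6] <- "NA"
    propagate_na_labels(path)
  })
  names(lin) <- paste0("R", 1:40)
  for (r in 1:5) {
    parent <- rank_composition(names(lin), lin, ranks[r])
    child <- rank_composition(names(lin), lin, ranks[r + 1])
    for (lab in names(parent)) {
      kids <- vapply(lin, function(l) l[[r]] == lab, logical(1))
      child_labels <- unique(vapply(lin[kids], `[[`, character(1), r + 1))
      expect_equal(unname(parent[[lab]]),
        sum(child[child_labels]),
        tolerance = 1e-12
      )
    }
  }

  expect_error(
    rank_composition(c(bin$contigs, "ghost"), bin$lineages, "phylum"),
    "ghost"
  )
})

test_that("subset_bin keeps labels strictly above the threshold", {
  bin <- toy_bin()
  subs <- subset_bin(bin$contigs, bin$lineages, "phylum",
    min_fraction = 0.5
  )
  expect_length(subs, 1)
  expect_equal(subs[[1]]$label, "Proteobacteria")
  expect_setequal(subs[[1]]$contig_ids, bin$majority)
  expect_equal(subs[[1]]$fraction, 0.8)

  # 50/50 bin at threshold 0.5: strictly-greater keeps nothing
  lin5050 <- c(
    stats::setNames(rep(list(propagate_na_labels(
      c("A", "B", "C", "D", "E", "F")
    )), 5), paste0("x", 1:5)),
    stats::setNames(rep(list(propagate_na_labels(
      c("Q", "R", "S", "T", "U", "V")
    )), 5), paste0("y", 1:5))
  )
  expect_length(
    subset_bin(names(lin5050), lin5050, "phylum", min_fraction = 0.5), 0
  )

  # threshold 0: exhaustive partition of the bin
  subs0 <- subset_bin(bin$contigs, bin$lineages, "species",
    min_fraction = 0
  )
  all_ids <- unlist(lapply(subs0, `[[`, "contig_ids"))
  expect_setequal(all_ids, bin$contigs)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("raising min_fraction never adds or enlarges a subset", {
  set.seed(21)
  lin <- lapply(1:30, function(i) {
    propagate_na_labels(
      paste0("T", sample(1:3, 6, replace = TRUE), "_", 1:6)
    )
  })
  names(lin) <- paste0("R", 1:30)
  for (rank in names(taxonomy_ranks())) {
    prev <- NULL
    for (f in c(0, 0.2, 0.4, 0.6, 0.8)) {
      subs <- subset_bin(names(lin), lin, rank, min_fraction = f)
      labs <- vapply(subs, `[[`, character(1), "label")
      if (!is.null(prev)) {
        expect_true(all(labs %in% prev$labs))
        for (s in subs) {
          expect_setequal(
            s$contig_ids,
            prev$sets[[s$label]]
          )
        }
      }
      prev <- list(
        labs = labs,
        sets = stats::setNames(lapply(subs, `[[`, "contig_ids"), labs)
      )
    }
  }
})

test_that("refine_across_ranks writes per-rank FASTA subsets and a report", {
  bin <- toy_bin()
  contigs <- data.frame(
    contig_id = bin$contigs, length_bp = 8L,
    sequence = strrep("ACGT", 2), stringsAsFactors = FALSE
  )
  out_dir <- withr::local_tempdir()
  res <- refine_across_ranks(bin$contigs, bin$lineages,
    min_fraction = 0.5, bin_id = "bin7", contigs = contigs,
    out_dir = out_dir
  )
  expect_named(res, names(taxonomy_ranks()))
  report <- attr(res, "report")
  expect_equal(nrow(report), 6) # one majority subset per rank
  expect_true(all(file.exists(report$fasta)))
  expect_true(all(grepl("^bin7\\.[PCOFGS]\\.", basename(report$fasta))))
  back <- read_fasta(report$fasta[report$rank == "species"])
  expect_setequal(back$contig_id, bin$majority)

  # a pure bin yields the whole bin at every rank
  pure <- bin$lineages[bin$majority]
  res_pure <- refine_across_ranks(bin$majority, pure)
  for (rk in names(res_pure)) {
    expect_length(res_pure[[rk]], 1)
    expect_setequal(res_pure[[rk]][[1]]$contig_ids, bin$majority)
  }

  # three phyla at 0.4/0.35/0.25: nothing survives the default threshold
  mix <- c(
    stats::setNames(rep(list(propagate_na_labels(
      c("A", "c", "o", "f", "g", "s")
    )), 8), paste0("a", 1:8)),
    stats::setNames(rep(list(propagate_na_labels(
      c("B", "c", "o", "f", "g", "s")
    )), 7), paste0("b", 1:7)),
    stats::setNames(rep(list(propagate_na_labels(
      c("D", "c", "o", "f", "g", "s")
    )), 5), paste0("d", 1:5))
  )
  expect_length(
    subset_bin(names(mix), mix, "phylum", min_fraction = 0.5), 0
  )
})

test_that("refinement candidates rank by completeness minus weighted
          contamination", {
  q <- data.frame(
    subset = c("s1", "s2"),
    completeness = c(90, 95),
    contamination = c(4, 12),
    stringsAsFactors = FALSE
  )
  ranked <- score_refinement(q, weight = 5)
  expect_equal(ranked$subset, c("s1", "s2"))
  expect_equal(ranked$score, c(70, 35))

  expect_equal(score_refinement(q[1, ])$subset, "s1")

  ties <- data.frame(
    subset = c("b", "a"), completeness = c(80, 80),
    contamination = c(1, 1), stringsAsFactors = FALSE
  )
  expect_equal(score_refinement(ties)$subset, c("a", "b"))

  q$contamination[1] <- 101
  expect_error(score_refinement(q), "\\[0, 100\\]")
})
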