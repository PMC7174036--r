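test_that("KO weights average contig weights over gene hits", {
  d <- demo_module_fixture(w1 = 2, w2 = 4)
  kw <- ko_weights_in_mag(c("C1", "C2"), d$annotations, d$contig_weights)
  expect_equal(kw[["K1"]], mean(c(2, 4))) # K1 on both contigs
  expect_equal(kw[["K2"]], 2)
  expect_equal(kw[["K3"]], 4)
  expect_equal(kw[["K6"]], 4)
  expect_false("K4" %in% names(kw)) # absent KO -> no entry

  # two hits of one KO on the same contig: per-hit vs per-contig averaging
  ann <- data.frame(
    gene_id = c("C1_1", "C1_2", "C2_1"),
    contig_id = c("C1", "C1", "C2"),
    ko_id = c("K9", "K9", "K9"), stringsAsFactors = FALSE
  )
  w <- c(C1 = 3, C2 = 9)
  expect_equal(
    ko_weights_in_mag(c("C1", "C2"), ann, w)[["K9"]],
    (3 + 3 + 9) / 3
  )
  expect_equal(
    ko_weights_in_mag(c("C1", "C2"), ann, w,
      per_contig_hits = TRUE
    )[["K9"]],
    (3 + 9) / 2
  )

  # annotations outside the MAG are ignored
  expect_equal(ko_weights_in_mag("C1", ann, w)[["K9"]], 3)
})

test_that("module abundance sums present-KO weights over module size", {
  d <- demo_module_fixture(w1 = 2, w2 = 4)
  kw <- ko_weights_in_mag(c("C1", "C2"), d$annotations, d$contig_weights)
  expect_equal(module_abundance_in_mag(kw, d$modules$M1), 3.0)
  expect_equal(module_abundance_in_mag(kw, d$modules$M2), 1.0)
  expect_equal(module_abundance_in_mag(kw, c("K98", "K99")), 0)

  # saturation identity: every KO present once at common weight w -> w
  for (w in c(0.5, 2, 13)) {
    dd <- demo_module_fixture(w1 = w, w2 = w)
    kww <- ko_weights_in_mag(
      c("C1", "C2"), dd$annotations, dd$contig_weights
    )
    expect_equal(module_abundance_in_mag(kww, dd$modules$M1), w)
  }
  # w2 = 0 empties M2
  d0 <- demo_module_fixture(w1 = 2, w2 = 0)
  kw0 <- ko_weights_in_mag(c("C1", "C2"), d0$annotations, d0$contig_weights)
  expect_equal(module_abundance_in_mag(kw0, d0$modules$M2), 0)

  # bounds: 0 <= abundance <= max KO weight in the MAG
  set.seed(41)
  for (i in 1:20) {
    dw <- demo_module_fixture(w1 = runif(1, 0, 5), w2 = runif(1, 0, 5))
    kwi <- ko_weights_in_mag(
      c("C1", "C2"), dw$annotations, dw$contig_weights
    )
    for (mod in dw$modules) {
      a <- module_abundance_in_mag(kwi, mod)
      expect_gte(a, 0)
      expect_lte(a, max(kwi) + 1e-12)
    }
  }
})

test_that("weight policies collapse profiles over group sample sets", {
  profile <- c(AL1 = 9, PL1 = 1, PL2 = 2, PL3 = 3, PL4 = 4)
  pl <- paste0("PL", 1:4)
  expect_equal(
    weight_policy(profile, "PL_ALL", "AL1", pl, "group-mean"),
    2.5
  )
  expect_equal(weight_policy(profile, "PL_P2", "AL1", pl), 2)
  expect_equal(weight_policy(profile, "AL", "AL1", pl), 9)
  expect_equal(weight_policy(profile, "BO", "AL1", pl), mean(profile))
  expect_equal(
    weight_policy(profile, "PL_ALL", "AL1", pl, policy = "max"), 4
  )
  # PL_SUB averages the contig's supra-threshold PL samples
  expect_equal(
    weight_policy(profile, "PL_SUB", "AL1", pl, th = 2.5), 3.5
  )
})

test_that("group aggregation is additive over MAGs", {
  com <- simulate_community(sim_config(seed = 19))
  ass <- assign_groups(com$normalized, com$samples)

  # single MAG entirely in one group: group value equals the MAG value
  cid <- ass$contig_id[ass$primary == "BO"][1:2]
  membership <- stats::setNames(rep("solo", 2), cid)
  mab <- module_abundance_by_group(
    ass, membership, com$annotations, com$modules, com$normalized
  )
  w <- vapply(cid, function(cc) {
    weight_policy(
      com$normalized$values[cc, ], "BO", attr(ass, "al_sample"),
      attr(ass, "pl_samples")
    )
  }, numeric(1))
  kw <- ko_weights_in_mag(cid, com$annotations, w)
  for (mod in names(com$modules)) {
    expect_equal(
      mab[mod, "BO"],
      module_abundance_in_mag(kw, com$modules[[mod]])
    )
  }

  # two MAGs in a group: column is the sum of the per-MAG columns
  cid4 <- ass$contig_id[ass$primary == "BO"][1:4]
  both <- stats::setNames(c("m1", "m1", "m2", "m2"), cid4)
  m12 <- module_abundance_by_group(
    ass, both, com$annotations, com$modules, com$normalized
  )
  a <- module_abundance_by_group(
    ass, both[1:2], com$annotations, com$modules, com$normalized
  )
  b <- module_abundance_by_group(
    ass, both[3:4], com$annotations, com$modules, com$normalized
  )
  expect_equal(m12[, "BO"], a[, "BO"] + b[, "BO"])
})

test_that("group-level module abundance matches a brute-force oracle", {
  cfg <- sim_config(
    seed = 101,
    group_design = c(
      AL = 10L, BO = 20L, LO = 8L, PL_SUB = 10L, PL_ALL = 10L,
      PL_P1 = 10L, PL_P2 = 10L, PL_P3 = 10L, PL_P4 = 10L, UN = 10L,
      KI = 10L, KD = 10L
    ),
    n_mags = 5L, n_modules = 20L
  )
  com <- simulate_community(cfg)
  ass <- assign_groups(com$normalized, com$samples)
  for (policy in c("group-mean", "max")) {
    for (scope in c("group", "whole-mag")) {
      got <- module_abundance_by_group(
        ass, com$membership, com$annotations, com$modules,
        com$normalized, policy = policy, scope = scope
      )
      want <- brute_module_abundance(
        ass, com$membership, com$annotations, com$modules,
        com$normalized, policy = policy, scope = scope
      )
      expect_equal(got[, colnames(want)], want, tolerance = 1e-9)
    }
  }
})

test_that("per-sample policy emits one column per group and sample", {
  com <- simulate_community(sim_config(seed = 55))
  ass <- assign_groups(com$normalized, com$samples)
  mab <- module_abundance_by_group(
    ass, com$membership, com$annotations, com$modules, com$normalized,
    policy = "per-sample"
  )
  expect_true(all(grepl("\\|", colnames(mab))))
  # the AL-group/AL-sample column equals the group-mean AL column,
  # because the AL group's sample set is the single AL sample
  mean_mab <- module_abundance_by_group(
    ass, com$membership, com$annotations, com$modules, com$normalized
  )
  expect_equal(mab[, "AL|AL1"], mean_mab[, "AL"])
})
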