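# Seed families and genomic precursor clusters.

test_that("seed extraction returns bases 2..k+1", {
  expect_identical(extract_seed("ACGUACGUACGU", 6), "CGUACG")
  expect_identical(extract_seed("AAAAAAAA", 7), "AAAAAAA")
  expect_error(extract_seed("ACGUACG", 7), class = "mirkit_too_short")
  expect_error(extract_seed("ACGUACGU", 8), class = "mirkit_bad_seed_length")
})

test_that("seed families equal a brute-force dictionary grouping", {
  ds <- cached_fixture()$ds
  m <- ds$tab$mature
  for (k in c(6L, 7L)) {
    want <- split(m$name[nchar(m$sequence) >= k + 1],
                  substr(m$sequence[nchar(m$sequence) >= k + 1], 2, k + 1))
    ms <- ds$tab$mature_seed_family[ds$tab$mature_seed_family$k == k, ]
    got <- split(ms$mature_name, ms$family_name)
    expect_identical(lapply(got, sort), lapply(want, sort))
    # partition law: every long-enough mature in exactly one family
    expect_identical(sort(ms$mature_name), sort(m$name[nchar(m$sequence) >= k + 1]))
    expect_false(anyDuplicated(ms$mature_name) > 0)
    # family sequences pairwise distinct, and every member matches its family
    fams <- ds$tab$seed_family[ds$tab$seed_family$k == k, ]
    expect_false(anyDuplicated(fams$sequence) > 0)
  }
  # the planted share group: first matures of sya-mir-1..3 share the 7mer seed
  seeds <- substr(m$sequence[match(sprintf("sya-miR-%d", 1:3), m$name)], 2, 8)
  expect_length(unique(seeds), 1L)
})

test_that("seed family derivation is idempotent and keyed by length", {
  ds <- fresh_dataset(derive = FALSE)
  build_seed_families(ds, 6); build_seed_families(ds, 7)
  snap <- dataset_fingerprint(ds)
  build_seed_families(ds, 7)  # rerun replaces, never duplicates
  expect_identical(dataset_fingerprint(ds), snap)
  # both groupings coexist, distinguished by sequence length
  expect_setequal(unique(nchar(ds$tab$seed_family$sequence)), c(6L, 7L))
  m1 <- get_entity(ds, "mature", "sya-miR-1")
  expect_length(traverse(m1, "seed_families"), 2L)
})

test_that("three-interval example clusters at gap <= 1000 on one strand", {
  ds <- toy_position_dataset(data.frame(
    xsome = "chr1", start = c(100, 900, 5000), end = c(180, 980, 5080),
    strand = "+"))
  build_precursor_clusters(ds, cluster_params(max_gap = 1000))
  cm <- cluster_members(ds)
  expect_length(cm, 1L)
  expect_identical(cm[[1]], c("syn-mir-1", "syn-mir-2"))
  expect_true(is.na(ds$tab$precursor$cluster_name[3]))

  nb <- neighborhood(ds, "syn-mir-1", 1000)
  expect_identical(vapply(nb, entity_id_of, ""), "syn-mir-2")
  expect_length(neighborhood(ds, "syn-mir-1", 0), 0L)
  all_nb <- neighborhood(ds, "syn-mir-1", 1e9)
  expect_identical(vapply(all_nb, entity_id_of, ""), c("syn-mir-2", "syn-mir-3"))
  expect_error(neighborhood(cached_fixture()$ds, "syc-mir-1", 1000),
               class = "mirkit_no_position")
})

test_that("strand requirement toggles adjacency", {
  pos <- data.frame(xsome = "chr1", start = c(100, 900), end = c(180, 980),
                    strand = c("+", "-"))
  ds <- toy_position_dataset(pos)
  build_precursor_clusters(ds, cluster_params(max_gap = 1000,
                                              same_strand_required = TRUE))
  expect_length(cluster_members(ds), 0L)
  build_precursor_clusters(ds, cluster_params(max_gap = 1000,
                                              same_strand_required = FALSE))
  expect_length(cluster_members(ds), 1L)
})

test_that("cluster memberships equal the brute-force transitive closure", {
  for (trial_seed in c(11L, 12L, 13L)) {
    set.seed(trial_seed)
    for (same_strand in c(TRUE, FALSE)) {
      pos <- random_positions(60, n_xsome = 3, span = 60000)
      ds <- toy_from_positions(pos)
      build_precursor_clusters(ds, cluster_params(max_gap = 2000,
                                                  same_strand_required = same_strand))
      got <- unname(cluster_members(ds))
      pos2 <- ds$tab$genome_position
      pos2$precursor_name <- pos2$precursor_name
      want <- brute_force_clusters(pos2, max_gap = 2000,
                                   same_strand_required = same_strand)
      expect_identical(got[order(vapply(got, `[[`, "", 1))],
                       want[order(vapply(want, `[[`, "", 1))],
                       label = sprintf("seed %d strand %s", trial_seed, same_strand))
    }
  }
})

test_that("the cluster partition coarsens monotonically in max_gap", {
  set.seed(99)
  pos <- random_positions(80, n_xsome = 2, span = 40000)
  ds <- toy_from_positions(pos)
  assignment <- function(gap) {
    build_precursor_clusters(ds, cluster_params(max_gap = gap))
    p <- ds$tab$precursor
    stats::setNames(p$cluster_name, p$name)
  }
  gaps <- c(0, 200, 1000, 5000, 20000)
  prev <- NULL
  for (g in gaps) {
    cur <- assignment(g)
    if (!is.null(prev)) {
      # co-members at the smaller gap stay co-members at the larger one
      nms <- names(cur)
      for (cl in unique(prev[!is.na(prev)])) {
        members <- nms[!is.na(prev) & prev == cl]
        expect_length(unique(cur[members]), 1L)
        expect_false(anyNA(cur[members]))
      }
    }
    prev <- cur
  }
})

test_that("fixture clusters split exactly at the planted threshold", {
  fx <- cached_fixture()
  want <- fx$gen$manifest$clusters$members
  got <- cluster_members(fx$ds)
  expect_identical(lapply(got, unname),
                   lapply(want, function(x) sort(unlist(x), method = "radix"))[names(got)])
  expect_setequal(names(got), names(want))
  # the max_gap gap joins, max_gap + 1 splits (species 1 ladder)
  expect_identical(got[["sya-cluster-chr1-1"]],
                   c("sya-mir-1", "sya-mir-2", "sya-mir-3"))
  expect_identical(got[["sya-cluster-chr1-2"]], c("sya-mir-4", "sya-mir-5"))
})

test_that("multi-locus precursors and per-species chromosomes are respected", {
  fx <- cached_fixture()
  gp <- fx$ds$tab$genome_position
  # the planted second locus exists
  expect_equal(sum(gp$precursor_name == "sya-mir-1"), 2L)
  # same chromosome label in two species never co-clusters
  p <- fx$ds$tab$precursor
  for (cl in unique(stats::na.omit(p$cluster_name))) {
    expect_length(unique(p$species_abbreviation[!is.na(p$cluster_name) &
                                                  p$cluster_name == cl]), 1L)
  }
})

test_that("rederiving clusters is idempotent and deterministic", {
  ds <- fresh_dataset()
  f1 <- dataset_fingerprint(ds)
  build_precursor_clusters(ds, cluster_params())
  expect_identical(dataset_fingerprint(ds), f1)
})
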