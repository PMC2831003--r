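# The relational core: identifier lookup, listing, association traversal,
# and runtime integrity checking.

test_that("entities are retrievable by canonical identifier, case-sensitively", {
  ds <- cached_fixture()$ds

  p <- get_entity(ds, "precursor", "sya-mir-1")
  expect_s3_class(p, "mir_entity")
  expect_equal(p$name, "sya-mir-1")
  expect_match(p$accession, "^MI\\d+$")

  # precursor and mature naming differ only by case and kind namespace
  m <- get_entity(ds, "mature", "sya-miR-1")
  expect_false(identical(m$accession, p$accession))
  expect_match(m$accession, "^MIMAT\\d+$")
  expect_error(get_entity(ds, "mature", "sya-mir-1"), class = "mirkit_not_found")
  expect_error(get_entity(ds, "precursor", "no-such-name"),
               class = "mirkit_not_found")
  expect_error(get_entity(ds, "unicorn", "x"), class = "mirkit_invalid_kind")

  # identifier bijection over every kind
  for (kind in names(ds$kinds)) {
    for (e in list_entities(ds, kind)) {
      id <- e[[ds$kinds[[kind]]$id_field]]
      expect_identical(get_entity(ds, kind, id)[[ds$kinds[[kind]]$id_field]], id)
    }
  }
})

test_that("listing is ordered, filterable and sliceable", {
  ds <- cached_fixture()$ds
  sp <- list_entities(ds, "species")
  expect_length(sp, 3L)
  ids <- vapply(sp, function(e) e$abbreviation, "")
  expect_identical(ids, sort(ids, method = "radix"))

  # filter equals a linear scan of the manifest
  man <- cached_fixture()$gen$manifest
  got <- vapply(list_entities(ds, "precursor", filter = list(species_abbreviation = "syb")),
                function(e) e$name, "")
  want <- sort(man$precursors$name[man$precursors$species == "syb"],
               method = "radix")
  expect_identical(got, want)

  # predicate filters work too
  long <- list_entities(ds, "mature",
                        filter = function(e) nchar(e$sequence) >= 23)
  expect_true(all(vapply(long, function(e) nchar(e$sequence) >= 23, logical(1))))

  expect_length(list_entities(ds, "precursor", window = c(0, 0)), 0L)
  expect_length(list_entities(ds, "precursor", window = c(0, 4)), 4L)
  # two identical calls return identical orderings
  expect_identical(vapply(list_entities(ds, "mature"), entity_id_of, ""),
                   vapply(list_entities(ds, "mature"), entity_id_of, ""))
})

test_that("associations traverse in both directions and respect cardinality", {
  ds <- cached_fixture()$ds
  p <- get_entity(ds, "precursor", "sya-mir-1")

  sp <- traverse(p, "species")
  expect_equal(sp$abbreviation, "sya")
  mats <- traverse(p, "matures")
  expect_true("sya-miR-1" %in% vapply(mats, entity_id_of, ""))
  # star strand lives under the same hairpin
  star_hosts <- vapply(traverse(get_entity(ds, "mature", "sya-miR-1*"),
                                "precursors"), entity_id_of, "")
  expect_true("sya-mir-1" %in% star_hosts)

  expect_error(traverse(p, "bogus"), class = "mirkit_unknown_association")
  expect_error(traverse(p, "bogus"), regexp = "matures")

  # a mature's papers are the deduplicated union over its precursors
  shared <- get_entity(ds, "mature", "sya-miR-4")  # carried by two hairpins
  pres <- traverse(shared, "precursors")
  expect_length(pres, 2L)
  union_meds <- sort(unique(unlist(lapply(pres, function(pp)
    vapply(traverse(pp, "papers"), entity_id_of, "")))), method = "radix")
  got_meds <- vapply(traverse(shared, "papers"), entity_id_of, "")
  expect_identical(got_meds, union_meds)
})

test_that("association membership is symmetric across declared inverse pairs", {
  ds <- cached_fixture()$ds
  inverses <- list(
    c("precursor", "matures", "precursors"),
    c("precursor", "papers", "precursors"),
    c("precursor", "genome_positions", "precursor"),
    c("precursor", "genome_contexts", "precursor"),
    c("species", "precursors", "species"),
    c("mature", "seed_families", "matures"),
    c("precursor_family", "precursors", "precursor_family"),
    c("precursor_cluster", "precursors", "precursor_cluster"))
  for (iv in inverses) {
    for (a in list_entities(ds, iv[[1]])) {
      linked <- traverse(a, iv[[2]])
      if (is.null(linked)) next
      if (inherits(linked, "mir_entity")) linked <- list(linked)
      for (b in linked) {
        back <- traverse(b, iv[[3]])
        back_ids <- if (inherits(back, "mir_entity")) entity_id_of(back)
                    else vapply(back, entity_id_of, "")
        expect_true(entity_id_of(a) %in% back_ids,
                    label = sprintf("%s in %s.%s of %s", entity_id_of(a),
                                    iv[[1]], iv[[3]], entity_id_of(b)))
      }
    }
  }
})

test_that("mature sequences are substrings of all linked hairpins", {
  ds <- cached_fixture()$ds
  for (m in list_entities(ds, "mature")) {
    for (p in traverse(m, "precursors")) {
      expect_true(grepl(m$sequence, p$sequence, fixed = TRUE),
                  label = sprintf("%s within %s", m$name, p$name))
    }
  }
})

test_that("validate_dataset reports constructed violations and nothing else", {
  ds <- fresh_dataset()
  expect_identical(nrow(validate_dataset(ds)), 0L)

  # corrupt a mature so it is no longer a substring of its hairpin
  i <- match("sya-miR-2", ds$tab$mature$name)
  ds$tab$mature$sequence[i] <- strrep("A", 22)
  rep1 <- validate_dataset(ds)
  expect_true(any(rep1$rule == "substring_law" & rep1$identifier == "sya-miR-2"))

  # duplicate precursor accession
  ds2 <- fresh_dataset()
  ds2$tab$precursor$accession[2] <- ds2$tab$precursor$accession[1]
  rep2 <- validate_dataset(ds2)
  expect_true(any(rep2$rule == "unique_identifier"))

  # an orphan genome position
  ds3 <- fresh_dataset()
  ds3$tab$genome_position$precursor_name[1] <- "ghost-mir-1"
  expect_true(any(validate_dataset(ds3)$rule == "orphan_position"))
})

test_that("datasets survive a save/load round trip", {
  ds <- cached_fixture()$ds
  path <- tempfile(fileext = ".rds")
  dataset_save(ds, path)
  ds2 <- dataset_load(path)
  expect_identical(dataset_fingerprint(ds2), dataset_fingerprint(ds))
  expect_identical(ds2$release_version, ds$release_version)
})
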