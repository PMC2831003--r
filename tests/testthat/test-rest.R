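# The resource layer: routing, representations, negotiation, read-only.

test_that("canonical URL paths follow the member/collection/nested scheme", {
  ds <- cached_fixture()$ds
  p <- get_entity(ds, "precursor", "sya-mir-1")
  expect_identical(route_for(p), "/precursors/sya-mir-1")
  expect_identical(route_for("precursor", dataset = ds), "/precursors")
  sp <- get_entity(ds, "species", "sya")
  expect_identical(route_for("precursors", nested_under = sp),
                   "/species/sya/precursors")
  m <- get_entity(ds, "mature", "sya-miR-1")
  expect_identical(route_for("papers", nested_under = m),
                   "/matures/sya-miR-1/papers")
  # star-strand names keep their literal '*'
  star <- get_entity(ds, "mature", "sya-miR-1*")
  expect_identical(route_for(star), "/matures/sya-miR-1*")
  expect_error(route_for("unicorns", dataset = ds),
               class = "mirkit_unregistered_kind")
})

test_that("every entity's canonical URL resolves to it in XML (bijection)", {
  ds <- cached_fixture()$ds
  seen <- character()
  for (kind in names(ds$kinds)) {
    info <- ds$kinds[[kind]]
    for (e in list_entities(ds, kind)) {
      url <- route_for(e)
      expect_false(url %in% seen)
      seen <- c(seen, url)
      resp <- resolve(ds, "GET", paste0(url, ".xml"))
      expect_equal(resp$status, 200L)
      doc <- xml2::read_xml(resp$body)
      expect_identical(xml2::xml_name(doc), kind)
      got_id <- xml2::xml_text(xml2::xml_find_first(doc, info$id_field))
      expect_identical(got_id, entity_id_of(e))
    }
  }
})

test_that("XML documents parse back to the exact model attributes", {
  ds <- cached_fixture()$ds
  for (kind in names(ds$kinds)) {
    attrs <- ds$kinds[[kind]]$attributes
    for (e in list_entities(ds, kind)) {
      doc <- xml2::read_xml(render_xml(e))
      for (a in attrs) {
        v <- e[[a]]
        v <- if (is.null(v) || is.na(v)) "" else as.character(v)
        expect_identical(xml2::xml_text(xml2::xml_find_first(doc, a)), v,
                         label = sprintf("%s/%s.%s", kind, entity_id_of(e), a))
      }
      # associations are links, not embedded objects
      links <- xml2::xml_find_all(doc, "link")
      expect_true(all(nzchar(xml2::xml_attr(links, "href"))))
    }
  }
  # collections: plural root with count
  col <- xml2::read_xml(render_xml(list_entities(ds, "species")))
  expect_identical(xml2::xml_name(col), "species")
  expect_identical(xml2::xml_attr(col, "count"), "3")
  empty <- xml2::read_xml(render_xml(list(), kind = "paper", dataset = ds))
  expect_identical(xml2::xml_attr(empty, "count"), "0")
  expect_length(xml2::xml_children(empty), 0L)
})

test_that("resolution covers member, collection, nested and error paths", {
  ds <- cached_fixture()$ds
  # member document carries the model's comment verbatim
  resp <- resolve(ds, "GET", "/precursors/sya-mir-1.xml")
  expect_equal(resp$status, 200L)
  expect_equal(resp$media_type, "application/xml")
  doc <- xml2::read_xml(resp$body)
  expect_identical(xml2::xml_text(xml2::xml_find_first(doc, "comment")),
                   get_entity(ds, "precursor", "sya-mir-1")$comment)

  # cardinality-one association returns a member document
  one <- resolve(ds, "GET", "/precursors/sya-mir-1/species.xml")
  expect_identical(xml2::xml_name(xml2::read_xml(one$body)), "species")

  expect_equal(resolve(ds, "GET", "/precursors/no-such.xml")$status, 404L)
  expect_equal(resolve(ds, "GET", "/unicorns")$status, 404L)
  expect_equal(resolve(ds, "GET", "/precursors/sya-mir-1/unknown.xml")$status, 404L)
  expect_equal(resolve(ds, "POST", "/precursors/sya-mir-1")$status, 405L)
  expect_equal(resolve(ds, "DELETE", "/precursors/sya-mir-1")$status, 405L)
  # FASTA of a sequence-free kind is not acceptable
  expect_equal(resolve(ds, "GET", "/seed_families.fasta")$status, 406L)
  expect_equal(resolve(ds, "GET", "/papers/90000001.fasta")$status, 406L)
})

test_that("format negotiation prefers the suffix over the fallback", {
  ds <- cached_fixture()$ds
  conflict <- resolve(ds, "GET", "/precursors/sya-mir-1.xml", format = "fasta")
  expect_equal(conflict$media_type, "application/xml")
  fallback <- resolve(ds, "GET", "/precursors/sya-mir-1", format = "fasta")
  expect_equal(fallback$media_type, "text/plain")
  expect_match(fallback$body, "^>sya-mir-1 ")
  default <- resolve(ds, "GET", "/precursors/sya-mir-1")
  expect_equal(default$media_type, "text/html")
  json <- resolve(ds, "GET", "/precursors/sya-mir-1.json")
  expect_equal(json$status, 200L)
  expect_identical(jsonlite::fromJSON(json$body)$name, "sya-mir-1")
})

test_that("species mature FASTA matches the species' mature count and parses", {
  ds <- cached_fixture()$ds
  resp <- resolve(ds, "GET", "/species/syb/matures.fasta")
  expect_equal(resp$status, 200L)
  tmp <- tempfile(fileext = ".fa")
  writeLines(sub("\n$", "", resp$body), tmp)
  fa <- Biostrings::readBStringSet(tmp)   # a standard FASTA reader
  want <- traverse(get_entity(ds, "species", "syb"), "matures")
  expect_length(fa, length(want))
  keys <- vapply(strsplit(names(fa), "\\s+"), `[[`, "", 1)
  expect_setequal(keys, vapply(want, entity_id_of, ""))
  expect_identical(unname(as.character(fa)),
                   vapply(want, function(m) m$sequence, "")[match(keys, vapply(want, entity_id_of, ""))])
})

test_that("pagination concatenates back to the full listing", {
  ds <- cached_fixture()$ds
  full <- xml2::read_xml(resolve(ds, "GET", "/matures.xml?per_page=all")$body)
  full_ids <- xml2::xml_text(xml2::xml_find_all(full, "mature/name"))
  paged <- character()
  page <- 1L
  repeat {
    resp <- resolve(ds, "GET", sprintf("/matures.xml?page=%d&per_page=7", page))
    ids <- xml2::xml_text(xml2::xml_find_all(xml2::read_xml(resp$body),
                                             "mature/name"))
    if (length(ids) == 0L) break
    paged <- c(paged, ids)
    page <- page + 1L
  }
  expect_identical(paged, full_ids)
  # default page size bounds a collection response
  dflt <- xml2::read_xml(resolve(ds, "GET", "/matures.xml")$body)
  expect_lte(length(xml2::xml_find_all(dflt, "mature")), 100L)
})

test_that("the dataset fingerprint is unchanged by any GET sequence", {
  ds <- fresh_dataset()
  before <- dataset_fingerprint(ds)
  for (path in crawl_paths(ds)) {
    for (fmt in c("", ".xml", ".fasta", ".json")) {
      resolve(ds, "GET", paste0(path, fmt))
    }
  }
  resolve(ds, "GET", "/described_routes.txt")
  expect_identical(dataset_fingerprint(ds), before)
})

test_that("described_routes lists exactly the routable templates", {
  ds <- cached_fixture()$ds
  txt <- described_routes(ds, "txt")
  expect_match(txt, "/precursors ", fixed = TRUE)
  expect_match(txt, "/precursors/{id}", fixed = TRUE)
  expect_match(txt, "/precursors/{id}/matures", fixed = TRUE)

  listed <- regmatches(txt, gregexpr("/[^ \\[]+", txt))[[1]]
  rt <- routes_table(ds)
  expect_setequal(listed, rt$path_template)

  # the XML variant agrees with the text variant
  doc <- xml2::read_xml(described_routes(ds, "xml"))
  xml_paths <- xml2::xml_attr(xml2::xml_find_all(doc, "route"), "path")
  expect_setequal(xml_paths, listed)

  # every template resolves for at least one fixture entity
  for (i in seq_len(nrow(rt))) {
    template <- rt$path_template[i]
    parts <- strsplit(sub("^/", "", template), "/")[[1]]
    kind <- mirkit:::kind_for_plural(ds, parts[[1]])
    ents <- list_entities(ds, kind)
    if (length(parts) == 1L) {
      expect_equal(resolve(ds, "GET", template)$status, 200L)
    } else if (length(ents)) {
      ok <- FALSE
      for (e in ents) {
        path <- sub("{id}", mirkit:::encode_segment(entity_id_of(e)),
                    template, fixed = TRUE)
        if (resolve(ds, "GET", paste0(path, ".xml"))$status == 200L) { ok <- TRUE; break }
      }
      expect_true(ok, label = sprintf("template %s resolves", template))
    }
  }

  # the route listing itself is resolvable
  expect_equal(resolve(ds, "GET", "/described_routes.txt")$status, 200L)
  expect_equal(resolve(ds, "GET", "/described_routes.xml")$status, 200L)
})

test_that("HTTP responses serialize with correct framing", {
  ds <- cached_fixture()$ds
  resp <- resolve(ds, "GET", "/precursors/sya-mir-1.xml")
  msg <- format_http_response(resp)
  expect_match(msg, "^HTTP/1.0 200 OK\r\n")
  expect_match(msg, "Content-Type: application/xml\r\n")
  len <- as.integer(sub(".*Content-Length: (\\d+).*", "\\1", msg))
  expect_identical(len, nchar(resp$body, type = "bytes"))
})
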