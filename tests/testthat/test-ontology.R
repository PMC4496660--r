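wx <- worked_example()
ont <- wx$ontology

test_that("OWL/XML subset loads with the expected edges", {
  path <- system.file("extdata", "fokb_snippet.owl", package = "foodont")
  g <- expect_no_warning(load_owlxml(path)) # implicit declarations, silent
  sub_keys <- paste(g$subclass$parent, g$subclass$child)
  expect_true(all(c("antioxidant ascorbic acid",
                    "ascorbic acid ascorbyl palmitate",
                    "ascorbic acid d-isoascorbic acid",
                    "ascorbic acid ester-c") %in% sub_keys))
  syn_keys <- paste(g$synonym$a, g$synonym$b)
  expect_setequal(syn_keys, c("ascorbic acid e300", "ascorbic acid c vitamin"))
  # non-synonym object properties and the class assertion land in properties
  expect_true("has deficiency disease" %in% g$properties$property)
  expect_true("class assertion" %in% g$properties$property)
  # referenced-but-undeclared IRIs are a validation error in strict mode
  expect_error(load_owlxml(path, implicit_declarations = FALSE),
               class = "foodont_validation")
  expect_error(load_owlxml(path, implicit_declarations = FALSE),
               "scurvy")
})

test_that("OWL documents with declarations only give isolated concepts", {
  tmp <- withr::local_tempfile(fileext = ".owl")
  writeLines(c('<?xml version="1.0"?>',
               '<Ontology xmlns="http://www.w3.org/2002/07/owl#">',
               '  <Declaration><Class IRI="#Water"/></Declaration>',
               '  <Declaration><NamedIndividual IRI="#E300"/></Declaration>',
               "</Ontology>"), tmp)
  g <- load_owlxml(tmp)
  expect_setequal(g$concepts$id, c("water", "e300"))
  expect_equal(nrow(g$subclass) + nrow(g$synonym) + nrow(g$group), 0)
})

test_that("unknown OWL elements warn and are skipped; bad XML errors", {
  tmp <- withr::local_tempfile(fileext = ".owl")
  writeLines(c('<?xml version="1.0"?>',
               '<Ontology xmlns="http://www.w3.org/2002/07/owl#">',
               '  <Declaration><Class IRI="#A"/></Declaration>',
               '  <DataPropertyAssertion><Thing IRI="#A"/></DataPropertyAssertion>',
               "</Ontology>"), tmp)
  expect_warning(g <- load_owlxml(tmp), class = "foodont_skipped_element")
  expect_equal(g$concepts$id, "a")
  bad <- withr::local_tempfile(fileext = ".owl")
  writeLines("<Ontology><unclosed", bad)
  expect_error(load_owlxml(bad))
})

test_that("OWL -> fixture -> fixture round trip preserves graph content", {
  path <- system.file("extdata", "fokb_snippet.owl", package = "foodont")
  g <- load_owlxml(path)
  fx <- withr::local_tempfile(fileext = ".yaml")
  save_fixture(g, fx)
  expect_same_graph(g, load_fixture(fx))
  # and the OWL writer round-trips too
  ox <- withr::local_tempfile(fileext = ".owl")
  write_owlxml(ont, ox)
  expect_same_graph(ont, load_owlxml(ox))
})

test_that("fixture loader reproduces the worked-example structure", {
  fx <- withr::local_tempfile(fileext = ".yaml")
  save_fixture(ont, fx)
  g <- load_fixture(fx)
  expect_length(direct_subclasses(g, "Ascorbic Acid"), 3)
  expect_length(direct_subclasses(g, "Algin"), 2)
  expect_length(setdiff(synonym_class(g, "Vitamin B3"), "vitamin b3"), 2)
  # schema violations carry a field path
  doc <- yaml::read_yaml(fx)
  doc$concepts[[1]]$id <- NULL
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, bad)
  expect_error(load_fixture(bad), "concepts\\[1\\]",
               class = "foodont_schema")
})

test_that("empty and duplicate concept lists behave per the invariants", {
  fx <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(concepts = list()), fx)
  g <- load_fixture(fx)
  expect_equal(nrow(g$concepts), 0)
  expect_error(food_ontology(c("Ascorbic Acid", "ascorbic_acid")),
               class = "foodont_validation")
  expect_error(
    food_ontology("A", subclass = rbind(c("A", "Missing"))),
    class = "foodont_validation")
})

test_that("resolve normalizes but does not cross synonym edges", {
  expect_equal(resolve(ont, "ascorbic acid"), "ascorbic acid")
  expect_equal(resolve(ont, "Ascorbic_Acid"), "ascorbic acid")
  expect_equal(resolve(ont, "E300"), "e300") # distinct, synonym-linked node
  expect_equal(resolve(ont, "Dehydroascorbic Acid"), "d-isoascorbic acid")
  err <- expect_error(resolve(ont, "Phytic acid"),
                      class = "foodont_not_found")
  expect_equal(err$term, "Phytic acid")
})

test_that("subclass cycles are rejected", {
  expect_error(
    food_ontology(c("A", "B"),
                  subclass = rbind(c("A", "B"), c("B", "A"))),
    class = "foodont_validation")
})

test_that("edge weights follow the 1/n rule with overrides taking precedence", {
  expect_equal(edge_weight(ont, "Ascorbic Acid", "D-Isoascorbic Acid"), 1 / 3)
  expect_equal(edge_weight(ont, "Antioxidant", "Ascorbic Acid"), 1) # only child
  expect_error(edge_weight(ont, "Ascorbic Acid", "Sodium Alginate"),
               class = "foodont_domain")

  g <- food_ontology(c("P", "A", "B", "C"),
                     subclass = rbind(c("P", "A"), c("P", "B"), c("P", "C")),
                     weight_overrides = data.frame(parent = "P", child = "A",
                                                   weight = 0.2))
  expect_equal(edge_weight(g, "P", "A"), 0.2) # override wins, unrenormalized
  expect_equal(edge_weight(g, "P", "B"), 1 / 3)
})

test_that("path weight and distance match the worked links", {
  expect_equal(path_weight(ont, "Ascorbic Acid", "D-Isoascorbic Acid"),
               list(weight = 1 / 3, distance = 1L))
  pw <- path_weight(ont, "D-Isoascorbic Acid", "Ascorbyl Palmitate")
  expect_equal(pw$weight, (1 / 3)^2)
  expect_equal(pw$distance, 2L)
  expect_equal(path_weight(ont, "Algin", "Algin"),
               list(weight = 1, distance = 0L))
  expect_equal(path_weight(ont, "Vitamin B3", "Niacin"),
               list(weight = 1, distance = 1L))
  expect_error(path_weight(ont, "Vitamin B3", "Folic Acid"),
               class = "foodont_not_connected")
})

test_that("path weight is traversal-symmetric and ties pick the max product", {
  pairs <- list(c("D-Isoascorbic Acid", "Ascorbyl Palmitate"),
                c("Ascorbic Acid", "Ester-C"),
                c("E300", "Ascorbate"))
  for (p in pairs) {
    expect_equal(path_weight(ont, p[1], p[2])$weight,
                 path_weight(ont, p[2], p[1])$weight)
  }
  # diamond: two 2-edge chains from X to Z; the heavier product must win
  g <- food_ontology(c("X", "A", "B", "Z", "A2", "B2", "B3"),
                     subclass = rbind(c("X", "A"), c("X", "B"),
                                      c("A", "Z"), c("B", "Z"),
                                      c("A", "A2"),
                                      c("B", "B2"), c("B", "B3")))
  # via A: (1/2)*(1/2) = 0.25; via B: (1/2)*(1/3) ~ 0.167
  expect_equal(path_weight(g, "X", "Z"), list(weight = 0.25, distance = 2L))
})

test_that("per-parent default child weights are 1/n and sum to one", {
  for (seed in 1:5) {
    g <- random_ontology(generator_params(seed = seed))
    for (p in unique(g$subclass$parent)) {
      kids <- direct_subclasses(g, p)
      w <- vapply(kids, function(k) edge_weight(g, p, k), numeric(1))
      expect_equal(unname(w), rep(1 / length(kids), length(kids)))
      expect_equal(sum(w), 1)
    }
  }
})

test_that("path weight agrees with exhaustive chain enumeration", {
  set.seed(42)
  for (seed in 1:8) {
    g <- random_ontology(generator_params(depth = 2, branching = c(1, 3),
                                          seed = seed))
    ids <- g$concepts$id
    expect_lte(length(ids), 40)
    for (i in 1:10) {
      ab <- sample(ids, 2)
      ref <- oracle_path(g, ab[1], ab[2])
      if (is.null(ref)) {
        expect_error(path_weight(g, ab[1], ab[2]),
                     class = "foodont_not_connected")
      } else {
        expect_equal(path_weight(g, ab[1], ab[2]),
                     ref, tolerance = 1e-12)
      }
    }
  }
})
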