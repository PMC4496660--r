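wx <- worked_example()
ont <- wx$ontology
exm <- match_config(direction = "example")
dfm <- match_config(direction = "definition")

test_that("relation classification reproduces the worked link algebra", {
  r <- classify_relation(ont, "Vitamin B3", "Niacin", exm)
  expect_equal(r[c("relation", "d_weight", "distance")],
               list(relation = "Exact", d_weight = 1, distance = 1L))

  r <- classify_relation(ont, "D-Isoascorbic Acid", "Ascorbic Acid", exm)
  expect_equal(r$relation, "Subsume")
  expect_equal(r$d_weight, 1 / 3, tolerance = 1e-9)
  expect_equal(r$distance, 1L)

  r <- classify_relation(ont, "Algin", "Sodium Alginate", exm)
  expect_equal(r$relation, "Plugin")
  expect_equal(r$d_weight, 0.5)
  expect_equal(r$distance, 1L)

  # sibling pair: two links through the common parent
  r <- classify_relation(ont, "D-Isoascorbic Acid", "Ascorbyl Palmitate", exm)
  expect_equal(r$relation, "Subsume")
  expect_equal(r$d_weight, (1 / 3)^2, tolerance = 1e-9)
  expect_equal(r$distance, 2L)

  r <- classify_relation(ont, "Algin", "Alginic Acid", exm)
  expect_equal(r$relation, "Exact")

  r <- classify_relation(ont, "Vitamin C", "Folic Acid", exm)
  expect_equal(r[c("relation", "degree", "d_weight")],
               list(relation = "Dissimilar", degree = 0, d_weight = 0))
  expect_true(is.na(r$distance))

  expect_error(classify_relation(ont, "Phytic acid", "Vitamin C", exm),
               class = "foodont_not_found")
})

test_that("definition mode swaps only Plugin/Subsume across the hierarchy", {
  # consumer subclass of product concept: Plugin under the prose definitions
  r <- classify_relation(ont, "Dehydroascorbic Acid", "Ascorbic Acid", dfm)
  expect_equal(r$relation, "Plugin")
  expect_equal(r$degree * r$d_weight / r$distance, 0.250, tolerance = 1e-3)

  for (pair in list(c("vitamin b3", "niacin"), c("vitamin c", "folic acid"),
                    c("d-isoascorbic acid", "ascorbyl palmitate"))) {
    a <- classify_relation(ont, pair[1], pair[2], exm)
    b <- classify_relation(ont, pair[1], pair[2], dfm)
    expect_equal(a$relation, b$relation) # Exact/Dissimilar/sibling unchanged
  }
  swap <- function(x) c(Plugin = "Subsume", Subsume = "Plugin")[[x]]
  for (pair in list(c("algin", "sodium alginate"),
                    c("d-isoascorbic acid", "ascorbic acid"),
                    c("e300", "ascorbate"))) {
    a <- classify_relation(ont, pair[1], pair[2], exm)
    b <- classify_relation(ont, pair[1], pair[2], dfm)
    expect_equal(b$relation, swap(a$relation))
    expect_equal(a$d_weight, b$d_weight)
  }
})

test_that("degree ordering Dissimilar < Subsume < Plugin < Exact holds", {
  expect_equal(relation_degree(c("Dissimilar", "Subsume", "Plugin", "Exact")),
               c(0, 0.5, 0.75, 1))
  set.seed(7)
  g <- random_ontology(generator_params(seed = 3))
  ids <- g$concepts$id
  for (i in 1:25) {
    ab <- sample(ids, 2)
    r <- classify_relation(g, ab[1], ab[2])
    expect_equal(r$degree, unname(relation_degree(r$relation)))
    expect_gte(r$d_weight, 0)
    expect_lte(r$d_weight, 1)
  }
})

test_that("pair terms divide the weighted degree by the distance", {
  expect_lt(abs(pair_term("Plugin", 1 / 3, 1) - 0.250), 1e-3)
  expect_lt(abs(pair_term("Subsume", 1 / 3, 1) - 0.1665), 1e-3)
  expect_equal(pair_term("Dissimilar", 0, NA_integer_), 0)
  expect_equal(pair_term("Exact", 1, 0), 1) # identical concepts cap at 1
})

test_that("greedy matching picks the max degree then removes both concepts", {
  # abstract three-by-three scenario: C1 has Plugin with P1 and Exact with
  # P2, C2 Subsume with P1 and Exact with P3, C3 Plugin with P1
  g <- food_ontology(
    c("P1", "C1", "C1s", "C2", "C2s", "C3", "X1", "X2"),
    subclass = rbind(c("C1", "P1"), c("C3", "P1"), c("C1", "X1"),
                     c("C3", "X2"), c("P1", "C2")),
    synonym = rbind(c("C1", "C1s"), c("C2", "C2s")))
  pairs <- greedy_match(g, c("C1", "C2", "C3"), c("P1", "C1s", "C2s"))
  expect_equal(pairs$p_concept, c("c1s", "c2s", "p1"))
  expect_equal(pairs$relation, c("Exact", "Exact", "Plugin"))

  # worked product P1: Subsume + Plugin + one Dissimilar leftover pair
  pairs <- greedy_match(ont, wx$consumer$intolerances,
                        wx$products$P1$ingredients, exm)
  expect_equal(pairs$relation, c("Subsume", "Plugin", "Dissimilar"))
  expect_equal(pairs$p_concept,
               c("ascorbic acid", "sodium alginate", "folic acid"))
})

test_that("size mismatches are padded with null partners", {
  pairs <- greedy_match(ont, character(0), c("Niacin", "Algin"))
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$relation == "Dissimilar"))
  expect_true(all(is.na(pairs$c_concept)))

  pairs <- greedy_match(ont, c("Vitamin B3", "Algin", "Folic Acid"), "Niacin")
  expect_equal(nrow(pairs), 3)
  expect_equal(sum(pairs$relation == "Exact"), 1)
  expect_equal(sum(is.na(pairs$p_concept)), 2)
})

test_that("matching is a partial injection on both lists", {
  for (seed in 1:10) {
    g <- random_ontology(generator_params(seed = seed))
    set.seed(seed + 100)
    C <- sample(g$concepts$id, min(5, nrow(g$concepts)))
    P <- sample(g$concepts$id, min(6, nrow(g$concepts)))
    pairs <- greedy_match(g, C, P)
    expect_equal(nrow(pairs), max(length(C), length(P)))
    expect_false(any(duplicated(stats::na.omit(pairs$c_concept))))
    expect_false(any(duplicated(stats::na.omit(pairs$p_concept))))
  }
})

test_that("the modified Jaro value follows the degree sums", {
  expect_equal(jaro(1.25, 3, 3), 0.4167, tolerance = 1e-4)
  expect_equal(jaro(0, 3, 5), 0)
  expect_equal(jaro(3, 3, 3), 1)
  expect_error(jaro(1, 0, 3), class = "foodont_undefined")
  # symmetry collapse: equal list sizes give d_j = m/n
  for (n in 1:5) expect_equal(jaro(n * 0.5, n, n), 0.5)
})

test_that("the Winkler adjustment scales toward 1 and clamps", {
  expect_equal(winkler(0.4167, 2, 0.1), 0.53336, tolerance = 1e-4)
  expect_equal(winkler(0.75, 3, 0.1), 0.825)
  expect_equal(winkler(1, 7, 0.1), 1)
  expect_equal(winkler(0.5, 20, 0.1), 1) # l*k > 1 clamps
})

test_that("intolerance scores and percentages match the worked products", {
  r1 <- evaluate_product(ont, wx$consumer, wx$products$P1, exm)
  expect_equal(r1$score, 1.015, tolerance = 2e-3)
  expect_equal(r1$percentage, 33L)

  r2 <- evaluate_product(ont, wx$consumer, wx$products$P2, exm)
  expect_equal(r2$m, 2.25)
  expect_equal(r2$l, 3L)
  expect_equal(r2$d_j, 0.75)
  expect_equal(r2$d_w, 0.825)
  expect_equal(r2$score, 1.7, tolerance = 2e-3)
  expect_equal(r2$percentage, 56L)

  # all pairs Dissimilar: the m = 0 branch absorbs the division singularity
  pairs <- greedy_match(ont, "Vitamin B3", "Folic Acid")
  expect_equal(intolerance_score(pairs, 0, 1, 1), 0)
})

test_that("percentage floors and clamps", {
  expect_equal(intolerance_percentage(1.0156, 3), 33L)
  expect_equal(intolerance_percentage(1.7003, 3), 56L)
  expect_equal(intolerance_percentage(0, 5), 0L)
  expect_equal(intolerance_percentage(12, 3), 100L)
})

test_that("evaluate_product composes the stages consistently", {
  r2 <- evaluate_product(ont, wx$consumer, wx$products$P2, exm)
  expect_equal(r2$m, sum(r2$pairs$degree))
  expect_equal(r2$l, sum(r2$pairs$relation != "Dissimilar"))
  expect_equal(r2$d_j, jaro(r2$m, r2$n_C, r2$n_P))
  expect_equal(r2$d_w, winkler(r2$d_j, r2$l, 0.1))
  expect_equal(r2$verdict$color, "RED") # the Exact niacin pair

  disjoint <- list(ean = "0", ingredients = "Folic Acid")
  r0 <- evaluate_product(ont, wx$consumer, disjoint, exm)
  expect_equal(r0$score, 0)
  expect_equal(r0$percentage, 0L)
  expect_equal(r0$verdict$color, "GREEN")

  empty_consumer <- list(intolerances = "Unobtainium")
  expect_error(
    suppressWarnings(evaluate_product(ont, empty_consumer, disjoint, exm)),
    class = "foodont_empty_list")
})

test_that("an all-Exact product saturates the score and goes RED", {
  terms <- c("Vitamin B3", "Algin", "Ascorbic Acid")
  consumer <- list(intolerances = terms, pre_enhanced = TRUE)
  product <- list(ean = "1", ingredients = terms)
  r <- evaluate_product(ont, consumer, product, exm)
  expect_equal(r$m, 3)
  expect_equal(r$d_j, 1)
  expect_equal(r$d_w, 1)
  expect_equal(r$score, 3)
  expect_equal(r$percentage, 100L)
  expect_equal(r$verdict$color, "RED")
})
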