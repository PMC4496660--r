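# Packaged worked-example data and a seeded synthetic generator, plus the
# brute-force matching oracle used by the property tests.

#' Packaged worked example: ontology, consumer and two products
#'
#' A small vitamin/additive ontology: Ascorbic Acid (synonyms E300,
#' Vitamin C, L-Ascorbic Acid; member of the Ascorbate group; direct
#' subclasses Ester-C, Ascorbyl Palmitate and D-Isoascorbic Acid, the last
#' also labelled Erythorbic Acid / Dehydroascorbic Acid), Algin (synonym
#' Alginic Acid; direct subclasses Calcium Alginate and Sodium Alginate),
#' Vitamin B3 (synonyms Niacin, Niacinamide) and an unrelated Folic Acid.
#' The consumer's (already enhanced) intolerance list is
#' D-Isoascorbic Acid, Algin, Vitamin B3.
#'
#' @param variant `"eq13"` (default): product P2 carries Sodium Alginate as
#'   its third ingredient, the list the quantitative worked results score.
#'   `"table11"`: P2 carries Alginic Acid instead (the literal printed
#'   ingredient table); being a synonym of Algin it matches Exact rather
#'   than Plugin.
#' @return list with `ontology` (a [food_ontology]), `consumer` (profile
#'   list) and `products` (list of product lists `P1`, `P2`).
#' @export
#' @examples
#' wx <- worked_example()
#' evaluate_product(wx$ontology, wx$consumer, wx$products$P1)$percentage
worked_example <- function(variant = c("eq13", "table11")) {
  variant <- match.arg(variant)
  concepts <- data.frame(
    label = c("Food Additive", "Antioxidant",
              "Ascorbic Acid", "E300", "Vitamin C", "L-Ascorbic Acid",
              "Ascorbate",
              "Ester-C", "Ascorbyl Palmitate", "D-Isoascorbic Acid",
              "Algin", "Alginic Acid", "Calcium Alginate", "Sodium Alginate",
              "Vitamin B3", "Niacin", "Niacinamide",
              "Folic Acid"),
    kind = c("class", "class",
             "class", "individual", "individual", "individual",
             "class",
             "class", "class", "class",
             "class", "individual", "class", "class",
             "class", "individual", "individual",
             "class"),
    stringsAsFactors = FALSE)
  concepts$aliases <- vector("list", nrow(concepts))
  concepts$aliases[[9]] <- list("Vitamin C Ester")
  concepts$aliases[[10]] <- list("Erythorbic Acid", "Dehydroascorbic Acid")

  ontology <- food_ontology(
    concepts = concepts,
    subclass = rbind(
      c("Food Additive", "Antioxidant"),
      c("Antioxidant", "Ascorbic Acid"),
      c("Ascorbic Acid", "Ester-C"),
      c("Ascorbic Acid", "Ascorbyl Palmitate"),
      c("Ascorbic Acid", "D-Isoascorbic Acid"),
      c("Algin", "Calcium Alginate"),
      c("Algin", "Sodium Alginate")),
    synonym = rbind(
      c("Ascorbic Acid", "E300"),
      c("Ascorbic Acid", "Vitamin C"),
      c("Ascorbic Acid", "L-Ascorbic Acid"),
      c("Algin", "Alginic Acid"),
      c("Vitamin B3", "Niacin"),
      c("Vitamin B3", "Niacinamide")),
    group = rbind(c("Ascorbic Acid", "Ascorbate")),
    annotations = list(
      "ascorbic acid" = list(rda = "90.0 mg", solubility = "water",
                             deficiency_disease = "scurvy"),
      "vitamin b3" = list(rda = "16.0 mg", solubility = "water",
                          deficiency_disease = "pellagra")))

  consumer <- list(
    id = "consumer-1",
    allergies = list("Lactose Allergy"),
    intolerances = c("D-Isoascorbic Acid", "Algin", "Vitamin B3"),
    pre_enhanced = TRUE,
    bmi = 26, bmr = 1500,
    blood_pressure = list(high = 125, low = 82),
    activity = 5)

  p2_third <- if (variant == "eq13") "Sodium Alginate" else "Alginic Acid"
  products <- list(
    P1 = list(ean = "8690000000017",
              ingredients = c("Sodium Alginate", "Ascorbic Acid",
                              "Folic Acid")),
    P2 = list(ean = "8690000000024",
              ingredients = c("Ascorbyl Palmitate", "Niacin", p2_third)))

  list(ontology = ontology, consumer = consumer, products = products)
}

#' Packaged allergen-rule example
#'
#' The aluminium-silicate lactose-risk scenario: an ontology fragment with
#' Aluminium Silicate (synonym Kaolin) and its three subclasses Sodium,
#' Potassium and Calcium Aluminium Silicate (E554, E555, E556), a fact base
#' for one consumer holding one product, and the lactose risk rule.
#'
#' @return list with `ontology`, `facts` (a [fact_base()]) and `rule` (a
#'   parsed `swrl_rule`).
#' @export
allergen_example <- function() {
  concepts <- data.frame(
    label = c("Aluminium Silicate", "Kaolin",
              "Sodium Aluminium Silicate", "E554",
              "Potassium Aluminium Silicate", "E555",
              "Calcium Aluminium Silicate", "E556",
              "Lactose Allergy"),
    kind = c("class", "individual", "class", "individual", "class",
             "individual", "class", "individual", "class"),
    stringsAsFactors = FALSE)
  ontology <- food_ontology(
    concepts = concepts,
    subclass = rbind(
      c("Aluminium Silicate", "Sodium Aluminium Silicate"),
      c("Aluminium Silicate", "Potassium Aluminium Silicate"),
      c("Aluminium Silicate", "Calcium Aluminium Silicate")),
    synonym = rbind(
      c("Aluminium Silicate", "Kaolin"),
      c("Sodium Aluminium Silicate", "E554"),
      c("Potassium Aluminium Silicate", "E555"),
      c("Calcium Aluminium Silicate", "E556")))
  facts <- fact_base(
    predicate = c("Consumer", "Has_Allergy", "Has_Ean_No",
                  "Has_Product_Additives_Name"),
    arg1 = c("c1", "c1", "c1", "p1"),
    arg2 = c(NA, "Lactose_Allergy", "p1", "Aluminium_Silicate"))
  rule <- parse_rule(paste(
    "Consumer(?c), Has_Allergy(?c, Lactose_Allergy), Has_Ean_No(?c, ?p),",
    "Has_Product_Additives_Name(?p, Aluminium_Silicate)",
    "-> HAS_LACTOSE_RISK(?c, Aluminium_Silicate)"))
  list(ontology = ontology, facts = facts, rule = rule)
}

#' Parameters for the synthetic generator
#'
#' @param depth number of hierarchy layers below the roots.
#' @param branching integer range (length-2) of children per node.
#' @param synonym_rate probability a node receives a synonym individual.
#' @param group_rate probability a node receives a hasGroup edge.
#' @param n_roots number of root concepts (independent trees).
#' @param n_products number of products [random_products()] draws.
#' @param ingredients_per_product integer range of ingredients per product.
#' @param seed integer seed; fully determines the output.
#' @return a `generator_params` list.
#' @export
generator_params <- function(depth = 3L, branching = c(1L, 3L),
                             synonym_rate = 0.3, group_rate = 0.1,
                             n_roots = 2L, n_products = 5L,
                             ingredients_per_product = c(2L, 5L),
                             seed = 1L) {
  stopifnot(depth >= 1, length(branching) == 2, branching[1] >= 1,
            branching[2] >= branching[1],
            synonym_rate >= 0, synonym_rate <= 1,
            group_rate >= 0, group_rate <= 1, n_roots >= 1)
  structure(list(depth = as.integer(depth), branching = as.integer(branching),
                 synonym_rate = synonym_rate, group_rate = group_rate,
                 n_roots = as.integer(n_roots),
                 n_products = as.integer(n_products),
                 ingredients_per_product = as.integer(ingredients_per_product),
                 seed = as.integer(seed)),
            class = "generator_params")
}

with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a random layered ontology
#'
#' Builds a layered subclass forest (acyclic by construction) with synonym
#' individuals and group edges added at the configured rates. The seed fully
#' determines the result.
#'
#' @param params a [generator_params()].
#' @return a [food_ontology].
#' @export
random_ontology <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, function() {
    labels <- character(); kinds <- character()
    subclass <- NULL; synonym <- NULL; group <- NULL
    counter <- 0L
    new_name <- function(prefix) {
      counter <<- counter + 1L
      sprintf("%s%03d", prefix, counter)
    }
    n_groups <- 0L
    add_node <- function(label) {
      labels <<- c(labels, label); kinds <<- c(kinds, "class")
      if (runif(1) < params$synonym_rate) {
        syn <- paste0(label, " Syn")
        labels <<- c(labels, syn); kinds <<- c(kinds, "individual")
        synonym <<- rbind(synonym, c(label, syn))
      }
      if (runif(1) < params$group_rate) {
        n_groups <<- n_groups + 1L
        gname <- sprintf("Group %02d", n_groups)
        if (!gname %in% labels) {
          labels <<- c(labels, gname); kinds <<- c(kinds, "class")
        }
        group <<- rbind(group, c(label, gname))
      }
    }
    layer <- character()
    for (r in seq_len(params$n_roots)) {
      nm <- new_name("Root ")
      add_node(nm)
      layer <- c(layer, nm)
    }
    for (d in seq_len(params$depth)) {
      nxt <- character()
      for (parent in layer) {
        k <- sample(params$branching[1]:params$branching[2], 1)
        for (i in seq_len(k)) {
          nm <- new_name("Node ")
          add_node(nm)
          subclass <- rbind(subclass, c(parent, nm))
          nxt <- c(nxt, nm)
        }
      }
      layer <- nxt
    }
    food_ontology(
      concepts = data.frame(label = labels, kind = kinds,
                            stringsAsFactors = FALSE),
      subclass = subclass, synonym = synonym, group = group)
  })
}

#' Draw random products / a random profile from an ontology
#'
#' @param graph a [food_ontology].
#' @param params a [generator_params()]; `seed` is offset so products differ
#'   from the graph draw but stay reproducible.
#' @return `random_products`: list of product lists; `random_profile`: a
#'   profile list with 1-3 intolerance terms.
#' @export
random_products <- function(graph, params = generator_params()) {
  with_seed(params$seed + 1000L, function() {
    lapply(seq_len(params$n_products), function(i) {
      k <- sample(params$ingredients_per_product[1]:
                    params$ingredients_per_product[2], 1)
      list(ean = sprintf("869%010d", i),
           ingredients = sample(graph$concepts$label,
                                min(k, nrow(graph$concepts))))
    })
  })
}

#' @rdname random_products
#' @export
random_profile <- function(graph, params = generator_params()) {
  with_seed(params$seed + 2000L, function() {
    k <- sample(1:3, 1)
    list(id = sprintf("synthetic-consumer-%d", params$seed),
         intolerances = sample(graph$concepts$label,
                               min(k, nrow(graph$concepts))),
         pre_enhanced = FALSE)
  })
}

#' Reference matching oracle
#'
#' Independent re-derivation of the greedy sequential matching used to
#' cross-check [greedy_match()]: walks the consumer list in order,
#' brute-forces every remaining candidate's classification, asserts that the
#' selected pair's degree is maximal among them, and applies the documented
#' tie-breaks (larger contribution term, then lowest product index).
#'
#' @param graph a [food_ontology].
#' @param C,P character vectors of concept terms (at most 8 each).
#' @param config a [match_config].
#' @return data.frame shaped like the [greedy_match()] result.
#' @export
oracle_match <- function(graph, C, P, config = match_config()) {
  if (inherits(C, "enhanced_list")) C <- C$concepts
  stopifnot(length(C) <= 8, length(P) <= 8)
  C <- vapply(C, function(t) resolve(graph, t), character(1),
              USE.NAMES = FALSE)
  P <- vapply(P, function(t) resolve(graph, t), character(1),
              USE.NAMES = FALSE)
  rows <- list()
  remaining <- P
  for (ci in C) {
    if (!length(remaining)) {
      rows[[length(rows) + 1]] <- list(ci, NA_character_, "Dissimilar",
                                       0, 0, NA_integer_, 0)
      next
    }
    info <- lapply(remaining, function(pj)
      classify_relation(graph, ci, pj, config))
    degs <- vapply(info, `[[`, numeric(1), "degree")
    trms <- vapply(info, function(x)
      pair_term(x$relation, x$d_weight, x$distance), numeric(1))
    pick <- order(-degs, -trms, seq_along(remaining))[1]
    # exhaustive per-step maximality check: the pick dominates every
    # remaining alternative on degree
    stopifnot(all(degs[pick] >= degs))
    cls <- info[[pick]]
    rows[[length(rows) + 1]] <- list(ci, remaining[pick], cls$relation,
                                     cls$degree, cls$d_weight, cls$distance,
                                     trms[pick])
    remaining <- remaining[-pick]
  }
  for (pj in remaining) {
    rows[[length(rows) + 1]] <- list(NA_character_, pj, "Dissimilar",
                                     0, 0, NA_integer_, 0)
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(c_concept = r[[1]], p_concept = r[[2]], relation = r[[3]],
               degree = r[[4]], d_weight = r[[5]], distance = r[[6]],
               term = r[[7]], stringsAsFactors = FALSE)))
  if (is.null(out)) {
    out <- data.frame(c_concept = character(), p_concept = character(),
                      relation = character(), degree = numeric(),
                      d_weight = numeric(), distance = integer(),
                      term = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
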