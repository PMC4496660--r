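# Stage 2 of the concept matching engine: per-pair relation classification,
# greedy sequential max matching, the modified Jaro-Winkler factor and the
# aggregate intolerance score.

RELATION_DEGREES <- c(Dissimilar = 0, Subsume = 0.5, Plugin = 0.75, Exact = 1)

#' Degree of a match relation
#'
#' The four degrees of match are fixed: Exact = 1, Plugin = 0.75,
#' Subsume = 0.5, Dissimilar = 0, ordered
#' Dissimilar < Subsume < Plugin < Exact.
#'
#' @param relation character vector of relation names.
#' @return numeric degree(s).
#' @export
relation_degree <- function(relation) {
  unname(RELATION_DEGREES[match.arg(relation, names(RELATION_DEGREES),
                                    several.ok = TRUE)])
}

#' Matching configuration
#'
#' @param winkler_k scaling constant of the Winkler adjustment; Winkler's
#'   standard value 0.1.
#' @param direction convention for assigning Plugin vs Subsume across the
#'   hierarchy. `"example"` (default): a consumer concept that is a strict
#'   ancestor (or group) of the product concept is Plugin and a strict
#'   descendant is Subsume, the convention the quantitative worked results
#'   use. `"definition"` swaps the two, matching the prose set-inclusion
#'   definitions (consumer subclass-of product is Plugin). Sibling pairs
#'   (related only through a common ancestor) are Subsume in both modes.
#' @param enhance_relations relation kinds used by [enhance()] inside
#'   [evaluate_product()].
#' @param enhance_hops group/is-a expansion depth for [enhance()].
#' @return an object of class `match_config`.
#' @export
match_config <- function(winkler_k = 0.1,
                         direction = c("example", "definition"),
                         enhance_relations = c("synonym", "group"),
                         enhance_hops = 1L) {
  stopifnot(winkler_k >= 0)
  structure(list(winkler_k = winkler_k,
                 direction = match.arg(direction),
                 enhance_relations = enhance_relations,
                 enhance_hops = enhance_hops),
            class = "match_config")
}

#' Classify the match relation between a consumer and a product concept
#'
#' Exact if the two concepts are identical (weight 1, distance 0) or synonym
#' equivalent (weight 1, distance 1). Otherwise the subsumption hierarchy
#' decides: under the `"example"` convention a consumer concept strictly above
#' the product concept is Plugin, strictly below is Subsume, and related only
#' through a common ancestor is Subsume; the `"definition"` convention swaps
#' Plugin/Subsume on the ancestor/descendant cases. Unrelated concepts are
#' Dissimilar with weight 0 and no distance.
#'
#' @param graph a [food_ontology].
#' @param c_term consumer-side term (an element of the enhanced list C).
#' @param p_term product-side term.
#' @param config a [match_config].
#' @return list with `relation`, `degree`, `d_weight`, `distance`
#'   (`NA_integer_` for Dissimilar).
#' @export
#' @examples
#' wx <- worked_example()
#' classify_relation(wx$ontology, "Vitamin B3", "Niacin")
classify_relation <- function(graph, c_term, p_term,
                              config = match_config()) {
  rel <- hierarchy_relation(graph, c_term, p_term)
  if (rel == "same") {
    ia <- resolve(graph, c_term)
    iz <- resolve(graph, p_term)
    d <- if (ia == iz) 0L else 1L
    return(list(relation = "Exact", degree = 1, d_weight = 1, distance = d))
  }
  if (rel == "unrelated") {
    return(list(relation = "Dissimilar", degree = 0, d_weight = 0,
                distance = NA_integer_))
  }
  pw <- path_weight(graph, c_term, p_term)
  name <- switch(rel,
    ancestor   = if (config$direction == "example") "Plugin" else "Subsume",
    descendant = if (config$direction == "example") "Subsume" else "Plugin",
    connected  = "Subsume")
  list(relation = name, degree = unname(RELATION_DEGREES[name]),
       d_weight = pw$weight, distance = pw$distance)
}

#' Contribution term of one matched pair
#'
#' `degree * d_weight / distance`; Dissimilar pairs contribute 0. Identical
#' concepts carry distance 0, in which case the divisor is taken as 1 so the
#' pair contributes its full degree (contributions are capped at 1).
#'
#' @param relation relation name.
#' @param d_weight path weight of the pair.
#' @param distance edge count of the connecting chain.
#' @return contribution in [0, 1].
#' @export
pair_term <- function(relation, d_weight, distance) {
  if (relation == "Dissimilar") return(0)
  stopifnot(is.na(distance) == FALSE)
  unname(RELATION_DEGREES[relation]) * d_weight / max(1, distance)
}

#' Greedy sequential matching of the lists C and P
#'
#' Iterates the consumer list in order; each consumer concept is classified
#' against every remaining product concept and the pair with the maximum
#' relation degree is taken (ties broken by larger contribution term, then by
#' lowest product index); both concepts are then removed. After the loop the
#' shorter side is padded with null partners (relation Dissimilar, term 0)
#' until both sides have `max(|C|, |P|)` entries.
#'
#' @param graph a [food_ontology].
#' @param C an [enhance()] result or character vector of consumer concept
#'   terms.
#' @param P character vector of product ingredient terms (must resolve).
#' @param config a [match_config].
#' @return data.frame with one row per (padded) pair: `c_concept`,
#'   `p_concept` (NA for padding), `relation`, `degree`, `d_weight`,
#'   `distance`, `term`.
#' @export
greedy_match <- function(graph, C, P, config = match_config()) {
  if (inherits(C, "enhanced_list")) C <- C$concepts
  C <- vapply(C, function(t) resolve(graph, t), character(1), USE.NAMES = FALSE)
  P <- vapply(P, function(t) resolve(graph, t), character(1), USE.NAMES = FALSE)

  empty_row <- function(c_id, p_id, cls) {
    data.frame(c_concept = c_id, p_concept = p_id,
               relation = cls$relation, degree = cls$degree,
               d_weight = cls$d_weight, distance = cls$distance,
               term = pair_term(cls$relation, cls$d_weight, cls$distance),
               stringsAsFactors = FALSE)
  }
  null_cls <- list(relation = "Dissimilar", degree = 0, d_weight = 0,
                   distance = NA_integer_)

  pairs <- NULL
  remaining <- P
  for (ci in C) {
    if (!length(remaining)) {
      pairs <- rbind(pairs, empty_row(ci, NA_character_, null_cls))
      next
    }
    cands <- lapply(remaining, function(pj)
      classify_relation(graph, ci, pj, config))
    degs <- vapply(cands, `[[`, numeric(1), "degree")
    terms <- vapply(cands, function(x)
      pair_term(x$relation, x$d_weight, x$distance), numeric(1))
    best <- which(degs == max(degs))
    if (length(best) > 1) best <- best[terms[best] == max(terms[best])]
    best <- best[1]
    pairs <- rbind(pairs, empty_row(ci, remaining[best], cands[[best]]))
    remaining <- remaining[-best]
  }
  for (pj in remaining) {
    pairs <- rbind(pairs, empty_row(NA_character_, pj, null_cls))
  }
  if (is.null(pairs)) {
    pairs <- empty_row(NA_character_, NA_character_, null_cls)[0, ]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Modified Jaro value for two concept lists
#'
#' `d_j = (m/n_C + m/n_P) / 2`, where `m` is the sum of the matched relation
#' degrees (#Exact*1 + #Plugin*0.75 + #Subsume*0.5).
#'
#' @param m summed match degrees.
#' @param n_C,n_P sizes of the lists C and P.
#' @return `d_j` in [0, 1].
#' @export
jaro <- function(m, n_C, n_P) {
  if (n_C < 1 || n_P < 1) {
    ont_stop("jaro is undefined for empty lists", "foodont_undefined")
  }
  (m / n_C + m / n_P) / 2
}

#' Winkler adjustment of the Jaro value
#'
#' `d_w = d_j + l * k * (1 - d_j)`, clamped to 1, where `l` is the number of
#' non-Dissimilar matched pairs and `k` the scaling constant (0.1 standard).
#'
#' @param d_j Jaro value.
#' @param l number of non-Dissimilar pairs.
#' @param k scaling constant.
#' @return `d_w` in [d_j, 1].
#' @export
winkler <- function(d_j, l, k = 0.1) {
  stopifnot(l >= 0, k >= 0)
  min(1, d_j + l * k * (1 - d_j))
}

#' Aggregate intolerance score
#'
#' The sum of the pair contribution terms divided by `(n_C / n_P) * d_w`.
#' When no pair matched (`m = 0`, hence `d_w = 0` with `l = 0`) the score is
#' defined as 0.
#'
#' @param pairs data.frame of pairs from [greedy_match()].
#' @param d_w Winkler value computed from the same pairs.
#' @param n_C,n_P sizes of the lists C and P.
#' @return score >= 0.
#' @export
intolerance_score <- function(pairs, d_w, n_C, n_P) {
  m <- sum(pairs$degree)
  if (m == 0) return(0)
  sum(pairs$term) / ((n_C / n_P) * d_w)
}

#' Integer intolerance percentage
#'
#' `floor(score * 100 / n_pairs)` clamped to [0, 100], where `n_pairs` is the
#' padded pair count `max(|C|, |P|)` (each pair can contribute at most 1, so
#' `n_pairs` is the maximum attainable score).
#'
#' @param score intolerance score.
#' @param n_pairs padded pair count.
#' @return integer in [0, 100].
#' @export
intolerance_percentage <- function(score, n_pairs) {
  stopifnot(n_pairs >= 1)
  as.integer(max(0, min(100, floor(score * 100 / n_pairs))))
}

#' Evaluate a product against a consumer profile
#'
#' Runs the full pipeline: semantic enhancement of the consumer's intolerance
#' terms (skipped when the profile is flagged `pre_enhanced`), greedy
#' matching against the product ingredient list, the modified Jaro-Winkler
#' factor, the intolerance score, the integer percentage, and the
#' traffic-light verdict.
#'
#' @param graph a [food_ontology].
#' @param consumer a consumer profile list (fields `intolerances`, optional
#'   `id`, `allergies`, `pre_enhanced`) or path to a profile file readable by
#'   [read_profile()].
#' @param product a product list (fields `ean`, `ingredients`) or path to a
#'   product file readable by [read_product()].
#' @param config a [match_config].
#' @return an object of class `match_result`: list with `pairs`, `m`, `l`,
#'   `n_C`, `n_P`, `n_pairs`, `d_j`, `d_w`, `score`, `percentage`, `verdict`,
#'   plus the enhanced list and product used.
#' @export
#' @examples
#' wx <- worked_example()
#' res <- evaluate_product(wx$ontology, wx$consumer, wx$products$P2)
#' res$percentage
evaluate_product <- function(graph, consumer, product,
                             config = match_config()) {
  if (is.character(consumer) && length(consumer) == 1) {
    consumer <- read_profile(consumer)
  }
  if (is.character(product) && length(product) == 1) {
    product <- read_product(product)
  }
  stopifnot(!is.null(consumer$intolerances), !is.null(product$ingredients))

  if (isTRUE(consumer$pre_enhanced)) {
    ids <- vapply(consumer$intolerances, function(t) resolve(graph, t),
                  character(1), USE.NAMES = FALSE)
    C <- structure(list(source_terms = consumer$intolerances, concepts = ids,
                        provenance = setNames(rep("seed", length(ids)), ids),
                        unresolved = character()),
                   class = "enhanced_list")
  } else {
    C <- enhance(graph, consumer$intolerances,
                 relations = config$enhance_relations,
                 hops = config$enhance_hops)
  }
  if (!length(C$concepts)) {
    ont_stop("enhanced consumer intolerance list is empty",
             "foodont_empty_list")
  }

  P <- character()
  unresolved_p <- character()
  for (t in product$ingredients) {
    id <- resolve(graph, t, quiet = TRUE)
    if (is.na(id)) unresolved_p <- c(unresolved_p, t) else P <- c(P, id)
  }
  if (length(unresolved_p)) {
    ont_warn(sprintf("unresolved product ingredient(s): %s",
                     paste(unresolved_p, collapse = ", ")),
             "foodont_unresolved_terms")
  }

  n_C <- length(C$concepts)
  n_P <- max(1L, length(P))
  pairs <- greedy_match(graph, C, P, config)
  m <- sum(pairs$degree)
  l <- sum(pairs$relation != "Dissimilar")
  d_j <- jaro(m, n_C, n_P)
  d_w <- winkler(d_j, l, config$winkler_k)
  score <- intolerance_score(pairs, d_w, n_C, n_P)
  n_pairs <- max(1L, nrow(pairs))
  pct <- intolerance_percentage(score, n_pairs)

  res <- structure(list(pairs = pairs, m = m, l = l, n_C = n_C, n_P = n_P,
                        n_pairs = n_pairs, d_j = d_j, d_w = d_w,
                        score = score, percentage = pct,
                        enhanced = C, product = product, config = config),
                   class = "match_result")
  res$verdict <- traffic_light(res)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: score %.4f, %d%%, verdict %s\n",
              if (!is.null(x$product$ean)) x$product$ean else "product",
              x$score, x$percentage, x$verdict$color))
  cat(sprintf("  m = %.3f, l = %d, d_j = %.4f, d_w = %.4f (n_C = %d, n_P = %d)\n",
              x$m, x$l, x$d_j, x$d_w, x$n_C, x$n_P))
  print(x$pairs[, c("c_concept", "p_concept", "relation", "term")])
  invisible(x)
}
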