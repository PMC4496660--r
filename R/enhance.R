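# Stage 1 of the concept matching engine: semantic enhancement of the raw
# consumer intolerance terms into the enhanced list C.

#' Semantically enhance a consumer intolerance term list
#'
#' Expands each resolvable term along the selected relation kinds: synonyms to
#' their full closure (the whole equivalence class), hasGroup targets and
#' direct is-a parents one hop each (depth configurable). Packaging labels are
#' noisy, so unresolvable terms are recorded with a warning rather than
#' failing; if no term resolves at all a condition of class
#' `foodont_empty_list` is signalled.
#'
#' The default relation set is `c("synonym", "group")`: synonym and group
#' links broaden a term to its equivalent and grouped forms (E-numbers, trade
#' names) without pulling in broad is-a ancestors such as entire additive
#' categories. Pass `relations = c("synonym", "group", "is_a")` to include
#' direct parents.
#'
#' @param graph a [food_ontology].
#' @param terms character vector of raw intolerance terms.
#' @param relations subset of `c("synonym", "group", "is_a")`.
#' @param hops expansion depth for group/is-a links (synonyms always close
#'   fully); default 1.
#' @return an object of class `enhanced_list`: list with `source_terms`,
#'   `concepts` (character vector of ids, duplicate-free, the list C),
#'   `provenance` (named character vector: relation that introduced each
#'   concept, `"seed"` for the terms themselves) and `unresolved`.
#' @export
#' @examples
#' wx <- worked_example()
#' enhance(wx$ontology, "Vitamin C")
enhance <- function(graph, terms,
                    relations = c("synonym", "group"),
                    hops = 1L) {
  stopifnot(inherits(graph, "food_ontology"), length(terms) >= 1)
  relations <- match.arg(relations, c("synonym", "group", "is_a"),
                         several.ok = TRUE)
  concepts <- character()
  provenance <- character()
  unresolved <- character()

  add <- function(ids, rel) {
    new <- setdiff(ids, concepts)
    if (length(new)) {
      concepts <<- c(concepts, new)
      provenance <<- c(provenance, setNames(rep(rel, length(new)), new))
    }
  }

  for (term in terms) {
    id <- resolve(graph, term, quiet = TRUE)
    if (is.na(id)) {
      unresolved <- c(unresolved, term)
      next
    }
    add(id, "seed")
    if ("synonym" %in% relations) {
      add(setdiff(synonym_class(graph, id), id), "synonym")
    }
    # group/is-a hops start from the whole synonym class: "Vitamin C" reaches
    # the Ascorbate group through its equivalent "Ascorbic Acid"
    frontier <- synonym_class(graph, id)
    for (h in seq_len(hops)) {
      nxt <- character()
      for (f in frontier) {
        par <- direct_parents(graph, f)
        if ("group" %in% relations && length(par$group)) {
          add(par$group, "group")
          nxt <- c(nxt, par$group)
        }
        if ("is_a" %in% relations && length(par$is_a)) {
          add(par$is_a, "is_a")
          nxt <- c(nxt, par$is_a)
        }
      }
      frontier <- unique(nxt)
      if (!length(frontier)) break
    }
  }

  if (length(unresolved)) {
    ont_warn(sprintf("unresolved intolerance term(s): %s",
                     paste(unresolved, collapse = ", ")),
             "foodont_unresolved_terms")
  }
  out <- structure(list(source_terms = as.character(terms),
                        concepts = concepts,
                        provenance = provenance,
                        unresolved = unresolved),
                   class = "enhanced_list")
  if (!length(concepts)) {
    # caller decides whether an empty C aborts the pipeline
    ont_warn("no intolerance term resolved; enhanced list is empty",
             "foodont_empty_list")
  }
  out
}

#' @export
print.enhanced_list <- function(x, ...) {
  cat(sprintf("<enhanced_list> %d seed term(s) -> %d concept(s)\n",
              length(x$source_terms), length(x$concepts)))
  if (length(x$concepts)) {
    cat(paste0("  ", x$concepts, " [", x$provenance[x$concepts], "]",
               collapse = "\n"), "\n")
  }
  if (length(x$unresolved)) {
    cat("  unresolved:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}
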