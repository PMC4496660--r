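# Food ontology graph: concepts plus typed edges (subclass, synonym, group,
# property assertions). Identifiers are normalized with normalize_term(); the
# first-seen display label is kept for reports. Synonym edges induce an
# equivalence partition; hierarchy traversal works on one node per synonym
# class so that e.g. "E300" sits at the same hierarchy position as
# "Ascorbic Acid".

#' Construct a food ontology graph
#'
#' Low-level constructor. Most users will read an ontology with
#' [load_fixture()] or [load_owlxml()] instead.
#'
#' @param concepts character vector of concept labels, or a data.frame with
#'   columns `label` and optionally `kind` ("class" or "individual") and
#'   `aliases` (list column of alternative labels).
#' @param subclass two-column data.frame or matrix of (parent, child) labels;
#'   direct subconcept edges.
#' @param synonym two-column data.frame or matrix of synonym pairs
#'   (undirected).
#' @param group two-column data.frame or matrix of (member, group) labels; a
#'   member-to-group edge is traversed like a subclass edge with the group as
#'   parent.
#' @param properties data.frame with columns `property`, `subject`, `object`:
#'   other object-property assertions, kept verbatim.
#' @param weight_overrides data.frame with columns `parent`, `child`,
#'   `weight`: developer-scored distance weights that take precedence over the
#'   1/n default for those edges.
#' @param annotations named list of per-concept annotation lists.
#'
#' @return an object of class `food_ontology`.
#' @export
food_ontology <- function(concepts = character(),
                          subclass = NULL,
                          synonym = NULL,
                          group = NULL,
                          properties = NULL,
                          weight_overrides = NULL,
                          annotations = list()) {
  if (is.data.frame(concepts)) {
    labels <- as.character(concepts$label)
    kind <- if ("kind" %in% names(concepts)) as.character(concepts$kind) else
      rep("class", length(labels))
    aliases <- if ("aliases" %in% names(concepts)) concepts$aliases else
      vector("list", length(labels))
  } else {
    labels <- as.character(concepts)
    kind <- rep("class", length(labels))
    aliases <- vector("list", length(labels))
  }
  ids <- normalize_term(labels)
  if (anyDuplicated(ids)) {
    ont_stop(sprintf("duplicate concept id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "foodont_validation")
  }
  cdf <- data.frame(id = ids, label = labels, kind = kind,
                    stringsAsFactors = FALSE)

  alias_df <- data.frame(alias = character(), id = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_along(aliases)) {
    if (length(aliases[[i]])) {
      alias_df <- rbind(alias_df, data.frame(
        alias = normalize_term(unlist(aliases[[i]])), id = ids[i],
        stringsAsFactors = FALSE))
    }
  }

  as_pairs <- function(x, nm) {
    if (is.null(x) || NROW(x) == 0) {
      return(setNames(data.frame(a = character(), b = character(),
                                 stringsAsFactors = FALSE), nm))
    }
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    out <- data.frame(a = normalize_term(x[[1]]), b = normalize_term(x[[2]]),
                      stringsAsFactors = FALSE)
    setNames(unique(out), nm)
  }
  sub_df <- as_pairs(subclass, c("parent", "child"))
  syn_df <- as_pairs(synonym, c("a", "b"))
  grp_df <- as_pairs(group, c("member", "group"))

  if (is.null(properties) || NROW(properties) == 0) {
    prop_df <- data.frame(property = character(), subject = character(),
                          object = character(), stringsAsFactors = FALSE)
  } else {
    properties <- as.data.frame(properties, stringsAsFactors = FALSE)
    prop_df <- data.frame(property = normalize_term(properties$property),
                          subject = normalize_term(properties$subject),
                          object = normalize_term(properties$object),
                          stringsAsFactors = FALSE)
  }

  if (is.null(weight_overrides) || NROW(weight_overrides) == 0) {
    wov <- data.frame(parent = character(), child = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  } else {
    weight_overrides <- as.data.frame(weight_overrides,
                                      stringsAsFactors = FALSE)
    wov <- data.frame(parent = normalize_term(weight_overrides$parent),
                      child = normalize_term(weight_overrides$child),
                      weight = as.numeric(weight_overrides$weight),
                      stringsAsFactors = FALSE)
    if (any(wov$weight <= 0 | wov$weight > 1)) {
      ont_stop("weight overrides must lie in (0, 1]", "foodont_validation")
    }
  }

  endpoints <- c(sub_df$parent, sub_df$child, syn_df$a, syn_df$b,
                 grp_df$member, grp_df$group)
  missing <- setdiff(unique(endpoints), cdf$id)
  if (length(missing)) {
    ont_stop(sprintf("edge endpoint(s) not declared as concepts: %s",
                     paste(missing, collapse = ", ")),
             "foodont_validation")
  }

  g <- structure(list(concepts = cdf, aliases = alias_df, subclass = sub_df,
                      synonym = syn_df, group = grp_df,
                      properties = prop_df, weight_overrides = wov,
                      annotations = annotations),
                 class = "food_ontology")
  g$index <- build_ont_index(g)
  g
}

# Collapses synonym classes to representative nodes and builds the directed
# hierarchy igraph (subclass parent->child, group group->member) with Eq.-style
# 1/n edge weights (overrides win). Also checks acyclicity.
build_ont_index <- function(g) {
  ids <- g$concepts$id
  rep_of <- setNames(ids, ids)
  if (nrow(g$synonym)) {
    sg <- igraph::graph_from_data_frame(g$synonym, directed = FALSE,
                                        vertices = data.frame(name = ids))
    comp <- igraph::components(sg)$membership
    for (m in unique(comp)) {
      members <- sort(names(comp)[comp == m])
      rep_of[members] <- members[1]
    }
  }

  # hierarchy edges at representative level
  he <- data.frame(parent = character(), child = character(),
                   type = character(), stringsAsFactors = FALSE)
  if (nrow(g$subclass)) {
    he <- rbind(he, data.frame(parent = unname(rep_of[g$subclass$parent]),
                               child = unname(rep_of[g$subclass$child]),
                               type = "subclass", stringsAsFactors = FALSE))
  }
  if (nrow(g$group)) {
    he <- rbind(he, data.frame(parent = unname(rep_of[g$group$group]),
                               child = unname(rep_of[g$group$member]),
                               type = "group", stringsAsFactors = FALSE))
  }
  he <- unique(he[he$parent != he$child, , drop = FALSE])

  # default weight: 1 / number of direct subconcepts of the parent (per edge
  # type); overrides, mapped to representative pairs, take precedence
  wt <- numeric(NROW(he))
  if (NROW(he)) {
    key <- paste(he$parent, he$type)
    nchild <- table(key)
    wt <- 1 / as.numeric(nchild[key])
    if (nrow(g$weight_overrides)) {
      ov <- g$weight_overrides
      ovp <- unname(rep_of[ov$parent])
      ovc <- unname(rep_of[ov$child])
      m <- match(paste(he$parent, he$child), paste(ovp, ovc))
      wt[!is.na(m)] <- ov$weight[m[!is.na(m)]]
    }
  }

  reps <- unique(unname(rep_of))
  hg <- igraph::graph_from_data_frame(
    if (NROW(he)) data.frame(from = he$parent, to = he$child) else
      data.frame(from = character(), to = character()),
    directed = TRUE, vertices = data.frame(name = reps))
  if (NROW(he)) {
    igraph::E(hg)$weight_factor <- wt
    igraph::E(hg)$type <- he$type
  }
  if (!igraph::is_acyclic(hg)) {
    ont_stop("subclass/group hierarchy contains a cycle", "foodont_validation")
  }
  list(rep_of = rep_of, hg = hg,
       hg_und = igraph::as_undirected(hg, mode = "each"))
}

#' @export
print.food_ontology <- function(x, ...) {
  cat(sprintf(
    "<food_ontology> %d concepts, %d subclass, %d synonym, %d group edges\n",
    nrow(x$concepts), nrow(x$subclass), nrow(x$synonym), nrow(x$group)))
  invisible(x)
}

#' Resolve a term to a concept
#'
#' Looks a term up by normalized identifier or alias. Lookup does not cross
#' synonym edges: `"E300"` resolves to the `E300` node, not to
#' `Ascorbic Acid` (synonym handling belongs to the matching engine).
#'
#' @param graph a [food_ontology].
#' @param term a single term.
#' @param quiet if `TRUE` return `NA_character_` instead of signalling when
#'   the term is unknown.
#' @return the concept id (normalized identifier).
#' @export
resolve <- function(graph, term, quiet = FALSE) {
  stopifnot(inherits(graph, "food_ontology"))
  id <- normalize_term(term)
  if (id %in% graph$concepts$id) return(id)
  hit <- match(id, graph$aliases$alias)
  if (!is.na(hit)) return(graph$aliases$id[hit])
  if (quiet) return(NA_character_)
  ont_stop(sprintf("concept not found: '%s'", term), "foodont_not_found",
           term = term)
}

#' @rdname resolve
#' @export
concept_label <- function(graph, term) {
  id <- resolve(graph, term)
  graph$concepts$label[match(id, graph$concepts$id)]
}

#' Synonym equivalence class of a concept
#'
#' @inheritParams resolve
#' @return character vector of concept ids sharing the term's synonym class
#'   (including the concept itself).
#' @export
synonym_class <- function(graph, term) {
  id <- resolve(graph, term)
  rep_of <- graph$index$rep_of
  sort(names(rep_of)[rep_of == rep_of[[id]]])
}

#' Direct subconcepts of a concept
#'
#' @inheritParams resolve
#' @param type `"subclass"` (default) or `"group"` (members of a group).
#' @return character vector of child concept ids.
#' @export
direct_subclasses <- function(graph, term, type = c("subclass", "group")) {
  type <- match.arg(type)
  id <- resolve(graph, term)
  if (type == "subclass") {
    sort(unique(graph$subclass$child[graph$subclass$parent == id]))
  } else {
    sort(unique(graph$group$member[graph$group$group == id]))
  }
}

#' Direct is-a parents / group targets of a concept
#'
#' @inheritParams resolve
#' @return list with elements `is_a` (direct superclass ids) and `group`
#'   (hasGroup target ids).
#' @export
direct_parents <- function(graph, term) {
  id <- resolve(graph, term)
  list(is_a = sort(unique(graph$subclass$parent[graph$subclass$child == id])),
       group = sort(unique(graph$group$group[graph$group$member == id])))
}

#' Distance weight of a direct subclass edge
#'
#' If the ontology developer supplied a weight override for the edge it is
#' returned; otherwise all direct subconcepts of a parent share the weight
#' `1 / (number of direct subconcepts)`.
#'
#' @inheritParams resolve
#' @param parent,child terms forming a direct subclass edge (parent above
#'   child).
#' @return the edge weight in (0, 1].
#' @export
#' @examples
#' wx <- worked_example()
#' edge_weight(wx$ontology, "Ascorbic Acid", "D-Isoascorbic Acid") # 1/3
edge_weight <- function(graph, parent, child) {
  p <- resolve(graph, parent)
  c_ <- resolve(graph, child)
  is_edge <- any(graph$subclass$parent == p & graph$subclass$child == c_)
  if (!is_edge) {
    ont_stop(sprintf("(%s, %s) is not a direct subclass edge", parent, child),
             "foodont_domain")
  }
  ov <- graph$weight_overrides
  hit <- which(ov$parent == p & ov$child == c_)
  if (length(hit)) return(ov$weight[hit[1]])
  1 / length(unique(graph$subclass$child[graph$subclass$parent == p]))
}

#' Path weight and distance between two concepts
#'
#' Traverses the subsumption hierarchy (subclass and group edges, undirected)
#' between the synonym classes of two concepts. The weight is the product of
#' edge weights along a minimum-edge-count connecting chain; among chains of
#' equal length the maximum weight product is chosen. Distance is the number
#' of hierarchy edges on that chain. Identical concepts give (1, 0); distinct
#' concepts in one synonym class give (1, 1).
#'
#' @inheritParams resolve
#' @param a,z terms for the two concepts.
#' @return list with elements `weight` and `distance`.
#' @export
#' @examples
#' wx <- worked_example()
#' path_weight(wx$ontology, "D-Isoascorbic Acid", "Ascorbyl Palmitate")
path_weight <- function(graph, a, z) {
  ia <- resolve(graph, a)
  iz <- resolve(graph, z)
  if (ia == iz) return(list(weight = 1, distance = 0L))
  rep_of <- graph$index$rep_of
  ra <- rep_of[[ia]]
  rz <- rep_of[[iz]]
  if (ra == rz) return(list(weight = 1, distance = 1L))
  hg_und <- graph$index$hg_und
  suppressWarnings(
    sp <- igraph::all_shortest_paths(hg_und, from = ra, to = rz,
                                     weights = NA))
  if (!length(sp$epaths)) {
    ont_stop(sprintf("no hierarchy chain connects '%s' and '%s'", a, z),
             "foodont_not_connected")
  }
  wf <- igraph::E(hg_und)$weight_factor
  prods <- vapply(sp$epaths, function(ep) prod(wf[as.integer(ep)]),
                  numeric(1))
  list(weight = max(prods), distance = length(sp$epaths[[1]]))
}

#' Hierarchy relationship between two synonym classes
#'
#' @inheritParams resolve
#' @param a,z terms for the two concepts.
#' @return one of `"same"` (one synonym class), `"ancestor"` (a strictly above
#'   z), `"descendant"` (a strictly below z), `"connected"` (related through
#'   the hierarchy but neither subsumes the other), or `"unrelated"`.
#' @export
hierarchy_relation <- function(graph, a, z) {
  ia <- resolve(graph, a)
  iz <- resolve(graph, z)
  rep_of <- graph$index$rep_of
  ra <- rep_of[[ia]]
  rz <- rep_of[[iz]]
  if (ra == rz) return("same")
  hg <- graph$index$hg
  d_out <- igraph::distances(hg, v = ra, to = rz, mode = "out", weights = NA)
  if (is.finite(d_out[1, 1])) return("ancestor")
  d_in <- igraph::distances(hg, v = ra, to = rz, mode = "in", weights = NA)
  if (is.finite(d_in[1, 1])) return("descendant")
  d_und <- igraph::distances(graph$index$hg_und, v = ra, to = rz, weights = NA)
  if (is.finite(d_und[1, 1])) return("connected")
  "unrelated"
}

#' All concepts semantically related to a term
#'
#' Every concept whose match degree against the term would be non-Dissimilar:
#' the full synonym class plus all concepts whose synonym class is connected
#' to it through the subsumption hierarchy.
#'
#' @inheritParams resolve
#' @return character vector of concept ids (the term's own id included).
#' @export
related_concepts <- function(graph, term) {
  id <- resolve(graph, term)
  rep_of <- graph$index$rep_of
  r <- rep_of[[id]]
  comp <- igraph::components(graph$index$hg_und)$membership
  reps_in_comp <- names(comp)[comp == comp[[r]]]
  sort(names(rep_of)[rep_of %in% reps_in_comp])
}
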