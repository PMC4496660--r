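# Readers and writers: structured YAML fixture format, the small OWL/XML
# dialect (Declaration, ClassAssertion, SubClassOf, ObjectPropertyAssertion),
# consumer profiles and product records.

#' Read an ontology from a structured fixture file
#'
#' The fixture format is YAML with top-level keys `concepts` (each entry
#' `id`, optional `kind`, `aliases`, `annotations`), `subclass_of`
#' (`parent`/`child` entries), `synonyms` (two-element lists), `groups`
#' (`member`/`group` entries), `properties`
#' (`property`/`subject`/`object` entries) and `weight_overrides`
#' (`parent`/`child`/`weight` entries). One file describes one ontology;
#' [save_fixture()] writes the same format, and the OWL and fixture loaders
#' produce equal graphs for equivalent content.
#'
#' @param path file path.
#' @return a [food_ontology].
#' @export
load_fixture <- function(path) {
  doc <- yaml::read_yaml(path)
  req <- function(entry, field, where) {
    if (is.null(entry[[field]])) {
      ont_stop(sprintf("fixture schema violation at %s: missing '%s'",
                       where, field), "foodont_schema")
    }
    entry[[field]]
  }
  concepts <- doc$concepts
  if (is.null(concepts)) concepts <- list()
  labels <- character(length(concepts))
  kinds <- character(length(concepts))
  aliases <- vector("list", length(concepts))
  annotations <- list()
  for (i in seq_along(concepts)) {
    where <- sprintf("concepts[%d]", i)
    labels[i] <- req(concepts[[i]], "id", where)
    kinds[i] <- if (is.null(concepts[[i]]$kind)) "class" else
      concepts[[i]]$kind
    if (!kinds[i] %in% c("class", "individual")) {
      ont_stop(sprintf("fixture schema violation at %s.kind: '%s'",
                       where, kinds[i]), "foodont_schema")
    }
    if (!is.null(concepts[[i]]$aliases)) {
      aliases[[i]] <- concepts[[i]]$aliases
    }
    if (!is.null(concepts[[i]]$annotations)) {
      annotations[[normalize_term(labels[i])]] <- concepts[[i]]$annotations
    }
  }
  pairs_of <- function(key, f1, f2) {
    entries <- doc[[key]]
    if (is.null(entries)) return(NULL)
    do.call(rbind, lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      where <- sprintf("%s[%d]", key, i)
      if (is.null(names(e))) {
        if (length(e) != 2) {
          ont_stop(sprintf("fixture schema violation at %s: need 2 terms",
                           where), "foodont_schema")
        }
        data.frame(a = e[[1]], b = e[[2]], stringsAsFactors = FALSE)
      } else {
        data.frame(a = req(e, f1, where), b = req(e, f2, where),
                   stringsAsFactors = FALSE)
      }
    }))
  }
  props <- if (is.null(doc$properties)) NULL else
    do.call(rbind, lapply(seq_along(doc$properties), function(i) {
      e <- doc$properties[[i]]
      where <- sprintf("properties[%d]", i)
      data.frame(property = req(e, "property", where),
                 subject = req(e, "subject", where),
                 object = req(e, "object", where), stringsAsFactors = FALSE)
    }))
  wov <- if (is.null(doc$weight_overrides)) NULL else
    do.call(rbind, lapply(seq_along(doc$weight_overrides), function(i) {
      e <- doc$weight_overrides[[i]]
      where <- sprintf("weight_overrides[%d]", i)
      data.frame(parent = req(e, "parent", where),
                 child = req(e, "child", where),
                 weight = as.numeric(req(e, "weight", where)),
                 stringsAsFactors = FALSE)
    }))
  food_ontology(
    concepts = data.frame(label = labels, kind = kinds,
                          aliases = I(aliases), stringsAsFactors = FALSE),
    subclass = pairs_of("subclass_of", "parent", "child"),
    synonym = pairs_of("synonyms", "a", "b"),
    group = pairs_of("groups", "member", "group"),
    properties = props,
    weight_overrides = wov,
    annotations = annotations)
}

#' Write an ontology to a structured fixture file
#'
#' @param graph a [food_ontology].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_fixture <- function(graph, path) {
  stopifnot(inherits(graph, "food_ontology"))
  cdf <- graph$concepts
  doc <- list(
    concepts = lapply(seq_len(nrow(cdf)), function(i) {
      entry <- list(id = cdf$label[i], kind = cdf$kind[i])
      al <- graph$aliases$alias[graph$aliases$id == cdf$id[i]]
      if (length(al)) entry$aliases <- as.list(al)
      ann <- graph$annotations[[cdf$id[i]]]
      if (!is.null(ann)) entry$annotations <- ann
      entry
    }))
  if (nrow(graph$subclass)) {
    doc$subclass_of <- lapply(seq_len(nrow(graph$subclass)), function(i)
      list(parent = graph$subclass$parent[i],
           child = graph$subclass$child[i]))
  }
  if (nrow(graph$synonym)) {
    doc$synonyms <- lapply(seq_len(nrow(graph$synonym)), function(i)
      list(graph$synonym$a[i], graph$synonym$b[i]))
  }
  if (nrow(graph$group)) {
    doc$groups <- lapply(seq_len(nrow(graph$group)), function(i)
      list(member = graph$group$member[i], group = graph$group$group[i]))
  }
  if (nrow(graph$properties)) {
    doc$properties <- lapply(seq_len(nrow(graph$properties)), function(i)
      list(property = graph$properties$property[i],
           subject = graph$properties$subject[i],
           object = graph$properties$object[i]))
  }
  if (nrow(graph$weight_overrides)) {
    doc$weight_overrides <- lapply(seq_len(nrow(graph$weight_overrides)),
                                   function(i)
      list(parent = graph$weight_overrides$parent[i],
           child = graph$weight_overrides$child[i],
           weight = graph$weight_overrides$weight[i]))
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read an ontology from the OWL/XML dialect
#'
#' Supports exactly the element kinds of the knowledge base's OWL 2.0
#' serialization subset: `Declaration` (of `Class` or `NamedIndividual`),
#' `ClassAssertion`, `SubClassOf` and `ObjectPropertyAssertion`. IRIs are
#' stripped of the leading `#` and normalized. `SubClassOf` (subclass first,
#' superclass second) becomes a subclass edge; `Has_Synonym` assertions
#' become synonym edges; `Has_Group` assertions become group edges; other
#' object property assertions (and class assertions) are kept as property
#' triples. Unknown element kinds are skipped with a warning.
#'
#' @param path file path.
#' @param implicit_declarations if `TRUE` (default) an IRI referenced by an
#'   axiom but never declared is added as a concept; if `FALSE` such a
#'   dangling reference is a validation error listing the IRI.
#' @return a [food_ontology].
#' @export
load_owlxml <- function(path, implicit_declarations = TRUE) {
  doc <- xml2::read_xml(path)
  iri_of <- function(node) sub("^#", "", xml2::xml_attr(node, "IRI"))

  labels <- character(); kinds <- character()
  sub_df <- NULL; syn_df <- NULL; grp_df <- NULL; prop_df <- NULL
  referenced <- character()
  declare <- function(label, kind) {
    id <- normalize_term(label)
    known <- normalize_term(labels)
    if (!id %in% known) {
      labels <<- c(labels, label)
      kinds <<- c(kinds, kind)
    }
  }

  for (node in xml2::xml_children(doc)) {
    kind <- xml2::xml_name(node)
    kids <- xml2::xml_children(node)
    if (kind == "Declaration") {
      entity <- kids[[1]]
      etype <- xml2::xml_name(entity)
      if (!etype %in% c("Class", "NamedIndividual")) {
        ont_warn(sprintf("skipping declaration of unknown entity kind '%s'",
                         etype), "foodont_skipped_element")
        next
      }
      declare(iri_of(entity),
              if (etype == "Class") "class" else "individual")
    } else if (kind == "SubClassOf") {
      sub <- iri_of(kids[[1]]); super <- iri_of(kids[[2]])
      referenced <- c(referenced, sub, super)
      sub_df <- rbind(sub_df, data.frame(parent = super, child = sub,
                                         stringsAsFactors = FALSE))
    } else if (kind == "ObjectPropertyAssertion") {
      prop <- iri_of(kids[[1]])
      s <- iri_of(kids[[2]]); o <- iri_of(kids[[3]])
      referenced <- c(referenced, s, o)
      np <- normalize_term(prop)
      if (np == "has synonym") {
        syn_df <- rbind(syn_df, data.frame(a = s, b = o,
                                           stringsAsFactors = FALSE))
      } else if (np == "has group") {
        grp_df <- rbind(grp_df, data.frame(member = s, group = o,
                                           stringsAsFactors = FALSE))
      } else {
        prop_df <- rbind(prop_df, data.frame(property = prop, subject = s,
                                             object = o,
                                             stringsAsFactors = FALSE))
      }
    } else if (kind == "ClassAssertion") {
      cls <- iri_of(kids[[1]]); ind <- iri_of(kids[[2]])
      referenced <- c(referenced, cls, ind)
      prop_df <- rbind(prop_df, data.frame(property = "Class_Assertion",
                                           subject = ind, object = cls,
                                           stringsAsFactors = FALSE))
    } else {
      ont_warn(sprintf("skipping unknown element kind '%s'", kind),
               "foodont_skipped_element")
    }
  }

  dangling <- setdiff(unique(normalize_term(referenced)),
                      normalize_term(labels))
  if (length(dangling)) {
    if (!implicit_declarations) {
      ont_stop(sprintf("dangling IRI reference(s): %s",
                       paste(dangling, collapse = ", ")),
               "foodont_validation")
    }
    for (lab in unique(referenced)) {
      declare(lab, "class")
    }
  }
  food_ontology(
    concepts = data.frame(label = labels, kind = kinds,
                          stringsAsFactors = FALSE),
    subclass = sub_df, synonym = syn_df, group = grp_df,
    properties = prop_df)
}

#' Write an ontology in the OWL/XML dialect
#'
#' Inverse of [load_owlxml()] for the supported element kinds. Aliases,
#' annotations and weight overrides have no OWL counterpart in the dialect
#' and are not written.
#'
#' @param graph a [food_ontology].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_owlxml <- function(graph, path) {
  stopifnot(inherits(graph, "food_ontology"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  label_of <- function(id)
    graph$concepts$label[match(id, graph$concepts$id)]
  lines <- c('<?xml version="1.0"?>',
             '<Ontology xmlns="http://www.w3.org/2002/07/owl#">')
  for (i in seq_len(nrow(graph$concepts))) {
    tag <- if (graph$concepts$kind[i] == "class") "Class" else
      "NamedIndividual"
    lines <- c(lines, sprintf('  <Declaration><%s IRI="#%s"/></Declaration>',
                              tag, esc(graph$concepts$label[i])))
  }
  for (i in seq_len(nrow(graph$subclass))) {
    lines <- c(lines, sprintf(
      '  <SubClassOf><Class IRI="#%s"/><Class IRI="#%s"/></SubClassOf>',
      esc(label_of(graph$subclass$child[i])),
      esc(label_of(graph$subclass$parent[i]))))
  }
  opa <- function(prop, s, o) sprintf(paste0(
    '  <ObjectPropertyAssertion><ObjectProperty IRI="#%s"/>',
    '<NamedIndividual IRI="#%s"/><NamedIndividual IRI="#%s"/>',
    '</ObjectPropertyAssertion>'), esc(prop), esc(s), esc(o))
  for (i in seq_len(nrow(graph$synonym))) {
    lines <- c(lines, opa("Has_Synonym", label_of(graph$synonym$a[i]),
                          label_of(graph$synonym$b[i])))
  }
  for (i in seq_len(nrow(graph$group))) {
    lines <- c(lines, opa("Has_Group", label_of(graph$group$member[i]),
                          label_of(graph$group$group[i])))
  }
  for (i in seq_len(nrow(graph$properties))) {
    p <- graph$properties
    if (normalize_term(p$property[i]) == "class assertion") {
      lines <- c(lines, sprintf(paste0(
        '  <ClassAssertion><Class IRI="#%s"/>',
        '<NamedIndividual IRI="#%s"/></ClassAssertion>'),
        esc(p$object[i]), esc(p$subject[i])))
    } else {
      lines <- c(lines, opa(p$property[i], p$subject[i], p$object[i]))
    }
  }
  writeLines(c(lines, "</Ontology>"), path)
  invisible(path)
}

#' Read a consumer profile file
#'
#' YAML with fields `intolerances` (required), and optional `id`,
#' `allergies`, `pre_enhanced`, `bmi`, `bmr`,
#' `blood_pressure` (`high`/`low`), `activity`.
#'
#' @param path file path.
#' @return a named list (the profile).
#' @export
read_profile <- function(path) {
  prof <- yaml::read_yaml(path)
  if (is.null(prof$intolerances)) {
    ont_stop("profile schema violation: missing 'intolerances'",
             "foodont_schema")
  }
  prof$intolerances <- as.character(unlist(prof$intolerances))
  prof
}

#' Read a product record file
#'
#' YAML with fields `ean` (string) and `ingredients` (term list).
#'
#' @param path file path.
#' @return a named list (the product).
#' @export
read_product <- function(path) {
  prod <- yaml::read_yaml(path)
  if (is.null(prod$ingredients)) {
    ont_stop("product schema violation: missing 'ingredients'",
             "foodont_schema")
  }
  prod$ean <- as.character(prod$ean)
  prod$ingredients <- as.character(unlist(prod$ingredients))
  prod
}
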