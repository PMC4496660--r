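# DL-safe forward chaining over SWRL-style rules: conjunctions of unary
# (class) and binary (property) atoms, variables written ?x, binding only to
# named individuals. Supported built-ins: greaterThan, lessThan.

BUILTIN_PREDICATES <- c("greaterthan", "lessthan")

#' Parse one rule
#'
#' Textual syntax: comma-separated atoms, `->` between body and head,
#' variables prefixed with `?`, e.g.
#' `Consumer(?c), Has_Allergy(?c, Lactose_Allergy),
#'  Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Aluminium_Silicate)
#'  -> HAS_LACTOSE_RISK(?c, Aluminium_Silicate)`.
#' Individual arguments are normalized as ontology identifiers; numeric
#' arguments are kept as numbers. Every head variable must occur in a
#' non-built-in body atom (DL-safety); the only built-ins accepted are
#' `greaterThan` and `lessThan`.
#'
#' @param text a single rule string.
#' @return an object of class `swrl_rule`: list with `body` and `head`, each
#'   a list of atoms `list(predicate, args, is_var, builtin)`.
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    ont_stop(sprintf("rule must contain exactly one '->': %s", text),
             "foodont_parse")
  }
  parse_atoms <- function(s, where) {
    m <- gregexpr("([A-Za-z_][A-Za-z0-9_]*)\\s*\\(([^)]*)\\)", s)[[1]]
    if (m[1] == -1) {
      ont_stop(sprintf("no atoms found in rule %s at '%s'", where, trimws(s)),
               "foodont_parse")
    }
    # anything outside the matched atoms other than commas/space is a syntax
    # error; report the first offending position
    covered <- rep(FALSE, nchar(s))
    for (i in seq_along(m)) {
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
    }
    rest <- strsplit(s, "")[[1]]
    bad <- which(!covered & !grepl("[,[:space:]]", rest))
    if (length(bad)) {
      ont_stop(sprintf("syntax error in rule %s at position %d: '%s'",
                       where, bad[1], substr(s, bad[1], bad[1])),
               "foodont_parse")
    }
    lapply(regmatches(s, gregexpr(
      "([A-Za-z_][A-Za-z0-9_]*)\\s*\\(([^)]*)\\)", s))[[1]], function(a) {
      pred <- sub("\\s*\\(.*$", "", a)
      argstr <- sub("^[^(]*\\(", "", sub("\\)\\s*$", "", a))
      raw <- trimws(strsplit(argstr, ",", fixed = TRUE)[[1]])
      if (!length(raw) || length(raw) > 2) {
        ont_stop(sprintf("atom '%s' must have arity 1 or 2", trimws(a)),
                 "foodont_parse")
      }
      is_var <- startsWith(raw, "?")
      args <- ifelse(is_var, tolower(sub("^\\?", "", raw)),
                     ifelse(grepl("^-?[0-9.]+$", raw), raw,
                            normalize_term(raw)))
      builtin <- normalize_term(pred) %in% BUILTIN_PREDICATES
      if (!builtin && grepl("^(greater|less|swrlb)", tolower(pred))) {
        ont_stop(sprintf("unsupported built-in predicate '%s'", pred),
                 "foodont_parse")
      }
      list(predicate = if (builtin) normalize_term(pred) else pred,
           args = args, is_var = is_var, builtin = builtin)
    })
  }
  body <- parse_atoms(parts[1], "body")
  head_ <- parse_atoms(parts[2], "head")
  if (any(vapply(head_, `[[`, logical(1), "builtin"))) {
    ont_stop("built-in predicates are not allowed in a rule head",
             "foodont_parse")
  }
  body_vars <- unique(unlist(lapply(body, function(a)
    a$args[a$is_var & !a$builtin])))
  head_vars <- unique(unlist(lapply(head_, function(a) a$args[a$is_var])))
  unsafe <- setdiff(head_vars, body_vars)
  if (length(unsafe)) {
    ont_stop(sprintf("head variable(s) not bound in body: %s",
                     paste0("?", unsafe, collapse = ", ")),
             "foodont_dl_safety")
  }
  structure(list(body = body, head = head_, text = trimws(text)),
            class = "swrl_rule")
}

#' Parse a rule file
#'
#' One rule per line in the [parse_rule()] syntax; blank lines and `#`
#' comments are ignored.
#'
#' @param path file path.
#' @return list of `swrl_rule` objects.
#' @export
parse_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lapply(lines[nzchar(lines)], parse_rule)
}

#' @export
print.swrl_rule <- function(x, ...) {
  fmt <- function(atoms) paste(vapply(atoms, function(a)
    sprintf("%s(%s)", a$predicate,
            paste0(ifelse(a$is_var, paste0("?", a$args), a$args),
                   collapse = ", ")), character(1)), collapse = ", ")
  cat(fmt(x$body), "->", fmt(x$head), "\n")
  invisible(x)
}

#' Construct a fact base
#'
#' @param predicate,arg1,arg2 vectors describing ground atoms; `arg2` is `NA`
#'   for unary (class) atoms. Arguments are normalized unless numeric.
#' @return a `fact_base`: duplicate-free data.frame with columns `predicate`,
#'   `arg1`, `arg2`.
#' @export
fact_base <- function(predicate = character(), arg1 = character(),
                      arg2 = NA_character_) {
  norm_arg <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | grepl("^-?[0-9.]+$", x), x, normalize_term(x))
  }
  df <- data.frame(predicate = as.character(predicate),
                   arg1 = norm_arg(arg1),
                   arg2 = norm_arg(rep_len(arg2, length(predicate))),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, class = c("fact_base", "data.frame"))
}

#' Read a fact file
#'
#' CSV-like lines `predicate, arg1[, arg2]`; `#` comments and blank lines
#' ignored.
#'
#' @param path file path.
#' @return a [fact_base()].
#' @export
read_facts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  bad <- which(vapply(parts, length, integer(1)) < 2 |
                 vapply(parts, length, integer(1)) > 3)
  if (length(bad)) {
    ont_stop(sprintf("fact line %d must have 2 or 3 fields", bad[1]),
             "foodont_parse")
  }
  fact_base(predicate = vapply(parts, `[[`, character(1), 1),
            arg1 = vapply(parts, `[[`, character(1), 2),
            arg2 = vapply(parts, function(p)
              if (length(p) == 3) p[[3]] else NA_character_, character(1)))
}

# All named individuals mentioned in a fact base (variables range over these)
fact_individuals <- function(facts) {
  vals <- c(facts$arg1, facts$arg2)
  vals <- vals[!is.na(vals) & !grepl("^-?[0-9.]+$", vals)]
  unique(vals)
}

# Bindings satisfying one atom against the facts, extending `bindings`
# (a list of named character vectors).
match_atom <- function(atom, facts, bindings) {
  if (atom$builtin) {
    keep <- vapply(bindings, function(b) {
      vals <- ifelse(atom$is_var, unname(b[atom$args]), atom$args)
      if (anyNA(vals)) return(FALSE)
      nums <- suppressWarnings(as.numeric(vals))
      if (anyNA(nums)) return(FALSE)
      if (atom$predicate == "greaterthan") nums[1] > nums[2] else
        nums[1] < nums[2]
    }, logical(1))
    return(bindings[keep])
  }
  rows <- facts[facts$predicate == atom$predicate, , drop = FALSE]
  if (length(atom$args) == 1) {
    rows <- rows[is.na(rows$arg2), , drop = FALSE]
  } else {
    rows <- rows[!is.na(rows$arg2), , drop = FALSE]
  }
  out <- list()
  for (b in bindings) {
    for (i in seq_len(nrow(rows))) {
      fact_args <- c(rows$arg1[i], rows$arg2[i])[seq_along(atom$args)]
      b2 <- b
      ok <- TRUE
      for (j in seq_along(atom$args)) {
        if (atom$is_var[j]) {
          v <- atom$args[j]
          if (v %in% names(b2)) {
            if (b2[[v]] != fact_args[j]) { ok <- FALSE; break }
          } else {
            b2[[v]] <- fact_args[j]
          }
        } else if (atom$args[j] != fact_args[j]) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1]] <- b2
    }
  }
  out
}

#' Forward-chain rules to a fixpoint
#'
#' Repeatedly binds rule bodies against the fact base (variables range over
#' the named individuals only), asserting head instantiations, until no new
#' fact is derived. Set semantics make the result independent of rule order;
#' termination is guaranteed by the finite individual set, with a safety cap
#' of `|individuals|^2` times the rule-head count on derivations.
#'
#' @param facts a [fact_base()].
#' @param rules a list of `swrl_rule` objects (or a single rule).
#' @return the saturated [fact_base()] (always a superset of the input).
#' @export
#' @examples
#' fb <- fact_base(
#'   c("Consumer", "Has_Allergy", "Has_Ean_No", "Has_Product_Additives_Name"),
#'   c("c1", "c1", "c1", "p1"),
#'   c(NA, "Lactose_Allergy", "p1", "Aluminium_Silicate"))
#' r <- parse_rule(paste(
#'   "Consumer(?c), Has_Allergy(?c, Lactose_Allergy), Has_Ean_No(?c, ?p),",
#'   "Has_Product_Additives_Name(?p, Aluminium_Silicate)",
#'   "-> HAS_LACTOSE_RISK(?c, Aluminium_Silicate)"))
#' forward_chain(fb, list(r))
forward_chain <- function(facts, rules) {
  if (inherits(rules, "swrl_rule")) rules <- list(rules)
  stopifnot(inherits(facts, "fact_base"))
  current <- facts
  cap <- max(1L, length(fact_individuals(facts)))^2 *
    max(1L, sum(vapply(rules, function(r) length(r$head), integer(1)))) + 100L
  derived <- 0L
  repeat {
    new_rows <- NULL
    for (rule in rules) {
      bindings <- list(setNames(character(), character()))
      for (atom in rule$body) {
        bindings <- match_atom(atom, current, bindings)
        if (!length(bindings)) break
      }
      for (b in bindings) {
        for (atom in rule$head) {
          args <- ifelse(atom$is_var, unname(unlist(b[atom$args])), atom$args)
          new_rows <- rbind(new_rows, data.frame(
            predicate = atom$predicate, arg1 = args[1],
            arg2 = if (length(args) == 2) args[2] else NA_character_,
            stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(new_rows)) break
    merged <- unique(rbind(as.data.frame(current), new_rows))
    if (nrow(merged) == nrow(current)) break
    derived <- derived + (nrow(merged) - nrow(current))
    if (derived > cap) {
      ont_stop("forward chaining exceeded the derivation safety cap",
               "foodont_chain_cap")
    }
    rownames(merged) <- NULL
    current <- structure(merged, class = c("fact_base", "data.frame"))
  }
  current
}

#' Expand a rule's concept arguments through the ontology
#'
#' For every individual argument of the rule that names an ontology concept,
#' emits rule variants substituting each semantically related concept
#' (synonyms, sub/superclasses, group members — everything with a
#' non-Dissimilar match degree), so that a product listing e.g. "Kaolin"
#' triggers the Aluminium Silicate rule. The original rule is always first;
#' the result is duplicate-free. Arguments that do not resolve in the
#' ontology are left unexpanded with a warning.
#'
#' @param graph a [food_ontology].
#' @param rule a `swrl_rule`.
#' @return list of `swrl_rule` objects, the original included.
#' @export
expand_rule_concepts <- function(graph, rule) {
  stopifnot(inherits(rule, "swrl_rule"))
  consts <- unique(unlist(lapply(c(rule$body, rule$head), function(a)
    a$args[!a$is_var & !a$builtin & !grepl("^-?[0-9.]+$", a$args)])))
  out <- list(rule)
  seen <- rule$text
  for (const in consts) {
    id <- resolve(graph, const, quiet = TRUE)
    if (is.na(id)) {
      ont_warn(sprintf(
        "rule argument '%s' not found in the ontology; not expanded", const),
        "foodont_unresolved_terms")
      next
    }
    for (rel in setdiff(related_concepts(graph, id), id)) {
      variant <- rule
      variant$body <- lapply(variant$body, substitute_const, const, rel)
      variant$head <- lapply(variant$head, substitute_const, const, rel)
      variant$text <- rule_text(variant)
      if (!variant$text %in% seen) {
        seen <- c(seen, variant$text)
        out[[length(out) + 1]] <- variant
      }
    }
  }
  out
}

substitute_const <- function(atom, from, to) {
  hit <- !atom$is_var & atom$args == from
  atom$args[hit] <- to
  atom
}

rule_text <- function(rule) {
  fmt <- function(atoms) paste(vapply(atoms, function(a)
    sprintf("%s(%s)", a$predicate,
            paste0(ifelse(a$is_var, paste0("?", a$args), a$args),
                   collapse = ", ")), character(1)), collapse = ", ")
  paste(fmt(rule$body), "->", fmt(rule$head))
}
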