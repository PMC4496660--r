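# Traffic-light verdict, profile band classification and report rendering.

YELLOW_ADVISORY <- paste("A possible issue was found: seek professional",
                         "medical advice before consuming this product.")

#' Traffic-light verdict for a match result
#'
#' RED if at least one pair has an Exact relation; YELLOW if there is no
#' Exact pair but at least one Plugin or Subsume pair; GREEN otherwise. The
#' color depends only on the multiset of pair relations, never on the score
#' magnitude.
#'
#' @param result a `match_result` from [evaluate_product()], or a pairs
#'   data.frame from [greedy_match()].
#' @return list with `color` (`"RED"`, `"YELLOW"` or `"GREEN"`) and
#'   `reasons` (character vector naming each contributing pair).
#' @export
traffic_light <- function(result) {
  pairs <- if (is.data.frame(result)) result else result$pairs
  rel <- pairs$relation
  matched <- which(rel != "Dissimilar")
  color <- if (any(rel == "Exact")) "RED"
    else if (length(matched)) "YELLOW"
    else "GREEN"
  reasons <- if (length(matched)) {
    sprintf("%s ~ %s [%s, term %.4f]",
            pairs$c_concept[matched], pairs$p_concept[matched],
            rel[matched], pairs$term[matched])
  } else {
    "no related ingredient found"
  }
  if (color == "YELLOW") reasons <- c(reasons, YELLOW_ADVISORY)
  list(color = color, reasons = reasons)
}

# Band tables. Boundary convention: closed lower bound, open upper bound,
# except the final open-ended band; printed ranges such as 1400-1600 and
# 1600-1900 overlap at the shared endpoint, so a convention is mandatory.
band_lookup <- function(value, lower, labels, upper = Inf) {
  if (!is.finite(value) || value < lower[1] || value >= upper) {
    return("unclassified")
  }
  labels[findInterval(value, lower)]
}

#' Classify profile values into their ontology bands
#'
#' Maps body mass index, basal metabolic rate, a blood pressure pair and
#' physical activity level onto the knowledge base's printed bands. A value
#' below the first band or above the last closed band is `"unclassified"`.
#'
#' @param bmi body mass index (kg/m^2).
#' @param bmr basal metabolic rate (kcal/day).
#' @param bp_high,bp_low systolic and diastolic blood pressure (mmHg); the
#'   more severe of the two classifications is reported.
#' @param activity physical activity level on the 1-10 scale.
#' @return named character vector of band labels (only the supplied values).
#' @export
#' @examples
#' classify_bands(bmi = 26, bmr = 1500)
classify_bands <- function(bmi = NULL, bmr = NULL,
                           bp_high = NULL, bp_low = NULL, activity = NULL) {
  out <- character()
  if (!is.null(bmi)) {
    out["bmi"] <- band_lookup(bmi, c(19, 25, 30, 35, 45),
                              c("normal overweight", "very overweight",
                                "class I obese", "class II obese",
                                "class III obese"))
  }
  if (!is.null(bmr)) {
    out["bmr"] <- band_lookup(bmr, c(0, 800, 1400, 1600, 1900),
                              c("sedentary", "lightly active",
                                "moderately active", "very active",
                                "extremely active"))
  }
  if (!is.null(bp_high) || !is.null(bp_low)) {
    bp_labels <- c("optimal blood pressure", "normal blood pressure",
                   "high-normal blood pressure", "degree I hypertension",
                   "degree II hypertension", "degree III hypertension")
    hi <- if (!is.null(bp_high)) {
      band_lookup(bp_high, c(80, 121, 131, 140, 160, 180), bp_labels)
    } else NA_character_
    lo <- if (!is.null(bp_low)) {
      band_lookup(bp_low, c(0, 81, 86, 91, 100, 110), bp_labels,
                  upper = 181)
    } else NA_character_
    both <- c(hi, lo)
    both <- both[!is.na(both) & both != "unclassified"]
    out["blood_pressure"] <- if (!length(both)) "unclassified" else
      bp_labels[max(match(both, bp_labels))]
  }
  if (!is.null(activity)) {
    out["activity"] <- band_lookup(activity, c(1, 3, 5, 7, 9),
                                   c("very light", "light",
                                     "activity medium", "heavy",
                                     "very heavy"), upper = 11)
  }
  out
}

#' Render a human-readable report
#'
#' Lists the product's ingredients, each matched pair with its relation and
#' contribution term, the score, the integer percentage, the verdict color,
#' and any fired allergy-risk facts.
#'
#' @param result a `match_result` from [evaluate_product()].
#' @param verdict a verdict from [traffic_light()]; defaults to the one in
#'   `result`.
#' @param inferred optional [fact_base()] of rule-inferred facts; only the
#'   risk-property rows (predicates containing `_RISK`) are shown.
#' @param format `"text"` for a printable character vector, `"structured"`
#'   for a serializable list.
#' @return character vector (text) or list (structured).
#' @export
render_report <- function(result, verdict = result$verdict, inferred = NULL,
                          format = c("text", "structured")) {
  format <- match.arg(format)
  risks <- if (!is.null(inferred)) {
    as.data.frame(inferred)[grepl("_RISK", inferred$predicate,
                                  ignore.case = TRUE), , drop = FALSE]
  } else {
    data.frame(predicate = character(), arg1 = character(),
               arg2 = character(), stringsAsFactors = FALSE)
  }
  if (format == "structured") {
    return(list(
      ean = result$product$ean,
      ingredients = result$product$ingredients,
      pairs = result$pairs,
      m = result$m, l = result$l, n_C = result$n_C, n_P = result$n_P,
      d_j = result$d_j, d_w = result$d_w,
      score = result$score, percentage = result$percentage,
      verdict = verdict, risks = risks))
  }
  lines <- c(
    sprintf("Product %s", if (!is.null(result$product$ean))
      result$product$ean else "(no EAN)"),
    sprintf("Ingredients: %s",
            paste(result$product$ingredients, collapse = ", ")),
    "Matched pairs:",
    sprintf("  %s ~ %s: %s (term %.4f)",
            ifelse(is.na(result$pairs$c_concept), "-",
                   result$pairs$c_concept),
            ifelse(is.na(result$pairs$p_concept), "-",
                   result$pairs$p_concept),
            result$pairs$relation, result$pairs$term),
    sprintf("Intolerance score: %.4f", result$score),
    sprintf("Intolerance percentage: %d%%", result$percentage),
    sprintf("Verdict: %s", verdict$color),
    paste0("  ", verdict$reasons))
  if (nrow(risks)) {
    lines <- c(lines, "Inferred risks:",
               sprintf("  %s(%s, %s)", risks$predicate, risks$arg1,
                       risks$arg2))
  }
  lines
}

#' Serialize / reparse a structured report
#'
#' @param report a structured report from
#'   `render_report(format = "structured")`.
#' @param path file path to write to (JSON) or read from.
#' @return `write_report` returns `path` invisibly; `read_report` returns the
#'   report list with the pairs and risk tables restored as data.frames.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$pairs <- as.data.frame(rep$pairs, stringsAsFactors = FALSE)
  rep$risks <- as.data.frame(rep$risks, stringsAsFactors = FALSE)
  rep
}
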