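#' Group summary predications by subject intervention
#'
#' Evaluation compares subject interventions to a reference standard, so
#' the summary is first restricted to assertions in the general form
#' *Intervention X*-TREATS/PREVENTS-*disease Y* and grouped by normalized
#' subject name. Under the treatment point of view the accepted predicate
#' set defaults to `TREATS`; under prevention, to `PREVENTS`. For those
#' core forms the object must name the disease topic (when `disease_names`
#' is given). Additional predicate forms whose value for a point of view
#' is established (e.g. admitting `AFFECTS` or `USES` assertions for
#' prevention) can be passed via `extra_predicates`; they are admitted
#' without the object constraint.
#'
#' @param summary a `predication_set` or `combo_summary`.
#' @param pov `"treatment"`, `"prevention"`, or `"none"` (no predicate or
#'   object restriction).
#' @param disease_names character vector of accepted disease labels for
#'   the object slot; `NULL` disables the object constraint.
#' @param extra_predicates additional accepted predicates.
#' @param include_negated count negated assertions too (default drops
#'   them).
#' @return a tibble with one row per subject group: `subject` (normalized),
#'   `display_name` (first seen spelling), `n_records`.
#' @export
group_subjects <- function(summary,
                           pov = c("treatment", "prevention", "none"),
                           disease_names = NULL,
                           extra_predicates = NULL,
                           include_negated = FALSE) {
  pov <- match.arg(pov)
  if (inherits(summary, "combo_summary")) summary <- summary$predications
  stopifnot(inherits(summary, "predication_set"))
  core <- switch(pov, treatment = "TREATS", prevention = "PREVENTS",
                 none = unique(summary$predicate))
  keep <- summary$predicate %in% core
  if (pov != "none" && !is.null(disease_names)) {
    keep <- keep &
      normalize_name(summary$object_name) %in% normalize_name(disease_names)
  }
  if (length(extra_predicates) > 0 && pov != "none") {
    keep <- keep | summary$predicate %in% extra_predicates
  }
  if (!include_negated) keep <- keep & !summary$negated
  kept <- summary[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(tibble::tibble(subject = character(),
                          display_name = character(),
                          n_records = integer()))
  }
  tibble::tibble(subject = normalize_name(kept$subject_name),
                 display_name = kept$subject_name) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(display_name = dplyr::first(.data$display_name),
                     n_records = dplyr::n(), .groups = "drop")
}

#' One-term-per-group structure for baseline terms
#'
#' Baseline output is a bare term list rather than predications; this
#' wraps it in the degenerate subject-group structure [match_reference()]
#' expects, so both summarizers are scored by the same code path.
#'
#' @param terms character vector of baseline terms.
#' @return a subject-group tibble as returned by [group_subjects()].
#' @export
groups_from_terms <- function(terms) {
  terms <- as.character(terms)
  tibble::tibble(subject = normalize_name(terms), display_name = terms) |>
    dplyr::distinct(.data$subject, .keep_all = TRUE) |>
    dplyr::mutate(n_records = 1L)
}

#' Score subject groups against a reference standard
#'
#' A subject group is a true positive when its normalized name -- or an
#' explicitly listed alias of it -- equals a reference-standard
#' intervention; an intervention is matched when any group claims it.
#' Recall is matched interventions over reference size; precision is
#' true-positive groups over total groups (reported as 0 and flagged when
#' there are no groups); F1 is the harmonic mean `2PR/(P+R)` (0 when
#' `P + R = 0`).
#'
#' @param groups the output of [group_subjects()] or [groups_from_terms()].
#' @param ref a `reference_standard`.
#' @param synonyms optional named character vector mapping a system term to
#'   the reference intervention it stands for (see [read_alias_map()]).
#' @return an object of class `evaluation_report`.
#' @export
match_reference <- function(groups, ref, synonyms = NULL) {
  stopifnot(inherits(ref, "reference_standard"))
  if (length(ref$interventions) == 0) {
    abort("reference standard is empty", class = "semsumm_argument_error")
  }
  syn <- synonyms %||% setNames(character(0), character(0))
  names(syn) <- normalize_name(names(syn))
  syn[] <- normalize_name(syn)

  # every reference entry a group can claim: its own name plus any alias
  claimed_by_group <- lapply(groups$subject, function(s) {
    intersect(unique(c(s, unname(syn[names(syn) == s]))),
              ref$interventions)
  })
  tp <- lengths(claimed_by_group) > 0
  matched <- unique(unlist(claimed_by_group))
  unmatched <- setdiff(ref$interventions, matched)

  n_groups <- nrow(groups)
  recall <- length(matched) / length(ref$interventions)
  precision <- if (n_groups == 0) 0 else sum(tp) / n_groups
  structure(list(
    recall = recall,
    precision = precision,
    f1 = f1_score(precision, recall),
    matched_interventions = matched,
    unmatched_interventions = unmatched,
    subject_groups_total = n_groups,
    subject_groups_true = sum(tp),
    true_positive_groups = groups$display_name[tp],
    false_positive_groups = groups$display_name[!tp],
    precision_defined = n_groups > 0,
    pairing_label = ref$pairing_label
  ), class = "evaluation_report")
}

#' Balanced F1 score
#'
#' Harmonic mean of precision and recall, defined as 0 when both are 0.
#'
#' @param precision,recall numeric vectors in `[0, 1]`.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' f1_score(0.50, 0.68)
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Inter-annotator agreement
#'
#' Fundamental agreement between two annotators: instances of agreement
#' divided by the sum of agreement and disagreement instances,
#' `matches / (matches + non-matches)`.
#'
#' @param agreements,disagreements non-negative integers, not both zero.
#' @return numeric in `[0, 1]`.
#' @examples
#' iaa(5, 5)
#' @export
iaa <- function(agreements, disagreements) {
  assert_count(agreements, "agreements", min = 0)
  assert_count(disagreements, "disagreements", min = 0)
  if (any(agreements + disagreements == 0)) {
    abort("`agreements + disagreements` must be positive",
          class = "semsumm_argument_error")
  }
  agreements / (agreements + disagreements)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation%s\n",
              if (nzchar(x$pairing_label)) paste0(" [", x$pairing_label, "]")
              else ""))
  cat(sprintf("  recall    %.3f (%d/%d interventions matched)\n", x$recall,
              length(x$matched_interventions),
              length(x$matched_interventions) +
                length(x$unmatched_interventions)))
  cat(sprintf("  precision %.3f (%d/%d subject groups true)%s\n",
              x$precision, x$subject_groups_true, x$subject_groups_total,
              if (!x$precision_defined) "  [no groups: reported as 0]"
              else ""))
  cat(sprintf("  F1        %.3f\n", x$f1))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param x an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  stopifnot(inherits(x, "evaluation_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
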