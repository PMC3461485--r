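#' Construct a seed topic
#'
#' The seed topic anchors the Relevance tier: a record is relevant when its
#' subject or object names the seed. A seed may carry several accepted
#' labels (e.g. `"Congestive heart failure"` OR `"Heart failure"`); matching
#' is exact after normalization -- deliberately not substring matching, so
#' "Heart failure" does not also fire inside "Congestive heart failure".
#'
#' @param names non-empty character vector of accepted seed concept labels.
#' @param semtypes optional expected semantic types of the seed concept.
#' @return an object of class `seed_topic`.
#' @export
seed_topic <- function(names, semtypes = NULL) {
  names <- as.character(names)
  norm <- unique(normalize_name(names))
  norm <- norm[nzchar(norm)]
  if (length(norm) == 0) {
    abort("a seed topic needs at least one non-empty name",
          class = "semsumm_argument_error")
  }
  structure(list(names = names, norm = norm,
                 semtypes = as.character(semtypes %||% character(0))),
            class = "seed_topic")
}

# Per-record: does subject / object name the seed?
seed_match_sides <- function(ps, seed) {
  list(subject = normalize_name(ps$subject_name) %in% seed$norm,
       object = normalize_name(ps$object_name) %in% seed$norm)
}

#' Novelty tier: drop vague predications
#'
#' Removes every predication whose subject or object name is on the
#' stoplist. The output is a subset of the input with relative order
#' preserved; an empty result is allowed (with a warning).
#'
#' @param data a `predication_set`.
#' @param stop a `novelty_stoplist`.
#' @return the filtered `predication_set`.
#' @export
novelty_filter <- function(data, stop) {
  stopifnot(inherits(data, "predication_set"),
            inherits(stop, "novelty_stoplist"))
  keep <- !(normalize_name(data$subject_name) %in% stop$generic_names |
              normalize_name(data$object_name) %in% stop$generic_names)
  if (nrow(data) > 0 && !any(keep)) {
    warn("novelty_filter removed every predication")
  }
  subset_predications(data, keep)
}

#' Relevance tier: keep seed-bearing predications
#'
#' Keeps predications whose subject or object names the seed topic.
#'
#' @param data a `predication_set`.
#' @param seed a `seed_topic`.
#' @return the filtered `predication_set`.
#' @export
relevance_filter <- function(data, seed) {
  stopifnot(inherits(data, "predication_set"), inherits(seed, "seed_topic"))
  m <- seed_match_sides(data, seed)
  keep <- m$subject | m$object
  if (nrow(data) > 0 && !any(keep)) {
    warn("relevance_filter matched no predication for the given seed")
  }
  subset_predications(data, keep)
}

# Semantic types carried by the non-seed argument of each seed-bearing
# record. A record whose two arguments both name the seed contributes none.
non_seed_semtypes <- function(relevant, seed) {
  m <- seed_match_sides(relevant, seed)
  out <- character(0)
  if (nrow(relevant) > 0) {
    from_obj <- m$subject & !m$object
    from_sub <- m$object & !m$subject
    out <- c(unlist(relevant$object_semtypes[from_obj]),
             unlist(relevant$subject_semtypes[from_sub]))
  }
  unique(out)
}

#' Connectivity tier: augment by shared semantic type
#'
#' Collects the semantic types of the non-seed arguments in `relevant`
#' (e.g. `phsu` from *cetuximab* in *cetuximab*-TREATS-*Endometrial
#' carcinoma*) and returns the predications of `data` outside `relevant`
#' that carry at least one of those types on either argument. With the seed
#' *Endometrial carcinoma*, *trastuzumab*[phsu]-TREATS-*Breast cancer* is
#' pulled in because trastuzumab shares the pharmacological-substance type.
#'
#' Membership in `relevant` is decided by the seed predicate, so the output
#' is disjoint from the relevance tier by construction. By default the
#' shared type may appear on either argument; set
#' `position_restricted = TRUE` to require it on the same argument position
#' (subject/object) where it was observed in `relevant`.
#'
#' @param data a `predication_set` (the novelty-filtered dataset).
#' @param relevant the output of [relevance_filter()] on `data`.
#' @param seed the `seed_topic` used to build `relevant`.
#' @param position_restricted restrict matching to the argument position
#'   where each type was seen in `relevant`.
#' @return the augmenting `predication_set`, disjoint from `relevant`.
#' @export
connectivity_filter <- function(data, relevant, seed,
                                position_restricted = FALSE) {
  stopifnot(inherits(data, "predication_set"),
            inherits(relevant, "predication_set"),
            inherits(seed, "seed_topic"))
  m <- seed_match_sides(data, seed)
  candidate <- !(m$subject | m$object)
  if (!position_restricted) {
    types <- non_seed_semtypes(relevant, seed)
    keep <- candidate & vapply(seq_len(nrow(data)), function(i) {
      any(c(data$subject_semtypes[[i]], data$object_semtypes[[i]]) %in% types)
    }, logical(1))
  } else {
    mr <- seed_match_sides(relevant, seed)
    sub_types <- unique(unlist(relevant$subject_semtypes[mr$object &
                                                           !mr$subject]))
    obj_types <- unique(unlist(relevant$object_semtypes[mr$subject &
                                                          !mr$object]))
    keep <- candidate & vapply(seq_len(nrow(data)), function(i) {
      any(data$subject_semtypes[[i]] %in% sub_types) ||
        any(data$object_semtypes[[i]] %in% obj_types)
    }, logical(1))
  }
  subset_predications(data, keep)
}

#' Parse static pattern triples
#'
#' Patterns are written `"subject_semtype PREDICATE object_semtype"`, one
#' per string, with `*` as a wildcard in any slot.
#'
#' @param lines character vector of pattern strings.
#' @return a tibble with columns `subject_semtype`, `predicate`,
#'   `object_semtype`.
#' @export
parse_patterns <- function(lines) {
  lines <- trimws(lines[nzchar(trimws(lines))])
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    stop_format(sprintf("pattern '%s' must have three fields", lines[bad[1]]))
  }
  tibble::tibble(subject_semtype = vapply(parts, `[`, character(1), 1),
                 predicate = vapply(parts, `[`, character(1), 2),
                 object_semtype = vapply(parts, `[`, character(1), 3))
}

#' Static-pattern filter
#'
#' A configurable stand-in for hard-coded point-of-view schemas: keeps
#' predications matching any of the supplied
#' (subject semtype, predicate, object semtype) triples. `*` is a wildcard;
#' a semtype slot matches when the argument carries that type among its
#' codes.
#'
#' @param data a `predication_set`.
#' @param patterns a data frame with columns `subject_semtype`, `predicate`,
#'   `object_semtype` (see [parse_patterns()]).
#' @return the filtered `predication_set`.
#' @export
static_pattern_filter <- function(data, patterns) {
  stopifnot(inherits(data, "predication_set"))
  patterns <- tibble::as_tibble(patterns)
  if (nrow(patterns) == 0) {
    abort("`patterns` must contain at least one triple",
          class = "semsumm_argument_error")
  }
  keep <- rep(FALSE, nrow(data))
  for (k in seq_len(nrow(patterns))) {
    ss <- patterns$subject_semtype[k]
    pp <- patterns$predicate[k]
    os <- patterns$object_semtype[k]
    hit <- (pp == "*" | data$predicate == pp)
    if (ss != "*") {
      hit <- hit & vapply(data$subject_semtypes, function(t) ss %in% t,
                          logical(1))
    }
    if (os != "*") {
      hit <- hit & vapply(data$object_semtypes, function(t) os %in% t,
                          logical(1))
    }
    keep <- keep | hit
  }
  subset_predications(data, keep)
}
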