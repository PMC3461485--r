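#' Predicate relative-frequency distribution of a dataset
#'
#' Distribution P of the saliency stage: relative frequencies of predicates
#' across the (novelty-filtered) dataset. Negated assertions are excluded by
#' default so that e.g. TREATS and its negation are not conflated.
#'
#' @param data a `predication_set`.
#' @param include_negated also count negated records.
#' @return a `predicate_distribution`: named numeric vector of relative
#'   frequencies summing to one (zero-count predicates absent).
#' @examples
#' ps <- predication_set("c", c("a", "a", "a", "b"), "t1",
#'                       c("TREATS", "TREATS", "TREATS", "AFFECTS"),
#'                       "x", "t2")
#' predicate_distribution(ps)
#' @export
predicate_distribution <- function(data, include_negated = FALSE) {
  stopifnot(inherits(data, "predication_set"))
  preds <- data$predicate[include_negated | !data$negated]
  if (length(preds) == 0) {
    stop_empty_input("no (non-negated) predications to build a distribution")
  }
  counts <- table(preds)
  relative_frequencies(setNames(as.numeric(counts), names(counts)))
}

#' Per-predicate Kullback--Leibler enrichment terms
#'
#' For each predicate x present in *both* distributions the term
#' `P(x) * log2(P(x) / Q(x))` is reported -- the contribution of x to the
#' divergence `D(P||Q) = sum P(x) log2(P(x)/Q(x))` before summing. A
#' positive term marks a predicate over-represented in the query dataset
#' relative to the background; terms are kept signed so under-enriched
#' predicates rank low. Predicates absent from `q` receive no term (they are
#' listed in the `"unscored"` attribute); the summed divergence over the
#' shared support is attached as `"divergence"`.
#'
#' @param p distribution P: a `predicate_distribution` (or named counts /
#'   a `predication_set`, coerced).
#' @param q distribution Q: the background (a `background_distribution`,
#'   `predicate_distribution`, or named counts).
#' @return a tibble with columns `predicate`, `p`, `q`, `kld_term`, plus
#'   attributes `divergence` and `unscored`.
#' @examples
#' p <- relative_frequencies(c(TREATS = 3, AFFECTS = 1))
#' q <- relative_frequencies(c(TREATS = 1, AFFECTS = 1))
#' kld_terms(p, q)
#' @export
kld_terms <- function(p, q) {
  if (inherits(p, "predication_set")) p <- predicate_distribution(p)
  p <- relative_frequencies(p)
  q <- relative_frequencies(q)
  shared <- intersect(names(p), names(q))
  unscored <- setdiff(names(p), shared)
  ps <- as.numeric(p[shared])
  qs <- as.numeric(q[shared])
  out <- tibble::tibble(
    predicate = shared,
    p = ps,
    q = qs,
    kld_term = ps * log2(ps / qs)
  )
  structure(out, divergence = sum(out$kld_term), unscored = unscored)
}

#' RlogF pattern-relevance statistic
#'
#' Riloff's relevance score for an extraction pattern, here a (semantic
#' type, predicate) pair: `log2(f) * (f / F)` where `f` is the pattern's
#' absolute semantic-type frequency and `F` the absolute frequency of all
#' semantic types paired with the same predicate. The quotient `f / F` is
#' the conditional probability of the pattern given its predicate; patterns
#' seen once score zero (`log2(1) = 0`).
#'
#' @param freq_pattern positive integer(s): the pattern frequency `f`.
#' @param freq_predicate_total positive integer(s): the predicate's semantic
#'   type total `F`, with `f <= F`.
#' @return non-negative numeric vector.
#' @examples
#' rlogf(8, 16) # 3 * 0.5 = 1.5
#' @export
rlogf <- function(freq_pattern, freq_predicate_total) {
  assert_count(freq_pattern, "freq_pattern", min = 1)
  assert_count(freq_predicate_total, "freq_predicate_total", min = 1)
  if (any(freq_pattern > freq_predicate_total)) {
    abort("`freq_pattern` cannot exceed `freq_predicate_total`",
          class = "semsumm_argument_error")
  }
  log2(freq_pattern) * (freq_pattern / freq_predicate_total)
}

#' PredScal scaling factor
#'
#' Scales raw RlogF scores by the spatial proportions of predicates in the
#' dataset: `1 / log2(c)` where `c` is the count of unique predicates. When
#' the dataset holds a single unique predicate the factor defaults to 1
#' (the formula would divide by zero).
#'
#' @param c positive integer vector: unique-predicate count(s).
#' @return positive numeric vector; 1 at `c = 1` and `c = 2`, strictly
#'   decreasing beyond.
#' @examples
#' predscal(c(1, 2, 8))
#' @export
predscal <- function(c) {
  assert_count(c, "c", min = 1)
  ifelse(c == 1, 1, 1 / log2(c))
}

#' Profile the scorable patterns of a filtered dataset
#'
#' Builds the pattern frequency table feeding RlogF. Relevance-tier
#' patterns pair each seed-bearing record's predicate with the semantic
#' type(s) of its *non-seed* argument (for *cetuximab*[phsu]-TREATS-*seed*,
#' the pattern is `(phsu, TREATS)`). Connectivity-tier patterns pair each
#' augmenting record's predicate with the semantic type(s) that licensed
#' its inclusion. With `semtype_mode = "all"` an argument carrying several
#' types contributes one pattern count per type; `"primary"` counts only
#' the first listed type.
#'
#' @param novel the novelty-filtered `predication_set` (negated records
#'   should already be excluded).
#' @param seed the `seed_topic`.
#' @param connectivity the output of [connectivity_filter()]; may be `NULL`
#'   or empty.
#' @param semtype_mode `"all"` or `"primary"`.
#' @return a list with `c` (unique predicate count of `novel`) and
#'   `patterns`, a tibble `tier`, `semtype`, `predicate`, `freq`,
#'   `predicate_total` where `predicate_total` sums `freq` over the
#'   patterns sharing a tier and predicate.
#' @export
dataset_profile <- function(novel, seed, connectivity = NULL,
                            semtype_mode = c("all", "primary")) {
  semtype_mode <- match.arg(semtype_mode)
  stopifnot(inherits(novel, "predication_set"))
  if (nrow(novel) == 0) {
    stop_empty_input("cannot profile an empty dataset")
  }
  pick <- function(types) {
    if (semtype_mode == "primary" && length(types) > 1) types[1] else types
  }

  m <- seed_match_sides(novel, seed)
  rel_rows <- which(xor(m$subject, m$object))
  rel <- dplyr::bind_rows(lapply(rel_rows, function(i) {
    types <- if (m$subject[i]) novel$object_semtypes[[i]]
             else novel$subject_semtypes[[i]]
    tibble::tibble(tier = "relevance", semtype = pick(types),
                   predicate = novel$predicate[i])
  }))

  conn <- NULL
  if (!is.null(connectivity) && nrow(connectivity) > 0) {
    licensed <- non_seed_semtypes(
      subset_predications(novel, m$subject | m$object), seed)
    conn <- dplyr::bind_rows(lapply(seq_len(nrow(connectivity)), function(i) {
      types <- intersect(
        pick(unique(c(connectivity$subject_semtypes[[i]],
                      connectivity$object_semtypes[[i]]))),
        licensed)
      if (length(types) == 0) return(NULL)
      tibble::tibble(tier = "connectivity", semtype = types,
                     predicate = connectivity$predicate[i])
    }))
  }

  long <- dplyr::bind_rows(rel, conn)
  patterns <- if (is.null(long) || nrow(long) == 0) {
    tibble::tibble(tier = character(), semtype = character(),
                   predicate = character(), freq = integer(),
                   predicate_total = integer())
  } else {
    long |>
      dplyr::count(.data$tier, .data$semtype, .data$predicate,
                   name = "freq") |>
      dplyr::group_by(.data$tier, .data$predicate) |>
      dplyr::mutate(predicate_total = sum(.data$freq)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$tier, .data$semtype, .data$predicate)
  }
  list(c = length(unique(novel$predicate)), patterns = patterns)
}

#' Combo-score the profiled patterns
#'
#' Attaches to every pattern its predicate's KLD enrichment term, its RlogF
#' value, the dataset's PredScal factor, and the Combo product
#' `KLD * RlogF * PredScal`. Patterns whose predicate has no KLD term
#' (predicate absent from the background) are emitted with `combo = NA` and
#' excluded from ranking.
#'
#' @param profile the output of [dataset_profile()].
#' @param klds the output of [kld_terms()] (or any data frame with columns
#'   `predicate`, `kld_term`).
#' @return a tibble `tier`, `semtype`, `predicate`, `freq`,
#'   `predicate_total`, `kld_term`, `rlogf`, `predscal`, `combo`.
#' @export
score_patterns <- function(profile, klds) {
  pat <- profile$patterns
  kl <- tibble::as_tibble(klds)[c("predicate", "kld_term")]
  scal <- predscal(profile$c)
  pat |>
    dplyr::left_join(kl, by = "predicate") |>
    dplyr::mutate(
      rlogf = rlogf(.data$freq, .data$predicate_total),
      predscal = scal,
      combo = .data$kld_term * .data$rlogf * .data$predscal
    )
}

#' Select the top-scoring patterns per tier
#'
#' Per tier, keeps the `top_k` highest Combo scores (fewer when fewer
#' scorable patterns exist). Ties are broken deterministically: descending
#' Combo, then descending pattern frequency, then lexicographic
#' (semtype, predicate). When every scorable Combo value is zero (e.g. the
#' dataset's predicate distribution equals the background) the selection
#' degenerates to tie-break order and is flagged via the `"no_enrichment"`
#' attribute.
#'
#' @param scored the output of [score_patterns()].
#' @param top_k patterns retained per tier (default 4).
#' @return the selected rows of `scored`, with attribute `no_enrichment`.
#' @export
select_top <- function(scored, top_k = 4) {
  assert_count(top_k, "top_k", min = 1)
  rankable <- scored |> dplyr::filter(!is.na(.data$combo))
  sel <- rankable |>
    dplyr::arrange(.data$tier, dplyr::desc(.data$combo),
                   dplyr::desc(.data$freq), .data$semtype, .data$predicate) |>
    dplyr::group_by(.data$tier) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup()
  structure(sel,
            no_enrichment = nrow(rankable) > 0 && all(rankable$combo == 0))
}

#' Dynamic summarization of a predication dataset
#'
#' Runs the full cascade: Novelty (stoplist) filtering, Relevance (seed
#' matching), Connectivity (shared non-seed semantic type), then the Combo
#' saliency stage. The dataset's predicate distribution P is computed from
#' *all* novelty-filtered predications (not only seed-bearing ones) and
#' compared against the background Q; relevance- and connectivity-tier
#' (semantic type, predicate) patterns are RlogF-profiled and scored, the
#' top `top_k` patterns of each tier are selected, and every predication
#' matching a selected pattern is returned.
#'
#' @param data a `predication_set`.
#' @param seed a `seed_topic` (or character vector of seed names).
#' @param background a `background_distribution` (distribution Q).
#' @param stoplist a `novelty_stoplist`; defaults to [default_stoplist()].
#' @param top_k patterns retained per tier (default 4).
#' @param smoothing additive smoothing pseudo-count applied to the
#'   background so predicates absent from it still receive KLD terms;
#'   `0` (default) keeps the strict shared-support rule.
#' @param semtype_mode `"all"` (each carried semantic type counts) or
#'   `"primary"` (first listed type only); see [dataset_profile()].
#' @param kld_mode `"per_predicate"` multiplies each pattern by its own
#'   predicate's KLD term (default); `"summed"` multiplies every pattern by
#'   the total divergence instead.
#' @param include_negated score negated assertions too (default drops them).
#' @param position_restricted see [connectivity_filter()].
#' @return an object of class `combo_summary`: a list with
#'   `predications` (the summary `predication_set`), `selected` (chosen
#'   patterns), `diagnostics` (full scored-pattern table), `kld` (per
#'   predicate terms), `profile`, `p`, `q`, and `counts` (records surviving
#'   each stage).
#' @export
summarize_predications <- function(data, seed, background,
                                   stoplist = default_stoplist(),
                                   top_k = 4, smoothing = 0,
                                   semtype_mode = c("all", "primary"),
                                   kld_mode = c("per_predicate", "summed"),
                                   include_negated = FALSE,
                                   position_restricted = FALSE) {
  semtype_mode <- match.arg(semtype_mode)
  kld_mode <- match.arg(kld_mode)
  if (is.character(seed)) seed <- seed_topic(seed)
  stopifnot(inherits(data, "predication_set"),
            inherits(seed, "seed_topic"),
            inherits(background, "background_distribution"))
  if (nrow(data) == 0) stop_empty_input("empty predication dataset")

  scored_input <- if (include_negated) data
                  else subset_predications(data, !data$negated)
  if (nrow(scored_input) == 0) {
    stop_empty_input("no non-negated predications to summarize")
  }
  novel <- novelty_filter(scored_input, stoplist)
  if (nrow(novel) == 0) {
    stop_empty_input("novelty filtering removed every predication")
  }
  relevant <- suppressWarnings(relevance_filter(novel, seed))
  if (nrow(relevant) == 0) {
    near <- nearest_names(novel, seed)
    stop_empty_input(paste0(
      "seed topic not found in the dataset; nearest concept names: ",
      paste(near, collapse = ", ")))
  }
  connectivity <- connectivity_filter(novel, relevant, seed,
                                      position_restricted)

  p <- predicate_distribution(novel, include_negated = include_negated)
  q <- smoothed_background(background, union(names(p),
                                             names(background$counts)),
                           smoothing)
  klds <- kld_terms(p, q)
  if (kld_mode == "summed") {
    klds$kld_term <- rep(attr(klds, "divergence"), nrow(klds))
  }

  profile <- dataset_profile(novel, seed, connectivity, semtype_mode)
  scored <- score_patterns(profile, klds)
  selected <- select_top(scored, top_k = top_k)

  keep <- matching_records(novel, seed, selected, position_restricted)
  out <- subset_predications(novel, keep)

  structure(list(
    predications = out,
    selected = selected,
    diagnostics = scored,
    kld = klds,
    profile = profile,
    p = p,
    q = q,
    seed = seed,
    no_enrichment = isTRUE(attr(selected, "no_enrichment")),
    counts = c(input = nrow(data), scored = nrow(scored_input),
               novel = nrow(novel), relevant = nrow(relevant),
               connectivity = nrow(connectivity), summary = nrow(out))
  ), class = "combo_summary")
}

# Records of `novel` matching at least one selected pattern: seed-bearing
# records are checked against relevance-tier patterns via their non-seed
# argument's types; non-seed records against connectivity-tier patterns via
# their licensed types.
matching_records <- function(novel, seed, selected, position_restricted) {
  m <- seed_match_sides(novel, seed)
  seedish <- m$subject | m$object
  licensed <- non_seed_semtypes(subset_predications(novel, seedish), seed)
  sel_key <- function(tier) {
    s <- selected[selected$tier == tier, ]
    paste(s$semtype, s$predicate, sep = "\r")
  }
  rel_keys <- sel_key("relevance")
  conn_keys <- sel_key("connectivity")
  vapply(seq_len(nrow(novel)), function(i) {
    if (xor(m$subject[i], m$object[i])) {
      types <- if (m$subject[i]) novel$object_semtypes[[i]]
               else novel$subject_semtypes[[i]]
      any(paste(types, novel$predicate[i], sep = "\r") %in% rel_keys)
    } else if (!seedish[i]) {
      types <- intersect(unique(c(novel$subject_semtypes[[i]],
                                  novel$object_semtypes[[i]])), licensed)
      any(paste(types, novel$predicate[i], sep = "\r") %in% conn_keys)
    } else {
      FALSE
    }
  }, logical(1))
}

smoothed_background <- function(background, vocabulary, smoothing) {
  if (smoothing <= 0) return(relative_frequencies(background))
  counts <- setNames(rep(0, length(vocabulary)), vocabulary)
  counts[names(background$counts)] <- background$counts
  relative_frequencies(counts + smoothing)
}

# Closest concept names to the seed, for the empty-relevance diagnostic.
nearest_names <- function(data, seed, k = 5) {
  cand <- unique(c(data$subject_name, data$object_name))
  d <- adist(seed$norm[1], normalize_name(cand))[1, ]
  cand[order(d)][seq_len(min(k, length(cand)))]
}

#' @export
print.combo_summary <- function(x, ...) {
  cat("Combo dynamic summarization\n")
  cat(sprintf("  records: %d in -> %d novel -> %d summary\n",
              x$counts[["input"]], x$counts[["novel"]],
              x$counts[["summary"]]))
  cat(sprintf("  unique predicates (c): %d, PredScal %.4f\n",
              x$profile$c, predscal(x$profile$c)))
  if (x$no_enrichment) {
    cat("  NOTE: no predicate enrichment over the background",
        "(all Combo scores zero); selection is tie-break order\n")
  }
  cat("  selected patterns:\n")
  sel <- x$selected
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("    [%s] %s__%s  freq=%d  combo=%.4g\n", sel$tier[i],
                sel$semtype[i], sel$predicate[i], sel$freq[i], sel$combo[i]))
  }
  invisible(x)
}

#' Write summarization outputs
#'
#' Writes `<prefix>_summary.tsv` (the selected predications, TSV dialect),
#' `<prefix>_patterns.tsv` (the full scored-pattern diagnostics) and
#' `<prefix>_log.txt` (run provenance).
#'
#' @param x a `combo_summary`.
#' @param prefix output path prefix.
#' @param provenance character vector of provenance lines for the headers.
#' @return the paths, invisibly.
#' @export
write_summary <- function(x, prefix, provenance = character(0)) {
  stopifnot(inherits(x, "combo_summary"))
  paths <- paste0(prefix, c("_summary.tsv", "_patterns.tsv", "_log.txt"))
  write_predications(x$predications, paths[1], header_comments = provenance)
  diag <- x$diagnostics
  lines <- c(
    if (length(provenance)) paste0("# ", provenance),
    paste(c("tier", "semtype", "predicate", "freq", "predicate_total",
            "kld_term", "rlogf", "predscal", "combo"), collapse = "\t"),
    paste(diag$tier, diag$semtype, diag$predicate, diag$freq,
          diag$predicate_total,
          format_num(diag$kld_term), format_num(diag$rlogf),
          format_num(diag$predscal), format_num(diag$combo), sep = "\t")
  )
  writeLines(lines, paths[2], useBytes = TRUE)
  writeLines(c(provenance,
               sprintf("records_%s=%d", names(x$counts), x$counts),
               sprintf("unique_predicates=%d", x$profile$c),
               sprintf("no_enrichment=%s", x$no_enrichment)),
             paths[3], useBytes = TRUE)
  invisible(paths)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}
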