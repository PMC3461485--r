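#' Specify a synthetic predication corpus
#'
#' The generator emulates the statistical structure of a predication
#' extraction run for one disease topic: a background predicate
#' distribution; a corpus in which a configurable fraction of records
#' involve the seed disease; Zipf-skewed concept-name frequencies (skew is
#' characteristic of literature term frequencies and is what the baseline's
#' mean-plus-one-SD threshold exploits); and optional planted
#' (semantic type, predicate) patterns whose probability among seed-bearing
#' records is tilted by an enrichment multiplier, providing ground truth
#' for saliency ranking. Generation is a pure function of the spec: the
#' same `rng_seed` yields an identical corpus.
#'
#' @param n_records corpus size.
#' @param predicate_weights named non-negative weights drawn on for both
#'   the background and the corpus.
#' @param semtype_pool semantic-type codes available to non-seed arguments.
#' @param seed_name,seed_semtype the disease concept and its semantic type.
#' @param planted_patterns data frame with columns `semtype`, `predicate`,
#'   `multiplier` (>= 1); `NULL` plants nothing.
#' @param seed_fraction fraction of records bearing the seed concept.
#' @param noise_name_count size of the non-seed concept-name pool.
#' @param intervention_name_count size of the intervention-name pool used
#'   as subjects of seed-bearing records.
#' @param zipf_exponent exponent of the Zipf name-frequency tail.
#' @param vague_fraction fraction of deliberately vague records (stoplist
#'   subjects/objects) exercising the Novelty tier.
#' @param negated_fraction fraction of negated assertions.
#' @param background_total total count mass of the background table.
#' @param rng_seed integer random seed.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 5000,
                        predicate_weights = c(TREATS = 1, PREVENTS = 1,
                                              AFFECTS = 2,
                                              ASSOCIATED_WITH = 2,
                                              INTERACTS_WITH = 1,
                                              CAUSES = 1),
                        semtype_pool = c("phsu", "topp", "orch", "aapp",
                                         "diap", "dsyn"),
                        seed_name = "Hypertensive disease",
                        seed_semtype = "dsyn",
                        planted_patterns = NULL,
                        seed_fraction = 0.3,
                        noise_name_count = 200,
                        intervention_name_count = 40,
                        zipf_exponent = 1.2,
                        vague_fraction = 0.02,
                        negated_fraction = 0.02,
                        background_total = 100000,
                        rng_seed = 1) {
  if (length(predicate_weights) == 0 || any(predicate_weights < 0) ||
      all(predicate_weights == 0) || is.null(names(predicate_weights))) {
    abort("`predicate_weights` must be named, non-negative, not all zero",
          class = "semsumm_argument_error")
  }
  assert_count(n_records, "n_records", min = 1)
  assert_count(rng_seed, "rng_seed", min = 0)
  if (!is.null(planted_patterns)) {
    planted_patterns <- tibble::as_tibble(planted_patterns)
    stopifnot(all(c("semtype", "predicate", "multiplier") %in%
                    names(planted_patterns)))
    if (any(planted_patterns$multiplier < 1)) {
      abort("planted multipliers must be >= 1",
            class = "semsumm_argument_error")
    }
    if (!all(planted_patterns$semtype %in% semtype_pool) ||
        !all(planted_patterns$predicate %in% names(predicate_weights))) {
      abort("planted patterns must use pooled semtypes and predicates",
            class = "semsumm_argument_error")
    }
  }
  stopifnot(seed_fraction >= 0, seed_fraction <= 1,
            vague_fraction >= 0, vague_fraction < 1,
            negated_fraction >= 0, negated_fraction < 1,
            zipf_exponent > 0, background_total >= 1)
  structure(list(
    n_records = n_records, predicate_weights = predicate_weights,
    semtype_pool = semtype_pool, seed_name = seed_name,
    seed_semtype = seed_semtype, planted_patterns = planted_patterns,
    seed_fraction = seed_fraction, noise_name_count = noise_name_count,
    intervention_name_count = intervention_name_count,
    zipf_exponent = zipf_exponent, vague_fraction = vague_fraction,
    negated_fraction = negated_fraction,
    background_total = background_total, rng_seed = rng_seed
  ), class = "corpus_spec")
}

# Largest-remainder apportionment of `total` across `weights`.
proportional_counts <- function(weights, total) {
  exact <- weights / sum(weights) * total
  counts <- floor(exact)
  short <- total - sum(counts)
  if (short > 0) {
    top <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  counts
}

zipf_weights <- function(n, exponent) seq_len(n)^(-exponent)

#' Generate a synthetic corpus and matching background
#'
#' Draws the background table exactly proportional to the predicate
#' weights (largest-remainder apportionment of `background_total`). Corpus
#' records come in three kinds: seed-bearing records
#' (*intervention*-predicate-*seed disease*) whose joint (subject semtype,
#' predicate) law is the base weight law tilted by the planted enrichment
#' multipliers; noise records between random concepts drawn from the base
#' law; and a small vague stratum with stoplisted arguments. Subject names
#' of seed-bearing records come from a Zipf-weighted intervention pool,
#' giving analytically known ground truth for evaluation.
#'
#' @param spec a `corpus_spec`.
#' @return a list of class `synthetic_corpus`: `predications`
#'   (a `predication_set`), `background` (a `background_distribution`),
#'   and `truth` (planted patterns, the intervention names attached to
#'   planted-pattern records, and the full intervention pool).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$rng_seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  w <- spec$predicate_weights[spec$predicate_weights > 0]
  background <- background_distribution(
    proportional_counts(w, spec$background_total))

  n <- spec$n_records
  n_vague <- round(spec$vague_fraction * n)
  n_seed <- round(spec$seed_fraction * (n - n_vague))
  n_noise <- n - n_vague - n_seed

  pool <- spec$semtype_pool
  # joint (subject semtype, predicate) law for seed-bearing records
  grid <- expand.grid(semtype = pool, predicate = names(w),
                      stringsAsFactors = FALSE)
  grid$weight <- w[grid$predicate] / length(pool)
  planted_key <- character(0)
  if (!is.null(spec$planted_patterns)) {
    key <- paste(grid$semtype, grid$predicate)
    pk <- paste(spec$planted_patterns$semtype,
                spec$planted_patterns$predicate)
    mult <- setNames(spec$planted_patterns$multiplier, pk)
    hit <- key %in% pk
    grid$weight[hit] <- grid$weight[hit] * mult[key[hit]]
    planted_key <- pk
  }

  interv_names <- sprintf("agent %03d", seq_len(spec$intervention_name_count))
  noise_names <- sprintf("concept %03d", seq_len(spec$noise_name_count))
  interv_w <- zipf_weights(length(interv_names), spec$zipf_exponent)
  noise_w <- zipf_weights(length(noise_names), spec$zipf_exponent)

  seed_df <- if (n_seed > 0) {
    cell <- sample.int(nrow(grid), n_seed, replace = TRUE,
                       prob = grid$weight)
    tibble::tibble(
      kind = "seed",
      subject_name = sample(interv_names, n_seed, replace = TRUE,
                            prob = interv_w),
      subject_semtypes = as.list(grid$semtype[cell]),
      predicate = grid$predicate[cell],
      object_name = spec$seed_name,
      object_semtypes = rep(list(spec$seed_semtype), n_seed),
      planted = paste(grid$semtype[cell], grid$predicate[cell]) %in%
        planted_key
    )
  }
  noise_df <- if (n_noise > 0) {
    extra <- runif(n_noise) < 0.3 # some arguments carry a second type
    tibble::tibble(
      kind = "noise",
      subject_name = sample(noise_names, n_noise, replace = TRUE,
                            prob = noise_w),
      subject_semtypes = lapply(seq_len(n_noise), function(i) {
        unique(c(sample(pool, 1),
                 if (extra[i]) sample(pool, 1)))
      }),
      predicate = sample(names(w), n_noise, replace = TRUE, prob = w),
      object_name = sample(noise_names, n_noise, replace = TRUE,
                           prob = noise_w),
      object_semtypes = as.list(sample(pool, n_noise, replace = TRUE)),
      planted = FALSE
    )
  }
  vague_df <- if (n_vague > 0) {
    tibble::tibble(
      kind = "vague",
      subject_name = "pharmaceutical preparation",
      subject_semtypes = rep(list("phsu"), n_vague),
      predicate = sample(names(w), n_vague, replace = TRUE, prob = w),
      object_name = "patients",
      object_semtypes = rep(list("humn"), n_vague),
      planted = FALSE
    )
  }

  df <- dplyr::bind_rows(seed_df, noise_df, vague_df)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  df$negated <- runif(nrow(df)) < spec$negated_fraction
  df$citation_id <- sprintf("SIM%06d", seq_len(nrow(df)))
  df$sentence_text <- paste(df$subject_name, tolower(df$predicate),
                            df$object_name)

  ps <- as_predication_set(
    df[c("citation_id", "subject_name", "subject_semtypes", "predicate",
         "object_name", "object_semtypes", "negated", "sentence_text")],
    provenance = sprintf("synthetic corpus (seed %d, n %d)",
                         spec$rng_seed, spec$n_records))
  truth <- list(
    planted_patterns = spec$planted_patterns,
    planted_subjects = sort(unique(df$subject_name[df$planted &
                                                     !df$negated])),
    intervention_names = interv_names
  )
  structure(list(predications = ps, background = background, truth = truth),
            class = "synthetic_corpus")
}

#' Generate a reference standard with known overlap
#'
#' Builds a reference list of `n_items` interventions of which a fraction
#' `overlap` is drawn from the supplied intervention names (e.g. the
#' planted subjects of a synthetic corpus) and the remainder are
#' distractors no summarizer output can match. The expected matched count
#' of a summarizer that reports every supplied intervention is therefore
#' `round(overlap * n_items)` by construction.
#'
#' @param interventions character vector of achievable intervention names,
#'   or a `synthetic_corpus` (its planted subjects are used).
#' @param n_items reference-standard size.
#' @param overlap fraction of entries drawn from `interventions`.
#' @param pairing_label disease topic + point-of-view tag.
#' @param rng_seed integer random seed.
#' @return a list: `reference` (a `reference_standard`), `aliases` (empty
#'   named character vector, a placeholder users can extend), and
#'   `expected_matched` (= `round(overlap * n_items)`).
#' @export
generate_reference <- function(interventions, n_items = 20, overlap = 1,
                               pairing_label = "synthetic", rng_seed = 1) {
  if (inherits(interventions, "synthetic_corpus")) {
    corpus <- interventions
    interventions <- corpus$truth$planted_subjects
    if (length(interventions) == 0) {
      interventions <- corpus$truth$intervention_names
    }
  }
  interventions <- unique(as.character(interventions))
  assert_count(n_items, "n_items", min = 1)
  stopifnot(overlap >= 0, overlap <= 1)
  k <- round(overlap * n_items)
  if (k > length(interventions)) {
    abort(sprintf(
      "need %d overlapping entries but only %d intervention name(s) given",
      k, length(interventions)), class = "semsumm_argument_error")
  }
  withr::with_seed(rng_seed, {
    hit <- if (k > 0) sample(interventions, k) else character(0)
    miss <- if (n_items > k) sprintf("distractor %03d", seq_len(n_items - k))
            else character(0)
    entries <- sample(c(hit, miss))
  })
  list(reference = reference_standard(entries, pairing_label = pairing_label),
       aliases = setNames(character(0), character(0)),
       expected_matched = k)
}
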