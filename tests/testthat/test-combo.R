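test_that("predicate distributions are relative frequencies", {
  ps <- make_ps(c("a", "b", "c", "d"),
                c("TREATS", "TREATS", "TREATS", "AFFECTS"),
                c("x", "x", "x", "x"))
  p <- predicate_distribution(ps)
  expect_equal(p[["TREATS"]], 0.75)
  expect_equal(p[["AFFECTS"]], 0.25)
  single <- predicate_distribution(make_ps("a", "TREATS", "x"))
  expect_equal(as.numeric(single), 1)
  expect_error(predicate_distribution(make_ps("a", "TREATS", "x",
                                              negated = TRUE)),
               class = "semsumm_empty_input_error")
})

test_that("predicate distribution matches an independent tally at n = 500", {
  withr::local_seed(61)
  ps <- rand_ps(500, negated_prob = 0.1)
  p <- predicate_distribution(ps)
  preds <- ps$predicate[!ps$negated]
  for (x in names(p)) {
    expect_equal(p[[x]], sum(preds == x) / length(preds))
  }
  expect_equal(sum(p), 1)
})

test_that("KLD terms reproduce hand-evaluated values and the identity", {
  p <- relative_frequencies(c(TREATS = 0.75, AFFECTS = 0.25))
  q <- relative_frequencies(c(TREATS = 0.5, AFFECTS = 0.5))
  k <- kld_terms(p, q)
  expect_equal(k$kld_term[k$predicate == "TREATS"], 0.75 * log2(1.5))
  expect_equal(k$kld_term[k$predicate == "AFFECTS"], -0.25)
  expect_equal(attr(k, "divergence"), 0.75 * log2(1.5) - 0.25)

  # P = Q: every term zero
  same <- kld_terms(p, p)
  expect_true(all(same$kld_term == 0))

  # shared-support rule: predicates absent from Q get no term
  k2 <- kld_terms(relative_frequencies(c(TREATS = 1, USES = 1)),
                  relative_frequencies(c(TREATS = 1)))
  expect_equal(k2$predicate, "TREATS")
  expect_equal(attr(k2, "unscored"), "USES")
})

test_that("renormalized shared-support divergence is non-negative", {
  withr::local_seed(71)
  vocab <- sprintf("P%02d", 1:10)
  for (rep in 1:200) {
    np <- sample(2:10, 1)
    nq <- sample(2:10, 1)
    p <- relative_frequencies(setNames(runif(np), sample(vocab, np)))
    q <- relative_frequencies(setNames(runif(nq), sample(vocab, nq)))
    shared <- intersect(names(p), names(q))
    if (length(shared) == 0) next
    pr <- relative_frequencies(setNames(as.numeric(p[shared]), shared))
    qr <- relative_frequencies(setNames(as.numeric(q[shared]), shared))
    expect_gte(attr(kld_terms(pr, qr), "divergence"), -1e-12)
  }
})

test_that("rlogf evaluates the log-weighted conditional probability", {
  expect_equal(rlogf(8, 16), 1.5)
  expect_equal(rlogf(4, 4), 2)
  expect_equal(rlogf(1, 37), 0)
  expect_error(rlogf(5, 4), class = "semsumm_argument_error")
  expect_error(rlogf(0, 4), class = "semsumm_argument_error")
})

test_that("predscal defaults to 1 for a single predicate and decreases", {
  expect_equal(predscal(1), 1)
  expect_equal(predscal(2), 1)
  expect_equal(predscal(8), 1 / 3)
  vals <- predscal(2:50)
  expect_true(all(diff(vals) < 0))
  expect_error(predscal(0), class = "semsumm_argument_error")
})

test_that("combo is the exact product of its three components", {
  # worked chain: kld 0.75*log2(1.5), rlogf(8,16)=1.5, c=8
  kld <- 0.75 * log2(1.5)
  expect_equal(kld * rlogf(8, 16) * predscal(8), kld * 1.5 / 3)
  withr::local_seed(83)
  for (rep in 1:3) {
    ps <- rand_ps(200)
    bg <- rand_background()
    res <- summarize_predications(ps, seed_topic("seed disease"), bg,
                                  stoplist = novelty_stoplist(character(0)))
    d <- res$diagnostics
    expect_equal(d$combo, d$kld_term * d$rlogf * d$predscal)
    # frequency-1 patterns are annihilated by rlogf
    expect_true(all(d$combo[d$freq == 1] == 0, na.rm = TRUE))
  }
})

test_that("the scored table equals the brute-force oracle", {
  withr::local_seed(97)
  for (rep in 1:10) {
    ps <- rand_ps(150, negated_prob = 0.1)
    bg <- rand_background(predicates = c("TREATS", "PREVENTS", "AFFECTS"))
    stop_names <- c("name 01", "name 07")
    got <- package_scores(ps, "seed disease", bg$counts, stop_names)
    want <- oracle_scores(ps, "seed disease", bg$counts, stop_names)
    expect_equal(got$tier, want$tier)
    expect_equal(got$semtype, want$semtype)
    expect_equal(got$predicate, want$predicate)
    expect_equal(got$freq, want$freq)
    expect_equal(got$combo, want$combo)
  }
})

test_that("duplicating every record changes scores only through log2(freq)", {
  withr::local_seed(101)
  ps <- rand_ps(80)
  bg <- rand_background()
  seed <- seed_topic("seed disease")
  one <- summarize_predications(ps, seed, bg,
                                stoplist = novelty_stoplist(character(0)))
  dup <- as_predication_set(rbind(as.data.frame(ps), as.data.frame(ps)))
  two <- summarize_predications(dup, seed, bg,
                                stoplist = novelty_stoplist(character(0)))
  d1 <- one$diagnostics[order(one$diagnostics$tier, one$diagnostics$semtype,
                              one$diagnostics$predicate), ]
  d2 <- two$diagnostics[order(two$diagnostics$tier, two$diagnostics$semtype,
                              two$diagnostics$predicate), ]
  # P, pattern proportions, conditional quotients, c are unchanged
  expect_equal(d2$freq, 2 * d1$freq)
  expect_equal(d2$kld_term, d1$kld_term)
  expect_equal(d2$predscal, d1$predscal)
  expect_equal(d2$freq / d2$predicate_total, d1$freq / d1$predicate_total)
  expect_equal(d2$rlogf, log2(2 * d1$freq) * d1$freq / d1$predicate_total)
})

test_that("top-pattern selection caps per tier and breaks ties as stated", {
  scored <- tibble::tibble(
    tier = c(rep("relevance", 6), "connectivity", "connectivity"),
    semtype = c("a", "b", "c", "d", "e", "f", "g", "h"),
    predicate = "TREATS",
    freq = c(9L, 8L, 7L, 5L, 5L, 5L, 3L, 2L),
    predicate_total = 40L,
    kld_term = 0.5, rlogf = 1, predscal = 1,
    combo = c(6, 5, 4, 3, 3, 3, 2, 1)
  )
  sel <- select_top(scored, top_k = 4)
  rel <- sel[sel$tier == "relevance", ]
  expect_equal(nrow(rel), 4)
  # rank 4 is a three-way combo tie at equal freq: lexicographic semtype
  expect_equal(rel$semtype, c("a", "b", "c", "d"))
  expect_equal(nrow(sel[sel$tier == "connectivity", ]), 2)

  # distinct scores: plain sort
  scored2 <- scored[order(-scored$combo), ]
  scored2$combo <- seq(8, 1)
  sel2 <- select_top(scored2, top_k = 4)
  expect_equal(sel2$combo[sel2$tier == "relevance"], c(8, 7, 6, 5))
})

test_that("summarization surfaces a planted dominant pattern first", {
  spec <- corpus_spec(n_records = 3000,
                      planted_patterns = data.frame(semtype = "phsu",
                                                    predicate = "TREATS",
                                                    multiplier = 8),
                      rng_seed = 2024)
  corpus <- generate_corpus(spec)
  res <- summarize_predications(corpus$predications,
                                seed_topic(spec$seed_name),
                                corpus$background)
  rel <- res$selected[res$selected$tier == "relevance", ]
  expect_equal(rel$semtype[1], "phsu")
  expect_equal(rel$predicate[1], "TREATS")
  # the summary is always a subset of the novelty-filtered input
  expect_lte(nrow(res$predications), res$counts[["novel"]])
  # and every summary predication matches a selected pattern (tautological
  # on construction, asserted through the record counts being positive)
  expect_gt(nrow(res$predications), 0)
})

test_that("a dataset matching the background yields all-zero combo scores", {
  ps <- make_ps(
    subject = c("drug a", "drug a", "drug b", "proc a"),
    predicate = c("TREATS", "TREATS", "AFFECTS", "AFFECTS"),
    object = rep("seed disease", 4),
    sub_types = list("phsu", "phsu", "phsu", "topp"))
  bg <- background_distribution(c(TREATS = 50, AFFECTS = 50))
  res <- summarize_predications(ps, seed_topic("seed disease"), bg,
                                stoplist = novelty_stoplist(character(0)))
  expect_true(all(res$diagnostics$combo == 0))
  expect_true(res$no_enrichment)
  expect_output(print(res), "no predicate enrichment")
})

test_that("a seed absent from the data raises a diagnostic error", {
  ps <- rand_ps(20)
  err <- tryCatch(
    summarize_predications(ps, seed_topic("no such disease"),
                           rand_background(),
                           stoplist = novelty_stoplist(character(0))),
    condition = function(e) e)
  expect_s3_class(err, "semsumm_empty_input_error")
  expect_match(conditionMessage(err), "nearest concept names")
})

test_that("smoothing admits predicates missing from the background", {
  ps <- make_ps(c("a", "a", "b"), c("TREATS", "TREATS", "USES"),
                rep("seed disease", 3))
  bg <- background_distribution(c(TREATS = 10, AFFECTS = 10))
  strict <- summarize_predications(ps, seed_topic("seed disease"), bg,
                                   stoplist = novelty_stoplist(character(0)))
  expect_true(any(is.na(strict$diagnostics$combo)))
  smoothed <- summarize_predications(ps, seed_topic("seed disease"), bg,
                                     stoplist = novelty_stoplist(character(0)),
                                     smoothing = 0.5)
  expect_false(any(is.na(smoothed$diagnostics$combo)))
})
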