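cetux <- function() {
  predication_set(
    citation_id = c("A", "B", "C", "D"),
    subject_name = c("cetuximab", "trastuzumab",
                     "pharmaceutical preparation", "radiography"),
    subject_semtypes = list("phsu", "phsu", "phsu", "diap"),
    predicate = c("TREATS", "TREATS", "TREATS", "DIAGNOSES"),
    object_name = c("Endometrial carcinoma", "Breast cancer", "patients",
                    "Breast cancer"),
    object_semtypes = list("neop", "neop", "humn", "neop")
  )
}

test_that("novelty filter drops stoplisted vague predications", {
  ps <- cetux()
  out <- novelty_filter(ps, default_stoplist())
  expect_equal(out$citation_id, c("A", "B", "D"))
  # empty stoplist is the identity
  same <- novelty_filter(ps, novelty_stoplist(character(0)))
  expect_equal(as.data.frame(same), as.data.frame(ps))
})

test_that("novelty filter agrees with a linear-scan oracle on random data", {
  withr::local_seed(11)
  pool <- sprintf("name %02d", 1:12)
  stop_names <- sample(pool, 4)
  ps <- rand_ps(100, names_pool = pool)
  out <- novelty_filter(ps, novelty_stoplist(stop_names))
  manual <- sum(vapply(seq_len(nrow(ps)), function(i) {
    !(tolower(ps$subject_name[i]) %in% tolower(stop_names) ||
        tolower(ps$object_name[i]) %in% tolower(stop_names))
  }, logical(1)))
  expect_equal(nrow(out), manual)
})

test_that("relevance filter keeps seed-bearing records only", {
  ps <- cetux()
  out <- relevance_filter(ps, seed_topic("Endometrial carcinoma"))
  expect_equal(out$citation_id, "A")
  expect_warning(empty <- relevance_filter(ps, seed_topic("Malaria")),
                 "no predication")
  expect_equal(nrow(empty), 0)
  # exact-name matching: a longer name must not fire on a contained one
  out2 <- suppressWarnings(relevance_filter(ps, seed_topic("carcinoma")))
  expect_equal(nrow(out2), 0)
})

test_that("a multi-name seed filters to the union of single-name filters", {
  withr::local_seed(23)
  ps <- rand_ps(150, seed_name = "heart failure")
  ps$object_name[sample(nrow(ps), 30)] <- "Congestive heart failure"
  ps <- as_predication_set(ps)
  both <- relevance_filter(ps, seed_topic(c("Congestive heart failure",
                                            "Heart failure")))
  a <- suppressWarnings(relevance_filter(ps, seed_topic("Heart failure")))
  b <- suppressWarnings(
    relevance_filter(ps, seed_topic("Congestive heart failure")))
  expect_equal(nrow(both), length(union(a$citation_id, b$citation_id)))
})

test_that("connectivity augments by shared non-seed semantic type", {
  ps <- cetux()
  # record E carries phsu only on its object argument
  ps <- as_predication_set(rbind(
    as.data.frame(ps),
    data.frame(citation_id = "E", subject_name = "radiotherapy",
               subject_semtypes = I(list("topp")), predicate = "AFFECTS",
               object_name = "doxorubicin", object_semtypes = I(list("phsu")),
               negated = FALSE, sentence_text = NA_character_)))
  seed <- seed_topic("Endometrial carcinoma")
  rel <- relevance_filter(ps, seed)
  conn <- connectivity_filter(ps, rel, seed)
  # the only licensed type is phsu (cetuximab, the non-seed argument of the
  # single relevant record); trastuzumab and the vague record carry it on
  # the subject, record E on the object; radiography (diap/neop) does not
  expect_setequal(conn$citation_id, c("B", "C", "E"))
  # position-restricted: phsu was observed in subject position only, so
  # record E no longer qualifies through its object
  conn2 <- connectivity_filter(ps, rel, seed, position_restricted = TRUE)
  expect_setequal(conn2$citation_id, c("B", "C"))
  # empty relevance tier licenses nothing
  none <- connectivity_filter(ps, suppressWarnings(
    relevance_filter(ps, seed_topic("Malaria"))), seed_topic("Malaria"))
  expect_equal(nrow(none), 0)
})

test_that("connectivity equals a brute-force two-pass scan on random data", {
  withr::local_seed(31)
  for (rep in 1:3) {
    ps <- rand_ps(200)
    seed <- seed_topic("seed disease")
    rel <- suppressWarnings(relevance_filter(ps, seed))
    conn <- connectivity_filter(ps, rel, seed)
    # oracle: collect non-seed-argument types, rescan
    seedish <- tolower(ps$subject_name) == "seed disease" |
      tolower(ps$object_name) == "seed disease"
    types <- character(0)
    for (i in which(seedish)) {
      if (tolower(ps$subject_name[i]) == "seed disease" &&
          tolower(ps$object_name[i]) != "seed disease") {
        types <- union(types, ps$object_semtypes[[i]])
      }
      if (tolower(ps$object_name[i]) == "seed disease" &&
          tolower(ps$subject_name[i]) != "seed disease") {
        types <- union(types, ps$subject_semtypes[[i]])
      }
    }
    manual <- vapply(seq_len(nrow(ps)), function(i) {
      !seedish[i] && any(c(ps$subject_semtypes[[i]],
                           ps$object_semtypes[[i]]) %in% types)
    }, logical(1))
    expect_equal(conn$citation_id, ps$citation_id[manual])
    # disjointness from the relevance tier
    expect_length(intersect(conn$citation_id, rel$citation_id), 0)
  }
})

test_that("static pattern filter honours triples and wildcards", {
  ps <- cetux()
  out <- static_pattern_filter(ps, parse_patterns("phsu TREATS neop"))
  expect_setequal(out$citation_id, c("A", "B"))
  all_out <- static_pattern_filter(ps, parse_patterns("* * *"))
  expect_equal(nrow(all_out), nrow(ps))
  expect_error(static_pattern_filter(ps, parse_patterns(character(0))),
               class = "semsumm_argument_error")
})

test_that("static pattern filter equals a brute-force match count", {
  withr::local_seed(41)
  semtypes <- c("phsu", "topp", "orch", "dsyn", "*")
  preds <- c("TREATS", "PREVENTS", "AFFECTS", "CAUSES", "*")
  for (rep in 1:5) {
    ps <- rand_ps(50)
    pat <- data.frame(subject_semtype = sample(semtypes, 3, replace = TRUE),
                      predicate = sample(preds, 3, replace = TRUE),
                      object_semtype = sample(semtypes, 3, replace = TRUE))
    out <- static_pattern_filter(ps, pat)
    manual <- vapply(seq_len(nrow(ps)), function(i) {
      any(vapply(seq_len(nrow(pat)), function(k) {
        (pat$predicate[k] == "*" || ps$predicate[i] == pat$predicate[k]) &&
          (pat$subject_semtype[k] == "*" ||
             pat$subject_semtype[k] %in% ps$subject_semtypes[[i]]) &&
          (pat$object_semtype[k] == "*" ||
             pat$object_semtype[k] %in% ps$object_semtypes[[i]])
      }, logical(1)))
    }, logical(1))
    expect_equal(nrow(out), sum(manual))
  }
})

test_that("filters are idempotent and record-wise filters commute", {
  withr::local_seed(53)
  ps <- rand_ps(120)
  stop <- novelty_stoplist(c("name 01", "name 02"))
  seed <- seed_topic("seed disease")

  nov1 <- novelty_filter(ps, stop)
  expect_equal(as.data.frame(novelty_filter(nov1, stop)),
               as.data.frame(nov1))
  rel1 <- relevance_filter(ps, seed)
  expect_equal(as.data.frame(relevance_filter(rel1, seed)),
               as.data.frame(rel1))
  pat <- parse_patterns("phsu TREATS *")
  sp1 <- static_pattern_filter(ps, pat)
  expect_equal(as.data.frame(static_pattern_filter(sp1, pat)),
               as.data.frame(sp1))

  ab <- relevance_filter(novelty_filter(ps, stop), seed)
  ba <- novelty_filter(relevance_filter(ps, seed), stop)
  expect_equal(as.data.frame(ab), as.data.frame(ba))
})
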