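# Shared fixtures and an independent brute-force oracle for the saliency
# kernel. The oracle deliberately uses plain loops and base R only, so it
# shares no code path with the package implementation it checks.

# Quick inline predication set.
make_ps <- function(subject, predicate, object,
                    sub_types = "phsu", obj_types = "dsyn",
                    negated = FALSE, citation = "C1") {
  predication_set(
    citation_id = citation,
    subject_name = subject,
    subject_semtypes = rep_len(as.list(sub_types), length(subject)),
    predicate = predicate,
    object_name = object,
    object_semtypes = rep_len(as.list(obj_types), length(subject)),
    negated = negated
  )
}

# Random predication set over small vocabularies; a fraction of records
# bears `seed_name` as object.
rand_ps <- function(n, seed_name = "seed disease",
                    predicates = c("TREATS", "PREVENTS", "AFFECTS",
                                   "CAUSES"),
                    semtypes = c("phsu", "topp", "orch", "dsyn"),
                    names_pool = sprintf("name %02d", 1:12),
                    seed_prob = 0.4, max_types = 2,
                    negated_prob = 0) {
  is_seed <- runif(n) < seed_prob
  sub_types <- lapply(seq_len(n), function(i) {
    unique(sample(semtypes, sample.int(max_types, 1), replace = TRUE))
  })
  obj_types <- lapply(seq_len(n), function(i) {
    if (is_seed[i]) "dsyn"
    else unique(sample(semtypes, sample.int(max_types, 1), replace = TRUE))
  })
  predication_set(
    citation_id = sprintf("R%04d", seq_len(n)),
    subject_name = sample(names_pool, n, replace = TRUE),
    subject_semtypes = sub_types,
    predicate = sample(predicates, n, replace = TRUE),
    object_name = ifelse(is_seed, seed_name,
                         sample(names_pool, n, replace = TRUE)),
    object_semtypes = obj_types,
    negated = runif(n) < negated_prob
  )
}

# Random background over the same predicate vocabulary.
rand_background <- function(predicates = c("TREATS", "PREVENTS", "AFFECTS",
                                           "CAUSES")) {
  background_distribution(
    setNames(sample(5:100, length(predicates), replace = TRUE), predicates))
}

oracle_norm <- function(x) tolower(gsub("[[:space:]]+", " ",
                                        gsub("^\\s+|\\s+$", "", x)))

# Straight-line recomputation of the full scored-pattern table:
# novelty/relevance/connectivity tiers, per-predicate KLD terms against the
# background, RlogF over (semtype, predicate) pattern counts, PredScal,
# and the Combo product. Returns a data.frame keyed by (tier, semtype,
# predicate) with columns kld_term, rlogf, predscal, combo (combo NA when
# the predicate is absent from the background).
oracle_scores <- function(ps, seed_names, bg_counts,
                          stop_names = character()) {
  df <- as.data.frame(ps[, c("subject_name", "predicate", "object_name",
                             "negated")])
  sub_t <- ps$subject_semtypes
  obj_t <- ps$object_semtypes
  keep <- !df$negated &
    !(oracle_norm(df$subject_name) %in% oracle_norm(stop_names)) &
    !(oracle_norm(df$object_name) %in% oracle_norm(stop_names))
  idx <- which(keep)

  seeds <- oracle_norm(seed_names)
  s_sub <- oracle_norm(df$subject_name) %in% seeds
  s_obj <- oracle_norm(df$object_name) %in% seeds

  # distribution P and KLD terms over shared support
  preds <- df$predicate[idx]
  p_tab <- table(preds) / length(preds)
  q_tab <- bg_counts[bg_counts > 0] / sum(bg_counts)
  kld <- list()
  for (x in names(p_tab)) {
    kld[[x]] <- if (x %in% names(q_tab)) {
      as.numeric(p_tab[[x]]) * log2(as.numeric(p_tab[[x]]) / q_tab[[x]])
    } else NA_real_
  }
  c_count <- length(unique(preds))
  scal <- if (c_count == 1) 1 else 1 / log2(c_count)

  # pattern counts
  counts <- new.env()
  bump <- function(tier, st, pr) {
    k <- paste(tier, st, pr, sep = "\r")
    counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
  }
  licensed <- character(0)
  for (i in idx) {
    if (s_sub[i] && !s_obj[i]) licensed <- union(licensed, obj_t[[i]])
    if (s_obj[i] && !s_sub[i]) licensed <- union(licensed, sub_t[[i]])
  }
  for (i in idx) {
    if (xor(s_sub[i], s_obj[i])) {
      types <- if (s_sub[i]) obj_t[[i]] else sub_t[[i]]
      for (st in types) bump("relevance", st, df$predicate[i])
    } else if (!s_sub[i] && !s_obj[i]) {
      types <- intersect(unique(c(sub_t[[i]], obj_t[[i]])), licensed)
      for (st in types) bump("connectivity", st, df$predicate[i])
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(data.frame(tier = character(), semtype = character(),
                      predicate = character(), freq = integer(),
                      kld_term = numeric(), rlogf = numeric(),
                      predscal = numeric(), combo = numeric()))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(tier = parts[, 1], semtype = parts[, 2],
                    predicate = parts[, 3],
                    freq = vapply(keys, function(k) counts[[k]], numeric(1)))
  totals <- tapply(out$freq, paste(out$tier, out$predicate), sum)
  out$predicate_total <- as.numeric(totals[paste(out$tier, out$predicate)])
  out$kld_term <- vapply(out$predicate,
                         function(x) kld[[x]] %||% NA_real_, numeric(1))
  out$rlogf <- log2(out$freq) * out$freq / out$predicate_total
  out$predscal <- scal
  out$combo <- out$kld_term * out$rlogf * out$predscal
  out <- out[order(out$tier, out$semtype, out$predicate), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience: scored table from the package for the same inputs.
package_scores <- function(ps, seed_names, bg_counts,
                           stop_names = character()) {
  res <- summarize_predications(ps, seed_topic(seed_names),
                                background_distribution(bg_counts),
                                stoplist = novelty_stoplist(stop_names))
  as.data.frame(res$diagnostics[order(res$diagnostics$tier,
                                      res$diagnostics$semtype,
                                      res$diagnostics$predicate), ])
}
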