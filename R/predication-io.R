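#' Construct a predication set
#'
#' A predication set is a tibble with one row per subject--predicate--object
#' assertion and columns `citation_id`, `subject_name`, `subject_semtypes`
#' (list of semantic-type codes), `predicate`, `object_name`,
#' `object_semtypes`, `negated`, `sentence_text`. Row order is meaningful
#' (input order) and duplicate records are permitted: pattern frequencies
#' drive the saliency stage, so every occurrence counts.
#'
#' @param citation_id opaque identifiers of the source citations.
#' @param subject_name,object_name concept labels (UMLS-preferred-style
#'   strings); must be non-empty after whitespace normalization.
#' @param subject_semtypes,object_semtypes semantic-type codes per record:
#'   either a list of character vectors or a character vector of
#'   comma-joined codes (e.g. `"phsu"` or `"phsu,orch"`). Each record needs
#'   at least one code.
#' @param predicate uppercase relation labels (e.g. `"TREATS"`); the
#'   vocabulary is open -- any non-empty label is accepted.
#' @param negated logical; whether the assertion is negated.
#' @param sentence_text optional free text of the summarized sentence.
#' @param provenance free-text label describing the dataset (query, cutoff
#'   date).
#' @return an object of class `predication_set` (a tibble).
#' @examples
#' predication_set(
#'   citation_id = "PMID1", subject_name = "cetuximab",
#'   subject_semtypes = "phsu", predicate = "TREATS",
#'   object_name = "Endometrial carcinoma", object_semtypes = "neop"
#' )
#' @export
predication_set <- function(citation_id, subject_name, subject_semtypes,
                            predicate, object_name, object_semtypes,
                            negated = FALSE, sentence_text = NA_character_,
                            provenance = "") {
  n <- length(subject_name)
  df <- tibble::tibble(
    citation_id = as.character(rep_len(citation_id, n)),
    subject_name = as.character(subject_name),
    subject_semtypes = if (is.list(subject_semtypes)) subject_semtypes
      else split_semtypes(subject_semtypes),
    predicate = as.character(predicate),
    object_name = as.character(object_name),
    object_semtypes = if (is.list(object_semtypes)) object_semtypes
      else split_semtypes(object_semtypes),
    negated = rep_len(as.logical(negated), n),
    sentence_text = as.character(rep_len(sentence_text, n))
  )
  as_predication_set(df, provenance = provenance)
}

#' Coerce a data frame to a predication set
#'
#' @param df a data frame with the predication columns (semantic types either
#'   as list columns or comma-joined strings).
#' @param provenance free-text dataset label.
#' @return a `predication_set`.
#' @export
as_predication_set <- function(df, provenance = "") {
  required <- c("citation_id", "subject_name", "subject_semtypes",
                "predicate", "object_name", "object_semtypes", "negated",
                "sentence_text")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_format(paste0("missing predication columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)[required]
  if (!is.list(df$subject_semtypes)) {
    df$subject_semtypes <- split_semtypes(df$subject_semtypes)
  }
  if (!is.list(df$object_semtypes)) {
    df$object_semtypes <- split_semtypes(df$object_semtypes)
  }
  ok <- predication_valid(df)
  if (!all(ok)) {
    stop_format(sprintf("%d invalid predication record(s): %s",
                        sum(!ok),
                        paste(head(which(!ok), 5), collapse = ", ")))
  }
  structure(df, class = c("predication_set", class(tibble::tibble())),
            provenance = provenance)
}

# Record-level validity: non-empty names and predicate, >= 1 semtype each.
predication_valid <- function(df) {
  nzchar(normalize_name(df$subject_name)) &
    nzchar(normalize_name(df$object_name)) &
    nzchar(trimws(df$predicate)) &
    lengths(df$subject_semtypes) >= 1 &
    lengths(df$object_semtypes) >= 1 &
    !is.na(df$negated)
}

#' @export
print.predication_set <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<predication_set: %d record(s)%s>\n", nrow(x),
              if (nzchar(prov %||% "")) paste0(", ", prov) else ""))
  NextMethod()
}

# Row subsetting that preserves class and provenance.
subset_predications <- function(ps, keep) {
  out <- tibble::as_tibble(unclass(ps))[keep, , drop = FALSE]
  as_predication_set(out, provenance = attr(ps, "provenance") %||% "")
}

#' Read a predication file
#'
#' Two dialects are supported. `"tsv"` is the authoritative on-disk format:
#' UTF-8, tab-delimited, header row, columns `citation_id`, `subject_name`,
#' `subject_semtypes` (comma-joined), `predicate`, `object_name`,
#' `object_semtypes`, `negated` (0/1), and optional `sentence_text` last.
#' `"semrep_fielded"` is a best-effort reader for pipe-delimited exports in
#' the style `subject|semtypes|PREDICATE|object|semtypes[|...]`, optionally
#' with a leading citation-id field; unknown trailing fields are ignored and
#' a `NEG_` predicate prefix is folded into the `negated` flag.
#'
#' Malformed lines are counted and skipped, not fatal; lines starting with
#' `#` are treated as comments. The parse report is attached as the
#' `"parse_report"` attribute (`lines_read`, `kept`, `skipped`).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"semrep_fielded"`.
#' @param quiet suppress the skipped-line message.
#' @return a `predication_set` with a `parse_report` attribute.
#' @export
read_predications <- function(path, dialect = c("tsv", "semrep_fielded"),
                              quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("cannot read predication file '%s'", path),
          class = "semsumm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  parsed <- switch(dialect,
    tsv = parse_predications_tsv(lines),
    semrep_fielded = parse_predications_semrep(lines)
  )
  if (nrow(parsed$df) == 0) {
    stop_empty_input(sprintf("no well-formed predication in '%s'", path))
  }
  if (!quiet && parsed$skipped > 0) {
    message(sprintf("read_predications: skipped %d malformed line(s) in '%s'",
                    parsed$skipped, path))
  }
  ps <- as_predication_set(parsed$df, provenance = basename(path))
  attr(ps, "parse_report") <- list(lines_read = parsed$lines_read,
                                   kept = nrow(parsed$df),
                                   skipped = parsed$skipped)
  ps
}

parse_predications_tsv <- function(lines) {
  lines_read <- length(lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(list(df = empty_predication_df(), skipped = 0,
                lines_read = lines_read))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("citation_id", "subject_name", "subject_semtypes",
                "predicate", "object_name", "object_semtypes", "negated")
  if (!all(required %in% header)) {
    stop_format(paste0("TSV header must contain: ",
                       paste(required, collapse = ", ")))
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  rows <- vector("list", length(body))
  skipped <- 0L
  for (i in seq_along(body)) {
    f <- fields[[i]]
    if (length(f) < length(header) - ("sentence_text" %in% header)) {
      skipped <- skipped + 1L
      next
    }
    length(f) <- length(header)
    rec <- setNames(as.list(f), header)
    neg <- rec$negated
    if (!neg %in% c("0", "1", "TRUE", "FALSE", "true", "false")) {
      skipped <- skipped + 1L
      next
    }
    row <- tibble::tibble(
      citation_id = rec$citation_id %||% "",
      subject_name = rec$subject_name,
      subject_semtypes = split_semtypes(rec$subject_semtypes),
      predicate = trimws(rec$predicate),
      object_name = rec$object_name,
      object_semtypes = split_semtypes(rec$object_semtypes),
      negated = neg %in% c("1", "TRUE", "true"),
      sentence_text = blank_to_na(rec$sentence_text)
    )
    if (!predication_valid(row)) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) dplyr::bind_rows(rows) else empty_predication_df()
  list(df = df, skipped = skipped, lines_read = lines_read)
}

parse_predications_semrep <- function(lines) {
  lines_read <- length(lines)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  skipped <- 0L
  looks_like_predicate <- function(x) grepl("^(NEG_)?[A-Z_]+$", x)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "|", fixed = TRUE)[[1]]
    # Layout without citation id: subject at slot 1, predicate at slot 3;
    # layout with a leading citation id shifts everything right by one.
    at <- if (length(f) >= 5 && looks_like_predicate(trimws(f[3]))) 0L
          else if (length(f) >= 6 && looks_like_predicate(trimws(f[4]))) 1L
          else NA_integer_
    if (is.na(at)) {
      skipped <- skipped + 1L
      next
    }
    pred <- trimws(f[3 + at])
    row <- tibble::tibble(
      citation_id = if (at == 1L) trimws(f[1]) else "",
      subject_name = trimws(f[1 + at]),
      subject_semtypes = split_semtypes(f[2 + at]),
      predicate = sub("^NEG_", "", pred),
      object_name = trimws(f[4 + at]),
      object_semtypes = split_semtypes(f[5 + at]),
      negated = startsWith(pred, "NEG_"),
      sentence_text = NA_character_
    )
    if (!predication_valid(row)) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) dplyr::bind_rows(rows) else empty_predication_df()
  list(df = df, skipped = skipped, lines_read = lines_read)
}

blank_to_na <- function(x) {
  x <- as.character(x %||% NA_character_)
  x[is.na(x) | !nzchar(trimws(x))] <- NA_character_
  x
}

empty_predication_df <- function() {
  tibble::tibble(citation_id = character(), subject_name = character(),
                 subject_semtypes = list(), predicate = character(),
                 object_name = character(), object_semtypes = list(),
                 negated = logical(), sentence_text = character())
}

#' Write a predication set in the TSV dialect
#'
#' Inverse of [read_predications()] for `dialect = "tsv"`: field values and
#' record order round-trip exactly (missing `sentence_text` is written as an
#' empty field and read back as `NA`).
#'
#' @param ps a `predication_set`.
#' @param path output path.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_predications <- function(ps, path, header_comments = NULL) {
  cols <- c("citation_id", "subject_name", "subject_semtypes", "predicate",
            "object_name", "object_semtypes", "negated", "sentence_text")
  body <- paste(
    ps$citation_id, ps$subject_name, join_semtypes(ps$subject_semtypes),
    ps$predicate, ps$object_name, join_semtypes(ps$object_semtypes),
    as.integer(ps$negated),
    ifelse(is.na(ps$sentence_text), "", ps$sentence_text),
    sep = "\t"
  )
  out <- c(
    if (length(header_comments)) paste0("# ", header_comments),
    paste(cols, collapse = "\t"),
    body
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a background predicate distribution
#'
#' The background (distribution Q of the saliency stage) is a predicate
#' frequency table from a broad literature corpus -- in the original setting,
#' a decade of citations processed into predications with only the subject
#' focus. Any such table is accepted; relative frequencies are
#' `count / total`.
#'
#' @param counts named non-negative numeric vector, predicate -> count.
#' @return an object of class `background_distribution` with elements
#'   `counts` and `total`.
#' @examples
#' bg <- background_distribution(c(TREATS = 50, AFFECTS = 50))
#' relative_frequencies(bg)
#' @export
background_distribution <- function(counts) {
  if (length(counts) == 0) {
    stop_empty_input("background distribution has no predicates")
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be named by predicate",
          class = "semsumm_argument_error")
  }
  assert_count(counts, "counts", min = 0)
  counts <- counts[!duplicated(names(counts))]
  structure(list(counts = counts, total = sum(counts)),
            class = "background_distribution")
}

#' @export
print.background_distribution <- function(x, ...) {
  cat(sprintf("<background_distribution: %d predicate(s), total %s>\n",
              length(x$counts), format(x$total)))
  invisible(x)
}

#' Relative frequencies of a distribution
#'
#' Converts counts to a proper relative-frequency vector. Zero-count
#' predicates are dropped, so all returned frequencies are strictly positive
#' and sum to one.
#'
#' @param x a `background_distribution`, a `predicate_distribution`, or a
#'   named count vector.
#' @return a `predicate_distribution`: named numeric vector of relative
#'   frequencies.
#' @export
relative_frequencies <- function(x) {
  if (inherits(x, "predicate_distribution")) return(x)
  counts <- if (inherits(x, "background_distribution")) x$counts else x
  if (length(counts) == 0 || sum(counts) <= 0) {
    stop_empty_input("distribution has no mass")
  }
  counts <- counts[counts > 0]
  structure(counts / sum(counts), class = "predicate_distribution")
}

#' Read a background predicate table
#'
#' Expects a two-column tab-delimited file `predicate<TAB>count`; counts
#' must be non-negative integers. Lines starting with `#` and blank lines
#' are ignored.
#'
#' @param path path to the file.
#' @return a `background_distribution`.
#' @export
read_background <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read background file '%s'", path),
          class = "semsumm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0) {
    stop_empty_input(sprintf("background file '%s' is empty", path))
  }
  counts <- numeric(length(idx))
  preds <- character(length(idx))
  for (j in seq_along(idx)) {
    f <- strsplit(lines[[idx[j]]], "\t", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2 || !nzchar(trimws(f[1])) || is.na(val) ||
        val < 0 || val != floor(val)) {
      stop_format(sprintf("background file '%s': bad count on line %d",
                          path, idx[j]))
    }
    preds[j] <- trimws(f[1])
    counts[j] <- val
  }
  background_distribution(setNames(counts, preds))
}

#' Write a background predicate table
#'
#' @param bg a `background_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  writeLines(paste(names(bg$counts), format(bg$counts, scientific = FALSE,
                                            trim = TRUE), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Construct a reference standard
#'
#' A reference standard is a vetted list of interventions for one disease
#' topic / point-of-view pairing, used as ground truth for recall and
#' precision. Entries are normalized (lower-cased, whitespace-collapsed) and
#' de-duplicated; the original order and spelling are kept for reporting.
#'
#' @param interventions character vector of intervention names.
#' @param pairing_label disease topic + point-of-view tag.
#' @return an object of class `reference_standard` with elements
#'   `interventions` (normalized, unique), `display` (original spellings),
#'   and `pairing_label`.
#' @export
reference_standard <- function(interventions, pairing_label = "") {
  interventions <- as.character(interventions)
  interventions <- interventions[nzchar(normalize_name(interventions))]
  if (length(interventions) == 0) {
    stop_empty_input("reference standard has no interventions")
  }
  norm <- normalize_name(interventions)
  keep <- !duplicated(norm)
  structure(list(interventions = norm[keep],
                 display = trimws(interventions[keep]),
                 pairing_label = pairing_label),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat(sprintf("<reference_standard: %d intervention(s)%s>\n",
              length(x$interventions),
              if (nzchar(x$pairing_label)) paste0(", ", x$pairing_label)
              else ""))
  invisible(x)
}

#' Read a reference standard
#'
#' Plain UTF-8 text, one intervention per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path path to the file.
#' @param pairing_label disease topic + point-of-view tag.
#' @return a `reference_standard`.
#' @export
read_reference_standard <- function(path, pairing_label = basename(path)) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read reference standard '%s'", path),
          class = "semsumm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    stop_empty_input(sprintf("reference standard '%s' is empty", path))
  }
  reference_standard(lines, pairing_label = pairing_label)
}

#' Construct a novelty stoplist
#'
#' The Novelty tier removes vague predications whose arguments are too
#' general to be informative (e.g. *pharmaceutical preparation*-TREATS-
#' *patients*). In the absence of an ontology generality model, membership
#' in a configurable stoplist of generic concept names stands in; matching
#' is case-insensitive.
#'
#' @param generic_names character vector of generic concept labels.
#' @return an object of class `novelty_stoplist`.
#' @seealso [default_stoplist()]
#' @export
novelty_stoplist <- function(generic_names) {
  norm <- unique(normalize_name(as.character(generic_names)))
  structure(list(generic_names = norm[nzchar(norm)]),
            class = "novelty_stoplist")
}

#' Read a stoplist file
#'
#' One concept name per line; blank lines and `#` comments ignored. An empty
#' file yields an empty stoplist (the Novelty tier then passes everything).
#'
#' @param path path to the file.
#' @return a `novelty_stoplist`.
#' @export
read_stoplist <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read stoplist '%s'", path),
          class = "semsumm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  novelty_stoplist(lines)
}

#' Default novelty stoplist
#'
#' A short list of generic clinical concepts shipped with the package
#' (`pharmaceutical preparation`, `patients`, `intervention regimes`, ...).
#' Users summarizing real exports should extend it for their domain.
#'
#' @return a `novelty_stoplist`.
#' @export
default_stoplist <- function() {
  read_stoplist(system.file("extdata", "generic_stoplist.txt",
                            package = "semsumm", mustWork = TRUE))
}

#' Read an alias map
#'
#' Two-column tab-delimited file `system_term<TAB>reference_term`, used
#' during evaluation to credit a system output term to a reference-standard
#' intervention it names less directly. Matching stays auditable: only
#' explicitly listed aliases are applied, there is no fuzzy matching.
#'
#' @param path path to the file.
#' @return named character vector: normalized system term -> normalized
#'   reference term.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read alias map '%s'", path),
          class = "semsumm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop_format(sprintf("alias map '%s': expected two fields on line %d",
                        path, bad[1]))
  }
  setNames(normalize_name(vapply(parts, `[`, character(1), 2)),
           normalize_name(vapply(parts, `[`, character(1), 1)))
}
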