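#' Construct a term-frequency table
#'
#' The baseline summarizer operates on a plain term -> count table for one
#' disease topic / point-of-view group (in the original setting, concept
#' mentions mapped from the citation text; any tokenizer may feed it).
#'
#' @param counts named vector of positive integer term counts.
#' @param group_label disease / point-of-view tag.
#' @return an object of class `term_frequency_table` with elements
#'   `counts`, `group_label`, `unique_terms`, `total`.
#' @export
term_frequency_table <- function(counts, group_label = "") {
  if (length(counts) == 0) {
    stop_empty_input("term-frequency table has no terms")
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be named by term", class = "semsumm_argument_error")
  }
  assert_count(counts, "counts", min = 1)
  counts <- counts[!duplicated(names(counts))]
  structure(list(counts = counts, group_label = group_label,
                 unique_terms = length(counts), total = sum(counts)),
            class = "term_frequency_table")
}

#' Read a term-frequency table
#'
#' Two-column tab-delimited file `term<TAB>count`; counts must be positive
#' integers.
#'
#' @param path path to the file.
#' @param group_label disease / point-of-view tag.
#' @return a `term_frequency_table`.
#' @export
read_term_table <- function(path, group_label = basename(path)) {
  bg <- read_background(path) # same 2-column format and validation
  if (any(bg$counts < 1)) {
    stop_format(sprintf("term table '%s': counts must be >= 1", path))
  }
  term_frequency_table(bg$counts, group_label = group_label)
}

#' Whitespace-token term counting
#'
#' A bundled fallback tokenizer for building term tables from raw text
#' lines when no concept mapper is available: lower-cases, strips
#' punctuation at token edges, and counts whitespace-delimited tokens.
#'
#' @param lines character vector of text lines.
#' @param group_label disease / point-of-view tag.
#' @return a `term_frequency_table`.
#' @export
term_table_from_lines <- function(lines, group_label = "") {
  tokens <- unlist(strsplit(tolower(lines), "\\s+"))
  tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) stop_empty_input("no tokens in input lines")
  counts <- table(tokens)
  term_frequency_table(setNames(as.numeric(counts), names(counts)),
                       group_label = group_label)
}

#' Frequency-threshold baseline
#'
#' Simulates what a busy clinician might notice when scanning citations:
#' the threshold is the mean term frequency of the group plus one standard
#' deviation, and terms whose count strictly exceeds it are retained. The
#' term table is treated as the entire group, so the population (divide by
#' N) standard deviation is the default; `sd_type = "sample"` switches to
#' the N-1 estimator.
#'
#' @param table a `term_frequency_table`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return an object of class `baseline_result`: a list with `mean`, `sd`,
#'   `threshold` (= mean + sd) and `retained`, a tibble of `(term, count)`
#'   sorted by descending count then term.
#' @examples
#' tab <- term_frequency_table(c(digoxin = 250, diuretic = 40, salt = 10))
#' frequency_threshold(tab)
#' @export
frequency_threshold <- function(table, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(table, "term_frequency_table"))
  x <- as.numeric(table$counts)
  m <- table$total / table$unique_terms
  s <- if (sd_type == "population") sqrt(mean((x - m)^2)) else stats::sd(x)
  if (is.na(s)) s <- 0 # single-term table under the sample estimator
  thr <- m + s
  keep <- which(x > thr)
  retained <- tibble::tibble(term = names(table$counts)[keep],
                             count = x[keep]) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$term)
  structure(list(mean = m, sd = s, threshold = thr, retained = retained,
                 sd_type = sd_type, group_label = table$group_label),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf(
    "Frequency-threshold baseline%s\n  mean %.1f + sd %.1f = threshold %.1f; %d term(s) retained\n",
    if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else "",
    x$mean, x$sd, x$threshold, nrow(x$retained)))
  invisible(x)
}

#' Prevention trigger-phrase line filter
#'
#' For prevention groups the baseline first narrows the citation text to
#' the lines mentioning prevention, by case-insensitive substring match on
#' a configurable trigger-phrase list, before term counting.
#'
#' @param citation_text character vector of text lines.
#' @param phrases trigger phrases; the defaults are `"prevent"`,
#'   `"prevents"`, `"for prevention of"`, `"for the prevention of"`.
#' @return the matching lines, order preserved.
#' @export
prevention_line_filter <- function(citation_text,
                                   phrases = c("prevent", "prevents",
                                               "for prevention of",
                                               "for the prevention of")) {
  low <- tolower(citation_text)
  phrases <- tolower(phrases)
  keep <- vapply(low, function(line) {
    any(vapply(phrases, grepl, logical(1), x = line, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  citation_text[keep]
}

#' Exclude term categories from a table
#'
#' Drops terms whose mapped category is excluded -- e.g. removing the
#' disorders semantic group from a prevention baseline, since the focus is
#' the preventive interventions rather than the diseases themselves. Terms
#' missing from the map are retained; matching is name-normalized.
#'
#' @param table a `term_frequency_table`.
#' @param category_map named character vector, term -> category.
#' @param excluded character vector of excluded categories.
#' @return the filtered `term_frequency_table`.
#' @export
category_exclusion <- function(table, category_map, excluded) {
  stopifnot(inherits(table, "term_frequency_table"))
  if (length(excluded) == 0 || length(category_map) == 0) return(table)
  names(category_map) <- normalize_name(names(category_map))
  cats <- category_map[normalize_name(names(table$counts))]
  keep <- is.na(cats) | !(cats %in% excluded)
  if (!any(keep)) {
    stop_empty_input("category exclusion removed every term")
  }
  term_frequency_table(table$counts[keep], group_label = table$group_label)
}

#' Read a term -> category map
#'
#' Two-column tab-delimited file `term<TAB>category`.
#'
#' @param path path to the file.
#' @return named character vector, term -> category.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read category map '%s'", path),
          class = "semsumm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop_format(sprintf("category map '%s': expected two fields on line %d",
                        path, bad[1]))
  }
  setNames(trimws(vapply(parts, `[`, character(1), 2)),
           trimws(vapply(parts, `[`, character(1), 1)))
}
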