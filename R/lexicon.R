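#' Category and weighted lexicons
#'
#' A category lexicon is a set of lower-case literal tokens and prefix
#' patterns (a single trailing `*` matches any continuation, the usual
#' word-count dictionary convention); its score is the percentage of a
#' day's words that match. A weighted lexicon maps terms to real weights
#' plus an intercept; its score is the weighted sum of relative term
#' frequencies, the standard linear form for lexicon-based trait models.
#'
#' @param name identifier (used as the feature column name).
#' @param terms character vector of literals and `prefix*` patterns.
#' @return object of class `category_lexicon`.
#' @export
category_lexicon <- function(name, terms) {
  terms <- tolower(trimws(terms))
  if (length(terms) == 0 || any(!nzchar(sub("\\*$", "", terms))))
    stop_("category lexicon '%s' has empty terms", name)
  structure(list(name = name,
                 literals = terms[!grepl("\\*$", terms)],
                 prefixes = sub("\\*$", "", terms[grepl("\\*$", terms)])),
            class = "category_lexicon")
}

#' @rdname category_lexicon
#' @param weights named numeric vector of term weights (at least one nonzero).
#' @param intercept intercept added to every score.
#' @export
weighted_lexicon <- function(name, weights, intercept = 0) {
  if (length(weights) == 0 || all(weights == 0))
    stop_("weighted lexicon '%s' needs at least one nonzero weight", name)
  names(weights) <- tolower(names(weights))
  structure(list(name = name, weights = weights, intercept = intercept),
            class = "weighted_lexicon")
}

#' Read lexicons from delimited text
#'
#' Category files have columns `category, term` (one file may define several
#' categories); weighted files have columns `term, weight` with the reserved
#' term `_intercept`. Both are lower-cased on load.
#'
#' @param path CSV file.
#' @return a list of `category_lexicon` objects, or one `weighted_lexicon`
#'   named after the file.
#' @export
read_category_lexicons <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("category", "term") %in% names(df)))
  sp <- split(tolower(df$term), tolower(df$category))
  Map(category_lexicon, names(sp), sp)
}

#' @rdname read_category_lexicons
#' @export
read_weighted_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = c(term = "character",
                                             weight = "numeric"))
  df$term <- tolower(df$term)
  ic <- df$term == "_intercept"
  weighted_lexicon(sub("\\.csv$", "", basename(path)),
                   stats::setNames(df$weight[!ic], df$term[!ic]),
                   intercept = if (any(ic)) df$weight[ic][1] else 0)
}

# word match indicator against a category lexicon (each word counted at most
# once per category, literal/prefix overlap notwithstanding)
match_category <- function(words, lex) {
  hit <- words %in% lex$literals
  for (p in lex$prefixes) hit <- hit | startsWith(words, p)
  hit
}

#' Score one word bag against a lexicon
#'
#' `score_category()` returns 100 times the fraction of the day's total
#' words matching any term (a LIWC-style percent, in \[0, 100\]).
#' `score_weighted()` returns `intercept + sum(weight * count/total)`.
#' An empty bag scores `NA`: a day with no typing carries no language
#' signal and must not be conflated with zero category usage.
#'
#' @param bag named integer vector (word -> count) or data frame with
#'   `word` and `count` columns.
#' @param lex a [category_lexicon()] or [weighted_lexicon()].
#' @return numeric scalar, `NA` for an empty bag.
#' @examples
#' score_category(c(i = 2, happy = 1, dog = 1),
#'                category_lexicon("self", c("i", "me", "my")))  # 50
#' @export
score_category <- function(bag, lex) {
  b <- as_bag(bag)
  if (b$total == 0) return(NA_real_)
  100 * sum(b$count[match_category(b$word, lex)]) / b$total
}

#' @rdname score_category
#' @export
score_weighted <- function(bag, lex) {
  b <- as_bag(bag)
  if (b$total == 0) return(NA_real_)
  idx <- match(names(lex$weights), b$word)
  rel <- ifelse(is.na(idx), 0, b$count[idx] / b$total)
  lex$intercept + sum(lex$weights * rel)
}

as_bag <- function(bag) {
  if (is.data.frame(bag)) {
    w <- tolower(bag$word); cnt <- bag$count
  } else {
    w <- tolower(names(bag)); cnt <- as.numeric(bag)
  }
  if (length(w) && anyDuplicated(w)) {      # canonical aggregation
    cnt <- tapply(cnt, w, sum)
    w <- names(cnt); cnt <- as.numeric(cnt)
  }
  list(word = w, count = cnt, total = sum(cnt))
}

#' Build the language feature matrix from daily word bags
#'
#' One row per participant-day present in the input (days with no words are
#' absent, i.e. missing, not zero); columns are the raw `word_count`
#' followed by one column per lexicon in the order given. Duplicate
#' (participant, date, word) rows are aggregated first, so the result is
#' invariant to input row order and to splitting a word's count across rows.
#'
#' @param bags long word-bag table: `participant_id`, `date`, `word`,
#'   `count`.
#' @param category_lexicons,weighted_lexicons lists of lexicons with unique
#'   names across both.
#' @return data frame (`participant_id`, `date`, `word_count`, features),
#'   class `feature_matrix`.
#' @export
build_feature_matrix <- function(bags, category_lexicons = list(),
                                 weighted_lexicons = list()) {
  nm <- c(vapply(category_lexicons, `[[`, "", "name"),
          vapply(weighted_lexicons, `[[`, "", "name"))
  if (anyDuplicated(c("word_count", nm)))
    stop_("duplicate feature names: %s",
          paste(unique(nm[duplicated(c("word_count", nm))[-1]]), collapse = ", "))
  bags$word <- tolower(bags$word)
  key <- paste(bags$participant_id, bags$date, sep = "\r")
  agg_key <- paste(key, bags$word, sep = "\r")
  if (anyDuplicated(agg_key)) {
    cnt <- rowsum(bags$count, agg_key)
    parts <- do.call(rbind, strsplit(rownames(cnt), "\r", fixed = TRUE))
    bags <- data.frame(participant_id = parts[, 1], date = parts[, 2],
                       word = parts[, 3], count = as.numeric(cnt))
    key <- paste(bags$participant_id, bags$date, sep = "\r")
  }
  ukey <- sort(unique(key))
  ridx <- match(key, ukey)
  total <- as.numeric(rowsum(bags$count, ridx))
  uw <- unique(bags$word)
  out <- data.frame(matrix(NA_real_, length(ukey), length(nm),
                           dimnames = list(NULL, nm)), check.names = FALSE)
  for (lex in category_lexicons) {
    hit <- match_category(uw, lex)[match(bags$word, uw)]
    matched <- as.numeric(rowsum(bags$count * hit, ridx))
    out[[lex$name]] <- 100 * matched / total
  }
  for (lex in weighted_lexicons) {
    wl <- lex$weights[match(bags$word, names(lex$weights))]
    wl[is.na(wl)] <- 0
    out[[lex$name]] <- lex$intercept +
      as.numeric(rowsum(bags$count * wl, ridx)) / total
  }
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  res <- data.frame(participant_id = parts[, 1],
                    date = as.Date(parts[, 2]),
                    word_count = total,
                    out, check.names = FALSE)
  class(res) <- c("feature_matrix", "data.frame")
  res
}

#' Standardise feature columns to mean 0, sd 1
#'
#' Z-scores every feature column (all columns except the row keys and the
#' raw `word_count`) using the mean and sample standard deviation
#' (denominator n-1) computed on `fit_rows` only, and stores the parameters
#' in `attr(, "normalization")` for reuse. Inside the split-half workflow
#' the fitting rows are the identification half, so validation data never
#' leak into the scaling. Missing cells stay missing. A normalised copy of
#' word count (`word_count_z`) is added as a candidate feature; the raw
#' column is kept for the extreme-count mask.
#'
#' @param matrix a [build_feature_matrix()] result.
#' @param fit_rows logical or integer row selector; default all rows.
#' @return the matrix with feature columns standardised.
#' @export
normalize_features <- function(matrix, fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(matrix))
  if (!"word_count_z" %in% names(matrix))
    matrix$word_count_z <- matrix$word_count
  cols <- setdiff(names(matrix), c("participant_id", "date", "word_count"))
  params <- list()
  for (cl in cols) {
    x <- matrix[[cl]][fit_rows]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2)
      stop_("cannot normalize zero-variance feature column '%s'", cl)
    m <- mean(x); s <- stats::sd(x)
    matrix[[cl]] <- (matrix[[cl]] - m) / s
    params[[cl]] <- c(mean = m, sd = s)
  }
  attr(matrix, "normalization") <- params
  matrix
}
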