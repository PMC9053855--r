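#' Keyword intelligibility score of one trial
#'
#' Percentage of a sentence's keywords that appear in the listener's
#' report. Matching is case-insensitive exact word matching after
#' punctuation stripping; each keyword is credited at most once, and a
#' reported word can credit only one keyword (multiset matching, so a
#' duplicated report word earns no double credit). Optional prefix
#' stemming treats a report word as matching when one is a prefix of the
#' other sharing at least `stem_min` characters.
#'
#' @param keywords character vector (or single space-separated string) of
#'   the sentence's keywords
#' @param reported character vector (or single string) of the listener's
#'   reported words
#' @param stem if `TRUE`, use prefix-stem matching instead of exact
#' @param stem_min minimum shared prefix length for a stem match
#' @return percent correct in `[0, 100]`
#' @export
intelligibility <- function(keywords, reported, stem = FALSE, stem_min = 4) {
  kw <- normalize_words(keywords)
  if (length(kw) == 0) stop("empty keyword list")
  rep_words <- normalize_words(reported)
  matched <- 0L
  for (k in kw) {
    hit <- if (stem) {
      which(substr(rep_words, 1, stem_min) == substr(k, 1, stem_min))
    } else {
      which(rep_words == k)
    }
    if (length(hit) > 0) {
      matched <- matched + 1L
      rep_words <- rep_words[-hit[1]]
    }
  }
  100 * matched / length(kw)
}

normalize_words <- function(x) {
  x <- paste(x, collapse = " ")
  x <- tolower(gsub("[^a-z0-9' ]", " ", tolower(x)))
  words <- strsplit(trimws(x), "\\s+")[[1]]
  words[nzchar(words)]
}

#' Compare stimulation and sham arms with Wilcoxon rank-sum tests
#'
#' Scores every trial (MOS as given; intelligibility via
#' [intelligibility()]), then, within each condition block
#' (`noise_type` x `snr_db` x `current_ma`), compares the stim and sham
#' arms with a two-sided Wilcoxon rank-sum test. The exact null
#' distribution is used for small untied samples and the normal
#' approximation with tie correction otherwise. One-armed blocks are
#' skipped with a warning.
#'
#' @param trials data.frame of behavioral trials (see
#'   [simulate_behavior_trials()] for the columns)
#' @param measure `"mos"` or `"intelligibility"`
#' @param stem passed to [intelligibility()]
#' @return data.frame with one row per block: block labels, arm ns, arm
#'   means and medians, `w` statistic and `p`
#' @export
compare_arms <- function(trials, measure = c("mos", "intelligibility"),
                         stem = FALSE) {
  measure <- match.arg(measure)
  stopifnot(all(c("condition", "mos") %in% names(trials)))
  score <- if (measure == "mos") as.numeric(trials$mos) else {
    vapply(seq_len(nrow(trials)), function(i) {
      intelligibility(trials$sentence_keywords[i], trials$reported_words[i],
                      stem = stem)
    }, numeric(1))
  }
  for (col in c("noise_type", "snr_db", "current_ma")) {
    if (is.null(trials[[col]])) trials[[col]] <- "all"
  }
  blocks <- unique(trials[, c("noise_type", "snr_db", "current_ma")])
  out <- lapply(seq_len(nrow(blocks)), function(b) {
    in_block <- trials$noise_type == blocks$noise_type[b] &
      trials$snr_db == blocks$snr_db[b] &
      trials$current_ma == blocks$current_ma[b]
    x <- score[in_block & trials$condition == "stim"]
    y <- score[in_block & trials$condition == "sham"]
    if (length(x) < 2 || length(y) < 2) {
      warning("block skipped (fewer than 2 trials in an arm): ",
              paste(unlist(blocks[b, ]), collapse = "/"))
      return(NULL)
    }
    wt <- rank_sum_test(x, y)
    data.frame(
      blocks[b, , drop = FALSE],
      n_stim = length(x), n_sham = length(y),
      mean_stim = mean(x), mean_sham = mean(y),
      median_stim = stats::median(x), median_sham = stats::median(y),
      w = wt$statistic, p = wt$p.value,
      row.names = NULL
    )
  })
  do.call(rbind, out)
}

#' Two-sided Wilcoxon rank-sum test with an exact small-sample path
#'
#' For arms of at most `exact_max` observations each, the two-sided p
#' value is computed from the exhaustive permutation distribution of the
#' rank sum (midranks under ties, so the exact path handles tied data —
#' which the classical exact tables cannot). Larger samples use the
#' normal approximation with tie correction via [stats::wilcox.test()].
#'
#' @param x,y the two samples
#' @param exact_max largest per-arm size for the exact path (default 10)
#' @return list: `statistic` (rank sum of `x`), `p.value`, `exact`
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    mu <- n1 * (n1 + n2 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    list(statistic = w_obs, p.value = p, exact = TRUE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(statistic = w_obs, p.value = wt$p.value, exact = FALSE)
  }
}
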