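#' Category distribution of a labeled group
#'
#' Exact integer counts over the 8 categories with percentage shares rounded
#' half-up to 2 decimal places (the convention of printed share tables).
#'
#' @param counts Named integer vector of per-category counts (names from
#'   \code{chatmood_categories()}; missing categories count 0), or a
#'   character vector of labels to be tabulated when \code{tabulate = TRUE}.
#' @param group Group name (e.g. \code{"Eastern"}).
#' @param tabulate If \code{TRUE}, \code{counts} is a label vector.
#' @return Object of class \code{category_distribution}: list with
#'   \code{group}, \code{counts}, \code{total}, \code{percent}.
#' @examples
#' category_distribution(c(apathy_sadness = 74045), "chatbot_total",
#'                       total = 148590)
#' @param total Optional explicit denominator (defaults to
#'   \code{sum(counts)}); lets printed numerator/denominator pairs be
#'   reproduced even when not all cells are published.
#' @export
category_distribution <- function(counts, group, tabulate = FALSE,
                                  total = NULL) {
  cats <- chatmood_categories()
  if (tabulate) {
    bad <- setdiff(unique(counts), cats)
    if (length(bad) > 0)
      stop("invalid category label(s): ", paste(sQuote(bad), collapse = ", "),
           call. = FALSE)
    counts <- table(factor(counts, levels = cats))
  }
  full <- stats::setNames(integer(length(cats)), cats)
  full[names(counts)] <- as.integer(counts)
  if (is.null(total)) total <- sum(full)
  if (total == 0) stop("distribution has zero total", call. = FALSE)
  structure(list(group = group, counts = full, total = as.integer(total),
                 percent = round_half_up(100 * full / total, 2)),
            class = "category_distribution")
}

#' Per-group category shares of classified utterances
#'
#' @param labels Named character vector (utterance id -> category).
#' @param groups Named character vector (utterance id -> group) aligned by
#'   id.
#' @return Named list of \code{\link{category_distribution}}, one per group.
#' @export
category_shares <- function(labels, groups) {
  stopifnot(!is.null(names(labels)), !is.null(names(groups)))
  groups <- groups[names(labels)]
  if (anyNA(groups)) stop("every labeled item needs a group", call. = FALSE)
  out <- lapply(split(labels, groups), function(lab)
    category_distribution(unname(lab), group = "", tabulate = TRUE))
  for (g in names(out)) out[[g]]$group <- g
  out
}

#' @export
print.category_distribution <- function(x, ...) {
  cat("<category_distribution> ", x$group, " (n = ", x$total, ")\n", sep = "")
  df <- data.frame(count = x$counts, percent = x$percent)
  print(df)
  invisible(x)
}

pearson_2x2 <- function(a1, n1, a2, n2) {
  # [in-category vs not] x [group1 vs group2], no continuity correction
  obs <- matrix(c(a1, n1 - a1, a2, n2 - a2), 2, 2, byrow = TRUE)
  expct <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expct)^2 / expct)
  list(statistic = stat, expected = expct)
}

#' Per-category Pearson chi-square comparison of two groups
#'
#' For each category, the 2x2 table (in-category vs not) x (group A vs
#' group B) is tested with Pearson's chi-square on 1 df, without continuity
#' correction (large-sample setting; enable \code{correct} for small
#' samples). Cells with an expected count below 1 are flagged unreliable.
#'
#' @param dist_a,dist_b \code{\link{category_distribution}} objects.
#' @param correct Apply the Yates continuity correction?
#' @return Data frame: category, statistic, df, p, unreliable.
#' @export
per_category_chi_square <- function(dist_a, dist_b, correct = FALSE) {
  stopifnot(dist_a$total > 0, dist_b$total > 0)
  cats <- names(dist_a$counts)
  rows <- lapply(cats, function(cat) {
    a1 <- dist_a$counts[[cat]]; a2 <- dist_b$counts[[cat]]
    obs <- matrix(c(a1, dist_a$total - a1, a2, dist_b$total - a2),
                  2, 2, byrow = TRUE)
    expct <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    adj <- if (correct) pmin(abs(obs - expct), 0.5) else 0
    stat <- sum((abs(obs - expct) - adj)^2 / expct)
    data.frame(category = cat, statistic = stat, df = 1L,
               p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               unreliable = any(expct < 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall 2 x 8 chi-square test of homogeneity
#'
#' @param dist_a,dist_b \code{\link{category_distribution}} objects.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
overall_chi_square <- function(dist_a, dist_b) {
  obs <- rbind(dist_a$counts, dist_b$counts)
  obs <- obs[, colSums(obs) > 0, drop = FALSE]
  expct <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expct)^2 / expct)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' The packaged cross-platform reference distribution
#'
#' Category shares of depressive discourse on Twitter as printed in the
#' comparison this package reproduces, with a per-cell provenance note. Only
#' cells with a printed source are present; the hiding-behind-a-mask cell
#' carries a flagged discrepancy between its printed percent (11.93) and
#' printed fraction (256/1978 = 12.94) and is stored verbatim.
#'
#' @return List with \code{platform}, \code{total}, and \code{categories}
#'   (per-cell \code{percent}, \code{numerator}, \code{provenance}).
#' @export
twitter_reference <- function() {
  jsonlite::fromJSON(chatmood_extdata("twitter_reference.json"),
                     simplifyVector = FALSE)
}

#' Compare a category distribution against a reference distribution
#'
#' Side-by-side percentage shares with differences; categories absent from
#' the reference appear as \code{NA}, never imputed.
#'
#' @param dist A \code{\link{category_distribution}}.
#' @param ref A reference distribution (see \code{\link{twitter_reference}}).
#' @return Data frame: category, percent, ref_percent, difference.
#' @export
compare_to_reference <- function(dist, ref) {
  cats <- names(dist$counts)
  ref_pct <- vapply(cats, function(cat) {
    cell <- ref$categories[[cat]]
    if (is.null(cell)) NA_real_ else cell$percent
  }, numeric(1))
  data.frame(category = cats,
             percent = unname(dist$percent),
             ref_percent = unname(ref_pct),
             difference = unname(dist$percent - ref_pct),
             stringsAsFactors = FALSE)
}

#' Render an analysis report
#'
#' Deterministic human-readable markdown plus, when \code{path} is given,
#' machine-readable JSON and TSV companions. The report header records the
#' seed, configuration hash and package version so any artifact names the
#' run that produced it.
#'
#' @param results Named list of result sections. Recognised names:
#'   \code{welch} (data frame), \code{ngrams} (data frame), \code{hourly}
#'   (output of \code{\link{hourly_profile}}), \code{agreement} (output of
#'   \code{\link{fleiss_kappa}}), \code{metrics} (data frame), \code{shares}
#'   (list of \code{category_distribution}), \code{chi_square} (data frame),
#'   \code{reference} (data frame). Missing sections render as "no results".
#' @param seed Seed to record.
#' @param config Configuration object to hash into the header.
#' @param path Optional output stem; writes \code{<path>.md},
#'   \code{<path>.json}, and a TSV per tabular section.
#' @return The markdown report as a character vector, invisibly when written.
#' @export
render_report <- function(results = list(), seed = NA, config = NULL,
                          path = NULL) {
  version <- as.character(utils::packageVersion("chatmood"))
  hash <- object_hash(list(config = config, seed = seed))
  fmt_df <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(no results)")
    txt <- utils::capture.output(print(df, row.names = FALSE, digits = 4))
    paste0("    ", txt)
  }
  lines <- c("# chatmood analysis report", "",
             paste0("- package version: ", version),
             paste0("- seed: ", seed),
             paste0("- config hash: ", hash), "")
  sections <- list(
    welch = "## Lexicon contrasts (Welch t tests)",
    ngrams = "## Top n-grams",
    metrics = "## Classifier metrics",
    chi_square = "## Per-category chi-square (East vs West)",
    reference = "## Cross-platform comparison")
  for (key in names(sections)) {
    lines <- c(lines, sections[[key]], "", fmt_df(results[[key]]), "")
  }
  lines <- c(lines, "## Diurnal profiles", "")
  if (is.null(results$hourly) || length(results$hourly) == 0) {
    lines <- c(lines, "(no results)", "")
  } else {
    for (h in results$hourly)
      lines <- c(lines, sprintf("- %s: peak hour %d (n = %d)",
                                h$region, h$peak_hour, h$n))
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Inter-rater agreement", "")
  if (is.null(results$agreement)) {
    lines <- c(lines, "(no results)", "")
  } else {
    lines <- c(lines, sprintf("- Fleiss kappa: %.4f (%d items, %d raters)",
                              results$agreement$kappa,
                              results$agreement$n_items,
                              results$agreement$n_raters), "")
  }
  lines <- c(lines, "## Category shares", "")
  if (is.null(results$shares) || length(results$shares) == 0) {
    lines <- c(lines, "(no results)", "")
  } else {
    for (d in results$shares) {
      lines <- c(lines, sprintf("### %s (n = %d)", d$group, d$total),
                 sprintf("- %s: %d (%.2f%%)", names(d$counts), d$counts,
                         d$percent), "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".md"), useBytes = TRUE)
    jsonlite::write_json(
      list(version = version, seed = seed, config_hash = hash,
           results = results),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    for (key in names(sections)) {
      df <- results[[key]]
      if (!is.null(df) && is.data.frame(df))
        utils::write.table(df, paste0(path, "_", key, ".tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    return(invisible(lines))
  }
  lines
}
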