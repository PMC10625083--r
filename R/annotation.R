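#' The eight depressive-discourse categories
#'
#' Fixed, ordered category scheme for classifying depressive-mood utterances:
#' dysfunctional thoughts (negative, hopeless self-evaluation), lifestyle
#' challenges (trouble eating/sleeping/functioning), social struggles
#' (relationships and loneliness), hiding behind a mask (pretending to be OK),
#' apathy and sadness (sadness and emptiness), suicidal thoughts and
#' behaviors, seeking relief, and a residual "etc" class for everything else
#' (including utterances directed at the bot's own mood).
#'
#' @return Character vector of the 8 category identifiers, in fixed order.
#' @export
chatmood_categories <- function() {
  c("dysfunctional_thoughts", "lifestyle_challenges", "social_struggles",
    "hiding_behind_mask", "apathy_sadness", "suicidal_thoughts",
    "seeking_relief", "etc")
}

check_annotation_matrix <- function(m, categories = chatmood_categories()) {
  stopifnot(is.matrix(m), nrow(m) >= 1, ncol(m) >= 1)
  if (anyNA(m)) stop("annotation matrix has missing cells", call. = FALSE)
  bad <- setdiff(unique(as.vector(m)), categories)
  if (length(bad) > 0)
    stop("invalid category label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  invisible(m)
}

#' Fleiss kappa for a fixed panel of raters
#'
#' Chance-corrected agreement for \code{n} items each labeled by the same
#' number of raters. Observed agreement is the mean over items of the
#' proportion of agreeing rater pairs; expected agreement is the sum of
#' squared pooled category proportions; kappa is
#' \code{(P_obs - P_exp) / (1 - P_exp)}.
#'
#' When every cell carries the same single category, expected agreement is 1
#' and the ratio is indeterminate; this case is reported as \code{kappa = 1}
#' with \code{degenerate = TRUE} rather than 0/0.
#'
#' @param m Character matrix, items in rows, raters in columns.
#' @param categories Category universe (defaults to the 8-category scheme).
#' @return List with \code{kappa}, \code{p_obs}, \code{p_exp},
#'   \code{per_category_agreement} (for each category, the probability that a
#'   second rater of a random item agrees with a rater who used that
#'   category), \code{n_items}, \code{n_raters}, \code{degenerate}.
#' @export
fleiss_kappa <- function(m, categories = chatmood_categories()) {
  check_annotation_matrix(m, categories)
  n <- nrow(m); r <- ncol(m)
  stopifnot(n >= 2, r >= 2)
  counts <- vapply(categories,
                   function(cat) rowSums(m == cat),
                   numeric(n))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  # counts: items x categories, each row sums to r
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_obs <- mean(p_i)
  p_j <- colSums(counts) / (n * r)
  p_exp <- sum(p_j^2)
  degenerate <- isTRUE(all.equal(p_exp, 1))
  kappa <- if (degenerate) 1 else (p_obs - p_exp) / (1 - p_exp)
  # conditional agreement: P(second rater says j | first rater said j)
  agree_j <- ifelse(colSums(counts) > 0,
                    colSums(counts * (counts - 1)) /
                      (colSums(counts) * (r - 1)),
                    NA_real_)
  names(agree_j) <- categories
  list(kappa = kappa, p_obs = p_obs, p_exp = p_exp,
       per_category_agreement = agree_j,
       n_items = n, n_raters = r, degenerate = degenerate)
}

#' Consensus filtering of multiply-annotated items
#'
#' An item is kept when its modal category reaches multiplicity
#' \code{min_agree} (default: 3 of 4 raters); its consensus label is that
#' modal category. Items whose raters disagree too much are discarded. With
#' general settings a modal tie at or above \code{min_agree} is possible
#' (impossible for 4 raters with \code{min_agree = 3}); ties are discarded.
#'
#' @param m Character matrix, items in rows (rownames = item ids), raters in
#'   columns.
#' @param min_agree Minimum modal multiplicity to keep an item.
#' @return List with \code{kept} (named character vector: item id ->
#'   consensus category) and \code{discarded} (character vector of item ids).
#' @export
consensus_filter <- function(m, min_agree = 3) {
  check_annotation_matrix(m)
  stopifnot(min_agree >= 1, min_agree <= ncol(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  kept <- character(0); discarded <- character(0)
  for (i in seq_len(nrow(m))) {
    tab <- table(m[i, ])
    top <- max(tab)
    modal <- names(tab)[tab == top]
    if (top >= min_agree && length(modal) == 1L) {
      kept[[ids[i]]] <- modal
    } else {
      discarded <- c(discarded, ids[i])
    }
  }
  list(kept = kept, discarded = discarded)
}

#' Read / write annotation matrices as TSV
#'
#' Format: a header row, first column \code{utterance_id}, one column per
#' rater, category names as strings.
#'
#' @param path File path.
#' @return For \code{read_annotations}, a character matrix with item ids as
#'   rownames and raters as columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  stopifnot(names(df)[1] == "utterance_id", ncol(df) >= 2)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$utterance_id
  check_annotation_matrix(m)
}

#' @rdname read_annotations
#' @param m Character matrix of annotations (rownames = item ids).
#' @export
write_annotations <- function(m, path) {
  df <- data.frame(utterance_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
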