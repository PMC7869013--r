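# --- virtual-screening evaluation --------------------------------------------

#' Build a ranked screening result
#'
#' Sorts records by descending score with ties broken by stable input order.
#'
#' @param score Numeric prediction scores.
#' @param label Binary activity labels (0/1), optional.
#' @param ligand_id Optional identifiers.
#' @return An object of class `"screen_result"`: data frame sorted by
#'   descending score with attributes `n_total` and `n_actives`.
#' @export
screen_result <- function(score, label = NULL, ligand_id = NULL) {
  n <- length(score)
  if (is.null(ligand_id)) ligand_id <- paste0("lig", seq_len(n))
  df <- data.frame(ligand_id = ligand_id, score = score)
  if (!is.null(label)) {
    stopifnot(length(label) == n, all(label %in% c(0, 1)))
    df$label <- label
  }
  ord <- order(-df$score, seq_len(n))  # stable: input order breaks ties
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("screen_result", "data.frame"),
            n_total = n, n_actives = if (is.null(label)) NA_integer_ else sum(label))
}

#' Area under the ROC curve
#'
#' Tie-corrected rank-based AUROC, equal to the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`: the probability that a random active scores
#' above a random inactive (ties count one half). Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores, or a [screen_result()] with labels.
#' @param labels Binary labels (0/1); ignored when `scores` is a
#'   `"screen_result"`.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1: perfect separation
#' @export
auroc <- function(scores, labels = NULL) {
  if (inherits(scores, "screen_result")) {
    labels <- scores$label
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Enrichment factor at the top X% of a ranked list
#'
#' `EF_X% = (actives in top N_X% / N_X%) / (n_actives / N_total)` with
#' `N_X% = ceiling(X * N_total / 100)`; ties at the cutoff are resolved by
#' the stable ranking of [screen_result()]. 1 means no enrichment over a
#' random ranking; the maximum is `min(N_total / N_X%, N_total / n_actives)`.
#'
#' @param result A [screen_result()] with labels, or numeric scores.
#' @param x_percent Percentage of the ranked list to inspect (0 < x <= 100).
#' @param labels Labels, when `result` is a numeric score vector.
#' @return The enrichment factor.
#' @examples
#' sc <- screen_result(100:1 / 100, c(rep(1, 5), rep(0, 90), rep(1, 5)))
#' enrichment_factor(sc, 10)  # (5/10)/(10/100) = 5
#' @export
enrichment_factor <- function(result, x_percent, labels = NULL) {
  if (!inherits(result, "screen_result")) {
    result <- screen_result(result, labels)
  }
  stopifnot(x_percent > 0, x_percent <= 100)
  y <- result$label
  if (is.null(y)) stop("enrichment factor needs labels")
  n_total <- attr(result, "n_total")
  n_act <- sum(y)
  if (n_act == 0) stop("no actives in the ranked list")
  n_top <- ceiling(x_percent * n_total / 100)
  (sum(y[seq_len(n_top)]) / n_top) / (n_act / n_total)
}

#' Conformation-consistency comparison of two screens
#'
#' Compares predictions for the same ligand list scored against two
#' conformations of one protein: counts of predicted actives/inactives per
#' conformation at a score threshold, the percent error
#' `100 * |actives_A - actives_B| / actives_A`, and the Pearson correlation
#' of the raw scores. A conformation-robust scorer shows near-zero percent
#' error and correlation near 1.
#'
#' @param scores_a,scores_b Scores for the identical, identically ordered
#'   ligand list on conformations A and B.
#' @param threshold Active/inactive score threshold (default 0.5).
#' @param ligand_id Optional shared identifiers (checked for equality when
#'   both score vectors carry names).
#' @return An object of class `"conformation_consistency"`: list with
#'   `actives` (A/B counts), `inactives`, `percent_error`, `correlation`
#'   and `n`.
#' @export
conformation_consistency <- function(scores_a, scores_b, threshold = 0.5,
                                     ligand_id = NULL) {
  if (length(scores_a) != length(scores_b)) {
    stop("mismatched ligand lists: ", length(scores_a), " vs ", length(scores_b))
  }
  if (!is.null(names(scores_a)) && !is.null(names(scores_b)) &&
      !identical(names(scores_a), names(scores_b))) {
    stop("mismatched ligand lists: names differ")
  }
  act_a <- sum(scores_a >= threshold)
  act_b <- sum(scores_b >= threshold)
  n <- length(scores_a)
  structure(list(actives = c(A = act_a, B = act_b),
                 inactives = c(A = n - act_a, B = n - act_b),
                 percent_error = if (act_a > 0) 100 * abs(act_a - act_b) / act_a else NA_real_,
                 correlation = if (stats::sd(scores_a) > 0 && stats::sd(scores_b) > 0)
                   stats::cor(scores_a, scores_b) else NA_real_,
                 threshold = threshold, n = n),
            class = "conformation_consistency")
}

#' @export
print.conformation_consistency <- function(x, ...) {
  cat(sprintf("conformation consistency over %d ligands (threshold %.2f)\n",
              x$n, x$threshold))
  cat(sprintf("  actives   A %d  B %d\n  inactives A %d  B %d\n",
              x$actives["A"], x$actives["B"], x$inactives["A"], x$inactives["B"]))
  cat(sprintf("  percent error %.2f%%, score correlation %s\n",
              x$percent_error,
              ifelse(is.na(x$correlation), "NA", sprintf("%.3f", x$correlation))))
  invisible(x)
}
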