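# Evaluation: binary classification metrics, binding-residue hit rate
# (BRHR@K) and per-type interaction hit rate (IHR@K).

.topk_residues <- function(scores, k) {
  order(-scores, seq_along(scores))[seq_len(min(k, length(scores)))]
}

#' Binding Residue Hit Rate at K (single pair)
#'
#' 1 iff at least one of the Top-K ranked residues is a true binding
#' residue; ranking ties broken by lower residue index.
#'
#' @param scores Residue score vector (length n).
#' @param true_residues Integer positions of true binding residues.
#' @param k Top-K cutoff.
#' @return 0 or 1.
#' @export
brhr_at_k <- function(scores, true_residues, k) {
  stopifnot(k >= 1)
  if (length(true_residues) == 0)
    stop("empty ground-truth residue set")
  as.integer(any(.topk_residues(scores, k) %in% true_residues))
}

#' Dataset-level BRHR@K
#'
#' Mean of [brhr_at_k()] over pairs; pairs with an empty ground-truth set
#' are excluded with a warning.
#'
#' @param score_list List of residue score vectors.
#' @param truth_list List of true-residue index vectors.
#' @param k Top-K cutoff.
#' @return Mean hit rate in `[0, 1]`.
#' @export
brhr <- function(score_list, truth_list, k) {
  stopifnot(length(score_list) == length(truth_list))
  keep <- lengths(truth_list) > 0
  if (!all(keep)) warning(sum(!keep), " pair(s) with empty truth excluded")
  if (!any(keep)) stop("no pair with a non-empty ground-truth set")
  mean(mapply(brhr_at_k, score_list[keep], truth_list[keep],
              MoreArgs = list(k = k)))
}

#' Interaction Hit Rate at K (single pair and type)
#'
#' Ranks all m x n residue-atom cells of a type score map and returns 1
#' iff a Top-K cell is a true contact of that type. Ties are broken by
#' lower residue index, then lower ligand-atom index.
#'
#' @param score_map m x n score matrix.
#' @param true_pairs Two-column matrix/data.frame of true (i, j) contacts.
#' @param k Top-K cutoff.
#' @return 0 or 1.
#' @export
ihr_at_k <- function(score_map, true_pairs, k) {
  stopifnot(k >= 1)
  tp <- as.matrix(true_pairs)
  if (nrow(tp) == 0) stop("no true contacts of this type")
  m <- nrow(score_map); n <- ncol(score_map)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  sc <- score_map[cbind(cells$i, cells$j)]
  ord <- order(-sc, cells$j, cells$i)[seq_len(min(k, m * n))]
  top <- paste(cells$i[ord], cells$j[ord])
  as.integer(any(paste(tp[, 1], tp[, 2]) %in% top))
}

#' Expected IHR@1 of a uniform random ranker
#'
#' With `n_true` annotated contacts among `m * n` candidate cells, a
#' uniformly random Top-1 pick succeeds with probability
#' `n_true / (m * n)`.
#'
#' @param n_true Number of true contacts.
#' @param m,n Map dimensions.
#' @return Probability in `[0, 1]`.
#' @export
expected_ihr1 <- function(n_true, m, n) n_true / (m * n)

#' Monte-Carlo IHR@1 of a uniform random ranker
#'
#' Simulates `trials` independent uniform random rankers of the m x n
#' residue-atom cells and reports the fraction whose Top-1 cell hits one
#' of `n_true` randomly placed true contacts. Because the Top-1 cell of
#' an i.i.d. uniform score map is itself uniformly distributed over the
#' cells, each ranker's Top-1 is drawn directly (distribution-identical
#' to materializing a full random score map and taking its argmax).
#' Converges to [expected_ihr1()].
#'
#' @param n_true Number of true contacts.
#' @param m,n Map dimensions.
#' @param trials Number of random rankers.
#' @param seed Seed.
#' @return List: `ihr1` (hit fraction), `se` (binomial standard error),
#'   `trials`.
#' @export
simulate_random_ihr1 <- function(n_true, m, n, trials = 1e5, seed = 1) {
  N <- m * n
  .with_seed(.hash_ints(c(seed, 509)), {
    truth <- sample(N, n_true)
    top <- sample.int(N, trials, replace = TRUE)
    p <- mean(top %in% truth)
    list(ihr1 = p, se = sqrt(p * (1 - p) / trials), trials = trials)
  })
}

#' Binary classification metrics
#'
#' Accuracy and F1 at threshold 0.5, AUROC, and AUPRC (average
#' precision).
#'
#' @param p Predicted probabilities.
#' @param y Labels in {0, 1}.
#' @param threshold Decision threshold for Acc/F1.
#' @return Named list: `acc`, `auroc`, `auprc`, `f1`.
#' @export
binary_metrics <- function(p, y, threshold = 0.5) {
  stopifnot(length(p) == length(y))
  if (length(unique(y)) < 2)
    stop("AUROC/AUPRC undefined for single-class input")
  yhat <- as.integer(p >= threshold)
  acc <- mean(yhat == y)
  tp <- sum(yhat == 1 & y == 1)
  prec <- if (sum(yhat == 1) > 0) tp / sum(yhat == 1) else 0
  rec <- tp / sum(y == 1)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auroc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p, levels = c(0, 1),
    direction = "<", quiet = TRUE)))
  # average precision: mean of precision at each positive, scores desc
  ord <- order(-p, seq_along(p))
  ys <- y[ord]
  precision_at <- cumsum(ys) / seq_along(ys)
  auprc <- sum(precision_at[ys == 1]) / sum(ys)
  list(acc = acc, auroc = auroc, auprc = auprc, f1 = f1)
}
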