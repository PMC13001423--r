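# Similarity-controlled train/test splitting: entities whose pairwise
# similarity exceeds the threshold are clustered (single linkage =
# connected components of the "too similar" graph) and every cluster is
# assigned whole to train or test, so no cross-split pair can exceed the
# threshold. In-distribution evaluation uses stratified random K-folds.

#' Pairwise similarity matrix for split construction
#'
#' @param items Character vector: sequences (`axis = "protein"`) or
#'   SMILES (`axis = "ligand"`).
#' @param axis `"protein"` (Needleman-Wunsch identity) or `"ligand"`
#'   (ECFP Tanimoto, scaled to percent).
#' @return Symmetric percent-similarity matrix with 100 on the diagonal.
#' @export
similarity_matrix <- function(items, axis = c("protein", "ligand")) {
  axis <- match.arg(axis)
  k <- length(items)
  S <- matrix(100, k, k)
  if (axis == "ligand") {
    fps <- lapply(items, ecfp_bits)
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      S[a, b] <- S[b, a] <- 100 * tanimoto(fps[[a]], fps[[b]])
  } else {
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      S[a, b] <- S[b, a] <- protein_similarity(items[a], items[b])
  }
  S
}

#' Build a similarity-controlled train/test split
#'
#' Entities connected by similarity strictly above `threshold` form
#' clusters that are assigned whole to train or test (largest-first
#' greedy fill of the train side), guaranteeing that no train-test pair
#' exceeds the threshold on the controlled axis.
#'
#' @param items Character vector of entities (sequences or SMILES), or
#'   anything when `S` is supplied.
#' @param axis `"protein"` or `"ligand"`.
#' @param threshold Percent similarity bound for train-test pairs.
#' @param test_fraction Target fraction of entities in the test side.
#' @param seed Seed for tie-shuffling of equal-size clusters.
#' @param S Optional precomputed percent-similarity matrix.
#' @return Object of class `split_spec`: `axis`, `threshold`, `train`,
#'   `test` (entity indices), `clusters`, and the realized `peak` and
#'   `mean` train-test similarity.
#' @export
build_split <- function(items, axis = c("protein", "ligand"), threshold,
                        test_fraction = 0.2, seed = 1, S = NULL) {
  axis <- match.arg(axis)
  if (is.null(S)) S <- similarity_matrix(items, axis)
  k <- nrow(S)
  adj <- which(S > threshold & upper.tri(S), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(adj) > 0) g <- igraph::add_edges(g, t(adj))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  if (length(sizes) < 2)
    stop("threshold infeasible: all ", k, " entities form one cluster ",
         "(cluster 1, size ", sizes[[1]], ")")
  ord <- .with_seed(.hash_ints(c(seed, 211)), {
    sh <- sample(length(sizes))
    names(sizes)[sh][order(-as.integer(sizes)[sh])]
  })
  train_target <- (1 - test_fraction) * k
  train_cl <- character(); n_train <- 0
  for (cl in ord) {
    if (n_train < train_target) {
      train_cl <- c(train_cl, cl)
      n_train <- n_train + sizes[[cl]]
    }
  }
  train <- which(as.character(comp) %in% train_cl)
  test <- setdiff(seq_len(k), train)
  if (length(test) == 0) {
    # move the smallest train cluster over so both sides are non-empty
    cl <- train_cl[which.min(sizes[train_cl])]
    test <- which(as.character(comp) == cl)
    train <- setdiff(seq_len(k), test)
  }
  cross <- S[train, test, drop = FALSE]
  structure(list(axis = axis, threshold = threshold, train = train,
                 test = test, clusters = comp,
                 peak = max(cross), mean = mean(cross)),
            class = "split_spec")
}

#' Post-hoc audit of a similarity-controlled split
#'
#' Recomputes every train-test similarity and checks the peak against
#' the threshold.
#'
#' @param split A `split_spec`.
#' @param S The percent-similarity matrix over the same entities.
#' @return List: `peak`, `mean`, `pass` (peak <= threshold).
#' @export
audit_split <- function(split, S) {
  cross <- S[split$train, split$test, drop = FALSE]
  list(peak = max(cross), mean = mean(cross),
       pass = max(cross) <= split$threshold)
}

#' Stratified random folds for in-distribution evaluation
#'
#' @param y Labels (stratification variable).
#' @param k Number of folds (default 5).
#' @param seed Seed.
#' @return Integer fold assignment per element.
#' @export
id_folds <- function(y, k = 5, seed = 1) {
  fold <- integer(length(y))
  .with_seed(.hash_ints(c(seed, 307)), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
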