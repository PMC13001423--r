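# Parameter-recovery experiment: can interaction-supervised attention
# recover planted contacts on held-out pairs, and does supervision
# (lambda > 0) beat label-only training (lambda = 0)?

#' Planted-contact recovery experiment
#'
#' Generates a planted-contact training corpus and a held-out set of
#' positive pairs, trains the interaction module twice from the same
#' initialization — once with attention supervision (`lambda`) and once
#' label-only (`lambda = 0`) — and evaluates held-out BRHR@1 against the
#' expected Top-1 hit rate of a uniform random ranker
#' (`n_true_residues / n` per pair).
#'
#' @param seed Experiment seed (drives specs, embeddings, init and
#'   batching).
#' @param n_train,n_test Number of training pairs / held-out positive
#'   pairs.
#' @param n,m Tokens per pair (protein residues / ligand atoms).
#' @param h Embedding dimension.
#' @param lambda Supervision weight of the supervised run.
#' @param epochs,lr,batch_size Training schedule.
#' @return List: `brhr1_supervised`, `brhr1_unsupervised`,
#'   `random_baseline`, `auroc_supervised`, the two fitted models and the
#'   held-out corpus.
#' @export
recovery_experiment <- function(seed = 1, n_train = 100, n_test = 40,
                                n = 30, m = 8, h = 64, lambda = 0.3,
                                epochs = 250, lr = 1e-2, batch_size = 10) {
  train_specs <- sample_pair_specs(n_train, n = n, m = m,
                                   seed = .hash_ints(c(seed, 1)))
  test_specs <- sample_pair_specs(2 * n_test, n = n, m = m,
                                  seed = .hash_ints(c(seed, 2)))
  ds_train <- make_dataset(train_specs, seed = .hash_ints(c(seed, 3)), h = h)
  ds_test <- make_dataset(test_specs, seed = .hash_ints(c(seed, 4)), h = h)

  cfg_sup <- model_config(h = h, lambda = lambda, epochs = epochs, lr = lr,
                          batch_size = batch_size,
                          seed = .hash_ints(c(seed, 5)))
  cfg_uns <- model_config(h = h, lambda = 0, epochs = epochs, lr = lr,
                          batch_size = batch_size,
                          seed = .hash_ints(c(seed, 5)))
  fit_sup <- train(ds_train, cfg_sup)
  fit_uns <- train(ds_train, cfg_uns)

  pos <- Filter(function(pr) pr$y == 1, ds_test)
  eval_brhr1 <- function(model) {
    scores <- lapply(pos, function(pr)
      predict_pair(model, pr$P, pr$D)$sites$residue_scores)
    truths <- lapply(pos, function(pr) which(pr$maps$residue_labels == 1))
    brhr(scores, truths, k = 1)
  }
  baseline <- mean(vapply(pos, function(pr)
    sum(pr$maps$residue_labels) / length(pr$maps$residue_labels),
    numeric(1)))

  probs <- vapply(ds_test, function(pr)
    predict_pair(fit_sup, pr$P, pr$D)$p, numeric(1))
  ys <- vapply(ds_test, `[[`, 0, "y")

  list(brhr1_supervised = eval_brhr1(fit_sup),
       brhr1_unsupervised = eval_brhr1(fit_uns),
       random_baseline = baseline,
       auroc_supervised = binary_metrics(probs, ys)$auroc,
       model_supervised = fit_sup, model_unsupervised = fit_uns,
       heldout = ds_test)
}
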