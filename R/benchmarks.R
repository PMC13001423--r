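#' Published in-distribution benchmark table
#'
#' Reported mean performance (%) of seven sequence-based binding
#' predictors and the interaction-supervised model on the in-distribution
#' benchmark, shipped as `inst/extdata/benchmark_indist.tsv`.
#'
#' @return data.frame with columns model, acc, auprc, auroc, f1, brhr1,
#'   brhr3, brhr5.
#' @export
benchmark_table <- function() {
  utils::read.delim(system.file("extdata", "benchmark_indist.tsv",
                                package = "crossbind"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' BRHR improvement over the best baseline
#'
#' Recomputes, from the benchmark table, the absolute percentage-point
#' gap at K in {1, 3, 5} between the interaction-supervised model and the
#' best-performing baseline at that K.
#'
#' @param tab Benchmark table (default [benchmark_table()]).
#' @return Named numeric vector `c(k1 = , k3 = , k5 = )`.
#' @export
brhr_gaps <- function(tab = benchmark_table()) {
  ours <- tab[tab$model == "interaction-supervised", ]
  base <- tab[tab$model != "interaction-supervised", ]
  vapply(c(k1 = "brhr1", k3 = "brhr3", k5 = "brhr5"),
         function(col) ours[[col]] - max(base[[col]]), numeric(1))
}
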