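# Long-format TSV serialization of interaction/score maps and JSON
# manifests.

#' Write maps as long-format TSV
#'
#' One row per nonzero cell: `type`, `ligand_index`, `residue_position`,
#' `strength`. The map dimensions travel in the accompanying manifest.
#'
#' @param maps Named list of m x n matrices (e.g. `$maps` of an
#'   `interaction_maps` object, or predicted type maps).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_maps_tsv <- function(maps, path) {
  rows <- do.call(rbind, lapply(names(maps), function(t) {
    nz <- which(maps[[t]] > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(NULL)
    data.frame(type = t, ligand_index = nz[, 1], residue_position = nz[, 2],
               strength = maps[[t]][nz])
  }))
  if (is.null(rows))
    rows <- data.frame(type = character(), ligand_index = integer(),
                       residue_position = integer(), strength = numeric())
  rows <- rows[order(rows$type, rows$ligand_index, rows$residue_position), ]
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read long-format map TSV
#'
#' @param path TSV written by [write_maps_tsv()].
#' @param m,n Map dimensions.
#' @return Named list of m x n matrices (one per type present).
#' @export
read_maps_tsv <- function(path, m, n) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (t in unique(df$type)) {
    sub <- df[df$type == t, ]
    out[[t]] <- build_map(data.frame(i = sub$ligand_index,
                                     j = sub$residue_position,
                                     strength = sub$strength), m, n)
  }
  out
}

#' Write a JSON manifest / report
#'
#' @param x Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize / load a training corpus
#'
#' @param corpus A `crossbind_corpus`.
#' @param path File path (RDS).
#' @return `path` / the corpus.
#' @export
write_corpus <- function(corpus, path) {
  saveRDS(corpus, path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) readRDS(path)
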