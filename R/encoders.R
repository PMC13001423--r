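# Pluggable frozen token encoders. Production use plugs in pretrained
# embeddings; the package ships a deterministic hash encoder that maps each
# (token, position) to a reproducible unit vector, which is enough to
# exercise and test every downstream component. Encoders are frozen by
# construction: nothing in training ever touches them.

.encoder_registry <- new.env(parent = emptyenv())

#' Register a token encoder
#'
#' An encoder is a function `f(tokens, h, seed)` returning a
#' `length(tokens) x h` numeric matrix, one row per token.
#'
#' @param name Encoder name.
#' @param fn Encoder function.
#' @export
register_encoder <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .encoder_registry)
  invisible(name)
}

# deterministic integer hash of an integer vector (stays < 2^31)
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (as.numeric(x) %% 2147483629)) %% 2147483629
  as.integer(h)
}

# run expr with a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.hash_encoder <- function(tokens, h, seed) {
  E <- matrix(0, length(tokens), h)
  for (k in seq_along(tokens)) {
    s <- .hash_ints(c(seed, utf8ToInt(tokens[k]), k))
    v <- .with_seed(s, stats::rnorm(h))
    E[k, ] <- v / sqrt(sum(v^2))
  }
  E
}

register_encoder("hash", .hash_encoder)

#' Embed protein and ligand token sequences
#'
#' Produces token-level embeddings `P` (n x h) and `D` (m x h) with a
#' registered frozen encoder. Inputs may be a `protein_sequence` /
#' `ligand_record` object or a plain character vector of tokens.
#'
#' @param protein Protein tokens (residue letters) or `protein_sequence`.
#' @param ligand Ligand tokens (atom symbols) or `ligand_record`.
#' @param h Hidden dimension.
#' @param encoder Registered encoder name (default `"hash"`).
#' @param seed Encoder seed; the same (tokens, h, seed) always yields the
#'   same embeddings.
#' @return List with matrices `P` (n x h) and `D` (m x h).
#' @export
encode <- function(protein, ligand, h = 64, encoder = "hash", seed = 1) {
  if (!exists(encoder, envir = .encoder_registry))
    stop("unknown encoder: ", encoder)
  fn <- get(encoder, envir = .encoder_registry)
  ptok <- if (inherits(protein, "protein_sequence")) protein$codes
          else if (length(protein) == 1 && nchar(protein[1]) > 1)
            strsplit(protein, "")[[1]]
          else protein
  dtok <- if (inherits(ligand, "ligand_record")) ligand$atom_tokens
          else ligand
  if (length(ptok) == 0 || any(!nzchar(ptok)))
    stop("empty protein token sequence")
  if (length(dtok) == 0 || any(!nzchar(dtok)))
    stop("empty ligand token sequence")
  list(P = fn(ptok, h, seed), D = fn(dtok, h, seed))
}
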