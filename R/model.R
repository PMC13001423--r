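# The interaction module: 8-head bidirectional cross- plus self-attention
# over frozen token embeddings, with six heads tied to the six non-covalent
# interaction types and two heads capturing overall binding. Supervised
# heads are aligned to physical interaction maps through a weighted KL
# divergence; a small MLP on pooled fused tokens predicts binding
# probability. Implemented in plain matrix code with analytic gradients
# (verified against finite differences in the test suite).

#' Model configuration
#'
#' @param h Hidden dimension (must be divisible by `H`).
#' @param H Number of attention heads; the first six are tied to
#'   [interaction_types()] in order, the last two are "overall" heads.
#' @param d Fused token dimension after output projection (default `h`).
#' @param mlp_widths Widths of the two hidden MLP layers.
#' @param lambda Mixing weight of the attention-alignment loss in
#'   `(1-lambda)*Lcls + lambda*Latt`; default 0.3.
#' @param supervise_overall Supervise the two overall heads with the
#'   overall map (default) or leave them free.
#' @param lr,beta1,beta2,eps Adam settings.
#' @param epochs,batch_size Training schedule.
#' @param seed RNG seed for init and batching.
#' @return List of class `crossbind_config`.
#' @export
model_config <- function(h = 64, H = 8, d = NULL, mlp_widths = c(64, 32),
                         lambda = 0.3, supervise_overall = TRUE,
                         lr = 2e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         epochs = 30, batch_size = 10, seed = 1) {
  if (!(is.numeric(lambda) && lambda >= 0 && lambda <= 1))
    stop("lambda must lie in [0, 1]")
  if (h %% H != 0) stop("h must be divisible by H")
  if (length(mlp_widths) != 2) stop("mlp_widths must have length 2")
  structure(list(h = h, H = H, d = if (is.null(d)) h else d,
                 mlp_widths = mlp_widths, lambda = lambda,
                 supervise_overall = supervise_overall,
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 epochs = epochs, batch_size = batch_size, seed = seed),
            class = "crossbind_config")
}

.head_names <- function(H) c(interaction_types(), paste0("overall", seq_len(H - 6)))

.head_slices <- function(h, H) {
  ht <- h / H
  lapply(seq_len(H), function(t) ((t - 1) * ht + 1):(t * ht))
}

.rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)

#' Initialize model parameters
#'
#' @param cfg A `crossbind_config`.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return Named list of weight matrices and bias vectors.
#' @export
init_params <- function(cfg, seed = cfg$seed) {
  .with_seed(seed, {
    h <- cfg$h; d <- cfg$d; u1 <- cfg$mlp_widths[1]; u2 <- cfg$mlp_widths[2]
    list(
      Wqd = .rmat(h, h), Wkd = .rmat(h, h), Wvd = .rmat(h, h),
      Wqp = .rmat(h, h), Wkp = .rmat(h, h), Wvp = .rmat(h, h),
      Wpo = .rmat(h, d), Wdo = .rmat(h, d),
      W1 = .rmat(2 * d, u1), b1 = numeric(u1),
      W2 = .rmat(u1, u2), b2 = numeric(u2),
      w3 = stats::rnorm(u2, sd = 1 / sqrt(u2)), b3 = 0
    )
  })
}

.softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

.softmax_rows_back <- function(A, dA) A * (dA - rowSums(A * dA))

#' Forward pass of the interaction module
#'
#' Computes per-head bidirectional cross-attention and self-attention,
#' type-specific fusion, output projection, mean pooling and the MLP head.
#'
#' @param P Protein token embeddings, n x h.
#' @param D Ligand token embeddings, m x h.
#' @param par Parameters from [init_params()].
#' @param cfg A `crossbind_config`.
#' @return List: `p` (binding probability), `stack` (per-head list with
#'   `name`, `A_pd` n x m, `A_dp` m x n, each row-stochastic), `Pstar`,
#'   `Dstar` (fused tokens), `F` (pair vector), and cached intermediates
#'   used by the backward pass.
#' @export
interaction_forward <- function(P, D, par, cfg) {
  if (ncol(P) != cfg$h || ncol(D) != cfg$h)
    stop("embedding dimension does not match config h")
  n <- nrow(P); m <- nrow(D)
  if (n < 1 || m < 1) stop("empty token sequence")
  sl <- .head_slices(cfg$h, cfg$H)
  s <- sqrt(cfg$h / cfg$H)
  Qd <- D %*% par$Wqd; Kd <- D %*% par$Wkd; Vd <- D %*% par$Wvd
  Qp <- P %*% par$Wqp; Kp <- P %*% par$Wkp; Vp <- P %*% par$Wvp
  heads <- vector("list", cfg$H)
  Pcat <- matrix(0, n, cfg$h); Dcat <- matrix(0, m, cfg$h)
  nms <- .head_names(cfg$H)
  for (t in seq_len(cfg$H)) {
    ix <- sl[[t]]
    Qpt <- Qp[, ix, drop = FALSE]; Kpt <- Kp[, ix, drop = FALSE]
    Vpt <- Vp[, ix, drop = FALSE]
    Qdt <- Qd[, ix, drop = FALSE]; Kdt <- Kd[, ix, drop = FALSE]
    Vdt <- Vd[, ix, drop = FALSE]
    A_pd <- .softmax_rows(Qpt %*% t(Kdt) / s)
    A_dp <- .softmax_rows(Qdt %*% t(Kpt) / s)
    A_pp <- .softmax_rows(Qpt %*% t(Kpt) / s)
    A_dd <- .softmax_rows(Qdt %*% t(Kdt) / s)
    Psa <- A_pp %*% Vpt; Dsa <- A_dd %*% Vdt
    Pcat[, ix] <- 0.5 * (Psa + A_pd %*% Vdt)
    Dcat[, ix] <- 0.5 * (Dsa + A_dp %*% Vpt)
    heads[[t]] <- list(name = nms[t], A_pd = A_pd, A_dp = A_dp,
                       A_pp = A_pp, A_dd = A_dd)
  }
  Pstar <- Pcat %*% par$Wpo; Dstar <- Dcat %*% par$Wdo
  pbar <- colMeans(Pstar); dbar <- colMeans(Dstar)
  F <- c(dbar, pbar)
  z1a <- as.vector(F %*% par$W1) + par$b1; z1 <- pmax(z1a, 0)
  z2a <- as.vector(z1 %*% par$W2) + par$b2; z2 <- pmax(z2a, 0)
  logit <- sum(z2 * par$w3) + par$b3
  p <- 1 / (1 + exp(-logit))
  list(p = p, stack = heads, Pstar = Pstar, Dstar = Dstar, F = F,
       cache = list(Qd = Qd, Kd = Kd, Vd = Vd, Qp = Qp, Kp = Kp, Vp = Vp,
                    Pcat = Pcat, Dcat = Dcat, z1a = z1a, z1 = z1,
                    z2a = z2a, z2 = z2, logit = logit, n = n, m = m))
}

#' Pooling and MLP classifier head
#'
#' Mean-pools fused token embeddings, concatenates the pooled ligand and
#' protein vectors into the pair representation `F = [dbar, pbar]`, and
#' applies the two-hidden-layer sigmoid MLP.
#'
#' @param Pstar Fused protein tokens, n x d.
#' @param Dstar Fused ligand tokens, m x d.
#' @param mlp List with `W1, b1, W2, b2, w3, b3`.
#' @return Binding probability in `[0, 1]`.
#' @export
classify <- function(Pstar, Dstar, mlp) {
  F <- c(colMeans(Dstar), colMeans(Pstar))
  z1 <- pmax(as.vector(F %*% mlp$W1) + mlp$b1, 0)
  z2 <- pmax(as.vector(z1 %*% mlp$W2) + mlp$b2, 0)
  1 / (1 + exp(-(sum(z2 * mlp$w3) + mlp$b3)))
}

#' Binary cross-entropy loss
#'
#' @param p Predicted probability.
#' @param y Label in {0, 1}.
#' @param eps Clamp bound keeping `log` finite.
#' @return Non-negative loss value.
#' @export
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# weighted KL of globally-normalized truth against globally-normalized
# prediction; truth_raw also provides the log(1 + A_raw) cell weights.
.weighted_kl <- function(truth_raw, pred, clamp = 1e-12) {
  At <- truth_raw / sum(truth_raw)
  Ah <- pmax(pred / sum(pred), clamp)
  nz <- At > 0
  sum(log1p(truth_raw[nz]) * At[nz] * log(At[nz] / Ah[nz]))
}

#' Attention alignment loss
#'
#' Weighted KL divergence between ground-truth interaction maps and
#' predicted attention, averaged over supervised heads. Truth and
#' prediction are each normalized over all residue-atom cells to discrete
#' distributions; each cell is weighted by `log(1 + A_raw)` where `A_raw`
#' is the unnormalized interaction strength. Supervision is applied
#' symmetrically to the ligand-to-protein attention `A_dp` and the
#' transposed protein-to-ligand attention `A_pd`, averaged. Supervised
#' heads whose ground-truth map is all zero are skipped with a warning.
#'
#' @param stack Attention stack from [interaction_forward()] (list of
#'   heads, each with `A_dp` m x n and optionally `A_pd` n x m).
#' @param maps Ground truth: an `interaction_maps` object or a list with
#'   `maps` (named per-type m x n matrices) and `overall`.
#' @param supervise_overall Include overall heads, supervised by the
#'   overall map.
#' @param quiet Suppress skipped-head warnings.
#' @return Loss value, or `NA_real_` when no supervised head had a usable
#'   ground-truth map.
#' @export
attention_alignment_loss <- function(stack, maps, supervise_overall = TRUE,
                                     quiet = FALSE) {
  vals <- numeric(0)
  for (t in seq_along(stack)) {
    hd <- stack[[t]]
    truth <- if (hd$name %in% interaction_types()) maps$maps[[hd$name]]
             else if (supervise_overall) maps$overall
             else NULL
    if (is.null(truth)) next
    if (sum(truth) == 0) {
      if (!quiet) warning("all-zero ground-truth map for supervised head '",
                          hd$name, "': head skipped")
      next
    }
    v <- .weighted_kl(truth, hd$A_dp)
    if (!is.null(hd$A_pd)) v <- (v + .weighted_kl(truth, t(hd$A_pd))) / 2
    vals <- c(vals, v)
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Combined training objective
#'
#' `(1 - lambda) * Lcls + lambda * Latt`; when `Latt` is `NA` (no
#' interaction annotation) only the classification loss applies.
#'
#' @param lcls Classification loss.
#' @param latt Attention alignment loss or `NA`.
#' @param lambda Mixing weight in `[0, 1]`.
#' @return Loss value.
#' @export
total_loss <- function(lcls, latt, lambda = 0.3) {
  if (!(is.numeric(lambda) && lambda >= 0 && lambda <= 1))
    stop("lambda must lie in [0, 1]")
  if (is.na(latt)) lcls else (1 - lambda) * lcls + lambda * latt
}

# gradient of .weighted_kl wrt the prediction matrix
.weighted_kl_grad <- function(truth_raw, pred, clamp = 1e-12) {
  S <- sum(pred)
  At <- truth_raw / sum(truth_raw)
  w <- log1p(truth_raw)
  Cw <- sum(w * At)
  G <- -(w * At) / pmax(pred, S * clamp) + Cw / S
  G
}

# forward + loss + analytic gradients for one pair
.loss_grads <- function(par, P, D, y, maps, cfg) {
  fw <- interaction_forward(P, D, par, cfg)
  ca <- fw$cache
  n <- ca$n; m <- ca$m
  sl <- .head_slices(cfg$h, cfg$H)
  s <- sqrt(cfg$h / cfg$H)

  lcls <- bce_loss(fw$p, y)
  latt <- if (is.null(maps)) NA_real_
          else attention_alignment_loss(fw$stack, maps,
                                        cfg$supervise_overall, quiet = TRUE)
  loss <- total_loss(lcls, latt, cfg$lambda)
  use_att <- !is.na(latt)
  scale_cls <- if (use_att) 1 - cfg$lambda else 1

  # which heads contribute to Latt, and their truths
  att_truth <- vector("list", cfg$H)
  if (use_att) {
    for (t in seq_len(cfg$H)) {
      nm <- fw$stack[[t]]$name
      tr <- if (nm %in% interaction_types()) maps$maps[[nm]]
            else if (cfg$supervise_overall) maps$overall else NULL
      if (!is.null(tr) && sum(tr) > 0) att_truth[[t]] <- tr
    }
  }
  n_sup <- sum(!vapply(att_truth, is.null, logical(1)))

  g <- lapply(par, function(x) x * 0)

  # classifier backward
  dlogit <- scale_cls * (fw$p - y)
  g$b3 <- dlogit
  g$w3 <- dlogit * ca$z2
  dz2a <- (dlogit * par$w3) * (ca$z2a > 0)
  g$W2 <- outer(ca$z1, dz2a)
  g$b2 <- dz2a
  dz1a <- as.vector(par$W2 %*% dz2a) * (ca$z1a > 0)
  g$W1 <- outer(fw$F, dz1a)
  g$b1 <- dz1a
  dF <- as.vector(par$W1 %*% dz1a)
  d <- cfg$d
  dDstar <- matrix(dF[seq_len(d)], m, d, byrow = TRUE) / m
  dPstar <- matrix(dF[d + seq_len(d)], n, d, byrow = TRUE) / n
  g$Wpo <- t(ca$Pcat) %*% dPstar
  g$Wdo <- t(ca$Dcat) %*% dDstar
  dPcat <- dPstar %*% t(par$Wpo)
  dDcat <- dDstar %*% t(par$Wdo)

  dQp <- matrix(0, n, cfg$h); dKp <- dQp; dVp <- dQp
  dQd <- matrix(0, m, cfg$h); dKd <- dQd; dVd <- dQd

  for (t in seq_len(cfg$H)) {
    ix <- sl[[t]]
    hd <- fw$stack[[t]]
    Qpt <- ca$Qp[, ix, drop = FALSE]; Kpt <- ca$Kp[, ix, drop = FALSE]
    Vpt <- ca$Vp[, ix, drop = FALSE]
    Qdt <- ca$Qd[, ix, drop = FALSE]; Kdt <- ca$Kd[, ix, drop = FALSE]
    Vdt <- ca$Vd[, ix, drop = FALSE]
    GPh <- dPcat[, ix, drop = FALSE]; GDh <- dDcat[, ix, drop = FALSE]

    dPsa <- 0.5 * GPh; dDsa <- 0.5 * GDh
    dA_pd <- 0.5 * GPh %*% t(Vdt)
    dVd[, ix] <- dVd[, ix] + t(hd$A_pd) %*% (0.5 * GPh)
    dA_dp <- 0.5 * GDh %*% t(Vpt)
    dVp[, ix] <- dVp[, ix] + t(hd$A_dp) %*% (0.5 * GDh)
    dA_pp <- dPsa %*% t(Vpt)
    dVp[, ix] <- dVp[, ix] + t(hd$A_pp) %*% dPsa
    dA_dd <- dDsa %*% t(Vdt)
    dVd[, ix] <- dVd[, ix] + t(hd$A_dd) %*% dDsa

    tr <- att_truth[[t]]
    if (!is.null(tr)) {
      wt <- cfg$lambda / (n_sup * 2)
      dA_dp <- dA_dp + wt * .weighted_kl_grad(tr, hd$A_dp)
      dA_pd <- dA_pd + wt * t(.weighted_kl_grad(tr, t(hd$A_pd)))
    }

    dS <- .softmax_rows_back(hd$A_pd, dA_pd)
    dQp[, ix] <- dQp[, ix] + dS %*% Kdt / s
    dKd[, ix] <- dKd[, ix] + t(dS) %*% Qpt / s
    dS <- .softmax_rows_back(hd$A_dp, dA_dp)
    dQd[, ix] <- dQd[, ix] + dS %*% Kpt / s
    dKp[, ix] <- dKp[, ix] + t(dS) %*% Qdt / s
    dS <- .softmax_rows_back(hd$A_pp, dA_pp)
    dQp[, ix] <- dQp[, ix] + dS %*% Kpt / s
    dKp[, ix] <- dKp[, ix] + t(dS) %*% Qpt / s
    dS <- .softmax_rows_back(hd$A_dd, dA_dd)
    dQd[, ix] <- dQd[, ix] + dS %*% Kdt / s
    dKd[, ix] <- dKd[, ix] + t(dS) %*% Qdt / s
  }

  g$Wqp <- t(P) %*% dQp; g$Wkp <- t(P) %*% dKp; g$Wvp <- t(P) %*% dVp
  g$Wqd <- t(D) %*% dQd; g$Wkd <- t(D) %*% dKd; g$Wvd <- t(D) %*% dVd

  list(loss = loss, lcls = lcls, latt = latt, grads = g, p = fw$p)
}

.adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0), t = 0)
}

.adam_step <- function(par, grads, st, cfg) {
  st$t <- st$t + 1
  for (nm in names(par)) {
    st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - cfg$beta1^st$t)
    vhat <- st$v[[nm]] / (1 - cfg$beta2^st$t)
    par[[nm]] <- par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
  }
  list(par = par, st = st)
}

#' Train the interaction module
#'
#' Minibatch Adam on the joint objective. Only the interaction-module
#' projections, output projections and the MLP head are updated; the token
#' embeddings in the dataset come from frozen encoders and are never
#' modified. Fully reproducible given `cfg$seed`.
#'
#' @param dataset List of pairs, each a list with `P` (n x h), `D` (m x h),
#'   `y` (0/1), and optionally `maps` (ground-truth interaction maps; `NULL`
#'   or absent means label-only supervision for that pair).
#' @param cfg A `crossbind_config`.
#' @param verbose Print per-epoch mean loss.
#' @return Object of class `crossbind_model`: `par`, `cfg`, `history`
#'   (per-epoch mean loss, classification and attention components).
#' @export
train <- function(dataset, cfg = model_config(), verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  .with_seed(cfg$seed, {
    par <- init_params(cfg, seed = cfg$seed)
    st <- .adam_init(par)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       lcls = numeric(), latt = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(dataset))
      ep_loss <- 0; ep_cls <- 0; ep_att <- 0; n_att <- 0
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (b in batches) {
        acc <- NULL
        bl <- 0
        for (k in b) {
          pr <- dataset[[k]]
          lg <- .loss_grads(par, pr$P, pr$D, pr$y, pr$maps, cfg)
          if (is.null(acc)) acc <- lg$grads
          else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + lg$grads[[nm]]
          bl <- bl + lg$loss
          ep_loss <- ep_loss + lg$loss; ep_cls <- ep_cls + lg$lcls
          if (!is.na(lg$latt)) { ep_att <- ep_att + lg$latt; n_att <- n_att + 1 }
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(b)
        upd <- .adam_step(par, acc, st, cfg)
        par <- upd$par; st <- upd$st
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = ep_loss / length(dataset),
        lcls = ep_cls / length(dataset),
        latt = if (n_att > 0) ep_att / n_att else NA_real_))
      if (verbose) message(sprintf("epoch %d loss %.4f", ep,
                                   ep_loss / length(dataset)))
    }
    structure(list(par = par, cfg = cfg, history = hist),
              class = "crossbind_model")
  })
}

#' @export
print.crossbind_model <- function(x, ...) {
  cat("crossbind_model: h =", x$cfg$h, ", H =", x$cfg$H,
      ", lambda =", x$cfg$lambda, "\n")
  cat("  trained", nrow(x$history), "epochs; final mean loss",
      sprintf("%.4f", utils::tail(x$history$loss, 1)), "\n")
  invisible(x)
}

#' Predict binding probability and attention maps for one pair
#'
#' @param model A `crossbind_model`.
#' @param P,D Token embeddings from the same frozen encoder used in
#'   training.
#' @return List: `p`, `stack`, `sites` (from
#'   [predict_sites_and_types()]).
#' @export
predict_pair <- function(model, P, D) {
  fw <- interaction_forward(P, D, model$par, model$cfg)
  list(p = fw$p, stack = fw$stack, sites = predict_sites_and_types(fw$stack))
}

#' Residue scores and per-type score maps from an attention stack
#'
#' Per-type score maps are the ligand-to-protein attention `A_dp` of the
#' six typed heads. The residue score of position j is the maximum over
#' ligand atoms of the mean of the two overall heads' `A_dp`. Ranking ties
#' are broken by lower residue index.
#'
#' @param stack Attention stack (list of heads with `name` and `A_dp`).
#' @return List: `residue_scores` (length n), `type_maps` (named list of
#'   m x n matrices).
#' @export
predict_sites_and_types <- function(stack) {
  nms <- vapply(stack, `[[`, "", "name")
  typed <- stack[nms %in% interaction_types()]
  overall <- stack[!(nms %in% interaction_types())]
  if (length(overall) == 0) overall <- typed   # degenerate stacks
  Ao <- Reduce(`+`, lapply(overall, `[[`, "A_dp")) / length(overall)
  list(residue_scores = apply(Ao, 2, max),
       type_maps = stats::setNames(lapply(typed, `[[`, "A_dp"),
                                   vapply(typed, `[[`, "", "name")))
}
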