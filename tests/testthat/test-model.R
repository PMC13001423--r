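test_that("encoders are deterministic, seed-sensitive, and reject empty input", {
  E1 <- encode("AGW", c("C", "O"), h = 16, seed = 3)
  E2 <- encode("AGW", c("C", "O"), h = 16, seed = 3)
  expect_identical(E1, E2)
  expect_equal(dim(E1$P), c(3, 16))
  E3 <- encode("AGW", c("C", "O"), h = 16, seed = 4)
  expect_false(isTRUE(all.equal(E1$P, E3$P)))
  expect_error(encode("", c("C"), h = 16), "empty protein")
  expect_error(encode("AGW", character(0), h = 16), "empty ligand")
  expect_error(encode("AGW", "C", h = 16, encoder = "esm2"),
               "unknown encoder")
})

test_that("attention rows are stochastic; zero projections give uniform rows", {
  cfg <- model_config(h = 16, H = 8, mlp_widths = c(4, 3), seed = 1)
  par <- init_params(cfg)
  set.seed(2)
  P <- matrix(rnorm(4 * 16), 4); D <- matrix(rnorm(3 * 16), 3)
  fw <- interaction_forward(P, D, par, cfg)
  for (hd in fw$stack) {
    expect_equal(rowSums(hd$A_pd), rep(1, 4), tolerance = 1e-6)
    expect_equal(rowSums(hd$A_dp), rep(1, 3), tolerance = 1e-6)
  }
  par0 <- par
  for (nm in c("Wqd", "Wkd", "Wqp", "Wkp")) par0[[nm]] <- par0[[nm]] * 0
  fw0 <- interaction_forward(P, D, par0, cfg)
  for (hd in fw0$stack) {
    expect_equal(hd$A_pd, matrix(1 / 3, 4, 3), tolerance = 1e-12)
    expect_equal(hd$A_dp, matrix(1 / 4, 3, 4), tolerance = 1e-12)
  }
  # single-token sequences collapse to [[1]]
  fw1 <- interaction_forward(P[1, , drop = FALSE], D[1, , drop = FALSE],
                             par, cfg)
  for (hd in fw1$stack) {
    expect_equal(hd$A_pd, matrix(1, 1, 1))
    expect_equal(hd$A_dp, matrix(1, 1, 1))
  }
  expect_error(interaction_forward(P[, 1:8], D, par, cfg), "dimension")
})

test_that("forward pass agrees with the straight-line dense oracle", {
  cfg <- model_config(h = 8, H = 8, mlp_widths = c(5, 4), seed = 7)
  par <- init_params(cfg)
  set.seed(21)
  P <- matrix(rnorm(4 * 8), 4); D <- matrix(rnorm(3 * 8), 3)
  fw <- interaction_forward(P, D, par, cfg)
  or <- oracle_forward(P, D, par, h = 8, H = 8)
  for (t in 1:8) {
    expect_equal(fw$stack[[t]]$A_pd, or$heads[[t]]$A_pd, tolerance = 1e-6)
    expect_equal(fw$stack[[t]]$A_dp, or$heads[[t]]$A_dp, tolerance = 1e-6)
  }
  expect_equal(fw$Pstar, or$Pstar, tolerance = 1e-6)
  expect_equal(fw$Dstar, or$Dstar, tolerance = 1e-6)
  expect_equal(fw$F, or$F, tolerance = 1e-6)
  expect_equal(fw$p, or$p, tolerance = 1e-6)
})

test_that("classifier pools means, and zero weights give p = 0.5", {
  d <- 6
  mlp <- list(W1 = matrix(0, 2 * d, 4), b1 = numeric(4),
              W2 = matrix(0, 4, 3), b2 = numeric(3),
              w3 = numeric(3), b3 = 0)
  set.seed(3)
  Pstar <- matrix(rnorm(5 * d), 5); Dstar <- matrix(rnorm(2 * d), 2)
  expect_equal(classify(Pstar, Dstar, mlp), 0.5)
  # identical token rows: pooled vector equals any single row
  row <- rnorm(d)
  Pid <- matrix(row, 4, d, byrow = TRUE)
  set.seed(4)
  mlp2 <- list(W1 = matrix(rnorm(2 * d * 4), 2 * d, 4), b1 = rnorm(4),
               W2 = matrix(rnorm(12), 4, 3), b2 = rnorm(3),
               w3 = rnorm(3), b3 = 0.2)
  expect_equal(classify(Pid, Pid, mlp2),
               classify(Pid[1, , drop = FALSE], Pid[1, , drop = FALSE], mlp2))
  # hand-computed mean/concat/affine chain
  F <- c(colMeans(Dstar), colMeans(Pstar))
  z1 <- pmax(as.vector(F %*% mlp2$W1) + mlp2$b1, 0)
  z2 <- pmax(as.vector(z1 %*% mlp2$W2) + mlp2$b2, 0)
  expect_equal(classify(Pstar, Dstar, mlp2),
               1 / (1 + exp(-(sum(z2 * mlp2$w3) + mlp2$b3))))
})

test_that("BCE closed forms hold", {
  expect_lt(bce_loss(1 - 1e-12, 1), 1e-9)
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.9, 0), -log(0.1))
  expect_gte(bce_loss(0.3, 0), 0)
})

test_that("attention alignment loss vanishes at exact distribution match", {
  set.seed(8)
  truth <- matrix(runif(12), 3, 4)
  stack <- lapply(interaction_types(), function(t)
    list(name = t, A_dp = truth / rowSums(truth)))
  maps <- list(maps = setNames(replicate(6, truth / rowSums(truth),
                                         simplify = FALSE),
                               interaction_types()),
               overall = truth / rowSums(truth))
  # truth equal to the (row-stochastic) prediction: both normalize to the
  # same global distribution, so every log-ratio vanishes
  expect_equal(attention_alignment_loss(stack, maps, FALSE), 0,
               tolerance = 1e-12)
})

test_that("hand-computed 1x2 weighted-KL example reproduces to 1e-9", {
  stack <- list(list(name = "hbond", A_dp = matrix(c(0.5, 0.5), 1, 2)))
  maps <- list(maps = list(hbond = matrix(c(1, 0), 1, 2)),
               overall = matrix(c(1, 0), 1, 2))
  got <- attention_alignment_loss(stack, maps, supervise_overall = FALSE)
  expect_equal(got, log(2)^2, tolerance = 1e-9)
})

test_that("all-zero truth maps skip the head with a warning", {
  stack <- list(list(name = "hbond", A_dp = matrix(c(0.5, 0.5), 1, 2)),
                list(name = "salt_bridge", A_dp = matrix(c(0.5, 0.5), 1, 2)))
  maps <- list(maps = list(hbond = matrix(c(1, 0), 1, 2),
                           salt_bridge = matrix(0, 1, 2)),
               overall = matrix(c(1, 0), 1, 2))
  expect_warning(v <- attention_alignment_loss(stack, maps, FALSE),
                 "skipped")
  expect_equal(v, log(2)^2, tolerance = 1e-9)
  # no usable head at all -> NA, and the total loss falls back to Lcls
  maps0 <- list(maps = list(hbond = matrix(0, 1, 2)),
                overall = matrix(0, 1, 2))
  expect_warning(v0 <- attention_alignment_loss(stack[1], maps0, FALSE))
  expect_true(is.na(v0))
  expect_equal(total_loss(0.8, v0, 0.3), 0.8)
})

test_that("the combined objective is a convex combination, linear in lambda", {
  expect_equal(total_loss(1.0, 2.0, 0), 1.0)
  expect_equal(total_loss(1.0, 2.0, 1), 2.0)
  expect_equal(total_loss(1.0, 2.0, 0.3), 1.3)
  expect_error(total_loss(1, 1, 1.2), "lambda")
  lam <- seq(0, 1, by = 0.1)
  vals <- vapply(lam, function(l) total_loss(0.7, 1.9, l), 0)
  expect_equal(diff(vals), rep((1.9 - 0.7) * 0.1, 10), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(h = 16, H = 8, mlp_widths = c(8, 6), lambda = 0.3,
                      seed = 3)
  par <- init_params(cfg)
  set.seed(42)
  n <- 4; m <- 3
  P <- matrix(rnorm(n * 16), n); D <- matrix(rnorm(m * 16), m)
  maps <- planted_maps(list(n = n, m = m, contacts = data.frame(
    type = c("hbond", "vdw"), i = c(1, 3), j = c(2, 4),
    dist = c(3.0, 3.2))))
  lg <- crossbind:::.loss_grads(par, P, D, 1, maps, cfg)
  eps <- 1e-6
  for (nm in names(par)) {
    for (rep in 1:3) {
      idx <- sample(length(par[[nm]]), 1)
      p2 <- par
      p2[[nm]][idx] <- p2[[nm]][idx] + eps
      l1 <- crossbind:::.loss_grads(p2, P, D, 1, maps, cfg)$loss
      p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
      l2 <- crossbind:::.loss_grads(p2, P, D, 1, maps, cfg)$loss
      numg <- (l1 - l2) / (2 * eps)
      expect_equal(lg$grads[[nm]][idx], numg, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("site and type prediction ranks residues with deterministic ties", {
  mk <- function(A7, A8, typed = NULL) {
    heads <- lapply(interaction_types(), function(t)
      list(name = t, A_dp = if (is.null(typed)) A7 else typed[[t]]))
    c(heads, list(list(name = "overall1", A_dp = A7),
                  list(name = "overall2", A_dp = A8)))
  }
  unif <- matrix(1 / 4, 2, 4)
  ps <- predict_sites_and_types(mk(unif, unif))
  expect_equal(ps$residue_scores, rep(1 / 4, 4))
  expect_equal(crossbind:::.topk_residues(ps$residue_scores, 1), 1L)
  dom <- matrix(0.1, 2, 4); dom[, 3] <- 0.7
  ps2 <- predict_sites_and_types(mk(dom, dom))
  expect_equal(which.max(ps2$residue_scores), 3L)
  set.seed(9)
  r1 <- matrix(runif(8), 2); r2 <- matrix(runif(8), 2)
  ps3 <- predict_sites_and_types(mk(r1, r2))
  sc <- apply((r1 + r2) / 2, 2, max)
  expect_equal(ps3$residue_scores, sc)
  expect_equal(crossbind:::.topk_residues(sc, 3),
               order(-sc, 1:4)[1:3])
  expect_named(ps3$type_maps, interaction_types())
})

test_that("training is deterministic and encoders stay frozen", {
  specs <- sample_pair_specs(6, n = 8, m = 4, seed = 5)
  ds <- make_dataset(specs, seed = 2, h = 16)
  cfg <- model_config(h = 16, mlp_widths = c(8, 6), epochs = 5,
                      batch_size = 3, seed = 11)
  before <- encode("AGW", c("C", "O"), h = 16, seed = 1)
  f1 <- train(ds, cfg)
  f2 <- train(ds, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$par, f2$par)
  after <- encode("AGW", c("C", "O"), h = 16, seed = 1)
  expect_identical(before, after)
  expect_error(train(list(), cfg), "empty")
})

test_that("two pairs can be overfit to near-zero classification loss", {
  specs <- sample_pair_specs(2, n = 8, m = 4, seed = 6)
  ds <- make_dataset(specs, seed = 3, h = 16)
  cfg <- model_config(h = 16, mlp_widths = c(8, 6), epochs = 150,
                      batch_size = 2, lr = 5e-3, lambda = 0, seed = 1)
  fit <- train(ds, cfg)
  expect_lt(tail(fit$history$lcls, 1), 0.1)
})
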