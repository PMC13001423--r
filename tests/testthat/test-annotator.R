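test_that("decay endpoints, midpoint and out-of-window behaviour", {
  expect_equal(decay_strength(3.5, 2.5, 3.5), 1e-6)
  expect_equal(decay_strength(2.5, 2.5, 3.5), 1)
  expect_equal(decay_strength(3.0, 2.5, 3.5), (1 + 1e-6) / 2)
  expect_equal(decay_strength(3.6, 2.5, 3.5), 0)
  expect_equal(decay_strength(1.0, 2.5, 3.5), 1)
  expect_error(decay_strength(-0.1, 2.5, 3.5), "non-negative")
  expect_error(decay_strength(3, 4, 3), "d_min")
})

test_that("decay is monotone non-increasing and continuous up to the cutoff", {
  set.seed(11)
  d <- sort(runif(200, 0, 5))
  s <- decay_strength(d, 2.5, 3.5)
  expect_true(all(diff(s) <= 1e-12))
  # approaching d_cut from below, the strength approaches the floor
  expect_equal(decay_strength(3.5 - 1e-9, 2.5, 3.5), 1e-6,
               tolerance = 1e-6)
  expect_true(all(s[d <= 3.5] >= 1e-6 & s[d <= 3.5] <= 1))
})

.hbond_cx <- function(d, with_h = FALSE, h_angle_deg = 165) {
  # ligand N donor above SER OG acceptor at distance d; optional donor H
  prot <- data.frame(
    elety = c("N", "CA", "C", "O", "CB", "OG"),
    resid = "SER", resno = 1,
    x = c(-1.4, 0, 1.3, 1.9, 0, 0), y = c(0.4, 0, 0.5, 0.5, -0.9, -0.9),
    z = c(0, 0, 0, 1.0, 1.0, 2.4),
    element = c("N", "C", "C", "O", "C", "O"))
  lig <- data.frame(elety = "N1", x = 0, y = -0.9, z = 2.4 + d,
                    element = "N")
  hyd <- NULL
  if (with_h) {
    # H placed so that the N-H...O angle equals h_angle_deg
    theta <- (180 - h_angle_deg) * pi / 180
    hyd <- data.frame(elety = "H1", resid = "LIG", resno = 900,
                      x = sin(theta), y = -0.9,
                      z = 2.4 + d - cos(theta), element = "H")
  }
  build_cx(prot, lig, hydrogens = hyd)
}

test_that("hydrogen-bond detection applies window and angular filter", {
  ct <- detect_contacts(.hbond_cx(2.9, with_h = TRUE, h_angle_deg = 165),
                        "hbond")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$d, 2.9, tolerance = 1e-9)
  expect_gt(ct$angle, 120)   # near-linear donor geometry passes the filter
  expect_equal(nrow(detect_contacts(.hbond_cx(5.2), "hbond")), 0)
  expect_equal(nrow(detect_contacts(
    .hbond_cx(3.0, with_h = TRUE, h_angle_deg = 90), "hbond")), 0)
  # without hydrogens the distance-only fallback applies
  expect_equal(nrow(detect_contacts(.hbond_cx(3.0), "hbond")), 1)
  expect_error(detect_contacts(.hbond_cx(3.0), "covalent"), "unknown")
})

test_that("build_map places strengths and validates indices", {
  empty <- data.frame(i = integer(), j = integer(), strength = numeric())
  expect_equal(build_map(empty, 3, 4), matrix(0, 3, 4))
  one <- data.frame(i = 2, j = 3, strength = 1)
  A <- build_map(one, 3, 4)
  expect_equal(sum(A > 0), 1)
  expect_equal(A[2, 3], 1)
  expect_error(build_map(data.frame(i = 4, j = 1, strength = 0.5), 3, 4),
               "out of range")
})

test_that("overall aggregation is an element-wise maximum", {
  set.seed(7)
  maps <- replicate(6, {
    A <- matrix(0, 5, 8)
    A[sample(40, 6)] <- runif(6, 1e-6, 1)
    A
  }, simplify = FALSE)
  ov <- aggregate_overall(maps)
  # element-wise oracle
  for (r in 1:5) for (c in 1:8)
    expect_equal(ov[r, c], max(vapply(maps, function(M) M[r, c], 0)))
  # identity under max with five zero maps
  z <- matrix(0, 5, 8)
  expect_equal(aggregate_overall(c(maps[1], replicate(5, z, simplify = FALSE))),
               maps[[1]])
  # max(0.4, 0.7) at a shared cell
  a <- z; b <- z; a[2, 2] <- 0.4; b[2, 2] <- 0.7
  expect_equal(aggregate_overall(list(a, b))[2, 2], 0.7)
  # idempotent and commutative
  expect_equal(aggregate_overall(c(maps, maps)), ov)
  expect_equal(aggregate_overall(rev(maps)), ov)
  expect_error(aggregate_overall(list(z, matrix(0, 2, 2))), "shape")
  expect_true(all(ov >= Reduce(pmax, maps) - 1e-15))
})

test_that("residue labels are the column-wise any-nonzero reduction", {
  z <- matrix(0, 4, 6)
  lab <- project_residue_labels(z)
  expect_equal(lab$residue_labels, rep(0L, 6))
  expect_equal(nrow(lab$site_pairs), 0)
  one <- z; one[2, 5] <- 0.3
  lab <- project_residue_labels(one)
  expect_equal(lab$residue_labels, c(0L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(lab$site_pairs, data.frame(i = 2L, j = 5L))
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(0, 6, 9); A[sample(54, 7)] <- runif(7)
    lab <- project_residue_labels(A)
    expect_equal(lab$residue_labels,
                 as.integer(apply(A, 2, function(col) any(col > 0))))
    expect_equal(nrow(lab$site_pairs), sum(A > 0))
  }
})

test_that("affinity stratification follows the -5 / -7 kcal/mol thresholds", {
  expect_equal(stratify_affinity(-4.2), "negative")
  expect_equal(stratify_affinity(-8.0), "positive")
  expect_equal(stratify_affinity(-6.0), "excluded")
  expect_equal(stratify_affinity(c(-5, -7)), c("negative", "positive"))
  expect_error(stratify_affinity(NA_real_), "finite")
})

test_that("contact detection matches the brute-force oracle on seeded complexes", {
  for (seed in 1:20) {
    mc <- make_complex(random_contact_spec(seed))
    ann <- annotate_complex(mc$cx)
    got <- ann$contacts[order(ann$contacts$type, ann$contacts$i,
                              ann$contacts$j), c("type", "i", "j", "d")]
    rownames(got) <- NULL
    exp <- oracle_contacts(mc$cx)
    exp <- exp[order(exp$type, exp$i, exp$j), ]
    rownames(exp) <- NULL
    expect_equal(got, exp, tolerance = 1e-9)
  }
})

test_that("nonzero strengths stay inside [1e-6, 1]", {
  for (seed in c(3, 14)) {
    ann <- annotate_complex(make_complex(random_contact_spec(seed))$cx)
    vals <- unlist(lapply(ann$maps, function(A) A[A > 0]))
    expect_true(all(vals >= 1e-6 - 1e-15 & vals <= 1))
    ov <- ann$overall[ann$overall > 0]
    expect_true(all(ov >= 1e-6 - 1e-15 & ov <= 1))
  }
})

test_that("pocket restriction loses no contact relative to a whole-protein scan", {
  mc <- make_complex(six_type_spec())
  for (t in interaction_types()) {
    near <- detect_contacts(mc$cx, t, pocket = localize_pocket(mc$cx, 10))
    all_res <- detect_contacts(mc$cx, t, pocket = mc$cx$protein$j)
    expect_equal(near[, c("type", "i", "j")], all_res[, c("type", "i", "j")])
  }
})

test_that("site pairs enumerate exactly the nonzero overall cells", {
  ann <- annotate_complex(make_complex(six_type_spec())$cx)
  expect_equal(nrow(ann$site_pairs), sum(ann$overall > 0))
  expect_true(all(ann$overall[as.matrix(ann$site_pairs)] > 0))
  expect_equal(sort(unique(ann$site_pairs$j)),
               which(ann$residue_labels == 1))
})
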