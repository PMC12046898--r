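.toy_groups <- function(n_per = 3) rep(c("root", "stem", "leaf"), each = n_per)

test_that("squared VIP scores average to one over variables", {
  withr::with_seed(1, {
    X <- matrix(rnorm(9 * 40), 9, 40,
                dimnames = list(NULL, sprintf("m%02d", 1:40)))
  })
  v <- plsda_vip(X, .toy_groups())
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-6)
  expect_equal(sum(v$vip^2), ncol(X), tolerance = 1e-6 * ncol(X))
})

test_that("a perfectly separating variable earns the top VIP", {
  withr::with_seed(2, {
    X <- matrix(rnorm(12 * 51), 12, 51,
                dimnames = list(NULL, sprintf("m%02d", 1:51)))
    y <- rep(c("g1", "g2"), each = 6)
    X[, 1] <- ifelse(y == "g1", 4, -4) + rnorm(12, 0, 0.1)
  })
  v <- plsda_vip(X, y)
  expect_equal(names(which.max(v$vip)), "m01")
  expect_gt(v$vip[["m01"]], 1)
})

test_that("NIPALS weights match the eigen-decomposition oracle", {
  withr::with_seed(3, {
    X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, letters[1:4]))
    y <- rep(c("u", "v"), each = 3)
  })
  v <- plsda_vip(X, y, n_components = 1)
  Xs <- scale(X)
  Ys <- scale(stats::model.matrix(~ factor(y) - 1), center = TRUE,
              scale = FALSE)
  M <- crossprod(Xs, Ys) %*% crossprod(Ys, Xs)
  w_oracle <- eigen(M, symmetric = TRUE)$vectors[, 1]
  cos_angle <- abs(sum(v$weights[, 1] * w_oracle))
  expect_equal(cos_angle, 1, tolerance = 1e-8)
})

test_that("degenerate VIP inputs are handled explicitly", {
  withr::with_seed(4, X <- matrix(rnorm(9 * 5), 9, 5,
                                  dimnames = list(NULL, letters[1:5])))
  expect_error(plsda_vip(X, rep("one", 9)), "2 groups")
  X[, 2] <- 7
  expect_warning(v <- plsda_vip(X, .toy_groups()), "zero-variance")
  expect_false("b" %in% names(v$vip))
})

test_that("DAM screening applies strict fold-change and VIP thresholds", {
  withr::with_seed(5, {
    m <- matrix(2^(14 + rnorm(20 * 9, 0, 0.2)), 20, 9,
                dimnames = list(sprintf("M%02d", 1:20),
                                paste0("s", 1:9)))
    groups <- .toy_groups()
    m["M01", groups == "root"] <- m["M01", groups == "root"] * 4
  })
  dams <- screen_dams(m, groups, c("root", "stem"))
  expect_true(dams$is_dam[dams$metabolite == "M01"])
  expect_gt(dams$fold_change[dams$metabolite == "M01"], 2)
  # identical groups can never yield DAMs
  m2 <- m
  m2[, 4:6] <- m2[, 1:3]
  dams2 <- screen_dams(m2, groups, c("root", "stem"))
  expect_equal(sum(dams2$is_dam), 0)
  expect_error(screen_dams(m, groups, c("root", "bark")), "absent")
  expect_error(screen_dams(m[, 1:5], groups[1:5], c("root", "stem")),
               ">= 3 samples")
})

test_that("a fold change of exactly two is not a DAM", {
  groups <- .toy_groups()
  m <- matrix(1000, 2, 9, dimnames = list(c("M1", "M2"), paste0("s", 1:9)))
  m["M1", groups == "root"] <- 2000   # exact doubling, zero noise
  withr::with_seed(6, m["M2", ] <- 2^(10 + rnorm(9)))
  dams <- screen_dams(m, groups, c("root", "stem"))
  expect_lt(dams$fold_change[1], 2)   # epsilon keeps the ratio under 2
  expect_false(dams$is_dam[1])
})

test_that("an exact linear metabolite-gene relation gives a unit edge", {
  withr::with_seed(7, {
    g <- matrix(2^(6 + rnorm(3 * 9)), 3, 9,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:9)))
  })
  m <- matrix(0, 1, 9, dimnames = list("M1", paste0("s", 1:9)))
  m["M1", ] <- 2^(2 * log2(g["g1", ] + 1) - 3) - 1
  net <- build_correlation_network(m, g)
  e <- net$edges[net$edges$gene == "g1", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$r, 1, tolerance = 1e-12)
  expect_equal(e$sign, "positive")
})

test_that("edge retention equals the brute-force rank-then-filter oracle", {
  withr::with_seed(8, {
    for (trial in 1:10) {
      m <- matrix(2^rnorm(8 * 9, 12), 8, 9,
                  dimnames = list(sprintf("M%d", 1:8), paste0("s", 1:9)))
      g <- matrix(2^rnorm(12 * 9, 6), 12, 9,
                  dimnames = list(sprintf("g%02d", 1:12), paste0("s", 1:9)))
      # plant a few strong links so the threshold is exercised
      m[1, ] <- 2^(log2(g[1, ] + 1) + rnorm(9, 0, 0.05))
      m[2, ] <- 2^(-log2(g[2, ] + 1) + rnorm(9, 0, 0.05))
      net <- build_correlation_network(m, g)
      oracle <- oracle_network_edges(m, g, 0.8, 5)
      got <- net$edges[order(net$edges$metabolite, net$edges$gene), ]
      want <- oracle[order(oracle$metabolite, oracle$gene), ]
      expect_equal(got$metabolite, want$metabolite)
      expect_equal(got$gene, want$gene)
      expect_equal(got$r, want$r, tolerance = 1e-12)
      expect_true(all(abs(got$r) > 0.8))
      expect_true(all(table(got$metabolite) <= 5))
    }
  })
})

test_that("sub-threshold correlations are excluded however strong", {
  s <- paste0("s", 1:9)
  withr::with_seed(9, z <- rnorm(9))
  g <- matrix(2^(6 + z), 1, 9, dimnames = list("g1", s))
  # mix to a known correlation of ~0.7 on the log scale
  withr::with_seed(10, e <- rnorm(9))
  zz <- 0.7 * scale(log2(g[1, ] + 1))[, 1] + sqrt(1 - 0.49) * scale(e)[, 1]
  m <- matrix(2^(12 + zz), 1, 9, dimnames = list("M1", s))
  r_actual <- cor(log2(m[1, ] + 1), log2(g[1, ] + 1))
  net <- build_correlation_network(m, g)
  if (abs(r_actual) <= 0.8) expect_equal(nrow(net$edges), 0)
  expect_error(build_correlation_network(m[, 1:2, drop = FALSE],
                                         g[, 1:2, drop = FALSE]),
               "matched samples")
})

test_that("the network is invariant to linear rescaling of intensities", {
  withr::with_seed(11, {
    m <- matrix(2^rnorm(5 * 9, 12), 5, 9,
                dimnames = list(sprintf("M%d", 1:5), paste0("s", 1:9)))
    g <- matrix(2^rnorm(8 * 9, 6), 8, 9,
                dimnames = list(sprintf("g%d", 1:8), paste0("s", 1:9)))
    m[1, ] <- 2^(log2(g[1, ] + 1) + rnorm(9, 0, 0.1))
  })
  n1 <- build_correlation_network(m, g, log_transform = FALSE)
  n2 <- build_correlation_network(m * 1000, g, log_transform = FALSE)
  expect_equal(n1$edges$metabolite, n2$edges$metabolite)
  expect_equal(n1$edges$gene, n2$edges$gene)
  expect_equal(n1$edges$r, n2$edges$r, tolerance = 1e-12)
})

test_that("planted links dominate the recovered network (precision/recall)", {
  # n = 9 samples; the gene pool is modest and partners are identifiable,
  # which is the regime in which a |r| > 0.8 network can separate planted
  # links from correlation noise at this sample size
  withr::with_seed(12, {
    expr <- matrix(2^(6 + rnorm(10 * 9)), 10, 9,
                   dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:9)))
  })
  met <- suppressWarnings(
    simulate_metabolome(expr, .toy_groups(), n_metabolites = 50,
                        linked_fraction = 0.2, target_r = 0.95, seed = 13))
  linked <- met$truth_links$metabolite
  net <- build_correlation_network(met$intensity[linked, , drop = FALSE],
                                   expr)
  got <- paste(net$edges$metabolite, net$edges$gene)
  want <- paste(met$truth_links$metabolite, met$truth_links$gene)
  expect_gte(mean(want %in% got), 0.9)   # recall
  expect_gte(mean(got %in% want), 0.9)   # precision
  # planted in-sample correlations sit exactly at the target
  for (k in seq_len(nrow(met$truth_links))) {
    r <- cor(log2(met$intensity[met$truth_links$metabolite[k], ] + 1),
             log2(expr[met$truth_links$gene[k], ] + 1))
    # exact up to the log2(x + 1) pseudo-count distortion
    expect_equal(abs(unname(r)), 0.95, tolerance = 1e-4)
  }
})

test_that("networks export to GraphML and SIF", {
  withr::with_seed(14, {
    g <- matrix(2^rnorm(3 * 9, 6), 3, 9,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:9)))
  })
  m <- matrix(2^(log2(g[1, ] + 1) + 12), 1, 9,
              dimnames = list("M1", paste0("s", 1:9)))
  net <- build_correlation_network(m, g)
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  export_network(net, graphml = gml, sif = sif)
  expect_true(file.exists(gml))
  expect_match(readLines(sif)[1], "positive")
})
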