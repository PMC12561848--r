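# exact rank-2 genotype x environment matrix, environment-centered by design
rank2_matrix <- function(g, e, d1 = 4, d2 = 1.5) {
  u1 <- scale(rnorm(g))[, 1]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- residuals(lm(rnorm(g) ~ u1)); u2 <- u2 / sqrt(sum(u2^2))
  v1 <- rnorm(e); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- residuals(lm(rnorm(e) ~ v1 - 1)); v2 <- v2 / sqrt(sum(v2^2))
  m <- d1 * outer(u1, v1) + d2 * outer(u2, v2)
  dimnames(m) <- list(paste0("G", seq_len(g)), paste0("E", seq_len(e)))
  m
}

test_that("a constant matrix gives a null model with degenerate views", {
  m <- matrix(5, 3, 4, dimnames = list(paste0("G", 1:3), paste0("E", 1:4)))
  mod <- fit_gge(m)
  expect_true(all(mod$centered == 0))
  expect_true(all(mod$genotype_coords == 0))
  expect_warning(ww <- which_won_where(mod), "collinear")
  expect_error(mean_vs_stability(mod), "zero length")
})

test_that("the 2x2 identity example matches the hand SVD", {
  m <- matrix(c(1, 0, 0, 1), nrow = 2,
              dimnames = list(c("A", "B"), c("E1", "E2")))
  mod <- fit_gge(m)
  expect_equal(unname(mod$centered),
               matrix(c(0.5, -0.5, -0.5, 0.5), nrow = 2))
  expect_equal(mod$theta1, 1)
  expect_equal(mod$theta2, 0)
  expect_equal(mod$var_explained, c(1, 0))
})

test_that("two biplot axes reconstruct matrices of rank at most 2 exactly", {
  set.seed(21)
  mats <- list()
  for (dims in list(c(3, 6), c(3, 3)))   # g = 3: centered rank <= 2 always
    mats[[length(mats) + 1]] <- matrix(rnorm(prod(dims), sd = 3), nrow = dims[1])
  mats[[3]] <- rank2_matrix(5, 3)        # g > 3 needs planted rank <= 2
  for (m in mats) {
    dimnames(m) <- list(paste0("G", seq_len(nrow(m))),
                        paste0("E", seq_len(ncol(m))))
    mod <- fit_gge(m)
    recon <- mod$genotype_coords %*% t(mod$environment_coords)
    expect_equal(recon, mod$centered, tolerance = 1e-8)
    # reconstruction holds for any singular-value partitioning
    for (f in c(0, 1)) {
      mf <- fit_gge(m, scaling_f = f)
      expect_equal(mf$genotype_coords %*% t(mf$environment_coords),
                   mf$centered, tolerance = 1e-8)
    }
  }
})

test_that("singular values and variance shares agree with a full SVD oracle", {
  set.seed(33)
  m <- matrix(rnorm(20, sd = 2), nrow = 4)
  mod <- fit_gge(m)
  sv <- svd(sweep(m, 2, colMeans(m)))$d
  expect_equal(mod$theta, sv, tolerance = 1e-10)
  expect_equal(mod$var_explained, sv^2 / sum(sv^2), tolerance = 1e-10)
  expect_lte(sum(mod$var_explained[1:2]), 1)
  expect_true(all(diff(mod$var_explained) <= 1e-12))
})

test_that("environment angles reflect column similarity", {
  set.seed(55)
  # identical centered columns -> zero angle
  base <- rnorm(4)
  m <- cbind(E1 = base, E2 = base + 2, E3 = rnorm(4))
  rownames(m) <- paste0("G", 1:4)
  rel <- env_relationship(fit_gge(m))
  expect_equal(rel$env_angles["E1", "E2"], 0, tolerance = 1e-6)
  expect_equal(rel$env_angles, t(rel$env_angles))
  expect_equal(unname(diag(rel$env_angles)), rep(0, 3))

  # proportional-but-opposite columns in a rank-1 model -> angle pi
  u <- c(1, -1, 2, -2)
  m2 <- cbind(E1 = u, E2 = -2 * u)
  rownames(m2) <- paste0("G", 1:4)
  rel2 <- env_relationship(fit_gge(m2))
  expect_equal(rel2$env_angles["E1", "E2"], pi, tolerance = 1e-8)

  # in an (exact) rank-2 model with environment-focused scaling the angle
  # cosine equals the Pearson correlation of the centered columns
  m3 <- rank2_matrix(5, 4)
  rel3 <- env_relationship(fit_gge(m3, scaling_f = 0))
  cc <- cor(sweep(m3, 2, colMeans(m3)))
  expect_equal(cos(rel3$env_angles), cc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("sector winners equal the per-environment argmax of centered values", {
  set.seed(77)
  for (i in 1:8) {
    m <- rank2_matrix(sample(3:6, 1), sample(3:6, 1))
    mod <- fit_gge(m)
    ww <- which_won_where(mod)
    centered <- mod$centered
    for (env in colnames(centered)) {
      expect_identical(unname(ww$sectors[env]),
                       rownames(centered)[which.max(centered[, env])])
      expect_true(ww$sectors[env] %in% ww$hull_vertices)
    }
    # invariance to the singular-value partitioning
    for (f in c(0, 1))
      expect_identical(which_won_where(fit_gge(m, scaling_f = f))$sectors,
                       ww$sectors)
  }
})

test_that("a uniformly dominant genotype wins every sector", {
  # rank-2 table in which G1's centered value is strictly largest at every
  # environment: all environments must fall in G1's sector
  u1 <- c(0.9, 0.1, -0.4, -0.6)
  u2 <- c(0, 1, -1, 0) / sqrt(2)
  v1 <- rep(1, 5) / sqrt(5)
  v2 <- c(2, -1, 0, 1, -2) / sqrt(10)
  m <- 5 * outer(u1, v1) + 0.3 * outer(u2, v2) + 20
  dimnames(m) <- list(paste0("G", 1:4), paste0("E", 1:5))
  mod <- fit_gge(m)
  centered <- mod$centered
  expect_true(all(apply(centered, 2, which.max) == 1))
  ww <- which_won_where(mod)
  expect_true(all(ww$sectors == "G1"))
})

test_that("mean-vs-stability behaves per its geometry", {
  set.seed(101)
  # rank-1 model: every genotype sits on the AEC axis, zero instability
  u <- c(3, 1, -1, -3); v <- c(1, 2, 2, 1, 4) / sqrt(26)
  m <- outer(u, v); dimnames(m) <- list(paste0("G", 1:4), paste0("E", 1:5))
  ms <- mean_vs_stability(fit_gge(m))
  expect_lt(max(ms$aec_distance), 1e-7)

  # exact rank-2: projection ranking equals centered row-mean ranking
  m2 <- rank2_matrix(5, 4)
  mod2 <- fit_gge(m2)
  ms2 <- mean_vs_stability(mod2)
  rm2 <- rowMeans(mod2$centered)
  expect_identical(order(ms2$aec_projection, decreasing = TRUE),
                   order(rm2, decreasing = TRUE))
  expect_identical(ms2$ranking_activity,
                   names(sort(rm2, decreasing = TRUE)))
  expect_true(all(ms2$aec_distance >= 0))
})

test_that("ideal-entry distances follow the concentric-circle geometry", {
  # rank-1 model: distance reduces to the projection gap
  u <- c(3, 1, -1, -3); v <- rep(1, 5) / sqrt(5)
  m <- outer(u, v); dimnames(m) <- list(paste0("G", 1:4), paste0("E", 1:5))
  mod <- fit_gge(m)
  ms <- mean_vs_stability(mod)
  ie <- ideal_entry(mod)
  expect_equal(unname(ie$ideal_distance),
               unname(max(ms$aec_projection) - ms$aec_projection),
               tolerance = 1e-8)
  # the genotype at the ideal point ranks first with distance zero
  expect_equal(unname(ie$ideal_distance[ie$ranking[1]]), 0, tolerance = 1e-8)
  expect_identical(ie$ranking[1], names(which.max(ms$aec_projection)))
})

test_that("a genotype with top mean and zero spread is the ideal entry", {
  m <- rbind(G1 = c(10, 10, 10, 10),   # high and perfectly flat
             G2 = c(6, 9, 3, 8),
             G3 = c(2, 1, 3, 2))
  colnames(m) <- paste0("E", 1:4)
  ie <- ideal_entry(fit_gge(m))
  expect_identical(ie$ranking[1], "G1")
})

test_that("outputs are equivariant under genotype relabeling", {
  set.seed(202)
  m <- rank2_matrix(5, 4)
  perm <- c(3, 1, 5, 2, 4)
  mod1 <- fit_gge(m); mod2 <- fit_gge(m[perm, ])
  expect_equal(mod2$theta, mod1$theta, tolerance = 1e-10)
  ie1 <- ideal_entry(mod1); ie2 <- ideal_entry(mod2)
  expect_equal(ie2$ideal_distance[rownames(m)], ie1$ideal_distance,
               tolerance = 1e-8)
  expect_identical(which_won_where(mod2)$sectors, which_won_where(mod1)$sectors)
})

test_that("plot method renders all four views without error", {
  set.seed(12)
  mod <- fit_gge(rank2_matrix(4, 5))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  for (v in c("relationship", "which-won-where", "mean-stability", "ideal"))
    expect_no_error(plot(mod, view = v))
})
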