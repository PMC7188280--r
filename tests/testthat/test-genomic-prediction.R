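test_that("marker effects at fixed lambda equal the closed-form ridge solution", {
  set.seed(41)
  cfg <- small_cfg(n_lines = 20, n_markers = 50, seed = 41)
  g <- simulate_founders(cfg)
  y <- setNames(rnorm(20, 5, 1), rownames(g$dosage))
  lam <- 3.7
  fit <- suppressWarnings(fit_rrblup(g, y, lambda = lam))
  # independent brute-force oracle: GLS intercept, then ridge normal equations
  W <- sweep(g$dosage, 2, colMeans(g$dosage))
  V <- W %*% t(W) + lam * diag(20)
  Vi <- solve(V)
  beta <- sum(Vi %*% y) / sum(Vi)
  a_or <- solve(t(W) %*% W + lam * diag(50), t(W) %*% (y - beta))
  expect_equal(unname(fit$marker_effects), as.numeric(a_or), tolerance = 1e-8)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
})

test_that("marker-model GEBVs equal K-model GEBVs (RRBLUP-GBLUP equivalence)", {
  for (s in 1:3) {
    cfg <- small_cfg(n_lines = 50, n_markers = 200, seed = 400 + s)
    g <- simulate_founders(cfg)
    tr <- simulate_trial(g, cfg)
    y <- pheno_values(adjust_single_env(tr$fieldbook, "E1"))
    fit <- fit_rrblup(g, y)
    # K-model BLUP at the fitted variance ratio, computed independently
    W <- sweep(g$dosage, 2, colMeans(g$dosage))
    cc <- fit$scaling_c
    K <- W %*% t(W) / cc
    V <- K + fit$lambda_K * diag(nrow(K))
    Vi <- solve(V)
    beta <- sum(Vi %*% y[rownames(K)]) / sum(Vi)
    u_K <- K %*% Vi %*% (y[rownames(K)] - beta)
    gebv_marker <- predict_gebv(fit, g)$gebv
    expect_equal(gebv_marker, as.numeric(u_K), tolerance = 1e-6)
  }
})

test_that("null phenotypes give a near-zero genetic variance share", {
  hits <- vapply(1:25, function(s) {
    cfg <- small_cfg(n_lines = 500, n_markers = 150, seed = 500 + s)
    g <- simulate_founders(cfg)
    set.seed(1000 + s)
    y <- setNames(rnorm(500, 4.5, 1), rownames(g$dosage))
    fit <- fit_rrblup(g, y)
    fit$sigma_u2 / (fit$sigma_u2 + fit$sigma_e2) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("prediction reproduces training GEBVs and zeroes all-mean profiles", {
  cfg <- small_cfg(n_lines = 60, n_markers = 100, seed = 42)
  g <- simulate_founders(cfg)
  tr <- simulate_trial(g, cfg)
  fit <- fit_rrblup(g, adjust_single_env(tr$fieldbook, "E1"))
  pr <- predict_gebv(fit, g)
  expect_equal(setNames(pr$gebv, pr$line_id)[fit$train_ids],
               fit$train_gebv, tolerance = 1e-8)
  # a line sitting exactly at the mean dosage profile has GEBV 0
  d <- rbind(g$dosage, MEAN = colMeans(g$dosage))
  pr2 <- predict_gebv(fit, genotype_matrix(d, g$map))
  expect_lt(abs(pr2$gebv[pr2$line_id == "MEAN"]), 1e-10)
})

test_that("GEBVs of related progeny track true genetic values", {
  rs <- vapply(1:10, function(s) {
    cfg <- small_cfg(n_lines = 400, n_markers = 300, n_qtl = 40,
                     h2_target = 0.8, gxe_corr = 1, seed = 600 + s)
    g <- simulate_founders(cfg)
    tr <- simulate_trial(g, cfg)
    fit <- fit_rrblup(g, adjust_single_env(tr$fieldbook, "E1"))
    set.seed(s)
    parents <- sample(rownames(g$dosage), 2)
    prog <- derive_biparental(geno_subset(g, lines = parents), 200,
                              pop_type = "DH", seed = 600 + s)
    ptr <- simulate_trial(prog, cfg, seed = 700 + s)
    # truth for progeny under the *founder* QTL effects
    cor(predict_gebv(fit, prog)$gebv,
        (prog$dosage[, tr$truth$qtl_ids] %*% tr$truth$qtl_effects[, "E1"]))
  }, numeric(1))
  expect_gte(mean(rs), 0.5)
})

test_that("predictive ability has the right fixed points and null behaviour", {
  g <- setNames(rnorm(50), sprintf("L%02d", 1:50))
  gr <- data.frame(line_id = names(g), gebv = g)
  expect_equal(predictive_ability(gr, g)$r, 1)
  expect_equal(predictive_ability(gr, -g)$r, -1)
  expect_error(predictive_ability(gr, setNames(rep(1, 50), names(g))), "variance")
  expect_error(predictive_ability(gr[1:2, ], g[1:2]), "3")
  # null distribution: |r| < 0.2 almost always at n = 450
  nulls <- vapply(1:40, function(s) {
    set.seed(s)
    abs(cor(rnorm(450), rnorm(450)))
  }, numeric(1))
  expect_gte(mean(nulls < 0.2), 0.95)
})

test_that("cross-validation partitions correctly and is seed-deterministic", {
  cfg <- small_cfg(n_lines = 60, n_markers = 80, seed = 44)
  g <- simulate_founders(cfg)
  y <- pheno_values(adjust_single_env(simulate_trial(g, cfg)$fieldbook, "E1"))
  cv1 <- cross_validate(g, y, folds = 5, seed = 9)
  cv2 <- cross_validate(g, y, folds = 5, seed = 9)
  expect_identical(cv1$oof, cv2$oof)
  expect_equal(cv1$fold_r, cv2$fold_r)
  expect_setequal(cv1$oof$line_id, names(y))
  expect_equal(anyDuplicated(cv1$oof$line_id), 0L)
  # leave-one-out on 10 lines: 10 singleton predictions
  g10 <- geno_subset(g, lines = rownames(g$dosage)[1:10])
  loo <- suppressWarnings(cross_validate(g10, y[1:10], folds = 10, seed = 1))
  expect_equal(nrow(loo$oof), 10)
  expect_true(all(table(loo$oof$fold) == 1))
  expect_true(all(is.na(loo$fold_r)))
  expect_error(cross_validate(g10, y[1:10], folds = 11, seed = 1), "folds")
})

test_that("shrinkage limits and translation invariance hold", {
  cfg <- small_cfg(n_lines = 40, n_markers = 60, seed = 45)
  g <- simulate_founders(cfg)
  y <- pheno_values(adjust_single_env(simulate_trial(g, cfg)$fieldbook, "E1"))
  f1 <- suppressWarnings(fit_rrblup(g, y, lambda = 1))
  f2 <- suppressWarnings(fit_rrblup(g, y, lambda = 1e4))
  f3 <- suppressWarnings(fit_rrblup(g, y, lambda = 1e8))
  m1 <- max(abs(f1$train_gebv)); m2 <- max(abs(f2$train_gebv))
  m3 <- max(abs(f3$train_gebv))
  expect_true(m1 > m2 && m2 > m3)          # monotone shrinkage
  expect_lt(m3, 1e-3)                      # lambda -> Inf: GEBVs -> 0
  # shifting phenotypes moves only the intercept
  fit <- suppressWarnings(fit_rrblup(g, y))
  fit_c <- suppressWarnings(fit_rrblup(g, y + 3))
  expect_equal(fit_c$beta[["(Intercept)"]], fit$beta[["(Intercept)"]] + 3,
               tolerance = 1e-6)
  expect_equal(fit_c$marker_effects, fit$marker_effects, tolerance = 1e-6)
})

test_that("fixed markers with exactly-zero GLS coefficients reproduce GS1", {
  # construct y = V z with z orthogonal to the fixed-effect columns: the
  # joint GLS estimate is exactly zero, so GS2 must equal GS1 at the same
  # lambda
  cfg <- small_cfg(n_lines = 40, n_markers = 80, seed = 46)
  g <- simulate_founders(cfg)
  fm <- colnames(g$dosage)[c(3, 17)]
  lam <- 2.5
  W <- sweep(g$dosage, 2, colMeans(g$dosage))
  V <- W %*% t(W) + lam * diag(40)
  X <- cbind(1, g$dosage[, fm])
  set.seed(46)
  z <- rnorm(40)
  z <- z - X %*% solve(crossprod(X), crossprod(X, z))  # z orthogonal to X
  y <- setNames(as.numeric(V %*% z), rownames(g$dosage))
  f_gs1 <- suppressWarnings(fit_rrblup(g, y, lambda = lam))
  f_gs2 <- suppressWarnings(fit_rrblup(g, y, fixed_markers = fm, lambda = lam))
  expect_lt(max(abs(f_gs2$beta[-1])), 1e-8)
  expect_equal(predict_gebv(f_gs2, g)$gebv, predict_gebv(f_gs1, g)$gebv,
               tolerance = 1e-6)
})

test_that("within-environment predictive ability exceeds cross-environment under low G-by-E correlation", {
  pa <- t(vapply(1:20, function(s) {
    cfg <- small_cfg(n_lines = 300, n_markers = 300, n_qtl = 40,
                     h2_target = 0.8, gxe_corr = 0.2, seed = 6000 + s)
    g <- simulate_founders(cfg)
    tr <- simulate_trial(g, cfg)
    a1 <- adjust_single_env(tr$fieldbook, "E1")
    a2 <- adjust_single_env(tr$fieldbook, "E2")
    set.seed(s)
    test_ids <- sample(rownames(g$dosage), 60)
    fit <- fit_rrblup(geno_subset(g, lines = setdiff(rownames(g$dosage),
                                                     test_ids)),
                      pheno_values(a1))
    pr <- predict_gebv(fit, geno_subset(g, lines = test_ids))
    c(within = predictive_ability(pr, a1)$r,
      cross = predictive_ability(pr, a2)$r)
  }, c(within = 0, cross = 0)))
  expect_gt(mean(pa[, "within"]), mean(pa[, "cross"]))
})

test_that("rank-deficient fixed designs and constant phenotypes are rejected", {
  cfg <- small_cfg(n_lines = 40, n_markers = 60, seed = 47)
  g <- simulate_founders(cfg)
  g$dosage[, 5] <- 2  # monomorphic marker
  y <- setNames(rnorm(40), rownames(g$dosage))
  expect_error(suppressWarnings(
    fit_rrblup(g, y, fixed_markers = colnames(g$dosage)[5])), "rank")
  expect_error(suppressWarnings(
    fit_rrblup(g, setNames(rep(1, 40), rownames(g$dosage)))), "constant")
})
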