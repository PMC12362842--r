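# Build a means table whose sample correlation matrix is EXACTLY `target`
# (traits in trait_names() order): orthonormalize centered Gaussian columns,
# then color them with chol(target).
means_with_exact_cor <- function(target, n = 40, seed = 1) {
  set.seed(seed)
  W <- scale(matrix(rnorm(n * 6), n, 6), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(W))          # orthonormal, still column-centered
  X <- Q %*% chol(target)
  colnames(X) <- trait_names()
  rows <- expand.grid(genotype_id = sprintf("G%04d", seq_len(n)),
                      trait = trait_names(), stringsAsFactors = FALSE)
  rows$location <- "HLJ"; rows$treatment <- "CK"
  rows$mean_value <- X[cbind(match(rows$genotype_id, sprintf("G%04d", seq_len(n))),
                             match(rows$trait, trait_names()))] + 10
  rows$n_reps_used <- 3L
  class(rows) <- c("shadetol_means", "data.frame")
  rows
}

test_that("paired correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 5, 4, 6)
  vals <- Map(function(ck, sh) c(CK = ck, shade = sh), x, y)
  names(vals) <- paste0("G", 1:5)
  m <- aggregate_to_means(toy_panel(vals, trait = "PH"))
  pc <- paired_correlation(m, "PH", "HLJ")
  # brute-force covariance formula
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  expect_equal(pc$r_squared, r_oracle^2, tolerance = 1e-12)
  b_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(pc$slope, b_oracle, tolerance = 1e-12)
  expect_equal(pc$intercept, mean(y) - b_oracle * mean(x), tolerance = 1e-12)
  expect_equal(pc$n, 5L)
})

test_that("identical shade and control values give the identity line", {
  x <- c(3, 7, 11, 5)
  vals <- Map(function(v) c(CK = v, shade = v), x)
  names(vals) <- paste0("G", 1:4)
  m <- aggregate_to_means(toy_panel(vals, trait = "SYP"))
  pc <- paired_correlation(m, "SYP", "HLJ")
  expect_equal(pc$r, 1)
  expect_equal(pc$slope, 1)
  expect_equal(pc$intercept, 0, tolerance = 1e-12)
})

test_that("paired correlation is invariant to affine rescaling", {
  m <- aggregate_to_means(simulate_panel(hlj_config(25, seed = 17)))
  r0 <- paired_correlation(m, "PNP", "HLJ")$r
  m2 <- m
  ck <- m2$treatment == "CK" & m2$trait == "PNP"
  m2$mean_value[ck] <- 3.7 * m2$mean_value[ck] + 11
  expect_equal(paired_correlation(m2, "PNP", "HLJ")$r, r0, tolerance = 1e-12)
})

test_that("degenerate paired inputs are flagged", {
  vals <- Map(function(v) c(CK = 5, shade = v), c(1, 2, 3))
  names(vals) <- paste0("G", 1:3)
  m <- aggregate_to_means(toy_panel(vals, trait = "BN"))
  expect_warning(pc <- paired_correlation(m, "BN", "HLJ"), "zero variance")
  expect_true(is.na(pc$r))
  expect_error(paired_correlation(m[m$genotype_id != "G1", ], "BN", "HLJ"),
               "at least 3")
})

test_that("orthogonal predictors make direct effects equal total correlations", {
  S <- diag(6)
  dimnames(S) <- list(trait_names(), trait_names())
  S["PH", "SYP"] <- S["SYP", "PH"] <- 0.6
  m <- means_with_exact_cor(S, n = 30, seed = 3)
  pm <- path_analysis(m, treatment = "CK")
  expect_equal(unname(pm$direct), unname(pm$r_xy), tolerance = 1e-10)
  off <- pm$indirect; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-10)
  expect_equal(pm$r_squared_total, 0.36, tolerance = 1e-10)
})

test_that("direct effects solve the correlation system (hand 2x2 oracle)", {
  # r(PH,BPH) = 0.5, r_xy = {0.6, 0.5}, other predictors orthogonal:
  # p_PH = (0.6 - 0.5*0.5)/(1 - 0.25) = 7/15, p_BPH = (0.5 - 0.5*0.6)/0.75 = 4/15
  S <- diag(6)
  dimnames(S) <- list(trait_names(), trait_names())
  S["PH", "BPH"] <- S["BPH", "PH"] <- 0.5
  S["PH", "SYP"] <- S["SYP", "PH"] <- 0.6
  S["BPH", "SYP"] <- S["SYP", "BPH"] <- 0.5
  m <- means_with_exact_cor(S, n = 40, seed = 5)
  pm <- path_analysis(m, treatment = "CK")
  expect_equal(unname(pm$direct[c("PH", "BPH")]), c(7 / 15, 4 / 15),
               tolerance = 1e-10)
  expect_equal(unname(pm$direct[c("NNP", "BN", "PNP")]), rep(0, 3),
               tolerance = 1e-10)
})

test_that("path decomposition identity and OLS equivalence hold on random data", {
  for (s in 1:10) {
    m <- aggregate_to_means(simulate_panel(hlj_config(30, seed = 400 + s)))
    pm <- path_analysis(m, treatment = "CK", location = "HLJ")
    # r_xy[i] = direct[i] + sum_j indirect[i, j]
    recon <- pm$direct + rowSums(pm$indirect)
    expect_equal(unname(recon), unname(pm$r_xy), tolerance = 1e-10)
    # direct effects = standardized OLS coefficients (independent route)
    w <- shadetol:::means_to_wide(m, location = "HLJ", treatment = "CK")
    X <- w$matrix; colnames(X) <- w$traits
    Z <- scale(X)
    beta <- qr.solve(cbind(1, Z[, 1:5]), Z[, "SYP"])[-1]
    expect_equal(unname(pm$direct), unname(beta), tolerance = 1e-10)
    expect_equal(pm$r_squared_total, sum(pm$direct * pm$r_xy), tolerance = 1e-12)
  }
})

test_that("collinear predictors abort with the offending pair named", {
  m <- aggregate_to_means(simulate_panel(hlj_config(20, seed = 6)))
  dup <- m$trait == "BPH"
  ph <- m[m$trait == "PH", ]
  m$mean_value[dup] <- ph$mean_value[match(
    paste(m$genotype_id[dup], m$treatment[dup]),
    paste(ph$genotype_id, ph$treatment))]
  expect_error(path_analysis(m, treatment = "CK"), "PH.*BPH|BPH.*PH")
})

test_that("PCA of two perfectly correlated variables collapses to one axis", {
  set.seed(8)
  a <- rnorm(50)
  M <- cbind(x = a, y = 2 * a + 3)
  p <- pca_traits(M)
  expect_equal(p$explained_variance_ratio, c(1, 0), tolerance = 1e-12)
})

test_that("PCA ratios, scores, and sign convention satisfy the contracts", {
  m <- aggregate_to_means(simulate_panel(default_sim_config(40, seed = 23)))
  p <- pca_traits(m, location = "HLJ")
  evr <- p$explained_variance_ratio
  expect_equal(sum(evr), 1, tolerance = 1e-12)
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  # scores are centered; their covariance is the eigenvalue diagonal
  expect_lt(max(abs(colMeans(p$scores))), 1e-8)
  cv <- cov(p$scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  # largest-|loading| entry of every component is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("isotropic traits spread variance evenly across components", {
  set.seed(12)
  M <- matrix(rnorm(460 * 6), 460, 6)
  colnames(M) <- trait_names()
  p <- pca_traits(M)
  expect_true(all(abs(p$explained_variance_ratio - 1 / 6) < 0.05))
})

test_that("constant trait columns are dropped with a warning", {
  set.seed(9)
  M <- cbind(a = rnorm(20), b = rnorm(20), c = rep(1, 20))
  expect_warning(p <- pca_traits(M), "constant")
  expect_equal(ncol(p$loadings), 2L)
})
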