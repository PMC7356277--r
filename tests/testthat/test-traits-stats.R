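test_that("NDVI senescence slope recovers a known linear decline", {
  daps <- seq(21, 105, by = 7)
  wiggle <- rep(c(1e-4, -1e-4), length.out = 7) # mean-zero, slope-neutral
  ndvi <- c(seq(0.2, 0.7, length.out = 6),
            0.7 - 0.004 * (daps[7:13] - daps[6]) + wiggle)
  pts <- canopy_points(daps, rep(0.5, 13), ndvi)
  out <- ndvi_senescence_slope(pts)
  expect_equal(out$slope, -0.004, tolerance = 1e-3)
  expect_equal(out$peak_dap, daps[6])
  expect_equal(out$n, 8L)
  short <- canopy_points(c(7, 14, 21), c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  expect_error(ndvi_senescence_slope(short), "at least 3 flights")
  no_ndvi <- canopy_points(c(7, 14, 21), c(0.1, 0.2, 0.3))
  expect_error(ndvi_senescence_slope(no_ndvi), "required")
})

test_that("Federer-adjusted means agree with a least-squares oracle", {
  for (s in c(1, 2, 3, 10)) {
    case <- random_dau_case(s)
    res <- dau_analysis(case$design, case$y)
    oracle <- lm_adjusted_means(case$design, case$y)
    am <- res$adjusted_means
    expect_equal(am$adjusted, as.numeric(oracle[am$accession]),
                 tolerance = 1e-8)
  }
})

test_that("DAU block effects and ANOVA partition are exact on a constructed case", {
  # 2 blocks, 2 checks, 2 new entries; hand-computable
  design <- data.frame(
    accession = c("C1", "C2", "N1", "C1", "C2", "N2"),
    block = c(1, 1, 1, 2, 2, 2),
    is_check = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  y <- c(10, 14, 20, 12, 16, 21)
  res <- dau_analysis(design, y)
  # check means: block1 12, block2 14, grand 13 -> effects -1, +1
  expect_equal(as.numeric(res$block_effects), c(-1, 1))
  am <- res$adjusted_means
  expect_equal(am$adjusted[am$accession == "N1"], 21) # 20 - (-1)
  expect_equal(am$adjusted[am$accession == "N2"], 20) # 21 - 1
  # checks-by-blocks interaction is exactly zero here (additive data)
  expect_equal(res$error_ms, 0)
  expect_equal(res$error_df, 1L)
  an <- res$anova
  expect_equal(an$ss[an$source == "Block (checks)"], 2 * 2 * 1) # c*sum(eff^2)
  expect_equal(an$ss[an$source == "Check"], 2 * 2 * 2^2) # means 11, 15
  # total checks SS is recovered by the partition
  checks_y <- y[design$is_check]
  expect_equal(sum(an$ss[an$source %in%
                           c("Block (checks)", "Check", "Error")]),
               sum((checks_y - mean(checks_y))^2))
})

test_that("DAU rejects malformed designs and incomplete checks", {
  design <- data.frame(accession = c("C1", "N1", "C1", "C2"),
                       block = c(1, 1, 2, 2),
                       is_check = c(TRUE, FALSE, TRUE, TRUE))
  expect_error(dau_analysis(design, 1:4), "missing check")
  case <- random_dau_case(4)
  expect_error(dau_analysis(case$design, case$y[-1]), "one value per")
  yna <- case$y
  yna[which(case$design$is_check)[1]] <- NA
  expect_error(dau_analysis(case$design, yna), "complete for checks")
})

test_that("Federer pair variances follow the four pair types", {
  ms <- 6; b <- 4; c_ <- 3
  expect_equal(dau_diff_var(ms, b, c_, TRUE, TRUE, FALSE), 2 * ms / b)
  expect_equal(dau_diff_var(ms, b, c_, FALSE, FALSE, TRUE), 2 * ms)
  expect_equal(dau_diff_var(ms, b, c_, FALSE, FALSE, FALSE),
               2 * ms * (1 + 1 / c_))
  expect_equal(dau_diff_var(ms, b, c_, TRUE, FALSE, FALSE),
               ms * (1 + 1 / b + 1 / c_ + 1 / (b * c_)))
})

test_that("Tukey letters separate distant means and join close ones", {
  case <- random_dau_case(6)
  # push one new entry far above everything
  y <- case$y
  top <- which(!case$design$is_check)[1]
  y[top] <- y[top] + 1000
  res <- dau_analysis(case$design, y)
  am <- res$adjusted_means
  expect_equal(am$accession[1], case$design$accession[top])
  # the outlier's letter set is disjoint from every other entry's
  top_letters <- strsplit(am$group[1], "")[[1]]
  others <- unlist(strsplit(am$group[-1], ""))
  expect_length(intersect(top_letters, others), 0)
  # identical check values (additive case) share a letter with themselves
  expect_true(all(nzchar(am$group)))
})

test_that("Pearson matrix matches cor() and flags zero variance", {
  set.seed(31)
  tab <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  r <- pearson_matrix(tab)
  expect_equal(r, stats::cor(as.matrix(tab)))
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  tab$d <- 5
  expect_warning(r2 <- pearson_matrix(tab), "zero-variance")
  expect_true(all(is.na(r2["d", c("a", "b", "c")])))
  expect_error(pearson_matrix(tab[1:2, ]), "at least 3")
})

test_that("PCA reproduces the spectral structure of the correlation matrix", {
  set.seed(41)
  n <- 30
  f <- rnorm(n)
  tab <- data.frame(accession = sprintf("A%02d", 1:n),
                    t1 = f + rnorm(n, 0, 0.1),
                    t2 = f + rnorm(n, 0, 0.1),
                    t3 = rnorm(n),
                    t4 = -f + rnorm(n, 0, 0.1))
  p <- trait_pca(tab, c("t1", "t2", "t3", "t4"))
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-8)
  expect_equal(p$cum_variance[4], 100, tolerance = 1e-8)
  expect_gt(p$eigenvalues[1], 2.5) # one dominant factor
  # sign rule: the largest-|loading| trait on each PC is positive
  for (k in 1:4) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
  # scores are centered with variance equal to the eigenvalue
  expect_equal(unname(colMeans(p$scores)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(p$scores, 2, stats::var)),
               unname(p$eigenvalues), tolerance = 1e-8)
  # scores reproduce z %*% loadings exactly
  z <- scale(as.matrix(tab[c("t1", "t2", "t3", "t4")]))
  expect_equal(unname(p$scores), unname(z %*% p$loadings))
})

test_that("PCA excludes incomplete accessions with a warning", {
  set.seed(42)
  tab <- data.frame(accession = sprintf("A%02d", 1:12),
                    t1 = rnorm(12), t2 = rnorm(12), t3 = rnorm(12))
  tab$t2[5] <- NA
  expect_warning(p <- trait_pca(tab, c("t1", "t2", "t3")), "A05")
  expect_equal(p$excluded, "A05")
  expect_equal(p$n, 11L)
  expect_error(trait_pca(tab, c("t1", "nope")), "absent")
})

test_that("Ward clustering separates well-spaced score clouds", {
  set.seed(51)
  sc <- rbind(matrix(rnorm(20, 0), ncol = 2),
              matrix(rnorm(20, 10), ncol = 2),
              matrix(rnorm(20, -10), ncol = 2))
  rownames(sc) <- sprintf("A%02d", 1:30)
  cl <- ward_cluster(sc, k = 3)
  expect_length(unique(cl$assignments), 3L)
  # each planted cloud maps to a single cluster
  expect_length(unique(cl$assignments[1:10]), 1L)
  expect_length(unique(cl$assignments[11:20]), 1L)
  expect_length(unique(cl$assignments[21:30]), 1L)
  expect_true(all(diff(cl$heights) >= -1e-12))
  expect_error(ward_cluster(sc, k = 31), "between 1")
})

test_that("PC regression recovers planted coefficients on orthogonal scores", {
  set.seed(61)
  n <- 40
  x <- scale(matrix(rnorm(n * 3), n, 3))
  colnames(x) <- paste0("PC", 1:3)
  ty <- 100 + 5 * x[, 1] - 2 * x[, 2] + rnorm(n, 0, 0.01)
  reg <- regress_on_pcs(ty, x, m = 3)
  expect_equal(unname(reg$coefficients[1]), mean(ty), tolerance = 1e-6)
  expect_equal(unname(reg$coefficients[2]), 5, tolerance = 0.01)
  expect_equal(unname(reg$coefficients[3]), -2, tolerance = 0.01)
  expect_gt(reg$r_squared, 0.999)
  expect_lt(reg$p_value, 1e-10)
  expect_error(regress_on_pcs(ty[-1], x), "align")
  expect_error(regress_on_pcs(ty, x, m = 4), "outside")
})
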