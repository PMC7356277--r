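# Trait statistics: senescence-delay slope, augmented-block-design ANOVA with
# Federer-adjusted means and Tukey grouping, Pearson correlations, PCA on the
# correlation matrix, Ward clustering in PC space, and regression of tuber
# yield on principal components.

#' NDVI senescence-decline slope
#'
#' Ordinary least-squares slope of NDVI against days after planting, from the
#' flight of maximum NDVI to the last flight. Used as a senescence-delay
#' proxy: values closer to zero mean a longer senescence delay.
#'
#' @param points a [canopy_points()] series with a non-missing `ndvi` column;
#'   at least 3 flights at or after the NDVI maximum.
#' @return a list with `slope` (NDVI per day, typically `<= 0`), `stderr`,
#'   `n` (flights used) and `peak_dap`.
#' @export
ndvi_senescence_slope <- function(points) {
  assert_that(!anyNA(points$ndvi), "NDVI values are required")
  i_max <- which.max(points$ndvi)
  usable <- points[seq(i_max, nrow(points)), ]
  assert_that(nrow(usable) >= 3,
              "need at least 3 flights at or after the NDVI maximum")
  fit <- stats::lm(ndvi ~ dap, data = usable)
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       stderr = unname(sm["dap", "Std. Error"]),
       n = nrow(usable),
       peak_dap = points$dap[i_max])
}

#' Augmented-block-design analysis (DAU)
#'
#' Classical analysis of an augmented randomized complete block design:
#' block effects are estimated from the replicated checks, test-entry values
#' are Federer-adjusted as `raw - (block check mean - grand check mean)`, and
#' the treatment variation is partitioned into checks, augmented entries and
#' the checks-vs-augmented contrast, all tested against the checks-by-blocks
#' error mean square. Tukey letter groups on the adjusted means use the
#' pair-type-specific Federer variances of a difference.
#'
#' @param design data frame with columns `accession`, `block`, `is_check`
#'   (every check present in every block).
#' @param values numeric trait values, one per row of `design`.
#' @param alpha significance level for the Tukey grouping.
#' @return a list of class `dau_result`: `adjusted_means` (data frame
#'   `accession`, `is_check`, `raw`, `adjusted`, `group`), `anova` (data
#'   frame of sources with df, SS, MS, F, p), `error_ms`, `error_df`,
#'   `block_effects`.
#' @export
dau_analysis <- function(design, values, alpha = 0.05) {
  assert_that(length(values) == nrow(design),
              "one value per design row required")
  assert_that(!anyNA(values[design$is_check]),
              "trait values must be complete for checks")
  validate_design_blocks(design)
  df <- data.frame(accession = design$accession, block = design$block,
                   is_check = design$is_check, y = values)

  checks <- df[df$is_check, ]
  b <- length(unique(df$block))
  c_ <- length(unique(checks$accession))
  assert_that(b >= 2 && c_ >= 2,
              "need at least 2 blocks and 2 checks for error estimation")

  # block effects from checks
  block_mean <- tapply(checks$y, checks$block, mean)
  grand_check <- mean(checks$y)
  block_eff <- block_mean - grand_check

  adj <- df$y - block_eff[as.character(df$block)]
  # check adjusted means: raw mean over blocks (block effects average out)
  raw_means <- tapply(df$y, df$accession, mean)
  adj_means <- tapply(adj, df$accession, mean)

  # checks-by-blocks two-way ANOVA for the error term (balanced by design,
  # so the additive sums of squares are closed-form)
  check_means <- tapply(checks$y, checks$accession, mean)
  ss_checks <- b * sum((check_means - grand_check)^2)
  df_checks <- c_ - 1L
  ss_block <- c_ * sum((block_mean - grand_check)^2)
  df_block <- b - 1L
  ss_error <- sum((checks$y - grand_check)^2) - ss_checks - ss_block
  ss_error <- max(ss_error, 0)
  df_error <- (b - 1L) * (c_ - 1L)
  assert_that(df_error > 0, "zero error degrees of freedom")
  ms_error <- ss_error / df_error

  new_adj <- adj_means[!(names(adj_means) %in% unique(checks$accession))]
  n_new <- length(new_adj)
  ss_aug <- if (n_new > 1) sum((new_adj - mean(new_adj))^2) else 0
  df_aug <- max(n_new - 1, 0)

  # checks-vs-augmented group contrast on adjusted means
  g_check <- mean(adj_means[unique(checks$accession)])
  g_new <- mean(new_adj)
  w <- 1 / (1 / (b * c_) + 1 / n_new)
  ss_cva <- w * (g_check - g_new)^2

  mk_row <- function(source, d, ss) {
    ms <- ss / d
    f <- ms / ms_error
    data.frame(source = source, df = d, ss = ss, ms = ms, f = f,
               p = stats::pf(f, d, df_error, lower.tail = FALSE))
  }
  anova_tab <- rbind(
    data.frame(source = "Block (checks)", df = df_block, ss = ss_block,
               ms = ss_block / df_block, f = NA_real_, p = NA_real_),
    mk_row("Check", df_checks, ss_checks),
    if (df_aug > 0) mk_row("Augmented", df_aug, ss_aug),
    mk_row("Check vs augmented", 1L, ss_cva),
    data.frame(source = "Error", df = df_error, ss = ss_error, ms = ms_error,
               f = NA_real_, p = NA_real_))
  rownames(anova_tab) <- NULL

  am <- data.frame(accession = names(adj_means),
                   is_check = names(adj_means) %in% unique(checks$accession),
                   raw = as.numeric(raw_means[names(adj_means)]),
                   adjusted = as.numeric(adj_means))
  block_of_new <- df$block[match(am$accession, df$accession)]
  am$group <- tukey_groups(am, ms_error, df_error, b, c_, block_of_new, alpha)
  am <- am[order(-am$adjusted, am$accession), ]
  rownames(am) <- NULL

  structure(list(adjusted_means = am, anova = anova_tab,
                 error_ms = ms_error, error_df = df_error,
                 block_effects = block_eff),
            class = "dau_result")
}

validate_design_blocks <- function(design) {
  checks <- unique(design$accession[design$is_check])
  assert_that(length(checks) > 0, "design must contain checks")
  for (bl in unique(design$block)) {
    present <- design$accession[design$is_check & design$block == bl]
    missing <- setdiff(checks, present)
    assert_that(length(missing) == 0,
                "block %s is missing check(s): %s", bl,
                paste(missing, collapse = ", "))
  }
  invisible(design)
}

# Federer variances of a difference between adjusted means, by pair type.
dau_diff_var <- function(ms, b, c_, i_check, j_check, same_block) {
  if (i_check && j_check) return(2 * ms / b)
  if (!i_check && !j_check) {
    return(if (same_block) 2 * ms else 2 * ms * (1 + 1 / c_))
  }
  ms * (1 + 1 / b + 1 / c_ + 1 / (b * c_))
}

# Letter display: sorted descending, maximal runs of mutually non-significant
# means share a letter; ties in ordering broken by ascending mean (stable
# sort on -adjusted then accession already applied upstream).
tukey_groups <- function(am, ms, df_error, b, c_, block_of_new, alpha) {
  ord <- order(-am$adjusted, am$accession)
  n <- nrow(am)
  k <- n
  qcrit <- suppressWarnings(stats::qtukey(1 - alpha, k, df_error))
  sig <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      a <- ord[i]; bb <- ord[j]
      same_block <- !am$is_check[a] && !am$is_check[bb] &&
        identical(block_of_new[a], block_of_new[bb])
      v <- dau_diff_var(ms, b, c_, am$is_check[a], am$is_check[bb], same_block)
      thr <- qcrit * sqrt(v / 2)
      # degenerate error terms (zero variance or low df): any non-tied
      # difference separates the means
      if (!is.finite(thr)) thr <- 0
      sig[i, j] <- abs(am$adjusted[a] - am$adjusted[bb]) > max(thr, 1e-10)
    }
  }
  # maximal non-significant runs over the sorted means
  runs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && !any(sig[i:j, j + 1])) j <- j + 1
    runs[[length(runs) + 1]] <- c(i, j)
    if (j >= n) break
    i <- i + 1
  }
  # drop runs contained in earlier ones
  keep <- rep(TRUE, length(runs))
  for (r in seq_along(runs)) {
    for (s in seq_along(runs)) {
      if (r != s && runs[[s]][1] <= runs[[r]][1] && runs[[r]][2] <= runs[[s]][2]) {
        keep[r] <- FALSE
      }
    }
  }
  runs <- runs[keep]
  letters_out <- rep("", n)
  for (r in seq_along(runs)) {
    span <- seq(runs[[r]][1], runs[[r]][2])
    letters_out[span] <- paste0(letters_out[span], letters[r])
  }
  res <- character(n)
  res[ord] <- letters_out
  res
}

#' @export
print.dau_result <- function(x, ...) {
  cat("Augmented-block-design analysis\n")
  print(x$anova, row.names = FALSE)
  cat("\nAdjusted means:\n")
  print(utils::head(x$adjusted_means, 10), row.names = FALSE)
  if (nrow(x$adjusted_means) > 10) cat("...\n")
  invisible(x)
}

#' Pearson correlation matrix of traits
#'
#' @param table data frame of trait values (rows: accessions).
#' @param traits character vector of columns to correlate (default: all
#'   numeric columns).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   traits yield `NA` off-diagonal entries with a warning.
#' @export
pearson_matrix <- function(table, traits = NULL) {
  if (is.null(traits)) {
    traits <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  x <- as.matrix(table[traits])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  assert_that(nrow(x) >= 3, "need at least 3 complete rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance trait(s): ",
            paste(traits[sds == 0], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}

#' Principal component analysis of the trait table
#'
#' Eigen-decomposition of the correlation matrix of z-standardized traits.
#' Component signs follow a deterministic rule: the trait with the largest
#' absolute loading on each component is made positive.
#'
#' @param table data frame of trait values with an `accession` column (or
#'   rownames) and the trait columns.
#' @param traits character vector of trait columns to use.
#' @return a list of class `pca_result`: `loadings` (trait x component),
#'   `eigenvalues`, `cum_variance` (percent), `scores` (accession x
#'   component), `traits`, `n`, `excluded` (accessions dropped for missing
#'   values, with a warning).
#' @export
trait_pca <- function(table, traits) {
  assert_that(all(traits %in% names(table)),
              "traits absent from table: %s",
              paste(setdiff(traits, names(table)), collapse = ", "))
  x <- as.matrix(table[traits])
  ids <- if ("accession" %in% names(table)) table$accession else
    rownames(table)
  complete <- stats::complete.cases(x)
  excluded <- ids[!complete]
  if (length(excluded) > 0) {
    warning("excluding accession(s) with incomplete traits: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  x <- x[complete, , drop = FALSE]
  assert_that(nrow(x) >= length(traits) + 1,
              "need more complete rows than traits")
  z <- scale(x)
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  vals <- eig$values
  if (any(vals < -1e-8)) warning("rank-deficient trait matrix", call. = FALSE)
  vals <- pmax(vals, 0)
  vecs <- eig$vectors
  # deterministic sign rule
  for (k in seq_len(ncol(vecs))) {
    top <- which.max(abs(vecs[, k]))
    if (vecs[top, k] < 0) vecs[, k] <- -vecs[, k]
  }
  dimnames(vecs) <- list(traits, paste0("PC", seq_along(vals)))
  scores <- z %*% vecs
  rownames(scores) <- ids[complete]
  structure(list(loadings = vecs,
                 eigenvalues = vals,
                 cum_variance = cumsum(vals) / length(traits) * 100,
                 scores = scores,
                 traits = traits,
                 n = nrow(x),
                 excluded = excluded),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA on %d traits, %d accessions\n", length(x$traits), x$n))
  show <- min(3, length(x$eigenvalues))
  tab <- rbind(Eigenvalue = x$eigenvalues[1:show],
               `TCV (%)` = x$cum_variance[1:show])
  colnames(tab) <- paste0("PC", 1:show)
  print(round(tab, 2))
  invisible(x)
}

#' Ward hierarchical clustering of PCA scores
#'
#' Agglomerative clustering with Ward's criterion (squared-distance update,
#' `ward.D2`) on the retained principal-component scores, cut at `k` groups.
#'
#' @param scores numeric matrix (rows: accessions; columns: retained
#'   components), e.g. the first columns of a [trait_pca()] `scores`.
#' @param k number of clusters, `<=` number of rows.
#' @return a list with `assignments` (named integer vector), `heights`
#'   (non-decreasing merge heights) and `tree` (the `hclust` object).
#' @export
ward_cluster <- function(scores, k) {
  scores <- as.matrix(scores)
  assert_that(k >= 1 && k <= nrow(scores),
              "k must lie between 1 and the number of rows")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  list(assignments = stats::cutree(hc, k = k), heights = hc$height, tree = hc)
}

#' Regress tuber yield on principal components
#'
#' Ordinary least squares of yield on the first `m` PC scores. With centered,
#' orthogonal regressors the intercept equals the mean yield and each
#' coefficient equals `cov(ty, score) / var(score)`.
#'
#' @param ty response vector (dry tuber yield per plant).
#' @param scores PCA score matrix aligned with `ty`.
#' @param m number of leading components to use (default 3).
#' @return a list of class `pc_regression`: `coefficients` (intercept and one
#'   per component), `r_squared`, `f_value`, `p_value`, `fit` (the `lm`
#'   object).
#' @export
regress_on_pcs <- function(ty, scores, m = 3L) {
  scores <- as.matrix(scores)
  assert_that(length(ty) == nrow(scores), "ty and scores must align")
  assert_that(m >= 1 && m <= ncol(scores), "m outside the score matrix")
  assert_that(m < length(ty), "need more observations than components")
  x <- scores[, seq_len(m), drop = FALSE]
  dat <- data.frame(ty = ty, x)
  fit <- stats::lm(ty ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = stats::coef(fit),
    r_squared = sm$r.squared,
    f_value = unname(fstat[1]),
    p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    fit = fit),
    class = "pc_regression")
}

#' @export
print.pc_regression <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("TY = %.1f %s  (R2 = %.2f, F = %.1f, p = %.3g)\n",
              co[1],
              paste(sprintf("%+.1f x %s", co[-1], names(co)[-1]),
                    collapse = " "),
              x$r_squared, x$f_value, x$p_value))
  invisible(x)
}
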