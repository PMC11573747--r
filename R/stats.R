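#' Paired difference test across donors
#'
#' Classical paired t test on within-donor differences, the test used for
#' comparisons of dependence metrics between two conditions measured in
#' the same donors. The degenerate all-zero-difference case returns
#' statistic 0 and p = 1 rather than failing.
#'
#' @param x,y Paired numeric vectors (same donors, same order). Pairs with
#'   a missing value are dropped.
#' @return List: `statistic` (t), `df`, `p_value` (two-sided), `n`
#'   (complete pairs), `mean_difference`.
#' @examples
#' paired_difference_test(c(2, 3, 4), c(1, 1, 1))
#' @export
paired_difference_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 3L)
    stop("stats error: paired test needs at least 3 complete pairs, got ", n,
         call. = FALSE)
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(stat), df = n - 1L)
  }
  list(statistic = stat, df = n - 1L, p_value = p, n = n, mean_difference = m)
}

#' Compare several conditions to a shared control (Dunnett-style)
#'
#' Within-donor differences of each treatment group against the control
#' are tested by paired t statistics, and the family-wise error across
#' the groups is controlled by referring each |t| to the Monte-Carlo null
#' distribution of the maximum |t| over the family. Because all contrasts
#' share the control arm the statistics are equicorrelated under the
#' null; simulating the joint maximum captures exactly that dependence
#' (the construction behind Dunnett's procedure). Adjusted p-values are
#' monotone and never below the raw paired-t p.
#'
#' @param values Numeric matrix, donors x groups, column names the group
#'   labels; must contain `control`. No missing cells (the repeated
#'   design requires every donor in every group).
#' @param control Name of the control column (default `"Medium"`).
#' @param n_mc Monte-Carlo draws of the joint null (default 10000).
#' @param seed Optional seed for the Monte-Carlo draw, restoring the RNG
#'   state afterwards.
#' @return `data.frame`: group, statistic, df, p_raw, p_adjusted, method.
#' @export
compare_to_control <- function(values, control = "Medium", n_mc = 10000L,
                               seed = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (!control %in% colnames(values))
    stop("stats error: control group '", control, "' not found", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("stats error: unbalanced design, missing cells: ",
         paste(paste0("donor ", bad[, 1], "/", colnames(values)[bad[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(values)
  if (n < 3L)
    stop("stats error: need at least 3 donors, got ", n, call. = FALSE)
  groups <- setdiff(colnames(values), control)
  k <- length(groups)
  tt <- lapply(groups, function(g)
    paired_difference_test(values[, g], values[, control]))
  t_obs <- vapply(tt, `[[`, numeric(1), "statistic")
  p_raw <- vapply(tt, `[[`, numeric(1), "p_value")

  if (k == 1L) {
    p_adj <- p_raw  # family of one: the paired t is the procedure
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    # joint null: k+1 arms of n iid normals; differencing against the
    # shared control reproduces the equicorrelated t family
    z <- matrix(stats::rnorm(n * (k + 1L) * n_mc), nrow = n)
    ctrl_cols <- seq(k + 1L, ncol(z), by = k + 1L)
    d <- z[, -ctrl_cols, drop = FALSE] -
      z[, rep(ctrl_cols, each = k), drop = FALSE]
    means <- colMeans(d)
    sds <- sqrt((colSums(d^2) - n * means^2) / (n - 1L))
    tnull <- abs(means / (sds / sqrt(n)))
    max_t <- apply(matrix(tnull, nrow = k), 2L, max)
    p_adj <- vapply(abs(t_obs), function(t0) mean(max_t >= t0), numeric(1))
    p_adj <- pmax(p_adj, p_raw)
  }
  data.frame(group = groups, statistic = t_obs,
             df = vapply(tt, `[[`, integer(1), "df"),
             p_raw = p_raw, p_adjusted = pmin(p_adj, 1),
             method = if (k == 1L) "paired t" else "Dunnett (Monte-Carlo max-|t|)",
             stringsAsFactors = FALSE)
}

#' Sidak family-wise adjustment
#'
#' Closed-form adjustment `1 - (1 - p)^k` for a family of `k` independent
#' comparisons.
#'
#' @param p Raw p-values.
#' @param k Family size (default: `length(p)`).
#' @return Adjusted p-values (always `>= p`).
#' @export
sidak_adjust <- function(p, k = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), k >= 1)
  pmin(1, 1 - (1 - p)^k)
}

#' Pairwise contrasts in a two-factor layout with Sidak correction
#'
#' Cell-means analysis of a complete two-factor design (e.g. metric x
#' stimulation): within each level of the first factor, all pairwise
#' comparisons of the second factor are tested by t contrasts on the
#' pooled residual variance of the cell-means model, and the whole family
#' is Sidak-adjusted.
#'
#' @param response Numeric vector of observations.
#' @param factor_a,factor_b Parallel factors (coerced); every (a, b) cell
#'   must be non-empty.
#' @return `data.frame`: factor_a level, contrast (b1 vs b2), estimate,
#'   statistic, df, p_raw, p_adjusted.
#' @export
pairwise_condition_tests <- function(response, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  stopifnot(length(response) == length(fa), length(fa) == length(fb))
  cells <- table(fa, fb)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)
    stop("stats error: empty cell(s): ",
         paste(paste0(rownames(cells)[bad[, 1]], "/",
                      colnames(cells)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  cell <- interaction(fa, fb, drop = FALSE)
  cell_means <- tapply(response, cell, mean)
  resid <- response - cell_means[cell]
  df_err <- length(response) - nlevels(cell)
  if (df_err < 1L)
    stop("stats error: no residual degrees of freedom", call. = FALSE)
  mse <- sum(resid^2) / df_err

  rows <- list()
  bl <- levels(fb)
  for (a in levels(fa)) {
    for (i in seq_len(length(bl) - 1L)) {
      for (j in seq((i + 1L), length(bl))) {
        m1 <- cell_means[paste(a, bl[i], sep = ".")]
        m2 <- cell_means[paste(a, bl[j], sep = ".")]
        n1 <- cells[a, bl[i]]; n2 <- cells[a, bl[j]]
        est <- unname(m1 - m2)
        stat <- est / sqrt(mse * (1 / n1 + 1 / n2))
        rows[[length(rows) + 1L]] <- data.frame(
          factor_a = a, contrast = paste(bl[i], "vs", bl[j]),
          estimate = est, statistic = stat, df = df_err,
          p_raw = 2 * stats::pt(-abs(stat), df_err),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- sidak_adjust(out$p_raw, k = nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble the sample x feature profile matrix
#'
#' Rows are samples (donor/tissue), columns are
#' `"<population>:<metric>"` features with metric restricted to the two
#' dependence measures — the capacities are exact affine complements and
#' would only duplicate variance in a PCA.
#'
#' @param profiles `data.frame` with columns `sample_id`, `population`,
#'   `glucose_dependence`, `mitochondrial_dependence` (one row per
#'   sample x population), e.g. stacked `profiles` components of
#'   [cencat()] fits.
#' @return Numeric matrix with sample ids as row names; a missing
#'   sample x population combination yields `NA`.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(all(c("sample_id", "population", "glucose_dependence",
                  "mitochondrial_dependence") %in% names(profiles)))
  samples <- unique(profiles$sample_id)
  pops <- sort(unique(profiles$population))
  feats <- as.vector(t(outer(pops, c("glucose_dependence",
                                     "mitochondrial_dependence"),
                             paste, sep = ":")))
  m <- matrix(NA_real_, length(samples), length(feats),
              dimnames = list(samples, feats))
  for (i in seq_len(nrow(profiles))) {
    r <- profiles[i, ]
    m[r$sample_id, paste0(r$population, ":glucose_dependence")] <-
      r$glucose_dependence
    m[r$sample_id, paste0(r$population, ":mitochondrial_dependence")] <-
      r$mitochondrial_dependence
  }
  m
}

#' PCA of dependence profiles
#'
#' Column-wise centred (and by default unit-variance scaled) singular
#' value decomposition of the complete-case profile matrix. The sign of
#' each component is fixed by requiring the largest-|loading| feature to
#' load positively, so results are reproducible across platforms.
#' Zero-variance features are dropped with a warning; rows with missing
#' features are dropped and reported.
#'
#' @param m Matrix from [profile_matrix()] (samples x features).
#' @param n_components Number of components to keep (default: all).
#' @param scale Unit-variance scaling (default `TRUE`).
#' @return Object of class `cencat_pca`: `scores`, `loadings`,
#'   `explained_variance_fraction`, `dropped_rows`, `dropped_features`,
#'   `center`, `scale`.
#' @export
pca_profiles <- function(m, n_components = NULL, scale = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  complete <- stats::complete.cases(m)
  dropped_rows <- rownames(m)[!complete]
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("stats error: PCA needs at least 2 complete samples", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  v <- apply(m, 2L, stats::var)
  dropped_features <- colnames(m)[v == 0]
  if (length(dropped_features)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped_features, collapse = ", "), call. = FALSE)
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2L)
    stop("stats error: PCA needs at least 2 features with nonzero variance",
         call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  if (is.null(n_components)) n_components <- ncol(pc$rotation)
  n_components <- min(n_components, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = ev[seq_len(n_components)],
                 dropped_rows = dropped_rows,
                 dropped_features = dropped_features,
                 center = pc$center, scale = pc$scale),
            class = "cencat_pca")
}

#' @export
print.cencat_pca <- function(x, ...) {
  cat("<cencat_pca> ", nrow(x$scores), " samples, ",
      nrow(x$loadings), " features, ", ncol(x$scores), " components\n",
      "  explained variance: ",
      paste(sprintf("PC%d=%.1f%%", seq_along(x$explained_variance_fraction),
                    100 * x$explained_variance_fraction), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Top-loading features of a principal component
#'
#' Features ranked by |loading| on one component (ties broken by feature
#' name, ascending), annotated with the signed loading and whether the
#' feature is a glucose- or mitochondrial-dependence measure.
#'
#' @param pca A [pca_profiles()] result.
#' @param component Component index (default 1).
#' @param k How many features (truncated to the feature count, with a
#'   message).
#' @return `data.frame`: feature, loading, metric.
#' @export
top_loadings <- function(pca, component = 1L, k = 5L) {
  stopifnot(inherits(pca, "cencat_pca"))
  if (component > ncol(pca$loadings))
    stop("component ", component, " not available (", ncol(pca$loadings),
         " kept)", call. = FALSE)
  l <- pca$loadings[, component]
  if (k > length(l)) {
    message("k = ", k, " exceeds feature count; truncating to ", length(l))
    k <- length(l)
  }
  ord <- order(-abs(l), names(l))
  sel <- ord[seq_len(k)]
  data.frame(feature = names(l)[sel], loading = unname(l[sel]),
             metric = ifelse(grepl(":glucose_dependence$", names(l)[sel]),
                             "glucose", "mitochondrial"),
             stringsAsFactors = FALSE)
}
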