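# Quartile of each rank position: position 1 = highest value -> Q4.
# Deterministic for any n; ties broken upstream by genotype id order.
position_quartile <- function(pos, n) {
  4L - floor(4 * (pos - 1) / n)
}

#' Elite-stable and shade-adaptive genotypes by quartile transition
#'
#' Ranks genotypes by a trait (default SYP) within each treatment
#' independently, assigns yield quartiles (Q4 = top 25% by value; ties
#' broken by genotype-id order, deterministically), and labels each
#' genotype: \code{elite_stable} if Q4 under both control and shade,
#' \code{shade_adaptive} if rising from Q1-Q3 under control to Q4 under
#' shade, \code{other} otherwise. Because ranks are used, labels are
#' invariant to any increasing transformation of the trait.
#'
#' @param means A \code{"shadetol_means"} table.
#' @param ranking_trait Trait used for ranking (default \code{"SYP"}).
#' @param location One location label.
#' @param control Control treatment label.
#' @return List of class \code{"shadetol_transitions"}: \code{table}
#'   (genotype_id, location, ck_quartile, shade_quartile, label),
#'   \code{summary} (label counts and percentages with their
#'   denominator), \code{flows} (control quartile -> Q4 counts).
#' @export
quartile_transition <- function(means, ranking_trait = "SYP", location,
                                control = "CK") {
  df <- as.data.frame(means)
  df <- df[df$trait == ranking_trait & df$location == location, , drop = FALSE]
  stress <- setdiff(unique(df$treatment), control)
  if (length(stress) != 1L) stop("need exactly one non-control treatment", call. = FALSE)
  ck <- df[df$treatment == control, c("genotype_id", "mean_value")]
  sh <- df[df$treatment == stress, c("genotype_id", "mean_value")]
  m <- merge(ck, sh, by = "genotype_id", suffixes = c("_ck", "_shade"))
  n <- nrow(m)
  if (n < 4L) stop("quartile transition needs at least 4 genotypes", call. = FALSE)

  quart <- function(value, id) {
    ord <- order(-value, id)          # position 1 = largest value
    pos <- integer(n); pos[ord] <- seq_len(n)
    paste0("Q", position_quartile(pos, n))
  }
  tab <- data.frame(
    genotype_id = m$genotype_id,
    location = location,
    ck_quartile = quart(m$mean_value_ck, m$genotype_id),
    shade_quartile = quart(m$mean_value_shade, m$genotype_id),
    stringsAsFactors = FALSE
  )
  tab$label <- ifelse(tab$ck_quartile == "Q4" & tab$shade_quartile == "Q4",
                      "elite_stable",
               ifelse(tab$shade_quartile == "Q4", "shade_adaptive", "other"))
  counts <- table(factor(tab$label, c("elite_stable", "shade_adaptive", "other")))
  summary <- data.frame(
    label = names(counts),
    count = as.vector(counts),
    percent = round(100 * as.vector(counts) / n, 1),
    denominator = n,
    stringsAsFactors = FALSE
  )
  adaptive <- tab[tab$label == "shade_adaptive", , drop = FALSE]
  flow_counts <- table(factor(adaptive$ck_quartile, paste0("Q", 1:3)))
  flows <- data.frame(
    from = names(flow_counts), to = "Q4",
    count = as.vector(flow_counts),
    percent = round(100 * as.vector(flow_counts) / n, 1),
    stringsAsFactors = FALSE
  )
  out <- list(table = tab, summary = summary, flows = flows,
              ranking_trait = ranking_trait, location = location, n = n)
  class(out) <- "shadetol_transitions"
  out
}

#' @export
print.shadetol_transitions <- function(x, ...) {
  cat(sprintf("Quartile transitions on %s at %s (denominator: %d genotypes)\n",
              x$ranking_trait, x$location, x$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Correlation between overall tolerance and yield stability
#'
#' Pearson correlation between the overall tolerance index and the
#' yield-stability index across genotype x location records: do
#' genotypes tolerating shade across all traits also hold their yield?
#'
#' @param profiles A \code{"shadetol_profiles"} table.
#' @return List: r, r_squared, p_value, n. r is NA (with a warning) on
#'   zero variance.
#' @export
tolerance_stability_correlation <- function(profiles) {
  df <- as.data.frame(profiles)
  keep <- stats::complete.cases(df[, c("overall_ti", "yield_stability_index")])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 profiles", call. = FALSE)
  x <- df$overall_ti; y <- df$yield_stability_index
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: tolerance-stability correlation undefined", call. = FALSE)
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_, n = nrow(df)))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = nrow(df))
}

#' K-means dissection of the tolerance space
#'
#' Standardizes the six per-trait tolerance indices, projects them onto
#' their leading principal components (via [pca_traits()]), and
#' partitions the records with k-means (multi-start Lloyd under the
#' given seed, so a fixed seed yields an identical partition).
#'
#' @param profiles A \code{"shadetol_profiles"} table.
#' @param k Number of clusters (default 3).
#' @param n_components Leading components to cluster on (default 2).
#' @param seed Integer seed.
#' @param nstart Random starts for k-means (default 25).
#' @return List of class \code{"shadetol_clusters"}: assignments
#'   (genotype_id, location, PC coordinates, cluster), k, seed,
#'   within_ss (per cluster), total_within_ss, pca (the fitted
#'   [pca_traits()] object).
#' @export
cluster_tolerance_space <- function(profiles, k = 3L, n_components = 2L,
                                    seed = 42L, nstart = 25L) {
  df <- as.data.frame(profiles)
  ti_cols <- paste0("TI_", trait_names())
  M <- as.matrix(df[, ti_cols, drop = FALSE])
  colnames(M) <- trait_names()
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  if (k > nrow(M)) stop("k exceeds the number of complete profiles", call. = FALSE)
  pca <- pca_traits(M, standardize = TRUE)
  n_components <- min(n_components, ncol(pca$scores))
  S <- pca$scores[, seq_len(n_components), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(S, centers = k, nstart = nstart, iter.max = 100L)
  assignments <- data.frame(
    genotype_id = df$genotype_id[keep],
    location = df$location[keep],
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_components)) assignments[[paste0("PC", j)]] <- S[, j]
  assignments$cluster <- km$cluster
  out <- list(assignments = assignments, k = k, seed = seed,
              within_ss = km$withinss, total_within_ss = km$tot.withinss,
              total_ss = km$totss, sizes = km$size, pca = pca)
  class(out) <- "shadetol_clusters"
  out
}

#' @export
print.shadetol_clusters <- function(x, ...) {
  cat(sprintf("k-means on tolerance-space PCs: k = %d, sizes = %s, within-SS = %.2f of %.2f total\n",
              x$k, paste(x$sizes, collapse = "/"), x$total_within_ss, x$total_ss))
  invisible(x)
}

#' Silhouette-style diagnostic scan over k
#'
#' Mean within-cluster SS fraction for a range of k; a diagnostic for
#' choosing k, never an automatic selector.
#'
#' @param profiles A \code{"shadetol_profiles"} table.
#' @param ks Candidate k values.
#' @param seed Integer seed.
#' @return Data frame: k, total_within_ss, within_fraction.
#' @export
cluster_k_scan <- function(profiles, ks = 2:6, seed = 42L) {
  rows <- lapply(ks, function(k) {
    cl <- cluster_tolerance_space(profiles, k = k, seed = seed)
    data.frame(k = k, total_within_ss = cl$total_within_ss,
               within_fraction = cl$total_within_ss / cl$total_ss)
  })
  do.call(rbind, rows)
}

#' Random-forest importance of trait tolerance indices
#'
#' Fits an ensemble of randomized regression trees (random forest) of a
#' target index on the six per-trait tolerance indices, with a seeded
#' held-out split, and reports normalized impurity-based feature
#' importances plus held-out and in-sample R-squared.
#'
#' @param profiles A \code{"shadetol_profiles"} table.
#' @param target Target column (default \code{"overall_ti"}), or a
#'   numeric vector aligned with \code{profiles} rows.
#' @param seed Integer seed.
#' @param n_trees Trees in the forest (default 500).
#' @param train_frac Fraction of records in the training split
#'   (default 0.8).
#' @param mtry Features tried at each split; defaults to all six
#'   (bagged regression trees, the common regression-forest default).
#' @return List of class \code{"shadetol_importance"}: importance (named,
#'   sums to 1), r_squared_holdout, r_squared_insample, n_train, n_test,
#'   hyperparameters, seed.
#' @export
importance_regression <- function(profiles, target = "overall_ti", seed = 42L,
                                  n_trees = 500L, train_frac = 0.8,
                                  mtry = NULL) {
  df <- as.data.frame(profiles)
  ti_cols <- paste0("TI_", trait_names())
  X <- as.matrix(df[, ti_cols, drop = FALSE])
  y <- if (is.character(target) && length(target) == 1L) df[[target]] else as.numeric(target)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(y) < 30L) stop("importance regression needs at least 30 profiles", call. = FALSE)
  if (stats::sd(y) == 0) stop("target is constant: importances undefined", call. = FALSE)
  set.seed(seed)
  n <- length(y)
  idx <- sample.int(n, size = floor(train_frac * n))
  if (is.null(mtry)) mtry <- ncol(X)
  rf <- randomForest::randomForest(x = X[idx, , drop = FALSE], y = y[idx],
                                   ntree = n_trees, mtry = mtry)
  imp <- randomForest::importance(rf)[, "IncNodePurity"]
  imp <- imp / sum(imp)
  names(imp) <- trait_names()
  pred_te <- stats::predict(rf, X[-idx, , drop = FALSE])
  y_te <- y[-idx]
  r2_hold <- 1 - sum((y_te - pred_te)^2) / sum((y_te - mean(y_te))^2)
  pred_tr <- stats::predict(rf, X[idx, , drop = FALSE])
  r2_in <- 1 - sum((y[idx] - pred_tr)^2) / sum((y[idx] - mean(y[idx]))^2)
  out <- list(
    importance = imp,
    r_squared_holdout = r2_hold,
    r_squared_insample = r2_in,
    n_train = length(idx), n_test = n - length(idx),
    hyperparameters = list(n_trees = n_trees, train_frac = train_frac,
                           mtry = rf$mtry, max_depth = "unlimited"),
    seed = seed
  )
  class(out) <- "shadetol_importance"
  out
}

#' @export
print.shadetol_importance <- function(x, ...) {
  cat(sprintf("Random-forest importance (n_trees = %d, seed = %d): held-out R^2 = %.3f\n",
              x$hyperparameters$n_trees, x$seed, x$r_squared_holdout))
  print(round(sort(x$importance, decreasing = TRUE), 3))
  invisible(x)
}
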