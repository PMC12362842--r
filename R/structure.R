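#' Control-versus-shade paired correlation for one trait
#'
#' Pearson correlation and least-squares regression of the shade
#' genotype mean on the control genotype mean across genotypes at one
#' location: the genotype x environment stability picture for a trait
#' (high r = consistent genotype ranking across light environments).
#'
#' @param means A \code{"shadetol_means"} table.
#' @param trait One canonical trait name.
#' @param location One location label.
#' @param control Control treatment label.
#' @return List of class \code{"shadetol_paircor"}: trait, location, n,
#'   r, r_squared, slope, intercept, p_value. r is NA (with a warning)
#'   when either vector has zero variance.
#' @export
paired_correlation <- function(means, trait, location, control = "CK") {
  df <- as.data.frame(means)
  df <- df[df$trait == trait & df$location == location, , drop = FALSE]
  stress <- setdiff(unique(df$treatment), control)
  if (length(stress) != 1L) stop("need exactly one non-control treatment", call. = FALSE)
  ck <- df[df$treatment == control, c("genotype_id", "mean_value")]
  sh <- df[df$treatment == stress, c("genotype_id", "mean_value")]
  m <- merge(ck, sh, by = "genotype_id", suffixes = c("_ck", "_shade"))
  if (nrow(m) < 3L) stop("need at least 3 genotypes with both treatments", call. = FALSE)
  x <- m$mean_value_ck; y <- m$mean_value_shade
  out <- list(trait = trait, location = location, n = nrow(m),
              r = NA_real_, r_squared = NA_real_,
              slope = NA_real_, intercept = NA_real_, p_value = NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in ", trait, " at ", location,
            ": correlation undefined", call. = FALSE)
  } else {
    ct <- stats::cor.test(x, y)
    fit <- stats::lm(y ~ x)
    out$r <- unname(ct$estimate)
    out$r_squared <- out$r^2
    out$slope <- unname(stats::coef(fit)[2L])
    out$intercept <- unname(stats::coef(fit)[1L])
    out$p_value <- ct$p.value
  }
  class(out) <- "shadetol_paircor"
  out
}

#' @export
print.shadetol_paircor <- function(x, ...) {
  cat(sprintf("CK vs shade, %s at %s (n = %d): r = %.3f, R^2 = %.3f, shade = %.3f + %.3f x CK\n",
              x$trait, x$location, x$n, x$r, x$r_squared, x$intercept, x$slope))
  invisible(x)
}

#' Path-coefficient analysis of seed yield
#'
#' Classical Wright path analysis of SYP on the five architectural
#' predictors (PH, BPH, NNP, BN, PNP): all variables are standardized,
#' the direct effects (path coefficients) solve the correlation system
#' \eqn{R_{xx} p = r_{xy}}, and the indirect effect of predictor i via
#' predictor j is \eqn{r_{xx}[i,j] \, p_j}. The direct effects are
#' identical to standardized partial-regression coefficients; their
#' p-values come from the t-statistics of the equivalent standardized
#' multiple regression. Total determination is
#' \eqn{R^2 = \sum_i p_i \, r_{xy}[i]}.
#'
#' @param means A \code{"shadetol_means"} table.
#' @param treatment Treatment stratum to analyze.
#' @param location Optional location label; NULL pools the locations
#'   (records are genotype x location).
#' @return List of class \code{"shadetol_path"}: stratum, n, r_xx, r_xy,
#'   direct, indirect (matrix, i row via j column), p_values,
#'   r_squared_total.
#' @export
path_analysis <- function(means, treatment, location = NULL) {
  w <- means_to_wide(means, location = location, treatment = treatment)
  X <- w$matrix
  colnames(X) <- w$traits
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  preds <- c("PH", "BPH", "NNP", "BN", "PNP")
  if (nrow(X) < length(preds) + 2L) {
    stop("path analysis needs more genotypes than predictors", call. = FALSE)
  }
  r_xx <- stats::cor(X[, preds, drop = FALSE])
  r_xy <- stats::cor(X[, preds, drop = FALSE], X[, "SYP"])[, 1L]
  if (kappa(r_xx, exact = TRUE) > 1e10) {
    off <- abs(r_xx); diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1L, ]
    stop("singular predictor correlation matrix: ", preds[ij[1L]], " and ",
         preds[ij[2L]], " are (near-)collinear", call. = FALSE)
  }
  direct <- solve(r_xx, r_xy)
  indirect <- r_xx * rep(direct, each = length(preds))
  diag(indirect) <- 0
  dimnames(indirect) <- list(via_of = preds, via = preds)

  Z <- scale(X)
  fit <- stats::lm(SYP ~ ., data = as.data.frame(Z)[, c(preds, "SYP")])
  coefs <- summary(fit)$coefficients
  p_values <- stats::setNames(coefs[preds, "Pr(>|t|)"], preds)

  out <- list(
    stratum = list(treatment = treatment,
                   location = if (is.null(location)) "pooled" else location),
    n = nrow(X),
    r_xx = r_xx,
    r_xy = r_xy,
    direct = stats::setNames(as.vector(direct), preds),
    indirect = indirect,
    p_values = p_values,
    r_squared_total = sum(direct * r_xy)
  )
  class(out) <- "shadetol_path"
  out
}

#' @export
print.shadetol_path <- function(x, ...) {
  cat(sprintf("Path analysis of SYP (%s, %s; n = %d genotype records)\n",
              x$stratum$treatment, x$stratum$location, x$n))
  tab <- data.frame(direct = x$direct,
                    total_r = x$r_xy,
                    p_value = x$p_values,
                    stars = significance_stars(x$p_values))
  print(tab, digits = 3)
  cat(sprintf("Total determination R^2 = %.3f\n", x$r_squared_total))
  invisible(x)
}

#' Principal component analysis of the trait space
#'
#' PCA of the genotype x trait matrix of means for a stratum. By default
#' traits are z-scored (correlation-matrix PCA) because the six traits
#' are on incommensurate scales. Constant columns are dropped with a
#' warning. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making runs and
#' implementations comparable.
#'
#' @param x A \code{"shadetol_means"} table, or a numeric matrix with
#'   named columns (rows = records).
#' @param location Optional location filter (means input only).
#' @param treatment Optional treatment filter; NULL keeps both
#'   treatments as separate records.
#' @param standardize z-score the columns (default TRUE).
#' @return List of class \code{"shadetol_pca"}: loadings (variable x
#'   component), scores (record x component), explained_variance_ratio,
#'   record annotation (genotype_id/location/treatment when available).
#' @export
pca_traits <- function(x, location = NULL, treatment = NULL, standardize = TRUE) {
  if (is.data.frame(x) && inherits(x, "shadetol_means")) {
    w <- means_to_wide(x, location = location, treatment = treatment)
    M <- w$matrix
    colnames(M) <- w$traits
    ann <- data.frame(genotype_id = w$genotype_id, location = w$location,
                      treatment = w$treatment, stringsAsFactors = FALSE)
  } else {
    M <- as.matrix(x)
    if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
    ann <- NULL
  }
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  if (!is.null(ann)) ann <- ann[keep, , drop = FALSE]
  if (nrow(M) < 3L) stop("PCA needs at least 3 records", call. = FALSE)
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(M)[sds == 0], collapse = ", "), call. = FALSE)
    M <- M[, sds > 0, drop = FALSE]
  }
  if (ncol(M) < 2L) stop("PCA needs at least 2 non-constant variables", call. = FALSE)
  pr <- stats::prcomp(M, center = TRUE, scale. = standardize)
  # deterministic sign: largest-|loading| entry of each PC is positive
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  out <- list(
    loadings = pr$rotation,
    scores = pr$x,
    explained_variance_ratio = pr$sdev^2 / sum(pr$sdev^2),
    records = ann,
    standardized = standardize
  )
  class(out) <- "shadetol_pca"
  out
}

#' @export
print.shadetol_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat("PCA of trait space:", nrow(x$scores), "records,",
      ncol(x$loadings), "components\n")
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(evr), 100 * evr), collapse = ", "),
      "\n")
  invisible(x)
}
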