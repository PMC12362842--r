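#' Split-plot ANOVA for one trait at one location
#'
#' Fits the split-plot RCBD decomposition of the trial's linear model:
#' replication (block), cropping system (whole-plot factor), whole-plot
#' error (replication x system), genotype (subplot factor), system x
#' genotype interaction, and subplot error. Sums of squares are
#' sequential (Type I) on the ordered model; the cropping-system F uses
#' the whole-plot error mean square as its denominator, genotype and the
#' interaction use the subplot error mean square, and replication is
#' tested against the whole-plot error.
#'
#' @param panel A \code{"shadetol_panel"} data frame.
#' @param trait One canonical trait name.
#' @param location One location label.
#' @return List of class \code{"shadetol_splitplot"}: \code{anova_table}
#'   (effect, df, sum_sq, mean_sq, statistic, p_value, stars),
#'   \code{stratum_means} (named by treatment), \code{trait},
#'   \code{location}, \code{n}.
#' @export
fit_split_plot <- function(panel, trait, location) {
  df <- as.data.frame(panel)
  df <- df[df$trait == trait & df$location == location, , drop = FALSE]
  if (!nrow(df)) stop("no rows for trait ", trait, " at ", location, call. = FALSE)
  if (length(unique(df$treatment)) < 2L) {
    stop("both treatments are required for the split-plot fit", call. = FALSE)
  }
  if (length(unique(df$replicate)) < 2L) {
    stop("at least two replicates are required", call. = FALSE)
  }
  df$R <- factor(df$replicate)
  df$C <- factor(df$treatment)
  df$G <- factor(df$genotype_id)

  counts <- table(df$G, df$C, df$R)
  if (any(counts != 1L)) {
    warning("unbalanced panel: sequential (Type I) sums of squares on the ordered model",
            call. = FALSE)
  }
  form <- stats::terms(value ~ R + C + R:C + G + C:G, keep.order = TRUE)
  fit <- stats::lm(form, data = df)
  a <- stats::anova(fit)

  pick <- function(nm) {
    i <- match(nm, rownames(a))
    c(df = a$Df[i], ss = a$`Sum Sq`[i])
  }
  rows <- list(
    replication      = pick("R"),
    cropping_system  = pick("C"),
    wholeplot_error  = pick("R:C"),
    genotype         = pick("G"),
    system_x_genotype = pick("C:G"),
    subplot_error    = pick("Residuals")
  )
  tab <- data.frame(
    effect = names(rows),
    df = vapply(rows, `[[`, 0, "df"),
    sum_sq = vapply(rows, `[[`, 0, "ss"),
    stringsAsFactors = FALSE
  )
  tab$mean_sq <- ifelse(tab$df > 0, tab$sum_sq / tab$df, NA_real_)
  ms_wp <- tab$mean_sq[tab$effect == "wholeplot_error"]
  ms_sp <- tab$mean_sq[tab$effect == "subplot_error"]
  denom <- c(replication = ms_wp, cropping_system = ms_wp,
             wholeplot_error = NA_real_, genotype = ms_sp,
             system_x_genotype = ms_sp, subplot_error = NA_real_)
  denom_df <- c(replication = tab$df[3L], cropping_system = tab$df[3L],
                wholeplot_error = NA_real_, genotype = tab$df[6L],
                system_x_genotype = tab$df[6L], subplot_error = NA_real_)
  tab$statistic <- tab$mean_sq / denom[tab$effect]
  tab$p_value <- stats::pf(tab$statistic, tab$df, denom_df[tab$effect],
                           lower.tail = FALSE)
  tab$p_value <- pmax(tab$p_value, 1e-300)
  tab$stars <- significance_stars(tab$p_value)
  rownames(tab) <- NULL

  sm <- tapply(df$value, df$C, mean)
  out <- list(
    anova_table = tab,
    stratum_means = stats::setNames(as.vector(sm), names(sm)),
    trait = trait,
    location = location,
    n = nrow(df)
  )
  class(out) <- "shadetol_splitplot"
  out
}

#' @export
print.shadetol_splitplot <- function(x, ...) {
  cat("Split-plot ANOVA:", x$trait, "at", x$location,
      sprintf("(n = %d)\n", x$n))
  print(x$anova_table, digits = 4)
  cat("Stratum means:",
      paste(sprintf("%s = %.3f", names(x$stratum_means), x$stratum_means),
            collapse = ", "), "\n")
  invisible(x)
}

#' Two-way ANOVA of location and treatment on genotype means
#'
#' Fixed-effects location x treatment ANOVA with genotypes as the
#' replication units (each genotype contributes one replicate-averaged
#' value per location x treatment cell). Significance stars follow the
#' *** < 0.001, ** < 0.01, * < 0.05, ns convention.
#'
#' @param means A \code{"shadetol_means"} table.
#' @param trait One canonical trait name.
#' @return Data frame with rows location, treatment,
#'   location_x_treatment, residuals: df, sum_sq, mean_sq, statistic,
#'   p_value, stars.
#' @export
two_way_anova <- function(means, trait) {
  df <- as.data.frame(means)
  df <- df[df$trait == trait, , drop = FALSE]
  if (length(unique(df$location)) < 2L) {
    stop("two-way ANOVA needs both locations", call. = FALSE)
  }
  if (length(unique(df$treatment)) < 2L) {
    stop("two-way ANOVA needs both treatments", call. = FALSE)
  }
  df$L <- factor(df$location)
  df$T <- factor(df$treatment)
  a <- stats::anova(stats::lm(mean_value ~ L * T, data = df))
  tab <- data.frame(
    effect = c("location", "treatment", "location_x_treatment", "residuals"),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    statistic = a$`F value`,
    p_value = pmax(a$`Pr(>F)`, 1e-300),
    stringsAsFactors = FALSE
  )
  tab$stars <- significance_stars(tab$p_value)
  rownames(tab) <- NULL
  tab
}

#' Percent change from control to shade
#'
#' 100 x (shade - control) / control, the headline "+7.5%"-style numbers
#' of the stratum-mean comparison. Exactly \code{(TI_uncapped - 1) * 100}
#' for any uncapped tolerance index computed from the same two means.
#'
#' @param ck_mean Control mean (> 0 for a defined change).
#' @param shade_mean Shade mean.
#' @return Percent change (vectorized); NA where \code{ck_mean} is 0.
#' @export
#' @examples
#' percent_change(118.60, 127.49)  # +7.5
percent_change <- function(ck_mean, shade_mean) {
  ifelse(ck_mean == 0, NA_real_, 100 * (shade_mean - ck_mean) / ck_mean)
}

#' Cohen's d for the shade effect
#'
#' Standardized mean difference (shade - control) / pooled SD with the
#' classical pooled-variance denominator
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#' Positive d means the trait is larger under shade (elongation traits);
#' negative d means reduction (reproductive traits). The small-sample
#' (Hedges) correction is off by default.
#'
#' @param shade_values,ck_values Numeric vectors, each of length >= 2.
#' @param hedges Apply the Hedges small-sample correction factor.
#' @return Numeric d; NA when the pooled SD is zero.
#' @export
cohens_d <- function(shade_values, ck_values, hedges = FALSE) {
  n1 <- length(shade_values); n2 <- length(ck_values)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(shade_values) + (n2 - 1) * stats::var(ck_values)) /
    (n1 + n2 - 2)
  if (sp2 == 0) return(NA_real_)
  d <- (mean(shade_values) - mean(ck_values)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  d
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk on the within-group-centered values and Levene's test
#' (via \code{car::leveneTest}) across groups. Diagnostic only: results
#' are reported, never used to gate an analysis. Shapiro-Wilk is limited
#' to 5000 observations; larger samples are tested on a seeded subsample
#' with a warning.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (factor/character) of the same length.
#' @return List with \code{shapiro_p}, \code{levene_p},
#'   \code{levene_statistic}; entries are NA (with a warning) when a
#'   test's sample-size requirements are not met.
#' @export
assumption_checks <- function(values, groups) {
  groups <- factor(groups)
  centered <- values - stats::ave(values, groups)
  shapiro_p <- NA_real_
  n <- length(centered)
  if (n < 3L) {
    warning("normality check skipped: fewer than 3 observations", call. = FALSE)
  } else {
    x <- centered
    if (n > 5000L) {
      warning("normality check on a seeded subsample of 5000 observations",
              call. = FALSE)
      x <- x[round(seq(1L, n, length.out = 5000L))]
    }
    if (stats::sd(x) == 0) {
      warning("normality check skipped: zero variance", call. = FALSE)
    } else {
      shapiro_p <- stats::shapiro.test(x)$p.value
    }
  }
  levene_p <- NA_real_; levene_stat <- NA_real_
  if (nlevels(groups) < 2L || min(table(groups)) < 3L) {
    warning("variance-homogeneity check skipped: need >= 2 groups with n >= 3",
            call. = FALSE)
  } else if (stats::sd(values) == 0) {
    levene_stat <- 0; levene_p <- 1
  } else {
    lt <- car::leveneTest(values ~ groups)
    levene_stat <- lt[1, "F value"]
    levene_p <- lt[1, "Pr(>F)"]
  }
  list(shapiro_p = shapiro_p, levene_p = levene_p, levene_statistic = levene_stat)
}

#' Shade effect sizes and percent changes per trait
#'
#' Convenience wrapper computing, per trait within a scope (one location
#' or pooled), the control and shade means, the percent change, and
#' Cohen's d across genotype means.
#'
#' @param means A \code{"shadetol_means"} table.
#' @param location Optional location label; NULL pools locations.
#' @param control Control treatment label.
#' @return Data frame: trait, scope, ck_mean, shade_mean, percent_change,
#'   cohens_d.
#' @export
shade_effect_table <- function(means, location = NULL, control = "CK") {
  df <- as.data.frame(means)
  scope <- if (is.null(location)) "pooled" else location
  if (!is.null(location)) df <- df[df$location == location, , drop = FALSE]
  stress <- setdiff(unique(df$treatment), control)
  out <- lapply(trait_names(), function(tr) {
    ck <- df$mean_value[df$trait == tr & df$treatment == control]
    sh <- df$mean_value[df$trait == tr & df$treatment == stress]
    data.frame(
      trait = tr, scope = scope,
      ck_mean = mean(ck), shade_mean = mean(sh),
      percent_change = round(percent_change(mean(ck), mean(sh)), 1),
      cohens_d = cohens_d(sh, ck),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
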