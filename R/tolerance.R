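#' Tolerance classification thresholds
#'
#' The four-category classification of shade tolerance by tolerance
#' index: sensitive (index <= sensitive_max), moderate
#' (sensitive_max, moderate_max], tolerant (moderate_max, tolerant_max],
#' enhanced (> tolerant_max). \code{cap} is the winsorization ceiling
#' applied to every tolerance index.
#'
#' @param sensitive_max,moderate_max,tolerant_max Category upper bounds
#'   (dimensionless, strictly increasing).
#' @param cap Upper truncation for all indices (default 2.0).
#' @return A list of class \code{"shadetol_thresholds"}.
#' @export
tolerance_thresholds <- function(sensitive_max = 0.681, moderate_max = 0.850,
                                 tolerant_max = 1.000, cap = 2.0) {
  th <- list(sensitive_max = sensitive_max, moderate_max = moderate_max,
             tolerant_max = tolerant_max, cap = cap)
  if (!(sensitive_max < moderate_max && moderate_max < tolerant_max &&
        tolerant_max < cap)) {
    stop("thresholds must satisfy sensitive_max < moderate_max < tolerant_max < cap",
         call. = FALSE)
  }
  class(th) <- "shadetol_thresholds"
  th
}

tolerance_categories <- function() {
  c("sensitive", "moderate", "tolerant", "enhanced")
}

#' Per-trait tolerance index
#'
#' TI = trait value under shade stress / trait value under control,
#' truncated above at \code{cap}. A value of 1 means no change under
#' shade, below 1 a reduction, above 1 enhancement. A zero control value
#' with positive shade value returns \code{cap}; 0/0 returns NA.
#'
#' @param ck_mean,shade_mean Non-negative trait values (vectorized).
#' @param cap Upper truncation (default 2.0); \code{Inf} disables capping.
#' @return Numeric vector of tolerance indices.
#' @export
#' @examples
#' trait_ti(118.60, 127.49)   # shade-avoidance PH increase, TI ~ 1.075
trait_ti <- function(ck_mean, shade_mean, cap = 2.0) {
  if (any(ck_mean < 0, na.rm = TRUE) || any(shade_mean < 0, na.rm = TRUE)) {
    stop("trait values must be non-negative", call. = FALSE)
  }
  ti <- ifelse(ck_mean == 0, ifelse(shade_mean == 0, NA_real_, cap),
               shade_mean / ck_mean)
  pmin(ti, cap)
}

#' Overall tolerance index
#'
#' Aggregates the per-trait tolerance indices of one genotype into a
#' single index; the default aggregator is the unweighted arithmetic mean
#' of the available (non-missing) trait TIs. Weights may be supplied per
#' trait; they are renormalized over the non-missing traits.
#'
#' @param tis Named numeric vector of per-trait TIs (NA allowed).
#' @param weights Optional named numeric weights per trait.
#' @return Single numeric index; attribute \code{"aggregator"} records
#'   the aggregation rule used.
#' @export
overall_ti <- function(tis, weights = NULL) {
  keep <- !is.na(tis)
  if (!any(keep)) stop("all trait tolerance indices are missing", call. = FALSE)
  if (is.null(weights)) {
    out <- mean(tis[keep])
    attr(out, "aggregator") <- "unweighted_mean"
  } else {
    if (is.null(names(weights)) || !all(names(tis)[keep] %in% names(weights))) {
      stop("weights must be named for every available trait", call. = FALSE)
    }
    w <- weights[names(tis)[keep]]
    out <- sum(w * tis[keep]) / sum(w)
    attr(out, "aggregator") <- "weighted_mean"
  }
  out
}

#' Yield-stability index
#'
#' A per-genotype measure of seed-yield maintenance under shade. The
#' default definition is the SYP tolerance ratio (shade SYP / control
#' SYP, capped); it is exposed under its own name so an alternative
#' stability definition can be swapped in without touching callers.
#'
#' @param syp_ck,syp_shade Seed yield per plant under control and shade.
#' @param cap Upper truncation (default 2.0).
#' @return Numeric index; attribute \code{"definition"} records the rule.
#' @export
yield_stability_index <- function(syp_ck, syp_shade, cap = 2.0) {
  out <- trait_ti(syp_ck, syp_shade, cap = cap)
  attr(out, "definition") <- "syp_ratio"
  out
}

#' Classify a tolerance index
#'
#' Maps an index to the four tolerance categories with left-open /
#' right-closed intervals so the categories tile the positive line:
#' sensitive (<= 0.681), moderate (0.681, 0.850], tolerant (0.850, 1.000],
#' enhanced (> 1.000) under the default thresholds.
#'
#' @param index Positive numeric vector of tolerance indices.
#' @param thresholds A [tolerance_thresholds()] object.
#' @return Ordered factor with levels sensitive < moderate < tolerant <
#'   enhanced.
#' @export
#' @examples
#' classify_tolerance(c(0.5, 0.7, 1.0, 1.2))
classify_tolerance <- function(index, thresholds = tolerance_thresholds()) {
  if (any(index <= 0, na.rm = TRUE)) {
    stop("tolerance index must be positive", call. = FALSE)
  }
  cut(index,
      breaks = c(0, thresholds$sensitive_max, thresholds$moderate_max,
                 thresholds$tolerant_max, Inf),
      labels = tolerance_categories(),
      right = TRUE, ordered_result = TRUE)
}

#' Tolerance profiles for a whole panel
#'
#' Builds one tolerance profile per genotype x location from replicate-
#' averaged genotype means: the six per-trait TIs, the overall tolerance
#' index, the yield-stability index, and the tolerance category (applied
#' to the overall TI by default, configurable via \code{classify_on}).
#' Genotypes missing either treatment at a location are skipped; the
#' count of skipped records is reported via a message and the
#' \code{"n_skipped"} attribute.
#'
#' @param means A \code{"shadetol_means"} table (see
#'   [aggregate_to_means()]).
#' @param thresholds A [tolerance_thresholds()] object (also carries the
#'   TI cap).
#' @param control Control treatment label (default \code{"CK"}).
#' @param classify_on Column used for classification:
#'   \code{"overall_ti"} (default) or one of \code{TI_PH ... TI_SYP} or
#'   \code{"yield_stability_index"}.
#' @param weights Optional trait weights passed to [overall_ti()].
#' @return Data frame of class \code{"shadetol_profiles"}: genotype_id,
#'   location, TI_PH..TI_SYP, overall_ti, yield_stability_index, category.
#' @export
profile_panel <- function(means, thresholds = tolerance_thresholds(),
                          control = "CK", classify_on = "overall_ti",
                          weights = NULL) {
  df <- as.data.frame(means)
  trts <- unique(df$treatment)
  if (!control %in% trts) stop("control treatment '", control, "' not present",
                               call. = FALSE)
  stress <- setdiff(trts, control)
  if (length(stress) != 1L) {
    stop("expected exactly one non-control treatment, found: ",
         paste(stress, collapse = ", "), call. = FALSE)
  }
  cap <- thresholds$cap
  traits <- trait_names()

  ck <- df[df$treatment == control, c("genotype_id", "location", "trait", "mean_value")]
  sh <- df[df$treatment == stress, c("genotype_id", "location", "trait", "mean_value")]
  merged <- merge(ck, sh, by = c("genotype_id", "location", "trait"),
                  suffixes = c("_ck", "_shade"), all = TRUE)
  merged$ti <- ifelse(is.na(merged$mean_value_ck) | is.na(merged$mean_value_shade),
                      NA_real_,
                      trait_ti(merged$mean_value_ck, merged$mean_value_shade, cap = cap))

  id <- paste(merged$genotype_id, merged$location, sep = "\r")
  ti_wide <- tapply(merged$ti, list(id, factor(merged$trait, traits)), mean)
  parts <- do.call(rbind, strsplit(rownames(ti_wide), "\r", fixed = TRUE))

  # a genotype x location record is scored only if both treatments were
  # observed for at least one trait
  scored <- rowSums(!is.na(ti_wide)) > 0
  n_skipped <- sum(!scored)
  if (n_skipped > 0) {
    message(n_skipped, " genotype x location record(s) skipped: missing one treatment")
  }
  ti_wide <- ti_wide[scored, , drop = FALSE]
  parts <- parts[scored, , drop = FALSE]

  ov <- apply(ti_wide, 1L, function(z) as.numeric(overall_ti(stats::setNames(z, traits),
                                                             weights = weights)))
  ysi <- ti_wide[, "SYP"]
  out <- data.frame(
    genotype_id = parts[, 1L],
    location = parts[, 2L],
    stringsAsFactors = FALSE
  )
  for (tr in traits) out[[paste0("TI_", tr)]] <- unname(ti_wide[, tr])
  out$overall_ti <- unname(ov)
  out$yield_stability_index <- unname(ysi)
  cls_col <- switch(classify_on,
                    overall_ti = out$overall_ti,
                    yield_stability_index = out$yield_stability_index,
                    {
                      if (!classify_on %in% paste0("TI_", traits)) {
                        stop("unknown classify_on column: ", classify_on, call. = FALSE)
                      }
                      out[[classify_on]]
                    })
  out$category <- classify_tolerance(cls_col, thresholds)
  out <- out[order(out$location, out$genotype_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "classify_on") <- classify_on
  class(out) <- c("shadetol_profiles", "data.frame")
  out
}
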