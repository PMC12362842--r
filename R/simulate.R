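#' Simulation configuration for a split-plot shade trial
#'
#' Builds and validates the parameter set for [simulate_panel()]. The
#' generative model per trait is the split-plot linear model
#' \deqn{Y_{ijk} = \mu + R_i + C_j + \delta_{ij} + G_k + (CG)_{jk} + \epsilon_{ijk}}
#' with stratum mean \eqn{\mu + C_j} supplied directly per
#' (location, treatment, trait), a random replication effect \eqn{R_i},
#' a whole-plot error \eqn{\delta_{ij}} shared by every genotype in a
#' replicate x treatment main plot, genotype-level effects, and a subplot
#' error \eqn{\epsilon_{ijk}}.
#'
#' Genotype-level control/shade dependence is parameterized two ways:
#' either a shared genotype main effect of SD \code{sd_genotype} plus an
#' independent genotype x treatment deviation of SD \code{sd_gxt}, or --
#' when \code{ck_shade_corr} is non-NA for a trait -- a bivariate normal
#' pair of per-treatment genotype expectations with common SD
#' \code{sd_genotype} and the requested correlation. The correlation
#' parameterization wins when both are set.
#'
#' @param n_genotypes Number of genotypes in the panel.
#' @param locations Character vector of location labels.
#' @param treatments Character vector of exactly two treatment labels;
#'   one must be the control label.
#' @param control Label of the control treatment (default \code{"CK"}).
#' @param n_reps Replicates (complete blocks) per location.
#' @param trait_means Data frame with columns location, treatment, trait,
#'   mean: the stratum mean for every combination, in trait units.
#' @param sd_genotype,sd_gxt,sd_rep,sd_wholeplot,sd_subplot Named numeric
#'   vectors (one entry per trait, trait units) of the SDs of the genotype
#'   effect, genotype x treatment interaction, replication effect,
#'   whole-plot error and subplot error.
#' @param ck_shade_corr Named numeric vector per trait in [-1, 1], or NA
#'   per trait to use the shared-effect + interaction parameterization.
#' @param seed Integer RNG seed.
#' @return A list of class \code{"shadetol_sim_config"}.
#' @seealso [default_sim_config()] for the calibrated defaults,
#'   [simulate_panel()] to draw a trial.
#' @export
sim_config <- function(n_genotypes,
                       locations = c("HLJ", "NM"),
                       treatments = c("CK", "shade"),
                       control = "CK",
                       n_reps = 3,
                       trait_means,
                       sd_genotype,
                       sd_gxt,
                       sd_rep,
                       sd_wholeplot,
                       sd_subplot,
                       ck_shade_corr = NULL,
                       seed = 42L) {
  traits <- trait_names()
  as_trait_vec <- function(x, name) {
    if (is.null(x)) x <- stats::setNames(rep(NA_real_, 6L), traits)
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 6L), traits)
    if (is.null(names(x)) && length(x) == 6L) names(x) <- traits
    if (!all(traits %in% names(x))) {
      stop("invalid config: `", name, "` must be named for all of ",
           paste(traits, collapse = ", "), call. = FALSE)
    }
    x[traits]
  }
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    locations = as.character(locations),
    treatments = as.character(treatments),
    control = control,
    n_reps = as.integer(n_reps),
    trait_means = trait_means,
    sd_genotype = as_trait_vec(sd_genotype, "sd_genotype"),
    sd_gxt = as_trait_vec(sd_gxt, "sd_gxt"),
    sd_rep = as_trait_vec(sd_rep, "sd_rep"),
    sd_wholeplot = as_trait_vec(sd_wholeplot, "sd_wholeplot"),
    sd_subplot = as_trait_vec(sd_subplot, "sd_subplot"),
    ck_shade_corr = as_trait_vec(ck_shade_corr, "ck_shade_corr"),
    seed = as.integer(seed)
  )
  class(cfg) <- "shadetol_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    stop("invalid config: `", field, "` ", msg, call. = FALSE)
  }
  if (!length(cfg$n_genotypes) || is.na(cfg$n_genotypes) || cfg$n_genotypes < 1L)
    bad("n_genotypes", "must be a positive count")
  if (!length(cfg$locations)) bad("locations", "must be non-empty")
  if (length(cfg$treatments) != 2L || anyDuplicated(cfg$treatments))
    bad("treatments", "must be two distinct labels")
  if (sum(cfg$treatments == cfg$control) != 1L)
    bad("control", "must match exactly one treatment label")
  if (is.na(cfg$n_reps) || cfg$n_reps < 1L) bad("n_reps", "must be a positive count")
  for (f in c("sd_genotype", "sd_gxt", "sd_rep", "sd_wholeplot", "sd_subplot")) {
    if (anyNA(cfg[[f]]) || any(cfg[[f]] < 0)) bad(f, "must be non-negative for every trait")
  }
  corr <- cfg$ck_shade_corr
  if (any(!is.na(corr) & (corr < -1 | corr > 1)))
    bad("ck_shade_corr", "must lie in [-1, 1]")
  tm <- cfg$trait_means
  need <- c("location", "treatment", "trait", "mean")
  if (!is.data.frame(tm) || !all(need %in% names(tm)))
    bad("trait_means", "must be a data frame with columns location, treatment, trait, mean")
  grid <- expand.grid(location = cfg$locations, treatment = cfg$treatments,
                      trait = trait_names(), stringsAsFactors = FALSE)
  key <- function(d) paste(d$location, d$treatment, d$trait)
  missing <- setdiff(key(grid), key(tm))
  if (length(missing))
    bad("trait_means", paste0("is missing strata: ", paste(missing, collapse = "; ")))
  if (anyNA(tm$mean)) bad("trait_means", "contains NA means")
  invisible(cfg)
}

#' @export
print.shadetol_sim_config <- function(x, ...) {
  cat("Split-plot shade-trial simulation config\n")
  cat("  genotypes:", x$n_genotypes,
      "| locations:", paste(x$locations, collapse = ", "),
      "| treatments:", paste(x$treatments, collapse = ", "),
      "(control:", paste0(x$control, ")"),
      "| reps:", x$n_reps, "\n")
  cat("  seed:", x$seed, "\n")
  cat("  genotype SD:", paste(sprintf("%s=%g", names(x$sd_genotype), x$sd_genotype),
                              collapse = " "), "\n")
  cat("  CK-shade corr:", paste(sprintf("%s=%g", names(x$ck_shade_corr), x$ck_shade_corr),
                                collapse = " "), "\n")
  invisible(x)
}

#' Calibrated default trial configuration
#'
#' Returns the configuration emulating the 460-genotype two-site trial:
#' locations HLJ and NM, treatments CK (monoculture control) and shade
#' (maize-intercrop), three replicates, and stratum means set to the
#' trial's reported location x treatment means. Genotype SDs give
#' between-genotype CVs of roughly 15--30% per trait (a diverse germplasm
#' panel); plot-level error SDs are small relative to genotype SDs because
#' plot values are means of 10 plants. Per-trait control/shade genotype
#' correlations default to the values observed at HLJ.
#'
#' @param n_genotypes Panel size (default 460).
#' @param seed RNG seed (default 42).
#' @return A \code{"shadetol_sim_config"}.
#' @export
#' @examples
#' cfg <- default_sim_config(n_genotypes = 20)
#' panel <- simulate_panel(cfg)
#' head(panel)
default_sim_config <- function(n_genotypes = 460L, seed = 42L) {
  sim_config(
    n_genotypes = n_genotypes,
    locations = c("HLJ", "NM"),
    treatments = c("CK", "shade"),
    control = "CK",
    n_reps = 3L,
    trait_means = default_trait_means(),
    sd_genotype = c(PH = 30,  BPH = 4.5, NNP = 2.8, BN = 0.65, PNP = 18, SYP = 0.35),
    sd_gxt      = c(PH = 8,   BPH = 1.5, NNP = 0.9, BN = 0.20, PNP = 6,  SYP = 0.12),
    sd_rep      = c(PH = 3,   BPH = 0.5, NNP = 0.5, BN = 0.08, PNP = 2,  SYP = 0.05),
    sd_wholeplot= c(PH = 3,   BPH = 0.5, NNP = 0.5, BN = 0.08, PNP = 2,  SYP = 0.05),
    sd_subplot  = c(PH = 6,   BPH = 1.0, NNP = 0.8, BN = 0.25, PNP = 5,  SYP = 0.12),
    ck_shade_corr = c(PH = 0.887, BPH = 0.687, NNP = 0.697,
                      BN = 0.656, PNP = 0.485, SYP = 0.622),
    seed = seed
  )
}

#' Simulate a split-plot shade trial
#'
#' Draws a complete long-format replicate-level phenotype panel from a
#' [sim_config()]. Within each location, every replicate block contains
#' both treatment main plots; the whole-plot error is shared by all
#' genotypes of a (replicate, treatment) main plot. Genotype effects are
#' drawn independently per location (each site is analyzed on its own).
#' Negative draws are truncated at 0. The same config and seed always
#' reproduce the same panel.
#'
#' @param config A \code{"shadetol_sim_config"}.
#' @return A data frame of class \code{"shadetol_panel"} with columns
#'   genotype_id, origin, location, treatment, replicate, trait, value.
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  traits <- trait_names()
  gids <- sprintf("G%04d", seq_len(config$n_genotypes))
  tm <- config$trait_means
  mu_key <- paste(tm$location, tm$treatment, tm$trait)
  mu_val <- stats::setNames(tm$mean, mu_key)

  grid <- expand.grid(
    replicate = seq_len(config$n_reps),
    genotype_id = gids,
    treatment = config$treatments,
    location = config$locations,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_cell <- nrow(grid)
  i_loc <- match(grid$location, config$locations)
  i_trt <- match(grid$treatment, config$treatments)
  i_gen <- match(grid$genotype_id, gids)
  i_rep <- grid$replicate
  is_ctl <- grid$treatment == config$control
  nL <- length(config$locations); nT <- 2L
  nG <- config$n_genotypes; nR <- config$n_reps

  out <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    tr <- traits[t]
    mu <- mu_val[paste(grid$location, grid$treatment, tr)]
    # replication effect: one draw per location x replicate
    R <- matrix(stats::rnorm(nL * nR, 0, config$sd_rep[tr]), nL, nR)
    # whole-plot error: per location x replicate x treatment main plot
    D <- array(stats::rnorm(nL * nR * nT, 0, config$sd_wholeplot[tr]), c(nL, nR, nT))
    rho <- config$ck_shade_corr[tr]
    if (!is.na(rho)) {
      # bivariate genotype expectations (control, stress) per location
      a <- matrix(stats::rnorm(nL * nG), nL, nG)
      b <- rho * a + sqrt(1 - rho^2) * matrix(stats::rnorm(nL * nG), nL, nG)
      g_ctl <- config$sd_genotype[tr] * a
      g_str <- config$sd_genotype[tr] * b
      gen_eff <- ifelse(is_ctl, g_ctl[cbind(i_loc, i_gen)], g_str[cbind(i_loc, i_gen)])
    } else {
      G <- matrix(stats::rnorm(nL * nG, 0, config$sd_genotype[tr]), nL, nG)
      CG <- array(stats::rnorm(nL * nG * nT, 0, config$sd_gxt[tr]), c(nL, nG, nT))
      gen_eff <- G[cbind(i_loc, i_gen)] + CG[cbind(i_loc, i_gen, i_trt)]
    }
    eps <- stats::rnorm(n_cell, 0, config$sd_subplot[tr])
    value <- mu + R[cbind(i_loc, i_rep)] + D[cbind(i_loc, i_rep, i_trt)] + gen_eff + eps
    value <- pmax(value, 0)
    out[[t]] <- data.frame(
      genotype_id = grid$genotype_id,
      origin = NA_character_,
      location = grid$location,
      treatment = grid$treatment,
      replicate = grid$replicate,
      trait = tr,
      value = value,
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$location, panel$treatment, panel$genotype_id,
                       panel$replicate, match(panel$trait, traits)), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("shadetol_panel", "data.frame")
  panel
}
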