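# Shared fixtures, all generated in code.

# Single-location (HLJ) variant of the calibrated default config.
hlj_config <- function(n_genotypes, seed = 42L) {
  cfg <- default_sim_config(n_genotypes, seed = seed)
  cfg$locations <- "HLJ"
  cfg$trait_means <- cfg$trait_means[cfg$trait_means$location == "HLJ", , drop = FALSE]
  cfg
}

# Null config for the cropping-system test: shade stratum means set equal
# to CK and no genotype x system interaction (ck_shade_corr = 1), i.e. the
# model's complete null (no C, no CG); every other component stays on.
null_config <- function(n_genotypes, seed = 42L) {
  cfg <- hlj_config(n_genotypes, seed = seed)
  cfg$ck_shade_corr[] <- 1
  tm <- cfg$trait_means
  for (tr in trait_names()) {
    tm$mean[tm$treatment == "shade" & tm$trait == tr] <-
      tm$mean[tm$treatment == "CK" & tm$trait == tr]
  }
  cfg$trait_means <- tm
  cfg
}

# Noise-free config except genotype effect: planted standardized shifts are
# exact Cohen's d values on genotype means.
planted_d_config <- function(n_genotypes, d = c(PH = 0.33, SYP = -0.30),
                             seed = 42L) {
  cfg <- hlj_config(n_genotypes, seed = seed)
  cfg$sd_genotype[] <- 1
  cfg$sd_gxt[] <- 0
  cfg$sd_rep[] <- 0
  cfg$sd_wholeplot[] <- 0
  cfg$sd_subplot[] <- 0
  cfg$ck_shade_corr[] <- 0.5
  tm <- cfg$trait_means
  # means far from 0 so truncation never bites
  for (tr in trait_names()) {
    tm$mean[tm$trait == tr] <- 100
    if (tr %in% names(d)) {
      tm$mean[tm$trait == tr & tm$treatment == "shade"] <- 100 + d[[tr]]
    }
  }
  cfg$trait_means <- tm
  cfg
}

# Compact long panel from a named list genotype -> c(CK = ..., shade = ...)
# for a single trait/location, replicated identically.
toy_panel <- function(values, trait = "SYP", location = "HLJ", n_reps = 1L) {
  rows <- list()
  for (g in names(values)) {
    for (trt in names(values[[g]])) {
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype_id = g, origin = NA_character_, location = location,
          treatment = trt, replicate = r, trait = trait,
          value = values[[g]][[trt]], stringsAsFactors = FALSE
        )
      }
    }
  }
  shadetol:::validate_panel(do.call(rbind, rows))
}

# Wrap a TI matrix (columns PH..SYP) as a profiles table for the
# clustering / importance operations.
profiles_from_ti <- function(ti, overall = rowMeans(ti)) {
  colnames(ti) <- trait_names()
  df <- data.frame(genotype_id = sprintf("G%04d", seq_len(nrow(ti))),
                   location = "HLJ", stringsAsFactors = FALSE)
  for (tr in trait_names()) df[[paste0("TI_", tr)]] <- ti[, tr]
  df$overall_ti <- overall
  df$yield_stability_index <- ti[, "SYP"]
  df$category <- classify_tolerance(pmax(df$overall_ti, 1e-6))
  class(df) <- c("shadetol_profiles", "data.frame")
  df
}

# Partition agreement up to relabeling (exact match required for k <= 3 toys).
same_partition <- function(a, b) {
  ta <- table(a, b)
  sum(apply(ta, 1L, max)) == length(a) && sum(apply(ta, 2L, max)) == length(b)
}

# Wrap an n x 6 matrix (columns PH..SYP) as a CK/HLJ means table.
means_from_matrix <- function(X) {
  n <- nrow(X)
  colnames(X) <- trait_names()
  rows <- expand.grid(genotype_id = sprintf("G%04d", seq_len(n)),
                      trait = trait_names(), stringsAsFactors = FALSE)
  rows$location <- "HLJ"; rows$treatment <- "CK"
  rows$mean_value <- X[cbind(match(rows$genotype_id, sprintf("G%04d", seq_len(n))),
                             match(rows$trait, trait_names()))]
  rows$n_reps_used <- 3L
  class(rows) <- c("shadetol_means", "data.frame")
  rows
}
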