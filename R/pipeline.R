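#' Run the shade-tolerance evaluation pipeline end-to-end
#'
#' Orchestrates the full analysis: load (or simulate) a replicate-level
#' panel, aggregate to genotype means, compute tolerance profiles and
#' categories, then the enabled analysis stages -- split-plot and
#' two-way ANOVA with assumption checks, shade effect sizes and percent
#' changes, control-vs-shade correlations, path analysis of seed yield,
#' PCA, quartile transitions, k-means dissection of the tolerance space,
#' and random-forest trait importance. Writes CSV tables, a
#' machine-readable \code{summary.json}, and a human-readable
#' \code{report.md} into \code{outdir}. Every stochastic stage runs
#' under a seed derived from \code{seed} and records it, so identical
#' configuration and seed reproduce identical outputs.
#'
#' @param outdir Output directory (created if absent).
#' @param input Path to a panel CSV (see [read_panel()]); ignored when
#'   \code{sim} is given.
#' @param sim A [sim_config()] to simulate the panel from; its seed is
#'   overridden by \code{seed}.
#' @param thresholds A [tolerance_thresholds()] object.
#' @param control Control treatment label.
#' @param seed Integer master seed.
#' @param anova,path,pca,transitions,clustering,importance Stage toggles.
#' @param verbose Print stage progress.
#' @return Invisibly, the summary list written to \code{summary.json}.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(outdir = tempfile("shadetol"),
#'                     sim = default_sim_config(n_genotypes = 50),
#'                     seed = 1)
#' names(out)
#' }
run_pipeline <- function(outdir,
                         input = NULL,
                         sim = NULL,
                         thresholds = tolerance_thresholds(),
                         control = "CK",
                         seed = 42L,
                         anova = TRUE,
                         path = TRUE,
                         pca = TRUE,
                         transitions = TRUE,
                         clustering = TRUE,
                         importance = TRUE,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[shadetol] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(input) && is.null(sim)) {
    stop("stage 'input' failed: provide either `input` (CSV path) or `sim` (a sim_config)",
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = as.integer(seed), control = control,
                  thresholds = unclass(thresholds))

  panel <- stage("input", {
    if (!is.null(sim)) {
      sim$seed <- as.integer(seed)
      say("simulating panel: ", sim$n_genotypes, " genotypes")
      p <- simulate_panel(sim)
      write_panel(p, file.path(outdir, "panel.csv"))
      p
    } else {
      say("reading panel: ", input)
      read_panel(input)
    }
  })
  locations <- sort(unique(panel$location))
  treatments <- unique(panel$treatment)
  summary$n_genotypes <- length(unique(panel$genotype_id))
  summary$locations <- locations
  summary$treatments <- treatments

  means <- stage("aggregate", aggregate_to_means(panel))
  utils::write.csv(means, file.path(outdir, "genotype_means.csv"), row.names = FALSE)

  stratum_means <- stats::aggregate(mean_value ~ location + treatment + trait,
                                    data = means, FUN = mean)
  names(stratum_means)[4L] <- "stratum_mean"
  stratum_means <- stratum_means[order(stratum_means$location, stratum_means$treatment,
                                       match(stratum_means$trait, trait_names())), ]
  summary$stratum_means <- stratum_means

  effects <- stage("effects", {
    do.call(rbind, c(lapply(locations, function(l) shade_effect_table(means, l, control)),
                     list(shade_effect_table(means, NULL, control))))
  })
  utils::write.csv(effects, file.path(outdir, "shade_effects.csv"), row.names = FALSE)
  summary$shade_effects <- effects

  profiles <- stage("tolerance", profile_panel(means, thresholds, control = control))
  utils::write.csv(as.data.frame(profiles), file.path(outdir, "tolerance.csv"),
                   row.names = FALSE)
  cat_counts <- as.data.frame(table(location = profiles$location,
                                    category = profiles$category))
  names(cat_counts)[3L] <- "count"
  summary$category_counts <- cat_counts
  summary$n_skipped_profiles <- attr(profiles, "n_skipped")
  ts_cor <- stage("tolerance", tolerance_stability_correlation(profiles))
  summary$tolerance_stability <- ts_cor

  if (anova) {
    say("ANOVA stage")
    summary$split_plot <- stage("anova", {
      rows <- list()
      for (l in locations) for (tr in trait_names()) {
        f <- fit_split_plot(panel, tr, l)
        t2 <- f$anova_table
        t2$trait <- tr; t2$location <- l
        chk <- suppressWarnings(assumption_checks(
          panel$value[panel$trait == tr & panel$location == l],
          interaction(panel$treatment, panel$replicate)[panel$trait == tr &
                                                          panel$location == l]))
        t2$shapiro_p <- chk$shapiro_p
        t2$levene_p <- chk$levene_p
        rows[[paste(l, tr)]] <- t2
      }
      sp <- do.call(rbind, rows)
      rownames(sp) <- NULL
      utils::write.csv(sp, file.path(outdir, "split_plot_anova.csv"), row.names = FALSE)
      sp
    })
    summary$two_way <- stage("anova", {
      tw <- do.call(rbind, lapply(trait_names(), function(tr) {
        t2 <- two_way_anova(means, tr); t2$trait <- tr; t2
      }))
      utils::write.csv(tw, file.path(outdir, "two_way_anova.csv"), row.names = FALSE)
      tw
    })
  }

  summary$paired_correlations <- stage("correlations", {
    pc <- do.call(rbind, lapply(locations, function(l) {
      do.call(rbind, lapply(trait_names(), function(tr) {
        p <- paired_correlation(means, tr, l, control = control)
        data.frame(trait = tr, location = l, n = p$n, r = p$r,
                   r_squared = p$r_squared, slope = p$slope,
                   intercept = p$intercept, p_value = p$p_value)
      }))
    }))
    utils::write.csv(pc, file.path(outdir, "paired_correlations.csv"),
                     row.names = FALSE)
    pc
  })

  if (path) {
    say("path-analysis stage")
    summary$path <- stage("path", {
      out <- lapply(treatments, function(trt) {
        pm <- path_analysis(means, treatment = trt)
        list(treatment = trt, location = "pooled", n = pm$n,
             direct = as.list(pm$direct),
             p_values = as.list(pm$p_values),
             r_squared_total = pm$r_squared_total)
      })
      jsonlite::write_json(out, file.path(outdir, "path_models.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    })
  }

  if (pca) {
    say("PCA stage")
    summary$pca <- stage("pca", {
      out <- lapply(locations, function(l) {
        pr <- pca_traits(means, location = l)
        list(location = l,
             explained_variance_ratio = pr$explained_variance_ratio,
             pc1_pc2_percent = round(100 * sum(pr$explained_variance_ratio[1:2]), 1),
             loadings = apply(pr$loadings, 2L, as.list))
      })
      jsonlite::write_json(out, file.path(outdir, "pca.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    })
  }

  if (transitions) {
    say("quartile-transition stage")
    summary$transitions <- stage("transitions", {
      out <- lapply(locations, function(l) {
        qt <- quartile_transition(means, location = l, control = control)
        utils::write.csv(qt$table,
                         file.path(outdir, paste0("transitions_", l, ".csv")),
                         row.names = FALSE)
        list(location = l, summary = qt$summary, flows = qt$flows,
             denominator = qt$n)
      })
      jsonlite::write_json(out, file.path(outdir, "transition_flows.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    })
  }

  if (clustering) {
    say("clustering stage")
    summary$clusters <- stage("clustering", {
      cl <- cluster_tolerance_space(profiles, k = 3L, seed = seed + 1L)
      utils::write.csv(cl$assignments, file.path(outdir, "clusters.csv"),
                       row.names = FALSE)
      list(k = cl$k, seed = cl$seed, sizes = cl$sizes,
           total_within_ss = cl$total_within_ss, total_ss = cl$total_ss)
    })
  }

  if (importance) {
    say("importance stage")
    summary$importance <- stage("importance", {
      im <- importance_regression(profiles, seed = seed + 2L)
      utils::write.csv(data.frame(trait = names(im$importance),
                                  importance = unname(im$importance)),
                       file.path(outdir, "importance.csv"), row.names = FALSE)
      list(importance = as.list(im$importance),
           r_squared_holdout = im$r_squared_holdout,
           r_squared_insample = im$r_squared_insample,
           seed = im$seed, hyperparameters = im$hyperparameters)
    })
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  write_report_md(summary, file.path(outdir, "report.md"))
  say("done: ", outdir)
  invisible(summary)
}

# Human-readable Markdown report of the headline numbers.
write_report_md <- function(summary, path) {
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  add("# Shade-tolerance evaluation report")
  add("")
  add("Seed: ", summary$seed, "; genotypes: ", summary$n_genotypes,
      "; locations: ", paste(summary$locations, collapse = ", "),
      "; treatments: ", paste(summary$treatments, collapse = ", "), ".")
  add("")
  add("## Stratum means and shade effects")
  add("")
  add("| trait | scope | CK mean | shade mean | % change | Cohen's d |")
  add("|---|---|---|---|---|---|")
  ef <- summary$shade_effects
  for (i in seq_len(nrow(ef))) {
    add("| ", ef$trait[i], " | ", ef$scope[i], " | ",
        sprintf("%.2f", ef$ck_mean[i]), " | ", sprintf("%.2f", ef$shade_mean[i]),
        " | ", sprintf("%+.1f", ef$percent_change[i]), " | ",
        sprintf("%.2f", ef$cohens_d[i]), " |")
  }
  add("")
  add("## Tolerance categories")
  add("")
  cc <- summary$category_counts
  for (l in unique(cc$location)) {
    sub <- cc[cc$location == l, ]
    add("- ", l, ": ", paste(sprintf("%s %d", sub$category, sub$count), collapse = ", "))
  }
  add("")
  add("Overall-tolerance vs yield-stability: r = ",
      sprintf("%.3f", summary$tolerance_stability$r),
      " (R^2 = ", sprintf("%.3f", summary$tolerance_stability$r_squared),
      ", p = ", format(summary$tolerance_stability$p_value, digits = 3), ").")
  if (!is.null(summary$path)) {
    add("")
    add("## Path analysis of SYP (direct effects)")
    add("")
    for (pm in summary$path) {
      add("- ", pm$treatment, " (", pm$location, ", n = ", pm$n, "): ",
          paste(sprintf("%s %.3f", names(pm$direct), unlist(pm$direct)),
                collapse = ", "),
          "; R^2 = ", sprintf("%.3f", pm$r_squared_total))
    }
  }
  if (!is.null(summary$pca)) {
    add("")
    add("## PCA")
    add("")
    for (p in summary$pca) {
      evr <- unlist(p$explained_variance_ratio)
      add("- ", p$location, ": PC1 ", sprintf("%.1f%%", 100 * evr[1]),
          ", PC2 ", sprintf("%.1f%%", 100 * evr[2]),
          " (PC1+PC2 ", sprintf("%.1f%%", p$pc1_pc2_percent), ")")
    }
  }
  if (!is.null(summary$transitions)) {
    add("")
    add("## Elite-stable and shade-adaptive genotypes")
    add("")
    for (t in summary$transitions) {
      s <- t$summary
      add("- ", t$location, " (denominator ", t$denominator, "): ",
          paste(sprintf("%s %d (%.1f%%)", s$label, s$count, s$percent),
                collapse = ", "))
    }
  }
  if (!is.null(summary$clusters)) {
    add("")
    add("## Tolerance-space clusters")
    add("")
    add("- k = ", summary$clusters$k, " (seed ", summary$clusters$seed, "), sizes: ",
        paste(unlist(summary$clusters$sizes), collapse = "/"))
  }
  if (!is.null(summary$importance)) {
    add("")
    add("## Random-forest trait importance")
    add("")
    imp <- unlist(summary$importance$importance)
    add("- importances: ", paste(sprintf("%s %.3f", names(imp), imp), collapse = ", "))
    add("- held-out R^2 = ", sprintf("%.3f", summary$importance$r_squared_holdout),
        " (in-sample ", sprintf("%.3f", summary$importance$r_squared_insample),
        "; seed ", summary$importance$seed, ")")
  }
  writeLines(ln, path)
  invisible(path)
}

#' Check a pipeline summary against the shipped schema
#'
#' Light structural validation of a \code{summary.json} written by
#' [run_pipeline()] against the JSON schema shipped in
#' \code{inst/schema/summary_schema.json}: required top-level fields must
#' be present and have the declared JSON types.
#'
#' @param summary_path Path to a summary.json file.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
check_summary_schema <- function(summary_path) {
  schema <- jsonlite::read_json(system.file("schema", "summary_schema.json",
                                            package = "shadetol"))
  s <- jsonlite::read_json(summary_path)
  for (field in unlist(schema$required)) {
    if (is.null(s[[field]])) stop("summary.json is missing required field: ", field,
                                  call. = FALSE)
  }
  for (field in names(schema$properties)) {
    if (is.null(s[[field]])) next
    type <- schema$properties[[field]]$type
    ok <- switch(type,
                 integer = ,
                 number = is.numeric(s[[field]]),
                 string = is.character(s[[field]]),
                 array = is.list(s[[field]]) || length(s[[field]]) > 1L,
                 object = is.list(s[[field]]),
                 TRUE)
    if (!ok) stop("summary.json field '", field, "' is not of type ", type,
                  call. = FALSE)
  }
  invisible(TRUE)
}
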