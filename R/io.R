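panel_columns <- function() {
  c("genotype_id", "origin", "location", "treatment", "replicate", "trait", "value")
}

# Validate a raw panel data.frame; returns it with canonical trait names
# and the shadetol_panel class, or stops with row-numbered messages.
validate_panel <- function(df, source = "panel") {
  required <- setdiff(panel_columns(), "origin")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(source, ": missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"origin" %in% names(df)) df$origin <- NA_character_
  df <- df[, panel_columns(), drop = FALSE]
  df$value <- as.numeric(df$value)
  df$replicate <- as.integer(df$replicate)

  canon <- canonical_trait(df$trait)
  if (anyNA(canon)) {
    rows <- which(is.na(canon))
    stop(source, ": unknown trait name(s) ",
         paste(unique(df$trait[rows]), collapse = ", "),
         " at row(s) ", paste(utils::head(rows, 10L), collapse = ", "),
         "; allowed traits: ", paste(trait_names(), collapse = ", "),
         call. = FALSE)
  }
  df$trait <- canon
  neg <- which(!is.na(df$value) & df$value < 0)
  if (length(neg)) {
    stop(source, ": negative trait value(s) at row(s) ",
         paste(utils::head(neg, 10L), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$genotype_id, df$location, df$treatment, df$replicate, df$trait)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(source, ": duplicate (genotype, location, treatment, replicate, trait) key at row(s) ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("shadetol_panel", "data.frame")
  df
}

#' Read a long-format phenotype panel
#'
#' Reads and validates a replicate-level phenotype table with columns
#' \code{genotype_id, origin, location, treatment, replicate, trait, value}
#' (\code{origin} optional). Trait names are canonicalized
#' case-insensitively to PH, BPH, NNP, BN, PNP, SYP; unknown traits,
#' duplicate keys and negative values are rejected with row numbers.
#'
#' @param path Path to a CSV file.
#' @return A \code{"shadetol_panel"} data frame.
#' @export
#' @seealso [write_panel()], [aggregate_to_means()]
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(df, source = basename(path))
}

#' Write a phenotype panel to CSV
#'
#' Long-format CSV with the canonical header; floats at full precision so
#' that read/write round-trips are lossless.
#'
#' @param panel A \code{"shadetol_panel"} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, panel_columns(), drop = FALSE]
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate replicates to genotype means
#'
#' Arithmetic mean per (genotype, location, treatment, trait) cell, the
#' "robust genotypic means" every downstream analysis consumes.
#' Missing replicates are tolerated (ragged panels are the norm in
#' germplasm work); the number of contributing replicates is recorded.
#'
#' @param panel A \code{"shadetol_panel"} data frame.
#' @return Data frame of class \code{"shadetol_means"} with columns
#'   genotype_id, location, treatment, trait, mean_value, n_reps_used.
#' @export
#' @examples
#' cfg <- default_sim_config(n_genotypes = 5)
#' m <- aggregate_to_means(simulate_panel(cfg))
#' head(m)
aggregate_to_means <- function(panel) {
  df <- as.data.frame(panel)
  if (!nrow(df)) stop("empty panel: nothing to aggregate", call. = FALSE)
  key <- interaction(df$genotype_id, df$location, df$treatment, df$trait,
                     sep = "\r", drop = TRUE, lex.order = TRUE)
  sums <- rowsum(df$value, key)
  counts <- as.vector(rowsum(rep(1L, nrow(df)), key))
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- data.frame(
    genotype_id = parts[, 1L],
    location = parts[, 2L],
    treatment = parts[, 3L],
    trait = parts[, 4L],
    mean_value = as.vector(sums) / counts,
    n_reps_used = counts,
    stringsAsFactors = FALSE
  )
  n_expected <- max(counts)
  n_short <- sum(counts < n_expected)
  if (n_short > 0) {
    warning(n_short, " cell(s) have fewer replicates than the panel maximum (",
            n_expected, ")", call. = FALSE)
  }
  out <- out[order(out$location, out$treatment, out$genotype_id,
                   match(out$trait, trait_names())), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shadetol_means", "data.frame")
  out
}

# Wide genotype x trait matrix of means for one stratum.
# Rows are genotype (x treatment, if `treatment` is NULL) records.
means_to_wide <- function(means, location = NULL, treatment = NULL) {
  df <- as.data.frame(means)
  if (!is.null(location)) df <- df[df$location %in% location, , drop = FALSE]
  if (!is.null(treatment)) df <- df[df$treatment %in% treatment, , drop = FALSE]
  if (!nrow(df)) stop("no records in the requested stratum", call. = FALSE)
  id <- paste(df$genotype_id, df$location, df$treatment, sep = "\r")
  wide <- tapply(df$mean_value, list(id, factor(df$trait, trait_names())), mean)
  parts <- do.call(rbind, strsplit(rownames(wide), "\r", fixed = TRUE))
  list(
    matrix = unname(wide[, trait_names(), drop = FALSE]),
    traits = trait_names(),
    genotype_id = parts[, 1L],
    location = parts[, 2L],
    treatment = parts[, 3L]
  )
}
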