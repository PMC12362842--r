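#' Canonical agronomic trait names
#'
#' The six traits scored in the shade-tolerance trials: plant height
#' (PH, cm), basal pod height (BPH, cm), node number per plant (NNP),
#' branch number (BN), pod number per plant (PNP), and seed yield per
#' plant (SYP, g).
#'
#' @return Character vector of the six canonical trait codes, in
#'   conventional reporting order.
#' @export
#' @examples
#' trait_names()
trait_names <- function() {
  c("PH", "BPH", "NNP", "BN", "PNP", "SYP")
}

# Canonicalize trait labels case-insensitively; unknown labels -> NA.
canonical_trait <- function(x) {
  ref <- trait_names()
  ref[match(toupper(trimws(x)), ref)]
}

#' Significance stars
#'
#' Maps p-values to the star convention used in trial reports:
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05,
#' \code{ns} otherwise.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns"))))
  out
}

# Default location x treatment x trait means (trait units) for the
# synthetic trial generator: the printed stratum means of the 460-accession
# panel at the two sites. NM shade PH reconstructed from the printed +11.7%.
default_trait_means <- function() {
  traits <- trait_names()
  means <- rbind(
    HLJ_CK    = c(PH = 118.60, BPH = 14.80, NNP = 18.66, BN = 2.11, PNP = 70.17, SYP = 1.17),
    HLJ_shade = c(PH = 127.49, BPH = 16.50, NNP = 18.75, BN = 1.75, PNP = 64.40, SYP = 0.89),
    NM_CK     = c(PH =  97.17, BPH = 13.53, NNP = 16.39, BN = 1.70, PNP = 41.81, SYP = 0.47),
    NM_shade  = c(PH = 108.55, BPH = 18.60, NNP = 15.84, BN = 1.47, PNP = 29.72, SYP = 0.48)
  )
  grid <- expand.grid(location = c("HLJ", "NM"), treatment = c("CK", "shade"),
                      trait = traits, stringsAsFactors = FALSE)
  grid$mean <- means[cbind(paste(grid$location, grid$treatment, sep = "_"), grid$trait)]
  grid[order(grid$location, grid$treatment, match(grid$trait, traits)), , drop = FALSE]
}
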