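# Simulation configuration for the synthetic tissue generator.

#' Planted TIL phenotype parameter sets
#'
#' Builds \code{k} Gaussian parameter sets in per-nucleus descriptor space
#' (see [descriptor_columns()]). All phenotypes share a lymphocyte-like base
#' profile (small, round, hematoxylin-dark nuclei) and differ by fixed
#' offsets along eight signature descriptors (area, eccentricity, red and
#' blue intensity, and four texture statistics), scaled by
#' \code{separation}. With \code{separation = 1} the phenotypes overlap the
#' way morphologically similar lymphocyte states do on H&E; large values
#' give well-separated populations for recovery experiments.
#'
#' @param k number of phenotypes.
#' @param separation scale of the between-phenotype mean offsets.
#' @return list of \code{k} lists with elements \code{mean} and \code{sd},
#'   named numeric vectors over [descriptor_columns()].
#' @export
default_phenotypes <- function(k = 8L, separation = 1) {
  base_mean <- c(
    area = 200, perimeter = 55, eccentricity = 0.40, equiv_diameter = 16,
    solidity = 0.96, mean_R = 0.35, mean_G = 0.30, mean_B = 0.55,
    har_asm = 0.10, har_contrast = 2.0, har_correlation = 0.30,
    har_variance = 8.0, har_idm = 0.50, har_sum_average = 30,
    har_sum_variance = 20, har_sum_entropy = 1.5, har_entropy = 2.5,
    har_diff_variance = 1.5, har_diff_entropy = 1.2, har_imc1 = -0.20)
  base_sd <- c(
    area = 25, perimeter = 6, eccentricity = 0.08, equiv_diameter = 1.2,
    solidity = 0.015, mean_R = 0.03, mean_G = 0.03, mean_B = 0.03,
    har_asm = 0.015, har_contrast = 0.3, har_correlation = 0.05,
    har_variance = 1.0, har_idm = 0.05, har_sum_average = 2.5,
    har_sum_variance = 2.5, har_sum_entropy = 0.15, har_entropy = 0.25,
    har_diff_variance = 0.2, har_diff_entropy = 0.12, har_imc1 = 0.04)
  # signature descriptors and per-descriptor offset amplitudes
  sig <- c(area = 40, eccentricity = 0.12, mean_R = 0.06, mean_B = 0.06,
           har_contrast = 1.0, har_entropy = 0.5, har_idm = 0.12,
           har_correlation = 0.12)
  lapply(seq_len(k), function(j) {
    m <- base_mean
    # sign pattern from the binary code of j - 1 over the 8 signature dims
    bits <- as.integer(intToBits(j - 1L))[1:8]
    signs <- ifelse(bits == 1L, 1, -1)
    m[names(sig)] <- m[names(sig)] + separation * signs * sig
    list(mean = m, sd = base_sd)
  })
}

# Descriptor distribution of non-lymphocyte nuclei: larger, paler, more
# irregular than TILs.
default_nontil_profile <- function() {
  list(mean = c(
         area = 600, perimeter = 95, eccentricity = 0.50,
         equiv_diameter = 27, solidity = 0.93, mean_R = 0.65,
         mean_G = 0.45, mean_B = 0.70, har_asm = 0.06, har_contrast = 3.5,
         har_correlation = 0.25, har_variance = 12, har_idm = 0.40,
         har_sum_average = 45, har_sum_variance = 35,
         har_sum_entropy = 1.8, har_entropy = 3.0, har_diff_variance = 2.2,
         har_diff_entropy = 1.5, har_imc1 = -0.15),
       sd = c(
         area = 90, perimeter = 12, eccentricity = 0.12,
         equiv_diameter = 2.2, solidity = 0.02, mean_R = 0.05,
         mean_G = 0.05, mean_B = 0.05, har_asm = 0.012, har_contrast = 0.5,
         har_correlation = 0.06, har_variance = 1.8, har_idm = 0.06,
         har_sum_average = 4, har_sum_variance = 4, har_sum_entropy = 0.2,
         har_entropy = 0.3, har_diff_variance = 0.3, har_diff_entropy = 0.15,
         har_imc1 = 0.05))
}

# Default marker mixes (CD4, CD8, CD20) per phenotype. Rows 1, 4 and 6
# follow the reported niche compositions (CD8-dominated, balanced, and
# CD8-rich with a B-cell component); the remainder are plausible mixes
# spanning helper-, cytotoxic- and B-cell-dominated niches.
default_subtype_mix <- function(k = 8L) {
  full <- rbind(
    c(0.10, 0.86, 0.04),
    c(0.60, 0.30, 0.10),
    c(0.33, 0.34, 0.33),
    c(0.25, 0.50, 0.25),
    c(0.15, 0.25, 0.60),
    c(0.09, 0.72, 0.19),
    c(0.45, 0.45, 0.10),
    c(0.05, 0.15, 0.80))
  m <- full[rep_len(seq_len(8L), k), , drop = FALSE]
  dimnames(m) <- list(paste0("P", seq_len(k)), c("CD4", "CD8", "CD20"))
  m
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic tissue generator. Defaults describe a
#' 2048 x 2048 px tile at 20x (0.5 um/px) with clustered TIL hotspots over a
#' homogeneous carpet of non-lymphocyte nuclei, eight planted TIL phenotypes,
#' a planted log-hazard vector for survival simulation, and independent
#' exponential censoring.
#'
#' @param tile_size tile side in pixels.
#' @param microns_per_pixel physical pixel size (um/px).
#' @param n_til_hotspots number of TIL hotspot centers (Thomas-process
#'   parents).
#' @param til_per_hotspot mean number of TILs per hotspot (Poisson).
#' @param hotspot_dispersion Gaussian dispersion of TILs around their
#'   hotspot, in pixels.
#' @param lambda_nontil intensity of the homogeneous non-TIL process, per
#'   square millimetre.
#' @param phenotypes list of planted phenotype parameter sets, as returned
#'   by [default_phenotypes()].
#' @param phenotype_separation separation passed to [default_phenotypes()]
#'   when \code{phenotypes} is NULL.
#' @param subtype_mix matrix (phenotypes x 3) of CD4/CD8/CD20 probabilities;
#'   rows must sum to 1.
#' @param beta_star planted log-hazard weights over the phenotype-count
#'   vector (length = number of phenotypes). The default alternates
#'   \code{+1.25 / -1.25}, a strong planted effect (hazard ratio about 3.5
#'   per standard deviation of a count column).
#' @param censor_rate expected fraction of censored patients, in \code{[0, 1)}.
#' @param render_noise_sd additive Gaussian noise of the tile renderer.
#' @param seed default RNG seed for generators when none is supplied.
#' @return object of class \code{sim_config} (a list).
#' @export
sim_config <- function(tile_size = 2048L,
                       microns_per_pixel = 0.5,
                       n_til_hotspots = 6L,
                       til_per_hotspot = 40,
                       hotspot_dispersion = 60,
                       lambda_nontil = 1500,
                       phenotypes = NULL,
                       phenotype_separation = 1,
                       subtype_mix = NULL,
                       beta_star = NULL,
                       censor_rate = 0.2,
                       render_noise_sd = 0.01,
                       seed = 1L) {
  if (is.null(phenotypes)) {
    phenotypes <- default_phenotypes(8L, separation = phenotype_separation)
  }
  k <- length(phenotypes)
  if (is.null(subtype_mix)) subtype_mix <- default_subtype_mix(k)
  if (is.null(beta_star)) beta_star <- rep_len(c(1.25, -1.25), k)
  cfg <- structure(list(
    tile_size = as.integer(tile_size),
    microns_per_pixel = microns_per_pixel,
    n_til_hotspots = as.integer(n_til_hotspots),
    til_per_hotspot = til_per_hotspot,
    hotspot_dispersion = hotspot_dispersion,
    lambda_nontil = lambda_nontil,
    phenotypes = phenotypes,
    subtype_mix = subtype_mix,
    beta_star = beta_star,
    censor_rate = censor_rate,
    render_noise_sd = render_noise_sd,
    nontil_profile = default_nontil_profile(),
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$tile_size <= 0L) rlang::abort("tile_size must be positive")
  if (cfg$microns_per_pixel <= 0) rlang::abort("microns_per_pixel must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    rlang::abort("censor_rate must lie in [0, 1)")
  }
  k <- length(cfg$phenotypes)
  if (nrow(cfg$subtype_mix) != k || ncol(cfg$subtype_mix) != 3L) {
    rlang::abort("subtype_mix must be a (phenotypes x 3) matrix")
  }
  if (any(abs(rowSums(cfg$subtype_mix) - 1) > 1e-9)) {
    rlang::abort("subtype_mix rows must sum to 1")
  }
  if (length(cfg$beta_star) != k) {
    rlang::abort("beta_star length must match the number of phenotypes")
  }
  invisible(cfg)
}
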