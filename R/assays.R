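#' Simulate a qPCR dilution series
#'
#' Noiseless model: `Ct(Q) = ct_at_1000ng - log_b(Q / 1000)` where `b` is
#' the per-cycle amplification factor (2 for a perfectly doubling assay,
#' 1.75 for a 75%-efficient one). Gaussian noise is added when
#' `noise_sd > 0`.
#'
#' @param per_cycle_amplification per-cycle factor `b` (1 < b <= 2).
#' @param ct_at_1000ng Ct at the 1000-ng anchor point.
#' @param quantities input quantities (ng); default the standard five-point
#'   series 1000/750/500/250/125.
#' @param noise_sd Gaussian Ct noise SD.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return tibble of class `oxbs_dilution`: `quantity`, `ct`.
#' @export
simulate_qpcr_dilution <- function(per_cycle_amplification = 1.75,
                                   ct_at_1000ng = 25,
                                   quantities = c(1000, 750, 500, 250, 125),
                                   noise_sd = 0, seed = 1) {
  stopifnot(per_cycle_amplification > 1, all(quantities > 0))
  ct <- ct_at_1000ng - log(quantities / 1000, base = per_cycle_amplification)
  if (noise_sd > 0) {
    ct <- with_substream(seed, "qpcr", expr = ct + rnorm(length(ct), 0, noise_sd))
  }
  out <- tibble(quantity = quantities, ct = ct)
  class(out) <- c("oxbs_dilution", class(out))
  out
}

#' Fit amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct on log10(quantity); efficiency
#' `E = 10^(-1/slope) - 1` (E = 1, i.e. 100%, at the ideal slope
#' -1/log10(2) = -3.3219). A non-negative slope means no amplification
#' signal and is an error.
#'
#' @param series tibble with `quantity` and `ct` (technical replicates
#'   allowed as repeated quantities); at least 3 distinct quantities.
#' @return object of class `oxbs_efficiency`: `slope`, `efficiency`,
#'   `r.squared`, `fit`.
#' @export
fit_efficiency <- function(series) {
  stopifnot(all(c("quantity", "ct") %in% names(series)))
  if (length(unique(series$quantity)) < 3) {
    abort("need at least 3 distinct quantities")
  }
  fit <- lm(ct ~ log10(quantity), data = series)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    abort("non-negative slope: no amplification signal in the series")
  }
  structure(list(slope = slope,
                 efficiency = 10^(-1 / slope) - 1,
                 # suppress the "essentially perfect fit" warning on
                 # noiseless series
                 r.squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit,
                 series = series),
            class = "oxbs_efficiency")
}

#' @export
print.oxbs_efficiency <- function(x, ...) {
  cat(sprintf("qPCR efficiency: %.1f%% (slope %.4f, R^2 %.4f)\n",
              100 * x$efficiency, x$slope, x$r.squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.oxbs_efficiency <- function(x, ...) {
  tibble(term = c("slope", "efficiency"),
         estimate = c(x$slope, x$efficiency))
}

#' @importFrom generics glance
#' @export
glance.oxbs_efficiency <- function(x, ...) {
  tibble(efficiency = x$efficiency, slope = x$slope,
         r.squared = x$r.squared, n = nrow(x$series))
}

#' Efficiency-corrected delta-delta-Ct fold changes
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` is `dCt` minus the
#' mean `dCt` of the calibrator group; fold change `(1 + E)^(-ddCt)`. With
#' the default `efficiency = 1` this is the classic `2^-ddCt` rule; with
#' `E = 0.75` it is the corrected 1.75-base rule.
#'
#' @param ct_table tibble: `sample_id`, `group`, `gene`, `ct` (one row per
#'   sample x gene).
#' @param reference_gene endogenous control gene name.
#' @param calibrator_group group whose mean dCt anchors the comparison.
#' @param efficiency amplification efficiency E (fraction, default 1).
#' @return tibble: `sample_id`, `group`, `gene`, `dct`, `ddct`,
#'   `fold_change` for every non-reference gene.
#' @export
ddct_fold_change <- function(ct_table, reference_gene, calibrator_group,
                             efficiency = 1) {
  ref <- ct_table |> filter(.data$gene == reference_gene) |>
    select("sample_id", ref_ct = "ct")
  targets <- ct_table |> filter(.data$gene != reference_gene)
  miss <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(miss)) {
    abort(paste0("missing reference-gene Ct for sample(s): ",
                 paste(miss, collapse = ", ")))
  }
  d <- targets |>
    inner_join(ref, by = "sample_id") |>
    mutate(dct = .data$ct - .data$ref_ct)
  cal <- d |>
    filter(.data$group == calibrator_group) |>
    group_by(.data$gene) |>
    summarise(cal_dct = mean(.data$dct), .groups = "drop")
  if (!nrow(cal)) abort("calibrator group has no samples")
  d |>
    inner_join(cal, by = "gene") |>
    mutate(ddct = .data$dct - .data$cal_dct,
           fold_change = (1 + efficiency)^(-.data$ddct)) |>
    select("sample_id", "group", "gene", "dct", "ddct", "fold_change")
}

#' Simulate a digital-PCR chip
#'
#' Each of `n_partitions` partitions is positive with probability
#' `1 - exp(-lambda)` (Poisson occupancy).
#'
#' @param lambda_per_partition mean template copies per partition.
#' @param n_partitions number of partitions (default 20000).
#' @param seed integer seed.
#' @return tibble: `positives`, `negatives`, `total`.
#' @export
simulate_dpcr <- function(lambda_per_partition, n_partitions = 20000, seed = 1) {
  stopifnot(lambda_per_partition >= 0, n_partitions > 0)
  with_substream(seed, "dpcr", expr = {
    pos <- rbinom(1, n_partitions, 1 - exp(-lambda_per_partition))
    tibble(positives = pos, negatives = n_partitions - pos,
           total = n_partitions)
  })
}

#' Poisson quantitation of digital-PCR counts
#'
#' `lambda = -ln(1 - positives/total)` copies per partition;
#' `copies/uL = lambda / partition_volume`; copies per ug input RNA applies
#' the dilution and mass bookkeeping assuming 1:1 RNA-to-cDNA carryover.
#'
#' @param positives,total positive wells and total partitions
#'   (`positives < total`; a saturated chip is an error).
#' @param partition_volume partition volume in uL (default 8.09e-4,
#'   QuantStudio-3D-class chips).
#' @param dilution_factor fold dilution of the template before loading.
#' @param template_volume template volume (uL) carried into the reaction.
#' @param rxn_template_mass template mass (ug) in the reaction.
#' @return tibble: `positives`, `total`, `lambda`, `copies_per_ul`,
#'   `copies_per_ug`.
#' @export
dpcr_copies <- function(positives, total, partition_volume = 8.09e-4,
                        dilution_factor = 1, template_volume = 1,
                        rxn_template_mass = 1) {
  if (any(total <= 0)) abort("total partitions must be positive")
  if (any(positives < 0 | positives > total)) abort("positives out of range")
  if (any(positives == total)) {
    abort("saturated chip (all partitions positive): lambda undefined")
  }
  lambda <- -log(1 - positives / total)
  copies_per_ul <- lambda / partition_volume
  tibble(positives = positives, total = total, lambda = lambda,
         copies_per_ul = copies_per_ul,
         copies_per_ug = copies_per_ul * template_volume * dilution_factor /
           rxn_template_mass)
}

#' Simulate an ELISA plate with CG-density bias
#'
#' Absorbance is an affine function of the per-base modified-cytosine
#' density of the well's material. Standards are mixtures of 0% and 100%
#' modified material at `standard_density` (modified-cytosine sites per
#' bp); the sample sits at its own genomic density, so a standard curve
#' built at a different density reads the sample's level biased by the
#' density ratio.
#'
#' @param true_mc_fraction the sample's true modified fraction of its CG
#'   cytosines.
#' @param sample_density the sample genome's CG-cytosine density (sites
#'   per bp).
#' @param standard_density the standard's CG-cytosine density.
#' @param standard_percents standard points as % modified.
#' @param intercept,slope affine absorbance response: `A = intercept +
#'   slope * density_modified`.
#' @param n_replicates sample technical replicates.
#' @param noise_sd absorbance noise SD.
#' @param seed integer seed.
#' @return tibble of class `oxbs_plate`: `role` (standard/sample),
#'   `percent` (standards only), `replicate`, `absorbance`, with the
#'   density ratio in attribute `"density_ratio"`.
#' @export
simulate_elisa <- function(true_mc_fraction, sample_density = 0.01,
                           standard_density = 0.05,
                           standard_percents = c(0, 5, 10, 25, 50, 100),
                           intercept = 0.05, slope = 20,
                           n_replicates = 3, noise_sd = 0, seed = 1) {
  std <- tibble(role = "standard", percent = standard_percents, replicate = 1L,
                density_mod = standard_percents / 100 * standard_density)
  smp <- tibble(role = "sample", percent = NA_real_,
                replicate = seq_len(n_replicates),
                density_mod = true_mc_fraction * sample_density)
  plate <- bind_rows(std, smp) |>
    mutate(absorbance = intercept + slope * .data$density_mod)
  if (noise_sd > 0) {
    plate <- with_substream(seed, "elisa", expr = {
      plate |> mutate(absorbance = .data$absorbance +
                        rnorm(n(), 0, noise_sd))
    })
  }
  plate <- plate |> select("role", "percent", "replicate", "absorbance")
  attr(plate, "density_ratio") <- standard_density / sample_density
  class(plate) <- c("oxbs_plate", class(plate))
  plate
}

#' Quantify a sample from an ELISA standard curve
#'
#' Fits a linear standard curve (absorbance on % modified), interpolates
#' each sample absorbance to a raw percentage, and applies the CG-density
#' correction `corrected = raw * density_ratio` where `density_ratio = k =
#' standard density / sample density`. Samples outside the standard range
#' are flagged as extrapolated.
#'
#' @param standards tibble with `percent` and `absorbance` (>= 2 points).
#' @param sample_absorbances numeric vector of sample replicate readings.
#' @param density_ratio k (default 1, matched densities).
#' @return tibble: `raw_percent` (per replicate mean +/- sd summarised in
#'   attributes), `corrected_percent`, `extrapolated`; summary row stats
#'   in columns `raw_mean`, `raw_sd`, `corrected_mean`.
#' @export
elisa_quantify <- function(standards, sample_absorbances, density_ratio = 1) {
  if (nrow(standards) < 2) abort("need at least 2 standard points")
  if (density_ratio <= 0) abort("density_ratio must be positive")
  fit <- lm(absorbance ~ percent, data = standards)
  b <- coef(fit)
  raw <- (sample_absorbances - b[1]) / b[2]
  extrapolated <- raw < min(standards$percent) | raw > max(standards$percent)
  if (any(extrapolated)) warn("sample absorbance outside the standard range")
  tibble(replicate = seq_along(raw),
         raw_percent = unname(raw),
         corrected_percent = unname(raw) * density_ratio,
         extrapolated = extrapolated,
         raw_mean = mean(raw), raw_sd = sd(raw),
         corrected_mean = mean(raw) * density_ratio)
}
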