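#' Estimate the bisulfite conversion rate from unmodified-C spike-ins
#'
#' The conversion rate is the converted (T) fraction at unmodified-C
#' spike-in sites of the named library, with a binomial standard error.
#'
#' @param spikeins spike-in counts tibble ([simulate_spikeins()] schema).
#' @param library `"BS"` or `"oxBS"`.
#' @return tibble: `library`, `rate`, `se`, `n_reads`.
#' @export
estimate_bisulfite_rate <- function(spikeins, library = c("BS", "oxBS")) {
  library <- match.arg(library)
  d <- spikeins |>
    filter(.data$site_class == "unmodified", .data$library == !!library)
  t_calls <- sum(d$count_unmodified)
  total <- t_calls + sum(d$count_modified)
  if (total == 0) abort("no coverage at unmodified-C spike-in sites")
  rate <- t_calls / total
  tibble(library = library, rate = rate,
         se = sqrt(rate * (1 - rate) / total), n_reads = total)
}

#' Estimate the oxidation efficiency from hmC spike-ins
#'
#' The raw converted (T) fraction at hmC spike-in sites in the oxBS
#' library confounds oxidation with bisulfite conversion (a molecule reads
#' T only if oxidized *and* converted), so the estimate is normalized by
#' the bisulfite rate measured in the same library:
#' `omega = T-fraction(hmC, oxBS) / beta_ox`. The standard error is
#' propagated by the delta method. Estimates above 1 are clipped and
#' flagged.
#'
#' @param spikeins spike-in counts tibble.
#' @return tibble: `omega`, `se`, `clipped`, `t_fraction`, `beta_ox`.
#' @export
estimate_oxidation_rate <- function(spikeins) {
  beta <- estimate_bisulfite_rate(spikeins, "oxBS")
  if (beta$rate == 0) abort("beta_ox is zero: oxidation efficiency undefined")
  d <- spikeins |>
    filter(.data$site_class == "hmC", .data$library == "oxBS")
  t_calls <- sum(d$count_unmodified)
  total <- t_calls + sum(d$count_modified)
  if (total == 0) abort("no coverage at hmC spike-in sites")
  tf <- t_calls / total
  omega <- tf / beta$rate
  se_tf <- sqrt(tf * (1 - tf) / total)
  # delta method for a ratio of independent estimates
  se <- omega * sqrt((se_tf / max(tf, .Machine$double.eps))^2 +
                       (beta$se / beta$rate)^2)
  clipped <- omega > 1
  tibble(omega = min(omega, 1), se = se, clipped = clipped,
         t_fraction = tf, beta_ox = beta$rate)
}

#' Conversion estimates for a set of samples
#'
#' Convenience wrapper: per sample, estimates beta in both libraries and
#' omega from the oxBS library.
#'
#' @param spikeins_by_sample named list of spike-in tibbles.
#' @return tibble: `sample_id`, `beta_bs`, `beta_ox`, `omega`, SEs,
#'   `omega_clipped`.
#' @export
conversion_estimates <- function(spikeins_by_sample) {
  purrr::imap_dfr(spikeins_by_sample, function(sp, sid) {
    b_bs <- estimate_bisulfite_rate(sp, "BS")
    ox <- estimate_oxidation_rate(sp)
    tibble(sample_id = sid,
           beta_bs = b_bs$rate, beta_bs_se = b_bs$se,
           beta_ox = ox$beta_ox, omega = ox$omega, omega_se = ox$se,
           omega_clipped = ox$clipped)
  })
}

#' Gate samples on conversion-QC thresholds
#'
#' Flags samples whose bisulfite conversion rate or oxidation efficiency
#' falls below threshold (defaults: beta >= 0.99, omega >= 0.97, the
#' assay's usual acceptance bounds, applied per sample). By default
#' failures produce warnings and the pipeline proceeds; `strict = TRUE`
#' turns a failure into an error.
#'
#' @param estimates tibble from [conversion_estimates()] (columns
#'   `sample_id`, `beta_bs`, `omega`).
#' @param beta_min,omega_min thresholds.
#' @param strict error on failure instead of warning.
#' @return `estimates` with `pass_beta`, `pass_omega`, `pass` columns.
#' @export
gate_samples <- function(estimates, beta_min = 0.99, omega_min = 0.97,
                         strict = FALSE) {
  if (!nrow(estimates)) {
    return(estimates |> mutate(pass_beta = logical(), pass_omega = logical(),
                               pass = logical()))
  }
  out <- estimates |>
    mutate(pass_beta = .data$beta_bs >= beta_min,
           pass_omega = .data$omega >= omega_min,
           pass = .data$pass_beta & .data$pass_omega)
  n_fail <- sum(!out$pass)
  if (n_fail > 0) {
    msg <- paste0(n_fail, " sample(s) failed conversion QC (beta >= ",
                  beta_min, ", omega >= ", omega_min, ")")
    if (strict) abort(msg) else warn(msg)
  }
  out
}
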