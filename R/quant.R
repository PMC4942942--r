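#' Per-site BS / oxBS levels and BS-minus-oxBS differencing
#'
#' The BS library reads out mC + hmC; the oxBS library reads out mC alone.
#' Per site, `level = count_modified / (count_modified + count_unmodified)`
#' in each library, `mc = level_oxbs`, `hmc_raw = level_bs - level_oxbs`
#' and `hmc = max(hmc_raw, 0)` (per-site negatives are sampling noise).
#' Sites with zero depth in either library are excluded; the number
#' excluded per reason is attached as the `"excluded"` attribute.
#'
#' @param counts an `oxbs_counts` tibble (`bs_m`, `bs_u`, `ox_m`, `ox_u`).
#' @return the input with `level_bs`, `level_ox`, `mc`, `hmc_raw`, `hmc`,
#'   `depth_bs`, `depth_ox` columns, zero-depth sites removed.
#' @export
site_levels <- function(counts) {
  counts <- counts |>
    mutate(depth_bs = .data$bs_m + .data$bs_u,
           depth_ox = .data$ox_m + .data$ox_u)
  excluded <- c(no_bs_coverage = sum(counts$depth_bs == 0 & counts$depth_ox > 0),
                no_ox_coverage = sum(counts$depth_ox == 0 & counts$depth_bs > 0),
                no_coverage = sum(counts$depth_bs == 0 & counts$depth_ox == 0))
  out <- counts |>
    filter(.data$depth_bs > 0, .data$depth_ox > 0) |>
    mutate(level_bs = .data$bs_m / .data$depth_bs,
           level_ox = .data$ox_m / .data$depth_ox,
           mc = .data$level_ox,
           hmc_raw = .data$level_bs - .data$level_ox,
           hmc = pmax(.data$hmc_raw, 0))
  attr(out, "excluded") <- excluded
  out
}

#' Invert the conversion chemistry for aggregate levels
#'
#' Solves the chemistry forward model
#' \deqn{L_{BS} = (m + h)\beta + (1 - \beta)}
#' \deqn{L_{BS} - L_{ox} = h\,\omega\beta}
#' for `(m, h)` given observed aggregate BS and oxBS levels and known (or
#' spike-in-estimated) `beta` and `omega` (inappropriate-conversion rates
#' assumed zero). In the `beta = omega = 1` limit this reduces to
#' `m = L_ox`, `h = L_BS - L_ox`. Estimates outside the simplex
#' `{m >= 0, h >= 0, m + h <= 1}` are clipped and flagged.
#'
#' @param level_bs,level_ox observed levels (vectors).
#' @param beta,omega chemistry rates in (0, 1].
#' @return tibble: `m_hat`, `h_hat`, `clipped`.
#' @export
corrected_levels <- function(level_bs, level_ox, beta = 1, omega = 1) {
  if (beta <= 0 || omega <= 0) abort("omega * beta must be positive")
  h <- (level_bs - level_ox) / (omega * beta)
  m <- (level_bs - (1 - beta)) / beta - h
  clipped <- m < 0 | h < 0 | m + h > 1
  h2 <- pmin(pmax(h, 0), 1)
  m2 <- pmin(pmax(m, 0), 1 - h2)
  tibble(m_hat = m2, h_hat = h2, clipped = clipped)
}

#' Pool levels over groups of sites (count-weighted)
#'
#' Pooled level per group is `sum(count_modified) / sum(total calls)` per
#' library -- i.e. the coverage-weighted mean of site levels, matching
#' summed methylation-call aggregation. The BS and oxBS readouts are pooled
#' separately and differenced afterwards (no per-site clamping enters the
#' pooled estimate). Groups with zero reads in either library are dropped.
#'
#' @param counts an `oxbs_counts` tibble.
#' @param ... grouping expressions passed to [dplyr::group_by()].
#' @return tibble per group: `n_sites`, `reads_bs`, `reads_ox`,
#'   `level_bs`, `level_ox`, `mc`, `hmc_raw`, `hmc`.
#' @export
pool_levels <- function(counts, ...) {
  counts |>
    group_by(...) |>
    summarise(n_sites = n(),
              reads_bs = sum(.data$bs_m + .data$bs_u),
              reads_ox = sum(.data$ox_m + .data$ox_u),
              level_bs = sum(.data$bs_m) / sum(.data$bs_m + .data$bs_u),
              level_ox = sum(.data$ox_m) / sum(.data$ox_m + .data$ox_u),
              .groups = "drop") |>
    filter(.data$reads_bs > 0, .data$reads_ox > 0) |>
    mutate(mc = .data$level_ox,
           hmc_raw = .data$level_bs - .data$level_ox,
           hmc = pmax(.data$hmc_raw, 0))
}

chrom_class_of <- function(chrom) {
  ifelse(chrom == "chrX", "chrX", ifelse(chrom == "chrY", "chrY", "autosomes"))
}

#' Sex-aware chromosome summary
#'
#' Pools each sample's counts by chromosome class (all autosomes together;
#' chrX and chrY separately) and context class (CG, CH). Female samples
#' must not contain chrY records: finding any is treated as a design /
#' label mismatch and raises an error.
#'
#' @param counts_by_sample named list of `oxbs_counts` tibbles, one per
#'   sample (names are sample ids), or a single tibble with a `sample_id`
#'   column.
#' @param design [sample_design()] tibble.
#' @return tibble: `sample_id`, `sex`, `age`, `chrom_class`,
#'   `context_class`, pooled level columns as in [pool_levels()].
#' @export
chromosome_summary <- function(counts_by_sample, design) {
  if (is.data.frame(counts_by_sample)) {
    counts_by_sample <- split(counts_by_sample, counts_by_sample$sample_id)
  }
  missing <- setdiff(design$sample_id, names(counts_by_sample))
  if (length(missing)) {
    abort(paste0("no count table for sample(s): ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(design$sample_id, function(sid) {
    info <- design |> filter(.data$sample_id == sid)
    counts <- counts_by_sample[[sid]]
    if (info$sex == "female" && any(counts$chrom == "chrY")) {
      abort(paste0("sample ", sid, " is labelled female but carries chrY records"))
    }
    counts |>
      mutate(chrom_class = chrom_class_of(.data$chrom)) |>
      pool_levels(.data$chrom_class, .data$context_class) |>
      mutate(sample_id = sid, sex = info$sex, age = info$age, .before = 1)
  })
}

#' Endpoint matrix from pipeline summaries
#'
#' Reshapes chromosome summaries (and optionally per-sample region
#' aggregates) into the long endpoint format consumed by [run_family()]:
#' one value per sample per endpoint, endpoints named like
#' `autosomes_mCG`, `chrX_hmCG`, `shore_up_hmCG`.
#'
#' @param chrom_summary output of [chromosome_summary()].
#' @param region_summary optional tibble with `sample_id`, `type`, `mc`,
#'   `hmc` (per-sample [region_aggregates()] rows).
#' @return tibble: `endpoint`, `sample_id`, `value`.
#' @export
summary_endpoints <- function(chrom_summary, region_summary = NULL) {
  a <- chrom_summary |>
    tidyr::pivot_longer(c("mc", "hmc"), names_to = "mod", values_to = "value") |>
    mutate(endpoint = paste0(.data$chrom_class, "_",
                             ifelse(.data$mod == "mc", "m", "hm"),
                             .data$context_class)) |>
    select("endpoint", "sample_id", "value")
  if (is.null(region_summary)) return(a)
  b <- region_summary |>
    tidyr::pivot_longer(c("mc", "hmc"), names_to = "mod", values_to = "value") |>
    mutate(endpoint = paste0(.data$type, "_",
                             ifelse(.data$mod == "mc", "m", "hm"), "CG")) |>
    select("endpoint", "sample_id", "value")
  bind_rows(a, b)
}
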