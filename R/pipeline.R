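#' Simulate and quantify a full oxBS experiment
#'
#' End-to-end driver: builds the mock reference, assigns per-sample truth
#' under the methylome profile, simulates paired BS/oxBS counts under the
#' conversion chemistry, and summarises each sample (chromosome classes,
#' CGI region classes, promoter super-bins, repeat surrogate). Samples are
#' processed one at a time so memory stays flat; set `keep_counts = TRUE`
#' to retain the per-site count tables.
#'
#' @param config [sim_config()].
#' @param profile [hippocampus_profile()].
#' @param chemistry [chemistry_params()].
#' @param design [sample_design()].
#' @param coverage mean depth per site per library.
#' @param seed top-level seed; every module draws from a named substream.
#' @param keep_counts retain per-sample `oxbs_counts` tables.
#' @return object of class `oxbs_experiment`: `reference`, `design`,
#'   `chrom_summary`, `region_summary` (per sample x region class),
#'   `repeat_summary`, `truth_summary` (per-sample true pooled means),
#'   and optionally `counts`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                profile = hippocampus_profile(),
                                chemistry = chemistry_params(),
                                design = sample_design(),
                                coverage = 10, seed = 1,
                                keep_counts = FALSE) {
  reference <- build_reference(config, seed)
  sites <- annotate_sites(reference, config$shore_width, config$shelf_width)
  bg <- calibrate_background(sites, profile)
  ann <- reference$annotations
  cgis <- ann |> filter(.data$type == "cgi")
  flanks <- derive_flanks(cgis, config$shore_width, config$shelf_width,
                          reference$chrom_lengths)
  proms <- ann |> filter(.data$type == "promoter")
  superbins <- promoter_superbins(proms |> select("chrom", "tss", "strand", "name"),
                                  flank = config$promoter_flank,
                                  chrom_lengths = reference$chrom_lengths)
  regions <- bind_rows(flanks |> select("chrom", "start", "end", "type", "element"),
                       superbins |> select("chrom", "start", "end", "type", "element"))
  reps <- ann |> filter(.data$type == "repeat")

  chrom_rows <- list(); region_rows <- list(); repeat_rows <- list()
  truth_rows <- list(); counts_list <- list()
  for (k in seq_len(nrow(design))) {
    info <- design[k, ]
    s <- if (info$sex == "female") sites |> filter(.data$chrom != "chrY") else sites
    means <- truth_means(s, profile, info$sex, info$age, background = bg)
    truth <- draw_sample_truth(means, profile$concentration, seed, info$sample_id)
    counts <- simulate_counts(truth, chemistry, coverage,
                              seed = substream_seed(seed, "counts", info$sample_id))
    truth_rows[[k]] <- truth |>
      filter(.data$context_class == "CG",
             chrom_class_of(.data$chrom) == "autosomes") |>
      summarise(m_true = mean(.data$m_true), h_true = mean(.data$h_true)) |>
      mutate(sample_id = info$sample_id, .before = 1)
    chrom_rows[[k]] <- counts |>
      mutate(chrom_class = chrom_class_of(.data$chrom)) |>
      pool_levels(.data$chrom_class, .data$context_class) |>
      mutate(sample_id = info$sample_id, sex = info$sex, age = info$age,
             .before = 1)
    region_rows[[k]] <- region_aggregates(counts, regions) |>
      mutate(sample_id = info$sample_id, sex = info$sex, age = info$age,
             .before = 1)
    repeat_rows[[k]] <- repeat_surrogate(counts, reps) |>
      mutate(sample_id = info$sample_id, .before = 1)
    if (keep_counts) counts_list[[info$sample_id]] <- counts
  }
  structure(list(reference = reference,
                 design = design,
                 background = bg,
                 chrom_summary = bind_rows(chrom_rows),
                 region_summary = bind_rows(region_rows),
                 repeat_summary = bind_rows(repeat_rows),
                 truth_summary = bind_rows(truth_rows),
                 counts = if (keep_counts) counts_list else NULL),
            class = "oxbs_experiment")
}

#' @export
print.oxbs_experiment <- function(x, ...) {
  cat("<oxbs_experiment> ", nrow(x$design), " samples, ",
      length(x$reference$genome), " chromosomes\n", sep = "")
  auto <- x$chrom_summary |>
    filter(.data$chrom_class == "autosomes", .data$context_class == "CG") |>
    summarise(mCG = mean(.data$mc), hmCG = mean(.data$hmc))
  cat(sprintf("pooled autosomal CG: mC %.1f%%, hmC %.1f%%\n",
              100 * auto$mCG, 100 * auto$hmCG))
  invisible(x)
}
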