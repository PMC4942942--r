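#' Derive CGI shores and shelves
#'
#' Shores span 0-2 kb and shelves 2-4 kb from each island edge (both
#' configurable). Where the flanks of neighboring islands would overlap,
#' the intervening span is split at the midpoint between the islands;
#' flanks running off a chromosome end are truncated. Truncated or split
#' regions are flagged. Coordinates are 0-based half-open.
#'
#' @param cgis tibble of islands: `chrom`, `start`, `end`, `name`.
#' @param shore_width,shelf_width widths in bp (defaults 2000 each).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return region tibble: `chrom`, `start`, `end`, `type` (island,
#'   shore_up, shore_down, shelf_up, shelf_down), `element`, `truncated`.
#' @export
derive_flanks <- function(cgis, shore_width = 2000, shelf_width = 2000,
                          chrom_lengths = NULL) {
  if (shore_width < 0 || shelf_width < 0) abort("widths must be non-negative")
  if (!nrow(cgis)) abort("empty CGI set")
  cgis <- cgis |> arrange(.data$chrom, .data$start)
  fl <- shore_width + shelf_width
  out <- cgis |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      L <- if (!is.null(chrom_lengths)) unname(chrom_lengths[key$chrom]) else Inf
      n <- nrow(d)
      prev_end <- c(-Inf, d$end[-n])
      next_start <- c(d$start[-1], Inf)
      lo_limit <- pmax(0, floor((prev_end + d$start) / 2))
      hi_limit <- pmin(L, ceiling((d$end + next_start) / 2))
      mk <- function(type, s, e) {
        tibble(start = pmax(s, lo_limit), end = pmin(e, hi_limit),
               type = type, element = d$name,
               truncated = s < lo_limit | e > hi_limit)
      }
      bind_rows(
        tibble(start = d$start, end = d$end, type = "island",
               element = d$name, truncated = FALSE),
        mk("shore_up", d$start - shore_width, d$start),
        mk("shelf_up", d$start - fl, d$start - shore_width),
        mk("shore_down", d$end, d$end + shore_width),
        mk("shelf_down", d$end + shore_width, d$end + fl)
      )
    }) |>
    ungroup() |>
    filter(.data$end > .data$start) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "type", "element", "truncated")
  out
}

#' Tile promoters into fixed-width bins around the TSS
#'
#' Bins are indexed -n..-1 (upstream of the TSS) and +1..+n (downstream) in
#' the gene's 5'-to-3' orientation; minus-strand promoters have their
#' genomic coordinates mirrored. Bins running off a chromosome end are
#' dropped and flagged on the remaining bins of that promoter.
#'
#' @param promoters tibble: `chrom`, `tss` (0-based), `strand`, `name`.
#' @param flank half-width around the TSS (default 2000).
#' @param bin_width bin width (default 100; `flank` must be a multiple).
#' @param chrom_lengths optional named vector for end truncation.
#' @return region tibble: `chrom`, `start`, `end`, `type` (`"promoter_bin"`),
#'   `element`, `bin`, `strand`, `truncated`.
#' @export
promoter_bins <- function(promoters, flank = 2000, bin_width = 100,
                          chrom_lengths = NULL) {
  if (flank %% bin_width != 0) abort("flank must be a multiple of bin_width")
  n <- flank / bin_width
  bins <- c(-n:-1, 1:n)
  out <- tidyr::expand_grid(promoters |> select("chrom", "tss", "strand", "name"),
                            bin = bins) |>
    mutate(
      # plus strand: bin k>0 covers [tss+(k-1)w, tss+kw); k<0 covers [tss+kw, tss+(k+1)w)
      g1 = ifelse(.data$bin > 0, .data$bin - 1, .data$bin),
      start = ifelse(.data$strand == "+",
                     .data$tss + .data$g1 * bin_width,
                     .data$tss - (.data$g1 + 1) * bin_width),
      end = .data$start + bin_width
    ) |>
    select(-"g1")
  trunc_elems <- character()
  if (!is.null(chrom_lengths)) {
    bad <- out$start < 0 | out$end > unname(chrom_lengths[out$chrom])
    trunc_elems <- unique(out$name[bad])
    out <- out[!bad, , drop = FALSE]
  }
  out |>
    mutate(type = "promoter_bin", element = .data$name,
           truncated = .data$element %in% trunc_elems,
           start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("chrom", "start", "end", "type", "element", "bin", "strand",
           "truncated")
}

#' Tile CGI flanks into edge-anchored profile bins
#'
#' Produces `n` bins of `bin_width` bp on each side of every island
#' (indexed -n..-1 upstream, +1..+n downstream) plus the variable-length
#' island body as bin 0. Unlike [derive_flanks()], profile bins are not
#' midpoint-truncated: overlapping elements each keep their full bins.
#'
#' @param cgis island tibble (`chrom`, `start`, `end`, `name`).
#' @param flank flank span per side (default 4000).
#' @param bin_width bin width (default 200).
#' @param chrom_lengths optional named vector; out-of-bounds bins dropped.
#' @return region tibble with `bin` (0 = island body).
#' @export
cgi_profile_bins <- function(cgis, flank = 4000, bin_width = 200,
                             chrom_lengths = NULL) {
  if (flank %% bin_width != 0) abort("flank must be a multiple of bin_width")
  n <- flank / bin_width
  up <- tidyr::expand_grid(cgis |> select("chrom", "start", "end", "name"),
                           bin = -n:-1) |>
    mutate(bs = .data$start + .data$bin * bin_width, be = .data$bs + bin_width)
  down <- tidyr::expand_grid(cgis |> select("chrom", "start", "end", "name"),
                             bin = 1:n) |>
    mutate(bs = .data$end + (.data$bin - 1) * bin_width,
           be = .data$bs + bin_width)
  body <- cgis |> mutate(bin = 0L, bs = .data$start, be = .data$end)
  out <- bind_rows(up, down, body) |>
    transmute(.data$chrom, start = as.integer(.data$bs),
              end = as.integer(.data$be), type = "cgi_bin",
              element = .data$name, bin = .data$bin)
  if (!is.null(chrom_lengths)) {
    out <- out |> filter(.data$start >= 0,
                         .data$end <= unname(chrom_lengths[.data$chrom]))
  }
  out
}

#' Promoter 1-kb super-bins
#'
#' Orientation-aware 1-kb windows tiling the TSS +/- 2 kb flank:
#' `promoter_-2kb`, `promoter_-1kb`, `promoter_+1kb`, `promoter_+2kb`.
#'
#' @inheritParams promoter_bins
#' @return region tibble with `type` carrying the super-bin label.
#' @export
promoter_superbins <- function(promoters, flank = 2000,
                               chrom_lengths = NULL) {
  promoter_bins(promoters, flank = flank, bin_width = 1000,
                chrom_lengths = chrom_lengths) |>
    mutate(type = paste0("promoter_", ifelse(.data$bin > 0, "+", ""),
                         .data$bin, "kb")) |>
    select(-"bin")
}

# Many-to-many overlap join of per-site records onto a region tibble.
# Sites may land in several regions (overlapping elements are retained).
overlap_join <- function(sites, regions) {
  if (!nrow(regions)) abort("region set is empty")
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, width = 1L))
  region_gr <- GenomicRanges::GRanges(regions$chrom,
                                      IRanges::IRanges(regions$start + 1L,
                                                       regions$end))
  hits <- GenomicRanges::findOverlaps(site_gr, region_gr)
  reg <- regions |> select(-"chrom", -"start", -"end")
  clash <- intersect(names(reg), c("strand", "truncated", names(sites)))
  names(reg)[match(clash, names(reg))] <- paste0("region_", clash)
  bind_cols(sites[S4Vectors::queryHits(hits), , drop = FALSE],
            reg[S4Vectors::subjectHits(hits), , drop = FALSE])
}

#' Meta-profile of modification levels over binned elements
#'
#' Within each element's bin, BS and oxBS counts are pooled
#' (count-weighted); across elements, the per-bin meta value is the
#' unweighted mean over elements with coverage in that bin. hmC per
#' element-bin is pooled BS minus pooled oxBS. Bins with no covered sites
#' in any element are absent from the output (missing, not zero).
#'
#' @param counts an `oxbs_counts` tibble (CG context is selected
#'   automatically when a `context_class` column is present).
#' @param regions binned region tibble from [cgi_profile_bins()] or
#'   [promoter_bins()].
#' @return tibble of class `oxbs_profile`: `bin`, `n_elements`, `mc`,
#'   `hmc`, `level_bs`, `level_ox`.
#' @export
profile_elements <- function(counts, regions) {
  if (!"bin" %in% names(regions)) abort("regions must carry a `bin` column")
  if ("context_class" %in% names(counts)) {
    counts <- counts |> filter(.data$context_class == "CG")
  }
  per_elem <- overlap_join(counts, regions) |>
    group_by(.data$element, .data$bin) |>
    summarise(bs_m = sum(.data$bs_m), bs_u = sum(.data$bs_u),
              ox_m = sum(.data$ox_m), ox_u = sum(.data$ox_u),
              .groups = "drop") |>
    filter(.data$bs_m + .data$bs_u > 0, .data$ox_m + .data$ox_u > 0) |>
    mutate(level_bs = .data$bs_m / (.data$bs_m + .data$bs_u),
           level_ox = .data$ox_m / (.data$ox_m + .data$ox_u),
           mc = .data$level_ox, hmc = .data$level_bs - .data$level_ox)
  out <- per_elem |>
    group_by(.data$bin) |>
    summarise(n_elements = n(),
              mc = mean(.data$mc), hmc = mean(.data$hmc),
              level_bs = mean(.data$level_bs), level_ox = mean(.data$level_ox),
              .groups = "drop") |>
    arrange(.data$bin)
  class(out) <- c("oxbs_profile", class(out))
  out
}

#' Region-class aggregates (CGI classes and promoter super-bins)
#'
#' Pools CG-context counts over all member sites of each region class
#' (island, shore_up, shore_down, shelf_up, shelf_down, promoter 1-kb
#' super-bins, repeat, ...) with [pool_levels()] semantics.
#'
#' @param counts an `oxbs_counts` tibble for one sample.
#' @param regions region tibble with a `type` column.
#' @return tibble: `type`, `n_sites`, `reads_bs`, `reads_ox`, `level_bs`,
#'   `level_ox`, `mc`, `hmc_raw`, `hmc`.
#' @export
region_aggregates <- function(counts, regions) {
  if ("context_class" %in% names(counts)) {
    counts <- counts |> filter(.data$context_class == "CG")
  }
  overlap_join(counts, regions) |>
    pool_levels(.data$type)
}

#' Repeat-element BS-level surrogate
#'
#' Pools the BS-library level (mC + hmC combined, no oxBS subtraction) over
#' repeat intervals -- the pyrosequencing-style surrogate for "global
#' methylation" -- and reports the genome-wide BS level beside it to expose
#' the surrogate's bias.
#'
#' @param counts an `oxbs_counts` tibble for one sample.
#' @param repeats repeat interval tibble (`chrom`, `start`, `end`).
#' @return tibble with rows `repeats` and `genome`: `n_sites`, `level_bs`.
#' @export
repeat_surrogate <- function(counts, repeats) {
  if ("context_class" %in% names(counts)) {
    counts <- counts |> filter(.data$context_class == "CG")
  }
  if (is.null(repeats) || !nrow(repeats)) {
    warn("no repeat annotation; returning empty surrogate table")
    return(tibble(region = character(), n_sites = integer(),
                  level_bs = double()))
  }
  rep_counts <- overlap_join(counts, repeats)
  bind_rows(
    tibble(region = "repeats",
           n_sites = nrow(rep_counts),
           level_bs = sum(rep_counts$bs_m) / sum(rep_counts$bs_m + rep_counts$bs_u)),
    tibble(region = "genome",
           n_sites = nrow(counts),
           level_bs = sum(counts$bs_m) / sum(counts$bs_m + counts$bs_u))
  )
}
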