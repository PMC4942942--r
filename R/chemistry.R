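#' Per-read probability of an unconverted (C) call
#'
#' Forward model of the bisulfite / oxidative-bisulfite chemistry. For a
#' site with true 5mC fraction `m` and 5hmC fraction `h`:
#' \deqn{P_C^{BS} = m(1-\epsilon_m) + h(1-\epsilon_h) + (1-m-h)(1-\beta)}
#' \deqn{P_C^{oxBS} = m(1-\epsilon_m) + h[(1-\omega)(1-\epsilon_h) +
#'   \omega(1-\beta)] + (1-m-h)(1-\beta)}
#' where `beta` is the bisulfite conversion rate of unmodified C, `omega`
#' the oxidation efficiency of hmC, and `eps_m`/`eps_h` the inappropriate
#' conversion rates of mC and hmC.
#'
#' @param m,h true modification fractions (vectors, `m + h <= 1`).
#' @param chemistry an [chemistry_params()] object.
#' @param library `"BS"` or `"oxBS"`.
#' @return vector of per-read C-call probabilities.
#' @export
conversion_prob <- function(m, h, chemistry = chemistry_params(),
                            library = c("BS", "oxBS")) {
  library <- match.arg(library)
  if (any(m + h > 1 + 1e-9)) abort("m + h > 1 at some site")
  b <- chemistry$beta; w <- chemistry$omega
  em <- chemistry$eps_m; eh <- chemistry$eps_h
  u <- (1 - m - h) * (1 - b)
  p <- if (library == "BS") {
    m * (1 - em) + h * (1 - eh) + u
  } else {
    m * (1 - em) + h * ((1 - w) * (1 - eh) + w * (1 - b)) + u
  }
  # guard against floating-point epsilon outside [0, 1]
  pmin(pmax(p, 0), 1)
}

#' Simulate paired BS / oxBS cytosine counts from a truth table
#'
#' Per site, sequencing depth is Poisson around the target coverage
#' independently in each library, and modified (C) calls are Binomial with
#' the [conversion_prob()] of that library. Zero-depth sites are emitted
#' with zero counts; downstream per-site estimation excludes them.
#'
#' @param truth tibble with `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, `m_true`, `h_true` (one sample's methylome truth).
#' @param chemistry an [chemistry_params()] object.
#' @param coverage target mean depth per site per library (>= 1).
#' @param seed integer seed.
#' @return tibble of class `oxbs_counts`: the truth's site columns plus
#'   `bs_m`, `bs_u`, `ox_m`, `ox_u` (modified / unmodified call counts per
#'   library).
#' @export
simulate_counts <- function(truth, chemistry = chemistry_params(),
                            coverage = 10, seed = 1) {
  stopifnot(coverage >= 1)
  if (any(truth$m_true + truth$h_true > 1 + 1e-9)) {
    abort("truth invariant breached: m_true + h_true > 1")
  }
  with_substream(seed, "counts", expr = {
    n <- nrow(truth)
    p_bs <- conversion_prob(truth$m_true, truth$h_true, chemistry, "BS")
    p_ox <- conversion_prob(truth$m_true, truth$h_true, chemistry, "oxBS")
    d_bs <- rpois(n, coverage)
    d_ox <- rpois(n, coverage)
    bs_m <- rbinom(n, d_bs, p_bs)
    ox_m <- rbinom(n, d_ox, p_ox)
    out <- truth |>
      mutate(bs_m = bs_m, bs_u = d_bs - bs_m,
             ox_m = ox_m, ox_u = d_ox - ox_m)
    class(out) <- c("oxbs_counts", class(out))
    out
  })
}

#' Write a Bismark-style cytosine report
#'
#' Columns: chromosome, 1-based position, strand, count methylated
#' (unconverted C calls), count unmethylated (converted T calls), context
#' (CG/CHG/CHH), trinucleotide. No header, tab separated.
#'
#' @param counts an `oxbs_counts` tibble (or long per-library counts with
#'   `count_modified`/`count_unmodified`).
#' @param library which library's counts to write (`"BS"` or `"oxBS"`);
#'   ignored when `counts` is already per-library.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(counts, library = c("BS", "oxBS"), path) {
  library <- match.arg(library)
  if (!all(c("count_modified", "count_unmodified") %in% names(counts))) {
    pre <- if (library == "BS") "bs" else "ox"
    counts <- counts |>
      mutate(count_modified = .data[[paste0(pre, "_m")]],
             count_unmodified = .data[[paste0(pre, "_u")]])
  }
  counts |>
    transmute(.data$chrom, pos = .data$pos + 1L, .data$strand,
              .data$count_modified, .data$count_unmodified,
              .data$context, .data$trinucleotide) |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' @param path TSV path written by [write_cytosine_report()] (or by
#'   bismark's coverage2cytosine).
#' @return per-library counts tibble with 0-based `pos`.
#' @export
read_cytosine_report <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "pos", "strand", "count_modified",
                                "count_unmodified", "context", "trinucleotide"),
                  col_types = "ciciicc", progress = FALSE) |>
    mutate(pos = .data$pos - 1L,
           context_class = ifelse(.data$context == "CG", "CG", "CH"))
}

#' Combine per-library BS and oxBS count tables into the wide schema
#'
#' @param bs,oxbs per-library counts tibbles (`count_modified`,
#'   `count_unmodified`) keyed by `chrom`, `pos`, `strand`.
#' @return `oxbs_counts` tibble with `bs_m`, `bs_u`, `ox_m`, `ox_u`.
#' @export
pair_counts <- function(bs, oxbs) {
  keys <- c("chrom", "pos", "strand")
  meta <- intersect(c("context", "context_class", "trinucleotide"), names(bs))
  out <- full_join(
    bs |> select(all_of(c(keys, meta)), bs_m = "count_modified", bs_u = "count_unmodified"),
    oxbs |> select(all_of(keys), ox_m = "count_modified", ox_u = "count_unmodified"),
    by = keys
  ) |>
    mutate(across(c("bs_m", "bs_u", "ox_m", "ox_u"), \(x) tidyr::replace_na(x, 0L)))
  class(out) <- c("oxbs_counts", class(out))
  out
}

# Fixed synthetic spike-in sequences: three short amplicons whose cytosine
# site classes are disjoint and exhaustive (all Cs of a given control share
# one class).
spikein_layout <- function(n_sites = 10) {
  classes <- c(spike_unmod = "unmodified", spike_mc = "mC", spike_hmc = "hmC")
  purrr::map2_dfr(names(classes), unname(classes), function(nm, cl) {
    tibble(seq_name = nm, site = seq_len(n_sites), site_class = cl)
  })
}

#' Simulate spike-in control counts
#'
#' Three synthetic control sequences carry cytosines of known class:
#' unmodified C (converts at rate `beta` in both libraries), 5mC (converts
#' at `eps_m`), and 5hmC (converts at `eps_h` in BS; at
#' `omega * beta + (1 - omega) * eps_h` in oxBS). Reads per class are split
#' evenly over that control's sites.
#'
#' @param chemistry an [chemistry_params()] object.
#' @param depth total reads per site class per library.
#' @param seed integer seed.
#' @param n_sites cytosine sites per control sequence.
#' @return tibble: `seq_name`, `site`, `site_class`, `library`,
#'   `count_modified` (C calls), `count_unmodified` (T calls).
#' @export
simulate_spikeins <- function(chemistry = chemistry_params(), depth = 1e5,
                              seed = 1, n_sites = 10) {
  with_substream(seed, "spikeins", expr = {
    b <- chemistry$beta; w <- chemistry$omega
    em <- chemistry$eps_m; eh <- chemistry$eps_h
    p_t <- tibble(site_class = c("unmodified", "mC", "hmC"),
                  BS = c(b, em, eh),
                  oxBS = c(b, em, w * b + (1 - w) * eh)) |>
      tidyr::pivot_longer(c("BS", "oxBS"), names_to = "library",
                          values_to = "p_convert")
    layout <- spikein_layout(n_sites)
    per_site <- round(depth / n_sites)
    tidyr::expand_grid(layout, library = c("BS", "oxBS")) |>
      left_join(p_t, by = c("site_class", "library")) |>
      mutate(count_unmodified = rbinom(n(), per_site, .data$p_convert),
             count_modified = per_site - .data$count_unmodified) |>
      select("seq_name", "site", "site_class", "library",
             "count_modified", "count_unmodified")
  })
}

#' Write / read spike-in count tables
#'
#' @param spikeins tibble from [simulate_spikeins()].
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_spikein_tsv <- function(spikeins, path) {
  readr::write_tsv(spikeins, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_spikein_tsv
#' @export
read_spikein_tsv <- function(path) {
  readr::read_tsv(path, col_types = "ciccii", progress = FALSE)
}
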