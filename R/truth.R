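#' Annotate cytosine sites with methylome compartments
#'
#' Enumerates all cytosine sites of a reference and flags, for each CG
#' site, the compartment that sets its baseline truth mean (CpG-island
#' interior > repeat > background, in that precedence) plus membership in
#' CGI shores/shelves and promoter TSS+/-1 kb windows (where the aging
#' effects act).
#'
#' @param reference an `oxbs_reference` with annotations.
#' @param shore_width,shelf_width flank widths used for the shore/shelf
#'   membership flags.
#' @return sites tibble from [cytosine_sites()] plus `compartment`,
#'   `in_shore_shelf`, `in_promoter_1kb`.
#' @export
annotate_sites <- function(reference, shore_width = 2000, shelf_width = 2000) {
  sites <- cytosine_sites(reference)
  ann <- reference$annotations
  if (is.null(ann)) abort("reference carries no annotations")
  flag <- function(regions) {
    if (!nrow(regions)) return(rep(FALSE, nrow(sites)))
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos + 1L, width = 1L))
    reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                     IRanges::IRanges(regions$start + 1L,
                                                      regions$end))
    IRanges::overlapsAny(site_gr, reg_gr)
  }
  cgis <- ann |> filter(.data$type == "cgi")
  reps <- ann |> filter(.data$type == "repeat")
  proms <- ann |> filter(.data$type == "promoter")
  in_cgi <- flag(cgis)
  in_rep <- flag(reps)
  shores <- if (nrow(cgis)) {
    derive_flanks(cgis, shore_width, shelf_width, reference$chrom_lengths) |>
      filter(.data$type != "island")
  } else cgis
  prom1kb <- proms |>
    mutate(start = .data$tss - 1000L, end = .data$tss + 1000L) |>
    filter(.data$start >= 0)
  sites |>
    mutate(compartment = ifelse(in_cgi, "cgi",
                                ifelse(in_rep, "repeat", "background")),
           in_shore_shelf = flag(shores),
           in_promoter_1kb = flag(prom1kb))
}

# Background-compartment CG means calibrated so that the CG-site-weighted
# mixture over background / CGI-interior / repeat compartments matches the
# profile's genome-wide targets in expectation (computed over autosomes).
calibrate_background <- function(sites, profile) {
  cg <- sites |>
    filter(.data$context_class == "CG",
           chrom_class_of(.data$chrom) == "autosomes")
  n <- table(factor(cg$compartment, c("background", "cgi", "repeat")))
  solve1 <- function(target, cgi_mean, rep_mean) {
    bg <- (target * sum(n) - cgi_mean * n[["cgi"]] - rep_mean * n[["repeat"]]) /
      n[["background"]]
    min(max(bg, 0), 1)
  }
  list(m = solve1(profile$mcg, profile$cgi_mcg, profile$repeat_mcg),
       h = solve1(profile$hmcg, profile$cgi_hmcg, profile$repeat_hmcg))
}

#' Per-site truth means for one sample
#'
#' Builds the mean (m, h) surface for a sample of given sex and age:
#' compartment baselines (calibrated background, CGI interior, repeat) for
#' CG sites, uniform CH targets, plus the chrX sex effects and the aging
#' effects (old vs young: +`age_shore_shelf_hmcg` hmCG in shores/shelves;
#' `age_promoter_mcg` mCG in male promoter TSS+/-1 kb windows). Means are
#' clipped to `[0, 1]` and to `m + h <= 1`; a warning reports how many
#' sites were clipped.
#'
#' @param sites annotated sites from [annotate_sites()].
#' @param profile an [hippocampus_profile()].
#' @param sex,age the sample's factor levels.
#' @param background optional precomputed [calibrate_background()] result.
#' @return `sites` with `m_mean`, `h_mean` columns.
#' @export
truth_means <- function(sites, profile, sex, age,
                        background = NULL) {
  bg <- background %||% calibrate_background(sites, profile)
  is_cg <- sites$context_class == "CG"
  m <- ifelse(is_cg,
              ifelse(sites$compartment == "cgi", profile$cgi_mcg,
                     ifelse(sites$compartment == "repeat", profile$repeat_mcg,
                            bg$m)),
              profile$mch)
  h <- ifelse(is_cg,
              ifelse(sites$compartment == "cgi", profile$cgi_hmcg,
                     ifelse(sites$compartment == "repeat", profile$repeat_hmcg,
                            bg$h)),
              profile$hmch)
  on_x <- sites$chrom == "chrX" & is_cg
  if (sex == "female") m <- m + on_x * profile$chrx_female_mcg
  if (sex == "male") h <- h + on_x * profile$chrx_male_hmcg
  if (age == "old") {
    h <- h + (is_cg & sites$in_shore_shelf) * profile$age_shore_shelf_hmcg
    if (sex == "male") {
      m <- m + (is_cg & sites$in_promoter_1kb) * profile$age_promoter_mcg
    }
  }
  m2 <- pmin(pmax(m, 0), 1)
  h2 <- pmin(pmax(h, 0), 1)
  over <- m2 + h2 > 1
  h2[over] <- 1 - m2[over]
  n_clip <- sum(abs(m2 - m) > 1e-9 | abs(h2 - h) > 1e-9)
  if (n_clip > 0) {
    warn(sprintf("%d site means clipped to keep (m, h) in the simplex", n_clip))
  }
  sites |> mutate(m_mean = m2, h_mean = h2)
}

# Beta draw around mean mu with given concentration; point mass at the
# mean when concentration is infinite or mu is degenerate.
draw_beta <- function(mu, concentration) {
  if (!is.finite(concentration)) return(mu)
  x <- mu
  mid <- mu > 0 & mu < 1
  x[mid] <- rbeta(sum(mid), mu[mid] * concentration,
                  (1 - mu[mid]) * concentration)
  x
}

draw_sample_truth <- function(site_means, concentration, seed, sample_id) {
  with_substream(seed, "truth", sample_id, expr = {
    m <- draw_beta(site_means$m_mean, concentration)
    h <- draw_beta(site_means$h_mean, concentration)
    tot <- m + h
    over <- tot > 1
    m[over] <- m[over] / tot[over]
    h[over] <- h[over] / tot[over]
    site_means |> mutate(m_true = m, h_true = h)
  })
}

#' Assign per-sample methylome truth
#'
#' Draws per-site true (m, h) fractions for every sample in the design:
#' Beta-distributed around the sample's [truth_means()] surface with the
#' profile's concentration (point mass in the infinite-concentration
#' limit). Draws exceeding `m + h = 1` are renormalized onto the simplex.
#' Female samples carry no chrY sites.
#'
#' @param reference an `oxbs_reference` with annotations.
#' @param profile an [hippocampus_profile()].
#' @param design a [sample_design()] tibble.
#' @param seed integer seed; each sample uses an independent substream.
#' @param sites optional precomputed [annotate_sites()] result.
#' @return named list (by `sample_id`) of truth tibbles with `m_true`,
#'   `h_true`.
#' @export
assign_truth <- function(reference, profile = hippocampus_profile(),
                         design = sample_design(), seed = 1, sites = NULL) {
  sites <- sites %||% annotate_sites(reference)
  bg <- calibrate_background(sites, profile)
  out <- purrr::pmap(design, function(sample_id, sex, age, ...) {
    s <- if (sex == "female") sites |> filter(.data$chrom != "chrY") else sites
    means <- truth_means(s, profile, sex, age, background = bg)
    draw_sample_truth(means, profile$concentration, seed, sample_id)
  })
  setNames(out, design$sample_id)
}
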