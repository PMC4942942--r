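#' Simulation configuration for the synthetic methylome
#'
#' Defaults describe a compact mock genome: three 300-kb autosomes plus a
#' 200-kb chrX and a 100-kb chrY (~1.2 Mb total, roughly 1e5 CG sites both
#' strands), with 60 CpG islands, 60 promoters and a 5% repeat fraction.
#' This is large enough that binomial sampling error on pooled CG levels is
#' well under one percentage point at 10x coverage, while a full 12-sample
#' simulation stays in the minutes range on one core.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#'   Autosomes are any name that is not `chrX`/`chrY`.
#' @param n_cgi number of CpG islands to place (distributed over chromosomes
#'   proportionally to length).
#' @param cgi_length_range min/max island length in bp.
#' @param cgi_cg_prob probability that a dinucleotide inside an island is CG;
#'   0.4 gives ~3.4x the background CG density of a uniform-random sequence.
#' @param n_promoters number of promoters (TSS positions with strand).
#' @param repeat_fraction fraction of each chromosome covered by repeat
#'   elements (background sequence composition, hypermethylated truth).
#' @param repeat_length repeat element length in bp.
#' @param promoter_flank promoter half-width around the TSS in bp.
#' @param shore_width,shelf_width CGI shore (0-2 kb) and shelf (2-4 kb)
#'   widths in bp.
#' @return a list of class `oxbs_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 3e5, chr2 = 3e5, chr3 = 3e5,
                                         chrX = 2e5, chrY = 1e5),
                       n_cgi = 60,
                       cgi_length_range = c(500, 1500),
                       cgi_cg_prob = 0.4,
                       n_promoters = 60,
                       repeat_fraction = 0.05,
                       repeat_length = 1500,
                       promoter_flank = 2000,
                       shore_width = 2000,
                       shelf_width = 2000) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            n_cgi >= 0, n_promoters >= 0,
            repeat_fraction >= 0, repeat_fraction < 1,
            cgi_cg_prob > 0, cgi_cg_prob <= 1)
  max_elem <- max(cgi_length_range[2], repeat_length, 2 * promoter_flank)
  flank <- shore_width + shelf_width
  if (any(chrom_lengths < 2 * (flank + max_elem))) {
    abort(paste0("every chromosome must be at least 2 x (flank width + max ",
                 "element length) = ", 2 * (flank + max_elem), " bp long"))
  }
  structure(list(chrom_lengths = chrom_lengths,
                 n_cgi = n_cgi,
                 cgi_length_range = cgi_length_range,
                 cgi_cg_prob = cgi_cg_prob,
                 n_promoters = n_promoters,
                 repeat_fraction = repeat_fraction,
                 repeat_length = repeat_length,
                 promoter_flank = promoter_flank,
                 shore_width = shore_width,
                 shelf_width = shelf_width),
            class = "oxbs_config")
}

#' Conversion-chemistry parameters
#'
#' Per-molecule probabilities of the bisulfite / oxidation chemistry:
#' `beta` is the bisulfite conversion probability of an unmodified cytosine,
#' `omega` the oxidation probability of 5hmC to 5fC in the oxBS reaction, and
#' `eps_m`/`eps_h` the inappropriate-conversion probabilities of 5mC and
#' 5hmC under bisulfite alone. Defaults (beta = 0.995, omega = 0.975) sit
#' just above the >99% / >97% rates typically required of the assay.
#'
#' @param beta,omega,eps_m,eps_h probabilities in \[0, 1\].
#' @return a list of class `oxbs_chemistry`.
#' @export
chemistry_params <- function(beta = 0.995, omega = 0.975, eps_m = 0, eps_h = 0) {
  p <- c(beta = beta, omega = omega, eps_m = eps_m, eps_h = eps_h)
  if (any(p < 0 | p > 1)) abort("chemistry probabilities must lie in [0, 1]")
  structure(as.list(p), class = "oxbs_chemistry")
}

#' Hippocampus-like methylome profile
#'
#' Compartment-level targets emulating adult mouse hippocampus: high genomic
#' mCG (~50%), substantial hmCG (~15%), very low CH-context modification,
#' hypomethylated CpG-island interiors, hypermethylated repeats, a small
#' female excess of chrX mCG and male excess of chrX hmCG, and aging effects
#' (old vs young): +3 points hmCG in CGI shores/shelves and -1.5 points mCG
#' in promoter TSS+/-1 kb windows of males.
#'
#' `mcg` and `hmcg` are genome-wide pooled CG targets; the background
#' compartment mean is calibrated at truth-assignment time so that the
#' CG-site-weighted mixture of background, CGI-interior and repeat
#' compartments matches them in expectation.
#'
#' @param mcg,hmcg genome-wide CG-context 5mC and 5hmC targets.
#' @param mch,hmch CH-context targets (uniform across the genome).
#' @param cgi_mcg,cgi_hmcg CpG-island interior CG targets.
#' @param repeat_mcg,repeat_hmcg repeat-element CG targets.
#' @param chrx_female_mcg female chrX mCG excess.
#' @param chrx_male_hmcg male chrX hmCG excess.
#' @param age_shore_shelf_hmcg old-vs-young hmCG excess in shores/shelves.
#' @param age_promoter_mcg old-vs-young mCG shift in promoter TSS+/-1 kb
#'   windows (applied to males).
#' @param concentration Beta concentration of per-site, per-sample truth
#'   draws around the compartment mean; `Inf` gives point-mass truth.
#' @return a list of class `oxbs_profile`.
#' @export
hippocampus_profile <- function(mcg = 0.50, hmcg = 0.15,
                                mch = 0.005, hmch = 0.0005,
                                cgi_mcg = 0.05, cgi_hmcg = 0.02,
                                repeat_mcg = 0.95, repeat_hmcg = 0.02,
                                chrx_female_mcg = 0.02,
                                chrx_male_hmcg = 0.02,
                                age_shore_shelf_hmcg = 0.03,
                                age_promoter_mcg = -0.015,
                                concentration = 20) {
  targets <- c(mcg, hmcg, mch, hmch, cgi_mcg, cgi_hmcg, repeat_mcg, repeat_hmcg)
  if (any(targets < 0 | targets > 1)) abort("profile targets must lie in [0, 1]")
  if (concentration <= 0) abort("concentration must be positive")
  structure(list(mcg = mcg, hmcg = hmcg, mch = mch, hmch = hmch,
                 cgi_mcg = cgi_mcg, cgi_hmcg = cgi_hmcg,
                 repeat_mcg = repeat_mcg, repeat_hmcg = repeat_hmcg,
                 chrx_female_mcg = chrx_female_mcg,
                 chrx_male_hmcg = chrx_male_hmcg,
                 age_shore_shelf_hmcg = age_shore_shelf_hmcg,
                 age_promoter_mcg = age_promoter_mcg,
                 concentration = concentration),
            class = "oxbs_profile")
}

#' Balanced sex-by-age sample design
#'
#' @param n_per_cell replicates per sex-by-age cell (default 3, i.e. 12
#'   samples for two ages).
#' @param ages age levels; two by default, a third (`"adult"`) is supported.
#' @param sexes sex levels.
#' @return tibble with `sample_id`, `sex`, `age`, `replicate`.
#' @export
sample_design <- function(n_per_cell = 3,
                          ages = c("young", "old"),
                          sexes = c("female", "male")) {
  stopifnot(n_per_cell >= 1)
  tidyr::expand_grid(sex = sexes, age = ages, replicate = seq_len(n_per_cell)) |>
    mutate(sample_id = sprintf("s_%s_%s_%d", substr(.data$sex, 1, 1),
                               .data$age, .data$replicate)) |>
    select("sample_id", "sex", "age", "replicate")
}
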