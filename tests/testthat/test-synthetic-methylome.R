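test_that("reference generation is deterministic and emits byte-identical files", {
  cfg <- tiny_config()
  ref1 <- build_reference(cfg, seed = 3)
  ref2 <- build_reference(cfg, seed = 3)
  expect_identical(ref1$genome, ref2$genome)
  expect_identical(ref1$annotations, ref2$annotations)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- file.path(d1, "ref.fa"); f2 <- file.path(d2, "ref.fa")
  write_reference_fasta(ref1, f1); write_reference_fasta(ref2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  b1 <- write_annotation_bed(ref1$annotations, d1)
  b2 <- write_annotation_bed(ref2$annotations, d2)
  expect_identical(unname(tools::md5sum(b1)), unname(tools::md5sum(b2)))

  # different seed changes the sequence
  expect_false(identical(build_reference(cfg, seed = 4)$genome, ref1$genome))
})

test_that("CG sites are palindromic and islands are CG-dense (from emitted FASTA)", {
  ref <- tiny_reference()
  dir <- withr::local_tempdir()
  write_reference_fasta(ref, file.path(dir, "ref.fa"))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "ref.fa"))

  for (i in seq_along(seqs)) {
    n_cg <- Biostrings::countPattern("CG", seqs[[i]])
    sites <- cytosine_sites(setNames(as.character(seqs[i]), names(seqs)[i])) |>
      filter(context == "CG")
    expect_equal(sum(sites$strand == "+"), n_cg)
    expect_equal(sum(sites$strand == "-"), n_cg)
  }

  # island CG density >= 3x genome background, counted on the FASTA directly
  cgis <- ref$annotations |> filter(type == "cgi")
  cg_in <- sum(purrr::pmap_int(cgis, function(chrom, start, end, ...) {
    Biostrings::countPattern("CG", Biostrings::subseq(seqs[[chrom]], start + 1, end))
  }))
  bp_in <- sum(cgis$end - cgis$start)
  cg_tot <- sum(vapply(seq_along(seqs), function(i)
    Biostrings::countPattern("CG", seqs[[i]]), 0L))
  bp_tot <- sum(Biostrings::width(seqs))
  background <- (cg_tot - cg_in) / (bp_tot - bp_in)
  expect_gte(cg_in / bp_in, 3 * background)
})

test_that("chromosomes shorter than flanks + elements are a configuration error", {
  expect_error(sim_config(chrom_lengths = c(chr1 = 5000)), "element length")
})

test_that("truth assignment hits compartment targets, effects, and the point-mass limit", {
  # point-mass limit on a background-only genome
  cfg0 <- sim_config(chrom_lengths = c(chr1 = 5e4, chrX = 3e4, chrY = 2e4),
                     n_cgi = 0, n_promoters = 2, repeat_fraction = 0)
  ref0 <- build_reference(cfg0, seed = 5)
  prof0 <- hippocampus_profile(concentration = Inf)
  truth <- assign_truth(ref0, prof0, sample_design(n_per_cell = 1), seed = 1)
  yf <- truth$s_f_young_1 |> filter(chrom == "chr1", context_class == "CG")
  expect_true(all(yf$m_true == 0.50))
  expect_true(all(yf$h_true == 0.15))

  # injected age effect: +0.03 shore/shelf hmCG in expectation (by averaging truth)
  ref <- tiny_reference()
  sites <- annotate_sites(ref)
  young <- truth_means(sites, hippocampus_profile(), "female", "young")
  old <- truth_means(sites, hippocampus_profile(), "female", "old")
  ss <- sites$in_shore_shelf & sites$context_class == "CG"
  expect_equal(mean(old$h_mean[ss]) - mean(young$h_mean[ss]), 0.03,
               tolerance = 1e-12)

  # chrX sex effects
  on_x <- sites$chrom == "chrX" & sites$context_class == "CG"
  fem <- truth_means(sites, hippocampus_profile(), "female", "young")
  mal <- truth_means(sites, hippocampus_profile(), "male", "young")
  expect_equal(mean(fem$m_mean[on_x]) - mean(mal$m_mean[on_x]), 0.02,
               tolerance = 1e-12)
  expect_equal(mean(mal$h_mean[on_x]) - mean(fem$h_mean[on_x]), 0.02,
               tolerance = 1e-12)

  # Beta sampling: genome-wide autosomal CG mean within 3 SE of the target
  tr <- oxbsq:::draw_sample_truth(young, 20, seed = 7, "s")
  cg <- tr |> filter(chrom == "chr1", context_class == "CG")
  expect_gt(nrow(cg), 5e3)
  se <- sqrt(0.5 * 0.5 / (20 + 1) / nrow(cg))
  expect_lt(abs(mean(cg$m_true) - 0.50), 3 * se + 0.002) # small calibration offset
  expect_true(all(tr$m_true + tr$h_true <= 1 + 1e-9))
})

test_that("count simulation follows the chemistry forward model", {
  # degenerate chemistry: fully methylated site is always read C in BS
  s1 <- tibble(chrom = "c", pos = 0L, strand = "+", context = "CG",
               trinucleotide = "CGA", context_class = "CG",
               m_true = 1, h_true = 0)
  chem1 <- chemistry_params(beta = 1, omega = 1)
  cts <- simulate_counts(s1, chem1, coverage = 10, seed = 1)
  expect_equal(cts$bs_u, 0L)
  expect_equal(cts$ox_u, 0L)

  # perfect oxidation converts all hmC in oxBS only
  s2 <- s1 |> mutate(m_true = 0, h_true = 1)
  cts2 <- simulate_counts(s2, chem1, coverage = 10, seed = 2)
  expect_equal(cts2$bs_u, 0L)
  expect_equal(cts2$ox_m, 0L)

  # closed-form P_C and Monte-Carlo agreement
  expect_equal(conversion_prob(0.5, 0.15, chemistry_params(0.99, 0.97), "BS"),
               0.6535)
  expect_equal(conversion_prob(0.5, 0.15, chemistry_params(0.99, 0.97), "oxBS"),
               0.509455)
  n_sites <- 1e5
  s3 <- tibble(chrom = "c", pos = seq_len(n_sites) * 2L, strand = "+",
               context = "CG", trinucleotide = "CGA", context_class = "CG",
               m_true = 0.5, h_true = 0.15)
  cts3 <- simulate_counts(s3, chemistry_params(0.99, 0.97), coverage = 10,
                          seed = 3)
  for (lib in c("bs", "ox")) {
    p <- if (lib == "bs") 0.6535 else 0.509455
    reads <- sum(cts3[[paste0(lib, "_m")]] + cts3[[paste0(lib, "_u")]])
    frac <- sum(cts3[[paste0(lib, "_m")]]) / reads
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / reads))
  }

  # invariant breach upstream is a hard error
  expect_error(simulate_counts(s1 |> mutate(m_true = 0.8, h_true = 0.4),
                               chem1, 10, 1), "m_true")
})

test_that("count tables round-trip through cytosine reports", {
  ref <- tiny_reference()
  truth <- flat_truth(ref)
  cts <- simulate_counts(truth, coverage = 3, seed = 9) |> head(500)
  dir <- withr::local_tempdir()
  write_cytosine_report(cts, "BS", file.path(dir, "bs.tsv"))
  write_cytosine_report(cts, "oxBS", file.path(dir, "ox.tsv"))
  back <- pair_counts(read_cytosine_report(file.path(dir, "bs.tsv")),
                      read_cytosine_report(file.path(dir, "ox.tsv")))
  expect_equal(back |> select(chrom, pos, strand, bs_m, bs_u, ox_m, ox_u),
               cts |> select(chrom, pos, strand, bs_m, bs_u, ox_m, ox_u),
               ignore_attr = TRUE)
})

test_that("spike-in simulation matches the chemistry rates", {
  # beta = 1: every unmodified-C read is converted
  sp1 <- simulate_spikeins(chemistry_params(beta = 1), depth = 1000, seed = 1)
  un <- sp1 |> filter(site_class == "unmodified")
  expect_true(all(un$count_modified == 0))
  # eps_m = 0: zero T calls at mC sites in BS
  mc <- sp1 |> filter(site_class == "mC", library == "BS")
  expect_true(all(mc$count_unmodified == 0))
  # hmC sites in oxBS convert at omega * beta = 0.970125
  sp2 <- simulate_spikeins(chemistry_params(), depth = 1e5, seed = 2)
  hm <- sp2 |> filter(site_class == "hmC", library == "oxBS")
  tf <- sum(hm$count_unmodified) / sum(hm$count_unmodified + hm$count_modified)
  p <- 0.975 * 0.995
  expect_lt(abs(tf - p), 3 * sqrt(p * (1 - p) / 1e5))
  # site classes are disjoint and exhaustive
  expect_equal(sort(unique(sp1$site_class)), c("hmC", "mC", "unmodified"))
  expect_equal(nrow(sp1 |> distinct(seq_name, site_class)), 3)
})

test_that("assay simulators behave as specified", {
  # qPCR: perfect doubling adds one Ct per halving; noiseless is deterministic
  d2 <- simulate_qpcr_dilution(2, 20, quantities = c(1000, 500, 250, 125))
  expect_equal(diff(d2$ct), c(1, 1, 1))
  d75a <- simulate_qpcr_dilution(1.75, 25)
  d75b <- simulate_qpcr_dilution(1.75, 25)
  expect_identical(d75a, d75b)
  expect_equal(fit_efficiency(d75a)$efficiency, 0.75, tolerance = 1e-12)

  # dPCR occupancy
  dp <- simulate_dpcr(log(2), 20000, seed = 1)
  expect_lt(abs(dp$positives - 10000), 3 * sqrt(20000 * 0.25))
  expect_equal(simulate_dpcr(0, 1000, seed = 1)$positives, 0)
  expect_equal(20000 * exp(-9.9), 1.0, tolerance = 0.01)

  # ELISA: matched calibration recovers the true level; plates deterministic
  pl <- simulate_elisa(0.42, sample_density = 0.05, standard_density = 0.05)
  est <- elisa_quantify(pl |> filter(role == "standard"),
                        pl$absorbance[pl$role == "sample"],
                        density_ratio = attr(pl, "density_ratio"))
  expect_equal(est$corrected_mean[1], 42, tolerance = 1e-9)
  expect_identical(simulate_elisa(0.3, seed = 5), simulate_elisa(0.3, seed = 5))
})

test_that("read simulation is deterministic and hits the configured noise rate", {
  ref <- build_reference(sim_config(chrom_lengths = c(chr1 = 9500),
                                    n_cgi = 1, n_promoters = 1,
                                    cgi_length_range = c(300, 500),
                                    promoter_flank = 500,
                                    shore_width = 500, shelf_width = 500),
                         seed = 2)
  truth <- flat_truth(ref)
  rd1 <- simulate_reads(ref, truth, read_length = 50, coverage = 2, seed = 4)
  rd2 <- simulate_reads(ref, truth, read_length = 50, coverage = 2, seed = 4)
  expect_identical(rd1, rd2)
  dir <- withr::local_tempdir()
  write_fastq_pair(rd1, file.path(dir, "a1.fq.gz"), file.path(dir, "a2.fq.gz"))
  write_fastq_pair(rd2, file.path(dir, "b1.fq.gz"), file.path(dir, "b2.fq.gz"))
  r1 <- read_fastq_pair(file.path(dir, "a1.fq.gz"), file.path(dir, "a2.fq.gz"))
  expect_equal(r1 |> arrange(id, mate), rd1 |> arrange(id, mate))

  expect_error(simulate_reads(ref, truth, read_length = 5), "exhaust")

  # fraction of mates with >= 2 N within 3 SE of the binomial expectation
  L <- 60; nf <- 0.5; pr <- 0.05
  rd <- simulate_reads(ref, truth, read_length = L, coverage = 12, seed = 6,
                       noise_frac = nf, n_rate = pr)
  n_n <- stringr::str_count(rd$seq, "N")
  p2 <- nf * (1 - (1 - pr)^L - L * pr * (1 - pr)^(L - 1))
  expect_lt(abs(mean(n_n >= 2) - p2), 3 * sqrt(p2 * (1 - p2) / nrow(rd)))
})
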