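test_that("shore and shelf intervals follow the 0-2 / 2-4 kb convention", {
  cgi <- tibble(chrom = "chr1", start = 10000L, end = 10500L, name = "cgi_1")
  fl <- derive_flanks(cgi, 2000, 2000, c(chr1 = 1e6))
  get <- function(tp) fl |> filter(type == tp)
  expect_equal(c(get("shore_up")$start, get("shore_up")$end), c(8000, 10000))
  expect_equal(c(get("shelf_up")$start, get("shelf_up")$end), c(6000, 8000))
  expect_equal(c(get("shore_down")$start, get("shore_down")$end), c(10500, 12500))
  expect_equal(c(get("shelf_down")$start, get("shelf_down")$end), c(12500, 14500))
  expect_false(any(fl$truncated))

  # island at the chromosome start: upstream flanks truncated and flagged
  near0 <- tibble(chrom = "chr1", start = 500L, end = 900L, name = "cgi_1")
  fl0 <- derive_flanks(near0, 2000, 2000, c(chr1 = 1e6))
  sh <- fl0 |> filter(type == "shore_up")
  expect_equal(c(sh$start, sh$end), c(0, 500))
  expect_true(sh$truncated)
  expect_equal(nrow(fl0 |> filter(type == "shelf_up")), 0)

  # two islands 3 kb apart: intervening flanks split at the midpoint
  two <- tibble(chrom = "chr1", start = c(10000L, 13500L),
                end = c(10500L, 14000L), name = c("a", "b"))
  fl2 <- derive_flanks(two, 2000, 2000, c(chr1 = 1e6))
  mid <- (10500 + 13500) / 2
  a_down <- fl2 |> filter(element == "a", type == "shore_down")
  b_up <- fl2 |> filter(element == "b", type == "shore_up")
  expect_equal(a_down$end, mid)
  expect_equal(b_up$start, mid)
  expect_true(a_down$truncated)
  expect_error(derive_flanks(two, -1, 2000), "non-negative")
})

test_that("promoter bins tile the flank exactly, with strand mirroring", {
  prom <- tibble(chrom = "chr1", tss = 10000L,
                 strand = c("+", "-"), name = c("p_plus", "p_minus"))
  bins <- promoter_bins(prom, flank = 2000, bin_width = 100)
  plus <- bins |> filter(element == "p_plus")
  expect_equal(plus |> filter(bin == -1) |> (\(d) c(d$start, d$end))(),
               c(9900, 10000))
  expect_equal(plus |> filter(bin == 1) |> (\(d) c(d$start, d$end))(),
               c(10000, 10100))
  minus <- bins |> filter(element == "p_minus")
  expect_equal(minus |> filter(bin == 1) |> (\(d) c(d$start, d$end))(),
               c(9900, 10000))
  # 40 bins x 100 bp = 2 x flank, and the tiling is gapless and disjoint
  for (el in c("p_plus", "p_minus")) {
    b <- bins |> filter(element == el) |> arrange(start)
    expect_equal(nrow(b), 40)
    expect_equal(sum(b$end - b$start), 4000)
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  }
})

test_that("CGI profile bins tile each flank without gaps or overlap", {
  cgis <- tiny_reference()$annotations |> filter(type == "cgi")
  bins <- cgi_profile_bins(cgis, flank = 4000, bin_width = 200,
                           chrom_lengths = tiny_reference()$chrom_lengths)
  expect_true(all(bins$end - bins$start == 200 | bins$bin == 0))
  for (el in unique(bins$element)) {
    up <- bins |> filter(element == el, bin < 0) |> arrange(start)
    if (nrow(up) == 20) {
      expect_true(all(up$start[-1] == up$end[-nrow(up)]))
      expect_equal(up$end[nrow(up)],
                   cgis$start[match(el, cgis$name)])
    }
  }
})

test_that("meta-profiles recover the U shape and treat empty bins as missing", {
  exp <- default_experiment()
  ref <- exp$reference
  cgis <- ref$annotations |> filter(type == "cgi")
  # rebuild one sample's counts at the default profile
  sites <- annotate_sites(ref)
  means <- truth_means(sites, hippocampus_profile(), "female", "young")
  truth <- oxbsq:::draw_sample_truth(means, 20, 42, "prof")
  cts <- simulate_counts(truth, coverage = 10, seed = 77)
  prof <- profile_elements(cts, cgi_profile_bins(cgis, chrom_lengths = ref$chrom_lengths))
  body <- prof$mc[prof$bin == 0]
  shore_bins <- prof$mc[abs(prof$bin) <= 10 & prof$bin != 0]
  shelf_bins <- prof$mc[abs(prof$bin) > 10]
  expect_lt(body, mean(shore_bins))
  expect_lt(body, mean(shelf_bins))

  # single element, one fully covered bin at level 0.3
  one <- tibble(chrom = "c", pos = c(10L, 20L), strand = "+", context = "CG",
                context_class = "CG", trinucleotide = "CGA",
                bs_m = 3L, bs_u = 7L, ox_m = 3L, ox_u = 7L)
  reg <- tibble(chrom = "c", start = 0L, end = 100L, type = "cgi_bin",
                element = "e1", bin = 1L)
  p1 <- profile_elements(one, reg)
  expect_equal(p1$mc, 0.3)
  expect_equal(p1$n_elements, 1L)

  # an uncovered element does not drag the bin mean toward zero
  reg2 <- bind_rows(reg, reg |> mutate(element = "e2", chrom = "other"))
  p2 <- profile_elements(one, reg2)
  expect_equal(p2$n_elements, 1L)
  expect_equal(p2$mc, 0.3)
  expect_error(profile_elements(one, reg[0, ]), "empty")
})

test_that("meta-profile is symmetric around elements under symmetric truth", {
  exp <- default_experiment()
  ref <- exp$reference
  cgis <- ref$annotations |> filter(type == "cgi")
  sites <- cytosine_sites(ref) |> mutate(m_true = 0.5, h_true = 0.1)
  cts <- simulate_counts(sites, coverage = 10, seed = 88)
  prof <- profile_elements(cts, cgi_profile_bins(cgis, chrom_lengths = ref$chrom_lengths))
  up <- prof |> filter(bin < 0) |> arrange(-abs(bin)) |> pull(mc)
  down <- prof |> filter(bin > 0) |> arrange(abs(bin)) |> pull(mc)
  expect_gt(stats::t.test(up, down, paired = TRUE)$p.value, 0.01)
})

test_that("region aggregates equal a brute-force site-membership scan", {
  ref <- tiny_reference()
  cgis <- ref$annotations |> filter(type == "cgi")
  fl <- derive_flanks(cgis, 2000, 2000, ref$chrom_lengths)
  truth <- flat_truth(ref, 0.5, 0.1)
  cts <- simulate_counts(truth, coverage = 5, seed = 55)
  agg <- region_aggregates(cts, fl)
  # brute force: loop regions, scan sites by coordinates
  cg <- cts |> filter(context_class == "CG")
  for (tp in unique(agg$type)) {
    rows <- fl |> filter(type == tp)
    hit <- logical(nrow(cg))
    for (i in seq_len(nrow(rows))) {
      hit <- hit | (cg$chrom == rows$chrom[i] & cg$pos >= rows$start[i] &
                      cg$pos < rows$end[i])
    }
    # sites in overlapping regions of the same class count once per region;
    # flanks from derive_flanks are disjoint within a class, so once total
    sub <- cg[hit, ]
    expect_equal(agg$level_ox[agg$type == tp],
                 sum(sub$ox_m) / sum(sub$ox_m + sub$ox_u))
  }

  # aging signal: old-minus-young shore hmC difference is positive
  exp <- default_experiment()
  shores <- exp$region_summary |>
    filter(type %in% c("shore_up", "shore_down", "shelf_up", "shelf_down")) |>
    group_by(age) |>
    summarise(hmc = mean(hmc))
  expect_gt(shores$hmc[shores$age == "old"], shores$hmc[shores$age == "young"])
})

test_that("repeat surrogate exceeds the genome-wide BS level on hypermethylated repeats", {
  ref <- tiny_reference()
  reps <- ref$annotations |> filter(type == "repeat")
  sites <- annotate_sites(ref)
  # hypermethylated repeats
  truth <- sites |>
    mutate(m_true = ifelse(compartment == "repeat" & context_class == "CG",
                           0.95, 0.5),
           h_true = 0.02)
  cts <- simulate_counts(truth, coverage = 10, seed = 66)
  sur <- repeat_surrogate(cts, reps)
  expect_gt(sur$level_bs[sur$region == "repeats"],
            sur$level_bs[sur$region == "genome"])
  expect_gt(sur$level_bs[sur$region == "repeats"], 0.9)

  # null case: repeats at background truth match the genome level
  truth0 <- sites |> mutate(m_true = 0.5, h_true = 0.02)
  cts0 <- simulate_counts(truth0, coverage = 10, seed = 67)
  sur0 <- repeat_surrogate(cts0, reps)
  expect_lt(abs(sur0$level_bs[1] - sur0$level_bs[2]), 0.02)

  # empty annotation: empty output with a warning
  expect_warning(out <- repeat_surrogate(cts0, reps[0, ]), "repeat")
  expect_equal(nrow(out), 0)
})
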