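suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Small genome used by most unit tests: fast to build, still a few
# thousand CG sites.
tiny_config <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 6e4, chrX = 4e4, chrY = 2e4),
             n_cgi = 6, n_promoters = 6, ...)
}

tiny_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference(tiny_config(), seed = 11)
    cache
  }
})

# Uniform point-mass truth over every cytosine of a reference.
flat_truth <- function(reference, m = 0.3, h = 0.2) {
  cytosine_sites(reference) |> mutate(m_true = m, h_true = h)
}

# One default-scale experiment, shared by the acceptance tests (the
# expensive fixture is built once per test run).
default_experiment <- local({
  cache <- NULL
  function() {
    # the default profile clips a few hundred chrX repeat/shore sites where
    # the additive sex + age effects overflow the simplex; that warning is
    # expected at these settings
    if (is.null(cache)) cache <<- suppressWarnings(simulate_experiment(seed = 42))
    cache
  }
})

# Hand-built read record with explicit tags (molecule conventions match
# simulate_reads).
make_read <- function(id, chrom, frag_start, frag_len, strand, lib, mate,
                      seq, qual = NULL, o5 = 0L, o3 = 0L) {
  tibble(id = id, chrom = chrom, frag_start = as.integer(frag_start),
         frag_len = as.integer(frag_len), strand = strand, lib = lib,
         mate = as.integer(mate), o5 = as.integer(o5), o3 = as.integer(o3),
         seq = seq,
         qual = qual %||% paste(rep("I", nchar(seq)), collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
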