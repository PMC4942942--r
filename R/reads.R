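revcomp_chars <- function(ch) rev(unname(comp_base[ch]))

qual_string <- function(q) intToUtf8(pmin(pmax(q, 2), 40) + 33L)

#' Simulate coordinate-tagged paired-end bisulfite reads
#'
#' Fragments are drawn uniformly from both strands; cytosines on the
#' fragment's strand are converted per read according to the chemistry
#' forward model ([conversion_prob()]) for the chosen library. Mate 1 is
#' the first `read_length` bases of the fragment in molecule orientation;
#' mate 2 is the reverse complement of its last `read_length` bases. Read
#' records carry explicit coordinate tags (chromosome, fragment start,
#' fragment length, strand, library, per-mate trim offsets) so that
#' placement is exact without alignment. A configurable fraction of mates
#' is "noisy": low mean quality and a per-base chance of an ambiguous `N`.
#'
#' @param reference an `oxbs_reference`.
#' @param truth truth tibble (`chrom`, `pos`, `strand`, `m_true`,
#'   `h_true`); cytosines absent from it are treated as unmodified.
#' @param chemistry an [chemistry_params()] object.
#' @param library `"BS"` or `"oxBS"`.
#' @param read_length mate length (>= 7; shorter reads would not survive
#'   end trimming).
#' @param coverage target per-base coverage from both mates.
#' @param gap inner gap between mates within the fragment.
#' @param noise_frac fraction of mates that are noisy.
#' @param n_rate per-base N probability within a noisy mate.
#' @param qual_high,qual_low mean Phred quality of clean / noisy mates.
#' @param seed integer seed.
#' @return tibble of read records: `id`, `chrom`, `frag_start`,
#'   `frag_len`, `strand`, `lib`, `mate`, `o5`, `o3`, `seq`, `qual`.
#' @export
simulate_reads <- function(reference, truth, chemistry = chemistry_params(),
                           library = c("BS", "oxBS"), read_length = 75,
                           coverage = 2, gap = 40, noise_frac = 0,
                           n_rate = 0.02, qual_high = 37, qual_low = 12,
                           seed = 1) {
  library <- match.arg(library)
  if (read_length < 7) abort("read_length < 7: trimming would exhaust the read")
  with_substream(seed, "reads", library, expr = {
    genome <- reference$genome
    frag_len <- 2 * read_length + gap
    rows <- list()
    counter <- 0
    for (chrom in names(genome)) {
      ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
      L <- length(ch)
      if (L < frag_len) next
      # strand-keyed truth lookups
      tt <- truth |> filter(.data$chrom == !!chrom)
      mP <- hP <- mM <- hM <- numeric(L)
      tp <- tt |> filter(.data$strand == "+")
      tm <- tt |> filter(.data$strand == "-")
      mP[tp$pos + 1] <- tp$m_true; hP[tp$pos + 1] <- tp$h_true
      mM[tm$pos + 1] <- tm$m_true; hM[tm$pos + 1] <- tm$h_true
      n_frag <- max(1, round(coverage * L / (2 * read_length)))
      starts <- sample.int(L - frag_len + 1, n_frag, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n_frag, replace = TRUE)
      for (f in seq_len(n_frag)) {
        fs <- starts[f]; sg <- strands[f]
        seg <- ch[(fs + 1):(fs + frag_len)]
        mol <- if (sg == "+") seg else revcomp_chars(seg)
        cpos <- which(mol == "C")
        if (length(cpos)) {
          j0 <- cpos - 1L
          refpos <- if (sg == "+") fs + j0 else fs + frag_len - 1L - j0
          m <- if (sg == "+") mP[refpos + 1] else mM[refpos + 1]
          h <- if (sg == "+") hP[refpos + 1] else hM[refpos + 1]
          p_c <- conversion_prob(m, h, chemistry, library)
          converted <- runif(length(cpos)) >= p_c
          mol[cpos[converted]] <- "T"
        }
        r1 <- mol[1:read_length]
        r2 <- revcomp_chars(mol[(frag_len - read_length + 1):frag_len])
        counter <- counter + 1
        id <- sprintf("r%07d", counter)
        for (mate in 1:2) {
          sq <- if (mate == 1) r1 else r2
          noisy <- runif(1) < noise_frac
          qmean <- if (noisy) qual_low else qual_high
          q <- round(rnorm(read_length, qmean, 2))
          if (noisy && n_rate > 0) {
            nmask <- runif(read_length) < n_rate
            sq[nmask] <- "N"
            q[nmask] <- 2
          }
          rows[[length(rows) + 1]] <- tibble(
            id = id, chrom = chrom, frag_start = fs, frag_len = frag_len,
            strand = sg, lib = library, mate = mate, o5 = 0L, o3 = 0L,
            seq = paste(sq, collapse = ""), qual = qual_string(q))
        }
      }
    }
    bind_rows(rows)
  })
}

encode_read_name <- function(reads) {
  paste(reads$id, reads$chrom, reads$frag_start, reads$frag_len,
        reads$strand, reads$lib, reads$mate, reads$o5, reads$o3, sep = "|")
}

decode_read_name <- function(names) {
  parts <- stringr::str_split_fixed(names, stringr::fixed("|"), 9)
  tibble(id = parts[, 1], chrom = parts[, 2],
         frag_start = as.integer(parts[, 3]),
         frag_len = as.integer(parts[, 4]),
         strand = parts[, 5], lib = parts[, 6],
         mate = as.integer(parts[, 7]),
         o5 = as.integer(parts[, 8]), o3 = as.integer(parts[, 9]))
}

#' Write / read a coordinate-tagged FASTQ pair
#'
#' Read names carry the full coordinate tag (`id|chrom|start|fraglen|
#' strand|library|mate|trim5|trim3`), so a round trip through FASTQ
#' preserves exact placement. Paths ending in `.gz` are compressed.
#'
#' @param reads read tibble from [simulate_reads()].
#' @param r1_path,r2_path output FASTQ paths for mates 1 and 2.
#' @return the paths (write) / the read tibble (read), invisibly.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  for (m in 1:2) {
    path <- if (m == 1) r1_path else r2_path
    d <- reads |> filter(.data$mate == m) |> arrange(.data$id)
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(d$seq, encode_read_name(d))),
      Biostrings::PhredQuality(d$qual))
    Biostrings::writeQualityScaledXStringSet(
      x, path, compress = grepl("\\.gz$", path))
  }
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  one <- function(path) {
    # metadata-drop warning from Biostrings is expected and irrelevant here
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    decode_read_name(names(x)) |>
      mutate(seq = as.character(x, use.names = FALSE),
             qual = as.character(Biostrings::quality(x), use.names = FALSE))
  }
  bind_rows(one(r1_path), one(r2_path)) |> arrange(.data$id, .data$mate)
}

mean_qual <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
}

min_qual <- function(qual) {
  vapply(qual, function(q) min(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
}

#' Filter read pairs on quality and ambiguous bases
#'
#' A pair is kept iff both mates have mean base quality >= `min_q` (or
#' per-base minimum >= `min_q` with `per_base = TRUE`) and each mate has
#' at most `max_ambiguous` N bases. Rejection is pair-level: if either
#' mate fails, both are dropped (downstream libraries are paired).
#'
#' @param reads read tibble (mates share an `id`).
#' @param min_q quality threshold (default 25).
#' @param max_ambiguous maximum N bases per mate (default 1).
#' @param per_base apply `min_q` to every base instead of the mate mean.
#' @return list: `kept` (read tibble), `dropped` (with `reason`),
#'   `report` (tibble of pair counts by outcome).
#' @export
filter_reads <- function(reads, min_q = 25, max_ambiguous = 1,
                         per_base = FALSE) {
  bad_len <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len)) {
    abort(paste0("malformed record (sequence/quality length mismatch): ",
                 reads$id[which(bad_len)[1]]))
  }
  qv <- if (per_base) min_qual(reads$qual) else mean_qual(reads$qual)
  per_mate <- reads |>
    mutate(q_ok = qv >= min_q,
           n_count = stringr::str_count(.data$seq, stringr::fixed("N")))
  per_pair <- per_mate |>
    group_by(.data$id) |>
    summarise(fail_q = any(!.data$q_ok),
              fail_n = any(.data$n_count > max_ambiguous),
              .groups = "drop") |>
    mutate(reason = ifelse(.data$fail_q, "quality",
                           ifelse(.data$fail_n, "ambiguous", "kept")))
  tagged <- reads |> left_join(per_pair |> select("id", "reason"), by = "id")
  report <- per_pair |> count(.data$reason, name = "n_pairs")
  list(kept = tagged |> filter(.data$reason == "kept") |> select(-"reason"),
       dropped = tagged |> filter(.data$reason != "kept"),
       report = report)
}

#' Trim both ends of every mate
#'
#' Removes `end_trim` bases from the 5' and 3' end of each mate (sequence
#' and qualities in lockstep) and updates the coordinate tags (`o5`, `o3`)
#' so placement stays exact. Mates whose remaining length would drop below
#' 1 are removed with reason `"exhausted"` (attached as the `"dropped"`
#' attribute) with a warning.
#'
#' @param reads read tibble.
#' @param end_trim bases to remove from each end (default 3).
#' @return trimmed read tibble.
#' @export
trim_reads <- function(reads, end_trim = 3) {
  if (end_trim < 0) abort("end_trim must be non-negative")
  if (end_trim == 0) return(reads)
  len <- nchar(reads$seq)
  new_len <- len - 2 * end_trim
  exhausted <- new_len < 1
  out <- reads[!exhausted, , drop = FALSE] |>
    mutate(seq = substr(.data$seq, end_trim + 1, len[!exhausted] - end_trim),
           qual = substr(.data$qual, end_trim + 1, len[!exhausted] - end_trim),
           o5 = .data$o5 + as.integer(end_trim),
           o3 = .data$o3 + as.integer(end_trim))
  if (any(exhausted)) {
    warn(paste0(sum(exhausted), " mate(s) exhausted by trimming"))
    attr(out, "dropped") <- reads[exhausted, , drop = FALSE] |>
      mutate(reason = "exhausted")
  }
  out
}

#' Reference placement of each mate
#'
#' Resolves every mate's coordinate tag to the 0-based reference interval
#' it covers, accounting for strand, mate role and trim offsets.
#'
#' @param reads read tibble.
#' @return `reads` with `ref_start` (leftmost covered reference position)
#'   and `ref_end` (exclusive).
#' @export
mate_alignment <- function(reads) {
  len <- nchar(reads$seq)
  left_anchored <- (reads$strand == "+") == (reads$mate == 1)
  ref_start <- ifelse(left_anchored,
                      reads$frag_start + reads$o5,
                      reads$frag_start + reads$frag_len - reads$o5 - len)
  reads |> mutate(ref_start = as.integer(ref_start),
                  ref_end = as.integer(ref_start + len))
}

#' Accumulate per-cytosine counts from coordinate-tagged reads
#'
#' For every reference cytosine (on the fragment's strand) covered by a
#' mate, the molecule-space base is recovered from the read (mate 2 is
#' complemented) and counted as modified (C), unmodified (T), or other
#' (anything else, e.g. N -- excluded from levels but reported). The
#' output schema matches the direct count simulator's per-library tables.
#'
#' @param reads read tibble (filtered/trimmed as desired).
#' @param reference the `oxbs_reference` the tags refer to.
#' @return per-library counts tibble: `chrom`, `pos` (0-based), `strand`,
#'   `library`, `count_modified`, `count_unmodified`, `count_other`, plus
#'   `context`/`context_class`/`trinucleotide`.
#' @export
reads_to_counts <- function(reads, reference) {
  sites <- cytosine_sites(reference)
  if (!nrow(reads)) {
    return(sites[0, ] |> mutate(library = character(), count_modified = integer(),
                                count_unmodified = integer(),
                                count_other = integer()))
  }
  lens <- reference$chrom_lengths
  bad <- reads$frag_start < 0 |
    reads$frag_start + reads$frag_len > unname(lens[reads$chrom])
  if (any(bad)) {
    abort(paste0("coordinate tag outside reference bounds: ",
                 reads$id[which(bad)[1]]))
  }
  pos_by <- split(sites$pos, paste(sites$chrom, sites$strand))
  acc_chrom <- acc_pos <- acc_strand <- acc_lib <- acc_call <- list()
  for (r in seq_len(nrow(reads))) {
    row <- reads[r, ]
    cyto <- pos_by[[paste(row$chrom, row$strand)]]
    if (is.null(cyto)) next
    len <- nchar(row$seq)
    # molecule-space j range covered by this mate after trimming
    j_lo <- if (row$mate == 1) row$o5 else row$frag_len - row$o5 - len
    j_hi <- j_lo + len - 1L
    # reference positions of molecule coordinates j_lo..j_hi
    if (row$strand == "+") {
      ref_lo <- row$frag_start + j_lo; ref_hi <- row$frag_start + j_hi
    } else {
      ref_lo <- row$frag_start + row$frag_len - 1L - j_hi
      ref_hi <- row$frag_start + row$frag_len - 1L - j_lo
    }
    p <- cyto[cyto >= ref_lo & cyto <= ref_hi]
    if (!length(p)) next
    j <- if (row$strand == "+") p - row$frag_start else
      row$frag_start + row$frag_len - 1L - p
    i <- if (row$mate == 1) j - row$o5 else row$frag_len - 1L - row$o5 - j
    b <- substring(row$seq, i + 1, i + 1)
    if (row$mate == 2) b <- unname(comp_base[b])
    call <- ifelse(b == "C", "modified", ifelse(b == "T", "unmodified", "other"))
    acc_chrom[[r]] <- rep(row$chrom, length(p))
    acc_pos[[r]] <- p
    acc_strand[[r]] <- rep(row$strand, length(p))
    acc_lib[[r]] <- rep(row$lib, length(p))
    acc_call[[r]] <- call
  }
  obs <- tibble(chrom = unlist(acc_chrom), pos = unlist(acc_pos),
                strand = unlist(acc_strand), library = unlist(acc_lib),
                call = unlist(acc_call))
  if (!nrow(obs)) {
    return(sites[0, ] |> mutate(library = character(), count_modified = integer(),
                                count_unmodified = integer(),
                                count_other = integer()))
  }
  obs |>
    count(.data$chrom, .data$pos, .data$strand, .data$library, .data$call) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n", values_fill = 0L) |>
    (\(d) {
      for (col in c("modified", "unmodified", "other")) {
        if (!col %in% names(d)) d[[col]] <- 0L
      }
      d
    })() |>
    rename(count_modified = "modified", count_unmodified = "unmodified",
           count_other = "other") |>
    left_join(sites, by = c("chrom", "pos", "strand")) |>
    select("chrom", "pos", "strand", "library", "context", "context_class",
           "trinucleotide", "count_modified", "count_unmodified", "count_other")
}
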