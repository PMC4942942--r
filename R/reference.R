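#' Build a mock reference genome with annotated elements
#'
#' Generates a small multi-chromosome genome (uniform-random background
#' sequence) with CG-dense CpG islands, repeat elements and stranded
#' promoters, as a stand-in for a real assembly at desk scale. Islands are
#' built from a dinucleotide process with elevated CG probability so their
#' CG density is at least 3x the genomic background by construction.
#' Coordinates are 0-based half-open throughout.
#'
#' @param config an [sim_config()] list.
#' @param seed integer seed; output is byte-identical for a fixed
#'   (config, seed).
#' @return an object of class `oxbs_reference`: a list with `genome`
#'   (named character vector of sequences), `chrom_lengths`, and
#'   `annotations` (tibble: chrom, start, end, type, strand, name, tss).
#' @export
build_reference <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "oxbs_config"))
  with_substream(seed, "reference", expr = {
    lens <- config$chrom_lengths
    chroms <- names(lens)
    genome <- lapply(lens, function(L) {
      sample(c("A", "C", "G", "T"), L, replace = TRUE)
    })
    names(genome) <- chroms

    margin <- config$shore_width + config$shelf_width
    n_per_chrom <- function(n_total) {
      raw <- n_total * lens / sum(lens)
      n <- floor(raw)
      rem <- n_total - sum(n)
      if (rem > 0) {
        extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
        n[extra] <- n[extra] + 1
      }
      n
    }

    place <- function(existing, L, len, margin, gap = 100, tries = 2000) {
      lo <- margin
      hi <- L - margin - len
      if (hi <= lo) return(NULL)
      for (i in seq_len(tries)) {
        s <- floor(runif(1, lo, hi + 1))
        ok <- !nrow(existing) ||
          all(s + len + gap <= existing$start | s >= existing$end + gap)
        if (ok) return(c(s, s + len))
      }
      NULL
    }

    empty <- tibble(start = integer(), end = integer())
    ann <- list()

    # CpG islands: dinucleotide process, CG with prob cgi_cg_prob
    n_cgi <- n_per_chrom(config$n_cgi)
    non_cg <- setdiff(as.vector(outer(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"), paste0)), "CG")
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      placed <- empty
      for (k in seq_len(n_cgi[ci])) {
        len <- 2 * floor(runif(1, config$cgi_length_range[1] / 2,
                               config$cgi_length_range[2] / 2 + 1))
        iv <- place(placed, lens[ci], len, margin)
        if (is.null(iv)) next
        placed <- bind_rows(placed, tibble(start = iv[1], end = iv[2]))
        n2 <- len / 2
        dinucs <- ifelse(runif(n2) < config$cgi_cg_prob, "CG",
                         sample(non_cg, n2, replace = TRUE))
        genome[[chrom]][(iv[1] + 1):iv[2]] <-
          unlist(strsplit(dinucs, ""), use.names = FALSE)
      }
      if (nrow(placed)) {
        ann[[length(ann) + 1]] <- placed |>
          arrange(.data$start) |>
          mutate(chrom = chrom, type = "cgi", strand = "*", tss = NA_integer_)
      }
    }

    # repeats: background composition, placed clear of islands
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      placed_so_far <- bind_rows(ann)
      existing <- if (nrow(placed_so_far)) {
        placed_so_far |> filter(.data$chrom == !!chrom) |> select("start", "end")
      } else empty
      n_rep <- floor(lens[ci] * config$repeat_fraction / config$repeat_length)
      placed <- existing
      reps <- empty
      for (k in seq_len(n_rep)) {
        iv <- place(placed, lens[ci], config$repeat_length, margin = 0)
        if (is.null(iv)) next
        row <- tibble(start = iv[1], end = iv[2])
        placed <- bind_rows(placed, row)
        reps <- bind_rows(reps, row)
      }
      if (nrow(reps)) {
        ann[[length(ann) + 1]] <- reps |>
          arrange(.data$start) |>
          mutate(chrom = chrom, type = "repeat", strand = "*", tss = NA_integer_)
      }
    }

    # promoters: TSS position + gene strand; windows may overlap anything
    n_prom <- n_per_chrom(config$n_promoters)
    fl <- config$promoter_flank
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      if (n_prom[ci] == 0) next
      tss <- floor(runif(n_prom[ci], fl, lens[ci] - fl))
      strand <- sample(c("+", "-"), n_prom[ci], replace = TRUE)
      ann[[length(ann) + 1]] <- tibble(start = as.integer(tss - fl),
                                      end = as.integer(tss + fl),
                                      chrom = chrom, type = "promoter",
                                      strand = strand, tss = as.integer(tss))
    }

    annotations <- bind_rows(ann) |>
      arrange(match(.data$chrom, chroms), .data$type, .data$start) |>
      group_by(.data$type) |>
      mutate(name = paste0(.data$type, "_", sprintf("%03d", row_number()))) |>
      ungroup() |>
      mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
      select("chrom", "start", "end", "type", "strand", "name", "tss")

    structure(list(genome = vapply(genome, paste, "", collapse = ""),
                   chrom_lengths = lens,
                   annotations = annotations),
              class = "oxbs_reference")
  })
}

#' @export
print.oxbs_reference <- function(x, ...) {
  cat("<oxbs_reference> ", length(x$genome), " chromosomes, ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp\n", sep = "")
  print(count(x$annotations, .data$type))
  invisible(x)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Enumerate cytosine sites with sequence context
#'
#' Finds every cytosine on both strands of a reference and assigns its
#' context (CG if the next base 3' on the same strand is G, else CHG/CHH
#' from the two downstream bases) and trinucleotide. Minus-strand context is
#' read from the reverse complement. Sites within 2 bp of a chromosome end
#' get an `N`-padded trinucleotide; when even the CG/CH call is impossible
#' the subclass is left as `"CH"` and flagged.
#'
#' @param reference an `oxbs_reference` (or a named character vector of
#'   sequences).
#' @return tibble: `chrom`, `pos` (0-based), `strand`, `context`
#'   (CG/CHG/CHH/CH), `context_class` (CG/CH), `trinucleotide`, `boundary`.
#' @export
cytosine_sites <- function(reference) {
  genome <- if (inherits(reference, "oxbs_reference")) reference$genome else reference
  out <- lapply(names(genome), function(chrom) {
    ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(ch)
    at <- function(i) ifelse(i >= 1 & i <= L, ch[pmax(pmin(i, L), 1)], "N")
    res <- list()
    ip <- which(ch == "C")
    if (length(ip)) {
      b1 <- at(ip + 1); b2 <- at(ip + 2)
      res$plus <- tibble(chrom = chrom, pos = ip - 1L, strand = "+",
                         context = context_from(b1, b2),
                         trinucleotide = paste0("C", b1, b2))
    }
    im <- which(ch == "G")
    if (length(im)) {
      b1 <- unname(comp_base[at(im - 1)]); b2 <- unname(comp_base[at(im - 2)])
      res$minus <- tibble(chrom = chrom, pos = im - 1L, strand = "-",
                          context = context_from(b1, b2),
                          trinucleotide = paste0("C", b1, b2))
    }
    bind_rows(res)
  })
  bind_rows(out) |>
    mutate(context_class = ifelse(.data$context == "CG", "CG", "CH"),
           boundary = grepl("N", .data$trinucleotide)) |>
    arrange(match(.data$chrom, names(genome)), .data$pos, .data$strand)
}

context_from <- function(b1, b2) {
  ifelse(b1 == "G", "CG",
         ifelse(b1 == "N", "CH",
                ifelse(b2 == "G", "CHG", ifelse(b2 == "N", "CH", "CHH"))))
}

#' Assign sequence context at given cytosine positions
#'
#' @param reference an `oxbs_reference` or named character vector.
#' @param chrom,pos,strand parallel vectors; `pos` is 0-based and must point
#'   at a cytosine on `strand`.
#' @return tibble with `context` and `trinucleotide` per input position.
#' @export
assign_context <- function(reference, chrom, pos, strand) {
  genome <- if (inherits(reference, "oxbs_reference")) reference$genome else reference
  n <- max(length(chrom), length(pos), length(strand))
  d <- tibble(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
              strand = rep_len(strand, n))
  sites <- cytosine_sites(genome[unique(d$chrom)])
  res <- d |> left_join(sites, by = c("chrom", "pos", "strand"))
  if (anyNA(res$context)) {
    bad <- res |> filter(is.na(.data$context)) |> slice(1)
    abort(sprintf("no cytosine on strand %s at %s:%d",
                  bad$strand, bad$chrom, bad$pos))
  }
  res |> select("chrom", "pos", "strand", "context", "trinucleotide")
}

#' Write the reference genome as FASTA
#'
#' @param reference an `oxbs_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(reference$genome)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return an `oxbs_reference` (without annotations).
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  genome <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  structure(list(genome = genome,
                 chrom_lengths = setNames(nchar(genome), names(genome)),
                 annotations = NULL),
            class = "oxbs_reference")
}

annotations_to_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*"),
    name = ann$name
  )
}

#' Write element annotations as BED6 (one file per element type)
#'
#' @param annotations annotation tibble from [build_reference()] (or a
#'   subset of it).
#' @param dir output directory; files are named `<type>.bed`.
#' @return named character vector of written paths, invisibly.
#' @export
write_annotation_bed <- function(annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  types <- unique(annotations$type)
  paths <- vapply(types, function(tp) {
    path <- file.path(dir, paste0(tp, ".bed"))
    gr <- annotations_to_granges(annotations |> filter(.data$type == tp))
    rtracklayer::export(gr, path, format = "BED")
    path
  }, "")
  invisible(paths)
}

#' Read a BED file as an annotation tibble (0-based half-open)
#'
#' @param path BED path.
#' @param type element type label to attach (e.g. `"cgi"`).
#' @return annotation tibble with `chrom`, `start`, `end`, `type`, `strand`,
#'   `name`.
#' @export
read_annotation_bed <- function(path, type) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         type = type,
         strand = as.character(GenomicRanges::strand(gr)),
         name = if (!is.null(gr$name)) gr$name else paste0(type, "_", seq_along(gr)),
         tss = NA_integer_)
}
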