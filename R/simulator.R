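#' Genome sets
#'
#' A `genome_set` is a tibble of reference sequences — one row per contig, with
#' columns `taxid` (species), `group`, `seq_id`, `seq` and `length` — wrapped
#' in a light S3 class. Stands in for a reference genome collection (e.g. a
#' RefSeq snapshot) at fixture scale.
#'
#' @param records Data frame with columns `taxid`, `group`, `seq_id`, `seq`.
#' @return A `genome_set` tibble.
#' @export
genome_set <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("taxid", "group", "seq_id", "seq")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`records` lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) abort("A genome set needs at least one sequence.")
  check_groups(records$group)
  if (anyDuplicated(records$seq_id)) abort("`seq_id` values must be unique.")
  if (any(!nzchar(records$seq))) abort("Sequences must be non-empty.")
  if (any(grepl("[^ACGTN]", records$seq))) {
    abort("Sequences must use the alphabet A/C/G/T/N (upper case).")
  }
  records$taxid <- as.integer(records$taxid)
  records$length <- nchar(records$seq)
  class(records) <- c("genome_set", class(records))
  records
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf(
    "<genome_set> %d sequences, %d species, %.3g Mbp total\n",
    nrow(x), dplyr::n_distinct(x$taxid), sum(x$length) / 1e6
  ))
  print(tibble::as_tibble(utils::head(dplyr::mutate(
    x, seq = paste0(substr(seq, 1L, 12L), "...")
  ), 6L)))
  invisible(x)
}

#' Default toy genome lengths
#'
#' Per-group genome lengths for the fixture generator, preserving the size
#' asymmetry of real genomes (viruses tens of kb, bacteria Mb-scale,
#' eukaryotes orders of magnitude larger) at a scaled-down absolute size.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
default_genome_lengths <- function() {
  c(bacteria = 200e3, virus = 20e3, eukaryote = 2e6)
}

#' Generate toy reference genomes
#'
#' One uniform-random A/C/G/T sequence per species, deterministic for a fixed
#' seed. Together with [make_toy_taxonomy()] this provides a complete
#' self-contained benchmark fixture: the same genomes serve as the simulation
#' source and as the classifier "database".
#'
#' @param species_groups Tibble with columns `taxid`, `group` (the `groups`
#'   element of [make_toy_taxonomy()]).
#' @param length_by_group Named lengths in bp per group
#'   (default [default_genome_lengths()]).
#' @param seed Integer seed.
#' @param read_length Read length the genomes must support; lengths below
#'   `2 * read_length` are rejected.
#' @return A [genome_set()].
#' @export
make_toy_genomes <- function(species_groups,
                             length_by_group = default_genome_lengths(),
                             seed = 1, read_length = 150) {
  species_groups <- tibble::as_tibble(species_groups)
  stopifnot(all(c("taxid", "group") %in% names(species_groups)))
  check_groups(species_groups$group)
  lens <- length_by_group[species_groups$group]
  if (anyNA(lens)) {
    abort("`length_by_group` must name every group present in `species_groups`.")
  }
  if (any(lens < 2 * read_length)) {
    abort(sprintf("Genome lengths must be >= 2 * read_length (%d bp).", 2L * as.integer(read_length)))
  }
  with_seed(seed, {
    seqs <- vapply(as.integer(lens), random_dna, character(1L))
    genome_set(tibble::tibble(
      taxid = species_groups$taxid,
      group = species_groups$group,
      seq_id = sprintf("seq_%d", species_groups$taxid),
      seq = seqs
    ))
  })
}

#' Copy a genome segment between species
#'
#' Overwrites a stretch of the recipient genome with a segment copied verbatim
#' from the donor, emulating horizontal transfer / integration events (e.g.
#' bacterial sequence embedded in a eukaryote assembly) that cause
#' cross-group misclassification. The copied segment aligns exactly to both
#' genomes afterwards.
#'
#' @param genomes A [genome_set()].
#' @param from_taxid,to_taxid Donor and recipient species taxids.
#' @param segment_length Length of the copied segment in bp (default 5000).
#' @param seed Integer seed choosing the donor and recipient positions.
#' @return The modified `genome_set`, with an attached `shared_segments`
#'   attribute recording donor/recipient coordinates (0-based starts).
#' @export
inject_shared_segment <- function(genomes, from_taxid, to_taxid,
                                  segment_length = 5000, seed = 1) {
  stopifnot(inherits(genomes, "genome_set"))
  from_row <- which(genomes$taxid == from_taxid)[1L]
  to_row <- which(genomes$taxid == to_taxid)[1L]
  if (is.na(from_row) || is.na(to_row)) abort("Donor or recipient taxid not in genome set.")
  if (segment_length > genomes$length[from_row] || segment_length > genomes$length[to_row]) {
    abort("`segment_length` exceeds a genome length.")
  }
  with_seed(seed, {
    from_start <- sample.int(genomes$length[from_row] - segment_length + 1L, 1L) - 1L
    to_start <- sample.int(genomes$length[to_row] - segment_length + 1L, 1L) - 1L
    segment <- substr(genomes$seq[from_row], from_start + 1L, from_start + segment_length)
    seq_to <- genomes$seq[to_row]
    substr(seq_to, to_start + 1L, to_start + segment_length) <- segment
    genomes$seq[to_row] <- seq_to
    genomes$length[to_row] <- nchar(seq_to)
    seg <- tibble::tibble(
      from_taxid = genomes$taxid[from_row], from_start = from_start,
      to_taxid = genomes$taxid[to_row], to_start = to_start,
      segment_length = as.integer(segment_length)
    )
    attr(genomes, "shared_segments") <- dplyr::bind_rows(attr(genomes, "shared_segments"), seg)
    genomes
  })
}

#' Simulated read sets
#'
#' A `read_set` bundles simulated reads with their truth labels: `reads` is a
#' tibble (`read_id`, `seq`), `truth` a tibble (`read_id`, `taxid`, `group`,
#' `seq_id`, `start`, `strand`) with 0-based half-open forward-strand
#' coordinates, and `params` the simulation parameters.
#'
#' @param reads,truth,params See description.
#' @return A `read_set` object.
#' @export
read_set <- function(reads, truth, params = list()) {
  reads <- tibble::as_tibble(reads)
  truth <- tibble::as_tibble(truth)
  if (anyDuplicated(reads$read_id)) abort("`read_id` values must be unique.")
  if (!identical(sort(reads$read_id), sort(truth$read_id))) {
    abort("`reads` and `truth` must cover exactly the same read ids.")
  }
  structure(list(reads = reads, truth = truth, params = params), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(
    "<read_set> %d reads x %s bp, %d species, %d group(s)\n",
    nrow(x$reads), x$params$read_length %||% "?",
    dplyr::n_distinct(x$truth$taxid), dplyr::n_distinct(x$truth$group)
  ))
  invisible(x)
}

#' @export
length.read_set <- function(x) nrow(x$reads)

#' Simulate truth-labelled single-end reads
#'
#' Per-read community simulation: each read independently draws its species
#' from the profile's expected abundances (exact multinomial sampling — the
#' realised species mix and per-group species counts are therefore stochastic,
#' landing near their targets rather than being imposed by quota), a source
#' contig within the species proportional to contig length, a uniform start
#' position, and a uniform strand; substitution errors are then applied i.i.d.
#' per base at `error_rate`, each substituted base uniform over the three
#' alternatives. Contigs shorter than `read_length` are excluded from sampling
#' with a warning. Deterministic for a fixed seed.
#'
#' @param genomes A [genome_set()] covering every profile taxid.
#' @param profile A community profile from [build_profile()].
#' @param n_target Number of reads to simulate (>= 1).
#' @param read_length Read length in bp (default 150).
#' @param error_rate Per-base substitution probability (default 0.0024, a
#'   published Illumina estimate; substitutions only, no indels).
#' @param seed Integer seed.
#' @return A [read_set()].
#' @export
simulate_reads <- function(genomes, profile, n_target,
                           read_length = 150, error_rate = 0.0024, seed = 1) {
  stopifnot(inherits(genomes, "genome_set"))
  if (!is_count(n_target)) abort("`n_target` must be a positive integer.")
  n_target <- as.integer(n_target)
  read_length <- as.integer(read_length)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    abort("`error_rate` must be in [0, 1).")
  }
  missing_tax <- setdiff(profile$taxid, genomes$taxid)
  if (length(missing_tax) > 0L) {
    abort(sprintf(
      "Profile taxid(s) absent from genome set: %s.",
      paste(utils::head(missing_tax, 5L), collapse = ", ")
    ))
  }

  usable <- genomes$length >= read_length
  if (!all(usable)) {
    warn(sprintf(
      "Excluding %d contig(s) shorter than the read length from sampling.",
      sum(!usable)
    ))
  }
  contigs <- tibble::as_tibble(genomes)[usable, ]
  lost <- setdiff(profile$taxid, contigs$taxid)
  if (length(lost) > 0L) {
    abort(sprintf(
      "No contig of length >= read_length for taxid(s): %s.",
      paste(utils::head(lost, 5L), collapse = ", ")
    ))
  }

  with_seed(seed, {
    # species per read: exact multinomial over profile abundances
    sp <- sample.int(nrow(profile), n_target, replace = TRUE,
                     prob = profile$expected_abundance)

    # contig per read, proportional to contig length within the species
    contig_row <- integer(n_target)
    by_tax <- split(seq_len(nrow(contigs)), contigs$taxid)
    for (i in seq_len(nrow(profile))) {
      take <- which(sp == i)
      if (length(take) == 0L) next
      rows <- by_tax[[as.character(profile$taxid[i])]]
      if (length(rows) == 1L) {
        contig_row[take] <- rows
      } else {
        contig_row[take] <- rows[sample.int(
          length(rows), length(take), replace = TRUE, prob = contigs$length[rows]
        )]
      }
    }

    max_start <- contigs$length[contig_row] - read_length  # 0-based maximum
    start <- as.integer(floor(stats::runif(n_target) * (max_start + 1)))
    start <- pmin(start, max_start)  # guard the measure-zero runif(1) == 1 edge
    strand <- ifelse(stats::runif(n_target) < 0.5, "+", "-")

    seqs <- substring(contigs$seq[contig_row], start + 1L, start + read_length)
    minus <- strand == "-"
    seqs[minus] <- revcomp(seqs[minus])
    if (error_rate > 0) {
      seqs <- apply_substitutions(seqs, read_length, error_rate)
    }

    read_id <- sprintf("r%07d", seq_len(n_target))
    read_set(
      reads = tibble::tibble(read_id = read_id, seq = seqs),
      truth = tibble::tibble(
        read_id = read_id,
        taxid = profile$taxid[sp],
        group = profile$group[sp],
        seq_id = contigs$seq_id[contig_row],
        start = start,
        strand = strand
      ),
      params = list(
        read_length = read_length, n_target = n_target,
        error_rate = error_rate, seed = seed
      )
    )
  })
}

# i.i.d. per-base substitution at `rate`, vectorised in chunks; the substituted
# base is uniform over the three alternatives (uniform over ACGT if the
# original is N).
apply_substitutions <- function(seqs, read_length, rate) {
  n <- length(seqs)
  chunk <- max(1L, min(n, as.integer(2e7 %/% read_length)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    m <- hi - lo + 1L
    hit <- which(stats::runif(m * read_length) < rate)
    if (length(hit) == 0L) next
    rd <- ((hit - 1L) %/% read_length) + 1L   # read within chunk
    pos <- ((hit - 1L) %% read_length) + 1L   # base within read
    block <- seqs[lo:hi]
    # substr<- keeps only the last write per element, so apply co-occurring
    # errors in rounds: the j-th error of each read per round
    occ <- stats::ave(rd, rd, FUN = seq_along)
    for (o in seq_len(max(occ))) {
      sel <- occ == o
      r <- rd[sel]
      p <- pos[sel]
      orig <- substr(block[r], p, p)  # vectorised elementwise
      code <- match(orig, DNA_BASES)
      shift <- sample.int(3L, length(r), replace = TRUE)
      new <- ifelse(
        is.na(code),
        DNA_BASES[sample.int(4L, length(r), replace = TRUE)],
        DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
      )
      tmp <- block[r]
      substr(tmp, p, p) <- new
      block[r] <- tmp
    }
    seqs[lo:hi] <- block
  }
  seqs
}

#' Deviation of realised simulation numbers from their targets
#'
#' Per-read sampling achieves read and species-count targets stochastically;
#' this reports `|realised - target| / target` for the total read count and
#' for the number of distinct species observed per group, flagging deviations
#' above the conventional 10% simulation tolerance.
#'
#' @param readset A [read_set()].
#' @param profile The community profile the reads were simulated from.
#' @param species_targets Named target species counts per group (default: the
#'   number of profile species per group).
#' @param n_target Target total read count (default: the read set's
#'   `n_target` parameter).
#' @param tolerance Flagging threshold on relative deviation (default 0.10).
#' @return Tibble with columns `metric`, `group`, `target`, `realized`,
#'   `deviation`, `flagged`.
#' @export
realized_deviation <- function(readset, profile,
                               species_targets = NULL, n_target = NULL,
                               tolerance = 0.10) {
  stopifnot(inherits(readset, "read_set"))
  n_target <- n_target %||% readset$params$n_target
  if (is.null(n_target)) abort("Supply `n_target` (not recorded in the read set).")
  if (is.null(species_targets)) {
    species_targets <- table(profile$group)
    species_targets <- stats::setNames(as.integer(species_targets), names(species_targets))
  }
  check_groups(names(species_targets), "species_targets name")

  realized_species <- readset$truth |>
    dplyr::distinct(.data$taxid, .data$group) |>
    dplyr::count(.data$group, name = "realized")

  rows <- tibble::tibble(
    metric = "total_reads", group = NA_character_,
    target = as.numeric(n_target), realized = as.numeric(nrow(readset$reads))
  )
  for (g in intersect(GROUP_LEVELS, names(species_targets))) {
    obs <- realized_species$realized[realized_species$group == g]
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = "species_count", group = g,
      target = as.numeric(species_targets[[g]]),
      realized = as.numeric(if (length(obs) == 1L) obs else 0)
    ))
  }
  rows |>
    dplyr::mutate(
      deviation = abs(.data$realized - .data$target) / .data$target,
      flagged = .data$deviation > tolerance
    )
}

#' Write simulated reads as FASTA / FASTQ
#'
#' Headers encode the truth label as `read_id|taxid|group`, so downstream
#' tools (and [read_reads_fasta()]) can recover per-read truth without the
#' separate table. FASTQ output carries a constant quality consistent with the
#' configured substitution rate, `Q = round(-10 log10(rate))` (Q40 when the
#' rate is 0).
#'
#' @param readset A [read_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  hdr <- read_headers(readset)
  readr::write_lines(
    as.vector(rbind(paste0(">", hdr), readset$reads$seq)), path
  )
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
write_reads_fastq <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  rate <- readset$params$error_rate %||% 0
  q <- if (rate > 0) as.integer(round(-10 * log10(rate))) else 40L
  qual <- strrep(rawToChar(as.raw(q + 33L)), nchar(readset$reads$seq))
  hdr <- read_headers(readset)
  readr::write_lines(
    as.vector(rbind(paste0("@", hdr), readset$reads$seq, "+", qual)), path
  )
  invisible(path)
}

read_headers <- function(readset) {
  truth <- readset$truth[match(readset$reads$read_id, readset$truth$read_id), ]
  paste(readset$reads$read_id, truth$taxid, truth$group, sep = "|")
}

#' Read simulated reads back from FASTA
#'
#' Parses `read_id|taxid|group` truth headers written by
#' [write_reads_fasta()]. Source coordinates are not encoded in headers, so
#' `seq_id`, `start` and `strand` come back as `NA`.
#'
#' @param path FASTA file path.
#' @return A [read_set()].
#' @export
read_reads_fasta <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) abort(sprintf("No reads in %s.", path))
  hdr_at <- startsWith(lines, ">")
  if (!hdr_at[1L] || any(diff(which(hdr_at)) != 2L)) {
    abort(sprintf("%s is not single-line-per-sequence FASTA.", path))
  }
  hdr <- sub("^>", "", lines[hdr_at])
  parts <- stringi::stri_split_fixed(hdr, "|", simplify = TRUE)
  if (ncol(parts) != 3L) abort("Headers must encode read_id|taxid|group.")
  read_set(
    reads = tibble::tibble(read_id = parts[, 1L], seq = lines[!hdr_at]),
    truth = tibble::tibble(
      read_id = parts[, 1L],
      taxid = as.integer(parts[, 2L]),
      group = parts[, 3L],
      seq_id = NA_character_, start = NA_integer_, strand = NA_character_
    ),
    params = list(read_length = nchar(lines[[2L]]))
  )
}

#' Write / read a truth table TSV
#'
#' Columns `read_id`, `taxid`, `group`, `seq_id`, `start` (0-based), `strand`.
#'
#' @param readset A [read_set()] (writer) .
#' @param path File path.
#' @return The truth tibble (reader); `path` invisibly (writer).
#' @export
write_truth <- function(readset, path) {
  readr::write_tsv(readset$truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    taxid = readr::col_integer(),
    group = readr::col_character(),
    seq_id = readr::col_character(),
    start = readr::col_integer(),
    strand = readr::col_character()
  ))
}
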