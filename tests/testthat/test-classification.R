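test_that("b6 parsing handles empty files, grouping, and malformed lines", {
  empty <- withr::local_tempfile(lines = character(0), fileext = ".b6")
  expect_equal(nrow(parse_b6(empty)), 0L)

  three <- withr::local_tempfile(lines = c(
    "r1\ts1\t99.3\t150\t1\t0\t1\t150\t10\t159\t1e-60\t200.1",
    "r1\ts2\t98.0\t150\t3\t0\t1\t150\t5\t154\t1e-55\t195.0",
    "r1\ts3\t97.1\t150\t4\t0\t1\t150\t2\t151\t1e-50\t180.0"
  ), fileext = ".b6")
  hits <- parse_b6(three)
  expect_equal(nrow(hits), 3L)
  expect_equal(unique(hits$read_id), "r1")
  expect_equal(hits$bit_score, c(200.1, 195.0, 180.0))
  expect_equal(hits$subject_id, c("s1", "s2", "s3")) # file order preserved

  bad <- withr::local_tempfile(lines = c(
    "r1\ts1\t99.3\t150\t1\t0\t1\t150\t10\t159\t1e-60\t200.1",
    "r2\ts1\t99.3\t150"
  ), fileext = ".b6")
  expect_error(parse_b6(bad), "line 2")
})

test_that("b6 writer and parser round-trip field for field", {
  withr::with_seed(17, {
    hits <- tibble::tibble(
      read_id = sprintf("r%d", sample(1:20, 50, replace = TRUE)),
      subject_id = sprintf("s%d", sample(1:10, 50, replace = TRUE)),
      percent_identity = round(stats::runif(50, 90, 100), 2),
      alignment_length = sample(50:150, 50, replace = TRUE),
      bit_score = round(stats::runif(50, 100, 300), 1)
    )
  })
  path <- withr::local_tempfile(fileext = ".b6")
  write_b6(hits, path)
  expect_equal(as.data.frame(parse_b6(path)), as.data.frame(hits))
})

test_that("LCA counting resolves single hits, ties, and unknown subjects", {
  toy <- make_toy_taxonomy(6, 2, 2, seed = 2)
  nodes <- toy$tree$nodes
  sp <- nodes$taxid[nodes$rank == "species"]
  genus_kids <- split(nodes$taxid[nodes$rank == "species"],
                      nodes$parent_taxid[nodes$rank == "species"])
  sibs <- genus_kids[[which(lengths(genus_kids) >= 2L)[1L]]]
  genus <- nodes$parent_taxid[nodes$taxid == sibs[1L]]
  smap <- stats::setNames(c(sp[1L], sibs[1L], sibs[2L]), c("s1", "sibA", "sibB"))

  hits <- tibble::tibble(
    read_id = c("r1", "r2", "r2"),
    subject_id = c("s1", "sibA", "sibB"),
    percent_identity = 99,
    alignment_length = 150L,
    bit_score = c(200, 180, 180)
  )
  res <- lca_count(hits, toy$tree, smap, read_ids = c("r1", "r2", "r3"))

  a <- stats::setNames(res$assignments$taxid, res$assignments$read_id)
  expect_equal(unname(a["r1"]), unname(sp[1L]))   # single hit: that taxid
  expect_equal(unname(a["r2"]), unname(genus))    # equal-score siblings: genus
  expect_true(is.na(a["r3"]))                     # no hits: unclassified
  # genus assignment contributes nothing at species level
  expect_equal(sum(res$counts_at_species$count), 1L)
  expect_equal(res$n_classified + res$n_unclassified, 3L)

  expect_error(lca_count(hits, toy$tree, smap["s1"]), "not in subject map")
})

test_that("the score margin keeps near-top hits in the LCA", {
  toy <- make_toy_taxonomy(6, 2, 2, seed = 2)
  nodes <- toy$tree$nodes
  genus_kids <- split(nodes$taxid[nodes$rank == "species"],
                      nodes$parent_taxid[nodes$rank == "species"])
  sibs <- genus_kids[[which(lengths(genus_kids) >= 2L)[1L]]]
  smap <- stats::setNames(sibs[1:2], c("A", "B"))
  hits <- tibble::tibble(
    read_id = "r1", subject_id = c("A", "B"),
    percent_identity = 99, alignment_length = 150L,
    bit_score = c(200, 198.5) # within 1% of the top
  )
  genus <- nodes$parent_taxid[nodes$taxid == sibs[1L]]
  expect_equal(lca_count(hits, toy$tree, smap)$assignments$taxid, unname(genus))
  # with a zero margin only the top hit survives
  expect_equal(
    lca_count(hits, toy$tree, smap, top_margin = 0)$assignments$taxid,
    unname(sibs[1L])
  )
})

test_that("LCA counting matches a brute-force oracle on randomized hit lists", {
  nodes <- random_tree_nodes(200, seed = 41)
  tree <- taxonomy_tree(nodes)
  subjects <- sprintf("sub%d", 1:60)
  withr::with_seed(42, {
    smap <- stats::setNames(sample(nodes$taxid, 60, replace = TRUE), subjects)
    n_reads <- 500L
    hits <- purrr::map_dfr(seq_len(n_reads), function(i) {
      k <- sample(1:5, 1L)
      tibble::tibble(
        read_id = sprintf("r%03d", i),
        subject_id = sample(subjects, k, replace = TRUE),
        percent_identity = 99,
        alignment_length = 150L,
        bit_score = round(stats::runif(k, 100, 300), 1)
      )
    })
  })
  read_ids <- sprintf("r%03d", 1:500)
  res <- lca_count(hits, tree, smap, top_margin = 0.01, read_ids = read_ids)
  oracle <- brute_lca_count(hits, nodes, smap, 0.01, read_ids)

  got <- stats::setNames(res$assignments$taxid, res$assignments$read_id)
  expect_equal(unname(got[read_ids]), oracle$taxid)
  got_counts <- stats::setNames(res$counts_at_species$count,
                                res$counts_at_species$taxid)
  expect_equal(got_counts[order(names(got_counts))],
               oracle$counts[order(names(oracle$counts))])

  # invariant to permuting hit order within reads
  withr::with_seed(43, shuffled <- hits[sample.int(nrow(hits)), ])
  res2 <- lca_count(shuffled, tree, smap, top_margin = 0.01, read_ids = read_ids)
  expect_equal(
    dplyr::arrange(res2$assignments, .data$read_id),
    dplyr::arrange(res$assignments, .data$read_id)
  )
})

test_that("assignment tables map the 0 sentinel and round-trip", {
  toy <- make_toy_taxonomy(3, 1, 1, seed = 1)
  sp <- toy$groups$taxid
  tab <- withr::local_tempfile(
    lines = c(
      sprintf("r%d\t%d", 1:6, sp[c(1, 1, 2, 3, 4, 5)]),
      "r7\t0", "r8\t0", "r9\t0", "r10\t0"
    ),
    fileext = ".tsv"
  )
  res <- read_assignment_table(tab, toy$tree)
  expect_equal(res$n_classified, 6L)
  expect_equal(res$n_unclassified, 4L)
  expect_true(all(c("r7", "r8", "r9", "r10") %in% unclassified_ids(res)))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_assignment_table(res, out)
  back <- read_assignment_table(out, toy$tree)
  expect_equal(back$assignments, res$assignments)
  expect_equal(back$counts_at_species, res$counts_at_species)

  bad <- withr::local_tempfile(lines = c("r1\tabc"), fileext = ".tsv")
  expect_error(read_assignment_table(bad, toy$tree), "non-integer taxid")
})

test_that("k-mer index boundary cases and parameter validation", {
  one <- genome_set(tibble::tibble(
    taxid = 9L, group = "virus", seq_id = "v", seq = strrep("ACGTT", 3) # 15 bp
  ))
  idx <- build_kmer_index(one, k = 15)
  expect_equal(idx$n_kmers, 1)

  twin <- genome_set(tibble::tibble(
    taxid = c(5L, 6L), group = "virus", seq_id = c("a", "b"),
    seq = rep(strrep("ACGATTTACGGCAT", 10), 2)
  ))
  idx2 <- build_kmer_index(twin, k = 13)
  km <- substr(twin$seq[1L], 1L, 13L)
  expect_equal(kmer_index_lookup(idx2, km)[[1L]], c(5L, 6L))

  gen <- small_fixture()$genomes
  expect_error(build_kmer_index(gen, k = 12), "odd")
  expect_error(build_kmer_index(gen, k = 9), "odd integer between")
})

test_that("k-mer membership agrees with direct substring search", {
  fix <- small_fixture()
  k <- 21L
  idx <- build_kmer_index(fix$genomes, k = k)
  withr::with_seed(55, {
    # half real k-mers drawn from genomes, half random
    real <- vapply(1:500, function(i) {
      row <- sample.int(nrow(fix$genomes), 1L)
      at <- sample.int(fix$genomes$length[row] - k + 1L, 1L)
      substr(fix$genomes$seq[row], at, at + k - 1L)
    }, character(1L))
    rand <- vapply(1:500, function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1L))
  })
  queries <- c(real, rand)
  got <- kmer_index_lookup(idx, queries)
  for (i in seq_along(queries)) {
    q <- queries[i]
    present <- vapply(seq_len(nrow(fix$genomes)), function(r) {
      grepl(q, fix$genomes$seq[r], fixed = TRUE) ||
        grepl(revcomp(q), fix$genomes$seq[r], fixed = TRUE)
    }, logical(1L))
    expect_equal(got[[i]], sort(unique(fix$genomes$taxid[present])))
  }
})

test_that("unique-signal reads classify to their source species", {
  fix <- small_fixture()
  idx <- build_kmer_index(fix$genomes, k = 31)
  rs <- simulate_reads(fix$genomes, fix$profile, 2000, read_length = 100,
                       error_rate = 0, seed = 19)
  res <- classify_kmer(rs, idx, fix$tree)
  truth <- stats::setNames(rs$truth$taxid, rs$truth$read_id)
  got <- stats::setNames(res$assignments$taxid, res$assignments$read_id)
  expect_equal(got[names(truth)], truth)
  sets <- species_sets(res, rs$truth, groups = fix$groups)
  expect_equal(
    evaluate_run(res, rs$truth, groups = fix$groups)$recall,
    rep(1, nrow(sets))
  )
})

test_that("reads from a shared segment resolve to the species' LCA", {
  fix <- small_fixture()
  donor <- fix$groups$taxid[fix$groups$group == "bacteria"][1L]
  recip <- fix$groups$taxid[fix$groups$group == "eukaryote"][1L]
  gen2 <- inject_shared_segment(fix$genomes, donor, recip,
                                segment_length = 500, seed = 23)
  seg <- attr(gen2, "shared_segments")
  idx <- build_kmer_index(gen2, k = 31)

  # a read wholly inside the shared segment
  read_seq <- substr(gen2$seq[gen2$taxid == donor],
                     seg$from_start + 101L, seg$from_start + 200L)
  rs <- read_set(
    reads = tibble::tibble(read_id = "shared1", seq = read_seq),
    truth = tibble::tibble(read_id = "shared1", taxid = donor, group = "bacteria",
                           seq_id = "x", start = 0L, strand = "+")
  )
  res <- classify_kmer(rs, idx, fix$tree)
  expect_equal(res$assignments$taxid, lca(fix$tree, c(donor, recip)))
})

test_that("limit behaviour: min_hits = Inf and k = read length", {
  fix <- small_fixture()
  idx <- build_kmer_index(fix$genomes, k = 31)
  rs <- simulate_reads(fix$genomes, fix$profile, 100, read_length = 31,
                       error_rate = 0, seed = 29)
  # min_hits = Inf classifies nothing
  res_inf <- classify_kmer(rs, idx, fix$tree, min_hits = Inf)
  expect_equal(res_inf$n_classified, 0L)
  expect_equal(res_inf$n_unclassified, 100L)

  # k == read length: exact-read lookup
  res <- classify_kmer(rs, idx, fix$tree)
  exact <- stats::setNames(rs$truth$taxid, rs$truth$read_id)
  got <- stats::setNames(res$assignments$taxid, res$assignments$read_id)
  classified <- !is.na(got)
  expect_equal(got[classified], exact[names(got)[classified]])

  # reads shorter than k warn and stay unclassified
  short <- read_set(
    reads = tibble::tibble(read_id = "tiny", seq = "ACGTACGTACGT"),
    truth = tibble::tibble(read_id = "tiny", taxid = fix$groups$taxid[1L],
                           group = "bacteria", seq_id = "x", start = 0L, strand = "+")
  )
  expect_warning(res_s <- classify_kmer(short, idx, fix$tree), "shorter than k")
  expect_equal(res_s$n_unclassified, 1L)
})

test_that("every classification result partitions its input reads", {
  fix <- small_fixture()
  idx <- build_kmer_index(fix$genomes, k = 31)
  rs <- simulate_reads(fix$genomes, fix$profile, 300, read_length = 100,
                       error_rate = 0.01, seed = 31)
  res <- classify_kmer(rs, idx, fix$tree, min_hits = 40)
  expect_equal(res$n_classified + res$n_unclassified, 300L)
  expect_setequal(
    c(classified_ids(res), unclassified_ids(res)),
    rs$reads$read_id
  )
  expect_length(intersect(classified_ids(res), unclassified_ids(res)), 0L)
})

test_that("species count tables carry names and subject maps round-trip", {
  fix <- small_fixture()
  idx <- build_kmer_index(fix$genomes, k = 31)
  rs <- simulate_reads(fix$genomes, fix$profile, 200, read_length = 100,
                       error_rate = 0, seed = 37)
  res <- classify_kmer(rs, idx, fix$tree)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_species_counts(res, fix$tree, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(sum(tab$count), res$n_classified)
  expect_true(all(grepl("species", tab$name)))

  smap <- stats::setNames(fix$groups$taxid, sprintf("ref%d", seq_len(nrow(fix$groups))))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_subject_map(smap, mpath)
  expect_equal(read_subject_map(mpath), smap)
})
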