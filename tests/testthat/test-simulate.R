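test_that("generators are seed-deterministic", {
  a <- simulate_genome_and_map(2, 60000, 0.008, 200, seed = 5)
  b <- simulate_genome_and_map(2, 60000, 0.008, 200, seed = 5)
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$map$markers, b$map$markers)
  c <- simulate_genome_and_map(2, 60000, 0.008, 200, seed = 6)
  expect_false(identical(a$genome$sequences, c$genome$sequences))

  r1 <- simulate_reads(a$genome, coverage = 5, mean_len = 4000, len_sd = 400,
                       error_rate = 0.1, seed = 9)
  r2 <- simulate_reads(a$genome, coverage = 5, mean_len = 4000, len_sd = 400,
                       error_rate = 0.1, seed = 9)
  expect_identical(r1, r2)

  o1 <- emit_overlaps(r1$truth, 500, spurious_n = 5, min_sep_bins = 5,
                      map = a$map, seed = 4)
  o2 <- emit_overlaps(r1$truth, 500, spurious_n = 5, min_sep_bins = 5,
                      map = a$map, seed = 4)
  expect_identical(o1, o2)
})

test_that("marker and bin densities land near their targets with spaced bins", {
  sim <- simulate_genome_and_map(1, 200000, 0.008, 200, seed = 77)
  m <- sim$map$markers
  expect_equal(nrow(m), 1600)
  bin_density <- nrow(sim$map$bins) / 200000
  expect_gt(bin_density, 0.0013)
  expect_lt(bin_density, 0.0027)

  # bins are separated by at least the spacing; markers within a bin are not
  first_pos <- tapply(m$pos, m$bin_id, min)
  last_pos <- tapply(m$pos, m$bin_id, max)
  ord <- order(first_pos)
  gaps <- first_pos[ord][-1] - last_pos[ord][-length(ord)]
  expect_true(all(gaps >= 200))
  within <- unlist(tapply(m$pos, m$bin_id, function(p) diff(sort(p))),
                   use.names = FALSE)
  expect_true(all(within < 200))
})

test_that("read counts follow the coverage arithmetic and truth tiles the genome", {
  sim <- simulate_genome_and_map(1, 300000, 0.008, 200, seed = 55)
  rd <- simulate_reads(sim$genome, coverage = 40, mean_len = 5000, len_sd = 500,
                       error_rate = 0, seed = 56)
  expect_equal(nrow(rd$truth), 2400, tolerance = 0.1)

  # breadth of coverage from the truth intervals
  tr <- rd$truth[order(rd$truth$start), ]
  covered <- 0
  reach <- 0
  for (i in seq_len(nrow(tr))) {
    s <- max(tr$start[i], reach)
    if (tr$end[i] > s) covered <- covered + tr$end[i] - s
    reach <- max(reach, tr$end[i])
  }
  expect_gte(covered / 300000, 0.99)
})

test_that("error-free reads are exact genome substrings; errors inflate length", {
  sim <- simulate_genome_and_map(1, 50000, 0.008, 200, seed = 61)
  rd <- simulate_reads(sim$genome, coverage = 3, mean_len = 3000, len_sd = 300,
                       error_rate = 0, seed = 62)
  genome <- sim$genome$sequences[[1]]
  for (i in seq_len(nrow(rd$truth))) {
    raw <- substr(genome, rd$truth$start[i] + 1, rd$truth$end[i])
    want <- if (rd$truth$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(raw)))
    } else raw
    expect_identical(unname(rd$reads[[rd$truth$read_id[i]]]), want)
  }

  err <- simulate_reads(sim$genome, coverage = 5, mean_len = 3000, len_sd = 300,
                        error_rate = 0.1, seed = 63)
  # insertion-biased 6:2:2 mix at 10% errors adds about 4% length
  ratio <- sum(err$truth$read_len) / sum(err$truth$span)
  expect_gt(ratio, 1.02)
  expect_lt(ratio, 1.06)
})

test_that("true alignments and overlaps reflect the recorded origins", {
  truth <- data.frame(read_id = c("ra", "rb"), chrom = "chr1",
                      start = c(0, 5000), end = c(8000, 13000),
                      strand = c("+", "-"), span = 8000, read_len = 8000,
                      stringsAsFactors = FALSE)
  aln <- emit_true_alignments(truth, c(chr1 = 20000))
  expect_equal(aln$qstart, c(0, 0))
  expect_equal(aln$qend, c(8000, 8000))
  expect_equal(aln$tstart, truth$start)
  expect_equal(aln$tend, truth$end)

  ovl <- emit_overlaps(truth, min_overlap = 2000)
  expect_equal(nrow(ovl), 1L)
  expect_equal(ovl$nmatch, 3000)
  expect_equal(ovl$strand, "-")
  # suffix of ra ([5000,8000) on a plus-strand read) ...
  expect_equal(c(ovl$qstart, ovl$qend), c(5000, 8000))
  # ... meets the prefix of rb, which on a minus-strand read is its tail
  expect_equal(c(ovl$tstart, ovl$tend), c(5000, 8000))
})

test_that("injected spurious overlaps join reads at least min_sep_bins apart", {
  sim <- simulate_genome_and_map(2, 60000, 0.008, 200, seed = 71)
  rd <- simulate_reads(sim$genome, coverage = 8, mean_len = 4000, len_sd = 400,
                       error_rate = 0, seed = 72)
  ovl <- emit_overlaps(rd$truth, min_overlap = 500, spurious_n = 20,
                       min_sep_bins = 5, map = sim$map, seed = 73)
  sp <- attr(ovl, "spurious_pairs")
  expect_equal(nrow(sp), 20L)
  rng <- acceptable_colour_range(rd$truth, sim$map)
  rownames(rng) <- rng$read_id
  tr <- rd$truth
  rownames(tr) <- tr$read_id
  for (i in seq_len(nrow(sp))) {
    a <- sp$a[i]; b <- sp$b[i]
    if (tr[a, "chrom"] != tr[b, "chrom"]) next
    gap <- max(rng[b, "low"] - rng[a, "high"], rng[a, "low"] - rng[b, "high"])
    expect_gte(gap, 5)
  }

  # with no injection the overlap file is purely truth-supported
  clean <- emit_overlaps(rd$truth, min_overlap = 500)
  g <- build_graph_from_paf(clean, min_overlap = 500)
  ev <- evaluate_edges(g, rd$truth)
  expect_equal(ev$links[ev$category == "spurious"], 0L)

  # impossible requests fail loudly
  tight <- rd$truth[1:2, ]
  expect_error(emit_overlaps(tight, 500, spurious_n = 5, min_sep_bins = 1000,
                             map = sim$map, seed = 1),
               "could not find")
})

test_that("acceptable colour ranges match a linear marker scan", {
  map <- mk_map(n_bins = 10, chroms = "chrA", spacing = 1000)
  # markers sit at 500, 1500, ..., 9500; a read over [3600, 6600) has
  # flanking markers in bins 3 and 7
  truth <- data.frame(read_id = "r", chrom = "chrA", start = 3600, end = 6600)
  rng <- acceptable_colour_range(truth, map)
  expect_equal(c(rng$low, rng$high), c(colour(0, 3), colour(0, 7)))

  # clamped at the chromosome start
  early <- data.frame(read_id = "r", chrom = "chrA", start = 0, end = 300)
  rng <- acceptable_colour_range(early, map)
  expect_equal(c(rng$low, rng$high), c(colour(0, 0), colour(0, 0)))

  sim <- simulate_genome_and_map(2, 50000, 0.008, 200, seed = 81)
  rd <- simulate_reads(sim$genome, coverage = 40, mean_len = 1500, len_sd = 150,
                       error_rate = 0, seed = 82)
  rng <- acceptable_colour_range(rd$truth, sim$map)
  m <- sim$map$markers
  for (i in sample(nrow(rd$truth), 1000)) {
    mm <- m[m$contig == rd$truth$chrom[i], ]
    before <- mm$colour[mm$pos <= rd$truth$start[i]]
    after <- mm$colour[mm$pos >= rd$truth$end[i]]
    low <- if (length(before) > 0) before[which.max(mm$pos[mm$pos <= rd$truth$start[i]])] else min(mm$colour)
    high <- if (length(after) > 0) after[which.min(mm$pos[mm$pos >= rd$truth$end[i]])] else max(mm$colour)
    expect_equal(c(rng$low[i], rng$high[i]), c(low, high))
  }
})

test_that("evaluation classifies colourings and edges against the truth", {
  env <- small_sim(seed = 33, spurious_n = 8)
  ev <- evaluate_against_truth(colouring = env$colouring, graph = env$graph,
                               map = env$sim$map, truth = env$truth)
  expect_equal(ev$colouring$pct[ev$colouring$category == "inside"], 100)

  # edge classification equals a brute re-classification from the truth
  cls <- maptig:::classify_links(env$graph, env$truth)
  tr <- env$truth
  rownames(tr) <- tr$read_id
  brute <- vapply(seq_len(nrow(cls)), function(i) {
    a <- cls$a[i]; b <- cls$b[i]
    tr[a, "chrom"] == tr[b, "chrom"] &&
      min(tr[a, "end"], tr[b, "end"]) > max(tr[a, "start"], tr[b, "start"])
  }, logical(1))
  expect_equal(cls$genomic, brute)
  expect_equal(ev$edges$links[ev$edges$category == "spurious"], sum(!brute))

  # a graph over unknown reads cannot be evaluated
  alien <- mk_graph(data.frame(from = "x+", to = "y+", ol = 1000))
  expect_error(evaluate_edges(alien, env$truth), "without truth")
})
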