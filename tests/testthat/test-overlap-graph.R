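test_that("overlap records classify into dovetail, containment and internal match", {
  # A[0,10000) and B[8000,18000): 2000 bp suffix-prefix overlap
  dove <- mk_paf("A", 10000, 8000, 10000, "+", "B", 10000, 0, 2000)
  g <- build_graph_from_paf(dove, min_overlap = 1000)
  expect_equal(nrow(g$edges), 2L)
  e <- g$edges[g$edges$from_id == "A", ]
  expect_equal(unname(unlist(e[c("from_strand", "to_id", "to_strand")])),
               c("+", "B", "+"))
  expect_equal(e$overlap_len, 2000)
  m <- g$edges[g$edges$from_id == "B", ]
  expect_equal(unname(unlist(m[c("from_strand", "to_id", "to_strand")])),
               c("-", "A", "-"))

  # read fully inside another: contained read removed, no edge
  cont <- mk_paf("B", 4000, 0, 4000, "+", "A", 10000, 3000, 7000)
  g <- build_graph_from_paf(cont, min_overlap = 1000)
  expect_false("B" %in% g$reads$read_id)
  expect_equal(nrow(g$edges), 0L)

  # long overhangs on both flanks: internal match, no edge
  int <- mk_paf("A", 10000, 3000, 6000, "+", "B", 10000, 4000, 7000)
  g <- build_graph_from_paf(int, min_overlap = 1000)
  expect_equal(nrow(g$edges), 0L)

  # opposite-strand dovetail: A+ -> B-
  rev <- mk_paf("A", 10000, 8000, 10000, "-", "B", 10000, 8000, 10000)
  g <- build_graph_from_paf(rev, min_overlap = 1000)
  e <- g$edges[g$edges$from_id == "A" & g$edges$from_strand == "+", ]
  expect_equal(nrow(e), 1L)
  expect_equal(unname(unlist(e[c("to_id", "to_strand")])), c("B", "-"))

  # overlaps below min_overlap and self-records are dropped
  short <- mk_paf("A", 10000, 9500, 10000, "+", "B", 10000, 0, 500)
  expect_equal(nrow(build_graph_from_paf(short, min_overlap = 1000)$edges), 0L)
  self <- mk_paf("A", 10000, 8000, 10000, "+", "A", 10000, 0, 2000)
  expect_equal(nrow(build_graph_from_paf(self)$edges), 0L)
})

test_that("a staggered read chain builds a single path per strand", {
  n <- 10
  truth <- data.frame(read_id = sprintf("r%02d", 1:n), chrom = "chr1",
                      start = (0:(n - 1)) * 5000, end = (0:(n - 1)) * 5000 + 8000,
                      strand = "+", span = 8000, read_len = 8000,
                      stringsAsFactors = FALSE)
  ovl <- emit_overlaps(truth, min_overlap = 2000)
  g <- build_graph_from_paf(ovl, min_overlap = 2000)
  expect_equal(nrow(g$reads), n)
  expect_equal(n_links(g), n - 1L)
  utg <- extract_unitigs(g)
  expect_length(utg, 1L)
  expect_equal(utg[[1]]$read_ids, sprintf("r%02d", 1:n))
  maptig:::assert_graph_symmetry(g)
})

test_that("GFA round-trips topology, overlap lengths and colour tags byte-stably", {
  g <- random_graph(n_reads = 12, n_links = 24, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".gfa")
  f2 <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, f1)
  back <- load_gfa(f1)
  expect_equal(back$reads, g$reads, ignore_attr = TRUE)
  eo <- function(e) e[order(e$from_id, e$from_strand, e$to_id, e$to_strand), ]
  expect_equal(eo(back$edges), eo(g$edges), ignore_attr = TRUE)
  expect_equal(back$colours, g$colours)
  write_gfa(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GFA parsing handles colour tags and rejects non-match CIGARs", {
  f <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0",
               "S\ta\t*\tLN:i:5000\tcl:Z:3,4",
               "S\tb\t*\tLN:i:6000",
               "L\ta\t+\tb\t+\t1200M"), f)
  g <- load_gfa(f)
  expect_equal(nrow(g$reads), 2L)
  expect_equal(nrow(g$edges), 2L)  # mirror restored
  expect_equal(g$colours[["a"]], c(3, 4))
  maptig:::assert_graph_symmetry(g)

  writeLines(c("S\ta\t*\tLN:i:5000", "S\tb\t*\tLN:i:6000",
               "L\ta\t+\tb\t+\t100M20D"), f)
  expect_error(load_gfa(f), "unsupported")
})

test_that("attached colours are shared by both orientations and stray reads counted", {
  g <- mk_graph(data.frame(from = c("a+", "b+"), to = c("b+", "c+"), ol = 2000))
  cl <- list(a = colour(0, 1), b = colour(0, 2), zz = colour(0, 9))
  g <- attach_colours(g, cl)
  expect_equal(g$colours[["a"]], colour(0, 1))
  expect_equal(g$colours[["c"]], numeric(0))
  expect_equal(attr(g, "ignored_colourings"), 1L)
  # one colour set per read: both orientations read the same set by construction
  expect_equal(colour_consistent_degrees(g, "b", "+", d = 1),
               colour_consistent_degrees(g, "b", "-", d = 1)[c(2, 1)],
               ignore_attr = TRUE)
})

test_that("colour-consistent degrees match the set-comprehension definition", {
  # v coloured {5} with in-neighbours {4}, {5}, {9}: indegree 2 at d = 1
  g <- mk_graph(data.frame(from = c("a+", "b+", "c+"), to = c("v+", "v+", "v+"),
                           ol = 1000),
                colours = list(v = colour(0, 5), a = colour(0, 4),
                               b = colour(0, 5), c = colour(0, 9)))
  expect_equal(unname(colour_consistent_degrees(g, "v", "+", d = 1)), c(2, 0))

  iso <- mk_graph(data.frame(from = "a+", to = "b+", ol = 1000),
                  extra_reads = "z")
  expect_equal(unname(colour_consistent_degrees(iso, "z", "+", d = 1)), c(0, 0))

  for (seed in 1:6) {
    g <- random_graph(n_reads = 20, n_links = 40, seed = seed)
    tab <- maptig:::cc_degree_table(g, 1)
    for (i in sample(nrow(tab), 10)) {
      expect_equal(c(tab$ccin[i], tab$ccout[i]),
                   unname(brute_cc_degrees(g, tab$vertex[i], 1)))
    }
  }
})

test_that("colour-consistent degree is bounded by plain degree and monotone in d", {
  g <- random_graph(n_reads = 15, n_links = 35, seed = 99)
  verts <- c(paste0(g$reads$read_id, "+"), paste0(g$reads$read_id, "-"))
  deg <- maptig:::degree_table(g$edges, verts)
  prev <- NULL
  for (d in 1:4) {
    tab <- maptig:::cc_degree_table(g, d)
    expect_true(all(tab$ccout <= deg$outdeg[tab$vertex]))
    expect_true(all(tab$ccin <= deg$indeg[tab$vertex]))
    if (!is.null(prev)) {
      expect_true(all(tab$ccout >= prev$ccout))
      expect_true(all(tab$ccin >= prev$ccin))
    }
    prev <- tab
  }
})
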