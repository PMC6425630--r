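green <- colour(0, 3)

test_that("colour propagation fills uncoloured reads from nearby coloured ones", {
  g <- mk_graph(data.frame(from = c("a+", "f+"), to = c("f+", "b+"), ol = 2000),
                colours = list(a = green, b = green))
  g2 <- propagate_colours(g, depth_limit = 10)
  expect_equal(g2$colours[["f"]], green)
  expect_equal(g2$propagated, "f")
})

test_that("propagation is depth-limited and seeded only by the original colouring", {
  # chain u01..u12 of uncoloured reads ending at a coloured read
  n <- 12
  ids <- sprintf("u%02d", 1:n)
  edges <- data.frame(from = paste0(c(ids, "c0"), "+")[1:n],
                      to = paste0(c(ids[-1], "c0"), "+"), ol = 2000)
  g <- mk_graph(edges, colours = list(c0 = colour(0, 7)))
  g2 <- propagate_colours(g, depth_limit = 10)
  expect_equal(lengths(g2$colours[c("u01", "u02")]), c(u01 = 0L, u02 = 0L))
  expect_true(all(lengths(g2$colours[ids[3:12]]) == 1L))
  # a second pass changes nothing: newly coloured reads never seed each other
  g3 <- propagate_colours(g2, depth_limit = 10)
  expect_equal(g3$colours, g2$colours)
  expect_equal(g3$propagated, g2$propagated)
})

test_that("an isolated uncoloured read stays uncoloured", {
  g <- mk_graph(data.frame(from = "a+", to = "b+", ol = 2000),
                colours = list(a = green), extra_reads = "far")
  g2 <- propagate_colours(g)
  expect_equal(g2$colours[["far"]], numeric(0))
})

test_that("propagated reads with gapped or multi-chromosome colours are removed", {
  mkprop <- function(cols) {
    g <- mk_graph(data.frame(from = c("a+", "f+"), to = c("f+", "b+"), ol = 2000),
                  colours = list(a = cols[[1]], b = cols[[2]]))
    propagate_colours(g)
  }
  # ordinals 2 and 7: four missing bins
  g <- drop_conflicting_vertices(mkprop(list(colour(0, 2), colour(0, 7))))
  expect_false("f" %in% g$reads$read_id)
  expect_equal(attr(g, "conflicts_removed"), 1L)

  # consecutive ordinals are fine
  g <- drop_conflicting_vertices(mkprop(list(colour(0, 2), colour(0, 3))))
  expect_true("f" %in% g$reads$read_id)

  # a single missing ordinal is within the adjacency slack
  g <- drop_conflicting_vertices(mkprop(list(colour(0, 2), colour(0, 4))))
  expect_true("f" %in% g$reads$read_id)

  # two chromosomes always conflict
  g <- drop_conflicting_vertices(mkprop(list(colour(0, 2), colour(1, 2))))
  expect_false("f" %in% g$reads$read_id)

  # mapping-derived (non-propagated) colourings are not touched
  g <- mk_graph(data.frame(from = "a+", to = "b+", ol = 2000),
                colours = list(a = c(colour(0, 0), colour(0, 9)), b = green))
  g2 <- drop_conflicting_vertices(propagate_colours(g))
  expect_true("a" %in% g2$reads$read_id)
})

test_that("inconsistently coloured edges are removed with their mirrors", {
  # ordinals 0 and 2 at d = 1: inconsistent
  g <- mk_graph(data.frame(from = "a+", to = "i+", ol = 2000),
                colours = list(a = colour(0, 0), i = colour(0, 2)))
  res <- remove_inconsistent_edges(g, d = 1)
  expect_equal(nrow(res$graph$edges), 0L)
  expect_equal(res$report$links_removed[res$report$chromosome == "total"], 1L)

  # a shared colour is consistent at any d
  g <- mk_graph(data.frame(from = "a+", to = "b+", ol = 2000),
                colours = list(a = c(colour(0, 0), colour(0, 5)),
                               b = colour(0, 5)))
  expect_equal(nrow(remove_inconsistent_edges(g, d = 0)$graph$edges), 2L)

  # an uncoloured endpoint keeps the edge
  g <- mk_graph(data.frame(from = "a+", to = "b+", ol = 2000),
                colours = list(a = colour(0, 0)))
  expect_equal(nrow(remove_inconsistent_edges(g, d = 0)$graph$edges), 2L)
})

test_that("edge removal matches the brute-force definition and is monotone in d", {
  for (seed in 1:8) {
    g <- random_graph(n_reads = 14, n_links = 30, seed = seed)
    prev <- NULL
    for (d in 0:3) {
      res <- remove_inconsistent_edges(g, d = d)
      kept <- res$graph$edges
      removed_brute <- brute_inconsistent_edges(g, d)
      key <- function(e) sort(paste(e$from_id, e$from_strand, e$to_id, e$to_strand))
      expect_equal(key(removed_brute),
                   key(g$edges[!(paste(g$edges$from_id, g$edges$from_strand,
                                       g$edges$to_id, g$edges$to_strand) %in%
                                   paste(kept$from_id, kept$from_strand,
                                         kept$to_id, kept$to_strand)), ]))
      maptig:::assert_graph_symmetry(res$graph)
      n_rem <- res$report$links_removed[res$report$chromosome == "total"]
      if (!is.null(prev)) expect_lte(n_rem, prev)
      prev <- n_rem
    }
  }
})

test_that("transitive edges and short side branches are simplified away", {
  # triangle with additive overlaps: reads 8000 bp, u->v 6000, v->w 6000,
  # direct u->w overlap 4000 = 6000 + 6000 - 8000
  tri <- mk_graph(data.frame(from = c("u+", "v+", "u+"), to = c("v+", "w+", "w+"),
                             ol = c(6000, 6000, 4000)))
  s <- simplify_graph(tri)
  expect_equal(n_links(s), 2L)
  expect_false(any(s$edges$from_id == "u" & s$edges$to_id == "w"))
  maptig:::assert_graph_symmetry(s)

  # 2-read dead-end branch merging into a long path
  ids <- sprintf("p%d", 1:8)
  main <- data.frame(from = paste0(ids[-8], "+"), to = paste0(ids[-1], "+"),
                     ol = 6000)
  tip <- data.frame(from = c("t1+", "t2+"), to = c("t2+", "p7+"), ol = 6000)
  g <- mk_graph(rbind(main, tip))
  s <- simplify_graph(g)
  expect_false(any(c("t1", "t2") %in% s$reads$read_id))
  expect_true(all(ids %in% s$reads$read_id))

  # a clean chain is left untouched
  chain <- mk_graph(main)
  s <- simplify_graph(chain)
  expect_equal(s$edges, chain$edges, ignore_attr = TRUE)
  expect_equal(nrow(s$reads), 8L)
})

test_that("the cleaning pipeline only ever shrinks the graph", {
  env <- small_sim(seed = 5, spurious_n = 5)
  g0 <- env$graph
  res <- clean_graph(g0, d = 1)
  g1 <- res$graph
  expect_true(all(g1$reads$read_id %in% g0$reads$read_id))
  ekey <- function(g) paste(g$edges$from_id, g$edges$from_strand,
                            g$edges$to_id, g$edges$to_strand)
  expect_true(all(ekey(g1) %in% ekey(g0)))
  for (id in g1$reads$read_id) {
    expect_true(all(g1$colours[[id]] %in%
                      c(g0$colours[[id]], unlist(g0$colours, use.names = FALSE))))
  }
  expect_true(all(unlist(res$report) >= 0))
  maptig:::assert_graph_symmetry(g1)
})
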