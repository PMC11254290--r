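test_that("edge lists read back what was written, with validation", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb\t1", "b\tc\t1", "a\tc\t1"), f)
  g <- read_edge_list(f)
  expect_s3_class(g, "ppi_graph")
  expect_equal(g$nodes, c("a", "b", "c"))
  expect_equal(nrow(g$edges), 3L)

  # round trip is bit-identical
  f2 <- withr::local_tempfile()
  write_edge_list(g, f2)
  g2 <- read_edge_list(f2)
  expect_identical(g, g2)
  f3 <- withr::local_tempfile()
  write_edge_list(g2, f3)
  expect_identical(readLines(f2), readLines(f3))

  # directed column survives a round trip
  gd <- orient_edges(g, data.frame(from = "a", to = "b"))
  f4 <- withr::local_tempfile()
  write_edge_list(gd, f4)
  expect_identical(read_edge_list(f4, directed_column = TRUE), gd)
})

test_that("malformed and invalid edge lists are rejected with context", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb\t1", "b\tc"), f)
  expect_error(read_edge_list(f), "line 2")

  writeLines(c("a\tb\t0"), f)
  expect_error(read_edge_list(f), "weight")

  writeLines(c("a\tb\t1", "b\ta\t2"), f)
  expect_error(read_edge_list(f), "duplicate")

  expect_error(ppi_graph(data.frame(u = "a", v = "a", weight = 1)),
               "self-loop")
})

test_that("symmetric normalization matches hand-computed walk matrices", {
  g2 <- ppi_graph(data.frame(u = "a", v = "b", weight = 1))
  W2 <- as.matrix(normalize_symmetric(g2))
  expect_equal(W2, matrix(c(0, 1, 1, 0), 2, 2,
                          dimnames = list(c("a", "b"), c("a", "b"))))

  gp <- path_graph(c("a", "b", "c"))
  Wp <- as.matrix(normalize_symmetric(gp))
  expect_equal(Wp["a", "b"], 1 / sqrt(2))
  expect_equal(Wp["b", "c"], 1 / sqrt(2))
  expect_equal(Wp["a", "c"], 0)
  expect_equal(Wp, t(Wp))
})

test_that("D^{1/2}1 is a left fixed vector of the symmetric walk matrix", {
  for (s in 1:3) {
    g <- er_connected(25, 0.15, seed = s)
    W <- normalize_symmetric(g)
    v <- sqrt(weighted_degrees(g))
    expect_lt(max(abs(as.numeric(v %*% W) - v)), 1e-10)
  }
})

test_that("column normalization is column-stochastic and checks strong connectivity", {
  g <- ppi_graph(data.frame(u = "a", v = "b", weight = 1))  # undirected 2-cycle
  W <- as.matrix(normalize_column(g))
  expect_equal(W, matrix(c(0, 1, 1, 0), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))

  g3 <- er_connected(20, 0.2, seed = 4)
  expect_equal(max(abs(Matrix::colSums(normalize_column(g3)) - 1)), 0,
               tolerance = 1e-12)

  one_way <- ppi_graph(data.frame(u = "a", v = "b", weight = 1, directed = 1))
  expect_error(normalize_column(one_way), "strongly connected")
  expect_error(normalize_symmetric(one_way), "undirected")
})

test_that("disconnected graphs are refused, with an opt-in largest component", {
  g <- ppi_graph(data.frame(u = c("a", "c", "x"), v = c("b", "a", "y"),
                            weight = 1))
  expect_error(normalize_symmetric(g), "component")
  expect_message(gl <- largest_component(g), "dropped 2")
  expect_equal(gl$nodes, c("a", "b", "c"))
})

test_that("orient_edges commits listed edges and rejects conflicts", {
  g <- triangle_graph()
  expect_identical(orient_edges(g, data.frame(u = character(), v = character())), g)

  go <- orient_edges(g, data.frame(from = "b", to = "a"))
  e <- go$edges
  expect_true(e$directed[e$u == "b" & e$v == "a"])
  expect_equal(sum(e$directed), 1L)
  expect_equal(sort(e$weight), sort(g$edges$weight))

  expect_error(orient_edges(g, data.frame(from = c("a", "b"), to = c("b", "a"))),
               "conflicting")
  expect_error(orient_edges(g, data.frame(from = "a", to = "zz")), "not in the network")
})

test_that("flip_directions reverses one-way edges and is an involution", {
  g <- triangle_graph()
  expect_identical(flip_directions(g), g)  # fully undirected: no-op
  go <- orient_edges(g, data.frame(from = "a", to = "b"))
  gf <- flip_directions(go)
  e <- gf$edges
  expect_true(e$directed[e$u == "b" & e$v == "a"])
  expect_identical(flip_directions(gf), go)
})
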