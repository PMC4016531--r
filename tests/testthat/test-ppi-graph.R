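test_that("interaction table reader drops self-loops and keeps max duplicate weight", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t3", "B\tC\t5", "A\tA\t9"), f)
  net <- read_interaction_table(f)
  expect_equal(nrow(net$edges), 2)
  expect_false("A" %in% net$edges$a & "A" %in% net$edges$b &
                 any(net$edges$a == net$edges$b))

  writeLines(c("A\tB\t3", "B\tA\t7"), f)
  expect_warning(net2 <- read_interaction_table(f), "duplicate")
  expect_equal(nrow(net2$edges), 1)
  expect_equal(edge_weight(net2, "A", "B"), 7)

  writeLines(character(0), f)
  empty <- read_interaction_table(f)
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$proteins, 0)
})

test_that("interaction table reader detects headers and reports bad rows", {
  f <- withr::local_tempfile()
  writeLines(c("proteinA\tproteinB\tscore", "A\tB\t3.5"), f)
  net <- read_interaction_table(f)
  expect_equal(edge_weight(net, "A", "B"), 3.5)

  writeLines(c("A\tB\t3", "C\tD"), f)
  expect_error(read_interaction_table(f), "line 2")

  writeLines(c("A\tB\t0"), f)
  expect_error(read_interaction_table(f), "[Nn]on-positive")

  writeLines(c("A\tB\t3", "C\tD\tx"), f)
  expect_error(read_interaction_table(f), "line 2")
})

test_that("writing then reading an interaction table round-trips exactly", {
  for (seed in 1:5) {
    edges <- random_graph_edges(8, 0.5, seed)
    net <- ppi_network(edges)
    f <- withr::local_tempfile()
    write_interaction_table(net, f)
    back <- read_interaction_table(f)
    expect_identical(back$edges, net$edges)
  }
})

test_that("domain table lookups are total and merge repeated rows as multisets", {
  f <- withr::local_tempfile()
  writeLines(c("A\td1\td2", "B\td1"), f)
  dom <- read_domain_table(f)
  expect_equal(domain_count(dom, "A"), 2)
  expect_equal(domain_count(dom, "B"), 1)
  expect_equal(protein_domains(dom, "C"), character(0))
  expect_equal(domain_count(dom, "C"), 0)

  writeLines(c("A\td1", "A\td1"), f)
  dom2 <- read_domain_table(f)
  expect_equal(protein_domains(dom2, "A"), c("d1", "d1"))
  expect_equal(domain_count(dom2, "A"), 2)

  expect_error(read_domain_table(file.path(tempdir(), "absent-file.tsv")),
               "not found")
})

test_that("complex catalogue partitions by size and validates members", {
  f <- withr::local_tempfile()
  writeLines(c("A B", "C D E", "F G H I J"), f)
  cat3 <- read_complex_catalogue(f)
  expect_equal(sort(cat3$sizes), c(2, 3, 5))
  expect_equal(length(catalogue_by_size(cat3, size = 3)), 1)
  expect_equal(length(catalogue_by_size(cat3, min_size = 4)), 1)

  writeLines(c("A B", "C C"), f)
  expect_error(read_complex_catalogue(f), "line 2")
})

test_that("triplet connectivity follows the single-connected-component rule", {
  net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C"),
                                weight = c(1, 1)))
  expect_true(is_connected_triplet(net, c("A", "B", "C")))   # path
  net1 <- ppi_network(data.frame(a = "A", b = "B", weight = 1))
  expect_false(is_connected_triplet(net1, c("A", "B", "C"))) # one edge
  tri <- ppi_network(data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
                                weight = c(1, 1, 1)))
  expect_true(is_connected_triplet(tri, c("A", "B", "C")))   # triangle
  expect_false(is_connected_triplet(net, c("A", "B", "Z")))  # absent member
})

test_that("triplet enumeration reproduces the worked fixture and simple graphs", {
  keys <- enumerate_connected_triplets(g0_network())
  expect_equal(triplet_members(keys),
               list(c("A", "B", "C"), c("A", "B", "D"), c("A", "C", "D"),
                    c("A", "D", "E"), c("B", "C", "D"), c("C", "D", "E")))

  tri <- ppi_network(data.frame(a = c("X", "Y", "X"), b = c("Y", "Z", "Z"),
                                weight = 1:3))
  expect_length(enumerate_connected_triplets(tri), 1)

  star <- ppi_network(data.frame(a = rep("H", 3), b = c("X", "Y", "Z"),
                                 weight = c(1, 2, 3)))
  expect_equal(triplet_members(enumerate_connected_triplets(star)),
               list(c("H", "X", "Y"), c("H", "X", "Z"), c("H", "Y", "Z")))
})

test_that("enumeration agrees with the cubic brute-force oracle on random graphs", {
  for (seed in 1:40) {
    n <- 5 + (seed %% 8)
    edges <- random_graph_edges(n, 0.35, seed)
    if (nrow(edges) == 0) next
    net <- ppi_network(edges)
    expect_identical(enumerate_connected_triplets(net),
                     oracle_all_triplets(edges))
  }
})

test_that("neighboring triplets match the shared-member filter and exclude x", {
  net <- g0_network()
  nx <- neighboring_triplets(net, c("A", "B", "C"))
  expect_equal(triplet_members(nx),
               list(c("A", "B", "D"), c("A", "C", "D"), c("A", "D", "E"),
                    c("B", "C", "D"), c("C", "D", "E")))
  expect_length(nx, 5)

  # isolated triangle: no neighboring triplets
  tri <- ppi_network(data.frame(a = c("X", "Y", "X"), b = c("Y", "Z", "Z"),
                                weight = 1:3))
  expect_length(neighboring_triplets(tri, c("X", "Y", "Z")), 0)

  for (seed in 1:15) {
    edges <- random_graph_edges(7, 0.45, seed + 100)
    net <- ppi_network(edges)
    all_keys <- enumerate_connected_triplets(net)
    if (length(all_keys) == 0) next
    for (k in all_keys[seq_len(min(3, length(all_keys)))]) {
      x <- triplet_members(k)[[1]]
      nx <- neighboring_triplets(net, x)
      expect_identical(nx, oracle_neighbors(edges, x))
      expect_true(all(nx %in% all_keys))
      expect_false(triplet_key(x) %in% nx)
      expect_true(all(vapply(triplet_members(nx), function(m) {
        length(intersect(m, x)) >= 1
      }, TRUE)))
    }
  }
})
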