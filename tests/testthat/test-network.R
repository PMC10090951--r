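# independent brute-force geodesic oracle: enumerate all simple paths by
# depth-first search over the adjacency list, keep those of minimum length
bruteGeodesics <- function(edges, from, to) {
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  paths <- list()
  walk <- function(node, visited) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    for (nxt in adj[[node]]) {
      if (!nxt %in% visited) walk(nxt, c(visited, nxt))
    }
  }
  if (!from %in% names(adj) || !to %in% names(adj)) return(character())
  walk(from, from)
  if (!length(paths)) return(character())
  lens <- lengths(paths)
  shortest <- paths[lens == min(lens)]
  unique(vapply(shortest, function(nodes) {
    if (nodes[1L] > nodes[length(nodes)]) nodes <- rev(nodes)
    paste(nodes, collapse = "->")
  }, ""))
}

edgeTable <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(protein1 = m[, 1], protein2 = m[, 2],
             combined_score = 900)
}

test_that("score cutoff filtering keeps the right edges", {
  df <- data.frame(protein1 = c("A", "B", "C"),
                   protein2 = c("B", "C", "D"),
                   combined_score = c(700, 500, 900))
  g <- loadInteractions(df, cutoff = 667)
  expect_equal(igraph::ecount(g@graph), 2L)
  gAll <- loadInteractions(df, cutoff = 0)
  expect_equal(igraph::ecount(gAll@graph), 3L)
  expect_error(loadInteractions(df, cutoff = 1000), "empty graph")
})

test_that("malformed and duplicate rows are handled", {
  df <- data.frame(protein1 = c("A", "B"), protein2 = c("B", "C"),
                   combined_score = c(700, NA))
  expect_error(loadInteractions(df, cutoff = 0), "malformed.*3")
  dup <- data.frame(protein1 = c("A", "B", "A"), protein2 = c("B", "A", "A"),
                    combined_score = c(700, 800, 999))
  g <- loadInteractions(dup, cutoff = 0)       # self-loop dropped, dup merged
  expect_equal(igraph::ecount(g@graph), 1L)
  expect_equal(igraph::E(g@graph)$combined_score, 800)
})

test_that("seeded geodesic sets are complete", {
  # path graph A-B-C: one geodesic
  g <- loadInteractions(edgeTable("A","B", "B","C"), cutoff = 0,
                        seeds = c("A", "C"))
  paths <- seededPaths(g)
  expect_identical(paths[["A|C"]], "A->B->C")

  # square A-B-C / A-D-C: two geodesics
  g2 <- loadInteractions(edgeTable("A","B", "B","C", "A","D", "D","C"),
                         cutoff = 0, seeds = c("A", "C"))
  expect_setequal(seededPaths(g2)[["A|C"]], c("A->B->C", "A->D->C"))

  # seeds in different components: empty set, no error
  g3 <- loadInteractions(edgeTable("A","B", "C","D"), cutoff = 0,
                         seeds = c("A", "C"))
  expect_length(seededPaths(g3)[["A|C"]], 0L)
})

test_that("geodesic engine agrees with brute-force enumeration on random small graphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    nodes <- LETTERS[seq_len(n)]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (sum(keep) < 2) next
    df <- data.frame(protein1 = pairs[keep, 1], protein2 = pairs[keep, 2],
                     combined_score = 900)
    g <- loadInteractions(df, cutoff = 0)   # seeds default to present nodes
    present <- igraph::V(g@graph)$name
    if (length(present) < 2) next
    for (k in 1:3) {
      pick <- sample(present, 2)
      got <- coupledGTPase:::.geodesics(g@graph, pick[1], pick[2])
      want <- bruteGeodesics(as.matrix(df[, 1:2]), pick[1], pick[2])
      expect_setequal(got, want)
    }
  }
})

test_that("node deletion produces the expected alteration fractions", {
  # square plus chord: A-L-C unique geodesic; deleting L leaves A-B-D-C-type
  # longer route, so the pair turns over completely (fraction 1)
  df <- edgeTable("A","L", "L","C", "A","B", "B","D", "D","C")
  g <- loadInteractions(df, cutoff = 0, seeds = c("A", "C"))
  d <- deleteNodeDiff(g, "L", anchor = "A")
  expect_equal(d$alteration_fraction[d$partner == "C"], 1)
  expect_equal(d$n_before[d$partner == "C"], 1L)
  expect_equal(d$n_after[d$partner == "C"], 1L)

  # deleting a node on no geodesic of the pair: fraction 0
  df2 <- edgeTable("A","C", "A","Z", "Z","C", "Z","Q")
  g2 <- loadInteractions(df2, cutoff = 0, seeds = c("A", "C", "Q"))
  d2 <- deleteNodeDiff(g2, "Q", anchor = "A")
  expect_equal(d2$alteration_fraction[d2$partner == "C"], 0)

  expect_error(deleteNodeDiff(g, "A", anchor = "A"), "not allowed")
  expect_error(deleteNodeDiff(g, "NOPE", anchor = "A"), "not found")
})

test_that("degree-0 and relabeled graphs behave as expected", {
  df <- edgeTable("A","B", "B","C", "A","D", "D","C", "E","B")
  g <- loadInteractions(rbind(df, data.frame(protein1 = "F", protein2 = "G",
                                             combined_score = 900)),
                        cutoff = 0, seeds = c("A", "C"))
  # E is on no A-C geodesic
  d <- deleteNodeDiff(g, "E", anchor = "A")
  expect_true(all(d$alteration_fraction == 0))

  # relabeling invariance: permute labels, fractions unchanged
  perm <- c(A = "W", B = "V", C = "U", D = "T", E = "S", F = "R", G = "Q")
  df2 <- data.frame(protein1 = perm[df$protein1], protein2 = perm[df$protein2],
                    combined_score = 900)
  g2 <- loadInteractions(df2, cutoff = 0, seeds = c("W", "U"))
  d2 <- deleteNodeDiff(g2, "V", anchor = "W")
  d1 <- deleteNodeDiff(g, "B", anchor = "A")
  expect_equal(sort(d2$alteration_fraction), sort(d1$alteration_fraction))
})

test_that("end-protein ranking counts impacted geodesics with stable ties", {
  df <- edgeTable("A","L", "L","C", "L","E", "A","F", "F","G", "G","C",
                  "G","E", "A","H")
  g <- loadInteractions(df, cutoff = 0, seeds = c("A", "C", "E", "H"))
  d <- deleteNodeDiff(g, "L", anchor = "A")
  r <- rankEndProteins(d)
  expect_true(all(r$partner %in% c("C", "E")))
  expect_true(all(diff(r$impact_count) <= 0))
  # no fraction-1 deltas -> empty ranking
  d0 <- deleteNodeDiff(g, "H", anchor = "A")
  expect_equal(nrow(rankEndProteins(d0)), 0L)
})

test_that("synthetic PPI fixture plants a recoverable linker", {
  fx <- generatePPIFixture(nNodes = 12, nSeeds = 5, seed = 3)
  d <- deleteNodeDiff(fx$graph, fx$linker, anchor = fx$anchor)
  hit <- d$partner[d$alteration_fraction == 1]
  expect_setequal(hit, fx$plantedPartners)
  r <- rankEndProteins(d)
  expect_setequal(r$partner, fx$plantedPartners)

  # minimal size and reproducibility
  fx6 <- generatePPIFixture(6, 3, seed = 9)
  d6 <- deleteNodeDiff(fx6$graph, fx6$linker, anchor = fx6$anchor)
  expect_setequal(d6$partner[d6$alteration_fraction == 1],
                  fx6$plantedPartners)
  fxA <- generatePPIFixture(10, 4, seed = 5)
  fxB <- generatePPIFixture(10, 4, seed = 5)
  expect_identical(fxA$edges, fxB$edges)

  expect_error(generatePPIFixture(6, 7, seed = 1), "infeasible")
  expect_error(generatePPIFixture(20, 2, seed = 1), "infeasible")
})
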