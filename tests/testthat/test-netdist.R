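rand_pair_data <- function(n_genes, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    list(expr = matrix(rnorm(n_genes * n_samples), n_genes,
                       dimnames = list(genes, paste0("s", 1:n_samples))),
         meth = matrix(rnorm(n_genes * n_samples), n_genes,
                       dimnames = list(genes, paste0("s", 1:n_samples))))
  })
}

test_that("combined similarity is a min-max normalized correlation product", {
  d <- rand_pair_data(5, seed = 2)
  cecm <- cecm_matrix(d$expr, d$meth)
  off <- cecm[upper.tri(cecm)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(cecm, t(cecm), ignore_attr = TRUE)
  # raw product check: all-ones biosim reduces to pure correlation product
  raw <- attr(cecm, "raw")
  expect_equal(raw[1, 2],
               cor(d$expr[1, ], d$expr[2, ]) * cor(d$meth[1, ], d$meth[2, ]))
  # extreme case: perfectly anti-correlated expression with correlated
  # methylation gives raw -1 -> mapped to the normalized minimum
  e <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  colnames(e) <- colnames(m) <- paste0("s", 1:4)
  cc <- cecm_matrix(e, m)
  expect_equal(attr(cc, "raw")["a", "b"], -1)
  expect_equal(cc["a", "b"], 0)

  expect_warning(cecm_matrix(rbind(e, z = rep(1, 4)), rbind(m, z = 1:4)),
                 "zero-variance")
})

test_that("dissimilarity is the elementwise complement", {
  expect_equal(dissimilarity(matrix(c(1, 0.3, 0.3, 1), 2)),
               matrix(c(0, 0.7, 0.7, 0), 2))
  expect_error(dissimilarity(matrix(c(1, 2), 1)), "\\[0, 1\\]")
  withr::with_seed(3, {
    x <- matrix(runif(16), 4); x <- (x + t(x)) / 2; diag(x) <- 1
    expect_equal(dissimilarity(x), 1 - x)
  })
})

test_that("PPI masking keeps exactly the listed edges with product weights", {
  genes <- paste0("g", 1:4)
  dsim <- matrix(0.5, 4, 4, dimnames = list(genes, genes)); diag(dsim) <- 0
  dsim["g1", "g2"] <- dsim["g2", "g1"] <- 0.3
  ppi <- data.frame(from = c("g1", "g3"), to = c("g2", "g4"), weight = c(1, 2))
  g <- mask_with_ppi(dsim, ppi)
  expect_equal(igraph::ecount(g), 2)
  expect_false(igraph::are_adjacent(g, "g1", "g3"))
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("g1", "g2"))]
  expect_equal(w, 1 * 0.3)
  w34 <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("g3", "g4"))]
  expect_equal(w34, 2 * 0.5)
  # a gene untouched by the edge list is kept as an isolated node
  g_iso <- mask_with_ppi(dsim, ppi[1, ])
  expect_true(all(genes %in% igraph::V(g_iso)$name))
  expect_equal(igraph::degree(g_iso)[["g4"]], 0)
  # full H on 4 genes -> complete weighted graph
  full <- data.frame(from = rep(genes, each = 4), to = rep(genes, 4))
  gf <- mask_with_ppi(dsim, full)
  expect_equal(igraph::ecount(gf), 6)
})

test_that("shortest distances take detours and match Floyd-Warshall", {
  # triangle shortcut p-x-q (0.2 + 0.3) beats the direct 0.9 edge
  genes <- c("p", "x", "q")
  dsim <- matrix(0, 3, 3, dimnames = list(genes, genes))
  dsim["p", "x"] <- dsim["x", "p"] <- 0.2
  dsim["x", "q"] <- dsim["q", "x"] <- 0.3
  dsim["p", "q"] <- dsim["q", "p"] <- 0.9
  ppi <- data.frame(from = c("p", "x", "p"), to = c("x", "q", "q"))
  wd <- all_pairs_wesd(mask_with_ppi(dsim, ppi))
  expect_equal(wd$wesd["p", "q"], 0.5)
  expect_equal(diag(wd$wesd), c(p = 0, x = 0, q = 0))
  expect_equal(wd$max, 0.5)
  expect_equal(wd$min, 0.2)
  expect_equal(wd$mean, mean(c(0.2, 0.3, 0.5)))

  # random graphs vs an independent all-pairs oracle
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      genes <- paste0("g", seq_len(n))
      adj <- matrix(Inf, n, n, dimnames = list(genes, genes))
      pairs <- which(upper.tri(adj), arr.ind = TRUE)
      on_ <- runif(nrow(pairs)) < 0.4
      w <- runif(nrow(pairs))
      edges <- data.frame(from = genes[pairs[on_, 1]], to = genes[pairs[on_, 2]])
      dsim <- matrix(0, n, n, dimnames = list(genes, genes))
      dsim[pairs[on_, , drop = FALSE]] <- w[on_]
      dsim <- pmax(dsim, t(dsim))
      adj[pairs[on_, , drop = FALSE]] <- w[on_]
      adj <- pmin(adj, t(adj))
      wd <- all_pairs_wesd(mask_with_ppi(dsim, edges))
      oracle <- oracle_floyd_warshall(adj)
      expect_equal(wd$wesd[genes, genes], oracle)
    }
  })
})

test_that("weighted distances form a metric on connected components", {
  withr::with_seed(21, {
    for (i in 1:5) {
      n <- 10
      genes <- paste0("g", 1:n)
      dsim <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
      dsim <- (dsim + t(dsim)) / 2; diag(dsim) <- 0
      pairs <- t(utils::combn(genes, 2))
      keep <- runif(nrow(pairs)) < 0.5
      wd <- all_pairs_wesd(mask_with_ppi(
        dsim, data.frame(from = pairs[keep, 1], to = pairs[keep, 2])))
      d <- wd$wesd
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      fin <- is.finite(d)
      for (a in 1:n) for (b in 1:n) if (fin[a, b])
        expect_true(all(d[a, b] <= d[a, ] + d[, b] + 1e-12))
    }
  })
})

test_that("pairwise thresholds follow the distance-deviation formula", {
  # hand-evaluated: UVmin 0.1, c1 0.10, c2 1.4826, med 1, MAD 0.5, WeSD 2
  # -> 0.1 * (1 - 0.10 * (2 - 1) / (1.4826 * 0.5)) = 0.0865506...
  genes <- paste0("g", 1:5)
  wesd <- matrix(0, 5, 5, dimnames = list(genes, genes))
  vals <- c(0.5, 0.5, 1, 1.5, 1.5, 2, 1, 1, 0.5, 1.5)  # med 1, MAD 0.5
  wesd[upper.tri(wesd)] <- vals
  wesd <- wesd + t(wesd)
  wv <- wv_threshold_matrix(wesd, uvmin = 0.1)
  expect_equal(median(vals), 1)
  expect_equal(median(abs(vals - 1)), 0.5)
  i2 <- which(wesd == 2, arr.ind = TRUE)[1, ]
  expect_equal(wv[i2[1], i2[2]], 0.1 * (1 - 0.10 * 1 / (1.4826 * 0.5)),
               tolerance = 1e-12)
  expect_equal(round(wv[i2[1], i2[2]], 5), 0.08651)
  # at the median the deviation vanishes; on the diagonal UVmin is returned
  imed <- which(wesd == 1, arr.ind = TRUE)[1, ]
  expect_equal(wv[imed[1], imed[2]], 0.1)
  expect_equal(unname(diag(wv)), rep(0.1, 5))
  # monotone decreasing in distance, proportional in UVmin
  expect_true(wv[which(wesd == 0.5)[1]] > wv[which(wesd == 1.5)[1]])
  expect_equal(wv_threshold_matrix(wesd, 0.2), 2 * wv)
  # degenerate spread falls back to UVmin
  flat <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(flat) <- 0
  expect_warning(wvf <- wv_threshold_matrix(flat, 0.3), "MAD = 0")
  expect_true(all(wvf == 0.3))
})

test_that("per-set thresholds average unordered pairs (ordered-sum oracle)", {
  genes <- c("a", "b", "c")
  wv <- matrix(0, 3, 3, dimnames = list(genes, genes))
  wv["a", "b"] <- wv["b", "a"] <- 0.1
  wv["a", "c"] <- wv["c", "a"] <- 0.2
  wv["b", "c"] <- wv["c", "b"] <- 0.3
  diag(wv) <- 0.15
  expect_equal(dbv_threshold(c("a+", "b-"), wv, 0.15), 0.1)
  expect_equal(dbv_threshold(c("a+", "b-", "c+"), wv, 0.15), 0.2)
  # oracle: ordered-pair sum with the /2 factor, divided by pair count
  ordered_sum <- 0
  for (p in genes) for (q in genes) if (p != q) ordered_sum <- ordered_sum + wv[p, q] / 2
  expect_equal(dbv_threshold(genes, wv, 0.15), ordered_sum / 3)
  expect_equal(dbv_threshold("a+", wv, 0.15), 0.15)          # singleton
  expect_equal(dbv_threshold(c("a+", "a-"), wv, 0.15), 0.15) # one gene, both signs
})

test_that("rule average distance handles degenerate and unreachable pairs", {
  genes <- c("a", "b", "c", "d")
  wesd <- matrix(Inf, 4, 4, dimnames = list(genes, genes))
  diag(wesd) <- 0
  wesd["a", "b"] <- wesd["b", "a"] <- 0.3
  wesd["a", "c"] <- wesd["c", "a"] <- 0.3
  wesd["b", "c"] <- wesd["c", "b"] <- 0.6
  expect_equal(avg_wesd(c("a+", "b-"), wesd), 0.3)
  expect_equal(avg_wesd(c("a+", "b-", "c+"), wesd), 0.4)
  expect_warning(aw <- avg_wesd(c("a+", "a-"), wesd), "single gene")
  expect_equal(aw, 0)
  # d unreachable: substitute the maximum finite distance (0.6)
  expect_equal(avg_wesd(c("a+", "d+"), wesd), 0.6)
})
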