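test_that("degree-centrality ranks match hand computation and tie handling", {
  n <- 5
  complete <- matrix(0.4, n, n); diag(complete) <- 0
  expect_equal(unname(degree_centrality_rank(complete)), rep((n + 1) / 2, n))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 0.5
  expect_equal(unname(which.max(degree_centrality_rank(star))), 1L)

  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.3
  w[3, 4] <- w[4, 3] <- 0.5
  # strengths: 0.2, 0.5, 0.8, 0.5
  expect_equal(unname(degree_centrality_rank(w)), c(1, 2.5, 4, 2.5))
  # invariant to uniform weight scaling
  expect_equal(degree_centrality_rank(3 * w), degree_centrality_rank(w))
  expect_error(degree_centrality_rank(-w), "negative")
})

test_that("neighborhood abnormality matches closed forms and brute force", {
  # constant map on a binary graph returns the constant
  gr <- (random_graph(15, 0.4, seed = 2) > 0) * 1
  a <- neighborhood_abnormality(gr, rep(3.3, 15))
  expect_equal(unname(a), rep(3.3, 15), tolerance = 1e-12)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 1.5
  expect_equal(neighborhood_abnormality(w, c(0, 2, 4))[[1]], 3.5)

  gr2 <- random_graph(20, 0.3, seed = 3)
  mp <- withr::with_seed(4, rnorm(20))
  a1 <- neighborhood_abnormality(gr2, mp)
  expect_equal(neighborhood_abnormality(2 * gr2, mp), 2 * a1, tolerance = 1e-12)
  # brute-force double loop
  oracle <- sapply(seq_len(20), function(i) {
    nb <- which(gr2[i, ] != 0)
    sum(mp[nb] * gr2[i, nb]) / length(nb)
  })
  expect_equal(unname(a1), oracle, tolerance = 1e-12)
  expect_error(neighborhood_abnormality(matrix(0, 3, 3), 1:3), "isolated")
})

test_that("diffusion gradients separate planted blocks and are equivariant", {
  n <- 40
  blocks <- rep(1:2, each = n / 2)
  aff <- matrix(0.01, n, n)
  aff[blocks == 1, blocks == 1] <- 0.9
  aff[blocks == 2, blocks == 2] <- 0.9
  aff <- aff + diag(0.1, n)
  withr::with_seed(5, aff <- aff + matrix(runif(n * n, 0, 0.02), n))
  aff <- (aff + t(aff)) / 2
  # sparsity kept high enough that the weak between-block links survive
  # row sparsification (top-10% would disconnect the planted blocks)
  g1 <- connectivity_gradients(aff, n_components = 2, sparsity = 0.6)
  expect_true(all(is.finite(g1)))
  s <- sign(g1[, 1])
  expect_true(all(s[blocks == 1] == s[1]) && all(s[blocks == 2] == -s[1]))

  perm <- withr::with_seed(6, sample.int(n))
  g2 <- connectivity_gradients(aff[perm, perm], n_components = 2, sparsity = 0.6)
  expect_equal(abs(g2[, 1]), abs(g1[perm, 1]), tolerance = 1e-6)

  disc <- matrix(0, 6, 6)
  disc[1:3, 1:3] <- 0.9; disc[4:6, 4:6] <- 0.9
  expect_error(connectivity_gradients(disc), "disconnected")
})

test_that("spatial correlation handles self, negation, and alignment errors", {
  g <- fixture_geometry(100)
  mp <- gen_smooth_map(g, 50, seed = 7)
  res <- spatial_correlation(mp, mp, nulls = "spin", n_null = 99,
                             geometry = g, seed = 1)
  expect_equal(res$rsp, 1)
  expect_equal(res$p_spin, 1 / 100)
  expect_equal(spatial_correlation(mp, -mp, nulls = character())$rsp, -1)
  expect_error(spatial_correlation(mp[1:5], mp[1:5], nulls = character()),
               "10 parcels")
})

test_that("rewire null recomputes the neighborhood statistic per surrogate", {
  g <- fixture_geometry(60)
  cn <- gen_connectome(g, decay = 60, density = 0.25, seed = 8)
  # effect map partially propagated over the connectome, so connected
  # neighbours genuinely share effects
  base <- gen_smooth_map(g, 50, seed = 9)
  w_norm <- cn / pmax(rowSums(cn), .Machine$double.eps)
  br <- as.numeric(scale(base + drop(w_norm %*% base)))
  nab <- neighborhood_abnormality(cn, br)
  res <- spatial_correlation(nab, br, nulls = "rewire", n_null = 30,
                             connectome = cn, base_map = br, seed = 2)
  expect_true(res$p_rewire >= 1 / 31 && res$p_rewire <= 1)
  # rewiring destroys the planted network coupling, so the observed rsp
  # sits in the tail of the rewired null
  expect_lt(res$p_rewire, 0.2)
})

test_that("cell density maps average z-scored member genes", {
  withr::with_seed(10, {
    base <- rnorm(30)
    e <- cbind(g1 = base, g2 = base, g3 = rnorm(30), g4 = -2 * rnorm(30))
  })
  catalog <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                        category = c("A", "A", "B", "B"))
  maps <- cell_density_maps(e, catalog)
  expect_equal(maps[, "A"], drop(scale(base)), ignore_attr = TRUE, tolerance = 1e-12)
  # hand-computed three-gene average
  z <- scale(e)
  expect_equal(maps[, "B"], rowMeans(z[, c("g3", "g4")]), ignore_attr = TRUE)
  # opposite maps cancel
  e2 <- cbind(p = base, q = -base)
  cat2 <- data.frame(gene = c("p", "q"), category = "C")
  expect_lt(max(abs(cell_density_maps(e2, cat2))), 1e-10)
})

test_that("perfectly enriched categories hit the Fisher-z cap with minimal q", {
  g <- fixture_geometry(60)
  dmat <- fixture_distances(60)
  eff <- gen_smooth_map(g, 50, seed = 11)
  noise <- gen_expression(g, 4, 5, seed = 12)
  expr <- noise$expression
  # one category is the effect map itself (plus per-gene constants)
  for (gene in noise$mapping$gene[noise$mapping$category == "Cat01"])
    expr[, gene] <- eff + rnorm(1)
  res <- gcea_cell_types(eff, expr, noise$mapping, n_surrogates = 60,
                         seed = 3, distances = dmat)
  row1 <- res[res$category == "Cat01", ]
  expect_equal(row1$z_rsp, atanh(1 - 1e-7), tolerance = 1e-6)
  expect_equal(row1$p, 1 / 61)
  expect_equal(min(res$q), row1$q)
})

test_that("both aggregation orders are available and small categories are skipped", {
  g <- fixture_geometry(60)
  dmat <- fixture_distances(60)
  eff <- gen_smooth_map(g, 50, seed = 13)
  ex <- gen_expression(g, 3, 4, seed = 14)
  r1 <- gcea_cell_types(eff, ex$expression, ex$mapping, n_surrogates = 30,
                        seed = 4, distances = dmat)
  r2 <- gcea_cell_types(eff, ex$expression, ex$mapping, n_surrogates = 30,
                        seed = 4, distances = dmat, aggregation = "category_mean")
  expect_equal(r1$category, r2$category)
  expect_false(identical(r1$z_rsp, r2$z_rsp))

  cat_small <- ex$mapping
  cat_small <- cat_small[-which(cat_small$category == "Cat03")[1:3], ]
  expect_warning(r3 <- gcea_cell_types(eff, ex$expression, cat_small,
                                       n_surrogates = 20, seed = 5,
                                       distances = dmat),
                 "fewer than 2")
  expect_false("Cat03" %in% r3$category)
})
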