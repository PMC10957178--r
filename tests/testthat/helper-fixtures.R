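# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture_geometry <- function(n = 200L) {
  key <- paste0("geom_", n)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- gen_sphere_parcellation(n, seed = 1L)
  fixture_env[[key]]
}

fixture_distances <- function(n = 200L) {
  key <- paste0("dist_", n)
  if (is.null(fixture_env[[key]])) {
    g <- fixture_geometry(n)
    fixture_env[[key]] <- as.matrix(stats::dist(as.matrix(g[, c("cx", "cy", "cz")])))
  }
  fixture_env[[key]]
}

# Random symmetric weighted graph with zero diagonal.
random_graph <- function(n, density = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    edge <- ut & (matrix(stats::runif(n * n), n, n) < density)
    w[edge] <- stats::runif(sum(edge))
    w + t(w)
  })
}

expect_same_multiset <- function(surrogates, original) {
  ref <- sort(as.numeric(original))
  ok <- apply(surrogates, 1, function(r) isTRUE(all.equal(sort(r), ref)))
  expect_true(all(ok))
}
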