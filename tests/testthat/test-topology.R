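test_that("lattice indexing is the paper's column-major raster convention", {
  expect_equal(cell_id(0, 0, "E"), 1L)
  expect_equal(cell_id(3, 5, "E"), 66L)   # 5 + 3*20 + 1
  expect_equal(cell_id(9, 9, "I"), 500L)
  expect_equal(cell_id(0, 0, "I"), 401L)

  # bijection over each lattice
  g <- expand.grid(x = 0:19, y = 0:19)
  idsE <- cell_id(g$x, g$y, "E")
  expect_setequal(idsE, 1:400)
  gI <- expand.grid(x = 0:9, y = 0:9)
  expect_setequal(cell_id(gI$x, gI$y, "I"), 401:500)
  expect_error(cell_id(20, 0, "E"), "out of range")
  expect_error(cell_id(0, 10, "I"), "out of range")
})

test_that("periodic distance implements the minimum-image metric", {
  expect_equal(periodic_distance(c(0, 0), c(19, 0), 20), 1)
  expect_equal(periodic_distance(c(0, 0), c(10, 10), 20), sqrt(200))
  expect_equal(periodic_distance(c(7, 3), c(7, 3), 20), 0)
  expect_equal(periodic_distance(c(0, 0), c(19, 19), 20), sqrt(2))

  # symmetry and triangle inequality on random triples
  set.seed(7)
  for (i in 1:50) {
    p <- runif(2, 0, 20); q <- runif(2, 0, 20); r <- runif(2, 0, 20)
    expect_equal(periodic_distance(p, q, 20), periodic_distance(q, p, 20))
    expect_lte(periodic_distance(p, r, 20),
               periodic_distance(p, q, 20) + periodic_distance(q, r, 20) + 1e-12)
  }
})

test_that("the default topology has the exact out-degrees and edge count", {
  topo <- default_topo()
  ed <- topo$edges
  expect_equal(nrow(ed), 400 * 50 + 100 * 499)  # 69,900

  eIDs <- 1:400; iIDs <- 401:500
  for (s in c(1, 57, 247, 400)) {
    tg <- ed$tgt[ed$src == s]
    expect_equal(sum(tg %in% eIDs), 40)
    expect_equal(sum(tg %in% iIDs), 10)
  }
  deg <- tabulate(ed$src, 500)
  expect_true(all(deg[eIDs] == 50))
  expect_true(all(deg[iIDs] == 499))
  for (s in c(401, 455, 500)) {
    tg <- ed$tgt[ed$src == s]
    expect_setequal(tg, setdiff(1:500, s))  # all cells, no autapse
  }
  expect_setequal(unique(ed$w), c(0.01, 0.05, 0.04))
  # class weights land on the right edge classes
  expect_true(all(ed$w[ed$src <= 400 & ed$tgt <= 400] == 0.01))
  expect_true(all(ed$w[ed$src <= 400 & ed$tgt > 400] == 0.05))
  expect_true(all(ed$w[ed$src > 400] == 0.04))
})

test_that("E-cell target sets match a brute-force nearest-neighbor oracle", {
  topo <- default_topo()
  ed <- topo$edges
  ex <- rep(0:19, each = 20); ey <- rep(0:19, times = 20)
  wrap <- function(d) (d + 10) %% 20 - 10
  for (s in c(1, 23, 178, 301, 400)) {
    # oracle: full pairwise sort with the same deterministic tie rule
    dx <- wrap(ex - ex[s]); dy <- wrap(ey - ey[s])
    d2 <- dx^2 + dy^2
    ord <- order(d2, abs(atan2(dy, dx)), seq_len(400))
    ord <- ord[ord != s]
    oracle <- sort(ord[1:40])
    got <- sort(ed$tgt[ed$src == s & ed$tgt <= 400])
    expect_equal(got, oracle)
  }
  # the sub-degenerate core (the 36 strictly nearer cells) is invariant
  # under both lattice reflections about the source
  s <- 1
  dx <- wrap(ex - ex[s]); dy <- wrap(ey - ey[s])
  d2 <- dx^2 + dy^2
  core <- which(d2 > 0 & d2 < 13)
  expect_equal(length(core), 36)
  key <- paste(dx[core], dy[core])
  expect_setequal(paste(-dx[core], dy[core]), key)
  expect_setequal(paste(dx[core], -dy[core]), key)
})

test_that("E-E rewiring preserves degrees and hits the analytic overlap at p = 1", {
  topo <- default_topo()
  expect_identical(rewire_ee(topo, 0), topo)

  r1 <- rewire_ee(topo, 0.875, seed = 3)
  deg_ee <- tabulate(r1$edges$src[r1$edges$tgt <= 400 & r1$edges$src <= 400], 400)
  expect_true(all(deg_ee == 40))
  # non-E-E edges untouched
  inh <- function(t) t$edges[t$edges$src > 400 | t$edges$tgt > 400, ]
  expect_equal(inh(r1), inh(topo))
  # no duplicates, no autapses
  ee <- r1$edges[r1$edges$src <= 400 & r1$edges$tgt <= 400, ]
  expect_false(any(ee$src == ee$tgt))
  expect_equal(anyDuplicated(paste(ee$src, ee$tgt)), 0)

  # p = 1: expected preserved fraction of original E-E edges ~ 40/399
  orig <- topo$edges[topo$edges$src <= 400 & topo$edges$tgt <= 400, ]
  okey <- paste(orig$src, orig$tgt)
  fr <- vapply(1:12, function(sd) {
    rw <- rewire_ee(topo, 1, seed = sd)
    ee <- rw$edges[rw$edges$src <= 400 & rw$edges$tgt <= 400, ]
    mean(paste(ee$src, ee$tgt) %in% okey)
  }, numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 40 / 399), 3 * se + 0.003)
})

test_that("inhibitory sparsification keeps the stated density and reweights", {
  topo <- default_topo()
  s1 <- sparsify_inhibition(topo, 1, 0.04, seed = 1)
  expect_equal(s1$edges, topo$edges)

  s4 <- sparsify_inhibition(topo, 0.4, 0.075, seed = 2)
  n_inh0 <- sum(topo$edges$src > 400)
  n_inh <- sum(s4$edges$src > 400)
  p_se <- sqrt(0.4 * 0.6 / n_inh0)
  expect_lt(abs(n_inh / n_inh0 - 0.4), 3 * p_se)
  expect_true(all(s4$edges$w[s4$edges$src > 400] == 0.075))
  # E-sourced edges untouched
  exc <- function(t) t$edges[t$edges$src <= 400, ]
  expect_equal(exc(s4), exc(topo))
})
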