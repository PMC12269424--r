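test_that("differential score is the selection mean minus the global mean", {
  # gene = 5 inside the selection, 0 outside, selection = half the cells
  X <- matrix(c(rep(5, 10), rep(0, 10)), 20, 1, dimnames = list(NULL, "g"))
  ds <- SpatialDataset(X, cbind(1:20, 1:20))
  sel <- select_explicit(ds, 1:10)
  expect_equal(differential_score(ds, sel, "g"), 2.5)
  # constant gene -> 0; selection = all cells -> 0
  Xc <- matrix(3, 20, 1, dimnames = list(NULL, "g"))
  dsc <- SpatialDataset(Xc, cbind(1:20, 1:20))
  expect_equal(differential_score(dsc, sel, "g"), 0)
  expect_equal(differential_score(ds, select_explicit(ds, 1:20), "g"), 0)
})

test_that("knn-binary weights follow pairwise distances; invdist guards degenerate input", {
  # 4 colinear equispaced points, k = 1: endpoints weight the inner neighbour
  co <- cbind(c(0, 1, 2, 3), 0)
  w <- build_weights(co, "knn", k = 1)
  expect_equal(w$W, 4)
  m <- as.matrix(w$w)
  expect_equal(m[1, ], c(0, 1, 0, 0))
  expect_equal(m[4, ], c(0, 0, 1, 0))
  # interior points tie between both neighbours; lower index wins
  expect_equal(m[2, ], c(1, 0, 0, 0))
  expect_equal(m[3, ], c(0, 1, 0, 0))
  # knn weights are generally asymmetric
  co2 <- cbind(c(0, 1, 1.5, 10), 0)
  w2 <- as.matrix(build_weights(co2, "knn", k = 1)$w)
  expect_true(w2[4, 3] == 1 && w2[3, 4] == 0)
  # cutoff below every distance -> W = 0 error
  expect_error(build_weights(co, "invdist", cutoff = 0.5), "W = 0")
  # coincident points under inverse distance -> advisory error
  expect_error(build_weights(rbind(co, c(0, 0)), "invdist", cutoff = 5),
               "knn")
  # inverse-distance weights equal 1/d within the cutoff
  wi <- as.matrix(build_weights(co, "invdist", cutoff = 2.5)$w)
  expect_equal(wi[1, ], c(0, 1, 1 / 2, 0))
  expect_lt(abs(wi[1, 4]), 1e-15)
})

test_that("Moran's I reproduces the hand-derived chain value and the null expectation", {
  # 4-cell chain, values +1 -1 +1 -1, symmetric binary chain adjacency
  x <- c(1, -1, 1, -1)
  w <- matrix(0, 4, 4)
  w[cbind(c(1, 2, 2, 3, 3, 4), c(2, 1, 3, 2, 4, 3))] <- 1
  ds <- SpatialDataset(matrix(x + 2, 4, 1, dimnames = list(NULL, "g")),
                       cbind(1:4, 0))
  sel <- select_explicit(ds, 1:4)
  res <- morans_i(ds, sel, "g", manual_weights(w))
  expect_equal(res$I, -1, tolerance = 1e-12)
  expect_equal(res$expected, -1 / 3)
  # E(I) = -1/(N-1): N = 5
  co5 <- cbind(seq_len(5), 0)
  ds5 <- SpatialDataset(matrix(rnorm(5) + 10, 5, 1, dimnames = list(NULL, "g")),
                        co5)
  r5 <- morans_i(ds5, select_explicit(ds5, 1:5), "g",
                 build_weights(co5, "knn", k = 2))
  expect_equal(r5$expected, -0.25)
  # constant values -> NA sentinel, not 0
  dsc <- SpatialDataset(matrix(2, 4, 1, dimnames = list(NULL, "g")),
                        cbind(1:4, 0))
  resc <- morans_i(dsc, select_explicit(dsc, 1:4), "g", manual_weights(w))
  expect_true(is.na(resc$I) && is.na(resc$z))
})

test_that("Moran's I equals the naive double-sum oracle on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    co <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    x <- rnorm(n, mean = 4)
    ds <- SpatialDataset(matrix(pmax(x, 0), n, 1, dimnames = list(NULL, "g")),
                         co)
    sel <- select_explicit(ds, seq_len(n))
    scheme <- if (rep %% 2) "knn" else "invdist"
    w <- if (scheme == "knn") build_weights(co, "knn", k = min(5, n - 1))
         else build_weights(co, "invdist", cutoff = 6)
    res <- morans_i(ds, sel, "g", w)
    expect_equal(res$I, moran_oracle(gene_values(ds, "g"), as.matrix(w$w)),
                 tolerance = 1e-10)
  }
})

test_that("Moran's I is invariant to shifts and positive rescaling of expression", {
  set.seed(8)
  co <- cbind(runif(30), runif(30))
  x <- rnorm(30, 5)
  w <- build_weights(co, "knn", k = 4)
  mk <- function(v) {
    d <- SpatialDataset(matrix(v, 30, 1, dimnames = list(NULL, "g")), co)
    morans_i(d, select_explicit(d, 1:30), "g", w)$I
  }
  base <- mk(x)
  expect_equal(mk(x + 7), base, tolerance = 1e-12)
  expect_equal(mk(3.5 * x), base, tolerance = 1e-12)
})

test_that("axis correlation hits the exact-gradient, reflection and symmetric cases", {
  co <- cbind(x = c(-2, -1, 0, 1, 2), y = 0)
  mkds <- function(v) SpatialDataset(matrix(v, 5, 1, dimnames = list(NULL, "g")),
                                     co)
  sel5 <- function(d) select_explicit(d, 1:5)
  d1 <- mkds(co[, 1] + 10)
  expect_equal(axis_correlation(d1, sel5(d1), "g", "x"), 1, tolerance = 1e-12)
  d2 <- mkds(-co[, 1] + 10)
  expect_equal(axis_correlation(d2, sel5(d2), "g", "x"), -1, tolerance = 1e-12)
  # expression = coordinate^2 on points symmetric about 0 -> r = 0
  d3 <- mkds(co[, 1]^2)
  expect_equal(axis_correlation(d3, sel5(d3), "g", "x"), 0, tolerance = 1e-12)
  # constant vector -> NA sentinel; missing axis errors
  d4 <- mkds(rep(1, 5))
  expect_true(is.na(axis_correlation(d4, sel5(d4), "g", "x")))
  expect_error(axis_correlation(d1, sel5(d1), "g", "z"), "2D")
})

test_that("filter_genes ranks by the documented keys and retains exactly n_keep", {
  sim <- generate_synthetic(synth_spec(
    n_gradient_pos = 5, n_gradient_neg = 5, n_hotspot = 0, n_marker = 0,
    n_noise = 90, seed = 17))
  ds <- sim$srt
  sel <- select_explicit(ds, seq_len(n_cells(ds)))
  tab <- filter_genes(ds, sel, "axis", n_keep = 10, axis = "x")
  planted <- sim$ground_truth$gene[sim$ground_truth$class == "gradient"]
  expect_setequal(retained_genes(tab), planted)
  # both gradient directions survive via |r|
  expect_true(any(tab$score[tab$retained] > 0) &&
              any(tab$score[tab$retained] < 0))
  # scores match the per-gene operation
  for (g in c(planted[1], "noise_01")) {
    expect_equal(tab$score[tab$gene == g],
                 axis_correlation(ds, sel, g, "x"), tolerance = 1e-12)
  }
  # byte-identical rerun (total order incl. lexicographic tie-break)
  tab2 <- filter_genes(ds, sel, "axis", n_keep = 10, axis = "x")
  expect_identical(tab, tab2)
})

test_that("ties break by gene symbol and undefined statistics drop out of ranking", {
  # two genes with identical expression (tied scores) + one constant gene
  co <- cbind(x = 1:6, y = 0)
  v <- c(1, 2, 3, 4, 5, 6)
  X <- cbind(zz = v, aa = v, const = rep(2, 6))
  ds <- SpatialDataset(X, co)
  sel <- select_explicit(ds, 1:6)
  tab <- filter_genes(ds, sel, "axis", n_keep = 1, axis = "x")
  expect_identical(tab$gene[1], "aa") # lexicographic tie-break
  expect_identical(retained_genes(tab), "aa")
  expect_true(is.na(tab$ranking_key[tab$gene == "const"]))
  expect_false(tab$retained[tab$gene == "const"])
  # n_keep beyond the finite-score genes retains all of them with a warning
  expect_warning(tab3 <- filter_genes(ds, sel, "axis", n_keep = 3, axis = "x"),
                 "finite")
  expect_setequal(retained_genes(tab3), c("aa", "zz"))
})

test_that("differential filter ranks a planted marker first for its region", {
  sim <- generate_synthetic(synth_spec(seed = 23))
  ds <- sim$srt
  sel <- select_by_annotation(ds, "region", "region_1")
  tab <- filter_genes(ds, sel, "differential", n_keep = 5)
  markers1 <- sim$ground_truth$gene[sim$ground_truth$class == "marker" &
                                    sim$ground_truth$param == "region_1" &
                                    sim$ground_truth$shared]
  expect_identical(tab$gene[1], markers1[1])
  expect_gt(tab$score[1], 0)
})
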