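test_that("fit_kpca matches the dense eigendecomposition oracle", {
  set.seed(41)
  for (dims in list(c(10, 5), c(30, 7), c(50, 20))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    m <- fit_kpca(X, kpca_config("rbf", gamma = 0.5))
    expect_proj_equal(m$projections, kpca_oracle(X, 0.5), tol = 1e-8)
    expect_true(all(diff(m$lambda) <= 0) && all(m$lambda > 0))
  }
})

test_that("duplicate points share projections; degenerate kernels are rejected", {
  set.seed(42)
  X <- matrix(rnorm(8 * 3), 8, 3)
  X[5, ] <- X[2, ]
  m <- fit_kpca(X, kpca_config("rbf", gamma = 0.7))
  expect_equal(m$projections[5, ], m$projections[2, ], tolerance = 1e-10)
  # gamma -> 0: kernel -> all-ones, centred kernel -> 0
  expect_error(fit_kpca(X, kpca_config("rbf", gamma = 1e-300)),
               class = "ab_degenerate_kernel")
  expect_error(fit_kpca(matrix(1, 5, 3), kpca_config("rbf", gamma = 1)),
               class = "ab_degenerate_kernel")
})

test_that("kpca_project reproduces training rows and validates dimensions", {
  set.seed(43)
  X <- matrix(rnorm(12 * 4), 12, 4)
  m <- fit_kpca(X, kpca_config("rbf", gamma = 0.3))
  expect_proj_equal(kpca_project(m, X), m$projections, tol = 1e-8)
  expect_equal(nrow(kpca_project(m, X[0, , drop = FALSE])), 0L)
  expect_error(kpca_project(m, matrix(0, 2, 5)), class = "ab_dimension_mismatch")
  # near-linear gamma: the midpoint of two training points projects between
  # them (exact in the linear limit, where the embedding map is affine)
  m2 <- fit_kpca(X, kpca_config("rbf", gamma = 0.002))
  pm <- kpca_project(m2, rbind((X[1, ] + X[2, ]) / 2))
  lo <- pmin(m2$projections[1, ], m2$projections[2, ])
  hi <- pmax(m2$projections[1, ], m2$projections[2, ])
  expect_true(all(pm >= lo - 1e-9 & pm <= hi + 1e-9))
})

test_that("make_ellipse derives radii, rotation and centre from the endpoints", {
  e1 <- make_ellipse(c(-2, 0), c(2, 0), h = 2)
  expect_equal(c(e1$a, e1$b, e1$theta), c(2, 1, 0))
  expect_equal(e1$center, c(0, 0))
  e2 <- make_ellipse(c(0, -3), c(0, 3), h = 2)
  expect_equal(c(e2$a, e2$b, e2$theta), c(3, 1, pi / 2))
  e3 <- make_ellipse(c(1, 1), c(3, 3), h = sqrt(2))
  expect_equal(c(e3$a, e3$b, e3$theta), c(sqrt(2), sqrt(2) / 2, pi / 4))
  expect_equal(e3$center, c(2, 2))
  expect_error(make_ellipse(c(1, 1), c(1, 1), 1), class = "ab_degenerate_ellipse")
  expect_error(make_ellipse(c(0, 0), c(1, 0), 0), class = "ab_degenerate_ellipse")
})

test_that("point_in_ellipse: centre and boundary inside, derived exterior point out", {
  e <- make_ellipse(c(-2, 0), c(2, 0), h = 2)
  expect_true(point_in_ellipse(e, c(0, 0)))
  expect_true(point_in_ellipse(e, c(2, 0)))          # endpoint on boundary
  expect_false(point_in_ellipse(e, c(1.9, 0.5)))     # 0.9025 + 0.25 > 1
})

test_that("analytic containment agrees with the 100-vertex polygon oracle", {
  set.seed(44)
  n_checked <- 0L; n_agree <- 0L
  for (rep_ in 1:4) {
    p1 <- rnorm(2, sd = 2); p2 <- rnorm(2, sd = 2)
    if (all(p1 == p2)) next
    e <- make_ellipse(p1, p2, h = runif(1, 0.5, 3))
    poly <- ellipse_polygon(e, 100L)
    pts <- cbind(runif(3000, min(poly[, 1]) - 1, max(poly[, 1]) + 1),
                 runif(3000, min(poly[, 2]) - 1, max(poly[, 2]) + 1))
    # exclude the boundary shell (canonical radial margin 1e-2)
    ct <- cos(e$theta); st <- sin(e$theta)
    xr <- (ct * (pts[, 1] - e$center[1]) + st * (pts[, 2] - e$center[2])) / e$a
    yr <- (-st * (pts[, 1] - e$center[1]) + ct * (pts[, 2] - e$center[2])) / e$b
    off <- abs(sqrt(xr^2 + yr^2) - 1) > 1e-2
    ana <- point_in_ellipse(e, pts[off, , drop = FALSE])
    ora <- vapply(which(off), function(i) in_polygon(poly, pts[i, 1], pts[i, 2]),
                  logical(1))
    n_checked <- n_checked + sum(off)
    n_agree <- n_agree + sum(ana == ora)
  }
  expect_gt(n_checked, 10000L)
  expect_gte(n_agree / n_checked, 0.999)
})

test_that("ellipse_from_reference: Z='all' captures every reference point", {
  cl <- generate_embedding_clouds(embedding_cloud_spec(seed = 1))
  ref <- cl$X[cl$group == "reference", ]
  e <- ellipse_from_reference(ref, "all")
  expect_true(all(point_in_ellipse(e, ref)))
  expect_error(ellipse_from_reference(ref[1:2, ], "all"),
               class = "ab_insufficient_reference")
  expect_error(ellipse_from_reference(ref, 0), class = "ab_degenerate_ellipse")
})

test_that("Z=2 reference capture approximates the 2-sd ellipse mass", {
  set.seed(42)
  ref <- matrix(rnorm(10000 * 2), 10000, 2)
  e <- ellipse_from_reference(ref, 2)
  # bivariate standard normal mass inside the 2-sd ellipse: 1 - exp(-2)
  expect_equal(mean(point_in_ellipse(e, ref)), 1 - exp(-2), tolerance = 0.03)
})

test_that("capture_rates and layer1_select match brute-force containment", {
  e <- make_ellipse(c(-1, 0), c(1, 0), h = 2)
  pts <- rbind(c(0, 0), c(0.5, 0), c(5, 5), c(6, 0))
  cr <- capture_rates(e, pts, c("a", "a", "b", "b"))
  expect_equal(unname(cr), c(100, 0))
  half <- capture_rates(e, pts, rep("g", 4))
  expect_equal(unname(half), 50)
  expect_error(capture_rates(e, pts[0, , drop = FALSE], factor(character(0))),
               class = "ab_empty_group")

  set.seed(45)
  q <- matrix(rnorm(200 * 2, sd = 1.5), 200, 2)
  ids <- sprintf("q%03d", 1:200)
  sel <- layer1_select(ids, q, e)
  brute <- ids[vapply(seq_len(200), function(i) point_in_ellipse(e, q[i, ]),
                      logical(1))]
  expect_identical(sel, brute)
  expect_identical(layer1_select(character(0), q[0, , drop = FALSE], e),
                   character(0))
})

test_that("gating is invariant to sign flips of either component", {
  set.seed(46)
  ref <- matrix(rnorm(80 * 2), 80, 2)
  q <- matrix(rnorm(300 * 2, sd = 2), 300, 2)
  base <- which(point_in_ellipse(ellipse_from_reference(ref, 1.5), q))
  for (flip in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    refl <- sweep(ref, 2, flip, "*"); qf <- sweep(q, 2, flip, "*")
    got <- which(point_in_ellipse(ellipse_from_reference(refl, 1.5), qf))
    expect_identical(got, base)
  }
})

test_that("retained sets are nested in Z (moment endpoints)", {
  for (sd_ in 1:3) {
    set.seed(sd_)
    ref <- matrix(rnorm(144 * 2), 144, 2)
    q <- matrix(rnorm(400 * 2, sd = 2), 400, 2)
    sets <- lapply(c(0.5, 1, 1.5, 2, 3), function(z)
      which(point_in_ellipse(
        ellipse_from_reference(ref, z, endpoints = "moment"), q)))
    for (i in 1:4) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})
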