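# brute-force MST: enumerate every labeled spanning tree via its Pruefer
# sequence (k^(k-2) trees), decode, and keep the minimum total length
mst_oracle <- function(pts) {
  k <- nrow(pts)
  dm <- as.matrix(dist(pts))
  if (k == 2) return(dm[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    deg <- rep(1L, k)
    for (v in pr) deg[v] <- deg[v] + 1L
    total <- 0
    for (v in pr) {
      u <- which(deg == 1L)[1]
      total <- total + dm[u, v]
      deg[u] <- 0L
      deg[v] <- deg[v] - 1L
    }
    rest <- which(deg == 1L)
    total <- total + dm[rest[1], rest[2]]
    best <- min(best, total)
  }
  best
}

test_that("MST matches brute-force spanning-tree enumeration", {
  # triangle: MST = two shortest sides
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  ls <- lumen_set(unit_square(side = 10, origin = c(-2, -2)),
                  lapply(seq_len(3), function(i) circle_poly(0.3, tri[i, ], 32)),
                  validate = FALSE)
  g <- build_graphs(ls)
  expect_equal(sum(g$mst$lengths), 7)
  # 3x3 unit grid: total length 8
  gr <- as.matrix(expand.grid(x = 0:2, y = 0:2)) * 10
  ls9 <- lumen_set(unit_square(side = 30, origin = c(-5, -5)),
                   lapply(seq_len(9), function(i) circle_poly(1, gr[i, ], 32)),
                   validate = FALSE)
  expect_equal(sum(build_graphs(ls9)$mst$lengths), 80)
  # random sets K <= 7 against exhaustive enumeration
  set.seed(33)
  for (rep in 1:6) {
    k <- sample(4:7, 1)
    pts <- matrix(runif(2 * k, 0, 100), ncol = 2)
    lsr <- lumen_set(unit_square(side = 120, origin = c(-10, -10)),
                     lapply(seq_len(k), function(i) circle_poly(1, pts[i, ], 32)),
                     validate = FALSE)
    expect_equal(sum(build_graphs(lsr)$mst$lengths), mst_oracle(pts),
                 tolerance = 1e-9)
  }
})

test_that("Delaunay triangles satisfy the empty-circumcircle property", {
  set.seed(44)
  pts <- matrix(runif(60, 0, 100), ncol = 2)
  tris <- delaunay_triangulate(pts)
  expect_gt(nrow(tris), 0)
  for (r in seq_len(nrow(tris))) {
    t <- tris[r, ]
    a <- pts[t[1], ]; b <- pts[t[2], ]; cc <- pts[t[3], ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
              cc[1] * (a[2] - b[2]))
    ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
           sum(cc^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
           sum(cc^2) * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    others <- pts[-t, , drop = FALSE]
    d2 <- (others[, 1] - ux)^2 + (others[, 2] - uy)^2
    expect_true(all(d2 >= r2 * (1 - 1e-9)))
  }
})

test_that("Voronoi cells tile the annotation polygon", {
  set.seed(55)
  pts <- matrix(runif(40, 10, 190), ncol = 2)
  ann <- unit_square(side = 200)
  areas <- vapply(seq_len(nrow(pts)), function(i)
    polygon_area(voronoi_cell(pts, i, ann)), numeric(1))
  expect_equal(sum(areas), polygon_area(ann), tolerance = 1e-3)
})

test_that("the global graph block is 52 long and flat for a regular grid", {
  gr <- as.matrix(expand.grid(x = 0:4, y = 0:4)) * 50 + 30
  ls <- lumen_set(unit_square(side = 280), lapply(seq_len(25), function(i)
    circle_poly(8, gr[i, ], 48)), validate = FALSE)
  gb <- global_graph_block(ls)
  expect_length(gb, 52)
  expect_equal(unname(gb["graph:density:value:gland_count"]), 25)
  # interior regularity: MST and NN-distance spread vanish on the grid
  expect_lt(gb["graph:mst:sd:edge_length"], 1e-9)
  expect_lt(gb["graph:nn:sd:dist_k1"], 1e-9)
  expect_equal(unname(gb["graph:nn:mean:dist_k1"]), 50)
  expect_equal(unname(gb["graph:density:value:glands_per_mm2"]),
               25 / (280^2 / 1e6))
})

test_that("subgraph block: 68 features, pinned conventions, centroid-only dependence", {
  tri <- rbind(c(0, 0), c(40, 0), c(20, 20 * sqrt(3)))
  ls <- lumen_set(unit_square(side = 80, origin = c(-20, -10)),
                  lapply(1:3, function(i) circle_poly(3, tri[i, ], 48)),
                  validate = FALSE)
  sg <- subgraph_block(ls)
  expect_length(sg, 68)
  # equilateral triangle: edge lengths equal -> SD and excess kurtosis 0
  expect_equal(unname(sg["subgraph:sd:edge_length"]), 0, tolerance = 1e-9)
  expect_identical(unname(sg["subgraph:kurtosis:edge_length"]), 0)
  # pooled kurtosis equals the direct fourth-moment computation
  set.seed(66)
  ctr <- matrix(runif(30, 0, 300), ncol = 2)
  ls2 <- lumen_set(unit_square(side = 320, origin = c(-10, -10)),
                   lapply(seq_len(15), function(i) circle_poly(4, ctr[i, ], 48)),
                   validate = FALSE)
  eg <- epsilon_graph(ls2)
  el <- igraph::E(eg$graph)$weight
  m2 <- mean((el - mean(el))^2); m4 <- mean((el - mean(el))^4)
  expect_equal(unname(subgraph_block(ls2)["subgraph:kurtosis:edge_length"]),
               m4 / m2^2 - 3, tolerance = 1e-9)
  # replacing every polygon by a different shape at the same centroid
  # leaves all subgraph features untouched
  ls3 <- lumen_set(ls2$region, lapply(seq_len(15), function(i) {
    sq <- unit_square(side = 6, origin = ctr[i, ] - 3)
    sq
  }), validate = FALSE)
  expect_equal(subgraph_block(ls2), subgraph_block(ls3), tolerance = 1e-9)
})

test_that("graphs degrade to sentinels below three usable centroids", {
  one <- lumen_set(unit_square(side = 50),
                   list(circle_poly(5, c(25, 25), 32)), validate = FALSE)
  g <- build_graphs(one)
  expect_false(g$present)
  gb <- global_graph_block(one)
  expect_true(is.na(gb["graph:mst:mean:edge_length"]))
  expect_equal(unname(gb["graph:density:value:gland_count"]), 1)
  coll <- lumen_set(unit_square(side = 100),
                    lapply(c(20, 50, 80), function(x)
                      circle_poly(3, c(x, 50), 32)), validate = FALSE)
  expect_false(build_graphs(coll)$present)
})
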