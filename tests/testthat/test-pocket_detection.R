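test_that("circumsphere matches the analytic regular tetrahedron", {
  cs <- circumsphere(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(cs$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(cs$radius, sqrt(3), tolerance = 1e-12)
  expect_error(circumsphere(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("circumsphere is equidistant from random quadruples", {
  set.seed(4)
  for (rep in 1:25) {
    P <- matrix(rnorm(12, sd = 3), 4, 3)
    vol <- abs(det(sweep(P[1:3, ], 2, P[4, ]))) / 6
    if (vol < 1e-3) next
    cs <- circumsphere(P[1, ], P[2, ], P[3, ], P[4, ])
    d <- sqrt(rowSums(sweep(P, 2, cs$center)^2))
    expect_true(all(abs(d - cs$radius) < 1e-9))
  }
})

test_that("a single tetrahedron yields one sphere inside the radius band", {
  P <- regular_tetrahedron(circumradius = 5)
  s <- point_structure(P)
  sp <- generate_alpha_spheres(s, detection_params())
  expect_equal(nrow(sp), 1)
  expect_equal(sp$radius, 5, tolerance = 1e-9)
  expect_true(sp$apolar)   # all four defining atoms are carbon
  # raising min_alpha_radius past the circumradius removes it
  sp2 <- generate_alpha_spheres(s, detection_params(min_alpha_radius = 5.5,
                                                    max_alpha_radius = 6.2))
  expect_equal(nrow(sp2), 0)
  expect_error(generate_alpha_spheres(point_structure(P[1:3, , drop = FALSE])),
               "4")
})

test_that("alpha-sphere generation equals the exhaustive enumeration oracle", {
  cage <- make_cage(cage_spec(n_shell_atoms = 60, shell_radius = 8,
                              cavity_radius = 4.6, seed = 1))
  P <- as.matrix(cage$atoms[cage$atoms$kind == "polymer",
                            c("x", "y", "z")])
  got <- generate_alpha_spheres(cage, detection_params())
  want <- oracle_alpha_spheres(P, 4, 6.2)
  expect_equal(nrow(got), nrow(want))
  key <- function(M) {
    o <- order(M[, 1], M[, 2], M[, 3], M[, 4])
    round(M[o, , drop = FALSE], 6)
  }
  got_m <- t(apply(as.matrix(got[, c("a1", "a2", "a3", "a4")]), 1, sort))
  got_m <- cbind(got_m, got$cx, got$cy, got$cz, got$radius)
  expect_equal(unname(key(got_m)), unname(key(want)), tolerance = 1e-6)
})

test_that("no retained sphere contains an atom center (soundness)", {
  for (seed in 1:3) {
    cage <- make_cage(cage_spec(n_shell_atoms = 150, seed = seed))
    P <- as.matrix(cage$atoms[, c("x", "y", "z")])
    sp <- generate_alpha_spheres(cage)
    for (i in seq_len(nrow(sp))) {
      d <- sqrt((P[, 1] - sp$cx[i])^2 + (P[, 2] - sp$cy[i])^2 +
                  (P[, 3] - sp$cz[i])^2)
      expect_gte(min(d), sp$radius[i] - 1e-6)
    }
  }
})

test_that("sphere clustering equals the union-find components oracle", {
  # two spheres 5 A apart merge at D = 6; 7 A apart do not
  two <- function(gap) data.frame(cx = c(0, gap), cy = 0, cz = 0,
                                  radius = 5, a1 = 1L, a2 = 2L, a3 = 3L,
                                  a4 = 4L, apolar = TRUE)
  expect_length(cluster_spheres(two(5), 6), 1)
  expect_length(cluster_spheres(two(7), 6), 2)
  expect_length(cluster_spheres(two(5)[0, ], 6), 0)
  # 50 random centers vs an independent union-find partition
  set.seed(7)
  sp <- data.frame(cx = runif(50, 0, 40), cy = runif(50, 0, 40),
                   cz = runif(50, 0, 40), radius = runif(50, 4, 6),
                   a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L, apolar = TRUE)
  pockets <- cluster_spheres(sp, 6)
  centers <- as.matrix(sp[, c("cx", "cy", "cz")])
  comp <- uf_components(centers, 6)
  want <- unname(split(seq_len(50), comp))
  got <- lapply(pockets, function(p)
    which(paste(centers[, 1]) %in% paste(p$spheres$cx)))
  canon <- function(part) sort(vapply(part, function(g)
    paste(sort(g), collapse = ","), character(1)))
  expect_equal(canon(got), canon(want))
})

test_that("pocket finalization filters, spans and apolar fractions", {
  cage <- make_cage(cage_spec(n_shell_atoms = 150, seed = 5))
  sp <- generate_alpha_spheres(cage)
  clustered <- cluster_spheres(sp, 6)
  # a high min-sphere threshold drops everything small
  few <- finalize_pockets(cage, clustered,
                          detection_params(min_spheres_per_pocket = 1e4))
  expect_length(few, 0)
  pockets <- finalize_pockets(cage, clustered, detection_params())
  expect_gte(length(pockets), 1)
  p <- pockets[[1]]
  # lining residues are exactly the owners of defining atoms
  atoms <- attr(sp, "atoms")
  aidx <- unique(unlist(p$spheres[, c("a1", "a2", "a3", "a4")]))
  expect_setequal(paste(p$lining$chain, p$lining$resno),
                  unique(paste(atoms$chain[aidx], atoms$resno[aidx])))
  expect_equal(p$span$start, min(p$lining$resno))
  expect_equal(p$span$end, max(p$lining$resno))
  expect_equal(p$apolar_fraction, 1.0)  # all-carbon cage
})

test_that("raising thresholds is monotone in sphere and pocket counts", {
  cage <- make_cage(cage_spec(n_shell_atoms = 150, seed = 8))
  n_prev <- Inf
  for (rmin in c(4, 4.5, 5, 5.5)) {
    sp <- generate_alpha_spheres(cage, detection_params(min_alpha_radius = rmin))
    expect_lte(nrow(sp), n_prev)
    n_prev <- nrow(sp)
  }
  sp <- generate_alpha_spheres(cage)
  k_prev <- Inf
  for (D in c(2, 4, 6, 10)) {
    k <- length(cluster_spheres(sp, D))
    expect_lte(k, k_prev)
    k_prev <- k
  }
})

test_that("detection is invariant to atom input order", {
  cage <- make_cage(cage_spec(n_shell_atoms = 150, seed = 9))
  shuffled <- cage
  set.seed(1)
  shuffled$atoms <- cage$atoms[sample(nrow(cage$atoms)), , drop = FALSE]
  rownames(shuffled$atoms) <- NULL
  a <- detect_pockets(cage)
  b <- detect_pockets(shuffled)
  expect_equal(length(a), length(b))
  centers <- function(p) round(p$spheres[, c("cx", "cy", "cz", "radius")], 9)
  for (i in seq_along(a)) {
    expect_equal(centers(a[[i]]), centers(b[[i]]))
    expect_equal(a[[i]]$span, b[[i]]$span)
  }
})

test_that("the cavity pocket is recovered across cavity sizes", {
  for (cr in c(4.5, 5.0, 5.5, 6.0)) {
    cage <- make_cage(cage_spec(n_shell_atoms = 200, shell_radius = 9.5,
                                cavity_radius = cr, mouth_half_angle = 20,
                                seed = 21))
    pockets <- detect_pockets(cage)
    expect_gte(length(pockets), 1)
    expect_lt(sqrt(sum(pockets[[1]]$centroid^2)), 2)
  }
})
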