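two_col <- function(x, y) encoded_alignment(cbind(x, y))

test_that("joint entropy matches closed forms and the brute-force oracle", {
  a <- two_col(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  expect_equal(joint_entropy(a, 1), 1.0)           # uniform binary column
  expect_equal(joint_entropy(a, c(1, 2)), 2.0)     # independent uniform pair
  for (seed in 1:5) {
    r <- rand_aln(6, 3, seed = seed)
    for (cols in list(1, c(1, 2), c(3, 1), c(1, 2, 3))) {
      args <- lapply(cols, function(cc) r$matrix[, cc])
      expect_equal(joint_entropy(r, cols), do.call(o_H, args),
                   tolerance = 1e-12)
    }
  }
  expect_error(joint_entropy(rand_aln(4, 4), c(1, 1)), "distinct")
  expect_error(joint_entropy(rand_aln(4, 4), c(1, 9)), "out of range")
})

test_that("pairwise MI: identical, independent and random columns", {
  x <- c(1L, 1L, 2L, 2L)
  expect_equal(mi_2d(two_col(x, x), 1, 2), 1.0)
  expect_equal(mi_2d(two_col(x, c(1L, 2L, 1L, 2L)), 1, 2), 0.0)
  for (seed in 1:5) {
    r <- rand_aln(30, 4, seed = seed)
    expect_equal(mi_2d(r, 2, 4), o_MI(r$matrix[, 2], r$matrix[, 4]),
                 tolerance = 1e-10)
    expect_equal(mi_2d(r, 2, 4), mi_2d(r, 4, 2))   # symmetry
  }
  expect_error(mi_2d(rand_aln(4, 4), 2, 2), "differ")
})

test_that("conditional MI given one column: limits, oracle, Eq.(4) identity", {
  set.seed(3)
  m <- cbind(sample.int(4, 40, TRUE), sample.int(4, 40, TRUE),
             rep(2L, 40))
  a <- encoded_alignment(m)
  # conditioning on a constant column returns plain MI
  expect_equal(cond_mi_given_one(a, 1, 2, 3), mi_2d(a, 1, 2),
               tolerance = 1e-10)
  # conditioning on a copy of one member gives 0
  b <- encoded_alignment(cbind(m[, 1], m[, 2], m[, 1]))
  expect_equal(cond_mi_given_one(b, 1, 2, 3), 0, tolerance = 1e-10)
  for (seed in 1:8) {
    r <- rand_aln(30, 3, nsym = 5, seed = seed)
    x <- r$matrix[, 1]; y <- r$matrix[, 2]; z <- r$matrix[, 3]
    # weighted per-stratum oracle
    expect_equal(cond_mi_given_one(r, 1, 2, 3), o_CMI1(x, y, z),
                 tolerance = 1e-9)
    # I(Xi;Xj) - I(Xi;Xj;Xk) == I(Xi;Xj|Xk)
    expect_equal(mi_2d(r, 1, 2) - interaction_information_3(r, 1, 2, 3),
                 cond_mi_given_one(r, 1, 2, 3), tolerance = 1e-9)
    # symmetric in (i, j)
    expect_equal(cond_mi_given_one(r, 1, 2, 3), cond_mi_given_one(r, 2, 1, 3),
                 tolerance = 1e-12)
  }
  expect_error(cond_mi_given_one(a, 1, 1, 2), "distinct")
})

test_that("conditional MI given two columns: limits and dual oracles", {
  set.seed(4)
  m <- cbind(sample.int(5, 50, TRUE), sample.int(5, 50, TRUE),
             rep(1L, 50), rep(3L, 50))
  a <- encoded_alignment(m)
  expect_equal(cond_mi_given_two(a, 1, 2, 3, 4), mi_2d(a, 1, 2),
               tolerance = 1e-10)
  b <- encoded_alignment(cbind(m[, 1], m[, 2], m[, 1], m[, 2]))
  expect_equal(cond_mi_given_two(b, 1, 2, 3, 4), 0, tolerance = 1e-10)
  for (seed in 1:8) {
    r <- rand_aln(30, 4, nsym = 4, seed = seed)
    v <- cond_mi_given_two(r, 1, 2, 3, 4)
    # chain-rule expansion in interaction informations
    expansion <- mi_2d(r, 1, 2) -
      interaction_information_3(r, 1, 2, 4) -
      interaction_information_3(r, 1, 2, 3) +
      interaction_information_4(r, 1, 2, 3, 4)
    expect_equal(v, expansion, tolerance = 1e-9)
    # stratified double-conditioning oracle
    expect_equal(v, o_CMI2(r$matrix[, 1], r$matrix[, 2],
                           r$matrix[, 3], r$matrix[, 4]),
                 tolerance = 1e-9)
    # symmetry in (i,j) and in (k,l)
    expect_equal(v, cond_mi_given_two(r, 2, 1, 4, 3), tolerance = 1e-12)
  }
})

test_that("2D map builder matches per-pair MI and is row-order invariant", {
  set.seed(9)
  x <- sample.int(6, 400, TRUE)
  a <- encoded_alignment(cbind(x, x, sample.int(6, 400, TRUE)))
  m <- build_map_2d(a)
  expect_gt(m$scores[1, 2], 0.5)
  expect_lt(m$scores[1, 3], 0.2)
  expect_lt(m$scores[2, 3], 0.2)
  r <- rand_aln(25, 5, seed = 11)
  m2 <- build_map_2d(r)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m2$scores[i, j], mi_2d(r, i, j), tolerance = 1e-12)
  perm <- rand_aln(25, 5, seed = 11)
  perm$matrix <- perm$matrix[sample(25), ]
  expect_equal(build_map_2d(perm)$scores, m2$scores, tolerance = 1e-12)
  expect_true(all(is.na(diag(m2$scores))))
})

test_that("3D map builder equals the explicit triple-loop oracle", {
  r <- rand_aln(20, 6, nsym = 6, seed = 21)
  m3 <- build_map_3d(r)
  for (i in 1:5) for (j in (i + 1):6) {
    ks <- setdiff(1:6, c(i, j))
    o <- mean(vapply(ks, function(k) cond_mi_given_one(r, i, j, k), 0))
    expect_equal(m3$scores[i, j], o, tolerance = 1e-10)
  }
  # L = 3: single-term average
  r3 <- rand_aln(15, 3, seed = 5)
  expect_equal(build_map_3d(r3)$scores[1, 2],
               cond_mi_given_one(r3, 1, 2, 3), tolerance = 1e-12)
  expect_error(build_map_3d(rand_aln(10, 2)), "L >= 3")
  # row permutation invariance
  perm <- rand_aln(20, 6, nsym = 6, seed = 21)
  perm$matrix <- perm$matrix[sample(20), ]
  expect_equal(build_map_3d(perm)$scores, m3$scores, tolerance = 1e-12)
})

test_that("planted ternary chain is suppressed by conditioning on its hub", {
  # X1 <- X3 -> X2 with independent noise: the conditional MI given the hub
  # vanishes as N grows while the marginal MI stays bounded away from 0
  set.seed(33)
  ns <- c(500, 2000, 8000)
  cmi <- mi <- numeric(length(ns))
  for (q in seq_along(ns)) {
    n <- ns[q]
    hub <- sample.int(20L, n, TRUE)
    copy <- function() ifelse(runif(n) < 0.9, hub, sample.int(20L, n, TRUE))
    a <- encoded_alignment(cbind(copy(), copy(), hub,
                                 sample.int(20L, n, TRUE)))
    cmi[q] <- cond_mi_given_one(a, 1, 2, 3)
    mi[q] <- mi_2d(a, 1, 2)
  }
  expect_lt(cmi[length(ns)], cmi[1])     # plug-in conditional MI shrinks
  expect_true(all(mi > 1))               # marginal coupling stays strong
  expect_lt(cmi[length(ns)], 0.5 * mi[length(ns)])
})

test_that("4D map builder equals the quadruple-loop oracle", {
  r <- rand_aln(15, 6, nsym = 4, seed = 8)
  m4 <- build_map_4d(r)
  for (i in 1:5) for (j in (i + 1):6) {
    rest <- setdiff(1:6, c(i, j))
    vals <- c()
    for (k in rest) for (l in setdiff(rest, k))
      vals <- c(vals, cond_mi_given_two(r, i, j, k, l))
    expect_equal(m4$scores[i, j], mean(vals), tolerance = 1e-10)
  }
  # L = 4: the two ordered (k,l) choices collapse to one unordered pair
  r4 <- rand_aln(12, 4, seed = 3)
  expect_equal(build_map_4d(r4)$scores[1, 2],
               cond_mi_given_two(r4, 1, 2, 3, 4), tolerance = 1e-12)
  # degenerate alignment of identical columns: the oracle gives 0 for all
  # pairs (conditioning on copies of the pair members kills every term)
  set.seed(12)
  x <- sample.int(8, 30, TRUE)
  deg <- encoded_alignment(cbind(x, x, x, x))
  o <- cond_mi_given_two(deg, 1, 2, 3, 4)
  expect_equal(build_map_4d(deg)$scores[1, 2], o, tolerance = 1e-12)
  expect_equal(o, 0, tolerance = 1e-10)
  expect_error(build_map_4d(rand_aln(10, 3)), "L >= 4")
  # the alternative X4 reading is a uniform rescale
  alt <- build_map_4d(r, x4_set = "include_pair")
  expect_equal(alt$scores, m4$scores * 3 / 5, tolerance = 1e-12)
})

test_that("entropy is monotone under adding columns", {
  for (seed in 1:5) {
    r <- rand_aln(25, 4, seed = seed)
    subsets <- list(1, c(1, 2), c(1, 2, 3))
    for (s in subsets) {
      extra <- setdiff(1:4, s)[1]
      expect_gte(joint_entropy(r, c(s, extra)) - joint_entropy(r, s), -1e-12)
    }
  }
})

test_that("iid alignments: maps converge toward zero as N grows", {
  # alphabet 4 so that N = 5000 reaches the asymptotic regime even for the
  # two-column conditioning strata (with 21 symbols the 4D estimator needs
  # N far beyond 21^2 rows per stratum before its bias starts to decay)
  ns <- c(50, 500, 5000)
  m2 <- m3 <- m4 <- numeric(length(ns))
  for (q in seq_along(ns)) {
    r <- rand_aln(ns[q], 6, nsym = 4, seed = 40 + q)
    m2[q] <- mean(build_map_2d(r)$scores, na.rm = TRUE)
    m3[q] <- mean(build_map_3d(r)$scores, na.rm = TRUE)
    m4[q] <- mean(build_map_4d(r)$scores, na.rm = TRUE)
  }
  expect_true(all(diff(m2) < 0))
  expect_true(all(diff(m3) < 0))
  expect_true(all(diff(m4) < 0))
  expect_lt(m2[3], 0.01)
  # conditioning inflates the finite-sample bias, it never deflates it
  expect_gte(m3[3], m2[3])
  expect_gte(m4[3], m3[3])
  # with 21 symbols only the pairwise map is in regime by N = 5000
  r21 <- rand_aln(5000, 6, seed = 44)
  expect_lt(mean(build_map_2d(r21)$scores, na.rm = TRUE), 0.1)
})
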