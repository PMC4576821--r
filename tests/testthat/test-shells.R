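test_that("PDB parsing honours the error contracts", {
  # minimal two-residue synthetic fixture
  lines <- pdb_lines(rbind(c(0, 0, 0), c(3, 4, 0)))
  m <- parse_structure(lines)
  expect_equal(nrow(m$residues), 2)
  expect_equal(m$atoms$x, c(0, 3))
  expect_equal(m$atoms$y, c(0, 4))

  het_only <- pdb_lines(rbind(c(0, 0, 0)), record = "HETATM")
  expect_error(parse_structure(het_only), "HETATM only")
  expect_error(parse_structure(c("REMARK nothing here", "END")),
               "no ATOM records")

  bad <- lines
  substr(bad[2], 31, 38) <- "  xx.yyy"
  expect_error(parse_structure(bad), "line 2")
})

test_that("altloc handling keeps the highest-occupancy copy", {
  a <- "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.30  0.00           C"
  b <- "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.70  0.00           C"
  m <- parse_structure(c(a, b, "END"))
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 9)
})

test_that("minimal triad distances follow Euclidean geometry", {
  # 3-4-5 triangle between two single-atom residues
  m <- model_from_xyz(rbind(c(0, 0, 0), c(3, 4, 0)))
  tri <- triad_definition("A:1", m)
  expect_equal(min_distance_to_triad(m, 2, tri), 5)
  expect_equal(min_distance_to_triad(m, 1, tri), 0)  # self distance
  expect_error(min_distance_to_triad(m, 99, tri), "99")
  expect_error(triad_definition("A:99", m), "absent")
})

test_that("triad distance is invariant under rigid-body transformation", {
  withr::local_seed(55)
  xyz <- matrix(stats::runif(30, -10, 10), ncol = 3)
  m <- model_from_xyz(xyz)
  tri <- triad_definition(c("A:1", "A:2"), m)
  d0 <- vapply(3:10, function(p) min_distance_to_triad(m, p, tri),
               numeric(1))
  for (i in 1:5) {
    R <- random_rotation()
    shift <- stats::rnorm(3, sd = 20)
    xyz_t <- sweep(xyz %*% R, 2, shift, "+")
    m_t <- model_from_xyz(xyz_t)
    d_t <- vapply(3:10, function(p) min_distance_to_triad(m_t, p, tri),
                  numeric(1))
    expect_equal(d_t, d0, tolerance = 1e-9)
  }
  # symmetric under atom reordering
  perm <- c(2, 1, 10:3)
  m_p <- model_from_xyz(xyz[perm, ], resno = (1:10)[perm])
  d_p <- vapply(3:10, function(p) min_distance_to_triad(m_p, p, tri),
                numeric(1))
  expect_equal(d_p, d0, tolerance = 1e-12)
})

test_that("shell assignment is a half-open partition of [0, Inf)", {
  expect_identical(assign_shell(c(0, 3.999, 4, 5.6, 7.999, 8, 11.999, 12, 40)),
                   c("first", "first", "second", "second", "second",
                     "third", "third", "beyond", "beyond"))
  # every distance lands in exactly one shell
  d <- seq(0, 30, by = 0.01)
  sh <- assign_shell(d)
  expect_false(anyNA(sh))
  expect_true(all(sh %in% c("first", "second", "third", "beyond")))
  expect_error(assign_shell(-0.1), ">= 0")
})

test_that("permutation p-values agree with the hypergeometric oracle", {
  # 10 eligible positions, 5 in the target shell, all 3 mutations in-shell
  ts <- toy_structure(13, c(second = 5, beyond = 5), seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts, f)
  m <- parse_structure(f)
  tri <- triad_definition(ts$triad, m)
  second <- ts$residues$resno[ts$residues$shell == "second"]
  muts <- data.frame(position = second[1:3], from_aa = "G", to_aa = "A",
                     round = "1", kind = "point")
  n_perm <- 2e4
  res <- shell_enrichment(m, tri, muts, n_permutations = n_perm, seed = 3)
  # exact upper tail: P(X >= 3), X ~ Hypergeom(5 in-shell, 5 out, draw 3)
  p_exact <- stats::phyper(2, 5, 5, 3, lower.tail = FALSE)
  expect_equal(p_exact, choose(5, 3) / choose(10, 3))
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se)
  expect_equal(res$observed_count, 3)
  expect_equal(res$n_mutations, 3)
})

test_that("degenerate enrichment cases hit the trivial bounds", {
  ts <- toy_structure(9, c(second = 6), seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts, f)
  m <- parse_structure(f)
  tri <- triad_definition(ts$triad, m)
  second <- ts$residues$resno
  # all eligible positions in the target shell -> p = 1
  muts <- data.frame(position = second[1:2], kind = "point")
  expect_equal(shell_enrichment(m, tri, muts, n_permutations = 500,
                                seed = 1)$p_value, 1)
  # observed count 0 -> p = 1
  ts2 <- toy_structure(10, c(second = 3, beyond = 4), seed = 5)
  write_pdb(ts2, f)
  m2 <- parse_structure(f)
  tri2 <- triad_definition(ts2$triad, m2)
  beyond <- ts2$residues$resno[ts2$residues$shell == "beyond"]
  muts0 <- data.frame(position = beyond[1:2], kind = "point")
  expect_equal(shell_enrichment(m2, tri2, muts0, n_permutations = 500,
                                seed = 1)$p_value, 1)
  # truncations are excluded from the placeable mutation set
  muts_tr <- rbind(muts0,
                   data.frame(position = beyond[3], kind = "truncation"))
  expect_equal(shell_enrichment(m2, tri2, muts_tr, n_permutations = 100,
                                seed = 1)$n_mutations, 2)
  # more mutations than eligible positions is a validation error
  many <- data.frame(position = rep(ts2$residues$resno, 2), kind = "point")
  expect_error(shell_enrichment(m2, tri2,
                                data.frame(position = 999, kind = "point"),
                                seed = 1), "not in the eligible set")
})

test_that("structures with only remote residues give zero in-shell counts", {
  ts <- toy_structure(11, c(beyond = 8), seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts, f)
  m <- parse_structure(f)
  tri <- triad_definition(ts$triad, m)
  muts <- data.frame(position = ts$residues$resno[1:5], kind = "point")
  res <- shell_enrichment(m, tri, muts, n_permutations = 200, seed = 1)
  expect_equal(res$observed_count, 0)
  expect_equal(res$p_value, 1)
})

test_that("triads can be recovered from SITE records when not specified", {
  lines <- c("SITE     1 AC1  3 HIS A  46  ASP A  81  GLY A   3",
             pdb_lines(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       resno = c(46, 81, 3)),
             "END")
  m <- parse_structure(lines)
  tri <- triad_definition(NULL, m)
  expect_setequal(tri$resno, c(46, 81, 3))
  m2 <- parse_structure(pdb_lines(rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_error(triad_definition(NULL, m2), "SITE")
})
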