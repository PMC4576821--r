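test_that("trace generator is exact at zero noise and seed-reproducible", {
  gen <- list(A1 = 0.4, kobs1 = 2, A2 = 0.6, kobs2 = 0.05)
  tr0 <- generate_trace(gen, n_points = 50, t_max = 80, noise_sd = 0,
                        seed = 1)
  expect_equal(tr0$signal,
               biphasic_curve(tr0$time, 0.4, 2, 0.6, 0.05))
  tr1 <- generate_trace(gen, n_points = 50, t_max = 80, noise_sd = 0.05,
                        seed = 9)
  tr2 <- generate_trace(gen, n_points = 50, t_max = 80, noise_sd = 0.05,
                        seed = 9)
  tr3 <- generate_trace(gen, n_points = 50, t_max = 80, noise_sd = 0.05,
                        seed = 10)
  expect_identical(tr1$signal, tr2$signal)
  expect_false(identical(tr1$signal, tr3$signal))
  expect_error(generate_trace(gen, noise_sd = -0.1), "noise_sd")
})

test_that("empirical trace noise matches the requested noise_sd", {
  tr <- generate_trace(list(A1 = 1, kobs1 = 0.1), n_points = 1e4,
                       t_max = 100, noise_sd = 0.05, seed = 4)
  resid <- tr$signal - attr(tr, "noiseless")
  expect_lt(abs(stats::sd(resid) - 0.05) / 0.05, 0.03)
})

test_that("epPCR library mutation counts are Poisson with the set mean", {
  for (lambda in c(0.5, 1.3, 3)) {
    cfg <- screen_config(library_size = 1e4, mutation_lambda = lambda,
                         seed = 100 + round(10 * lambda))
    lib <- generate_library(parent_variant(cfg), cfg)
    counts <- vapply(lib, function(v) nrow(v$mutations), integer(1))
    # sample mean within 3 SE of the configured mean
    se <- sqrt(lambda / length(counts))
    expect_lt(abs(mean(counts) - lambda), 3 * se)
    # chi-squared goodness of fit against Poisson(lambda); the tail is
    # pooled so every category has expected count >= 5
    n <- length(counts)
    tail_exp <- vapply(1:20, function(k) {
      n * stats::ppois(k - 1, lambda, lower.tail = FALSE)
    }, numeric(1))
    kcut <- max(which(tail_exp >= 5))
    obs <- tabulate(pmin(counts, kcut) + 1L, nbins = kcut + 1L)
    p <- c(stats::dpois(0:(kcut - 1), lambda),
           stats::ppois(kcut - 1, lambda, lower.tail = FALSE))
    gof <- stats::chisq.test(obs, p = p)
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("lambda = 0 libraries are clones of the parent", {
  cfg <- screen_config(library_size = 50, mutation_lambda = 0, seed = 5)
  parent <- parent_variant(cfg)
  lib <- generate_library(parent, cfg)
  expect_true(all(vapply(lib, function(v) v$sequence == parent$sequence,
                         logical(1))))
  expect_true(all(vapply(lib, function(v)
    v$true_log10_activity_ser == parent$true_log10_activity_ser,
    logical(1))))
})

test_that("no library variant reverts the nucleophile position", {
  cfg <- screen_config(library_size = 2000, mutation_lambda = 3,
                       gene_length = 160, seed = 6)
  parent <- parent_variant(cfg)
  lib <- generate_library(parent, cfg)
  muts <- do.call(rbind, lapply(lib, `[[`, "mutations"))
  at151 <- muts[muts$position == 151, , drop = FALSE]
  expect_false(any(at151$to_aa == "C"))
  # position 151 itself is still mutable to other residues
  expect_gt(nrow(at151), 0)
})

test_that("effect draws are correlated between nucleophile backgrounds", {
  cfg <- screen_config(library_size = 4000, mutation_lambda = 1, seed = 8)
  lib <- generate_library(parent_variant(cfg), cfg)
  one <- vapply(lib, function(v) nrow(v$mutations), integer(1)) == 1L
  ser <- vapply(lib[one], `[[`, numeric(1), "true_log10_activity_ser") -
    cfg$parent_log10_ser
  cys <- vapply(lib[one], `[[`, numeric(1), "true_log10_activity_cys") -
    cfg$parent_log10_cys
  expect_gt(stats::cor(ser, cys), 0.8)
})

test_that("campaigns are monotone on truth and flat without mutations", {
  cfg0 <- screen_config(rounds = 5, library_size = 120,
                        screen_noise_sd = 0, seed = 21)
  tab0 <- simulate_de(cfg0)
  expect_true(all(diff(tab0$log10_ser) >= 0))

  cfg_flat <- screen_config(rounds = 4, library_size = 50,
                            mutation_lambda = 0, seed = 22)
  tab_flat <- simulate_de(cfg_flat)
  expect_equal(tab_flat$log10_ser, rep(cfg_flat$parent_log10_ser, 5))
  expect_equal(tab_flat$n_mutations, rep(0L, 5))
})

test_that("campaigns are reproducible per seed and respond to the seed", {
  cfg <- screen_config(rounds = 3, library_size = 60, seed = 31)
  t1 <- simulate_de(cfg)
  t2 <- simulate_de(cfg)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_de(screen_config(rounds = 3, library_size = 60, seed = 32))
  expect_false(identical(t1$log10_ser, t3$log10_ser))
})

test_that("toy structures plant exactly the requested shell geometry", {
  ts <- toy_structure(15, c(first = 2, second = 5, third = 3, beyond = 2),
                      seed = 14)
  got <- table(factor(ts$residues$shell,
                      levels = c("first", "second", "third", "beyond")))
  expect_equal(as.integer(got), c(2L, 5L, 3L, 2L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts, f)
  m <- parse_structure(f)
  tri <- triad_definition(ts$triad, m)
  # triad residues sit at distance zero from their own triad
  expect_equal(min_distance_to_triad(m, 1, tri), 0)
  st <- shell_table(m, tri, positions = ts$residues$resno)
  # planted distances recovered within PDB coordinate precision
  expect_equal(st$min_distance_A, ts$residues$planted_distance,
               tolerance = 1e-3)
  expect_identical(st$shell, ts$residues$shell)
  expect_error(toy_structure(10, c(second = 5)), "infeasible")
  expect_error(toy_structure(9, c(middle = 6)), "unknown shell")
})
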