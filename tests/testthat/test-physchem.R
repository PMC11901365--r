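test_that("cdr_h3_length: base window is 8, insertions extend it", {
  expect_equal(cdr_h3_length(fx_heavy_numbered()), 8L)
  n14 <- number_chain(chain_sequence("s14", "heavy",
                                     heavy_with_loop("DGGYSRRYSGYQTY")))
  expect_equal(cdr_h3_length(n14), 14L)   # 8 base + H100A..H100F
})

test_that("cysteine rule fails only above two cysteines", {
  expect_true(cysteine_filter("ACCA")$pass)
  f <- cysteine_filter("ACCCA")
  expect_false(f$pass); expect_equal(f$count, 3L)
  f0 <- cysteine_filter("AGGA")
  expect_true(f0$pass); expect_equal(f0$count, 0L)
})

test_that("delta_g is an additive per-residue sum (independent oracle)", {
  tt <- thermo_tables()
  expect_identical(delta_g_unfolding("", tt), 0)
  expect_equal(delta_g_unfolding("AA", tt), 2 * delta_g_unfolding("A", tt))
  # brute-force summation straight off the packaged CSV
  tab <- read.csv(system.file("extdata", "thermo_unfolding_synthetic.csv",
                              package = "abtriage"), comment.char = "#")
  brute <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- match(ch, tab$residue)
    sum(tab$dH_kJ_mol[i] - 298.15 * tab$dS_kJ_mol_K[i])
  }
  set.seed(11)
  for (i in 1:20) {
    s <- random_peptide(sample(5:120, 1))
    expect_equal(delta_g_unfolding(s, tt), brute(s), tolerance = 1e-12)
  }
  # linearity property: dG(s + t) = dG(s) + dG(t)
  for (i in 1:10) {
    s <- random_peptide(30); t <- random_peptide(40)
    expect_equal(delta_g_unfolding(paste0(s, t), tt),
                 delta_g_unfolding(s, tt) + delta_g_unfolding(t, tt))
  }
  expect_error(delta_g_unfolding("AXZ", tt), class = "ab_unknown_residue")
})

test_that("isoelectric_point hits closed forms for tiny ampholytes", {
  pk <- pi_params()$pka
  # "GG": no ionisable side chains -> midpoint of the terminal pKas
  expect_equal(isoelectric_point("GG"), (pk[["Nterm"]] + pk[["Cterm"]]) / 2,
               tolerance = 1e-3)
  # single K: midpoint of the two basic pKas
  expect_equal(isoelectric_point("K"), (pk[["Nterm"]] + pk[["K"]]) / 2,
               tolerance = 1e-3)
})

test_that("isoelectric_point satisfies its charge contract and the grid-scan oracle", {
  params <- pi_params()
  ph_grid <- seq(0, 14, by = 0.001)
  set.seed(21)
  for (i in 1:40) {
    s <- random_peptide(sample(3:60, 1))
    pi_hat <- isoelectric_point(s, params)
    expect_lte(abs(net_charge(s, pi_hat, params)), params$tolerance)
    pi_scan <- ph_grid[which.min(abs(charge_curve(s, ph_grid)))]
    expect_lte(abs(pi_hat - pi_scan), 0.01)
  }
})

test_that("mean_pair_pi averages the two chain values", {
  expect_equal(mean_pair_pi("GG", "GG"), isoelectric_point("GG"))
  a <- isoelectric_point("DDD"); b <- isoelectric_point("KKK")
  expect_equal(mean_pair_pi("DDD", "KKK"), (a + b) / 2)
})

test_that("reference_stats uses sample sd and needs two records", {
  r10 <- paired_antibody("a", heavy_with_loop("DGGYSRRGDY"), fx_refs()[["kappa"]])
  r14 <- paired_antibody("b", heavy_with_loop("DGGYSRRYSGYQTY"), fx_refs()[["kappa"]])
  st <- reference_stats(list(r10, r14))
  expect_equal(unname(st$mean["cdr_h3_length"]), 12)
  expect_equal(unname(st$sd["cdr_h3_length"]), sqrt(8), tolerance = 1e-12)
  st2 <- reference_stats(list(r10, r10))
  expect_equal(unname(st2$sd), rep(0, 5))
  expect_error(reference_stats(list(r10)), class = "ab_insufficient_data")
})

test_that("physchem_filter gates on Z and names failing features", {
  rec <- paired_antibody("q", heavy_with_loop("DGGYSRRGDY"), fx_refs()[["kappa"]])
  f <- physchem_features(rec)
  at <- function(mean, sd) structure(list(mean = mean, sd = sd, n = 10L),
                                     class = "reference_stats")
  # value == mean on all features -> retained for any Z > 0
  expect_true(physchem_filter(rec, at(f, f * 0 + 1))$retained)
  # one feature at mean + 3 sd with Z = 2 -> rejected, named in reasons
  m <- f; m["cdr_h3_length"] <- f["cdr_h3_length"] - 3
  v <- physchem_filter(rec, at(m, f * 0 + 1), stage_thresholds(2))
  expect_false(v$retained)
  expect_true("cdr_h3_length" %in% v$reasons)
  # all thresholds off -> pass-through
  far <- physchem_filter(rec, at(f + 100, f * 0 + 1e-6),
                         stage_thresholds(off = "all"))
  expect_true(far$retained)
  # cysteine hard rule fires independently of Z
  bad <- paired_antibody("c", heavy_with_loop("DCCYSCRGDY"), fx_refs()[["kappa"]])
  vb <- physchem_filter(bad, at(physchem_features(bad), f * 0 + 1))
  expect_false(vb$retained)
  expect_true("cysteine_heavy" %in% vb$reasons)
})

test_that("physchem_filter retained set is monotone in Z", {
  recs <- fx_repertoire()[1:15]
  st <- reference_stats(recs)
  kept <- lapply(c(0.5, 1, 2, 4), function(z)
    Filter(function(r) physchem_filter(r, st, stage_thresholds(z))$retained,
           recs))
  ids <- lapply(kept, vapply, `[[`, "", "id")
  for (i in 1:3) expect_true(all(ids[[i]] %in% ids[[i + 1]]))
})

test_that("compare_groups: exact enumeration and symmetry", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2/20 of the C(6,3) assignments
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  a <- c(0.3, 1.2, 2.2, 0.1); b <- c(1.4, 0.9, 3.1)
  expect_equal(compare_groups(a, b)$p, compare_groups(b, a)$p)
  expect_error(compare_groups(numeric(0), 1), class = "ab_degenerate_input")
})

test_that("compare_groups matches wilcox.test in both regimes", {
  set.seed(31)
  for (i in 1:25) {   # exact, all group sizes <= 6
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    r <- compare_groups(a, b)
    w <- wilcox.test(a, b, exact = TRUE)
    expect_equal(unname(r$U), unname(w$statistic))
    expect_equal(r$p, w$p.value, tolerance = 1e-12)
  }
  for (i in 1:15) {   # normal approximation with continuity correction
    a <- rnorm(14); b <- rnorm(11) + 0.4
    r <- compare_groups(a, b)
    w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(r$p, w$p.value, tolerance = 1e-10)
  }
})
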