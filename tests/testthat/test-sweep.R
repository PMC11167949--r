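test_that("site FST components match the independent Weir-Cockerham oracle", {
  # fixed difference with equal complete samples -> theta = 1
  g <- cbind(matrix(2L, 1, 10), matrix(0L, 1, 10))
  co <- make_cohort(pos = 100, geno = g)
  comp <- fst_components(co, two_pop_table(10, 10), "POPA", "POPB")
  expect_equal(comp$theta, 1)
  # identical genotype arrays -> non-positive estimate
  arr <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 1L), 2), nrow = 1)
  co2 <- make_cohort(pos = 100, geno = arr)
  comp2 <- fst_components(co2, two_pop_table(6, 6), "POPA", "POPB")
  expect_lte(comp2$theta, 0)
  # HWE-consistent counts: 30/88 ALT in A, 10/58 ALT in B
  set.seed(21)
  mk_hwe <- function(k, n) {
    # genotypes hitting an exact allele count, HWE-like arrangement
    g <- integer(n); g[seq_len(k %/% 2)] <- 2L
    if (k %% 2) g[k %/% 2 + 1] <- 1L
    sample(g)
  }
  g3 <- matrix(c(mk_hwe(30, 44), mk_hwe(10, 29)), nrow = 1)
  co3 <- make_cohort(pos = 100, geno = g3)
  comp3 <- fst_components(co3, two_pop_table(44, 29), "POPA", "POPB")
  oc <- oracle_wc_components(list(g3[1, 1:44], g3[1, 45:73]))
  expect_equal(comp3$a, unname(oc["a"]), tolerance = 1e-10)
  expect_equal(comp3$b, unname(oc["b"]), tolerance = 1e-10)
  expect_equal(comp3$c, unname(oc["c"]), tolerance = 1e-10)
})

test_that("window FST and pi match brute-force oracles on random windows", {
  set.seed(77)
  pops <- two_pop_table(12, 9)
  for (i in 1:50) {
    n_sites <- sample(1:10, 1)
    g <- random_two_pop_geno(n_sites, 12, 9)
    pos <- sort(sample.int(9000, n_sites))
    co <- make_cohort(pos = pos, geno = g)
    ws <- window_stats(co, pops, c(chr1 = 10000), "POPA", "POPB",
                       window = 10000L, step = 10000L)
    expect_equal(nrow(ws), 1L)
    ofst <- oracle_window_fst(g[, 1:12, drop = FALSE],
                              g[, 13:21, drop = FALSE])
    if (!is.na(ws$fst)) {
      expect_equal(ws$fst, ofst, tolerance = 1e-10,
                   info = paste("window", i))
    }
    expect_equal(ws$pi_a,
                 oracle_window_pi(g[, 1:12, drop = FALSE], 10000),
                 tolerance = 1e-10)
    expect_equal(ws$pi_b,
                 oracle_window_pi(g[, 13:21, drop = FALSE], 10000),
                 tolerance = 1e-10)
  }
})

test_that("windowed statistics honour their closed-form examples", {
  pops <- two_pop_table(5, 5)
  # one 10 kb window, one site with 5 REF and 5 ALT alleles in pop A
  g <- matrix(c(2L, 2L, 1L, 0L, 0L, rep(0L, 5)), nrow = 1)
  co <- make_cohort(pos = 5000, geno = g)
  ws <- window_stats(co, pops, c(chr1 = 10000), "POPA", "POPB",
                     window = 10000L, step = 10000L)
  expect_equal(ws$pi_a, (2 * 5 * 5 / (10 * 9)) / 10000, tolerance = 1e-12)
  expect_equal(ws$pi_b, 0)               # monomorphic window
  expect_equal(ws$pi_ratio, 0)
  # ratio undefined when the denominator population is monomorphic
  co_flip <- co; co_flip$geno <- co$geno[, c(6:10, 1:5), drop = FALSE]
  ws_na <- window_stats(co_flip, pops, c(chr1 = 10000), "POPA", "POPB",
                        window = 10000L, step = 10000L)
  expect_true(is.na(ws_na$pi_ratio))
  # doubling the window length halves per-bp pi
  ws2 <- window_stats(co, pops, c(chr1 = 20000), "POPA", "POPB",
                      window = 20000L, step = 20000L)
  expect_equal(ws2$pi_a, ws$pi_a / 2, tolerance = 1e-12)
  # all-fixed-difference window -> weighted FST = 1
  g3 <- rbind(c(rep(2L, 5), rep(0L, 5)), c(rep(0L, 5), rep(2L, 5)))
  co3 <- make_cohort(pos = c(1000, 2000), geno = g3)
  ws3 <- window_stats(co3, pops, c(chr1 = 10000), "POPA", "POPB",
                      window = 10000L, step = 10000L)
  expect_equal(ws3$fst, 1)
  # single-site window equals that site's theta
  comp <- fst_components(co, pops, "POPA", "POPB")
  expect_equal(ws$fst, comp$theta)
})

test_that("statistics are invariant to allele relabeling and population order", {
  set.seed(99)
  g <- random_two_pop_geno(8, 10, 7)
  pos <- sort(sample.int(40000, 8))
  co <- make_cohort(pos = pos, geno = g)
  pops <- two_pop_table(10, 7)
  ws <- window_stats(co, pops, c(chr1 = 50000), "POPA", "POPB",
                     window = 50000L, step = 50000L)
  # REF/ALT relabeling: dosage flips 2 - g
  co_flip <- co; co_flip$geno <- 2L - co$geno
  ws_flip <- window_stats(co_flip, pops, c(chr1 = 50000), "POPA", "POPB",
                          window = 50000L, step = 50000L)
  expect_equal(ws_flip$pi_a, ws$pi_a, tolerance = 1e-12)
  expect_equal(ws_flip$fst, ws$fst, tolerance = 1e-12)
  # population order swap: FST unchanged, pi-ratio inverts
  ws_sw <- window_stats(co, pops, c(chr1 = 50000), "POPB", "POPA",
                        window = 50000L, step = 50000L)
  expect_equal(ws_sw$fst, ws$fst, tolerance = 1e-12)
  expect_equal(ws_sw$pi_ratio, 1 / ws$pi_ratio, tolerance = 1e-12)
})

test_that("top-window selection uses nearest-rank quantiles with ties", {
  set.seed(3)
  w <- data.frame(chrom = "chr1", start = (0:99) * 1e4,
                  end = (0:99) * 1e4 + 5e4, n_sites = 10,
                  fst = sample(seq(0.01, 1, length.out = 100)),
                  pi_a = 1e-3, pi_b = 1e-3,
                  pi_ratio = sample(seq(0.1, 3, length.out = 100)))
  sel <- select_top_windows(w)
  expect_equal(sum(sel$top_fst), 5L)
  expect_equal(sum(sel$top_ratio), 5L)
  expect_equal(which(sel$candidate), which(sel$top_fst & sel$top_ratio))
  # sort-based oracle for the thresholds
  expect_equal(attr(sel, "fst_threshold"), sort(w$fst)[96])
  expect_equal(attr(sel, "ratio_threshold"), sort(w$pi_ratio)[96])
  # degenerate ties: all windows identical -> all candidates
  w2 <- w; w2$fst <- 0.4; w2$pi_ratio <- 1.2
  sel2 <- select_top_windows(w2)
  expect_true(all(sel2$candidate))
  w3 <- w[1:10, ]
  expect_warning(select_top_windows(w3), "unstable")
})

test_that("candidate windows map to genes by >= 1 bp overlap", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chrom = "chr1",
                      start = c(10000, 60000, 100000, 200000),
                      end = c(20000, 70000, 100050, 210000))
  w <- data.frame(chrom = "chr1", start = c(0, 50000, 100000),
                  end = c(50000, 100000, 150000),
                  candidate = c(TRUE, FALSE, TRUE))
  expect_setequal(windows_to_genes(w, genes), c("g1", "g3"))
  # 1 bp edge: gene starting exactly at the window's last base
  genes2 <- data.frame(gene_id = "edge", chrom = "chr1",
                       start = 50000, end = 60000)
  w2 <- data.frame(chrom = "chr1", start = 0, end = 50000, candidate = TRUE)
  expect_equal(windows_to_genes(w2, genes2), "edge")
  genes3 <- data.frame(gene_id = "out", chrom = "chr1",
                       start = 50001, end = 60000)
  expect_equal(windows_to_genes(w2, genes3), character(0))
  expect_equal(windows_to_genes(w2[!w2$candidate, ], genes2), character(0))
})

test_that("a planted sweep region is detected across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_sites = 3000, chrom_lengths = c(chr1 = 1.5e6),
                      frac_specific_a = 0, frac_specific_b = 0,
                      frac_predominant_a = 0, frac_predominant_b = 0,
                      sweep_region = list(chrom = "chr1", start = 600001,
                                          end = 800000, target = "a",
                                          diversity_factor = 0.15),
                      n_genes = 5, seed = seed)
    sim <- simulate_cohort(cfg, withr::local_tempdir())
    ws <- window_stats(sim$cohort, sim$populations, cfg$chrom_lengths,
                       "POPA", "POPB")
    sel <- select_top_windows(ws)
    cand <- sel[sel$candidate, ]
    if (any(cand$start < 800000 & cand$end > 600000)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
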