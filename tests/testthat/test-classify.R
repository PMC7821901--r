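# Cell classification, Freeman-Halton exact test, composition and pairing.

fake_result <- function(excited, inhibited, ext_e = 0.99, ext_i = 0.5) {
  structure(list(excited = excited, inhibited = inhibited,
                 extremity_excited = ext_e, extremity_inhibited = ext_i),
            class = "resampling_result")
}

test_that("cells are classified from the shuffle flags, extremity breaking ties", {
  expect_equal(classify_cell(fake_result(TRUE, FALSE)), "excited")
  expect_equal(classify_cell(fake_result(FALSE, TRUE)), "inhibited")
  expect_equal(classify_cell(fake_result(FALSE, FALSE)), "uncorrelated")
  expect_message(
    lab <- classify_cell(fake_result(TRUE, TRUE, ext_e = 0.999, ext_i = 0.96)),
    "both excited")
  expect_equal(lab, "excited")
  expect_message(
    lab2 <- classify_cell(fake_result(TRUE, TRUE, ext_e = 0.96, ext_i = 0.999)))
  expect_equal(lab2, "inhibited")
})

test_that("the 2x2 exact test matches the hypergeometric closed form", {
  expect_equal(fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, 2)), 34 / 70,
               tolerance = 1e-12)
  # random 2x2 tables against stats::fisher.test
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rpois(4, 5) + 1, 2, 2)
    expect_equal(fisher_exact_rxc(m), fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("the r x c exact test agrees with stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:15) {
    m <- matrix(rpois(6, 4) + 1, 2, 3)
    expect_equal(fisher_exact_rxc(m), fisher.test(m)$p.value, tolerance = 1e-7)
  }
  m3 <- matrix(c(4, 1, 2, 2, 3, 5, 1, 4, 2), 3, 3)
  expect_equal(fisher_exact_rxc(m3), fisher.test(m3)$p.value, tolerance = 1e-7)
})

test_that("exact-test edge cases: identical rows, symmetry, degenerate input", {
  expect_equal(fisher_exact_rxc(matrix(2, 2, 3)), 1, tolerance = 1e-12)
  m <- matrix(c(6, 1, 2, 5, 3, 3), 2, 3)
  expect_equal(fisher_exact_rxc(m), fisher_exact_rxc(m[2:1, ]), tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(m), fisher_exact_rxc(m[, c(3, 1, 2)]), tolerance = 1e-12)
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 2, 2), 2, 2)), "integer")
  expect_error(fisher_exact_rxc(matrix(c(-1, 1, 2, 2), 2, 2)), "integer")
  expect_warning(p <- fisher_exact_rxc(matrix(c(3, 1, 1, 3, 0, 0), 2, 3)), "zero")
  expect_equal(p, 34 / 70, tolerance = 1e-12)
  expect_error(fisher_exact_rxc(matrix(150, 2, 2)), "enum_limit")
})

test_that("exact test agrees with the brute-force oracle on small tables", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(6, 1.2), 2, 3)
    if (sum(m) == 0) next
    p_impl <- suppressWarnings(fisher_exact_rxc(m))
    expect_equal(p_impl, fisher_oracle_2xc(m), tolerance = 1e-12)
  }
})

test_that("composition test builds the group x class table and detects disjoint groups", {
  cells <- tibble::tibble(
    location = rep(c("medial", "lateral"), each = 10),
    class = c(rep("excited", 10), rep("inhibited", 10))
  )
  ct <- composition_test(cells)
  expect_equal(ct$p_value, fisher_exact_rxc(matrix(c(10, 0, 0, 10), 2, 2)),
               tolerance = 1e-12)
  expect_lt(ct$p_value, 0.001)
  expect_error(composition_test(cells[1:10, ]), "2 groups")
  expect_error(composition_test(cells[0, ]), "empty")
})

test_that("matched class proportions are usually not significant", {
  ok <- 0
  for (s in 1:10) {
    set.seed(2000 + s)
    cls <- sample(c("excited", "inhibited", "uncorrelated"), 200, TRUE,
                  prob = c(0.5, 0.25, 0.25))
    cells <- tibble::tibble(location = rep(c("medial", "lateral"), 100), class = cls)
    if (composition_test(cells)$p_value > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("cross-context comparison applies the one-context inclusion rule", {
  a <- tibble::tibble(cell_id = sprintf("c%d", 1:6),
                      class = c("excited", "excited", "inhibited", "uncorrelated",
                                "uncorrelated", "excited"),
                      peak = c(1, 0.8, 0.2, 0.1, 0.05, 0.9))
  b <- tibble::tibble(cell_id = sprintf("c%d", 1:6),
                      class = c("excited", "uncorrelated", "inhibited", "uncorrelated",
                                "excited", "inhibited"),
                      peak = c(0.9, 0.3, 0.25, 0.12, 0.7, 0.4))
  cc <- cross_context_compare(a, b)
  # c4 significant in neither context -> excluded
  expect_false("c4" %in% cc$paired$cell_id)
  expect_equal(cc$counts$n_shared, 5)
  expect_equal(cc$counts$n_both_significant, 3)   # c1, c3, c6
  expect_equal(cc$counts$n_same_sign, 2)          # c1 (exc/exc), c3 (inh/inh)
  expect_equal(cc$counts$n_opposite_sign, 1)      # c6
  expect_equal(cc$counts$n_excited_both, 1)
  # identical result sets: every significant cell consistent
  cc2 <- cross_context_compare(a, a)
  expect_equal(cc2$counts$n_same_sign, cc2$counts$n_both_significant)
  expect_error(cross_context_compare(a, dplyr::mutate(b, cell_id = paste0("x", cell_id))),
               "shared")
})

test_that("start/stop pairing counts opposite-sign cells", {
  stops <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                          class = c("inhibited", "excited", "uncorrelated"),
                          peak = c(0.2, 0.7, 0.1))
  starts <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                           class = c("excited", "excited", "uncorrelated"),
                           peak = c(0.6, 0.5, 0.1))
  p <- start_stop_pairing(stops, starts)
  expect_equal(p$counts$n_opposite_sign, 1)
  expect_equal(p$counts$n_same_sign, 1)
  # no start-modulated cells -> zero both-significant rows
  starts2 <- dplyr::mutate(starts, class = "uncorrelated")
  p2 <- start_stop_pairing(stops, starts2)
  expect_equal(p2$counts$n_both_significant, 0)
})

test_that("cross-context peaks correlate for context-independent cells", {
  # same ground-truth cell simulated in two 'contexts' (independent
  # behaviour seeds), planted reliability 0.8, ~60 events per context
  peaks_a <- numeric(8); peaks_b <- numeric(8)
  for (i in 1:8) {
    amp <- 0.3 + 0.25 * i   # cells differ in amplitude -> correlated peaks
    for (ctx in c("a", "b")) {
      seed <- 3000 + 100 * i + (ctx == "b")
      set.seed(seed)
      on <- sort(sample(100:4700, 60))
      hit <- runif(60) < 0.8
      tr <- planted_trace(4800, on[hit], amp = amp, noise_sd = 0.1, seed = seed)
      ea <- event_triggered_average(tr, events_at(on / 20), rate_hz = 20)
      if (ctx == "a") peaks_a[i] <- ea$peak else peaks_b[i] <- ea$peak
    }
  }
  expect_gt(cor(peaks_a, peaks_b), 0.8)
})
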