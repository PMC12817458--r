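# Greedy placement, preprocessing against installed AEDs, oracles, sweep.

test_that("preprocessing removes within 297 m and decays within 495 m", {
  net <- line_network(c(100, 300))  # nodes at x = 0, 100, 400
  cand <- data.frame(id = 1:2, node = 2:3, x = c(100, 400), y = 0,
                     risk = c(8L, 7L))
  aed <- data.frame(id = 1, x = 0, y = 0, always_available = TRUE)

  none <- preprocess_existing(cand, aed[0, ], net)
  expect_equal(none$candidates, cand)

  pre <- preprocess_existing(cand, aed, net, reduction_constant = 2)
  expect_equal(pre$candidates$id, 2)           # 100 m candidate removed
  expect_equal(pre$candidates$risk, 5)         # 297 < 400 <= 495: 7 - 2
  expect_setequal(pre$log$action, c("removed", "decayed"))

  # risk floor at level 1
  cand$risk <- c(2L, 1L)
  pre <- preprocess_existing(cand, aed, net, reduction_constant = 9)
  expect_equal(pre$candidates$risk, 1)
})

test_that("greedy handles trivial and mutually exclusive candidates", {
  net <- line_network(100)
  one <- data.frame(id = 1, node = 1, x = 0, y = 0, risk = 5L)
  res <- greedy_place(one, net, termination("count", n = 1))
  expect_equal(res$selected$id, 1)

  two <- data.frame(id = 1:2, node = 1:2, x = c(0, 100), y = 0,
                    risk = c(9L, 9L))
  expect_warning(res <- greedy_place(two, net, termination("count", n = 2)),
                 "ran out")
  expect_equal(nrow(res$selected), 1)
  expect_length(res$log, 1)
  expect_equal(res$log[[1]]$removed, 2)
})

test_that("greedy matches an independent naive re-implementation", {
  net <- line_network(rep(120, 9))  # 10 nodes on a line
  set.seed(3)
  cand <- data.frame(id = 1:10, node = 1:10,
                     x = net$nodes$x, y = 0,
                     risk = sample(1:9, 10, replace = TRUE))
  res <- greedy_place(cand, net, termination("count", n = 3),
                      reduction_constant = 2)

  # naive loop over a Floyd-Warshall distance matrix
  D <- fw_distances(net$nodes, net$edges)
  risk <- cand$risk
  alive <- rep(TRUE, 10)
  picked <- integer()
  while (length(picked) < 3 && any(alive)) {
    pool <- which(alive)
    best <- pool[order(-risk[pool], cand$id[pool])][1]
    picked <- c(picked, cand$id[best])
    alive[best] <- FALSE
    rem <- which(alive & D[best, ] <= 297)
    alive[rem] <- FALSE
    dec <- which(alive & D[best, ] <= 495)
    risk[dec] <- pmax(1, risk[dec] - 2)
  }
  expect_equal(res$selected$id, picked)
})

test_that("ties break by raw score, then by smallest id", {
  net <- road_network(data.frame(id = 1:3, x = c(0, 1000, 2000), y = 0),
                      data.frame(from = 1:2, to = 2:3, length = 1000))
  cand <- data.frame(id = 1:3, node = 1:3, x = c(0, 1000, 2000), y = 0,
                     risk = c(7L, 7L, 7L), score = c(6.8, 7.4, 6.8))
  res <- greedy_place(cand, net, termination("count", n = 3))
  expect_equal(res$selected$id, c(2, 1, 3))
  cand$score <- NULL
  res <- greedy_place(cand, net, termination("count", n = 3))
  expect_equal(res$selected$id, 1:3)
})

test_that("risk-threshold termination stops when the level is exhausted", {
  net <- road_network(data.frame(id = 1:3, x = c(0, 1000, 2000), y = 0),
                      data.frame(from = 1:2, to = 2:3, length = 1000))
  cand <- data.frame(id = 1:3, node = 1:3, x = c(0, 1000, 2000), y = 0,
                     risk = c(7L, 5L, 3L))
  res <- greedy_place(cand, net, termination("risk_threshold", min_risk = 5))
  expect_equal(res$selected$id, c(1, 2))
  expect_true(all(res$selected$risk_at_selection >= 5))
})

test_that("selected sites are pairwise separated; risks stay within bounds", {
  for (seed in c(2, 5, 8)) {
    inst <- random_instance(seed)
    res <- suppressWarnings(greedy_place(inst$candidates, inst$network,
                                         termination("count", n = 4)))
    sel <- res$selected
    if (nrow(sel) > 1) {
      for (i in seq_len(nrow(sel) - 1)) {
        for (j in (i + 1):nrow(sel)) {
          expect_gt(network_distance(inst$network, sel$node[i], sel$node[j]),
                    297)
        }
      }
    }
    init <- stats::setNames(inst$candidates$risk, inst$candidates$id)
    for (rec in res$log) {
      if (nrow(rec$decayed) > 0) {
        expect_true(all(rec$decayed$after >= 1))
        expect_true(all(rec$decayed$after <= init[as.character(rec$decayed$id)]))
      }
    }
  }
})

test_that("greedy placement is deterministic, including the log", {
  inst <- random_instance(13)
  a <- greedy_place(inst$candidates, inst$network, termination("count", n = 3))
  b <- greedy_place(inst$candidates, inst$network, termination("count", n = 3))
  expect_identical(a, b)
})

test_that("exhaustive search covers edge cases and bounds the greedy", {
  inst <- random_instance(5)
  all_ids <- brute_force_best(inst$candidates, inst$network, inst$alerts,
                              n = nrow(inst$candidates))
  expect_equal(all_ids$ids, sort(inst$candidates$id))

  one_alert <- inst$alerts[1, , drop = FALSE]
  bf <- brute_force_best(inst$candidates, inst$network, one_alert, n = 1)
  reachable <- any(naive_covered(one_alert, inst$candidates))
  expect_equal(bf$n_covered, as.integer(reachable))

  res <- greedy_place(inst$candidates, inst$network,
                      termination("count", n = 3))
  greedy_cov <- sum(naive_covered(inst$alerts, res$selected))
  bf3 <- brute_force_best(inst$candidates, inst$network, inst$alerts, n = 3)
  expect_lte(greedy_cov, bf3$n_covered)

  big <- data.frame(id = 1:40, node = 1, x = 0, y = 0, risk = 1L)
  expect_error(brute_force_best(big, NULL, inst$alerts, n = 10), "too large")
})

test_that("sensitivity sweep reruns the greedy per constant and flags argmax", {
  inst <- random_instance(7)
  term <- termination("count", n = 3)
  sweep <- sensitivity_sweep(inst$candidates, inst$network, inst$alerts,
                             term, constants = 0:4)
  expect_equal(nrow(sweep), 5)
  expect_true(all(sweep$percent >= 0 & sweep$percent <= 100))
  expect_equal(sum(sweep$best), 1)
  manual <- vapply(0:4, function(k) {
    res <- greedy_place(inst$candidates, inst$network, term,
                        reduction_constant = k)
    aeds_df <- data.frame(x = res$selected$x, y = res$selected$y,
                          always_available = TRUE)
    coverage(inst$alerts, aeds_df)$percent
  }, numeric(1))
  expect_equal(sweep$percent, manual)
  expect_equal(which(sweep$best), which.max(manual))

  single <- sensitivity_sweep(inst$candidates, inst$network, inst$alerts,
                              term, constants = 2)
  expect_equal(nrow(single), 1)
})
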