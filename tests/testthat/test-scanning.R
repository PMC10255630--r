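test_that("subset enumeration matches the combinatorial counts", {
  expect_length(enumerate_subsets(letters[1:6]), 63)
  expect_length(enumerate_subsets("a"), 1)
  subs <- enumerate_subsets(c("a", "b", "c"))
  expect_length(subs, 7)
  # brute-force bitmask oracle
  oracle <- lapply(1:7, function(m) c("a", "b", "c")[bitwAnd(m, c(1, 2, 4)) > 0])
  expect_setequal(vapply(subs, paste, character(1), collapse = ","),
                  vapply(oracle, paste, character(1), collapse = ","))
  # deterministic order: by size, then lexicographic
  expect_equal(lengths(subs), c(1, 1, 1, 2, 2, 2, 3))
  expect_identical(subs[[4]], c("a", "b"))
  expect_error(enumerate_subsets(c("a", "a")), "duplicate")
  expect_error(enumerate_subsets(character(0)), "1 to 12")
})

test_that("the default grid spans 63 subsets x 10 neuron counts", {
  g <- scan_grid(include_sp = FALSE)
  expect_length(g$subsets, 63)
  expect_equal(length(g$subsets) * length(g$neurons), 630)
  expect_equal(length(g$subsets) * length(g$neurons) * g$replicates, 6300)
  # SP joins as an ordinary 64th member when requested
  g2 <- scan_grid()
  expect_length(g2$subsets, 64)
  expect_identical(g2$subsets[[1]], character(0))
})

test_that("integrated score matches a hand-computed pooled SSE/SST oracle", {
  targets <- cbind(a = c(0.2, 0.4, 0.6, 0.8), b = c(0.1, 0.3, 0.2, 0.4))
  preds <- cbind(a = c(0.25, 0.35, 0.55, 0.85), b = c(0.2, 0.2, 0.2, 0.2))
  sc <- integrated_score(preds, targets)
  # independent evaluation of the defining formulae
  sse_a <- sum((targets[, 1] - preds[, 1])^2)
  sse_b <- sum((targets[, 2] - preds[, 2])^2)
  sst_a <- sum((targets[, 1] - mean(targets[, 1]))^2)
  sst_b <- sum((targets[, 2] - mean(targets[, 2]))^2)
  expect_equal(sc$integrated_r2, 1 - (sse_a + sse_b) / (sst_a + sst_b))
  expect_equal(sc$integrated_mse, (sse_a + sse_b) / 8)
  expect_equal(sc$per_factor$r2, c(1 - sse_a / sst_a, 1 - sse_b / sst_b))

  # perfect predictions
  sc1 <- integrated_score(targets, targets)
  expect_equal(sc1$integrated_r2, 1)
  expect_equal(sc1$integrated_mse, 0)
  # per-factor mean predictions have R^2 exactly 0
  mp <- cbind(a = rep(mean(targets[, 1]), 4), b = rep(mean(targets[, 2]), 4))
  expect_equal(integrated_score(mp, targets)$per_factor$r2, c(0, 0))
  expect_equal(integrated_score(mp, targets)$integrated_r2, 0)
})

test_that("zero-variance targets are flagged and excluded from pooling", {
  targets <- cbind(a = c(1, 2, 3, 4) / 4, b = rep(0.5, 4))
  preds <- cbind(a = c(1, 2, 3, 4) / 4, b = rep(0.4, 4))
  expect_warning(sc <- integrated_score(preds, targets), "zero variance")
  expect_true(sc$per_factor$flagged[2])
  expect_true(is.na(sc$per_factor$r2[2]))
  expect_equal(sc$integrated_r2, 1)
})

test_that("scaled-down scans cover the grid exactly once and reproduce bit-identically", {
  sc <- small_scan()
  res <- sc$result
  g <- sc$grid
  n_expected <- length(g$subsets) * length(g$neurons) * g$replicates
  expect_equal(nrow(res$ledger), n_expected)
  key <- paste(res$ledger$subset, res$ledger$n_hidden, res$ledger$replicate)
  expect_equal(anyDuplicated(key), 0L)
  expect_false(any(res$ledger$diverged))
  # same base seed: bit-identical ledger
  res2 <- run_scan(g, sc$weekly, sc$split, control = fnn_control(maxit = 60))
  expect_identical(res2$ledger, res$ledger)
})

test_that("a persisted ledger makes the scan resumable without retraining", {
  sc <- small_scan()
  path <- tempfile(fileext = ".csv")
  write_scan_ledger(sc$result, path)
  t0 <- Sys.time()
  res2 <- run_scan(sc$grid, sc$weekly, sc$split,
                   control = fnn_control(maxit = 60), ledger_file = path)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_equal(res2$ledger$val_r2, sc$result$ledger$val_r2)
  expect_lt(elapsed, 5) # resumed, not retrained
})

fake_result <- function(scores, neurons = 1L, candidates = c("a", "b", "c")) {
  # scores: named vector subset-key -> mean validation R^2
  grid <- scan_grid(candidates = candidates, neurons = neurons,
                    replicates = 1, include_sp = TRUE)
  keys <- vapply(grid$subsets, algaescan:::subset_key, character(1))
  conditions <- do.call(rbind, lapply(keys, function(k)
    data.frame(subset = k, size = if (k == "SP") 0L else lengths(regmatches(k, gregexpr("\\+", k))) + 1L,
               n_hidden = neurons, train_r2 = scores[[k]], train_mse = 0.1,
               val_r2 = scores[[k]], val_mse = 0.1,
               train_r2_sd = 0, val_r2_sd = 0,
               best_seed = 1L, best_replicate = 1L)))
  structure(list(ledger = conditions, conditions = conditions, grid = grid),
            class = "scan_result")
}

test_that("closed-system selection applies the Granger retention rule", {
  scores <- c(SP = 0.2, a = 0.5, b = 0.3, c = 0.21,
              "a+b" = 0.7, "a+c" = 0.5, "b+c" = 0.3, "a+b+c" = 0.7)
  res <- fake_result(scores)
  sel <- select_closed_systems(res, top_k = 2, tolerance = 0.01, models = FALSE)
  # {a,b}: members each help (0.7 > 0.5, 0.7 > 0.3), adding c gains 0
  expect_equal(sel$systems[[1]]$key, "a+b")
  expect_true(sel$systems[[1]]$passes_property)
  # {c}: scores above SP by only 0.01, not > tolerance -> fails
  ck <- sel$ranking
  expect_false(ck$passes[ck$subset == "c"])
  # a subset whose superset scores higher fails the property
  expect_false(ck$passes[ck$subset == "a"]) # a+b adds 0.2 > tolerance
  # ties break toward smaller subsets: a+b (size 2) ranks above a+b+c (size 3)
  expect_lt(which(ck$subset == "a+b"), which(ck$subset == "a+b+c"))
})

test_that("an infinite tolerance reduces selection to pure ranking", {
  scores <- c(SP = 0.2, a = 0.5, b = 0.3, c = 0.1,
              "a+b" = 0.45, "a+c" = 0.4, "b+c" = 0.3, "a+b+c" = 0.35)
  res <- fake_result(scores)
  sel <- select_closed_systems(res, top_k = 3, tolerance = Inf, models = FALSE)
  expect_true(all(sel$ranking$passes))
  expect_equal(sel$systems[[1]]$key, "a")
  expect_equal(vapply(sel$systems, function(s) s$key, character(1)),
               c("a", "a+b", "a+c"))
})

test_that("no passing subset is reported, not hidden", {
  # every subset is beaten by some superset: nothing passes
  scores <- c(SP = 0.0, a = 0.1, b = 0.1, c = 0.1,
              "a+b" = 0.2, "a+c" = 0.2, "b+c" = 0.2, "a+b+c" = 0.9)
  scores[["a+b+c"]] <- 0.15 # supersets of pairs score lower, pairs beat singles by little
  scores <- c(SP = 0.0, a = 0.1, b = 0.1, c = 0.1,
              "a+b" = 0.105, "a+c" = 0.105, "b+c" = 0.105, "a+b+c" = 0.2)
  res <- fake_result(scores)
  sel <- select_closed_systems(res, top_k = 2, tolerance = 0.2, models = FALSE)
  expect_true(sel$fallback)
  expect_false(any(vapply(sel$systems, function(s) s$passes_property, logical(1))))
})

test_that("best neuron count per subset uses the smallest on ties and covers all subsets", {
  g <- scan_grid(candidates = c("a", "b"), neurons = 1:3, replicates = 1)
  keys <- vapply(g$subsets, algaescan:::subset_key, character(1))
  conditions <- do.call(rbind, lapply(keys, function(k)
    data.frame(subset = k, size = if (k == "SP") 0L else 1L,
               n_hidden = 1:3, train_r2 = 0.5, train_mse = 0.1,
               val_r2 = c(0.4, 0.4, 0.4), val_mse = 0.1,
               train_r2_sd = 0, val_r2_sd = 0, best_seed = 1L,
               best_replicate = 1L)))
  res <- structure(list(conditions = conditions, grid = g), class = "scan_result")
  bn <- best_neurons_per_subset(res)
  expect_setequal(bn$subset, keys)
  expect_true(all(bn$n_hidden == 1)) # identical scores -> smallest network
})
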