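test_that("binning and z-scoring produce unit-variance rows matching a recount", {
  units <- planted_units(30)
  Z <- bin_and_zscore(units, epoch = c(0, 120))
  expect_equal(unname(rowMeans(Z)), rep(0, nrow(Z)), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 1, sd)), rep(1, nrow(Z)), tolerance = 1e-12)
  # counts recomputed independently for a few units
  kept <- attr(Z, "kept")
  for (u in c(1, 10, 25)) {
    st <- units[[kept[u]]]
    st <- st[st >= 0 & st < 120]
    cnt <- hist(st, breaks = seq(0, 120, by = 0.03), plot = FALSE)$counts
    expect_equal(Z[u, ] * sd(cnt) + mean(cnt), cnt, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("constant-count units are dropped with a warning", {
  units <- list(
    seq(0.015, 120, by = 0.03),              # exactly one spike per bin
    sort(runif(300, 0, 120)),
    sort(runif(300, 0, 120)))
  expect_warning(Z <- bin_and_zscore(units, epoch = c(0, 120)), "dropped")
  expect_equal(nrow(Z), 2)
  expect_equal(attr(Z, "kept"), 2:3)
})

test_that("short epochs are rejected", {
  units <- list(runif(10), runif(10))
  expect_error(bin_and_zscore(units, epoch = c(0, 2)), "at least 100 bins")
})

test_that("the Marchenko-Pastur bound has its closed form", {
  expect_equal(marchenko_pastur_bound(50, 20000), 1.1025, tolerance = 1e-12)
  expect_equal(marchenko_pastur_bound(60, 15000),
               (1 + sqrt(60 / 15000))^2, tolerance = 1e-15)
})

test_that("i.i.d. noise yields no significant assemblies", {
  for (seed in 1:3) {
    set.seed(seed)
    M <- matrix(rnorm(60 * 8000), 60)
    Z <- (M - rowMeans(M)) / apply(M, 1, sd)
    expect_equal(detect_assemblies(Z)$n_significant, 0L)
  }
})

test_that("a planted 8-unit assembly is recovered with its members", {
  units <- planted_units(31)
  Z <- bin_and_zscore(units, epoch = c(0, 480))
  am <- detect_assemblies(Z, seed = 2)
  expect_gte(am$n_significant, 1)
  expect_equal(unname(colSums(am$weights^2)), rep(1, am$n_significant),
               tolerance = 1e-9)
  # the assembly with the strongest loading on units 1..8
  score <- vapply(seq_len(am$n_significant), function(j)
    sum(abs(am$weights[1:8, j])), 0)
  j <- which.max(score)
  top8 <- order(am$weights[, j], decreasing = TRUE)[1:8]
  jac <- length(intersect(top8, 1:8)) / length(union(top8, 1:8))
  expect_gte(jac, 0.9)
  # sign convention: largest-magnitude weight is positive
  for (k in seq_len(am$n_significant))
    expect_gt(am$weights[which.max(abs(am$weights[, k])), k], 0)
})

test_that("activation strength matches the zero-diagonal quadratic form", {
  set.seed(33)
  N <- 20
  w <- rnorm(N); w <- w / sqrt(sum(w^2))
  Z <- matrix(rnorm(N * 50), N)
  s <- assembly_strength(w, Z)
  brute <- vapply(seq_len(50), function(t) {
    acc <- 0
    for (i in seq_len(N)) for (j in seq_len(N))
      if (i != j) acc <- acc + w[i] * w[j] * Z[i, t] * Z[j, t]
    acc
  }, 0)
  expect_equal(s, brute, tolerance = 1e-10)
  # zero population vector and single-unit activity both give zero
  expect_equal(assembly_strength(w, matrix(0, N, 1)), 0)
  z1 <- numeric(N); z1[3] <- 5
  expect_equal(assembly_strength(w, matrix(z1)), 0, tolerance = 1e-12)
})

test_that("strength is equivariant under unit relabeling", {
  set.seed(34)
  N <- 15
  w <- rnorm(N); w <- w / sqrt(sum(w^2))
  Z <- matrix(rnorm(N * 40), N)
  perm <- sample(N)
  expect_equal(assembly_strength(w, Z),
               assembly_strength(w[perm], Z[perm, ]), tolerance = 1e-12)
})

test_that("assemblies are labeled by where their high-weight units fire", {
  g <- default_geometry()
  N <- 20
  w <- rep(0.05, N); w[1:2] <- 0.7  # two units clear of the mean + 2 SD cut
  w <- w / sqrt(sum(w^2))
  model <- structure(list(weights = matrix(w), eigenvalues = NULL,
                          lambda_max = 1, n_significant = 1L),
                     class = "assembly_model")
  maps <- matrix(0.01, N, g$n_bins)
  end_bins <- which(region_mask(g, "target_end", 1))
  box_bins <- which(region_mask(g, "box"))
  maps_t <- maps; maps_t[1:2, end_bins] <- 5
  expect_equal(label_assemblies(model, maps_t, g, 1)$label, "target")
  maps_b <- maps; maps_b[1:2, box_bins] <- 5
  lb <- label_assemblies(model, maps_b, g, 1)
  expect_equal(lb$label, "non_target")
  # no high-weight units: flagged non-target
  flat <- structure(list(weights = matrix(rep(1 / sqrt(N), N)),
                         eigenvalues = NULL, lambda_max = 1,
                         n_significant = 1L), class = "assembly_model")
  lf <- label_assemblies(flat, maps_t, g, 1)
  expect_equal(lf$label, "non_target")
  expect_true(lf$flagged)
})

test_that("activation ratio is 1 for matched times and scale-invariant", {
  set.seed(35)
  n <- 5000
  s <- abs(rnorm(n))
  bt <- (seq_len(n) - 0.5) * 0.03
  ev <- bt[sample.int(n, 50)]
  elig <- rep(TRUE, n)
  # events drawn from the same distribution as the random pool: ratio near 1
  r <- activation_ratio(s, bt, ev, elig, n_random = 2000, seed = 3)
  expect_gt(r$ratio, 0.5); expect_lt(r$ratio, 2)
  # planted strong events
  s2 <- s; s2[match(ev, bt)] <- s2[match(ev, bt)] + 50
  r2 <- activation_ratio(s2, bt, ev, elig, n_random = 2000, seed = 3)
  expect_gt(r2$ratio, 10)
  expect_lt(r2$p, 1e-6)
  # global rescaling cancels
  r3 <- activation_ratio(s2 * 7, bt, ev, elig, n_random = 2000, seed = 3)
  expect_equal(r3$ratio, r2$ratio, tolerance = 1e-12)
  # max-strength filter
  expect_null(activation_ratio(s, bt, ev, elig, seed = 3,
                               max_strength_min = 1e6))
  expect_error(activation_ratio(s, bt, ev[1:5], elig), "at least 10")
})

test_that("high-weight cells active before an event are counted exactly", {
  N <- 20
  w <- rep(0.02, N); w[1:2] <- 0.7
  w <- w / sqrt(sum(w^2))
  model <- structure(list(weights = matrix(w), n_significant = 1L),
                     class = "assembly_model")
  unit_times <- rep(list(numeric(0)), N)
  unit_times[[1]] <- c(9.95, 20)   # inside the 90 ms window before t=10
  unit_times[[2]] <- c(9.5)        # outside the window
  unit_times[[3]] <- c(9.93, 9.99) # active but not high-weight
  out <- count_active_high_weight_cells(model, 1, unit_times, 10)
  expect_equal(out$count, 1)
  expect_equal(out$n_high_weight, 2)
  expect_equal(out$fraction, 1 / 2)
  out0 <- count_active_high_weight_cells(model, 1,
                                         rep(list(numeric(0)), N), 10)
  expect_equal(out0$count, 0)
})
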