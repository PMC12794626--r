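test_that("R-squared matches its definition including negative values", {
  y <- c(0.1, 0.4, 0.9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  # hand-computed: SS_res = 5, SS_tot = 2 -> 1 - 5/2 = -1.5
  expect_equal(r_squared(c(0, 1, 2), c(0, 0, 0)), -1.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), class = "drp_undefined_score")
  expect_error(r_squared(1, 1), class = "drp_domain_error")
})

test_that("G matrix averages splits with the sample-std convention", {
  store <- data.frame(model = "m", source = "a", target = "a",
                      split = 1:2, r_squared = c(0.5, 0.7), stage = "within")
  G <- build_g(store, "m")
  expect_equal(G$mean["a", "a"], 0.6)
  expect_equal(G$std["a", "a"], sqrt(0.02 / 1), tolerance = 1e-12)  # ddof = 1
  # N = 1 defines the std as 0
  G1 <- build_g(store[1, ], "m")
  expect_equal(G1$mean["a", "a"], 0.5)
  expect_equal(G1$std["a", "a"], 0)
})

test_that("incomplete score stores are rejected with the missing cells", {
  store <- random_store(d = 2, n_splits = 3)
  broken <- store[-5, ]
  err <- tryCatch(build_g(broken, "m"), drp_incomplete_store = identity)
  expect_match(conditionMessage(err), "missing")
  expect_error(build_g(store, "absent"), class = "drp_incomplete_store")
})

test_that("G/Ga/Gn/Gna match brute-force loop oracles on random instances", {
  set.seed(100)
  for (rep in 1:25) {
    d <- sample(2:8, 1)
    n <- sample(1:12, 1)
    store <- random_store(d, n, seed = rep)
    datasets <- sort(unique(store$source))
    scores <- split(store$r_squared,
                    paste(store$source, store$target, store$split))
    G <- build_g(store, "m")
    orc <- oracle_g(scores, datasets, seq_len(n))
    expect_equal(G$mean, orc$mean, tolerance = 1e-12)
    expect_equal(G$std, orc$std, tolerance = 1e-12)
    expect_equal(unname(aggregate_ga(G)), oracle_ga(G$mean), tolerance = 1e-12)
    Gn <- suppressWarnings(normalize_gn(G))
    expect_equal(unname(Gn$values), oracle_gn(G$mean), tolerance = 1e-12)
    expect_equal(unname(as.numeric(suppressWarnings(aggregate_gna(Gn)))),
                 oracle_gna(oracle_gn(G$mean)), tolerance = 1e-12)
  }
})

test_that("normalization reproduces the worked ratio and masks bad baselines", {
  mean_m <- matrix(c(0.8113, 0.1, 0.4012, 0.6), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
  G <- structure(list(mean = mean_m, std = mean_m * 0, datasets = c("a", "b"),
                      n_splits = 10), class = "g_matrix")
  Gn <- normalize_gn(G)
  expect_equal(round(Gn$values["a", "b"], 4), 0.4945, tolerance = 0.001)
  expect_equal(diag(Gn$values), c(a = 1, b = 1))
  # non-positive within-dataset score masks the source row with a warning
  G$mean["b", "b"] <- -0.2
  expect_warning(Gn2 <- normalize_gn(G), regexp = "b")
  expect_true(all(is.na(Gn2$values["b", ])))
  expect_false(any(is.na(Gn2$values["a", ])))
})

test_that("row aggregation handles constants, hand cases, and masked entries", {
  mk_g <- function(m) structure(
    list(mean = m, std = m * 0, datasets = rownames(m), n_splits = 1),
    class = "g_matrix")
  # all off-diagonal entries equal c -> Ga = c
  m <- matrix(0.37, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m) <- 0.9
  expect_equal(unname(aggregate_ga(mk_g(m))), rep(0.37, 3))
  # d = 5 with off-diagonal {0.1, 0.2, 0.3, 0.4} -> 0.25
  m5 <- diag(5) * 0.8
  dimnames(m5) <- list(letters[1:5], letters[1:5])
  m5["a", -1] <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(aggregate_ga(mk_g(m5))["a"]), 0.25)
  expect_error(aggregate_ga(mk_g(matrix(1, 1, 1, dimnames = list("a", "a")))),
               class = "drp_undefined_metric")
  # Gna over a partially masked row averages the defined entries
  gn <- structure(list(
    values = matrix(c(1, 0.2, NA, 0.8, 1, 0.3, 0.5, 0.7, 1), 3, 3,
                    byrow = TRUE, dimnames = list(letters[1:3], letters[1:3])),
    defined = matrix(TRUE, 3, 3), datasets = letters[1:3]),
    class = "gn_matrix")
  gn$values["a", "c"] <- NA
  gna <- aggregate_gna(gn)
  expect_equal(unname(gna["a"]), 0.2)
  expect_true(attr(gna, "flagged")["a"])
  expect_false(attr(gna, "flagged")["b"])
})

test_that("metric gaps reproduce the reported aggregate differences", {
  expect_equal(metric_gap(0.3380, 0.2284)$delta, 0.1096, tolerance = 1e-12)
  expect_equal(metric_gap(0.4868, 0.3114)$delta, 0.1754, tolerance = 1e-12)
  expect_equal(metric_gap(0.4945, 0.2629)$delta, 0.2316, tolerance = 1e-12)
  expect_equal(metric_gap(0.5, 0.5)$delta, 0)
  expect_true(is.na(metric_gap(NA, 0.5)$delta))
})

test_that("coverage is the source-over-target fraction and is asymmetric", {
  sets <- list(big = paste0("d", 1:8), small = paste0("d", 1:4),
               other = paste0("x", 1:3))
  C <- coverage(sets, "drug")
  expect_equal(diag(C$values), c(big = 1, small = 1, other = 1))
  expect_equal(C$values["big", "small"], 1)        # all 4 of small covered
  expect_equal(C$values["small", "big"], 0.5)      # 4 of 8 covered
  expect_equal(C$values["big", "other"], 0)        # disjoint
  expect_false(isSymmetric(C$values))
  # |intersection| = 3, |target| = 4 -> 0.75
  C2 <- coverage(list(s = paste0("d", 1:3), t = paste0("d", c(1:3, 9))), "cell")
  expect_equal(C2$values["s", "t"], 0.75)
  expect_warning(coverage(list(a = "d1", b = character(0))), "empty")
})

test_that("entity sets are extracted from bundles per kind", {
  w <- tiny_world(seed = 12)
  bundles <- emit_all_studies(w, n_splits = 3)
  dsets <- bundle_entity_sets(bundles, "drug")
  csets <- bundle_entity_sets(bundles, "cell")
  expect_equal(sort(dsets[[1]]), sort(unique(bundles[[1]]$response$drug_id)))
  expect_equal(sort(csets[[2]]), sort(unique(bundles[[2]]$response$cell_id)))
})

test_that("coverage-performance correlation behaves as a rank statistic", {
  d <- 4
  g <- matrix(runif(16), d, d, dimnames = list(letters[1:4], letters[1:4]))
  off <- !diag(d)
  g[off] <- seq(0.1, 0.9, length.out = sum(off))
  G <- structure(list(mean = g, std = g * 0, datasets = letters[1:4],
                      n_splits = 1), class = "g_matrix")
  cv <- g
  cv[off] <- rank(g[off]) / 20   # strictly increasing with g
  C <- structure(list(values = cv, kind = "drug", datasets = letters[1:4]),
                 class = "coverage_matrix")
  expect_equal(coverage_correlation(G, C)$rho, 1)
  # invariance under strictly increasing transforms of g
  G2 <- G
  G2$mean[off] <- exp(3 * G$mean[off])
  expect_equal(coverage_correlation(G2, C)$rho, 1)
  # agreement with an independent rank-then-linear-correlation oracle
  set.seed(21)
  G3 <- G
  G3$mean[off] <- runif(sum(off))
  C3 <- C
  C3$values[off] <- runif(sum(off))
  rho <- coverage_correlation(G3, C3)$rho
  oracle <- stats::cor(rank(C3$values[off]), rank(G3$mean[off]))
  expect_equal(rho, oracle, tolerance = 1e-12)
})

test_that("pairwise model tests detect shifts and flag degenerate cases", {
  store_a <- random_store(d = 5, n_splits = 3, model = "A", seed = 31)
  store_b <- store_a
  store_b$model <- "B"
  store_b$r_squared <- store_b$r_squared + 0.1
  store <- rbind(store_a, store_b)
  rep <- pairwise_model_tests(store, c("A", "B"))
  expect_equal(rep$n_units, 20L)  # d (d - 1) off-diagonal pairs
  expect_lt(rep$p_values["A", "B"], 0.001)
  # identical scores -> undefined test, flagged via warning and NA
  store_c <- store_a
  store_c$model <- "C"
  expect_warning(rep2 <- pairwise_model_tests(rbind(store_a, store_c),
                                              c("A", "C")),
                 regexp = "all differences zero")
  expect_true(is.na(rep2$p_values["A", "C"]))
})

test_that("wilcoxon p-values agree with a sign-flip permutation oracle", {
  set.seed(41)
  n <- 18
  base <- runif(n, -0.5, 0.5)
  shift <- base + rnorm(n, mean = 0.05, sd = 0.2)
  store <- do.call(rbind, lapply(c("A", "B"), function(m) {
    grid <- expand.grid(source = paste0("s", 1:6), target = paste0("t", 1:3),
                        stringsAsFactors = FALSE)
    data.frame(model = m, source = grid$source, target = grid$target,
               split = 1L, r_squared = if (m == "A") base else shift,
               stage = "cross")
  }))
  p <- pairwise_model_tests(store, c("A", "B"))$p_values["A", "B"]
  # oracle: permutation distribution of the signed-rank statistic
  d <- shift - base
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  set.seed(42)
  w_perm <- replicate(1e5, {
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    sum(r[flip])
  })
  mu <- n * (n + 1) / 4
  p_perm <- mean(abs(w_perm - mu) >= abs(w_obs - mu) - 1e-9)
  expect_lt(abs(p - p_perm), 0.02)
})

test_that("reports round-trip through CSV and mark masked entries", {
  store <- random_store(d = 3, n_splits = 4, seed = 17)
  G <- build_g(store, "m")
  # force one non-positive diagonal so a masked row is rendered
  store2 <- store
  sel <- store2$source == "ds2" & store2$target == "ds2"
  store2$r_squared[sel] <- -0.5
  G2 <- build_g(store2, "m")
  out <- withr::local_tempdir()
  suppressWarnings(render_reports(G2, out, heatmaps = TRUE))
  expect_true(file.exists(file.path(out, "G_mean.csv")))
  expect_true(file.exists(file.path(out, "Gn_footnote.txt")))
  expect_true(file.exists(file.path(out, "G_heatmap.png")))
  back <- utils::read.csv(file.path(out, "G_mean.csv"), row.names = 1)
  expect_equal(as.matrix(back), G2$mean, tolerance = 1e-6,
               ignore_attr = TRUE)
  gn_back <- utils::read.csv(file.path(out, "Gn.csv"), row.names = 1)
  expect_true(all(is.na(gn_back["ds2", ])))
  js <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_equal(js$n_splits, 4L)
})
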