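make_stage1_inputs <- function(seed = 1, n_fish = 4, noise_sd = 0,
                               states = "dominant") {
  cfg <- synthetic_config(seed, noise_sd = noise_sd)
  list(cfg = cfg,
       patches = gen_conspicuousness_dataset(cfg, n_fish, states = states,
                                             seed = seed),
       sys = gen_visual_system(cfg),
       env = gen_light_environment(cfg))
}

test_that("adjacency map is symmetric, irreflexive, and validated", {
  m <- default_adjacency()
  expect_true(all(m$matrix == t(m$matrix)))
  expect_true(all(diag(m$matrix) == FALSE))
  expect_true(is_adjacent(m, "white", "black_horizontal_stripe"))
  expect_false(is_adjacent(m, "yellow", "blue"))
  expect_error(adjacency_map(rbind(c("blue", "blue"))), "irreflexive")
  expect_error(is_adjacent(m, "white", "magenta"), "missing")
})

test_that("pairwise contrasts produce one record per unordered pair", {
  inp <- make_stage1_inputs(n_fish = 2)
  rec <- pairwise_contrasts(inp$patches, default_adjacency(), inp$sys,
                            inp$env)
  expect_equal(nrow(rec), 2 * choose(5, 2))
  expect_equal(sum(rec$adjacent) / 2, 6)
  expect_true(all(rec$delta_S >= 0 & rec$delta_L >= 0))
  # pair labels follow the canonical order, stored once
  labs <- patch_labels()
  expect_true(all(match(rec$patch_a, labs) < match(rec$patch_b, labs)))
})

test_that("identical spectra in a pair give zero contrast", {
  cfg <- synthetic_config(1, noise_sd = 0)
  p <- gen_face_spectra(cfg, "f1", "dominant")
  # duplicate the white spectrum into the blue slot
  p[[4]] <- color_patch("f1", "dominant", "blue", p[[3]]$reflectance)
  rec <- pairwise_contrasts(p, default_adjacency(), gen_visual_system(cfg),
                            gen_light_environment(cfg))
  r <- rec[rec$patch_a == "white" & rec$patch_b == "blue", ]
  expect_equal(r$delta_S, 0, tolerance = 1e-9)
  expect_equal(r$delta_L, 0, tolerance = 1e-9)
})

test_that("a patch without an adjacency entry is a configuration error", {
  inp <- make_stage1_inputs(n_fish = 1)
  small_map <- adjacency_map(rbind(c("white", "blue")),
                             labels = c("white", "blue"))
  expect_error(pairwise_contrasts(inp$patches, small_map, inp$sys, inp$env),
               "no adjacency entry")
})

test_that("per-fish aggregation equals a direct group-by oracle", {
  inp <- make_stage1_inputs(seed = 5, n_fish = 6, noise_sd = 0.05,
                            states = c("dominant", "subordinate"))
  rec <- pairwise_contrasts(inp$patches, default_adjacency(), inp$sys,
                            inp$env)
  agg <- aggregate_per_fish(rec)
  expect_equal(nrow(agg), 6 * 2)
  for (i in seq_len(nrow(agg))) {
    sel <- rec$fish_id == agg$fish_id[i] & rec$state == agg$state[i] &
      rec$adjacent == agg$adjacent[i]
    expect_equal(agg$mean_delta_S[i], mean(rec$delta_S[sel]))
    expect_equal(agg$mean_delta_L[i], mean(rec$delta_L[sel]))
    expect_equal(agg$n_pairs[i], sum(sel))
  }
  # two adjacent records of 2 and 4 JND average to 3
  toy <- data.frame(fish_id = "f", state = "dominant", patch_a = c("a", "a"),
                    patch_b = c("b", "c"), adjacent = TRUE,
                    delta_S = c(2, 4), delta_L = c(2, 4))
  expect_warning(agg2 <- aggregate_per_fish(toy), "without both")
  expect_equal(nrow(agg2), 0)
  toy2 <- rbind(toy, within(toy, adjacent <- FALSE))
  expect_equal(aggregate_per_fish(toy2)$mean_delta_S, c(3, 3))
})

test_that("adjacency model with zero fish variance matches fixed ANOVA", {
  set.seed(41)
  agg <- simulate_aggregated(12, effect = 1.5, fish_sd = 0, resid_sd = 0.7)
  # force all fish means equal so the random-intercept REML estimate is
  # exactly at the zero boundary (the case the oracle speaks to)
  agg$mean_delta_S <- agg$mean_delta_S -
    ave(agg$mean_delta_S, agg$fish_id) + 5
  fit <- adjacency_lmm(agg, "chromatic", "dominant_only")
  expect_equal(fit$variance_components$vcov[1], 0, tolerance = 1e-10)
  oracle_f <- anova(lm(mean_delta_S ~ adjacent, agg))[1, "F value"]
  expect_equal(fit$anova_table$F[1], oracle_f, tolerance = 1e-6)
  # containment denominator df: N - g - 1
  expect_equal(fit$anova_table$ddf[1], 24 - 12 - 1)
})

test_that("adjacency model recovers a known effect in one draw", {
  set.seed(42)
  agg <- simulate_aggregated(20, effect = 3, fish_sd = 0.5, resid_sd = 0.5)
  fit <- adjacency_lmm(agg, "chromatic", "dominant_only")
  est <- fit$adjacency_effect$estimate
  expect_lt(abs(est - 3), 0.5)
  expect_lt(fit$anova_table$p[1], 1e-6)
  expect_true(is.finite(fit$shapiro_p))
})

test_that("two-state adjacency model reports the classical df pattern", {
  inp <- make_stage1_inputs(seed = 2, n_fish = 20, noise_sd = 0.05,
                            states = c("dominant", "subordinate"))
  rec <- pairwise_contrasts(inp$patches, default_adjacency(), inp$sys,
                            inp$env)
  agg <- aggregate_per_fish(rec)
  fit10 <- adjacency_lmm(agg, "chromatic", "dominant_only")
  expect_equal(fit10$anova_table$ddf, 9)
  fit20 <- adjacency_lmm(agg, "achromatic", "dominant_and_subordinate")
  expect_equal(fit20$anova_table$term,
               c("adjacency", "stripe", "adjacency:stripe"))
  expect_equal(fit20$anova_table$ddf, c(18, 18, 18))
  expect_identical(fit20$transform, "sqrt")
})

test_that("variance partition matches a projection oracle and edge cases", {
  set.seed(43)
  n <- 200
  adjacent <- rep(c(TRUE, FALSE), n / 2)
  stripe <- rep(c("dark", "pale"), each = n / 2)
  y <- 2 * adjacent + 0.5 * (stripe == "pale") + rnorm(n)
  dat <- data.frame(y = y, adjacency = factor(adjacent),
                    stripe = factor(stripe))
  vp <- stripesignal:::sequential_varpart(y ~ adjacency * stripe, dat)
  mm <- model.matrix(~adjacency * stripe, dat)
  ss <- seq_ss_oracle(y, list(mm[, 2, drop = FALSE], mm[, 3, drop = FALSE],
                              mm[, 4, drop = FALSE]))
  tot <- sum((y - mean(y))^2)
  expect_equal(vp$percent, 100 * ss / tot, tolerance = 1e-8)
  expect_gt(vp$percent[1], vp$percent[2])  # adjacency share dominates
  # response exactly equal to the adjacency indicator
  dat2 <- dat; dat2$y <- as.numeric(adjacent)
  vp2 <- suppressWarnings(  # perfect fit is the point of this case
    stripesignal:::sequential_varpart(y ~ adjacency * stripe, dat2))
  expect_equal(vp2$percent[1], 100, tolerance = 1e-8)
  # pure noise explains almost nothing
  dat3 <- dat; dat3$y <- rnorm(n)
  vp3 <- stripesignal:::sequential_varpart(y ~ adjacency * stripe, dat3)
  expect_lt(vp3$total_explained[1], 5)
})

test_that("dominance change tests use Mann-Whitney with BH per family", {
  inp <- make_stage1_inputs(seed = 6, n_fish = 12, noise_sd = 0.05,
                            states = c("dominant", "subordinate"))
  rec <- pairwise_contrasts(inp$patches, default_adjacency(), inp$sys,
                            inp$env)
  tab <- per_patch_change_tests(rec)
  expect_equal(nrow(tab), 20)  # 10 pair types x 2 contrast kinds
  # BH adjustment within each kind equals the step-up oracle
  for (kind in c("chromatic", "achromatic")) {
    sub <- tab[tab$kind == kind, ]
    expect_equal(sub$p_adj, bh_oracle(sub$p), tolerance = 1e-12)
  }
  # only stripe-involving achromatic pairs change on paling
  flagged <- tab[tab$significant, ]
  expect_true(all(flagged$kind == "achromatic"))
  expect_true(all(flagged$patch_a == "black_horizontal_stripe" |
                    flagged$patch_b == "black_horizontal_stripe"))
})

test_that("identical groups yield no discoveries", {
  set.seed(44)
  rec <- expand.grid(fish_id = sprintf("f%d", 1:5),
                     state = c("dominant", "subordinate"),
                     patch_a = "blue", patch_b = "yellow",
                     stringsAsFactors = FALSE)
  rec$adjacent <- FALSE
  vals <- rnorm(5, 10)
  rec$delta_S <- rep(vals, 2)  # identical across states
  rec$delta_L <- rep(vals, 2)
  tab <- per_patch_change_tests(rec)
  expect_true(all(!tab$significant))
  expect_true(all(tab$p_adj > 0.99))
})

test_that("Mann-Whitney machinery equals exhaustive enumeration", {
  x <- c(1.2, 3.4, 0.5)
  y <- c(2.2, 0.9, 4.1)
  or <- mann_whitney_enum(x, y)
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(unname(wt$statistic), or$U)
  expect_equal(wt$p.value, or$p, tolerance = 1e-12)
  # a case with a clear shift
  x2 <- c(5, 6, 7); y2 <- c(1, 2, 3)
  or2 <- mann_whitney_enum(x2, y2)
  wt2 <- wilcox.test(x2, y2, exact = TRUE)
  expect_equal(unname(wt2$statistic), or2$U)
  expect_equal(or2$U, 9)  # all 9 cross-pairs favour x2
  expect_equal(wt2$p.value, or2$p, tolerance = 1e-12)
})
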