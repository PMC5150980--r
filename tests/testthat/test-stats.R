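balanced_design <- function(seed = 2, shift = 0) {
  set.seed(seed)
  df <- expand.grid(species = letters[1:3], health = c("b", "p"),
                    rep = 1:5, KEEP.OUT.ATTRS = FALSE)
  df$value <- rnorm(nrow(df)) + shift * as.numeric(df$species)
  df
}

test_that("Type-II ANOVA reduces to the classical balanced decomposition", {
  df <- balanced_design(shift = 1)
  mine <- two_way_anova(df)
  ref <- summary(stats::aov(value ~ species * health, data = df))[[1]]
  expect_equal(mine$ss, ref$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(mine$F, ref$`F value`[1:3], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1:3], tolerance = 1e-10)
  expect_equal(mine$df_num, ref$Df[1:3])
})

test_that("Type-II ANOVA handles unbalanced designs and refuses empty cells", {
  df <- balanced_design(seed = 4, shift = 1)
  df <- df[-c(1, 2, 8), ]   # unbalance some cells
  mine <- two_way_anova(df)
  # oracle: explicit model-comparison sums of squares
  rss <- function(f) sum(resid(lm(f, data = df))^2)
  expect_equal(mine$ss[1], rss(value ~ health) - rss(value ~ species + health))
  expect_equal(mine$ss[2], rss(value ~ species) - rss(value ~ species + health))
  expect_equal(mine$ss[3],
               rss(value ~ species + health) - rss(value ~ species * health))

  empty <- df[!(df$species == "a" & df$health == "b"), ]
  expect_error(two_way_anova(empty), "a:b")
})

test_that("one-factor ANOVA F equals the squared pooled t statistic", {
  set.seed(3)
  df <- data.frame(species = rep(c("x", "y"), each = 8),
                   health = "h", value = rnorm(16))
  a <- two_way_anova(df)
  tt <- two_sample_t(df$value[df$species == "x"],
                     df$value[df$species == "y"], "pooled")
  expect_equal(nrow(a), 1)
  expect_equal(a$F, tt$t^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p, tolerance = 1e-12)
})

test_that("ANOVA type-I error rate is nominal over seeded null simulations", {
  set.seed(1)
  reject <- replicate(200, {
    df <- expand.grid(species = letters[1:3], health = c("b", "p"),
                      rep = 1:6, KEEP.OUT.ATTRS = FALSE)
    df$value <- rnorm(nrow(df))
    any_p <- two_way_anova(df)$p
    any_p < 0.05
  })
  rate <- mean(reject)   # 600 effect-level decisions
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("ANOVA detects a strong species effect and no health effect", {
  set.seed(8)
  df <- expand.grid(species = letters[1:3], health = c("b", "p"),
                    rep = 1:10, KEEP.OUT.ATTRS = FALSE)
  df$value <- rnorm(nrow(df)) + 5 * as.numeric(df$species)
  res <- two_way_anova(df)
  expect_lt(res$p[res$effect == "species"], 0.001)
  expect_gt(res$p[res$effect == "health"], 0.05)
})

test_that("Tukey-Kramer HSD matches TukeyHSD and orders by separation", {
  df <- balanced_design(seed = 5, shift = 2)
  mine <- tukey_hsd(df, "value", "species")
  ref <- stats::TukeyHSD(stats::aov(value ~ species, data = df))$species
  expect_equal(mine$p, unname(ref[, "p adj"]), tolerance = 1e-9)
  expect_equal(mine$diff, unname(ref[, "diff"]), tolerance = 1e-12)

  # identical groups: all p ~ 1
  set.seed(6)
  same <- data.frame(species = rep(letters[1:3], each = 10),
                     value = rnorm(30))
  expect_true(all(tukey_hsd(same, "value", "species")$p > 0.2))

  # only the extremes differ: middle-vs-extreme p exceeds extreme-vs-extreme
  set.seed(7)
  three <- data.frame(species = rep(c("lo", "mid", "hi"), each = 8),
                      value = rnorm(24) + rep(c(0, 2, 4), each = 8))
  tk <- tukey_hsd(three, "value", "species")
  p_of <- function(g1, g2) tk$p[(tk$group1 == g1 & tk$group2 == g2) |
                                  (tk$group1 == g2 & tk$group2 == g1)]
  expect_gt(p_of("mid", "hi"), p_of("lo", "hi"))
  expect_gt(p_of("lo", "mid"), p_of("lo", "hi"))
  expect_error(tukey_hsd(data.frame(species = rep(c("a", "b"), 5),
                                    value = rnorm(10)), "value", "species"),
               ">= 3 groups")
})

test_that("two-sample t agrees with t.test and honors the conventions", {
  set.seed(9)
  a <- rnorm(8); b <- rnorm(10, 0.5, 2)
  w <- two_sample_t(a, b, "unequal_variance")
  ref <- stats::t.test(a, b)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  p <- two_sample_t(a, b, "pooled")
  refp <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(p$t, unname(refp$statistic), tolerance = 1e-12)
  expect_equal(p$df, unname(refp$parameter))

  # textbook pair
  hand <- two_sample_t(c(1, 2, 3), c(2, 3, 4), "pooled")
  expect_equal(hand$t, -1.224745, tolerance = 1e-6)
  expect_equal(hand$df, 4)

  # identical samples and the double-zero-variance convention
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  zz <- two_sample_t(c(2, 2, 2), c(2, 2), "unequal_variance")
  expect_equal(zz$p, 1)

  # Welch df never exceeds pooled df
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0, runif(1, .2, 4))
    expect_lte(two_sample_t(x, y, "unequal_variance")$df,
               length(x) + length(y) - 2 + 1e-9)
  }
})

test_that("Bray-Curtis matches hand values, vegan, and its axioms", {
  expect_equal(bray_curtis(rbind(x = c(1, 1), y = c(1, 3)))["x", "y"], 1 / 3)
  expect_equal(bray_curtis(rbind(a = c(2, 5), b = c(2, 5)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(4, 0), b = c(0, 7)))["a", "b"], 1)
  expect_error(bray_curtis(rbind(a = c(1, 2), zz = c(0, 0))), "zz")

  set.seed(11)
  m <- matrix(rpois(7 * 12, 9), nrow = 7,
              dimnames = list(paste0("s", 1:7), NULL))
  d <- bray_curtis(m)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # invariant to taxon order
  expect_equal(bray_curtis(m[, sample(ncol(m))]), d)
  # independent oracle
  expect_equal(max(abs(d - as.matrix(vegan::vegdist(m)))), 0)
})

test_that("ANOSIM matches vegan's statistic and the exhaustive oracle", {
  set.seed(12)
  m <- matrix(rpois(8 * 10, 10), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  g <- rep(c("u", "v"), each = 4)
  d <- bray_curtis(m)
  mine <- anosim(d, g, n_permutations = 999, seed = 3L)
  ref <- vegan::anosim(stats::as.dist(d), g, permutations = 99)
  expect_equal(mine$R, unname(ref$statistic), tolerance = 1e-12)
  expect_true(mine$R >= -1 && mine$R <= 1)

  # exhaustive mode equals an independently coded enumeration (n = 8 -> 70)
  ex <- anosim(d, g, exact = TRUE)
  oracle <- anosim_exhaustive_oracle(d, g)
  expect_equal(ex$R, oracle$R)
  expect_equal(ex$p, oracle$p)
  expect_equal(ex$n_permutations, 70)

  # 6 samples, 2 groups of 3: all 20 assignments
  d6 <- bray_curtis(m[1:6, ])
  g6 <- rep(c("u", "v"), each = 3)
  ex6 <- anosim(d6, g6, exact = TRUE)
  or6 <- anosim_exhaustive_oracle(d6, g6)
  expect_equal(ex6$n_permutations, 20)
  expect_equal(ex6$p, or6$p)

  # perfectly separated groups: R = 1 exactly
  sep <- rbind(a1 = c(10, 0, 1), a2 = c(9, 1, 1),
               b1 = c(0, 10, 9), b2 = c(1, 9, 8))
  expect_equal(anosim(bray_curtis(sep), c("a", "a", "b", "b"),
                      exact = TRUE)$R, 1)

  # refusals
  expect_error(anosim(d, c("u", rep("v", 7))), ">= 2 samples")
  expect_error(anosim(d, rep("u", 8)), ">= 2 groups")
})

test_that("ANOSIM is unbiased under the null and seed-reproducible", {
  set.seed(13)
  null_R <- replicate(60, {
    m <- matrix(rpois(20 * 15, 8), nrow = 20)
    rownames(m) <- paste0("s", 1:20)
    d <- bray_curtis(m)
    anosim(d, sample(rep(c("g1", "g2"), each = 10)),
           n_permutations = 99, seed = sample.int(1e6, 1))$R
  })
  expect_lt(abs(mean(null_R)), 0.05)

  m <- matrix(rpois(8 * 6, 7), nrow = 8)
  rownames(m) <- paste0("s", 1:8)
  d <- bray_curtis(m)
  r1 <- anosim(d, rep(c("u", "v"), each = 4), 199, seed = 5L)
  r2 <- anosim(d, rep(c("u", "v"), each = 4), 199, seed = 5L)
  expect_identical(r1$p, r2$p)
  # p is invariant to renaming the groups
  r3 <- anosim(d, rep(c("AA", "BB"), each = 4), 199, seed = 5L)
  expect_identical(r1$p, r3$p)
  expect_identical(r1$R, r3$R)
})
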