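test_that("paired t matches hand computation and the reference routine", {
  b <- c(0, 0, 0); a <- c(1, 2, 3)
  r <- paired_t(a, b)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)

  same <- c(2, 5, 9, 4)
  expect_equal(paired_t(same, same)[c("t", "p")], list(t = 0, p = 1))
  expect_error(paired_t(1:2, 3:4), "n >= 3")
  expect_error(paired_t(1:4, 1:3), "equal length")
  expect_warning(r0 <- paired_t(c(3, 4, 5), c(2, 3, 4)), "zero variance")
  expect_equal(r0$t, Inf)
  expect_equal(r0$p, 0)

  # antisymmetry
  set.seed(2)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(paired_t(x, y)$t, -paired_t(y, x)$t)
  expect_equal(paired_t(x, y)$p, paired_t(y, x)$p)
})

test_that("spearman rho and exact p match reference implementations", {
  x <- c(1, 2, 5, 7, 9, 12); y <- x^2
  expect_equal(spearman(x, y)$rho, 1)
  expect_equal(spearman(x, -y)$rho, -1)

  set.seed(4)
  a <- rnorm(9); b <- rnorm(9)
  ours <- spearman(a, b)
  ref <- cor.test(a, b, method = "spearman") # exact for n < 10, no ties
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$method, "exact")

  # midranks under ties agree with the reference rho
  at <- c(1, 2, 2, 3, 5, 5, 7, 8); bt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  expect_equal(spearman(at, bt)$rho,
               unname(cor.test(at, bt, method = "spearman",
                               exact = FALSE)$estimate))

  expect_error(spearman(1:3, 2:4), "n >= 4")
  expect_warning(rc <- spearman(rep(1, 6), rnorm(6)), "constant")
  expect_true(is.na(rc$rho))
})

test_that("exact permutation p at n = 13 agrees with a sampled oracle", {
  set.seed(6)
  x <- rnorm(13); y <- x + rnorm(13, 0, 2)
  ours <- spearman(x, y)
  expect_equal(ours$method, "exact")
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  B <- 1e5
  hits <- 0L
  for (i in seq_len(B))
    if (abs(cor(sample(rx), ry)) >= obs - 1e-12) hits <- hits + 1L
  expect_lt(abs(ours$p - hits / B), 0.01)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rexp(11); y <- rnorm(11)
  r0 <- spearman(x, y)
  r1 <- spearman(log(x), y)
  r2 <- spearman(x, exp(y))
  expect_equal(r0$rho, r1$rho)
  expect_equal(r0$p, r1$p)
  expect_equal(r0$rho, r2$rho)
})

test_that("cohort tables validate and drive the paired comparisons", {
  co <- make_cohort(n_subjects = 13, seed = 3,
                    bmi_rho = c(LV = -0.65))
  expect_s3_class(co, "data.frame")
  expect_error(cohort_table(rbind(co, co[1, ])), "duplicate")
  bad <- co; bad$muscle <- as.character(bad$muscle); bad$muscle[1] <- "soleus"
  expect_error(cohort_table(bad), "splenius")

  cmp <- compare_muscles(co)
  expect_equal(nrow(cmp), 7)
  expect_equal(cmp$n, rep(13, 7))
  # strongly planted effects should be detected
  expect_lt(cmp$p[cmp$metric == "LL"], 0.05)
  expect_gt(cmp$mean_vastus[cmp$metric == "LL"],
            cmp$mean_splenius[cmp$metric == "LL"])

  cor_res <- correlate_bmi(co, metrics = "LV")
  expect_equal(nrow(cor_res), 2)
  expect_true(all(cor_res$rho < 0)) # planted negative BMI effect
})

test_that("planted cohort effects are recovered at realistic power", {
  # Br dens shift at printed magnitudes: paired_t significant in most reps
  hits <- 0L
  for (s in 1:40) {
    co <- make_cohort(n_subjects = 13, seed = 1000 + s)
    d <- co[co$metric == "br_dens", ]
    p <- paired_t(d$value[d$muscle == "splenius"],
                  d$value[d$muscle == "vastus"])$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 40, 0.5)

  # planted monotone BMI dependence: sign recovered almost always
  neg <- 0L
  for (s in 1:40) {
    co <- make_cohort(n_subjects = 13, seed = 2000 + s,
                      bmi_rho = c(LV = -0.65))
    d <- co[co$metric == "LV" & co$muscle == "splenius", ]
    if (spearman(d$bmi, d$value)$rho < 0) neg <- neg + 1L
  }
  expect_gte(neg / 40, 0.95)
})
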