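mkSubjectTable <- function(values, sites, metric = "vr") {
  data.frame(subject_id = paste0("s", seq_along(values)), site = sites,
             metric = metric, mean = values, stringsAsFactors = FALSE)
}

test_that("per-subject aggregation averages repeated frames", {
  meas <- data.frame(
    subject_id = rep(c("p1", "p2"), each = 6),
    site = "neuroma", metric = "vr",
    value = c(rep(40, 6), c(10, 20, 10, 20, 10, 20)))
  tab <- aggregatePerSubject(meas)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean[tab$subject_id == "p1"], 40)
  expect_equal(tab$mean[tab$subject_id == "p2"], 15)
  expect_error(aggregatePerSubject(data.frame(x = 1)),
               class = "sq_validation_error")
})

test_that("the D'Agostino-Pearson K2 test matches the reference implementation", {
  ## expected values computed independently with scipy.stats.normaltest
  r1 <- dagostinoPearsonTest(c(2.3, 3.1, 4.8, 5.2, 1.9, 3.3, 4.1, 2.8, 3.9, 5.5))
  expect_equal(r1$statistic, 0.95149457298599, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.6214205037607277, tolerance = 1e-10)
  r2 <- dagostinoPearsonTest(c(1.0, 1.2, 1.1, 8.0, 1.3, 1.15, 1.05, 1.25,
                               1.18, 1.22, 1.3, 1.1))
  expect_equal(r2$statistic, 33.47953773562974, tolerance = 1e-10)
  expect_equal(r2$p.value, 5.370450925033083e-08, tolerance = 1e-8)
  expect_error(dagostinoPearsonTest(1:7), class = "sq_validation_error")
})

test_that("star coding boundaries are inclusive at 0.05, 0.01 and 0.001", {
  expect_identical(pSignifStars(c(0.2, 0.051, 0.05, 0.011, 0.01, 0.0011, 0.001)),
                   c("", "", "*", "*", "**", "**", "***"))
})

test_that("group comparison validates its inputs", {
  tab <- mkSubjectTable(c(1, 2, 3, 4), rep(c("neuroma", "unaffected"), each = 2))
  expect_error(compareGroups(tab, "vr", "neuroma"), class = "sq_validation_error")
  tab1 <- mkSubjectTable(c(1, 2, 3), c("neuroma", "neuroma", "unaffected"))
  expect_error(compareGroups(tab1, "vr", c("neuroma", "unaffected")),
               "n >= 2", class = "sq_validation_error")
})

test_that("identical groups produce no significance and empty stars", {
  tab <- mkSubjectTable(rep(5, 8), rep(c("neuroma", "unaffected"), each = 4))
  r <- compareGroups(tab, "vr", c("neuroma", "unaffected"))
  expect_identical(r$stars, "")
  expect_true(r$p.value > 0.05)
  expect_true(any(grepl("zero variance", r$notes)))
})

test_that("the normality gate picks the sample-size-appropriate test", {
  set.seed(55)
  tab <- mkSubjectTable(c(rnorm(9, 10), rnorm(4, 10)),
                        rep(c("neuroma", "healthy_control"), c(9, 4)))
  r <- compareGroups(tab, "vr", c("neuroma", "healthy_control"))
  expect_identical(r$normality$test[r$normality$site == "neuroma"],
                   "dagostino_pearson")
  expect_identical(r$normality$test[r$normality$site == "healthy_control"],
                   "shapiro_wilk")
  expect_identical(r$method, "one-way ANOVA")
})

test_that("skewed data fall back to the nonparametric branch", {
  set.seed(56)
  v <- c(exp(rnorm(9, 0, 1.5)), exp(rnorm(9, 2, 1.5)))
  ## force at least one group non-normal by injecting a hard outlier
  v[9] <- 500
  tab <- mkSubjectTable(v, rep(c("a1", "a2"), each = 9))
  tab$site <- rep(c("muscle_denervated", "muscle_control"), each = 9)
  r <- compareGroups(tab, "vr", c("muscle_denervated", "muscle_control"))
  if (!all(r$normality$normal)) expect_identical(r$method, "Mann-Whitney")
  expect_true(r$p.value >= 0 && r$p.value <= 1)
})

test_that("three skewed groups use Kruskal-Wallis with Bonferroni-Dunn post-hoc", {
  set.seed(57)
  v <- c(exp(rnorm(9)), exp(rnorm(9)) + 30, exp(rnorm(4)))
  v[1] <- 800  # ensure the gate trips
  tab <- mkSubjectTable(v, rep(c("neuroma", "unaffected", "healthy_control"),
                               c(9, 9, 4)))
  r <- compareGroups(tab, "vr", c("neuroma", "unaffected", "healthy_control"))
  expect_match(r$method, "Kruskal-Wallis")
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$p_adj >= 0 & r$pairwise$p_adj <= 1))
  ## agreement with base R on the omnibus statistic
  kw <- kruskal.test(v, factor(rep(c("n", "u", "h"), c(9, 9, 4))))
  expect_equal(r$statistic, unname(kw$statistic))
})

test_that("Dunn z-statistics match a hand-computed no-tie example", {
  ## 3 groups of 3 with fully separated values: ranks 1-3, 4-6, 7-9;
  ## z_12 = (2 - 5) / sqrt((9*10/12) * (2/3)) = -3/sqrt(5)
  dn <- SonoQuant:::.dunnTest(c(1, 2, 3, 14, 15, 16, 27, 28, 29),
                              rep(c("g1", "g2", "g3"), each = 3))
  z12 <- -3 / sqrt(5)
  expect_equal(unname(dn$z[1]), z12)
  expect_equal(dn$p_adj[1], min(1, 2 * pnorm(z12) * 3))
  ## z_13 spans the full rank range: (2 - 8) / sqrt(5)
  expect_equal(unname(dn$z[2]), -6 / sqrt(5))
})

test_that("Pearson correlation matches hand computations and validates input", {
  t1 <- rbind(mkSubjectTable(1:5, "neuroma", metric = "fr"),
              mkSubjectTable(2 * (1:5) + 1, "neuroma", metric = "vr"))
  expect_equal(correlateMetrics(t1, "fr", "vr")$r, 1)
  t2 <- rbind(mkSubjectTable(1:5, "neuroma", metric = "fr"),
              mkSubjectTable(-(1:5), "neuroma", metric = "vr"))
  expect_equal(correlateMetrics(t2, "fr", "vr")$r, -1)
  t3 <- rbind(mkSubjectTable(1:4, "neuroma", metric = "fr"),
              mkSubjectTable(c(2, 1, 4, 3), "neuroma", metric = "vr"))
  expect_equal(correlateMetrics(t3, "fr", "vr")$r, 0.6)
  t4 <- rbind(mkSubjectTable(1:4, "neuroma", metric = "fr"),
              mkSubjectTable(rep(2, 4), "neuroma", metric = "vr"))
  expect_error(correlateMetrics(t4, "fr", "vr"),
               class = "sq_undefined_correlation")
})

test_that("a rendered synthetic cohort reproduces the expected group ordering", {
  ## small end-to-end cohort: images -> measurements -> statistics
  sites <- cohortSiteDefaults()
  sites <- sites[sites$metric %in% c("vr", "mpr"), ]
  sites$nSubjects <- pmin(sites$nSubjects, c(5L, 5L, 4L, 5L, 5L))
  man <- simulateCohort(sites, framesPerSite = 3L, seed = 2024,
                        frameSize = 96L, roiRadius = 32)
  tab <- aggregatePerSubject(measureCohort(man))

  vr <- tab[tab$metric == "vr", ]
  mu <- tapply(vr$mean, vr$site, mean)
  expect_gt(mu[["neuroma"]], 2 * mu[["unaffected"]])
  expect_gt(mu[["neuroma"]], 2 * mu[["healthy_control"]])
  expect_lt(abs(mu[["unaffected"]] - mu[["healthy_control"]]), 10)

  mpr <- tab[tab$metric == "mpr", ]
  mum <- tapply(mpr$mean, mpr$site, mean)
  expect_lt(mum[["muscle_denervated"]], mum[["muscle_control"]] / 2)

  rv <- compareGroups(vr, "vr", c("neuroma", "unaffected", "healthy_control"))
  expect_true(rv$p.value <= 0.001)
  rm <- compareGroups(mpr, "mpr", c("muscle_denervated", "muscle_control"))
  expect_true(rm$p.value <= 0.05)
})
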