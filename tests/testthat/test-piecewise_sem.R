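test_that("DAG construction validates acyclicity and correlated errors", {
  dag <- sem_dag(c("A -> B", "B -> C"))
  expect_s3_class(dag, "gm_dag")
  expect_setequal(dag$nodes, c("A", "B", "C"))
  expect_error(sem_dag(c("A -> B", "B -> A")), class = "gm_dag_error")
  expect_error(sem_dag(c("A -> B", "B -> C", "C -> A")),
               class = "gm_dag_error")
  expect_error(sem_dag("A -> B", correlated = "A ~~ B"),
               class = "gm_dag_error")
  expect_error(sem_dag("A - B"), class = "gm_dag_error")
  # model files round-trip through the parser
  f <- withr::local_tempfile(lines = c("# comment", "A -> B", "",
                                       "B -> C", "A ~~ C"))
  dag2 <- read_dag(f)
  expect_identical(nrow(dag2$edges), 2L)
  expect_identical(nrow(dag2$correlated), 1L)
})

test_that("basis sets match textbook cases", {
  bs <- basis_set(sem_dag(c("A -> B", "B -> C")))
  expect_length(bs, 1L)
  expect_identical(sort(c(bs[[1]]$x, bs[[1]]$y)), c("A", "C"))
  expect_identical(bs[[1]]$conditioning, "B")
  # response is the downstream node
  expect_identical(bs[[1]]$y, "C")

  # complete DAG: no claims
  expect_length(basis_set(sem_dag(c("A -> B", "A -> C", "B -> C"))), 0L)

  # correlated-error pairs are excluded
  dag <- sem_dag(c("A -> B", "A -> C"), correlated = "B ~~ C")
  expect_length(basis_set(dag), 0L)

  # conditioning is the union of both nodes' parents
  dag5 <- sem_dag(c("A -> C", "B -> C", "C -> D", "B -> E"))
  bs5 <- basis_set(dag5)
  claim_AD <- Filter(function(cl) setequal(c(cl$x, cl$y), c("A", "D")), bs5)
  expect_length(claim_AD, 1L)
  # parents(A) = {}, parents(D) = {C}
  expect_identical(claim_AD[[1]]$conditioning, "C")
  claim_AE <- Filter(function(cl) setequal(c(cl$x, cl$y), c("A", "E")), bs5)
  expect_identical(claim_AE[[1]]$conditioning, "B")
})

test_that("basis-set size equals exhaustive pair enumeration on random DAGs", {
  set.seed(25)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    rd <- random_dag(n, p_edge = runif(1, 0.2, 0.7))
    edges <- rd$edges
    if (!nrow(edges)) next
    dag <- sem_dag(as.data.frame(edges), nodes = rd$nodes)
    expected <- enum_nonadjacent(rd$nodes, edges)
    got <- basis_set(dag)
    expect_length(got, length(expected))
    got_pairs <- lapply(got, function(cl) sort(c(cl$x, cl$y)))
    expect_setequal(vapply(got_pairs, paste, "", collapse = "|"),
                    vapply(expected, paste, "", collapse = "|"))
    for (cl in got) {
      expect_identical(cl$conditioning,
                       sort(setdiff(union(
                         edges[edges[, 2] == cl$x, 1],
                         edges[edges[, 2] == cl$y, 1]), c(cl$x, cl$y))))
    }
  }
})

test_that("Fisher's C follows its closed forms and monotonicity", {
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, 4 * log(2), tolerance = 1e-12)
  expect_identical(fc$df, 4L)
  expect_equal(fishers_c(rep(1, 5))$C, 0)
  expect_identical(fishers_c(runif(7))$df, 14L)
  expect_identical(fishers_c(numeric(0)), list(C = 0, df = 0L, p = 1))
  expect_error(fishers_c(c(0.5, 0)), class = "gm_domain_error")
  # monotone decreasing in each p-value
  base <- fishers_c(c(0.3, 0.6, 0.9))$C
  expect_gt(fishers_c(c(0.2, 0.6, 0.9))$C, base)
  expect_lt(fishers_c(c(0.3, 0.7, 0.9))$C, base)
})

test_that("component fits collapse to OLS without group structure", {
  set.seed(26)
  n <- 60
  dat <- data.frame(x = rnorm(n), z = rnorm(n), region = rep(c("a", "b"), 30))
  dat$y <- 1 + 0.5 * dat$x - 0.3 * dat$z + rnorm(n)
  ols <- lm(y ~ x + z, data = dat)
  # zero between-group variance: the mixed fit is singular, falls back
  comp <- fit_component(dat, "y", c("x", "z"), group = "region")
  comp_null <- fit_component(dat, "y", c("x", "z"), group = NULL)
  if (comp$engine == "ols") {
    expect_equal(comp$coefficients$estimate, unname(coef(ols)),
                 tolerance = 1e-10)
  }
  expect_equal(comp_null$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-12)
  expect_equal(comp_null$r2[["marginal"]],
               var(fitted(ols)) / (var(fitted(ols)) + summary(ols)$sigma^2),
               tolerance = 1e-10)
  expect_error(fit_component(cbind(dat, k = 1), "y", "k"),
               class = "gm_degenerate_fit_error")
})

test_that("REML variance components match closed-form ANOVA estimators", {
  set.seed(27)
  n_g <- 8; n_per <- 12
  g <- rep(letters[1:n_g], each = n_per)
  y <- rep(rnorm(n_g, 0, 2), each = n_per) + rnorm(n_g * n_per, 0, 1)
  dat <- data.frame(y = y, region = g)
  comp <- fit_component(dat, "y", character(0), group = "region")
  expect_identical(comp$engine, "lmm")
  # balanced one-way layout: REML equals the MS-based moment estimators
  ms <- anova(lm(y ~ region, data = dat))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  vc <- as.data.frame(lme4::VarCorr(comp$fit))
  expect_equal(vc$vcov[vc$grp == "region"], (msb - msw) / n_per,
               tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], msw, tolerance = 1e-6)
  expect_gt(comp$r2[["conditional"]], comp$r2[["marginal"]] - 1e-12)
})

test_that("mixed-model slopes are recovered in simulation", {
  set.seed(28)
  n_g <- 6; n_per <- 50
  dat <- data.frame(region = rep(LETTERS[1:n_g], each = n_per),
                    x = rnorm(n_g * n_per))
  dat$y <- 2 + 0.7 * dat$x + rep(rnorm(n_g, 0, 1), each = n_per) +
    rnorm(n_g * n_per, 0, 0.8)
  comp <- fit_component(dat, "y", "x", group = "region")
  est <- comp$coefficients[comp$coefficients$term == "x", ]
  expect_equal(est$estimate, 0.7, tolerance = 3 * est$se)
  expect_true(comp$r2[["conditional"]] >= comp$r2[["marginal"]])
  expect_true(comp$r2[["conditional"]] <= 1)
})

test_that("d-separation tests respond to real dependence", {
  set.seed(29)
  n <- 80
  A <- rnorm(n); B <- 0.8 * A + rnorm(n); C <- 0.8 * B + rnorm(n)
  dat <- data.frame(A = A, B = B, C = C)
  claim <- list(x = "A", y = "C", conditioning = "B")
  p_ok <- dsep_test(claim, dat)
  # maximal dependence: A copied into C, unconditioned claim
  dat2 <- data.frame(A = A, C = A + 1e-8 * rnorm(n))
  p_dep <- dsep_test(list(x = "A", y = "C", conditioning = character(0)),
                     dat2)
  expect_lt(p_dep, 1e-10)
  expect_gt(p_ok, p_dep)
  expect_error(dsep_test(claim, transform(dat, A = 1)),
               class = "gm_degenerate_fit_error")
})

test_that("d-separation p-values are calibrated under the true chain", {
  set.seed(30)
  rejections <- 0; reps <- 200
  for (i in seq_len(reps)) {
    n <- 50
    A <- rnorm(n); B <- 0.7 * A + rnorm(n); C <- 0.7 * B + rnorm(n)
    p <- dsep_test(list(x = "A", y = "C", conditioning = "B"),
                   data.frame(A = A, B = B, C = C))
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / reps, 0.01)
  expect_lt(rejections / reps, 0.10)
})

test_that("standardized coefficients equal refitting on z-scored data", {
  set.seed(31)
  n <- 70
  dat <- data.frame(x = rnorm(n, 0, 3), w = rnorm(n))
  dat$y <- 2 * dat$x - 1.5 * dat$w + rnorm(n, 0, 2)
  comp <- fit_component(dat, "y", c("x", "w"))
  zdat <- as.data.frame(scale(dat))
  zcomp <- fit_component(zdat, "y", c("x", "w"))
  tab <- comp$coefficients; ztab <- zcomp$coefficients
  for (v in c("x", "w")) {
    expect_equal(tab$std_estimate[tab$term == v],
                 ztab$estimate[ztab$term == v], tolerance = 1e-10)
  }
  # exact linear relation: standardized beta = 1
  dat2 <- data.frame(x = rnorm(20)); dat2$y <- 2 * dat2$x
  comp2 <- suppressWarnings(fit_component(dat2, "y", "x"))
  expect_equal(comp2$coefficients$std_estimate[
    comp2$coefficients$term == "x"], 1, tolerance = 1e-10)
})

test_that("the full SEM assembles components, claims and Fisher's C", {
  set.seed(32)
  dag <- sem_dag(c("A -> B", "B -> C"))
  dat <- simulate_from_dag(dag, 80, beta = 0.7)
  dat$region <- rep(c("r1", "r2", "r3", "r4"), each = 20)
  fit <- fit_sem(dag, dat, group = "region")
  expect_length(fit$claims, 1L)
  expect_equal(fit$C, -2 * log(fit$claims[[1]]$p), tolerance = 1e-12)
  expect_identical(fit$C_df, 2L)
  expect_identical(rownames(fit$r2), c("B", "C"))
  expect_true(all(fit$r2[, "conditional"] >= fit$r2[, "marginal"] - 1e-12))
  expect_true(all(fit$r2 <= 1))

  # saturated model: C = 0, df = 0, p = 1
  sat <- sem_dag(c("A -> B", "A -> C", "B -> C"))
  fsat <- fit_sem(sat, dat, group = NULL)
  expect_identical(c(fsat$C, fsat$C_p), c(0, 1))

  # a missing strong path is flagged as the most significant claim
  dag_wrong <- sem_dag(c("A -> B", "A -> C"), nodes = "D")
  dat$D <- rnorm(80)
  fw <- fit_sem(dag_wrong, dat, group = NULL)
  worst <- fw$claims[[which.min(vapply(fw$claims, `[[`, 1, "p"))]]
  expect_setequal(c(worst$x, worst$y), c("B", "C"))
  expect_match(fw$suggested_path, "B")
  expect_error(fit_sem(dag, dat[, c("A", "B")], group = NULL),
               class = "gm_dag_error")
})

test_that("with no group variance the SEM equals its OLS counterpart", {
  set.seed(33)
  dag <- sem_dag(c("A -> B", "A -> C", "B -> C"))
  dat <- simulate_from_dag(dag, 60, beta = 0.5)
  dat$region <- rep(c("u", "v"), 30) # no real group structure
  f_grp <- fit_sem(dag, dat, group = "region")
  f_ols <- fit_sem(dag, dat, group = NULL)
  engines <- vapply(f_grp$components, `[[`, "", "engine")
  for (resp in names(f_grp$components)[engines == "ols"]) {
    expect_equal(f_grp$components[[resp]]$coefficients$estimate,
                 f_ols$components[[resp]]$coefficients$estimate,
                 tolerance = 1e-10)
  }
})
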