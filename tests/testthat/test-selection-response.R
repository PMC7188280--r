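test_that("top-fraction selection uses floor(q*N) with deterministic ties", {
  set.seed(61)
  v <- setNames(rnorm(456), sprintf("L%03d", 1:456))
  expect_length(select_top_fraction(v, 0.20), 91)   # floor(0.20 * 456)
  expect_length(select_top_fraction(v, 1), 456)
  v5 <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  expect_setequal(select_top_fraction(v5, 0.4), c("e", "d"))
  # minimum of one line even when floor(q*N) = 0
  expect_length(select_top_fraction(v5[1:3], 0.1), 1)
  # ties broken lexicographically by line ID
  vt <- setNames(c(1, 1, 1, 0), c("d", "b", "a", "c"))
  expect_identical(select_top_fraction(vt, 0.5), c("a", "b"))
  expect_error(select_top_fraction(numeric(0)), "empty")
  expect_error(select_top_fraction(v5, 0), "q")
})

test_that("marker selection requires the favorable dosage at every locus", {
  g <- toy_geno(rbind(c(2, 0), c(2, 2), c(0, 0), c(2, 0)),
                lines = c("w", "x", "y", "z"),
                markers = c("S1A_10", "S2B_20"))
  alleles <- data.frame(marker = c("S1A_10", "S2B_20"),
                        favorable_dosage = c(2, 0))
  expect_setequal(marker_select(g, alleles), c("w", "z"))
  # vacuous condition: empty set selects everything
  expect_setequal(marker_select(g, alleles[0, ]), c("w", "x", "y", "z"))
  # no line qualifies: empty result is valid, and R is not-applicable
  alleles2 <- data.frame(marker = c("S1A_10", "S2B_20"),
                         favorable_dosage = c(0, 2))
  sel <- marker_select(g, alleles2)
  expect_length(sel, 0)
  expect_true(is.na(selection_differential(sel, setNames(1:4, c("w", "x", "y", "z")))))
  # heterozygotes (F5 residual) fail a homozygous requirement
  gh <- toy_geno(rbind(c(1), c(2)), lines = c("het", "hom"),
                 markers = "S1A_10")
  expect_identical(marker_select(gh, data.frame(marker = "S1A_10",
                                                favorable_dosage = 2)), "hom")
})

test_that("PS+GS is the intersection and shrinks accordingly", {
  expect_identical(combine_ps_gs(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_length(combine_ps_gs(c("a", "b"), c("c", "d")), 0)
  expect_identical(combine_ps_gs(c("a", "b"), c("a", "b")), c("a", "b"))
  set.seed(62)
  v <- setNames(rnorm(100), sprintf("L%03d", 1:100))
  w <- setNames(rnorm(100), names(v))
  ps <- select_top_fraction(v, 0.2); gs <- select_top_fraction(w, 0.2)
  expect_lte(length(combine_ps_gs(ps, gs)), min(length(ps), length(gs)))
})

test_that("selection differential and response reproduce the worked examples", {
  # population mean 3.58, selected mean 5.33 -> S = 1.75, R = H2 S
  sel <- c(a = 5.33 + 0.4, b = 5.33 - 0.4)          # mean exactly 5.33
  rest_mean <- (3.58 * 10 - 5.33 * 2) / 8           # forces pop mean 3.58
  rest <- rest_mean + seq(-0.7, 0.7, length.out = 8)
  names(rest) <- letters[3:10]
  vals <- c(sel, rest)
  S <- selection_differential(c("a", "b"), vals)
  expect_equal(S, 5.33 - 3.58, tolerance = 1e-10)
  expect_equal(round(response_to_selection(0.15, S), 2), 0.26)
  # negative differential: selected below average on validation yields
  expect_equal(response_to_selection(0.56, -0.50), -0.28)
  expect_equal(selection_differential(names(vals), vals), 0)  # select all
  expect_equal(response_to_selection(0.5, 0), 0)
  expect_error(response_to_selection(1.2, 1), "H")
})

test_that("response versus checks replaces the unselected mean by the check mean", {
  vals <- setNames(c(5, 4, 3, 2), c("a", "b", "c", "d"))
  # check mean equal to the population mean: identical to vs-unselected
  r1 <- response_vs_checks("a", check_pheno = c(CH = 3.5), vals, h2 = 0.5)
  expect_equal(r1$S, selection_differential("a", vals))
  # selected mean 5, check mean 4, H2 = 0.5 -> R = 0.5
  r2 <- response_vs_checks("a", check_pheno = c(CH = 4), vals, h2 = 0.5)
  expect_equal(r2$R, 0.5)
  expect_error(response_vs_checks("a", numeric(0), vals, 0.5), "check")
})

test_that("paired strategy comparisons match the textbook t-test and handle degeneracy", {
  rmat <- rbind(A = c(0.1, 0.2, 0.3), B = c(0.05, 0.15, 0.2))
  out <- compare_strategies(rmat)
  d <- c(0.05, 0.05, 0.1)
  t_or <- mean(d) / (sd(d) / sqrt(3))
  p_or <- 2 * pt(-abs(t_or), df = 2)
  expect_equal(out$t, t_or, tolerance = 1e-10)
  expect_equal(out$p, p_or, tolerance = 1e-10)
  expect_false(out$degenerate)
  # identical vectors: p = 1 by convention
  out2 <- compare_strategies(rbind(A = c(0.1, 0.2), B = c(0.1, 0.2)))
  expect_equal(out2$p, 1)
  expect_true(out2$degenerate)
  # constant shift: |t| = Inf, p = 0, flagged
  out3 <- compare_strategies(rbind(A = c(0.2, 0.3, 0.4), B = c(0.1, 0.2, 0.3)))
  expect_equal(out3$t, Inf)
  expect_equal(out3$p, 0)
  expect_true(out3$degenerate)
  # NA cells are dropped pairwise; too few pairs is an error
  rmat_na <- rbind(A = c(0.1, NA, 0.3), B = c(0.05, 0.2, NA))
  expect_error(compare_strategies(rmat_na), "pairs")
})

test_that("standardized selection differential approaches the truncated-normal value", {
  # closed-form oracle at q = 0.20: i = dnorm(qnorm(1 - q)) / q = 1.3998
  i_expected <- dnorm(qnorm(0.8)) / 0.2
  s <- vapply(1:20, function(k) {
    set.seed(k)
    y <- rnorm(5000)
    sel <- select_top_fraction(setNames(y, sprintf("L%04d", 1:5000)), 0.2)
    selection_differential(sel, setNames(y, sprintf("L%04d", 1:5000))) / sd(y)
  }, numeric(1))
  expect_lt(abs(mean(s) - i_expected), 0.05)
})

test_that("same-environment PS maximizes the selection differential", {
  set.seed(63)
  y <- setNames(rnorm(200, 5), sprintf("L%03d", 1:200))
  gebv <- setNames(rnorm(200), names(y))
  ps <- select_top_fraction(y, 0.2)
  for (other in list(select_top_fraction(gebv, 0.2),
                     sample(names(y), 40),
                     combine_ps_gs(select_top_fraction(y, 0.2),
                                   select_top_fraction(gebv, 0.2)))) {
    if (length(other) == 0) next
    expect_gte(selection_differential(ps, y) + 1e-12,
               selection_differential(other, y))
  }
})

test_that("cross-environment selection under zero G-by-E correlation gains nothing", {
  s <- vapply(1:30, function(k) {
    set.seed(900 + k)
    y1 <- setNames(rnorm(500), sprintf("L%03d", 1:500))  # selection env
    y2 <- setNames(rnorm(500), names(y1))                # independent env
    selection_differential(select_top_fraction(y1, 0.2), y2)
  }, numeric(1))
  expect_lt(abs(mean(s)), 3 / sqrt(30 * 100))  # ~3 SE of the MC mean
})
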