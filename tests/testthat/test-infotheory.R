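test_that("uniform-count binning gives balanced, rank-invariant symbols", {
  s <- discretize_uniform_count(1:8, 4)
  expect_equal(tabulate(s$symbols + 1, 4), rep(2, 4))
  # large Gaussian sample: each bin within 1% of 25%
  set.seed(11)
  x <- rnorm(1e5)
  sg <- discretize_uniform_count(x, 4)
  expect_true(all(abs(tabulate(sg$symbols + 1, 4) / 1e5 - 0.25) < 0.01))
  # strictly monotone transform leaves the symbol sequence unchanged
  sexp <- discretize_uniform_count(exp(x), 4)
  expect_identical(sg$symbols, sexp$symbols)
  # ties share the lower bin
  st <- discretize_uniform_count(c(1, 1, 1, 2, 3, 4, 5, 6), 4)
  expect_equal(st$symbols[1:3], rep(0L, 3))
  expect_error(discretize_uniform_count(rep(1, 10), 2), "Constant")
  expect_error(discretize_uniform_count(1:3, 4), "shorter")
})

test_that("mutual information matches exact hand-computed tables", {
  # MI(X;X) for uniform 4 symbols = log2(4) = 2 bits exactly
  s <- as_oc_symbols(rep(0:3, 25), 4)
  expect_equal(mutual_information(s, s), 2, tolerance = 1e-12)
  # hand-worked 2x2 table p(0,0)=p(1,1)=3/8, p(0,1)=p(1,0)=1/8:
  # MI = 0.75*log2(1.5) + 0.25*log2(0.5) = 0.1887218755408671
  x <- as_oc_symbols(c(0, 0, 0, 1, 1, 1, 0, 1), 2)
  y <- as_oc_symbols(c(0, 0, 0, 1, 1, 1, 1, 0), 2)
  expect_equal(mutual_information(x, y), 0.75 * log2(1.5) + 0.25 * log2(0.5),
               tolerance = 1e-14)
  expect_equal(mutual_information(x, y), 0.1887218755408671, tolerance = 1e-12)
  # symmetry
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  # independence at n = 1e5: below the plug-in bias bound scale
  set.seed(12)
  a <- discretize_uniform_count(rnorm(1e5), 4)
  b <- discretize_uniform_count(rnorm(1e5), 4)
  expect_lt(mutual_information(a, b), 0.001)
  expect_error(mutual_information(a, as_oc_symbols(0:3, 4)), "equal length")
})

test_that("data processing inequality holds under symbol merges", {
  set.seed(13)
  n <- 5000
  x <- sample(0:3, n, replace = TRUE)
  y <- (x + sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))) %% 4
  sx <- as_oc_symbols(x, 4)
  sy <- as_oc_symbols(y, 4)
  for (merge_map in list(c(0, 0, 1, 1), c(0, 1, 1, 0), c(0, 0, 0, 1))) {
    sm <- as_oc_symbols(merge_map[x + 1], 2)
    expect_lte(mutual_information(sm, sy),
               mutual_information(sx, sy) + 1e-12)
  }
})

test_that("transfer entropy identifies a pure copy process", {
  set.seed(14)
  n <- 4000
  lag_true <- 7
  src <- sample(0:3, n, replace = TRUE) # i.i.d.: history uninformative
  dst <- c(sample(0:3, lag_true, replace = TRUE), src[1:(n - lag_true)])
  ss <- as_oc_symbols(src, 4)
  sd_ <- as_oc_symbols(dst, 4)
  te_true <- transfer_entropy_at_lag(ss, sd_, lag_true)
  expect_gt(te_true, 1.95) # ~ H(dst) = 2 bits
  for (l in c(2, 12)) {
    expect_lt(transfer_entropy_at_lag(ss, sd_, l), 0.05)
  }
  # lag-averaged TE is dominated by the true-lag contribution
  te_avg <- transfer_entropy_avg(ss, sd_, 1:20)
  expect_gt(te_avg, te_true / 20 * 0.9)
  expect_lt(te_avg, te_true / 20 + 0.05)
  # dst driven only by its own past carries no TE beyond bias
  dst_self <- Reduce(function(prev, i) (prev + 1) %% 4, 1:(n - 1),
                     accumulate = TRUE, init = 0)
  expect_lt(transfer_entropy_at_lag(ss, as_oc_symbols(dst_self, 4), 3), 0.01)
  # independent processes
  set.seed(15)
  i1 <- as_oc_symbols(sample(0:3, 1e5, TRUE), 4)
  i2 <- as_oc_symbols(sample(0:3, 1e5, TRUE), 4)
  expect_lt(transfer_entropy_at_lag(i1, i2, 5), 0.005)
})

test_that("MI and TE equal exhaustive brute force on short sequences", {
  # random sequences of length <= 12 over <= 3 symbols, plus exhaustive
  # binary length-4 pairs; agreement to 1e-12
  set.seed(16)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    kx <- sample(2:3, 1)
    ky <- sample(2:3, 1)
    x <- sample(0:(kx - 1), n, replace = TRUE)
    y <- sample(0:(ky - 1), n, replace = TRUE)
    sx <- as_oc_symbols(x, kx)
    sy <- as_oc_symbols(y, ky)
    expect_equal(mutual_information(sx, sy), mi_brute(x, y, kx, ky),
                 tolerance = 1e-12)
    lag <- sample(1:(n - 2), 1)
    expect_equal(transfer_entropy_at_lag(sx, sy, lag),
                 max(te_brute(x, y, lag, kx, ky), 0), tolerance = 1e-12)
  }
  grid <- expand.grid(replicate(4, 0:1, simplify = FALSE))
  for (i in seq_len(nrow(grid))) {
    x <- as.integer(grid[i, ])
    for (j in c(1, 5, 11, 16)) {
      y <- as.integer(grid[((i + j - 1) %% 16) + 1, ])
      expect_equal(mutual_information(as_oc_symbols(x, 2), as_oc_symbols(y, 2)),
                   mi_brute(x, y, 2, 2), tolerance = 1e-12)
      expect_equal(transfer_entropy_at_lag(as_oc_symbols(x, 2),
                                           as_oc_symbols(y, 2), 1),
                   max(te_brute(x, y, 1, 2, 2), 0), tolerance = 1e-12)
    }
  }
})

test_that("run boundaries are honored and shuffling destroys TE", {
  set.seed(17)
  n <- 3000
  src <- sample(0:2, n, replace = TRUE)
  dst <- c(0, 0, src[1:(n - 2)])
  runs <- c(1000, 800, 1200)
  ss <- as_oc_symbols(src, 3, runs = runs)
  sd_ <- as_oc_symbols(dst, 3, runs = runs)
  expect_equal(transfer_entropy_at_lag(ss, sd_, 2),
               max(te_brute(src, dst, 2, 3, 3, runs = runs), 0),
               tolerance = 1e-12)
  # permutation null: shuffled source
  sh <- as_oc_symbols(sample(src), 3, runs = runs)
  expect_lt(transfer_entropy_at_lag(sh, sd_, 2), 0.01)
  # mismatched runs are rejected
  expect_error(
    transfer_entropy_at_lag(as_oc_symbols(src, 3), sd_, 2), "run structure")
  expect_error(transfer_entropy_at_lag(ss, sd_, 0), "lag")
})

test_that("it_metrics detects directed coupling in decimated series", {
  # unidirectional copy embedded in two series at 500 Hz
  set.seed(18)
  n <- 20000
  x <- stats::filter(rnorm(n), rep(1 / 20, 20), circular = TRUE)
  y <- 0.9 * c(rep(0, 4), head(as.numeric(x), -4)) + 0.4 * rnorm(n)
  m <- it_metrics(matrix(as.numeric(x), 1), matrix(y, 1), srate = 500,
                  n_bins = 4, lags = 1:10, srate_it = 250)
  expect_gt(m$te_a2p, m$te_p2a)
  expect_gt(m$mi, 0.05)
})
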