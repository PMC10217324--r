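# Consensus malignancy, n-back similarity, binning, semantic scores.

test_that("consensus malignancy pins the endpoints and interpolates linearly", {
  expect_equal(consensus_malignancy(0, 50), -100)
  expect_equal(consensus_malignancy(50, 50), 100)
  expect_equal(consensus_malignancy(25, 50), 0)
  expect_equal(consensus_malignancy(3, 4), 50)
  expect_error(consensus_malignancy(1, 0), class = "serialdep_undefined_consensus")
  # odd under vote complement
  k <- 0:25
  expect_equal(consensus_malignancy(k, 25), -consensus_malignancy(25 - k, 25))
})

test_that("n-back similarity matches direct arithmetic and the brute-force oracle", {
  stimuli <- tibble::tibble(stimulus_id = c("a", "b", "c"),
                            true_label = "benign",
                            malignancy = c(-100, 100, 35))
  trials <- tibble::tibble(user_id = "u1", seq_index = 0:3,
                           timestamp = NA_character_,
                           stimulus_id = c("a", "b", "c", "x"),
                           true_label = "benign", response = "benign")
  trials$stimulus_id[4] <- "c"
  trials$stimulus_id <- c("a", "b", "c", "c")
  out <- nback_similarity(trials, stimuli, lag = 1)
  expect_equal(out$similarity, c(NA, 200, 65, 0))

  # |35 - (-20)| = 55, and sign of the malignancy difference never matters
  s2 <- tibble::tibble(stimulus_id = c("p", "q"), true_label = "benign",
                       malignancy = c(35, -20))
  t2 <- tibble::tibble(user_id = "u1", seq_index = 0:1, timestamp = NA_character_,
                       stimulus_id = c("p", "q"), true_label = "benign",
                       response = "benign")
  expect_equal(nback_similarity(t2, s2, lag = 1)$similarity[2], 55)
  t2r <- t2; t2r$stimulus_id <- c("q", "p")
  expect_equal(nback_similarity(t2r, s2, lag = 1)$similarity[2], 55)

  for (s in 1:5) {
    fx <- random_fixture(120, seed = s)
    for (lg in c(1, 2, 4)) {
      got <- nback_similarity(fx$trials, fx$stimuli, lag = lg)
      expect_equal(got$similarity, unname(oracle_nback(fx$trials, fx$stimuli, lg)))
    }
  }
})

test_that("unknown stimulus ids raise a lookup error naming the id", {
  fx <- random_fixture(20, seed = 1)
  tr <- fx$trials
  tr$stimulus_id[5] <- "sXXX"
  expect_error(nback_similarity(tr, fx$stimuli, 1), "sXXX",
               class = "serialdep_lookup_error")
})

test_that("the malignancy domain splits into exactly 20 width-10 groups", {
  spec <- malignancy_bins()
  expect_equal(spec$n_bins, 20L)
  expect_equal(assign_bins(0, spec), 1L)
  expect_equal(assign_bins(200, spec), 20L)   # last bin closed
  expect_equal(assign_bins(199.999, spec), 20L)
  expect_equal(assign_bins(10, spec), 2L)     # half-open left bins
  expect_true(is.na(assign_bins(-0.1, spec)))
})

test_that("the semantic domain gives 19 bins and out-of-range values are excluded", {
  spec <- semantic_bins()
  expect_equal(spec$n_bins, 19L)
  expect_true(is.na(assign_bins(0.29, spec)))
  expect_equal(assign_bins(0.3, spec), 1L)
  expect_equal(assign_bins(0.68, spec), 19L)
})

test_that("binning partitions in-range values", {
  spec <- bin_spec(0, 200, 10)
  withr::with_seed(8, {
    v <- runif(500, -20, 220)
    b <- assign_bins(v, spec)
    inr <- v >= 0 & v <= 200
    expect_true(all(!is.na(b[inr])))
    expect_true(all(is.na(b[!inr])))
    expect_equal(sum(tabulate(b, spec$n_bins)), sum(inr))
  })
})

test_that("bad bin specifications are rejected", {
  expect_error(bin_spec(0, 200, 0), class = "serialdep_config_error")
  expect_error(bin_spec(0, 200, 7), class = "serialdep_config_error")
})

test_that("filter-bank distance is zero for identical images and symmetric", {
  withr::with_seed(3, {
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
  })
  expect_equal(filter_bank_distance(a, a), 0)
  expect_gt(filter_bank_distance(a, b), 0)
  expect_equal(filter_bank_distance(a, b), filter_bank_distance(b, a))
  expect_error(filter_bank_distance(a, b[1:16, ]), class = "serialdep_config_error")
})

test_that("semantic scores round-trip through CSV in both layouts", {
  withr::with_seed(5, {
    imgs <- list(s1 = matrix(runif(256), 16), s2 = matrix(runif(256), 16),
                 s3 = matrix(runif(256), 16))
  })
  sc <- semantic_similarity(imgs, backend = "filter-bank")
  path <- withr::local_tempfile(fileext = ".csv")
  write_semantic_scores(sc, path)
  back <- read_semantic_scores(path)
  expect_equal(back$pairs$score, sc$pairs$score)
  lookup <- serialdep:::.score_fun(back)
  expect_equal(lookup("s1", "s2"), lookup("s2", "s1"))
  expect_equal(lookup("s2", "s2"), filter_bank_distance(imgs$s2, imgs$s2))
  expect_error(lookup("s1", "s9"), class = "serialdep_missing_score")

  # square-matrix layout
  mpath <- withr::local_tempfile(fileext = ".csv")
  ids <- c("s1", "s2", "s3")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  for (i in 1:3) for (j in 1:3) {
    m[i, j] <- lookup(ids[i], ids[j])
  }
  utils::write.csv(data.frame(id = ids, m, check.names = FALSE), mpath, row.names = FALSE)
  back2 <- read_semantic_scores(mpath)
  l2 <- serialdep:::.score_fun(back2)
  expect_equal(l2("s1", "s3"), lookup("s1", "s3"))
})

test_that("super-group split uses a strict below-mean rule", {
  s <- c(0.2, 0.8)
  lab <- split_supergroups(s)
  expect_equal(as.vector(lab), c("similar", "dissimilar"))
  expect_equal(attr(lab, "threshold"), 0.5)
  # degenerate tie: nothing strictly below the mean
  expect_true(all(split_supergroups(rep(0.4, 5)) == "dissimilar"))
  withr::with_seed(2, {
    s2 <- runif(50)
    lab2 <- split_supergroups(s2)
    expect_equal(sum(lab2 == "similar") + sum(lab2 == "dissimilar"), 50)
  })
})
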