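test_that("probabilities over all tag sequences sum to one", {
  set.seed(23)
  for (r in 1:20) {
    K <- sample(2:5, 1)
    n <- sample(1:4, 1)
    E <- matrix(rnorm(n * K, sd = 2), n, K)
    Tr <- matrix(rnorm(K * K, sd = 2), K, K)
    st <- deidr:::crf_forward_stats(E, Tr)
    seqs <- all_tag_seqs(n, K)
    sc <- apply(seqs, 1, function(y) brute_crf_score(E, Tr, y))
    expect_lt(abs(sum(exp(sc - st$logZ)) - 1), 1e-9)
  }
})

test_that("Viterbi agrees with brute-force argmax on random models", {
  set.seed(29)
  for (r in 1:40) {
    K <- sample(2:5, 1)
    n <- sample(1:5, 1)
    E <- matrix(rnorm(n * K, sd = 2), n, K)
    Tr <- matrix(rnorm(K * K, sd = 2), K, K)
    v <- deidr:::crf_viterbi_path(E, Tr)
    seqs <- all_tag_seqs(n, K)
    sc <- apply(seqs, 1, function(y) brute_crf_score(E, Tr, y))
    expect_identical(as.integer(v), as.integer(seqs[which.max(sc), ]))
  }
})

test_that("analytic gradient matches central finite differences", {
  data <- separable_crf_data(4, seed = 3)
  data <- lapply(data, function(d) list(obs = d$obs, tags = d$tags))
  m <- train_crf(data, epochs = 1)
  packed <- deidr:::crf_pack(data, m)
  l2 <- 0.0003
  set.seed(7)
  W_obs <- matrix(rnorm(length(m$features) * length(m$tags), sd = 0.3),
                  length(m$features), length(m$tags))
  W_trans <- matrix(rnorm(length(m$tags)^2, sd = 0.3),
                    length(m$tags), length(m$tags))
  g <- deidr:::crf_ll_grad(W_obs, W_trans, packed, l2)
  eps <- 1e-5
  obj <- function(Wo, Wt) {
    deidr:::crf_ll_grad(Wo, Wt, packed, l2)$objective
  }
  for (probe in 1:12) {
    if (probe %% 2 == 0) {
      i <- sample(nrow(W_obs), 1); j <- sample(ncol(W_obs), 1)
      Wp <- W_obs; Wp[i, j] <- Wp[i, j] + eps
      Wm <- W_obs; Wm[i, j] <- Wm[i, j] - eps
      fd <- (obj(Wp, W_trans) - obj(Wm, W_trans)) / (2 * eps)
      an <- g$g_obs[i, j]
    } else {
      i <- sample(nrow(W_trans), 1); j <- sample(ncol(W_trans), 1)
      Wp <- W_trans; Wp[i, j] <- Wp[i, j] + eps
      Wm <- W_trans; Wm[i, j] <- Wm[i, j] - eps
      fd <- (obj(W_obs, Wp) - obj(W_obs, Wm)) / (2 * eps)
      an <- g$g_trans[i, j]
    }
    denom <- max(abs(fd), abs(an), 1e-8)
    expect_lt(abs(fd - an) / denom, 1e-5)
  }
})

test_that("training separates the toy date language completely", {
  raw <- separable_crf_data(50, seed = 11)
  data <- lapply(raw, function(d) list(obs = d$obs, tags = d$tags))
  m <- train_crf(data, lr = 0.1, epochs = 80)
  acc <- mean(unlist(lapply(data, function(d)
    crf_decode(m, d$obs) == d$tags)))
  expect_equal(acc, 1)
  # objective is non-decreasing up to numerical tolerance
  expect_true(all(diff(m$objective) > -1e-6))
  # generalization: an unseen sentence "on 2071"
  tt <- space_tokens(c("on", "2071"))
  ftab <- feature_table("on 2071", tt, heuristic_pos_ner)
  expect_identical(crf_decode(m, crf_observations(ftab, NULL)),
                   c("O", "B(DATE)"))
  # trained gold sequences outscore every enumerated alternative
  d1 <- data[[1]]
  K <- length(m$tags)
  n <- length(d1$tags)
  if (n <= 4) {
    seqs <- all_tag_seqs(n, K)
    lps <- apply(seqs, 1, function(y)
      crf_sequence_log_prob(m, d1$obs, m$tags[y]))
    expect_identical(m$tags[seqs[which.max(lps), ]], d1$tags)
  }
})

test_that("training is deterministic and validates its inputs", {
  data <- lapply(separable_crf_data(10, seed = 5), function(d)
    list(obs = d$obs, tags = d$tags))
  m1 <- train_crf(data, lr = 0.05, epochs = 15)
  m2 <- train_crf(data, lr = 0.05, epochs = 15)
  expect_identical(m1$W_obs, m2$W_obs)
  expect_identical(m1$W_trans, m2$W_trans)
  expect_error(train_crf(list()), "empty")
  bad <- list(list(obs = data[[1]]$obs, tags = data[[1]]$tags[-1]))
  expect_error(train_crf(bad), "mismatch")
})

test_that("zero-weight models are uniform and decode to the first tag", {
  data <- lapply(separable_crf_data(5, seed = 9), function(d)
    list(obs = d$obs, tags = d$tags))
  m <- train_crf(data, epochs = 1)
  m$W_obs[] <- 0
  m$W_trans[] <- 0
  obs <- data[[1]]$obs[1:3]
  expect_true(all(crf_decode(m, obs) == m$tags[1]))
  K <- length(m$tags)
  # every sequence has log probability -n log K
  expect_equal(crf_sequence_log_prob(m, obs, rep("O", 3)), -3 * log(K))
  expect_equal(crf_sequence_log_prob(m, obs, rep(m$tags[K], 3)),
               -3 * log(K))
})

test_that("more L2 regularization never increases the weight norm", {
  data <- lapply(separable_crf_data(20, seed = 13), function(d)
    list(obs = d$obs, tags = d$tags))
  norms <- vapply(c(0.0003, 0.01, 0.1, 1), function(l2) {
    m <- train_crf(data, lr = 0.05, l2 = l2, epochs = 30)
    sqrt(sum(m$W_obs^2) + sum(m$W_trans^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("single-sentence single-tag training decodes that sequence", {
  tt <- space_tokens(c("only", "tag"))
  ftab <- feature_table("only tag", tt, heuristic_pos_ner)
  obs <- crf_observations(ftab, NULL)
  m <- train_crf(list(list(obs = obs, tags = c("O", "O"))), epochs = 5)
  expect_identical(crf_decode(m, obs), c("O", "O"))
})

test_that("CRF models round-trip through the JSON container", {
  data <- lapply(separable_crf_data(8, seed = 21), function(d)
    list(obs = d$obs, tags = d$tags))
  m <- train_crf(data, lr = 0.05, epochs = 10)
  p <- tempfile(fileext = ".json")
  write_crf(m, p)
  back <- read_crf(p)
  expect_equal(back$W_obs, m$W_obs)
  expect_equal(back$W_trans, m$W_trans)
  expect_identical(back$tags, m$tags)
  expect_identical(crf_decode(back, data[[1]]$obs),
                   crf_decode(m, data[[1]]$obs))
  expect_error(read_crf({writeLines("{}", p2 <- tempfile()); p2}),
               "container")
})
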