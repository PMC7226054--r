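# Linear-chain conditional random field. The model assigns
#   P(T | S) = exp( sum_i [ W_obs[f, t_i] + W_trans[t_i, t_i+1] ] ) / Z(S)
# over indicator feature functions: one weight per (observation feature,
# tag) pair and one per tag bigram. Training maximizes the L2-penalized
# conditional log-likelihood by batch gradient ascent; decoding is Viterbi.

#' Observation features for the CRF
#'
#' Turns a feature table into per-token lists of active indicator features:
#' surface form in a -1..+1 window, shape features (all-digits,
#' initial-uppercase, length), 3-character prefix/suffix, stem, section,
#' POS/NER labels, and every feature cross declared in `cross_spec`. Each
#' active feature is a string like `"token@0=Edwin"`; the CRF learns one
#' weight per (feature string, tag) pair.
#'
#' @param ftab a feature table from [feature_table()].
#' @param cross_spec a cross specification ([default_cross_spec()]), or
#'   `NULL` for no crosses.
#' @return a list with one character vector of active features per token.
#' @export
crf_observations <- function(ftab, cross_spec = default_cross_spec()) {
  n <- nrow(ftab)
  if (n == 0) return(list())
  cols <- list()
  for (off in -1:1) {
    cols[[sprintf("token@%d", off)]] <- shift_feature(ftab$token, off)
  }
  for (f in c("all_digits", "init_upper", "length", "prefix3", "suffix3",
              "stem", "section", "pos", "ner")) {
    cols[[paste0(f, "@0")]] <- as.character(ftab[[f]])
  }
  if (!is.null(cross_spec)) {
    fx <- build_crosses(ftab, cross_spec)
    for (cr in cross_spec) {
      cols[[cr$name]] <- as.character(fx[[cr$name]])
    }
  }
  nm <- names(cols)
  lapply(seq_len(n), function(i) {
    paste0(nm, "=", vapply(cols, `[`, character(1), i))
  })
}

#' Train a linear-chain CRF by regularized maximum likelihood
#'
#' Maximizes `sum(log P(T | S)) - l2 * ||w||^2` over all weights by batch
#' gradient ascent (gradients are computed exactly with the
#' forward-backward algorithm). Weights start at zero, so training is a
#' deterministic function of the data and configuration. The per-epoch
#' objective is recorded and `NaN` in the objective aborts with
#' diagnostics.
#'
#' @param data a list of sequences, each `list(obs = <crf_observations()>,
#'   tags = <gold IOB tag vector>)`.
#' @param lr learning rate for the gradient ascent (default 0.0005).
#' @param l2 L2 regularization weight (default 0.0003).
#' @param epochs number of full-corpus gradient steps (default 100).
#' @param tags optional explicit tag vocabulary; default is `"O"` plus the
#'   tags observed in `data`, `"O"` first then sorted.
#' @param verbose print the objective every 10 epochs.
#' @return an object of class `crf_model` with the feature index, weight
#'   matrices, tag vocabulary and the training `objective` trajectory.
#' @export
train_crf <- function(data, lr = 0.0005, l2 = 0.0003, epochs = 100L,
                      tags = NULL, verbose = FALSE) {
  if (!length(data)) stop("empty training data", call. = FALSE)
  for (d in data) {
    if (length(d$obs) != length(d$tags)) {
      stop("observation/tag length mismatch in training data", call. = FALSE)
    }
  }
  if (lr <= 0 || l2 < 0) stop("rates must be positive", call. = FALSE)
  data <- Filter(function(d) length(d$tags) > 0, data)
  if (is.null(tags)) {
    seen <- unique(unlist(lapply(data, `[[`, "tags"), use.names = FALSE))
    tags <- c("O", sort(setdiff(seen, "O"), method = "radix"))
  }
  feats <- sort(unique(unlist(lapply(data, function(d)
    unlist(d$obs, use.names = FALSE)), use.names = FALSE)), method = "radix")
  model <- structure(list(
    tags = tags,
    features = feats,
    W_obs = matrix(0, length(feats), length(tags),
                   dimnames = list(NULL, tags)),
    W_trans = matrix(0, length(tags), length(tags)),
    lr = lr, l2 = l2, epochs = as.integer(epochs),
    objective = numeric(0)
  ), class = "crf_model")
  packed <- crf_pack(data, model)
  # gradient ascent with backtracking: a step that lowers the objective is
  # rolled back and retried at half the rate, so the recorded per-epoch
  # objective is non-decreasing
  g <- crf_ll_grad(model$W_obs, model$W_trans, packed, l2)
  if (!is.finite(g$objective)) {
    stop("CRF objective is not finite at initialization", call. = FALSE)
  }
  step <- lr
  for (ep in seq_len(epochs)) {
    accepted <- FALSE
    while (step > lr * 2^-30) {
      W_obs_new <- model$W_obs + step * g$g_obs
      W_trans_new <- model$W_trans + step * g$g_trans
      g_new <- crf_ll_grad(W_obs_new, W_trans_new, packed, l2)
      if (!is.finite(g_new$objective)) {
        stop(sprintf(
          "CRF objective is not finite at epoch %d; reduce lr", ep),
          call. = FALSE)
      }
      if (g_new$objective >= g$objective - 1e-9) {
        model$W_obs <- W_obs_new
        model$W_trans <- W_trans_new
        g <- g_new
        accepted <- TRUE
        step <- step * 1.05  # bold-driver: grow gently, halve on failure
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    model$objective <- c(model$objective, g$objective)
    if (verbose && ep %% 10 == 0) {
      message(sprintf("epoch %d: objective %.4f", ep, g$objective))
    }
  }
  model
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf(
    "<crf_model: %d tags, %d observation features, %d epochs, objective %.3f>\n",
    length(x$tags), length(x$features), length(x$objective),
    if (length(x$objective)) utils::tail(x$objective, 1) else NA_real_))
  invisible(x)
}

# integer-encode sequences against the model's feature/tag vocabulary and
# build one sparse token-by-feature indicator matrix for the whole corpus;
# unknown observation features are dropped (they contribute 0)
crf_pack <- function(data, model) {
  lens <- vapply(data, function(d) length(d$tags), integer(1))
  offsets <- c(0L, cumsum(lens))
  y_all <- integer(sum(lens))
  pair_tok <- list()
  pair_fid <- list()
  for (s in seq_along(data)) {
    d <- data[[s]]
    n <- lens[s]
    fid <- lapply(d$obs, function(o) {
      ids <- match(o, model$features)
      ids[!is.na(ids)]
    })
    y <- match(d$tags, model$tags)
    if (anyNA(y)) {
      stop("tag outside model vocabulary: ",
           d$tags[which(is.na(y))[1]], call. = FALSE)
    }
    y_all[offsets[s] + seq_len(n)] <- y
    pair_tok[[s]] <- offsets[s] + rep(seq_len(n), lengths(fid))
    pair_fid[[s]] <- unlist(fid, use.names = FALSE)
  }
  M <- Matrix::sparseMatrix(
    i = unlist(pair_tok, use.names = FALSE),
    j = unlist(pair_fid, use.names = FALSE),
    x = 1,
    dims = c(sum(lens), length(model$features))
  )
  K <- length(model$tags)
  n_tot <- sum(lens)
  Y <- Matrix::sparseMatrix(i = seq_len(n_tot), j = y_all, x = 1,
                            dims = c(n_tot, K))
  # empirical counts are constant across epochs
  emp_obs <- as.matrix(Matrix::crossprod(M, Y))
  bi_from <- integer(0)
  bi_to <- integer(0)
  for (s in seq_along(lens)) {
    if (lens[s] > 1) {
      idx <- offsets[s] + seq_len(lens[s])
      bi_from <- c(bi_from, y_all[utils::head(idx, -1)])
      bi_to <- c(bi_to, y_all[idx[-1]])
    }
  }
  emp_trans <- matrix(0, K, K)
  for (q in seq_along(bi_from)) {
    emp_trans[bi_from[q], bi_to[q]] <- emp_trans[bi_from[q], bi_to[q]] + 1
  }
  list(M = M, y = y_all, lens = lens, offsets = offsets,
       emp_obs = emp_obs, emp_trans = emp_trans,
       bi_from = bi_from, bi_to = bi_to)
}

# L2-penalized log-likelihood and its exact gradient over packed data
crf_ll_grad <- function(W_obs, W_trans, packed, l2) {
  K <- ncol(W_obs)
  n_tot <- length(packed$y)
  E_all <- as.matrix(packed$M %*% W_obs)
  P_all <- matrix(0, n_tot, K)
  texp <- matrix(0, K, K)
  logZ <- 0
  for (s in seq_along(packed$lens)) {
    n <- packed$lens[s]
    idx <- packed$offsets[s] + seq_len(n)
    st <- crf_forward_stats(E_all[idx, , drop = FALSE], W_trans)
    logZ <- logZ + st$logZ
    P_all[idx, ] <- st$marginals
    texp <- texp + st$trans_expected
  }
  score <- sum(E_all[cbind(seq_len(n_tot), packed$y)]) +
    sum(W_trans[cbind(packed$bi_from, packed$bi_to)])
  ll <- score - logZ
  g_obs <- packed$emp_obs - as.matrix(Matrix::crossprod(packed$M, P_all))
  g_trans <- packed$emp_trans - texp
  list(
    objective = ll - l2 * (sum(W_obs^2) + sum(W_trans^2)),
    g_obs = g_obs - 2 * l2 * W_obs,
    g_trans = g_trans - 2 * l2 * W_trans
  )
}

# emission matrix for a new sequence (unknown features contribute 0)
crf_emissions <- function(model, obs) {
  n <- length(obs)
  K <- length(model$tags)
  E <- matrix(0, n, K)
  for (i in seq_len(n)) {
    ids <- match(obs[[i]], model$features)
    ids <- ids[!is.na(ids)]
    if (length(ids)) E[i, ] <- colSums(model$W_obs[ids, , drop = FALSE])
  }
  E
}

#' Viterbi decoding
#'
#' Returns the tag sequence maximizing the CRF score. Ties are broken by
#' the fixed tag-index order (with all-zero weights every token receives
#' the first tag, `"O"`). Observation features unseen in training
#' contribute nothing.
#'
#' @param model a `crf_model`.
#' @param obs per-token feature lists from [crf_observations()].
#' @return a character vector of IOB tags.
#' @export
crf_decode <- function(model, obs) {
  if (!length(obs)) return(character())
  E <- crf_emissions(model, obs)
  path <- crf_viterbi_path(E, model$W_trans)
  model$tags[path]
}

#' Log probability of a tag sequence
#'
#' Computes `score(T, S) - log Z(S)` with the forward algorithm. Summing
#' `exp()` of this quantity over all possible tag sequences yields 1; with
#' all-zero weights every length-`n` sequence over `k` tags has log
#' probability `-n log k`.
#'
#' @inheritParams crf_decode
#' @param tags the tag sequence to score.
#' @return the log probability (a scalar).
#' @export
crf_sequence_log_prob <- function(model, obs, tags) {
  stopifnot(length(obs) == length(tags))
  n <- length(obs)
  if (n == 0) return(0)
  y <- match(tags, model$tags)
  if (anyNA(y)) stop("tag outside model vocabulary", call. = FALSE)
  E <- crf_emissions(model, obs)
  st <- crf_forward_stats(E, model$W_trans)
  score <- sum(E[cbind(seq_len(n), y)])
  if (n > 1) score <- score + sum(model$W_trans[cbind(y[-n], y[-1])])
  score - st$logZ
}

#' Serialize a CRF model to a versioned JSON container
#'
#' @param model a `crf_model`.
#' @param path output path.
#' @export
write_crf <- function(model, path) {
  obj <- list(
    container = "deidr-crf", version = 1L,
    tags = model$tags, features = model$features,
    W_obs = as.numeric(model$W_obs), W_trans = as.numeric(model$W_trans),
    lr = model$lr, l2 = model$l2, epochs = model$epochs,
    objective = model$objective
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$container, "deidr-crf")) {
    stop("not a deidr CRF container: ", path, call. = FALSE)
  }
  K <- length(obj$tags)
  structure(list(
    tags = obj$tags, features = obj$features,
    W_obs = matrix(obj$W_obs, length(obj$features), K,
                   dimnames = list(NULL, obj$tags)),
    W_trans = matrix(obj$W_trans, K, K),
    lr = obj$lr, l2 = obj$l2, epochs = obj$epochs,
    objective = obj$objective
  ), class = "crf_model")
}
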