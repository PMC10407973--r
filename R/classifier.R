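# Desk-scale reference relation classifier: a multinomial logistic model over
# hashed token n-gram features of the marked sequence, trained by mini-batch
# SGD under a linear warmup/decay learning-rate schedule. Marker tokens are
# atomic vocabulary items and participate as ordinary features, so their
# weights are trainable parameters just like token embeddings would be in a
# transformer backbone; larger backbones attach through the same
# fit/predict/export contract.

#' Classifier configuration
#'
#' @param backbone Backbone identifier; `"reference"` selects the built-in
#'   hashed n-gram linear model. Other names are adapter identifiers for
#'   external backbones implementing the same contract.
#' @param marker_vocab Character vector of marker strings that must be
#'   tokenized as single units (asserted at construction).
#' @param peak_lr Peak learning rate, reached at the end of warmup.
#' @param warm_rate Fraction of `max_steps` used for linear warmup
#'   (default 0.05).
#' @param batch_size Mini-batch size.
#' @param max_steps Total number of optimization steps.
#' @param hash_dim Number of hash buckets for n-gram features.
#' @param ngram Maximum n-gram order (1 = unigrams only).
#' @param l2 L2 penalty applied to touched weights at each step.
#' @param seed Integer seed controlling example shuffling.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(backbone = "reference",
                              marker_vocab = unlist(marker_tokens(),
                                                    use.names = FALSE),
                              peak_lr = 0.5, warm_rate = 0.05,
                              batch_size = 32, max_steps = 300,
                              hash_dim = 16384, ngram = 2, l2 = 0,
                              seed = 0) {
  # max_steps = 0 is a valid degenerate fit (used for pure weight transfer)
  stopifnot(peak_lr > 0, warm_rate > 0, warm_rate < 1,
            batch_size >= 1, max_steps >= 0, hash_dim >= 2, ngram >= 1)
  for (mk in marker_vocab) {
    if (length(tokenize_text(mk)) != 1) {
      stop("marker token is not tokenized as a single unit: ", mk,
           call. = FALSE)
    }
  }
  structure(
    list(backbone = backbone, marker_vocab = marker_vocab,
         n_labels = length(relation_labels()), peak_lr = peak_lr,
         warm_rate = warm_rate, batch_size = as.integer(batch_size),
         max_steps = as.integer(max_steps), hash_dim = as.integer(hash_dim),
         ngram = as.integer(ngram), l2 = l2, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Linear warmup / linear decay learning-rate schedule
#'
#' The rate rises linearly from 0 to `peak_lr` over the first
#' `warm_rate * max_steps` steps, then decays linearly to 0 at
#' `max_steps`:
#' \deqn{lr(s) = \eta s/(wT) \text{ for } s \le wT; \quad
#'       \eta (T-s)/((1-w)T) \text{ otherwise.}}
#'
#' @param step Step index (vectorized), `0 <= step <= max_steps`.
#' @param cfg A [classifier_config()] (or any list with `peak_lr`,
#'   `warm_rate`, `max_steps`).
#' @return Numeric vector of learning rates.
#' @export
lr_schedule <- function(step, cfg) {
  T <- cfg$max_steps
  w <- cfg$warm_rate
  eta <- cfg$peak_lr
  if (any(step < 0) || any(step > T)) {
    stop("step must lie in [0, max_steps]", call. = FALSE)
  }
  warm_end <- w * T
  ifelse(step <= warm_end,
         eta * step / warm_end,
         eta * (T - step) / ((1 - w) * T))
}

# ---- Tokenization and feature hashing --------------------------------------

# Lowercase and split into word-ish tokens; hyphenated marker tokens such as
# CHEM-S survive as single units.
tokenize_text <- function(text) {
  toks <- stringr::str_extract_all(tolower(text),
                                   "[a-z0-9_'-]+|[^a-z0-9_'\\s-]")
  if (length(toks) == 1) toks[[1]] else toks
}

# Deterministic polynomial string hash into 1..dim (platform independent:
# exact in double precision).
hash_strings <- function(x, dim) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
    as.integer(h %% dim) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

# Sparse n-gram count matrix (n_texts x (hash_dim + 1)); the last column is
# a constant intercept feature.
featurize <- function(texts, cfg) {
  n <- length(texts)
  toks <- tokenize_text(texts)
  if (n == 1) toks <- list(toks)
  grams <- lapply(toks, function(tk) {
    g <- tk
    if (cfg$ngram >= 2 && length(tk) >= 2) {
      for (k in 2:cfg$ngram) {
        if (length(tk) >= k) {
          idx <- seq_len(length(tk) - k + 1)
          gk <- tk[idx]
          for (j in 1:(k - 1)) gk <- paste(gk, tk[idx + j], sep = "\x1f")
          g <- c(g, gk)
        }
      }
    }
    g
  })
  all_grams <- unlist(grams, use.names = FALSE)
  lens <- lengths(grams)
  if (length(all_grams) == 0) {
    return(Matrix::sparseMatrix(i = seq_len(n), j = rep(cfg$hash_dim + 1L, n),
                                x = 1, dims = c(n, cfg$hash_dim + 1L)))
  }
  uniq <- unique(all_grams)
  buckets <- hash_strings(uniq, cfg$hash_dim)
  j <- buckets[match(all_grams, uniq)]
  i <- rep(seq_len(n), lens)
  # intercept
  i <- c(i, seq_len(n))
  j <- c(j, rep(cfg$hash_dim + 1L, n))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, cfg$hash_dim + 1L))
}

# ---- Model ------------------------------------------------------------------

#' Create an (untrained) reference relation classifier
#'
#' @param cfg A [classifier_config()].
#' @return Object of class `relex_model`.
#' @export
relex_model <- function(cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  if (cfg$backbone != "reference") {
    stop("only the 'reference' backbone ships with the package; ",
         "external backbones attach via the adapter contract",
         call. = FALSE)
  }
  structure(
    list(cfg = cfg,
         W = matrix(0, nrow = cfg$n_labels, ncol = cfg$hash_dim + 1L,
                    dimnames = list(relation_labels(), NULL)),
         trained = FALSE, steps_done = 0L),
    class = "relex_model"
  )
}

#' @export
print.relex_model <- function(x, ...) {
  cat("<relex_model backbone=", x$cfg$backbone,
      if (x$trained) paste0(" trained (", x$steps_done, " steps)>")
      else " untrained>", "\n", sep = "")
  invisible(x)
}

local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Fit the reference relation classifier
#'
#' Trains multinomial logistic weights over hashed n-gram features with
#' mini-batch SGD under [lr_schedule()]. Training is deterministic given
#' the example order, configuration and seed. Pass `init` (an exported
#' parameter set) to continue training from previous weights, as in
#' transfer from the weak-supervision phase.
#'
#' @param model A [relex_model()].
#' @param texts Character vector of marked sequences.
#' @param labels Character vector of relation labels (NONE allowed).
#' @param init Optional parameter set from [export_params()].
#' @param checkpoint_every Optional positive integer: snapshot the model
#'   every this many steps (and at the final step).
#' @param eval_fn Optional function taking the in-progress `relex_model`
#'   and returning a development micro-F1; its value is stored on each
#'   checkpoint as `dev_f1`.
#' @return The trained `relex_model`. When checkpointing is on, the
#'   `checkpoints` element holds a list of [make_checkpoint()] records with
#'   strictly increasing steps.
#' @export
relex_fit <- function(model, texts, labels, init = NULL,
                      checkpoint_every = NULL, eval_fn = NULL) {
  stopifnot(inherits(model, "relex_model"))
  if (length(texts) == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(texts) == length(labels))
  assert_labels(labels)
  cfg <- model$cfg
  if (!is.null(init)) model <- import_params(model, init)

  X <- featurize(texts, cfg)
  n <- nrow(X)
  Y <- Matrix::sparseMatrix(i = seq_len(n), j = label_index(labels),
                            x = 1, dims = c(n, cfg$n_labels))
  W <- model$W
  checkpoints <- list()
  restore <- local_seed(cfg$seed)
  on.exit(restore())
  order_pool <- sample.int(n)
  pos <- 1L
  for (step in seq_len(cfg$max_steps)) {
    if (pos + cfg$batch_size - 1L > n) {
      order_pool <- sample.int(n)
      pos <- 1L
    }
    take <- order_pool[pos:min(n, pos + cfg$batch_size - 1L)]
    pos <- pos + cfg$batch_size
    Xb <- X[take, , drop = FALSE]
    cols <- which(Matrix::colSums(Xb) > 0)
    Xs <- Xb[, cols, drop = FALSE]
    S <- W[, cols, drop = FALSE] %*% Matrix::t(Xs)      # L x b
    S <- as.matrix(S)
    S <- sweep(S, 2, apply(S, 2, max))
    P <- exp(S)
    P <- sweep(P, 2, colSums(P), "/")
    Yb <- Matrix::t(Y[take, , drop = FALSE])            # L x b
    G <- as.matrix((P - Yb) %*% Xs) / length(take)
    lr <- lr_schedule(step, cfg)
    W[, cols] <- W[, cols] - lr * (G + cfg$l2 * W[, cols, drop = FALSE])
    if (!is.null(checkpoint_every) &&
        (step %% checkpoint_every == 0 || step == cfg$max_steps)) {
      snap <- model
      snap$W <- W
      snap$trained <- TRUE
      snap$steps_done <- model$steps_done + step
      dev_f1 <- if (is.null(eval_fn)) NA_real_ else eval_fn(snap)
      checkpoints[[length(checkpoints) + 1]] <-
        make_checkpoint(step, export_params(snap), dev_f1)
    }
  }
  model$W <- W
  model$trained <- TRUE
  model$steps_done <- model$steps_done + cfg$max_steps
  if (length(checkpoints) > 0) model$checkpoints <- checkpoints
  model
}

#' Predict relation labels for marked sequences
#'
#' @param object A trained [relex_model()].
#' @param texts Character vector of marked sequences.
#' @param ... Unused.
#' @return Tibble with one row per input, in input order: `label` (argmax
#'   of the scores; ties resolved toward the lower enum index) and one
#'   `score_*` column per label, each row a normalized distribution.
#' @export
predict.relex_model <- function(object, texts, ...) {
  if (!object$trained) stop("classifier is untrained", call. = FALSE)
  if (length(texts) == 0) {
    out <- tibble::tibble(label = character(0))
    for (cc in score_columns()) out[[cc]] <- numeric(0)
    return(out)
  }
  X <- featurize(texts, object$cfg)
  S <- as.matrix(object$W %*% Matrix::t(X))            # L x n
  S <- sweep(S, 2, apply(S, 2, max))
  P <- exp(S)
  P <- sweep(P, 2, colSums(P), "/")
  lab <- relation_labels()[apply(P, 2, which.max)]
  scores <- t(P)
  colnames(scores) <- score_columns()
  out <- tibble::as_tibble(scores)
  out <- dplyr::bind_cols(tibble::tibble(label = lab), out)
  out
}

# ---- Parameter export / import ---------------------------------------------

#' Export / import classifier parameters
#'
#' `export_params()` returns a versioned parameter set that fully
#' determines the model's predictions; `import_params()` loads it into a
#' compatible model (same backbone, hash dimension and label set), as used
#' for weight transfer between training phases. [write_params()] /
#' [read_params()] serialize the set as a flat key-value text artifact.
#'
#' @param model A [relex_model()].
#' @return `export_params()`: a list of class `relex_params`.
#' @export
export_params <- function(model) {
  stopifnot(inherits(model, "relex_model"))
  structure(
    list(version = 1L, backbone = model$cfg$backbone,
         hash_dim = model$cfg$hash_dim, ngram = model$cfg$ngram,
         labels = relation_labels(), marker_vocab = model$cfg$marker_vocab,
         trained = model$trained, steps_done = model$steps_done,
         W = model$W),
    class = "relex_params"
  )
}

#' @rdname export_params
#' @param params A `relex_params` object.
#' @export
import_params <- function(model, params) {
  stopifnot(inherits(model, "relex_model"), inherits(params, "relex_params"))
  if (params$backbone != model$cfg$backbone ||
      params$hash_dim != model$cfg$hash_dim ||
      params$ngram != model$cfg$ngram ||
      !identical(params$labels, relation_labels())) {
    stop("parameter set is incompatible with this model configuration",
         call. = FALSE)
  }
  model$W <- params$W
  model$trained <- params$trained
  model$steps_done <- params$steps_done
  model
}

#' @rdname export_params
#' @param path File path for the flat key-value artifact.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "relex_params"))
  nz <- which(params$W != 0, arr.ind = TRUE)
  header <- c(
    paste0("version\t", params$version),
    paste0("backbone\t", params$backbone),
    paste0("hash_dim\t", params$hash_dim),
    paste0("ngram\t", params$ngram),
    paste0("trained\t", as.integer(params$trained)),
    paste0("steps_done\t", params$steps_done),
    paste0("labels\t", paste(params$labels, collapse = "|")),
    paste0("marker_vocab\t", paste(params$marker_vocab, collapse = "|")),
    paste0("n_weights\t", nrow(nz))
  )
  wlines <- sprintf("w\t%d\t%d\t%s", nz[, 1], nz[, 2],
                    formatC(params$W[nz], format = "g", digits = 17))
  writeLines(c(header, wlines), path)
  invisible(params)
}

#' @rdname export_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  get1 <- function(k) kv[[which(keys == k)[1]]][2]
  hash_dim <- as.integer(get1("hash_dim"))
  labels <- strsplit(get1("labels"), "|", fixed = TRUE)[[1]]
  W <- matrix(0, nrow = length(labels), ncol = hash_dim + 1L,
              dimnames = list(labels, NULL))
  wrows <- kv[keys == "w"]
  if (length(wrows) > 0) {
    ijv <- matrix(unlist(wrows)[c(FALSE, TRUE, TRUE, TRUE)],
                  ncol = 3, byrow = TRUE)
    W[cbind(as.integer(ijv[, 1]), as.integer(ijv[, 2]))] <-
      as.numeric(ijv[, 3])
  }
  structure(
    list(version = as.integer(get1("version")), backbone = get1("backbone"),
         hash_dim = hash_dim, ngram = as.integer(get1("ngram")),
         labels = labels,
         marker_vocab = strsplit(get1("marker_vocab"), "|", fixed = TRUE)[[1]],
         trained = as.logical(as.integer(get1("trained"))),
         steps_done = as.integer(get1("steps_done")), W = W),
    class = "relex_params"
  )
}

#' Turn classifier output into a predictions table
#'
#' Binds pair keys (and KB linking ids when present) from a candidate-pair
#' table onto the classifier's per-sequence output, yielding the
#' predictions format consumed by [refine()], [evaluate_relations()] and
#' [write_predictions()].
#'
#' @param pairs Candidate pairs from [preprocess_corpus()].
#' @param scored Output of [predict.relex_model()] on `pairs$marked`.
#' @return Predictions tibble.
#' @export
as_predictions <- function(pairs, scored) {
  stopifnot(nrow(pairs) == nrow(scored))
  keep <- intersect(c("pmid", "arg1", "arg2", "chem_id", "gene_id",
                      "chem_surface", "gene_surface"), names(pairs))
  dplyr::bind_cols(pairs[, keep], scored)
}
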