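# The eight classifier configurations: four shallow learners and four small
# dense neural networks, with a common train/predict surface. Positive class
# is Pre-levodopa (the OFF state).

#' Specification of one of the eight classifier configurations
#'
#' Families: `tree` (CART, Gini impurity, at most 129 splits), `qd`
#' (quadratic discriminant), `svm` (linear kernel), `knn` (k = 21, city-block
#' distance, equal weights) and the four dense networks `dnn1`-`dnn4`
#' (batch-norm input layer, 32-unit hidden layers, 1-unit sigmoid output):
#' `dnn1` three ReLU hidden layers, `dnn2` two ReLU, `dnn3` two hidden layers
#' mixing Tanh then ReLU, `dnn4` a single ReLU hidden layer. Networks train
#' with binary cross-entropy; `dnn1`-`dnn3` use Nadam, `dnn4` RMSProp.
#'
#' @param family One of `"tree"`, `"qd"`, `"svm"`, `"knn"`,
#'   `"dnn1"`, `"dnn2"`, `"dnn3"`, `"dnn4"`.
#' @return A list of class `wo_model_spec`.
#' @export
model_spec <- function(family = c("tree", "qd", "svm", "knn",
                                  "dnn1", "dnn2", "dnn3", "dnn4")) {
  family <- match.arg(family)
  spec <- switch(family,
    tree = list(max_splits = 129L, criterion = "gini"),
    qd   = list(discriminant = "quadratic"),
    svm  = list(kernel = "linear"),
    knn  = list(k = 21L, distance = "cityblock", weights = "equal"),
    dnn1 = list(hidden = c(32L, 32L, 32L), activations = rep("relu", 3),
                optimizer = "nadam"),
    dnn2 = list(hidden = c(32L, 32L), activations = rep("relu", 2),
                optimizer = "nadam"),
    dnn3 = list(hidden = c(32L, 32L), activations = c("tanh", "relu"),
                optimizer = "nadam"),
    dnn4 = list(hidden = 32L, activations = "relu", optimizer = "rmsprop"))
  spec$family <- family
  spec$loss <- if (is_dnn(family)) "binary_crossentropy" else NA_character_
  spec$k_folds <- 4L
  structure(spec, class = "wo_model_spec")
}

is_dnn <- function(family) grepl("^dnn", family)

#' Train a classifier on a stride feature table
#'
#' Fits the requested model on the feature columns of `table`, with the
#' condition label as the class (`positive` = Pre-levodopa/OFF by default).
#' Scale-sensitive shallow learners (SVM, KNN, quadratic discriminant) are
#' z-scored with training-set statistics; the networks rely on their
#' batch-norm input layer. Networks train by minibatch gradient descent with
#' early stopping on a held-out fold of a 4-fold split. Deterministic under a
#' fixed seed.
#'
#' @param spec A [model_spec()] (or a family name).
#' @param table Feature data.frame with a `condition` column and the feature
#'   columns.
#' @param seed Integer seed.
#' @param features Feature columns (default the 7 muscular features).
#' @param positive Positive-class label (default `"pre"`).
#' @param epochs,batch_size,patience,lr Network training controls.
#' @return A `wo_model` object.
#' @export
wo_train <- function(spec, table, seed = 1L, features = muscular_features(),
                     positive = "pre", epochs = 200L, batch_size = 32L,
                     patience = 20L, lr = 0.001) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "wo_model_spec"))
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"condition" %in% names(table)) stop("table needs a 'condition' column",
                                           call. = FALSE)
  X <- as.matrix(table[features])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("feature table contains non-finite values",
                               call. = FALSE)
  y <- as.integer(table$condition == positive)
  if (length(unique(y)) < 2L) stop("training table must contain both classes",
                                   call. = FALSE)

  scaling <- NULL
  fit <- NULL
  set.seed(seed)
  if (spec$family %in% c("svm", "knn", "qd")) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    scaling <- list(center = ctr, scale = scl)
    Xs <- scale(X, center = ctr, scale = scl)
  } else {
    Xs <- X
  }

  if (spec$family == "tree") {
    df <- data.frame(Xs, y = factor(y, levels = c(0, 1)))
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(cp = 0, xval = 0,
                                                       maxsurrogate = 0,
                                                       maxcompete = 0))
    nsplit <- fit$cptable[, "nsplit"]
    if (max(nsplit) > spec$max_splits) {
      ok <- which(nsplit <= spec$max_splits)
      fit <- rpart::prune(fit, cp = fit$cptable[max(ok), "CP"])
    }
  } else if (spec$family == "qd") {
    fit <- fit_qda(Xs, y)
  } else if (spec$family == "svm") {
    fit <- e1071::svm(x = Xs, y = factor(y, levels = c(0, 1)),
                      kernel = "linear", probability = TRUE, scale = FALSE)
  } else if (spec$family == "knn") {
    if (spec$k > nrow(Xs)) {
      stop(sprintf("k = %d exceeds the %d training rows", spec$k, nrow(Xs)),
           call. = FALSE)
    }
    fit <- list(ref = Xs, y = y, k = spec$k)
  }
  if (is_dnn(spec$family)) {
    net <- nn_init(c(spec$hidden, 1L), c(spec$activations, "sigmoid"),
                   n_in = ncol(X), seed = seed)
    fit <- nn_train(net, Xs, y, optimizer = spec$optimizer, lr = lr,
                    batch_size = batch_size, epochs = epochs,
                    patience = patience, k_folds = spec$k_folds, seed = seed)
  }

  structure(list(spec = spec, fit = fit, features = features,
                 positive = positive, scaling = scaling, seed = seed,
                 n_train = nrow(X)),
            class = "wo_model")
}

# Quadratic discriminant with a ridge fallback when a class covariance is
# singular: per-class Gaussian log-densities with shrunk covariance.
fit_qda <- function(X, y) {
  g <- factor(y, levels = c(0, 1))
  out <- tryCatch(list(kind = "qda", fit = MASS::qda(X, grouping = g)),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  classes <- levels(g)
  stats <- lapply(classes, function(cl) {
    Xi <- X[g == cl, , drop = FALSE]
    S <- stats::cov(Xi)
    lam <- 1e-3 * mean(diag(S)) + 1e-8
    S <- S + diag(lam, ncol(X))
    list(mu = colMeans(Xi), S = S, Sinv = solve(S),
         logdet = determinant(S, logarithm = TRUE)$modulus,
         prior = mean(g == cl))
  })
  names(stats) <- classes
  list(kind = "ridge", stats = stats)
}

qda_scores <- function(fit, X) {
  if (fit$kind == "qda") {
    return(predict(fit$fit, X)$posterior[, "1"])
  }
  lp <- sapply(fit$stats, function(s) {
    d <- sweep(X, 2, s$mu)
    -0.5 * rowSums((d %*% s$Sinv) * d) - 0.5 * as.numeric(s$logdet) + log(s$prior)
  })
  1 / (1 + exp(lp[, "0"] - lp[, "1"]))
}

knn_scores <- function(fit, X) {
  apply(X, 1, function(x) {
    d <- colSums(abs(t(fit$ref) - x))  # city-block
    nn <- order(d)[seq_len(fit$k)]     # distance ties broken by lowest index
    mean(fit$y[nn])
  })
}

#' Score and classify the rows of a feature table
#'
#' One probability-like score per row (positive class = Pre-levodopa/OFF) and
#' a hard label: networks threshold the sigmoid score at 0.5; shallow models
#' use their native decision rule.
#'
#' @param model A `wo_model` from [wo_train()].
#' @param table Feature data.frame containing the model's feature columns.
#' @return A data.frame with columns `score` and `label`.
#' @export
predict_table <- function(model, table) {
  stopifnot(inherits(model, "wo_model"))
  if (nrow(table) == 0L) {
    return(data.frame(score = numeric(0), label = character(0)))
  }
  miss <- setdiff(model$features, names(table))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- as.matrix(table[model$features])
  storage.mode(X) <- "double"
  if (!is.null(model$scaling)) {
    X <- scale(X, center = model$scaling$center, scale = model$scaling$scale)
  }
  fam <- model$spec$family
  score <- switch(fam,
    tree = {
      df <- as.data.frame(X)
      predict(model$fit, df, type = "prob")[, "1"]
    },
    qd = qda_scores(model$fit, X),
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    knn = knn_scores(model$fit, X),
    forward_dense(model, X))
  score <- as.numeric(score)
  lab01 <- if (is_dnn(fam)) as.integer(score >= 0.5) else as.integer(score > 0.5)
  neg <- if (model$positive == "pre") "post" else "pre"
  data.frame(score = score,
             label = ifelse(lab01 == 1L, model$positive, neg),
             stringsAsFactors = FALSE)
}

#' @export
print.wo_model <- function(x, ...) {
  cat(sprintf("<wo_model> family %s, %d features, trained on %d rows (seed %d)\n",
              x$spec$family, length(x$features), x$n_train, x$seed))
  if (is_dnn(x$spec$family)) {
    tr <- x$fit$training
    cat(sprintf("  %s, best epoch %d/%d, val loss %.4f\n",
                tr$optimizer, tr$best_epoch, tr$epochs_run, tr$val_loss))
  }
  invisible(x)
}

#' Implementation-complexity report of a trained model
#'
#' For the dense networks, counts parameters and multiply-accumulate (MACC)
#' operations per the following convention: a dense layer `in -> out` costs
#' `in*out` multiply-accumulates plus `out` bias accumulates; the input
#' batch-norm costs 2 per input feature (one multiply, one add, with the
#' normalization folded into scale/shift); activations are counted separately
#' as non-MACC operations. ROM is 4 bytes per stored parameter (float32);
#' RAM is 4 bytes per live activation at the widest layer transition plus the
#' input/output buffers. Shallow families report a parameter count only.
#'
#' @param model A `wo_model`.
#' @return A list of class `wo_complexity`: `n_params`, `macc_dense`,
#'   `macc_total`, `non_macc_ops`, `rom_bytes`, `ram_bytes`,
#'   `counting_convention`.
#' @export
complexity <- function(model) {
  stopifnot(inherits(model, "wo_model"))
  fam <- model$spec$family
  if (!is_dnn(fam)) {
    n_par <- switch(fam,
      tree = sum(model$fit$frame$var != "<leaf>") * 2L,  # feature id + threshold
      qd = {
        d <- length(model$features)
        2L * (d + d * (d + 1L) / 2L) + 2L
      },
      svm = length(model$features) + 1L,
      knn = length(model$fit$y) * (length(model$features) + 1L))
    return(structure(list(n_params = as.integer(n_par), macc_dense = NA_integer_,
                          macc_total = NA_integer_, non_macc_ops = NA_integer_,
                          rom_bytes = NA_integer_, ram_bytes = NA_integer_,
                          counting_convention = "parameter count only (non-NN family)"),
                     class = "wo_complexity"))
  }
  net <- model$fit
  sizes <- c(net$n_in, vapply(net$layers[-1L], function(l) ncol(l$W), integer(1)))
  dense_in <- sizes[-length(sizes)]
  dense_out <- sizes[-1L]
  macc_dense <- sum(dense_in * dense_out) + sum(dense_out)
  macc_bn <- 2L * net$n_in
  n_params <- 4L * net$n_in + sum(dense_in * dense_out + dense_out)
  non_macc <- sum(dense_out)  # one activation evaluation per unit
  max_pair <- max(dense_in + dense_out)
  structure(list(n_params = as.integer(n_params),
                 macc_dense = as.integer(macc_dense),
                 macc_total = as.integer(macc_dense + macc_bn),
                 non_macc_ops = as.integer(non_macc),
                 rom_bytes = as.integer(4L * n_params),
                 ram_bytes = as.integer(4L * (max_pair + net$n_in + 1L)),
                 counting_convention = paste(
                   "dense in*out MACC + out bias accumulates;",
                   "batch-norm 2/input; activations non-MACC; float32")),
            class = "wo_complexity")
}

#' @export
print.wo_complexity <- function(x, ...) {
  cat("<wo_complexity>\n")
  cat(sprintf("  params: %d (ROM %s bytes)\n", x$n_params,
              format(x$rom_bytes)))
  if (!is.na(x$macc_total)) {
    cat(sprintf("  MACC: %d dense (+%d batch-norm), RAM %d bytes\n",
                x$macc_dense, x$macc_total - x$macc_dense, x$ram_bytes))
  }
  cat("  convention:", x$counting_convention, "\n")
  invisible(x)
}

#' Save or load a trained dense-network model as JSON
#'
#' Serializes the network specification and flattened parameter arrays
#' (row-major weight matrices with documented shapes) to a JSON document.
#' Only the dense-NN families are portable this way; shallow models keep
#' their fitted objects in-session.
#'
#' @param model A dense-NN `wo_model`.
#' @param path Output/input file path.
#' @return `save_model` returns `path` invisibly; `load_model` a `wo_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wo_model"))
  if (!is_dnn(model$spec$family)) {
    stop("JSON serialization supports the dense-NN families only", call. = FALSE)
  }
  net <- model$fit
  layers <- lapply(net$layers, function(ly) {
    if (ly$type == "batchnorm") {
      list(type = "batchnorm", gamma = ly$gamma, beta = ly$beta,
           mean = ly$mean, var = ly$var, eps = ly$eps)
    } else {
      list(type = "dense", shape = dim(ly$W),
           W = as.vector(t(ly$W)),  # row-major
           b = ly$b, activation = ly$activation)
    }
  })
  doc <- list(package = "wotrack", kind = "dense_nn",
              family = model$spec$family, features = model$features,
              positive = model$positive, n_in = net$n_in, seed = model$seed,
              layers = layers)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$kind, "dense_nn")) stop("not a dense-NN model file",
                                             call. = FALSE)
  layers <- lapply(seq_len(nrow(doc$layers)), function(i) NULL)
  # jsonlite may simplify the layer list to a data.frame; normalize
  raw <- if (is.data.frame(doc$layers)) split(doc$layers, seq_len(nrow(doc$layers)))
         else doc$layers
  layers <- lapply(raw, function(ly) {
    ly <- as.list(ly)
    unwrap <- function(v) if (is.list(v)) unlist(v) else v
    if (unwrap(ly$type) == "batchnorm") {
      list(type = "batchnorm", gamma = unwrap(ly$gamma), beta = unwrap(ly$beta),
           mean = unwrap(ly$mean), var = unwrap(ly$var), eps = unwrap(ly$eps))
    } else {
      shape <- unwrap(ly$shape)
      list(type = "dense",
           W = matrix(unwrap(ly$W), nrow = shape[1], ncol = shape[2], byrow = TRUE),
           b = unwrap(ly$b), activation = unwrap(ly$activation))
    }
  })
  names(layers) <- NULL
  net <- structure(list(layers = layers, n_in = doc$n_in), class = "wo_nn")
  structure(list(spec = model_spec(doc$family), fit = net,
                 features = doc$features, positive = doc$positive,
                 scaling = NULL, seed = doc$seed, n_train = NA_integer_),
            class = "wo_model")
}
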